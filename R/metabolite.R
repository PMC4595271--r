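#' Internal standard description
#'
#' Parameters of the spiked internal standard used for GC-MS
#' semi-quantification. The default is 10 uL of 4-methyl-2-pentanol at
#' 1.0018 g/L spiked into 5 mL of juice, giving an in-sample concentration
#' of 2.0036 mg/L.
#'
#' @param name compound name.
#' @param stock_g_L stock concentration (g/L).
#' @param spiked_mL spiked volume (mL).
#' @param sample_mL sample volume (mL).
#' @return object of class `internal_standard` with the derived in-sample
#'   concentration `conc_ug_L`.
#' @export
internal_standard <- function(name = "4-methyl-2-pentanol",
                              stock_g_L = 1.0018, spiked_mL = 0.010,
                              sample_mL = 5) {
  stopifnot(stock_g_L > 0, spiked_mL > 0, sample_mL > 0)
  structure(list(name = name, stock_g_L = stock_g_L, spiked_mL = spiked_mL,
                 sample_mL = sample_mL,
                 conc_ug_L = stock_g_L * 1e6 * spiked_mL / sample_mL),
            class = "internal_standard")
}

#' Internal-standard relative quantification
#'
#' Semi-quantifies an analyte in internal-standard equivalents: the analyte
#' peak area divided by the internal-standard peak area, times the in-sample
#' internal-standard concentration. The response factor is taken as 1 (no
#' compound-specific calibration curves), so concentrations are
#' IS-equivalents in ug/L.
#'
#' @param analyte_area analyte peak area (>= 0); vectorized.
#' @param is_area internal-standard peak area (> 0).
#' @param is_std an [internal_standard()] object.
#' @return concentration in ug/L (IS-equivalents); linear in `analyte_area`.
#' @export
#' @examples
#' quantify_relative(2e5, 1e5)  # 4007.2 ug/L = 4.0072 mg/L
quantify_relative <- function(analyte_area, is_area,
                              is_std = internal_standard()) {
  if (any(is_area <= 0)) stop("internal-standard peak area must be > 0")
  if (any(analyte_area < 0)) stop("analyte peak area must be >= 0")
  (analyte_area / is_area) * is_std$conc_ug_L
}

#' Odor activity value
#'
#' OAV = concentration / sensory threshold; a compound is flagged as a
#' potential aroma contributor when OAV >= 1 (the boundary is counted as
#' contributing so threshold-equal compounds are kept for review).
#'
#' @param concentration concentration (same units as `threshold`).
#' @param threshold sensory perception threshold (> 0).
#' @return data.frame with columns `oav` and `contributing`.
#' @export
#' @examples
#' odor_activity(c(50, 10, 25), 25)
odor_activity <- function(concentration, threshold) {
  if (any(threshold <= 0)) stop("sensory threshold must be > 0")
  oav <- concentration / threshold
  data.frame(oav = oav, contributing = oav >= 1)
}

#' Total volatile concentration per form and condition
#'
#' For each (region, year, stage, form) cell, sums compound concentrations
#' within each biological replicate and reports the replicate mean and SD of
#' those sums. Free and bound forms are never pooled; cells with no records
#' are absent from the output (missing, not zero).
#'
#' @param records data.frame of metabolite records with columns `compound`,
#'   `form`, `region`, `year`, `stage`, `replicate`, `concentration_ug_L`.
#' @return data.frame with columns `region`, `year`, `stage`, `form`,
#'   `total_ug_L` (mean of per-replicate sums), `sd_ug_L` (NA without
#'   replication), `n_replicates`.
#' @export
totals_by_form <- function(records) {
  need <- c("compound", "form", "region", "year", "stage", "replicate",
            "concentration_ug_L")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (any(records$concentration_ug_L < 0)) stop("negative concentration")
  if (!all(records$form %in% c("free", "bound")))
    stop("form must be 'free' or 'bound'")
  key <- interaction(records$region, records$year, records$stage,
                     records$form, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    sums <- tapply(d$concentration_ug_L, d$replicate, sum)
    data.frame(region = d$region[1], year = d$year[1], stage = d$stage[1],
               form = d$form[1], total_ug_L = mean(sums),
               sd_ug_L = if (length(sums) > 1) sd(sums) else NA_real_,
               n_replicates = length(sums), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Compares group means by one-way ANOVA, then assigns Duncan letter codes by
#' the stepwise studentized-range procedure: sorted means spanning `p` ranks
#' are compared against the least significant range
#' `R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)` with Duncan's protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)` and `n_h` the harmonic mean
#' group size; a non-significant range protects all ranges it contains.
#' Groups sharing any letter are not significantly different.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @param alpha nominal level (default 0.05).
#' @return object of class `duncan_test`: list with `F`, `p`, `df`, a
#'   `means` data.frame (group, n, mean, letters, sorted by decreasing
#'   mean), and the logical matrix `different` of pairwise decisions.
#' @export
#' @examples
#' anova_duncan(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
anova_duncan <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  n_i <- table(groups)
  fit <- aov(values ~ groups)
  an <- anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  Fv <- an["groups", "F value"]
  pv <- an["groups", "Pr(>F)"]
  if (!is.finite(mse) || mse < .Machine$double.eps * (mean(values^2) + 1)) {
    # zero within-group variance: distinct means are trivially separated
    mse <- 0
    Fv <- if (var(tapply(values, groups, mean)) > 0) Inf else 0
    pv <- if (is.infinite(Fv)) 0 else 1
  }
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  nh <- k / sum(1 / n_i[names(means)])
  ns <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  diag(ns) <- TRUE
  for (span in seq(k, 2)) {
    alpha_p <- 1 - (1 - alpha)^(span - 1)
    Rp <- if (mse > 0 && dfe > 0)
      qtukey(1 - alpha_p, span, dfe) * sqrt(mse / nh) else 0
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (ns[i, j]) next  # protected by a wider non-significant range
      if (means[i] - means[j] <= Rp) ns[i:j, i:j] <- TRUE
    }
  }
  # letters: maximal runs of mutually non-different sorted means
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && ns[i, j + 1]) j <- j + 1
    intervals[[length(intervals) + 1]] <- c(i, j)
  }
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) for (b in seq_along(intervals))
    if (a != b && keep[b] &&
        intervals[[a]][1] <= intervals[[b]][1] &&
        intervals[[a]][2] >= intervals[[b]][2] &&
        !identical(intervals[[a]], intervals[[b]])) keep[b] <- FALSE
  intervals <- unique(intervals[keep])
  letters_out <- rep("", k)
  for (li in seq_along(intervals)) {
    rng <- intervals[[li]]
    letters_out[rng[1]:rng[2]] <- paste0(letters_out[rng[1]:rng[2]],
                                         letters[li])
  }
  res <- list(F = Fv, p = pv, df = c(groups = k - 1, residuals = dfe),
              means = data.frame(group = names(means), n = as.integer(n_i[names(means)]),
                                 mean = as.numeric(means),
                                 letters = letters_out,
                                 stringsAsFactors = FALSE),
              different = !ns, alpha = alpha)
  class(res) <- "duncan_test"
  res
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (df %d, %d)\n",
              x$F, x$p, x$df[1], x$df[2]))
  cat(sprintf("Duncan's multiple range test at alpha = %g:\n", x$alpha))
  print(x$means, row.names = FALSE)
  invisible(x)
}
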