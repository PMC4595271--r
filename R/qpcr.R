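#' Relative expression by the 2^-dCT method
#'
#' Computes relative qPCR expression with a multi-reference baseline:
#' technical replicates are first averaged (arithmetic mean of Ct values),
#' the reference Ct is the geometric mean of the per-reference-gene means,
#' and expression is `2^-(Ct_target - Ct_ref)`.
#'
#' @param ct_target numeric Ct values of the target gene (technical
#'   replicates).
#' @param ct_refs reference-gene Ct values: a numeric vector (one value per
#'   reference gene) or a list of technical-replicate vectors.
#' @return relative expression (single number).
#' @export
#' @examples
#' expression_2ddct(25, c(20, 20, 20))   # 2^-5 = 0.03125
expression_2ddct <- function(ct_target, ct_refs) {
  if (is.numeric(ct_refs)) ct_refs <- as.list(ct_refs)
  if (length(ct_refs) == 0) stop("need at least one reference gene")
  ref_means <- vapply(ct_refs, function(v) mean(as.numeric(v)), 0)
  cts <- c(mean(as.numeric(ct_target)), ref_means)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be finite and positive")
  ct_ref <- exp(mean(log(ref_means)))
  2^(-(mean(as.numeric(ct_target)) - ct_ref))
}

#' Relative expression for a whole qPCR table
#'
#' Applies [expression_2ddct()] per (sample, target gene), using the
#' sample's reference-gene rows as the baseline.
#'
#' @param qpcr data.frame with columns `sample`, `gene`, `role`
#'   (`"target"`/`"reference"`), `ct` (and optionally `tech_rep`).
#' @return data.frame with columns `sample`, `gene`, `expression`.
#' @export
qpcr_expression <- function(qpcr) {
  stopifnot(all(c("sample", "gene", "role", "ct") %in% names(qpcr)))
  out <- do.call(rbind, lapply(split(qpcr, qpcr$sample), function(d) {
    refs <- d[d$role == "reference", ]
    if (nrow(refs) == 0) stop("sample without reference genes: ", d$sample[1])
    ref_list <- split(refs$ct, refs$gene)
    tg <- d[d$role == "target", ]
    do.call(rbind, lapply(split(tg, tg$gene), function(t1) {
      data.frame(sample = t1$sample[1], gene = t1$gene[1],
                 expression = expression_2ddct(t1$ct, ref_list),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Validate RNA-seq expression against qPCR
#'
#' Correlates per-gene RPKM and 2^-dCT values across samples. The pass
#' criterion is computed on log2-transformed values and additionally
#' requires a positive correlation (an anti-correlated gene with high R^2
#' must not validate).
#'
#' @param qpcr_values named numeric vector of 2^-dCT values per sample.
#' @param rpkm_values named numeric vector of RPKM values on the same
#'   samples.
#' @param r2_min R^2 pass threshold (default 0.7).
#' @return data.frame with `n`, `r_log` (Pearson r of log2 values),
#'   `r_squared` (`r_log^2`), `r_raw` (untransformed r), `pass`
#'   (`r_squared > r2_min & r_log > 0`).
#' @export
validate_against_rpkm <- function(qpcr_values, rpkm_values, r2_min = 0.7) {
  if (!is.null(names(qpcr_values)) && !is.null(names(rpkm_values))) {
    common <- intersect(names(qpcr_values), names(rpkm_values))
    qpcr_values <- qpcr_values[common]
    rpkm_values <- rpkm_values[common]
  }
  n <- length(qpcr_values)
  if (n < 3 || length(rpkm_values) != n)
    stop("need at least 3 paired samples")
  if (any(qpcr_values <= 0) || any(rpkm_values < 0))
    stop("expression values must be positive (RPKM >= 0)")
  eps <- .Machine$double.eps
  r_log <- cor(log2(qpcr_values + eps), log2(rpkm_values + eps))
  r_raw <- cor(qpcr_values, rpkm_values)
  data.frame(n = n, r_log = r_log, r_squared = r_log^2, r_raw = r_raw,
             pass = r_log^2 > r2_min & r_log > 0)
}
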