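#' Berry sampling design configuration
#'
#' Describes the factorial sampling design the simulator emulates: regions x
#' vintages x ordered E-L developmental stages, with an uneven number of
#' RNA-seq libraries per stage (limited RNA at the pea-size and intermediate
#' Brix stages) and a fixed number of biological repeats for the metabolite
#' samples. The default design is 2 regions (CL, GT) x 2 years (2010, 2011) x
#' 4 stages (E-L31, E-L35, E-L36, E-L38) with 1 library per region-year cell
#' at E-L31/E-L36 and 2 at E-L35/E-L38 (24 libraries in total) and 2
#' metabolite repeats per cell (32 samples).
#'
#' @param regions character vector of region labels.
#' @param years vector of vintage labels.
#' @param stages ordered character vector of E-L stage labels.
#' @param libs_per_cell named integer vector, RNA-seq libraries per
#'   region-year cell at each stage; names must cover `stages`.
#' @param metab_reps_per_cell biological repeats per metabolite cell.
#' @param n_transcripts named integer vector, transcripts per functional
#'   category (`MEP`, `MVA`, `TPS-a`, `TPS-b`, `TPS-g`, `UGT`, `TF`,
#'   `ripening`, `other`).
#' @param n_compounds named integer vector, volatile compounds per form
#'   (`free`, `bound`).
#' @param total_reads target mapped reads per library.
#' @param nb_dispersion negative-binomial dispersion (1/size) for read counts.
#' @param noise_sd per-library log2-scale biological/technical noise SD.
#' @param bound_factor multiplicative excess of bound-form over free-form
#'   mean concentration (glycosides dominate in muscat berries).
#' @param seed integer seed; fully determines the generated bundle.
#' @return object of class `berry_design`.
#' @export
#' @examples
#' d <- design_config()
#' d$n_libraries   # 24
#' d$n_metab_samples  # 32
design_config <- function(regions = c("CL", "GT"),
                          years = c(2010L, 2011L),
                          stages = c("E-L31", "E-L35", "E-L36", "E-L38"),
                          libs_per_cell = c("E-L31" = 1L, "E-L35" = 2L,
                                            "E-L36" = 1L, "E-L38" = 2L),
                          metab_reps_per_cell = 2L,
                          n_transcripts = c(MEP = 8L, MVA = 8L, "TPS-a" = 6L,
                                            "TPS-b" = 6L, "TPS-g" = 4L,
                                            UGT = 12L, TF = 20L,
                                            ripening = 10L, other = 26L),
                          n_compounds = c(free = 8L, bound = 8L),
                          total_reads = 1e6,
                          nb_dispersion = 0.05,
                          noise_sd = 0.05,
                          bound_factor = 5,
                          seed = 1L) {
  stopifnot(length(stages) >= 1, !anyDuplicated(stages),
            length(regions) >= 1, length(years) >= 1)
  if (!all(stages %in% names(libs_per_cell)))
    stop("libs_per_cell must name every stage")
  libs_per_cell <- libs_per_cell[stages]
  if (any(libs_per_cell < 1)) stop("libs_per_cell entries must be >= 1")
  if (metab_reps_per_cell < 1) stop("metab_reps_per_cell must be >= 1")
  if (total_reads <= 0) stop("total_reads must be positive")
  n_cells <- length(regions) * length(years)
  out <- list(
    regions = regions, years = years, stages = stages,
    libs_per_cell = libs_per_cell,
    metab_reps_per_cell = as.integer(metab_reps_per_cell),
    n_transcripts = n_transcripts, n_compounds = n_compounds,
    total_reads = total_reads, nb_dispersion = nb_dispersion,
    noise_sd = noise_sd, bound_factor = bound_factor,
    seed = as.integer(seed),
    n_libraries = n_cells * sum(libs_per_cell),
    n_metab_samples = n_cells * length(stages) * as.integer(metab_reps_per_cell)
  )
  class(out) <- "berry_design"
  out
}

#' @export
print.berry_design <- function(x, ...) {
  cat("Berry sampling design:\n")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  cat("  years:  ", paste(x$years, collapse = ", "), "\n")
  cat("  stages: ", paste(x$stages, collapse = " < "), "\n")
  cat("  RNA-seq libraries:", x$n_libraries,
      "( per region-year cell:", paste(x$libs_per_cell, collapse = "/"), ")\n")
  cat("  metabolite samples:", x$n_metab_samples, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

.archetypes <- c("increasing", "decreasing", "peaked", "stable")

#' Planted effect for the simulator
#'
#' Declares a developmental profile archetype, an optional regional fold
#' change at the final stage, and correlation partners whose profiles are
#' generated to track the target at a chosen Pearson correlation. Partner ids
#' naming transcripts plant gene-gene (e.g. TF-anchor) structure; ids naming
#' compounds plant gene-metabolite structure.
#'
#' @param target transcript or compound id the effect applies to.
#' @param archetype one of `"increasing"`, `"decreasing"`, `"peaked"`,
#'   `"stable"`.
#' @param region region label receiving the multiplier (default: none).
#' @param region_multiplier fold change (> 0) in `region` at the final stage,
#'   ramped in log scale across stages.
#' @param partners optional data.frame with columns `id` and `r` (target
#'   Pearson correlation in `[-1, 1]`).
#' @param noise_sd log2-scale noise SD used when realising partner profiles.
#' @return object of class `planted_effect`.
#' @export
planted_effect <- function(target, archetype = "increasing",
                           region = NULL, region_multiplier = 1,
                           partners = NULL, noise_sd = 0.05) {
  archetype <- match.arg(archetype, .archetypes)
  if (region_multiplier <= 0) stop("region_multiplier must be > 0")
  if (!is.null(partners)) {
    stopifnot(is.data.frame(partners), all(c("id", "r") %in% names(partners)))
    if (any(abs(partners$r) > 1))
      stop("impossible correlation request: |r| > 1")
  }
  structure(list(target = target, archetype = archetype, region = region,
                 region_multiplier = region_multiplier, partners = partners,
                 noise_sd = noise_sd),
            class = "planted_effect")
}

# log2 stage trajectory for an archetype, amplitude `amp`, over S stages
stage_trajectory <- function(archetype, n_stages, amp = 3) {
  archetype <- match.arg(archetype, .archetypes)
  s <- seq_len(n_stages)
  switch(archetype,
    increasing = amp * (s - 1) / (n_stages - 1),
    decreasing = amp * (n_stages - s) / (n_stages - 1),
    peaked = {
      peak <- ceiling((n_stages + 1) / 2)  # interior stage
      amp * (1 - abs(s - peak) / max(peak - 1, n_stages - peak))
    },
    stable = rep(0, n_stages)
  )
}
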