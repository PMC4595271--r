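#' Condition cells of a design
#'
#' Enumerates the region x year x stage condition cells in a canonical order
#' (stages fastest, then years, then regions) with a `cell` id and the
#' 1-based stage index used as the developmental covariate.
#'
#' @param design a [design_config()] object.
#' @return data.frame with columns `cell`, `region`, `year`, `stage`,
#'   `stage_index`.
#' @export
design_cells <- function(design) {
  g <- expand.grid(stage = design$stages, year = design$years,
                   region = design$regions, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("region", "year", "stage")]
  g$stage_index <- match(g$stage, design$stages)
  g$cell <- paste(g$region, g$year, g$stage, sep = "_")
  rownames(g) <- NULL
  g[, c("cell", "region", "year", "stage", "stage_index")]
}

#' Realize a profile correlated with a target profile
#'
#' Planting primitive used by the simulator: the target profile is
#' standardized over cells and mixed with independent Gaussian noise as
#' `r * z + sqrt(1 - r^2) * e`, then rescaled to SD `amp` around `base`.
#' The realized sample correlation is close to, not exactly, `r` (honest
#' about sampling error at a finite number of cells).
#'
#' @param target numeric target profile over condition cells.
#' @param r target Pearson correlation in `[-1, 1]`.
#' @param base,amp location and scale of the returned profile.
#' @return numeric profile of the same length.
#' @export
plant_correlated_profile <- function(target, r, base = 4, amp = 1.5) {
  if (abs(r) > 1) stop("impossible correlation request: |r| > 1")
  z <- as.numeric(scale(target))
  if (any(!is.finite(z))) stop("target profile has zero variance")
  mix <- r * z + sqrt(1 - r^2) * rnorm(length(z))
  base + amp * mix
}

#' Generate a complete synthetic berry dataset
#'
#' Draws a seeded bundle with the statistical structure the downstream
#' analysis assumes: per-library unique read counts (negative binomial around
#' archetype-driven cell means) plus multi-read candidate groups, metabolite
#' concentrations (log-normal, bound form more abundant than free), sensory
#' thresholds, a qPCR Ct table consistent with the expression profiles, and a
#' phenophase climate table. Planted effects fix archetypes, regional fold
#' changes and correlation partners for chosen targets; everything else is
#' drawn from a background mixture (mostly stable profiles).
#'
#' @param design a [design_config()] object; its `seed` fully determines the
#'   output.
#' @param effects list of [planted_effect()] objects. Targets must exist
#'   among generated transcript ids (`<CATEGORY>_<nn>`) or compound ids
#'   (`freeCpd<nn>` / `boundCpd<nn>`).
#' @return object of class `berry_bundle`: a list with elements
#'   `transcripts`, `libraries`, `unique_counts` (matrix, transcripts x
#'   libraries), `multiread_groups`, `metabolites`, `thresholds`, `qpcr`,
#'   `climate`, `latent_expression` (log2 cell means, transcripts x cells),
#'   `latent_metabolites` (log cell means), `cells`, `design`, `effects`.
#' @export
#' @examples
#' b <- simulate_berry_dataset(design_config(seed = 7))
#' ncol(b$unique_counts)        # 24 libraries
#' nrow(unique(b$metabolites[, c("region", "year", "stage", "replicate")]))
simulate_berry_dataset <- function(design = design_config(), effects = list()) {
  stopifnot(inherits(design, "berry_design"))
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  with_seed(design$seed, {
    cells <- design_cells(design)
    S <- length(design$stages)

    ## transcript annotation
    cat_ids <- unlist(lapply(names(design$n_transcripts), function(cat) {
      sprintf("%s_%02d", cat, seq_len(design$n_transcripts[[cat]]))
    }))
    categories <- rep(names(design$n_transcripts), design$n_transcripts)
    transcripts <- data.frame(id = cat_ids, length_nt = sample(600:3000, length(cat_ids),
                                                               replace = TRUE),
                              category = categories, stringsAsFactors = FALSE)

    ## compound ids
    cpd_ids <- unlist(lapply(names(design$n_compounds), function(f) {
      sprintf("%sCpd%02d", f, seq_len(design$n_compounds[[f]]))
    }))
    cpd_form <- rep(names(design$n_compounds), design$n_compounds)

    eff_targets <- vapply(effects, `[[`, "", "target")
    unknown <- setdiff(eff_targets, c(transcripts$id, cpd_ids))
    if (length(unknown))
      stop("effect targets not among generated ids: ",
           paste(unknown, collapse = ", "))

    ## background archetypes (terpene accumulation biases compounds upward)
    draw_arch <- function(n, probs) sample(.archetypes, n, replace = TRUE, prob = probs)
    gene_arch <- draw_arch(nrow(transcripts), c(0.15, 0.15, 0.10, 0.60))
    names(gene_arch) <- transcripts$id
    cpd_arch <- draw_arch(length(cpd_ids), c(0.55, 0.10, 0.15, 0.20))
    names(cpd_arch) <- cpd_ids

    ## latent log2 expression per cell: baseline + stage trajectory +
    ## small vintage offset (+ planted regional log-ramp)
    base_expr <- rnorm(nrow(transcripts), 5, 1.5)
    latent <- matrix(0, nrow(transcripts), nrow(cells),
                     dimnames = list(transcripts$id, cells$cell))
    year_off <- matrix(rnorm(nrow(transcripts) * length(design$years), 0, 0.2),
                       nrow(transcripts),
                       dimnames = list(transcripts$id, as.character(design$years)))
    for (i in seq_len(nrow(transcripts))) {
      traj <- stage_trajectory(gene_arch[i], S)
      latent[i, ] <- base_expr[i] + traj[cells$stage_index] +
        year_off[i, as.character(cells$year)]
    }

    ## latent log metabolite cell means (natural log of ug/L)
    cpd_base <- log(20) + log(ifelse(cpd_form == "bound", design$bound_factor, 1)) +
      rnorm(length(cpd_ids), 0, 0.4)
    latent_met <- matrix(0, length(cpd_ids), nrow(cells),
                         dimnames = list(cpd_ids, cells$cell))
    for (i in seq_along(cpd_ids)) {
      traj <- stage_trajectory(cpd_arch[i], S, amp = 2)  # natural-log amplitude
      latent_met[i, ] <- cpd_base[i] + traj[cells$stage_index] +
        rnorm(1, 0, 0.1) * (cells$year == design$years[1])
    }

    ## apply planted effects
    for (eff in effects) {
      tgt <- eff$target
      is_gene <- tgt %in% transcripts$id
      traj <- stage_trajectory(eff$archetype, S, amp = if (is_gene) 3 else 2)
      ramp <- if (!is.null(eff$region))
        log2(eff$region_multiplier) * (cells$stage_index - 1) / (S - 1) *
          (cells$region == eff$region) else 0
      if (is_gene) {
        latent[tgt, ] <- base_expr[match(tgt, transcripts$id)] +
          traj[cells$stage_index] + ramp
        gene_arch[tgt] <- eff$archetype
      } else {
        latent_met[tgt, ] <- cpd_base[match(tgt, cpd_ids)] +
          traj[cells$stage_index] + ramp * log(2)
        cpd_arch[tgt] <- eff$archetype
      }
      if (!is.null(eff$partners)) {
        tgt_prof <- if (is_gene) latent[tgt, ] else latent_met[tgt, ]
        for (j in seq_len(nrow(eff$partners))) {
          pid <- eff$partners$id[j]
          prof <- plant_correlated_profile(tgt_prof, eff$partners$r[j])
          if (pid %in% transcripts$id) {
            latent[pid, ] <- 5 + 1.5 * as.numeric(scale(prof))
          } else if (pid %in% cpd_ids) {
            latent_met[pid, ] <- log(30) + 1.2 * as.numeric(scale(prof))
          } else stop("unknown partner id: ", pid)
        }
      }
    }

    ## RNA-seq libraries
    lib_rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
      nlib <- design$libs_per_cell[[cells$stage[ci]]]
      data.frame(cell = cells$cell[ci], region = cells$region[ci],
                 year = cells$year[ci], stage = cells$stage[ci],
                 replicate = seq_len(nlib), stringsAsFactors = FALSE)
    }))
    lib_rows$library <- sprintf("%s_r%d", lib_rows$cell, lib_rows$replicate)
    libraries <- lib_rows[, c("library", "cell", "region", "year", "stage",
                              "replicate")]
    size <- 1 / design$nb_dispersion
    U <- matrix(0, nrow(transcripts), nrow(libraries),
                dimnames = list(transcripts$id, libraries$library))
    groups <- vector("list", nrow(libraries))
    for (li in seq_len(nrow(libraries))) {
      lam <- 2^(latent[, libraries$cell[li]] +
                  rnorm(nrow(transcripts), 0, design$noise_sd))
      mu <- lam / sum(lam) * design$total_reads * 0.95
      U[, li] <- rnbinom(length(mu), mu = mu, size = size)
      ## multi-read groups among same-category transcript pairs
      n_grp <- 5L
      g <- lapply(seq_len(n_grp), function(k) {
        cat <- sample(unique(transcripts$category), 1)
        ids <- sample(transcripts$id[transcripts$category == cat],
                      min(2, sum(transcripts$category == cat)))
        list(candidates = ids,
             multiplicity = rpois(1, design$total_reads * 0.01 / n_grp))
      })
      groups[[li]] <- data.frame(
        library = libraries$library[li], group = seq_len(n_grp),
        candidates = vapply(g, function(x) paste(x$candidates, collapse = ","), ""),
        multiplicity = vapply(g, function(x) as.numeric(x$multiplicity), 0))
    }
    multiread_groups <- do.call(rbind, groups)
    libraries$total_reads <- colSums(U) +
      vapply(split(multiread_groups$multiplicity, multiread_groups$library),
             sum, 0)[libraries$library]

    ## metabolite samples (biological repeats per cell)
    met <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
      do.call(rbind, lapply(seq_len(design$metab_reps_per_cell), function(rep) {
        conc <- exp(latent_met[, cells$cell[ci]] + rnorm(length(cpd_ids), 0, 0.1))
        data.frame(compound = cpd_ids, form = cpd_form,
                   region = cells$region[ci], year = cells$year[ci],
                   stage = cells$stage[ci], replicate = rep,
                   concentration_ug_L = conc, stringsAsFactors = FALSE)
      }))
    }))
    rownames(met) <- NULL
    thresholds <- data.frame(compound = cpd_ids,
                             threshold_ug_L = exp(rnorm(length(cpd_ids),
                                                        log(40), 0.8)))

    ## qPCR: first 6 transcripts as targets, 3 reference genes, one sample
    ## per cell, 3 technical replicates; Ct tracks -log2(expression)
    qp_genes <- transcripts$id[seq_len(min(6, nrow(transcripts)))]
    refs <- c("GAPDH", "actin", "ubiquitin")
    qpcr <- do.call(rbind, lapply(cells$cell, function(cl) {
      rbind(
        do.call(rbind, lapply(qp_genes, function(g) {
          ct <- 25 - (latent[g, cl] - mean(latent[g, ])) +
            rnorm(3, 0, 0.15)
          data.frame(sample = cl, gene = g, role = "target",
                     tech_rep = 1:3, ct = ct, stringsAsFactors = FALSE)
        })),
        do.call(rbind, lapply(refs, function(g) {
          data.frame(sample = cl, gene = g, role = "reference",
                     tech_rep = 1:3, ct = rnorm(3, 20, 0.1),
                     stringsAsFactors = FALSE)
        })))
    }))
    rownames(qpcr) <- NULL

    ## climate table in the published phenophase layout, values drawn from
    ## plausible viticultural ranges (not the published measurements)
    phenos <- c("Flowering", "Berry development", "Veraison", "Ripening")
    climate <- do.call(rbind, lapply(design$regions, function(rg) {
      do.call(rbind, lapply(design$years, function(yr) {
        days <- round(runif(4, c(5, 40, 15, 20), c(15, 60, 30, 40)))
        data.frame(region = rg, year = yr, phenophase = phenos, days = days,
                   rad_kj_m2 = round(days * runif(4, 1500, 3000)),
                   gdd = round(days * runif(4, 8, 14), 2),
                   sunshine_h = round(days * runif(4, 5, 11), 2),
                   rainfall_mm = round(runif(4, 0, 200), 2),
                   temp_diff_c = round(runif(4, 5, 17), 2),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(climate) <- NULL

    structure(list(transcripts = transcripts, libraries = libraries,
                   unique_counts = U, multiread_groups = multiread_groups,
                   metabolites = met, thresholds = thresholds, qpcr = qpcr,
                   climate = climate, latent_expression = latent,
                   latent_metabolites = latent_met, cells = cells,
                   design = design, effects = effects),
              class = "berry_bundle")
  })
}

#' @export
print.berry_bundle <- function(x, ...) {
  cat("Synthetic berry dataset (seed", x$design$seed, ")\n")
  cat(" ", nrow(x$transcripts), "transcripts,", ncol(x$unique_counts),
      "RNA-seq libraries,",
      nrow(unique(x$metabolites[, c("region", "year", "stage", "replicate")])),
      "metabolite samples\n")
  invisible(x)
}

#' Small hand-checkable worked fixture
#'
#' A fixed miniature bundle (8 genes, 3 compounds, one region-year, 4 stages)
#' whose numbers are all literal: `HDRlike` unique counts strictly increase
#' across stages (trend class "increased"); the multi-read group
#' `{GENEA, GENEB}` has unique counts 30/10 in every library so proportional
#' rescue splits each group's 100 reads as 75/25; each library's total mapped
#' reads equals the unique-count sum plus the group multiplicity.
#'
#' @return a `berry_bundle`-like list (no latent matrices).
#' @export
make_worked_fixture <- function() {
  stages <- c("E-L31", "E-L35", "E-L36", "E-L38")
  transcripts <- data.frame(
    id = c("HDRlike", "GT14like", "TFup", "TFdown", "RIPE1", "GENEA",
           "GENEB", "STABLE1"),
    length_nt = c(2000L, 1500L, 1200L, 1100L, 1000L, 1000L, 1000L, 900L),
    category = c("MEP", "UGT", "TF", "TF", "ripening", "other", "other",
                 "other"),
    stringsAsFactors = FALSE)
  U <- rbind(HDRlike = c(10, 40, 160, 640),
             GT14like = c(20, 80, 200, 400),
             TFup = c(5, 20, 50, 100),
             TFdown = c(100, 50, 20, 5),
             RIPE1 = c(8, 30, 90, 200),
             GENEA = c(30, 30, 30, 30),
             GENEB = c(10, 10, 10, 10),
             STABLE1 = c(50, 52, 48, 50))
  libs <- paste0("CL_2011_", stages, "_r1")
  colnames(U) <- libs
  libraries <- data.frame(library = libs,
                          cell = paste0("CL_2011_", stages),
                          region = "CL", year = 2011L, stage = stages,
                          replicate = 1L,
                          total_reads = colSums(U) + 100,
                          stringsAsFactors = FALSE)
  multiread_groups <- data.frame(library = libs, group = 1L,
                                 candidates = "GENEA,GENEB",
                                 multiplicity = 100,
                                 stringsAsFactors = FALSE)
  metabolites <- do.call(rbind, lapply(1:2, function(rep) {
    data.frame(compound = rep(c("linalool", "geraniol", "geranyl_glucoside"),
                              each = 4),
               form = rep(c("free", "free", "bound"), each = 4),
               region = "CL", year = 2011L, stage = rep(stages, 3),
               replicate = rep,
               concentration_ug_L = c(5, 10, 20, 40,
                                      4, 8, 16, 32,
                                      20, 60, 120, 240) + (rep - 1),
               stringsAsFactors = FALSE)
  }))
  thresholds <- data.frame(compound = c("linalool", "geraniol",
                                        "geranyl_glucoside"),
                           threshold_ug_L = c(25, 30, 1000),
                           stringsAsFactors = FALSE)
  qpcr <- do.call(rbind, lapply(seq_along(stages), function(si) {
    cl <- paste0("CL_2011_", stages[si])
    rbind(data.frame(sample = cl, gene = "HDRlike", role = "target",
                     tech_rep = 1:3, ct = c(27, 25, 23, 21)[si],
                     stringsAsFactors = FALSE),
          data.frame(sample = cl, gene = rep(c("GAPDH", "actin", "ubiquitin"),
                                             each = 3),
                     role = "reference", tech_rep = rep(1:3, 3), ct = 20,
                     stringsAsFactors = FALSE))
  }))
  climate <- data.frame(region = "CL", year = 2011L,
                        phenophase = c("Flowering", "Berry development",
                                       "Veraison", "Ripening"),
                        days = c(10, 20, 30, 40),
                        rad_kj_m2 = c(10000, 20000, 30000, 40000),
                        gdd = c(100, 200, 300, 400),
                        sunshine_h = c(50, 100, 150, 200),
                        rainfall_mm = c(10, 20, 30, 40),
                        temp_diff_c = c(8, 10, 12, 14),
                        stringsAsFactors = FALSE)
  cells <- data.frame(cell = paste0("CL_2011_", stages), region = "CL",
                      year = 2011L, stage = stages,
                      stage_index = seq_along(stages),
                      stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, libraries = libraries,
                 unique_counts = U, multiread_groups = multiread_groups,
                 metabolites = metabolites, thresholds = thresholds,
                 qpcr = qpcr, climate = climate, cells = cells,
                 design = design_config(regions = "CL", years = 2011L,
                                        libs_per_cell = c("E-L31" = 1L,
                                                          "E-L35" = 1L,
                                                          "E-L36" = 1L,
                                                          "E-L38" = 1L)),
                 effects = list()),
            class = "berry_bundle")
}

#' Write a dataset bundle to tabular files
#'
#' Serializes every table of a bundle to TSV/CSV plus a JSON manifest
#' recording the design, the seed and the written files. The same bundle
#' always produces byte-identical files.
#'
#' @param bundle a `berry_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_dataset_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(bundle$transcripts, "transcripts.tsv")
  uc <- data.frame(id = rownames(bundle$unique_counts), bundle$unique_counts,
                   check.names = FALSE)
  tsv(uc, "unique_counts.tsv")
  tsv(bundle$multiread_groups, "multiread_groups.tsv")
  utils::write.csv(bundle$metabolites, file.path(dir, "metabolites.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$thresholds, file.path(dir, "thresholds.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$qpcr, file.path(dir, "qpcr.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c("transcripts.tsv", "unique_counts.tsv", "multiread_groups.tsv",
             "metabolites.csv", "thresholds.csv", "qpcr.csv", "climate.csv")
  manifest <- list(seed = bundle$design$seed,
                   design = bundle$design[c("regions", "years", "stages",
                                            "metab_reps_per_cell",
                                            "total_reads")],
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
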