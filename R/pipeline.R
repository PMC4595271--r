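#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow plus the simulation
#' seed and output directory. Configurations validate on construction and
#' round-trip unchanged through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param seed simulation seed (used when no bundle is supplied).
#' @param outdir output directory for stage files.
#' @param alpha DEG / correlation significance level in (0, 1).
#' @param lfc minimum absolute log2 ratio for DEG calls (>= 0).
#' @param r_network co-expression |r| threshold in [0, 1].
#' @param r_trend trend-classification |r| threshold in [0, 1].
#' @param oav_threshold odor-activity cutoff (> 0).
#' @param r2_min qPCR validation R^2 threshold in [0, 1].
#' @param kmeans_k number of k-means clusters (>= 2).
#' @param kmeans_seed k-means initialization seed.
#' @param network_inclusive include edges at exactly `r_network`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("grapeterp_run_"),
                            alpha = 0.05, lfc = 1, r_network = 0.8,
                            r_trend = 0.7, oav_threshold = 1, r2_min = 0.7,
                            kmeans_k = 9L, kmeans_seed = 1L,
                            network_inclusive = TRUE) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, alpha = alpha,
              lfc = lfc, r_network = r_network, r_trend = r_trend,
              oav_threshold = oav_threshold, r2_min = r2_min,
              kmeans_k = as.integer(kmeans_k),
              kmeans_seed = as.integer(kmeans_seed),
              network_inclusive = isTRUE(network_inclusive))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$lfc >= 0, "lfc must be >= 0")
  chk(cfg$r_network >= 0 && cfg$r_network <= 1, "r_network must be in [0, 1]")
  chk(cfg$r_trend >= 0 && cfg$r_trend <= 1, "r_trend must be in [0, 1]")
  chk(cfg$oav_threshold > 0, "oav_threshold must be > 0")
  chk(cfg$r2_min >= 0 && cfg$r2_min <= 1, "r2_min must be in [0, 1]")
  chk(cfg$kmeans_k >= 2, "kmeans_k must be >= 2")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a dataset bundle (simulated
#' from `config$seed` when none is given): multi-read rescue and RPKM,
#' regional DEG calls per year-stage, metabolite totals / OAV / ANOVA-Duncan,
#' profile scaling with hierarchical and k-means clustering and trend
#' classes, gene-metabolite correlation and candidate nomination, the
#' anchored co-expression network with Cytoscape exports, qPCR validation,
#' and climate season summaries. Every output file is listed in a JSON
#' manifest with an MD5 content hash; identical config + bundle reproduce
#' identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param bundle optional `berry_bundle`; default simulates
#'   `design_config(seed = config$seed)`.
#' @param anchors anchor gene ids for the network stage (default: the two
#'   top-ranked nominated candidates, falling back to the two
#'   highest-expressed pathway genes).
#' @return invisibly, the manifest list (`files` with md5 hashes, `config`).
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL,
                         anchors = NULL) {
  validate_pipeline_config(config)
  if (is.null(bundle)) {
    eff <- list(planted_effect("UGT_01", "increasing", region = "CL",
                               region_multiplier = 4,
                               partners = data.frame(id = c("boundCpd01",
                                                            "boundCpd02",
                                                            "boundCpd03"),
                                                     r = 0.9)),
                planted_effect("MEP_01", "increasing", region = "CL",
                               region_multiplier = 3,
                               partners = data.frame(id = "freeCpd01",
                                                     r = 0.9)))
    bundle <- simulate_berry_dataset(design_config(seed = config$seed), eff)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(d, f, csv = FALSE) {
    p <- file.path(config$outdir, f)
    if (csv) utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
    else utils::write.table(d, p, sep = "\t", quote = FALSE,
                            row.names = FALSE)
    written <<- c(written, p)
    p
  }

  ## expression: rescue + RPKM
  libs <- bundle$libraries
  counts <- vapply(libs$library, function(l) {
    grp <- bundle$multiread_groups[bundle$multiread_groups$library == l, ,
                                   drop = FALSE]
    assign_multireads(bundle$unique_counts[, l], grp)
  }, numeric(nrow(bundle$unique_counts)))
  rpkm_m <- rpkm(counts, bundle$transcripts$length_nt, libs$total_reads)
  emit(data.frame(id = rownames(rpkm_m), rpkm_m, check.names = FALSE),
       "rpkm_matrix.tsv")

  ## regional DEG per (year, stage)
  regions <- unique(libs$region)
  deg <- NULL
  if (length(regions) >= 2) {
    cmb <- unique(libs[, c("year", "stage")])
    comparisons <- lapply(seq_len(nrow(cmb)), function(i) {
      cls <- paste(regions[1:2], cmb$year[i], cmb$stage[i], sep = "_")
      if (all(cls %in% libs$cell)) cls else NULL
    })
    comparisons <- Filter(Negate(is.null), comparisons)
    deg <- call_degs(counts, libs, comparisons, alpha = config$alpha,
                     lfc = config$lfc)
    emit(deg, "deg_results.tsv")
  }

  ## metabolites
  totals <- totals_by_form(bundle$metabolites)
  emit(totals, "totals.tsv")
  met_mean <- stats::aggregate(concentration_ug_L ~ compound + region + year +
                                 stage, data = bundle$metabolites, FUN = mean)
  thr <- setNames(bundle$thresholds$threshold_ug_L,
                  bundle$thresholds$compound)
  oav <- cbind(met_mean[, c("compound", "region", "year", "stage")],
               odor_activity(met_mean$concentration_ug_L,
                             thr[met_mean$compound]))
  oav$contributing <- oav$oav >= config$oav_threshold
  emit(oav, "oav.tsv")
  an_rows <- do.call(rbind, lapply(
    split(totals, interaction(totals$region, totals$year, totals$form,
                              drop = TRUE)),
    function(d) {
      cell <- bundle$metabolites[bundle$metabolites$region == d$region[1] &
                                   bundle$metabolites$year == d$year[1] &
                                   bundle$metabolites$form == d$form[1], ]
      sums <- stats::aggregate(concentration_ug_L ~ stage + replicate,
                               data = cell, FUN = sum)
      if (length(unique(sums$stage)) < 2 || nrow(sums) < 4) return(NULL)
      dt <- anova_duncan(sums$concentration_ug_L, sums$stage,
                         alpha = config$alpha)
      data.frame(region = d$region[1], year = d$year[1], form = d$form[1],
                 F = dt$F, p = dt$p,
                 groups = paste(dt$means$group, dt$means$letters,
                                sep = ":", collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(an_rows)) emit(an_rows, "anova_duncan.tsv")

  ## profiles on condition-cell means
  cmeans <- cell_means(rpkm_m, libs)
  keep <- apply(cmeans, 1, sd) > 0
  scaled <- row_scale(cmeans[keep, , drop = FALSE])
  emit(data.frame(id = rownames(scaled), scaled, check.names = FALSE),
       "scaled_matrix.tsv")
  hc <- hierarchical_cluster(scaled)
  nw <- file.path(config$outdir, "dendrogram.nwk")
  writeLines(hc$newick, nw); written <- c(written, nw)
  cell_idx <- bundle$cells$stage_index[match(colnames(scaled),
                                             bundle$cells$cell)]
  ugt <- rownames(scaled)[bundle$transcripts$category[
    match(rownames(scaled), bundle$transcripts$id)] == "UGT"]
  km_rows <- if (length(ugt) >= config$kmeans_k) scaled[ugt, , drop = FALSE]
             else scaled
  km <- kmeans_trends(km_rows, min(config$kmeans_k, nrow(km_rows)),
                      seed = config$kmeans_seed, stage_index = cell_idx,
                      r_up = config$r_trend)
  emit(data.frame(id = names(km$labels), cluster = km$labels,
                  upward = names(km$labels) %in% km$upward_members),
       "clusters.tsv")
  stage_means <- vapply(sort(unique(cell_idx)), function(s)
    rowMeans(cmeans[, cell_idx == s, drop = FALSE]), numeric(nrow(cmeans)))
  trends <- t(vapply(rownames(cmeans), function(g) {
    tc <- classify_trend(stage_means[g, ], r_trend = config$r_trend)
    c(class = tc$class, peaked = tc$peaked)
  }, c(class = "", peaked = "")))
  emit(data.frame(id = rownames(trends), trends, check.names = FALSE),
       "trend_classes.tsv")

  ## integration: terpene-pathway genes vs compounds
  path_cat <- c("MEP", "MVA", "TPS-a", "TPS-b", "TPS-g", "UGT")
  path_genes <- bundle$transcripts$id[bundle$transcripts$category %in% path_cat]
  path_genes <- intersect(path_genes, rownames(cmeans)[keep])
  met_cells <- stats::aggregate(
    concentration_ug_L ~ compound + region + year + stage,
    data = bundle$metabolites, FUN = mean)
  met_cells$cell <- paste(met_cells$region, met_cells$year, met_cells$stage,
                          sep = "_")
  metab_m <- t(vapply(unique(met_cells$compound), function(cm) {
    d <- met_cells[met_cells$compound == cm, ]
    setNames(d$concentration_ug_L, d$cell)[colnames(cmeans)]
  }, numeric(ncol(cmeans))))
  colnames(metab_m) <- colnames(cmeans)
  corr <- correlate_all(cmeans[path_genes, , drop = FALSE], metab_m,
                        cells = bundle$cells)
  emit(corr, "gene_metabolite_corr.tsv")
  cand <- if (!is.null(deg))
    nominate_candidates(corr, deg, r_min = config$r_network,
                        alpha = config$alpha) else NULL
  if (!is.null(cand)) emit(cand, "candidates.tsv")

  ## anchored network
  if (is.null(anchors)) {
    anchors <- if (!is.null(cand) && nrow(cand) >= 2) cand$gene[1:2]
               else path_genes[order(-rowMeans(cmeans[path_genes, ,
                                                      drop = FALSE]))][1:2]
  }
  tf_ids <- intersect(bundle$transcripts$id[bundle$transcripts$category == "TF"],
                      rownames(scaled))
  rip_ids <- intersect(
    bundle$transcripts$id[bundle$transcripts$category == "ripening"],
    rownames(scaled))
  net <- build_anchored_network(cmeans[anchors, , drop = FALSE],
                                cmeans[tf_ids, , drop = FALSE],
                                cmeans[rip_ids, , drop = FALSE],
                                threshold = config$r_network,
                                inclusive = config$network_inclusive)
  written <- c(written,
               export_network(net, config$outdir, "network",
                              node_categories = setNames(
                                bundle$transcripts$category,
                                bundle$transcripts$id)))

  ## qPCR validation against RPKM
  qex <- qpcr_expression(bundle$qpcr)
  emit(qex, "qpcr_expression.tsv")
  val <- do.call(rbind, lapply(split(qex, qex$gene), function(d) {
    rp <- cell_means(rpkm_m[d$gene[1], , drop = FALSE], libs)[1, d$sample]
    cbind(data.frame(gene = d$gene[1], stringsAsFactors = FALSE),
          validate_against_rpkm(setNames(d$expression, d$sample), rp,
                                r2_min = config$r2_min))
  }))
  emit(val, "validation.tsv")

  ## climate
  summ <- do.call(rbind, lapply(
    split(bundle$climate, interaction(bundle$climate$region,
                                      bundle$climate$year, drop = TRUE)),
    season_summary))
  emit(summ, "climate_summary.tsv")

  manifest <- list(config = unclass(config),
                   files = lapply(sort(unique(written)), function(p)
                     list(file = basename(p),
                          md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
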