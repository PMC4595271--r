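#' Thresholded signed correlation edges between two profile sets
#'
#' Scores every cross pair of two profile sets by Pearson correlation over
#' the shared condition cells and keeps edges with `|r| >= threshold`
#' (inclusive by default; set `inclusive = FALSE` for a strict `>`). Edges
#' are undirected and reported once with canonical (alphabetical) endpoint
#' ordering; self pairs are skipped and zero-variance profiles are dropped
#' with a warning.
#'
#' @param a,b numeric matrices, profiles x cells, identical columns.
#' @param threshold absolute correlation threshold (default 0.8).
#' @param inclusive include edges at exactly the threshold (default TRUE).
#' @return data.frame with columns `source`, `target`, `r`, `sign`
#'   (`"pos"`/`"neg"`).
#' @export
correlation_edges <- function(a, b, threshold = 0.8, inclusive = TRUE) {
  stopifnot(is.matrix(a), is.matrix(b), identical(colnames(a), colnames(b)))
  if (ncol(a) < 3) stop("need at least 3 condition cells")
  drop_const <- function(m, nm) {
    cst <- apply(m, 1, sd) == 0
    if (any(cst)) warning("zero-variance profiles skipped in ", nm, ": ",
                          paste(rownames(m)[cst], collapse = ", "))
    m[!cst, , drop = FALSE]
  }
  a <- drop_const(a, "a"); b <- drop_const(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(source = character(), target = character(),
                      r = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  cc <- cor(t(a), t(b))
  idx <- which(if (inclusive) abs(cc) >= threshold else abs(cc) > threshold,
               arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(source = character(), target = character(),
                      r = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  e <- data.frame(source = rownames(a)[idx[, 1]],
                  target = rownames(b)[idx[, 2]],
                  r = cc[idx], stringsAsFactors = FALSE)
  e <- e[e$source != e$target, , drop = FALSE]
  flip <- e$source > e$target
  tmp <- e$source[flip]; e$source[flip] <- e$target[flip]; e$target[flip] <- tmp
  e <- e[!duplicated(e[, c("source", "target")]), , drop = FALSE]
  e$sign <- ifelse(e$r >= 0, "pos", "neg")
  e <- e[order(e$source, e$target), ]
  rownames(e) <- NULL
  e
}

#' Anchored three-layer co-expression network
#'
#' Builds the focused network around anchor genes (e.g. the HDR and GT14
#' candidates): a transcription factor is admitted only when its profile
#' correlates with **every** anchor at `|r| >= threshold`; a
#' ripening-associated gene is admitted when it correlates at threshold with
#' at least one admitted TF. Edges run anchor-TF and TF-ripening only. TFs
#' are labelled `"pos"`/`"neg"` when their anchor correlations share a sign
#' and `"mixed"` otherwise.
#'
#' @param anchors matrix of anchor profiles (rows) x cells.
#' @param tfs matrix of transcription-factor profiles x cells.
#' @param ripening matrix of ripening-associated gene profiles x cells.
#' @param threshold absolute correlation threshold (default 0.8).
#' @param inclusive boundary handling as in [correlation_edges()].
#' @param tf_threshold,ripening_threshold optional per-layer overrides.
#' @return object of class `anchored_network`: list with `anchors`, `tfs`
#'   (data.frame id/sign), `ripening` (ids), `edges` (source, target, r,
#'   sign, layer) and the thresholds used. Empty layers are valid.
#' @export
build_anchored_network <- function(anchors, tfs, ripening,
                                   threshold = 0.8, inclusive = TRUE,
                                   tf_threshold = NULL,
                                   ripening_threshold = NULL) {
  stopifnot(is.matrix(anchors), nrow(anchors) >= 1)
  if (is.null(tf_threshold)) tf_threshold <- threshold
  if (is.null(ripening_threshold)) ripening_threshold <- threshold
  qual <- function(r, thr) if (inclusive) abs(r) >= thr else abs(r) > thr
  r_at <- cor(t(tfs), t(anchors))  # TFs x anchors
  keep_tf <- apply(r_at, 1, function(rr) isTRUE(all(qual(rr, tf_threshold))))
  tf_ids <- rownames(tfs)[keep_tf]
  tf_sign <- vapply(tf_ids, function(tf) {
    s <- sign(r_at[tf, ])
    if (all(s > 0)) "pos" else if (all(s < 0)) "neg" else "mixed"
  }, "")
  at_edges <- if (length(tf_ids)) do.call(rbind, lapply(tf_ids, function(tf) {
    data.frame(source = rownames(anchors), target = tf,
               r = r_at[tf, ], sign = ifelse(r_at[tf, ] >= 0, "pos", "neg"),
               layer = "anchor-TF", stringsAsFactors = FALSE)
  })) else NULL
  rip_ids <- character(); tr_edges <- NULL
  if (length(tf_ids) && nrow(ripening)) {
    r_tr <- cor(t(ripening), t(tfs[tf_ids, , drop = FALSE]))
    hits <- which(qual(r_tr, ripening_threshold), arr.ind = TRUE)
    if (nrow(hits)) {
      tr_edges <- data.frame(source = tf_ids[hits[, 2]],
                             target = rownames(ripening)[hits[, 1]],
                             r = r_tr[hits],
                             sign = ifelse(r_tr[hits] >= 0, "pos", "neg"),
                             layer = "TF-ripening", stringsAsFactors = FALSE)
      rip_ids <- unique(tr_edges$target)
    }
  }
  edges <- rbind(at_edges, tr_edges)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        r = numeric(), sign = character(),
                        layer = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(anchors = rownames(anchors),
                 tfs = data.frame(id = tf_ids, sign = unname(tf_sign),
                                  stringsAsFactors = FALSE),
                 ripening = rip_ids, edges = edges,
                 threshold = c(tf = tf_threshold, ripening = ripening_threshold),
                 inclusive = inclusive),
            class = "anchored_network")
}

#' @export
print.anchored_network <- function(x, ...) {
  cat("Anchored co-expression network\n")
  cat("  anchors:", paste(x$anchors, collapse = ", "), "\n")
  cat("  TFs admitted:", nrow(x$tfs),
      sprintf("(pos %d / neg %d / mixed %d)\n",
              sum(x$tfs$sign == "pos"), sum(x$tfs$sign == "neg"),
              sum(x$tfs$sign == "mixed")))
  cat("  ripening genes:", length(x$ripening), " edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Export a network for Cytoscape
#'
#' Writes a SIF file (`source pos|neg target`), node and edge attribute
#' tables, and a GraphML file (edge weight = r) that round-trips losslessly
#' through igraph. Accepts either an `anchored_network` or a plain edge
#' data.frame from [correlation_edges()]. Empty networks produce valid empty
#' files with a warning.
#'
#' @param network `anchored_network` or edge data.frame.
#' @param dir output directory (created if needed).
#' @param name file stem (default `"network"`).
#' @param node_categories optional named character vector of node categories
#'   for the node attribute table.
#' @return invisibly, the vector of written file paths.
#' @export
export_network <- function(network, dir, name = "network",
                           node_categories = NULL) {
  edges <- if (inherits(network, "anchored_network")) network$edges
           else network
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "r", "sign") %in% names(edges)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(name, c(".sif", ".graphml",
                                         "_nodes.tsv", "_edges.tsv")))
  if (nrow(edges) == 0) warning("exporting empty network")
  writeLines(if (nrow(edges)) paste(edges$source, edges$sign, edges$target)
             else character(), paths[1])
  nodes <- unique(c(edges$source, edges$target))
  ncat <- if (is.null(node_categories)) rep(NA_character_, length(nodes))
          else unname(node_categories[nodes])
  if (inherits(network, "anchored_network")) {
    ncat <- ifelse(nodes %in% network$anchors, "anchor",
            ifelse(nodes %in% network$tfs$id, "TF",
            ifelse(nodes %in% network$ripening, "ripening", ncat)))
  }
  utils::write.table(data.frame(id = nodes, category = ncat,
                                stringsAsFactors = FALSE),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("source", "target")]
    else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = nodes, category = ifelse(is.na(ncat), "", ncat),
                          stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$weight <- edges$r
    igraph::E(g)$sign <- edges$sign
  }
  igraph::write_graph(g, paths[2], format = "graphml")
  invisible(paths)
}
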