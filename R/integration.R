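#' Pearson correlation with t-based p-value
#'
#' Textbook Pearson correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Perfect correlations report p = 0 at machine level.
#'
#' @param x,y aligned numeric vectors, `n >= 3`.
#' @return list with `r`, `p`, `n`. Zero-variance input gives `r = NA`,
#'   `p = NA` with a warning.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 aligned points")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance profile: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x, y)
  r2 <- min(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  list(r = r, p = min(1, 2 * pt(tt, n - 2, lower.tail = FALSE)), n = n)
}

#' Gene-metabolite profile correlation
#'
#' Correlates an expression profile with a metabolite concentration profile
#' over matched condition cells. In `"instantaneous"` mode the cells are
#' correlated as-is; in `"cumulative"` mode the expression value at each
#' stage is first replaced by its running sum over that and earlier stages
#' within each region-year series, capturing glycosides that integrate the
#' activity of a transiently expressed glucosyltransferase.
#'
#' @param expression named numeric vector of expression values per cell.
#' @param metabolite named numeric vector of concentrations on the same
#'   cells.
#' @param cells data.frame describing the cells ([design_cells()] layout:
#'   `cell`, `region`, `year`, `stage_index`). Required for cumulative mode;
#'   in instantaneous mode names are checked when present.
#' @param mode `"instantaneous"` or `"cumulative"`.
#' @return data.frame with columns `mode`, `n`, `r`, `p`.
#' @export
#' @examples
#' cells <- design_cells(design_config())
#' x <- seq_len(16); names(x) <- cells$cell
#' gene_metabolite_corr(x, 2 * x, cells)$r   # 1
gene_metabolite_corr <- function(expression, metabolite, cells = NULL,
                                 mode = c("instantaneous", "cumulative")) {
  mode <- match.arg(mode)
  if (!is.null(names(expression)) && !is.null(names(metabolite))) {
    if (!setequal(names(expression), names(metabolite)))
      stop("expression and metabolite profiles are on different cells")
    metabolite <- metabolite[names(expression)]
  } else if (length(expression) != length(metabolite)) {
    stop("misaligned profiles")
  }
  if (mode == "cumulative") {
    if (is.null(cells)) stop("cumulative mode requires cell metadata")
    idx <- match(names(expression), cells$cell)
    if (anyNA(idx)) stop("cells not described in cell metadata")
    series <- interaction(cells$region[idx], cells$year[idx], drop = TRUE)
    for (s in levels(series)) {
      j <- which(series == s)
      j <- j[order(cells$stage_index[idx][j])]
      expression[j] <- cumsum(expression[j])
    }
  }
  res <- pearson_test(as.numeric(expression), as.numeric(metabolite))
  data.frame(mode = mode, n = res$n, r = res$r, p = res$p)
}

#' Correlate many genes against many metabolites
#'
#' Applies [gene_metabolite_corr()] to every gene x compound pair of two
#' cell-aligned profile matrices.
#'
#' @param expr matrix, genes x cells.
#' @param metab matrix, compounds x cells (same columns).
#' @param cells cell metadata (for cumulative mode).
#' @param mode correlation mode, see [gene_metabolite_corr()].
#' @return data.frame with columns `gene`, `metabolite`, `mode`, `n`, `r`,
#'   `p`.
#' @export
correlate_all <- function(expr, metab, cells = NULL,
                          mode = c("instantaneous", "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(identical(colnames(expr), colnames(metab)))
  out <- do.call(rbind, lapply(rownames(expr), function(g) {
    do.call(rbind, lapply(rownames(metab), function(cm) {
      res <- suppressWarnings(
        gene_metabolite_corr(expr[g, ], metab[cm, ], cells, mode))
      cbind(data.frame(gene = g, metabolite = cm, stringsAsFactors = FALSE),
            res)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Nominate candidate genes from correlation and regional DE evidence
#'
#' A gene is nominated when (a) it has at least one supporting
#' gene-metabolite correlation with `|r| >= r_min` and `p <= alpha`, all
#' supporting correlations agreeing in sign, and (b) it is significantly
#' differentially expressed between the regions at one or more stages. The
#' rank score is `max|r| * (1 + n_supporting / 10)`; ties break on gene id.
#'
#' @param corr data.frame from [correlate_all()] (columns `gene`,
#'   `metabolite`, `r`, `p`).
#' @param deg data.frame from [call_degs()] (columns `id`, `comparison`,
#'   `significant`), with comparisons contrasting regions.
#' @param r_min minimum supporting |r| (default 0.8, matching the network
#'   threshold).
#' @param alpha maximum supporting raw correlation p (default 0.05).
#' @return data.frame of nominated genes sorted by decreasing `score`:
#'   `gene`, `max_abs_r`, `n_support`, `support_sign`, `supporting`
#'   (comma-separated metabolites), `n_deg_comparisons`, `score`.
#' @export
nominate_candidates <- function(corr, deg, r_min = 0.8, alpha = 0.05) {
  stopifnot(all(c("gene", "metabolite", "r", "p") %in% names(corr)),
            all(c("id", "significant") %in% names(deg)))
  if (nrow(corr) == 0 || nrow(deg) == 0)
    stop("empty correlation or DEG input")
  deg_genes <- table(deg$id[deg$significant])
  out <- do.call(rbind, lapply(split(corr, corr$gene), function(d) {
    sup <- d[!is.na(d$r) & abs(d$r) >= r_min & !is.na(d$p) & d$p <= alpha, ]
    if (nrow(sup) == 0) return(NULL)
    if (length(unique(sign(sup$r))) > 1) return(NULL)  # discordant signs
    g <- d$gene[1]
    ndeg <- if (g %in% names(deg_genes)) as.integer(deg_genes[[g]]) else 0L
    if (ndeg == 0) return(NULL)
    data.frame(gene = g, max_abs_r = max(abs(sup$r)), n_support = nrow(sup),
               support_sign = if (sup$r[1] > 0) "pos" else "neg",
               supporting = paste(sup$metabolite, collapse = ","),
               n_deg_comparisons = ndeg,
               score = max(abs(sup$r)) * (1 + nrow(sup) / 10),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(gene = character(), max_abs_r = numeric(),
                      n_support = integer(), support_sign = character(),
                      supporting = character(), n_deg_comparisons = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  out
}
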