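#' Filter raw reads by trimmed length and ambiguous bases
#'
#' Applies the read QC rule used before mapping: two nucleotides are trimmed
#' from both ends of each read (4 nt total), then reads shorter than 60 nt
#' after trimming or carrying more than two ambiguous nucleotides are
#' excluded.
#'
#' @param reads data.frame with columns `length` (raw read length, nt) and
#'   `ambiguous` (ambiguous-base count).
#' @param min_length minimum trimmed length kept (default 60).
#' @param max_ambiguous maximum ambiguous bases kept (default 2).
#' @param trim_each_end nucleotides trimmed from each end (default 2).
#' @return `reads` with added columns `trimmed_length` and `kept`.
#' @export
#' @examples
#' filter_reads(data.frame(length = c(64, 63, 100), ambiguous = c(0, 0, 3)))$kept
filter_reads <- function(reads, min_length = 60, max_ambiguous = 2,
                         trim_each_end = 2) {
  stopifnot(is.data.frame(reads), all(c("length", "ambiguous") %in% names(reads)))
  if (any(reads$length < 0)) stop("negative read length")
  reads$trimmed_length <- pmax(reads$length - 2 * trim_each_end, 0)
  reads$kept <- reads$trimmed_length >= min_length &
    reads$ambiguous <= max_ambiguous
  reads
}

#' Proportional multi-read rescue
#'
#' Distributes each multi-mapping read group over its candidate transcripts
#' in proportion to the unique reads already mapped to each candidate
#' (`U_t / sum(U)` within the group); when no candidate has unique reads the
#' group is split uniformly. Assigned counts are fractional.
#'
#' @param unique_counts named numeric vector of unique read counts per
#'   transcript.
#' @param groups list of groups, each `list(candidates =, multiplicity =)`,
#'   or a data.frame with columns `candidates` (comma-separated ids) and
#'   `multiplicity`.
#' @return named numeric vector of assigned counts
#'   `C_t = U_t + sum(shares)`; `sum(C)` equals `sum(U) + sum(multiplicity)`.
#' @export
#' @examples
#' assign_multireads(c(A = 30, B = 10),
#'                   list(list(candidates = c("A", "B"), multiplicity = 100)))
assign_multireads <- function(unique_counts, groups) {
  stopifnot(!is.null(names(unique_counts)), all(unique_counts >= 0))
  if (is.data.frame(groups))
    groups <- lapply(seq_len(nrow(groups)), function(i)
      list(candidates = strsplit(groups$candidates[i], ",", fixed = TRUE)[[1]],
           multiplicity = groups$multiplicity[i]))
  assigned <- unique_counts
  for (g in groups) {
    cand <- g$candidates
    if (length(cand) == 0) stop("empty candidate set")
    if (!all(cand %in% names(unique_counts)))
      stop("candidate not among transcripts: ",
           paste(setdiff(cand, names(unique_counts)), collapse = ", "))
    if (g$multiplicity < 0) stop("negative multiplicity")
    u <- unique_counts[cand]
    w <- if (sum(u) > 0) u / sum(u) else rep(1 / length(cand), length(cand))
    assigned[cand] <- assigned[cand] + g$multiplicity * w
  }
  assigned
}

#' RPKM expression values
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `1e9 * C / (N * L)` for assigned count `C`, transcript length `L` (nt)
#' and library total `N`.
#'
#' @param counts assigned counts (vector or transcripts x libraries matrix).
#' @param length_nt transcript lengths in nt (recycled along rows).
#' @param total_reads total mapped reads (recycled along columns).
#' @return RPKM values with the shape of `counts`.
#' @export
#' @examples
#' rpkm(1000, 2000, 1e6)  # 500
rpkm <- function(counts, length_nt, total_reads) {
  if (any(length_nt <= 0)) stop("transcript length must be > 0")
  if (any(total_reads <= 0)) stop("total mapped reads must be > 0")
  if (is.matrix(counts)) {
    stopifnot(length(length_nt) %in% c(1, nrow(counts)),
              length(total_reads) %in% c(1, ncol(counts)))
    1e9 * sweep(sweep(counts, 1, length_nt, "/"), 2, total_reads, "/")
  } else {
    1e9 * counts / (total_reads * length_nt)
  }
}

#' Exact test for differential digital expression between two libraries
#'
#' Replicate-free test for tag/read counts: conditional on the pooled count
#' `k = x + y`, under the null of equal relative abundance
#' `X | k ~ Binomial(k, N1 / (N1 + N2))`; the two-sided p-value doubles the
#' smaller tail (including the observed point), capped at 1. Counts of zero
#' are floored at one before testing and fold-change calculation (the
#' convention for transcripts undetected in one library), and fractional
#' rescued counts are rounded to the nearest integer (ties up).
#'
#' @param x,y counts in the two libraries (non-negative).
#' @param n1,n2 total mapped reads of the two libraries (positive).
#' @return named vector `c(log2_ratio =, p =)` where
#'   `log2_ratio = log2((x/n1)/(y/n2))`.
#' @export
#' @examples
#' deg_test(50, 1e6, 50, 1e6)   # ratio 0, p 1
#' deg_test(0, 1e6, 64, 1e6)    # ratio -6
deg_test <- function(x, n1, y, n2) {
  if (n1 <= 0 || n2 <= 0) stop("library totals must be positive")
  if (x < 0 || y < 0) stop("counts must be non-negative")
  x <- max(floor(x + 0.5), 1)
  y <- max(floor(y + 0.5), 1)
  k <- x + y
  p0 <- n1 / (n1 + n2)
  lower <- pbinom(x, k, p0)
  upper <- pbinom(x - 1, k, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  c(log2_ratio = log2((x / n1) / (y / n2)), p = p)
}

#' Call differentially expressed genes between conditions
#'
#' Runs [deg_test()] for every transcript in each requested pairwise
#' comparison, after summing replicate libraries within each condition
#' (configurable), applies Bonferroni adjustment over the transcripts tested
#' in the comparison, and flags significance at
#' `adjusted_p <= alpha & |log2_ratio| >= lfc`.
#'
#' @param counts assigned-count matrix, transcripts x libraries.
#' @param libraries data.frame describing columns of `counts`, with columns
#'   `library`, `total_reads`, and a `condition` column (or `cell`).
#' @param comparisons list of two-element character vectors
#'   `c(condition_a, condition_b)`; the ratio is a over b.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param lfc minimum absolute log2 ratio (default 1).
#' @param pool_replicates sum replicate libraries within a condition before
#'   testing (default TRUE); if FALSE each condition must have exactly one
#'   library.
#' @return data.frame with columns `id`, `comparison`, `log2_ratio`, `p`,
#'   `adjusted_p`, `significant`, sorted by `adjusted_p` then decreasing
#'   `|log2_ratio|` within each comparison.
#' @export
call_degs <- function(counts, libraries, comparisons, alpha = 0.05, lfc = 1,
                      pool_replicates = TRUE) {
  stopifnot(is.matrix(counts))
  cond <- if ("condition" %in% names(libraries)) libraries$condition
          else libraries$cell
  stopifnot(length(cond) == ncol(counts))
  res <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    if (!all(cmp %in% cond))
      stop("unknown condition label: ",
           paste(setdiff(cmp, cond), collapse = ", "))
    pick <- function(cl) {
      j <- which(cond == cl)
      if (!pool_replicates && length(j) > 1)
        stop("condition ", cl, " has replicates; set pool_replicates = TRUE")
      list(x = rowSums(counts[, j, drop = FALSE]),
           n = sum(libraries$total_reads[j]))
    }
    a <- pick(cmp[1]); b <- pick(cmp[2])
    m <- nrow(counts)
    tst <- t(vapply(seq_len(m),
                    function(i) deg_test(a$x[i], a$n, b$x[i], b$n),
                    c(log2_ratio = 0, p = 0)))
    out <- data.frame(id = rownames(counts),
                      comparison = paste(cmp[1], "vs", cmp[2]),
                      log2_ratio = tst[, "log2_ratio"], p = tst[, "p"],
                      adjusted_p = pmin(1, m * tst[, "p"]),
                      stringsAsFactors = FALSE)
    out$significant <- out$adjusted_p <= alpha & abs(out$log2_ratio) >= lfc
    out[order(out$adjusted_p, -abs(out$log2_ratio), out$id), ]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
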