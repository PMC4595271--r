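# Independent brute-force oracles kept deliberately naive so they cannot
# share bugs with the implementation.

# multi-read rescue: assign every read of every group one at a time
oracle_assign_multireads <- function(unique_counts, groups) {
  assigned <- unique_counts
  for (g in groups) {
    u <- unique_counts[g$candidates]
    w <- if (sum(u) > 0) u / sum(u) else rep(1 / length(u), length(u))
    for (read in seq_len(g$multiplicity)) {
      for (ci in seq_along(g$candidates)) {
        assigned[g$candidates[ci]] <- assigned[g$candidates[ci]] + w[ci]
      }
    }
  }
  assigned
}

# all cross pairs, double loop, textbook Pearson formula
oracle_all_pairs <- function(a, b, threshold, inclusive = TRUE) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    x <- a[i, ]; y <- b[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    keep <- if (inclusive) abs(r) >= threshold else abs(r) > threshold
    if (keep && rownames(a)[i] != rownames(b)[j]) {
      ids <- sort(c(rownames(a)[i], rownames(b)[j]))
      out <- rbind(out, data.frame(source = ids[1], target = ids[2], r = r,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame(source = character(),
                                      target = character(), r = numeric()))
  out <- out[!duplicated(out[, c("source", "target")]), ]
  out[order(out$source, out$target), ]
}

# Lloyd's algorithm from given centers, plain loops
oracle_lloyd <- function(m, centers, iter = 100) {
  for (it in seq_len(iter)) {
    lab <- apply(m, 1, function(row)
      which.min(colSums((t(centers) - row)^2)))
    new_centers <- centers
    for (k in seq_len(nrow(centers))) {
      if (any(lab == k))
        new_centers[k, ] <- colMeans(m[lab == k, , drop = FALSE])
    }
    if (all(abs(new_centers - centers) < 1e-12)) break
    centers <- new_centers
  }
  list(labels = lab, centers = centers)
}

# Duncan pairwise decisions: for sorted means, test every pair against its
# least significant range, then protect subranges of non-significant spans
oracle_duncan_pairs <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  mts <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(mts)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  nh <- k / sum(1 / table(groups)[names(mts)])
  sig <- matrix(FALSE, k, k, dimnames = list(names(mts), names(mts)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    span <- j - i + 1
    Rp <- stats::qtukey((1 - alpha)^(span - 1), span, dfe) * sqrt(mse / nh)
    sig[i, j] <- sig[j, i] <- (mts[i] - mts[j]) > Rp
  }
  # protection: a pair inside any non-significant span is non-significant
  for (span in seq(k, 2)) for (i in seq_len(k - span + 1)) {
    j <- i + span - 1
    if (!sig[i, j]) sig[i:j, i:j] <- FALSE
  }
  sig
}

# tiny deterministic profile pair with target correlation (log scale)
make_correlated_pair <- function(n = 16, rho = 0.9) {
  z <- as.numeric(scale(rnorm(n)))
  x <- 5 + 1.5 * z
  y <- 4 + 1.2 * (rho * z + sqrt(1 - rho^2) * rnorm(n))
  list(x = x, y = y)
}
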