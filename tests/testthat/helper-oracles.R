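# Independent oracles: literal, unoptimized transcriptions of the stated
# formulas, kept separate from the implementation paths they check.

# TMM factor for one sample vs the reference, written as a direct loop over
# the definition: M/A per co-expressed gene, two-sided trims on each, then
# an inverse-variance weighted mean of the surviving log-ratios.
oracle_tmm_factor <- function(m, k, ref, logratio_trim = 0.3,
                              abs_intensity_trim = 0.05, weighted = TRUE) {
  x <- m[, k]; r <- m[, ref]
  Nk <- sum(x); Nr <- sum(r)
  M <- c(); A <- c(); w <- c()
  for (g in seq_len(nrow(m))) {
    if (x[g] > 0 && r[g] > 0) {
      M <- c(M, log2(x[g] / r[g]))
      A <- c(A, 0.5 * log2(x[g] * r[g] / 1e12))
      w <- c(w, if (weighted)
        1 / ((1 - x[g] / Nk) / (1e6 * x[g] / Nk) +
             (1 - r[g] / Nr) / (1e6 * r[g] / Nr))
      else 1)
    }
  }
  n <- length(M)
  cutM <- floor(n * logratio_trim)
  cutA <- floor(n * abs_intensity_trim)
  keep <- rank(M) > cutM & rank(M) <= n - cutM &
          rank(A) > cutA & rank(A) <= n - cutA
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

oracle_tmm_factors <- function(m, ref, ...) {
  f <- vapply(colnames(m), function(k)
    if (k == ref) 1 else oracle_tmm_factor(m, k, ref, ...), numeric(1))
  f / exp(mean(log(f)))
}

# Exhaustive specificity checker: tests every candidate defining set of
# size <= 10, in the same precedence order as the classifier but without
# any greedy shortcut. Returns only the category.
oracle_specificity_category <- function(x, fold = 4, cutoff = 1,
                                        clamp = 0.01) {
  n <- length(x)
  for (g in seq_len(n)) {
    denom <- max(clamp, max(x[-g]))
    if (x[g] >= cutoff && x[g] >= fold * denom) return("enriched")
  }
  for (s in 2:min(10, n - 1)) {
    combs <- utils::combn(n, s)
    for (ci in seq_len(ncol(combs))) {
      S <- combs[, ci]
      if (all(x[S] >= cutoff) &&
          mean(x[S]) >= fold * max(clamp, max(x[-S]))) return("group-enriched")
    }
  }
  for (g in seq_len(n)) {
    mg <- max(clamp, mean(x[-g]))
    if (x[g] >= cutoff && x[g] >= fold * mg) return("enhanced")
  }
  if (any(x >= cutoff)) return("low-specificity")
  "not-detected"
}

# Direct running-sum enrichment score: walks every position of the ranked
# list, accumulating weighted hit increments and uniform miss decrements,
# and records the signed maximal deviation.
oracle_es <- function(stats_sorted, in_set, weight_exponent = 1) {
  n <- length(stats_sorted)
  m <- sum(in_set)
  hw <- abs(stats_sorted)^weight_exponent
  tot <- sum(hw[in_set])
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      running <- running + (if (tot > 0) hw[i] / tot else 1 / m)
    } else {
      running <- running - 1 / (n - m)
    }
    if (abs(running) > abs(best)) best <- running
    else if (abs(running) == abs(best) && running > best) best <- running
  }
  unname(best)
}

# Naive complete-linkage agglomeration on a distance matrix: at each step
# merge the pair of clusters with the smallest maximum inter-point
# distance. Returns the sorted merge heights.
oracle_complete_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Small random expression matrix with distinct positive values.
random_ptpm <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 3, sdlog = 1.5),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    sweep(m, 2, colSums(m) / 1e6, "/")
  })
}
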