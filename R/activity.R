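#' Validate a signature weight matrix
#'
#' Gene-by-signature numeric matrix; zero means the gene is not part of
#' the signature. Every signature needs at least three nonzero weights.
#'
#' @param w numeric matrix, genes in rows (named), signatures in columns
#'   (named).
#' @return `w`, invisibly validated.
#' @export
signature_matrix <- function(w) {
  if (!is.matrix(w) || !is.numeric(w)) stop("weights must be a numeric matrix")
  if (is.null(rownames(w)) || is.null(colnames(w)))
    stop("signature matrix needs gene row names and signature column names")
  if (anyDuplicated(rownames(w))) stop("duplicate gene IDs in signature matrix")
  nnz <- colSums(w != 0)
  if (any(nnz < 3L))
    stop("signature(s) with fewer than 3 nonzero weights: ",
         paste(colnames(w)[nnz < 3L], collapse = ", "))
  w
}

.shared_genes <- function(x, w) {
  genes <- intersect(rownames(x), rownames(w))
  if (length(genes) < 3L) stop("fewer than 3 genes shared with the signatures")
  genes
}

#' Univariate linear model activity scores
#'
#' For each signature and sample, the sample's centered-log expression is
#' regressed on the signature's weight vector (simple regression with
#' intercept); the activity score is the slope t-statistic. Signatures
#' sharing fewer than three genes with the expression matrix are skipped
#' with a message. Perfect fits are capped at a large finite t.
#'
#' @param x centered-log expression matrix (genes x samples).
#' @param w signature weight matrix (genes x signatures).
#' @return score matrix, signatures in rows, samples in columns.
#' @export
ulm_scores <- function(x, w) {
  genes <- .shared_genes(x, w)
  xs <- x[genes, , drop = FALSE]
  keep <- colSums(w[genes, , drop = FALSE] != 0) >= 3L
  if (any(!keep))
    message("signature(s) skipped (fewer than 3 shared genes): ",
            paste(colnames(w)[!keep], collapse = ", "))
  ws <- w[genes, keep, drop = FALSE]
  df <- length(genes) - 2L
  r <- suppressWarnings(stats::cor(ws, xs))    # signatures x samples
  r[!is.finite(r)] <- 0                        # constant column: no signal
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))
  dimnames(t) <- list(colnames(ws), colnames(xs))
  t
}

#' Multivariate linear model activity scores
#'
#' One regression per sample with all signature weight columns (plus
#' intercept) as covariates; scores are the per-covariate partial
#' t-statistics with `shared genes - signatures - 1` degrees of freedom.
#'
#' @inheritParams ulm_scores
#' @return score matrix, signatures in rows, samples in columns.
#' @export
mlm_scores <- function(x, w) {
  genes <- .shared_genes(x, w)
  xs <- x[genes, , drop = FALSE]
  ws <- w[genes, , drop = FALSE]
  S <- ncol(ws)
  if (length(genes) <= S + 1L)
    stop("need more shared genes than signatures plus one")
  X <- cbind(intercept = 1, ws)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dup <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient signature matrix; collinear column(s): ",
         paste(dup, collapse = ", "))
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  coef <- xtx_inv %*% crossprod(X, xs)          # (S+1) x samples
  res <- xs - X %*% coef
  df <- length(genes) - S - 1L
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  t <- coef / pmax(se, 1e-12)
  t <- t[-1L, , drop = FALSE]
  dimnames(t) <- list(colnames(ws), colnames(xs))
  t
}

#' Weighted-sum activity scores with a gene-permutation z
#'
#' The raw score is the weighted sum of the sample's expression over the
#' signature weights. A null is built by permuting the gene labels of the
#' expression column `n_perm` times (one shared permutation per iteration
#' across samples); the score is the z of the raw value against that
#' null.
#'
#' @inheritParams ulm_scores
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed integer seed.
#' @return score matrix (z-scores), signatures in rows, samples in
#'   columns.
#' @export
wsum_scores <- function(x, w, n_perm = 1000, seed = 1L) {
  genes <- .shared_genes(x, w)
  xs <- x[genes, , drop = FALSE]
  ws <- w[genes, , drop = FALSE]
  raw <- crossprod(ws, xs)                     # signatures x samples
  n <- length(genes)
  sum1 <- array(0, dim(raw)); sum2 <- array(0, dim(raw))
  withr::with_seed(seed, for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    nullr <- crossprod(ws, xs[p, , drop = FALSE])
    sum1 <- sum1 + nullr
    sum2 <- sum2 + nullr^2
  })
  mu <- sum1 / n_perm
  sd <- sqrt(pmax(sum2 / n_perm - mu^2, 0))
  z <- (raw - mu) / sd
  zero <- sd == 0
  if (any(zero)) {
    warning("zero null standard deviation; z set to 0 for ",
            sum(zero), " entr(ies)")
    z[zero] <- 0
  }
  dimnames(z) <- list(colnames(ws), colnames(xs))
  z
}

#' Consensus activity z-scores across methods
#'
#' Each method's score matrix is standardized per signature across
#' samples (mean 0, sd 1), and the consensus z is the unweighted mean of
#' the standardized scores. Entries with `|z| > 1` are flagged
#' significant. A method with zero variance for a signature is excluded
#' for that signature with a message.
#'
#' @param scores named list of at least two score matrices of identical
#'   shape (signatures x samples), e.g. from [ulm_scores()],
#'   [mlm_scores()], [wsum_scores()].
#' @param z_threshold significance threshold on `|z|` (default 1).
#' @return list of class `activity_table` with `z`, `significant`,
#'   `method = "consensus"`.
#' @export
consensus_scores <- function(scores, z_threshold = 1) {
  if (length(scores) < 2L) stop("need at least two methods")
  d <- dim(scores[[1L]])
  if (!all(vapply(scores, function(m) identical(dim(m), d), logical(1))))
    stop("all score matrices must have identical shape")
  std <- lapply(names(scores), function(nm) {
    m <- scores[[nm]]
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    flat <- sd == 0
    if (any(flat))
      message("method ", nm, " excluded (zero variance) for signature(s): ",
              paste(rownames(m)[flat], collapse = ", "))
    out <- (m - mu) / sd
    out[flat, ] <- NA_real_
    out
  })
  z <- Reduce(`+`, lapply(std, function(m) {
    m[is.na(m)] <- 0
    m
  })) / Reduce(`+`, lapply(std, function(m) 0 + !is.na(m)))
  structure(list(z = z, significant = abs(z) > z_threshold,
                 method = "consensus"), class = "activity_table")
}

#' Ridge-regression cytokine activity with permutation significance
#'
#' Per sample, a ridge-penalised multivariate fit of the centered-log
#' expression on all signature columns gives the observed coefficients; a
#' null is built from `n_perm` gene-label permutations. Scores are the z
#' of each coefficient against its null, with a two-sided permutation
#' p-value; entries with `p < p_threshold` are flagged significant.
#'
#' @inheritParams ulm_scores
#' @param ridge_lambda positive ridge penalty (default 1e4; rankings are
#'   stable over an order of magnitude around the default).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param p_threshold significance threshold (default 0.05).
#' @return list of class `activity_table` with `z`, `p_value`,
#'   `significant`, `method = "permutation"`.
#' @export
permutation_activity <- function(x, w, ridge_lambda = 1e4, n_perm = 10000,
                                 seed = 1L, p_threshold = 0.05) {
  if (ridge_lambda <= 0) stop("ridge_lambda must be positive")
  genes <- .shared_genes(x, w)
  xs <- x[genes, , drop = FALSE]
  ws <- w[genes, , drop = FALSE]
  S <- ncol(ws)
  H <- solve(crossprod(ws) + diag(ridge_lambda, S), t(ws))  # S x genes
  obs <- H %*% xs                                            # S x samples
  n <- length(genes)
  sum1 <- array(0, dim(obs)); sum2 <- array(0, dim(obs))
  exceed <- array(0L, dim(obs))
  withr::with_seed(seed, for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    nullc <- H %*% xs[p, , drop = FALSE]
    sum1 <- sum1 + nullc
    sum2 <- sum2 + nullc^2
    exceed <- exceed + (abs(nullc) >= abs(obs))
  })
  mu <- sum1 / n_perm
  sd <- sqrt(pmax(sum2 / n_perm - mu^2, 0))
  z <- (obs - mu) / ifelse(sd == 0, Inf, sd)
  pval <- (exceed + 1) / (n_perm + 1)
  pval[sd == 0] <- 1
  dimnames(z) <- dimnames(pval) <- list(colnames(ws), colnames(xs))
  structure(list(z = z, p_value = pval, significant = pval < p_threshold,
                 method = "permutation"), class = "activity_table")
}

#' Mean squared error between two activity tables
#'
#' MSE over shared signatures for every pair of samples (one from each
#' table); the workhorse of MSE-based cell-line-to-cohort matching.
#'
#' @param a,b `activity_table` objects (or plain z matrices, signatures x
#'   samples).
#' @return matrix of MSE values, samples of `a` in rows, samples of `b`
#'   in columns.
#' @export
activity_mse <- function(a, b) {
  za <- if (inherits(a, "activity_table")) a$z else a
  zb <- if (inherits(b, "activity_table")) b$z else b
  sigs <- intersect(rownames(za), rownames(zb))
  if (!length(sigs)) stop("no shared signatures")
  za <- za[sigs, , drop = FALSE]; zb <- zb[sigs, , drop = FALSE]
  S <- length(sigs)
  (matrix(colSums(za^2), ncol(za), ncol(zb)) +
   matrix(colSums(zb^2), ncol(za), ncol(zb), byrow = TRUE) -
   2 * crossprod(za, zb)) / S
}

#' Combine pathway- and cytokine-MSE rankings for one cohort
#'
#' Cell lines are ranked ascending by pathway MSE and by cytokine MSE
#' (average ranks on ties); the combined score is the mean rank, and the
#' final ordering breaks ties by lower pathway MSE, then ID. Lines
#' missing from either table are excluded with a message.
#'
#' @param pathway_mse,cytokine_mse named numeric vectors of per-line MSE
#'   to the cohort's activity profile.
#' @param top_k selection depth (default 5).
#' @return data frame with `cell_line_id`, both ranks, `combined_rank`,
#'   `final_rank`, `selected`.
#' @export
prioritize_by_mse <- function(pathway_mse, cytokine_mse, top_k = 5) {
  common <- intersect(names(pathway_mse), names(cytokine_mse))
  dropped <- setdiff(union(names(pathway_mse), names(cytokine_mse)), common)
  if (length(dropped))
    message("line(s) missing from one MSE table, excluded: ",
            paste(dropped, collapse = ", "))
  pm <- pathway_mse[common]; cm <- cytokine_mse[common]
  rec <- data.frame(cell_line_id = common,
                    rank_pathway = rank(pm, ties.method = "average"),
                    rank_cytokine = rank(cm, ties.method = "average"),
                    stringsAsFactors = FALSE)
  rec$combined_rank <- (rec$rank_pathway + rec$rank_cytokine) / 2
  ord <- .tie_break_order(rec$combined_rank, pm, rec$cell_line_id)
  rec <- rec[ord, , drop = FALSE]
  rec$final_rank <- seq_len(nrow(rec))
  kth <- rec$combined_rank[min(top_k, nrow(rec))]
  rec$selected <- rec$final_rank <= top_k | rec$combined_rank == kth
  rownames(rec) <- NULL
  rec
}
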