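#' Rescale TPM over protein-coding genes (pTPM)
#'
#' Restricts a TPM matrix to protein-coding genes and rescales every sample
#' so its coding expression sums to one million. pTPM is the unit on which
#' between-sample TMM scaling operates.
#'
#' @param tpm expression matrix in TPM unit.
#' @param coding_ids character vector of protein-coding gene IDs; must be a
#'   subset of `rownames(tpm)`. Defaults to all genes.
#' @return expression matrix in pTPM unit with rows restricted to
#'   `coding_ids`; every column sums to 1e6.
#' @examples
#' m <- expr_matrix(matrix(c(3e5, 1e5), 2, 1,
#'        dimnames = list(c("a", "b"), "s1")), unit = "TPM")
#' to_ptpm(m)
#' @export
to_ptpm <- function(tpm, coding_ids = rownames(tpm)) {
  .check_unit(tpm, "TPM", "to_ptpm")
  if (!all(coding_ids %in% rownames(tpm)))
    stop("coding_ids contains genes absent from the matrix")
  m <- tpm[coding_ids, , drop = FALSE]
  cs <- colSums(m)
  bad <- cs <= 0
  if (any(bad))
    stop("sample(s) with all-zero coding expression: ",
         paste(colnames(m)[bad], collapse = ", "))
  out <- sweep(m, 2L, cs / 1e6, "/")
  expr_matrix(out, unit = "pTPM")
}

#' TMM tuning parameters
#'
#' @param logratio_trim two-sided trim fraction on the log-ratios M
#'   (default 0.3, the value used throughout this pipeline).
#' @param abs_intensity_trim two-sided trim fraction on the average log
#'   intensities A (default 0.05).
#' @param do_weighting use inverse asymptotic-variance (delta-method
#'   binomial) weights for the trimmed mean (default `TRUE`).
#' @return a list of class `tmm_params`.
#' @export
tmm_params <- function(logratio_trim = 0.3, abs_intensity_trim = 0.05,
                       do_weighting = TRUE) {
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abs_intensity_trim < 0 || abs_intensity_trim >= 0.5)
    stop("trim fractions must lie in [0, 0.5)")
  structure(list(logratio_trim = logratio_trim,
                 abs_intensity_trim = abs_intensity_trim,
                 do_weighting = isTRUE(do_weighting)),
            class = "tmm_params")
}

#' Choose the median reference column for TMM
#'
#' Returns the sample whose upper-quartile expression (over genes with
#' positive expression in that sample) is the median of those statistics
#' across samples. With an even number of samples the sample closest to the
#' median is taken; ties go to the lexicographically smallest sample ID.
#'
#' @param m pTPM expression matrix.
#' @return a sample ID.
#' @export
select_tmm_reference <- function(m) {
  if (ncol(m) < 1L) stop("need at least one sample")
  uq <- apply(m, 2L, function(x) {
    x <- x[x > 0]
    if (!length(x)) return(0)
    stats::quantile(x, 0.75, names = FALSE)
  })
  med <- stats::median(uq)
  d <- abs(uq - med)
  cand <- colnames(m)[d == min(d)]
  sort(cand)[1L]
}

#' Trimmed mean of M-values scaling factors
#'
#' For each sample k against the reference r, over genes with positive
#' expression in both, compute M_g = log2(x_gk / x_gr) and
#' A_g = 0.5 * log2(x_gk * x_gr / 1e12). The most extreme `logratio_trim`
#' fraction of M on each side and `abs_intensity_trim` fraction of A on each
#' side are discarded; the factor is 2 to the power of the weighted mean of
#' the surviving M values, where the weights are the inverse delta-method
#' binomial variances (pseudo-library size 1e6, matching the pTPM column
#' sum) when `do_weighting` is on, uniform otherwise. All factors are
#' finally divided by their geometric mean so they multiply to one. The
#' delta-method weights are computed from each gene's within-sample
#' proportion at the nominal depth of 1e6 (identical to the classic count
#' formulation on pTPM input), which makes them invariant to per-sample
#' rescaling, so recomputing factors on the scaled output returns exactly
#' one (TMM fixed point).
#'
#' If fewer than 10 genes survive the trims for a sample, the trims are
#' dropped for that sample with a warning; a sample sharing no positive
#' gene with the reference is an error.
#'
#' @param m pTPM expression matrix (nTPM also accepted, e.g. for fixed-point
#'   checks).
#' @param ref reference sample ID, usually [select_tmm_reference()].
#' @param params a [tmm_params()] list.
#' @return named vector of positive per-sample scaling factors with
#'   geometric mean one.
#' @export
tmm_factors <- function(m, ref = select_tmm_reference(m), params = tmm_params()) {
  .check_unit(m, c("pTPM", "nTPM"), "tmm_factors")
  if (!ref %in% colnames(m)) stop("reference sample not in matrix")
  r <- m[, ref]
  libs <- colSums(m)
  Nr <- libs[ref]
  f <- vapply(colnames(m), function(k) {
    if (k == ref) return(1)
    x <- m[, k]
    Nk <- libs[k]
    keep <- x > 0 & r > 0
    if (!any(keep))
      stop("sample ", k, " shares no positively expressed gene with the reference")
    xk <- x[keep]; xr <- r[keep]
    M <- log2(xk / xr)
    A <- 0.5 * log2(xk * xr / 1e12)
    n <- length(M)
    loM <- floor(n * params$logratio_trim) + 1L
    hiM <- n - floor(n * params$logratio_trim)
    loA <- floor(n * params$abs_intensity_trim) + 1L
    hiA <- n - floor(n * params$abs_intensity_trim)
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(sel) < 10L) {
      warning("sample ", k, ": fewer than 10 genes survive the TMM trims; ",
              "using all co-expressed genes")
      sel <- rep(TRUE, n)
    }
    pk <- xk / Nk; pr <- xr / Nr
    w <- if (params$do_weighting)
      1 / ((1 - pk) / (1e6 * pk) + (1 - pr) / (1e6 * pr))
    else rep(1, n)
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Apply TMM factors to obtain nTPM
#'
#' Divides every sample column by its scaling factor. The result is the
#' nTPM unit used by all downstream classification and comparison steps.
#'
#' @param m pTPM expression matrix.
#' @param factors positive per-sample factors, one per column (named or in
#'   column order), as returned by [tmm_factors()].
#' @return expression matrix in nTPM unit.
#' @export
apply_tmm <- function(m, factors) {
  if (length(factors) != ncol(m))
    stop("need one factor per sample")
  if (any(factors <= 0)) stop("scaling factors must be positive")
  if (!is.null(names(factors))) factors <- factors[colnames(m)]
  out <- sweep(m, 2L, factors, "/")
  expr_matrix(unname_attr(out), unit = "nTPM")
}

# strip a stale unit attribute before re-declaring
unname_attr <- function(m) {
  attr(m, "unit") <- NULL
  m
}

#' Median-of-ratios size factors for count matrices
#'
#' Per gene, the geometric mean across samples is taken over genes positive
#' in every sample; each sample's factor is the median of its count-to-
#' geometric-mean ratios. Factors are not rescaled further. This is the
#' size-factor convention used for the activity-scoring branch of the
#' pipeline, where counts are variance-stabilised rather than TMM-scaled.
#'
#' @param counts expression matrix of counts.
#' @return named vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  .check_unit(counts, "counts", "size_factors_median_of_ratios")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene is positive in all samples; size factors undefined")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(x) stats::median(x / geo))
}

#' Size-factor-normalised, log-transformed, gene-centered expression
#'
#' Computes log2(count / factor + 1), then subtracts each gene's row mean
#' so every row sums to zero. This centered log space is the input
#' expected by the activity-inference methods ([ulm_scores()] and
#' friends); the log2(x + 1) transform stands in for a variance-stabilising
#' transform and is documented as such an approximation.
#'
#' @param counts expression matrix of counts.
#' @param factors positive per-sample size factors.
#' @return expression matrix in centered-log unit; rows sum to zero.
#' @export
log_center <- function(counts, factors = size_factors_median_of_ratios(counts)) {
  if (any(factors <= 0)) stop("size factors must be positive")
  if (!is.null(names(factors))) factors <- factors[colnames(counts)]
  lg <- log2(sweep(counts, 2L, factors, "/") + 1)
  out <- lg - rowMeans(lg)
  expr_matrix(unname_attr(out), unit = "centered-log")
}

#' One-call nTPM normalization
#'
#' Convenience wrapper chaining [to_ptpm()], [select_tmm_reference()],
#' [tmm_factors()] and [apply_tmm()].
#'
#' @inheritParams to_ptpm
#' @inheritParams tmm_factors
#' @return expression matrix in nTPM unit.
#' @export
normalize_ntpm <- function(tpm, coding_ids = rownames(tpm), params = tmm_params()) {
  p <- to_ptpm(tpm, coding_ids)
  f <- tmm_factors(p, select_tmm_reference(p), params)
  apply_tmm(p, f)
}
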