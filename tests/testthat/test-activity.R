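# small orthogonal signature world for exact linear-model checks
ortho_world <- function() {
  genes <- paste0("g", 1:8)
  w <- matrix(0, 8, 2, dimnames = list(genes, c("sA", "sB")))
  w[1:4, "sA"] <- c(1, -1, 1, -1)
  w[5:8, "sB"] <- c(2, -2, 2, -2)
  w
}

test_that("ulm scores are slope t-statistics with symmetric sign", {
  w <- ortho_world()
  # x proportional to a signature: strongly positive, capped not infinite
  x <- expr_matrix(cbind(s1 = 3 * w[, "sA"]), unit = "centered-log")
  t1 <- ulm_scores(x, w)
  expect_gt(t1["sA", "s1"], 1e3)
  expect_true(is.finite(t1["sA", "s1"]))
  # orthogonal signature scores zero
  expect_lt(abs(t1["sB", "s1"]), 1e-6)
  # negated expression flips the sign with equal magnitude
  xneg <- expr_matrix(cbind(s1 = -3 * w[, "sA"]), unit = "centered-log")
  t2 <- ulm_scores(xneg, w)
  expect_equal(t2["sA", "s1"], -t1["sA", "s1"], tolerance = 1e-8)
  # a signature sharing < 3 genes is skipped with a message
  w3 <- rbind(w, g9 = c(0, 0))
  w3 <- cbind(w3, tiny = c(rep(0, 8), 1))
  w3["g1", "tiny"] <- 1
  w3["g2", "tiny"] <- 1
  expect_message(t3 <- ulm_scores(x, w3), "tiny")
  expect_false("tiny" %in% rownames(t3))
})

test_that("mlm equals ulm for a single signature and flags collinearity", {
  withr::with_seed(14, {
    genes <- paste0("g", 1:40)
    w1 <- matrix(stats::rnorm(40), 40, 1, dimnames = list(genes, "solo"))
    x <- expr_matrix(matrix(stats::rnorm(40 * 6), 40, 6,
                            dimnames = list(genes, paste0("s", 1:6))),
                     unit = "centered-log")
    expect_equal(mlm_scores(x, w1), ulm_scores(x, w1), tolerance = 1e-9)

    # orthogonal signatures, no noise: signs match planted activities
    w <- ortho_world()
    act <- matrix(c(2, -3, -1, 2), 2, 2,
                  dimnames = list(c("sA", "sB"), c("p", "q")))
    x2 <- expr_matrix(w %*% act, unit = "centered-log")
    t <- mlm_scores(x2, w)
    expect_identical(sign(t), sign(act))

    # duplicated signature column errors with the culprit named
    wd <- cbind(w, dup = w[, "sA"])
    expect_error(mlm_scores(x, wd[genes[1:8], , drop = FALSE]),
                 "collinear")
  })
})

test_that("wsum z is permutation-based and scale invariant", {
  w <- matrix(c(1, 1, -1), 3, 1,
              dimnames = list(paste0("g", 1:3), "sig"))
  x <- expr_matrix(matrix(c(2, 2, 2), 3, 1,
                          dimnames = list(paste0("g", 1:3), "s1")),
                   unit = "centered-log")
  # raw weighted sum is 2 (permutation-invariant input gives z = 0)
  expect_warning(z <- wsum_scores(x, w, n_perm = 200, seed = 1),
                 "zero null")
  expect_equal(unname(z["sig", "s1"]), 0)

  withr::with_seed(3, {
    genes <- paste0("g", 1:60)
    wr <- matrix(0, 60, 1, dimnames = list(genes, "sig"))
    wr[1:15, 1] <- stats::rnorm(15, 1, 0.2)
    xr <- expr_matrix(matrix(stats::rnorm(60 * 4), 60, 4,
                             dimnames = list(genes, paste0("s", 1:4))),
                      unit = "centered-log")
    z1 <- wsum_scores(xr, wr, n_perm = 500, seed = 7)
    # doubling the weights doubles the raw score but not the z
    z2 <- wsum_scores(xr, 2 * wr, n_perm = 500, seed = 7)
    expect_equal(z1, z2, tolerance = 1e-9)
    # exchangeable expression: z is centered at zero on average (each
    # individual z is a standard-normal-scale draw under the null)
    xm <- expr_matrix(matrix(stats::rnorm(60 * 200), 60, 200,
                             dimnames = list(genes, paste0("m", 1:200))),
                      unit = "centered-log")
    zz <- wsum_scores(xm, wr, n_perm = 1000, seed = 11)
    expect_lt(abs(mean(zz)), 0.2)
    expect_lt(abs(mean(abs(zz)) - sqrt(2 / pi)), 0.2)  # half-normal mean
  })
})

test_that("consensus standardizes per signature and flags |z| > 1", {
  withr::with_seed(25, {
    sw <- generate_signature_matrix(n_genes = 250, n_signatures = 5,
                                    genes_per_signature = 30, seed = 25,
                                    n_samples = 40, noise_sd = 0.1)
    x <- sw$expression
    w <- sw$weights
    scores <- list(ulm = ulm_scores(x, w), mlm = mlm_scores(x, w),
                   wsum = wsum_scores(x, w, n_perm = 300, seed = 2))
    cons <- consensus_scores(scores)
    # bookkeeping: significance is exactly the |z| > 1 count
    expect_identical(sum(cons$significant), sum(abs(cons$z) > 1))
    expect_identical(dim(cons$z), dim(scores$ulm))

    # per-method standardized scores have mean 0 / sd 1 per signature
    std <- (scores$ulm - rowMeans(scores$ulm)) /
      apply(scores$ulm, 1, stats::sd)
    expect_lt(max(abs(rowMeans(std))), 1e-9)
    expect_equal(unname(apply(std, 1, stats::sd)), rep(1, 5),
                 tolerance = 1e-9)

    # identical methods: consensus equals the common standardized score
    cons2 <- consensus_scores(list(a = scores$ulm, b = scores$ulm))
    expect_equal(cons2$z, std, tolerance = 1e-9)

    # planted activities recovered: r > 0.9 per signature
    r <- vapply(colnames(w), function(s)
      stats::cor(sw$activities[, s], cons$z[s, ]), numeric(1))
    expect_true(all(r > 0.9))

    expect_error(consensus_scores(scores["ulm"]), "two methods")
  })
})

test_that("ridge permutation activity finds the planted cytokine", {
  withr::with_seed(36, {
    sw <- generate_signature_matrix(n_genes = 200, n_signatures = 4,
                                    genes_per_signature = 25, seed = 36,
                                    n_samples = 1, noise_sd = 0)
    # make one sample with a single strongly active signature
    w <- sw$weights
    act <- c(3, 0, 0, 0)
    x <- expr_matrix(w %*% matrix(act, 4, 1,
                                  dimnames = list(colnames(w), "s1")),
                     unit = "centered-log")
    res <- permutation_activity(x, w, ridge_lambda = 1, n_perm = 2000,
                                seed = 5)
    expect_identical(names(which.max(res$z[, "s1"])), colnames(w)[1])
    expect_lt(res$p_value[1, "s1"], 0.05)
    expect_true(res$significant[1, "s1"])

    # all-zero expression: z = 0, p = 1
    x0 <- expr_matrix(matrix(0, 200, 1,
                             dimnames = list(rownames(w), "s0")),
                      unit = "centered-log")
    res0 <- permutation_activity(x0, w, ridge_lambda = 1, n_perm = 200,
                                 seed = 5)
    expect_true(all(res0$z == 0))
    expect_true(all(res0$p_value == 1))

    expect_error(permutation_activity(x, w, ridge_lambda = 0), "positive")

    # rankings are stable across an order of magnitude of ridge penalty
    sw2 <- generate_signature_matrix(n_genes = 200, n_signatures = 4,
                                     genes_per_signature = 25, seed = 37,
                                     n_samples = 6, noise_sd = 0.2)
    rA <- permutation_activity(sw2$expression, sw2$weights,
                               ridge_lambda = 10, n_perm = 300, seed = 9)
    rB <- permutation_activity(sw2$expression, sw2$weights,
                               ridge_lambda = 100, n_perm = 300, seed = 9)
    expect_gt(stats::cor(as.vector(rA$z), as.vector(rB$z),
                         method = "spearman"), 0.9)
    # the strongest signature per sample is unchanged
    expect_identical(apply(rA$z, 2, which.max), apply(rB$z, 2, which.max))
  })
})

test_that("activity MSE matching separates replicate pairs", {
  a <- matrix(c(1, 2, 3, 0, -1, 1), 3, 2,
              dimnames = list(paste0("sig", 1:3), c("x", "y")))
  # identical vectors: MSE 0; constant offset c: MSE c^2
  mse <- activity_mse(a, a + 2)
  expect_equal(unname(diag(mse)), c(4, 4))
  expect_equal(unname(activity_mse(a, a)["x", "x"]), 0)
  expect_error(activity_mse(a, matrix(1, 1, 1,
                                      dimnames = list("other", "z"))),
               "shared signatures")

  # replicate panels: same planted activities, fresh noise. Common pairs
  # must be closer than non-common pairs (rank-sum p < 0.05)
  sw1 <- generate_signature_matrix(n_genes = 250, n_signatures = 6,
                                   genes_per_signature = 30, seed = 50,
                                   n_samples = 25, noise_sd = 0.3)
  noise <- withr::with_seed(99,
    matrix(stats::rnorm(250 * 25, 0, 0.3), 250, 25))
  x2 <- expr_matrix(sw1$weights %*% t(sw1$activities) + noise,
                    unit = "centered-log")
  dimnames(x2) <- dimnames(sw1$expression)
  w <- sw1$weights
  z1 <- consensus_scores(list(ulm = ulm_scores(sw1$expression, w),
                              mlm = mlm_scores(sw1$expression, w)))$z
  z2 <- consensus_scores(list(ulm = ulm_scores(x2, w),
                              mlm = mlm_scores(x2, w)))$z
  colnames(z2) <- colnames(z1)
  mse2 <- activity_mse(z1, z2)
  common <- diag(mse2)
  noncommon <- mse2[row(mse2) != col(mse2)]
  p <- stats::wilcox.test(common, noncommon, alternative = "less",
                          exact = FALSE)$p.value
  expect_lt(p, 0.05)
})

test_that("MSE-based rank combination mirrors the two-metric integration", {
  pm <- c(a = 0.1, b = 0.5, c = 0.3)
  cm <- c(a = 0.2, b = 0.1, c = 0.4)
  # pathway ranks 1,3,2; cytokine ranks 2,1,3 -> combined 1.5, 2.0, 2.5
  out <- prioritize_by_mse(pm, cm)
  expect_identical(out$cell_line_id, c("a", "b", "c"))
  expect_equal(out$combined_rank, c(1.5, 2.0, 2.5))
  # minimum in both tables wins outright
  pm2 <- c(a = 0.1, b = 0.5); cm2 <- c(a = 0.1, b = 0.3)
  expect_identical(prioritize_by_mse(pm2, cm2)$cell_line_id[1], "a")
  # lines missing from either table are excluded with a message
  expect_message(out3 <- prioritize_by_mse(c(a = 1, b = 2), c(a = 1, z = 3)),
                 "excluded")
  expect_identical(out3$cell_line_id, "a")
})
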