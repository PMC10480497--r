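test_that("cohort mean and disease baseline follow their averaging rules", {
  m <- expr_matrix(matrix(c(1, 5, 3, 9), 2, 2,
                          dimnames = list(c("g1", "g2"), c("t1", "t2"))),
                   unit = "nTPM")
  expect_equal(cohort_mean_profile(m), c(g1 = 2, g2 = 7))
  one <- m[, 1, drop = FALSE]
  expect_equal(cohort_mean_profile(one), m[, 1])

  # disease baseline averages CLD means, not cell lines: with unequal
  # disease sizes (3 lines of A at 0, 1 line of B at 12) the grand mean
  # over lines would be 3, the baseline over CLD means is 6
  clds <- expr_matrix(matrix(c(0, 12), 1, 2,
                             dimnames = list("g", c("A", "B"))),
                      unit = "nTPM")
  expect_equal(unname(disease_baseline(clds)), 6)       # (0 + 12) / 2
  expect_error(disease_baseline(clds[, 1, drop = FALSE]), "two CLD")
})

test_that("correlation metric is rank-invariant with a gene floor", {
  withr::with_seed(21, {
    genes <- sprintf("g%03d", 1:150)
    cm <- setNames(stats::rlnorm(150, 2, 1), genes)
    lines <- matrix(c(cm, cm^2, rev(cm)), 150, 3,
                    dimnames = list(genes, c("same", "mono", "rev")))
    rho <- correlation_metric(lines, cm, min_genes = 100)
    expect_equal(unname(rho["same"]), 1)
    expect_equal(unname(rho["mono"]), 1)   # strictly monotone transform
    expect_error(correlation_metric(lines[1:50, ], cm[1:50]), "floor")
  })
})

test_that("ranked fold changes use the pseudocount and deterministic ties", {
  base <- c(gA = 3, gB = 0, gC = 7)
  line <- c(gA = 7, gB = 0, gC = 7)
  s <- ranked_fold_changes(line, base)
  expect_equal(unname(s["gA"]), 1)          # log2(8/4)
  expect_equal(unname(s["gB"]), 0)          # 0/0 guarded by pseudocount
  expect_identical(names(s), c("gA", "gB", "gC"))  # tie 0,0 broken by ID
  # identical vectors: all statistics zero
  expect_true(all(ranked_fold_changes(base, base) == 0))
  expect_error(ranked_fold_changes(line[1:2], base), "same genes")
})

test_that("preranked ES matches the direct running-sum oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- 200
      stats_v <- sort(stats::rnorm(n, 0, 2), decreasing = TRUE)
      names(stats_v) <- sprintf("g%03d", sample.int(n))
      m <- sample(5:40, 1)
      set <- sample(names(stats_v), m)
      r <- gsea_preranked(stats_v, set,
                          gsea_params(n_permutations = 100, seed = i))
      ord <- order(-stats_v, names(stats_v), method = "radix")
      es_oracle <- oracle_es(stats_v[ord], names(stats_v)[ord] %in% set)
      expect_equal(r$es, es_oracle, tolerance = 1e-12)
      expect_true(r$es >= -1 && r$es <= 1)
    }
  })
})

test_that("preranked ES agrees with fgsea's statistic", {
  withr::with_seed(32, {
    n <- 300
    stats_v <- sort(stats::rnorm(n, 0.2, 1.5), decreasing = TRUE)
    names(stats_v) <- sprintf("g%03d", seq_len(n))
    for (m in c(5, 25, 80)) {
      set <- sample(names(stats_v), m)
      r <- gsea_preranked(stats_v, set,
                          gsea_params(n_permutations = 100, seed = m))
      es_fgsea <- fgsea::calcGseaStat(stats_v,
                                      which(names(stats_v) %in% set))
      expect_equal(r$es, es_fgsea, tolerance = 1e-10)
    }
  })
})

test_that("single top-ranked hit gives ES 1 and reversal flips the sign", {
  stats_v <- setNames(seq(5, 0.1, length.out = 50), sprintf("g%02d", 1:50))
  r <- gsea_preranked(stats_v, "g01", gsea_params(n_permutations = 100))
  expect_equal(r$es, 1)
  # reversing the ranking sends a top-concentrated set to the bottom
  top_set <- sprintf("g%02d", 1:5)
  fwd <- gsea_preranked(stats_v, top_set, gsea_params(n_permutations = 100))
  rev_stats <- setNames(-stats_v, names(stats_v))
  bwd <- gsea_preranked(rev_stats, top_set, gsea_params(n_permutations = 100))
  expect_gt(fwd$es, 0)
  expect_lt(bwd$es, 0)
  expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)  # symmetric statistics
  expect_error(gsea_preranked(stats_v, character(0)), "at least one")
  expect_error(gsea_preranked(stats_v, names(stats_v)), "fewer than all")
})

test_that("random gene sets give near-uniform GSEA p-values", {
  withr::with_seed(41, {
    n <- 200
    stats_v <- sort(stats::rnorm(n), decreasing = TRUE)
    names(stats_v) <- sprintf("g%03d", seq_len(n))
    ps <- vapply(1:60, function(i) {
      set <- sample(names(stats_v), 15)
      gsea_preranked(stats_v, set,
                     gsea_params(n_permutations = 500, seed = i))$p_value
    }, numeric(1))
    expect_gt(mean(ps), 0.35)
    expect_lt(mean(ps), 0.65)
    expect_gt(min(ps), 0.001)
  })
})

test_that("rank integration averages ranks with the documented tie chain", {
  rec <- data.frame(cell_line_id = c("a", "b", "c"),
                    rho = c(0.9, 0.8, 0.7),
                    nes = c(1.2, 2.0, 1.5))
  # corr ranks 1,2,3; gsea ranks 3,1,2 -> combined 2.0, 1.5, 2.5
  out <- integrate_ranks(rec)
  expect_identical(out$cell_line_id, c("b", "a", "c"))
  expect_equal(out$combined_rank, c(1.5, 2.0, 2.5))

  # a line ranked 1 on both is final rank 1
  rec2 <- data.frame(cell_line_id = c("x", "y"), rho = c(0.9, 0.5),
                     nes = c(2, 1))
  expect_identical(integrate_ranks(rec2)$cell_line_id[1], "x")

  # monotone transforms of the metrics leave the ordering unchanged
  rec3 <- rec
  rec3$rho <- rec$rho^3
  rec3$nes <- exp(rec$nes)
  expect_identical(integrate_ranks(rec3)$cell_line_id,
                   out$cell_line_id)

  # ties with the 5th combined value are all selected
  rec4 <- data.frame(cell_line_id = letters[1:7],
                     rho = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.5, 0.3),
                     nes = c(7, 6, 5, 4, 3, 3, 1))
  out4 <- integrate_ranks(rec4)
  expect_identical(sum(out4$selected), 6L)  # e and f tie at rank 5

  expect_error(integrate_ranks(data.frame(cell_line_id = "a", rho = 1,
                                          nes = NA_real_)), "both metrics")
})

test_that("the planted best line is prioritized first for its cohort", {
  cfg <- panel_config(seed = 55)
  p <- generate_panel(cfg)
  co <- generate_cohorts(cfg, p$truth)
  ntpm <- normalize_ntpm(p$tpm)
  cntpm <- normalize_ntpm(co$tpm)
  clds <- aggregate_cld(ntpm, p$annotation)
  cmeans <- aggregate_cld(cntpm,
    data.frame(sample_id = co$annotation$sample_id,
               disease = co$annotation$cohort))
  ccalls <- classify_genes(cmeans)
  base <- disease_baseline(clds)
  hits <- vapply(colnames(cmeans), function(coid) {
    d <- names(co$truth$disease_cohort)[co$truth$disease_cohort == coid]
    lines <- ntpm[, p$annotation$sample_id[p$annotation$disease == d],
                  drop = FALSE]
    pr <- prioritize_lines(lines,
      cohort_mean_profile(cntpm[, co$annotation$sample_id[
        co$annotation$cohort == coid], drop = FALSE]),
      elevated_set(ccalls, coid), base,
      params = gsea_params(seed = 5), min_genes = 100)
    pr$cell_line_id[pr$final_rank == 1] == co$truth$cohort_best_line[coid]
  }, logical(1))
  expect_true(all(hits))
})

test_that("correlation- and GSEA-based ranks agree in direction", {
  # graded line perturbation and no stage planting: fidelity differences
  # between lines are one-dimensional, so the two metrics should order
  # the lines concordantly
  cfg <- panel_config(seed = 19, stage_genes_per_disease = 0)
  p <- generate_panel(cfg)
  co <- generate_cohorts(cfg, p$truth)
  ntpm <- normalize_ntpm(p$tpm)
  cntpm <- normalize_ntpm(co$tpm)
  clds <- aggregate_cld(ntpm, p$annotation)
  cmeans <- aggregate_cld(cntpm,
    data.frame(sample_id = co$annotation$sample_id,
               disease = co$annotation$cohort))
  ccalls <- classify_genes(cmeans)
  base <- disease_baseline(clds)
  pooled <- do.call(rbind, lapply(colnames(cmeans), function(coid) {
    d <- names(co$truth$disease_cohort)[co$truth$disease_cohort == coid]
    lines <- ntpm[, p$annotation$sample_id[p$annotation$disease == d],
                  drop = FALSE]
    prioritize_lines(lines,
      cohort_mean_profile(cntpm[, co$annotation$sample_id[
        co$annotation$cohort == coid], drop = FALSE]),
      elevated_set(ccalls, coid), base,
      params = gsea_params(seed = 5), min_genes = 100)
  }))
  expect_gt(cor(pooled$rank_corr, pooled$rank_gsea, method = "spearman"), 0)
})

test_that("stage-level prioritization recovers the planted stage line", {
  cfg <- panel_config(seed = 77)
  p <- generate_panel(cfg)
  co <- generate_cohorts(cfg, p$truth, n_stages = 3)
  ntpm <- normalize_ntpm(p$tpm)
  cntpm <- normalize_ntpm(co$tpm)
  clds <- aggregate_cld(ntpm, p$annotation)
  base <- disease_baseline(clds)
  d <- names(co$truth$disease_cohort)[1]
  coid <- co$truth$disease_cohort[[1]]
  sel <- co$annotation$cohort == coid
  cohort <- cntpm[, co$annotation$sample_id[sel], drop = FALSE]
  labels <- setNames(co$annotation$stage[sel], co$annotation$sample_id[sel])
  lines <- ntpm[, p$annotation$sample_id[p$annotation$disease == d],
                drop = FALSE]
  # only stage 2 carries a planted signature: the other stages take the
  # documented correlation-only fallback (each with its own warning)
  res <- suppressWarnings(
    prioritize_stage_or_subtype(lines, cohort, labels, base,
                                params = gsea_params(seed = 3)))
  expect_identical(sort(names(res)), sort(unique(co$annotation$stage[sel])))
  planted_stage <- co$truth$stage[[coid]]$stage
  expect_false(anyNA(res[[planted_stage]]$nes))   # full two-metric ranking
  expect_true(all(is.na(res[["stage1"]]$nes)))    # fallback path
  # the designated stage-matching line leads the planted stage's ranking
  planted <- co$truth$stage[[coid]]$line
  expect_identical(res[[planted_stage]]$cell_line_id[
    res[[planted_stage]]$final_rank == 1], planted)

  # identical stage means: empty signatures fall back with a warning
  flat <- cohort[, 1:2, drop = FALSE]
  flat[, 2] <- flat[, 1]
  colnames(flat) <- c("fa", "fb")
  w <- capture_warnings(
    res2 <- prioritize_stage_or_subtype(lines, flat, c("s1", "s2"), base,
                                        params = gsea_params(seed = 3)))
  expect_true(all(grepl("empty signature", w)))
  expect_length(w, 2)  # both identical stages fall back
  expect_true(all(vapply(res2, function(r) is.na(r$nes[1]), logical(1))))
})
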