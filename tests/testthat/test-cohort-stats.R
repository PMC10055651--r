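test_that("association chi-square equals the textbook arithmetic", {
  # arithmetic oracle: sum((O - E)^2 / E) with E from the margins
  obs <- matrix(c(20, 10, 10, 40), nrow = 2, byrow = TRUE)
  status <- rep(c("LOI", "ROI"), times = rowSums(obs))
  germ <- c(rep(c(TRUE, FALSE), obs[1, ]), rep(c(TRUE, FALSE), obs[2, ]))
  res <- association_test(status, germ)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(res$chi_square, sum((obs - expected)^2 / expected))
  expect_equal(res$df, 1)

  # perfectly independent table: statistic 0, p = 1
  status2 <- rep(c("A", "B"), each = 20)
  germ2 <- rep(c(TRUE, FALSE), times = 20)
  res2 <- association_test(status2, germ2)
  expect_equal(res2$chi_square, 0)
  expect_equal(res2$p_value, 1)

  expect_error(association_test(factor(c("A", "A"), levels = c("A", "B")),
                                c(TRUE, FALSE)), "empty status level")
})

test_that("simulated germline/mosaic split yields a strong association", {
  set.seed(30)
  hits <- 0L
  for (i in 1:20) {
    # germline patients -> LOH or ROI tumors; mosaic patients -> LOI
    n <- 60
    germ <- sample(c(TRUE, FALSE), n, replace = TRUE)
    status <- ifelse(germ, sample(c("LOH", "ROI"), n, replace = TRUE), "LOI")
    # mild label noise
    flip <- runif(n) < 0.05
    status[flip] <- sample(c("LOH", "LOI", "ROI"), sum(flip), replace = TRUE)
    p <- suppressWarnings(association_test(status, germ))$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("blood group comparison reports pairwise Mann-Whitney results", {
  x <- c(0.50, 0.51, 0.52, 0.50, 0.51)
  res <- blood_group_compare(c(x, x), rep(c("LOI", "ROI"), each = 5))
  expect_equal(nrow(res), 1L)
  expect_gt(res$p_value, 0.9)  # identical groups
  expect_equal(res$median1, res$median2)

  res2 <- blood_group_compare(c(x, x, 0.6, 0.61),
                              c(rep(c("LOI", "ROI"), each = 5), "LOH", "LOH"))
  skipped <- res2[res2$skipped != "", ]
  expect_equal(nrow(skipped), 2L)  # both LOH comparisons below min n
  expect_true(all(is.na(skipped$p_value)))
})

test_that("low-level blood mosaicism is detectable at cohort size", {
  cfg <- sim_config(seed = 1)
  sig <- 0L
  runs <- 20L
  for (i in seq_len(runs)) {
    set.seed(100 + i)
    f_loi <- imprintscope:::draw_fraction(30, cfg$f_blood[["mean"]],
                                          cfg$f_blood[["sd"]])
    loi <- vapply(0.5 + 0.5 * f_loi, function(m) {
      mean(imprintscope:::rbeta_mp(cfg$n_icr1_probes, m, cfg$beta_precision))
    }, numeric(1))
    roi <- vapply(rep(0.5, 30), function(m) {
      mean(imprintscope:::rbeta_mp(cfg$n_icr1_probes, m, cfg$beta_precision))
    }, numeric(1))
    res <- blood_group_compare(c(loi, roi), rep(c("LOI", "ROI"), each = 30))
    if (res$p_value < 0.05) sig <- sig + 1L
    # none of the mosaic blood samples crosses the frank-LOI threshold
    expect_true(all(loi < 0.7))
  }
  expect_gte(sig / runs, 0.9)
})

test_that("age model recovers a noise-free line exactly", {
  age <- c(5, 20, 35, 50)
  m <- fit_age_model(age, 0.6 - 0.001 * age)
  expect_equal(m$slope, -0.001)
  expect_equal(m$intercept, 0.6)
  expect_equal(m$residual_sd, 0, tolerance = 1e-12)
  expect_error(fit_age_model(c(1, 2), c(0.5, 0.6)), "at least 3")
  expect_error(fit_age_model(c(5, 5, 5), c(0.5, 0.6, 0.7)), "constant ages")
})

test_that("age model recovers the simulated control drift slope", {
  set.seed(9)
  d <- simulate_blood_drift(282, slope = -0.0005, sd = 0.01)
  m <- fit_age_model(d$age, d$blood_icr1)
  se <- summary(m$fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(m$slope - (-0.0005)), 2 * se)
})

test_that("prediction intervals have near-nominal coverage", {
  set.seed(10)
  cov <- replicate(50, {
    train <- simulate_blood_drift(100, slope = -0.0005, sd = 0.01)
    test <- simulate_blood_drift(50, slope = -0.0005, sd = 0.01)
    m <- fit_age_model(train$age, train$blood_icr1)
    pr <- predict(m, test$age)
    mean(test$blood_icr1 >= pr$lwr & test$blood_icr1 <= pr$upr)
  })
  expect_lt(abs(mean(cov) - 0.95), 0.03)
})

test_that("group-versus-model comparison detects the drift sign reversal", {
  set.seed(11)
  ctrl <- simulate_blood_drift(282, slope = -0.0005, sd = 0.01)
  m <- fit_age_model(ctrl$age, ctrl$blood_icr1)

  case <- simulate_blood_drift(68, slope = 0.001, sd = 0.01)
  res <- compare_group_to_model(m, case$age, case$blood_icr1)
  expect_gt(res$group_slope, 0)
  expect_true(res$slope_sign_differs)

  same <- compare_group_to_model(m, ctrl$age, ctrl$blood_icr1)
  expect_false(same$slope_sign_differs)
  expect_lt(same$fraction_above_pi, 0.08)
})

test_that("top variable probes rank by variance and exclude sex chromosomes", {
  man <- tiny_manifest()
  set.seed(12)
  m <- matrix(rnorm(8 * 6, sd = 0.1), nrow = 8,
              dimnames = list(man$probe_id, paste0("s", 1:6)))
  m["cg6", ] <- c(-4, 4, -4, 4, -4, 4)   # autosomal, huge variance
  m["cg8", ] <- c(-9, 9, -9, 9, -9, 9)   # chrX, even bigger: must be excluded
  top <- top_variable_probes(m, 3, man)
  expect_equal(top[1], "cg6")
  expect_false("cg8" %in% top)
  expect_equal(top_variable_probes(m, 0, man), character(0))
  expect_warning(all_probes <- top_variable_probes(m, 100, man), "available")
  expect_equal(length(all_probes), 7L)

  # permutation invariance over sample order
  perm <- sample(ncol(m))
  expect_identical(top_variable_probes(m[, perm], 3, man), top)

  # deterministic lexicographic tie-break
  tie <- matrix(rep(c(0, 1), each = 3), nrow = 3, byrow = FALSE,
                dimnames = list(c("cgB", "cgA", "cgC"), c("x", "y")))
  tie_man <- data.frame(probe_id = rownames(tie), chrom = "chr1", pos = 1:3)
  expect_equal(top_variable_probes(tie, 3, tie_man), c("cgA", "cgB", "cgC"))
})

test_that("clustering views separate simulated groups and filter purity", {
  set.seed(13)
  n_probes <- 100
  shift <- rep(c(0, 3), each = 25)  # two well-separated groups of samples
  m <- vapply(seq_len(50), function(j) rnorm(n_probes, shift[j], 0.3),
              numeric(n_probes))
  dimnames(m) <- list(sprintf("p%03d", 1:n_probes), sprintf("s%02d", 1:50))
  sheet <- data.frame(sample_id = colnames(m), patient_id = colnames(m),
                      tissue = "tumor", laterality = "L", age_years = 5,
                      group = "bwt_case",
                      purity = c(0.5, rep(0.9, 49)),
                      stringsAsFactors = FALSE)
  cv <- cluster_views(m, sheet, purity_min = 0.8, k = 2)
  expect_false("s01" %in% cv$samples_used)  # purity 0.5 filtered out
  labels <- cv$clusters
  truth <- shift[match(names(labels), colnames(m))] > 0
  # flat cut at k = 2 recovers the groups exactly (Rand index 1)
  expect_true(length(unique(labels[truth])) == 1 &&
                length(unique(labels[!truth])) == 1 &&
                labels[truth][1] != labels[!truth][1])

  # duplicate samples correlate exactly at 1 in the Spearman view
  m2 <- cbind(m[, 2:4], dup = m[, 2])
  colnames(m2) <- c("a", "b", "c", "dup")
  sheet2 <- data.frame(sample_id = colnames(m2), patient_id = colnames(m2),
                       tissue = "blood", laterality = NA, age_years = 5,
                       group = "control", purity = NA)
  cv2 <- cluster_views(m2, sheet2, k = 2)
  expect_equal(cv2$spearman["a", "dup"], 1)

  # embedding is reproducible bit for bit
  cv3 <- cluster_views(m, sheet, purity_min = 0.8, k = 2)
  expect_identical(cv$embedding, cv3$embedding)

  expect_error(cluster_views(m[, 1:3], sheet[1:3, ], purity_min = 0.99),
               "fewer than 3")
})
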