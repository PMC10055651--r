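# Cohort-level statistics: the germline x 11p15.5 association test, blood
# mosaicism group comparisons, the control-calibrated age-methylation drift
# model and genome-wide methylation clustering views.

#' Chi-square association between tumor 11p15.5 status and germline variants
#'
#' Pearson chi-square (no continuity correction) on the status x germline
#' contingency table, with expected counts reported.
#'
#' @param status Per-tumor 11p15.5 status labels (factor or character).
#' @param germline Per-tumor logical (does the patient carry an included
#'   germline variant).
#' @return List `chi_square`, `df`, `p_value`, `observed`, `expected`.
#' @export
association_test <- function(status, germline) {
  tab <- table(status = status, germline = germline)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("contingency table must be at least 2x2")
  }
  zero_row <- rowSums(tab) == 0
  zero_col <- colSums(tab) == 0
  if (any(zero_row)) stop("empty status level: ", rownames(tab)[zero_row][1L])
  if (any(zero_col)) stop("empty germline level: ", colnames(tab)[zero_col][1L])
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, observed = tab, expected = ht$expected)
}

#' Compare blood ICR1 methylation across tumor-status groups
#'
#' Pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests of the blood
#' H19/ICR1 region means between patients grouped by the 11p15.5 status of
#' their tumors. Patients with 11p15.5 LOI tumors are expected to show a
#' low-level gain of blood methylation (somatic mosaicism) relative to ROI
#' patients. Groups below the minimum size are skipped with a notice.
#'
#' @param blood_icr1 Numeric blood region-mean betas.
#' @param group Group label per value (e.g. the patient-consensus tumor
#'   status).
#' @param min_n Minimum group size for a comparison (default 3).
#' @return data.frame of pairwise results: groups, n, medians, U statistic,
#'   p value, and `skipped` with a reason when a group is too small.
#' @export
blood_group_compare <- function(blood_icr1, group, min_n = 3L) {
  sp <- split(blood_icr1, group)
  gnames <- names(sp)
  if (length(gnames) < 2L) stop("need at least two groups")
  combos <- utils::combn(gnames, 2L)
  out <- lapply(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1L, k]; g2 <- combos[2L, k]
    x <- sp[[g1]][!is.na(sp[[g1]])]
    y <- sp[[g2]][!is.na(sp[[g2]])]
    base <- data.frame(group1 = g1, group2 = g2,
                       n1 = length(x), n2 = length(y),
                       median1 = stats::median(x), median2 = stats::median(y),
                       stringsAsFactors = FALSE)
    if (length(x) < min_n || length(y) < min_n) {
      base$u <- NA_real_; base$p_value <- NA_real_
      base$skipped <- sprintf("group below n = %d", min_n)
    } else {
      ht <- stats::wilcox.test(x, y, exact = FALSE)
      base$u <- unname(ht$statistic); base$p_value <- ht$p.value
      base$skipped <- ""
    }
    base
  })
  do.call(rbind, out)
}

#' Fit the control age-methylation drift model
#'
#' Ordinary least squares of blood H19/ICR1 region-mean beta on age in a
#' reference (healthy control) population, with 95% prediction intervals
#' carrying the standard leverage term. In controls the drift slope is
#' expected to be slightly negative; mosaic loss-of-imprinting carriers
#' drift upward as hypermethylated clones expand in blood.
#'
#' @param age Ages in years.
#' @param blood_icr1 Blood region-mean betas.
#' @return An `age_model` object: slope (beta per year), intercept,
#'   residual_sd, n, and the underlying `lm` fit.
#' @export
fit_age_model <- function(age, blood_icr1) {
  keep <- !is.na(age) & !is.na(blood_icr1)
  age <- age[keep]; blood_icr1 <- blood_icr1[keep]
  if (length(age) < 3L) stop("need at least 3 control points")
  if (stats::sd(age) == 0) stop("constant ages: slope is unidentifiable")
  fit <- stats::lm(blood_icr1 ~ age, data = data.frame(age, blood_icr1))
  structure(list(slope = unname(stats::coef(fit)[["age"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 residual_sd = summary(fit)$sigma,
                 n = length(age), fit = fit),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf(
    "Age-methylation drift model (n = %d)\n  slope     % .3e beta/year\n  intercept % .4f\n  residual sd %.4f\n",
    x$n, x$slope, x$intercept, x$residual_sd))
  invisible(x)
}

#' Predict from the age model with 95% prediction intervals
#'
#' @param object An `age_model`.
#' @param age Query ages.
#' @param level Interval level (default 0.95).
#' @param ... Unused.
#' @return data.frame age, fit, lwr, upr.
#' @export
predict.age_model <- function(object, age, level = 0.95, ...) {
  pr <- stats::predict(object$fit, newdata = data.frame(age = age),
                       interval = "prediction", level = level)
  data.frame(age = age, fit = pr[, "fit"], lwr = pr[, "lwr"],
             upr = pr[, "upr"])
}

#' Compare a patient group against the control drift model
#'
#' Fits the group's own OLS slope and reports whether its sign differs from
#' the control model's, plus the fraction of group points above the control
#' model's upper 95% prediction bound at their ages.
#'
#' @param model An `age_model` fit on controls.
#' @param age,blood_icr1 Group observations.
#' @return List `group_slope`, `group_slope_p`, `slope_sign_differs`,
#'   `fraction_above_pi`, `n`.
#' @export
compare_group_to_model <- function(model, age, blood_icr1) {
  keep <- !is.na(age) & !is.na(blood_icr1)
  age <- age[keep]; blood_icr1 <- blood_icr1[keep]
  if (length(age) < 3L) stop("need at least 3 group points")
  gfit <- stats::lm(blood_icr1 ~ age)
  slope <- unname(stats::coef(gfit)[["age"]])
  slope_p <- summary(gfit)$coefficients["age", "Pr(>|t|)"]
  pr <- predict.age_model(model, age)
  list(group_slope = slope, group_slope_p = slope_p,
       slope_sign_differs = sign(slope) != sign(model$slope),
       fraction_above_pi = mean(blood_icr1 > pr$upr),
       n = length(age))
}

#' Top variable probes for clustering
#'
#' Ranks probes by variance of their M values across samples, after
#' excluding chrX/chrY probes (to avoid a biological-sex axis dominating
#' the clustering). Ties are broken lexicographically by probe id so the
#' selection is deterministic.
#'
#' @param m_matrix Probes x samples M-value matrix.
#' @param n Number of probes to return (default 10000).
#' @param manifest Probe manifest with chromosome labels.
#' @return Character vector of probe ids, most variable first.
#' @export
top_variable_probes <- function(m_matrix, n = 10000L, manifest) {
  sex <- manifest$probe_id[manifest$chrom %in% c("chrX", "chrY", "X", "Y")]
  keep <- setdiff(rownames(m_matrix), sex)
  m <- m_matrix[keep, , drop = FALSE]
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  ord <- order(-v, names(v))
  if (n > length(ord)) {
    warning("requested ", n, " probes but only ", length(ord), " available")
    n <- length(ord)
  }
  names(v)[ord][seq_len(n)]
}

#' Clustering views of a methylation cohort
#'
#' Three coordinated views of a top-probe M-value matrix: average-linkage
#' hierarchical clustering on Euclidean distance with a flat cut, a
#' deterministic 2-D principal-component embedding, and a Spearman
#' correlation matrix over samples. Tumor samples with purity below
#' `purity_min` are excluded before clustering (low-purity specimens blur
#' tumor-intrinsic methylation signal toward the stromal background);
#' non-tumor samples are never purity-filtered.
#'
#' @param m_matrix Probes x samples M-value matrix (already restricted to
#'   the top variable probes).
#' @param sample_sheet Sample sheet covering the matrix columns.
#' @param purity_min Tumor purity filter (default 0.8).
#' @param k Number of flat clusters to cut (default 2).
#' @return List: `hclust` (the tree), `clusters` (named flat labels),
#'   `embedding` (data.frame sample_id, dim1, dim2), `spearman` (sample
#'   correlation matrix), `samples_used`.
#' @export
cluster_views <- function(m_matrix, sample_sheet, purity_min = 0.8, k = 2L) {
  sheet <- sample_sheet[match(colnames(m_matrix), sample_sheet$sample_id), ]
  drop <- sheet$tissue == "tumor" & !is.na(sheet$purity) &
    sheet$purity < purity_min
  keep <- colnames(m_matrix)[!drop]
  if (length(keep) < 3L) stop("fewer than 3 samples after purity filtering")
  m <- m_matrix[, keep, drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]

  hc <- stats::hclust(stats::dist(t(m)), method = "average")
  clusters <- stats::cutree(hc, k = k)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  emb <- data.frame(sample_id = keep, dim1 = pc$x[, 1L],
                    dim2 = if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  sp <- stats::cor(m, method = "spearman")
  list(hclust = hc, clusters = clusters, embedding = emb, spearman = sp,
       samples_used = keep)
}
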