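# Independent enumeration oracle for the triage tree, written as flat
# precedence-ordered conditions over precomputed predicates.
oracle_triage <- function(in_panel, vclass, clinvar, provean_deleterious,
                          polyphen, vaf_sig) {
  if (!in_panel) return(FALSE)
  if (vclass %in% c("nonsense", "frameshift", "inframe_indel")) return(TRUE)
  if (clinvar %in% c("pathogenic", "likely_pathogenic")) return(TRUE)
  if (clinvar %in% c("benign", "likely_benign")) return(FALSE)
  provean_deleterious || polyphen %in% c("possibly_damaging", "damaging") ||
    vaf_sig
}

# Exact one-sided hypergeometric tail via log-binomial coefficients; fully
# independent of fisher.test.
oracle_vaf_p <- function(g_ref, g_alt, t_ref, t_alt) {
  alt_tot <- g_alt + t_alt
  ref_tot <- g_ref + t_ref
  n_tum <- t_ref + t_alt
  k <- t_alt:min(alt_tot, n_tum)
  sum(exp(lchoose(alt_tot, k) + lchoose(ref_tot, n_tum - k) -
            lchoose(alt_tot + ref_tot, n_tum)))
}

test_that("headline triage rules fire in precedence order", {
  # indels/nonsense are always counted, whatever the annotations say
  r <- triage_variant("WT1", "frameshift", "benign", provean_score = 3)
  expect_true(r$include)
  expect_true("indel_nonsense" %in% r$reason)

  # a curated benign assertion pre-empts a deleterious in-silico score
  r <- triage_variant("WT1", "missense", "benign", provean_score = -6)
  expect_false(r$include)
  expect_true("clinvar_benign_excluded" %in% r$reason)

  # the PALB2-style case: panel missense VUS, deleterious by PROVEAN
  r <- triage_variant("PALB2", "missense", "vus", provean_score = -2.5)
  expect_true(r$include)
  expect_true("provean_deleterious" %in% r$reason)

  # the panel gate comes first
  r <- triage_variant("GENEX", "nonsense", "pathogenic")
  expect_false(r$include)
  expect_equal(r$reason, "off_panel")

  # ClinVar pathogenic includes a missense directly
  expect_true(triage_variant("TP53", "missense", "pathogenic")$include)

  # VAF enrichment rescues an otherwise unsupported VUS
  r <- triage_variant("NYNRIN", "missense", "vus",
                      germline_ref = 50, germline_alt = 50,
                      tumor_ref = 5, tumor_alt = 95)
  expect_true(r$include)
  expect_true("vaf_loh_rescue" %in% r$reason)

  # nothing at step 5: excluded with a warning
  expect_warning(
    r <- triage_variant("NYNRIN", "missense", "vus"),
    "no in-silico scores")
  expect_false(r$include)
  expect_true("insufficient_annotation" %in% r$reason)
})

test_that("triage matches the enumeration oracle over the full cross-product", {
  grid <- expand.grid(
    gene = c("WT1", "NOT_ON_PANEL"),
    vclass = c("nonsense", "frameshift", "inframe_indel", "missense",
               "splice", "other"),
    clinvar = c("pathogenic", "likely_pathogenic", "benign", "likely_benign",
                "vus", "no_assertion", "unreported"),
    provean = c(-5, 0, NA),
    polyphen = c("benign", "possibly_damaging", "damaging"),
    vaf_sig = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  # depth pairs with a decisively significant / nonsignificant one-sided test
  depths <- list(sig = c(50, 50, 5, 95), nonsig = c(50, 50, 50, 50))
  mism <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- if (g$vaf_sig) depths$sig else depths$nonsig
    got <- suppressWarnings(triage_variant(
      g$gene, g$vclass, g$clinvar, g$provean, g$polyphen,
      d[1], d[2], d[3], d[4]))
    want <- oracle_triage(g$gene == "WT1", g$vclass, g$clinvar,
                          !is.na(g$provean) && g$provean <= -2.5,
                          g$polyphen, g$vaf_sig)
    if (got$include != want) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
  expect_gte(nrow(grid), 1000L)
})

test_that("VAF enrichment test matches the hypergeometric tail exactly", {
  # balanced depths: no enrichment
  r <- vaf_enrichment_test(50, 50, 50, 50)
  expect_false(r$significant)
  expect_gt(r$p_value, 0.5)

  # strong tumor enrichment: significant, p equals the enumerated tail
  r <- vaf_enrichment_test(50, 50, 5, 95)
  expect_true(r$significant)
  expect_equal(r$p_value, oracle_vaf_p(50, 50, 5, 95), tolerance = 1e-10)

  # depletion is the wrong direction for the one-sided alternative
  expect_false(vaf_enrichment_test(50, 50, 95, 5)$significant)

  expect_error(vaf_enrichment_test(0, 0, 10, 10), "zero total depth")
  expect_error(vaf_enrichment_test(NA, 1, 1, 1), "non-missing")
})

test_that("Fisher p equals enumeration for random and exhaustive small tables", {
  # exhaustive: all tables with per-tissue totals <= 6
  for (gt in 1:6) for (tt in 1:6) {
    for (ga in 0:gt) for (ta in 0:tt) {
      got <- vaf_enrichment_test(gt - ga, ga, tt - ta, ta)$p_value
      expect_equal(got, oracle_vaf_p(gt - ga, ga, tt - ta, ta),
                   tolerance = 1e-9,
                   label = sprintf("table %d/%d %d/%d", gt - ga, ga,
                                   tt - ta, ta))
    }
  }
  # random deep tables up to total depth 200 per tissue
  set.seed(6)
  for (i in 1:50) {
    gt <- sample.int(200, 1); tt <- sample.int(200, 1)
    ga <- sample.int(gt + 1, 1) - 1; ta <- sample.int(tt + 1, 1) - 1
    got <- vaf_enrichment_test(gt - ga, ga, tt - ta, ta)$p_value
    expect_equal(got, oracle_vaf_p(gt - ga, ga, tt - ta, ta),
                 tolerance = 1e-9)
  }
})

test_that("lowering the PROVEAN score never flips include to exclude", {
  scores <- seq(0, -8, by = -0.5)
  inc <- vapply(scores, function(s) {
    suppressWarnings(triage_variant("PALB2", "missense", "vus",
                                    provean_score = s))$include
  }, logical(1))
  expect_true(all(diff(inc) >= 0))  # FALSE -> TRUE transitions only
})

test_that("per-patient germline summary counts included variants", {
  tab <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2"),
    gene = c("WT1", "TP53", "BLM", "GENEX"),
    variant_class = c("frameshift", "missense", "missense", "nonsense"),
    clinvar = c("unreported", "pathogenic", "benign", "unreported"),
    stringsAsFactors = FALSE)
  res <- summarize_germline(suppressWarnings(triage_table(tab)))
  p1 <- res$per_patient[res$per_patient$patient_id == "p1", ]
  expect_equal(p1$n_included, 2L)
  expect_equal(p1$genes, "TP53,WT1")
  p2 <- res$per_patient[res$per_patient$patient_id == "p2", ]
  expect_false(p2$any_included)  # off panel
  expect_equal(res$prevalence, 0.5)

  empty <- summarize_germline(suppressWarnings(
    triage_table(tab[0, ])))
  expect_equal(nrow(empty$per_patient), 0L)
  expect_true(is.na(empty$prevalence))
})

test_that("synthetic germline modes drive the cohort prevalence", {
  probs <- c(germline_wt1 = 0.5, germline_other = 0.5, mosaic_loi = 0,
             mosaic_loh = 0, none = 0)
  cfg <- sim_config(n_patients = 20, mode_probs = probs, seed = 17,
                    n_controls = 0, n_bwt_survivors = 0, n_uwt_survivors = 0)
  res <- simulate_cohort(cfg, tempfile())
  triaged <- triage_table(res$germline)
  summ <- summarize_germline(triaged)
  expect_equal(summ$prevalence, 1)  # every planted germline variant triages in
  # and the planted benign background never does
  benign <- triaged[triaged$clinvar == "benign", ]
  expect_false(any(benign$include))
})
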