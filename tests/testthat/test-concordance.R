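test_that("shared/private partition is exact set algebra on variant keys", {
  l <- variants_at(c(1, 2, 3), "L")
  r <- variants_at(c(2, 3, 4), "R")
  part <- shared_private_partition(l, r)
  expect_equal(nrow(part$shared), 2L)
  expect_equal(nrow(part$private_l), 1L)
  expect_equal(nrow(part$private_r), 1L)

  disjoint <- shared_private_partition(variants_at(1:3, "L"),
                                       variants_at(4:6, "R"))
  expect_equal(nrow(disjoint$shared), 0L)

  expect_warning(
    dup <- shared_private_partition(variants_at(c(1, 1, 2), "L"),
                                    variants_at(3, "R")),
    "duplicate")
  expect_equal(nrow(dup$private_l), 2L)
})

test_that("partition conserves totals over random variant sets", {
  set.seed(4)
  for (i in 1:20) {
    l <- variants_at(sample.int(50, sample.int(30, 1)), "L")
    r <- variants_at(sample.int(50, sample.int(30, 1)), "R")
    part <- shared_private_partition(l, r)
    expect_equal(nrow(part$shared) + nrow(part$private_l), nrow(l))
    expect_equal(nrow(part$shared) + nrow(part$private_r), nrow(r))
  }
})

test_that("coding and noncoding counts are reported separately", {
  l <- rbind(variants_at(1:3, "L", "noncoding"),
             variants_at(101:102, "L", "coding"))
  r <- rbind(variants_at(2:4, "R", "noncoding"),
             variants_at(102:104, "R", "coding"))
  counts <- shared_private_partition(l, r)$counts
  nc <- counts[counts$region_class == "noncoding", ]
  cod <- counts[counts$region_class == "coding", ]
  expect_equal(c(nc$n_l, nc$n_r, nc$n_shared), c(3L, 3L, 2L))
  expect_equal(c(cod$n_l, cod$n_r, cod$n_shared), c(2L, 3L, 1L))
})

test_that("CNV similarity is 1 for identical and -1 for mirrored profiles", {
  segs <- data.frame(chrom = "chr2", start = 1e6, end = 6e7,
                     log_ratio = 0.6, baf_dev = NA, state = "gain",
                     sample_id = "a")
  expect_equal(cnv_profile_similarity(segs, segs), 1)
  mirror <- segs; mirror$log_ratio <- -0.6; mirror$state <- "loss"
  expect_equal(cnv_profile_similarity(segs, mirror), -1)
})

test_that("CNV similarity matches a brute-force bin correlation", {
  # independent oracle: rasterize by explicit per-bin loops
  oracle <- function(sl, sr, bin = 1e6) {
    sizes <- imprintscope:::.chrom_sizes
    prof <- function(segs) {
      unlist(lapply(names(sizes), function(ch) {
        nb <- ceiling(sizes[[ch]] / bin)
        v <- numeric(nb)
        for (i in seq_len(nrow(segs))) {
          if (segs$chrom[i] != ch) next
          for (b in seq_len(nb)) {
            b_start <- (b - 1) * bin + 1; b_end <- b * bin
            if (segs$start[i] <= b_end && segs$end[i] >= b_start) {
              v[b] <- segs$log_ratio[i]
            }
          }
        }
        v
      }))
    }
    pl <- prof(sl); pr <- prof(sr)
    keep <- abs(pl) >= 0.1 | abs(pr) >= 0.1
    stats::cor(pl[keep], pr[keep])
  }
  set.seed(8)
  for (i in 1:5) {
    mk <- function(chrom) {
      start <- sample.int(5e7, 1)
      data.frame(chrom = chrom, start = start, end = start + 3e7,
                 log_ratio = 0.6, baf_dev = NA, state = "gain",
                 sample_id = "x")
    }
    sl <- mk("chr5"); sr <- mk("chr9")
    got <- cnv_profile_similarity(sl, sr)
    expect_equal(got, oracle(sl, sr), tolerance = 1e-12)
    expect_lte(got, 0)  # disjoint single gains can only anti-correlate
  }
})

test_that("all-neutral or empty profiles yield missing similarity", {
  neutral <- data.frame(chrom = "chr2", start = 1, end = 1e7, log_ratio = 0,
                        baf_dev = NA, state = "neutral", sample_id = "a")
  expect_true(is.na(cnv_profile_similarity(neutral, neutral)))
  expect_warning(sim <- cnv_profile_similarity(neutral[0, ], neutral),
                 "empty")
  expect_true(is.na(sim))
})

test_that("1q gain calls grade none / partial / whole-arm by coverage", {
  none <- detect_1q_gain(data.frame(chrom = "chr2", start = 1, end = 1e7,
                                    log_ratio = 0.6))
  expect_equal(none$call, "none")
  expect_equal(none$fraction, 0)

  q <- imprintscope:::.chr1q
  whole <- detect_1q_gain(data.frame(chrom = "chr1", start = q[["start"]],
                                     end = q[["end"]], log_ratio = 0.6))
  expect_equal(whole$call, "whole_arm")
  expect_equal(whole$fraction, 1)

  arm_len <- q[["end"]] - q[["start"]] + 1
  half <- detect_1q_gain(data.frame(chrom = "chr1", start = q[["start"]],
                                    end = q[["start"]] + arm_len / 2 - 1,
                                    log_ratio = 0.6))
  expect_equal(half$call, "partial")
  expect_equal(half$fraction, 0.5, tolerance = 1e-8)

  # low-level gain counts only toward the low-level fraction
  low <- detect_1q_gain(data.frame(chrom = "chr1", start = q[["start"]],
                                   end = q[["end"]], log_ratio = 0.2))
  expect_equal(low$call, "none")
  expect_equal(low$fraction_low, 1)

  # overlapping segments are unioned, not double-counted
  two <- detect_1q_gain(data.frame(
    chrom = "chr1", start = c(q[["start"]], q[["start"]] + 1e7),
    end = c(q[["start"]] + 5e7, q[["start"]] + 6e7), log_ratio = 0.6))
  expect_equal(two$fraction, (6e7 + 1) / arm_len, tolerance = 1e-8)
})

test_that("clonality flag separates the published positive from negatives", {
  # 63 shared of min(102, 121): fraction 0.617, far above threshold
  pos <- flag_clonally_related(102, 121, 63, NA)
  expect_true(pos$flag)
  expect_match(pos$reason, "0.618")  # 63 / 102 = 0.6176
  # max in-table negative: 6 shared of min(54, 74) = 0.111
  expect_false(flag_clonally_related(54, 74, 6, NA)$flag)
  # vacuous evidence
  expect_false(flag_clonally_related(0, 0, 0, NA)$flag)
  # high shared fraction but discordant CNV profile vetoes the flag
  expect_false(flag_clonally_related(100, 100, 50, 0.2)$flag)
  expect_true(flag_clonally_related(100, 100, 50, 0.95)$flag)
})

test_that("pair status agreement handles indeterminate calls as missing", {
  expect_true(pair_status_agreement("LOI", "LOI"))
  expect_false(pair_status_agreement("LOI", "ROI"))
  expect_true(is.na(pair_status_agreement("indeterminate", "LOI")))
})

test_that("the shipped pair summary fixture reproduces the cohort claims", {
  tab <- analyze_pair_summary(read_pair_summary_table())
  expect_equal(nrow(tab), 15L)
  no_germ <- tab[!tab$has_germline, ]
  # every no-germline pair shows LOI in at least one tumor and shares
  # noncoding variants; five of them are uniformly LOI (the sixth is the
  # one status-discordant LOI/ROI pair)
  expect_true(all(no_germ$has_loi))
  expect_true(all(no_germ$n_shared_noncoding >= 1))
  expect_equal(sum(no_germ$uniform_loi), 5L)
  expect_equal(tab$case_id[tab$clonal_flag], "SJWLM069391")
})

test_that("clonality flag false-positive control on simulated bilateral pairs", {
  cfg <- sim_config(n_patients = 40, seed = 21, n_controls = 0,
                    n_bwt_survivors = 0, n_uwt_survivors = 0)
  res <- simulate_cohort(cfg, tempfile())
  flags <- vapply(res$truth$patient_id, function(pid) {
    vl <- res$variants[res$variants$sample_id == paste0(pid, "_TL") &
                         res$variants$region_class == "noncoding", ]
    vr <- res$variants[res$variants$sample_id == paste0(pid, "_TR") &
                         res$variants$region_class == "noncoding", ]
    flag_clonally_related(nrow(vl), nrow(vr),
                          nrow(shared_private_partition(vl, vr)$shared),
                          NA)$flag
  }, logical(1))
  expect_equal(sum(flags), 0L)
  # same-kidney clone: half the variants shared, near-identical CNV
  clone_flag <- flag_clonally_related(100, 100, 50, 0.95)
  expect_true(clone_flag$flag)
})
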