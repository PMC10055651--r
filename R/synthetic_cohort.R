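# Synthetic bilateral-Wilms-tumor cohort generator.
#
# The generator encodes the embryonic-timing structure the analysis assumes:
# predisposing events that occur before lateralization of the mesoderm
# (germline variants, post-zygotic mosaic 11p15.5 alterations) are shared by
# both kidneys and leave a mosaic footprint in blood and adjacent kidney,
# while post-lateralization events (somatic coding/noncoding variants,
# independent 11p cnLOH breakpoints) are private to each tumor.
#
# Methylation betas are drawn from beta distributions whose means follow a
# three-population mixture at the two imprinting control regions: normal
# (ROI) cells contribute (0.5, 0.5) at (ICR1, ICR2), loss-of-imprinting
# cells (1.0, 0.5) and LOH cells (1.0, 0.0).

#' Build a simulation configuration
#'
#' All knobs of the synthetic cohort in one validated list. Defaults emulate
#' a bilateral Wilms tumor study population: predisposition modes split
#' between germline variants and post-zygotic mosaic 11p15.5 alterations,
#' low blood mosaic fractions (so blood never crosses the 0.7 calling
#' threshold) against high tumor fractions, beta noise at precision 100
#' (per-probe SD around 0.05), and noncoding variant loads in the range
#' seen for whole-genome-sequenced tumor pairs.
#'
#' @param n_patients Number of bilateral-tumor patients.
#' @param mode_probs Named probabilities over the predisposition modes
#'   `germline_wt1`, `germline_other`, `mosaic_loi`, `mosaic_loh`, `none`;
#'   must sum to 1.
#' @param f_blood,f_kidney,f_tumor Mosaic-fraction distributions per tissue,
#'   each `c(mean, sd)` of a beta distribution.
#' @param beta_precision Concentration of the per-probe beta noise.
#' @param lambda_noncoding Poisson mean of private noncoding variants per
#'   tumor.
#' @param lambda_shared Poisson mean of shared (pre-lateralization)
#'   noncoding variants per pair.
#' @param age_range Patient age range in years at diagnosis.
#' @param drift_slope_case,drift_slope_control Per-year change of blood
#'   H19/ICR1 beta in mosaic-LOI individuals and controls respectively.
#' @param drift_sd Inter-individual SD of blood region-mean beta around the
#'   drift line.
#' @param n_icr1_probes,n_icr2_probes,n_background_probes Probe counts of
#'   the synthetic manifest.
#' @param n_controls,n_bwt_survivors,n_uwt_survivors Blood-only samples of
#'   the survivorship arm.
#' @param seed Master RNG seed (per-patient substreams are derived from it).
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 60L,
                       mode_probs = c(germline_wt1 = 0.15,
                                      germline_other = 0.20,
                                      mosaic_loi = 0.40,
                                      mosaic_loh = 0.05,
                                      none = 0.20),
                       f_blood = c(mean = 0.08, sd = 0.03),
                       f_kidney = c(mean = 0.50, sd = 0.15),
                       f_tumor = c(mean = 0.90, sd = 0.05),
                       beta_precision = 100,
                       lambda_noncoding = 90,
                       lambda_shared = 1.5,
                       age_range = c(0.5, 10),
                       drift_slope_case = 0.001,
                       drift_slope_control = -0.0005,
                       drift_sd = 0.01,
                       n_icr1_probes = 12L, n_icr2_probes = 6L,
                       n_background_probes = 300L,
                       n_controls = 60L, n_bwt_survivors = 20L,
                       n_uwt_survivors = 30L,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), mode_probs = mode_probs,
              f_blood = f_blood, f_kidney = f_kidney, f_tumor = f_tumor,
              beta_precision = beta_precision,
              lambda_noncoding = lambda_noncoding,
              lambda_shared = lambda_shared, age_range = age_range,
              drift_slope_case = drift_slope_case,
              drift_slope_control = drift_slope_control, drift_sd = drift_sd,
              n_icr1_probes = as.integer(n_icr1_probes),
              n_icr2_probes = as.integer(n_icr2_probes),
              n_background_probes = as.integer(n_background_probes),
              n_controls = as.integer(n_controls),
              n_bwt_survivors = as.integer(n_bwt_survivors),
              n_uwt_survivors = as.integer(n_uwt_survivors),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.sim_modes <- c("germline_wt1", "germline_other", "mosaic_loi", "mosaic_loh",
                "none")

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 0L) stop("n_patients must be nonnegative")
  if (!setequal(names(cfg$mode_probs), .sim_modes)) {
    stop("mode_probs must be named over: ", paste(.sim_modes, collapse = ", "))
  }
  if (abs(sum(cfg$mode_probs) - 1) > 1e-8) stop("mode_probs must sum to 1")
  if (any(cfg$mode_probs < 0)) stop("mode_probs must be nonnegative")
  for (nm in c("f_blood", "f_kidney", "f_tumor")) {
    f <- cfg[[nm]]
    if (f[["mean"]] < 0 || f[["mean"]] > 1 || f[["sd"]] < 0) {
      stop(nm, " mean must lie in [0,1], sd >= 0")
    }
  }
  if (cfg$beta_precision <= 0) stop("beta_precision must be positive")
  if (cfg$lambda_noncoding < 0 || cfg$lambda_shared < 0) {
    stop("Poisson means must be nonnegative")
  }
  invisible(cfg)
}

# Beta draw parameterized by (mean, precision); degenerate means short-circuit.
rbeta_mp <- function(n, mean, precision) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * precision, (1 - mean) * precision)
}

# Fraction draw with target mean/sd via moment-matched beta; sd = 0 is exact.
draw_fraction <- function(n, mean, sd) {
  if (sd == 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  conc <- mean * (1 - mean) / sd^2 - 1
  if (conc <= 0) conc <- 1e-3
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Expected ICR betas under the cell-population mixture
#'
#' Expectation of the (H19/ICR1, KCNQ1OT1/ICR2) region means for a tissue in
#' which a fraction `f` of cells carry the altered state: ROI cells
#' contribute (0.5, 0.5), LOI cells (1.0, 0.5) and LOH cells (1.0, 0.0), so
#' the expectation is `(1 - f) * ROI + f * altered`.
#'
#' @param mode Cell-population state: `roi`, `loi` or `loh` (predisposition
#'   mode names are accepted aliases: `mosaic_loi` means LOI,
#'   `mosaic_loh`/`germline_wt1` mean LOH, `none`/`germline_other` mean ROI).
#' @param f Altered-cell fraction in \[0, 1\].
#' @return Named numeric vector `c(icr1, icr2)`.
#' @export
expected_icr_beta <- function(mode, f) {
  if (is.na(f) || f < 0 || f > 1) stop("mosaic fraction must lie in [0, 1]")
  state <- switch(mode,
                  roi = , none = , germline_other = "roi",
                  loi = , mosaic_loi = "loi",
                  loh = , mosaic_loh = , germline_wt1 = "loh",
                  stop("unknown mode/state: ", mode))
  altered <- switch(state, roi = c(0.5, 0.5), loi = c(1.0, 0.5),
                    loh = c(1.0, 0.0))
  e <- (1 - f) * c(0.5, 0.5) + f * altered
  c(icr1 = e[1L], icr2 = e[2L])
}

# Synthetic EPIC-style manifest: probes in both ICR windows plus background
# probes spread over the autosomes and a handful on chrX/chrY.
make_manifest <- function(cfg) {
  icr1 <- default_regions()$icr1
  icr2 <- default_regions()$icr2
  icr1_pos <- round(seq(icr1$start, icr1$end, length.out = cfg$n_icr1_probes))
  icr2_pos <- round(seq(icr2$start, icr2$end, length.out = cfg$n_icr2_probes))
  n_bg <- cfg$n_background_probes
  n_sex <- max(2L, round(n_bg * 0.05))
  n_auto <- n_bg - n_sex
  auto_chrom <- paste0("chr", 1 + (seq_len(n_auto) - 1L) %% 22)
  sex_chrom <- rep(c("chrX", "chrY"), length.out = n_sex)
  data.frame(
    probe_id = sprintf("cg%07d", seq_len(cfg$n_icr1_probes +
                                           cfg$n_icr2_probes + n_bg)),
    chrom = c(rep("chr11", cfg$n_icr1_probes + cfg$n_icr2_probes),
              auto_chrom, sex_chrom),
    pos = c(icr1_pos, icr2_pos,
            10000L + 97L * seq_len(n_auto), 10000L + 97L * seq_len(n_sex)),
    stringsAsFactors = FALSE
  )
}

# Per-probe, per-tissue background baselines (drawn once per cohort so
# tissues separate in clustering); returns probes x tissue matrix.
make_baselines <- function(manifest, cfg) {
  n_icr <- cfg$n_icr1_probes + cfg$n_icr2_probes
  n_bg <- nrow(manifest) - n_icr
  base <- stats::runif(n_bg, 0.2, 0.8)
  shift_k <- stats::rnorm(n_bg, 0, 0.08)
  shift_t <- stats::rnorm(n_bg, 0, 0.15)
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  out <- cbind(blood = c(rep(NA, n_icr), clamp(base)),
               kidney_adjacent = c(rep(NA, n_icr), clamp(base + shift_k)),
               tumor = c(rep(NA, n_icr), clamp(base + shift_t)))
  rownames(out) <- manifest$probe_id
  out
}

# Draw the beta column for one sample: ICR probes from the mixture mean,
# background probes from the tissue baseline.
draw_sample_beta <- function(state, f, tissue, manifest, baselines, cfg) {
  e <- expected_icr_beta(state, f)
  n1 <- cfg$n_icr1_probes; n2 <- cfg$n_icr2_probes
  icr_means <- c(rep(e[["icr1"]], n1), rep(e[["icr2"]], n2))
  bg_means <- baselines[(n1 + n2 + 1):nrow(manifest), tissue]
  means <- c(icr_means, bg_means)
  vapply(means, function(m) rbeta_mp(1L, m, cfg$beta_precision), numeric(1))
}

random_noncoding <- function(n, sample_id) {
  if (n == 0L) return(empty_variants())
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
             pos = sample.int(1e8, n), ref = ref, alt = alt,
             sample_id = sample_id, region_class = "noncoding",
             gene = NA_character_,
             ref_depth = stats::rpois(n, 40), alt_depth = stats::rpois(n, 20),
             stringsAsFactors = FALSE)
}

# Independent 11p cnLOH segment for one tumor: always covers 11p15.5,
# covers the WT1/11p13 locus with probability p_cover_wt1; breakpoints are
# drawn continuously so two tumors essentially never match.
draw_cnloh_segment <- function(sample_id, f, p_cover_wt1 = 0.95) {
  icr2_end <- default_regions()$icr2$end
  wt1_end <- default_regions()$wt1$end
  start <- round(stats::runif(1L, 1e5, default_regions()$icr1$start - 1))
  end <- if (stats::runif(1L) < p_cover_wt1) {
    round(stats::runif(1L, wt1_end + 1, 53.7e6))
  } else {
    round(stats::runif(1L, icr2_end + 1, default_regions()$wt1$start - 1))
  }
  baf_dev <- min(0.5, 0.5 * f)
  data.frame(chrom = "chr11", start = start, end = end,
             log_ratio = stats::rnorm(1L, 0, 0.02), baf_dev = baf_dev,
             state = if (baf_dev >= 0.35) "cnloh" else "partial_cnloh",
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# Random independent CNV backbone for one tumor (post-lateralization events).
draw_background_cnv <- function(sample_id, n = NULL) {
  if (is.null(n)) n <- stats::rpois(1L, 1.5)
  if (n == 0L) return(NULL)
  chroms <- sample(names(.chrom_sizes)[1:22], n, replace = TRUE)
  out <- lapply(seq_len(n), function(i) {
    len <- stats::runif(1L, 5e6, 8e7)
    start <- round(stats::runif(1L, 1, max(1, .chrom_sizes[[chroms[i]]] - len)))
    lr <- sample(c(-0.6, 0.6), 1L)
    data.frame(chrom = chroms[i], start = start, end = round(start + len),
               log_ratio = lr, baf_dev = NA_real_,
               state = if (lr > 0) "gain" else "loss",
               sample_id = sample_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate one patient bundle
#'
#' Draws one patient's four samples (blood, adjacent kidney, paired L/R
#' tumors) under a predisposition mode. Mosaic modes draw one altered-cell
#' fraction per tissue (blood low, kidney and tumors high) and both tumors
#' inherit the same imprinting state - shared by construction, as for any
#' pre-lateralization event. Germline modes place the predisposing variant
#' in every sample at VAF around 0.5; the WT1 mode additionally gives each
#' tumor an independent 11p copy-neutral LOH segment (independent
#' breakpoints) and a private activating CTNNB1-like coding variant. Each
#' tumor receives its own Poisson load of private noncoding variants, and
#' the pair shares a Poisson number of pre-lateralization noncoding
#' variants.
#'
#' Uses the current RNG state; seed management is the caller's job (see
#' [simulate_cohort()]).
#'
#' @param patient_id Patient label.
#' @param mode One of germline_wt1, germline_other, mosaic_loi, mosaic_loh,
#'   none.
#' @param cfg A [sim_config()].
#' @param manifest,baselines Cohort-level probe manifest and baselines (from
#'   the internal builders; [simulate_cohort()] supplies them).
#' @return List: `samples` (sample-sheet rows), `true_f` (per tissue),
#'   `beta` (probes x 4 matrix), `variants`, `segments`,
#'   `germline_variants`, `mode`.
#' @export
simulate_patient <- function(patient_id, mode, cfg, manifest, baselines) {
  stopifnot(mode %in% .sim_modes)
  age <- stats::runif(1L, cfg$age_range[1L], cfg$age_range[2L])
  sample_ids <- paste0(patient_id, c("_B", "_K", "_TL", "_TR"))
  tissues <- c("blood", "kidney_adjacent", "tumor", "tumor")
  purity <- c(NA, NA, draw_fraction(2L, 0.85, 0.08))

  # per-tissue altered-cell fractions and imprinting states
  if (mode %in% c("mosaic_loi", "mosaic_loh")) {
    f <- c(draw_fraction(1L, cfg$f_blood[["mean"]], cfg$f_blood[["sd"]]),
           draw_fraction(1L, cfg$f_kidney[["mean"]], cfg$f_kidney[["sd"]]),
           draw_fraction(2L, cfg$f_tumor[["mean"]], cfg$f_tumor[["sd"]]))
    states <- rep(if (mode == "mosaic_loi") "loi" else "loh", 4L)
  } else if (mode == "germline_wt1") {
    # cnLOH is an independent somatic event in each tumor; clonal there
    f <- c(0, 0, purity[3:4])
    states <- c("roi", "roi", "loh", "loh")
  } else {
    f <- rep(0, 4L)
    states <- rep("roi", 4L)
  }

  beta <- vapply(1:4, function(i) {
    draw_sample_beta(states[i], f[i], tissues[i], manifest, baselines, cfg)
  }, numeric(nrow(manifest)))
  dimnames(beta) <- list(manifest$probe_id, sample_ids)

  # noncoding variants: shared pre-lateralization + private per tumor
  n_shared <- stats::rpois(1L, cfg$lambda_shared)
  shared <- random_noncoding(n_shared, sample_ids[3L])
  shared_r <- shared
  if (nrow(shared_r)) shared_r$sample_id <- sample_ids[4L]
  priv_l <- random_noncoding(stats::rpois(1L, cfg$lambda_noncoding),
                             sample_ids[3L])
  priv_r <- random_noncoding(stats::rpois(1L, cfg$lambda_noncoding),
                             sample_ids[4L])
  variants <- rbind(shared, shared_r, priv_l, priv_r)

  segments <- NULL
  germline <- NULL
  if (mode == "germline_wt1") {
    segments <- rbind(draw_cnloh_segment(sample_ids[3L], f[3L]),
                      draw_cnloh_segment(sample_ids[4L], f[4L]))
    # private activating CTNNB1-like coding variant per tumor
    ctnnb1 <- do.call(rbind, lapply(3:4, function(i) {
      data.frame(chrom = "chr3", pos = 41224600L + sample.int(500L, 1L),
                 ref = "C", alt = "T", sample_id = sample_ids[i],
                 region_class = "coding", gene = "CTNNB1",
                 ref_depth = stats::rpois(1L, 30),
                 alt_depth = stats::rpois(1L, 25),
                 stringsAsFactors = FALSE)
    }))
    variants <- rbind(variants, ctnnb1)
    g_alt <- stats::rbinom(1L, 60L, 0.5)
    germline <- data.frame(
      patient_id = patient_id, gene = "WT1", variant_class = "frameshift",
      clinvar = "pathogenic", provean_score = NA_real_, polyphen2 = "missing",
      germline_ref = 60L - g_alt, germline_alt = g_alt,
      tumor_ref = stats::rbinom(1L, 60L, 1 - 0.5 * (1 + purity[3L])),
      tumor_alt = stats::rbinom(1L, 60L, 0.5 * (1 + purity[3L])),
      stringsAsFactors = FALSE)
  } else if (mode == "germline_other") {
    gene <- sample(setdiff(default_wt_panel(), "WT1"), 1L)
    g_alt <- stats::rbinom(1L, 60L, 0.5)
    germline <- data.frame(
      patient_id = patient_id, gene = gene, variant_class = "missense",
      clinvar = sample(c("likely_pathogenic", "vus"), 1L),
      provean_score = stats::runif(1L, -8, -3), polyphen2 = "damaging",
      germline_ref = 60L - g_alt, germline_alt = g_alt,
      tumor_ref = stats::rbinom(1L, 60L, 0.5),
      tumor_alt = stats::rbinom(1L, 60L, 0.5),
      stringsAsFactors = FALSE)
  }
  if (mode == "mosaic_loh") {
    # one pre-lateralization cnLOH event: identical breakpoints everywhere
    seg <- draw_cnloh_segment(sample_ids[3L], f[3L])
    seg_r <- seg; seg_r$sample_id <- sample_ids[4L]
    seg_r$baf_dev <- min(0.5, 0.5 * f[4L])
    seg_r$state <- if (seg_r$baf_dev >= 0.35) "cnloh" else "partial_cnloh"
    segments <- rbind(seg, seg_r)
  }
  # benign background germline variant (exercises the exclusion rules)
  bg_alt <- stats::rbinom(1L, 50L, 0.5)
  background <- data.frame(
    patient_id = patient_id, gene = sample(default_wt_panel(), 1L),
    variant_class = "missense", clinvar = "benign",
    provean_score = stats::runif(1L, -1, 1), polyphen2 = "benign",
    germline_ref = 50L - bg_alt, germline_alt = bg_alt,
    tumor_ref = stats::rbinom(1L, 50L, 0.5),
    tumor_alt = stats::rbinom(1L, 50L, 0.5), stringsAsFactors = FALSE)
  germline <- rbind(germline, background)

  # independent post-lateralization CNVs for each tumor
  segments <- rbind(segments, draw_background_cnv(sample_ids[3L]),
                    draw_background_cnv(sample_ids[4L]))

  samples <- data.frame(
    sample_id = sample_ids, patient_id = patient_id, tissue = tissues,
    laterality = c(NA, NA, "L", "R"), age_years = age, group = "bwt_case",
    purity = purity, stringsAsFactors = FALSE)

  list(patient_id = patient_id, mode = mode, samples = samples,
       true_f = stats::setNames(f, c("blood", "kidney_adjacent",
                                     "tumor_L", "tumor_R")),
       beta = beta, variants = variants, segments = segments,
       germline_variants = germline, n_shared_noncoding = n_shared)
}

#' Simulate blood methylation drift with age
#'
#' Blood H19/ICR1 region-mean betas as a linear function of age plus
#' Gaussian inter-individual noise: positive slope in mosaic-LOI carriers
#' (clonal expansion of hypermethylated cells over time), slightly negative
#' slope in controls. Uses the current RNG state.
#'
#' @param n Number of individuals.
#' @param slope Beta change per year.
#' @param intercept Beta at age 0 (default 0.5).
#' @param sd Residual SD.
#' @param age_range Uniform age range in years.
#' @return data.frame `age`, `blood_icr1`.
#' @export
simulate_blood_drift <- function(n, slope, intercept = 0.5, sd = 0.01,
                                 age_range = c(1, 60)) {
  age <- stats::runif(n, age_range[1L], age_range[2L])
  beta <- pmin(pmax(intercept + slope * age + stats::rnorm(n, 0, sd), 0), 1)
  data.frame(age = age, blood_icr1 = beta)
}

derive_seed <- function(seed, index, stream = 0L) {
  (as.double(seed) * 1000003 + index * 7919 + stream * 104729) %% 2147483647
}

#' Simulate a complete cohort to disk
#'
#' Generates `n_patients` bilateral-tumor patients plus the blood-only
#' survivorship arm (controls, bilateral and unilateral survivors whose
#' blood ICR1 betas follow the configured age-drift slopes) and writes every
#' pipeline input format to `out_dir`:
#' `manifest.tsv`, `regions.tsv`, `beta.tsv`, `sheet.tsv`, `variants.tsv`,
#' `segments.tsv`, `germline.tsv` and a `truth.tsv`
#' (patient_id, mode, per-tissue altered-cell fraction, planted shared
#' noncoding count) for parameter-recovery tests. Output is deterministic
#' given `cfg$seed`; per-patient RNG substreams are derived from the patient
#' index, so a patient's data do not change when the cohort grows.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths, the truth table and the
#'   sample sheet.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  validate_sim_config(cfg)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  set.seed(derive_seed(cfg$seed, 0L))
  manifest <- make_manifest(cfg)
  baselines <- make_baselines(manifest, cfg)
  modes <- if (cfg$n_patients > 0L) {
    sample(.sim_modes, cfg$n_patients, replace = TRUE,
           prob = cfg$mode_probs[.sim_modes])
  } else character()

  bundles <- lapply(seq_len(cfg$n_patients), function(i) {
    set.seed(derive_seed(cfg$seed, i))
    simulate_patient(sprintf("P%04d", i), modes[i], cfg, manifest, baselines)
  })

  # survivorship arm: blood-only samples with age-drifted ICR1 betas
  set.seed(derive_seed(cfg$seed, 0L, stream = 1L))
  surv_groups <- c(rep("control", cfg$n_controls),
                   rep("bwt_survivor", cfg$n_bwt_survivors),
                   rep("uwt_survivor", cfg$n_uwt_survivors))
  n_surv <- length(surv_groups)
  surv_beta <- NULL
  surv_sheet <- NULL
  if (n_surv > 0L) {
    slope <- ifelse(surv_groups == "bwt_survivor",
                    cfg$drift_slope_case, cfg$drift_slope_control)
    age <- stats::runif(n_surv, 5, 60)
    icr1_mean <- pmin(pmax(0.5 + slope * age +
                             stats::rnorm(n_surv, 0, cfg$drift_sd), 0), 1)
    ids <- sprintf("S%04d_B", seq_len(n_surv))
    surv_beta <- vapply(seq_len(n_surv), function(j) {
      n1 <- cfg$n_icr1_probes; n2 <- cfg$n_icr2_probes
      means <- c(rep(icr1_mean[j], n1), rep(0.5, n2),
                 baselines[(n1 + n2 + 1):nrow(manifest), "blood"])
      vapply(means, function(m) rbeta_mp(1L, m, cfg$beta_precision),
             numeric(1))
    }, numeric(nrow(manifest)))
    dimnames(surv_beta) <- list(manifest$probe_id, ids)
    surv_sheet <- data.frame(
      sample_id = ids, patient_id = sprintf("S%04d", seq_len(n_surv)),
      tissue = "blood", laterality = NA_character_, age_years = age,
      group = surv_groups, purity = NA_real_, stringsAsFactors = FALSE)
  }

  beta <- do.call(cbind, c(lapply(bundles, `[[`, "beta"),
                           if (!is.null(surv_beta)) list(surv_beta)))
  if (is.null(beta)) {
    beta <- matrix(numeric(), nrow = nrow(manifest), ncol = 0L,
                   dimnames = list(manifest$probe_id, character()))
  }
  sheet <- do.call(rbind, c(lapply(bundles, `[[`, "samples"),
                            if (!is.null(surv_sheet)) list(surv_sheet)))
  if (is.null(sheet)) {
    sheet <- data.frame(sample_id = character(), patient_id = character(),
                        tissue = character(), laterality = character(),
                        age_years = numeric(), group = character(),
                        purity = numeric(), stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, c(list(empty_variants()),
                               lapply(bundles, `[[`, "variants")))
  segments <- do.call(rbind, c(
    list(data.frame(chrom = character(), start = numeric(), end = numeric(),
                    log_ratio = numeric(), baf_dev = numeric(),
                    state = character(), sample_id = character(),
                    stringsAsFactors = FALSE)),
    lapply(bundles, `[[`, "segments")))
  germline <- do.call(rbind, c(
    list(data.frame(patient_id = character(), gene = character(),
                    variant_class = character(), clinvar = character(),
                    provean_score = numeric(), polyphen2 = character(),
                    germline_ref = numeric(), germline_alt = numeric(),
                    tumor_ref = numeric(), tumor_alt = numeric(),
                    stringsAsFactors = FALSE)),
    lapply(bundles, `[[`, "germline_variants")))
  truth <- do.call(rbind, c(
    list(data.frame(patient_id = character(), mode = character(),
                    f_blood = numeric(), f_kidney = numeric(),
                    f_tumor_L = numeric(), f_tumor_R = numeric(),
                    n_shared_noncoding = integer(),
                    stringsAsFactors = FALSE)),
    lapply(bundles, function(b) {
      data.frame(patient_id = b$patient_id, mode = b$mode,
                 f_blood = b$true_f[["blood"]],
                 f_kidney = b$true_f[["kidney_adjacent"]],
                 f_tumor_L = b$true_f[["tumor_L"]],
                 f_tumor_R = b$true_f[["tumor_R"]],
                 n_shared_noncoding = b$n_shared_noncoding,
                 stringsAsFactors = FALSE)
    })))

  paths <- list(
    manifest = file.path(out_dir, "manifest.tsv"),
    regions = file.path(out_dir, "regions.tsv"),
    beta = file.path(out_dir, "beta.tsv"),
    sheet = file.path(out_dir, "sheet.tsv"),
    variants = file.path(out_dir, "variants.tsv"),
    segments = file.path(out_dir, "segments.tsv"),
    germline = file.path(out_dir, "germline.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_probe_manifest(manifest, paths$manifest)
  write_regions(default_regions(), paths$regions)
  write_beta_matrix(beta, paths$beta)
  utils::write.table(sheet, paths$sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_variants(variants, paths$variants)
  write_segments(segments, paths$segments)
  utils::write.table(germline, paths$germline, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth = truth, sheet = sheet,
                 manifest = manifest, beta = beta, variants = variants,
                 segments = segments, germline = germline))
}
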