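# End-to-end orchestration: load inputs, classify imprinting status, build
# pair reports, triage germline variants, run cohort statistics, and write
# every stage table plus a config snapshot and a structured run log.

#' Build a run configuration
#'
#' Paths to the pipeline inputs plus every tunable threshold, with the
#' shipped defaults: the H19/ICR1 and KCNQ1OT1/ICR2 windows, the 0.7/0.3
#' beta thresholds, the triage cutoffs and the clustering parameters.
#' `segments` and `germline` may be `NA`; the pipeline then degrades to
#' methylation-only LOH calls and skips triage, logging the degradation.
#'
#' @param beta,manifest,sheet Input paths (required at run time).
#' @param variants,segments,germline Optional input paths (`NA` to skip).
#' @param regions Named list of [genomic_region()]s with `icr1`, `icr2`
#'   (and optionally `wt1`).
#' @param icr1_thresh,icr2_thresh Classification thresholds in (0, 1).
#' @param min_probes Minimum usable probes per ICR window.
#' @param baseline_icr1,baseline_icr2 Mosaic-fraction baselines.
#' @param provean_cutoff,vaf_alpha Triage cutoffs.
#' @param shared_frac_min,cnv_similarity_min Clonality-flag thresholds.
#' @param n_top_probes,purity_min,cluster_k Clustering parameters.
#' @param seed RNG seed for any stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(beta = NA, manifest = NA, sheet = NA,
                       variants = NA, segments = NA, germline = NA,
                       regions = default_regions(),
                       icr1_thresh = 0.7, icr2_thresh = 0.3,
                       min_probes = 3L,
                       baseline_icr1 = 0.5, baseline_icr2 = 0.5,
                       provean_cutoff = -2.5, vaf_alpha = 0.05,
                       shared_frac_min = 0.25, cnv_similarity_min = 0.8,
                       n_top_probes = 10000L, purity_min = 0.8,
                       cluster_k = 2L, seed = 1L) {
  cfg <- list(beta = beta, manifest = manifest, sheet = sheet,
              variants = variants, segments = segments, germline = germline,
              regions = regions, icr1_thresh = icr1_thresh,
              icr2_thresh = icr2_thresh, min_probes = as.integer(min_probes),
              baseline_icr1 = baseline_icr1, baseline_icr2 = baseline_icr2,
              provean_cutoff = provean_cutoff, vaf_alpha = vaf_alpha,
              shared_frac_min = shared_frac_min,
              cnv_similarity_min = cnv_similarity_min,
              n_top_probes = as.integer(n_top_probes),
              purity_min = purity_min, cluster_k = as.integer(cluster_k),
              seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (th in c("icr1_thresh", "icr2_thresh", "baseline_icr1",
               "baseline_icr2", "purity_min")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || is.na(v) || v <= 0 || v >= 1) {
      stop("config ", th, " must lie strictly inside (0, 1), got ", v)
    }
  }
  for (r in c("icr1", "icr2")) {
    if (!inherits(cfg$regions[[r]], "genomic_region")) {
      stop("config regions must include a genomic_region named ", r)
    }
  }
  if (cfg$min_probes < 1L) stop("min_probes must be >= 1")
  invisible(cfg)
}

# YAML snapshot: regions flattened to plain lists so the round trip is exact.
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$regions <- lapply(cfg$regions, function(r) {
    list(chrom = r$chrom, start = r$start, end = r$end, name = r$name)
  })
  out
}

#' Write / read a run-config snapshot
#'
#' Parsing an emitted snapshot reproduces the configuration exactly.
#'
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$regions <- lapply(raw$regions, function(r) {
    genomic_region(r$chrom, r$start, r$end, r$name)
  })
  raw[c("beta", "manifest", "sheet", "variants", "segments", "germline")] <-
    lapply(raw[c("beta", "manifest", "sheet", "variants", "segments",
                 "germline")], function(x) if (is.null(x)) NA else x)
  do.call(run_config, raw)
}

# Patient-level consensus 11p15.5 status from the tumor calls: an altered
# status wins over ROI (LOI over LOH when the pair is discordant), so a
# patient with any LOI tumor is an LOI patient.
consensus_status <- function(statuses) {
  statuses <- statuses[statuses != "indeterminate"]
  if (length(statuses) == 0L) return("indeterminate")
  for (s in c("LOI", "LOH", "ROI")) if (s %in% statuses) return(s)
  "indeterminate"
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(line)
}

#' Run the full pipeline
#'
#' Stages, in dependency order: load inputs, classify per-sample 11p15.5
#' imprinting status, build per-patient pair reports, triage germline
#' variants, and run cohort statistics (association test, blood-group
#' comparison, control age model, clustering views). Each stage writes its
#' table under `out_dir`; a config snapshot (`config.yaml`), its MD5 hash
#' and a structured `run.log` accompany them. Re-running with identical
#' config and inputs reproduces identical outputs.
#'
#' @param cfg A [run_config()] whose `beta`, `manifest` and `sheet` paths
#'   exist; `variants`, `segments`, `germline` are optional.
#' @param out_dir Output directory.
#' @return Invisibly, a list of the in-memory stage results and file paths.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_run_config(cfg)
  for (p in c("beta", "manifest", "sheet")) {
    if (is.na(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop("required input ", p, " missing: ", cfg[[p]])
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  snap <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, snap)
  cfg_hash <- unname(tools::md5sum(snap))
  log_line(log_path, "config", paste("snapshot hash", cfg_hash))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log_line(log_path, stage, paste("FAILED:", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(cfg$seed)

  # -- load ------------------------------------------------------------------
  manifest <- run_stage("load", read_probe_manifest(cfg$manifest))
  beta <- run_stage("load", read_beta_matrix(cfg$beta, manifest))
  sheet <- run_stage("load", read_sample_sheet(cfg$sheet))
  segments <- NULL
  if (!is.na(cfg$segments) && file.exists(cfg$segments)) {
    segments <- run_stage("load", read_segments(cfg$segments))
  } else {
    log_line(log_path, "load",
             "no segments file: LOH calls are methylation-only")
  }
  variants <- NULL
  if (!is.na(cfg$variants) && file.exists(cfg$variants)) {
    variants <- run_stage("load", read_variants(cfg$variants))
  }
  log_line(log_path, "load", sprintf(
    "beta %d x %d (md5 %s), %d sheet rows", nrow(beta), ncol(beta),
    unname(tools::md5sum(cfg$beta)), nrow(sheet)))

  # -- classify --------------------------------------------------------------
  calls <- run_stage("classify", classify_cohort(
    beta, manifest, cfg$regions, segments, cfg$min_probes,
    cfg$baseline_icr1, cfg$baseline_icr2))
  calls$config_hash <- cfg_hash
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_line(log_path, "classify", sprintf("%d calls", nrow(calls)))

  # -- pair ------------------------------------------------------------------
  pair_reports <- NULL
  if (!is.null(variants)) {
    pair_reports <- run_stage("pair", {
      tum <- sheet[sheet$tissue == "tumor", ]
      paired <- split(tum, tum$patient_id)
      paired <- paired[vapply(paired, nrow, integer(1)) == 2L]
      reports <- lapply(paired, function(p) {
        p <- p[order(p$laterality), ]
        seg_of <- function(sid) {
          if (is.null(segments)) return(NULL)
          s <- segments[segments$sample_id == sid, , drop = FALSE]
          if (nrow(s)) s else NULL
        }
        pair_report(
          p$patient_id[1L],
          variants[variants$sample_id == p$sample_id[1L], , drop = FALSE],
          variants[variants$sample_id == p$sample_id[2L], , drop = FALSE],
          seg_of(p$sample_id[1L]), seg_of(p$sample_id[2L]),
          calls[calls$sample_id == p$sample_id[1L], , drop = FALSE],
          calls[calls$sample_id == p$sample_id[2L], , drop = FALSE],
          shared_frac_min = cfg$shared_frac_min,
          cnv_similarity_min = cfg$cnv_similarity_min)
      })
      do.call(rbind, reports)
    })
    if (!is.null(pair_reports)) {
      pair_reports$config_hash <- cfg_hash
      utils::write.table(pair_reports, file.path(out_dir, "pair_reports.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line(log_path, "pair", sprintf("%d pairs", nrow(pair_reports)))
    }
  } else {
    log_line(log_path, "pair", "skipped: no variants file")
  }

  # -- triage ----------------------------------------------------------------
  triaged <- NULL
  germline_summary <- NULL
  if (!is.na(cfg$germline) && file.exists(cfg$germline)) {
    triaged <- run_stage("triage", triage_table(
      utils::read.delim(cfg$germline, stringsAsFactors = FALSE),
      provean_cutoff = cfg$provean_cutoff, vaf_alpha = cfg$vaf_alpha))
    germline_summary <- summarize_germline(triaged)
    triaged$config_hash <- cfg_hash
    utils::write.table(triaged, file.path(out_dir, "triage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(germline_summary$per_patient,
                       file.path(out_dir, "germline_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(log_path, "triage",
             sprintf("%d variants, prevalence %.3f", nrow(triaged),
                     germline_summary$prevalence))
  } else {
    log_line(log_path, "triage", "skipped: no germline file")
  }

  # -- cohort ----------------------------------------------------------------
  cohort <- run_stage("cohort", {
    res <- list()
    merged <- merge(calls, sheet, by = "sample_id")
    tum <- merged[merged$tissue == "tumor", ]
    patient_status <- vapply(split(tum$status, tum$patient_id),
                             consensus_status, character(1))
    res$patient_status <- patient_status
    if (!is.null(germline_summary) &&
        nrow(germline_summary$per_patient) > 0L) {
      gs <- germline_summary$per_patient
      common <- intersect(names(patient_status), gs$patient_id)
      st <- patient_status[common]
      keep <- st != "indeterminate"
      gl <- gs$any_included[match(common, gs$patient_id)]
      if (length(unique(st[keep])) >= 2L && length(unique(gl[keep])) >= 2L) {
        res$association <- association_test(st[keep], gl[keep])
      }
    }
    blood <- merged[merged$tissue == "blood" & merged$group == "bwt_case", ]
    if (nrow(blood)) {
      grp <- patient_status[blood$patient_id]
      keep <- !is.na(grp) & grp != "indeterminate" & !is.na(blood$mean_icr1)
      if (length(unique(grp[keep])) >= 2L) {
        res$blood_compare <- blood_group_compare(blood$mean_icr1[keep],
                                                 grp[keep])
      }
    }
    ctrl <- merged[merged$group == "control" & merged$tissue == "blood" &
                     !is.na(merged$mean_icr1), ]
    if (nrow(ctrl) >= 3L) {
      res$age_model <- fit_age_model(ctrl$age_years, ctrl$mean_icr1)
      for (g in c("bwt_survivor", "uwt_survivor")) {
        gm <- merged[merged$group == g & merged$tissue == "blood" &
                       !is.na(merged$mean_icr1), ]
        if (nrow(gm) >= 3L) {
          res[[paste0("drift_", g)]] <- compare_group_to_model(
            res$age_model, gm$age_years, gm$mean_icr1)
        }
      }
    }
    m <- beta_to_m(beta)
    top <- top_variable_probes(m, min(cfg$n_top_probes, nrow(m)), manifest)
    res$cluster <- tryCatch(
      cluster_views(m[top, , drop = FALSE], sheet, cfg$purity_min,
                    cfg$cluster_k),
      error = function(e) NULL)
    res
  })
  if (!is.null(cohort$association)) {
    assoc <- data.frame(chi_square = cohort$association$chi_square,
                        df = cohort$association$df,
                        p_value = cohort$association$p_value)
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$blood_compare)) {
    utils::write.table(cohort$blood_compare,
                       file.path(out_dir, "blood_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$age_model)) {
    am <- cohort$age_model
    jsonlite::write_json(list(slope = am$slope, intercept = am$intercept,
                              residual_sd = am$residual_sd, n = am$n),
                         file.path(out_dir, "age_model.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cohort$cluster)) {
    utils::write.table(cohort$cluster$embedding,
                       file.path(out_dir, "embedding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(cohort$cluster$clusters),
                 cluster = cohort$cluster$clusters),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  log_line(log_path, "cohort", "done")
  invisible(list(calls = calls, pair_reports = pair_reports,
                 triaged = triaged, germline_summary = germline_summary,
                 cohort = cohort, config_hash = cfg_hash,
                 out_dir = out_dir))
}
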