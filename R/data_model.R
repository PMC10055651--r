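# Core domain containers and readers/writers for the tabular formats the
# pipeline exchanges: beta matrices, probe manifests, genomic regions, sample
# sheets, somatic/germline variant tables and copy-number segment tracks.
# All genomic coordinates are 1-based and inclusive on both ends.

#' Construct a genomic region
#'
#' A minimal 1-based, both-ends-inclusive interval used for region-mean
#' methylation and overlap tests.
#'
#' @param chrom Chromosome name (e.g. `"chr11"`).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param name Region label.
#' @return A `genomic_region` object (named list).
#' @export
genomic_region <- function(chrom, start, end, name = "") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    stop("invalid region: need 1 <= start <= end, got [", start, ", ", end, "]")
  }
  structure(list(chrom = chrom, start = start, end = end, name = name),
            class = "genomic_region")
}

#' Default 11p15.5 imprinting-control-region windows
#'
#' The H19/ICR1 and KCNQ1OT1/ICR2 windows on GRCh38 used for region-mean
#' beta values, plus the WT1/11p13 locus used in cnLOH overlap reports.
#' The WT1 window is a configurable default (the WT1 gene body), not a
#' measured quantity; override it if your annotation differs.
#'
#' @return Named list of [genomic_region()] objects: `icr1`, `icr2`, `wt1`.
#' @export
default_regions <- function() {
  list(
    icr1 = genomic_region("chr11", 2019974, 2024738, "H19_ICR1"),
    icr2 = genomic_region("chr11", 2721228, 2722228, "KCNQ1OT1_ICR2"),
    wt1  = genomic_region("chr11", 32387775, 32435539, "WT1_11p13")
  )
}

# -- probe manifest -----------------------------------------------------------

#' Read a probe manifest
#'
#' @param path TSV with columns `probe_id`, `chrom`, `pos` (1-based GRCh38).
#' @return data.frame with those columns, `probe_id` unique.
#' @export
read_probe_manifest <- function(path) {
  man <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("manifest ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(man$probe_id)) {
    stop("manifest has duplicate probe_id: ",
         man$probe_id[duplicated(man$probe_id)][1L])
  }
  man$pos <- as.numeric(man$pos)
  if (any(!nzchar(man$chrom)) || any(is.na(man$pos)) || any(man$pos < 1)) {
    stop("manifest has empty chrom or pos < 1")
  }
  man[need]
}

#' @rdname read_probe_manifest
#' @param manifest Manifest data.frame.
#' @export
write_probe_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- beta matrix --------------------------------------------------------------

#' Read a methylation beta matrix
#'
#' Reads a probes x samples TSV of beta values (methylated signal over total
#' signal, in \[0, 1\]). The first column holds probe ids, the header row
#' sample ids; missing cells are the literal string `NA`. Probes absent from
#' the manifest are retained and recorded in the `"unknown_probes"` attribute.
#'
#' @param path TSV path.
#' @param manifest Optional probe manifest (see [read_probe_manifest()]).
#' @return Numeric matrix, probes as rownames, samples as colnames.
#' @export
read_beta_matrix <- function(path, manifest = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 1L) stop("no probes in ", path)
  probes <- as.character(raw[[1L]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe_id in beta matrix: ", probes[duplicated(probes)][1L])
  }
  samples <- names(raw)[-1L]
  if (length(samples) == 0L) stop("no samples in ", path)
  if (anyDuplicated(samples)) stop("duplicate sample_id in beta matrix header")
  beta <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(beta) <- "double")
  # a cell that failed numeric coercion but was not the literal NA marker
  bad_coerce <- is.na(beta) & !is.na(raw[, -1L, drop = FALSE]) &
    raw[, -1L, drop = FALSE] != "NA"
  if (any(bad_coerce)) {
    idx <- which(bad_coerce, arr.ind = TRUE)[1L, ]
    stop("non-numeric beta value at probe ", probes[idx[1L]],
         ", sample ", samples[idx[2L]])
  }
  out_of_range <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
    stop("beta value outside [0,1] at probe ", probes[idx[1L]],
         ", sample ", samples[idx[2L]], ": ", beta[idx[1L], idx[2L]])
  }
  dimnames(beta) <- list(probes, samples)
  if (!is.null(manifest)) {
    unknown <- setdiff(probes, manifest$probe_id)
    attr(beta, "unknown_probes") <- unknown
    if (length(unknown)) {
      warning(length(unknown), " probe(s) absent from manifest (retained)")
    }
  }
  beta
}

#' Write a beta matrix to TSV
#'
#' Inverse of [read_beta_matrix()]: cell-identical round trips for valid
#' matrices, missing values written as `NA`.
#'
#' @param beta Numeric probes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)),
            ncol(beta) == 0L || !is.null(colnames(beta)))
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Beta to M value conversion
#'
#' M = log2(beta / (1 - beta)), the variance-stabilised logit of the
#' methylated fraction. Betas are clamped to `[eps, 1 - eps]` before the
#' ratio so the boundary values map to large finite M rather than +/-Inf.
#'
#' @param beta Numeric vector/matrix of values in \[0, 1\] (NA passed through).
#' @param eps Clamp width, default `1e-6`.
#' @return M values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

# -- regions file -------------------------------------------------------------

#' Read a regions table
#'
#' 4-column TSV `chrom, start, end, name`; unlike BED these coordinates are
#' 1-based and inclusive on both ends.
#'
#' @param path TSV path.
#' @return List of [genomic_region()] objects named by region name.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "name")
  if (!all(need %in% names(df))) {
    stop("regions file needs columns: ", paste(need, collapse = ", "))
  }
  regs <- lapply(seq_len(nrow(df)), function(i) {
    genomic_region(df$chrom[i], df$start[i], df$end[i], df$name[i])
  })
  names(regs) <- df$name
  regs
}

#' @rdname read_regions
#' @param regions List of `genomic_region` objects.
#' @export
write_regions <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, start = r$start, end = r$end, name = r$name,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- sample sheet -------------------------------------------------------------

.tissues <- c("blood", "kidney_adjacent", "tumor")
.groups  <- c("bwt_case", "bwt_survivor", "uwt_survivor", "control")

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id, patient_id, tissue, laterality,
#'   age_years, group, purity`. Tissue is one of blood / kidney_adjacent /
#'   tumor; tumors carry laterality L or R; purity (tumor cell fraction) may
#'   be missing.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "laterality", "age_years",
            "group", "purity")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  validate_sample_sheet(df)
  df[need]
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  bad_tissue <- setdiff(unique(df$tissue), .tissues)
  if (length(bad_tissue)) stop("unknown tissue: ", bad_tissue[1L])
  bad_group <- setdiff(unique(df$group), .groups)
  if (length(bad_group)) stop("unknown group: ", bad_group[1L])
  tum <- df$tissue == "tumor"
  if (any(tum & !df$laterality %in% c("L", "R"))) {
    stop("tumor samples must have laterality L or R")
  }
  ok_pur <- is.na(df$purity) | (df$purity >= 0 & df$purity <= 1)
  if (!all(ok_pur)) stop("purity outside [0, 1]")
  if (any(!is.na(df$age_years) & df$age_years < 0)) stop("negative age_years")
  invisible(df)
}

# -- variants -----------------------------------------------------------------

.variant_cols <- c("chrom", "pos", "ref", "alt", "sample_id", "region_class",
                   "gene", "ref_depth", "alt_depth")

#' Read somatic variant records
#'
#' Accepts either a VCF 4.2 file with per-sample `AD` depths or a TSV with
#' explicit `ref_depth`/`alt_depth` columns. Multi-allelic sites are
#' decomposed into one record per alt allele; the AD field is split
#' accordingly. Missing depth fields yield records with `NA` depths and a
#' warning rather than an error.
#'
#' @param path VCF (`.vcf`) or TSV path.
#' @param sample_id Sample the records belong to. For a multi-sample VCF,
#'   also selects the genotype column; defaults to the first.
#' @return data.frame with columns chrom, pos, ref, alt, sample_id,
#'   region_class, gene, ref_depth, alt_depth. VAF is `alt / (ref + alt)`,
#'   defined only when total depth is positive (see [variant_vaf()]).
#' @export
read_variants <- function(path, sample_id = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variants_vcf(path, sample_id)
  } else {
    read_variants_tsv(path, sample_id)
  }
}

read_variants_tsv <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("variant TSV needs columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!"sample_id" %in% names(df)) {
    if (is.null(sample_id)) stop("variant TSV lacks sample_id; supply one")
    df$sample_id <- rep(sample_id, nrow(df))
  } else if (!is.null(sample_id)) {
    df <- df[df$sample_id == sample_id, , drop = FALSE]
  }
  for (col in c("region_class", "gene")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
  }
  for (col in c("ref_depth", "alt_depth")) {
    if (!col %in% names(df)) {
      warning("variant TSV lacks ", col, "; depths recorded as missing")
      df[[col]] <- rep(NA_real_, nrow(df))
    }
  }
  validate_variants(df[.variant_cols])
}

read_variants_vcf <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(validate_variants(empty_variants()))
  }
  gt_samples <- colnames(vcf@gt)[-1L]
  col <- if (!is.null(sample_id) && sample_id %in% gt_samples) sample_id
         else gt_samples[1L]
  ad <- tryCatch(
    vcfR::extract.gt(vcf, element = "AD")[, col],
    error = function(e) rep(NA_character_, nrow(fix))
  )
  if (all(is.na(ad))) warning("no AD depths in VCF; depths recorded as missing")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    depths <- if (is.na(ad[i])) rep(NA_real_, length(alts) + 1L)
              else suppressWarnings(as.numeric(strsplit(ad[i], ",")[[1L]]))
    if (length(depths) < length(alts) + 1L) {
      depths <- c(depths, rep(NA_real_, length(alts) + 1L - length(depths)))
    }
    out[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      sample_id = if (is.null(sample_id)) col else sample_id,
      region_class = NA_character_, gene = NA_character_,
      ref_depth = depths[1L], alt_depth = depths[seq_along(alts) + 1L],
      stringsAsFactors = FALSE
    )
  }
  validate_variants(do.call(rbind, out))
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), sample_id = character(),
             region_class = character(), gene = character(),
             ref_depth = numeric(), alt_depth = numeric(),
             stringsAsFactors = FALSE)
}

validate_variants <- function(df) {
  if (any(df$ref == df$alt)) stop("variant with ref == alt")
  ok <- function(x) is.na(x) | x >= 0
  if (!all(ok(df$ref_depth)) || !all(ok(df$alt_depth))) {
    stop("negative read depth")
  }
  rownames(df) <- NULL
  df
}

#' Variant allele fraction
#'
#' @param variants Variant data.frame with `ref_depth`/`alt_depth`.
#' @return Numeric VAF vector; NA where total depth is zero or missing.
#' @export
variant_vaf <- function(variants) {
  tot <- variants$ref_depth + variants$alt_depth
  ifelse(!is.na(tot) & tot > 0, variants$alt_depth / tot, NA_real_)
}

#' @rdname read_variants
#' @param variants Variant data.frame.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- segments -----------------------------------------------------------------

.segment_states <- c("neutral", "gain", "loss", "low_gain", "low_loss",
                     "cnloh", "partial_cnloh")

#' Read a copy-number segment track
#'
#' TSV `chrom, start, end, log_ratio, baf_dev[, state, sample_id]` with
#' 1-based inclusive coordinates. `log_ratio` is the copy-number log2 ratio;
#' `baf_dev` the mean absolute deviation of the B-allele fraction from 0.5
#' (in \[0, 0.5\], may be missing). If `state` is absent it is derived from
#' the log-ratio thresholds via [segment_state()].
#'
#' @param path TSV path.
#' @return Validated segment data.frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "log_ratio")
  if (!all(need %in% names(df))) {
    stop("segments file needs columns: ", paste(need, collapse = ", "))
  }
  if (!"baf_dev" %in% names(df)) df$baf_dev <- NA_real_
  if (!"state" %in% names(df)) df$state <- segment_state(df$log_ratio, df$baf_dev)
  if (!"sample_id" %in% names(df)) df$sample_id <- NA_character_
  validate_segments(df)
}

validate_segments <- function(df) {
  if (any(df$start > df$end)) stop("segment with start > end")
  bad_baf <- !is.na(df$baf_dev) & (df$baf_dev < 0 | df$baf_dev > 0.5)
  if (any(bad_baf)) stop("baf_dev outside [0, 0.5]")
  bad_state <- setdiff(unique(df$state), .segment_states)
  if (length(bad_state)) stop("unknown segment state: ", bad_state[1L])
  rownames(df) <- NULL
  df
}

#' Copy-number state from log-ratio thresholds
#'
#' Full gain/loss at |log2 ratio| >= 0.5, low-level gain/loss in
#' \[0.1, 0.5); copy-neutral segments with B-allele-fraction deviation
#' >= 0.15 are labelled cnloh (>= 0.35, near-pure) or partial_cnloh.
#'
#' @param log_ratio Numeric log2 copy-number ratios.
#' @param baf_dev Mean |BAF - 0.5| per segment (NA allowed).
#' @return Character state vector.
#' @export
segment_state <- function(log_ratio, baf_dev = NA_real_) {
  baf_dev <- rep_len(baf_dev, length(log_ratio))
  state <- rep("neutral", length(log_ratio))
  state[log_ratio >= 0.1] <- "low_gain"
  state[log_ratio <= -0.1] <- "low_loss"
  state[log_ratio >= 0.5] <- "gain"
  state[log_ratio <= -0.5] <- "loss"
  cn_neutral <- abs(log_ratio) < 0.1 & !is.na(baf_dev)
  state[cn_neutral & baf_dev >= 0.15] <- "partial_cnloh"
  state[cn_neutral & baf_dev >= 0.35] <- "cnloh"
  state
}

#' @rdname read_segments
#' @param segments Segment data.frame.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
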