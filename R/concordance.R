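# Paired synchronous-tumor analysis: shared/private somatic-variant
# partition, copy-number profile similarity, 1q-gain calls, the
# clonal-relatedness outlier flag and pairwise 11p15.5-status agreement.
#
# Variants are compared by exact (chrom, pos, ref, alt) key equality; calls
# are assumed harmonized upstream, so no position-window fuzzing is applied.

# GRCh38 chromosome lengths used for rasterizing copy-number profiles.
.chrom_sizes <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415
)

# GRCh38 chr1 q-arm (centromere end to chromosome end), used for 1q-gain
# coverage fractions.
.chr1q <- c(start = 123400001, end = 248956422)

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Partition two tumors' variants into shared and private sets
#'
#' Exact set algebra on (chrom, pos, ref, alt) keys, with shared/private
#' counts reported separately for coding and noncoding records. Duplicate
#' keys within one tumor are deduplicated with a warning.
#'
#' @param variants_l,variants_r Variant data.frames (see [read_variants()]).
#' @return List with `shared`, `private_l`, `private_r` (data.frames keyed
#'   as the left tumor for `shared`) and `counts`, a data.frame per
#'   region_class of n_l, n_r, n_shared.
#' @export
shared_private_partition <- function(variants_l, variants_r) {
  dedup <- function(v, side) {
    k <- variant_key(v)
    if (anyDuplicated(k)) {
      warning("duplicate variant keys in ", side, " tumor; deduplicated")
      v <- v[!duplicated(k), , drop = FALSE]
    }
    v
  }
  vl <- dedup(variants_l, "left")
  vr <- dedup(variants_r, "right")
  kl <- variant_key(vl); kr <- variant_key(vr)
  shared <- vl[kl %in% kr, , drop = FALSE]
  priv_l <- vl[!kl %in% kr, , drop = FALSE]
  priv_r <- vr[!kr %in% kl, , drop = FALSE]

  classes <- c("coding", "noncoding")
  cnt <- function(cls, v) sum(v$region_class %in% cls)
  counts <- data.frame(
    region_class = classes,
    n_l = vapply(classes, cnt, integer(1), v = vl),
    n_r = vapply(classes, cnt, integer(1), v = vr),
    n_shared = vapply(classes, cnt, integer(1), v = shared),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(shared = shared, private_l = priv_l, private_r = priv_r,
       counts = counts)
}

# Rasterize a segment track's log ratio onto fixed-width genome bins.
# Bins not covered by any segment are 0 (neutral).
rasterize_log_ratio <- function(segments, bin_kb = 1000,
                                chrom_sizes = .chrom_sizes) {
  bin <- bin_kb * 1000
  offsets <- c(0, cumsum(ceiling(chrom_sizes / bin)))
  names(offsets) <- c(names(chrom_sizes), "end")
  total_bins <- offsets[["end"]]
  prof <- numeric(total_bins)
  for (i in seq_len(nrow(segments))) {
    chrom <- segments$chrom[i]
    if (!chrom %in% names(chrom_sizes)) next
    b0 <- floor((segments$start[i] - 1) / bin)
    b1 <- floor((segments$end[i] - 1) / bin)
    b1 <- min(b1, ceiling(chrom_sizes[[chrom]] / bin) - 1)
    idx <- offsets[[chrom]] + (b0:b1) + 1
    prof[idx] <- segments$log_ratio[i]
  }
  prof
}

#' Copy-number profile similarity of a tumor pair
#'
#' Rasterizes both tumors' log2 ratios onto fixed genome-wide bins (default
#' 1000 kb) and reports the Pearson correlation over bins where at least one
#' profile is non-neutral (|log ratio| >= `neutral_tol`). Correlation over
#' an all-neutral genome is undefined and would inflate similarity, so two
#' entirely neutral profiles yield `NA`.
#'
#' @param segments_l,segments_r Segment data.frames.
#' @param bin_kb Bin width in kb.
#' @param neutral_tol |log ratio| below which a bin counts as neutral.
#' @return Pearson correlation in \[-1, 1\], or NA.
#' @export
cnv_profile_similarity <- function(segments_l, segments_r, bin_kb = 1000,
                                   neutral_tol = 0.1) {
  if (is.null(segments_l) || is.null(segments_r) ||
      nrow(segments_l) == 0L || nrow(segments_r) == 0L) {
    warning("empty segment track; similarity is missing")
    return(NA_real_)
  }
  pl <- rasterize_log_ratio(segments_l, bin_kb)
  pr <- rasterize_log_ratio(segments_r, bin_kb)
  keep <- abs(pl) >= neutral_tol | abs(pr) >= neutral_tol
  if (!any(keep)) return(NA_real_)
  x <- pl[keep]; y <- pr[keep]
  if (all(x == 0) || all(y == 0)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    # a single uniform event leaves a constant profile over its own bins,
    # where Pearson is undefined; cosine similarity gives the natural 1/-1
    # for identical/mirrored profiles there
    return(sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
  }
  stats::cor(x, y)
}

# Length of the union of [start, end] intervals (inclusive coordinates).
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e + 1) {
      cur_e <- max(cur_e, end[i])
    } else {
      tot <- tot + (cur_e - cur_s + 1)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  tot + (cur_e - cur_s + 1)
}

#' Detect 1q gain
#'
#' Unions the chr1 q-arm intersections of all segments with log2 ratio
#' >= 0.5 (full gain; low-level gain >= 0.1 is reported separately) and
#' classifies the result by the covered fraction of 1q: `whole_arm` at
#' >= `whole_arm_frac` coverage, `partial` above zero, else `none`.
#'
#' @param segments Segment data.frame (any chromosome; only chr1 is used).
#' @param whole_arm_frac Coverage fraction called whole-arm (default 0.95).
#' @return List: `call` (none/partial/whole_arm), `fraction` of 1q covered
#'   by full gain, `fraction_low` covered at the low-level threshold.
#' @export
detect_1q_gain <- function(segments, whole_arm_frac = 0.95) {
  arm_len <- .chr1q[["end"]] - .chr1q[["start"]] + 1
  cover <- function(min_lr) {
    hit <- segments$chrom == "chr1" & segments$log_ratio >= min_lr &
      segments$end >= .chr1q[["start"]]
    if (!any(hit)) return(0)
    s <- pmax(segments$start[hit], .chr1q[["start"]])
    e <- pmin(segments$end[hit], .chr1q[["end"]])
    interval_union_length(s, e) / arm_len
  }
  frac_full <- cover(0.5)
  frac_low <- cover(0.1)
  call <- if (frac_full >= whole_arm_frac) "whole_arm"
          else if (frac_full > 0) "partial" else "none"
  list(call = call, fraction = frac_full, fraction_low = frac_low)
}

#' Flag a pair as clonally related
#'
#' Paired synchronous bilateral tumors arise independently, so shared
#' noncoding variants are few and copy-number profiles differ. A pair whose
#' shared noncoding fraction `n_shared / min(n_l, n_r)` reaches
#' `shared_frac_min` while the copy-number similarity is high (or
#' unavailable) is atypical for independent bilateral tumors and more
#' consistent with multifocal disease from one kidney; it is flagged.
#'
#' @param n_l,n_r Noncoding variant counts per tumor.
#' @param n_shared Shared noncoding count.
#' @param cnv_similarity Pearson similarity from
#'   [cnv_profile_similarity()], or NA when unavailable.
#' @param shared_frac_min,cnv_similarity_min Flag thresholds.
#' @return List `flag` (logical) and `reason` (string, empty when not
#'   flagged).
#' @export
flag_clonally_related <- function(n_l, n_r, n_shared, cnv_similarity = NA,
                                  shared_frac_min = 0.25,
                                  cnv_similarity_min = 0.8) {
  if (n_l == 0 || n_r == 0) {
    return(list(flag = FALSE, reason = ""))
  }
  frac <- n_shared / min(n_l, n_r)
  cnv_ok <- is.na(cnv_similarity) || cnv_similarity >= cnv_similarity_min
  if (frac >= shared_frac_min && cnv_ok) {
    reason <- sprintf(
      "shared noncoding fraction %.3f >= %.2f%s",
      frac, shared_frac_min,
      if (is.na(cnv_similarity)) " (CNV similarity unavailable)"
      else sprintf(" and CNV similarity %.2f >= %.2f",
                   cnv_similarity, cnv_similarity_min))
    list(flag = TRUE, reason = reason)
  } else {
    list(flag = FALSE, reason = "")
  }
}

#' Do paired tumors share their 11p15.5 status?
#'
#' @param status_l,status_r Status labels (ROI/LOI/LOH/indeterminate).
#' @return TRUE/FALSE, or NA when either side is indeterminate.
#' @export
pair_status_agreement <- function(status_l, status_r) {
  ifelse(status_l == "indeterminate" | status_r == "indeterminate",
         NA, status_l == status_r)
}

#' Build a full pair report for one patient
#'
#' Runs the shared/private partition, CNV profile similarity, 11p15.5
#' agreement and the clonality flag for one synchronous tumor pair.
#'
#' @param patient_id Patient label.
#' @param variants_l,variants_r Somatic variant data.frames.
#' @param segments_l,segments_r Segment tracks (optional, NULL allowed).
#' @param call_l,call_r One-row imprinting-call data.frames (optional).
#' @param ... Threshold overrides passed to [flag_clonally_related()].
#' @return One-row data.frame mirroring the pair-report fields.
#' @export
pair_report <- function(patient_id, variants_l, variants_r,
                        segments_l = NULL, segments_r = NULL,
                        call_l = NULL, call_r = NULL, ...) {
  part <- shared_private_partition(variants_l, variants_r)
  nc <- part$counts[part$counts$region_class == "noncoding", ]
  cod <- part$counts[part$counts$region_class == "coding", ]
  sim <- if (!is.null(segments_l) && !is.null(segments_r)) {
    cnv_profile_similarity(segments_l, segments_r)
  } else NA_real_
  agree <- if (!is.null(call_l) && !is.null(call_r)) {
    pair_status_agreement(call_l$status, call_r$status)
  } else NA
  cl <- flag_clonally_related(nc$n_l, nc$n_r, nc$n_shared, sim, ...)
  data.frame(
    patient_id = patient_id,
    n_coding_l = cod$n_l, n_coding_r = cod$n_r, n_shared_coding = cod$n_shared,
    n_noncoding_l = nc$n_l, n_noncoding_r = nc$n_r,
    n_shared_noncoding = nc$n_shared,
    cnv_similarity = sim, status_shared = agree,
    clonal_flag = cl$flag, flag_reason = cl$reason,
    stringsAsFactors = FALSE
  )
}

#' Read the shipped paired-tumor summary fixture
#'
#' A 15-row table of whole-genome-sequenced synchronous pairs: per-tumor
#' noncoding somatic variant counts, shared noncoding counts, 11p15.5
#' status and predisposing germline variant genes ("No" when none was
#' identified). Transcribed field-for-field from the published study table.
#'
#' @param path Path to the TSV; defaults to the copy shipped under
#'   `inst/extdata/table1.tsv`.
#' @return data.frame with columns case_id, n_noncoding_t1, n_noncoding_t2,
#'   n_shared_noncoding, status_11p15, germline_genes.
#' @export
read_pair_summary_table <- function(path = system.file(
  "extdata", "table1.tsv", package = "imprintscope")) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Analyze a paired-tumor summary table
#'
#' Applies the clonality flag to each row of a count-level pair summary
#' (as from [read_pair_summary_table()]) and tabulates the
#' germline-versus-11p15.5 predisposition split: pairs lacking a germline
#' variant, whether those pairs show loss of imprinting, and whether each
#' shares at least one noncoding variant.
#'
#' @param tab data.frame as returned by [read_pair_summary_table()].
#' @param ... Threshold overrides for [flag_clonally_related()].
#' @return The table with appended columns `has_germline`, `has_loi` (LOI
#'   detected in at least one tumor), `uniform_loi` (both tumors LOI),
#'   `clonal_flag`, `flag_reason`.
#' @export
analyze_pair_summary <- function(tab, ...) {
  flags <- lapply(seq_len(nrow(tab)), function(i) {
    flag_clonally_related(tab$n_noncoding_t1[i], tab$n_noncoding_t2[i],
                          tab$n_shared_noncoding[i], NA, ...)
  })
  tab$has_germline <- tab$germline_genes != "No"
  tab$has_loi <- grepl("LOI", tab$status_11p15)
  tab$uniform_loi <- tab$status_11p15 == "LOI"
  tab$clonal_flag <- vapply(flags, `[[`, logical(1), "flag")
  tab$flag_reason <- vapply(flags, `[[`, character(1), "reason")
  tab
}
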