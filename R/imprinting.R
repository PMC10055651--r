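# 11p15.5 imprinting-status classification, mosaic-fraction estimation and a
# change-point caller for copy-neutral LOH on folded B-allele fractions.
#
# Status vocabulary:
#   ROI  - retention of imprinting: ICR1 and ICR2 both near the one-allele-
#          methylated expectation of 0.5.
#   LOI  - loss of imprinting: gain of methylation at H19/ICR1 (beta > 0.7)
#          with normal KCNQ1OT1/ICR2 (beta > 0.3).
#   LOH  - (copy-neutral) loss of heterozygosity / paternal uniparental
#          disomy: ICR1 hypermethylated (> 0.7) and ICR2 hypomethylated
#          (< 0.3), or LOH evidence from segmentation.
# Boundary equalities (exactly 0.7 / 0.3) are deliberately indeterminate:
# the thresholds are defined by strict inequalities on both sides.

#' Region-mean beta for one sample
#'
#' Unweighted mean of all non-missing in-window probes. Probe membership is
#' inclusive on both window ends. Zero usable probes is a reportable
#' condition, not an error: the mean comes back `NA` with `n_probes = 0`.
#'
#' @param beta Probes x samples beta matrix (see [read_beta_matrix()]).
#' @param manifest Probe manifest data.frame.
#' @param region A [genomic_region()].
#' @param sample_id Column to average.
#' @return List with `mean` (beta or NA) and `n_probes` used.
#' @export
region_mean_beta <- function(beta, manifest, region, sample_id) {
  if (!sample_id %in% colnames(beta)) {
    stop("sample ", sample_id, " not in beta matrix")
  }
  in_win <- manifest$chrom == region$chrom &
    manifest$pos >= region$start & manifest$pos <= region$end
  probes <- intersect(manifest$probe_id[in_win], rownames(beta))
  vals <- beta[probes, sample_id]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    return(list(mean = NA_real_, n_probes = 0L))
  }
  list(mean = mean(vals), n_probes = length(vals))
}

#' Classify 11p15.5 imprinting status
#'
#' Applies the beta-threshold rule table to the H19/ICR1 and KCNQ1OT1/ICR2
#' region means: ICR1 < 0.7 and ICR2 > 0.3 is ROI; ICR1 > 0.7 and
#' ICR2 > 0.3 is LOI; ICR1 > 0.7 and ICR2 < 0.3 is LOH. Samples with
#' LOH or partial LOH detected from sequencing-based segmentation are
#' designated LOH regardless of the methylation call. Values exactly at a
#' threshold, missing means, or the unnamed fourth quadrant (ICR1 < 0.7,
#' ICR2 < 0.3) are `indeterminate`.
#'
#' @param mean_icr1,mean_icr2 Region-mean betas (vectors, NA allowed).
#' @param seg_cnloh Logical: cnLOH/partial cnLOH evidence from segmentation.
#' @param icr1_thresh,icr2_thresh Classification thresholds (strict
#'   inequalities on both sides).
#' @return data.frame with columns `status` (ROI/LOI/LOH/indeterminate) and
#'   `loh_source` (methylation/segmentation/both/none).
#' @export
classify_imprinting <- function(mean_icr1, mean_icr2, seg_cnloh = FALSE,
                                icr1_thresh = 0.7, icr2_thresh = 0.3) {
  n <- max(length(mean_icr1), length(mean_icr2), length(seg_cnloh))
  m1 <- rep_len(as.numeric(mean_icr1), n)
  m2 <- rep_len(as.numeric(mean_icr2), n)
  seg <- rep_len(as.logical(seg_cnloh), n)
  seg[is.na(seg)] <- FALSE
  if (any(!is.na(m1) & (m1 < 0 | m1 > 1)) ||
      any(!is.na(m2) & (m2 < 0 | m2 > 1))) {
    stop("region-mean beta outside [0, 1]")
  }

  status <- rep("indeterminate", n)
  usable <- !is.na(m1) & !is.na(m2)
  hi1 <- usable & m1 > icr1_thresh
  lo1 <- usable & m1 < icr1_thresh
  hi2 <- usable & m2 > icr2_thresh
  lo2 <- usable & m2 < icr2_thresh
  status[lo1 & hi2] <- "ROI"
  status[hi1 & hi2] <- "LOI"
  status[hi1 & lo2] <- "LOH"

  meth_loh <- status == "LOH"
  status[seg] <- "LOH"
  loh_source <- rep("none", n)
  loh_source[meth_loh & !seg] <- "methylation"
  loh_source[!meth_loh & seg] <- "segmentation"
  loh_source[meth_loh & seg] <- "both"
  data.frame(status = status, loh_source = loh_source,
             stringsAsFactors = FALSE)
}

#' Estimate the mosaic fraction from region-mean betas
#'
#' Inverts the cell-population mixture model: normal (ROI) cells contribute
#' (0.5, 0.5) at (ICR1, ICR2), LOI cells (1.0, 0.5) and LOH cells
#' (1.0, 0.0), so a tissue with altered-cell fraction f has expectation
#' `b1 + (1 - b1) f` at ICR1 and, for LOH, `b2 (1 - f)` at ICR2. For LOI
#' (and ROI, where the estimate is a noise floor) only the ICR1 inversion is
#' used; for LOH the ICR1- and ICR2-derived estimates are averaged.
#' Baselines default to the theoretical 0.5 but may be recalibrated to an
#' observed control mean, since array betas are attenuated toward 0.5.
#'
#' @param mean_icr1,mean_icr2 Region-mean betas.
#' @param status One of ROI/LOI/LOH (vectors recycled).
#' @param baseline_icr1,baseline_icr2 Unaltered-tissue baselines in (0, 1).
#' @return Estimated fraction(s) in \[0, 1\].
#' @export
estimate_mosaic_fraction <- function(mean_icr1, mean_icr2, status,
                                     baseline_icr1 = 0.5,
                                     baseline_icr2 = 0.5) {
  if (baseline_icr1 <= 0 || baseline_icr1 >= 1 ||
      baseline_icr2 <= 0 || baseline_icr2 >= 1) {
    stop("baselines must lie strictly inside (0, 1)")
  }
  n <- max(length(mean_icr1), length(mean_icr2), length(status))
  m1 <- rep_len(as.numeric(mean_icr1), n)
  m2 <- rep_len(as.numeric(mean_icr2), n)
  st <- rep_len(as.character(status), n)
  if (any(!st %in% c("ROI", "LOI", "LOH"))) {
    stop("status must be ROI, LOI or LOH")
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  f1 <- clamp01((m1 - baseline_icr1) / (1 - baseline_icr1))
  f2 <- clamp01((baseline_icr2 - m2) / baseline_icr2)
  ifelse(st == "LOH", (f1 + f2) / 2, f1)
}

#' Full per-sample imprinting call table
#'
#' Convenience wrapper running [region_mean_beta()], [classify_imprinting()]
#' and [estimate_mosaic_fraction()] over every sample. Samples with fewer
#' than `min_probes` usable probes in either window are indeterminate.
#'
#' @param beta Beta matrix.
#' @param manifest Probe manifest.
#' @param regions List with `icr1` and `icr2` regions
#'   (default [default_regions()]).
#' @param segments Optional segment track with `sample_id` column; samples
#'   owning a chr11 cnloh/partial_cnloh segment overlapping ICR1 gain
#'   segmentation LOH evidence.
#' @param min_probes Minimum usable probes per window (default 3).
#' @param baseline_icr1,baseline_icr2 Passed to
#'   [estimate_mosaic_fraction()].
#' @return data.frame of imprinting calls, one row per sample: region means,
#'   probe counts, status, loh_source, mosaic_f (NA for indeterminate).
#' @export
classify_cohort <- function(beta, manifest, regions = default_regions(),
                            segments = NULL, min_probes = 3L,
                            baseline_icr1 = 0.5, baseline_icr2 = 0.5) {
  samples <- colnames(beta)
  m1 <- m2 <- numeric(length(samples))
  n1 <- n2 <- integer(length(samples))
  for (i in seq_along(samples)) {
    r1 <- region_mean_beta(beta, manifest, regions$icr1, samples[i])
    r2 <- region_mean_beta(beta, manifest, regions$icr2, samples[i])
    m1[i] <- r1$mean; n1[i] <- r1$n_probes
    m2[i] <- r2$mean; n2[i] <- r2$n_probes
  }
  low_cov <- n1 < min_probes | n2 < min_probes
  m1[low_cov] <- NA_real_
  m2[low_cov] <- NA_real_

  seg_ev <- rep(FALSE, length(samples))
  if (!is.null(segments) && nrow(segments)) {
    loh_segs <- segments[segments$state %in% c("cnloh", "partial_cnloh") &
                           segments$chrom == regions$icr1$chrom, , drop = FALSE]
    covers <- loh_segs$start <= regions$icr1$end &
      loh_segs$end >= regions$icr1$start
    seg_ev <- samples %in% loh_segs$sample_id[covers]
  }
  cls <- classify_imprinting(m1, m2, seg_ev)
  mosaic_f <- rep(NA_real_, length(samples))
  est <- cls$status %in% c("LOI", "LOH", "ROI") & !is.na(m1) & !is.na(m2)
  if (any(est)) {
    mosaic_f[est] <- estimate_mosaic_fraction(
      m1[est], m2[est], cls$status[est], baseline_icr1, baseline_icr2)
  }
  data.frame(sample_id = samples, mean_icr1 = m1, mean_icr2 = m2,
             n_probes_icr1 = n1, n_probes_icr2 = n2,
             status = cls$status, loh_source = cls$loh_source,
             mosaic_f = mosaic_f, stringsAsFactors = FALSE)
}

# -- cnLOH calling from folded BAF -------------------------------------------

# Recursive binary segmentation on a numeric series: repeatedly place the
# change point that maximally reduces the within-segment sum of squares,
# honouring a minimum segment length, then merge adjacent segments whose
# means differ by less than merge_tol. Returns integer segment start indices.
binseg_breaks <- function(x, min_len = 10L, merge_tol = 0.05) {
  n <- length(x)
  best_split <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_len) return(NULL)
    seg <- x[lo:hi]
    cs <- cumsum(seg); tot <- cs[len]
    k <- seq.int(min_len, len - min_len)
    # SSE reduction of splitting after position k (within-segment index)
    gain <- cs[k]^2 / k + (tot - cs[k])^2 / (len - k) - tot^2 / len
    kbest <- k[which.max(gain)]
    if (max(gain) <= 0) return(NULL)
    # require the split to move the means materially
    m_l <- cs[kbest] / kbest
    m_r <- (tot - cs[kbest]) / (len - kbest)
    if (abs(m_l - m_r) < merge_tol) return(NULL)
    lo + kbest - 1L
  }
  recurse <- function(lo, hi) {
    sp <- best_split(lo, hi)
    if (is.null(sp)) return(integer())
    c(recurse(lo, sp), sp, recurse(sp + 1L, hi))
  }
  cuts <- recurse(1L, n)
  starts <- c(1L, cuts + 1L)
  # merge pass: collapse adjacent segments with near-equal means
  repeat {
    if (length(starts) < 2L) break
    ends <- c(starts[-1L] - 1L, n)
    means <- vapply(seq_along(starts),
                    function(i) mean(x[starts[i]:ends[i]]), numeric(1))
    d <- abs(diff(means))
    if (all(d >= merge_tol)) break
    drop <- which.min(d) + 1L
    starts <- starts[-drop]
  }
  starts
}

#' Call copy-neutral LOH on 11p from a SNP-level BAF track
#'
#' A deliberately simple stand-in for sequencing-based CNV/LOH callers:
#' recursive binary segmentation on the folded B-allele fraction
#' `|BAF - 0.5|` with a minimum segment of `min_snps` SNPs, followed by
#' state assignment. A segment is LOH-like when its mean folded BAF is at
#' least 0.15 while the copy-number log ratio stays within (-0.1, 0.1)
#' (copy-neutral); deviation >= 0.35 is called `cnloh` (near-pure), below
#' that `partial_cnloh`. Fewer than `min_informative` SNPs yields a no-call
#' with a reason instead of segments.
#'
#' @param snp_track data.frame with columns `pos`, `baf` and `log_ratio`
#'   (per-SNP or per-bin log2 ratio aligned to the SNPs), chr11p sorted by
#'   position.
#' @param min_informative Minimum heterozygous-informative SNPs (default 20).
#' @param min_snps Minimum SNPs per segment for the change-point search.
#' @param merge_tol Mean folded-BAF difference below which adjacent segments
#'   are merged.
#' @return List with `segments` (data.frame chrom/start/end/log_ratio/
#'   baf_dev/state/n_snps) and `no_call_reason` (NULL when called).
#' @export
call_cnloh_11p <- function(snp_track, min_informative = 20L, min_snps = 10L,
                           merge_tol = 0.05) {
  if (nrow(snp_track) < min_informative) {
    return(list(segments = NULL,
                no_call_reason = sprintf(
                  "only %d informative SNPs (need >= %d)",
                  nrow(snp_track), min_informative)))
  }
  ord <- order(snp_track$pos)
  pos <- snp_track$pos[ord]
  fold <- abs(snp_track$baf[ord] - 0.5)
  lr <- snp_track$log_ratio[ord]
  starts <- binseg_breaks(fold, min_len = min_snps, merge_tol = merge_tol)
  ends <- c(starts[-1L] - 1L, length(fold))
  segs <- do.call(rbind, lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    data.frame(chrom = "chr11", start = pos[starts[i]], end = pos[ends[i]],
               log_ratio = mean(lr[idx]), baf_dev = mean(fold[idx]),
               n_snps = length(idx), stringsAsFactors = FALSE)
  }))
  segs$state <- "neutral"
  copy_neutral <- abs(segs$log_ratio) < 0.1
  segs$state[copy_neutral & segs$baf_dev >= 0.15] <- "partial_cnloh"
  segs$state[copy_neutral & segs$baf_dev >= 0.35] <- "cnloh"
  list(segments = segs, no_call_reason = NULL)
}

#' Does an 11p segment cover the imprinted and WT1 loci?
#'
#' Inclusive interval-intersection test of one segment against the 11p15.5
#' ICR window and the WT1/11p13 locus.
#'
#' @param segment One-row segment data.frame (chrom/start/end).
#' @param icr_region,wt1_region [genomic_region()]s; default the shipped
#'   windows.
#' @return List `covers_11p15_5`, `covers_wt1` (logicals).
#' @export
loci_overlap <- function(segment,
                         icr_region = default_regions()$icr1,
                         wt1_region = default_regions()$wt1) {
  if (segment$chrom != icr_region$chrom) {
    stop("segment must be on ", icr_region$chrom)
  }
  hits <- function(r) segment$start <= r$end && segment$end >= r$start
  list(covers_11p15_5 = hits(icr_region), covers_wt1 = hits(wt1_region))
}
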