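# Germline predisposition-variant triage: a fixed-precedence decision tree
# over annotated variant tables (gene panel, variant class, ClinVar
# assertion, PROVEAN/PolyPhen2 in-silico scores, tumor VAF enrichment).

#' Default Wilms-tumor predisposition gene mini-panel
#'
#' The 21 WT predisposition genes used as the shipped default panel; the
#' full cancer-gene panel (hundreds of genes) is user-supplied.
#'
#' @return Character vector of gene symbols.
#' @export
default_wt_panel <- function() {
  c("DICER1", "IGF2", "TP53", "WT1", "ASXL1", "BRCA2", "CDC73", "FBXW7",
    "PIK3CA", "BLM", "BUB1B", "CTR9", "DIS3L2", "GPC3", "KDM3B", "NYNRIN",
    "PALB2", "REST", "TRIP13", "TRIM28", "TRIM37")
}

.variant_classes <- c("nonsense", "frameshift", "inframe_indel", "missense",
                      "splice", "other")
.clinvar_states <- c("pathogenic", "likely_pathogenic", "benign",
                     "likely_benign", "vus", "no_assertion", "unreported")
.polyphen_states <- c("benign", "possibly_damaging", "damaging", "missing")

#' One-sided Fisher test for tumor VAF enrichment
#'
#' Tests whether the variant allele fraction is significantly higher in the
#' tumor than in the germline tissue (consistent with retention of the
#' mutated allele through tumor LOH), via a one-sided Fisher exact test on
#' the 2x2 ref/alt x tissue depth table.
#'
#' @param germline_ref,germline_alt,tumor_ref,tumor_alt Read depths.
#' @param alpha Significance level (default 0.05).
#' @return List `p_value`, `significant`.
#' @export
vaf_enrichment_test <- function(germline_ref, germline_alt,
                                tumor_ref, tumor_alt, alpha = 0.05) {
  depths <- c(germline_ref, germline_alt, tumor_ref, tumor_alt)
  if (any(is.na(depths)) || any(depths < 0)) {
    stop("depths must be nonnegative and non-missing")
  }
  if (germline_ref + germline_alt == 0 || tumor_ref + tumor_alt == 0) {
    stop("zero total depth in one tissue")
  }
  tab <- matrix(c(germline_ref, germline_alt, tumor_ref, tumor_alt),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("germline", "tumor"), c("ref", "alt")))
  # odds ratio (germline_ref * tumor_alt) / (germline_alt * tumor_ref):
  # "greater" is the tumor-alt-enriched direction
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(p_value = p, significant = p < alpha)
}

#' Triage one annotated germline variant
#'
#' Fixed rule order: (1) genes outside the panel are excluded; (2) all
#' insertion/deletion and nonsense variants are included; (3) ClinVar
#' pathogenic / likely pathogenic are included; (4) ClinVar benign / likely
#' benign are excluded (pre-empting in-silico scores — a curated benign
#' assertion outranks a prediction); (5) VUS / no-assertion / unreported
#' variants are included when PROVEAN calls them deleterious
#' (score <= `provean_cutoff`), PolyPhen2 calls them possibly damaging or
#' damaging, or the tumor shows significant VAF enrichment over germline
#' ([vaf_enrichment_test()]); otherwise excluded. Splice variants carry no
#' indel/nonsense shortcut and traverse step 5 like missense.
#'
#' @param gene Gene symbol (case-insensitive against the panel).
#' @param variant_class One of nonsense, frameshift, inframe_indel,
#'   missense, splice, other.
#' @param clinvar One of pathogenic, likely_pathogenic, benign,
#'   likely_benign, vus, no_assertion, unreported.
#' @param provean_score Numeric or NA.
#' @param polyphen2 One of benign, possibly_damaging, damaging, missing.
#' @param germline_ref,germline_alt,tumor_ref,tumor_alt Depths for the VAF
#'   step (NA allowed; the step is then unavailable).
#' @param panel Gene panel, default [default_wt_panel()].
#' @param provean_cutoff PROVEAN deleterious cutoff (default -2.5, the
#'   tool's published default).
#' @param vaf_alpha Significance level for the VAF step.
#' @return List `include` (logical) and `reason` (character vector of rule
#'   codes fired, in order).
#' @export
triage_variant <- function(gene, variant_class, clinvar,
                           provean_score = NA, polyphen2 = "missing",
                           germline_ref = NA, germline_alt = NA,
                           tumor_ref = NA, tumor_alt = NA,
                           panel = default_wt_panel(),
                           provean_cutoff = -2.5, vaf_alpha = 0.05) {
  if (!variant_class %in% .variant_classes) {
    stop("unknown variant_class: ", variant_class)
  }
  if (!clinvar %in% .clinvar_states) stop("unknown clinvar state: ", clinvar)
  if (!polyphen2 %in% .polyphen_states) {
    stop("unknown polyphen2 state: ", polyphen2)
  }

  if (!toupper(gene) %in% toupper(panel)) {
    return(list(include = FALSE, reason = "off_panel"))
  }
  reason <- "panel"
  if (variant_class %in% c("nonsense", "frameshift", "inframe_indel")) {
    return(list(include = TRUE, reason = c(reason, "indel_nonsense")))
  }
  if (clinvar %in% c("pathogenic", "likely_pathogenic")) {
    return(list(include = TRUE, reason = c(reason, "clinvar_plp")))
  }
  if (clinvar %in% c("benign", "likely_benign")) {
    return(list(include = FALSE, reason = c(reason, "clinvar_benign_excluded")))
  }
  # step 5: VUS / no assertion / unreported
  if (!is.na(provean_score) && provean_score <= provean_cutoff) {
    return(list(include = TRUE, reason = c(reason, "provean_deleterious")))
  }
  if (polyphen2 %in% c("possibly_damaging", "damaging")) {
    return(list(include = TRUE, reason = c(reason, "polyphen_damaging")))
  }
  depths <- c(germline_ref, germline_alt, tumor_ref, tumor_alt)
  if (!any(is.na(depths)) &&
      germline_ref + germline_alt > 0 && tumor_ref + tumor_alt > 0) {
    vt <- vaf_enrichment_test(germline_ref, germline_alt, tumor_ref,
                              tumor_alt, alpha = vaf_alpha)
    if (vt$significant) {
      return(list(include = TRUE, reason = c(reason, "vaf_loh_rescue")))
    }
    return(list(include = FALSE, reason = c(reason, "excluded_default")))
  }
  if (is.na(provean_score) && polyphen2 == "missing") {
    warning("variant in ", gene,
            " has no in-silico scores or usable depths at step 5; excluded")
    return(list(include = FALSE, reason = c(reason, "insufficient_annotation")))
  }
  list(include = FALSE, reason = c(reason, "excluded_default"))
}

#' Triage a table of annotated germline variants
#'
#' Vectorized driver over [triage_variant()].
#'
#' @param variants data.frame with columns patient_id, gene, variant_class,
#'   clinvar, provean_score, polyphen2, germline_ref, germline_alt,
#'   tumor_ref, tumor_alt.
#' @inheritParams triage_variant
#' @return Input with appended `include` (logical) and `reason`
#'   (comma-joined rule codes).
#' @export
triage_table <- function(variants, panel = default_wt_panel(),
                         provean_cutoff = -2.5, vaf_alpha = 0.05) {
  need <- c("gene", "variant_class", "clinvar")
  if (!all(need %in% names(variants))) {
    stop("triage table needs columns: ", paste(need, collapse = ", "))
  }
  opt <- c(provean_score = NA_real_, polyphen2 = "missing",
           germline_ref = NA_real_, germline_alt = NA_real_,
           tumor_ref = NA_real_, tumor_alt = NA_real_)
  for (col in names(opt)) {
    if (!col %in% names(variants)) {
      variants[[col]] <- rep(opt[[col]], nrow(variants))
    }
  }
  res <- lapply(seq_len(nrow(variants)), function(i) {
    triage_variant(variants$gene[i], variants$variant_class[i],
                   variants$clinvar[i], variants$provean_score[i],
                   variants$polyphen2[i], variants$germline_ref[i],
                   variants$germline_alt[i], variants$tumor_ref[i],
                   variants$tumor_alt[i], panel = panel,
                   provean_cutoff = provean_cutoff, vaf_alpha = vaf_alpha)
  })
  variants$include <- vapply(res, `[[`, logical(1), "include")
  variants$reason <- vapply(res, function(r) paste(r$reason, collapse = ","),
                            character(1))
  variants
}

#' Per-patient germline summary
#'
#' @param triaged Output of [triage_table()] with a `patient_id` column.
#' @return List with `per_patient` (patient_id, any_included, n_included,
#'   genes) and `prevalence`, the fraction of patients with at least one
#'   included variant.
#' @export
summarize_germline <- function(triaged) {
  if (nrow(triaged) == 0L) {
    return(list(per_patient = data.frame(patient_id = character(),
                                         any_included = logical(),
                                         n_included = integer(),
                                         genes = character(),
                                         stringsAsFactors = FALSE),
                prevalence = NA_real_))
  }
  sp <- split(triaged, triaged$patient_id)
  per_patient <- do.call(rbind, lapply(names(sp), function(pid) {
    inc <- sp[[pid]][sp[[pid]]$include, , drop = FALSE]
    data.frame(patient_id = pid, any_included = nrow(inc) > 0,
               n_included = nrow(inc),
               genes = paste(sort(unique(inc$gene)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(per_patient) <- NULL
  list(per_patient = per_patient,
       prevalence = mean(per_patient$any_included))
}
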