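# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Tiny manifest: 3 ICR1 probes, 2 ICR2 probes, 2 background autosomal
# probes and 1 chrX probe.
tiny_manifest <- function() {
  data.frame(
    probe_id = paste0("cg", 1:8),
    chrom = c(rep("chr11", 5), "chr2", "chr7", "chrX"),
    pos = c(2019974, 2022000, 2024738, 2721228, 2722228,
            5e6, 9e6, 3e6),
    stringsAsFactors = FALSE
  )
}

# Beta matrix over the tiny manifest for named samples; `icr1`, `icr2` and
# `bg` give per-sample region values.
tiny_beta <- function(samples, icr1, icr2, bg = 0.5) {
  bg <- rep_len(bg, length(samples))
  beta <- vapply(seq_along(samples), function(i) {
    c(rep(icr1[i], 3), rep(icr2[i], 2), rep(bg[i], 3))
  }, numeric(8))
  dimnames(beta) <- list(paste0("cg", 1:8), samples)
  beta
}

# Variant table from bare position keys (chr1, given positions).
variants_at <- function(pos, sample_id = "S1", region_class = "noncoding") {
  if (length(pos) == 0L) return(imprintscope:::empty_variants())
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
             sample_id = sample_id, region_class = region_class,
             gene = NA_character_, ref_depth = 30, alt_depth = 20,
             stringsAsFactors = FALSE)
}

write_tmp_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tmp.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
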