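# shared fixtures: bundled knowledge base (loaded once per run) and a
# constructor for hand-built annotation rows.

bundled_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- load_knowledge_base()
    kb
  }
})

# one-row variant annotation with sensible defaults; fields override.
make_variant <- function(gene, so_terms, pos = 1000L, ref = "A", alt = "T",
                         transcript_id = paste0(gene, "_TOY"),
                         population_af = 1e-6, variant_class = NULL,
                         hgvs_p = NA_character_, hgvs_c = NA_character_,
                         protein_pos = NA_integer_, exon_inclusion = NA_real_,
                         lof_confidence = NA_character_,
                         clin_sig = NA_character_, splice_evidence = FALSE,
                         nmd_tag = NA_character_, canonical = TRUE,
                         genotypes = NULL, chrom = "chrT") {
  df <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    variant_key = sprintf("%s:%d:%s:%s", chrom, pos, ref, alt),
    gene = gene, transcript_id = transcript_id, canonical = canonical,
    so_terms = so_terms, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    protein_pos = protein_pos, exon_rank = NA_integer_,
    population_af = population_af, lof_confidence = lof_confidence,
    clin_sig = clin_sig, splice_evidence = splice_evidence,
    nmd_tag = nmd_tag, stringsAsFactors = FALSE)
  df$nmd_status <- "not_applicable"
  df$variant_class <- NA_character_
  df$exon_inclusion <- exon_inclusion
  if (!is.null(variant_class)) {
    df$nmd_status <- if (grepl("escaping", variant_class)) "escaping"
                     else if (variant_class == "nmd_truncating") "triggering"
                     else "not_applicable"
    df$variant_class <- variant_class
  }
  if (!is.null(genotypes)) df$genotypes <- list(genotypes)
  class(df) <- c("g2p_variants", "data.frame")
  df
}

rbind_variants <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("g2p_variants", "data.frame")
  out
}
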