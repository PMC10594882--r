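# Independent flat-rule oracles, deliberately written as single boolean
# expressions per pipeline rather than the staged engine's pass/fail traces.

oracle_freq <- function(af, threshold = 1e-4) is.na(af) || af < threshold

# pipeline 3 as one flat expression over (gene, class, af, constraints).
oracle_p3 <- function(v, kb, threshold = 1e-4) {
  if (!oracle_freq(v$population_af, threshold)) return(FALSE)
  recs <- records_for_gene(kb, v$gene)
  if (!length(recs)) return(FALSE)
  strip <- function(x) gsub("^[pc]\\.|[()[:space:]]", "", sub("^.*:", "", x))
  hgvs <- strip(stats::na.omit(c(v$hgvs_p, v$hgvs_c)))
  any(vapply(recs, function(r) {
    forced <- any(vapply(r$constraints, function(cn)
      cn$kind == "class_force_retain" &&
        identical(cn$target_class, "intronic_splice_affecting") &&
        any(strsplit(v$so_terms, "&")[[1]] %in%
              c("intron_variant", "splice_region_variant")), logical(1)))
    if (forced) return(TRUE)
    cls <- v$variant_class
    if (is.na(cls) || !cls %in% r$variant_classes) return(FALSE)
    all(vapply(r$constraints, function(cn) {
      mode <- if (is.na(cn$mode)) "restrict" else cn$mode
      if (mode != "restrict") return(TRUE)
      if (cn$kind %in% c("variant_allowlist", "class_drop_except_allowlist") &&
          identical(cn$target_class, cls))
        return(length(hgvs) > 0 && any(hgvs %in% strip(cn$alleles)))
      if (cn$kind == "exon_mask" && identical(cn$target_class, cls))
        return(is.na(v$exon_inclusion) || v$exon_inclusion > cn$threshold)
      TRUE
    }, logical(1)))
  }, logical(1)))
}

oracle_p1 <- function(v, gene_set, threshold = 1e-4) {
  pav <- c("missense_variant", "stop_gained", "frameshift_variant",
           "inframe_insertion", "inframe_deletion", "splice_acceptor_variant",
           "splice_donor_variant", "start_lost", "stop_lost",
           "protein_altering_variant", "transcript_ablation",
           "exon_loss_variant", "feature_truncation")
  v$gene %in% gene_set && oracle_freq(v$population_af, threshold) &&
    any(strsplit(v$so_terms, "&")[[1]] %in% pav)
}

oracle_p2 <- function(v, gene_set, threshold = 1e-4) {
  trunc <- c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
             "splice_donor_variant", "transcript_ablation", "exon_loss_variant")
  plp <- !is.na(v$clin_sig) &&
    any(tolower(trimws(strsplit(v$clin_sig, "[&,;]")[[1]])) %in%
          c("pathogenic", "likely_pathogenic", "pathogenic/likely_pathogenic"))
  v$gene %in% gene_set && oracle_freq(v$population_af, threshold) &&
    ((any(strsplit(v$so_terms, "&")[[1]] %in% trunc) &&
        identical(v$lof_confidence, "HC")) || plp)
}

# exhaustive Fisher oracle: enumerate every table with the observed margins,
# computing each probability from factorials, and sum those no more likely
# than the observed table.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ptab <- function(x) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
          lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, ptab, numeric(1))
  sum(probs[probs <= ptab(a) * (1 + 1e-7)])
}
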