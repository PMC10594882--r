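#' Closed vocabularies for the cardiac gene-disease knowledge base
#'
#' The knowledge base uses a small set of closed vocabularies derived from the
#' GenCC standardised terminology: disease panels, ClinGen gene-disease
#' validity grades, inheritance modes and qualifiers, allelic requirement,
#' disease-associated variant-consequence ("mechanism") terms, and the variant
#' classes reported with evidence of pathogenicity. Every loader and validator
#' in the package enforces these vocabularies strictly: an unknown token is an
#' error naming the offending value, never a silent coercion.
#'
#' @format Each object is a character vector of permitted tokens.
#' @name g2p_vocabulary
NULL

#' @rdname g2p_vocabulary
#' @export
G2P_PANELS <- c("HCM", "HCM_syndromic", "DCM", "ARVC",
                "LQTS", "BrS", "CPVT", "SQTS")

#' @rdname g2p_vocabulary
#' @export
G2P_PANEL_GROUPS <- list(
  cardiomyopathy = c("HCM", "HCM_syndromic", "DCM", "ARVC"),
  channelopathy  = c("LQTS", "BrS", "CPVT", "SQTS")
)

#' @rdname g2p_vocabulary
#' @export
G2P_VALIDITY <- c("Definitive", "Strong", "Moderate", "Limited", "Disputed")

# Validity grades at which a record counts as curated (given non-empty
# mechanisms); Limited/Disputed rows are metadata carried for completeness.
G2P_VALIDITY_CURATED <- c("Definitive", "Strong", "Moderate")

#' @rdname g2p_vocabulary
#' @export
G2P_INHERITANCE_MODES <- c("autosomal_dominant", "autosomal_recessive", "x_linked")

#' @rdname g2p_vocabulary
#' @export
G2P_INHERITANCE_QUALIFIERS <- c("incomplete_penetrance", "age_related_onset",
                                "typically_de_novo")

#' @rdname g2p_vocabulary
#' @export
G2P_ALLELIC_REQUIREMENTS <- c("monoallelic_autosomal", "biallelic_autosomal",
                              "monoallelic_x_linked")

#' @rdname g2p_vocabulary
#' @export
G2P_MECHANISM_TERMS <- c("decreased_gene_product_level",
                         "altered_gene_product_sequence",
                         "absent_gene_product_level")

#' @rdname g2p_vocabulary
#' @export
G2P_VARIANT_CLASSES <- c("missense", "inframe_indel", "nmd_truncating",
                         "stop_gained_nmd_escaping", "frameshift_nmd_escaping",
                         "splice_donor_nmd_escaping", "splice_acceptor_nmd_escaping",
                         "structural_exon_deletion", "whole_gene_deletion",
                         "structural_duplication", "complex_rearrangement",
                         "intronic_splice_affecting")

#' @rdname g2p_vocabulary
#' @export
G2P_CONSTRAINT_KINDS <- c("variant_allowlist", "class_drop_except_allowlist",
                          "region_flag", "exon_mask", "class_force_retain")

# SO consequence terms recognised by the classifier, most severe first.  The
# ordering is the usual VEP-style severity ranking and is the documented
# tie-break when an annotation carries several terms.
SO_SEVERITY_ORDER <- c(
  "transcript_ablation",
  "exon_loss_variant",
  "feature_truncation",
  "duplication",
  "feature_elongation",
  "frameshift_variant",
  "stop_gained",
  "splice_acceptor_variant",
  "splice_donor_variant",
  "stop_lost",
  "start_lost",
  "inframe_insertion",
  "inframe_deletion",
  "missense_variant",
  "protein_altering_variant",
  "splice_region_variant",
  "synonymous_variant",
  "stop_retained_variant",
  "start_retained_variant",
  "coding_sequence_variant",
  "5_prime_UTR_variant",
  "3_prime_UTR_variant",
  "intron_variant",
  "upstream_gene_variant",
  "downstream_gene_variant",
  "intergenic_variant"
)

# Terms counted as protein-altering by the generic PAV pipeline.
SO_PROTEIN_ALTERING <- c("missense_variant", "stop_gained", "frameshift_variant",
                         "inframe_insertion", "inframe_deletion",
                         "splice_acceptor_variant", "splice_donor_variant",
                         "start_lost", "stop_lost", "protein_altering_variant",
                         "transcript_ablation", "exon_loss_variant",
                         "feature_truncation")

# High-impact truncating terms for the LOFTEE arm of pipeline 2.
SO_HIGH_IMPACT_TRUNCATING <- c("stop_gained", "frameshift_variant",
                               "splice_acceptor_variant", "splice_donor_variant",
                               "transcript_ablation", "exon_loss_variant")

# Terms that can introduce a premature termination codon, i.e. the inputs to
# NMD adjudication.
SO_PTC_TERMS <- c("stop_gained", "frameshift_variant",
                  "splice_acceptor_variant", "splice_donor_variant")

# ClinVar tokens accepted as an unambiguous P/LP assertion (case-insensitive,
# exact token match after splitting aggregate strings).  Conflicting
# interpretation strings deliberately match nothing here.
CLINVAR_PLP_TOKENS <- c("pathogenic", "likely_pathogenic",
                        "pathogenic/likely_pathogenic")

#' Map a variant class to its implied disease-associated consequence terms
#'
#' Classes that abolish or reduce the amount of full-length gene product
#' (NMD-triggering truncations, exon or whole-gene deletions) imply
#' `decreased_gene_product_level`; classes that leave a product of altered
#' sequence (missense, inframe indels, NMD-escaping truncations, duplications,
#' complex rearrangements, and splice-affecting intronic variants whose
#' in-frame effect is unknown) imply `altered_gene_product_sequence`.  The
#' mapping is total over [G2P_VARIANT_CLASSES].
#'
#' @param vc Character vector of variant-class labels.
#' @return For a single label, a character vector of mechanism terms; for
#'   several labels, the union over all of them.
#' @examples
#' class_to_mechanism("nmd_truncating")
#' class_to_mechanism(c("missense", "whole_gene_deletion"))
#' @export
class_to_mechanism <- function(vc) {
  bad <- setdiff(vc, G2P_VARIANT_CLASSES)
  if (length(bad))
    stop("unknown variant class label(s): ", paste(bad, collapse = ", "))
  decreased <- c("nmd_truncating", "structural_exon_deletion", "whole_gene_deletion")
  out <- unique(unlist(lapply(vc, function(x) {
    if (x %in% decreased) "decreased_gene_product_level"
    else "altered_gene_product_sequence"
  })))
  out
}

# internal: check tokens against a vocabulary, with a context string for the
# error message ("row 12, column mechanisms").
check_vocab <- function(tokens, vocab, context) {
  bad <- setdiff(tokens, vocab)
  if (length(bad))
    stop(sprintf("%s: token(s) not in vocabulary: %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(tokens)
}

# internal: split a semicolon-joined cell into trimmed tokens.
split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}
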