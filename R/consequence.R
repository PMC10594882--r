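#' Adjudicate nonsense-mediated decay for a PTC-introducing variant
#'
#' Applies the canonical 50-nucleotide rule: a premature termination codon
#' escapes NMD when it falls in the last exon, within the final
#' `escape_window` (default 50) coding nucleotides upstream of the last
#' exon-exon junction, or when the transcript has a single (coding) exon;
#' otherwise the transcript is expected to be degraded (triggering).  Variants
#' that introduce no PTC (anything other than stop gained, frameshift, or
#' splice acceptor/donor disruption) return `not_applicable`.
#'
#' When the annotation already carries an NMD-escape tag from an upstream
#' annotator (`nmd_tag` of `"escaping"` or `"triggering"`), the tag overrides
#' the transcript-geometry computation, since upstream annotators may use
#' richer models than exon geometry alone.
#'
#' For frameshift variants the variant position is used as the PTC proxy (the
#' true PTC lies somewhere downstream, unresolvable without sequence); for
#' splice variants the nearest coding position on the 5' side of the
#' disrupted site is used.
#'
#' @param tm A `g2p_transcript` containing the variant.
#' @param variant A one-row variant data frame (or list) with at least `pos`
#'   and `so_terms` (`&`-separated SO terms), optionally `nmd_tag`.
#' @param escape_window Width in coding nucleotides of the escape zone
#'   upstream of the final junction (default 50).
#' @return One of `"triggering"`, `"escaping"`, `"not_applicable"`.
#' @examples
#' tm <- transcript_model("T1", "GENE", "+", c(1, 301), c(200, 500), 1, 500)
#' v  <- list(pos = 50, so_terms = "stop_gained")
#' classify_nmd(tm, v)
#' @export
classify_nmd <- function(tm, variant, escape_window = 50) {
  terms <- so_split(variant$so_terms)
  if (!any(terms %in% SO_PTC_TERMS)) return("not_applicable")
  tag <- variant$nmd_tag %||% NA_character_
  if (!is.na(tag) && nzchar(tag)) {
    check_vocab(tag, c("escaping", "triggering"), "nmd_tag")
    return(tag)
  }
  pos <- variant$pos
  if (pos < min(tm$exon_starts) || pos > max(tm$exon_ends))
    stop(sprintf("variant at %d lies outside transcript %s (%d-%d)",
                 pos, tm$transcript_id, min(tm$exon_starts), max(tm$exon_ends)))
  ce <- coding_exons(tm)
  if (nrow(ce) <= 1) return("escaping")
  off <- coding_offset(tm, pos)
  if (is.na(off)) {
    # upstream of the CDS in transcript sense: a PTC proxy there affects the
    # whole CDS and is NMD-competent
    return("triggering")
  }
  lens <- ce$end - ce$start + 1
  # coding offset of the last base before the final exon-exon junction
  last_junction <- sum(lens) - if (tm$strand == "+") lens[nrow(ce)] else lens[1]
  if (off > last_junction - escape_window) "escaping" else "triggering"
}

# internal: split a VEP-style '&'-joined consequence string.
so_split <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, "&", fixed = TRUE)[[1]])
}

#' Assign the knowledge-base variant class for one annotation
#'
#' Deterministic priority mapping from SO consequence terms (most severe
#' first, as ordered internally) to the closed variant-class vocabulary:
#' truncating terms (stop gained, frameshift, splice acceptor/donor) map to
#' `nmd_truncating` when NMD-triggering and to the corresponding
#' `*_nmd_escaping` label when escaping; missense maps to `missense`; inframe
#' insertions/deletions to `inframe_indel`; whole-gene and exon-level deletion
#' terms to `whole_gene_deletion`/`structural_exon_deletion`; duplications to
#' `structural_duplication`.  Intronic or splice-region annotations map to
#' `intronic_splice_affecting` only when the annotation carries an explicit
#' splice-evidence tag; a bare intron variant maps to no class (`NA`), as do
#' synonymous, UTR and other non-protein-affecting terms.
#'
#' @param variant One-row variant data frame (or list) with `so_terms` and
#'   optionally `splice_evidence`.
#' @param nmd NMD status from [classify_nmd()].
#' @return A variant-class label, or `NA_character_` when the (recognised)
#'   terms map to no class.  Unrecognised terms raise an error listing them.
#' @export
assign_variant_class <- function(variant, nmd = "not_applicable") {
  terms <- so_split(variant$so_terms)
  if (!length(terms)) stop("annotation has no SO consequence terms")
  unknown <- setdiff(terms, SO_SEVERITY_ORDER)
  if (length(unknown) == length(terms))
    stop("no recognised SO term among: ", paste(terms, collapse = ", "))
  terms <- terms[order(match(terms, SO_SEVERITY_ORDER))]
  splice_ev <- isTRUE(variant$splice_evidence %||% FALSE) ||
    isTRUE(as.logical(variant$splice_evidence %||% FALSE))
  escape_label <- c(stop_gained = "stop_gained_nmd_escaping",
                    frameshift_variant = "frameshift_nmd_escaping",
                    splice_acceptor_variant = "splice_acceptor_nmd_escaping",
                    splice_donor_variant = "splice_donor_nmd_escaping")
  for (t in terms) {
    lab <- switch(t,
      transcript_ablation = "whole_gene_deletion",
      exon_loss_variant = ,
      feature_truncation = "structural_exon_deletion",
      duplication = ,
      feature_elongation = "structural_duplication",
      frameshift_variant = ,
      stop_gained = ,
      splice_acceptor_variant = ,
      splice_donor_variant =
        if (identical(nmd, "escaping")) escape_label[[t]] else "nmd_truncating",
      inframe_insertion = ,
      inframe_deletion = "inframe_indel",
      missense_variant = "missense",
      splice_region_variant = ,
      intron_variant = if (splice_ev) "intronic_splice_affecting" else NA_character_,
      NA_character_)
    if (!is.null(lab) && !is.na(lab)) return(lab)
  }
  NA_character_
}

#' Classify a table of variant annotations
#'
#' Vectorised driver: for each annotation, looks up its transcript model (when
#' available), adjudicates NMD, assigns the variant class, and attaches the
#' exon-inclusion fraction at the variant position (for exon-mask
#' constraints).  Annotations on transcripts absent from `transcripts` are
#' classified with NMD geometry unknown: truncating terms default to
#' `nmd_truncating` unless tagged as escaping.
#'
#' @param variants A `g2p_variants` data frame (see [read_annotated_vcf()]).
#' @param transcripts Optional named list of `g2p_transcript`.
#' @param escape_window Passed to [classify_nmd()].
#' @return `variants` with columns `nmd_status`, `variant_class`,
#'   `exon_inclusion` added.
#' @export
classify_variants <- function(variants, transcripts = NULL, escape_window = 50) {
  n <- nrow(variants)
  nmd <- character(n); cls <- character(n); incl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- as.list(variants[i, , drop = FALSE])
    tm <- if (!is.null(transcripts)) transcripts[[v$transcript_id]] else NULL
    nmd[i] <- if (!is.null(tm)) {
      classify_nmd(tm, v, escape_window)
    } else if (any(so_split(v$so_terms) %in% SO_PTC_TERMS)) {
      tag <- v$nmd_tag %||% NA_character_
      if (!is.na(tag) && nzchar(tag)) tag else "triggering"
    } else "not_applicable"
    cls[i] <- tryCatch(assign_variant_class(v, nmd[i]),
                       error = function(e) NA_character_)
    if (!is.null(tm)) incl[i] <- inclusion_at(tm, v$pos)
  }
  variants$nmd_status <- nmd
  variants$variant_class <- cls
  variants$exon_inclusion <- incl
  variants
}
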