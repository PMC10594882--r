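#' Read a VEP-annotated VCF into a variant-annotation table
#'
#' Parses a VCF 4.2 file whose INFO column carries per-transcript functional
#' annotation in a VEP-style pipe-delimited payload (key `CSQ` by default;
#' the field schema is taken from the `Format: ...` clause of the INFO header
#' line).  Multi-allelic records are decomposed per alternate allele; one row
#' is emitted per variant-transcript annotation, positions stay 1-based as in
#' the VCF.  Both `SYMBOL`/`Gene` and `Feature`/`Feature_id` field spellings
#' are accepted; the population allele frequency is read from `af_field`
#' (default the gnomAD global AF field).
#'
#' @param path VCF path (plain or bgzipped).
#' @param csq_field INFO key of the annotation payload (default `"CSQ"`).
#' @param af_field Annotation field holding the population allele frequency.
#' @return A data frame of class `g2p_variants` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `variant_key`, `gene`, `transcript_id`, `canonical`,
#'   `so_terms`, `hgvs_c`, `hgvs_p`, `protein_pos`, `exon_rank`,
#'   `population_af`, `lof_confidence`, `clin_sig`, `splice_evidence`,
#'   `nmd_tag`, and (when the VCF has samples) a `genotypes` list-column of
#'   named vectors `sample -> {hom_ref, het, hom_alt, missing}`.
#' @export
read_annotated_vcf <- function(path, csq_field = "CSQ", af_field = "gnomAD_AF") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  hdr <- VariantAnnotation::header(vcf)
  info_hdr <- VariantAnnotation::info(hdr)
  if (!csq_field %in% rownames(info_hdr))
    stop("annotation INFO key '", csq_field, "' not declared in VCF header")
  desc <- info_hdr[csq_field, "Description"]
  fmt <- sub(".*Format:\\s*", "", desc)
  schema <- trimws(strsplit(gsub('"', "", fmt), "|", fixed = TRUE)[[1]])
  for (needed in list(c("Consequence"), c("SYMBOL", "Gene"),
                      c("Feature", "Feature_id"))) {
    if (!any(needed %in% schema))
      stop("annotation schema missing field: ", paste(needed, collapse = "/"))
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0) return(empty_variants())
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  csq <- VariantAnnotation::info(vcf)[[csq_field]]
  gt <- if (ncol(vcf) > 0 && "GT" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$GT else NULL
  pick <- function(fields, candidates) {
    hit <- candidates[candidates %in% names(fields)]
    if (length(hit)) fields[[hit[1]]] else NA_character_
  }
  rows <- list()
  for (i in seq_len(n)) {
    entries <- csq[[i]]
    if (length(entries) == 0 || all(is.na(entries))) next
    key <- sprintf("%s:%d:%s:%s", chrom[i], pos[i], ref[i], alt[i])
    gts <- if (!is.null(gt)) parse_genotypes(gt[i, ], alt_index = 1L) else NULL
    for (entry in entries) {
      parts <- strsplit(entry, "|", fixed = TRUE)[[1]]
      length(parts) <- length(schema)
      parts[is.na(parts)] <- ""
      fields <- stats::setNames(as.list(parts), schema)
      # per-allele payload: keep entries whose Allele matches this alt (VEP
      # writes the trimmed allele; accept either spelling), or all entries
      # when the field is absent
      if ("Allele" %in% schema && nzchar(fields$Allele) &&
          !fields$Allele %in% c(alt[i], vep_allele(ref[i], alt[i]))) next
      af_raw <- pick(fields, c(af_field, "AF", "gnomAD_AF"))
      pp_raw <- pick(fields, c("Protein_position"))
      exon_raw <- pick(fields, c("EXON"))
      row <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
        variant_key = key,
        gene = pick(fields, c("SYMBOL", "Gene")),
        transcript_id = pick(fields, c("Feature", "Feature_id")),
        canonical = identical(pick(fields, "CANONICAL"), "YES"),
        so_terms = fields$Consequence,
        hgvs_c = pick(fields, "HGVSc"),
        hgvs_p = pick(fields, "HGVSp"),
        protein_pos = parse_leading_int(pp_raw),
        exon_rank = parse_leading_int(exon_raw),
        population_af = if (is.na(af_raw) || !nzchar(af_raw)) NA_real_
                        else as.numeric(af_raw),
        lof_confidence = na_if_empty(pick(fields, c("LoF"))),
        clin_sig = na_if_empty(pick(fields, c("CLIN_SIG", "ClinVar_CLNSIG"))),
        splice_evidence = identical(pick(fields, "SPLICE_EVIDENCE"), "1"),
        nmd_tag = nmd_tag_of(pick(fields, "NMD")),
        stringsAsFactors = FALSE)
      if (!is.null(gts)) row$genotypes <- list(gts)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_variants())
  class(out) <- c("g2p_variants", "data.frame")
  out
}

empty_variants <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), variant_key = character(),
                    gene = character(), transcript_id = character(),
                    canonical = logical(), so_terms = character(),
                    hgvs_c = character(), hgvs_p = character(),
                    protein_pos = integer(), exon_rank = integer(),
                    population_af = numeric(), lof_confidence = character(),
                    clin_sig = character(), splice_evidence = logical(),
                    nmd_tag = character(), stringsAsFactors = FALSE)
  class(out) <- c("g2p_variants", "data.frame")
  out
}

na_if_empty <- function(x) if (is.na(x) || !nzchar(x)) NA_character_ else x

parse_leading_int <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_integer_)
  m <- regmatches(x, regexpr("^[0-9]+", x))
  if (length(m)) as.integer(m) else NA_integer_
}

nmd_tag_of <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  if (grepl("escap", x, ignore.case = TRUE)) "escaping" else "triggering"
}

# internal: VEP-style trimmed allele for simple indels ("-" for a pure
# deletion), so CSQ Allele matching works for either convention.
vep_allele <- function(ref, alt) {
  if (nchar(ref) > 1 && nchar(alt) == 1 && substr(ref, 1, 1) == alt) return("-")
  if (nchar(alt) > 1 && nchar(ref) == 1 && substr(alt, 1, 1) == ref)
    return(substr(alt, 2, nchar(alt)))
  alt
}

# internal: GT strings -> {hom_ref, het, hom_alt, missing} for one expanded
# alternate allele.
parse_genotypes <- function(gt_row, alt_index = 1L) {
  out <- vapply(gt_row, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    hits <- sum(alleles == as.character(alt_index))
    if (hits >= 2) "hom_alt" else if (hits == 1) "het" else "hom_ref"
  }, character(1))
  stats::setNames(out, names(gt_row))
}

#' Select the analysis transcript among a variant's annotations
#'
#' Policy, in order: the knowledge-base-designated transcript for the gene
#' (taken from a `transcript=<id>` token in the record narrative, e.g. the
#' TTN meta-transcript); otherwise the annotation tagged canonical; otherwise
#' the most severe consequence; ties broken by lexicographically smallest
#' transcript id.
#'
#' @param annotations Rows of a `g2p_variants` table for one variant-gene.
#' @param kb Optional `cardiac_g2p` knowledge base supplying designated
#'   transcripts.
#' @return A single row of `annotations`.
#' @export
select_transcript <- function(annotations, kb = NULL) {
  stopifnot(nrow(annotations) >= 1)
  if (nrow(annotations) == 1) return(annotations)
  if (!is.null(kb)) {
    designated <- designated_transcripts(kb, annotations$gene[1])
    hit <- which(annotations$transcript_id %in% designated)
    if (length(hit)) annotations <- annotations[hit, , drop = FALSE]
  }
  if (nrow(annotations) > 1 && any(annotations$canonical))
    annotations <- annotations[annotations$canonical, , drop = FALSE]
  if (nrow(annotations) > 1) {
    sev <- vapply(annotations$so_terms, function(s)
      min(match(so_split(s), SO_SEVERITY_ORDER), na.rm = TRUE), numeric(1))
    annotations <- annotations[sev == min(sev), , drop = FALSE]
  }
  annotations[order(annotations$transcript_id)[1], , drop = FALSE]
}

# internal: transcript ids named in a gene's record narratives.
designated_transcripts <- function(kb, gene) {
  recs <- records_for_gene(kb, gene)
  unlist(lapply(recs, function(r) {
    m <- regmatches(r$narrative,
                    gregexpr("transcript=([A-Za-z0-9_.]+)", r$narrative))[[1]]
    sub("^transcript=", "", m)
  }))
}

#' Reduce an annotation table to one row per variant-gene
#'
#' Applies [select_transcript()] within each (variant key, gene) group,
#' preserving input order of first appearance.  Pipelines evaluate each gene
#' a variant annotates separately and retain the variant if any gene-record
#' matches.
#'
#' @param variants A `g2p_variants` data frame.
#' @param kb Optional knowledge base for designated-transcript preference.
#' @return A `g2p_variants` data frame with one row per variant-gene.
#' @export
prepare_variants <- function(variants, kb = NULL) {
  if (nrow(variants) == 0) return(variants)
  grp <- paste(variants$variant_key, variants$gene, sep = "\r")
  keep <- unsplit_rows(lapply(split(seq_len(nrow(variants)), grp)[unique(grp)],
    function(idx) {
      sel <- select_transcript(variants[idx, , drop = FALSE], kb)
      idx[match(sel$transcript_id, variants$transcript_id[idx])][1]
    }))
  out <- variants[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

unsplit_rows <- function(x) as.integer(unlist(x, use.names = FALSE))

#' Write / read a decision table
#'
#' Tab-separated decision traces with columns `variant_key, gene, transcript,
#' class, pipeline, retained, matched_records, flags, stage_trace`; the
#' read-back reproduces the decisions (round trip).
#'
#' @param result A `g2p_result` (or its `decisions` data frame).
#' @param path Output path.
#' @return `write_decisions`: `path` invisibly; `read_decisions`: the
#'   decisions data frame.
#' @export
write_decisions <- function(result, path) {
  d <- if (inherits(result, "g2p_result")) result$decisions else result
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  d <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                         colClasses = "character", na.strings = NULL)
  d$retained <- d$retained == "TRUE"
  d$class[!nzchar(d$class)] <- NA_character_
  d$transcript[!nzchar(d$transcript)] <- NA_character_
  d
}
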