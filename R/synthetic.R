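#' Deterministic toy transcript models for fixtures
#'
#' A miniature contig (`chrT`) carries one toy transcript per panel gene used
#' by the fixture generator.  The set includes, by construction: a TTN-like
#' multi-exon transcript whose per-exon inclusion fractions straddle the 0.9
#' PSI cut-off (values 1.0, 0.95 and 0.5), a two-exon transcript for NMD
#' boundary tests, a single-exon transcript, and a minus-strand transcript.
#' Coordinates are synthetic; the filtering rules depend on annotations, not
#' sequence, so no reference genome is involved.
#'
#' @param seed Unused (the set is fully deterministic); kept so all fixture
#'   entry points share a signature.
#' @return Named list of `g2p_transcript`.
#' @export
build_toy_transcripts <- function(seed = 1L) {
  mk <- function(id, gene, base, lens, strand = "+", incl = NULL,
                 intron = 500L, utr = 60L) {
    starts <- integer(length(lens)); ends <- integer(length(lens))
    at <- base
    for (i in seq_along(lens)) {
      starts[i] <- at; ends[i] <- at + lens[i] - 1L
      at <- ends[i] + intron + 1L
    }
    transcript_model(id, gene, strand, starts, ends,
                     cds_start = starts[1] + utr, cds_end = ends[length(lens)] - utr,
                     exon_inclusion = incl)
  }
  tms <- list(
    mk("MYH7_TOY",   "MYH7",   100000L, c(300L, 240L, 300L, 240L, 300L)),
    mk("MYBPC3_TOY", "MYBPC3", 200000L, c(300L, 300L, 300L, 300L)),
    mk("TTN_TOY",    "TTN",    300000L, rep(300L, 8),
       incl = c(1, 1, 0.95, 0.5, 1, 1, 1, 1)),
    mk("TNNT2_TOY",  "TNNT2",  400000L, c(400L, 400L)),
    mk("MYL2_TOY",   "MYL2",   500000L, 600L),
    mk("TMEM43_TOY", "TMEM43", 600000L, c(500L, 500L, 400L)),
    mk("KCNQ1_TOY",  "KCNQ1",  700000L, c(600L, 600L, 600L, 500L)),
    mk("LMNA_TOY",   "LMNA",   800000L, c(300L, 300L, 300L, 300L)),
    mk("FLNC_TOY",   "FLNC",   900000L, c(400L, 400L, 400L)),
    mk("RBM20_TOY",  "RBM20", 1000000L, c(700L, 700L, 700L, 400L), strand = "-"),
    mk("SCN5A_TOY",  "SCN5A", 1100000L, c(500L, 500L, 500L)),
    mk("DES_TOY",    "DES",   1200000L, c(400L, 400L, 400L))
  )
  stats::setNames(tms, vapply(tms, `[[`, character(1), "transcript_id"))
}

# recipe registry: how each requested variant is realised on its toy
# transcript, which SO terms it is annotated with, and whether it is
# protein-altering / truncating for the generic pipelines.
RECIPES <- c("missense", "missense_allowlisted", "s358l", "v141m",
             "missense_hotspot", "missense_nonhotspot",
             "stop_gained_triggering", "stop_gained_escaping",
             "frameshift_triggering", "splice_acceptor_triggering",
             "splice_donor_triggering", "splice_donor_escaping",
             "inframe_deletion", "synonymous", "intronic",
             "intronic_with_evidence", "gap_intronic", "gap_synonymous",
             "ttn_high_psi_truncating", "ttn_low_psi_truncating")

RECIPE_PAV <- c("missense", "missense_allowlisted", "s358l", "v141m",
                "missense_hotspot", "missense_nonhotspot",
                "stop_gained_triggering", "stop_gained_escaping",
                "frameshift_triggering", "splice_acceptor_triggering",
                "splice_donor_triggering", "splice_donor_escaping",
                "inframe_deletion", "ttn_high_psi_truncating",
                "ttn_low_psi_truncating")

RECIPE_TRUNCATING <- c("stop_gained_triggering", "stop_gained_escaping",
                       "frameshift_triggering", "splice_acceptor_triggering",
                       "splice_donor_triggering", "splice_donor_escaping",
                       "ttn_high_psi_truncating", "ttn_low_psi_truncating")

#' Fixture composition specification
#'
#' One row per requested cell: `n` variants of a `recipe` on a `gene`, in an
#' allele-frequency stratum (`absent`: no population AF; `rare`: AF below
#' 1e-4; `borderline`: AF exactly 1e-4, pinning the strict inequality;
#' `common`: AF well above).  `lof` optionally tags truncating variants with
#' a LOFTEE-style confidence, `clin_sig` with a ClinVar-style assertion.
#'
#' @param gene,recipe,af_stratum,n,lof,clin_sig Vectors recycled to a common
#'   length.
#' @return Data frame of class `g2p_fixture_spec`.
#' @export
fixture_spec <- function(gene, recipe, af_stratum = "rare", n = 1,
                         lof = NA_character_, clin_sig = NA_character_) {
  df <- if (length(gene) == 0) {
    data.frame(gene = character(), recipe = character(),
               af_stratum = character(), n = integer(), lof = character(),
               clin_sig = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(gene = gene, recipe = recipe, af_stratum = af_stratum,
               n = as.integer(n), lof = lof, clin_sig = clin_sig,
               stringsAsFactors = FALSE)
  }
  check_vocab(df$recipe, RECIPES, "fixture recipe")
  check_vocab(df$af_stratum, c("absent", "rare", "borderline", "common"),
              "af stratum")
  stopifnot(all(df$n >= 0))
  class(df) <- c("g2p_fixture_spec", "data.frame")
  df
}

#' Default fixture composition
#'
#' The full cross of every gene-appropriate recipe with all four
#' allele-frequency strata, `n_per_cell` variants each (>= 500 variants at
#' the default 3), spanning every variant class, the PSI exon mask, the
#' allowlists, the hotspot region, force-retained intronic variants, and the
#' designed annotation-gap variants (truly splice-affecting, annotated only
#' as intronic/synonymous) that emulate how incomplete upstream annotation
#' defeats knowledge-base filtering.
#'
#' @param n_per_cell Variants per (gene, recipe, stratum) cell.
#' @return A `g2p_fixture_spec`.
#' @export
default_fixture_spec <- function(n_per_cell = 3) {
  combos <- list(
    MYH7   = c("missense", "stop_gained_triggering", "stop_gained_escaping",
               "frameshift_triggering", "inframe_deletion", "synonymous",
               "intronic", "splice_donor_triggering"),
    MYBPC3 = c("missense", "stop_gained_triggering", "frameshift_triggering",
               "splice_acceptor_triggering", "inframe_deletion",
               "stop_gained_escaping", "intronic"),
    TTN    = c("missense", "ttn_high_psi_truncating",
               "ttn_low_psi_truncating", "frameshift_triggering", "synonymous"),
    TMEM43 = c("missense"),
    RBM20  = c("missense_hotspot", "missense_nonhotspot",
               "stop_gained_triggering"),
    KCNQ1  = c("missense", "stop_gained_triggering",
               "frameshift_triggering"),
    LMNA   = c("missense", "frameshift_triggering", "stop_gained_triggering",
               "inframe_deletion", "synonymous", "intronic", "gap_intronic",
               "gap_synonymous"),
    FLNC   = c("stop_gained_triggering", "frameshift_triggering", "missense"),
    SCN5A  = c("missense", "frameshift_triggering", "stop_gained_triggering",
               "inframe_deletion"),
    DES    = c("missense", "stop_gained_triggering"),
    TNNT2  = c("stop_gained_escaping", "splice_donor_escaping", "missense",
               "stop_gained_triggering"),
    MYL2   = c("missense", "stop_gained_escaping")
  )
  rows <- do.call(rbind, lapply(names(combos), function(g)
    expand.grid(gene = g, recipe = combos[[g]],
                af_stratum = c("absent", "rare", "borderline", "common"),
                stringsAsFactors = FALSE)))
  rows$n <- n_per_cell
  # fixed single-allele repertoire entries exist once, in the rare stratum
  fixed <- data.frame(
    gene = c("TMEM43", "TTN", "KCNQ1"),
    recipe = c("s358l", "missense_allowlisted", "v141m"),
    af_stratum = "rare", n = 1L, stringsAsFactors = FALSE)
  rows <- rbind(rows, fixed)
  fixture_spec(rows$gene, rows$recipe, rows$af_stratum, n = rows$n)
}

# internal: genomic position at a 1-based coding offset.
genomic_pos_at_offset <- function(tm, off) {
  ce <- coding_exons(tm)
  lens <- ce$end - ce$start + 1
  if (tm$strand == "+") {
    cum <- cumsum(lens)
    i <- which(off <= cum)[1]
    if (is.na(i)) stop("coding offset beyond CDS")
    ce$start[i] + (off - c(0, cum)[i]) - 1L
  } else {
    ord <- rev(seq_len(nrow(ce)))
    cum <- cumsum(lens[ord])
    k <- which(off <= cum)[1]
    if (is.na(k)) stop("coding offset beyond CDS")
    i <- ord[k]
    ce$end[i] - (off - c(0, cum)[k]) + 1L
  }
}

# internal: realise variant k (0-based within its cell) of a recipe on a toy
# transcript.  Returns the fields that go into the CSQ payload.
realise_recipe <- function(tm, recipe, k) {
  ce <- coding_exons(tm)
  lens <- ce$end - ce$start + 1
  total <- sum(lens)
  n_ex <- length(tm$exon_starts)
  if (grepl("triggering", recipe) && n_ex == 1)
    stop("impossible combination: NMD-triggering recipe on single-exon transcript ",
         tm$transcript_id)
  if (grepl("^ttn_", recipe) && tm$gene != "TTN")
    stop("impossible combination: ", recipe, " requested on gene ", tm$gene)
  at_off <- function(off, terms, hp = NA_character_, ref = "A", alt = "T",
                     syn = FALSE) {
    pos <- genomic_pos_at_offset(tm, off)
    res <- ceiling(off / 3)
    list(pos = pos, ref = ref, alt = alt, so_terms = terms,
         hgvs_c = sprintf("c.%d%s>%s", off, ref, alt),
         hgvs_p = if (!is.na(hp)) hp else if (syn) sprintf("p.Leu%d=", res)
                  else sprintf("p.Xaa%dYaa", res),
         protein_pos = res, splice_evidence = FALSE)
  }
  # intron j is between transcript-sense exons j and j+1; donor side abuts
  # exon j, acceptor side abuts exon j+1 (mind the strand)
  donor_pos <- function(j, off) {
    if (tm$strand == "+") tm$exon_ends[j] + off
    else tm$exon_starts[n_ex - j + 1] - off
  }
  acceptor_pos <- function(j, off) {
    if (tm$strand == "+") tm$exon_starts[j + 1] - off
    else tm$exon_ends[n_ex - j] + off
  }
  switch(recipe,
    missense = at_off(3 * (70 + k) - 1, "missense_variant"),
    missense_allowlisted = at_off(3 * 178 - 1, "missense_variant",
                                  hp = "p.Ala178Asp", ref = "C", alt = "A"),
    s358l = at_off(3 * 358 - 1, "missense_variant", hp = "p.Ser358Leu",
                   ref = "C", alt = "T"),
    v141m = at_off(3 * 141 - 2, "missense_variant", hp = "p.Val141Met",
                   ref = "G", alt = "A"),
    missense_hotspot = at_off(3 * (634 + k %% 5) - (k %/% 5) %% 3,
                              "missense_variant",
                              alt = c("T", "G", "C")[1 + (k %/% 15) %% 3]),
    missense_nonhotspot = at_off(3 * (100 + k) - 1, "missense_variant"),
    stop_gained_triggering = at_off(3 * (15 + k), "stop_gained"),
    stop_gained_escaping = at_off(total - 30 - 3 * k, "stop_gained"),
    frameshift_triggering = {
      out <- at_off(125 + 3 * k, "frameshift_variant", ref = "AG", alt = "A")
      out$hgvs_c <- sprintf("c.%ddel", 125 + 3 * k)
      out$hgvs_p <- sprintf("p.Xaa%dfs", out$protein_pos); out
    },
    splice_acceptor_triggering = list(
      pos = acceptor_pos(1, 1 + k), ref = "A", alt = "G",
      so_terms = "splice_acceptor_variant",
      hgvs_c = sprintf("c.%d-%dA>G", lens[1] + 1, 1 + k),
      hgvs_p = NA_character_, protein_pos = NA_integer_,
      splice_evidence = FALSE),
    splice_donor_triggering = list(
      pos = donor_pos(1, 1 + k), ref = "G", alt = "A",
      so_terms = "splice_donor_variant",
      hgvs_c = sprintf("c.%d+%dG>A", lens[1], 1 + k),
      hgvs_p = NA_character_, protein_pos = NA_integer_,
      splice_evidence = FALSE),
    splice_donor_escaping = list(
      pos = donor_pos(n_ex - 1, 1 + k), ref = "G", alt = "A",
      so_terms = "splice_donor_variant",
      hgvs_c = sprintf("c.%d+%dG>A", total - lens[length(lens)], 1 + k),
      hgvs_p = NA_character_, protein_pos = NA_integer_,
      splice_evidence = FALSE),
    inframe_deletion = {
      out <- at_off(3 * (130 + k) + 1, "inframe_deletion", ref = "AGCA", alt = "A")
      out$hgvs_c <- sprintf("c.%d_%ddel", 3 * (130 + k) + 2, 3 * (130 + k) + 4)
      out$hgvs_p <- sprintf("p.Xaa%ddel", out$protein_pos + 1); out
    },
    synonymous = at_off(3 * (110 + k), "synonymous_variant", syn = TRUE,
                        ref = "C", alt = "T"),
    intronic = list(pos = donor_pos(1, 100 + k), ref = "A", alt = "G",
                    so_terms = "intron_variant",
                    hgvs_c = sprintf("c.%d+%dA>G", lens[1], 100 + k),
                    hgvs_p = NA_character_, protein_pos = NA_integer_,
                    splice_evidence = FALSE),
    intronic_with_evidence = {
      out <- list(pos = donor_pos(1, 140 + k), ref = "A", alt = "G",
                  so_terms = "intron_variant",
                  hgvs_c = sprintf("c.%d+%dA>G", lens[1], 140 + k),
                  hgvs_p = NA_character_, protein_pos = NA_integer_,
                  splice_evidence = TRUE)
      out
    },
    gap_intronic = list(pos = donor_pos(2, 180 + k), ref = "A", alt = "G",
                        so_terms = "intron_variant",
                        hgvs_c = sprintf("c.%d+%dA>G", sum(lens[1:2]), 180 + k),
                        hgvs_p = NA_character_, protein_pos = NA_integer_,
                        splice_evidence = FALSE),
    gap_synonymous = at_off(3 * (120 + k), "synonymous_variant", syn = TRUE,
                            ref = "G", alt = "A"),
    ttn_high_psi_truncating = at_off(600 + 3 * k, "stop_gained"),
    ttn_low_psi_truncating = at_off(850 + 3 * k, "stop_gained"),
    stop("unknown recipe: ", recipe))
}

# internal: knowledge-base verdict table for pipeline 3 (all panels), derived
# independently of the filter engine from the written record rules.  reason
# codes explain an expected drop.
P3_TRUTH <- local({
  yes <- function(...) list(retain = TRUE, reason = "")
  no <- function(reason) list(retain = FALSE, reason = reason)
  list(
    "MYH7:missense" = yes(), "MYH7:stop_gained_escaping" = yes(),
    "MYH7:inframe_deletion" = yes(),
    "MYH7:stop_gained_triggering" = no("class_not_disease_relevant"),
    "MYH7:frameshift_triggering" = no("class_not_disease_relevant"),
    "MYH7:splice_donor_triggering" = no("class_not_disease_relevant"),
    "MYH7:synonymous" = no("unclassified"),
    "MYH7:intronic" = no("unclassified"),
    "MYBPC3:missense" = yes(), "MYBPC3:stop_gained_triggering" = yes(),
    "MYBPC3:frameshift_triggering" = yes(),
    "MYBPC3:splice_acceptor_triggering" = yes(),
    "MYBPC3:inframe_deletion" = yes(),
    "MYBPC3:stop_gained_escaping" = no("class_not_disease_relevant"),
    "MYBPC3:intronic" = yes(),
    "TTN:missense" = no("restricted_repertoire"),
    "TTN:missense_allowlisted" = yes(),
    "TTN:ttn_high_psi_truncating" = yes(),
    "TTN:ttn_low_psi_truncating" = no("restricted_repertoire"),
    "TTN:frameshift_triggering" = yes(),
    "TTN:synonymous" = no("unclassified"),
    "TMEM43:s358l" = yes(),
    "TMEM43:missense" = no("restricted_repertoire"),
    "RBM20:missense_hotspot" = yes(), "RBM20:missense_nonhotspot" = yes(),
    "RBM20:stop_gained_triggering" = yes(),
    "KCNQ1:v141m" = yes(), "KCNQ1:missense" = yes(),
    "KCNQ1:stop_gained_triggering" = yes(),
    "KCNQ1:frameshift_triggering" = yes(),
    "LMNA:missense" = yes(), "LMNA:frameshift_triggering" = yes(),
    "LMNA:stop_gained_triggering" = yes(),
    "LMNA:inframe_deletion" = no("class_not_disease_relevant"),
    "LMNA:synonymous" = no("unclassified"),
    "LMNA:intronic" = no("unclassified"),
    "LMNA:gap_intronic" = no("annotation_gap"),
    "LMNA:gap_synonymous" = no("annotation_gap"),
    "FLNC:stop_gained_triggering" = yes(),
    "FLNC:frameshift_triggering" = yes(),
    "FLNC:missense" = yes(),
    "SCN5A:missense" = yes(), "SCN5A:frameshift_triggering" = yes(),
    "SCN5A:stop_gained_triggering" = yes(),
    "SCN5A:inframe_deletion" = yes(),
    "DES:missense" = yes(),
    "DES:stop_gained_triggering" = yes(),
    "TNNT2:stop_gained_escaping" = yes(),
    "TNNT2:splice_donor_escaping" = yes(),
    "TNNT2:missense" = yes(),
    "TNNT2:stop_gained_triggering" = no("class_not_disease_relevant"),
    "MYL2:missense" = yes(),
    "MYL2:stop_gained_escaping" = no("class_not_disease_relevant")
  )
})

#' Generate an annotated truth-set VCF with per-pipeline expected verdicts
#'
#' Realises a [fixture_spec()] on the toy transcripts: writes a VCF 4.2 file
#' with a VEP-style CSQ INFO payload, a tab-separated truth-label table (one
#' expected retain/drop verdict per pipeline per variant, with a reason
#' code), and the transcript table.  Truth labels are computed from the
#' written rules by construction - never by running the filter engine - so
#' the closed loop (generator, engine, flat-rule oracle) is a genuine
#' three-way check.
#'
#' Gold-positive status (`gold`) emulates a P/LP gold-standard set: rare
#' variants designed to be disease-causing, including the annotation-gap
#' variants (truly splice-affecting but annotated only as intronic or
#' synonymous) that no consequence-based filter can retain.
#'
#' @param spec A `g2p_fixture_spec`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every random draw (allele frequencies).
#' @return List with `vcf` (path), `labels` (data frame), `transcripts`
#'   (named list), `transcripts_path`, `variants` (the realised annotation
#'   rows as written).
#' @export
generate_truth_set <- function(spec, dir = tempfile("truthset"), seed = 1L) {
  stopifnot(inherits(spec, "g2p_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tms <- build_toy_transcripts()
  by_gene <- stats::setNames(tms, vapply(tms, `[[`, character(1), "gene"))
  rows <- list(); labels <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  cell_counter <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(spec))) {
    gene <- spec$gene[r]; recipe <- spec$recipe[r]
    tm <- by_gene[[gene]]
    if (is.null(tm)) stop("no toy transcript for gene ", gene)
    cell <- paste0(gene, ":", recipe)
    k0 <- get0(cell, envir = cell_counter, ifnotfound = 0L)
    assign(cell, k0 + spec$n[r], envir = cell_counter)
    for (k in k0 + seq_len(spec$n[r]) - 1L) {
      v <- realise_recipe(tm, recipe, k)
      af <- switch(spec$af_stratum[r],
                   absent = NA_real_,
                   rare = signif(stats::runif(1, 1e-6, 8e-5), 3),
                   borderline = 1e-4,
                   common = signif(stats::runif(1, 5e-3, 5e-2), 3))
      lof <- spec$lof[r]
      if (is.na(lof) && recipe %in% RECIPE_TRUNCATING)
        lof <- if (k %% 2 == 0) "HC" else "LC"
      clin <- spec$clin_sig[r]
      key <- sprintf("chrT:%d:%s:%s", v$pos, v$ref, v$alt)
      freq_ok <- spec$af_stratum[r] %in% c("absent", "rare")
      p3 <- P3_TRUTH[[paste0(gene, ":", recipe)]]
      if (is.null(p3))
        stop("no truth rule for combination ", gene, ":", recipe)
      p1 <- freq_ok && recipe %in% RECIPE_PAV
      p2 <- freq_ok && ((recipe %in% RECIPE_TRUNCATING && identical(lof, "HC")) ||
                          (!is.na(clin) && is_clinvar_plp(clin)))
      p3_ok <- freq_ok && p3$retain
      reason <- if (!freq_ok) "allele_frequency" else p3$reason
      gold <- spec$af_stratum[r] == "rare" &&
        (p3$retain || p3$reason == "annotation_gap")
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chrT", pos = v$pos, ref = v$ref, alt = v$alt,
        variant_key = key, gene = gene, transcript_id = tm$transcript_id,
        canonical = TRUE, so_terms = v$so_terms, hgvs_c = v$hgvs_c,
        hgvs_p = v$hgvs_p, protein_pos = v$protein_pos,
        exon_rank = exon_rank_of(tm, v$pos), population_af = af,
        lof_confidence = if (recipe %in% RECIPE_TRUNCATING) lof else NA_character_,
        clin_sig = clin, splice_evidence = v$splice_evidence,
        nmd_tag = NA_character_, stringsAsFactors = FALSE)
      labels[[length(labels) + 1]] <- data.frame(
        variant_key = key, gene = gene, recipe = recipe,
        af_stratum = spec$af_stratum[r], gold = gold,
        p1 = p1, p2 = p2, p3 = p3_ok, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  labels <- do.call(rbind, labels)
  if (!is.null(variants) && anyDuplicated(variants$variant_key))
    stop("fixture generator produced duplicate variant keys")
  vcf_path <- file.path(dir, "truth.vcf")
  write_fixture_vcf(variants, vcf_path)
  tx_path <- file.path(dir, "transcripts.tsv")
  write_transcripts(tms, tx_path)
  if (!is.null(labels))
    utils::write.table(labels, file.path(dir, "truth_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(vcf = vcf_path, labels = labels, transcripts = tms,
       transcripts_path = tx_path, variants = variants)
}

# internal: serialise annotation rows as a VEP-style annotated VCF.
write_fixture_vcf <- function(variants, path, genotypes = NULL,
                              samples = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=2000000>",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from VEP. Format: Allele|Consequence|SYMBOL|Gene|",
           "Feature|CANONICAL|EXON|HGVSc|HGVSp|Protein_position|gnomAD_AF|",
           "LoF|CLIN_SIG|SPLICE_EVIDENCE|NMD\">"))
  has_gt <- !is.null(genotypes)
  if (has_gt)
    header <- c(header,
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) cols <- c(cols, "FORMAT", samples)
  body <- character()
  if (!is.null(variants) && nrow(variants)) {
    ord <- order(variants$pos)
    variants <- variants[ord, , drop = FALSE]
    if (has_gt) genotypes <- genotypes[ord, , drop = FALSE]
    na2empty <- function(x) ifelse(is.na(x), "", as.character(x))
    csq <- sprintf("%s|%s|%s|%s|%s|YES|%s|%s|%s|%s|%s|%s|%s|%s|",
                   variants$alt, variants$so_terms, variants$gene,
                   variants$gene, variants$transcript_id,
                   na2empty(variants$exon_rank),
                   na2empty(variants$hgvs_c), na2empty(variants$hgvs_p),
                   na2empty(variants$protein_pos),
                   na2empty(variants$population_af),
                   na2empty(variants$lof_confidence),
                   na2empty(variants$clin_sig),
                   ifelse(variants$splice_evidence, "1", "0"))
    body <- paste("chrT", variants$pos, ".", variants$ref, variants$alt,
                  ".", "PASS", paste0("CSQ=", csq), sep = "\t")
    if (has_gt)
      body <- paste(body, "GT",
                    apply(genotypes, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Generate a multi-sample cohort VCF with deterministic genotypes
#'
#' Extends [generate_truth_set()] with per-sample genotypes: by default every
#' variant is heterozygous in one rotating carrier sample.  Designated
#' biallelic test cases can be requested: `hom_alt_genes` makes the first
#' variant of each named gene homozygous-alternate in sample 1;
#' `compound_het_genes` makes the first two variants of each named gene
#' heterozygous in sample 1 (a phase-unknown compound heterozygote).
#'
#' @param spec A `g2p_fixture_spec`.
#' @param n_samples Number of samples (>= 1).
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param hom_alt_genes,compound_het_genes Character vectors of gene symbols.
#' @return As [generate_truth_set()], plus `samples`.
#' @export
generate_cohort_vcf <- function(spec, n_samples, dir = tempfile("cohort"),
                                seed = 1L, hom_alt_genes = character(),
                                compound_het_genes = character()) {
  stopifnot(n_samples >= 1)
  ts <- generate_truth_set(spec, dir = dir, seed = seed)
  v <- ts$variants
  samples <- sprintf("S%03d", seq_len(n_samples))
  gt <- matrix("0/0", nrow = nrow(v), ncol = n_samples,
               dimnames = list(NULL, samples))
  for (i in seq_len(nrow(v))) gt[i, ((i - 1) %% n_samples) + 1] <- "0/1"
  for (g in hom_alt_genes) {
    i <- which(v$gene == g)[1]
    if (!is.na(i)) { gt[i, ] <- "0/0"; gt[i, 1] <- "1/1" }
  }
  for (g in compound_het_genes) {
    i <- which(v$gene == g)[1:2]
    if (!anyNA(i)) { gt[i, ] <- "0/0"; gt[i, 1] <- "0/1" }
  }
  vcf_path <- file.path(dir, "cohort.vcf")
  write_fixture_vcf(v, vcf_path, genotypes = gt, samples = samples)
  ts$vcf <- vcf_path
  ts$samples <- samples
  ts
}
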