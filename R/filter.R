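#' Pipeline configuration
#'
#' @param pipeline One of `"generic_pav"` (pipeline 1: rare protein-altering
#'   variants), `"lof_or_clinvar"` (pipeline 2: rare high-confidence LoF or
#'   ClinVar P/LP), `"g2p"` (pipeline 3: mechanism-, class- and
#'   repertoire-aware filtering against the knowledge base).
#' @param af_threshold Population allele-frequency cut-off; variants are
#'   retained only when AF is strictly below it (default `1e-4`).
#' @param panels Panels interrogated by pipeline 3 (default: all).
#' @param missing_af_policy `"retain"` (default) or `"drop"` for variants with
#'   no population AF annotation; a variant absent from the population
#'   database cannot be shown to be common, hence the default.
#' @param constraint_mode_default Mode applied to repertoire constraints that
#'   do not declare one; declared modes always win. `"restrict"` drops
#'   mismatches, `"flag"` retains them with a flag.
#' @param zygosity_mode `"off"` (default; positive-rate counting over unique
#'   variants, as for merged cohort VCFs) or `"per_sample"` (records with an
#'   exclusively biallelic requirement additionally need a sample satisfying
#'   it).
#' @return A list of class `g2p_pipeline_config`.
#' @export
pipeline_config <- function(pipeline = c("generic_pav", "lof_or_clinvar", "g2p"),
                            af_threshold = 1e-4,
                            panels = G2P_PANELS,
                            missing_af_policy = c("retain", "drop"),
                            constraint_mode_default = c("restrict", "flag"),
                            zygosity_mode = c("off", "per_sample")) {
  pipeline <- match.arg(pipeline)
  stopifnot(is.numeric(af_threshold), af_threshold > 0, af_threshold <= 1)
  check_vocab(panels, G2P_PANELS, "panels")
  structure(list(pipeline = pipeline,
                 af_threshold = af_threshold,
                 panels = panels,
                 missing_af_policy = match.arg(missing_af_policy),
                 constraint_mode_default = match.arg(constraint_mode_default),
                 zygosity_mode = match.arg(zygosity_mode)),
            class = "g2p_pipeline_config")
}

#' Allele-frequency stage
#'
#' Strict inequality, as printed in the pipelines' definition (AF < 1e-4): a
#' variant at exactly the threshold is dropped.  A missing AF follows
#' `missing_af_policy` (default retain).
#'
#' @param variant One-row variant data frame or list with `population_af`.
#' @param cfg A `g2p_pipeline_config`.
#' @return Logical.
#' @export
passes_frequency <- function(variant, cfg) {
  af <- variant$population_af
  if (is.null(af) || is.na(af)) return(cfg$missing_af_policy == "retain")
  af < cfg$af_threshold
}

# internal: build one decision row.
decision_row <- function(v, pipeline, retained, stages, matched = character(),
                         flags = character()) {
  data.frame(
    variant_key = v$variant_key, gene = v$gene,
    transcript = v$transcript_id %||% NA_character_,
    class = v$variant_class %||% NA_character_,
    pipeline = pipeline, retained = retained,
    matched_records = paste(matched, collapse = ";"),
    flags = paste(sort(unique(flags)), collapse = ";"),
    stage_trace = paste(stages, collapse = ";"),
    stringsAsFactors = FALSE)
}

finish_result <- function(decisions, variants) {
  decisions <- do.call(rbind, decisions)
  if (is.null(decisions))
    decisions <- decision_row(list(variant_key = character(), gene = character(),
                                   transcript = character(), variant_class = character()),
                              character(), logical(), character())[0, ]
  structure(list(
    decisions = decisions,
    unique_variants_considered = length(unique(variants$variant_key)),
    unique_variants_retained =
      length(unique(decisions$variant_key[decisions$retained]))
  ), class = "g2p_result")
}

#' @export
print.g2p_result <- function(x, ...) {
  cat(sprintf("<g2p_result> %s: %d/%d unique variants retained\n",
              x$decisions$pipeline[1] %||% "?", x$unique_variants_retained,
              x$unique_variants_considered))
  invisible(x)
}

#' Pipeline 1: rare protein-altering variants
#'
#' Retains a variant iff its gene is on the interrogated gene list, its
#' population AF passes the frequency stage, and at least one consequence
#' term is protein-altering (missense, stop gained, frameshift, inframe
#' indel, splice acceptor/donor, start/stop lost, exon- or gene-level
#' deletion).  Synonymous and non-evidence intronic variants are dropped.
#'
#' @param variants A `g2p_variants` data frame, one row per variant-gene
#'   annotation (see [prepare_variants()]).
#' @param gene_set Character vector of interrogated HGNC symbols.
#' @param cfg A `g2p_pipeline_config` with `pipeline = "generic_pav"`.
#' @return A `g2p_result`.
#' @export
run_pipeline1 <- function(variants, gene_set, cfg = pipeline_config("generic_pav")) {
  stopifnot(cfg$pipeline == "generic_pav")
  decisions <- lapply(seq_len(nrow(variants)), function(i) {
    v <- as.list(variants[i, , drop = FALSE])
    stages <- character(); ok <- TRUE
    in_gene <- v$gene %in% gene_set
    stages <- c(stages, paste0("gene=", if (in_gene) "pass" else "fail"))
    ok <- ok && in_gene
    if (ok) {
      freq <- passes_frequency(v, cfg)
      stages <- c(stages, paste0("frequency=", if (freq) "pass" else "fail"))
      ok <- ok && freq
    }
    if (ok) {
      pav <- any(so_split(v$so_terms) %in% SO_PROTEIN_ALTERING)
      stages <- c(stages, paste0("protein_altering=", if (pav) "pass" else "fail"))
      ok <- ok && pav
    }
    decision_row(v, "generic_pav", ok, stages)
  })
  finish_result(decisions, variants)
}

#' Pipeline 2: rare high-confidence LoF or ClinVar P/LP variants
#'
#' Retains a variant iff its gene is interrogated, the frequency stage
#' passes, and either (a) it carries a high-impact truncating term and a
#' high-confidence (`HC`) LOFTEE-style tag, or (b) its clinical-significance
#' annotation contains an unambiguous pathogenic / likely-pathogenic token
#' (case-insensitive exact tokens; conflicting-interpretation strings never
#' match).
#'
#' @inheritParams run_pipeline1
#' @param cfg A `g2p_pipeline_config` with `pipeline = "lof_or_clinvar"`.
#' @return A `g2p_result`.
#' @export
run_pipeline2 <- function(variants, gene_set, cfg = pipeline_config("lof_or_clinvar")) {
  stopifnot(cfg$pipeline == "lof_or_clinvar")
  decisions <- lapply(seq_len(nrow(variants)), function(i) {
    v <- as.list(variants[i, , drop = FALSE])
    stages <- character(); ok <- TRUE
    in_gene <- v$gene %in% gene_set
    stages <- c(stages, paste0("gene=", if (in_gene) "pass" else "fail"))
    ok <- ok && in_gene
    if (ok) {
      freq <- passes_frequency(v, cfg)
      stages <- c(stages, paste0("frequency=", if (freq) "pass" else "fail"))
      ok <- ok && freq
    }
    if (ok) {
      lof_hc <- any(so_split(v$so_terms) %in% SO_HIGH_IMPACT_TRUNCATING) &&
        identical(v$lof_confidence, "HC")
      plp <- is_clinvar_plp(v$clin_sig)
      stages <- c(stages, sprintf("lof_or_clinvar=%s(lof=%s,clinvar=%s)",
                                  if (lof_hc || plp) "pass" else "fail",
                                  lof_hc, plp))
      ok <- ok && (lof_hc || plp)
    }
    decision_row(v, "lof_or_clinvar", ok, stages)
  })
  finish_result(decisions, variants)
}

# internal: unambiguous P/LP token match.
is_clinvar_plp <- function(clin_sig) {
  if (is.null(clin_sig) || is.na(clin_sig) || !nzchar(clin_sig)) return(FALSE)
  tokens <- tolower(trimws(strsplit(clin_sig, "[&,;]")[[1]]))
  any(tokens %in% CLINVAR_PLP_TOKENS)
}

#' Apply a record's restricted-repertoire constraints to one variant
#'
#' Gene-specific refinements of the class-level filter, applied in the order
#' they are declared on the record:
#' * `class_drop_except_allowlist` - variants of the target class not on the
#'   allowlist are dropped (restrict) or flagged (flag), e.g. TTN missense
#'   variants outside the segregation-evidence allowlist;
#' * `variant_allowlist` - only listed alleles of the target class are
#'   retained, e.g. TMEM43 p.Ser358Leu;
#' * `region_flag` - a protein-residue interval of higher confidence; outside
#'   it, `outside_hotspot_region` is flagged (flag mode, the default for
#'   hotspots) or the variant is dropped (restrict);
#' * `exon_mask` - variants of the target class in exons whose inclusion
#'   fraction is at or below the threshold are dropped (the TTN PSI > 0.9
#'   rule);
#' * `class_force_retain` - the target class is retained unconditionally
#'   (e.g. all MYBPC3 intronic variants).
#'
#' A constraint that needs an annotation the variant lacks (protein position
#' for a region, exon inclusion for a mask) yields `flag_only` with
#' `annotation_incomplete` rather than a drop.
#'
#' @param variant One-row variant (list or data frame row) carrying
#'   `variant_class`, `hgvs_p`/`hgvs_c`, `protein_pos`, `exon_inclusion`,
#'   `so_terms`.
#' @param record A `g2p_record` matched by gene.
#' @param cfg A `g2p_pipeline_config`.
#' @return List with `verdict` (`"retain"`, `"drop"`, `"flag_only"`, or
#'   `"force_retain"`) and `flags` (character vector).
#' @export
apply_repertoire_constraints <- function(variant, record,
                                         cfg = pipeline_config("g2p")) {
  verdict <- "retain"; flags <- character()
  vclass <- variant$variant_class %||% NA_character_
  for (cons in record$constraints) {
    mode <- if (!is.na(cons$mode)) cons$mode else cfg$constraint_mode_default
    targets_class <- is.na(cons$target_class) ||
      identical(cons$target_class, vclass)
    switch(cons$kind,
      class_drop_except_allowlist = ,
      variant_allowlist = {
        if (targets_class && !is.na(vclass)) {
          if (!allele_listed(variant, cons$alleles)) {
            if (mode == "restrict") verdict <- "drop"
            flags <- c(flags, "restricted_repertoire_mismatch")
          }
        }
      },
      region_flag = {
        pp <- variant$protein_pos %||% NA_integer_
        if (is.na(pp)) {
          flags <- c(flags, "annotation_incomplete")
          if (verdict == "retain") verdict <- "flag_only"
        } else if (pp < cons$region$start || pp > cons$region$end) {
          flags <- c(flags, "outside_hotspot_region")
          if (mode == "restrict") verdict <- "drop"
        }
      },
      exon_mask = {
        if (targets_class && !is.na(vclass)) {
          incl <- variant$exon_inclusion %||% NA_real_
          if (is.na(incl)) {
            flags <- c(flags, "annotation_incomplete")
            if (verdict == "retain") verdict <- "flag_only"
          } else if (incl <= cons$threshold) {
            if (mode == "restrict") verdict <- "drop"
            flags <- c(flags, "restricted_repertoire_mismatch")
          }
        }
      },
      class_force_retain = {
        forced <- identical(cons$target_class, vclass) ||
          (identical(cons$target_class, "intronic_splice_affecting") &&
             any(so_split(variant$so_terms) %in%
                   c("intron_variant", "splice_region_variant")))
        if (forced) return(list(verdict = "force_retain", flags = flags))
      })
  }
  list(verdict = verdict, flags = flags)
}

# internal: does the variant's HGVS (protein or cDNA) match an allowlist
# entry?  Comparison is on the description after stripping the "p."/"c."
# prefix, parentheses and whitespace, so "p.(Ser358Leu)" matches
# "p.Ser358Leu".
allele_listed <- function(variant, alleles) {
  norm <- function(x) gsub("^[pc]\\.|[()[:space:]]", "",
                           sub("^.*:", "", as.character(x)))
  have <- c(variant$hgvs_p %||% NA_character_, variant$hgvs_c %||% NA_character_)
  have <- norm(have[!is.na(have) & nzchar(have)])
  length(have) > 0 && any(have %in% norm(alleles))
}

#' Pipeline 3: knowledge-base (G2P) filtering
#'
#' For each variant-gene annotation: the gene must carry at least one curated
#' record on the interrogated panels; the frequency stage must pass; the
#' assigned variant class must be among the record's disease-relevant classes
#' after applying the record's restricted-repertoire constraints.  A variant
#' is retained when at least one matching record retains it; the decision
#' trace names the matching records and accumulated flags.  Unclassifiable
#' variants (annotations whose recognised terms map to no class, e.g. bare
#' intronic or synonymous) are dropped with an `unclassified` outcome unless
#' a `class_force_retain` constraint captures them.
#'
#' With `zygosity_mode = "per_sample"` and genotypes available, records whose
#' requirement is exclusively biallelic additionally require some sample to
#' satisfy the allelic requirement over the gene's candidate variants
#' ([check_allelic_requirement()]); failing variants are dropped with flag
#' `allelic_requirement_unmet`.
#'
#' @param variants A `g2p_variants` data frame, one row per variant-gene
#'   annotation; must carry `variant_class` (run [classify_variants()] or
#'   supply `transcripts`).
#' @param kb A `cardiac_g2p` knowledge base.
#' @param cfg A `g2p_pipeline_config` with `pipeline = "g2p"`.
#' @param transcripts Optional transcript models for on-the-fly
#'   classification when `variants` lacks `variant_class`.
#' @return A `g2p_result`.
#' @export
run_pipeline3_g2p <- function(variants, kb, cfg = pipeline_config("g2p"),
                              transcripts = NULL) {
  stopifnot(cfg$pipeline == "g2p", inherits(kb, "cardiac_g2p"))
  if (is.null(variants$variant_class))
    variants <- classify_variants(variants, transcripts)
  recs <- Filter(function(r) r$panel %in% cfg$panels, curated(kb))
  by_gene <- split(recs, vapply(recs, `[[`, character(1), "gene"))
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- as.list(variants[i, , drop = FALSE])
    stages <- character(); matched <- character(); flags <- character()
    gene_recs <- by_gene[[v$gene]]
    if (is.null(gene_recs)) {
      rows[[i]] <- decision_row(v, "g2p", FALSE, "gene=fail")
      next
    }
    stages <- c(stages, "gene=pass")
    if (!passes_frequency(v, cfg)) {
      rows[[i]] <- decision_row(v, "g2p", FALSE, c(stages, "frequency=fail"))
      next
    }
    stages <- c(stages, "frequency=pass")
    retained <- FALSE
    for (r in gene_recs) {
      res <- apply_repertoire_constraints(v, r, cfg)
      hit <- if (res$verdict == "force_retain") {
        TRUE
      } else if (is.na(v$variant_class %||% NA_character_)) {
        flags <- c(flags, "unclassified")
        FALSE
      } else if (!v$variant_class %in% r$variant_classes) {
        FALSE
      } else {
        flags <- c(flags, res$flags)
        res$verdict != "drop"
      }
      if (hit) {
        retained <- TRUE
        matched <- c(matched, paste0(r$gene, "|", r$disease_label))
        flags <- c(flags, res$flags)
      }
    }
    stages <- c(stages, paste0("class_repertoire=",
                               if (retained) "pass" else
                                 if ("unclassified" %in% flags) "unclassified" else "fail"))
    rows[[i]] <- decision_row(v, "g2p", retained, stages, matched, flags)
  }
  result <- finish_result(rows, variants)
  if (cfg$zygosity_mode == "per_sample" && !is.null(variants$genotypes))
    result <- enforce_zygosity(result, variants, by_gene)
  result
}

# internal: post-pass dropping retained variants whose only matching records
# are exclusively biallelic and unsatisfied by every sample.
enforce_zygosity <- function(result, variants, by_gene) {
  d <- result$decisions
  for (g in unique(d$gene[d$retained])) {
    gene_recs <- by_gene[[g]]
    if (is.null(gene_recs)) next
    excl_bi <- vapply(gene_recs, function(r)
      setequal(r$allelic_requirement, "biallelic_autosomal"), logical(1))
    mono_labels <- unlist(lapply(gene_recs[!excl_bi], function(r)
      paste0(r$gene, "|", r$disease_label)))
    idx <- which(d$retained & d$gene == g)
    vg <- variants[variants$gene == g &
                     variants$variant_key %in% d$variant_key[idx], , drop = FALSE]
    for (k in idx) {
      matched <- strsplit(d$matched_records[k], ";", fixed = TRUE)[[1]]
      only_biallelic <- length(matched) > 0 && !any(matched %in% mono_labels)
      if (!only_biallelic) next
      rec <- gene_recs[excl_bi][[1]]
      if (!check_allelic_requirement(vg, rec)) {
        d$retained[k] <- FALSE
        d$flags[k] <- paste(sort(unique(c(
          strsplit(d$flags[k], ";", fixed = TRUE)[[1]],
          "allelic_requirement_unmet"))), collapse = ";")
        d$stage_trace[k] <- paste0(d$stage_trace[k], ";zygosity=fail")
      } else {
        d$stage_trace[k] <- paste0(d$stage_trace[k], ";zygosity=pass")
      }
    }
  }
  result$decisions <- d
  result$unique_variants_retained <-
    length(unique(d$variant_key[d$retained]))
  result
}

#' Check the allelic requirement for one gene in one-or-more samples
#'
#' Monoallelic requirements are satisfied by any non-reference genotype.
#' Exclusively biallelic requirements need, for at least one sample, either a
#' homozygous-alternate genotype or two or more distinct heterozygous
#' variants in the gene (phase unknown is accepted).  Missing genotypes fail.
#'
#' @param variant_group Variant rows of one gene, with a `genotypes`
#'   list-column (named vectors `sample -> {hom_ref, het, hom_alt, missing}`).
#' @param record The `g2p_record` whose requirement is checked.
#' @return Logical: TRUE when some sample satisfies the requirement.
#' @export
check_allelic_requirement <- function(variant_group, record) {
  gts <- variant_group$genotypes
  if (is.null(gts) || !length(gts)) return(FALSE)
  samples <- unique(unlist(lapply(gts, names)))
  if (!length(samples)) return(FALSE)
  biallelic <- setequal(record$allelic_requirement, "biallelic_autosomal")
  for (s in samples) {
    calls <- vapply(gts, function(g)
      if (s %in% names(g)) g[[s]] else "missing", character(1))
    if (!biallelic) {
      if (any(calls %in% c("het", "hom_alt"))) return(TRUE)
    } else {
      if (any(calls == "hom_alt") || sum(calls == "het") >= 2) return(TRUE)
    }
  }
  FALSE
}

#' Dispatch a pipeline by number
#'
#' Convenience wrapper used by the command-line interface: pipeline 1 is the
#' generic protein-altering filter, 2 the LoF/ClinVar filter, and 3 the
#' knowledge-base filter.
#'
#' @param variants A `g2p_variants` data frame.
#' @param kb A `cardiac_g2p` knowledge base (gene list for pipelines 1/2 is
#'   derived from its panels).
#' @param pipeline Integer 1, 2 or 3.
#' @param cfg Optional `g2p_pipeline_config` (defaults to the pipeline's own).
#' @param transcripts Optional transcript models (pipeline 3).
#' @return A `g2p_result`.
#' @export
run_pipeline <- function(variants, kb, pipeline, cfg = NULL, transcripts = NULL) {
  genes <- panel_genes(kb, (cfg %||% list(panels = G2P_PANELS))$panels %||% G2P_PANELS)
  switch(as.character(pipeline),
    "1" = run_pipeline1(variants, genes, cfg %||% pipeline_config("generic_pav")),
    "2" = run_pipeline2(variants, genes, cfg %||% pipeline_config("lof_or_clinvar")),
    "3" = run_pipeline3_g2p(variants, kb, cfg %||% pipeline_config("g2p"),
                            transcripts),
    stop("pipeline must be 1, 2 or 3"))
}
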