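#' Load a cardiac gene-disease panel into a knowledge base
#'
#' Reads a panel file in the G2P-style TSV dialect (UTF-8, one gene-disease
#' record per row; semicolon-joined set-valued columns; a JSON cell for
#' gene-specific repertoire constraints) and returns a validated knowledge
#' base.  With `source = "bundled"` (the default) the two panel files shipped
#' with the package are loaded: the core cardiomyopathy and channelopathy
#' tables, plus the reconstructed syndromic-HCM table and the
#' "Limited"/unestablished rows carried for completeness (see
#' `vignette("cardiacg2p-methods")` for what is transcribed and what is a
#' documented stand-in).
#'
#' Rows with gene-disease validity below Moderate are retained as metadata but
#' carry empty mechanism sets and are excluded from statistics and filtering;
#' `curated(kb)` returns the remaining records (65 in the bundled dataset).
#'
#' @param source `"bundled"`, or a path to one panel TSV, or a character
#'   vector of paths (concatenated in order).
#' @return An object of class `cardiac_g2p`: a list with elements `records`
#'   (list of `g2p_record`), `version`, and `source`.
#' @examples
#' kb <- load_knowledge_base()
#' kb
#' @export
load_knowledge_base <- function(source = "bundled") {
  if (identical(source, "bundled")) {
    source <- c(
      system.file("extdata", "cardiac_g2p_core.tsv", package = "cardiacg2p"),
      system.file("extdata", "cardiac_g2p_syndromic_synthetic.tsv",
                  package = "cardiacg2p")
    )
    if (any(!nzchar(source)))
      stop("bundled panel files not found; is the package installed?")
  }
  records <- list()
  for (path in source) {
    if (!file.exists(path)) stop("panel file not found: ", path)
    records <- c(records, parse_panel_file(path))
  }
  kb <- structure(
    list(records = records, version = "cardiacg2p-panel-1.0",
         source = paste(source, collapse = ";")),
    class = "cardiac_g2p")
  issues <- unlist(lapply(curated(kb), validate_record))
  if (length(issues))
    stop("panel fails record validation:\n  ", paste(issues, collapse = "\n  "))
  keys <- vapply(kb$records, function(r)
    paste(r$gene, r$disease_label, paste(sort(r$allelic_requirement), collapse = ";"),
          sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (gene, disease, allelic requirement) record(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  kb
}

REQUIRED_PANEL_COLUMNS <- c("gene", "disease_label", "panel", "validity",
                            "inheritance_modes", "inheritance_qualifiers",
                            "allelic_requirement", "mechanisms",
                            "variant_classes", "constraints", "narrative",
                            "references")

parse_panel_file <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  missing <- setdiff(REQUIRED_PANEL_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("panel file %s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    ctx <- function(col) sprintf("%s row %d, column %s", basename(path), i, col)
    row <- df[i, ]
    gene <- trimws(row$gene)
    if (!nzchar(gene)) stop(ctx("gene"), ": empty gene symbol")
    panel <- trimws(row$panel)
    check_vocab(panel, G2P_PANELS, ctx("panel"))
    validity <- trimws(row$validity)
    check_vocab(validity, G2P_VALIDITY, ctx("validity"))
    modes <- check_vocab(split_tokens(row$inheritance_modes),
                         G2P_INHERITANCE_MODES, ctx("inheritance_modes"))
    quals <- check_vocab(split_tokens(row$inheritance_qualifiers),
                         G2P_INHERITANCE_QUALIFIERS, ctx("inheritance_qualifiers"))
    req <- check_vocab(split_tokens(row$allelic_requirement),
                       G2P_ALLELIC_REQUIREMENTS, ctx("allelic_requirement"))
    mech <- check_vocab(split_tokens(row$mechanisms),
                        G2P_MECHANISM_TERMS, ctx("mechanisms"))
    classes <- check_vocab(split_tokens(row$variant_classes),
                           G2P_VARIANT_CLASSES, ctx("variant_classes"))
    cons_raw <- trimws(row$constraints)
    constraints <- if (nzchar(cons_raw)) {
      parsed <- tryCatch(jsonlite::fromJSON(cons_raw, simplifyVector = FALSE),
                         error = function(e)
                           stop(ctx("constraints"), ": invalid JSON (",
                                conditionMessage(e), ")", call. = FALSE))
      lapply(parsed, parse_constraint, ctx = ctx("constraints"))
    } else list()
    structure(list(
      gene = gene,
      disease_label = trimws(row$disease_label),
      panel = panel,
      validity = validity,
      inheritance = list(modes = modes, qualifiers = quals),
      allelic_requirement = req,
      mechanisms = mech,
      variant_classes = classes,
      constraints = constraints,
      narrative = row$narrative,
      references = split_tokens(row$references)
    ), class = "g2p_record")
  })
}

parse_constraint <- function(x, ctx) {
  if (is.null(x$kind) || !x$kind %in% G2P_CONSTRAINT_KINDS)
    stop(ctx, ": unknown constraint kind: ",
         if (is.null(x$kind)) "<missing>" else x$kind, call. = FALSE)
  cons <- list(
    kind = x$kind,
    target_class = x$target_class %||% NA_character_,
    alleles = as.character(unlist(x$alleles %||% character())),
    region = if (!is.null(x$region))
      list(start = as.numeric(x$region$start), end = as.numeric(x$region$end)),
    mask = x$mask %||% NA_character_,
    threshold = as.numeric(x$threshold %||% NA_real_),
    mode = x$mode %||% NA_character_
  )
  if (!is.na(cons$target_class))
    check_vocab(cons$target_class, G2P_VARIANT_CLASSES, ctx)
  if (cons$kind %in% c("variant_allowlist", "class_drop_except_allowlist") &&
      length(cons$alleles) == 0)
    stop(ctx, ": ", cons$kind, " requires a non-empty allele list", call. = FALSE)
  if (cons$kind == "region_flag" && is.null(cons$region))
    stop(ctx, ": region_flag requires a region", call. = FALSE)
  if (cons$kind == "exon_mask" && (is.na(cons$mask) || is.na(cons$threshold)))
    stop(ctx, ": exon_mask requires a mask name and threshold", call. = FALSE)
  if (!is.na(cons$mode)) check_vocab(cons$mode, c("restrict", "flag"), ctx)
  structure(cons, class = "g2p_constraint")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Curated records of a knowledge base
#'
#' A record counts as curated when its validity is Definitive, Strong or
#' Moderate and it carries at least one disease-associated consequence term;
#' Limited/Disputed rows are metadata only and take no part in statistics or
#' filtering.
#'
#' @param kb A `cardiac_g2p` knowledge base.
#' @return A list of `g2p_record`.
#' @export
curated <- function(kb) {
  stopifnot(inherits(kb, "cardiac_g2p"))
  Filter(function(r) r$validity %in% G2P_VALIDITY_CURATED &&
           length(r$mechanisms) > 0, kb$records)
}

#' Validate a single gene-disease record against the type invariants
#'
#' Checks the closed vocabularies, non-emptiness of inheritance and allelic
#' requirement for curated records, consistency between inheritance modes and
#' allelic requirement (dominant implies monoallelic autosomal, recessive
#' implies biallelic autosomal, X-linked implies monoallelic X-linked), and
#' the mechanism-implication invariant: the consequence terms implied by the
#' record's variant classes (via [class_to_mechanism()]) must be present in
#' its mechanism set.  Two tolerances are deliberate: `absent_gene_product_level`
#' satisfies a `decreased_gene_product_level` implication (absence is the
#' limiting case of decrease), and `structural_exon_deletion` is satisfied by
#' either term because an in-frame exon deletion yields an altered rather
#' than reduced product (e.g. the RYR2 exon 3 deletion).
#'
#' @param record A `g2p_record`.
#' @return Character vector of issue descriptors; empty when all invariants hold.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "g2p_record"))
  issues <- character()
  who <- paste0(record$gene, "-", record$panel)
  is_curated <- record$validity %in% G2P_VALIDITY_CURATED
  if (is_curated && length(record$inheritance$modes) == 0)
    issues <- c(issues, paste0(who, ": curated record with empty inheritance modes"))
  if (is_curated && length(record$allelic_requirement) == 0)
    issues <- c(issues, paste0(who, ": curated record with empty allelic requirement"))
  if (is_curated && length(record$mechanisms) == 0)
    issues <- c(issues, paste0(who, ": curated record with empty mechanisms"))
  modes <- record$inheritance$modes
  req <- record$allelic_requirement
  if ("autosomal_dominant" %in% modes && !"monoallelic_autosomal" %in% req)
    issues <- c(issues, paste0(who, ": autosomal dominant without monoallelic_autosomal requirement"))
  if ("autosomal_recessive" %in% modes && !"biallelic_autosomal" %in% req)
    issues <- c(issues, paste0(who, ": autosomal recessive without biallelic_autosomal requirement"))
  if ("x_linked" %in% modes && !"monoallelic_x_linked" %in% req)
    issues <- c(issues, paste0(who, ": x-linked without monoallelic_x_linked requirement"))
  if (!"autosomal_dominant" %in% modes && !"x_linked" %in% modes &&
      "monoallelic_autosomal" %in% req && !"autosomal_recessive" %in% modes)
    issues <- c(issues, paste0(who, ": monoallelic requirement without a dominant mode"))
  if (length(record$variant_classes) && length(record$mechanisms)) {
    for (vc in record$variant_classes) {
      implied <- class_to_mechanism(vc)
      satisfied_by <- lapply(implied, function(term) {
        if (vc == "structural_exon_deletion") G2P_MECHANISM_TERMS
        else if (term == "decreased_gene_product_level")
          c("decreased_gene_product_level", "absent_gene_product_level")
        else term
      })
      ok <- vapply(satisfied_by, function(s) any(s %in% record$mechanisms), logical(1))
      if (!all(ok))
        issues <- c(issues, sprintf(
          "%s: variant class %s implies %s, absent from mechanisms {%s}",
          who, vc, paste(implied[!ok], collapse = ","),
          paste(record$mechanisms, collapse = ",")))
    }
  }
  issues
}

#' Query records for one gene
#'
#' @param kb A `cardiac_g2p` knowledge base.
#' @param gene HGNC gene symbol (exact match; alias resolution is out of scope).
#' @param panel Optional panel to restrict to.
#' @return A list of curated `g2p_record`, ordered by (panel, disease label);
#'   empty for an unknown gene.
#' @export
records_for_gene <- function(kb, gene, panel = NULL) {
  recs <- Filter(function(r) r$gene == gene, curated(kb))
  if (!is.null(panel)) {
    check_vocab(panel, G2P_PANELS, "panel filter")
    recs <- Filter(function(r) r$panel %in% panel, recs)
  }
  ord <- order(vapply(recs, function(r) match(r$panel, G2P_PANELS), integer(1)),
               vapply(recs, `[[`, character(1), "disease_label"))
  recs[ord]
}

#' Summary statistics of a knowledge base
#'
#' Counts are computed over curated records only (validity at least Moderate
#' and non-empty mechanisms).  Unique-gene counts deduplicate HGNC symbols
#' within the cardiomyopathy (HCM, syndromic HCM, DCM, ARVC) and channelopathy
#' (LQTS, BrS, CPVT, SQTS) groups.
#'
#' @param kb A `cardiac_g2p` knowledge base.
#' @param panel_filter Optional character vector of panels to restrict to.
#' @return A list of class `g2p_kb_stats` with elements `pairs_total`,
#'   `pairs_by_panel`, `unique_genes_by_group`, `pairs_without_level_decrease`,
#'   `pairs_exclusively_biallelic`, and `pairs_with_dual_ad_ar`.
#' @examples
#' kb_stats(load_knowledge_base(), panel_filter = c("LQTS", "BrS", "CPVT", "SQTS"))
#' @export
kb_stats <- function(kb, panel_filter = NULL) {
  recs <- curated(kb)
  if (!is.null(panel_filter)) {
    check_vocab(panel_filter, G2P_PANELS, "panel filter")
    recs <- Filter(function(r) r$panel %in% panel_filter, recs)
  }
  panels <- vapply(recs, `[[`, character(1), "panel")
  genes <- vapply(recs, `[[`, character(1), "gene")
  keep <- if (is.null(panel_filter)) G2P_PANELS else
    G2P_PANELS[G2P_PANELS %in% panel_filter]
  by_panel <- vapply(keep, function(p) sum(panels == p), integer(1))
  groups <- vapply(names(G2P_PANEL_GROUPS), function(g)
    length(unique(genes[panels %in% G2P_PANEL_GROUPS[[g]]])), integer(1))
  no_decrease <- vapply(recs, function(r)
    !any(c("decreased_gene_product_level", "absent_gene_product_level") %in%
           r$mechanisms), logical(1))
  excl_bi <- vapply(recs, function(r)
    setequal(r$allelic_requirement, "biallelic_autosomal"), logical(1))
  dual <- vapply(recs, function(r)
    all(c("autosomal_dominant", "autosomal_recessive") %in%
          r$inheritance$modes), logical(1))
  structure(list(
    pairs_total = length(recs),
    pairs_by_panel = by_panel,
    unique_genes_by_group = groups,
    pairs_without_level_decrease = sum(no_decrease),
    pairs_exclusively_biallelic = sum(excl_bi),
    pairs_with_dual_ad_ar = sum(dual)
  ), class = "g2p_kb_stats")
}

#' Count curated pairs whose mechanisms exclude any level decrease
#'
#' A pair counts when neither `decreased_gene_product_level` nor
#' `absent_gene_product_level` appears among its disease-associated
#' consequence terms, i.e. loss of function is not an established mechanism
#' and protein-truncating variants are not known to be pathogenic.
#'
#' @inheritParams kb_stats
#' @return Integer count.
#' @export
count_pairs_without_level_decrease <- function(kb, panel_filter = NULL) {
  kb_stats(kb, panel_filter)$pairs_without_level_decrease
}

#' Serialise a knowledge base back to the panel TSV dialect
#'
#' Field-by-field round trip: `load_knowledge_base(write_knowledge_base(kb, f))`
#' reproduces `kb$records` exactly.
#'
#' @param kb A `cardiac_g2p` knowledge base.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "cardiac_g2p"))
  rows <- vapply(kb$records, function(r) {
    cons <- if (length(r$constraints)) {
      jsonlite::toJSON(lapply(r$constraints, function(cn) {
        out <- list(kind = cn$kind)
        if (!is.na(cn$target_class)) out$target_class <- cn$target_class
        if (length(cn$alleles)) out$alleles <- cn$alleles
        if (!is.null(cn$region)) out$region <- cn$region
        if (!is.na(cn$mask)) out$mask <- cn$mask
        if (!is.na(cn$threshold)) out$threshold <- cn$threshold
        if (!is.na(cn$mode)) out$mode <- cn$mode
        out
      }), auto_unbox = TRUE)
    } else "[]"
    paste(r$gene, r$disease_label, r$panel, r$validity,
          paste(r$inheritance$modes, collapse = ";"),
          paste(r$inheritance$qualifiers, collapse = ";"),
          paste(r$allelic_requirement, collapse = ";"),
          paste(r$mechanisms, collapse = ";"),
          paste(r$variant_classes, collapse = ";"),
          cons, r$narrative, paste(r$references, collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c(paste(REQUIRED_PANEL_COLUMNS, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Curated genes of one or more panels
#'
#' @param kb A `cardiac_g2p` knowledge base.
#' @param panels Panels to include (default: all).
#' @return Sorted character vector of unique HGNC symbols.
#' @export
panel_genes <- function(kb, panels = G2P_PANELS) {
  check_vocab(panels, G2P_PANELS, "panels")
  recs <- Filter(function(r) r$panel %in% panels, curated(kb))
  sort(unique(vapply(recs, `[[`, character(1), "gene")))
}

#' @export
print.cardiac_g2p <- function(x, ...) {
  st <- kb_stats(x)
  cat(sprintf("<cardiac_g2p> %d records (%d curated), version %s\n",
              length(x$records), st$pairs_total, x$version))
  cat("  pairs by panel: ",
      paste(sprintf("%s=%d", names(st$pairs_by_panel), st$pairs_by_panel),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.g2p_record <- function(x, ...) {
  cat(sprintf("<g2p_record> %s - %s [%s, %s]\n", x$gene, x$disease_label,
              x$panel, x$validity))
  cat("  inheritance: ", paste(x$inheritance$modes, collapse = "; "),
      if (length(x$inheritance$qualifiers))
        paste0(" (", paste(x$inheritance$qualifiers, collapse = "; "), ")"),
      "\n", sep = "")
  cat("  allelic requirement: ", paste(x$allelic_requirement, collapse = "; "), "\n",
      "  mechanisms: ", paste(x$mechanisms, collapse = "; "), "\n",
      "  variant classes: ", paste(x$variant_classes, collapse = "; "), "\n",
      sep = "")
  if (length(x$constraints))
    cat("  constraints: ",
        paste(vapply(x$constraints, `[[`, character(1), "kind"), collapse = "; "),
        "\n", sep = "")
  invisible(x)
}

#' @export
print.g2p_kb_stats <- function(x, ...) {
  cat("pairs_total:", x$pairs_total, "\n")
  cat("pairs_by_panel:",
      paste(sprintf("%s=%d", names(x$pairs_by_panel), x$pairs_by_panel),
            collapse = ", "), "\n")
  cat("unique_genes_by_group:",
      paste(sprintf("%s=%d", names(x$unique_genes_by_group),
                    x$unique_genes_by_group), collapse = ", "), "\n")
  cat("pairs_without_level_decrease:", x$pairs_without_level_decrease, "\n")
  cat("pairs_exclusively_biallelic:", x$pairs_exclusively_biallelic, "\n")
  cat("pairs_with_dual_ad_ar:", x$pairs_with_dual_ad_ar, "\n")
  invisible(x)
}
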