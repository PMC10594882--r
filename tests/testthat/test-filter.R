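cfg1 <- pipeline_config("generic_pav")
cfg2 <- pipeline_config("lof_or_clinvar")
cfg3 <- pipeline_config("g2p")

# rows built with variant_class already set just pass through pipeline 3
classify_defaults <- function(v) {
  if (is.null(v$variant_class)) v$variant_class <- NA_character_
  if (is.null(v$exon_inclusion)) v$exon_inclusion <- NA_real_
  v
}

test_that("frequency stage uses a strict threshold and a missing-AF policy", {
  expect_true(passes_frequency(list(population_af = 0.00009), cfg1))
  expect_false(passes_frequency(list(population_af = 0.0001), cfg1))
  expect_false(passes_frequency(list(population_af = 0.01), cfg1))
  expect_true(passes_frequency(list(population_af = NA_real_), cfg1))
  drop_cfg <- pipeline_config("generic_pav", missing_af_policy = "drop")
  expect_false(passes_frequency(list(population_af = NA_real_), drop_cfg))
})

test_that("pipeline 1 retains rare protein-altering variants only", {
  genes <- panel_genes(bundled_kb())
  v <- rbind_variants(
    make_variant("MYH7", "frameshift_variant", pos = 101L),
    make_variant("MYH7", "synonymous_variant", pos = 102L),
    make_variant("MYH7", "missense_variant", pos = 103L, population_af = 0.01),
    make_variant("NOTAPANELGENE", "missense_variant", pos = 104L))
  res <- run_pipeline1(v, genes, cfg1)
  expect_equal(res$decisions$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$unique_variants_considered, 4)
  expect_equal(res$unique_variants_retained, 1)
})

test_that("pipeline 2 needs high-confidence LoF or an unambiguous P/LP tag", {
  genes <- panel_genes(bundled_kb())
  v <- rbind_variants(
    make_variant("MYH7", "frameshift_variant", pos = 201L, lof_confidence = "HC"),
    make_variant("MYH7", "frameshift_variant", pos = 202L, lof_confidence = "LC"),
    make_variant("MYH7", "missense_variant", pos = 203L,
                 clin_sig = "likely_pathogenic"),
    make_variant("MYH7", "missense_variant", pos = 204L,
                 clin_sig = "Pathogenic"),
    make_variant("MYH7", "missense_variant", pos = 205L,
                 clin_sig = "conflicting_interpretations_of_pathogenicity"),
    make_variant("MYH7", "missense_variant", pos = 206L))
  res <- run_pipeline2(v, genes, cfg2)
  expect_equal(res$decisions$retained, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("pipeline 3 enforces disease-relevant classes per record", {
  kb <- bundled_kb()
  v <- rbind_variants(
    # MYH7-HCM lists no NMD-triggering class: rare truncating variant dropped
    make_variant("MYH7", "frameshift_variant", pos = 301L,
                 variant_class = "nmd_truncating"),
    # MYBPC3 haploinsufficiency: same class retained
    make_variant("MYBPC3", "frameshift_variant", pos = 302L,
                 variant_class = "nmd_truncating"),
    # MYH7 NMD-escaping stop is in its repertoire
    make_variant("MYH7", "stop_gained", pos = 303L,
                 variant_class = "stop_gained_nmd_escaping"),
    # synonymous: no class, dropped as unclassified
    make_variant("MYH7", "synonymous_variant", pos = 304L),
    # common MYBPC3 truncating fails the frequency stage
    make_variant("MYBPC3", "frameshift_variant", pos = 305L,
                 variant_class = "nmd_truncating", population_af = 0.02))
  res <- run_pipeline3_g2p(classify_defaults(v), kb, cfg3)
  expect_equal(res$decisions$retained, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_match(res$decisions$stage_trace[4], "unclassified")
  expect_match(res$decisions$stage_trace[5], "frequency=fail")
  expect_match(res$decisions$matched_records[2], "MYBPC3")
})

test_that("restricted repertoires: allowlists, exon mask, hotspot, force-retain", {
  kb <- bundled_kb()
  v <- rbind_variants(
    # TTN missense off the allowlist vs the allowlisted allele
    make_variant("TTN", "missense_variant", pos = 401L,
                 variant_class = "missense", hgvs_p = "p.Gly123Ser"),
    make_variant("TTN", "missense_variant", pos = 402L,
                 variant_class = "missense", hgvs_p = "p.Ala178Asp"),
    # TTN truncating in a low- vs high-inclusion exon
    make_variant("TTN", "stop_gained", pos = 403L,
                 variant_class = "nmd_truncating", exon_inclusion = 0.5),
    make_variant("TTN", "stop_gained", pos = 404L,
                 variant_class = "nmd_truncating", exon_inclusion = 0.95),
    # the exon-mask threshold itself is exclusive: PSI = 0.9 is dropped
    make_variant("TTN", "stop_gained", pos = 405L,
                 variant_class = "nmd_truncating", exon_inclusion = 0.9),
    # TMEM43: only p.Ser358Leu
    make_variant("TMEM43", "missense_variant", pos = 406L,
                 variant_class = "missense", hgvs_p = "p.Ser358Leu",
                 protein_pos = 358L),
    make_variant("TMEM43", "missense_variant", pos = 407L,
                 variant_class = "missense", hgvs_p = "p.Arg28Trp",
                 protein_pos = 28L),
    # MYBPC3 bare intronic is force-retained
    make_variant("MYBPC3", "intron_variant", pos = 408L),
    # LMNA bare intronic is not
    make_variant("LMNA", "intron_variant", pos = 409L),
    # RBM20 hotspot vs non-hotspot missense
    make_variant("RBM20", "missense_variant", pos = 410L,
                 variant_class = "missense", protein_pos = 636L),
    make_variant("RBM20", "missense_variant", pos = 411L,
                 variant_class = "missense", protein_pos = 100L))
  res <- run_pipeline3_g2p(classify_defaults(v), kb, cfg3)
  expect_equal(res$decisions$retained,
               c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                 TRUE, TRUE))
  expect_match(res$decisions$flags[1], "restricted_repertoire_mismatch")
  expect_false(grepl("outside_hotspot_region", res$decisions$flags[10]))
  expect_match(res$decisions$flags[11], "outside_hotspot_region")
})

test_that("constraints missing their annotation flag rather than drop", {
  kb <- bundled_kb()
  rec <- records_for_gene(kb, "RBM20", "DCM")[[1]]
  out <- apply_repertoire_constraints(
    list(variant_class = "missense", protein_pos = NA_integer_), rec, cfg3)
  expect_equal(out$verdict, "flag_only")
  expect_true("annotation_incomplete" %in% out$flags)
  ttn <- records_for_gene(kb, "TTN", "DCM")[[1]]
  out <- apply_repertoire_constraints(
    list(variant_class = "nmd_truncating", exon_inclusion = NA_real_,
         hgvs_p = NA_character_), ttn, cfg3)
  expect_equal(out$verdict, "flag_only")
  expect_true("annotation_incomplete" %in% out$flags)
})

test_that("allelic requirement logic over genotype configurations", {
  kb <- bundled_kb()
  tecrl <- records_for_gene(kb, "TECRL")[[1]]   # exclusively biallelic
  gt <- function(...) c(...)
  v1 <- make_variant("TECRL", "missense_variant", pos = 501L,
                     variant_class = "missense",
                     genotypes = gt(S1 = "het", S2 = "hom_ref"))
  v2 <- make_variant("TECRL", "missense_variant", pos = 502L,
                     variant_class = "missense",
                     genotypes = gt(S1 = "het", S2 = "hom_ref"))
  vh <- make_variant("TECRL", "missense_variant", pos = 503L,
                     variant_class = "missense",
                     genotypes = gt(S1 = "hom_ref", S2 = "hom_alt"))
  # single het cannot satisfy a biallelic requirement
  expect_false(check_allelic_requirement(v1, tecrl))
  # hom_alt satisfies it
  expect_true(check_allelic_requirement(vh, tecrl))
  # two distinct hets in one sample satisfy it (phase unknown accepted)
  expect_true(check_allelic_requirement(rbind_variants(v1, v2), tecrl))
  # two hets in different samples do not
  v3 <- make_variant("TECRL", "missense_variant", pos = 504L,
                     variant_class = "missense",
                     genotypes = gt(S1 = "hom_ref", S2 = "het"))
  expect_false(check_allelic_requirement(rbind_variants(v1, v3), tecrl))
  # missing genotypes fail
  expect_false(check_allelic_requirement(
    make_variant("TECRL", "missense_variant", pos = 505L,
                 variant_class = "missense"), tecrl))
  # monoallelic requirement: one het suffices
  myh7 <- records_for_gene(kb, "MYH7", "HCM")[[1]]
  expect_true(check_allelic_requirement(v1, myh7))
})

test_that("per-sample zygosity mode drops unsatisfied biallelic-only genes", {
  kb <- bundled_kb()
  zcfg <- pipeline_config("g2p", zygosity_mode = "per_sample")
  lone <- make_variant("TECRL", "missense_variant", pos = 601L,
                       variant_class = "missense",
                       genotypes = c(S1 = "het", S2 = "hom_ref"))
  res <- run_pipeline3_g2p(classify_defaults(lone), kb, zcfg)
  expect_false(res$decisions$retained[1])
  expect_match(res$decisions$flags[1], "allelic_requirement_unmet")
  hom <- make_variant("TECRL", "missense_variant", pos = 602L,
                      variant_class = "missense",
                      genotypes = c(S1 = "hom_alt", S2 = "hom_ref"))
  res <- run_pipeline3_g2p(classify_defaults(hom), kb, zcfg)
  expect_true(res$decisions$retained[1])
  # genes with a monoallelic record are unaffected by the zygosity stage
  het <- make_variant("MYH7", "missense_variant", pos = 603L,
                      variant_class = "missense",
                      genotypes = c(S1 = "het", S2 = "hom_ref"))
  res <- run_pipeline3_g2p(classify_defaults(het), kb, zcfg)
  expect_true(res$decisions$retained[1])
})

test_that("every pipeline obeys retained <= frequency-passing <= input", {
  kb <- bundled_kb()
  ts <- generate_truth_set(default_fixture_spec(1), seed = 11)
  v <- classify_variants(prepare_variants(read_annotated_vcf(ts$vcf), kb),
                         ts$transcripts)
  genes <- panel_genes(kb)
  freq_pass <- v$variant_key[is.na(v$population_af) | v$population_af < 1e-4]
  for (res in list(run_pipeline1(v, genes, cfg1),
                   run_pipeline2(v, genes, cfg2),
                   run_pipeline3_g2p(v, kb, cfg3))) {
    ret <- unique(res$decisions$variant_key[res$decisions$retained])
    expect_true(all(ret %in% freq_pass))
    expect_true(all(ret %in% v$variant_key))
    expect_lte(res$unique_variants_retained, res$unique_variants_considered)
  }
})

test_that("pipeline 3 is monotone in classes and anti-monotone in constraints", {
  kb <- bundled_kb()
  ts <- generate_truth_set(default_fixture_spec(1), seed = 12)
  v <- classify_variants(prepare_variants(read_annotated_vcf(ts$vcf), kb),
                         ts$transcripts)
  base <- run_pipeline3_g2p(v, kb, cfg3)
  base_ret <- unique(base$decisions$variant_key[base$decisions$retained])

  # adding a variant class to a record never shrinks the retained set
  kb_plus <- kb
  idx <- which(vapply(kb_plus$records, function(r)
    r$gene == "MYH7" && r$panel == "HCM", logical(1)))
  kb_plus$records[[idx]]$variant_classes <-
    c(kb_plus$records[[idx]]$variant_classes, "nmd_truncating")
  kb_plus$records[[idx]]$mechanisms <-
    c(kb_plus$records[[idx]]$mechanisms, "decreased_gene_product_level")
  more <- run_pipeline3_g2p(v, kb_plus, cfg3)
  more_ret <- unique(more$decisions$variant_key[more$decisions$retained])
  expect_true(all(base_ret %in% more_ret))

  # removing a restrict-mode constraint never shrinks the retained set
  kb_free <- kb
  idx <- which(vapply(kb_free$records, function(r)
    r$gene == "TTN" && r$panel == "DCM", logical(1)))
  kb_free$records[[idx]]$constraints <- list()
  free <- run_pipeline3_g2p(v, kb_free, cfg3)
  free_ret <- unique(free$decisions$variant_key[free$decisions$retained])
  expect_true(all(base_ret %in% free_ret))
  expect_gt(length(free_ret), length(base_ret))   # TTN missense now retained
})

test_that("staged engine agrees with the flat-rule oracle on 1000+ variants", {
  kb <- bundled_kb()
  ts <- generate_truth_set(default_fixture_spec(6), seed = 13)
  v <- classify_variants(prepare_variants(read_annotated_vcf(ts$vcf), kb),
                         ts$transcripts)
  expect_gte(nrow(v), 1000)
  genes <- panel_genes(kb)
  r1 <- run_pipeline1(v, genes, cfg1)
  r2 <- run_pipeline2(v, genes, cfg2)
  r3 <- run_pipeline3_g2p(v, kb, cfg3)
  for (i in seq_len(nrow(v))) {
    vi <- as.list(v[i, , drop = FALSE])
    expect_identical(r1$decisions$retained[i], oracle_p1(vi, genes),
                     label = paste("p1", vi$variant_key))
    expect_identical(r2$decisions$retained[i], oracle_p2(vi, genes),
                     label = paste("p2", vi$variant_key))
    expect_identical(r3$decisions$retained[i], oracle_p3(vi, kb),
                     label = paste("p3", vi$variant_key))
  }
})
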