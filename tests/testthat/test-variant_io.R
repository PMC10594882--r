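# hand-written mini VCF with a configurable CSQ payload
write_mini_vcf <- function(lines, path,
                           csq_desc = paste0(
                             "Consequence annotations from VEP. Format: ",
                             "Allele|Consequence|SYMBOL|Gene|Feature|CANONICAL|",
                             "EXON|HGVSc|HGVSp|Protein_position|gnomAD_AF|LoF|",
                             "CLIN_SIG|SPLICE_EVIDENCE|NMD")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=2000000>",
    sprintf("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"%s\">", csq_desc),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    lines), path)
  path
}

csq_entry <- function(alt, cons, gene, tx, canonical = "YES", af = "",
                      extra = c(hgvsc = "", hgvsp = "", pp = "", lof = "",
                                clin = "", ev = "0", nmd = "")) {
  sprintf("%s|%s|%s|%s|%s|%s||%s|%s|%s|%s|%s|%s|%s|%s", alt, cons, gene, gene,
          tx, canonical, extra[["hgvsc"]], extra[["hgvsp"]], extra[["pp"]],
          af, extra[["lof"]], extra[["clin"]], extra[["ev"]], extra[["nmd"]])
}

test_that("one annotation row per variant-transcript, count conserved", {
  path <- withr::local_tempfile(fileext = ".vcf")
  lines <- vapply(1:10, function(i) {
    csq <- paste(csq_entry("T", "missense_variant", "MYH7", "TX1"),
                 csq_entry("T", "synonymous_variant", "MYH7", "TX2",
                           canonical = ""), sep = ",")
    sprintf("chrT\t%d\t.\tA\tT\t.\tPASS\tCSQ=%s", 1000 + i, csq)
  }, character(1))
  v <- read_annotated_vcf(write_mini_vcf(lines, path))
  expect_equal(nrow(v), 20)
  expect_equal(length(unique(v$variant_key)), 10)
  expect_true(all(v$pos >= 1001 & v$pos <= 1010))
})

test_that("multi-allelic records decompose into one key per alternate allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  csq <- paste(csq_entry("C", "missense_variant", "MYH7", "TX1"),
               csq_entry("T", "synonymous_variant", "MYH7", "TX1"), sep = ",")
  v <- read_annotated_vcf(write_mini_vcf(
    sprintf("chrT\t1500\t.\tA\tC,T\t.\tPASS\tCSQ=%s", csq), path))
  expect_setequal(v$variant_key, c("chrT:1500:A:C", "chrT:1500:A:T"))
  # per-allele CSQ matching keeps each annotation with its own allele
  expect_equal(v$so_terms[v$alt == "C"], "missense_variant")
  expect_equal(v$so_terms[v$alt == "T"], "synonymous_variant")
})

test_that("missing annotation key or schema fields are errors", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrT,length=2000000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrT\t100\t.\tA\tT\t.\tPASS\t."), path)
  expect_error(read_annotated_vcf(path), "CSQ")

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf("chrT\t100\t.\tA\tT\t.\tPASS\tCSQ=T|x", path2,
                 csq_desc = "Format: Allele|Impact")
  expect_error(read_annotated_vcf(path2), "Consequence")
})

test_that("annotation fields are typed and parsed", {
  path <- withr::local_tempfile(fileext = ".vcf")
  csq <- csq_entry("T", "stop_gained", "TTN", "ENST00000589042", af = "5e-05",
                   extra = c(hgvsc = "c.100A>T", hgvsp = "p.Lys34Ter",
                             pp = "34", lof = "HC", clin = "pathogenic",
                             ev = "0", nmd = "NMD_escaping_variant"))
  v <- read_annotated_vcf(write_mini_vcf(
    sprintf("chrT\t2000\t.\tA\tT\t.\tPASS\tCSQ=%s", csq), path))
  expect_equal(v$population_af, 5e-5)
  expect_equal(v$protein_pos, 34L)
  expect_equal(v$lof_confidence, "HC")
  expect_equal(v$clin_sig, "pathogenic")
  expect_equal(v$nmd_tag, "escaping")
  expect_equal(v$hgvs_p, "p.Lys34Ter")
})

test_that("transcript selection prefers designated, canonical, severity, id", {
  kb <- bundled_kb()
  mk <- function(tx, terms, canonical = FALSE)
    make_variant("TTN", terms, transcript_id = tx, canonical = canonical)
  # KB-designated TTN meta-transcript beats another canonical annotation
  sel <- select_transcript(
    rbind_variants(mk("ENST00000999999", "missense_variant", canonical = TRUE),
                   mk("ENST00000589042", "missense_variant")), kb)
  expect_equal(sel$transcript_id, "ENST00000589042")
  # canonical beats non-canonical
  sel <- select_transcript(
    rbind_variants(mk("TX_A", "missense_variant"),
                   mk("TX_B", "missense_variant", canonical = TRUE)))
  expect_equal(sel$transcript_id, "TX_B")
  # most severe consequence
  sel <- select_transcript(
    rbind_variants(mk("TX_A", "synonymous_variant"),
                   mk("TX_B", "stop_gained")))
  expect_equal(sel$transcript_id, "TX_B")
  # deterministic lexicographic tie-break
  sel <- select_transcript(
    rbind_variants(mk("TX_B", "missense_variant"),
                   mk("TX_A", "missense_variant")))
  expect_equal(sel$transcript_id, "TX_A")
  # identity for a single annotation
  single <- mk("TX_ONLY", "missense_variant")
  expect_equal(select_transcript(single)$transcript_id, "TX_ONLY")
})

test_that("genotype strings map onto the genotype vocabulary", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=2000000>",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Format: ",
           "Allele|Consequence|SYMBOL|Gene|Feature\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3\tS4",
    paste0("chrT\t100\t.\tA\tT\t.\tPASS\tCSQ=T|missense_variant|MYH7|MYH7|TX1",
           "\tGT\t0/0\t0/1\t1/1\t./.")), path)
  v <- read_annotated_vcf(path)
  expect_equal(unname(v$genotypes[[1]]),
               c("hom_ref", "het", "hom_alt", "missing"))
})

test_that("decision tables round-trip through TSV", {
  kb <- bundled_kb()
  v <- rbind_variants(
    make_variant("MYH7", "missense_variant", pos = 700L,
                 variant_class = "missense"),
    make_variant("TTN", "missense_variant", pos = 701L,
                 variant_class = "missense", hgvs_p = "p.Gly9Ser"),
    make_variant("MYBPC3", "frameshift_variant", pos = 702L,
                 variant_class = "nmd_truncating"))
  res <- run_pipeline3_g2p(v, kb, pipeline_config("g2p"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decisions(res, path)
  back <- read_decisions(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$retained, res$decisions$retained)
  expect_equal(back$variant_key, res$decisions$variant_key)
  expect_equal(back$stage_trace, res$decisions$stage_trace)
  # header only for an empty decision set
  empty <- res; empty$decisions <- res$decisions[0, ]
  write_decisions(empty, path)
  expect_equal(length(readLines(path)), 1)
})
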