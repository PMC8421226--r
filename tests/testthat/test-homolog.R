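make_block <- function(ref_start, ref_text, tgt_text,
                       ref_name = "hg.chr1", tgt_name = "mm.chr1",
                       tgt_start = 0L) {
  data.frame(ref_name = ref_name, ref_start = ref_start,
             ref_size = nchar(gsub("-", "", ref_text)), ref_strand = "+",
             ref_srcsize = 1000L, ref_text = ref_text,
             tgt_name = tgt_name, tgt_start = tgt_start,
             tgt_size = nchar(gsub("-", "", tgt_text)), tgt_strand = "+",
             tgt_srcsize = 1000L, tgt_text = tgt_text,
             stringsAsFactors = FALSE)
}

occ_at <- function(start, seq = strrep("A", 13), chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = start + 13L, strand = "+",
             matched_seq = seq, source_genome = "hg",
             stringsAsFactors = FALSE)
}

test_that("projection statuses: ok, indel, partial, unaligned", {
  # gap-free block covering hg.chr1:[0,19) with a known target row
  ref <- "TGAGAACAGAGTGTTCTTT"
  tgt <- "TGAGAACGGAGTGTTCTTT"
  idx <- index_alignment(make_block(0L, ref, tgt))
  r <- project_occurrence(idx, occ_at(3L, "GAACAGAGTGTTC"))
  expect_equal(r$status, "ok")
  expect_equal(r$homolog_seq, "GAACGGAGTGTTC")
  # gap in the target row inside the motif columns
  idx2 <- index_alignment(make_block(0L, ref, "TGAGAAC-GAGTGTTCTTTA"))
  expect_equal(project_occurrence(idx2, occ_at(3L))$status, "indel")
  # gap in the reference row (insertion in the target) is also an indel
  idx3 <- index_alignment(
    make_block(0L, "TGAGAAC-AGAGTGTTCTTT", "TGAGAACTAGAGTGTTCTTT"))
  expect_equal(project_occurrence(idx3, occ_at(3L))$status, "indel")
  # block covers only half the occurrence
  idx4 <- index_alignment(make_block(0L, "TGAGAACAG", "TGAGAACAG"))
  expect_equal(project_occurrence(idx4, occ_at(3L))$status, "partial")
  # no block at all, or blocks elsewhere
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines("##maf version=1", f)
  expect_equal(project_occurrence(index_alignment(read_maf(f)),
                                  occ_at(3L))$status, "unaligned")
  idx5 <- index_alignment(make_block(500L, "ACGTACGTACGTA", "ACGTACGTACGTA"))
  expect_equal(project_occurrence(idx5, occ_at(3L))$status, "unaligned")
})

test_that("identity self-alignment returns the occurrence's own sequence", {
  seq <- "TGAGAACAGAGTGTTCTTT"
  idx <- index_alignment(make_block(0L, seq, seq))
  occ <- scan_sequence(gr_motif(), seq, "chr1")
  r <- project_occurrence(idx, occ)
  expect_equal(r$status, "ok")
  expect_equal(r$homolog_seq, occ$matched_seq)
})

test_that("projection is order-independent and ties break deterministically", {
  ref <- "TGAGAACAGAGTGTTCTTT"
  b1 <- make_block(0L, ref, "TGAGAACGGAGTGTTCTTT", tgt_name = "mm.chr2")
  b2 <- make_block(0L, ref, "TGAGAACTGAGTGTTCTTT", tgt_name = "mm.chr1")
  fwd <- project_occurrence(index_alignment(rbind(b1, b2)), occ_at(3L))
  rev <- project_occurrence(index_alignment(rbind(b2, b1)), occ_at(3L))
  expect_identical(fwd, rev)
  # tie on overlap resolved by (tgt_name, tgt_start): mm.chr1 wins
  expect_equal(fwd$homolog_seq, "GAACTGAGTGTTC")
})

test_that("collect_homologs on a mutation-free simulation reproduces the human sequence", {
  cfg <- sim_config(genome_length = 20000L, n_cpg_sites = 10L,
                    n_tpg_sites = 20L, mu = 0, delta = 0, seed = 5L)
  ds <- simulate_dataset(cfg)
  occ <- scan_genome(gr_motif(), ds$human, "humanlike")
  hom <- suppressMessages(
    collect_homologs(occ, index_alignment(ds$maf), "other"))
  expect_true(all(hom$status == "ok"))
  expect_identical(hom$homolog_seq, hom$human_seq)
})

test_that("no indel statuses arise when the indel rate is zero", {
  cfg <- sim_config(genome_length = 20000L, n_cpg_sites = 10L,
                    n_tpg_sites = 20L, mu = 0.02, delta = 0, seed = 6L)
  ds <- simulate_dataset(cfg)
  occ <- scan_genome(gr_motif(), ds$human, "humanlike")
  hom <- suppressMessages(
    collect_homologs(occ, index_alignment(ds$maf), "other"))
  expect_false(any(hom$status == "indel"))
  expect_true(all(hom$status == "ok"))
})
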