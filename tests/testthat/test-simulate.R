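test_that("ancestor generation is seeded, plants exact motifs, checks feasibility", {
  cfg <- sim_config(genome_length = 10000L, n_cpg_sites = 5L,
                    n_tpg_sites = 5L, seed = 3L)
  a1 <- make_ancestor(cfg)
  a2 <- make_ancestor(cfg)
  expect_identical(a1, a2)
  expect_equal(nchar(a1$seq), 10000L)
  # every planted locus carries an exact pattern instance
  m_cpg <- compile_motif("GnACGnnnTGTnC")
  m_tpg <- gr_motif()
  for (i in seq_len(nrow(a1$truth))) {
    site <- substr(a1$seq, a1$truth$anc_start[i] + 1, a1$truth$anc_end[i])
    m <- if (a1$truth$class[i] == "cpg") m_cpg else m_tpg
    expect_equal(classify_homolog(site, m)$kind, "identical")
  }
  # planted sites are non-overlapping
  tr <- a1$truth[order(a1$truth$anc_start), ]
  expect_true(all(diff(tr$anc_start) >= 13))
  expect_error(sim_config(genome_length = 100L, n_cpg_sites = 5L,
                          n_tpg_sites = 5L), "50x")
})

test_that("a silent lineage equals the ancestor with an identity alignment", {
  cfg <- sim_config(genome_length = 5000L, n_cpg_sites = 5L,
                    n_tpg_sites = 5L, mu = 0, delta = 0, seed = 9L)
  anc <- make_ancestor(cfg)
  lin <- evolve_lineage(anc$seq, cfg, 123L)
  expect_identical(lin$seq, anc$seq)
  expect_true(all(lin$kept))
  ds <- simulate_dataset(cfg)
  expect_identical(unname(ds$human), anc$seq)
  expect_false(grepl("-", ds$maf$ref_text, fixed = TRUE))
  expect_false(grepl("-", ds$maf$tgt_text, fixed = TRUE))
})

test_that("zero indel rate yields a gap-free alignment", {
  cfg <- sim_config(genome_length = 20000L, n_cpg_sites = 20L,
                    n_tpg_sites = 40L, mu = 0.05, delta = 0, seed = 2L)
  ds <- simulate_dataset(cfg)
  expect_false(grepl("-", ds$maf$ref_text, fixed = TRUE))
  expect_false(grepl("-", ds$maf$tgt_text, fixed = TRUE))
  expect_equal(nchar(ds$maf$ref_text), nchar(unname(ds$human)))
})

test_that("CpG deamination saturates as one event per dinucleotide", {
  # lambda*mu = 1: each planted CpG is destroyed with prob 1 - exp(-1)
  cfg <- sim_config(genome_length = 60000L, n_cpg_sites = 400L,
                    n_tpg_sites = 400L, mu = 0.02, lambda = 50,
                    delta = 0, seed = 13L)
  anc <- make_ancestor(cfg)
  lin <- evolve_lineage(anc$seq, cfg, 77L)
  cpg <- anc$truth[anc$truth$class == "cpg", ]
  retained <- vapply(seq_len(nrow(cpg)), function(i) {
    site <- paste(lin$anc_base[(cpg$anc_start[i] + 1):cpg$anc_end[i]],
                  collapse = "")
    substr(site, 4, 5) == "CG"
  }, NA)
  frac <- mean(retained)
  expect_gt(frac, exp(-1) - 0.07)
  expect_lt(frac, exp(-1) + 0.07)
  # destroyed sites resolve to TpG or CpA, never TpA (single-strand event)
  destroyed <- vapply(seq_len(nrow(cpg)), function(i) {
    site <- paste(lin$anc_base[(cpg$anc_start[i] + 1):cpg$anc_end[i]],
                  collapse = "")
    substr(site, 4, 5)
  }, "")
  expect_false(any(destroyed == "TA"))
})

test_that("dataset emission is byte-identical under a fixed seed", {
  cfg <- sim_config(genome_length = 8000L, n_cpg_sites = 8L,
                    n_tpg_sites = 16L, seed = 31L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_dataset(cfg, d1)
  p2 <- emit_dataset(cfg, d2)
  for (f in c("humanlike.fa", "other.fa", "alignment.maf",
              "regulatory.bed", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # emitted files are readable by the package's own readers
  expect_equal(nchar(read_fasta(p1$human_fasta)[[1]]),
               nchar(unname(p1$data$human)))
  maf <- read_maf(p1$maf)
  expect_equal(nchar(gsub("-", "", maf$ref_text)), maf$ref_size)
  expect_identical(maf, p1$data$maf)
})

test_that("a motif-free configuration still emits valid files", {
  cfg <- sim_config(genome_length = 3000L, n_cpg_sites = 0L,
                    n_tpg_sites = 0L, seed = 1L)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$truth), 0L)
  expect_equal(nrow(ds$regulatory), 0L)
  expect_equal(nchar(unname(ds$other)) > 0, TRUE)
})

test_that("full-stack null: no mutations, no variants, no pre-GBS calls", {
  cfg <- sim_config(genome_length = 40000L, n_cpg_sites = 50L,
                    n_tpg_sites = 100L, mu = 0, delta = 0, seed = 17L)
  ds <- simulate_dataset(cfg)
  res <- run_deamination_pipeline(ds$human, list(other = ds$maf),
                                  list(reg = ds$regulatory),
                                  source_genome = "humanlike")
  expect_gte(nrow(res$occurrences), 100L)
  expect_equal(res$spectra$n_variants, 0L)
  expect_equal(res$spectra$other_count, 0L)
  expect_equal(res$pre_gbs$total, 0L)
  expect_equal(res$pre_gbs$unique, 0L)
})

test_that("truth-guided recall: retained-CpG witnesses are all recovered", {
  cfg <- sim_config(genome_length = 100000L, n_cpg_sites = 300L,
                    n_tpg_sites = 300L, mu = 0.02, lambda = 25,
                    delta = 0, seed = 19L)
  ds <- simulate_dataset(cfg)
  res <- run_deamination_pipeline(ds$human, list(other = ds$maf),
                                  source_genome = "humanlike")
  # truth: planted CpG sites converted in the human lineage whose other
  # lineage copy is a single5 G variant of the consensus
  tr <- ds$truth
  witness <- tr$deamination_derived & !is.na(tr$other_seq) &
    vapply(seq_len(nrow(tr)), function(i) {
      if (is.na(tr$other_seq[i])) return(FALSE)
      cls <- classify_homolog(tr$other_seq[i])
      !is.na(cls$pooled_nt) && cls$pooled_nt == "G"
    }, NA)
  expected_keys <- paste("chr1", tr$human_start[witness], sep = ":")
  got_keys <- paste(res$pre_gbs$sites$chrom, res$pre_gbs$sites$start,
                    sep = ":")
  expect_true(all(expected_keys %in% got_keys))
  expect_gt(sum(witness), 10)
})

test_that("the recovery experiment reports spectra across the rate grid", {
  cfg <- sim_config(genome_length = 200000L, n_cpg_sites = 300L,
                    n_tpg_sites = 900L, mu = 0.02, delta = 0, seed = 23L)
  out <- recovery_experiment(cfg, lambdas = c(1, 20))
  expect_equal(out$lambda, c(1, 20))
  expect_true(all(out$n_variants > 0))
  expect_gt(out$fraction_G[2], 0.5)
  expect_lt(out$chisq_p[2], 0.005)  # starred in the figure-style report
  expect_true(nzchar(out$chisq_stars[2]))
  expect_gt(out$fraction_G[2], out$fraction_G[1])
})
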