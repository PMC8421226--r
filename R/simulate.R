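CPG_SITE_PATTERN <- "GnACGnnnTGTnC"  # pre-GBS: CpG at motif positions 4-5
TPG_SITE_PATTERN <- "GnACAnnnTGTnC"  # modern consensus: TpG-equivalent state

derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2147483647) * 48271 + k * 100003) %% 2147483629 + 1
}

#' Configuration for the genome-evolution simulator
#'
#' The generator plants CpG-containing pre-GBS motifs (`GnACGnnnTGTnC`) and
#' modern consensus motifs (`GnACAnnnTGTnC`) into an i.i.d. ancestral
#' background, then evolves two descendant lineages under a CpG-hypermutable
#' substitution model with optional small indels. Four modern sites are
#' planted per CpG site by default, mirroring the roughly 4-fold CpG
#' depletion of mammalian genomes relative to other dinucleotides.
#'
#' @param genome_length Ancestor length in bp.
#' @param gc_content Background GC fraction in (0,1).
#' @param n_cpg_sites,n_tpg_sites Planted CpG-containing and consensus motif
#'   counts (wildcards drawn uniformly).
#' @param mu Per-site substitution probability per lineage.
#' @param lambda CpG deamination rate multiplier (>= 1). Each CpG
#'   dinucleotide suffers a deamination event with probability
#'   `1 - exp(-lambda * mu)`, resolving with equal probability to TpG
#'   (C to T on the strand carrying the C) or CpA (G to A, the
#'   complementary-strand deamination); non-CpG sites substitute uniformly.
#' @param delta Per-site indel probability (geometric lengths, mean
#'   `indel_mean`).
#' @param indel_mean Mean indel length.
#' @param rho Probability that a deamination-derived site is covered by the
#'   regulatory track.
#' @param rho0 Coverage probability for all other planted sites.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 150000L, gc_content = 0.41,
                       n_cpg_sites = 300L, n_tpg_sites = 4L * n_cpg_sites,
                       mu = 0.02, lambda = 20, delta = 0.001,
                       indel_mean = 2, rho = 0.9, rho0 = 0.3, seed = 1L) {
  stopifnot(genome_length > 0, gc_content > 0, gc_content < 1,
            n_cpg_sites >= 0, n_tpg_sites >= 0,
            mu >= 0, mu <= 1, lambda >= 1, delta >= 0, delta <= 1,
            indel_mean >= 1, rho >= 0, rho <= 1, rho0 >= 0, rho0 <= 1)
  if (genome_length < 50 * (n_cpg_sites + n_tpg_sites))
    stop("genome_length must be at least 50x the number of planted sites",
         call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content,
                 n_cpg_sites = as.integer(n_cpg_sites),
                 n_tpg_sites = as.integer(n_tpg_sites),
                 mu = mu, lambda = lambda, delta = delta,
                 indel_mean = indel_mean, rho = rho, rho0 = rho0,
                 seed = as.integer(seed)),
            class = "sim_config")
}

instantiate_motif <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  wild <- ch %in% c("n", "N")
  ch[wild] <- sample(c("A", "C", "G", "T"), sum(wild), replace = TRUE)
  ch
}

#' Generate the ancestral genome with planted motif sites
#'
#' Background bases are i.i.d. with the configured GC content; motifs are
#' planted at uniformly drawn non-overlapping loci. Deterministic under the
#' config seed.
#'
#' @param config A `sim_config`.
#' @return A list: `seq` (the ancestor as one string), `truth` (data.frame
#'   `site_id`, `class` in {cpg, tpg}, `anc_start`, `anc_end`; 0-based
#'   half-open).
#' @export
make_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  L <- config$genome_length
  gc <- config$gc_content
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  n_total <- config$n_cpg_sites + config$n_tpg_sites
  width <- nchar(CPG_SITE_PATTERN)
  occupied <- logical(L)
  starts <- integer(n_total)
  for (i in seq_len(n_total)) {
    placed <- FALSE
    for (try in 1:200) {
      cand <- sample.int(L - width + 1L, 1L)
      if (!any(occupied[cand:(cand + width - 1L)])) {
        occupied[cand:(cand + width - 1L)] <- TRUE
        starts[i] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place non-overlapping motif sites; genome too dense",
           call. = FALSE)
  }
  cls <- sample(rep(c("cpg", "tpg"),
                    c(config$n_cpg_sites, config$n_tpg_sites)))
  for (i in seq_len(n_total)) {
    pat <- if (cls[i] == "cpg") CPG_SITE_PATTERN else TPG_SITE_PATTERN
    base[starts[i]:(starts[i] + width - 1L)] <- instantiate_motif(pat)
  }
  truth <- data.frame(site_id = seq_len(n_total), class = cls,
                      anc_start = starts - 1L, anc_end = starts - 1L + width,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$anc_start), , drop = FALSE]
  truth$site_id <- seq_len(n_total)
  rownames(truth) <- NULL
  list(seq = paste(base, collapse = ""), truth = truth)
}

#' Evolve one descendant lineage from the ancestor
#'
#' Substitutions are applied in a single simultaneous pass from the
#' pre-pass sequence: CpG dinucleotides (scanned on the ancestral sequence)
#' deaminate as one event per dinucleotide with probability
#' `1 - exp(-lambda * mu)`, resolving to TpG or CpA with equal probability;
#' every other site substitutes to a uniformly chosen different base with
#' probability `mu`. Indels (insertion/deletion with equal probability,
#' geometric lengths) are then applied with per-site probability `delta`
#' from an RNG stream separate from the substitution draws. With
#' `mu = delta = 0` the derived genome equals the ancestor.
#'
#' @param ancestor_seq Ancestor sequence string.
#' @param config A `sim_config`.
#' @param lineage_seed Integer seed for this lineage.
#' @return A list: `seq` (derived sequence), `anc_base` (post-substitution
#'   bases in ancestor coordinates), `kept` (logical; FALSE where deleted),
#'   `ins` (insertion string after each ancestor position), `map`
#'   (0-based derived coordinate of each ancestor base, `NA` if deleted).
#' @export
evolve_lineage <- function(ancestor_seq, config, lineage_seed) {
  stopifnot(inherits(config, "sim_config"))
  s <- strsplit(ancestor_seq, "")[[1]]
  L <- length(s)
  bases <- c("A", "C", "G", "T")
  # --- substitutions (stream 1) ---
  set.seed(derive_seed(lineage_seed, 11))
  s2 <- s
  if (config$mu > 0 && L > 1L) {
    cpg_c <- which(s[-L] == "C" & s[-1L] == "G")
    p_deam <- 1 - exp(-config$lambda * config$mu)
    if (length(cpg_c)) {
      ev <- runif(length(cpg_c)) < p_deam
      fwd <- runif(length(cpg_c)) < 0.5
      s2[cpg_c[ev & fwd]] <- "T"          # CG -> TG (forward-strand 5mC)
      s2[cpg_c[ev & !fwd] + 1L] <- "A"    # CG -> CA (reverse-strand 5mC)
    }
    in_cpg <- logical(L)
    in_cpg[cpg_c] <- TRUE
    in_cpg[cpg_c + 1L] <- TRUE
    hit <- runif(L) < config$mu & !in_cpg
    if (any(hit)) {
      cur <- match(s[hit], bases)
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s2[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  # --- indels (stream 2) ---
  set.seed(derive_seed(lineage_seed, 12))
  kept <- rep(TRUE, L)
  ins <- character(L)
  ins[] <- ""
  if (config$delta > 0) {
    ev_pos <- which(runif(L) < config$delta)
    if (length(ev_pos)) {
      is_ins <- runif(length(ev_pos)) < 0.5
      len <- 1L + rgeom(length(ev_pos), prob = 1 / config$indel_mean)
      del_pos <- ev_pos[!is_ins]
      del_len <- len[!is_ins]
      if (length(del_pos)) {
        rm_idx <- unlist(Map(function(p, l) p:min(L, p + l - 1L),
                             del_pos, del_len))
        kept[rm_idx] <- FALSE
      }
      ins_pos <- ev_pos[is_ins]
      ins_len <- len[is_ins]
      if (length(ins_pos)) {
        ins[ins_pos] <- vapply(ins_len, function(l)
          paste(sample(bases, l, replace = TRUE), collapse = ""), "")
      }
    }
  }
  pieces <- paste0(ifelse(kept, s2, ""), ins)
  np <- nchar(pieces)
  offset <- cumsum(np) - np
  map <- ifelse(kept, offset, NA_integer_)
  list(seq = paste(pieces, collapse = ""), anc_base = s2, kept = kept,
       ins = ins, map = map)
}

# Compose the ground-truth pairwise alignment of two lineages via the
# ancestor frame; returns a one-block MAF data.frame (lineage A = reference).
compose_alignment <- function(linA, linB, ref_name, tgt_name) {
  both_gone <- !linA$kept & !linB$kept
  a_main <- ifelse(both_gone, "", ifelse(linA$kept, linA$anc_base, "-"))
  b_main <- ifelse(both_gone, "", ifelse(linB$kept, linB$anc_base, "-"))
  gap_a <- strrep("-", nchar(linA$ins))
  gap_b <- strrep("-", nchar(linB$ins))
  a_text <- paste(paste0(a_main, linA$ins, gap_b), collapse = "")
  b_text <- paste(paste0(b_main, gap_a, linB$ins), collapse = "")
  a_len <- nchar(linA$seq)
  b_len <- nchar(linB$seq)
  data.frame(ref_name = ref_name, ref_start = 0L, ref_size = a_len,
             ref_strand = "+", ref_srcsize = a_len, ref_text = a_text,
             tgt_name = tgt_name, tgt_start = 0L, tgt_size = b_len,
             tgt_strand = "+", tgt_srcsize = b_len, tgt_text = b_text,
             stringsAsFactors = FALSE)
}

map_interval <- function(lin, start0, end0) {
  idx <- (start0 + 1L):end0
  if (any(!lin$kept[idx])) return(c(NA_integer_, NA_integer_))
  if (any(nzchar(lin$ins[idx[-length(idx)]])))
    return(c(NA_integer_, NA_integer_))  # internal insertion breaks the site
  c(lin$map[idx[1L]], lin$map[idx[length(idx)]] + 1L)
}

#' Simulate a complete two-lineage dataset in memory
#'
#' Runs [make_ancestor()] and [evolve_lineage()] for a human-like and an
#' other-species lineage, composes the ground-truth alignment, derives the
#' truth table (planted class, post-evolution state per lineage, descendant
#' coordinates) and draws the regulatory track: a deamination-derived site
#' (a planted CpG site whose human-lineage copy became an intact consensus
#' motif) is covered with probability `rho`, every other planted site with
#' probability `rho0`.
#'
#' @param config A `sim_config`.
#' @return A list: `ancestor`, `human` (named sequence vector), `other`,
#'   `maf` (alignment blocks, human-like reference), `regulatory`
#'   (BED-style data.frame in human coordinates), `truth` (data.frame).
#' @export
simulate_dataset <- function(config) {
  anc <- make_ancestor(config)
  lin_h <- evolve_lineage(anc$seq, config, derive_seed(config$seed, 2))
  lin_o <- evolve_lineage(anc$seq, config, derive_seed(config$seed, 3))
  maf <- compose_alignment(lin_h, lin_o, "humanlike.chr1", "other.chr1")
  truth <- anc$truth
  motif <- gr_motif()
  site_seq <- function(lin, st, en) {
    idx <- (st + 1L):en
    if (any(!lin$kept[idx]) || any(nzchar(lin$ins[idx[-length(idx)]])))
      return(NA_character_)
    paste(lin$anc_base[idx], collapse = "")
  }
  n <- nrow(truth)
  h_seq <- o_seq <- character(n)
  h_start <- h_end <- o_start <- o_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    h_seq[i] <- site_seq(lin_h, truth$anc_start[i], truth$anc_end[i])
    o_seq[i] <- site_seq(lin_o, truth$anc_start[i], truth$anc_end[i])
    hm <- map_interval(lin_h, truth$anc_start[i], truth$anc_end[i])
    om <- map_interval(lin_o, truth$anc_start[i], truth$anc_end[i])
    h_start[i] <- hm[1L]; h_end[i] <- hm[2L]
    o_start[i] <- om[1L]; o_end[i] <- om[2L]
  }
  matches <- function(seqs) {
    out <- rep(FALSE, length(seqs))
    okl <- !is.na(seqs)
    if (any(okl)) {
      cls <- classify_homolog(seqs[okl], motif)
      out[okl] <- cls$kind == "identical"
    }
    out
  }
  truth$human_seq <- h_seq
  truth$other_seq <- o_seq
  truth$human_start <- h_start
  truth$human_end <- h_end
  truth$other_start <- o_start
  truth$other_end <- o_end
  truth$human_consensus <- matches(h_seq)
  truth$other_consensus <- matches(o_seq)
  truth$deamination_derived <- truth$class == "cpg" & truth$human_consensus
  # regulatory track (stream 4)
  set.seed(derive_seed(config$seed, 4))
  p_cov <- ifelse(truth$deamination_derived, config$rho, config$rho0)
  covered <- runif(n) < p_cov & !is.na(truth$human_start)
  truth$regulatory <- covered
  reg <- if (any(covered)) {
    data.frame(chrom = "chr1", start = truth$human_start[covered],
               end = truth$human_end[covered],
               name = paste0("reg_site", truth$site_id[covered]),
               score = 0, strand = "+", extra = "",
               stringsAsFactors = FALSE)
  } else {
    empty_intervals()
  }
  reg <- reg[order(reg$start), , drop = FALSE]
  rownames(reg) <- NULL
  list(ancestor = anc$seq,
       human = c(chr1 = lin_h$seq),
       other = c(chr1 = lin_o$seq),
       maf = maf, regulatory = reg, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the human-like FASTA, other-species FASTA, ground-truth MAF
#' (human-like as reference), regulatory BED and truth TSV. Outputs are
#' byte-identical across runs with the same config and seed.
#'
#' @param config A `sim_config`.
#' @param outdir Writable output directory (created if needed).
#' @return Invisibly, a named list of file paths plus the in-memory dataset
#'   under `$data`.
#' @export
emit_dataset <- function(config, outdir) {
  ds <- simulate_dataset(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    human_fasta = file.path(outdir, "humanlike.fa"),
    other_fasta = file.path(outdir, "other.fa"),
    maf = file.path(outdir, "alignment.maf"),
    regulatory_bed = file.path(outdir, "regulatory.bed"),
    truth_tsv = file.path(outdir, "truth.tsv"))
  write_fasta(ds$human, paths$human_fasta)
  write_fasta(ds$other, paths$other_fasta)
  write_maf(ds$maf, paths$maf)
  write_bed(ds$regulatory, paths$regulatory_bed)
  write_report(ds$truth, paths$truth_tsv)
  invisible(c(paths, list(data = ds)))
}

#' Deamination-signal recovery experiment over a grid of rate multipliers
#'
#' For each CpG hypermutability multiplier in `lambdas`, simulates a
#' dataset (same ancestor, lineages re-evolved), runs the full pipeline —
#' scan the human-like genome, extract gapless homologs, classify variants,
#' tally the pooled spectrum — and reports the pooled G fraction with the
#' uniform-null chi-square test.
#'
#' @param config A `sim_config` (its `lambda` is overridden per run).
#' @param lambdas Numeric vector of multipliers.
#' @return A data.frame: `lambda`, `n_occurrences`, `n_ok`, `n_C`, `n_G`,
#'   `n_T`, `n_variants`, `fraction_G`, `chisq_p`, `chisq_stars`.
#' @export
recovery_experiment <- function(config, lambdas = c(1, 5, 10, 20, 50)) {
  motif <- gr_motif()
  rows <- lapply(seq_along(lambdas), function(i) {
    cfg <- config
    cfg$lambda <- lambdas[i]
    cfg$seed <- as.integer(derive_seed(config$seed, 100 + i))
    ds <- simulate_dataset(cfg)
    occ <- scan_genome(motif, ds$human, source_genome = "humanlike")
    hom <- suppressMessages(
      collect_homologs(occ, index_alignment(ds$maf), species = "other"))
    spec <- tally_spectra(classify_homologs(hom, motif), motif)
    p <- if (spec$n_variants[1] > 0)
      chisq_uniform(c(C = spec$n_C[1], G = spec$n_G[1],
                      T = spec$n_T[1]))$p_value else NA_real_
    data.frame(lambda = lambdas[i], n_occurrences = nrow(occ),
               n_ok = spec$n_ok[1], n_C = spec$n_C[1], n_G = spec$n_G[1],
               n_T = spec$n_T[1], n_variants = spec$n_variants[1],
               fraction_G = spec$fraction_G[1], chisq_p = p,
               chisq_stars = chisq_stars(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
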