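#' Run the full deamination-inference pipeline
#'
#' Scans the reference genome for the degenerate motif, projects every
#' occurrence through each pairwise alignment to extract gapless homologs,
#' classifies single-base variants at the CpG-informative positions with
#' strand folding, tallies per-species spectra, selects pre-GBS candidates
#' (pooled-G supports), labels occurrences as regulatory by annotation
#' overlap, and computes the accompanying statistics, including the
#' hypergeometric test for regulatory overlap of the unique pre-GBS set
#' (population = all motif occurrences, successes = regulatory occurrences,
#' draws = unique pre-GBS sites, observed = regulatory pre-GBS sites).
#'
#' @param genome Named character vector of reference sequences.
#' @param alignments Named list (species -> alignment blocks from
#'   [read_maf()], an `alignment_index`, or a MAF path).
#' @param tracks Named list of annotation interval data.frames (may be
#'   empty).
#' @param motif A `degenerate_motif` (default [gr_motif()]).
#' @param source_genome Label for the reference genome.
#' @param flank Flank (bp) for the regulatory overlap query.
#' @return A list: `occurrences` (regulatory-labeled), `homologs`
#'   (classified records for all species), `spectra`, `pre_gbs`,
#'   `report` (per-species spectrum report), `hypergeom`
#'   (list with N, K, n, k and `p_value`).
#' @export
run_deamination_pipeline <- function(genome, alignments, tracks = list(),
                                     motif = gr_motif(),
                                     source_genome = "human", flank = 0L) {
  occ <- scan_genome(motif, genome, source_genome = source_genome)
  homologs <- do.call(rbind, lapply(names(alignments), function(sp)
    suppressMessages(collect_homologs(occ, alignments[[sp]], species = sp))))
  if (is.null(homologs))
    homologs <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), human_seq = character(0),
                           species = character(0), status = character(0),
                           homolog_seq = character(0),
                           stringsAsFactors = FALSE)
  classified <- classify_homologs(homologs, motif)
  spectra <- if (nrow(classified)) tally_spectra(classified, motif) else NULL
  pre_gbs <- select_pre_gbs(classified, motif)
  labeled <- classify_regulatory(occ, tracks, flank = flank)
  report <- if (nrow(classified))
    spectrum_report(classified, labeled) else NULL
  N <- nrow(occ)
  K <- sum(labeled$regulatory)
  n_draw <- pre_gbs$unique
  k_obs <- 0L
  if (n_draw > 0L) {
    key <- paste(labeled$chrom, labeled$start, labeled$end, sep = ":")
    reg_map <- setNames(labeled$regulatory, key)
    site_key <- paste(pre_gbs$sites$chrom, pre_gbs$sites$start,
                      pre_gbs$sites$end, sep = ":")
    k_obs <- sum(reg_map[site_key], na.rm = TRUE)
  }
  hyp <- list(N = N, K = K, n = n_draw, k = k_obs,
              p_value = if (N > 0L) hypergeom_tail(N, K, n_draw, k_obs)
              else NA_real_)
  list(occurrences = labeled, homologs = classified, spectra = spectra,
       pre_gbs = pre_gbs, report = report, hypergeom = hyp)
}
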