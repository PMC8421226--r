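#' Classify homologous motif sequences against the consensus
#'
#' Compares each motif-length homolog to the fixed positions of the motif.
#' A homolog is `identical` when every fixed position matches, `single5`
#' (`single9`) when the CpG-informative forward (reverse) position is the
#' only fixed mismatch, and `other` otherwise (including any non-ACGT base).
#' Wildcard positions never constrain. Position-9 variants are folded onto
#' the position-5 frame by complementing the variant base, which is valid
#' because the GR core motif is its own reverse complement; the pooled base
#' is therefore never the position-5 consensus `A`.
#'
#' @param seqs Character vector of homolog sequences (motif length each).
#' @param motif A `degenerate_motif`; defaults to [gr_motif()].
#' @param pos_fwd Forward-frame variant position (default 5); the reverse
#'   frame position is `motif$length + 1 - pos_fwd` (9 for the GR core).
#' @return A data.frame with columns `kind` (`identical`, `single5`,
#'   `single9`, `other`), `raw_nt` and `pooled_nt` (`NA` unless single5/9).
#' @export
classify_homolog <- function(seqs, motif = gr_motif(), pos_fwd = 5L) {
  stopifnot(inherits(motif, "degenerate_motif"))
  if (length(seqs) == 0L)
    return(data.frame(kind = character(0), raw_nt = character(0),
                      pooled_nt = character(0), stringsAsFactors = FALSE))
  if (any(nchar(seqs) != motif$length))
    stop("homolog sequence length does not match motif length",
         call. = FALSE)
  pos_rev <- motif$length + 1L - pos_fwd
  fixed_pos <- as.integer(names(motif$fixed))
  n <- length(seqs)
  up <- toupper(seqs)
  mism <- matrix(FALSE, n, length(fixed_pos))
  for (j in seq_along(fixed_pos)) {
    p <- fixed_pos[j]
    mism[, j] <- !substring(up, p, p) %in% motif$fixed[[j]]
  }
  non_acgt <- grepl("[^ACGT]", up)
  n_mism <- rowSums(mism)
  at5 <- mism[, match(pos_fwd, fixed_pos)]
  at9 <- mism[, match(pos_rev, fixed_pos)]
  kind <- rep("other", n)
  kind[n_mism == 0L] <- "identical"
  kind[n_mism == 1L & at5] <- "single5"
  kind[n_mism == 1L & at9] <- "single9"
  kind[non_acgt] <- "other"
  raw <- rep(NA_character_, n)
  pooled <- rep(NA_character_, n)
  s5 <- kind == "single5"
  s9 <- kind == "single9"
  raw[s5] <- substring(up[s5], pos_fwd, pos_fwd)
  pooled[s5] <- raw[s5]
  raw[s9] <- substring(up[s9], pos_rev, pos_rev)
  pooled[s9] <- unname(IUPAC_COMPLEMENT[raw[s9]])
  data.frame(kind = kind, raw_nt = raw, pooled_nt = pooled,
             stringsAsFactors = FALSE)
}

#' Classify a table of homolog records
#'
#' Adds `kind`, `raw_nt` and `pooled_nt` columns to a homolog record table
#' (see [collect_homologs()]); records whose status is not `ok` get `NA`s.
#'
#' @param records Homolog record data.frame.
#' @param motif A `degenerate_motif`.
#' @return The input with classification columns appended.
#' @export
classify_homologs <- function(records, motif = gr_motif()) {
  records$kind <- rep(NA_character_, nrow(records))
  records$raw_nt <- rep(NA_character_, nrow(records))
  records$pooled_nt <- rep(NA_character_, nrow(records))
  ok <- records$status == "ok"
  if (any(ok)) {
    cls <- classify_homolog(records$homolog_seq[ok], motif)
    records$kind[ok] <- cls$kind
    records$raw_nt[ok] <- cls$raw_nt
    records$pooled_nt[ok] <- cls$pooled_nt
  }
  records
}

#' Tally per-species pooled variant spectra
#'
#' Counts pooled position-5 variant nucleotides (C/G/T), identical and
#' other homologs per species, over `ok`-status records.
#'
#' @param records Classified homolog records (see [classify_homologs()]);
#'   unclassified records are classified first.
#' @param motif A `degenerate_motif`, used if classification is needed.
#' @return A data.frame with one row per species: `species`, `n_ok`,
#'   `identical_count`, `other_count`, `n_C`, `n_G`, `n_T`, `n_variants`
#'   and `fraction_G` (`NA` when a species has no variants).
#' @export
tally_spectra <- function(records, motif = gr_motif()) {
  if (!"kind" %in% names(records))
    records <- classify_homologs(records, motif)
  ok <- records[records$status == "ok", , drop = FALSE]
  species <- unique(records$species)
  if (length(species) == 0L)
    return(data.frame(species = character(0), n_ok = integer(0),
                      identical_count = integer(0), other_count = integer(0),
                      n_C = integer(0), n_G = integer(0), n_T = integer(0),
                      n_variants = integer(0), fraction_G = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(species, function(sp) {
    r <- ok[ok$species == sp, , drop = FALSE]
    pooled <- table(factor(r$pooled_nt, levels = c("C", "G", "T")))
    nv <- sum(pooled)
    data.frame(species = sp, n_ok = nrow(r),
               identical_count = sum(r$kind == "identical"),
               other_count = sum(r$kind == "other"),
               n_C = unname(pooled[["C"]]), n_G = unname(pooled[["G"]]),
               n_T = unname(pooled[["T"]]), n_variants = nv,
               fraction_G = if (nv > 0) unname(pooled[["G"]]) / nv else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select deamination-candidate pre-GBS sites
#'
#' A pre-GBS support is an (occurrence, species) pair whose pooled variant
#' base is `G`, i.e. the homolog retains a CpG where the modern motif has
#' TpG (equivalently CA on the opposite strand). The total count is the
#' number of supports; the unique count deduplicates on the human genomic
#' interval, so a site appearing in several species is counted once.
#'
#' @param records Classified homolog records.
#' @param motif A `degenerate_motif`, used if classification is needed.
#' @return A list with `sites` (one row per unique human interval: `chrom`,
#'   `start`, `end`, `human_seq`, `n_species`, `species`), `total` and
#'   `unique` counts.
#' @export
select_pre_gbs <- function(records, motif = gr_motif()) {
  if (!"kind" %in% names(records))
    records <- classify_homologs(records, motif)
  g <- records[records$status == "ok" & !is.na(records$pooled_nt) &
                 records$pooled_nt == "G", , drop = FALSE]
  total <- nrow(g)
  if (total == 0L) {
    sites <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), human_seq = character(0),
                        n_species = integer(0), species = character(0),
                        stringsAsFactors = FALSE)
    return(list(sites = sites, total = 0L, unique = 0L))
  }
  key <- paste(g$chrom, g$start, g$end, sep = ":")
  first <- !duplicated(key)
  sp <- vapply(split(g$species, key), function(s)
    paste(sort(unique(s)), collapse = ","), "")
  nsp <- vapply(split(g$species, key), function(s)
    length(unique(s)), 0L)
  sites <- data.frame(chrom = g$chrom[first], start = g$start[first],
                      end = g$end[first], human_seq = g$human_seq[first],
                      n_species = unname(nsp[key[first]]),
                      species = unname(sp[key[first]]),
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, total = total, unique = nrow(sites))
}
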