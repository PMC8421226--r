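IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Compile a degenerate IUPAC motif
#'
#' Positions are partitioned into fixed positions (a proper subset of bases
#' allowed) and wildcard positions (`N`/`n`, any base). Matching is
#' case-insensitive; the canonical GR core motif is `GnACAnnnTGTnC` with
#' fixed positions 1,3,4,5,9,10,11,13 and wildcards 2,6,7,8,12.
#'
#' @param pattern Non-empty string over IUPAC nucleotide codes.
#' @return An object of class `degenerate_motif` with elements `pattern`,
#'   `length`, `fixed` (named list, 1-based position -> allowed base set)
#'   and `wildcard` (integer positions).
#' @export
compile_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!nzchar(pattern)) stop("empty motif pattern", call. = FALSE)
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("illegal IUPAC code '%s' at motif position %d",
                 strsplit(pattern, "")[[1]][bad[1]], bad[1]), call. = FALSE)
  wildcard <- which(chars == "N")
  fixed_pos <- setdiff(seq_along(chars), wildcard)
  fixed <- setNames(IUPAC_SETS[chars[fixed_pos]], fixed_pos)
  structure(list(pattern = pattern, upper = paste(chars, collapse = ""),
                 length = length(chars), fixed = fixed,
                 wildcard = wildcard),
            class = "degenerate_motif")
}

#' The degenerate GR core motif
#'
#' Convenience constructor for the 13-mer glucocorticoid receptor core
#' `GnACAnnnTGTnC`, the self-reverse-complementary search pattern used
#' throughout the package.
#'
#' @return A `degenerate_motif`.
#' @export
gr_motif <- function() compile_motif("GnACAnnnTGTnC")

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("degenerate motif %s (length %d, %d fixed, %d wildcard)\n",
              x$pattern, x$length, length(x$fixed), length(x$wildcard)))
  invisible(x)
}

#' Reverse complement of an IUPAC string
#'
#' The standard complement table extended to degenerate codes (`N` maps to
#' `N`); lowercase input is complemented in lowercase.
#'
#' @param seq Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  from <- paste(c(names(IUPAC_COMPLEMENT),
                  tolower(names(IUPAC_COMPLEMENT))), collapse = "")
  to <- paste(c(IUPAC_COMPLEMENT, tolower(IUPAC_COMPLEMENT)), collapse = "")
  bad <- grepl(sprintf("[^%s]", from), seq)
  if (any(bad))
    stop("illegal character in sequence: not an IUPAC nucleotide code",
         call. = FALSE)
  comp <- chartr(from, to, seq)
  vapply(strsplit(comp, ""), function(ch)
    paste(rev(ch), collapse = ""), "")
}

new_occurrences <- function(chrom = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            matched_seq = character(0),
                            source_genome = character(0)) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             matched_seq = matched_seq, source_genome = source_genome,
             stringsAsFactors = FALSE)
}

#' Scan one sequence for a degenerate motif on both strands
#'
#' Every forward-strand window matching all fixed positions is reported in
#' coordinate order; the reverse strand is scanned as well and reported as
#' the corresponding forward-coordinate interval with strand `-`. Intervals
#' identical to a forward match are deduplicated, so a self-reverse-
#' complementary motif such as the GR core yields one occurrence per genomic
#' interval. Windows containing `N` (or any non-ACGT base) never match,
#' wildcard positions included.
#'
#' @param motif A `degenerate_motif` from [compile_motif()].
#' @param seq A single sequence string (normalized, uppercase).
#' @param seqname Sequence (chromosome/contig) name.
#' @param source_genome Genome label recorded with each occurrence.
#' @return A data.frame of occurrences: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `matched_seq` (forward-genome orientation),
#'   `source_genome`.
#' @export
scan_sequence <- function(motif, seq, seqname = "seq",
                          source_genome = "genome") {
  stopifnot(inherits(motif, "degenerate_motif"),
            is.character(seq), length(seq) == 1L)
  if (nchar(seq) < motif$length) return(new_occurrences())
  subject <- Biostrings::DNAString(seq)
  pat_fwd <- Biostrings::DNAString(motif$upper)
  pat_rev <- Biostrings::DNAString(reverse_complement(motif$upper))
  hit_starts <- function(pat) {
    Biostrings::start(Biostrings::matchPattern(pat, subject,
                                               fixed = "subject"))
  }
  fwd <- hit_starts(pat_fwd)
  rev <- hit_starts(pat_rev)
  strand <- c(rep("+", length(fwd)), rep("-", length(rev)))
  start1 <- c(fwd, rev)
  if (length(start1) == 0L) return(new_occurrences())
  # dedup identical intervals, forward match wins; then coordinate order
  keep <- !duplicated(start1)
  start1 <- start1[keep]
  strand <- strand[keep]
  o <- order(start1)
  start1 <- start1[o]
  strand <- strand[o]
  matched <- substring(seq, start1, start1 + motif$length - 1L)
  ok <- !grepl("[^ACGT]", matched)
  new_occurrences(chrom = rep(seqname, sum(ok)),
                  start = start1[ok] - 1L,
                  end = start1[ok] - 1L + motif$length,
                  strand = strand[ok], matched_seq = matched[ok],
                  source_genome = rep(source_genome, sum(ok)))
}

#' Scan a whole genome for a degenerate motif
#'
#' Concatenation of per-sequence scans in input order; no windows span
#' record boundaries.
#'
#' @param motif A `degenerate_motif`.
#' @param genome Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @param source_genome Genome label recorded with each occurrence.
#' @return A data.frame of occurrences (see [scan_sequence()]).
#' @export
scan_genome <- function(motif, genome, source_genome = "genome") {
  stopifnot(is.character(genome))
  if (length(genome) == 0L) return(new_occurrences())
  nm <- names(genome)
  if (is.null(nm)) nm <- paste0("seq", seq_along(genome))
  hits <- lapply(seq_along(genome), function(i)
    scan_sequence(motif, genome[[i]], seqname = nm[i],
                  source_genome = source_genome))
  do.call(rbind, hits)
}
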