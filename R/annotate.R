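#' Build a searchable index over an annotation track
#'
#' Wraps the track in an interval tree supporting overlap queries in
#' O(log n + k); duplicate intervals are all kept.
#'
#' @param track An interval data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, e.g. from [read_bed()]).
#' @return An object of class `interval_index`.
#' @export
build_interval_index <- function(track) {
  gr <- if (is.null(track) || nrow(track) == 0L) {
    GenomicRanges::GRanges()
  } else {
    GenomicRanges::GRanges(track$chrom,
                           IRanges::IRanges(track$start + 1L, track$end))
  }
  structure(list(granges = gr, track = track), class = "interval_index")
}

#' Test whether a query interval overlaps any track interval
#'
#' Overlap is >= 1 bp under half-open semantics: a track interval `t`
#' overlaps query `q` iff `t$chrom == q$chrom`, `t$start < q$end` and
#' `q$start < t$end`; intervals that merely touch do not overlap.
#'
#' @param index An `interval_index` from [build_interval_index()].
#' @param chrom,start,end Query interval(s), 0-based half-open (vectorized).
#' @return Logical vector, one element per query.
#' @export
overlaps_any <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "interval_index"))
  if (length(chrom) == 0L) return(logical(0))
  if (length(index$granges) == 0L) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  # disjoint seqlevels between query and track are an expected "no overlap"
  suppressWarnings(
    GenomicRanges::countOverlaps(q, index$granges, minoverlap = 1L) > 0L)
}

#' Label motif occurrences as regulatory by annotation overlap
#'
#' An occurrence is regulatory iff it overlaps (>= 1 bp) at least one
#' interval of at least one provided track (e.g. DHS, TF ChIP-seq peaks,
#' conserved non-coding elements). The query is the occurrence interval
#' itself, optionally extended by `flank` bp on each side.
#'
#' @param occurrences Occurrence data.frame (see [scan_genome()]).
#' @param tracks Named list of interval data.frames (or `interval_index`
#'   objects).
#' @param flank Non-negative integer extension of the query on each side
#'   (default 0).
#' @return The occurrences with a logical `regulatory` column, a `hits`
#'   column (comma-separated names of overlapping tracks), and per-track
#'   logical columns `hit_<track>`. A summary is attached as attribute
#'   `summary` (counts per track and regulatory/non-regulatory totals).
#' @export
classify_regulatory <- function(occurrences, tracks, flank = 0L) {
  stopifnot(is.list(tracks), flank >= 0L)
  n <- nrow(occurrences)
  nm <- names(tracks)
  if (length(tracks) > 0L && (is.null(nm) || any(!nzchar(nm))))
    stop("tracks must be a named list", call. = FALSE)
  qs <- pmax(occurrences$start - as.integer(flank), 0L)
  qe <- occurrences$end + as.integer(flank)
  hit_mat <- matrix(FALSE, n, length(tracks),
                    dimnames = list(NULL, nm))
  for (tn in nm) {
    idx <- tracks[[tn]]
    if (!inherits(idx, "interval_index")) idx <- build_interval_index(idx)
    hit_mat[, tn] <- overlaps_any(idx, occurrences$chrom, qs, qe)
  }
  reg <- if (length(tracks) == 0L) rep(FALSE, n) else rowSums(hit_mat) > 0L
  occurrences$regulatory <- reg
  occurrences$hits <- if (length(tracks) == 0L) rep("", n) else
    apply(hit_mat, 1L, function(h) paste(nm[h], collapse = ","))
  for (tn in nm) occurrences[[paste0("hit_", tn)]] <- hit_mat[, tn]
  attr(occurrences, "summary") <- list(
    regulatory = sum(reg), non_regulatory = sum(!reg),
    per_track = if (length(tracks)) colSums(hit_mat) else integer(0))
  occurrences
}
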