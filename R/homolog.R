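#' Build a projection index over pairwise alignment blocks
#'
#' Indexes reference-genome coordinates of each block for interval-searchable
#' projection. Reference rows must all come from one genome and be on the
#' `+` strand (the UCSC pairwise-MAF convention); target rows may be on
#' either strand, in which case MAF semantics already orient the target text
#' to the reference. Overlapping reference blocks are all kept; projection
#' resolves ties deterministically (see [project_occurrence()]).
#'
#' @param blocks A data.frame of alignment blocks from [read_maf()].
#' @return An object of class `alignment_index`.
#' @export
index_alignment <- function(blocks) {
  stopifnot(is.data.frame(blocks))
  n <- nrow(blocks)
  if (n > 0L && any(blocks$ref_strand != "+"))
    stop("reference rows must be on the '+' strand", call. = FALSE)
  ranges <- if (n == 0L) {
    GenomicRanges::GRanges()
  } else {
    # MAF names follow the UCSC "genome.chrom" convention; queries arrive
    # with bare chromosome names, so index on the part after the first dot
    chrom <- sub("^[^.]+\\.", "", blocks$ref_name)
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = blocks$ref_start + 1L,
                                width = blocks$ref_size))
  }
  # per-block map: k-th reference base -> alignment column (1-based)
  ref_cols <- lapply(seq_len(n), function(i) {
    ch <- strsplit(blocks$ref_text[i], "")[[1]]
    which(ch != "-")
  })
  structure(list(blocks = blocks, ranges = ranges, ref_cols = ref_cols),
            class = "alignment_index")
}

#' Project a motif occurrence through a pairwise alignment
#'
#' Statuses follow the indel filter used for homolog extraction:
#' `unaligned` if no block covers any base of the occurrence; `partial` if
#' covered but not end-to-end by a single block; `indel` if the covering
#' columns contain a gap in either row; otherwise `ok`, with the homologous
#' target-row sequence reported in the reference-forward orientation. When
#' several blocks cover the occurrence fully, the block with the longest
#' reference overlap wins, ties broken by (target name, target start).
#'
#' @param index An `alignment_index` from [index_alignment()].
#' @param occ A one-row occurrence data.frame (see [scan_sequence()]).
#' @return A list with `status` and `homolog_seq` (`NA` unless `ok`).
#' @export
project_occurrence <- function(index, occ) {
  stopifnot(inherits(index, "alignment_index"))
  q <- GenomicRanges::GRanges(occ$chrom,
                              IRanges::IRanges(occ$start + 1L, occ$end))
  ovl <- suppressWarnings(GenomicRanges::findOverlaps(q, index$ranges))
  project_one(index, occ$start, occ$end, S4Vectors::subjectHits(ovl))
}

project_one <- function(index, start0, end0, cand) {
  if (length(cand) == 0L)
    return(list(status = "unaligned", homolog_seq = NA_character_))
  b <- index$blocks[cand, , drop = FALSE]
  covers <- b$ref_start <= start0 & (b$ref_start + b$ref_size) >= end0
  if (!any(covers))
    return(list(status = "partial", homolog_seq = NA_character_))
  full <- cand[covers]
  bf <- index$blocks[full, , drop = FALSE]
  ov <- pmin(bf$ref_start + bf$ref_size, end0) - pmax(bf$ref_start, start0)
  pick <- full[order(-ov, bf$tgt_name, bf$tgt_start)][1L]
  blk <- index$blocks[pick, , drop = FALSE]
  cols <- index$ref_cols[[pick]]
  cs <- cols[start0 - blk$ref_start + 1L]
  ce <- cols[end0 - blk$ref_start]
  # a reference-row gap inside the span widens the column range
  if ((ce - cs + 1L) != (end0 - start0))
    return(list(status = "indel", homolog_seq = NA_character_))
  tgt <- substr(blk$tgt_text, cs, ce)
  if (grepl("-", tgt, fixed = TRUE))
    return(list(status = "indel", homolog_seq = NA_character_))
  list(status = "ok", homolog_seq = tgt)
}

#' Extract gapless homologs for a set of occurrences
#'
#' Projects every occurrence through the alignment and returns one record
#' per occurrence; results are a pure function of the occurrence and the
#' block set (block input order does not matter).
#'
#' @param occurrences Occurrence data.frame (see [scan_genome()]).
#' @param alignment Either a path to a MAF file or a block data.frame from
#'   [read_maf()], or an `alignment_index`.
#' @param species Genome build label recorded with each record.
#' @return A data.frame: `chrom`, `start`, `end`, `human_seq`, `species`,
#'   `status`, `homolog_seq`.
#' @export
collect_homologs <- function(occurrences, alignment, species) {
  index <- if (inherits(alignment, "alignment_index")) {
    alignment
  } else if (is.character(alignment)) {
    index_alignment(read_maf(alignment))
  } else {
    index_alignment(alignment)
  }
  n <- nrow(occurrences)
  status <- character(n)
  homolog <- rep(NA_character_, n)
  if (n > 0L) {
    q <- GenomicRanges::GRanges(
      occurrences$chrom,
      IRanges::IRanges(occurrences$start + 1L, occurrences$end))
    ovl <- suppressWarnings(GenomicRanges::findOverlaps(q, index$ranges))
    cand <- split(S4Vectors::subjectHits(ovl), S4Vectors::queryHits(ovl))
    for (i in seq_len(n)) {
      ci <- cand[[as.character(i)]]
      r <- project_one(index, occurrences$start[i], occurrences$end[i],
                       if (is.null(ci)) integer(0) else ci)
      status[i] <- r$status
      homolog[i] <- r$homolog_seq
    }
  }
  out <- data.frame(chrom = occurrences$chrom, start = occurrences$start,
                    end = occurrences$end,
                    human_seq = occurrences$matched_seq,
                    species = rep(species, n), status = status,
                    homolog_seq = homolog, stringsAsFactors = FALSE)
  cnt <- table(factor(out$status,
                      levels = c("ok", "indel", "unaligned", "partial")))
  message(sprintf("homologs [%s]: %d ok, %d indel, %d unaligned, %d partial",
                  species, cnt[["ok"]], cnt[["indel"]], cnt[["unaligned"]],
                  cnt[["partial"]]))
  out
}
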