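#' @importFrom utils read.table write.table
#' @importFrom stats setNames
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

fmt_error <- function(path, line, msg) {
  stop(sprintf("format error in '%s' (line %d): %s", path, line, msg),
       call. = FALSE)
}

#' Read a FASTA file into normalized sequence records
#'
#' Sequences are uppercased (soft-masked lowercase is treated as ordinary
#' sequence) and validated against the IUPAC nucleotide alphabet; anything
#' else is a format error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase sequence per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  is_header <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (!is_header[which(nonblank)[1]])
    fmt_error(path, which(nonblank)[1], "sequence data before first header")
  # validate sequence lines and locate illegal characters precisely
  for (i in seq_along(lines)) {
    if (is_header[i]) {
      if (nchar(trimws(lines[i])) < 2L)
        fmt_error(path, i, "malformed (empty) FASTA header")
      next
    }
    bad <- gsub(sprintf("[%s%s]", paste(IUPAC_CODES, collapse = ""),
                        paste(tolower(IUPAC_CODES), collapse = "")),
                "", lines[i])
    if (nzchar(bad))
      fmt_error(path, i,
                sprintf("illegal character '%s' outside the IUPAC alphabet",
                        substr(bad, 1, 1)))
  }
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequence records to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Columns
#' beyond the sixth are retained, tab-joined, as an opaque `extra` payload.
#'
#' @param path Path to a tab-separated BED file (at least 3 columns).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `extra`. Missing optional columns are filled with
#'   `"."`, `0` and `"+"` respectively.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  out <- empty_intervals()
  if (!any(keep)) return(out)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L))
    fmt_error(path, idx[which(n < 3L)[1]], "fewer than 3 BED columns")
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2L, NA)))
  end <- suppressWarnings(as.integer(get(3L, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    fmt_error(path, idx[bad[1]], "non-integer BED coordinates")
  bad <- which(end <= start | start < 0L)
  if (length(bad))
    fmt_error(path, idx[bad[1]],
              "invalid interval (need 0 <= start < end, half-open)")
  strand <- get(6L, "+")
  strand[!strand %in% c("+", "-")] <- "+"
  extra <- vapply(fields, function(f) {
    if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else ""
  }, "")
  data.frame(chrom = get(1L, "."), start = start, end = end,
             name = get(4L, "."),
             score = suppressWarnings(as.numeric(get(5L, "0"))),
             strand = strand, extra = extra, stringsAsFactors = FALSE)
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = numeric(0), strand = character(0),
             extra = character(0), stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED
#'
#' @param intervals A data.frame as returned by [read_bed()] (columns beyond
#'   `chrom`, `start`, `end` optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  col <- function(nm, default) {
    if (nm %in% names(intervals)) intervals[[nm]] else rep(default, n)
  }
  line <- paste(intervals$chrom, intervals$start, intervals$end,
                col("name", "."), col("score", 0), col("strand", "+"),
                sep = "\t")
  extra <- col("extra", "")
  has_extra <- nzchar(extra)
  line[has_extra] <- paste(line[has_extra], extra[has_extra], sep = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Read a pairwise MAF alignment
#'
#' Each alignment block must contain exactly two `s` lines, the reference
#' genome first. MAF semantics are preserved: `start` is 0-based on the
#' stated strand, and minus-strand starts count from the end of the source
#' sequence. The only gap character is `-`.
#'
#' @param path Path to a MAF file.
#' @return A data.frame with one row per block: `ref_name`, `ref_start`,
#'   `ref_size`, `ref_strand`, `ref_srcsize`, `ref_text` and the `tgt_*`
#'   counterparts.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  a_idx <- which(startsWith(lines, "a"))
  blocks <- vector("list", length(a_idx))
  bounds <- c(a_idx, length(lines) + 1L)
  for (b in seq_along(a_idx)) {
    span <- lines[a_idx[b]:(bounds[b + 1L] - 1L)]
    s_rel <- which(startsWith(span, "s "))
    if (length(s_rel) != 2L)
      fmt_error(path, a_idx[b],
                sprintf("alignment block with %d sequence lines (need 2, reference first)",
                        length(s_rel)))
    rows <- lapply(span[s_rel], function(l) strsplit(trimws(l), "[ \t]+")[[1]])
    for (k in 1:2) {
      r <- rows[[k]]
      if (length(r) != 7L)
        fmt_error(path, a_idx[b] + s_rel[k] - 1L, "malformed 's' line")
      txt <- toupper(r[7])
      if (grepl("[^ACGTUNRYSWKMBDHV-]", txt))
        fmt_error(path, a_idx[b] + s_rel[k] - 1L,
                  "illegal character in alignment text")
      size <- as.integer(r[4])
      if (nchar(gsub("-", "", txt, fixed = TRUE)) != size)
        fmt_error(path, a_idx[b] + s_rel[k] - 1L,
                  "declared size does not match ungapped text length")
      rows[[k]] <- list(name = r[2], start = as.integer(r[3]), size = size,
                        strand = r[5], srcsize = as.integer(r[6]), text = txt)
    }
    if (nchar(rows[[1]]$text) != nchar(rows[[2]]$text))
      fmt_error(path, a_idx[b], "alignment rows of unequal length")
    blocks[[b]] <- data.frame(
      ref_name = rows[[1]]$name, ref_start = rows[[1]]$start,
      ref_size = rows[[1]]$size, ref_strand = rows[[1]]$strand,
      ref_srcsize = rows[[1]]$srcsize, ref_text = rows[[1]]$text,
      tgt_name = rows[[2]]$name, tgt_start = rows[[2]]$start,
      tgt_size = rows[[2]]$size, tgt_strand = rows[[2]]$strand,
      tgt_srcsize = rows[[2]]$srcsize, tgt_text = rows[[2]]$text,
      stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0L) return(empty_maf())
  do.call(rbind, blocks)
}

empty_maf <- function() {
  data.frame(ref_name = character(0), ref_start = integer(0),
             ref_size = integer(0), ref_strand = character(0),
             ref_srcsize = integer(0), ref_text = character(0),
             tgt_name = character(0), tgt_start = integer(0),
             tgt_size = integer(0), tgt_strand = character(0),
             tgt_srcsize = integer(0), tgt_text = character(0),
             stringsAsFactors = FALSE)
}

#' Write pairwise alignment blocks as MAF
#'
#' @param blocks A data.frame as returned by [read_maf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blocks))) {
    writeLines("a score=0", con)
    writeLines(sprintf("s %s %d %d %s %d %s",
                       blocks$ref_name[i], blocks$ref_start[i],
                       blocks$ref_size[i], blocks$ref_strand[i],
                       blocks$ref_srcsize[i], blocks$ref_text[i]), con)
    writeLines(sprintf("s %s %d %d %s %d %s",
                       blocks$tgt_name[i], blocks$tgt_start[i],
                       blocks$tgt_size[i], blocks$tgt_strand[i],
                       blocks$tgt_srcsize[i], blocks$tgt_text[i]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a homogeneous set of records as a TSV report
#'
#' Human-readable reports are the only place 1-based coordinates may appear;
#' everything written here is passed through unchanged, so callers keep the
#' package-wide 0-based half-open convention unless they relabel explicitly.
#'
#' @param rows A data.frame (header-only output if it has zero rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (is.list(rows)) {
      shapes <- unique(vapply(rows, function(r)
        paste(sort(names(r)), collapse = "\r"), ""))
      if (length(shapes) > 1L)
        stop("mixed record shapes: all rows must share the same fields",
             call. = FALSE)
      rows <- do.call(rbind, lapply(rows, as.data.frame,
                                    stringsAsFactors = FALSE))
    } else {
      stop("rows must be a data.frame or a list of homogeneous records",
           call. = FALSE)
    }
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path Path to the report.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             comment.char = "", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}
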