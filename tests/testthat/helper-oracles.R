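# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the code paths they check: position-by-position window matching,
# quadratic all-pairs interval overlap, and exact-table enumeration from
# binomial coefficients.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
comp_iupac <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                H = "D", V = "B", N = "N")

naive_revcomp <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  paste(comp_base[ch], collapse = "")
}

# brute-force both-strand scan: checks every window position by position;
# windows with non-ACGT bases never match; intervals deduplicated
naive_scan_starts <- function(pattern, seq) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  rc <- unname(rev(comp_iupac[pat]))
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  k <- length(pat)
  if (L < k) return(integer(0))
  match_at <- function(p, i) {
    w <- ch[i:(i + k - 1L)]
    all(w %in% c("A", "C", "G", "T")) &&
      all(mapply(function(b, code) b %in% iupac_sets[[code]], w, p))
  }
  hits <- integer(0)
  for (i in seq_len(L - k + 1L)) {
    if (match_at(pat, i) || match_at(rc, i)) hits <- c(hits, i - 1L)
  }
  hits
}

# same window-by-window semantics as naive_scan_starts, vectorized over
# positions (one membership test per motif offset) for the large oracle runs
naive_scan_starts_vec <- function(pattern, seq) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  rc <- unname(rev(comp_iupac[pat]))
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  k <- length(pat)
  if (L < k) return(integer(0))
  n_win <- L - k + 1L
  acgt <- ch %in% c("A", "C", "G", "T")
  hits_for <- function(p) {
    ok <- rep(TRUE, n_win)
    for (j in seq_len(k)) {
      idx <- j:(n_win + j - 1L)
      ok <- ok & acgt[idx] & ch[idx] %in% iupac_sets[[p[j]]]
    }
    ok
  }
  sort(which(hits_for(pat) | hits_for(rc)) - 1L)
}

# all 13-mers at fixed-position Hamming distance <= 2 from the GR consensus,
# for one assignment of the five wildcard positions
gr_variants_filled <- function(fill) {
  stopifnot(nchar(fill) == 5L)
  base <- gr_fixed_variants()
  n <- length(base)
  m <- matrix("", n, 13L)
  for (j in 1:13) m[, j] <- substring(base, j, j)
  fill_ch <- strsplit(fill, "")[[1]]
  wild <- c(2L, 6L, 7L, 8L, 12L)
  for (w in seq_along(wild)) m[, wild[w]] <- fill_ch[w]
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

random_degenerate_motif <- function(len) {
  codes <- names(iupac_sets)
  # bias toward informative codes so random 10 kb sequences still get hits
  w <- ifelse(codes %in% c("A", "C", "G", "T"), 4,
              ifelse(codes == "N", 3, 0.5))
  paste(sample(codes, len, replace = TRUE, prob = w), collapse = "")
}

random_sequence <- function(len, n_frac = 0.01) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_frac) / 4, 4), n_frac)), collapse = "")
}

# quadratic all-pairs overlap check (half-open, >= 1 bp)
naive_overlaps_any <- function(track, chrom, start, end) {
  vapply(seq_along(chrom), function(i) {
    any(track$chrom == chrom[i] & track$start < end[i] &
          start[i] < track$end)
  }, NA)
}

# exact one-sided Fisher p by enumerating all tables with the observed
# margins, from binomial coefficients only
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(r1, xs) * choose(N - r1, c1 - xs) / choose(N, c1)
  sum(probs[xs >= a])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 10000L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(50L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# all 13-mers whose fixed positions are within Hamming distance <= 2 of the
# GR consensus, with wildcard positions held at a given fill
gr_fixed_variants <- function(fill = "A") {
  consensus <- strsplit("GAACAAAATGTAC", "")[[1]]  # wildcards filled with A
  consensus[c(2, 6, 7, 8, 12)] <- fill
  fixed <- c(1, 3, 4, 5, 9, 10, 11, 13)
  bases <- c("A", "C", "G", "T")
  out <- list(paste(consensus, collapse = ""))
  for (i in seq_along(fixed)) {
    for (bi in setdiff(bases, consensus[fixed[i]])) {
      v <- consensus; v[fixed[i]] <- bi
      out[[length(out) + 1L]] <- paste(v, collapse = "")
      for (j in seq_along(fixed)) {
        if (j <= i) next
        for (bj in setdiff(bases, consensus[fixed[j]])) {
          v2 <- v; v2[fixed[j]] <- bj
          out[[length(out) + 1L]] <- paste(v2, collapse = "")
        }
      }
    }
  }
  unlist(out)
}
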