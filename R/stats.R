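#' @importFrom stats pchisq qbinom median optimize quantile runif rnorm rgeom
NULL

#' Significance stars for the variant-spectrum chi-square test
#'
#' `**` for p < 0.0001, `*` for 0.0001 <= p < 0.005, empty otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star labels.
#' @export
chisq_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "**", ifelse(p < 5e-3, "*", "")))
}

#' Chi-square goodness-of-fit of a C/G/T variant spectrum against uniform
#'
#' Tests the pooled position-5 variant counts against the uniform null
#' (expected total/3 per category, df = 2). The direction of any G excess
#' (CpG retention, i.e. a CG->CA transition witnessed in the other genome)
#' is reported separately as `g_excess`.
#'
#' @param counts Numeric vector of length 3 (C, G, T counts; names
#'   optional).
#' @return A list of class `pregbs_test`: `statistic`, `df`, `p_value`,
#'   `stars`, `g_excess`.
#' @export
chisq_uniform <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("no variant counts to test", call. = FALSE)
  e <- total / 3
  stat <- sum((counts - e)^2 / e)
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  g <- if (!is.null(names(counts)) && "G" %in% names(counts))
    counts[["G"]] else counts[[2L]]
  structure(list(statistic = stat, df = 2L, p_value = p,
                 stars = chisq_stars(p), g_excess = g > e),
            class = "pregbs_test")
}

#' @export
print.pregbs_test <- function(x, ...) {
  if (is.null(x$statistic)) {
    cat(sprintf("exact test: p = %.4g %s\n", x$p_value,
                if (!is.null(x$stars)) x$stars else ""))
  } else {
    cat(sprintf("chi-square = %.4g, df = %d, p = %.4g %s\n",
                x$statistic, x$df, x$p_value, x$stars))
  }
  invisible(x)
}

log_hyper_pmf <- function(x, N, K, n) {
  lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
}

#' Hypergeometric probability mass
#'
#' Probability of exactly `k` successes when drawing `n` items without
#' replacement from a population of `N` containing `K` successes; computed
#' in log space from log binomial coefficients.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param k Observed successes (vectorized).
#' @return P(X = k).
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  check_hyper(N, K, n)
  out <- numeric(length(k))
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  inside <- k >= lo & k <= hi
  out[inside] <- exp(log_hyper_pmf(k[inside], N, K, n))
  out
}

check_hyper <- function(N, K, n) {
  if (!(N >= 0 && K >= 0 && n >= 0 && K <= N && n <= N))
    stop("inconsistent hypergeometric parameters (need 0 <= K <= N, 0 <= n <= N)",
         call. = FALSE)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n), computed by log-space
#' summation over the support so it stays accurate at genome scale. `k = 0`
#' gives 1; `k` above the support gives 0.
#'
#' @inheritParams hypergeom_pmf
#' @param k Observed successes (scalar).
#' @return Upper-tail probability P(X >= k).
#' @export
hypergeom_tail <- function(N, K, n, k) {
  check_hyper(N, K, n)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  hi <- min(K, n)
  lo <- max(0, n - (N - K))
  if (k <= lo) return(1)
  if (k > hi) return(0)
  xs <- k:hi
  lp <- log_hyper_pmf(xs, N, K, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Rows are regulatory / non-regulatory, columns pooled-G / pooled-{C,T};
#' the alternative is that the regulatory row is enriched for pooled-G,
#' i.e. the exact upper-tail probability of observing at least `a` in cell
#' (1,1) with all margins fixed. Degenerate margins (an empty row or
#' column) give p = 1 by construction.
#'
#' @param a,b,c,d Non-negative integer cells: `a` = regulatory & G,
#'   `b` = regulatory & C/T, `c` = non-regulatory & G,
#'   `d` = non-regulatory & C/T. Alternatively `a` may be a 2x2 matrix.
#' @param stars_threshold Significance threshold for the star label
#'   (default 0.05, the Figure-1B-style cutoff).
#' @return A list of class `pregbs_test` with `p_value` and `stars`.
#' @export
fisher_one_sided <- function(a, b = NULL, c = NULL, d = NULL,
                             stars_threshold = 0.05) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  N <- a + b + c + d
  p <- hypergeom_tail(N, K = a + b, n = a + c, k = a)
  structure(list(statistic = NULL, df = NULL, p_value = p,
                 stars = if (!is.na(p) && p < stars_threshold) "*" else ""),
            class = "pregbs_test")
}

#' Per-species variant-spectrum report with both tests
#'
#' Assembles, for each species, the pooled C/G/T variant fractions with the
#' uniform-null chi-square test, and the regulatory vs non-regulatory
#' G-composition with the one-sided Fisher test. Regulatory labels of the
#' human occurrence are joined onto the homolog records by genomic interval.
#'
#' @param records Classified homolog records (see [classify_homologs()]).
#' @param labeled_occurrences Occurrences with a `regulatory` column from
#'   [classify_regulatory()]; optional — without it the Fisher columns are
#'   `NA`.
#' @return A data.frame, one row per species: variant counts and fractions,
#'   `chisq_p` and `chisq_stars`, regulatory / non-regulatory G fractions,
#'   `fisher_p` and `fisher_stars`. Species with no variants get `NA`
#'   p-values.
#' @export
spectrum_report <- function(records, labeled_occurrences = NULL) {
  if (!"kind" %in% names(records))
    records <- classify_homologs(records)
  if (!is.null(labeled_occurrences)) {
    key <- paste(labeled_occurrences$chrom, labeled_occurrences$start,
                 labeled_occurrences$end, sep = ":")
    reg_map <- setNames(labeled_occurrences$regulatory, key)
    records$regulatory <-
      unname(reg_map[paste(records$chrom, records$start, records$end,
                           sep = ":")])
  } else {
    records$regulatory <- rep(NA, nrow(records))
  }
  vr <- records[records$status == "ok" & !is.na(records$pooled_nt), ,
                drop = FALSE]
  empty <- data.frame(species = character(0), n_variants = integer(0),
                      fraction_C = numeric(0), fraction_G = numeric(0),
                      fraction_T = numeric(0), chisq_p = numeric(0),
                      chisq_stars = character(0),
                      regulatory_fraction_G = numeric(0),
                      nonregulatory_fraction_G = numeric(0),
                      fisher_p = numeric(0), fisher_stars = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  rows <- lapply(unique(records$species), function(sp) {
    v <- vr[vr$species == sp, , drop = FALSE]
    cnt <- table(factor(v$pooled_nt, levels = c("C", "G", "T")))
    nv <- sum(cnt)
    chisq_p <- NA_real_
    if (nv > 0) chisq_p <- chisq_uniform(as.numeric(cnt))$p_value
    fisher_p <- NA_real_
    reg_fg <- nonreg_fg <- NA_real_
    if (!is.null(labeled_occurrences) && nv > 0 && !anyNA(v$regulatory)) {
      a <- sum(v$regulatory & v$pooled_nt == "G")
      b <- sum(v$regulatory & v$pooled_nt != "G")
      cc <- sum(!v$regulatory & v$pooled_nt == "G")
      dd <- sum(!v$regulatory & v$pooled_nt != "G")
      fisher_p <- fisher_one_sided(a, b, cc, dd)$p_value
      if (a + b > 0) reg_fg <- a / (a + b)
      if (cc + dd > 0) nonreg_fg <- cc / (cc + dd)
    }
    data.frame(species = sp, n_variants = nv,
               fraction_C = if (nv > 0) cnt[["C"]] / nv else NA_real_,
               fraction_G = if (nv > 0) cnt[["G"]] / nv else NA_real_,
               fraction_T = if (nv > 0) cnt[["T"]] / nv else NA_real_,
               chisq_p = chisq_p, chisq_stars = chisq_stars(chisq_p),
               regulatory_fraction_G = reg_fg,
               nonregulatory_fraction_G = nonreg_fg,
               fisher_p = fisher_p,
               fisher_stars = ifelse(!is.na(fisher_p) & fisher_p < 0.05,
                                     "*", ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
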