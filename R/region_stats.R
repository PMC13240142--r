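#' Fold enrichment of region FST over the genome-wide mean
#'
#' Arithmetic mean of the region windows' FST divided by the arithmetic mean
#' of the genome-wide windows' FST. By convention the genome-wide list
#' includes the region's own windows.
#'
#' @param region_fst FST values of the region's windows.
#' @param genome_fst FST values of all genome-wide windows.
#' @return the fold enrichment, or `NA` (with a warning) when the genome
#'   mean is not positive.
#' @export
fold_enrichment <- function(region_fst, genome_fst) {
  region_fst <- region_fst[!is.na(region_fst)]
  genome_fst <- genome_fst[!is.na(genome_fst)]
  stopifnot(length(region_fst) > 0, length(genome_fst) > 0)
  g <- mean(genome_fst)
  if (g <= 0) {
    warning("genome-wide mean FST is not positive; fold enrichment undefined")
    return(NA_real_)
  }
  mean(region_fst) / g
}

#' Percentile rank of a region mean within the genome-wide distribution
#'
#' Fraction of genome-wide windows whose FST lies strictly below
#' `region_mean`, among windows with defined FST.
#'
#' @param region_mean mean FST of the region.
#' @param genome_fst FST values of all genome-wide windows.
#' @return a fraction in `[0, 1]`.
#' @export
percentile_rank <- function(region_mean, genome_fst) {
  genome_fst <- genome_fst[!is.na(genome_fst)]
  stopifnot(length(genome_fst) > 0)
  mean(genome_fst < region_mean)
}

#' Fractions of region windows exceeding genome-wide FST percentiles
#'
#' For each requested percentile, the fraction of region windows whose FST
#' lies strictly above the genome-wide empirical percentile (type-7
#' quantile) of window FST.
#'
#' @inheritParams fold_enrichment
#' @param percentiles percentiles of the genome-wide distribution.
#' @return named numeric vector, one fraction per percentile.
#' @export
exceedance_fractions <- function(region_fst, genome_fst,
                                 percentiles = c(0.95, 0.99)) {
  region_fst <- region_fst[!is.na(region_fst)]
  genome_fst <- genome_fst[!is.na(genome_fst)]
  stopifnot(length(region_fst) > 0, length(genome_fst) > 0)
  thr <- stats::quantile(genome_fst, percentiles, type = 7)
  out <- vapply(thr, function(t) mean(region_fst > t), numeric(1))
  names(out) <- paste0("p", format(100 * percentiles, trim = TRUE))
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test with midranks
#'
#' The statistic is the rank sum of `x` in the pooled sample, with midranks
#' for ties. For small samples (`min(|x|, |y|) < 8`) the p-value is exact,
#' computed from the full permutation distribution of the rank sum
#' (enumerated by dynamic programming over subsets, so ties are handled
#' exactly); otherwise a normal approximation with tie-corrected variance and
#' a 0.5 continuity correction is used. Two-sided p-values double the smaller
#' tail and are capped at 1.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return list with `statistic` (rank sum of `x`), `p_value`, and `exact`
#'   (logical).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = W, p_value = 1, exact = TRUE))

  exact <- min(m, n) < 8 && N <= 500
  if (exact) {
    r2 <- as.integer(round(2 * r))    # midranks are multiples of 1/2
    dist <- subset_sum_counts(r2, m)  # counts over rank-sum * 2
    w2 <- as.integer(round(2 * W))
    tot <- sum(dist)
    sums <- seq_along(dist) - 1L
    p_le <- sum(dist[sums <= w2]) / tot
    p_ge <- sum(dist[sums >= w2]) / tot
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    return(list(statistic = W, p_value = p, exact = TRUE))
  }

  mu <- m * (N + 1) / 2
  ties <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p_value = 1, exact = FALSE))
  sd <- sqrt(sigma2)
  z_hi <- (W - mu - 0.5) / sd
  z_lo <- (W - mu + 0.5) / sd
  p_ge <- stats::pnorm(z_hi, lower.tail = FALSE)
  p_le <- stats::pnorm(z_lo)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge, less = p_le)
  list(statistic = W, p_value = p, exact = FALSE)
}

# number of size-k subsets of `vals` (integers) attaining each sum;
# returns counts for sums 0..sum(vals) for subsets of size exactly k
subset_sum_counts <- function(vals, k) {
  maxsum <- sum(vals)
  dp <- matrix(0, nrow = k + 1, ncol = maxsum + 1)
  dp[1, 1] <- 1
  for (v in vals) {
    for (kk in seq.int(k, 1)) {
      shifted <- c(rep(0, v), dp[kk, seq_len(maxsum + 1 - v)])
      dp[kk + 1, ] <- dp[kk + 1, ] + shifted
    }
  }
  dp[k + 1, ]
}

#' Wilcoxon signed-rank test with midranks
#'
#' Pairs with zero difference are dropped; the remaining absolute
#' differences are midranked and the statistic is the sum of ranks of
#' positive differences. For at most 25 nonzero pairs the p-value is exact
#' (full sign-flip distribution via dynamic programming, ties handled);
#' otherwise a normal approximation with tie correction and 0.5 continuity
#' correction is used. Two-sided by default.
#'
#' @param a,b paired numeric vectors; alternatively pass the differences as
#'   `a` and omit `b`.
#' @param alternative `"two.sided"` (default), `"greater"` (differences tend
#'   positive) or `"less"`.
#' @return list with `statistic` (positive-rank sum `V`), `p_value`,
#'   `n_used` (nonzero pairs) and `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  d <- if (is.null(b)) a else a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n_used = 0L,
                          exact = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])

  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    dist <- signflip_sum_counts(r2)
    v2 <- as.integer(round(2 * V))
    tot <- sum(dist)
    sums <- seq_along(dist) - 1L
    p_le <- sum(dist[sums <= v2]) / tot
    p_ge <- sum(dist[sums >= v2]) / tot
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    return(list(statistic = V, p_value = p, n_used = n, exact = TRUE))
  }

  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(list(statistic = V, p_value = 1, n_used = n,
                               exact = FALSE))
  sd <- sqrt(sigma2)
  p_ge <- stats::pnorm((V - mu - 0.5) / sd, lower.tail = FALSE)
  p_le <- stats::pnorm((V - mu + 0.5) / sd)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge, less = p_le)
  list(statistic = V, p_value = p, n_used = n, exact = FALSE)
}

# counts of sum over all 2^n sign assignments of integer ranks
signflip_sum_counts <- function(vals) {
  maxsum <- sum(vals)
  dp <- numeric(maxsum + 1)
  dp[1] <- 1
  for (v in vals) {
    shifted <- c(rep(0, v), dp[seq_len(maxsum + 1 - v)])
    dp <- dp + shifted
  }
  dp
}

#' Pi ratio and reduction of diversity (ROD)
#'
#' `pi_ratio = mean(pi_ref) / mean(pi_focal)` and
#' `rod = 1 - mean(pi_focal) / mean(pi_ref)`; the identity
#' `rod = 1 - 1/pi_ratio` holds to floating-point precision.
#'
#' @param pi_focal,pi_ref equal-length per-window Pi vectors for the focal
#'   and reference populations over the region.
#' @return list with `pi_ratio` and `rod`; both `NA` (with a warning) when a
#'   mean is not positive.
#' @export
pi_ratio_rod <- function(pi_focal, pi_ref) {
  stopifnot(length(pi_focal) == length(pi_ref))
  mf <- mean(pi_focal, na.rm = TRUE)
  mr <- mean(pi_ref, na.rm = TRUE)
  if (!is.finite(mf) || !is.finite(mr) || mf <= 0 || mr <= 0) {
    warning("non-positive mean Pi; ratio and ROD undefined")
    return(list(pi_ratio = NA_real_, rod = NA_real_))
  }
  list(pi_ratio = mr / mf, rod = 1 - mf / mr)
}

#' Fraction of region windows with lower Pi in the focal population
#'
#' @inheritParams pi_ratio_rod
#' @return fraction of windows with `pi_focal` strictly below `pi_ref`.
#' @export
fraction_windows_lower_pi <- function(pi_focal, pi_ref) {
  stopifnot(length(pi_focal) == length(pi_ref))
  ok <- !is.na(pi_focal) & !is.na(pi_ref)
  mean(pi_focal[ok] < pi_ref[ok])
}

#' Region-versus-background enrichment battery
#'
#' Quantifies how one candidate region differs from the genome-wide
#' background: FST fold enrichment, percentile rank of the region mean,
#' fractions of region windows above the genome-wide 95th/99th FST
#' percentiles, a rank-sum test of region versus non-region window FST, the
#' focal/reference Pi ratio and ROD over the region, the fraction of region
#' windows with lower focal Pi, and a paired signed-rank test on per-window
#' (Pi focal, Pi ref).
#'
#' Region windows are the scan windows fully contained in
#' `[region$start, region$end]` on `region$chrom`. The background for the
#' distribution summaries (fold, percentile rank, exceedance) is the full
#' genome-wide window set, including the region's own windows, unless
#' `exclude_region_background = TRUE`; the rank-sum test always contrasts
#' region windows against the complementary windows.
#'
#' @param stats scan table from [genome_scan()].
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param pair two population labels for FST columns.
#' @param focal,ref focal and reference population labels for Pi.
#' @param exclude_region_background exclude region windows from the
#'   background used by fold/percentile/exceedance summaries.
#' @return one-row `data.frame` with columns `fold`, `percentile_rank`,
#'   `frac_exceed_p95`, `frac_exceed_p99`, `ranksum_p`, `pi_ratio`, `rod`,
#'   `frac_lower_pi`, `signedrank_p`, `n_region_windows`.
#' @export
region_enrichment <- function(stats, region, pair, focal, ref,
                              exclude_region_background = FALSE) {
  stats <- data.table::as.data.table(stats)
  fcol <- fst_column(stats, pair)
  in_region <- stats$CHROM == region$chrom &
    stats$BIN_START >= region$start & stats$BIN_END <= region$end
  if (!any(in_region)) stop("no scan window fully contained in the region")
  reg_fst <- stats[[fcol]][in_region]
  bg_idx <- if (exclude_region_background) !in_region else rep(TRUE, nrow(stats))
  bg_fst <- stats[[fcol]][bg_idx]
  exc <- exceedance_fractions(reg_fst, bg_fst)
  rs <- wilcoxon_rank_sum(reg_fst[!is.na(reg_fst)],
                          stats[[fcol]][!in_region & !is.na(stats[[fcol]])])
  pf <- stats[[paste0("PI_", focal)]][in_region]
  pr <- stats[[paste0("PI_", ref)]][in_region]
  ratio <- pi_ratio_rod(pf, pr)
  sr <- wilcoxon_signed_rank(pf, pr)
  data.frame(
    fold = fold_enrichment(reg_fst, bg_fst),
    percentile_rank = percentile_rank(mean(reg_fst, na.rm = TRUE), bg_fst),
    frac_exceed_p95 = unname(exc[1]),
    frac_exceed_p99 = unname(exc[2]),
    ranksum_p = rs$p_value,
    pi_ratio = ratio$pi_ratio,
    rod = ratio$rod,
    frac_lower_pi = fraction_windows_lower_pi(pf, pr),
    signedrank_p = sr$p_value,
    n_region_windows = sum(in_region)
  )
}
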