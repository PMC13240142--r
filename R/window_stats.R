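#' Sliding-window layout over chromosomes
#'
#' Windows are 1-based inclusive intervals `[start, start + size - 1]` with
#' starts `1, 1 + step, 1 + 2*step, ...`; a window is emitted iff its start
#' does not exceed the chromosome length, and trailing windows are truncated
#' at the chromosome end. Defaults are 100 kb windows advanced in 10 kb
#' steps, the usual scale for genome scans in non-model vertebrates.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param size window length in bp.
#' @param step offset between consecutive window starts in bp.
#' @return `data.frame` with columns `chrom`, `start`, `end`, sorted by
#'   `(chrom, start)`.
#' @export
make_windows <- function(chrom_lengths, size = 100000L, step = 10000L) {
  stopifnot(size >= step, step >= 1, all(chrom_lengths >= 1))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, len, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, len))
  })
  do.call(rbind, out)[, c("chrom", "start", "end")]
}

#' Per-site nucleotide diversity within one population
#'
#' Unbiased per-site heterozygosity `2 j (m - j) / (m (m - 1))` where `m` is
#' the number of called alleles and `j` the alternate-allele count; this
#' equals the mean pairwise difference among the `m` sampled alleles.
#'
#' @param calls dosage vector (0/1/2/NA) for the population's samples at one
#'   site.
#' @return per-site diversity, or `NA` when fewer than 2 alleles are called.
#' @export
site_pi <- function(calls) {
  m <- 2 * sum(!is.na(calls))
  if (m < 2) return(NA_real_)
  j <- sum(calls, na.rm = TRUE)
  2 * j * (m - j) / (m * (m - 1))
}

#' Weir-Cockerham variance components at one site for a population pair
#'
#' Two-level hierarchy (populations / individuals / alleles): returns the
#' among-population (`a`), among-individual-within-population (`b`) and
#' within-individual (`c`) components computed from the called genotypes of
#' the two populations. The per-pair windowed FST is `sum(a) / sum(a+b+c)`.
#'
#' @param calls_a,calls_b dosage vectors for the two populations at one site.
#' @return named numeric vector `c(a =, b =, c =)`; all `NA` when the site is
#'   unusable (a population with no called genotype, or fewer than 3 called
#'   diploids overall).
#' @export
site_wc_components <- function(calls_a, calls_b) {
  n1 <- sum(!is.na(calls_a)); n2 <- sum(!is.na(calls_b))
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3)
    return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  p1 <- sum(calls_a, na.rm = TRUE) / (2 * n1)
  p2 <- sum(calls_b, na.rm = TRUE) / (2 * n2)
  h1 <- sum(calls_a == 1, na.rm = TRUE) / n1
  h2 <- sum(calls_b == 1, na.rm = TRUE) / n2
  unlist(wc_from_freqs(n1, n2, p1, p2, h1, h2))
}

# vector-capable WC84 two-population components from per-pop summaries
wc_from_freqs <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  list(a = a, b = b, c = hbar / 2)
}

# per-site summaries for one population: called diploids, alt count,
# called alleles, site pi, segregating flag
pop_site_summary <- function(gm, population) {
  x <- gm$calls[pop_rows(gm, population), , drop = FALSE]
  ncalled <- colSums(!is.na(x))
  j <- colSums(x, na.rm = TRUE)
  m <- 2 * ncalled
  pi <- ifelse(m >= 2, 2 * j * (m - j) / (m * (m - 1)), NA_real_)
  list(ncalled = ncalled, j = j, m = m, pi = pi,
       seg = m >= 2 & j > 0 & j < m)
}

# per-site WC components for a population pair, vectorized over sites
pair_wc_summary <- function(gm, pop_a, pop_b) {
  xa <- gm$calls[pop_rows(gm, pop_a), , drop = FALSE]
  xb <- gm$calls[pop_rows(gm, pop_b), , drop = FALSE]
  n1 <- colSums(!is.na(xa)); n2 <- colSums(!is.na(xb))
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  p1 <- ifelse(n1 > 0, colSums(xa, na.rm = TRUE) / (2 * n1), 0)
  p2 <- ifelse(n2 > 0, colSums(xb, na.rm = TRUE) / (2 * n2), 0)
  h1 <- ifelse(n1 > 0, colSums(xa == 1, na.rm = TRUE) / n1, 0)
  h2 <- ifelse(n2 > 0, colSums(xb == 1, na.rm = TRUE) / n2, 0)
  comp <- wc_from_freqs(n1, n2, p1, p2, h1, h2)
  comp$a[!usable] <- NA_real_
  comp$b[!usable] <- NA_real_
  comp$c[!usable] <- NA_real_
  c(comp, list(usable = usable))
}

sites_in_window <- function(gm, chrom, start, end) {
  which(gm$sites$chrom == chrom & gm$sites$pos >= start & gm$sites$pos <= end)
}

#' Windowed per-bp nucleotide diversity
#'
#' Sum of [site_pi()] over the window's polymorphic sites divided by the
#' window's bp span `end - start + 1`. Monomorphic sites contribute zero, so
#' the value is invariant to adding them; a window with no polymorphic sites
#' returns 0.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom,start,end window coordinates (1-based inclusive).
#' @param population population label.
#' @return per-bp diversity (dimensionless).
#' @export
window_pi <- function(gm, chrom, start, end, population) {
  idx <- sites_in_window(gm, chrom, start, end)
  s <- pop_site_summary(subset_sites(gm, idx), population)
  sum(s$pi, na.rm = TRUE) / (end - start + 1)
}

#' Windowed weighted Weir-Cockerham FST
#'
#' Ratio-of-sums estimator `sum(a) / sum(a + b + c)` over the window's usable
#' sites (sites with at least one called genotype in each population and at
#' least 3 called diploids overall). May be slightly negative; values are
#' reported as computed, never clamped.
#'
#' @inheritParams window_pi
#' @param pops character vector of two population labels.
#' @return weighted FST, or `NA` when the window has no usable site.
#' @export
window_weighted_fst <- function(gm, chrom, start, end, pops) {
  stopifnot(length(pops) == 2)
  idx <- sites_in_window(gm, chrom, start, end)
  w <- pair_wc_summary(subset_sites(gm, idx), pops[1], pops[2])
  if (!any(w$usable)) return(NA_real_)
  sum(w$a[w$usable]) / sum(w$a[w$usable] + w$b[w$usable] + w$c[w$usable])
}

#' Constants of Tajima's D
#'
#' The standard constants for `n` sampled sequences:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i` in `1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n number of sequences (2 x called diploids); must be >= 4.
#' @return named list with `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from_sums <- function(pi_sum, S, n) {
  if (S < 1 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Windowed Tajima's D within one population
#'
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))` where `pi_sum` is the
#' unscaled sum of [site_pi()] over the window's segregating sites, `S` their
#' count, and the constants come from [tajima_constants()]. Under missing
#' data a single `n` is required: it is fixed at 2 x the minimum number of
#' called diploids across the window's segregating sites.
#'
#' @inheritParams window_pi
#' @return Tajima's D, or `NA` when the window has no segregating site in the
#'   population or fewer than 4 sequences.
#' @export
window_tajima_d <- function(gm, chrom, start, end, population) {
  idx <- sites_in_window(gm, chrom, start, end)
  s <- pop_site_summary(subset_sites(gm, idx), population)
  if (!any(s$seg)) return(NA_real_)
  n <- 2 * min(s$ncalled[s$seg])
  tajima_d_from_sums(sum(s$pi[s$seg]), sum(s$seg), n)
}

#' Genome-wide sliding-window scan
#'
#' Computes, for every sliding window on every chromosome, per-population
#' per-bp nucleotide diversity and Tajima's D and the weighted
#' Weir-Cockerham FST of every population pair. Windows with no site report
#' `N_SITES = 0`, `PI = 0` and undefined (`NA`) FST and Tajima's D.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param chrom_lengths named vector of chromosome lengths in bp; when `NULL`
#'   the largest site position per chromosome is used.
#' @param size,step window size and step in bp, see [make_windows()].
#' @param pops populations to include (default: all in `gm`).
#' @return a `data.table` with one row per window: `CHROM`, `BIN_START`,
#'   `BIN_END`, `N_SITES`, then `PI_<pop>`, `TAJIMA_D_<pop>` per population
#'   and `FST_<A>_<B>` per pair.
#' @export
genome_scan <- function(gm, chrom_lengths = NULL, size = 100000L,
                        step = 10000L, pops = NULL) {
  if (is.null(pops)) pops <- populations(gm)
  if (is.null(chrom_lengths)) {
    if (nrow(gm$sites) == 0) {
      warning("empty genotype matrix: empty scan")
      return(empty_scan_table(pops))
    }
    chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  win <- make_windows(chrom_lengths, size = size, step = step)
  wdt <- data.table::data.table(win)
  wdt[, win_id := .I]

  map <- site_window_map(gm$sites, chrom_lengths, size, step)
  res <- data.table::copy(wdt)
  data.table::setnames(res, c("chrom", "start", "end"),
                       c("CHROM", "BIN_START", "BIN_END"))

  if (nrow(map) == 0) {
    res[, N_SITES := 0L]
    for (p in pops) {
      res[, (paste0("PI_", p)) := 0]
      res[, (paste0("TAJIMA_D_", p)) := NA_real_]
    }
    if (length(pops) >= 2) for (pr in pair_list(pops))
      res[, (paste0("FST_", pr[1], "_", pr[2])) := NA_real_]
    res[, win_id := NULL]
    return(res[])
  }

  nsit <- map[, .(N_SITES = .N), by = win_id]
  res[nsit, N_SITES := i.N_SITES, on = "win_id"]
  res[is.na(N_SITES), N_SITES := 0L]

  span <- res$BIN_END - res$BIN_START + 1

  for (p in pops) {
    s <- pop_site_summary(gm, p)
    dt <- map[, .(win_id, pi = s$pi[site_idx], seg = s$seg[site_idx],
                  ncalled = s$ncalled[site_idx])]
    agg <- dt[, .(pi_sum = sum(pi, na.rm = TRUE),
                  S = sum(seg, na.rm = TRUE),
                  nmin = if (any(seg, na.rm = TRUE))
                    as.numeric(min(ncalled[which(seg)])) else NA_real_),
              by = win_id]
    agg[, tajd := {
      vapply(seq_len(.N), function(i) {
        if (is.na(nmin[i])) NA_real_
        else tajima_d_from_sums(pi_sum[i], S[i], 2 * nmin[i])
      }, numeric(1))
    }]
    picol <- paste0("PI_", p); tdcol <- paste0("TAJIMA_D_", p)
    res[, (picol) := 0]
    res[agg, (picol) := i.pi_sum, on = "win_id"]
    res[, (picol) := get(picol) / span]
    res[, (tdcol) := NA_real_]
    res[agg, (tdcol) := i.tajd, on = "win_id"]
  }

  if (length(pops) >= 2) {
    for (pr in pair_list(pops)) {
      w <- pair_wc_summary(gm, pr[1], pr[2])
      dt <- map[, .(win_id, a = w$a[site_idx],
                    abc = w$a[site_idx] + w$b[site_idx] + w$c[site_idx])]
      agg <- dt[!is.na(a), .(fst = sum(a) / sum(abc)), by = win_id]
      fcol <- paste0("FST_", pr[1], "_", pr[2])
      res[, (fcol) := NA_real_]
      res[agg, (fcol) := i.fst, on = "win_id"]
    }
  }
  res[, win_id := NULL]
  res[]
}

pair_list <- function(pops) {
  if (length(pops) < 2) return(list())
  cmb <- utils::combn(pops, 2, simplify = FALSE)
  cmb
}

empty_scan_table <- function(pops) {
  res <- data.table::data.table(CHROM = character(), BIN_START = integer(),
                                BIN_END = integer(), N_SITES = integer())
  for (p in pops) {
    res[, (paste0("PI_", p)) := numeric()]
    res[, (paste0("TAJIMA_D_", p)) := numeric()]
  }
  for (pr in pair_list(pops))
    res[, (paste0("FST_", pr[1], "_", pr[2])) := numeric()]
  res
}

# long table (site_idx, win_id) assigning each site to every window
# covering it; window ids follow make_windows() row order
site_window_map <- function(sites, chrom_lengths, size, step) {
  chroms <- names(chrom_lengths)
  n_win <- vapply(chroms, function(ch)
    length(seq.int(1L, chrom_lengths[[ch]], by = step)), numeric(1))
  offset <- stats::setNames(cumsum(c(0, n_win[-length(n_win)])), chroms)
  pieces <- lapply(chroms, function(ch) {
    idx <- which(sites$chrom == ch & sites$pos <= chrom_lengths[[ch]])
    if (!length(idx)) return(NULL)
    p <- sites$pos[idx]
    k_max <- pmin(floor((p - 1) / step) + 1, n_win[[ch]])
    k_min <- pmax(ceiling((p - size) / step) + 1, 1)
    reps <- k_max - k_min + 1
    data.table::data.table(
      site_idx = rep(idx, reps),
      win_id = offset[[ch]] +
        unlist(mapply(seq.int, k_min, k_max, SIMPLIFY = FALSE))
    )
  })
  out <- data.table::rbindlist(pieces)
  if (nrow(out) == 0)
    out <- data.table::data.table(site_idx = integer(), win_id = integer())
  out
}

utils::globalVariables(c(
  "win_id", "N_SITES", "i.N_SITES", "site_idx", "pi_sum", "S", "nmin",
  "tajd", "i.pi_sum", "i.tajd", "a", "abc", "fst", "i.fst", ".I", ".N", "seg",
  "ncalled", "i.S"))
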