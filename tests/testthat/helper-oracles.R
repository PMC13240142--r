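# Independent scalar oracles, deliberately coded as naive loops/enumeration,
# never sharing code with the package's vectorized paths.

# mean pairwise difference among sampled alleles, by exhaustive enumeration
oracle_site_pi <- function(calls) {
  calls <- calls[!is.na(calls)]
  alleles <- unlist(lapply(calls, function(g) c(rep(1, g), rep(0, 2 - g))))
  m <- length(alleles)
  if (m < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m))
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(m, 2)
}

# direct transcription of the two-population variance-component formulas
oracle_wc_site <- function(ca, cb) {
  ca <- ca[!is.na(ca)]; cb <- cb[!is.na(cb)]
  n1 <- length(ca); n2 <- length(cb)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return(NULL)
  r <- 2
  p1 <- sum(ca) / (2 * n1); p2 <- sum(cb) / (2 * n2)
  h1 <- mean(ca == 1); h2 <- mean(cb == 1)
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s_sq <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- n_bar / n_c *
    (s_sq - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s_sq - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s_sq -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

oracle_window_pi <- function(calls, span) {
  tot <- 0
  for (j in seq_len(ncol(calls))) {
    v <- oracle_site_pi(calls[, j])
    if (!is.na(v)) tot <- tot + v
  }
  tot / span
}

oracle_window_fst <- function(calls_a, calls_b) {
  num <- 0; den <- 0; any_usable <- FALSE
  for (j in seq_len(ncol(calls_a))) {
    comp <- oracle_wc_site(calls_a[, j], calls_b[, j])
    if (is.null(comp)) next
    any_usable <- TRUE
    num <- num + comp[["a"]]
    den <- den + comp[["a"]] + comp[["b"]] + comp[["c"]]
  }
  if (!any_usable) NA_real_ else num / den
}

# step-by-step Tajima's D with hand-written constants
oracle_tajima_d <- function(calls) {
  seg <- logical(ncol(calls))
  ncalled <- integer(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    v <- calls[, j][!is.na(calls[, j])]
    ncalled[j] <- length(v)
    m <- 2 * length(v); k <- sum(v)
    seg[j] <- m >= 2 && k > 0 && k < m
  }
  if (!any(seg)) return(NA_real_)
  n <- 2 * min(ncalled[seg])
  if (n < 4) return(NA_real_)
  S <- sum(seg)
  pi_sum <- 0
  for (j in which(seg)) pi_sum <- pi_sum + oracle_site_pi(calls[, j])
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact rank-sum p by enumerating every size-m subset of pooled ranks
oracle_ranksum_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  sums <- apply(utils::combn(length(r), m), 2, function(idx) sum(r[idx]))
  p_le <- mean(sums <= W + 1e-9)
  p_ge <- mean(sums >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact signed-rank p by enumerating all 2^k sign assignments
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  k <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  sums <- as.vector(signs %*% r)
  p_le <- mean(sums <= V + 1e-9)
  p_ge <- mean(sums >= V - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# additive distance matrix from a random tree, plus the generating tree
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  tree <- ape::unroot(tree)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
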