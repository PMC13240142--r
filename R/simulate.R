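#' Simulation configuration
#'
#' Describes a synthetic multi-population diploid SNP panel drawn from the
#' Balding-Nichols island model: each site has an ancestral allele frequency
#' `p` drawn from `ancestral_freq_law`, each population `k` draws its own
#' frequency `p_k ~ Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k)` (so
#' `E[p_k] = p`, `Var[p_k] = F_k p (1-p)`), and each diploid's dosage is
#' `Binomial(2, p_k)`. The default design mirrors a three-population marine
#' panel: ST (n = 14), ZH (n = 10), HN (n = 10) with per-population
#' divergence `F = 0.001` (pairwise FST on the order of 10^-3) on one 1 Mb
#' chromosome. The default site density of 0.008 sites/bp makes the expected
#' per-bp diversity about 3e-3 under the default uniform ancestral law
#' (`E[2pq] ~ 0.365`).
#'
#' An optional planted `block` substitutes `F_block` for the focal
#' population's divergence inside `[start, end]` and, when
#' `diversity_scale < 1`, shrinks the focal population's per-site
#' heterozygosity by that factor via a boundary-ward frequency transform
#' (`p' (1-p') = scale * p_k (1-p_k)`, keeping `p'` on the same side of 1/2),
#' producing elevated differentiation with smoothly reduced diversity.
#'
#' @param pops named numeric vector of diploid sample sizes per population.
#' @param F_divergence named numeric vector (same names) of per-population
#'   Balding-Nichols divergence coefficients, each in (0, 1); values below
#'   1e-12 are treated as exactly 0 (population frequency equals ancestral).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param site_density expected polymorphic-site density per bp; ignored
#'   when `n_sites` is given.
#' @param n_sites optional total site count, split across chromosomes
#'   proportionally to length.
#' @param ancestral_freq_law list: `list(type = "uniform", min, max)` or
#'   `list(type = "beta", a, b)`.
#' @param block optional list with `chrom`, `start`, `end`, `F_block`,
#'   `diversity_scale` (default 1) and `focal_pop` (default first
#'   population).
#' @param missing_rate i.i.d. per-genotype missingness probability.
#' @param seed integer RNG seed; the full dataset is reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pops = c(ST = 14, ZH = 10, HN = 10),
                       F_divergence = c(ST = 0.001, ZH = 0.001, HN = 0.001),
                       chrom_lengths = c(chr1 = 1e6),
                       site_density = 0.008,
                       n_sites = NULL,
                       ancestral_freq_law = list(type = "uniform",
                                                 min = 0.05, max = 0.95),
                       block = NULL,
                       missing_rate = 0,
                       seed = 1) {
  stopifnot(length(pops) >= 1, all(pops >= 1),
            identical(sort(names(pops)), sort(names(F_divergence))),
            all(F_divergence >= 0), all(F_divergence < 1),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(block)) {
    stopifnot(block$chrom %in% names(chrom_lengths),
              block$start >= 1,
              block$end <= chrom_lengths[[block$chrom]],
              block$start <= block$end,
              block$F_block >= 0, block$F_block < 1)
    if (is.null(block$diversity_scale)) block$diversity_scale <- 1
    if (is.null(block$focal_pop)) block$focal_pop <- names(pops)[1]
    stopifnot(block$focal_pop %in% names(pops),
              block$diversity_scale > 0, block$diversity_scale <= 1)
  }
  structure(list(pops = pops, F_divergence = F_divergence[names(pops)],
                 chrom_lengths = chrom_lengths, site_density = site_density,
                 n_sites = n_sites, ancestral_freq_law = ancestral_freq_law,
                 block = block, missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' Analytic expected pairwise FST under the Balding-Nichols draw
#'
#' For two populations with divergence `F_a` and `F_b` around a common
#' ancestral frequency `p`, the among-population variance component at a
#' site has expectation `((F_a + F_b)/2) p (1-p)` and the total expectation
#' is `p (1-p)`; the `p`-dependence cancels in the ratio-of-sums, so the
#' expected weighted Weir-Cockerham estimate over many sites is simply
#' `(F_a + F_b) / 2`, independent of the ancestral law. The derivation is
#' validated against brute-force Monte-Carlo integration in the test suite.
#'
#' @param F_a,F_b per-population divergence coefficients.
#' @return expected pairwise weighted FST.
#' @export
expected_fst <- function(F_a, F_b) {
  stopifnot(F_a >= 0, F_a < 1, F_b >= 0, F_b < 1)
  (F_a + F_b) / 2
}

draw_ancestral <- function(law, n) {
  switch(law$type,
         uniform = stats::runif(n, law$min, law$max),
         beta = stats::rbeta(n, law$a, law$b),
         stop("unknown ancestral frequency law: ", law$type))
}

bn_draw <- function(p, F) {
  if (F < 1e-12) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# shrink heterozygosity p(1-p) by `scale`, keeping p on the same side of 1/2
shrink_het <- function(p, scale) {
  disc <- pmax(0, 1 - 4 * scale * p * (1 - p))
  lo <- (1 - sqrt(disc)) / 2
  ifelse(p <= 0.5, lo, 1 - lo)
}

#' Simulate a multi-population diploid SNP panel
#'
#' Draws a panel under the Balding-Nichols model described in
#' [sim_config()]. All randomness flows from `cfg$seed` through one
#' generator stream in a fixed order (per chromosome: positions, alleles,
#' ancestral frequencies; then per population: population frequencies;
#' then genotypes; then missingness), so the same config yields a
#' bit-identical panel.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (list:
#'   `ancestral` per-site ancestral frequency, `pop_freq` sites x
#'   populations matrix of realised frequencies, `block`, `seed`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    chroms <- names(cfg$chrom_lengths)
    lens <- as.numeric(cfg$chrom_lengths)
    n_per_chrom <- if (!is.null(cfg$n_sites)) {
      alloc <- round(cfg$n_sites * lens / sum(lens))
      alloc[length(alloc)] <- cfg$n_sites - sum(alloc[-length(alloc)])
      alloc
    } else {
      round(cfg$site_density * lens)
    }

    sites_list <- vector("list", length(chroms))
    anc_list <- vector("list", length(chroms))
    bases <- c("A", "C", "G", "T")
    for (ci in seq_along(chroms)) {
      ns <- n_per_chrom[ci]
      pos <- sort(sample.int(lens[ci], ns))
      ref <- sample(bases, ns, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                    character(1))
      sites_list[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                                     ref = ref, alt = unname(alt),
                                     qual = 100, stringsAsFactors = FALSE)
      anc_list[[ci]] <- draw_ancestral(cfg$ancestral_freq_law, ns)
    }
    sites <- do.call(rbind, sites_list)
    ancestral <- unlist(anc_list)
    n_sites <- nrow(sites)

    in_block <- rep(FALSE, n_sites)
    if (!is.null(cfg$block))
      in_block <- sites$chrom == cfg$block$chrom &
        sites$pos >= cfg$block$start & sites$pos <= cfg$block$end

    pop_names <- names(cfg$pops)
    pop_freq <- matrix(NA_real_, n_sites, length(pop_names),
                       dimnames = list(NULL, pop_names))
    for (pn in pop_names) {
      Fvec <- rep(cfg$F_divergence[[pn]], n_sites)
      focal <- !is.null(cfg$block) && pn == cfg$block$focal_pop
      if (focal) Fvec[in_block] <- cfg$block$F_block
      # one rbeta stream per population; sites with F = 0 copy the ancestral
      pk <- ancestral
      pos_F <- Fvec >= 1e-12
      if (any(pos_F))
        pk[pos_F] <- stats::rbeta(sum(pos_F),
                                  ancestral[pos_F] * (1 - Fvec[pos_F]) / Fvec[pos_F],
                                  (1 - ancestral[pos_F]) * (1 - Fvec[pos_F]) / Fvec[pos_F])
      if (focal && cfg$block$diversity_scale < 1)
        pk[in_block] <- shrink_het(pk[in_block], cfg$block$diversity_scale)
      pop_freq[, pn] <- pk
    }

    samples <- unlist(lapply(pop_names, function(pn)
      sprintf("%s_%02d", pn, seq_len(cfg$pops[[pn]]))))
    pop_of <- stats::setNames(rep(pop_names, cfg$pops[pop_names]), samples)
    calls <- matrix(NA_integer_, length(samples), n_sites,
                    dimnames = list(samples, NULL))
    for (pn in pop_names) {
      rows <- which(pop_of == pn)
      np <- length(rows)
      calls[rows, ] <- matrix(
        stats::rbinom(np * n_sites, 2, rep(pop_freq[, pn], each = np)),
        nrow = np)
    }
    if (cfg$missing_rate > 0) {
      drop <- stats::runif(length(calls)) < cfg$missing_rate
      calls[drop] <- NA_integer_
    }

    gm <- genotype_matrix(calls, sites, pop_of, samples = samples)
    list(gm = gm,
         truth = list(ancestral = ancestral, pop_freq = pop_freq,
                      block = cfg$block, seed = cfg$seed))
  })
}

#' Write a simulated fixture to disk
#'
#' Emits `<prefix>.vcf` (VCFv4.2), `<prefix>.pops.tsv` (sample/population
#' table) and `<prefix>.truth.json` (generating parameters and realised
#' per-site frequencies) — together sufficient to run every pipeline stage.
#'
#' @param cfg a [sim_config()].
#' @param out_prefix output path prefix.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(cfg, out_prefix) {
  sim <- simulate_genotypes(cfg)
  paths <- c(vcf = paste0(out_prefix, ".vcf"),
             pops = paste0(out_prefix, ".pops.tsv"),
             truth = paste0(out_prefix, ".truth.json"))
  write_vcf(sim$gm, paths[["vcf"]])
  utils::write.table(
    data.frame(sample = sim$gm$samples, population = unname(sim$gm$pop_of)),
    paths[["pops"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  truth <- sim$truth
  truth$pop_freq <- as.data.frame(truth$pop_freq)
  truth$config <- unclass(cfg)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(paths)
}
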