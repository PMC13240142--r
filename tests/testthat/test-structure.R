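test_that("p-distance counts shared alleles at co-called sites", {
  pops <- c(s1 = "A", s2 = "A", s3 = "A")
  gm <- toy_gm(rbind(rep(0L, 10), rep(0L, 10), rep(2L, 10)), pops)
  d <- p_distance_matrix(gm)
  expect_equal(d["s1", "s2"], 0)           # identical samples
  expect_equal(d["s1", "s3"], 1)           # opposite homozygotes throughout
  expect_equal(diag(d), setNames(rep(0, 3), names(pops)))
  expect_equal(d, t(d))

  # one 0/0 vs 0/1 site among 10 otherwise identical sites -> 0.05
  a <- rep(0L, 10); b <- rep(0L, 10); b[1] <- 1L
  gm2 <- toy_gm(rbind(a, b), c(a = "A", b = "A"))
  expect_equal(p_distance_matrix(gm2)["a", "b"], 0.05)

  # a pair with no co-called site is an error naming the pair
  cal <- rbind(c(0L, NA), c(NA, 1L))
  gm3 <- toy_gm(cal, c(u = "A", v = "A"))
  expect_error(p_distance_matrix(gm3), "u.*v")
})

test_that("NJ solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  pd <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(pd, d, tolerance = 1e-12)   # x=(d12+d13-d23)/2 etc.
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(29)
  for (k in 1:8) {
    case <- random_additive_case(sample(5:12, 1))
    tr <- neighbor_joining(case$d)
    pd <- ape::cophenetic.phylo(tr)[rownames(case$d), colnames(case$d)]
    expect_lt(max(abs(pd - case$d)), 1e-10)
    expect_equal(ape::dist.topo(ape::unroot(tr), case$tree),
                 structure(0, Size=2, class="dist"), ignore_attr = TRUE)
  }
})

test_that("NJ handles degenerate and invalid inputs", {
  # star-like equal distances: all internal branches near zero
  n <- 6
  d <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  tr <- neighbor_joining(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_lt(max(tr$edge.length[internal]), 1e-12)
  expect_true(all(tr$edge.length >= 0))

  bad <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(neighbor_joining(bad), "3")
  d2 <- d; d2[1, 2] <- NA; d2[2, 1] <- NA
  expect_error(neighbor_joining(d2), "finite")
  d3 <- d; d3[1, 2] <- 9
  expect_error(neighbor_joining(d3), "symmetric")
})

test_that("NJ output is deterministic under ties", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  expect_identical(to_newick(neighbor_joining(d)),
                   to_newick(neighbor_joining(d)))
})

test_that("newick serialization round-trips", {
  set.seed(31)
  tr <- ape::rtree(10)
  txt <- to_newick(tr)
  expect_match(txt, ";$")
  back <- ape::read.tree(text = txt)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)),
               structure(0, class = "dist"), ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-12)

  tr$tip.label[1] <- "sample one"
  expect_match(to_newick(tr), "sample_one")
  expect_match(to_newick(tr, spaces = "quote"), "'sample one'")

  p <- file.path(withr::local_tempdir(), "t.nwk")
  to_newick(tr, path = p)
  expect_true(file.exists(p))
})

test_that("PCA matches a dense eigen oracle and its invariants", {
  set.seed(37)
  gm <- random_gm(15, 50, missing_rate = 0.08)
  pca <- genotype_pca(gm)
  # oracle: eigendecomposition of the covariance of the same imputed matrix
  g <- gm$calls[, pca$site_index, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  x <- sweep(g, 2, mu); x[is.na(x)] <- 0
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  k <- ncol(pca$scores)
  expect_equal(pca$explained_variance,
               (ev$values / sum(ev$values))[seq_len(k)], tolerance = 1e-8)
  for (j in 1:3)  # scores equal up to sign
    expect_equal(abs(pca$scores[, j]),
                 abs(ev$vectors[, j] * sqrt(ev$values[j])), tolerance = 1e-8,
                 ignore_attr = TRUE)

  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)  # centred scores

  # duplicated samples get identical score rows
  dup <- genotype_matrix(gm$calls[c(1, 1, 2:15), ], gm$sites,
                         setNames(gm$pop_of[c(1, 1:15)],
                                  c("dup", names(gm$pop_of))),
                         samples = c("dup", gm$samples))
  sc <- genotype_pca(dup)$scores
  expect_equal(sc[1, ], sc[2, ], ignore_attr = TRUE)

  # site order permutation leaves scores unchanged up to sign
  perm <- sample(50)
  gm_p <- toy_gm(gm$calls[, perm], gm$pop_of)
  expect_equal(abs(genotype_pca(gm_p)$scores), abs(pca$scores),
               tolerance = 1e-8)

  mono <- toy_gm(matrix(2L, 4, 3), setNames(rep("A", 4), paste0("s", 1:4)))
  expect_error(genotype_pca(mono), "polymorphic")
})

test_that("patterson scaling upweights rare variants", {
  set.seed(41)
  gm <- random_gm(10, 40, missing_rate = 0)
  p1 <- genotype_pca(gm, scaling = "patterson")
  expect_equal(dim(p1$scores), c(10, 9))
  expect_false(isTRUE(all.equal(p1$explained_variance,
                                genotype_pca(gm)$explained_variance)))
})

test_that("dapc_lite separates planted clusters and respects duplicates", {
  cfg <- sim_config(pops = c(A = 12, B = 12),
                    F_divergence = c(A = 0.5, B = 0.5),
                    chrom_lengths = c(chr1 = 2e5), n_sites = 1500, seed = 5)
  gm <- simulate_genotypes(cfg)$gm
  fit <- dapc_lite(gm, k_max = 5)
  expect_equal(fit$k, 2L)
  truth <- as.integer(factor(gm$pop_of))
  agree <- max(mean(fit$assignments == truth),
               mean(fit$assignments == 3 - truth))
  expect_gte(agree, 0.95)
  expect_equal(ncol(fit$discriminants), 1L)

  # duplicated dataset: co-duplicates are always co-assigned
  dup <- genotype_matrix(rbind(gm$calls, gm$calls), gm$sites,
                         setNames(rep(gm$pop_of, 2),
                                  c(gm$samples, paste0(gm$samples, "_d"))),
                         samples = c(gm$samples, paste0(gm$samples, "_d")))
  fit2 <- dapc_lite(dup, k_max = 5)
  n <- length(gm$samples)
  expect_equal(unname(fit2$assignments[seq_len(n)]),
               unname(fit2$assignments[n + seq_len(n)]))

  expect_error(dapc_lite(gm, k_max = 24), "k_max")
})

test_that("dapc_lite declares homogeneous data unstructured", {
  hits <- vapply(1:5, function(s) {
    gm <- simulate_genotypes(sim_config(n_sites = 3000, seed = 100 + s))$gm
    dapc_lite(gm)$k
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.8)
})

test_that("bootstrap support is high for well-separated clades", {
  cfg <- sim_config(pops = c(A = 5, B = 5), F_divergence = c(A = .6, B = .6),
                    chrom_lengths = c(chr1 = 1e5), n_sites = 800, seed = 9)
  gm <- simulate_genotypes(cfg)$gm
  bs <- nj_bootstrap(gm, n_rep = 30, seed = 2)
  expect_s3_class(bs$tree, "phylo")
  expect_true(any(bs$support >= 27, na.rm = TRUE))  # the A|B split
})
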