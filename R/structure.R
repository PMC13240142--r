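#' Pairwise shared-allele p-distance matrix
#'
#' For each sample pair the distance is `1 - mean(shared allele fraction)`
#' over sites called in both samples, where the shared fraction at a site is
#' the number of alleles the two diploid genotypes have in common (counted
#' with multiplicity) divided by 2. In dosage terms the fraction is
#' `(2 - |g_i - g_j|) / 2`. The result is a semimetric: symmetric and zero
#' on identical samples, but the triangle inequality is not guaranteed under
#' arbitrary missingness patterns.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @return symmetric numeric matrix with sample labels as dimnames.
#' @export
p_distance_matrix <- function(gm) {
  n <- length(gm$samples)
  stopifnot(n >= 2)
  g <- gm$calls
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok))
        stop("samples ", gm$samples[i], " and ", gm$samples[j],
             " share no co-called site")
      shared <- (2 - abs(g[i, ok] - g[j, ok])) / 2
      d[i, j] <- d[j, i] <- 1 - mean(shared)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair minimising
#' the Q-criterion `(r-2) d_ij - R_i - R_j`, assign branch lengths by the
#' rate-corrected formulas, reduce the matrix, and stop when three nodes
#' remain (joined in an unrooted star). Ties on Q are broken by the
#' lexicographically smallest active index pair, making the output
#' deterministic. A negative branch length is clamped to zero and its
#' deficit transferred to the sister branch, preserving the pair's summed
#' length. The result is exact on additive (tree-metric) inputs.
#'
#' @param dm symmetric numeric matrix with finite entries, zero diagonal and
#'   taxon labels as dimnames; at least 3 taxa.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(!is.finite(dm)))
    stop("distance matrix must be symmetric with finite entries")
  n <- nrow(dm)
  stopifnot(n >= 3)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # working Newick fragment per active node
  frag <- gsub("[ ,;():]", "_", labels)
  D <- unname(dm)

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin <= 0, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], vi, frag[j], vj)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
  }

  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  v1 <- max(0, (d12 + d13 - d23) / 2)
  v2 <- max(0, (d12 + d23 - d13) / 2)
  v3 <- max(0, (d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = nwk)
}

#' Serialize a tree to Newick text
#'
#' Standard Newick with branch lengths and a terminating semicolon; a
#' parse-serialize round trip preserves topology and branch lengths. Labels
#' containing spaces are underscored (default) or single-quoted.
#'
#' @param tree an `ape::phylo` object.
#' @param path optional file path; when given the text is also written there.
#' @param spaces how to protect labels containing spaces: `"underscore"` or
#'   `"quote"`.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL, spaces = c("underscore", "quote")) {
  spaces <- match.arg(spaces)
  has_space <- grepl(" ", tree$tip.label)
  placeholder <- "\001"
  if (any(has_space)) {
    tree$tip.label <- if (spaces == "underscore")
      gsub(" ", "_", tree$tip.label)
    else  # placeholder survives write.tree's own space munging
      ifelse(has_space,
             paste0("'", gsub(" ", placeholder, tree$tip.label), "'"),
             tree$tip.label)
  }
  txt <- gsub(placeholder, " ", ape::write.tree(tree, digits = 17),
              fixed = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Resamples sites with replacement, rebuilds the p-distance NJ tree for
#' each replicate, and counts how often each internal bipartition of the
#' main tree recurs.
#'
#' @param gm a [genotype_matrix()].
#' @param n_rep number of site-resampling replicates.
#' @param seed RNG seed.
#' @return list with `tree` (the main NJ tree) and `support` (counts per
#'   internal node, on the `n_rep` scale).
#' @export
nj_bootstrap <- function(gm, n_rep = 100, seed = 1) {
  main <- neighbor_joining(p_distance_matrix(gm))
  bs <- local_seed(seed, lapply(seq_len(n_rep), function(k) {
    idx <- sample.int(nrow(gm$sites), replace = TRUE)
    gm_b <- genotype_matrix(gm$calls[, idx, drop = FALSE],
                            rebuild_positions(gm$sites[idx, , drop = FALSE]),
                            gm$pop_of, samples = gm$samples)
    neighbor_joining(p_distance_matrix(gm_b))
  }))
  list(tree = main, support = ape::prop.clades(main, bs, rooted = FALSE))
}

# resampled site tables may break position monotonicity; positions carry no
# information for distance computations, so renumber
rebuild_positions <- function(sites) {
  sites$pos <- seq_len(nrow(sites))
  sites$chrom <- "resampled"
  sites
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site, sites are centred, monomorphic
#' sites dropped, and (optionally) Patterson-normalised by
#' `sqrt(p (1 - p))` with `p` the site allele frequency over called alleles.
#' Scores come from the singular value decomposition of the scaled matrix;
#' component signs are fixed so the loading of largest magnitude is
#' positive, making results deterministic.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples and 1 polymorphic
#'   site.
#' @param scaling `"none"` or `"patterson"`.
#' @return object of class `pca_result`: list with `scores` (samples x
#'   components), `explained_variance` (fraction per component,
#'   nonincreasing), `loadings`, `site_index` (columns used).
#' @export
genotype_pca <- function(gm, scaling = c("none", "patterson")) {
  scaling <- match.arg(scaling)
  n <- length(gm$samples)
  stopifnot(n >= 2)
  g <- gm$calls
  called <- colSums(!is.na(g))
  p <- ifelse(called > 0, colSums(g, na.rm = TRUE) / (2 * called), NA)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic site; PCA undefined")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  mu <- colMeans(g, na.rm = TRUE)
  x <- sweep(g, 2, mu)
  x[is.na(x)] <- 0           # mean imputation after centring
  if (scaling == "patterson") x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(x)
  k <- min(n - 1, ncol(x))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 loadings = loadings, site_index = which(poly)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  ev <- x$explained_variance[seq_len(min(5, length(x$explained_variance)))]
  cat("explained variance:", paste(sprintf("%.3f", ev), collapse = " "),
      if (length(x$explained_variance) > 5) "..." else "", "\n")
  invisible(x)
}

#' DAPC-style clustering of the genotype matrix
#'
#' Three steps mirroring standard discriminant analysis of principal
#' components: (1) PCA keeping the smallest number of components whose
#' cumulative explained variance reaches `var_retained`; (2) k-means (10
#' restarts, seeded) over `k = 1..k_max`, recording the within-cluster sum
#' of squares (WSS); the cluster number is chosen by the maximum-curvature
#' (second-difference) rule, guarded by a homogeneity check: if the best
#' 2-cluster split fails to remove at least `homogeneity_frac` of the total
#' WSS, the data are declared unstructured and `k = 1` is returned with no
#' discriminant step; (3) linear discriminant analysis of the retained
#' components against the chosen clusters.
#'
#' The guard threshold default (0.25) comes from random-matrix
#' considerations: for an unstructured sample the best split captures on the
#' order of the leading eigenvalue share of an eigenvalue bulk
#' (roughly 10-15% at the package's desk scales), while genuinely separated
#' clusters put most of the variance on the separation axis.
#'
#' @param gm a [genotype_matrix()].
#' @param var_retained fraction of variance the retained components must
#'   reach.
#' @param k_max largest cluster number examined; must be < number of samples.
#' @param seed RNG seed for k-means restarts.
#' @param homogeneity_frac minimum fraction of WSS a 2-cluster split must
#'   explain for any clustering to be accepted.
#' @return list with `k` (chosen cluster count), `assignments` (named
#'   integer vector; all 1 when `k = 1`), `wss` (per examined k),
#'   `n_components`, `discriminants` (samples x (k-1) LDA coordinates, or
#'   `NULL` when `k = 1`), `pca` (the [genotype_pca()] fit).
#' @export
dapc_lite <- function(gm, var_retained = 0.95, k_max = 6, seed = 1,
                      homogeneity_frac = 0.25) {
  n <- length(gm$samples)
  if (k_max >= n) stop("k_max must be smaller than the number of samples")
  pca <- genotype_pca(gm)
  cum <- cumsum(pca$explained_variance)
  ncomp <- max(1L, which(cum >= var_retained)[1])
  if (is.na(ncomp)) ncomp <- length(cum)
  z <- pca$scores[, seq_len(ncomp), drop = FALSE]

  wss <- numeric(k_max)
  fits <- vector("list", k_max)
  wss[1] <- sum(sweep(z, 2, colMeans(z))^2)
  local_seed(seed, for (k in seq.int(2, k_max)) {
    fits[[k]] <- stats::kmeans(z, centers = k, nstart = 10, iter.max = 50)
    wss[k] <- fits[[k]]$tot.withinss
  })

  if ((wss[1] - wss[2]) / wss[1] < homogeneity_frac) {
    return(list(k = 1L,
                assignments = stats::setNames(rep(1L, n), gm$samples),
                wss = wss, n_components = ncomp, discriminants = NULL,
                pca = pca))
  }
  if (k_max >= 4) {
    interior <- seq.int(2, k_max - 1)
    curv <- wss[interior - 1] - 2 * wss[interior] + wss[interior + 1]
    k_star <- interior[which.max(curv)]
  } else {
    k_star <- 2L
  }
  cl <- fits[[k_star]]$cluster
  disc <- tryCatch({
    fit <- MASS::lda(z, grouping = factor(cl))
    stats::predict(fit, z)$x
  }, error = function(e) NULL)
  list(k = as.integer(k_star),
       assignments = stats::setNames(as.integer(cl), gm$samples),
       wss = wss, n_components = ncomp, discriminants = disc, pca = pca)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
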