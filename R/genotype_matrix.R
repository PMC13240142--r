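#' Construct a genotype matrix
#'
#' The central in-memory container of the package: an n_samples x n_sites
#' matrix of diploid alternate-allele dosages (0, 1, 2, or `NA` for a missing
#' call) together with per-site metadata and a population label per sample.
#' All windowed statistics, outlier scans and structure summaries operate on
#' this object.
#'
#' @param calls integer matrix, samples in rows, sites in columns; entries in
#'   \{0, 1, 2, NA\}. Row names are taken as sample identifiers if `samples`
#'   is missing.
#' @param sites `data.frame` with one row per site and at least columns
#'   `chrom` (character), `pos` (integer, 1-based), `ref`, `alt`. `alt` holds
#'   comma-separated alternate alleles; sites with more than one alternate are
#'   retained but flagged in the `multiallelic` column. Optional columns:
#'   `qual` and any of `QD`, `MQ`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`.
#' @param pop_of named character vector mapping every sample to a population
#'   label.
#' @param samples character vector of sample identifiers, in matrix row order.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `sites`, `samples`, `pop_of`.
#' @export
genotype_matrix <- function(calls, sites, pop_of, samples = rownames(calls)) {
  if (is.null(samples)) stop("sample identifiers are required (rownames or `samples`)")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  rownames(calls) <- samples
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$multiallelic)) {
    sites$multiallelic <- grepl(",", sites$alt, fixed = TRUE)
  }
  gm <- structure(
    list(calls = calls, sites = sites, samples = as.character(samples),
         pop_of = pop_of[samples]),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  if (nrow(gm$calls) != length(gm$samples))
    stop("call matrix must have one row per sample")
  if (ncol(gm$calls) != nrow(gm$sites))
    stop("call matrix must have one column per site")
  bad <- !(gm$calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("calls must be 0, 1, 2 or NA")
  if (any(is.na(gm$pop_of)))
    stop("population label missing for sample(s): ",
         paste(gm$samples[is.na(gm$pop_of)], collapse = ", "))
  if (any(gm$sites$pos < 1L)) stop("site positions must be >= 1")
  if (any(vapply(split(gm$sites$pos, gm$sites$chrom), is.unsorted, logical(1))))
    stop("site positions must be nondecreasing within each chromosome")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites\n",
              length(x$samples), nrow(x$sites)))
  tab <- table(x$pop_of)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Population labels present in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return character vector of unique population labels, in order of first
#'   appearance.
#' @export
populations <- function(gm) unique(unname(gm$pop_of))

#' Subset a genotype matrix by site index
#'
#' @param gm a `genotype_matrix`
#' @param site_idx integer or logical index into the site dimension
#' @return a new `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, site_idx) {
  genotype_matrix(gm$calls[, site_idx, drop = FALSE],
                  gm$sites[site_idx, , drop = FALSE],
                  gm$pop_of, samples = gm$samples)
}

# indices of samples belonging to one population
pop_rows <- function(gm, population) {
  idx <- which(gm$pop_of == population)
  if (!length(idx)) stop("unknown population label: ", population)
  idx
}
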