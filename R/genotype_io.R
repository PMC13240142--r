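#' Filtering configuration
#'
#' Bundles the variant-quality and site-level filters applied to a raw
#' multi-sample SNP call set. Defaults follow common GATK/VCFtools practice
#' for short-read panels: hard annotation thresholds (QD < 2.0, MQ < 40.0,
#' FS > 60.0, SOR > 3.0, MQRankSum < -12.5, ReadPosRankSum < -8.0) plus
#' QUAL > 40, MAF >= 0.05 and call rate >= 0.95 on biallelic SNPs.
#'
#' @param qual_min minimum phred site quality; retained sites need
#'   `QUAL > qual_min`. A missing QUAL fails the rule.
#' @param maf_min minimum minor allele frequency, computed on called alleles
#'   only.
#' @param min_call_rate minimum fraction of samples with a called genotype.
#' @param biallelic_only drop sites with more than one alternate allele.
#' @param hard_filter_thresholds named list of annotation thresholds; see
#'   [apply_hard_filters()].
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(qual_min = 40, maf_min = 0.05, min_call_rate = 0.95,
                          biallelic_only = TRUE,
                          hard_filter_thresholds = list(
                            QD_min = 2.0, MQ_min = 40.0, FS_max = 60.0,
                            SOR_max = 3.0, MQRankSum_min = -12.5,
                            ReadPosRankSum_min = -8.0)) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            min_call_rate >= 0, min_call_rate <= 1)
  structure(list(qual_min = qual_min, maf_min = maf_min,
                 min_call_rate = min_call_rate,
                 biallelic_only = isTRUE(biallelic_only),
                 hard_filter_thresholds = hard_filter_thresholds),
            class = "filter_config")
}

#' Read a sample-to-population assignment table
#'
#' Two whitespace- or tab-separated columns: sample identifier, population
#' label. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return named character vector mapping sample to population.
#' @export
read_pop_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample))
    stop("duplicated sample in population table: ",
         tab$sample[duplicated(tab$sample)][1])
  stats::setNames(tab$population, tab$sample)
}

INFO_KEYS <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCFv4.2 file with diploid GT calls. Only the GT subfield of the
#' FORMAT column is consulted; phased (`|`) and unphased (`/`) separators are
#' treated identically. The dosage of a genotype is the number of alleles
#' equal to alternate index 1; any `.` allele (including half-calls such as
#' `./1`) yields a missing call. Multiallelic sites are retained and flagged
#' for removal by [apply_site_filters()]. QUAL `.` and absent INFO
#' annotations are stored as `NA`.
#'
#' @param path path to an uncompressed VCF.
#' @param pop_table named character vector (sample -> population) or the path
#'   of a table readable by [read_pop_table()]. Every VCF sample must appear.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_table) {
  if (is.character(pop_table) && length(pop_table) == 1 && is.null(names(pop_table)))
    pop_table <- read_pop_table(pop_table)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1)
    stop("not a valid VCF: expected exactly one #CHROM header line")
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(fields) < 10 || !identical(fields[9], "FORMAT"))
    stop("VCF must carry a FORMAT column and at least one sample")
  samples <- fields[-(1:9)]
  missing_pop <- setdiff(samples, names(pop_table))
  if (length(missing_pop))
    stop("sample(s) absent from population table: ",
         paste(missing_pop, collapse = ", "))

  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n_sites <- length(body)
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = n_sites,
                  dimnames = list(samples, NULL))
  sites <- data.frame(chrom = character(n_sites), pos = integer(n_sites),
                      ref = character(n_sites), alt = character(n_sites),
                      qual = rep(NA_real_, n_sites),
                      stringsAsFactors = FALSE)
  for (k in INFO_KEYS) sites[[k]] <- rep(NA_real_, n_sites)

  if (n_sites > 0) {
    toks <- strsplit(body, "\t", fixed = TRUE)
    nfield <- lengths(toks)
    bad <- which(nfield != length(fields))
    if (length(bad))
      stop(sprintf("malformed VCF line %d: expected %d fields, found %d",
                   hdr + bad[1], length(fields), nfield[bad[1]]))
    tokm <- matrix(unlist(toks), nrow = length(fields))
    sites$chrom <- tokm[1, ]
    pos <- suppressWarnings(as.integer(tokm[2, ]))
    if (anyNA(pos))
      stop(sprintf("malformed VCF line %d: non-integer POS '%s'",
                   hdr + which(is.na(pos))[1], tokm[2, which(is.na(pos))[1]]))
    sites$pos <- pos
    sites$ref <- tokm[4, ]
    sites$alt <- tokm[5, ]
    qual <- tokm[6, ]
    sites$qual <- suppressWarnings(as.numeric(ifelse(qual == ".", NA, qual)))
    info <- parse_info(tokm[8, ])
    for (k in INFO_KEYS) sites[[k]] <- info[[k]]

    gt_at <- vapply(strsplit(tokm[9, ], ":", fixed = TRUE),
                    function(f) match("GT", f), integer(1))
    if (anyNA(gt_at))
      stop(sprintf("malformed VCF line %d: FORMAT lacks GT",
                   hdr + which(is.na(gt_at))[1]))
    for (j in seq_len(n_sites)) {
      gt <- tokm[9 + seq_along(samples), j]
      if (gt_at[j] > 1L)
        gt <- vapply(strsplit(gt, ":", fixed = TRUE), `[`, character(1), gt_at[j])
      else
        gt <- sub(":.*", "", gt)
      calls[, j] <- gt_to_dosage(gt)
    }
  }
  genotype_matrix(calls, sites, pop_table, samples = samples)
}

# diploid GT token -> alt-1 dosage; any "." allele -> NA
gt_to_dosage <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

parse_info <- function(info_str) {
  out <- lapply(INFO_KEYS, function(k) {
    v <- rep(NA_real_, length(info_str))
    pat <- paste0("(?:^|;)", k, "=([^;]+)")
    m <- regmatches(info_str, regexec(pat, info_str))
    has <- lengths(m) == 2
    v[has] <- suppressWarnings(as.numeric(vapply(m[has], `[`, character(1), 2)))
    v
  })
  names(out) <- INFO_KEYS
  out
}

#' Apply GATK-style hard annotation filters
#'
#' A site is removed iff any *present* annotation violates its threshold:
#' `QD < QD_min`, `MQ < MQ_min`, `FS > FS_max`, `SOR > SOR_max`,
#' `MQRankSum < MQRankSum_min` or `ReadPosRankSum < ReadPosRankSum_min`.
#' Absent (`NA`) annotations never trigger removal: rank-sum annotations are
#' undefined at sites without heterozygotes, and dropping such sites would
#' discard fixed differences.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return a new `genotype_matrix`; the input is not modified.
#' @export
apply_hard_filters <- function(gm, cfg = filter_config()) {
  th <- cfg$hard_filter_thresholds
  s <- gm$sites
  ann <- function(k) if (is.null(s[[k]])) rep(NA_real_, nrow(s)) else s[[k]]
  viol <- function(x, bad) !is.na(x) & bad(x)
  drop <- viol(ann("QD"), function(x) x < th$QD_min) |
    viol(ann("MQ"), function(x) x < th$MQ_min) |
    viol(ann("FS"), function(x) x > th$FS_max) |
    viol(ann("SOR"), function(x) x > th$SOR_max) |
    viol(ann("MQRankSum"), function(x) x < th$MQRankSum_min) |
    viol(ann("ReadPosRankSum"), function(x) x < th$ReadPosRankSum_min)
  subset_sites(gm, !drop)
}

#' Apply site-level quality, MAF and call-rate filters
#'
#' Retains sites that are biallelic (exactly one alternate allele, when
#' `biallelic_only`), have `QUAL > qual_min` (a missing QUAL fails), a call
#' rate of at least `min_call_rate`, and a minor allele frequency of at least
#' `maf_min`. MAF is `min(p, 1 - p)` with `p` the alternate-allele count over
#' *called* alleles; a site with no called genotype is dropped via the
#' call-rate rule, never a division error.
#'
#' @inheritParams apply_hard_filters
#' @return a new `genotype_matrix`.
#' @export
apply_site_filters <- function(gm, cfg = filter_config()) {
  n <- length(gm$samples)
  called <- colSums(!is.na(gm$calls))
  call_rate <- called / n
  alt <- colSums(gm$calls, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), 0)
  maf <- pmin(p, 1 - p)
  keep <- call_rate >= cfg$min_call_rate &
    !is.na(gm$sites$qual) & gm$sites$qual > cfg$qual_min &
    maf >= cfg$maf_min
  if (cfg$biallelic_only) keep <- keep & !gm$sites$multiallelic
  subset_sites(gm, keep)
}

#' Write a genotype matrix as a VCFv4.2 file
#'
#' Emits a GT-only FORMAT; missing calls are written `./.`, dosages 0/1/2 as
#' `0/0`, `0/1`, `1/1`. Reading the file back with [read_vcf()] reproduces
#' calls, positions, alleles and sample order exactly (phasing is not
#' preserved: all genotypes are written unphased).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  s <- gm$sites
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=popgenscan %s",
                   as.character(utils::packageVersion("popgenscan"))),
           vapply(INFO_KEYS, function(k) sprintf(
             "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k),
             character(1)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  n_sites <- nrow(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_sites == 0) return(invisible(path))

  info <- vapply(seq_len(n_sites), function(j) {
    kv <- vapply(INFO_KEYS, function(k) {
      v <- s[[k]][j]
      if (is.null(v) || is.na(v)) NA_character_ else sprintf("%s=%s", k, format(v))
    }, character(1))
    kv <- kv[!is.na(kv)]
    if (length(kv)) paste(kv, collapse = ";") else "."
  }, character(1))
  qual <- ifelse(is.na(s$qual), ".", vapply(s$qual, format, character(1)))
  gt <- matrix("./.", nrow = length(gm$samples), ncol = n_sites)
  gt[!is.na(gm$calls)] <- c("0/0", "0/1", "1/1")[gm$calls[!is.na(gm$calls)] + 1L]
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, qual, ".", info, "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
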