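# Fixture builders: everything is generated in code at test time.

# small genotype matrix from a dosage matrix (samples x sites)
toy_gm <- function(calls, pops, chrom = "chr1",
                   pos = seq_len(ncol(as.matrix(calls))),
                   qual = rep(100, ncol(as.matrix(calls))),
                   alt = rep("T", ncol(as.matrix(calls)))) {
  calls <- as.matrix(calls)
  samples <- names(pops)
  if (is.null(samples)) {
    samples <- paste0("s", seq_len(nrow(calls)))
    names(pops) <- samples
  }
  rownames(calls) <- samples
  ns <- ncol(calls)
  sites <- data.frame(chrom = rep_len(chrom, ns), pos = pos,
                      ref = rep_len("A", ns), alt = rep_len(alt, ns),
                      qual = rep_len(qual, ns), stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, pops, samples = samples)
}

# random matrix with optional missingness, two or three populations
random_gm <- function(n_samples, n_sites, n_pops = 2, missing_rate = 0.05,
                      pos = sort(sample.int(n_sites * 20, n_sites))) {
  calls <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
                  n_samples, n_sites)
  if (missing_rate > 0)
    calls[matrix(stats::runif(length(calls)) < missing_rate,
                 nrow(calls))] <- NA_integer_
  pop <- rep(paste0("P", seq_len(n_pops)), length.out = n_samples)
  names(pop) <- paste0("s", seq_len(n_samples))
  toy_gm(calls, pop, pos = pos)
}

# write a VCF from raw body lines (header generated); returns the path
write_test_vcf <- function(samples, body_lines,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, qual, info, gts) {
  paste(c(chrom, pos, ".", ref, alt, qual, ".", info, "GT", gts),
        collapse = "\t")
}
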