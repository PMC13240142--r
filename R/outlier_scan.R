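#' Outlier-scan configuration
#'
#' Parameters of the joint FST-quantile + reduced-Pi candidate-window rule
#' and of region merging. A window is a candidate when its pairwise FST lies
#' strictly above the genome-wide `fst_top_quantile` (default 0.95, the "top
#' 5%") *and* its Pi is "reduced" — strictly below the population's
#' genome-wide `pi_reduction_quantile` of window Pi (default 0.50, i.e. below
#' the median) — in at least one of the populations considered.
#'
#' @param fst_top_quantile quantile `q` of the genome-wide window-FST
#'   distribution; candidates must exceed it strictly.
#' @param pi_reduction_quantile quantile `r` defining "reduced Pi".
#' @param merge_max_gap largest bp gap between consecutive candidate windows
#'   merged into one region; 0 merges only overlapping or abutting windows.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(fst_top_quantile = 0.95, pi_reduction_quantile = 0.50,
                        merge_max_gap = 0) {
  stopifnot(fst_top_quantile > 0, fst_top_quantile < 1,
            pi_reduction_quantile >= 0, pi_reduction_quantile < 1,
            merge_max_gap >= 0)
  structure(list(fst_top_quantile = fst_top_quantile,
                 pi_reduction_quantile = pi_reduction_quantile,
                 merge_max_gap = merge_max_gap),
            class = "scan_config")
}

fst_column <- function(stats, pair) {
  cand <- c(paste0("FST_", pair[1], "_", pair[2]),
            paste0("FST_", pair[2], "_", pair[1]))
  hit <- cand[cand %in% names(stats)]
  if (!length(hit))
    stop("no FST column for pair ", pair[1], "/", pair[2], " in scan table")
  hit[1]
}

#' Genome-wide FST quantile threshold
#'
#' Empirical `q`-quantile (linear interpolation between order statistics,
#' [stats::quantile()] type 7) of the defined window FST values for one
#' population pair, pooled across chromosomes. Windows with undefined FST
#' are excluded.
#'
#' @param stats scan table from [genome_scan()].
#' @param pair two population labels.
#' @param q quantile in (0, 1).
#' @return the threshold value.
#' @export
fst_threshold <- function(stats, pair, q = 0.95) {
  v <- stats[[fst_column(stats, pair)]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no window with defined FST for pair ",
                       pair[1], "/", pair[2])
  unname(stats::quantile(v, q, type = 7))
}

#' Detect candidate differentiation windows
#'
#' A window is a candidate iff its pair FST is strictly greater than the
#' genome-wide `q`-quantile *and* its window Pi is strictly below the
#' genome-wide `r`-quantile of window Pi in at least one of `pi_pops`
#' (default: the two populations of the pair). Strict inequalities make the
#' degenerate all-equal case yield zero candidates.
#'
#' @inheritParams fst_threshold
#' @param cfg a [scan_config()].
#' @param pi_pops populations whose reduced Pi can satisfy the rule; set to a
#'   single focal population to require the reduction there.
#' @return the candidate rows of `stats`, sorted by `(CHROM, BIN_START)`.
#' @export
detect_candidate_windows <- function(stats, pair, cfg = scan_config(),
                                     pi_pops = pair) {
  stats <- data.table::as.data.table(stats)
  fst <- stats[[fst_column(stats, pair)]]
  thr <- fst_threshold(stats, pair, cfg$fst_top_quantile)
  low_pi <- rep(FALSE, nrow(stats))
  for (p in pi_pops) {
    col <- paste0("PI_", p)
    if (!col %in% names(stats)) stop("no Pi column for population ", p)
    pq <- unname(stats::quantile(stats[[col]], cfg$pi_reduction_quantile,
                                 type = 7, na.rm = TRUE))
    low_pi <- low_pi | (!is.na(stats[[col]]) & stats[[col]] < pq)
  }
  keep <- !is.na(fst) & fst > thr & low_pi
  out <- stats[keep]
  data.table::setorder(out, CHROM, BIN_START)
  out[]
}

#' Merge candidate windows into candidate regions
#'
#' Single linear pass per chromosome over the sorted candidate windows: the
#' open region is extended while the next window starts at or before
#' `current end + 1 + merge_max_gap`, otherwise it is closed and a new one
#' opened. With the default gap of 0 only overlapping or abutting windows
#' merge. Regions on different chromosomes are never merged.
#'
#' @param candidates table from [detect_candidate_windows()]; must contain
#'   `CHROM`, `BIN_START`, `BIN_END` and the pair's FST column.
#' @param pair two population labels (used for the region mean FST).
#' @param cfg a [scan_config()].
#' @return `data.table` of regions with columns `chrom`, `start`, `end`,
#'   `n_windows`, `mean_fst`, and a list column `member_windows` of row
#'   indices into `candidates`.
#' @export
merge_candidate_windows <- function(candidates, pair, cfg = scan_config()) {
  candidates <- data.table::as.data.table(candidates)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_windows = integer(), mean_fst = numeric(), member_windows = list())
  if (nrow(candidates) == 0) return(empty)
  data.table::setorder(candidates, CHROM, BIN_START)
  fst <- candidates[[fst_column(candidates, pair)]]
  gap <- cfg$merge_max_gap

  regions <- list()
  open <- NULL
  for (i in seq_len(nrow(candidates))) {
    ch <- candidates$CHROM[i]
    s <- candidates$BIN_START[i]; e <- candidates$BIN_END[i]
    if (is.null(open)) {
      open <- list(chrom = ch, start = s, end = e, members = i)
    } else if (ch == open$chrom && s <= open$end + 1 + gap) {
      open$end <- max(open$end, e)
      open$members <- c(open$members, i)
    } else {
      regions[[length(regions) + 1]] <- open
      open <- list(chrom = ch, start = s, end = e, members = i)
    }
  }
  regions[[length(regions) + 1]] <- open
  data.table::rbindlist(lapply(regions, function(r) data.table::data.table(
    chrom = r$chrom, start = r$start, end = r$end,
    n_windows = length(r$members),
    mean_fst = mean(fst[r$members]),
    member_windows = list(r$members))))
}

#' Write candidate regions as BED plus a summary TSV
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `bed_start = start - 1` and `bed_end = end` exactly.
#'
#' @param regions table from [merge_candidate_windows()].
#' @param bed_path output BED path.
#' @param tsv_path optional TSV path with `chrom`, `start`, `end`,
#'   `n_windows`, `mean_fst`.
#' @return `bed_path`, invisibly.
#' @export
write_regions_bed <- function(regions, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1,
                    end = regions$end)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    tsv <- as.data.frame(regions[, c("chrom", "start", "end", "n_windows",
                                     "mean_fst")])
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}

utils::globalVariables(c("CHROM", "BIN_START", "BIN_END"))
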