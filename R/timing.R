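# Methylation trajectories across germ-cell development: genome bins,
# region-level methylation, early/late timing classification, ChIP RPKM.

#' Tile the genome into fixed bins
#'
#' Non-overlapping bins of `bin` bp; a trailing partial bin is kept iff it
#' is at least half a bin long.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin Bin width in bp (default 1000).
#' @return Interval `data.table` (`chrom, start, end`, 0-based half-open).
#' @export
bin_genome <- function(chrom_sizes, bin = 1000L) {
  bin <- as.integer(bin)
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    n_full <- len %/% bin
    rem <- len - n_full * bin
    starts <- seq.int(0L, by = bin, length.out = n_full)
    ends <- starts + bin
    if (rem >= bin / 2) {
      starts <- c(starts, n_full * bin)
      ends <- c(ends, len)
    }
    data.table::data.table(chrom = ch, start = as.integer(starts),
                           end = as.integer(ends))
  })
  data.table::rbindlist(out)[]
}

#' Coverage-weighted mean methylation of regions
#'
#' For each region, `100 * sum(meth) / sum(cov)` over CpGs with coverage at
#' least `min_cov` falling inside the region; `NA` when no eligible CpG.
#'
#' @param regions Interval table (0-based half-open).
#' @param callset A `callset` (single track, e.g. one developmental
#'   timepoint).
#' @param min_cov Minimum per-CpG coverage (default 5, suited to
#'   WGBS-depth tracks).
#' @return Numeric vector of percentages (0-100) aligned to `regions`,
#'   with attribute `n_cpgs` (eligible CpGs per region).
#' @export
region_methylation <- function(regions, callset, min_cov = 5L) {
  regions <- data.table::as.data.table(regions)
  n <- nrow(regions)
  out <- rep(NA_real_, n)
  ncp <- integer(n)
  cs <- data.table::as.data.table(callset)[cov >= min_cov]
  if (n && nrow(cs)) {
    sites <- data.table::data.table(chrom = cs$chrom, start = cs$pos - 1L,
                                    end = cs$pos)
    h <- GenomicRanges::findOverlaps(as_gr(sites), as_gr(regions))
    if (length(h)) {
      dt <- data.table::data.table(r = S4Vectors::subjectHits(h),
                                   meth = cs$meth[S4Vectors::queryHits(h)],
                                   cov = cs$cov[S4Vectors::queryHits(h)])
      agg <- dt[, .(meth = sum(meth), cov = sum(cov), k = .N), by = r]
      out[agg$r] <- 100 * agg$meth / agg$cov
      ncp[agg$r] <- agg$k
    }
  }
  attr(out, "n_cpgs") <- ncp
  out
}

#' Sample a background bin subset without replacement
#'
#' @param bins Bin table from [bin_genome()].
#' @param n Sample size (default 50000); must not exceed the bin count.
#' @param seed RNG seed; sampling is reproducible and does not disturb the
#'   caller's RNG state.
#' @return Sampled subset of `bins`, in genomic order.
#' @export
sample_background <- function(bins, n = 50000L, seed = 1L) {
  if (n > nrow(bins))
    stopf("sample_background: n (%d) exceeds available bins (%d)",
          n, nrow(bins))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sort(sample.int(nrow(bins), n))
  bins[idx]
}

#' Build a region x timepoint trajectory matrix
#'
#' @param regions Interval table.
#' @param tracks Named list of `callset`s, one per timepoint, in
#'   developmental order.
#' @param min_cov Per-CpG coverage floor (default 5).
#' @return Numeric matrix, rows = regions, columns = timepoints; cells with
#'   no eligible CpG are `NA`.
#' @export
trajectory_matrix <- function(regions, tracks, min_cov = 5L) {
  m <- vapply(tracks, function(tr) region_methylation(regions, tr, min_cov),
              numeric(nrow(data.table::as.data.table(regions))))
  m <- matrix(m, ncol = length(tracks),
              dimnames = list(NULL, names(tracks)))
  m
}

#' Classify methylation timing from a four-timepoint trajectory
#'
#' Trajectories are (E13.5, E16.5, P0, sperm)-analog percentages.  A region
#' is `late` iff its E16.5-analog level is at most `late_max_e16` and the
#' final level exceeds the E16.5 level by at least `min_gain` points;
#' `early` iff the E16.5-analog level is at least `early_min_e16`;
#' otherwise `ambiguous` (including a missing E16.5 cell).  The thresholds
#' separate "dramatic gain only after E16.5" from genome-typical early
#' acquisition and are configurable.
#'
#' @param trajectory Numeric vector of length >= 3 (one region) or a matrix
#'   with >= 3 ordered timepoint columns; the second column is the
#'   E16.5 analog and the last column the terminal timepoint.
#' @param late_max_e16 Late ceiling at E16.5 (default 25).
#' @param min_gain Minimum post-E16.5 gain for late (default 40).
#' @param early_min_e16 Early floor at E16.5 (default 60).
#' @return Character vector of `"early"`, `"late"`, `"ambiguous"`.
#' @export
classify_timing <- function(trajectory, late_max_e16 = 25, min_gain = 40,
                            early_min_e16 = 60) {
  if (is.null(dim(trajectory))) trajectory <- matrix(trajectory, nrow = 1)
  stopifnot(ncol(trajectory) >= 3)
  e16 <- trajectory[, 2]
  final <- trajectory[, ncol(trajectory)]
  lab <- rep("ambiguous", nrow(trajectory))
  late <- !is.na(e16) & !is.na(final) & e16 <= late_max_e16 &
    (final - e16) >= min_gain
  early <- !is.na(e16) & e16 >= early_min_e16
  lab[late] <- "late"
  lab[early] <- "early"
  lab
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = overlapping read count / (region length in kb x library size in
#' millions)`.
#'
#' @param regions Interval table.
#' @param reads Read interval table (0-based half-open).
#' @param library_size Total mapped reads; must be positive.
#' @return Numeric vector of RPKM values aligned to `regions`.
#' @export
rpkm <- function(regions, reads, library_size) {
  if (library_size <= 0) stopf("rpkm: library size must be positive")
  regions <- data.table::as.data.table(regions)
  reads <- data.table::as.data.table(reads)
  n <- nrow(regions)
  if (n == 0) return(numeric())
  counts <- if (nrow(reads) == 0) integer(n)
            else GenomicRanges::countOverlaps(as_gr(regions), as_gr(reads))
  len_kb <- (regions$end - regions$start) / 1000
  counts / (len_kb * library_size / 1e6)
}

#' Joint DNA methylation / ChIP RPKM profile of regions
#'
#' @param regions Interval table.
#' @param methylation_callset `callset` for the matching timepoint.
#' @param chip_reads Read intervals for the same timepoint.
#' @param library_size Total mapped ChIP reads.
#' @param min_cov Per-CpG coverage floor for methylation (default 5).
#' @return `data.table(region = index, meth, rpkm)`; a region with no
#'   eligible CpG has `meth = NA` (the pair is reported but incomplete).
#' @export
joint_profile <- function(regions, methylation_callset, chip_reads,
                          library_size, min_cov = 5L) {
  regions <- data.table::as.data.table(regions)
  if (nrow(regions) == 0)
    return(data.table::data.table(region = integer(), meth = numeric(),
                                  rpkm = numeric()))
  data.table::data.table(
    region = seq_len(nrow(regions)),
    meth = as.numeric(region_methylation(regions, methylation_callset, min_cov)),
    rpkm = rpkm(regions, chip_reads, library_size))
}

#' Compare region methylation between wild-type and knockout tracks
#'
#' @param regions Interval table.
#' @param callset_wt,callset_ko Call sets on the same genome.
#' @param min_cov Per-CpG coverage floor (default 5).
#' @param drop_threshold Loss (WT - KO, percentage points) at which a
#'   region counts as "dropped" (default 20).
#' @return `list(pairs = data.table(region, wt, ko, dropped),
#'   dropped_fraction = fraction of complete pairs with loss >=
#'   drop_threshold)`.
#' @export
ko_comparison <- function(regions, callset_wt, callset_ko, min_cov = 5L,
                          drop_threshold = 20) {
  regions <- data.table::as.data.table(regions)
  wt <- as.numeric(region_methylation(regions, callset_wt, min_cov))
  ko <- as.numeric(region_methylation(regions, callset_ko, min_cov))
  dropped <- !is.na(wt) & !is.na(ko) & (wt - ko) >= drop_threshold
  complete <- sum(!is.na(wt) & !is.na(ko))
  list(pairs = data.table::data.table(region = seq_len(nrow(regions)),
                                      wt = wt, ko = ko, dropped = dropped),
       dropped_fraction = if (complete > 0) sum(dropped) / complete
                          else NA_real_)
}

#' Top regions by size
#'
#' Sorts descending by span with ties broken by leftmost coordinate
#' (chromosome then start) and keeps the first `n`.
#'
#' @param regions Interval table.
#' @param n Number to keep (default 200).
#' @return Subset of `regions`.
#' @export
top_regions_by_size <- function(regions, n = 200L) {
  regions <- data.table::as.data.table(regions)
  sz <- regions$end - regions$start
  ord <- order(-sz, regions$chrom, regions$start)
  regions[ord[seq_len(min(n, nrow(regions)))]]
}
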