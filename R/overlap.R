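# Cross-cohort set operations on tiles and DMRs: grid intersections, the
# four-way nesting taxonomy, three-way intersections, percentage summaries.

tile_key <- function(x, tile_size = 100L) {
  if (nrow(x) && any(x$start %% tile_size != 0))
    stopf("tile set contains off-grid tiles (start not a multiple of %d)",
          tile_size)
  paste(x$chrom, x$start, sep = ":")
}

#' Intersect two tile sets on the fixed grid
#'
#' Tiles are shared iff they have identical (chrom, start); both sets must
#' sit on the same grid.
#'
#' @param setA,setB Tile tables with `chrom`, `start` columns.
#' @param tile_size Grid size for the off-grid check (default 100).
#' @return `list(shared, a_only, b_only)` counts plus `shared_keys`.
#' @export
intersect_tiles <- function(setA, setB, tile_size = 100L) {
  ka <- unique(tile_key(setA, tile_size))
  kb <- unique(tile_key(setB, tile_size))
  shared <- intersect(ka, kb)
  list(shared = length(shared),
       a_only = length(setdiff(ka, kb)),
       b_only = length(setdiff(kb, ka)),
       shared_keys = shared)
}

#' Classify the overlap relationship of one interval pair
#'
#' Exactly one of five mutually exclusive labels holds for any pair of
#' intervals: `identical` (same coordinates), `b_within_a` (a strictly
#' contains b), `a_within_b`, `partial` (positive overlap, neither
#' containment nor identity), `disjoint`.
#'
#' @param a,b Lists or one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return One of `"identical"`, `"b_within_a"`, `"a_within_b"`,
#'   `"partial"`, `"disjoint"`.
#' @export
classify_pair <- function(a, b) {
  if (a$chrom != b$chrom) return("disjoint")
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return("disjoint")
  if (a$start == b$start && a$end == b$end) return("identical")
  if (a$start <= b$start && b$end <= a$end) return("b_within_a")
  if (b$start <= a$start && a$end <= b$end) return("a_within_b")
  "partial"
}

#' Overlap two DMR sets and classify every overlapping pair
#'
#' Each B region overlapping at least one A region counts as shared (once,
#' regardless of how many A partners it has) and is classified by
#' [classify_pair()] against the A region of maximal overlap length, ties
#' broken by leftmost A start.  Percentages use the B side as denominator
#' (the later generation, matching "% of F2 DMRs" phrasing).
#'
#' @param A,B Interval tables (`chrom, start, end`, 0-based half-open).
#' @return `list(pairs = data.table(b_idx, a_idx, overlap_bp, class),
#'   summary = list(n_a, n_b, shared_b, pct_shared_b, class_counts,
#'   class_pct))`.
#' @export
overlap_dmr_sets <- function(A, B) {
  A <- data.table::as.data.table(A); B <- data.table::as.data.table(B)
  empty_pairs <- data.table::data.table(b_idx = integer(), a_idx = integer(),
                                        overlap_bp = integer(),
                                        class = character())
  classes <- c("identical", "b_within_a", "a_within_b", "partial")
  if (nrow(A) == 0 || nrow(B) == 0) {
    cc <- stats::setNames(integer(4), classes)
    return(list(pairs = empty_pairs, summary = list(
      n_a = nrow(A), n_b = nrow(B), shared_b = 0L,
      pct_shared_b = if (nrow(B)) 0 else NA_real_,
      class_counts = cc, class_pct = cc * NA_real_)))
  }
  hits <- GenomicRanges::findOverlaps(as_gr(B), as_gr(A))
  bi <- S4Vectors::queryHits(hits); ai <- S4Vectors::subjectHits(hits)
  ov <- pmin(B$end[bi], A$end[ai]) - pmax(B$start[bi], A$start[ai])
  keep <- ov > 0
  pr <- data.table::data.table(b_idx = bi[keep], a_idx = ai[keep],
                               overlap_bp = as.integer(ov[keep]))
  # best partner per B region: max overlap, then leftmost A start
  pr[, a_start := A$start[a_idx]]
  data.table::setorder(pr, b_idx, -overlap_bp, a_start)
  best <- pr[, .SD[1], by = b_idx]
  best[, class := vapply(seq_len(.N), function(i)
    classify_pair(A[best$a_idx[i]], B[best$b_idx[i]]), character(1))]
  best[, a_start := NULL]
  cc <- stats::setNames(integer(4), classes)
  tb <- table(factor(best$class, levels = classes))
  cc[] <- as.integer(tb)
  shared <- nrow(best)
  list(pairs = best[],
       summary = list(
         n_a = nrow(A), n_b = nrow(B), shared_b = shared,
         pct_shared_b = proportion(shared, nrow(B)),
         class_counts = cc,
         class_pct = if (shared > 0) proportion(cc, shared) else cc * NA_real_))
}

#' Three-way tile/region intersection summary
#'
#' For tile sets, membership is identical (chrom, start).  Reports pairwise
#' and triple intersection counts and the triple count as a percentage of
#' each pairwise intersection.
#'
#' @param A,B,C Tile tables (`chrom, start`).
#' @param tile_size Grid size (default 100).
#' @return `list(n_a, n_b, n_c, ab, ac, bc, abc, pct_abc_of_ab, ...)`.
#' @export
three_way <- function(A, B, C, tile_size = 100L) {
  ka <- unique(tile_key(A, tile_size))
  kb <- unique(tile_key(B, tile_size))
  kc <- unique(tile_key(C, tile_size))
  ab <- intersect(ka, kb); ac <- intersect(ka, kc); bc <- intersect(kb, kc)
  abc <- intersect(ab, kc)
  pct <- function(num, den) if (den > 0) proportion(num, den) else NA_real_
  list(n_a = length(ka), n_b = length(kb), n_c = length(kc),
       ab = length(ab), ac = length(ac), bc = length(bc),
       abc = length(abc),
       pct_abc_of_ab = pct(length(abc), length(ab)),
       pct_abc_of_ac = pct(length(abc), length(ac)),
       pct_abc_of_bc = pct(length(abc), length(bc)))
}
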