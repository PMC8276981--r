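# Per-CpG differential methylation and bedtools-style merging of proximal
# DMCs into regions (DMRs).

#' Call differentially methylated CpGs (DMCs)
#'
#' Each CpG is tested on pooled per-group counts; a CpG is tested iff its
#' pooled coverage is at least `min_cov` in both groups.  BH correction is
#' applied across all tested CpGs; a DMC needs `q < q_threshold` and
#' `|diff| >= min_diff` percentage points.
#'
#' @param callsets List of `callset` objects (both groups), or a united
#'   site table from [unite_callsets()].
#' @param min_cov Minimum pooled coverage per group (default 10).
#' @param min_diff Minimum |difference| in percentage points (default 10).
#' @param q_threshold BH FDR threshold (default 0.01; the same threshold as
#'   tiles, exposed as a flag since per-CpG practice varies).
#' @param method `"logistic"` or `"fisher_pooled"`, as for tiles.
#' @param overdispersion `"MN"` (replicate-scatter dispersion correction,
#'   default) or `"none"`; see [test_tiles()].
#' @return `list(sites = all tested CpGs with p, q, diff, direction;
#'   dmcs = the significant subset)`.
#' @export
call_dmcs <- function(callsets, min_cov = 10L, min_diff = 10,
                      q_threshold = 0.01,
                      method = c("logistic", "fisher_pooled"),
                      overdispersion = c("MN", "none")) {
  method <- match.arg(method)
  overdispersion <- match.arg(overdispersion)
  u <- if (is.data.frame(callsets)) callsets else unite_callsets(callsets)
  groups <- attr(u, "groups")
  cc <- cov_cols(u); mc <- meth_cols(u)
  ctrl <- which(groups == "control"); mut <- which(groups == "mutant")
  s <- data.table::data.table(
    chrom = u$chrom, pos = u$pos, strand = u$strand,
    ctrl_meth = Reduce(`+`, as.list(u[, mc[ctrl], with = FALSE])),
    ctrl_cov  = Reduce(`+`, as.list(u[, cc[ctrl], with = FALSE])),
    mut_meth  = Reduce(`+`, as.list(u[, mc[mut], with = FALSE])),
    mut_cov   = Reduce(`+`, as.list(u[, cc[mut], with = FALSE])))
  s[, tested := ctrl_cov >= min_cov & mut_cov >= min_cov]
  s[, `:=`(p = NA_real_, diff = NA_real_,
           pct_control = ifelse(ctrl_cov > 0, 100 * ctrl_meth / ctrl_cov, NA_real_),
           pct_mutant  = ifelse(mut_cov > 0, 100 * mut_meth / mut_cov, NA_real_))]
  if (any(s$tested)) {
    res <- test_tile(s$ctrl_meth[s$tested], s$ctrl_cov[s$tested],
                     s$mut_meth[s$tested], s$mut_cov[s$tested], method)
    if (method == "logistic" && overdispersion == "MN" && length(mc) >= 3) {
      wide <- cbind(s[s$tested, c("ctrl_meth", "ctrl_cov", "mut_meth",
                                  "mut_cov")],
                    u[s$tested, c(mc, cc), with = FALSE])
      phi <- estimate_phi(wide, groups)
      res$p <- moderated_p(res$p, phi)
    }
    s[tested == TRUE, `:=`(p = res$p, diff = res$diff)]
  }
  s[, q := NA_real_]
  s[tested == TRUE, q := stats::p.adjust(p, method = "BH")]
  s[, dmc := tested & !is.na(q) & q < q_threshold & abs(diff) >= min_diff]
  s[, direction := ifelse(dmc, ifelse(diff < 0, "hypo", "hyper"), NA_character_)]
  list(sites = s[], dmcs = s[dmc == TRUE])
}

#' Merge proximal same-direction DMCs into DMRs
#'
#' Transitive single-linkage merge: consecutive DMCs on the same chromosome
#' whose positions are at most `gap` bp apart (inclusive) join one cluster.
#' Clusters of two or more DMCs become DMRs; singleton clusters are the
#' "single CpG" set.  DMR span follows the first-to-last member convention:
#' `start = first member position, end = last member position`, so
#' `size = end - start` bp.
#'
#' @param dmcs DMC table (needs `chrom, pos, diff`; a `direction` column is
#'   checked for homogeneity).  Mixed hypo/hyper input is an error: split by
#'   direction first.
#' @param gap Maximum distance between consecutive members (default 100 bp,
#'   inclusive).
#' @param direction Expected direction; used for validation and labeling.
#' @return `list(dmrs = data.table(chrom, start, end, n_dmcs, mean_diff,
#'   size), singles = data.table of singleton DMCs)`.
#' @export
merge_dmcs <- function(dmcs, gap = 100L, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  dmcs <- data.table::as.data.table(dmcs)
  if (nrow(dmcs) && "direction" %in% names(dmcs)) {
    dirs <- unique(dmcs$direction)
    if (length(dirs) > 1)
      stopf("merge_dmcs: mixed directions (%s); split by direction first",
            paste(dirs, collapse = ", "))
    if (length(dirs) == 1 && !is.na(dirs) && dirs != direction)
      stopf("merge_dmcs: input direction %s does not match requested %s",
            dirs, direction)
  }
  empty_dmrs <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_dmcs = integer(), mean_diff = numeric(), size = integer())
  if (nrow(dmcs) == 0)
    return(list(dmrs = empty_dmrs, singles = dmcs))
  if (!"diff" %in% names(dmcs)) dmcs[, diff := NA_real_]
  dmcs <- dmcs[order(chrom, pos)]
  n <- nrow(dmcs)
  brk <- c(TRUE, dmcs$chrom[-1] != dmcs$chrom[-n] |
                 dmcs$pos[-1] - dmcs$pos[-n] > gap)
  dmcs[, cluster := cumsum(brk)]
  cl <- dmcs[, .(chrom = chrom[1], start = pos[1], end = pos[.N],
                 n_dmcs = .N,
                 mean_diff = mean(diff)), by = cluster]
  cl[, size := end - start]
  dmrs <- cl[n_dmcs >= 2L,
             .(chrom, start = as.integer(start), end = as.integer(end),
               n_dmcs, mean_diff, size = as.integer(size))]
  single_ids <- cl[n_dmcs == 1L, cluster]
  singles <- dmcs[cluster %in% single_ids][, cluster := NULL]
  dmcs[, cluster := NULL]
  data.table::setorder(dmrs, chrom, start)
  list(dmrs = dmrs[], singles = singles[])
}

#' Partition DMRs into size classes
#'
#' @param dmrs DMR table from [merge_dmcs()].
#' @param cut Size cut in bp (default 100); a DMR of exactly `cut` bp falls
#'   in the lower class ("equal to or smaller").
#' @return `list(counts = c(small, large), cut, sizes, max_size)`.
#' @export
size_classes <- function(dmrs, cut = 100L) {
  sizes <- if (nrow(dmrs)) dmrs$size else integer()
  counts <- c(small = sum(sizes <= cut), large = sum(sizes > cut))
  list(counts = counts, cut = cut, sizes = sizes,
       max_size = if (length(sizes)) max(sizes) else NA_integer_)
}

#' Pearson chi-square comparing two cohorts' size-class tables
#'
#' Textbook (uncorrected) chi-square on the 2x2 table of
#' {<=cut, >cut} x {cohort A, cohort B}.
#'
#' @param a,b Outputs of [size_classes()].
#' @return `list(statistic, p)`.
#' @export
size_class_chisq <- function(a, b) {
  tab <- rbind(a$counts, b$counts)
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}
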