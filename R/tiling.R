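# Tile-based differential methylation: 100 bp non-overlapping windows,
# per-CpG coverage filtering, group test, BH correction, DMT calling.

#' Unite call sets from two groups onto a common site table
#'
#' Full outer join of all samples on (chrom, pos, strand); sites absent in a
#' sample get coverage 0 there (which makes them ineligible under per-sample
#' coverage filters).
#'
#' @param callsets List of `callset` objects; each must carry a `group`
#'   attribute of `"control"` or `"mutant"`, and both groups must be present.
#' @return A `data.table` with columns `chrom, pos, strand`, then
#'   `meth_<i>`/`cov_<i>` per sample, with attributes `groups` (character
#'   vector per sample) and `sample_ids`.
#' @export
unite_callsets <- function(callsets) {
  stopifnot(length(callsets) >= 2)
  groups <- vapply(callsets, function(x) attr(x, "group"), character(1))
  if (!all(c("control", "mutant") %in% groups))
    stopf("unite_callsets: need samples in both groups")
  tabs <- lapply(seq_along(callsets), function(i) {
    dt <- data.table::as.data.table(callsets[[i]])[
      , c("chrom", "pos", "strand", "meth", "cov")]
    data.table::setnames(dt, c("meth", "cov"),
                         c(sprintf("meth_%d", i), sprintf("cov_%d", i)))
    dt
  })
  u <- Reduce(function(a, b)
    merge(a, b, by = c("chrom", "pos", "strand"), all = TRUE), tabs)
  for (cl in setdiff(names(u), c("chrom", "pos", "strand")))
    data.table::set(u, which(is.na(u[[cl]])), cl, 0L)
  data.table::setorder(u, chrom, pos, strand)
  data.table::setattr(u, "groups", unname(groups))
  data.table::setattr(u, "sample_ids",
                      vapply(callsets, function(x)
                        as.character(attr(x, "sample_id") %||% ""), character(1)))
  u[]
}

#' Assign CpG sites to fixed non-overlapping tiles
#'
#' A CpG at 1-based position p belongs to the window
#' `[floor((p-1)/size)*size, +size)` (0-based half-open).  Only
#' `step == tile_size` (non-overlapping stepwise windows) is supported.
#'
#' @param callsets List of `callset` objects (both groups), or an already
#'   united site table from [unite_callsets()].
#' @param tile_size Window width in bp (default 100).
#' @param step Window step; must equal `tile_size`.
#' @return The united site table with an added `tile_start` column; class
#'   `"tile_sites"`, tile size stored as attribute.
#' @export
build_tiles <- function(callsets, tile_size = 100L, step = tile_size) {
  if (step != tile_size)
    stopf("build_tiles: only non-overlapping windows (step == tile_size) are supported")
  u <- if (is.data.frame(callsets)) callsets else unite_callsets(callsets)
  u <- data.table::copy(u)
  u[, tile_start := as.integer(floor((pos - 1L) / tile_size) * tile_size)]
  data.table::setattr(u, "tile_size", as.integer(tile_size))
  data.table::setattr(u, "class", unique(c("tile_sites", class(u))))
  u[]
}

cov_cols  <- function(u) grep("^cov_",  names(u), value = TRUE)
meth_cols <- function(u) grep("^meth_", names(u), value = TRUE)

#' Filter tiles on CpG count and per-sample coverage
#'
#' A CpG is eligible iff its coverage is at least `min_cov` in every sample
#' of both groups; a tile is retained iff it holds at least `min_cpgs`
#' eligible CpGs.  Pooled group counts are accumulated over eligible CpGs
#' only.
#'
#' @param tiles `tile_sites` from [build_tiles()].
#' @param min_cpgs Minimum eligible CpGs per tile (default 2).
#' @param min_cov Minimum per-sample coverage per CpG (default 10).
#' @return Tile-level `data.table` (class `"tiles"`): `chrom, start, end,
#'   n_cpgs`, pooled `ctrl_meth, ctrl_cov, mut_meth, mut_cov`.
#' @export
filter_tiles <- function(tiles, min_cpgs = 2L, min_cov = 10L) {
  groups <- attr(tiles, "groups")
  tile_size <- attr(tiles, "tile_size") %||% 100L
  cc <- cov_cols(tiles)
  mc <- meth_cols(tiles)
  eligible <- Reduce(`&`, lapply(cc, function(cl) tiles[[cl]] >= min_cov))
  el <- tiles[eligible]
  if (nrow(el) == 0) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_cpgs = integer(),
                                  ctrl_meth = integer(), ctrl_cov = integer(),
                                  mut_meth = integer(), mut_cov = integer())
  } else {
    ctrl <- which(groups == "control"); mut <- which(groups == "mutant")
    # per-sample tile sums are kept: the overdispersion correction needs
    # the replicate scatter, not just the pooled 2x2
    out <- el[, c(list(n_cpgs = .N), lapply(.SD, sum)),
              by = .(chrom, start = tile_start), .SDcols = c(mc, cc)]
    out[, `:=`(
      ctrl_meth = Reduce(`+`, .SD[, mc[ctrl], with = FALSE]),
      ctrl_cov  = Reduce(`+`, .SD[, cc[ctrl], with = FALSE]),
      mut_meth  = Reduce(`+`, .SD[, mc[mut], with = FALSE]),
      mut_cov   = Reduce(`+`, .SD[, cc[mut], with = FALSE]))]
    out <- out[n_cpgs >= min_cpgs]
    out[, end := start + tile_size]
    data.table::setcolorder(out, c("chrom", "start", "end", "n_cpgs"))
    data.table::setorder(out, chrom, start)
  }
  data.table::setattr(out, "groups", groups)
  data.table::setattr(out, "tile_size", tile_size)
  data.table::setattr(out, "class", unique(c("tiles", class(out))))
  out[]
}

#' Likelihood-ratio (logistic) test for a group effect on methylation
#'
#' The binomial GLM with a group indicator as the only covariate has
#' closed-form maximum-likelihood fits (the pooled per-group proportions),
#' so the likelihood-ratio statistic against the no-group-effect null
#' reduces to a G-statistic on the pooled 2x2 table; p from chi-square with
#' 1 df.  Identical to `anova(glm(cbind(meth, cov - meth) ~ group,
#' family = binomial), test = "Chisq")` applied per sample.
#'
#' @param m1,c1 Pooled methylated / total counts, group 1 (control).
#' @param m2,c2 Pooled methylated / total counts, group 2 (mutant).
#' @return Vector of p-values (NA where a group has zero total coverage).
#' @export
meth_lrt_test <- function(m1, c1, m2, c2) {
  p <- rep(NA_real_, length(m1))
  ok <- c1 > 0 & c2 > 0
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  p1 <- m1 / c1; p2 <- m2 / c2
  p0 <- (m1 + m2) / (c1 + c2)
  ll <- function(m, c, pr) xlogy(m, pr) + xlogy(c - m, 1 - pr)
  lrt <- 2 * (ll(m1, c1, p1) + ll(m2, c2, p2) -
              ll(m1, c1, p0) - ll(m2, c2, p0))
  lrt <- pmax(lrt, 0)
  p[ok] <- stats::pchisq(lrt[ok], df = 1, lower.tail = FALSE)
  p
}

#' Two-sided Fisher exact test on pooled counts
#' @inheritParams meth_lrt_test
#' @return Vector of two-sided p-values (NA where a group is uncovered).
#' @export
meth_fisher_test <- function(m1, c1, m2, c2) {
  n <- length(m1)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (c1[i] > 0 && c2[i] > 0) {
      tab <- matrix(c(m1[i], c1[i] - m1[i], m2[i], c2[i] - m2[i]), nrow = 2)
      p[i] <- stats::fisher.test(tab)$p.value
    }
  }
  p
}

#' Test one tile's pooled counts for a group difference
#'
#' @param ctrl_meth,ctrl_cov,mut_meth,mut_cov Pooled counts.
#' @param method `"logistic"` (likelihood-ratio; the default, appropriate
#'   with replicates) or `"fisher_pooled"` (exact test on the pooled 2x2).
#' @return `list(p = , diff = )` with `diff = 100 * (mutant - control)`
#'   proportion difference in percentage points; `p` is `NA` (not tested)
#'   if a group has zero coverage.
#' @export
test_tile <- function(ctrl_meth, ctrl_cov, mut_meth, mut_cov,
                      method = c("logistic", "fisher_pooled")) {
  method <- match.arg(method)
  p <- if (method == "logistic")
    meth_lrt_test(ctrl_meth, ctrl_cov, mut_meth, mut_cov)
  else meth_fisher_test(ctrl_meth, ctrl_cov, mut_meth, mut_cov)
  diff <- ifelse(ctrl_cov > 0 & mut_cov > 0,
                 100 * (mut_meth / mut_cov - ctrl_meth / ctrl_cov), NA_real_)
  list(p = p, diff = diff)
}

# Per-row McCullagh-Nelder dispersion factor from replicate scatter around
# the fitted group proportions.  The raw per-row estimate X2 / (n - 2) has
# few degrees of freedom, so it is shrunk toward the dataset-wide common
# dispersion sum(X2) / sum(df) with d0 prior df (the within-group scatter
# is unaffected by true group differences, so signal rows do not
# contaminate the common value).  Floored at 1.
estimate_phi <- function(dt, groups, d0 = 20) {
  mc <- meth_cols(dt); cc <- cov_cols(dt)
  if (length(mc) < 3) return(rep(1, nrow(dt)))
  p_ctrl <- ifelse(dt$ctrl_cov > 0, dt$ctrl_meth / dt$ctrl_cov, NA_real_)
  p_mut  <- ifelse(dt$mut_cov > 0, dt$mut_meth / dt$mut_cov, NA_real_)
  x2 <- numeric(nrow(dt)); used <- integer(nrow(dt))
  for (i in seq_along(mc)) {
    pg <- if (groups[i] == "control") p_ctrl else p_mut
    m <- dt[[mc[i]]]; cv <- dt[[cc[i]]]
    denom <- cv * pg * (1 - pg)
    ok <- !is.na(pg) & cv > 0 & denom > 0
    x2 <- x2 + ifelse(ok, (m - cv * pg)^2 / denom, 0)
    used <- used + as.integer(ok)
  }
  df <- pmax(used - 2L, 0L)
  phi_common <- if (sum(df) > 0) sum(x2) / sum(df) else 1
  phi <- pmax(1, (d0 * phi_common + x2) / (d0 + df))
  # effective df of the shrunk estimator (Satterthwaite): the common part
  # is estimated from all rows and contributes almost no variance, so
  # var(phi_shrunk) ~ (df / (d0 + df))^2 var(phi_raw)
  attr(phi, "df2") <- (d0 + df)^2 / pmax(df, 1)
  phi
}

# moderated p-value: LRT / phi against F(1, df2) since phi is estimated,
# not known (chi-square would be anticonservative in the far tail)
moderated_p <- function(p_raw, phi) {
  lrt <- stats::qchisq(p_raw, df = 1, lower.tail = FALSE)
  ifelse(is.na(p_raw), NA_real_,
         stats::pf(lrt / phi, df1 = 1, df2 = attr(phi, "df2"),
                   lower.tail = FALSE))
}

#' Test all tiles and attach p, diff and group percentages
#'
#' With `overdispersion = "MN"` (the default for the logistic method when
#' per-sample columns are present), the likelihood-ratio statistic is
#' scaled by a McCullagh-Nelder dispersion factor estimated from the
#' replicate scatter, which restores type-I control under beta-binomial
#' counts; `"none"` gives the plain LRT.
#'
#' @param tiles Output of [filter_tiles()].
#' @param method See [test_tile()].
#' @param overdispersion `"MN"` or `"none"`.
#' @return `tiles` with added `pct_control, pct_mutant, diff, p, status`
#'   (`"tested"` / `"not_tested"`).
#' @export
test_tiles <- function(tiles, method = c("logistic", "fisher_pooled"),
                       overdispersion = c("MN", "none")) {
  method <- match.arg(method)
  overdispersion <- match.arg(overdispersion)
  tiles <- data.table::copy(tiles)
  res <- test_tile(tiles$ctrl_meth, tiles$ctrl_cov,
                   tiles$mut_meth, tiles$mut_cov, method)
  if (method == "logistic" && overdispersion == "MN" &&
      length(meth_cols(tiles)) >= 3) {
    phi <- estimate_phi(tiles, attr(tiles, "groups"))
    res$p <- moderated_p(res$p, phi)
  }
  tiles[, `:=`(
    pct_control = ifelse(ctrl_cov > 0, 100 * ctrl_meth / ctrl_cov, NA_real_),
    pct_mutant  = ifelse(mut_cov > 0, 100 * mut_meth / mut_cov, NA_real_),
    diff = res$diff, p = res$p,
    status = ifelse(is.na(res$p), "not_tested", "tested"))]
  tiles[]
}

#' Call differentially methylated tiles (DMTs)
#'
#' Benjamini-Hochberg correction is applied jointly over all tested tiles
#' of all chromosomes; a tile is a DMT iff `q < q_threshold` and
#' `|diff| >= min_diff`.  Direction is `"hypo"` for negative `diff`
#' (mutant below control) and `"hyper"` otherwise.
#'
#' @param tiles Output of [test_tiles()] (or [filter_tiles()], in which
#'   case testing is run with `method`).
#' @param q_threshold FDR threshold (default 0.01).
#' @param min_diff Minimum absolute difference in percentage points
#'   (default 10).
#' @param method Test used if `tiles` lacks p-values.
#' @return `list(tiles = all tested tiles with q, dmt flag, direction;
#'   dmts = the DMT subset)`.
#' @export
call_dmts <- function(tiles, q_threshold = 0.01, min_diff = 10,
                      method = c("logistic", "fisher_pooled")) {
  if (!"p" %in% names(tiles)) tiles <- test_tiles(tiles, method)
  tiles <- data.table::copy(tiles)
  tested <- tiles$status == "tested"
  if (!any(tested)) {
    warnf("call_dmts: no tested tiles")
    tiles[, `:=`(q = NA_real_, dmt = FALSE, direction = NA_character_)]
    return(list(tiles = tiles[], dmts = tiles[dmt == TRUE]))
  }
  tiles[, q := NA_real_]
  tiles[status == "tested", q := stats::p.adjust(p, method = "BH")]
  tiles[, dmt := !is.na(q) & q < q_threshold & abs(diff) >= min_diff]
  tiles[, direction := ifelse(dmt, ifelse(diff < 0, "hypo", "hyper"),
                              NA_character_)]
  list(tiles = tiles[], dmts = tiles[dmt == TRUE])
}

#' Histogram of DMT effect magnitudes
#'
#' Bins `|diff|` with lower edge inclusive, upper exclusive, into the
#' standard magnitude classes.
#'
#' @param dmts DMT table with a `diff` column.
#' @param breaks Bin edges (default `c(10, 15, 20, 25, 30, 40, Inf)`).
#' @return Named integer vector of counts; sums to `nrow(dmts)`.
#' @export
magnitude_histogram <- function(dmts, breaks = c(10, 15, 20, 25, 30, 40, Inf)) {
  labels <- vapply(seq_len(length(breaks) - 1), function(i) {
    if (is.infinite(breaks[i + 1])) sprintf(">%g", breaks[i])
    else sprintf("%g-%g", breaks[i], breaks[i + 1])
  }, character(1))
  counts <- stats::setNames(integer(length(labels)), labels)
  if (nrow(dmts) == 0) return(counts)
  a <- abs(dmts$diff)
  idx <- findInterval(a, breaks, left.open = FALSE)  # lower edge inclusive
  idx <- idx[idx >= 1 & idx <= length(labels)]
  tab <- table(factor(idx, levels = seq_along(labels)))
  counts[] <- as.integer(tab)
  counts
}
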