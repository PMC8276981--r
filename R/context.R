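# Annotation of regions to genomic elements, CpG-island context and
# repeats; enrichment against the all-sequenced background; young-LINE and
# DNMT3C-sensitivity rules.

#' The young L1Md LINE-1 subfamilies used by default
#'
#' The eight evolutionarily young mouse LINE-1 (L1Md) subfamilies whose
#' expression responds to loss of DNMT3C; used as the default "young" list
#' when flagging repeats.
#' @return Character vector of subfamily names.
#' @export
young_l1md_subfamilies <- function() {
  c("L1MdA_I", "L1MdTf_I", "L1MdTf_II", "L1MdA_II",
    "L1MdGf_I", "L1MdTf_III", "L1MdGf_II", "L1MdA_III")
}

element_levels <- function() {
  c("promoter", "TTS", "5UTR", "3UTR", "exon", "intron",
    "noncoding", "intergenic")
}

#' Annotate regions to genomic elements by midpoint
#'
#' The region midpoint is assigned by fixed precedence
#' promoter > TTS > 5UTR > 3UTR > exon > intron > noncoding > intergenic.
#' Promoter is TSS +/- `promoter_window`; the terminator window is
#' TTS +/- `tts_window`.
#'
#' @param query Interval table (`chrom, start, end`, 0-based half-open).
#' @param bundle An annotation bundle (list) with `genes` (columns `chrom,
#'   start, end, strand, tss, tts, coding`), `exons`, and optional `utr5`,
#'   `utr3` interval tables; non-coding gene bodies are labeled
#'   `noncoding`.
#' @param promoter_window,tts_window Half-widths in bp (default 1000).
#' @return Factor of element labels, one per query region.
#' @export
annotate_elements <- function(query, bundle, promoter_window = 1000L,
                              tts_window = 1000L) {
  query <- data.table::as.data.table(query)
  n <- nrow(query)
  lab <- rep("intergenic", n)
  if (n == 0) return(factor(lab, levels = element_levels()))
  mid <- floor((query$start + query$end) / 2)  # 0-based point
  pts <- data.table::data.table(chrom = query$chrom, start = mid,
                                end = mid + 1L)
  g <- bundle$genes
  hit_any <- function(feat) {
    res <- rep(FALSE, n)
    if (is.null(feat) || nrow(feat) == 0) return(res)
    h <- GenomicRanges::findOverlaps(as_gr(pts), as_gr(feat))
    res[unique(S4Vectors::queryHits(h))] <- TRUE
    res
  }
  coding <- if (!is.null(g) && nrow(g)) g[g$coding %||% TRUE == TRUE] else g
  nonc   <- if (!is.null(g) && nrow(g)) g[!(g$coding %||% TRUE)] else g
  win <- function(center, w)
    data.table::data.table(chrom = g$chrom,
                           start = pmax(0L, as.integer(center - w)),
                           end = as.integer(center + w + 1L))
  in_prom <- if (!is.null(g) && nrow(g)) hit_any(win(g$tss, promoter_window)) else rep(FALSE, n)
  in_tts  <- if (!is.null(g) && nrow(g)) hit_any(win(g$tts, tts_window)) else rep(FALSE, n)
  in_u5   <- hit_any(bundle$utr5)
  in_u3   <- hit_any(bundle$utr3)
  in_ex   <- hit_any(bundle$exons)
  in_gene <- hit_any(coding)
  in_nc   <- hit_any(nonc)
  lab[in_nc]   <- "noncoding"
  lab[in_gene] <- "intron"   # refined below by exon/UTR hits
  lab[in_ex]   <- "exon"
  lab[in_u3]   <- "3UTR"
  lab[in_u5]   <- "5UTR"
  lab[in_tts]  <- "TTS"
  lab[in_prom] <- "promoter"
  factor(lab, levels = element_levels())
}

#' CpG-island context of regions
#'
#' Distance is measured from region edges to the nearest island edge:
#' `island` for positive overlap, `shore` for 1-2000 bp, `shelf` for
#' 2001-4000 bp, `open_sea` beyond 4 kb.
#'
#' @param query Interval table (0-based half-open).
#' @param cgis CpG island interval table.
#' @param shore_max,shelf_max Outer distance bounds in bp for shore
#'   (default 2000) and shelf (default 4000); open sea lies beyond.
#' @return `data.table(label, distance)`; `distance` is `NA` when no island
#'   exists on any chromosome.
#' @export
cgi_context <- function(query, cgis, shore_max = 2000L, shelf_max = 4000L) {
  query <- data.table::as.data.table(query)
  n <- nrow(query)
  out <- data.table::data.table(label = rep("open_sea", n),
                                distance = rep(NA_integer_, n))
  if (n == 0) {
    out[, label := factor(label, levels = c("island", "shore", "shelf", "open_sea"))]
    return(out[])
  }
  if (is.null(cgis) || nrow(cgis) == 0) {
    out[, label := factor(label, levels = c("island", "shore", "shelf", "open_sea"))]
    return(out[])
  }
  qg <- as_gr(query); ig <- as_gr(cgis)
  d <- suppressWarnings(GenomicRanges::distanceToNearest(qg, ig))
  dist <- rep(NA_integer_, n)
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  lab <- ifelse(is.na(dist), "open_sea",
         ifelse(dist == 0, NA, # resolved below: overlap vs adjacency
         ifelse(dist <= shore_max, "shore",
         ifelse(dist <= shelf_max, "shelf", "open_sea"))))
  # distance 0 from IRanges means overlapping OR bookended; only a positive
  # overlap is "island", a bookended neighbour is a shore at distance 0
  zero <- which(!is.na(dist) & dist == 0)
  if (length(zero)) {
    ovl <- GenomicRanges::countOverlaps(qg[zero], ig, minoverlap = 1L) > 0
    lab[zero] <- ifelse(ovl, "island", "shore")
  }
  out[, `:=`(label = factor(lab, levels = c("island", "shore", "shelf", "open_sea")),
             distance = as.integer(dist))]
  out[]
}

# per-region repeat class by maximal overlap, leftmost tie-break
region_repeat_class <- function(regions, repeats,
                                classes = c("LINE", "SINE", "LTR")) {
  regions <- data.table::as.data.table(regions)
  n <- nrow(regions)
  lab <- rep("none", n)
  if (n == 0 || is.null(repeats) || nrow(repeats) == 0) return(lab)
  repeats <- data.table::as.data.table(repeats)
  h <- GenomicRanges::findOverlaps(as_gr(regions), as_gr(repeats))
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  if (length(qi)) {
    ov <- pmin(regions$end[qi], repeats$end[si]) -
          pmax(regions$start[qi], repeats$start[si])
    pr <- data.table::data.table(q = qi, s = si, ov = ov,
                                 rstart = repeats$start[si])
    pr <- pr[ov > 0]
    data.table::setorder(pr, q, -ov, rstart)
    best <- pr[, .SD[1], by = q]
    cls <- repeats$class[best$s]
    cls[!cls %in% classes] <- "other"
    lab[best$q] <- cls
  }
  lab
}

# textbook uncorrected 2x2 chi-square on counts (k in n) fg vs bg
enrichment_chisq <- function(k_fg, n_fg, k_bg, n_bg) {
  tab <- matrix(c(k_fg, n_fg - k_fg, k_bg, n_bg - k_bg), nrow = 2,
                byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fg <- k_fg / n_fg; bg <- k_bg / n_bg
  list(fg_prop = fg, bg_prop = bg,
       statistic = unname(ct$statistic), p = unname(ct$p.value),
       fold = if (bg > 0) fg / bg else Inf)
}

#' Repeat-class composition of regions with enrichment vs background
#'
#' Each region is assigned to the repeat class of maximal overlap (at least
#' 1 bp; `none` if no repeat overlaps); per class an uncorrected chi-square
#' on the 2x2 (in-class vs not, foreground vs background) quantifies
#' enrichment against the all-sequenced background regions.
#'
#' @param regions Foreground interval table (e.g. hypomethylated DMRs).
#' @param repeats Repeat table with a `class` column (LINE/SINE/LTR/...).
#' @param background Background interval table (all sequenced regions);
#'   required for enrichment.
#' @return `list(classes = per-region labels, proportions = named fg
#'   proportions, enrichment = per-class EnrichmentResult or NULL)`.
#' @export
repeat_composition <- function(regions, repeats, background = NULL) {
  lv <- c("LINE", "SINE", "LTR", "other", "none")
  fg <- region_repeat_class(regions, repeats)
  props <- prop.table(table(factor(fg, levels = lv)))
  if (is.null(repeats) || nrow(data.table::as.data.table(repeats)) == 0) {
    warnf("repeat_composition: no repeats supplied; enrichment skipped")
    return(list(classes = fg, proportions = props, enrichment = NULL))
  }
  if (is.null(background) || nrow(data.table::as.data.table(background)) == 0)
    stopf("repeat_composition: enrichment requires a non-empty background")
  bg <- region_repeat_class(background, repeats)
  n_fg <- length(fg); n_bg <- length(bg)
  enr <- lapply(setdiff(lv, "none"), function(cl)
    enrichment_chisq(sum(fg == cl), n_fg, sum(bg == cl), n_bg))
  names(enr) <- setdiff(lv, "none")
  list(classes = fg, proportions = props, enrichment = enr)
}

#' Enrichment of regions in young LINE subfamilies
#'
#' Foreground = fraction of regions overlapping (>=1 bp) a repeat whose
#' subfamily is in `young_list`; compared with the same fraction over the
#' all-sequenced background by uncorrected chi-square.
#'
#' @param regions Foreground intervals.
#' @param repeats Repeat table with `subfamily` column.
#' @param background Background intervals.
#' @param young_list Young subfamily names (default the eight L1Md
#'   subfamilies); unknown names simply never match.
#' @return EnrichmentResult list: `fg_prop, bg_prop, statistic, p, fold`.
#' @export
young_line_overlap <- function(regions, repeats, background,
                               young_list = young_l1md_subfamilies()) {
  repeats <- data.table::as.data.table(repeats)
  young <- repeats[repeats$subfamily %in% young_list]
  count_hit <- function(x) {
    x <- data.table::as.data.table(x)
    if (nrow(x) == 0 || nrow(young) == 0) return(c(0L, nrow(x)))
    k <- sum(GenomicRanges::countOverlaps(as_gr(x), as_gr(young)) > 0)
    c(k, nrow(x))
  }
  fg <- count_hit(regions); bg <- count_hit(background)
  if (bg[2] == 0) stopf("young_line_overlap: empty background")
  enrichment_chisq(fg[1], fg[2], bg[1], bg[2])
}

#' Select DNMT3C-sensitive repeat subfamilies by expression fold change
#'
#' Subfamilies with strictly more than `fold_threshold`-fold higher
#' expression in the knockout than in the control are returned.  The table
#' may carry a precomputed `fold` column, or `ko` and `control` expression
#' columns; subfamilies with non-positive control expression are skipped
#' with a warning.
#'
#' @param expression_table `data.frame` with `subfamily` and either `fold`
#'   or (`ko`, `control`) columns.
#' @param fold_threshold Strict fold-change threshold (default 5).
#' @return Character vector of sensitive subfamily names.
#' @export
dnmt3c_sensitive_subfamilies <- function(expression_table, fold_threshold = 5) {
  et <- data.table::as.data.table(expression_table)
  if (nrow(et) == 0) return(character())
  if (!"fold" %in% names(et)) {
    bad <- et$control <= 0
    if (any(bad)) {
      warnf("dnmt3c_sensitive_subfamilies: skipping %d subfamilies with non-positive control expression",
            sum(bad))
      et <- et[!bad]
    }
    et[, fold := ko / control]
  }
  et$subfamily[et$fold > fold_threshold]
}

#' Fraction of flank-extended regions overlapping a set of elements
#'
#' Each region is widened by `flank` bp on both sides (clipped at 0 and,
#' when `chrom_sizes` is supplied, at the chromosome end) before overlap
#' counting.
#'
#' @param regions Interval table.
#' @param elements Interval table to overlap against.
#' @param flank Extension in bp (default 1000); 0 is plain overlap.
#' @param chrom_sizes Named lengths; if supplied, every region chromosome
#'   must be present (error otherwise).
#' @return `list(n, k, prop, hits)` where `prop = k / n` and `hits` is the
#'   per-region logical.
#' @export
flanked_overlap <- function(regions, elements, flank = 1000L,
                            chrom_sizes = NULL) {
  regions <- data.table::as.data.table(regions)
  elements <- data.table::as.data.table(elements)
  n <- nrow(regions)
  if (n == 0) return(list(n = 0L, k = 0L, prop = NA_real_, hits = logical()))
  ext <- data.table::data.table(chrom = regions$chrom,
                                start = pmax(0L, regions$start - as.integer(flank)),
                                end = regions$end + as.integer(flank))
  if (!is.null(chrom_sizes)) {
    missing_chr <- setdiff(unique(ext$chrom), names(chrom_sizes))
    if (length(missing_chr))
      stopf("flanked_overlap: missing chrom size for %s", missing_chr[1])
    ext[, end := pmin(end, chrom_sizes[chrom])]
  }
  hits <- if (nrow(elements) == 0) rep(FALSE, n)
          else GenomicRanges::countOverlaps(as_gr(ext), as_gr(elements)) > 0
  list(n = n, k = sum(hits), prop = sum(hits) / n, hits = hits)
}
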