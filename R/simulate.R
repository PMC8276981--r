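# Synthetic-cohort generator: genome annotation, two-group RRBS-style
# beta-binomial count data with planted intergenerational epimutations,
# developmental methylation tracks, and histone ChIP read tracks.
#
# All generators are deterministic given config$seed; each derives its own
# child seed so the pieces can be regenerated independently.

#' Simulation configuration with field-realistic defaults
#'
#' Defaults encode the stated world the pipeline is validated against:
#' 100 bp tiles with >= 2 CpGs at 10x, planted hypomethylation effects of
#' 10-40 percentage points biased to intergenic/young-TE/late-methylating
#' sequence, a 0.84 cross-cohort shared fraction, 4 vs 4 samples at 30x
#' mean coverage, beta-binomial overdispersion rho = 0.05.
#'
#' @param seed Master RNG seed.
#' @param n_chroms,chrom_length Genome shape (default 2 x 1.5 Mb).
#' @param n_samples_per_group Samples per group (default 4).
#' @param mean_coverage Negative-binomial mean per-site coverage (default 30).
#' @param coverage_dispersion NB `size` parameter (default 8).
#' @param rho Beta-binomial intra-site correlation in `[0, 1)`
#'   (default 0.05; 0 gives pure binomial counts).
#' @param baseline Named baseline methylation percentages per context
#'   (`cgi`, `gene`, `repeat`, `intergenic`).
#' @param cpg_spacing Mean CpG spacing in bp within covered non-island
#'   fragments (default 25); island fragments use `cgi_spacing`
#'   (default 15).
#' @param cgi_spacing See `cpg_spacing`.
#' @param fragment_gap Mean gap between covered restriction fragments in
#'   bp (default 1800); with ~180 bp fragments this covers roughly 10% of
#'   the genome, emulating reduced-representation coverage.
#' @param n_planted Planted regions in cohort A (default 200).
#' @param planted_length Length range in bp (default c(200, 500)).
#' @param delta_range Hypomethylation effect range in percentage points
#'   (default c(10, 40)); `delta_fixed` overrides with one value.
#' @param delta_fixed Optional fixed effect size.
#' @param frac_hyper Fraction of plants that gain rather than lose
#'   methylation (default 0.02; the observed direction split is >99% hypo).
#' @param placement_bias Sampling weights over anchor categories
#'   `c(intergenic, young_te, late)` (default c(1, 3, 3)).
#' @param shared_fraction Probability a cohort-B plant is nested inside a
#'   cohort-A plant (default 0.84).
#' @param frac_late_background Fraction of non-planted intergenic anchors
#'   flagged late-methylating (default 0.15).
#' @param timepoints Developmental timepoint labels, in order.
#' @param traj_early,traj_late,traj_cgi Mean methylation trajectories (%)
#'   used by the developmental-track generator.
#' @param chip_enrichment Read-rate multiplier over late regions at the
#'   E16.5 analog (default 4).
#' @param chip_library Total ChIP reads per timepoint (default 2e5).
#' @param chip_read_length Read length in bp (default 50).
#' @return A named list (class `sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 1500000L,
                       n_samples_per_group = 4L,
                       mean_coverage = 30, coverage_dispersion = 8,
                       rho = 0.05,
                       baseline = c(cgi = 5, gene = 75, repeat. = 85,
                                    intergenic = 80),
                       cpg_spacing = 25L, cgi_spacing = 15L,
                       fragment_gap = 1800,
                       n_planted = 100L,
                       planted_length = c(200L, 500L),
                       delta_range = c(10, 40), delta_fixed = NULL,
                       frac_hyper = 0.02,
                       placement_bias = c(intergenic = 1, young_te = 3,
                                          late = 3),
                       shared_fraction = 0.84,
                       frac_late_background = 0.15,
                       timepoints = c("E13.5", "E16.5", "P0", "sperm"),
                       traj_early = c(30, 88, 95, 95),
                       traj_late = c(5, 10, 60, 85),
                       traj_cgi = c(3, 3, 3, 3),
                       chip_enrichment = 4,
                       chip_library = 200000L,
                       chip_read_length = 50L) {
  cfg <- as.list(environment())
  names(cfg$baseline) <- sub("^repeat\\.$", "repeat", names(cfg$baseline))
  stopifnot(cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$rho >= 0, cfg$rho < 1,
            all(cfg$delta_range > 0), all(cfg$delta_range < 100),
            length(cfg$timepoints) >= 3)
  class(cfg) <- "sim_config"
  cfg
}

# beta-binomial draws; rho = 0 degenerates to binomial
rbetabinom <- function(n, size, pi, rho) {
  pi <- pmin(pmax(pi, 1e-4), 1 - 1e-4)
  if (rho <= 0) return(stats::rbinom(n, size, pi))
  nu <- 1 / rho - 1
  p <- stats::rbeta(n, pi * nu, (1 - pi) * nu)
  stats::rbinom(n, size, p)
}

#' Simulate a genome annotation and ground-truth skeleton
#'
#' Lays out genes (with exons and UTRs), promoter and orphan CpG islands,
#' and repeat clusters (LINE/SINE/LTR/DNA, with a configurable young LINE
#' subfamily list) along each chromosome without overlap, places CpG sites
#' at context-dependent density, and records candidate anchor intervals for
#' planting epimutations.  Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return `list(bundle = annotation bundle, candidates = anchor table)`;
#'   the bundle holds `genes, exons, utr5, utr3, cgis, repeats,
#'   chrom_sizes, cpg_sites` (per-site context, timing and baseline
#'   methylation).
#' @export
simulate_annotation <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  young <- young_l1md_subfamilies()
  old_lines <- c("L1_Mus3", "L1VL1", "Lx8", "L1M2")
  genes <- list(); exons <- list(); u5 <- list(); u3 <- list()
  cgis <- list(); repeats <- list(); anchors <- list()
  if (config$chrom_length < 50000L)
    stopf("simulate_annotation: chromosomes shorter than 50 kb cannot host the feature layout")
  for (ci in seq_len(config$n_chroms)) {
    ch <- sprintf("chr%d", ci)
    pos <- 2000L
    L <- config$chrom_length
    while (pos + 15000L < L) {
      u <- stats::runif(1)
      if (u < 0.30) {                       # gene block
        glen <- as.integer(round(stats::runif(1, 4000, 9000)))
        strand <- sample(c("+", "-"), 1)
        coding <- stats::runif(1) > 0.1
        tss <- if (strand == "+") pos else pos + glen
        tts <- if (strand == "+") pos + glen else pos
        genes[[length(genes) + 1]] <- data.table::data.table(
          chrom = ch, start = pos, end = pos + glen, strand = strand,
          tss = tss, tts = tts, coding = coding,
          name = sprintf("gene_%s_%d", ch, pos))
        if (coding) {
          nex <- sample(3:5, 1)
          estart <- as.integer(seq(pos, pos + glen - 400L, length.out = nex))
          elen <- as.integer(round(stats::runif(nex, 150, 300)))
          exons[[length(exons) + 1]] <- data.table::data.table(
            chrom = ch, start = estart, end = estart + elen)
          u5[[length(u5) + 1]] <- data.table::data.table(
            chrom = ch, start = estart[1], end = estart[1] + 80L)
          u3[[length(u3) + 1]] <- data.table::data.table(
            chrom = ch, start = estart[nex] + elen[nex] - 120L,
            end = estart[nex] + elen[nex])
        }
        if (stats::runif(1) < 0.6)          # promoter island
          cgis[[length(cgis) + 1]] <- data.table::data.table(
            chrom = ch, start = max(0L, tss - 500L), end = tss + 500L,
            name = sprintf("CGI_%s_%d", ch, pos))
        pos <- pos + glen + as.integer(round(stats::runif(1, 1000, 3000)))
      } else if (u < 0.70) {                # repeat cluster in intergenic
        nrep <- sample(2:4, 1)
        for (k in seq_len(nrep)) {
          rlen <- as.integer(round(stats::runif(1, 400, 1500)))
          cls <- sample(c("LINE", "SINE", "LTR", "DNA"), 1,
                        prob = c(0.4, 0.3, 0.2, 0.1))
          if (cls == "LINE") {
            fam <- "L1"
            isyoung <- stats::runif(1) < 0.35
            sub <- if (isyoung) sample(young, 1) else sample(old_lines, 1)
          } else if (cls == "SINE") {
            fam <- sample(c("B1", "B2"), 1); sub <- paste0(fam, "_Mus1")
            isyoung <- FALSE
          } else if (cls == "LTR") {
            fam <- "ERVK"; sub <- "IAPEz-int"; isyoung <- FALSE
          } else {
            fam <- "hAT"; sub <- "Charlie1"; isyoung <- FALSE
          }
          repeats[[length(repeats) + 1]] <- data.table::data.table(
            chrom = ch, start = pos, end = pos + rlen,
            name = sub, class = cls, family = fam, subfamily = sub,
            young = isyoung)
          if (cls == "LINE" && isyoung)
            anchors[[length(anchors) + 1]] <- data.table::data.table(
              chrom = ch, start = pos, end = pos + rlen,
              category = "young_te")
          pos <- pos + rlen + as.integer(round(stats::runif(1, 300, 800)))
        }
      } else {                              # plain intergenic stretch
        glen <- as.integer(round(stats::runif(1, 3000, 7000)))
        if (stats::runif(1) < 0.12)         # orphan island
          cgis[[length(cgis) + 1]] <- data.table::data.table(
            chrom = ch, start = pos + 500L, end = pos + 500L +
              as.integer(round(stats::runif(1, 500, 1200))),
            name = sprintf("CGI_%s_%d", ch, pos))
        else {
          cat_lab <- if (stats::runif(1) < config$frac_late_background)
            "late" else "intergenic"
          anchors[[length(anchors) + 1]] <- data.table::data.table(
            chrom = ch, start = pos + 500L, end = pos + glen - 500L,
            category = cat_lab)
        }
        pos <- pos + glen + as.integer(round(stats::runif(1, 500, 1500)))
      }
    }
  }
  bind <- function(x, proto) if (length(x)) data.table::rbindlist(x) else proto
  empty_iv <- data.table::data.table(chrom = character(), start = integer(),
                                     end = integer())
  bundle <- list(
    genes = bind(genes, data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), tss = integer(), tts = integer(),
      coding = logical(), name = character())),
    exons = bind(exons, empty_iv), utr5 = bind(u5, empty_iv),
    utr3 = bind(u3, empty_iv),
    cgis = bind(cgis, data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      name = character())),
    repeats = bind(repeats, data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      name = character(), class = character(), family = character(),
      subfamily = character(), young = logical())),
    chrom_sizes = stats::setNames(
      rep(as.integer(config$chrom_length), config$n_chroms),
      sprintf("chr%d", seq_len(config$n_chroms))))
  candidates <- bind(anchors, data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    category = character()))
  bundle$cpg_sites <- place_cpgs(bundle, candidates, config)
  class(bundle) <- c("annotation_bundle", "list")
  list(bundle = bundle, candidates = candidates)
}

# RRBS-style CpG site placement: reads fall on CpG-dense restriction
# fragments, not genome-wide, so covered CpGs cluster in fragments of
# ~120-250 bp spaced ~2 kb apart, CpG islands are always covered, and the
# 5' end of every young LINE carries a fragment (their promoter monomers
# are CpG-rich).  Per-site context, timing class and baseline methylation
# are attached.
place_cpgs <- function(bundle, candidates, config) {
  set.seed(child_seed(config$seed, 2L))
  frag_gap <- config$fragment_gap %||% 1800
  frags <- list()
  for (ch in names(bundle$chrom_sizes)) {
    L <- bundle$chrom_sizes[[ch]]
    n_max <- ceiling(L / frag_gap) + 20
    gaps <- stats::rexp(n_max, 1 / frag_gap) + 150
    st <- as.integer(round(cumsum(gaps)))
    st <- st[st < L - 400L]
    len <- as.integer(round(stats::runif(length(st), 120, 250)))
    frags[[length(frags) + 1]] <-
      data.table::data.table(chrom = ch, start = st, end = st + len)
  }
  if (nrow(bundle$cgis))
    frags[[length(frags) + 1]] <- bundle$cgis[, .(chrom, start, end)]
  yl <- bundle$repeats[bundle$repeats$young == TRUE]
  if (nrow(yl))
    frags[[length(frags) + 1]] <-
      data.table::data.table(chrom = yl$chrom, start = yl$start,
                             end = pmin(yl$end, yl$start + 250L))
  fr <- data.table::rbindlist(frags)
  data.table::setorder(fr, chrom, start)
  in_cgi_frag <- GenomicRanges::countOverlaps(
    as_gr(fr), as_gr(bundle$cgis)) > 0
  sp <- ifelse(in_cgi_frag, config$cgi_spacing, config$cpg_spacing)
  s <- fr[, {
    i <- .I
    pos_list <- lapply(seq_len(.N), function(k) {
      p <- seq(start[k] + 3L, end[k] - 1L, by = sp[i[k]])
      as.integer(p + sample(-2:2, length(p), replace = TRUE))
    })
    list(pos = unlist(pos_list))
  }, by = chrom]
  s <- unique(s, by = c("chrom", "pos"))
  data.table::setorder(s, chrom, pos)
  pt <- data.table::data.table(chrom = s$chrom, start = s$pos - 1L,
                               end = s$pos)
  in_set <- function(iv) {
    res <- rep(FALSE, nrow(s))
    if (!is.null(iv) && nrow(iv)) {
      h <- GenomicRanges::findOverlaps(as_gr(pt), as_gr(iv))
      res[unique(S4Vectors::queryHits(h))] <- TRUE
    }
    res
  }
  ctx <- rep("intergenic", nrow(s))
  ctx[in_set(bundle$genes)] <- "gene"
  ctx[in_set(bundle$repeats)] <- "repeat"
  ctx[in_set(bundle$cgis)] <- "cgi"
  s[, context := ctx]
  late_anchor <- candidates[category %in% c("late", "young_te")]
  s[, timing := ifelse(context == "cgi", "cgi",
                       ifelse(in_set(late_anchor), "late", "early"))]
  s[, pi0 := config$baseline[ifelse(context %in% names(config$baseline),
                                    context, "intergenic")] / 100]
  s[, strand := "+"]
  s[]
}

#' Plant epimutated regions and build the ground truth
#'
#' Cohort A receives `n_planted` regions drawn from candidate anchors with
#' `placement_bias` weights; each cohort-B region is, with probability
#' `shared_fraction`, nested strictly inside a distinct cohort-A region,
#' otherwise placed on an unused anchor.  Effects are drawn from
#' `delta_range` (or `delta_fixed`), hypomethylating except for a
#' `frac_hyper` fraction.  Every planted region is guaranteed at least
#' three CpG sites.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config A [sim_config()].
#' @param cohorts Cohort labels; the first is the reference (A) cohort.
#' @return `data.table` of planted regions (`cohort, region_id, chrom,
#'   start, end, delta, direction, timing, young_te, nested_in`).
#' @export
plant_regions <- function(annotation, config, cohorts = c("F1", "F2")) {
  set.seed(child_seed(config$seed, 3L))
  cand <- data.table::copy(annotation$candidates)
  sites <- data.table::as.data.table(annotation$bundle$cpg_sites)
  # keep anchors able to host a region with >= 3 CpGs
  pt <- data.table::data.table(chrom = sites$chrom, start = sites$pos - 1L,
                               end = sites$pos)
  ncpg <- GenomicRanges::countOverlaps(as_gr(cand), as_gr(pt))
  cand <- cand[ncpg >= 3 & (end - start) >= config$planted_length[1]]
  if (nrow(cand) < config$n_planted)
    stopf("plant_regions: only %d usable anchors for %d requested plants; enlarge the genome",
          nrow(cand), config$n_planted)
  w <- c(intergenic = unname(config$placement_bias["intergenic"]),
         young_te = unname(config$placement_bias["young_te"]),
         late = unname(config$placement_bias["late"]))
  cand[, weight := w[category]]
  draw_delta <- function(n) {
    if (!is.null(config$delta_fixed)) rep(config$delta_fixed, n)
    else stats::runif(n, config$delta_range[1], config$delta_range[2])
  }
  site_pos <- split(sites$pos, sites$chrom)
  # window inside [a_start, a_end) guaranteed to contain >= 3 CpGs: anchor
  # a run of three consecutive sites and pad to the drawn length
  clip_region <- function(chrom, a_start, a_end) {
    cp <- site_pos[[chrom]]
    cp <- cp[cp > a_start & cp <= a_end]
    len <- min(as.integer(round(stats::runif(1, config$planted_length[1],
                                             config$planted_length[2]))),
               a_end - a_start)
    # prefer a triple of consecutive CpGs on one covered fragment
    span <- cp[-(1:2)] - cp[seq_len(length(cp) - 2L)]
    tight <- which(span <= 150L)
    i0 <- if (length(tight)) tight[sample.int(length(tight), 1)]
          else which.min(span)
    p1 <- cp[i0]; p3 <- cp[min(i0 + 2L, length(cp))]
    st <- max(a_start, p1 - 1L - sample.int(50L, 1))
    en <- max(min(a_end, st + len), min(a_end, p3 + 10L))
    c(as.integer(st), as.integer(en))
  }
  out <- list()
  idxA <- sample.int(nrow(cand), config$n_planted, prob = cand$weight)
  A <- cand[idxA]
  regA <- t(vapply(seq_len(nrow(A)), function(i)
    clip_region(A$chrom[i], A$start[i], A$end[i]), integer(2)))
  dirA <- ifelse(stats::runif(config$n_planted) < config$frac_hyper,
                 "hyper", "hypo")
  out[[1]] <- data.table::data.table(
    cohort = cohorts[1], region_id = sprintf("%s_%04d", cohorts[1],
                                             seq_len(config$n_planted)),
    chrom = A$chrom, start = regA[, 1], end = regA[, 2],
    delta = draw_delta(config$n_planted), direction = dirA,
    timing = "late", young_te = A$category == "young_te",
    nested_in = NA_character_)
  used <- idxA
  for (cb in cohorts[-1]) {
    nB <- config$n_planted
    shared <- stats::runif(nB) < config$shared_fraction
    donors <- sample.int(config$n_planted, nB, replace = FALSE)
    rows <- vector("list", nB)
    free <- setdiff(seq_len(nrow(cand)), used)
    fresh_pool <- sample(free, sum(!shared),
                         prob = cand$weight[free])
    fi <- 0L
    for (i in seq_len(nB)) {
      if (shared[i]) {
        a <- out[[1]][donors[i]]
        # shared plants mirror the observed taxonomy: a minority carry the
        # donor's exact coordinates, the rest nest inside it with modest
        # margins (so the shared tile footprint stays close to the donor's)
        if (stats::runif(1) < 0.4) {
          st <- a$start; en <- a$end
        } else {
          alen <- a$end - a$start
          st <- a$start + sample.int(max(1L, as.integer(0.15 * alen)), 1)
          en <- a$end - sample.int(max(1L, as.integer(0.15 * alen)), 1)
          cp <- site_pos[[a$chrom]]
          cp <- cp[cp > st & cp <= en]
          if (en - st < 60L || length(cp) < 1) { st <- a$start; en <- a$end }
        }
        rows[[i]] <- data.table::data.table(
          cohort = cb, region_id = sprintf("%s_%04d", cb, i),
          chrom = a$chrom, start = st, end = en, delta = a$delta,
          direction = a$direction, timing = "late",
          young_te = a$young_te, nested_in = a$region_id)
      } else {
        fi <- fi + 1L
        anc <- cand[fresh_pool[fi]]
        r <- clip_region(anc$chrom, anc$start, anc$end)
        rows[[i]] <- data.table::data.table(
          cohort = cb, region_id = sprintf("%s_%04d", cb, i),
          chrom = anc$chrom, start = r[1], end = r[2],
          delta = draw_delta(1),
          direction = ifelse(stats::runif(1) < config$frac_hyper,
                             "hyper", "hypo"),
          timing = "late", young_te = anc$category == "young_te",
          nested_in = NA_character_)
      }
    }
    used <- c(used, fresh_pool)
    out[[length(out) + 1]] <- data.table::rbindlist(rows)
  }
  truth <- data.table::rbindlist(out)
  # invariant: every plant holds >= 1 CpG (guaranteed >= 3 by anchor filter
  # only for full anchors; re-check after clipping)
  k <- GenomicRanges::countOverlaps(as_gr(truth), as_gr(pt))
  stopifnot(all(k >= 1))
  truth[]
}

#' Simulate two-group RRBS-style methylomes for one cohort
#'
#' Per-site coverage is negative-binomial; methylated counts are
#' beta-binomial around the site baseline, which is shifted by the planted
#' effect (mutant samples only, inside that cohort's planted regions).
#' Sites drawing zero coverage in a sample are unobserved there.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param truth Planted-region table from [plant_regions()] (may be empty
#'   for a null simulation).
#' @param config A [sim_config()].
#' @param cohort Cohort label to simulate.
#' @return List of `callset`s (controls then mutants), each with group and
#'   cohort attributes set.
#' @export
simulate_methylomes <- function(annotation, truth, config, cohort = "F1") {
  set.seed(child_seed(config$seed, 10L + sum(utf8ToInt(cohort)) %% 997L))
  sites <- data.table::copy(annotation$bundle$cpg_sites)
  n <- nrow(sites)
  sites[, pi_mut := pi0]
  keep_cohort <- if (!is.null(truth) && nrow(truth))
    which(truth[["cohort"]] == cohort) else integer()
  tr <- if (length(keep_cohort)) truth[keep_cohort] else NULL
  if (!is.null(tr) && nrow(tr)) {
    pt <- data.table::data.table(chrom = sites$chrom, start = sites$pos - 1L,
                                 end = sites$pos)
    h <- GenomicRanges::findOverlaps(as_gr(pt), as_gr(tr))
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    shift <- ifelse(tr$direction[si] == "hypo", -tr$delta[si], tr$delta[si])
    sites$pi_mut[qi] <- pmin(pmax(sites$pi0[qi] + shift / 100, 0.02), 0.98)
  }
  draw_sample <- function(pi, sample_id, group) {
    cov <- stats::rnbinom(n, mu = config$mean_coverage,
                          size = config$coverage_dispersion)
    keep <- cov > 0
    meth <- integer(n)
    meth[keep] <- rbetabinom(sum(keep), cov[keep], pi[keep], config$rho)
    dt <- data.table::data.table(chrom = sites$chrom[keep],
                                 pos = sites$pos[keep],
                                 strand = sites$strand[keep],
                                 meth = as.integer(meth[keep]),
                                 cov = as.integer(cov[keep]))
    new_callset(dt, sample_id, group, cohort)
  }
  k <- config$n_samples_per_group
  c(lapply(seq_len(k), function(i)
      draw_sample(sites$pi0, sprintf("%s_ctl_%d", cohort, i), "control")),
    lapply(seq_len(k), function(i)
      draw_sample(sites$pi_mut, sprintf("%s_mut_%d", cohort, i), "mutant")))
}

#' Simulate per-timepoint developmental methylation tracks
#'
#' Sites follow one of three mean trajectories: `traj_cgi` (islands stay
#' low), `traj_early` (genome-typical acquisition, >= 80% by the E16.5
#' analog), or `traj_late` (low at E16.5, strong gain afterwards).  Planted
#' regions are forced onto the late trajectory.
#'
#' @inheritParams simulate_methylomes
#' @return Named list of `callset`s, one per timepoint.
#' @export
simulate_developmental_tracks <- function(annotation, truth, config) {
  set.seed(child_seed(config$seed, 30L))
  sites <- data.table::copy(annotation$bundle$cpg_sites)
  timing <- sites$timing
  if (!is.null(truth) && nrow(truth)) {
    pt <- data.table::data.table(chrom = sites$chrom, start = sites$pos - 1L,
                                 end = sites$pos)
    h <- GenomicRanges::findOverlaps(as_gr(pt), as_gr(truth))
    timing[unique(S4Vectors::queryHits(h))] <- "late"
  }
  timing[sites$context == "cgi"] <- "cgi"
  traj <- rbind(early = config$traj_early, late = config$traj_late,
                cgi = config$traj_cgi)
  n <- nrow(sites)
  out <- lapply(seq_along(config$timepoints), function(tix) {
    pi <- traj[timing, tix] / 100
    cov <- stats::rnbinom(n, mu = config$mean_coverage,
                          size = config$coverage_dispersion)
    keep <- cov > 0
    meth <- integer(n)
    meth[keep] <- rbetabinom(sum(keep), cov[keep], pi[keep],
                             min(config$rho, 0.02))
    dt <- data.table::data.table(chrom = sites$chrom[keep],
                                 pos = sites$pos[keep], strand = "+",
                                 meth = as.integer(meth[keep]),
                                 cov = as.integer(cov[keep]))
    new_callset(dt, config$timepoints[tix], "control", "devel")
  })
  stats::setNames(out, config$timepoints)
}

#' Simulate a histone ChIP read track
#'
#' Reads fall uniformly per bp at a background rate, multiplied by
#' `config$chip_enrichment` over late regions (planted regions plus
#' late-methylating background anchors) at the given timepoint; at other
#' timepoints the enrichment factor is 1.
#'
#' @inheritParams simulate_methylomes
#' @param timepoint Timepoint label; enrichment applies at the E16.5
#'   analog (the second configured timepoint) and later.
#' @return `list(reads = interval table, library_size, enriched_regions)`.
#' @export
simulate_chip_track <- function(annotation, truth, config,
                                timepoint = config$timepoints[2]) {
  tix <- match(timepoint, config$timepoints)
  set.seed(child_seed(config$seed, 40L + tix))
  sizes <- annotation$bundle$chrom_sizes
  late <- if (!is.null(truth) && nrow(truth))
    unique(truth[, .(chrom, start, end)]) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer())
  factor_now <- if (tix >= 2) config$chip_enrichment else 1
  total_bp <- sum(as.numeric(sizes))
  late_bp <- if (nrow(late)) sum(late$end - late$start) else 0
  n_reads <- config$chip_library
  if (n_reads == 0)
    return(list(reads = data.table::data.table(chrom = character(),
                                               start = integer(),
                                               end = integer()),
                library_size = 0L, enriched_regions = late))
  # uniform unit rate genome-wide plus (factor - 1) extra over late
  # regions, so the late : background rate ratio is exactly the factor
  w_bg <- total_bp
  w_late <- late_bp * (factor_now - 1)
  n_late <- stats::rbinom(1, n_reads, w_late / (w_bg + w_late))
  n_bg <- n_reads - n_late
  # background reads: uniform over the genome
  chr_idx <- sample.int(length(sizes), n_bg, replace = TRUE,
                        prob = as.numeric(sizes))
  bg_start <- as.integer(floor(stats::runif(n_bg) *
                               (as.numeric(sizes)[chr_idx] -
                                config$chip_read_length)))
  reads_bg <- data.table::data.table(chrom = names(sizes)[chr_idx],
                                     start = bg_start,
                                     end = bg_start + config$chip_read_length)
  reads_late <- NULL
  if (n_late > 0 && nrow(late)) {
    lw <- late$end - late$start
    li <- sample.int(nrow(late), n_late, replace = TRUE, prob = lw)
    ls <- late$start[li] + as.integer(floor(stats::runif(n_late) * lw[li]))
    reads_late <- data.table::data.table(chrom = late$chrom[li], start = ls,
                                         end = ls + config$chip_read_length)
  }
  reads <- data.table::rbindlist(list(reads_bg, reads_late))
  data.table::setorder(reads, chrom, start)
  list(reads = reads[], library_size = n_reads, enriched_regions = late)
}

#' Generate a complete synthetic multi-cohort dataset
#'
#' Convenience wrapper: annotation, planted truth, per-cohort methylomes,
#' developmental tracks and a ChIP track, all from one config.
#'
#' @param config A [sim_config()].
#' @param cohorts Cohort labels (first is the reference cohort).
#' @return `list(bundle, truth, methylomes = per-cohort callset lists,
#'   tracks, chip)`.
#' @export
simulate_cohorts <- function(config, cohorts = c("F1", "F2")) {
  ann <- simulate_annotation(config)
  truth <- if (config$n_planted > 0) plant_regions(ann, config, cohorts)
           else data.table::data.table(
             cohort = character(), region_id = character(),
             chrom = character(), start = integer(), end = integer(),
             delta = numeric(), direction = character(),
             timing = character(), young_te = logical(),
             nested_in = character())
  meth <- lapply(stats::setNames(cohorts, cohorts), function(cb)
    simulate_methylomes(ann, truth, config, cb))
  tracks <- simulate_developmental_tracks(ann, truth, config)
  chip <- simulate_chip_track(ann, truth, config)
  list(bundle = ann$bundle, candidates = ann$candidates, truth = truth,
       methylomes = meth, tracks = tracks, chip = chip)
}
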