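# End-to-end orchestration: simulate -> write -> read -> tile DMT calling
# -> DMC merging -> cross-cohort overlap -> annotation -> timing, in one
# run directory with a manifest and a machine-readable report.

#' Default run configuration
#'
#' Every analysis threshold with its standard value: 100 bp tiles, at least
#' 2 CpGs at 10x per sample, 10-point minimum difference, q < 0.01 BH,
#' 100 bp DMC merge gap, 1 kb flanks, 5-fold expression rule, 50,000
#' background bins.
#'
#' @param seed RNG seed.
#' @param ... Overrides for any default or for [sim_config()] fields.
#' @return Named list (class `run_config`).
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    tile_size = 100L, min_cpgs = 2L, min_cov = 10L,
    min_diff = 10, q_threshold = 0.01,
    gap = 100L, flank = 1000L, fold_threshold = 5,
    background_n = 50000L,
    test_method = "logistic",
    cohorts = c("F1", "F2"),
    sim = NULL)
  dots <- list(...)
  sim_keys <- names(formals(sim_config))
  cfg[names(dots)[names(dots) %in% names(cfg)]] <-
    dots[names(dots) %in% names(cfg)]
  sim_dots <- dots[names(dots) %in% setdiff(sim_keys, "seed")]
  cfg$sim <- do.call(sim_config, c(list(seed = cfg$seed), sim_dots))
  class(cfg) <- "run_config"
  cfg
}

write_run_inputs <- function(sim, dir) {
  dir.create(file.path(dir, "input"), recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cb in names(sim$methylomes)) {
    for (cs in sim$methylomes[[cb]]) {
      f <- file.path(dir, "input", sprintf("%s_%s.cov", cb,
                                           attr(cs, "sample_id")))
      write_callset(cs, f)
      paths[[length(paths) + 1]] <- f
    }
  }
  b <- sim$bundle
  write_chrom_sizes(b$chrom_sizes, file.path(dir, "input", "chrom.sizes"))
  write_regions(b$cgis, file.path(dir, "input", "cgi.bed"), "bed")
  rp <- b$repeats[, .(chrom, start, end, name, class, family, subfamily)]
  data.table::fwrite(rp, file.path(dir, "input", "rmsk.tsv"), sep = "\t",
                     col.names = FALSE)
  invisible(dir)
}

stage_counts <- function(...) list(...)

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, per-cohort DMT calling, per-cohort DMC calling and
#' hypo-DMC merging, cross-cohort tile and DMR overlap, genomic/CGI/repeat
#' annotation of the reference cohort's DMRs, and developmental timing
#' classification, writing all outputs plus a `manifest.json` into
#' `run_dir`.
#'
#' @param config A [run_config()].
#' @param run_dir Output directory (created; must not contain a previous
#'   manifest).
#' @return Invisible list with all in-memory stage results (also written
#'   to disk).
#' @export
run_pipeline <- function(config, run_dir = tempfile("methylkin_run_")) {
  t0 <- Sys.time()
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[methylkin] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  say("simulate: seed=%d cohorts=%s", config$seed,
      paste(config$cohorts, collapse = ","))
  sim <- stage("simulate", simulate_cohorts(config$sim, config$cohorts))
  write_run_inputs(sim, run_dir)

  res <- list(config = config, truth = sim$truth)
  counts <- list()
  for (cb in config$cohorts) {
    cs <- sim$methylomes[[cb]]
    tiles <- stage("dmt", {
      tl <- build_tiles(cs, config$tile_size)
      tl <- filter_tiles(tl, config$min_cpgs, config$min_cov)
      call_dmts(test_tiles(tl, config$test_method),
                config$q_threshold, config$min_diff)
    })
    dmc <- stage("dmc", call_dmcs(cs, config$min_cov, config$min_diff,
                                  config$q_threshold, config$test_method))
    hypo <- dmc$dmcs[direction == "hypo"]
    merged <- stage("merge", merge_dmcs(hypo, config$gap, "hypo"))
    res[[cb]] <- list(tiles = tiles, dmc = dmc, merged = merged)
    counts[[cb]] <- stage_counts(
      tested_tiles = sum(tiles$tiles$status == "tested"),
      dmts = nrow(tiles$dmts),
      dmts_hypo = sum(tiles$dmts$direction == "hypo"),
      dmts_hyper = sum(tiles$dmts$direction == "hyper"),
      dmcs = nrow(dmc$dmcs), dmcs_hypo = nrow(hypo),
      dmrs = nrow(merged$dmrs), singles = nrow(merged$singles))
    say("%s: %d tested tiles, %d DMTs (%d hypo), %d DMCs, %d DMRs",
        cb, counts[[cb]]$tested_tiles, counts[[cb]]$dmts,
        counts[[cb]]$dmts_hypo, counts[[cb]]$dmcs, counts[[cb]]$dmrs)
    write_regions(tiles$dmts, file.path(run_dir, sprintf("%s_dmts.tsv", cb)),
                  "tsv")
    write_regions(merged$dmrs, file.path(run_dir, sprintf("%s_dmrs.bed", cb)),
                  "bed")
  }

  overlap <- NULL
  if (length(config$cohorts) >= 2) {
    a <- config$cohorts[1]; b <- config$cohorts[2]
    hypoA <- res[[a]]$tiles$dmts[direction == "hypo"]
    hypoB <- res[[b]]$tiles$dmts[direction == "hypo"]
    overlap <- stage("overlap", list(
      tiles = intersect_tiles(hypoA, hypoB, config$tile_size),
      dmrs = overlap_dmr_sets(res[[a]]$merged$dmrs, res[[b]]$merged$dmrs)))
    overlap$pct_b_tiles_shared <- if (nrow(hypoB))
      proportion(overlap$tiles$shared, nrow(hypoB)) else NA_real_
    say("overlap: %d shared hypo tiles (%.1f%% of %s), %s DMR overlap %.1f%%",
        overlap$tiles$shared, overlap$pct_b_tiles_shared, b, b,
        overlap$dmrs$summary$pct_shared_b)
  }

  refc <- config$cohorts[1]
  dmrs <- res[[refc]]$merged$dmrs
  annot <- stage("annotate", {
    bg <- bin_genome(sim$bundle$chrom_sizes, 1000L)
    list(elements = table(annotate_elements(dmrs, sim$bundle)),
         cgi = table(cgi_context(dmrs, sim$bundle$cgis)$label),
         repeats = repeat_composition(dmrs, sim$bundle$repeats, bg),
         young = young_line_overlap(dmrs, sim$bundle$repeats, bg))
  })
  timing <- stage("timing", {
    tm <- trajectory_matrix(dmrs, sim$tracks)
    list(labels = table(classify_timing(tm)), matrix_dim = dim(tm))
  })
  say("annotate+timing: %d DMRs annotated", nrow(dmrs))

  manifest <- list(
    package_version = as.character(utils::packageVersion("methylkin")),
    seed = config$seed,
    thresholds = config[c("tile_size", "min_cpgs", "min_cov", "min_diff",
                          "q_threshold", "gap", "flank", "fold_threshold",
                          "background_n")],
    counts = counts,
    overlap = if (!is.null(overlap)) list(
      shared_tiles = overlap$tiles$shared,
      pct_b_tiles_shared = overlap$pct_b_tiles_shared,
      dmr_summary = overlap$dmrs$summary) else NULL,
    input_md5 = as.list(tools::md5sum(
      list.files(file.path(run_dir, "input"), full.names = TRUE))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(run_dir, "run.log"))
  res$overlap <- overlap; res$annot <- annot; res$timing <- timing
  res$counts <- counts; res$run_dir <- run_dir; res$sim <- sim
  invisible(res)
}

#' Summarize a completed run directory
#'
#' Rebuilds the human-facing summary tables (counts, hypo/hyper split,
#' overlap percentages) from the stored manifest; every percentage is
#' recomputed from the stored integer counts via [proportion()].
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List with `counts`, `percentages` and the manifest; also prints
#'   a text summary.
#' @export
report <- function(run_dir) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf))
    stopf("report: %s has no manifest.json (incomplete run)", run_dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  pct <- list()
  for (cb in names(manifest$counts)) {
    cc <- manifest$counts[[cb]]
    if (cc$dmts > 0)
      pct[[cb]] <- list(
        pct_hypo = proportion(cc$dmts_hypo, cc$dmts),
        pct_hyper = proportion(cc$dmts_hyper, cc$dmts),
        pct_single_dmcs = if (cc$dmcs_hypo > 0)
          proportion(cc$singles, cc$dmcs_hypo) else NA_real_)
    cat(sprintf("%s: %d DMTs (%d hypo / %d hyper), %d DMCs, %d DMRs\n",
                cb, cc$dmts, cc$dmts_hypo, cc$dmts_hyper, cc$dmcs, cc$dmrs))
  }
  if (!is.null(manifest$overlap))
    cat(sprintf("shared hypo tiles: %d (%.1f%%)\n",
                manifest$overlap$shared_tiles,
                manifest$overlap$pct_b_tiles_shared))
  invisible(list(counts = manifest$counts, percentages = pct,
                 manifest = manifest))
}
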