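test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(shared_fraction = 1.2))
  expect_error(sim_config(rho = 1))
  expect_error(sim_config(delta_range = c(0, 50)))
  cfg <- sim_config()
  expect_equal(cfg$shared_fraction, 0.84)
  expect_equal(cfg$rho, 0.05)
  expect_equal(names(cfg$baseline),
               c("cgi", "gene", "repeat", "intergenic"))
})

test_that("annotation simulation is deterministic and well-formed", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 400000L,
                    n_planted = 10L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$bundle$genes, a2$bundle$genes)
  expect_identical(a1$bundle$cpg_sites, a2$bundle$cpg_sites)
  expect_identical(a1$candidates, a2$candidates)
  # all features within chromosome bounds
  for (nm in c("genes", "cgis", "repeats")) {
    f <- a1$bundle[[nm]]
    expect_true(all(f$start >= 0 & f$end <= cfg$chrom_length))
  }
  # young flags only on configured subfamilies
  rp <- a1$bundle$repeats
  expect_true(all(rp$subfamily[rp$young] %in% young_l1md_subfamilies()))
  # too-short chromosomes refuse to host the layout
  expect_error(simulate_annotation(sim_config(chrom_length = 10000L)),
               "shorter")
})

test_that("planted regions carry >= 1 CpG and honor the shared fraction", {
  cfg <- sim_config(seed = 19, n_chroms = 2, chrom_length = 1200000L,
                    n_planted = 60L, shared_fraction = 0.5)
  ann <- simulate_annotation(cfg)
  truth <- plant_regions(ann, cfg)
  sites <- ann$bundle$cpg_sites
  pts <- data.table::data.table(chrom = sites$chrom, start = sites$pos - 1L,
                                end = sites$pos)
  expect_true(all(count_hits(truth, pts) >= 1))
  tB <- truth[cohort == "F2"]
  shared <- !is.na(tB$nested_in)
  # nested plants really are contained in their donors
  tA <- truth[cohort == "F1"]
  for (i in which(shared)) {
    don <- tA[region_id == tB$nested_in[i]]
    expect_true(don$chrom == tB$chrom[i] && don$start <= tB$start[i] &&
                tB$end[i] <= don$end)
  }
  # unshared plants land on unused anchors, disjoint from cohort-A plants
  expect_true(all(count_hits(tB[!shared], tA) == 0))
})

test_that("null simulation produces no group difference beyond noise", {
  cfg <- sim_config(seed = 71, n_chroms = 1, chrom_length = 600000L,
                    n_planted = 0L)
  sim <- simulate_cohorts(cfg, cohorts = "F1")
  tl <- filter_tiles(build_tiles(sim$methylomes$F1))
  out <- call_dmts(test_tiles(tl))
  expect_lte(nrow(out$dmts), max(5, 0.005 * nrow(tl)))
})

test_that("planted effects are recovered in the pooled difference", {
  cfg <- sim_config(seed = 73, n_chroms = 2, chrom_length = 1200000L,
                    n_planted = 100L, delta_fixed = 30, frac_hyper = 0)
  sim <- simulate_cohorts(cfg, cohorts = "F1")
  u <- unite_callsets(sim$methylomes$F1)
  truth <- sim$truth
  pts <- data.table::data.table(chrom = u$chrom, start = u$pos - 1L,
                                end = u$pos)
  inside <- count_hits(pts, truth) > 0
  cc <- grep("^cov_", names(u)); mc <- grep("^meth_", names(u))
  ctrl <- which(attr(u, "groups") == "control")
  mut <- which(attr(u, "groups") == "mutant")
  pool <- function(rows, cols) sum(sapply(cols, function(j)
    sum(u[[j]][rows])))
  d_in <- 100 * (pool(which(inside), mc[mut]) / pool(which(inside), cc[mut]) -
                 pool(which(inside), mc[ctrl]) / pool(which(inside), cc[ctrl]))
  # Monte-Carlo mean over 100 planted regions within +/- 3 points of -30
  expect_lt(abs(d_in - (-30)), 3)
  # outside planted regions the pooled difference is near zero
  d_out <- 100 * (pool(which(!inside), mc[mut]) / pool(which(!inside), cc[mut]) -
                  pool(which(!inside), mc[ctrl]) / pool(which(!inside), cc[ctrl]))
  expect_lt(abs(d_out), 1)
})

test_that("rho = 0 reduces to binomial site variance", {
  cfg <- sim_config(seed = 79, n_chroms = 1, chrom_length = 700000L,
                    n_planted = 0L, rho = 0, mean_coverage = 50,
                    coverage_dispersion = 1e8)  # ~Poisson coverage 50
  sim <- simulate_cohorts(cfg, cohorts = "F1")
  u <- unite_callsets(sim$methylomes$F1)
  s <- sim$bundle$cpg_sites
  key <- paste(u$chrom, u$pos)
  pi0 <- s$pi0[match(key, paste(s$chrom, s$pos))]
  sel <- which(abs(pi0 - 0.8) < 1e-9 & u$cov_1 > 0)
  props <- u$meth_1[sel] / u$cov_1[sel]
  expect_gt(length(sel), 500)
  # binomial moment check: var(p_hat) = p(1-p) E[1/cov] when rho = 0
  expected <- 0.8 * 0.2 * mean(1 / u$cov_1[sel])
  expect_lt(abs(var(props) - expected) / expected, 0.1)
})

test_that("developmental tracks follow the configured trajectories", {
  cfg <- sim_config(seed = 83, n_chroms = 1, chrom_length = 800000L,
                    n_planted = 30L)
  sim <- simulate_cohorts(cfg, cohorts = "F1")
  tracks <- sim$tracks
  expect_equal(names(tracks), c("E13.5", "E16.5", "P0", "sperm"))
  # CGI regions stay <= 10% at every timepoint
  cgis <- sim$bundle$cgis
  for (tp in names(tracks)) {
    m <- region_methylation(cgis, tracks[[tp]], 5)
    expect_lte(max(m, na.rm = TRUE), 10)
  }
  # planted (late) regions: low at the E16.5 analog, high in sperm
  tr <- trajectory_matrix(sim$truth, tracks)
  expect_lte(mean(tr[, 2], na.rm = TRUE), 25)
  expect_gte(mean(tr[, 4], na.rm = TRUE), 70)
  # early background (excluding anchors that received a plant) reaches
  # >= 80% by the E16.5 analog
  early <- sim$candidates[category == "intergenic"]
  early <- early[count_hits(early, sim$truth) == 0]
  tre <- trajectory_matrix(early, tracks)
  expect_gte(mean(tre[, 2], na.rm = TRUE), 80)
  # monotone non-decreasing mean trajectory for planted regions
  mt <- colMeans(tr, na.rm = TRUE)
  expect_true(all(diff(mt) > -2))
  # seed-fixed rerun is identical
  sim2 <- simulate_cohorts(cfg, cohorts = "F1")
  expect_identical(as.data.frame(sim$tracks[[2]]),
                   as.data.frame(sim2$tracks[[2]]))
})

test_that("chip track enrichment matches the configured factor", {
  cfg <- sim_config(seed = 89, n_chroms = 1, chrom_length = 800000L,
                    n_planted = 40L, chip_enrichment = 4,
                    chip_library = 300000L)
  ann <- simulate_annotation(cfg)
  truth <- plant_regions(ann, cfg, cohorts = "F1")
  chip <- simulate_chip_track(ann, truth, cfg, timepoint = "E16.5")
  late_rpkm <- mean(rpkm(truth, chip$reads, chip$library_size))
  bins <- bin_genome(ann$bundle$chrom_sizes, 1000L)
  bg <- count_hits(bins, truth) == 0
  bg_rpkm <- mean(rpkm(bins[bg], chip$reads, chip$library_size))
  expect_gt(late_rpkm, 3.2 * bg_rpkm)
  expect_lt(late_rpkm, 4.8 * bg_rpkm)
  # factor 1: late regions indistinguishable from background
  cfg1 <- sim_config(seed = 89, n_chroms = 1, chrom_length = 800000L,
                     n_planted = 40L, chip_enrichment = 1,
                     chip_library = 300000L)
  chip1 <- simulate_chip_track(ann, truth, cfg1, timepoint = "E16.5")
  lr <- rpkm(truth, chip1$reads, chip1$library_size)
  # compare against length-matched background: the late regions shifted
  # into unenriched sequence (read-length edge effects cancel this way)
  shifted <- data.table::copy(truth)[, `:=`(start = start + 5000L,
                                            end = end + 5000L)]
  shifted <- shifted[count_hits(shifted, truth) == 0]
  br <- rpkm(shifted, chip1$reads, chip1$library_size)
  expect_gt(t.test(lr, br)$p.value, 0.01)
  # zero reads -> all RPKM zero
  cfg0 <- sim_config(seed = 89, n_chroms = 1, chrom_length = 800000L,
                     n_planted = 40L, chip_library = 0L)
  chip0 <- simulate_chip_track(ann, truth, cfg0, timepoint = "E16.5")
  expect_equal(chip0$library_size, 0L)
  expect_equal(nrow(chip0$reads), 0L)
})

test_that("a zero-repeat layout still flows through enrichment ops", {
  cfg <- sim_config(seed = 97, n_chroms = 1, chrom_length = 300000L,
                    n_planted = 5L)
  ann <- simulate_annotation(cfg)
  bg <- bin_genome(ann$bundle$chrom_sizes, 1000L)
  expect_warning(
    rc <- repeat_composition(bg[1:50], ann$bundle$repeats[0], bg),
    "skipped")
  expect_true(all(rc$classes == "none"))
})
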