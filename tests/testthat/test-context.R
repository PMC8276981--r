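# hand-built gene model: one + strand coding gene 10000-18000 with 3 exons,
# one noncoding gene 30000-33000
toy_bundle <- function() {
  list(
    genes = data.table::data.table(
      chrom = "chr1", start = c(10000L, 30000L), end = c(18000L, 33000L),
      strand = "+", tss = c(10000L, 30000L), tts = c(18000L, 33000L),
      coding = c(TRUE, FALSE), name = c("g1", "nc1")),
    exons = data.table::data.table(
      chrom = "chr1", start = c(10000L, 13000L, 17500L),
      end = c(10300L, 13400L, 18000L)),
    utr5 = data.table::data.table(chrom = "chr1", start = 10000L,
                                  end = 10080L),
    utr3 = data.table::data.table(chrom = "chr1", start = 17880L,
                                  end = 18000L),
    cgis = data.table::data.table(chrom = "chr1", start = 9500L,
                                  end = 10500L, name = "cgi1"),
    chrom_sizes = c(chr1 = 100000L))
}

test_that("annotate_elements follows the precedence by midpoint", {
  b <- toy_bundle()
  q <- data.table::data.table(
    chrom = "chr1",
    start = c(9650L, 13150L, 15000L, 31000L, 60000L, 17850L),
    end   = c(9750L, 13250L, 15100L, 31100L, 60100L, 17950L))
  lab <- as.character(annotate_elements(q, b))
  expect_equal(lab, c("promoter",    # 300 bp upstream of TSS
                      "exon", "intron", "noncoding", "intergenic",
                      "TTS"))        # inside TTS window beats 3UTR
  # labels partition: exactly one label per query
  expect_equal(length(lab), nrow(q))

  # brute-force oracle on random queries
  set.seed(43)
  q2 <- rand_intervals(1000, chroms = "chr1", max_pos = 90000, max_len = 200)
  lab2 <- as.character(annotate_elements(q2, b))
  mid <- floor((q2$start + q2$end) / 2)
  oracle <- vapply(mid, function(m) {
    inw <- function(ft) any(ft$start <= m & m < ft$end)
    if (any(abs(m - b$genes$tss) <= 1000)) "promoter"
    else if (any(abs(m - b$genes$tts) <= 1000)) "TTS"
    else if (inw(b$utr5)) "5UTR"
    else if (inw(b$utr3)) "3UTR"
    else if (inw(b$exons)) "exon"
    else if (inw(b$genes[coding == TRUE])) "intron"
    else if (inw(b$genes[coding == FALSE])) "noncoding"
    else "intergenic"
  }, character(1))
  expect_equal(lab2, oracle)
})

test_that("cgi_context distances and shore/shelf/open-sea boundaries", {
  cgis <- data.table::data.table(chrom = "chr1", start = 10000L,
                                 end = 11000L)
  q <- data.table::data.table(
    chrom = "chr1",
    start = c(10200L, 12999L, 13000L, 13001L, 15000L, 15001L, 9000L),
    end   = c(10300L, 13099L, 13100L, 13101L, 15100L, 15101L, 9100L))
  ctx <- cgi_context(q, cgis)
  # edge distances: q2 is 1999 bp from the island end
  expect_equal(as.character(ctx$label),
               c("island", "shore", "shore", "shelf", "shelf", "open_sea",
                 "shore"))
  expect_equal(ctx$distance,
               c(0L, 1999L, 2000L, 2001L, 4000L, 4001L, 900L))
  # >4 kb means open sea
  far <- cgi_context(data.table::data.table(chrom = "chr1", start = 15002L,
                                            end = 15102L), cgis)
  expect_equal(as.character(far$label), "open_sea")
  # no islands at all -> open_sea with NA distance
  none <- cgi_context(q[1], cgis[0])
  expect_equal(as.character(none$label), "open_sea")
  expect_true(is.na(none$distance))
})

test_that("repeat composition assigns by maximal overlap with enrichment", {
  repeats <- data.table::data.table(
    chrom = "chr1", start = c(100L, 260L, 1000L),
    end = c(230L, 400L, 1500L),
    class = c("SINE", "LINE", "LINE"),
    family = c("B1", "L1", "L1"),
    subfamily = c("B1_Mus1", "L1MdA_I", "L1_Mus3"))
  # region overlaps SINE by 30 bp and LINE by 70 bp -> LINE
  r <- data.table::data.table(chrom = "chr1", start = 200L, end = 330L)
  rc_classes <- repeat_composition(r, repeats,
                                   background = rand_intervals(50))$classes
  expect_equal(rc_classes, "LINE")
  # fully inside a LINE
  expect_equal(repeat_composition(
    data.table::data.table(chrom = "chr1", start = 1100L, end = 1200L),
    repeats, rand_intervals(50))$classes, "LINE")
  # no repeats: all none, enrichment skipped with warning
  expect_warning(
    rc0 <- repeat_composition(r, repeats[0], rand_intervals(10)),
    "skipped")
  expect_null(rc0$enrichment)
  expect_equal(rc0$classes, "none")
  # empty background is an error
  expect_error(repeat_composition(r, repeats, repeats[0][, 1:3]),
               "background")

  # chi-square equals the closed-form 2x2 at fg 60% vs bg 30%
  fg <- data.table::data.table(chrom = "chr1",
                               start = seq(0L, by = 2000L, length.out = 200))
  fg[, end := start + 100L]
  fg_line <- 120  # first 120 regions overlap a LINE
  bg_line <- 600; n_bg <- 2000
  res <- enrich <- methylkin:::enrichment_chisq(fg_line, 200, bg_line, n_bg)
  expect_equal(res$statistic,
               oracle_chisq_2x2(fg_line, 200 - fg_line, bg_line,
                                n_bg - bg_line), tolerance = 1e-12)
  expect_equal(res$fold, (120 / 200) / (600 / 2000))
})

test_that("chi-square enrichment is symmetric under fg/bg swap", {
  a <- methylkin:::enrichment_chisq(30, 100, 200, 1000)
  b <- methylkin:::enrichment_chisq(200, 1000, 30, 100)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
  expect_equal(a$fold, 1 / b$fold)
})

test_that("young LINE overlap counts only young subfamilies", {
  repeats <- data.table::data.table(
    chrom = "chr1", start = c(100L, 1000L), end = c(600L, 1600L),
    class = "LINE", family = "L1",
    subfamily = c("L1MdA_I", "L1_Mus3"))
  young_hit <- data.table::data.table(chrom = "chr1", start = 150L,
                                      end = 250L)
  old_hit <- data.table::data.table(chrom = "chr1", start = 1100L,
                                    end = 1200L)
  bg <- data.table::data.table(chrom = "chr1",
                               start = seq(2000L, by = 1000L,
                                           length.out = 50))
  bg[, end := start + 100L]
  r1 <- young_line_overlap(young_hit, repeats, bg)
  expect_equal(r1$fg_prop, 1)
  r2 <- young_line_overlap(old_hit, repeats, bg)
  expect_equal(r2$fg_prop, 0)
  # unknown subfamilies in the young list simply never match
  r3 <- young_line_overlap(young_hit, repeats, bg,
                           young_list = c("NotAFamily"))
  expect_equal(r3$fg_prop, 0)
})

test_that("the 5-fold expression rule is strict and guards bad controls", {
  tab <- data.frame(subfamily = c("A", "B", "C"), fold = c(6.0, 4.9, 5.0))
  expect_equal(dnmt3c_sensitive_subfamilies(tab), "A")
  expect_equal(dnmt3c_sensitive_subfamilies(tab[0, ]), character())
  tab2 <- data.frame(subfamily = c("A", "B"), ko = c(12, 10),
                     control = c(2, 0))
  expect_warning(res <- dnmt3c_sensitive_subfamilies(tab2), "non-positive")
  expect_equal(res, "A")
  # the eight young L1Md subfamilies come out of a table built to match
  et <- data.frame(subfamily = c(young_l1md_subfamilies(), "L1_Mus3", "IAPEz"),
                   fold = c(rep(8, 8), 1.2, 0.8))
  expect_setequal(dnmt3c_sensitive_subfamilies(et), young_l1md_subfamilies())
})

test_that("flanked_overlap extends, clips, and matches brute force", {
  regions <- data.table::data.table(chrom = "chr1", start = 5000L,
                                    end = 5100L)
  elements <- data.table::data.table(chrom = "chr1", start = 5600L,
                                     end = 5700L)
  expect_equal(flanked_overlap(regions, elements, 1000)$k, 1L)
  expect_equal(flanked_overlap(regions, elements, 0)$k, 0L)  # plain overlap
  expect_error(flanked_overlap(regions, elements, 1000,
                               chrom_sizes = c(chr2 = 1e6)), "missing chrom")
  # brute force with manual extension on random data
  set.seed(47)
  for (rep in 1:4) {
    r <- rand_intervals(100, max_pos = 50000)
    e <- rand_intervals(100, max_pos = 50000)
    fl <- sample(c(0L, 500L, 1000L), 1)
    got <- flanked_overlap(r, e, fl)
    r2 <- data.table::copy(r)[, `:=`(start = pmax(0L, start - fl),
                                     end = end + fl)]
    expect_equal(got$hits, lengths(oracle_overlaps(e, r2)) > 0)
  }
})

test_that("annotation results are invariant to query ordering", {
  b <- toy_bundle()
  set.seed(53)
  q <- rand_intervals(200, chroms = "chr1", max_pos = 90000)
  perm <- sample.int(nrow(q))
  expect_equal(as.character(annotate_elements(q, b))[perm],
               as.character(annotate_elements(q[perm], b)))
  expect_equal(cgi_context(q, b$cgis)$label[perm],
               cgi_context(q[perm], b$cgis)$label)
})
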