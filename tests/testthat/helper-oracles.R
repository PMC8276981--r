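# Independent brute-force oracles and tiny fixture builders.  None of
# these call into the package code paths they are used to check.

suppressPackageStartupMessages(library(data.table))

# --- fixtures ---------------------------------------------------------------

make_callset <- function(df, sample_id = "s1", group = "control",
                         cohort = "F1") {
  f <- tempfile(fileext = ".cov")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  read_callset(f, sample_id, group, cohort)
}

# callsets for k control + k mutant samples over given sites with fixed
# per-site (meth, cov) offsets so tests are deterministic without RNG
flat_callsets <- function(pos, meth_ctrl, cov_ctrl, meth_mut, cov_mut,
                          k = 2, chrom = "chr1") {
  mk <- function(meth, cov, id, grp)
    make_callset(data.frame(chrom = chrom, pos = pos, strand = "+",
                            meth = meth, cov = cov),
                 id, grp)
  c(lapply(seq_len(k), function(i)
      mk(meth_ctrl, cov_ctrl, paste0("c", i), "control")),
    lapply(seq_len(k), function(i)
      mk(meth_mut, cov_mut, paste0("m", i), "mutant")))
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000,
                           max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

# --- oracles ----------------------------------------------------------------

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the same margins
oracle_fisher <- function(m1, c1, m2, c2) {
  k <- m1 + m2            # total methylated
  n <- c1 + c2
  lo <- max(0, k - c2); hi <- min(k, c1)
  probs <- dhyper(lo:hi, c1, c2, k)
  p_obs <- dhyper(m1, c1, c2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) single-linkage clustering of positions with gap threshold:
# adjacency matrix + breadth-first components
oracle_cluster <- function(chrom, pos, gap) {
  n <- length(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(pos[i] - pos[j]) <= gap)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      frontier <- i
      while (length(frontier)) {
        comp[frontier] <- k
        nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                     is.na(comp))
        frontier <- nxt
      }
    }
  }
  comp
}

# brute-force all-pairs overlap: for each B row, indices of overlapping A
oracle_overlaps <- function(A, B) {
  lapply(seq_len(nrow(B)), function(j) {
    hits <- integer()
    for (i in seq_len(nrow(A))) {
      if (A$chrom[i] == B$chrom[j] &&
          min(A$end[i], B$end[j]) - max(A$start[i], B$start[j]) > 0)
        hits <- c(hits, i)
    }
    hits
  })
}

# closed-form Pearson chi-square on a 2x2 of counts (no correction)
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  num / den
}

# interval pair classification by first principles
oracle_classify <- function(a, b) {
  if (a$chrom != b$chrom) return("disjoint")
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) "disjoint"
  else if (a$start == b$start && a$end == b$end) "identical"
  else if (a$start <= b$start && b$end <= a$end) "b_within_a"
  else if (b$start <= a$start && a$end <= b$end) "a_within_b"
  else "partial"
}

gr_regions <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

count_hits <- function(x, y) GenomicRanges::countOverlaps(gr_regions(x),
                                                          gr_regions(y))
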