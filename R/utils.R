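#' @import data.table
#' @importFrom methods is
#' @importFrom stats pchisq fisher.test p.adjust rbinom rnbinom rbeta runif
#'   chisq.test complete.cases setNames quantile glm anova binomial cor
#' @importFrom utils head tail write.table read.table
NULL

# interval data.frames are 0-based half-open throughout; GRanges is 1-based
# closed, so the conversion adds 1 to start only.
as_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Round a percentage the way results tables do
#'
#' Computes `100 * numerator / denominator` rounded half-up to one decimal
#' on the 0-100 scale.  Percentages throughout the package are derived from
#' stored integer counts with this function only, so printed summaries can
#' always be recomputed exactly.
#'
#' @param numerator,denominator Non-negative integer counts;
#'   `denominator` must be positive.
#' @return Percentage on the 0-100 scale with one decimal place.
#' @examples
#' proportion(8296, 8296 + 63)  # 99.2
#' proportion(892, 3545)        # 25.2 -- see also three_way()
#' @export
proportion <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("proportion(): zero or negative denominator")
  if (any(numerator < 0)) stop("proportion(): negative numerator")
  x <- 100 * numerator / denominator
  floor(x * 10 + 0.5) / 10  # round half-up, not banker's
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# deterministic child seed: keep well below 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147480000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
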