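# Readers/writers for the external formats used by the pipeline.
#
# Conventions:
#  * per-CpG coverage-call files are 1-based (bismark/bsmap coverage dialect)
#  * BED-like files and every internal interval table are 0-based half-open
#  * the 1-based -> internal conversion happens exactly once, here
#  * percent methylation is always on the 0-100 scale

#' Read a per-CpG bisulfite call table
#'
#' Ingests a tab-delimited coverage-call file with columns
#' `chrom, pos (1-based position of the C), strand, meth, cov` and returns a
#' validated, sorted call set.  Plus- and minus-strand calls are kept as
#' separate sites (no symmetric-CpG collapsing), matching the default
#' behaviour of tile-based RRBS tools; set `destrand = TRUE` to pool a minus
#' strand call into the plus-strand CpG one base upstream.
#'
#' @param path File path (tab-delimited, optional `#` comment lines).
#' @param sample_id Sample identifier stored on the result.
#' @param group `"control"` or `"mutant"`.
#' @param cohort Cohort label, e.g. `"F1"`, `"F2"`, `"MatDef"`.
#' @param destrand Pool strands onto the plus-strand C? Default `FALSE`.
#' @return A `callset`: a `data.table` with columns
#'   `chrom, pos, strand, meth, cov` sorted by `(chrom, pos, strand)`, with
#'   attributes `sample_id`, `group`, `cohort`.
#' @export
read_callset <- function(path, sample_id, group = c("control", "mutant"),
                         cohort = "custom", destrand = FALSE) {
  group <- match.arg(group)
  if (!file.exists(path)) stopf("read_callset: no such file: %s", path)
  if (file.size(path) == 0)
    return(new_callset(empty_sites(), sample_id, group, cohort))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = c(1, 3)),
                      col.names = c("chrom", "pos", "strand", "meth", "cov")),
    error = function(e) stopf("read_callset: malformed file %s: %s",
                              path, conditionMessage(e)))
  if (nrow(dt) == 0) return(new_callset(empty_sites(), sample_id, group, cohort))
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stopf("read_callset: bad strand at line %d", bad[1])
  bad <- which(is.na(dt$pos) | dt$pos < 1 | is.na(dt$meth) | is.na(dt$cov))
  if (length(bad)) stopf("read_callset: malformed line %d", bad[1])
  bad <- which(dt$cov < 1)
  if (length(bad)) stopf("read_callset: coverage < 1 at line %d", bad[1])
  bad <- which(dt$meth > dt$cov)
  if (length(bad)) stopf("read_callset: meth exceeds coverage at line %d", bad[1])
  if (destrand) {
    dt[strand == "-", pos := pos - 1L]
    dt <- dt[, .(meth = sum(meth), cov = sum(cov)), by = .(chrom, pos)]
    dt[, strand := "+"]
    data.table::setcolorder(dt, c("chrom", "pos", "strand", "meth", "cov"))
  }
  data.table::setorder(dt, chrom, pos, strand)
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stopf("read_callset: duplicate site in %s", path)
  new_callset(dt, sample_id, group, cohort)
}

empty_sites <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), meth = integer(),
                         cov = integer())
}

new_callset <- function(dt, sample_id, group, cohort) {
  dt[, `:=`(pos = as.integer(pos), meth = as.integer(meth),
            cov = as.integer(cov))]
  data.table::setattr(dt, "sample_id", sample_id)
  data.table::setattr(dt, "group", group)
  data.table::setattr(dt, "cohort", cohort)
  data.table::setattr(dt, "class", c("callset", class(dt)))
  dt[]
}

#' Write a call set back to the coverage-call dialect
#' @param callset A `callset` from [read_callset()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(callset, path) {
  data.table::fwrite(callset[, c("chrom", "pos", "strand", "meth", "cov")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> sample=%s group=%s cohort=%s sites=%d\n",
              attr(x, "sample_id"), attr(x, "group"), attr(x, "cohort"),
              nrow(x)))
  if (nrow(x)) print(data.table::as.data.table(x), topn = 3)
  invisible(x)
}

#' Read a BED-like annotation file
#'
#' BED3+ with 0-based half-open coordinates.  `kind = "repeat"` expects a
#' RepeatMasker-style layout `chrom start end name class family subfamily
#' [strand]` and flags young LINE subfamilies from `young_list`.
#'
#' @param path File path.
#' @param kind One of `"generic"`, `"cgi"`, `"gene"`, `"repeat"`.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   given, intervals beyond the bounds are an error.
#' @param young_list Subfamily names flagged young for `kind = "repeat"`;
#'   defaults to [young_l1md_subfamilies()].
#' @return `data.table` of 0-based half-open intervals sorted by
#'   `(chrom, start, end)`; repeat kind adds `class`, `family`, `subfamily`,
#'   `young` columns.
#' @export
read_bed <- function(path, kind = c("generic", "cgi", "gene", "repeat"),
                     chrom_sizes = NULL, young_list = young_l1md_subfamilies()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("read_bed: no such file: %s", path)
  dt <- if (file.size(path) == 0) data.table::data.table()
        else data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character())
    if (kind == "repeat")
      out[, `:=`(class = character(), family = character(),
                 subfamily = character(), young = logical())]
    return(out)
  }
  need <- if (kind == "repeat") 7L else 3L
  if (ncol(dt) < need)
    stopf("read_bed: %s requires >= %d columns, got %d", kind, need, ncol(dt))
  out <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]),
    end   = as.integer(dt[[3]]),
    name  = if (ncol(dt) >= 4) as.character(dt[[4]]) else ".")
  bad <- which(!(out$start < out$end) | out$start < 0)
  if (length(bad)) stopf("read_bed: start >= end at line %d", bad[1])
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(out$chrom), names(chrom_sizes))
    if (length(unknown)) stopf("read_bed: unknown chrom %s", unknown[1])
    if (any(out$end > chrom_sizes[out$chrom]))
      stopf("read_bed: interval beyond chromosome end")
  }
  if (kind == "repeat") {
    out[, `:=`(class = as.character(dt[[5]]), family = as.character(dt[[6]]),
               subfamily = as.character(dt[[7]]))]
    out[, young := subfamily %in% young_list]
  }
  if (ncol(dt) >= 5 && kind != "repeat") out[, score := dt[[5]]]
  if (ncol(dt) >= 6 && kind != "repeat") out[, strand := as.character(dt[[6]])]
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' Write regions to BED or a stats-bearing TSV
#'
#' Output is deterministic: fixed column order and fixed-precision floats so
#' repeated runs are byte-identical.
#'
#' @param regions Interval `data.frame` (0-based half-open); extra numeric
#'   columns are written with 4 decimal places in `"tsv"` format.
#' @param path Output path.
#' @param format `"bed"` (chrom start end name score) or `"tsv"` (all
#'   columns, header line).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  regions <- data.table::as.data.table(regions)
  if (format == "bed") {
    out <- data.table::data.table(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      name  = regions$name %||% sprintf("region_%d", seq_len(nrow(regions))),
      score = if (!is.null(regions$score))
        sprintf("%.4f", regions$score) else ".")
    if (nrow(out) == 0)
      out <- out[0]
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  } else {
    out <- data.table::copy(regions)
    for (cl in names(out))
      if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.4f", out[[cl]])
    data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  }
  invisible(path)
}

#' Read a chrom.sizes file
#' @param path Two-column file: chromosome name, length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2) stopf("read_chrom_sizes: need 2 columns")
  stats::setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}

#' Write a chrom.sizes file
#' @param sizes Named vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  data.table::fwrite(data.table::data.table(names(sizes), as.integer(sizes)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
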