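# Read-level PUP abundance in metagenome samples: percent reads mapped to
# characterized PUPs, RPKM per target, and two-group comparisons.

#' Percent of reads whose best hit passes the E-value cutoff
#'
#' Each read is counted once, by its best (lowest E-value) hit against the
#' PUP reference; the percentage is over the sample's total read count, not
#' just the reads with hits.
#'
#' @param hits data.frame with columns `read_id`, `target_id`, `evalue`.
#' @param total_reads total reads in the sample (> 0).
#' @param evalue_cutoff strict E-value cutoff (default 1e-5).
#' @return percentage in \[0, 100\].
#' @export
percent_reads_mapped <- function(hits, total_reads, evalue_cutoff = 1e-5) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (nrow(hits) == 0) return(0)
  best <- tapply(hits$evalue, hits$read_id, min)
  100 * sum(best < evalue_cutoff) / total_reads
}

#' Reads per kilobase of target per million mapped reads
#'
#' `read_count / ((target_length_bp / 1000) * (total_mapped / 1e6))`; the
#' per-target, library-size- and length-normalised abundance unit.
#'
#' @param read_count reads assigned to the target (vectorised).
#' @param target_length_bp target length in bp (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(read_count, target_length_bp, total_mapped) {
  if (any(target_length_bp <= 0)) stop("target_length_bp must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  read_count / ((target_length_bp / 1000) * (total_mapped / 1e6))
}

#' Significance label for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, otherwise `n.s.`.
#'
#' @param p numeric p-value(s).
#' @return character label(s).
#' @export
significance_label <- function(p) {
  cut_lab <- function(x) {
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*"
    else "n.s."
  }
  vapply(p, cut_lab, character(1))
}

#' Two-group comparison of abundance values
#'
#' Welch's two-sided t-test by default (`var_equal = TRUE` for the pooled
#' variance variant), with the conventional significance label.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param var_equal assume equal variances (default `FALSE`, Welch).
#' @return list with `statistic`, `df`, `p_value`, `label`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # degenerate constant groups: no evidence of a difference
    return(list(statistic = 0, df = NA_real_, p_value = 1, label = "n.s."))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, label = significance_label(tt$p.value))
}

#' Per-sample RPKM table from count tables
#'
#' @param counts data.frame with columns `sample_id`, `target_id`,
#'   `length_bp`, `count`.
#' @param sample_sheet data.frame with `sample_id`, `group` and the
#'   normalising library size: a `total_mapped` column (reads mapped
#'   sample-wide) or, failing that, `total_reads`. Normalising by the
#'   sample-wide library size (not by reads mapped to the PUP targets alone)
#'   is what lets RPKM differences reflect differences in PUP content.
#' @param aggregate `"target"` (RPKM per target), `"family"` (sum per
#'   `family_id` column of `counts`), or `"sample"` (per-sample total).
#' @return data.frame in long format with an `rpkm` column.
#' @export
sample_rpkm <- function(counts, sample_sheet,
                        aggregate = c("target", "family", "sample")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("sample_id", "target_id", "length_bp", "count") %in% names(counts)))
  lib_col <- intersect(c("total_mapped", "total_reads"), names(sample_sheet))
  if (length(lib_col) == 0) {
    stop("sample sheet needs a total_mapped or total_reads column")
  }
  lib <- stats::setNames(as.numeric(sample_sheet[[lib_col[1]]]),
                         sample_sheet$sample_id)
  if (anyNA(lib[counts$sample_id])) {
    stop("counts contain samples missing from the sample sheet")
  }
  counts$total_mapped <- as.numeric(lib[counts$sample_id])
  if (any(counts$total_mapped <= 0)) {
    stop("sample with zero mapped reads: cannot normalise")
  }
  counts$rpkm <- rpkm(counts$count, counts$length_bp, counts$total_mapped)
  counts <- merge(counts, sample_sheet[, c("sample_id", "group")],
                  by = "sample_id")
  if (aggregate == "target") {
    out <- counts[, c("sample_id", "group", "target_id", "length_bp",
                      "count", "rpkm")]
  } else if (aggregate == "family" && "family_id" %in% names(counts)) {
    out <- stats::aggregate(rpkm ~ sample_id + group + family_id,
                            data = counts, FUN = sum)
  } else {
    out <- stats::aggregate(rpkm ~ sample_id + group, data = counts, FUN = sum)
  }
  out <- out[do.call(order, out[intersect(c("sample_id", "target_id",
                                            "family_id"), names(out))]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
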