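#' Base-level error rate from alignment edit distances
#'
#' Sum of per-read edit distances (NM: mismatches plus small indels) over
#' mapped records, divided by the total aligned query bases.
#'
#' @param records alignment record data frame (see
#'   [read_alignment_tsv()]).
#' @return fraction.
#' @export
error_rate <- function(records) {
  m <- records$mapped == 1
  if (!any(m)) stop("no mapped records")
  total <- sum(records$aligned_bases[m])
  if (total == 0) stop("zero aligned bases")
  sum(records$nm[m]) / total
}

#' Improper-pair rate
#'
#' @param records alignment record data frame; `paired` and
#'   `proper_pair` flags are used.
#' @return fraction of paired reads flagged improper, or `NA` when no
#'   paired records exist.
#' @export
improper_pair_rate <- function(records) {
  p <- records$paired == 1
  if (!any(p)) return(NA_real_)
  sum(records$proper_pair[p] == 0) / sum(p)
}

#' Mapping rate and breadth of coverage
#'
#' @param records alignment record data frame; placed reads need
#'   `chrom`, `start`, `end` columns.
#' @param chrom_lengths named vector of genome chromosome lengths.
#' @param min_depth depth floor defining a covered base.
#' @return named vector: `mapping_rate`, `breadth`.
#' @export
mapping_and_breadth <- function(records, chrom_lengths, min_depth = 1) {
  if (nrow(records) == 0) return(c(mapping_rate = 0, breadth = 0))
  mapping_rate <- mean(records$mapped == 1)
  if (!("chrom" %in% names(records)))
    return(c(mapping_rate = mapping_rate, breadth = 0))
  rec <- records[records$mapped == 1 & !is.na(records$chrom), ,
                 drop = FALSE]
  if (nrow(rec) == 0) return(c(mapping_rate = mapping_rate, breadth = 0))
  covered <- 0
  for (ch in names(chrom_lengths)) {
    r <- rec[rec$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) next
    cov <- IRanges::coverage(IRanges::IRanges(r$start + 1, r$end),
                             width = chrom_lengths[[ch]])
    covered <- covered + sum(cov >= min_depth)
  }
  c(mapping_rate = mapping_rate, breadth = covered / sum(chrom_lengths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contig N50
#'
#' Largest length L such that contigs of length >= L sum to at least
#' half the assembly.
#'
#' @param lengths numeric vector of positive contig lengths.
#' @return N50 value.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly QC report from alignment summaries
#'
#' @param records alignment record data frame.
#' @param contig_lengths contig length vector for N50 (optional).
#' @param chrom_lengths named chromosome lengths for breadth (optional).
#' @param min_depth depth floor for breadth.
#' @return object of class `qc_report` (list of metrics).
#' @export
qc_report <- function(records, contig_lengths = NULL, chrom_lengths = NULL,
                      min_depth = 1) {
  mb <- if (!is.null(chrom_lengths))
    mapping_and_breadth(records, chrom_lengths, min_depth) else
      c(mapping_rate = mean(records$mapped == 1), breadth = NA_real_)
  structure(list(error_rate = error_rate(records),
                 improper_pair_rate = improper_pair_rate(records),
                 mapping_rate = unname(mb["mapping_rate"]),
                 breadth = unname(mb["breadth"]),
                 n50 = if (is.null(contig_lengths)) NA_real_ else
                   n50(contig_lengths),
                 n_records = nrow(records)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Assembly QC report (", x$n_records, " alignment records)\n",
      sep = "")
  cat(sprintf("  error rate:         %.6f\n", x$error_rate))
  cat(sprintf("  improper-pair rate: %.6f\n", x$improper_pair_rate))
  cat(sprintf("  mapping rate:       %.6f\n", x$mapping_rate))
  if (!is.na(x$breadth))
    cat(sprintf("  coverage breadth:   %.6f\n", x$breadth))
  if (!is.na(x$n50))
    cat(sprintf("  contig N50:         %s bp\n",
                format(x$n50, big.mark = ",")))
  invisible(x)
}
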