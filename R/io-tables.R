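#' Read a BED3/BED4 annotation track
#'
#' BED is 0-based half-open, matching this package's internal convention.
#' A 4th column, when present, becomes the feature class label (`name`).
#'
#' @param path BED file (>= 3 tab-separated columns, no header).
#' @return interval data frame, sorted within chromosome.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) stop("BED parse error in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 3) stop("BED file needs >= 3 columns: ", path)
  iv <- data.frame(chrom = as.character(df[[1]]),
                   start = as.numeric(df[[2]]),
                   end = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4) iv$name <- as.character(df[[4]])
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad))
    stop("invalid BED record (start >= end) at line ", bad[1], " of ", path)
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  as_intervals(iv)
}

#' Write intervals as BED
#'
#' @param iv interval data frame; a `name` column (and `score` column, if
#'   present) is written as BED4/BED5.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  cols <- iv[, intersect(c("chrom", "start", "end", "name", "score"),
                         names(iv)), drop = FALSE]
  write.table(format(cols, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a syntenic anchor table
#'
#' Expected columns: query chrom, query start, query end, target chrom,
#' target start, target end, and optionally orientation (`+`/`-`). When the
#' orientation column is absent it is inferred per anchor from the sign of
#' the target-coordinate difference to the next anchor (the last anchor
#' inherits the preceding sign). Anchors are sorted by query position.
#'
#' @param path tab-separated anchor file, no header.
#' @param genomes optional character vector of valid chromosome names;
#'   records on other chromosomes trigger a warning but are kept.
#' @return data frame with columns `q_chrom`, `q_start`, `q_end`,
#'   `t_chrom`, `t_start`, `t_end`, `orientation`.
#' @export
read_anchor_table <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  if (ncol(df) < 6) stop("anchor table needs >= 6 columns: ", path)
  an <- data.frame(q_chrom = as.character(df[[1]]),
                   q_start = as.numeric(df[[2]]),
                   q_end = as.numeric(df[[3]]),
                   t_chrom = as.character(df[[4]]),
                   t_start = as.numeric(df[[5]]),
                   t_end = as.numeric(df[[6]]),
                   stringsAsFactors = FALSE)
  if (ncol(df) >= 7) an$orientation <- as.character(df[[7]])
  if (!is.null(genomes)) {
    unknown <- setdiff(unique(c(an$q_chrom, an$t_chrom)), genomes)
    if (length(unknown))
      warning("anchor chromosomes not in bound genomes: ",
              paste(unknown, collapse = ", "), " (records kept)")
  }
  an <- an[order(an$q_chrom, an$q_start), , drop = FALSE]
  rownames(an) <- NULL
  if (is.null(an$orientation)) an$orientation <- infer_orientation(an)
  an
}

#' Infer per-anchor orientation from the target coordinate trend
#'
#' @param anchors anchor data frame sorted by query position.
#' @return character vector of `+`/`-` per anchor.
#' @export
infer_orientation <- function(anchors) {
  unlist(lapply(split(seq_len(nrow(anchors)), anchors$q_chrom), function(ix) {
    tm <- (anchors$t_start[ix] + anchors$t_end[ix]) / 2
    n <- length(tm)
    if (n == 1) return("+")
    d <- diff(tm)
    ori <- ifelse(d < 0, "-", "+")
    c(ori, ori[n - 1])
  }), use.names = FALSE)
}

#' Read / write a bedgraph coverage track
#'
#' @param path bedgraph file (chrom, start, end, value; 0-based half-open).
#' @return data frame with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 4) stop("bedgraph needs 4 columns: ", path)
  data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
             end = as.numeric(df[[3]]), depth = as.numeric(df[[4]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param profile data frame with `chrom`, `start`, `end`, `depth`.
#' @export
write_bedgraph <- function(profile, path) {
  write.table(format(profile[, c("chrom", "start", "end", "depth")],
                     scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write alignment summary records
#'
#' Alignment summaries are consumed as a TSV (one row per read) with
#' columns `read_id`, `mapped` (0/1), `aligned_bases`, `nm` (edit
#' distance), `paired` (0/1), `proper_pair` (0/1), and optionally `chrom`,
#' `start`, `end` for placed reads. Such a table is produced from standard
#' alignment output with, e.g.,
#' `samtools view aln.bam | awk '{...print NM and flags...}'`.
#'
#' @param path TSV file with a header row.
#' @return data frame of alignment records.
#' @export
read_alignment_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("read_id", "mapped", "aligned_bases", "nm", "paired",
            "proper_pair")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("alignment TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$nm < 0, na.rm = TRUE)) stop("negative NM value")
  df
}

#' @rdname read_alignment_tsv
#' @param records alignment record data frame.
#' @export
write_alignment_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
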