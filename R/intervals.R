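#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval covers bases `start .. end - 1`. Intervals are plain data
#' frames with columns `chrom`, `start`, `end` and optionally `strand` and
#' `name`; every interval-consuming function accepts such a data frame.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end numeric vectors of 0-based half-open coordinates,
#'   `0 <= start < end`.
#' @param strand optional character vector in `+`/`-`.
#' @param name optional character vector of feature labels.
#' @return A data frame of class `intervals`.
#' @examples
#' intervals("chr1", 0, 100)
#' @export
intervals <- function(chrom = character(), start = numeric(), end = numeric(),
                      strand = NULL, name = NULL) {
  iv <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(strand)) iv$strand <- as.character(strand)
  if (!is.null(name)) iv$name <- as.character(name)
  validate_intervals(iv)
  class(iv) <- c("intervals", "data.frame")
  iv
}

validate_intervals <- function(iv, chrom_lengths = NULL) {
  stopifnot(is.data.frame(iv), all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0) return(invisible(iv))
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[iv$chrom]
    if (anyNA(len)) stop("interval on unknown chromosome: ",
                         paste(unique(iv$chrom[is.na(len)]), collapse = ", "))
    if (any(iv$end > len)) stop("interval end exceeds chromosome length")
  }
  invisible(iv)
}

empty_intervals <- function() {
  intervals(character(), numeric(), numeric())
}

#' Coerce a data frame to a validated interval set
#'
#' @param df data frame with at least `chrom`, `start`, `end` columns
#'   (0-based half-open).
#' @return the same data frame, validated, with class `intervals`.
#' @export
as_intervals <- function(df) {
  iv <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_intervals(iv)
  class(iv) <- c("intervals", "data.frame")
  iv
}

## IRanges bridge: 0-based half-open <-> 1-based closed
.iv_to_ir <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

.ir_to_iv <- function(ir, chrom) {
  data.frame(chrom = chrom,
             start = as.numeric(IRanges::start(ir)) - 1,
             end = as.numeric(IRanges::end(ir)),
             stringsAsFactors = FALSE)
}

.per_chrom <- function(iv, other = NULL, fun) {
  chroms <- sort(unique(c(iv$chrom, other$chrom)))
  out <- lapply(chroms, function(ch) {
    a <- iv[iv$chrom == ch, , drop = FALSE]
    if (is.null(other)) fun(a, ch) else {
      b <- other[other$chrom == ch, , drop = FALSE]
      fun(a, b, ch)
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(empty_intervals())
  as_intervals(res)
}

#' Interval set operations
#'
#' Merge (union of overlapping/adjacent intervals), intersect, subtract and
#' total covered length, all under half-open semantics. `iv_merge` with
#' `min_gap > 0` also fuses intervals separated by fewer than `min_gap`
#' bases. `iv_total_length` counts each base once (it merges first).
#'
#' @param iv,a,b interval data frames (see [intervals()]).
#' @param min_gap merge intervals separated by less than this many bases.
#' @return An interval data frame, or a single number for
#'   `iv_total_length`.
#' @examples
#' iv_merge(intervals(c("c1", "c1"), c(0, 5), c(10, 15)))
#' iv_intersect(intervals("c1", 0, 10), intervals("c1", 10, 20)) # empty
#' @export
iv_merge <- function(iv, min_gap = 0) {
  validate_intervals(iv)
  if (nrow(iv) == 0) return(empty_intervals())
  .per_chrom(iv, fun = function(a, ch) {
    r <- IRanges::reduce(.iv_to_ir(a), min.gapwidth = min_gap + 1L)
    .ir_to_iv(r, ch)
  })
}

#' @rdname iv_merge
#' @export
iv_intersect <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  .per_chrom(a, b, function(x, y, ch) {
    if (nrow(x) == 0 || nrow(y) == 0) return(NULL)
    r <- IRanges::intersect(.iv_to_ir(x), .iv_to_ir(y))
    if (length(r) == 0) return(NULL)
    .ir_to_iv(r, ch)
  })
}

#' @rdname iv_merge
#' @export
iv_subtract <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(iv_merge(a))
  .per_chrom(a, b, function(x, y, ch) {
    if (nrow(x) == 0) return(NULL)
    if (nrow(y) == 0) return(.ir_to_iv(IRanges::reduce(.iv_to_ir(x)), ch))
    r <- IRanges::setdiff(.iv_to_ir(x), .iv_to_ir(y))
    if (length(r) == 0) return(NULL)
    .ir_to_iv(r, ch)
  })
}

#' @rdname iv_merge
#' @export
iv_total_length <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0) return(0)
  m <- iv_merge(iv)
  sum(m$end - m$start)
}

#' Tile chromosomes into fixed-size windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window window size in bases.
#' @param step step between window starts (default: `window`,
#'   non-overlapping).
#' @return interval data frame of windows; the last window of each
#'   chromosome is clipped at the chromosome end.
#' @export
iv_windows <- function(chrom_lengths, window, step = window) {
  stopifnot(window > 0, step > 0, step <= window)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, L - 1), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, L), stringsAsFactors = FALSE)
  })
  as_intervals(do.call(rbind, out))
}
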