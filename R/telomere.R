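#' Detect terminal telomere repeat runs
#'
#' Scans each chromosome for maximal tandem runs of the telomere motif
#' (5' end) or its reverse complement (3' end). A run qualifies when it
#' has at least `min_copies` exact tandem copies and lies within
#' `terminal_window` of the respective chromosome end (run start for the
#' 5' end, run end for the 3' end). At most one hit is reported per end:
#' the qualifying run closest to that end.
#'
#' @param genome a [genome_seq()].
#' @param motif telomere repeat unit as found at the 5' end (default the
#'   plant motif `CCCTAAA`); length >= 5.
#' @param min_copies minimum tandem copies per run.
#' @param terminal_window maximum distance (bp) from the chromosome end.
#' @return data frame with columns `chrom`, `start`, `end`, `name`
#'   (`5prime`/`3prime`), `copies`, `motif`; zero rows when nothing is
#'   found.
#' @export
find_telomeres <- function(genome, motif = "CCCTAAA", min_copies = 4,
                           terminal_window = 10000) {
  motif <- toupper(motif)
  if (nchar(motif) < 5) stop("motif length must be >= 5")
  if (terminal_window < nchar(motif) * min_copies)
    stop("terminal_window must be >= motif length * min_copies")
  m <- nchar(motif)
  rc <- revcomp(motif)
  out <- NULL
  for (ch in names(genome$seq)) {
    subject <- genome$seq[[ch]]
    L <- length(subject)
    runs5 <- .tandem_runs(motif, subject, m)
    runs3 <- .tandem_runs(rc, subject, m)
    cand5 <- runs5[runs5$copies >= min_copies &
                     runs5$start < terminal_window, , drop = FALSE]
    cand3 <- runs3[runs3$copies >= min_copies &
                     L - runs3$end < terminal_window, , drop = FALSE]
    if (nrow(cand5)) {
      best <- cand5[which.min(cand5$start), ]
      out <- rbind(out, data.frame(chrom = ch, start = best$start,
                                   end = best$end, name = "5prime",
                                   copies = best$copies, motif = motif,
                                   stringsAsFactors = FALSE))
    }
    if (nrow(cand3)) {
      best <- cand3[which.max(cand3$end), ]
      out <- rbind(out, data.frame(chrom = ch, start = best$start,
                                   end = best$end, name = "3prime",
                                   copies = best$copies, motif = rc,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      copies = integer(), motif = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## maximal tandem runs of an exact motif: 0-based half-open coordinates
.tandem_runs <- function(motif, subject, m) {
  hits <- Biostrings::matchPattern(motif, subject)
  if (length(hits) == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      copies = integer()))
  s <- sort(Biostrings::start(hits))
  ## chain matches spaced exactly one motif apart; off-register overlaps
  ## inside a chain are ignored
  starts <- integer(0); copies <- integer(0)
  cur_start <- s[1]; cur_next <- s[1] + m; n <- 1L
  for (x in s[-1]) {
    if (x == cur_next) {
      cur_next <- cur_next + m
      n <- n + 1L
    } else if (x > cur_next) {
      starts <- c(starts, cur_start); copies <- c(copies, n)
      cur_start <- x; cur_next <- x + m; n <- 1L
    } # x < cur_next: overlapping off-register match, ignore
  }
  starts <- c(starts, cur_start); copies <- c(copies, n)
  data.frame(start = as.numeric(starts) - 1,
             end = as.numeric(starts) - 1 + as.numeric(copies) * m,
             copies = copies)
}
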