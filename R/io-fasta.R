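#' Genome sequence container
#'
#' A `genome_seq` holds an ordered set of named chromosome sequences
#' (uppercase A/C/G/T/N) plus an optional soft-mask track: lowercase bases
#' in the source FASTA are recorded as intervals rather than hard-masked.
#' Ambiguity codes other than N are rejected.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param mask optional interval data frame of soft-masked regions.
#' @return A `genome_seq` object (list with elements `seq`, a
#'   `DNAStringSet`, and `mask`, an interval data frame).
#' @export
genome_seq <- function(seqs, mask = NULL) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("all chromosomes must be named")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  nm <- names(seqs)
  if (anyDuplicated(nm)) stop("duplicate chromosome id: ",
                              nm[duplicated(nm)][1])
  if (any(Biostrings::width(seqs) == 0)) stop("zero-length chromosome")
  freq <- rowSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T", "N")))
  if (any(freq != Biostrings::width(seqs)))
    stop("sequence contains letters outside A/C/G/T/N (ambiguity codes are ",
         "not supported): ", nm[which(freq != Biostrings::width(seqs))[1]])
  if (is.null(mask)) mask <- empty_intervals() else validate_intervals(mask)
  structure(list(seq = seqs, mask = as_intervals(mask)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq:", length(x$seq), "chromosome(s),",
      format(sum(Biostrings::width(x$seq)), big.mark = ","), "bp total\n")
  lens <- chrom_lengths(x)
  for (i in seq_along(lens))
    cat("  ", names(lens)[i], ": ", format(lens[i], big.mark = ","), " bp\n",
        sep = "")
  invisible(x)
}

#' @rdname genome_seq
#' @param genome a `genome_seq` object.
#' @return `chrom_lengths`: named numeric vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(as.numeric(Biostrings::width(genome$seq)), names(genome$seq))
}

#' Extract a chromosome or region as a character string
#'
#' @param genome a `genome_seq`.
#' @param chrom chromosome id.
#' @param start,end optional 0-based half-open bounds (default whole
#'   chromosome).
#' @return character scalar.
#' @export
genome_subseq <- function(genome, chrom, start = 0,
                          end = chrom_lengths(genome)[[chrom]]) {
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  L <- chrom_lengths(genome)[[chrom]]
  stopifnot(start >= 0, end <= L, start < end)
  as.character(Biostrings::subseq(genome$seq[[chrom]], start + 1, end))
}

#' Read a FASTA file into a genome_seq
#'
#' Sequences are uppercased; lowercase (soft-masked) stretches are recorded
#' on the mask track. Duplicate headers and letters outside A/C/G/T/N are
#' rejected.
#'
#' @param path FASTA file.
#' @return a [genome_seq()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) stop("duplicate FASTA header: ",
                              nm[duplicated(nm)][1])
  names(raw) <- nm
  ## lowercase runs -> soft-mask intervals
  mask <- do.call(rbind, lapply(seq_along(raw), function(i) {
    s <- as.character(raw[[i]])
    m <- gregexpr("[a-z]+", s)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(chrom = nm[i], start = as.numeric(m) - 1,
               end = as.numeric(m) + attr(m, "match.length") - 1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(mask)) mask <- empty_intervals()
  genome_seq(setNames(toupper(as.character(raw)), nm), mask = mask)
}

#' Write a genome_seq to FASTA
#'
#' @param genome a [genome_seq()].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  Biostrings::writeXStringSet(genome$seq, path, width = width)
  invisible(path)
}
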