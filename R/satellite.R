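#' Scan a genome for satellite monomer hits
#'
#' Finds non-overlapping monomer-sized hits tiling each satellite array,
#' scored by alignment identity against the monomer in both orientations;
#' hits below `min_identity` are suppressed. Two modes share the same
#' scoring: `"seeded"` (default) restricts candidate start positions to
#' exact k-mer seed matches and is fast enough for Mb-scale genomes;
#' `"exact"` evaluates every start position and serves as the exhaustive
#' reference for moderate sequences. Candidate identity is
#' `(m - d) / m` where `d` is the number of mismatches of the monomer
#' laid gap-free against the sequence at the candidate position and `m`
#' the monomer length: satellite monomer copies diverge predominantly by
#' substitution, and copies with larger indels simply fall below the
#' identity threshold. Hits are tiled greedily by descending identity,
#' ties broken by leftmost start.
#'
#' @param genome a [genome_seq()].
#' @param monomer monomer sequence (A/C/G/T/N), length >= 50.
#' @param min_identity minimum identity in `[0, 1]` (default 0.90).
#' @param mode `"seeded"` or `"exact"`.
#' @param seed_k,seed_every k-mer seed length and spacing along the
#'   monomer (seeded mode).
#' @param skip_masked drop hits overlapping the genome's soft-mask track.
#' @return data frame with columns `chrom`, `start`, `end`, `identity`,
#'   `orientation` (`+`/`-`), sorted by position.
#' @export
scan_satellite <- function(genome, monomer, min_identity = 0.90,
                           mode = c("seeded", "exact"), seed_k = 13,
                           seed_every = 31, skip_masked = FALSE) {
  mode <- match.arg(mode)
  monomer <- toupper(monomer)
  if (grepl("[^ACGTN]", monomer))
    stop("monomer contains letters outside A/C/G/T/N")
  m <- nchar(monomer)
  if (m < 50) stop("monomer length must be >= 50")
  pats <- c(`+` = monomer, `-` = revcomp(monomer))
  out <- NULL
  for (ch in names(genome$seq)) {
    subject <- genome$seq[[ch]]
    L <- length(subject)
    if (L < m) next
    cand <- NULL
    for (ori in names(pats)) {
      pat <- Biostrings::DNAString(pats[[ori]])
      starts1 <- if (mode == "exact") seq_len(L - m + 1) else
        .seed_candidates(pat, subject, m, L, seed_k, seed_every)
      if (length(starts1) == 0) next
      d <- Biostrings::neditStartingAt(pat, subject, starting.at = starts1,
                                       with.indels = FALSE)
      ident <- (m - d) / m
      keep <- ident >= min_identity
      if (!any(keep)) next
      cand <- rbind(cand, data.frame(start = starts1[keep] - 1,
                                     identity = ident[keep],
                                     orientation = ori,
                                     stringsAsFactors = FALSE))
    }
    if (is.null(cand) || nrow(cand) == 0) next
    sel <- .greedy_tile(cand, m, L)
    if (nrow(sel) == 0) next
    out <- rbind(out, data.frame(chrom = ch, start = sel$start,
                                 end = pmin(sel$start + m, L),
                                 identity = sel$identity,
                                 orientation = sel$orientation,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), identity = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (skip_masked && nrow(out) > 0 && nrow(genome$mask) > 0) {
    hitiv <- as_intervals(out[, c("chrom", "start", "end")])
    ov <- iv_intersect(hitiv, genome$mask)
    if (nrow(ov) > 0) {
      drop <- vapply(seq_len(nrow(out)), function(i) {
        any(ov$chrom == out$chrom[i] & ov$start < out$end[i] &
              ov$end > out$start[i])
      }, logical(1))
      out <- out[!drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

## candidate 1-based start positions from exact k-mer seed matches
.seed_candidates <- function(pat, subject, m, L, k, every) {
  offs <- unique(c(seq(1, m - k + 1, by = every), m - k + 1))
  starts <- integer(0)
  for (o in offs) {
    seed <- Biostrings::subseq(pat, o, o + k - 1)
    hits <- Biostrings::start(Biostrings::matchPattern(seed, subject))
    if (length(hits)) starts <- c(starts, hits - o + 1L)
  }
  starts <- unique(starts)
  sort(starts[starts >= 1 & starts <= L - m + 1])
}

## greedy non-overlapping selection by descending identity, leftmost ties
.greedy_tile <- function(cand, m, L) {
  cand <- cand[order(-cand$identity, cand$start), , drop = FALSE]
  taken <- logical(L)
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i] + 1
    e <- min(cand$start[i] + m, L)
    if (!any(taken[s:e])) {
      taken[s:e] <- TRUE
      sel[i] <- TRUE
    }
  }
  res <- cand[sel, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Consensus of a set of satellite monomers
#'
#' Star alignment around the medoid monomer: every monomer is globally
#' aligned to the medoid, bases are projected onto medoid columns
#' (insertions relative to the medoid are dropped), and each column takes
#' the majority base, ties broken in fixed order A < C < G < T.
#' Gap-majority columns are dropped.
#'
#' @param monomers character vector of >= 2 monomer sequences of
#'   comparable length (range must not exceed 50% of the shortest).
#' @return consensus sequence (character scalar).
#' @export
build_consensus <- function(monomers) {
  monomers <- toupper(monomers)
  n <- length(monomers)
  if (n < 2) stop("need >= 2 monomers")
  lens <- nchar(monomers)
  if ((max(lens) - min(lens)) / min(lens) > 0.5)
    stop("monomer lengths differ by more than 50%; split the class first")
  ## medoid from a deterministic subsample
  ix <- unique(round(seq(1, n, length.out = min(n, 15))))
  sub <- monomers[ix]
  idm <- vapply(seq_along(sub), function(i) {
    mean(vapply(seq_along(sub)[-i], function(j)
      pairwise_identity(sub[i], sub[j]), numeric(1)))
  }, numeric(1))
  medoid <- sub[which.max(idm)]
  mlen <- nchar(medoid)
  ## project every monomer onto medoid columns
  cols <- matrix("-", nrow = n, ncol = mlen)
  for (i in seq_len(n)) {
    if (monomers[i] == medoid) {
      cols[i, ] <- strsplit(medoid, "")[[1]]
      next
    }
    aln <- .nw_align(monomers[i], medoid)
    qa <- strsplit(aln$a, "")[[1]]
    sa <- strsplit(aln$b, "")[[1]]
    pos <- 0L
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        pos <- pos + 1L
        cols[i, pos] <- qa[k]
      }
    }
  }
  base_order <- c("A", "C", "G", "T")
  cons <- vapply(seq_len(mlen), function(j) {
    v <- cols[, j]
    ngap <- sum(v == "-")
    if (ngap > n / 2) return("")
    cnt <- vapply(base_order, function(b) sum(v == b), numeric(1))
    base_order[which.max(cnt)]
  }, character(1))
  paste(cons, collapse = "")
}

## global Needleman-Wunsch via Biostrings; returns aligned strings
.nw_align <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Count variant bases of a monomer against a consensus
#'
#' The monomer is globally aligned to the consensus; the count is the
#' number of aligned columns with differing bases plus one per gap
#' opening (a multi-base indel counts once).
#'
#' @param monomer,consensus nucleotide strings.
#' @return integer variant count.
#' @export
count_variants <- function(monomer, consensus) {
  if (!nzchar(monomer) || !nzchar(consensus)) stop("empty input sequence")
  aln <- .nw_align(toupper(monomer), toupper(consensus))
  a <- strsplit(aln$a, "")[[1]]
  b <- strsplit(aln$b, "")[[1]]
  gap <- a == "-" | b == "-"
  mism <- sum(!gap & a != b)
  openings <- sum(diff(c(FALSE, gap)) == 1)
  as.integer(mism + openings)
}

#' Global pairwise identity of two sequences
#'
#' Identity is matches divided by alignment columns of a global
#' Needleman-Wunsch alignment (match +1, mismatch -1, gap -1 per base).
#'
#' @param a,b nucleotide strings (nonempty).
#' @return fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  if (a == b) return(1)
  aln <- .nw_align(toupper(a), toupper(b))
  x <- strsplit(aln$a, "")[[1]]
  y <- strsplit(aln$b, "")[[1]]
  sum(x == y & x != "-") / length(x)
}

#' Monomer similarity summarised by comparison stratum
#'
#' Pairwise identities are summarised within three strata: pairs from the
#' same chromosome of the same genome, pairs from different chromosomes of
#' the same genome, and pairs from different genomes. Monomer sets larger
#' than `cap` are first subsampled proportionally by chromosome (fixed
#' seed); identities are then computed on up to `max_pairs` random pairs
#' per stratum.
#'
#' @param monomers data frame with columns `seq`, `genome`, `chrom`.
#' @param cap monomer subsample cap (default 1800).
#' @param max_pairs pairs scored per stratum.
#' @param seed subsampling seed.
#' @return data frame: `stratum`, `n_monomers`, `n_pairs`, `mean`, `q25`,
#'   `median`, `q75`. Strata with fewer than 2 monomers are omitted with
#'   a warning.
#' @export
similarity_classes <- function(monomers, cap = 1800, max_pairs = 500,
                               seed = 1) {
  stopifnot(all(c("seq", "genome", "chrom") %in% names(monomers)))
  set.seed(seed)
  if (nrow(monomers) > cap) {
    key <- paste(monomers$genome, monomers$chrom)
    tab <- table(key)
    take <- pmax(1, round(as.numeric(tab) / nrow(monomers) * cap))
    keep <- unlist(lapply(names(tab), function(k) {
      ix <- which(key == k)
      sample(ix, min(length(ix), take[names(tab) == k]))
    }))
    monomers <- monomers[sort(keep), , drop = FALSE]
  }
  n <- nrow(monomers)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i < pairs$j, ]
  same_genome <- monomers$genome[pairs$i] == monomers$genome[pairs$j]
  same_chrom <- monomers$chrom[pairs$i] == monomers$chrom[pairs$j]
  strata <- list(
    within_chromosome = which(same_genome & same_chrom),
    among_chromosomes = which(same_genome & !same_chrom),
    between_genomes = which(!same_genome))
  out <- NULL
  for (s in names(strata)) {
    px <- strata[[s]]
    if (length(px) == 0) {
      warning("stratum ", s, " has fewer than 2 monomers; omitted")
      next
    }
    px <- if (length(px) > max_pairs) sample(px, max_pairs) else px
    ids <- vapply(px, function(p) pairwise_identity(
      monomers$seq[pairs$i[p]], monomers$seq[pairs$j[p]]), numeric(1))
    q <- quantile(ids, c(0.25, 0.5, 0.75), names = FALSE)
    out <- rbind(out, data.frame(
      stratum = s,
      n_monomers = length(unique(c(pairs$i[strata[[s]]],
                                   pairs$j[strata[[s]]]))),
      n_pairs = length(px), mean = mean(ids), q25 = q[1], median = q[2],
      q75 = q[3], stringsAsFactors = FALSE))
  }
  out
}
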