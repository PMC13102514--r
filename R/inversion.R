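#' Detect inversions from syntenic anchors
#'
#' An inversion is a maximal run of at least `min_anchors` anchors in
#' reverse orientation (target coordinates decreasing along the query),
#' tolerating up to `max_noise` interleaved discordant anchors between
#' consecutive reverse anchors; longer discordant stretches split runs.
#' Call bounds span the first to the last reverse anchor of the run on
#' both genomes.
#'
#' @param anchors anchor data frame (`q_chrom`, `q_start`, `q_end`,
#'   `t_chrom`, `t_start`, `t_end`, optional `orientation`); orientation
#'   is inferred from the target trend when absent. Unsorted input is
#'   sorted with a warning.
#' @param min_anchors minimum reverse anchors per call.
#' @param max_noise maximum interleaved discordant anchors tolerated.
#' @return data frame of calls: `id`, `q_chrom`, `q_start`, `q_end`,
#'   `t_chrom`, `t_start`, `t_end`, `n_anchors`, `n_noise`,
#'   `consistency`.
#' @export
detect_inversions <- function(anchors, min_anchors = 5, max_noise = 2) {
  if (nrow(anchors) == 0) return(.empty_inv_calls())
  ord <- order(anchors$q_chrom, anchors$q_start)
  if (!identical(ord, seq_len(nrow(anchors)))) {
    warning("anchors not sorted by query coordinate; sorting")
    anchors <- anchors[ord, , drop = FALSE]
  }
  if (is.null(anchors$orientation))
    anchors$orientation <- infer_orientation(anchors)
  out <- NULL
  for (ch in unique(anchors$q_chrom)) {
    an <- anchors[anchors$q_chrom == ch, , drop = FALSE]
    minus <- which(an$orientation == "-")
    if (length(minus) == 0) next
    ## split where more than max_noise discordant anchors intervene
    gap <- c(0, diff(minus) - 1)
    run_id <- cumsum(gap > max_noise)
    for (rid in unique(run_id)) {
      ix <- minus[run_id == rid]
      if (length(ix) < min_anchors) next
      span <- an[ix, , drop = FALSE]
      n_noise <- (max(ix) - min(ix) + 1) - length(ix)
      out <- rbind(out, data.frame(
        q_chrom = ch, q_start = span$q_start[1],
        q_end = span$q_end[nrow(span)],
        t_chrom = span$t_chrom[1], t_start = min(span$t_start),
        t_end = max(span$t_end), n_anchors = length(ix),
        n_noise = n_noise,
        consistency = length(ix) / (length(ix) + n_noise),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(.empty_inv_calls())
  out <- out[order(out$q_chrom, out$q_start), , drop = FALSE]
  out <- cbind(id = sprintf("inv%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.empty_inv_calls <- function() {
  data.frame(id = character(), q_chrom = character(), q_start = numeric(),
             q_end = numeric(), t_chrom = character(), t_start = numeric(),
             t_end = numeric(), n_anchors = integer(), n_noise = integer(),
             consistency = numeric(), stringsAsFactors = FALSE)
}

#' Breakpoint flank windows for inversion calls
#'
#' For each inversion edge, a window of `flank` bases extending outward
#' from the call boundary (or centered on it with `centered = TRUE`),
#' clipped at chromosome ends; clipping is recorded.
#'
#' @param calls inversion-call data frame (see [detect_inversions()]).
#' @param chrom_lengths named vector of query chromosome lengths.
#' @param flank flank width in bases (default 40 kb); must be > 0.
#' @param centered center the windows on the boundaries instead of
#'   extending outward.
#' @return interval data frame with columns `chrom`, `start`, `end`,
#'   `name` (`<id>_left` / `<id>_right`), `clipped`.
#' @export
define_breakpoints <- function(calls, chrom_lengths, flank = 40000,
                               centered = FALSE) {
  if (flank <= 0) stop("flank must be > 0")
  if (nrow(calls) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      clipped = logical(), stringsAsFactors = FALSE))
  out <- NULL
  for (i in seq_len(nrow(calls))) {
    ch <- calls$q_chrom[i]
    L <- chrom_lengths[[ch]]
    id <- if (!is.null(calls$id)) calls$id[i] else sprintf("inv%02d", i)
    if (centered) {
      lw <- c(calls$q_start[i] - flank / 2, calls$q_start[i] + flank / 2)
      rw <- c(calls$q_end[i] - flank / 2, calls$q_end[i] + flank / 2)
    } else {
      lw <- c(calls$q_start[i] - flank, calls$q_start[i])
      rw <- c(calls$q_end[i], calls$q_end[i] + flank)
    }
    for (side in c("left", "right")) {
      w <- if (side == "left") lw else rw
      s <- max(0, w[1]); e <- min(L, w[2])
      if (e <= s) next
      out <- rbind(out, data.frame(
        chrom = ch, start = s, end = e, name = paste0(id, "_", side),
        clipped = s != w[1] || e != w[2], stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fraction of a region covered at a depth floor
#'
#' @param profile coverage data frame (`chrom`, `start`, `end`, `depth`);
#'   bins must cover the interval.
#' @param interval one-row interval data frame.
#' @param min_depth depth floor defining "covered" (default 1).
#' @return fraction in `[0, 1]`; partial bins are weighted by overlap.
#' @export
covered_fraction <- function(profile, interval, min_depth = 1) {
  stopifnot(nrow(interval) == 1)
  p <- profile[profile$chrom == interval$chrom, , drop = FALSE]
  span <- iv_merge(data.frame(chrom = p$chrom, start = p$start,
                              end = p$end))
  covered_by_bins <- nrow(span) > 0 &&
    any(span$start <= interval$start & span$end >= interval$end)
  if (!covered_by_bins)
    stop("coverage profile does not span the requested interval")
  ov <- pmax(0, pmin(p$end, interval$end) - pmax(p$start, interval$start))
  sum(ov[p$depth >= min_depth]) / (interval$end - interval$start)
}

#' Coverage-based inversion genotype
#'
#' Classifies an accession as reference (`REF`) when its covered fraction
#' over the inversion strictly exceeds the threshold, otherwise inverted
#' (`INV`). The default 0.94 makes 0.94 itself an `INV` call.
#'
#' @param fraction covered fraction(s) in `[0, 1]`.
#' @param threshold strict lower bound for a `REF` call.
#' @return character vector of `REF`/`INV`.
#' @export
genotype_by_coverage <- function(fraction, threshold = 0.94) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction > threshold, "REF", "INV")
}

## exact 1-D two-means: minimise within-cluster SS over all split points
.two_means_1d <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); css <- cumsum(xs^2)
  ss <- vapply(seq_len(n - 1), function(k) {
    s1 <- cs[k]; s2 <- cs[n] - cs[k]
    q1 <- css[k]; q2 <- css[n] - css[k]
    (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
  }, numeric(1))
  k <- which.min(ss)
  cl <- integer(n)
  cl[ord] <- rep(1:2, c(k, n - k))
  cl
}

#' Inversion genotyping from inversion-region PCA
#'
#' Genotypes are centered and scaled per site (zero-variance sites
#' dropped, missing genotypes mean-imputed), decomposed by PCA, and
#' accessions are partitioned by exact 1-D two-means on PC1. Cluster
#' labels are mapped to `REF`/`INV` to maximise agreement with coverage
#' calls when supplied, otherwise the minority cluster is labelled `INV`.
#'
#' @param geno genotype matrix (accessions x sites, 0/1/2/NA) or a
#'   [variant_set()].
#' @param sites optional column index/logical vector restricting to
#'   inversion-region sites.
#' @param coverage_calls optional named `REF`/`INV` vector used to orient
#'   cluster labels.
#' @return list with `calls` (named `REF`/`INV`/`NA` vector), `varfrac`
#'   (per-PC variance fractions), `scores` (PC coordinates).
#' @export
pca_genotype <- function(geno, sites = NULL, coverage_calls = NULL) {
  if (inherits(geno, "variant_set")) geno <- geno$geno
  if (!is.null(sites)) geno <- geno[, sites, drop = FALSE]
  acc <- rownames(geno)
  na_calls <- setNames(rep(NA_character_, nrow(geno)), acc)
  if (nrow(geno) < 2 || ncol(geno) < 2)
    return(list(calls = na_calls, varfrac = numeric(0), scores = NULL))
  v <- apply(geno, 2, stats::var, na.rm = TRUE)
  keep <- !is.na(v) & v > 0
  if (sum(keep) < 2)
    return(list(calls = na_calls, varfrac = numeric(0), scores = NULL))
  x <- geno[, keep, drop = FALSE]
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  cl <- .two_means_1d(pc$x[, 1])
  calls <- character(nrow(x))
  if (!is.null(coverage_calls)) {
    cov <- coverage_calls[acc]
    agree1 <- sum(ifelse(cl == 1, "REF", "INV") == cov, na.rm = TRUE)
    agree2 <- sum(ifelse(cl == 1, "INV", "REF") == cov, na.rm = TRUE)
    ref_cluster <- if (agree1 >= agree2) 1 else 2
  } else {
    ref_cluster <- if (sum(cl == 1) >= sum(cl == 2)) 1 else 2
  }
  calls <- ifelse(cl == ref_cluster, "REF", "INV")
  list(calls = setNames(calls, acc), varfrac = varfrac, scores = pc$x)
}

#' Reconcile coverage and PCA inversion genotypes
#'
#' Concordant calls pass through; discordant calls take the coverage call
#' (the primary signal) with the conflict flag set, replacing manual
#' inspection with an explicit flag. Accessions present in only one input
#' get an `NA` final call with a warning.
#'
#' @param coverage_calls,pca_calls named `REF`/`INV` vectors.
#' @param groups optional named group labels; when given, per-group
#'   frequencies of the `INV` call are attached as attribute
#'   `group_freq`.
#' @return data frame: `accession`, `coverage_call`, `pca_call`,
#'   `final_call`, `conflict`.
#' @export
reconcile_genotypes <- function(coverage_calls, pca_calls, groups = NULL) {
  acc <- union(names(coverage_calls), names(pca_calls))
  in_cov <- acc %in% names(coverage_calls)
  in_pca <- acc %in% names(pca_calls)
  if (any(!in_cov | !in_pca))
    warning("accession(s) present in only one input; final call NA")
  cov <- ifelse(in_cov, coverage_calls[acc], NA_character_)
  pca <- ifelse(in_pca, pca_calls[acc], NA_character_)
  ## coverage is the primary signal; a PCA NA (e.g. monomorphic region)
  ## falls back to it without raising a conflict
  final <- ifelse(in_cov & in_pca, cov, NA_character_)
  conflict <- !is.na(cov) & !is.na(pca) & cov != pca
  out <- data.frame(accession = acc, coverage_call = unname(cov),
                    pca_call = unname(pca), final_call = unname(final),
                    conflict = unname(conflict), stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    g <- groups[acc]
    freq <- tapply(out$final_call == "INV", g, mean, na.rm = TRUE)
    attr(out, "group_freq") <- freq
  }
  out
}
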