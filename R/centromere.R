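#' Windowed tandem-repeat density
#'
#' Fraction of bases covered by tandem/satellite annotation per window.
#'
#' @param hits interval data frame of satellite/tandem-repeat features.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window,step window size and step (bp), `window >= step > 0`.
#' @return data frame `chrom`, `start`, `end`, `density`.
#' @export
tandem_density <- function(hits, chrom_lengths, window = 1e5,
                           step = window) {
  stopifnot(window >= step, step > 0)
  win <- iv_windows(chrom_lengths, window, step)
  merged <- iv_merge(hits)
  win$density <- 0
  for (ch in unique(win$chrom)) {
    wix <- which(win$chrom == ch)
    h <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(h) == 0) next
    cov <- IRanges::coverage(.iv_to_ir(h), width = chrom_lengths[[ch]])
    v <- IRanges::Views(cov, start = win$start[wix] + 1, end = win$end[wix])
    win$density[wix] <- IRanges::viewSums(v) / (win$end[wix] -
                                                  win$start[wix])
  }
  win
}

#' Delineate one centromere per chromosome
#'
#' Satellite hits within `merge_gap` of each other are merged into
#' arrays; the array overlapping the densest tandem-repeat window is the
#' centromere (mode `array-anchored`). Chromosomes without satellite hits
#' fall back to the maximal contiguous run of windows with density >=
#' `min_density` (mode `density-inferred`). Chromosomes with neither
#' signal are reported as `undetermined` (NA bounds), not an error.
#'
#' @param hits satellite hit intervals (e.g. from [scan_satellite()]).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param density optional density track from [tandem_density()];
#'   computed from `hits` when `NULL`.
#' @param merge_gap merge satellite hits closer than this (bp).
#' @param min_density density floor for the fallback mode.
#' @param window density window size when `density` is computed here.
#' @return data frame: `chrom`, `start`, `end`, `n_hits`, `mean_density`,
#'   `mode`.
#' @export
delineate_centromere <- function(hits, chrom_lengths, density = NULL,
                                 merge_gap = 5e4, min_density = 0.5,
                                 window = 1e5) {
  if (is.null(density)) density <- tandem_density(hits, chrom_lengths,
                                                  window)
  out <- NULL
  for (ch in names(chrom_lengths)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    dch <- density[density$chrom == ch, , drop = FALSE]
    row <- data.frame(chrom = ch, start = NA_real_, end = NA_real_,
                      n_hits = 0L, mean_density = NA_real_,
                      mode = "undetermined", stringsAsFactors = FALSE)
    if (nrow(h) > 0) {
      arrays <- iv_merge(h, min_gap = merge_gap)
      ## array overlapping the densest window; fall back to largest array
      pick <- NULL
      if (nrow(dch) > 0 && any(dch$density > 0)) {
        dw <- dch[which.max(dch$density), ]
        ov <- arrays$start < dw$end & arrays$end > dw$start
        if (any(ov)) pick <- arrays[which(ov)[1], ]
      }
      if (is.null(pick))
        pick <- arrays[which.max(arrays$end - arrays$start), ]
      n_sup <- sum(h$start >= pick$start & h$end <= pick$end)
      dens_in <- dch$density[dch$start < pick$end & dch$end > pick$start]
      row <- data.frame(chrom = ch, start = pick$start, end = pick$end,
                        n_hits = n_sup,
                        mean_density = if (length(dens_in))
                          mean(dens_in) else NA_real_,
                        mode = "array-anchored", stringsAsFactors = FALSE)
    } else if (nrow(dch) > 0 && any(dch$density >= min_density)) {
      ok <- dch$density >= min_density
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- data.frame(s = starts[r$values], e = ends[r$values])
      runs$len <- runs$e - runs$s + 1
      best <- runs[which.max(runs$len), ]
      row <- data.frame(chrom = ch, start = dch$start[best$s],
                        end = dch$end[best$e], n_hits = 0L,
                        mean_density = mean(dch$density[best$s:best$e]),
                        mode = "density-inferred", stringsAsFactors = FALSE)
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Chromosome arm ratio around a centromere
#'
#' Arms are measured from the chromosome ends to the centromere edges;
#' the ratio is long arm / short arm (>= 1). A centromere touching a
#' chromosome end yields an infinite ratio (telocentric flag).
#'
#' @param chrom_length chromosome length (bp).
#' @param centromere one-row interval data frame (within the chromosome).
#' @return data frame: `chrom`, `short_arm`, `long_arm`, `ratio`,
#'   `telocentric`.
#' @export
arm_ratio <- function(chrom_length, centromere) {
  stopifnot(nrow(centromere) == 1, centromere$end <= chrom_length)
  left <- centromere$start
  right <- chrom_length - centromere$end
  short <- min(left, right); long <- max(left, right)
  data.frame(chrom = centromere$chrom, short_arm = short, long_arm = long,
             ratio = if (short == 0) Inf else long / short,
             telocentric = short == 0, stringsAsFactors = FALSE)
}

#' Call centromere repositioning between two syntenic chromosomes
#'
#' The centromere midpoint of genome A is projected into genome B by
#' linear interpolation between the nearest flanking syntenic anchors;
#' the verdict is `repositioned` when the projected point falls outside
#' the genome-B centromere extended by `threshold` on both sides. When an
#' inversion call overlaps the query-side projection path it is attached.
#'
#' @param cenA,cenB one-row centromere intervals in genomes A and B (same
#'   syntenic chromosome pair).
#' @param anchors anchor data frame (`q_*` = genome A, `t_*` = genome B)
#'   for that chromosome pair.
#' @param threshold distance tolerance (bp, default 1 Mb).
#' @param inversions optional inversion-call data frame (from
#'   [detect_inversions()]); an overlapping call's id is attached.
#' @return data frame: `chrom_a`, `chrom_b`, `projected`, `distance`,
#'   `verdict`, `inversion_id`.
#' @export
detect_repositioning <- function(cenA, cenB, anchors, threshold = 1e6,
                                 inversions = NULL) {
  stopifnot(nrow(cenA) == 1, nrow(cenB) == 1)
  an <- anchors[anchors$q_chrom == cenA$chrom, , drop = FALSE]
  an <- an[order(an$q_start), , drop = FALSE]
  mid <- (cenA$start + cenA$end) / 2
  qm <- (an$q_start + an$q_end) / 2
  tm <- (an$t_start + an$t_end) / 2
  li <- which(qm <= mid)
  ri <- which(qm >= mid)
  res <- data.frame(chrom_a = cenA$chrom, chrom_b = cenB$chrom,
                    projected = NA_real_, distance = NA_real_,
                    verdict = "undetermined", inversion_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(li) == 0 || length(ri) == 0) return(res)
  l <- max(li); r <- min(ri)
  proj <- if (qm[r] == qm[l]) tm[l] else
    tm[l] + (mid - qm[l]) / (qm[r] - qm[l]) * (tm[r] - tm[l])
  dist <- if (proj >= cenB$start && proj <= cenB$end) 0 else
    min(abs(proj - cenB$start), abs(proj - cenB$end))
  verdict <- if (proj < cenB$start - threshold ||
                 proj > cenB$end + threshold) "repositioned" else
                   "conserved"
  res$projected <- proj
  res$distance <- dist
  res$verdict <- verdict
  if (!is.null(inversions) && nrow(inversions) > 0) {
    lo <- min(mid, proj); hi <- max(mid, proj)
    ov <- inversions$q_chrom == cenA$chrom &
      inversions$q_start < hi & inversions$q_end > lo
    if (any(ov)) res$inversion_id <- inversions$id[which(ov)[1]]
  }
  res
}
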