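#' Occupancy of an annotation within an interval set
#'
#' Total bases of overlap between the interval set and the annotation,
#' each base counted once.
#'
#' @param iv interval data frame (e.g. breakpoint windows).
#' @param annotation interval data frame of one repeat class.
#' @return number of overlapping bases.
#' @export
occupancy <- function(iv, annotation) {
  if (nrow(iv) == 0 || nrow(annotation) == 0) return(0)
  iv_total_length(iv_intersect(iv_merge(iv), iv_merge(annotation)))
}

## cumulative coverage lookup: C[[ch]][i+1] = covered bases in [0, i)
.cum_cov <- function(annotation, chrom_lengths) {
  merged <- iv_merge(annotation)
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    d <- numeric(L + 1)
    h <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(h) > 0) {
      for (i in seq_len(nrow(h))) {
        d[h$start[i] + 1] <- d[h$start[i] + 1] + 1
        if (h$end[i] < L) d[h$end[i] + 1 + 1] <- d[h$end[i] + 1 + 1] - 1
      }
    }
    out[[ch]] <- c(0, cumsum(cumsum(d)[seq_len(L)]))
  }
  out
}

## allowed start-position intervals for an interval of length len that
## must avoid the mask entirely; returns data.frame + cumulative weights
.allowed_starts <- function(len, chrom_lengths, mask) {
  space <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < len) return(NULL)
    data.frame(chrom = ch, start = 0, end = L - len + 1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(space)) return(NULL)
  space <- as_intervals(space)
  if (!is.null(mask) && nrow(mask) > 0) {
    forb <- mask
    forb$start <- pmax(0, forb$start - len + 1)
    forb <- forb[forb$start < forb$end, , drop = FALSE]
    space <- iv_subtract(space, as_intervals(forb))
  }
  if (nrow(space) == 0) return(NULL)
  space$w <- space$end - space$start
  space$cum <- cumsum(space$w)
  space
}

## draw n start positions uniformly over the allowed space
.draw_starts <- function(space, n) {
  u <- runif(n) * space$cum[nrow(space)]
  seg <- findInterval(u, c(0, space$cum), rightmost.closed = TRUE)
  start <- pmin(floor(space$start[seg] + (u - c(0, space$cum)[seg])),
                space$end[seg] - 1)
  data.frame(chrom = space$chrom[seg], start = start,
             stringsAsFactors = FALSE)
}

#' Sample length-matched random intervals avoiding a mask
#'
#' For each requested length, one interval is placed uniformly at random
#' among all start positions (across chromosomes, weighted by available
#' unmasked span) such that it avoids the mask entirely. Sampled
#' intervals may overlap each other.
#'
#' @param lengths numeric vector of interval lengths.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param mask optional interval data frame to avoid.
#' @return interval data frame with one row per requested length.
#' @export
sample_matched_intervals <- function(lengths, chrom_lengths, mask = NULL) {
  out <- lapply(lengths, function(len) {
    space <- .allowed_starts(len, chrom_lengths, mask)
    if (is.null(space))
      stop("no valid unmasked placement for an interval of length ", len)
    s <- .draw_starts(space, 1)
    data.frame(chrom = s$chrom, start = s$start, end = s$start + len,
               stringsAsFactors = FALSE)
  })
  as_intervals(do.call(rbind, out))
}

#' Permutation test of repeat occupancy at breakpoint windows
#'
#' The observed occupancy of each annotation class within the breakpoint
#' windows is compared against `n_perm` sets of length-matched random
#' intervals sampled uniformly from the unmasked genome (one shared
#' permutation set per iteration across classes). With `k` the number of
#' iterations where the observed occupancy strictly exceeds the permuted
#' one, the p-value is `(N - k) / N`; ties count against enrichment.
#' `smoothed = TRUE` reports `(N - k + 1) / (N + 1)` instead.
#'
#' Matched intervals are sampled independently per breakpoint (no joint
#' non-overlap constraint) and each interval's overlap is summed
#' independently into the permuted occupancy; bases shared by two
#' sampled intervals of the same iteration count once per interval.
#'
#' Breakpoint windows overlapping the mask are matched at their unmasked
#' (clipped) length, with a warning; the observed occupancy is still
#' computed on the real windows, and a fully masked window contributes a
#' zero-length (always empty) matched interval.
#'
#' @param breakpoints interval data frame of breakpoint windows.
#' @param annotation one interval data frame (single class) or a named
#'   list of them (one per repeat class).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param mask interval data frame masked out of the sampling space
#'   (e.g. centromeres + telomeres), or `NULL`.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed; results are reproducible bit-exactly.
#' @param smoothed use the add-one smoothed p-value.
#' @return object of class `permutation_test`: a list with `table` (one
#'   row per class: `class`, `observed`, `expected_mean`, `fold`, `k`,
#'   `n_perm`, `p`), `perm` (classes x iterations occupancy matrix),
#'   `seed`.
#' @export
permutation_test <- function(breakpoints, annotation, chrom_lengths,
                             mask = NULL, n_perm = 1000, seed = 1,
                             smoothed = FALSE) {
  stopifnot(n_perm >= 1)
  if (is.data.frame(annotation)) annotation <- list(class = annotation)
  if (is.null(names(annotation)))
    names(annotation) <- paste0("class", seq_along(annotation))
  validate_intervals(breakpoints)
  set.seed(seed)
  ## matched lengths: clip breakpoints out of the mask space
  lens <- breakpoints$end - breakpoints$start
  if (!is.null(mask) && nrow(mask) > 0) {
    clipped <- vapply(seq_len(nrow(breakpoints)), function(i) {
      iv_total_length(iv_subtract(breakpoints[i, , drop = FALSE], mask))
    }, numeric(1))
    if (any(clipped < lens)) {
      warning("breakpoint window(s) overlap the mask; matched at the ",
              "clipped length")
      lens <- clipped
    }
  }
  cum <- lapply(annotation, .cum_cov, chrom_lengths = chrom_lengths)
  nonzero <- which(lens > 0)
  spaces <- lapply(lens[nonzero], .allowed_starts,
                   chrom_lengths = chrom_lengths, mask = mask)
  if (any(vapply(spaces, is.null, logical(1))))
    stop("no valid unmasked placement for breakpoint length(s) ",
         paste(lens[nonzero][vapply(spaces, is.null, logical(1))],
               collapse = ", "))
  ## draw all permutation starts up front (one shared set per iteration)
  draws <- lapply(spaces, .draw_starts, n = n_perm)
  observed <- vapply(annotation, function(ann)
    occupancy(breakpoints, ann), numeric(1))
  perm <- matrix(0, nrow = length(annotation), ncol = n_perm,
                 dimnames = list(names(annotation), NULL))
  for (b in seq_along(nonzero)) {
    d <- draws[[b]]
    len <- lens[nonzero[b]]
    for (cl in names(annotation)) {
      C <- cum[[cl]]
      ov <- numeric(n_perm)
      for (ch in unique(d$chrom)) {
        ix <- which(d$chrom == ch)
        v <- C[[ch]]
        ov[ix] <- v[d$start[ix] + len + 1] - v[d$start[ix] + 1]
      }
      perm[cl, ] <- perm[cl, ] + ov
    }
  }
  k <- rowSums(perm < observed)
  p <- if (smoothed) (n_perm - k + 1) / (n_perm + 1) else
    (n_perm - k) / n_perm
  expected <- rowMeans(perm)
  tab <- data.frame(class = names(annotation), observed = observed,
                    expected_mean = expected,
                    fold = ifelse(expected > 0, observed / expected,
                                  ifelse(observed > 0, Inf, NA_real_)),
                    k = as.integer(k), n_perm = n_perm, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, perm = perm, seed = seed,
                 smoothed = smoothed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Permutation test of breakpoint repeat occupancy (",
      x$table$n_perm[1], " permutations, seed ", x$seed, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
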