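#' Default variant hard-filter thresholds
#'
#' The standard GATK-style hard-filter disjunction for SNPs: a site is
#' removed when any criterion fires. Rank-sum thresholds follow the GATK
#' convention (`MQRankSum <= -12.5`, `ReadPosRankSum <= -8.0`); pass a
#' modified list to `apply_hard_filters()` for other readings.
#'
#' @return named list of `list(op, value)` criteria; `op` is one of
#'   `"lt"`, `"gt"`, `"le"`, `"ge"`.
#' @export
hard_filter_defaults <- function() {
  list(QD = list(op = "lt", value = 2.0),
       QUAL = list(op = "lt", value = 30.0),
       SOR = list(op = "gt", value = 3.0),
       FS = list(op = "gt", value = 60.0),
       MQ = list(op = "lt", value = 40.0),
       MQRankSum = list(op = "le", value = -12.5),
       ReadPosRankSum = list(op = "le", value = -8.0))
}

#' Apply hard filters to variant sites
#'
#' A record is removed when ANY criterion fires on its annotation value.
#' Missing annotations (NA or absent column) never fire. Non-numeric
#' annotation values are treated as missing with a warning.
#'
#' @param vs a [variant_set()] or a site data frame.
#' @param thresholds criterion list as from [hard_filter_defaults()].
#' @return list with `kept` and `removed` (same class as input) and
#'   `counts`, the number of records each criterion fired on.
#' @export
apply_hard_filters <- function(vs, thresholds = hard_filter_defaults()) {
  sites <- if (inherits(vs, "variant_set")) vs$sites else vs
  n <- nrow(sites)
  fired <- matrix(FALSE, nrow = n, ncol = length(thresholds),
                  dimnames = list(NULL, names(thresholds)))
  for (k in names(thresholds)) {
    if (!k %in% names(sites)) next
    v <- sites[[k]]
    if (!is.numeric(v)) {
      warning("annotation ", k, " is non-numeric; treated as missing ",
              "where not coercible")
      v <- suppressWarnings(as.numeric(v))
    }
    th <- thresholds[[k]]
    f <- switch(th$op,
                lt = v < th$value, gt = v > th$value,
                le = v <= th$value, ge = v >= th$value,
                stop("unknown op: ", th$op))
    f[is.na(f)] <- FALSE
    fired[, k] <- f
  }
  removed <- rowSums(fired) > 0
  subset_vs <- function(idx) {
    if (inherits(vs, "variant_set")) vs[idx] else
      sites[idx, , drop = FALSE]
  }
  list(kept = subset_vs(which(!removed)),
       removed = subset_vs(which(removed)),
       counts = colSums(fired))
}

#' Minor-allele-frequency and missingness site filter
#'
#' Keeps sites with minor-allele frequency at least `maf` (computed over
#' non-missing alleles; the boundary is inclusive) and missing-genotype
#' fraction at most `max_missing`. Sites with all genotypes missing are
#' removed and counted.
#'
#' @param vs a [variant_set()].
#' @param maf minimum minor-allele frequency (default 0.03).
#' @param max_missing maximum missing-genotype fraction (default 0.1).
#' @return list with `kept` (variant_set) and `counts` (removals by
#'   reason: `maf`, `missing`, `all_missing`).
#' @export
maf_missing_filter <- function(vs, maf = 0.03, max_missing = 0.1) {
  stopifnot(inherits(vs, "variant_set"))
  g <- vs$geno
  n_acc <- nrow(g)
  n_miss <- colSums(is.na(g))
  n_called <- n_acc - n_miss
  alt <- colSums(g, na.rm = TRUE)
  af <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf_site <- pmin(af, 1 - af)
  all_missing <- n_called == 0
  fail_missing <- !all_missing & (n_miss / n_acc) > max_missing
  fail_maf <- !all_missing & !fail_missing & maf_site < maf
  keep <- !all_missing & !fail_missing & !fail_maf
  list(kept = vs[which(keep)],
       counts = c(maf = sum(fail_maf), missing = sum(fail_missing),
                  all_missing = sum(all_missing)))
}

## per-site pi: average pairwise difference over non-missing alleles
.site_pi <- function(geno) {
  n_called <- colSums(!is.na(geno))
  c_alt <- colSums(geno, na.rm = TRUE)
  n <- 2 * n_called
  c_ref <- n - c_alt
  ifelse(n >= 2, 2 * c_ref * c_alt / (n * (n - 1)), 0)
}

#' Sliding-window nucleotide diversity
#'
#' Per-site diversity is `2 * c_ref * c_alt / (n * (n - 1))` over
#' non-missing allele counts; the window value divides the summed
#' per-site diversity by the window length (monomorphic bases contribute
#' zero), matching the usual windowed-pi convention. Set
#' `denominator = "sites"` to divide by the number of variant sites
#' instead.
#'
#' @param vs a [variant_set()].
#' @param accessions accession ids forming the group (default: all).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window,step window size and step (bp; default 50 kb,
#'   non-overlapping).
#' @param denominator `"window"` (length) or `"sites"`.
#' @return data frame: `chrom`, `start`, `end`, `n_sites`, `stat`,
#'   `value`.
#' @export
window_pi <- function(vs, accessions = NULL, chrom_lengths,
                      window = 50000, step = window,
                      denominator = c("window", "sites")) {
  stopifnot(inherits(vs, "variant_set"))
  denominator <- match.arg(denominator)
  g <- vs$geno
  if (!is.null(accessions)) g <- g[accessions, , drop = FALSE]
  if (nrow(g) == 0) stop("empty accession group")
  pi_site <- .site_pi(g)
  win <- iv_windows(chrom_lengths, window, step)
  win$n_sites <- 0L
  win$stat <- "pi"
  win$value <- 0
  for (i in seq_len(nrow(win))) {
    ix <- which(vs$sites$chrom == win$chrom[i] &
                  vs$sites$pos0 >= win$start[i] &
                  vs$sites$pos0 < win$end[i])
    win$n_sites[i] <- length(ix)
    if (length(ix) == 0) next
    tot <- sum(pi_site[ix])
    win$value[i] <- if (denominator == "window")
      tot / (win$end[i] - win$start[i]) else tot / length(ix)
  }
  as.data.frame(win)
}

#' Per-site Weir-Cockerham variance components for two groups
#'
#' Returns the `a` (among-population), `b` (among individuals within
#' populations) and `c` (within individuals) components of the Weir &
#' Cockerham (1984) F_ST estimator for every site; sites that are
#' monomorphic overall or callable in fewer than two copies per group
#' get NA components.
#'
#' @param geno genotype matrix (accessions x sites, 0/1/2/NA).
#' @param g1,g2 row indices or names of the two groups.
#' @return data frame with columns `a`, `b`, `c`.
#' @export
wc_fst_components <- function(geno, g1, g2) {
  x1 <- geno[g1, , drop = FALSE]
  x2 <- geno[g2, , drop = FALSE]
  n1 <- colSums(!is.na(x1)); n2 <- colSums(!is.na(x2))
  p1 <- ifelse(n1 > 0, colSums(x1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(x2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(x1 == 1, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(x2 == 1, na.rm = TRUE) / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  bad <- is.na(pbar) | pbar <= 0 | pbar >= 1 | n1 < 1 | n2 < 1 |
    nbar <= 1 | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Sliding-window Weir-Cockerham F_ST between two groups
#'
#' Windowed (weighted) F_ST is `sum(a) / sum(a + b + c)` over the sites
#' in each window — the ratio-of-sums convention. Windows without
#' polymorphic sites are NA.
#'
#' @param vs a [variant_set()].
#' @param groupA,groupB accession id vectors.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window,step window size and step (bp; default 50 kb).
#' @return data frame: `chrom`, `start`, `end`, `n_sites`, `stat`,
#'   `value`.
#' @export
window_fst <- function(vs, groupA, groupB, chrom_lengths, window = 50000,
                       step = window) {
  stopifnot(inherits(vs, "variant_set"), length(groupA) >= 2,
            length(groupB) >= 2)
  comp <- wc_fst_components(vs$geno, groupA, groupB)
  win <- iv_windows(chrom_lengths, window, step)
  win$n_sites <- 0L
  win$stat <- "fst"
  win$value <- NA_real_
  for (i in seq_len(nrow(win))) {
    ix <- which(vs$sites$chrom == win$chrom[i] &
                  vs$sites$pos0 >= win$start[i] &
                  vs$sites$pos0 < win$end[i])
    ok <- ix[!is.na(comp$a[ix])]
    win$n_sites[i] <- length(ok)
    if (length(ok) == 0) next
    denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
    win$value[i] <- if (denom == 0) NA_real_ else sum(comp$a[ok]) / denom
  }
  as.data.frame(win)
}

#' Genome-wide (ratio-of-sums) Weir-Cockerham F_ST
#'
#' @inheritParams window_fst
#' @param sites optional site index restricting the estimate.
#' @return single F_ST estimate.
#' @export
wc_fst <- function(vs, groupA, groupB, sites = NULL) {
  comp <- wc_fst_components(vs$geno, groupA, groupB)
  if (!is.null(sites)) comp <- comp[sites, , drop = FALSE]
  comp <- comp[!is.na(comp$a), , drop = FALSE]
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Population PCA on a genotype matrix
#'
#' Sites are mean-centered and scaled by their standard deviation
#' (zero-variance sites dropped, missing genotypes mean-imputed), and the
#' accession coordinates come from the principal component decomposition.
#'
#' @param vs a [variant_set()] or genotype matrix.
#' @param n_pc number of components to return (truncated to what the
#'   data supports).
#' @return list with `scores` (accessions x PCs), `varfrac` (variance
#'   fractions over all computed PCs, summing to 1), `n_sites_used`.
#' @export
population_pca <- function(vs, n_pc = 10) {
  g <- if (inherits(vs, "variant_set")) vs$geno else vs
  if (nrow(g) < 2 || ncol(g) < 2)
    stop("need >= 2 accessions and >= 2 sites")
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  keep <- !is.na(v) & v > 0
  if (sum(keep) < 2) stop("fewer than 2 polymorphic sites")
  x <- g[, keep, drop = FALSE]
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       varfrac = pc$sdev^2 / sum(pc$sdev^2),
       n_sites_used = sum(keep))
}
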