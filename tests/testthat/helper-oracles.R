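## Independent oracles used across the suite. These deliberately use
## naive per-base / brute-force implementations, not the package's code
## paths.

rand_ivs <- function(n, chroms = c("c1", "c2"), L = 1000) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - 10, n, replace = TRUE) - 1
  len <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + len, L), stringsAsFactors = FALSE)
}

## per-base bitmap of covered positions, one logical vector per chrom
bitmap_of <- function(iv, chroms, L) {
  out <- lapply(chroms, function(ch) logical(L))
  names(out) <- chroms
  for (i in seq_len(nrow(iv))) {
    ch <- iv$chrom[i]
    out[[ch]][(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  out
}

bitmap_to_ivs <- function(bm) {
  out <- NULL
  for (ch in names(bm)) {
    r <- rle(bm[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                   end = ends[keep],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  out[order(out$chrom, out$start), , drop = FALSE]
}

oracle_merge <- function(iv, chroms, L) bitmap_to_ivs(bitmap_of(iv, chroms, L))

oracle_intersect <- function(a, b, chroms, L) {
  ba <- bitmap_of(a, chroms, L); bb <- bitmap_of(b, chroms, L)
  bitmap_to_ivs(mapply(function(x, y) x & y, ba, bb, SIMPLIFY = FALSE))
}

oracle_subtract <- function(a, b, chroms, L) {
  ba <- bitmap_of(a, chroms, L); bb <- bitmap_of(b, chroms, L)
  bitmap_to_ivs(mapply(function(x, y) x & !y, ba, bb, SIMPLIFY = FALSE))
}

oracle_total_length <- function(iv, chroms, L) {
  sum(vapply(bitmap_of(iv, chroms, L), sum, numeric(1)))
}

## Needleman-Wunsch DP (match +1, mismatch -1, gap -1) with traceback;
## returns matches / alignment columns
oracle_nw_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + if (x[i] == y[j]) 1 else -1,
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  ## traceback (diagonal preferred)
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (x[i] == y[j]) 1 else -1)) {
      if (x[i] == y[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  matches / cols
}

## independent Weir & Cockerham (1984) two-population per-site estimator,
## written from the variance-component definitions with explicit tallies
oracle_wc_site <- function(g1, g2) {
  tally <- function(g) {
    g <- g[!is.na(g)]
    n <- length(g)
    list(n = n, p = sum(g) / (2 * n), h = mean(g == 1))
  }
  t1 <- tally(g1); t2 <- tally(g2)
  r <- 2
  nbar <- (t1$n + t2$n) / r
  nc <- (r * nbar - (t1$n^2 + t2$n^2) / (r * nbar)) / (r - 1)
  pbar <- (t1$n * t1$p + t2$n * t2$p) / (r * nbar)
  s2 <- (t1$n * (t1$p - pbar)^2 + t2$n * (t2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (t1$n * t1$h + t2$n * t2$h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

## per-site pi by explicit enumeration of allele pairs
oracle_site_pi <- function(g) {
  g <- g[!is.na(g)]
  alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(0)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / (n * (n - 1) / 2)
}

## brute-force maximal reverse-anchor runs with noise tolerance
oracle_minus_runs <- function(ori, min_anchors, max_noise) {
  minus <- which(ori == "-")
  if (length(minus) == 0) return(list())
  valid <- function(a, b) {
    ix <- minus[minus >= a & minus <= b]
    if (length(ix) == 0 || ix[1] != a || ix[length(ix)] != b) return(FALSE)
    all(diff(ix) - 1 <= max_noise)
  }
  runs <- list()
  for (a in minus) for (b in minus[minus >= a]) {
    if (!valid(a, b)) next
    ## maximal: no valid extension to another minus anchor
    ext_l <- any(vapply(minus[minus < a], valid, b = b, logical(1)))
    ext_r <- any(vapply(minus[minus > b], function(bb) valid(a, bb),
                        logical(1)))
    if (!ext_l && !ext_r &&
        length(minus[minus >= a & minus <= b]) >= min_anchors)
      runs[[length(runs) + 1]] <- c(a, b)
  }
  unique(runs)
}

## quick two-group genotype simulator at fixed allele frequencies
sim_geno_at <- function(p1, p2, n1, n2) {
  n_sites <- length(p1)
  g <- matrix(0L, n1 + n2, n_sites)
  for (j in seq_len(n_sites)) {
    g[1:n1, j] <- rbinom(n1, 2, p1[j])
    g[(n1 + 1):(n1 + n2), j] <- rbinom(n2, 2, p2[j])
  }
  rownames(g) <- sprintf("a%03d", seq_len(n1 + n2))
  g
}

## exactly round((1 - identity) * len) substitutions at distinct positions
mutate_to_identity <- function(seq, identity) {
  s <- strsplit(seq, "")[[1]]
  k <- round((1 - identity) * length(s))
  pos <- sample(length(s), k)
  for (i in pos) s[i] <- setdiff(c("A", "C", "G", "T"), s[i])[1]
  paste(s, collapse = "")
}
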