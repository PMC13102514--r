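mk_anchors <- function(ori, spacing = 1000, len = 100) {
  n <- length(ori)
  starts <- (seq_len(n) - 1) * spacing
  data.frame(q_chrom = "c1", q_start = starts, q_end = starts + len,
             t_chrom = "c1", t_start = starts, t_end = starts + len,
             orientation = ori, stringsAsFactors = FALSE)
}

test_that("colinear maps give no inversion calls", {
  an <- simulate_anchor_map(c(c1 = 1e6), NULL, spacing = 2e4)
  expect_equal(nrow(detect_inversions(an)), 0)
})

test_that("a simulated inversion is recovered within one anchor spacing", {
  cl <- c(c1 = 8e6)
  inv <- intervals("c1", 2e6, 6e6)
  an <- simulate_anchor_map(cl, inv, spacing = 1e5)
  calls <- detect_inversions(an, min_anchors = 5)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$q_start - 2e6), 1e5)
  expect_lte(abs(calls$q_end - 6e6), 1e5)
  expect_lte(abs(calls$t_start - 2e6), 1e5)
  expect_lte(abs(calls$t_end - 6e6), 1e5)
  expect_gte(calls$n_anchors, 39)
})

test_that("discordant stretches longer than max_noise split runs", {
  ori <- c(rep("-", 6), rep("+", 10), rep("-", 7))
  an <- mk_anchors(ori)
  calls <- detect_inversions(an, min_anchors = 5, max_noise = 2)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$n_anchors, c(6L, 7L))

  ## short discordant gaps are tolerated inside one call
  ori2 <- c(rep("-", 4), "+", "+", rep("-", 4))
  calls2 <- detect_inversions(mk_anchors(ori2), min_anchors = 5,
                              max_noise = 2)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$n_anchors, 8L)
  expect_equal(calls2$n_noise, 2L)
})

test_that("run finding matches the brute-force oracle on random maps", {
  set.seed(21)
  for (rep in 1:20) {
    ori <- sample(c("+", "-"), 40, TRUE, prob = c(0.5, 0.5))
    an <- mk_anchors(ori)
    min_a <- sample(2:4, 1); max_n <- sample(0:2, 1)
    calls <- detect_inversions(an, min_anchors = min_a, max_noise = max_n)
    runs <- oracle_minus_runs(ori, min_a, max_n)
    expect_equal(nrow(calls), length(runs))
    if (length(runs)) {
      first <- sort(vapply(runs, `[`, numeric(1), 1))
      expect_equal(calls$q_start, an$q_start[first])
    }
  }
})

test_that("unsorted anchors are sorted with a warning", {
  an <- mk_anchors(rep("-", 6))
  expect_warning(calls <- detect_inversions(an[sample(6), ]), "sorted")
  expect_equal(nrow(calls), 1)
})

test_that("breakpoint flanks extend 40 kb outward and clip at ends", {
  calls <- data.frame(id = "inv01", q_chrom = "c1", q_start = 1e6,
                      q_end = 2e6, stringsAsFactors = FALSE)
  bp <- define_breakpoints(calls, c(c1 = 1e7))
  expect_equal(bp$start, c(960000, 2000000))
  expect_equal(bp$end, c(1000000, 2040000))
  expect_false(any(bp$clipped))

  calls2 <- data.frame(id = "inv01", q_chrom = "c1", q_start = 10000,
                       q_end = 50000, stringsAsFactors = FALSE)
  bp2 <- define_breakpoints(calls2, c(c1 = 60000))
  expect_equal(bp2$start, c(0, 50000))
  expect_equal(bp2$end, c(10000, 60000))
  expect_true(all(bp2$clipped))

  expect_error(define_breakpoints(calls, c(c1 = 1e7), flank = 0), "> 0")

  bpc <- define_breakpoints(calls, c(c1 = 1e7), centered = TRUE)
  expect_equal(bpc$start, c(980000, 1980000))
  expect_equal(bpc$end, c(1020000, 2020000))
})

test_that("covered_fraction weights partial bins and validates span", {
  prof <- data.frame(chrom = "c1", start = seq(0, 900, 100),
                     end = seq(100, 1000, 100), depth = 30)
  iv <- intervals("c1", 0, 1000)
  expect_equal(covered_fraction(prof, iv), 1)

  prof$depth[1:5] <- 0
  expect_equal(covered_fraction(prof, iv), 0.5)

  ## partial bin overlap weighting
  expect_equal(covered_fraction(prof, intervals("c1", 450, 650)),
               150 / 200)
  expect_error(covered_fraction(prof, intervals("c1", 500, 1500)),
               "span")

  set.seed(5)
  for (i in 1:10) {
    depth <- rpois(20, 3)
    p <- data.frame(chrom = "c1", start = seq(0, 1900, 100),
                    end = seq(100, 2000, 100), depth = depth)
    s <- sample(0:1000, 1); e <- s + sample(100:900, 1)
    per_base <- rep(depth, each = 100)
    want <- mean(per_base[(s + 1):e] >= 2)
    expect_equal(covered_fraction(p, intervals("c1", s, e), min_depth = 2),
                 want)
  }
})

test_that("coverage genotyping applies the strict 94% rule", {
  expect_equal(genotype_by_coverage(0.95), "REF")
  expect_equal(genotype_by_coverage(0.94), "INV")
  expect_equal(genotype_by_coverage(0.10), "INV")
  ## monotone with a single discontinuity at the threshold
  f <- seq(0, 1, by = 0.01)
  calls <- genotype_by_coverage(f)
  expect_true(all(diff(calls == "REF") >= 0))
  expect_equal(sum(diff(calls == "REF") == 1), 1)
})

test_that("PCA genotyping separates divergent inversion haplotypes", {
  set.seed(31)
  n_sites <- 300
  p_ref <- runif(n_sites, 0, 0.15)
  p_inv <- runif(n_sites, 0.85, 1)
  carrier <- rep(c(TRUE, FALSE), c(60, 140))
  geno <- matrix(0L, 200, n_sites)
  for (j in seq_len(n_sites)) {
    geno[carrier, j] <- rbinom(60, 2, p_inv[j])
    geno[!carrier, j] <- rbinom(140, 2, p_ref[j])
  }
  rownames(geno) <- sprintf("a%03d", 1:200)
  res <- pca_genotype(geno)
  expect_gte(mean((res$calls == "INV") == carrier), 0.99)
  expect_equal(sum(res$varfrac), 1)
  expect_true(all(diff(res$varfrac) <= 1e-8))

  ## labels follow coverage calls when provided
  cov_calls <- setNames(ifelse(carrier, "INV", "REF"), rownames(geno))
  res2 <- pca_genotype(geno, coverage_calls = cov_calls)
  expect_gte(mean((res2$calls == "INV") == carrier), 0.99)

  ## identical genotypes: NA calls
  flat <- matrix(1L, 10, 20,
                 dimnames = list(sprintf("a%02d", 1:10), NULL))
  expect_true(all(is.na(pca_genotype(flat)$calls)))
})

test_that("reconciliation prefers coverage and flags conflicts", {
  cov <- c(a1 = "REF", a2 = "INV", a3 = "INV")
  pca <- c(a1 = "REF", a2 = "REF", a3 = "INV")
  rec <- reconcile_genotypes(cov, pca)
  expect_equal(rec$final_call, c("REF", "INV", "INV"))
  expect_equal(rec$conflict, c(FALSE, TRUE, FALSE))

  expect_warning(rec2 <- reconcile_genotypes(cov, pca[1:2]), "only one")
  expect_true(is.na(rec2$final_call[rec2$accession == "a3"]))

  g <- c(a1 = "g1", a2 = "g1", a3 = "g2")
  rec3 <- reconcile_genotypes(cov, pca, groups = g)
  expect_equal(unname(attr(rec3, "group_freq")["g1"]), 0.5)
  expect_equal(unname(attr(rec3, "group_freq")["g2"]), 1)
})
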