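mk_vs <- function(geno, pos0 = NULL, chrom = "c1", ...) {
  n_sites <- ncol(geno)
  if (is.null(pos0)) pos0 <- seq_len(n_sites) * 10
  extra <- list(...)
  sites <- data.frame(chrom = chrom, pos0 = pos0,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  for (k in names(extra)) sites[[k]] <- extra[[k]]
  variant_set(sites, geno)
}

test_that("hard filters fire per criterion and never on missing values", {
  sites <- data.frame(chrom = "c1", pos0 = c(10, 20, 30), ref = "A",
                      alt = "G",
                      QUAL = c(100, 100, 100), QD = c(1.5, 25, NA),
                      SOR = c(1, 1, 1), FS = c(0, 0, 0),
                      MQ = c(60, 60, 60), MQRankSum = c(0, 0, NA),
                      ReadPosRankSum = c(0, 0, NA),
                      stringsAsFactors = FALSE)
  res <- apply_hard_filters(sites)
  expect_equal(nrow(res$kept), 2)          # QD = 1.5 removed
  expect_equal(unname(res$counts["QD"]), 1)
  expect_equal(sum(res$counts), 1)
  ## record with missing annotations is kept
  expect_true(30 %in% res$kept$pos0)
})

test_that("hard filtering equals the brute-force disjunction oracle", {
  set.seed(41)
  n <- 100
  sites <- data.frame(
    chrom = "c1", pos0 = seq_len(n), ref = "A", alt = "G",
    QUAL = round(runif(n, 0, 100), 1), QD = round(runif(n, 0, 40), 2),
    SOR = round(runif(n, 0, 5), 2), FS = round(runif(n, 0, 100), 1),
    MQ = round(runif(n, 20, 70), 1),
    MQRankSum = round(runif(n, -20, 5), 2),
    ReadPosRankSum = round(runif(n, -15, 5), 2),
    stringsAsFactors = FALSE)
  sites$QD[sample(n, 10)] <- NA
  res <- apply_hard_filters(sites)
  keep_oracle <- vapply(seq_len(n), function(i) {
    fire <- c(isTRUE(sites$QD[i] < 2), isTRUE(sites$QUAL[i] < 30),
              isTRUE(sites$SOR[i] > 3), isTRUE(sites$FS[i] > 60),
              isTRUE(sites$MQ[i] < 40), isTRUE(sites$MQRankSum[i] <= -12.5),
              isTRUE(sites$ReadPosRankSum[i] <= -8))
    !any(fire)
  }, logical(1))
  expect_equal(res$kept$pos0, sites$pos0[keep_oracle])
  ## idempotence
  res2 <- apply_hard_filters(res$kept)
  expect_equal(res2$kept, res$kept)
  expect_equal(sum(res2$counts), 0)
})

test_that("MAF and missingness filters use inclusive printed bounds", {
  ## 100 accessions, 200 alleles: 6 alt alleles = MAF 0.03 exactly
  g_boundary <- matrix(0L, 100, 3)
  g_boundary[1:6, 1] <- 1L    # MAF 0.03  -> kept (inclusive)
  g_boundary[1:4, 2] <- 1L    # MAF 0.02  -> removed
  g_boundary[1:50, 3] <- 1L   # MAF 0.25  -> kept
  vs <- mk_vs(g_boundary)
  res <- maf_missing_filter(vs, maf = 0.03, max_missing = 0.1)
  expect_equal(res$kept$sites$pos0, c(10, 30))
  expect_equal(unname(res$counts["maf"]), 1)

  ## missingness: 11% missing removed at the 0.1 bound, 10% kept
  g <- matrix(1L, 100, 2)
  g[1:11, 1] <- NA
  g[1:10, 2] <- NA
  g[12:61, ] <- 0L   # keep sites polymorphic
  res2 <- maf_missing_filter(mk_vs(g))
  expect_equal(res2$kept$sites$pos0, 20)
  ## all-missing site removed and counted
  g3 <- cbind(g_boundary[, 3], NA_integer_)
  res3 <- maf_missing_filter(mk_vs(g3))
  expect_equal(unname(res3$counts["all_missing"]), 1)
})

test_that("windowed pi matches arithmetic and the pairwise-difference oracle", {
  ## monomorphic window -> 0
  g <- matrix(0L, 4, 2)
  expect_equal(window_pi(mk_vs(g), chrom_lengths = c(c1 = 100),
                         window = 100)$value, 0)

  ## one site, 2 haplotypes differing, window 100 bp -> 0.01
  g1 <- matrix(c(1L), 1, 1, dimnames = list("a1", NULL))
  vs1 <- mk_vs(g1, pos0 = 50)
  expect_equal(window_pi(vs1, chrom_lengths = c(c1 = 100),
                         window = 100)$value, 0.01)

  ## random genotypes: window pi equals summed per-site average pairwise
  ## differences (explicit enumeration) over the window length
  set.seed(42)
  g2 <- matrix(sample(c(0L, 1L, 2L, NA), 8 * 30, TRUE), 8, 30,
               dimnames = list(sprintf("a%d", 1:8), NULL))
  vs2 <- mk_vs(g2, pos0 = sort(sample(0:999, 30)))
  win <- window_pi(vs2, chrom_lengths = c(c1 = 1000), window = 250)
  for (i in seq_len(nrow(win))) {
    ix <- which(vs2$sites$pos0 >= win$start[i] &
                  vs2$sites$pos0 < win$end[i])
    want <- sum(vapply(ix, function(j) oracle_site_pi(g2[, j]),
                       numeric(1))) / (win$end[i] - win$start[i])
    expect_equal(win$value[i], want)
  }
  ## per-site denominator option
  win_s <- window_pi(vs2, chrom_lengths = c(c1 = 1000), window = 250,
                     denominator = "sites")
  expect_equal(win_s$value[1] * win_s$n_sites[1],
               win$value[1] * 250 / 1)
})

test_that("per-site F_ST agrees with the hand-computed textbook toy", {
  ## pop1: 4 hom-ref, 4 het, 2 hom-alt; pop2: 8 hom-ref, 1 het, 1 hom-alt
  g <- matrix(c(rep(0L, 4), rep(1L, 4), rep(2L, 2),
                rep(0L, 8), 1L, 2L), ncol = 1)
  rownames(g) <- sprintf("a%02d", 1:20)
  comp <- wc_fst_components(g, 1:10, 11:20)
  expect_equal(comp$a, 0.017777777777777788, tolerance = 1e-12)
  expect_equal(comp$b, 0.07222222222222223, tolerance = 1e-12)
  expect_equal(comp$c, 0.125, tolerance = 1e-12)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 0.08268733850129203,
               tolerance = 1e-12)
  ## and with the independently coded oracle on random sites
  set.seed(43)
  for (i in 1:20) {
    gg <- matrix(sample(c(0L, 1L, 2L, NA), 30, TRUE,
                        prob = c(0.4, 0.3, 0.25, 0.05)), ncol = 1)
    rownames(gg) <- sprintf("a%02d", 1:30)
    comp <- wc_fst_components(gg, 1:12, 13:30)
    o <- oracle_wc_site(gg[1:12, 1], gg[13:30, 1])
    if (is.na(comp$a)) {
      p_all <- mean(gg[!is.na(gg)]) / 2
      expect_true(p_all %in% c(0, 1) || sum(!is.na(gg[1:12])) == 0 ||
                    sum(!is.na(gg[13:30])) == 0)
    } else {
      expect_equal(unname(comp$a), unname(o["a"]), tolerance = 1e-12)
      expect_equal(unname(comp$b), unname(o["b"]), tolerance = 1e-12)
      expect_equal(unname(comp$c), unname(o["c"]), tolerance = 1e-12)
    }
  }
})

test_that("F_ST hits its analytic extremes on constructed toys", {
  ## fixed difference, no heterozygotes -> exactly 1
  g <- matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 1,
              dimnames = list(sprintf("a%02d", 1:20), NULL))
  vs <- mk_vs(g, pos0 = 5)
  expect_equal(window_fst(vs, sprintf("a%02d", 1:10),
                          sprintf("a%02d", 11:20),
                          chrom_lengths = c(c1 = 100),
                          window = 100)$value, 1)
  ## identical genotype composition in both groups, equal sizes -> <= 0
  w <- rep(c(0L, 1L, 1L, 2L), 5)[1:10]
  col <- rep(w, each = 2)           # rows 2k-1 and 2k identical
  g2 <- matrix(rep(col, 5), ncol = 5)
  rownames(g2) <- sprintf("a%02d", 1:20)
  fst <- window_fst(mk_vs(g2), sprintf("a%02d", seq(1, 20, 2)),
                    sprintf("a%02d", seq(2, 20, 2)),
                    chrom_lengths = c(c1 = 100), window = 100)$value
  expect_lte(fst, 0)
  ## no polymorphic sites -> NA
  g3 <- matrix(2L, 20, 1, dimnames = list(sprintf("a%02d", 1:20), NULL))
  expect_true(is.na(window_fst(mk_vs(g3), sprintf("a%02d", 1:10),
                               sprintf("a%02d", 11:20),
                               chrom_lengths = c(c1 = 100),
                               window = 100)$value))
})

test_that("F_ST is invariant to group swap and accession order", {
  set.seed(45)
  g <- sim_geno_at(runif(50, 0.1, 0.9), runif(50, 0.1, 0.9), 15, 25)
  vs <- mk_vs(g, pos0 = seq_len(50))
  ga <- rownames(g)[1:15]; gb <- rownames(g)[16:40]
  f1 <- wc_fst(vs, ga, gb)
  f2 <- wc_fst(vs, gb, ga)
  expect_equal(f1, f2)
  perm <- sample(nrow(g))
  vs_p <- variant_set(vs$sites, g[perm, ])
  expect_equal(wc_fst(vs_p, ga, gb), f1)
})

test_that("population PCA separates duplicated accession blocks", {
  set.seed(46)
  proto1 <- sample(c(0L, 2L), 40, TRUE)
  proto2 <- 2L - proto1
  g <- rbind(matrix(rep(proto1, 6), 6, byrow = TRUE),
             matrix(rep(proto2, 6), 6, byrow = TRUE))
  rownames(g) <- sprintf("a%02d", 1:12)
  res <- population_pca(g)
  pc1 <- res$scores[, 1]
  expect_true(max(pc1[1:6]) < min(pc1[7:12]) ||
                min(pc1[1:6]) > max(pc1[7:12]))
  expect_equal(sum(res$varfrac), 1)
  expect_true(all(diff(res$varfrac) <= 1e-8))
})
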