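rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("telomere runs are found at both ends with correct copy counts", {
  set.seed(1)
  chrom <- paste0(strrep("CCCTAAA", 20), rand_seq(1000),
                  strrep("TTTAGGG", 20))
  g <- genome_seq(c(chr = chrom))
  hits <- find_telomeres(g, "CCCTAAA", min_copies = 4,
                         terminal_window = 500)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$copies, c(20, 20))
  expect_equal(hits$end - hits$start, c(140, 140))
  expect_equal(hits$name, c("5prime", "3prime"))
  expect_equal(hits$start[1], 0)
  expect_equal(hits$end[2], nchar(chrom))
})

test_that("absent or non-terminal motifs yield no telomere hits", {
  set.seed(2)
  g <- genome_seq(c(chr = rand_seq(2000)))
  expect_equal(nrow(find_telomeres(g, "CCCTAAA", terminal_window = 500)), 0)
  ## run only mid-chromosome, outside the terminal window
  mid <- paste0(rand_seq(3000), strrep("CCCTAAA", 10), rand_seq(3000))
  g2 <- genome_seq(c(chr = mid))
  expect_equal(nrow(find_telomeres(g2, "CCCTAAA", terminal_window = 1000)),
               0)
})

test_that("telomere detection is strand-symmetric", {
  set.seed(3)
  chrom <- paste0(strrep("CCCTAAA", 12), rand_seq(700),
                  strrep("TTTAGGG", 7))
  g <- genome_seq(c(chr = chrom))
  L <- nchar(chrom)
  fwd <- find_telomeres(g, "CCCTAAA", min_copies = 4,
                        terminal_window = 300)
  grc <- genome_seq(c(chr = revcomp(chrom)))
  rev <- find_telomeres(grc, "CCCTAAA", min_copies = 4,
                        terminal_window = 300)
  ## 5' and 3' hits swap, with mirrored coordinates
  f5 <- fwd[fwd$name == "5prime", ]; r3 <- rev[rev$name == "3prime", ]
  expect_equal(r3$start, L - f5$end)
  expect_equal(r3$end, L - f5$start)
  expect_equal(r3$copies, f5$copies)
  f3 <- fwd[fwd$name == "3prime", ]; r5 <- rev[rev$name == "5prime", ]
  expect_equal(r5$start, L - f3$end)
  expect_equal(r5$copies, f3$copies)
})

test_that("satellite scan recovers perfect arrays and drops divergent copies", {
  set.seed(4)
  monomer <- rand_seq(100)
  array10 <- strrep(monomer, 10)
  g <- genome_seq(c(chr = paste0(rand_seq(500), array10, rand_seq(500))))
  for (mode in c("exact", "seeded")) {
    hits <- scan_satellite(g, monomer, mode = mode)
    expect_equal(nrow(hits), 10)
    expect_true(all(hits$identity == 1))
    expect_equal(hits$start, 500 + (0:9) * 100)
  }

  ## one copy diluted to 85% identity is suppressed at the 0.90 threshold
  bad <- mutate_to_identity(monomer, 0.85)
  copies <- c(rep(monomer, 4), bad, rep(monomer, 5))
  g2 <- genome_seq(c(chr = paste0(rand_seq(300),
                                  paste(copies, collapse = ""),
                                  rand_seq(300))))
  hits2 <- scan_satellite(g2, monomer, min_identity = 0.90, mode = "exact")
  expect_equal(nrow(hits2), 9)
  expect_false(any(hits2$start == 300 + 4 * 100))

  ## random sequence has no hits
  g3 <- genome_seq(c(chr = rand_seq(5000)))
  expect_equal(nrow(scan_satellite(g3, monomer)), 0)

  expect_error(scan_satellite(g3, "ACGRT"), "outside A/C/G/T/N")
})

test_that("exact and seeded satellite scans agree on 50-kb sequences", {
  set.seed(5)
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr = 5e4),
                    telomere_copies = 10, satellite_copies = 50,
                    satellite_div = 0.04, inversion = NULL, n_te = 3)
  sim <- simulate_genome(cfg)
  ex <- scan_satellite(sim$genome, sim$truth$monomer, mode = "exact")
  se <- scan_satellite(sim$genome, sim$truth$monomer, mode = "seeded")
  expect_equal(se, ex)
  expect_equal(nrow(ex), 50)
})

test_that("scan finds reverse-orientation arrays", {
  set.seed(6)
  monomer <- rand_seq(120)
  arr <- strrep(revcomp(monomer), 8)
  g <- genome_seq(c(chr = paste0(rand_seq(400), arr, rand_seq(400))))
  hits <- scan_satellite(g, monomer, mode = "exact")
  expect_equal(nrow(hits), 8)
  expect_true(all(hits$orientation == "-"))
})

test_that("consensus building recovers the true monomer", {
  set.seed(7)
  monomer <- rand_seq(150)
  expect_equal(build_consensus(rep(monomer, 5)), monomer)

  one_sub <- sub("^(.{30}).", paste0("\\1", "A"), monomer)
  expect_equal(build_consensus(c(monomer, one_sub, monomer)), monomer)

  copies <- vapply(1:100, function(i) .mutate_subs(monomer, 0.02),
                   character(1))
  expect_equal(build_consensus(copies), monomer)

  expect_error(build_consensus(monomer), ">= 2")
  expect_error(build_consensus(c(rand_seq(100), rand_seq(300))), "50%")
})

test_that("variant counting follows the mismatch-plus-gap-opening rule", {
  set.seed(8)
  cons <- rand_seq(120)
  expect_equal(count_variants(cons, cons), 0)

  s <- strsplit(cons, "")[[1]]
  for (i in c(10, 50, 90)) s[i] <- setdiff(c("A", "C", "G", "T"), s[i])[1]
  expect_equal(count_variants(paste(s, collapse = ""), cons), 3)

  ## one 2-bp deletion plus one substitution -> 2 (hand-checked alignment)
  s2 <- strsplit(cons, "")[[1]]
  s2[100] <- setdiff(c("A", "C", "G", "T"), s2[100])[1]
  del <- paste(s2[-c(40, 41)], collapse = "")
  expect_equal(count_variants(del, cons), 2)

  expect_error(count_variants("", cons), "empty")
})

test_that("pairwise identity matches the independent DP oracle", {
  set.seed(9)
  a455 <- rand_seq(455)
  expect_equal(pairwise_identity(a455, a455), 1.0)
  s <- strsplit(a455, "")[[1]]
  s[200] <- setdiff(c("A", "C", "G", "T"), s[200])[1]
  expect_equal(pairwise_identity(paste(s, collapse = ""), a455), 454 / 455)

  for (i in 1:8) {
    a <- rand_seq(sample(60:90, 1))
    b <- .mutate_subs(a, 0.1)
    if (i %% 2 == 0) b <- paste0(substr(b, 1, 30), substr(b, 34, nchar(b)))
    expect_lt(abs(pairwise_identity(a, b) - oracle_nw_identity(a, b)),
              0.02)
  }
})

test_that("similarity strata reflect within-chromosome homogeneity", {
  set.seed(10)
  base <- rand_seq(100)
  mono <- function(chrom_seed, n) {
    chrom_base <- .mutate_subs(base, 0.05)
    vapply(seq_len(n), function(i) .mutate_subs(chrom_base, 0.01),
           character(1))
  }
  df <- do.call(rbind, lapply(c("c1", "c2", "c3"), function(ch)
    data.frame(seq = mono(ch, 8), genome = "g1", chrom = ch,
               stringsAsFactors = FALSE)))
  df2 <- df; df2$genome <- "g2"
  df2$seq <- vapply(df2$seq, function(s) .mutate_subs(s, 0.03),
                    character(1))
  res <- similarity_classes(rbind(df, df2), max_pairs = 100, seed = 2)
  expect_setequal(res$stratum, c("within_chromosome", "among_chromosomes",
                                 "between_genomes"))
  w <- res$mean[res$stratum == "within_chromosome"]
  a <- res$mean[res$stratum == "among_chromosomes"]
  expect_gt(w, a)

  ident <- data.frame(seq = rep(base, 6), genome = rep(c("g1", "g2"), 3),
                      chrom = rep(c("c1", "c1", "c2"), 2),
                      stringsAsFactors = FALSE)
  res2 <- similarity_classes(ident, max_pairs = 50, seed = 1)
  expect_true(all(res2$mean == 1))
})

test_that("monomer subsampling respects the configured cap", {
  set.seed(11)
  big <- data.frame(seq = replicate(60, rand_seq(60)),
                    genome = "g1",
                    chrom = sample(c("c1", "c2", "c3"), 60, TRUE),
                    stringsAsFactors = FALSE)
  expect_warning(res <- similarity_classes(big, cap = 30, max_pairs = 40,
                                           seed = 3),
                 "between_genomes")  # single-genome input has no such pairs
  n_within <- res$n_monomers[res$stratum == "within_chromosome"]
  expect_lte(n_within, 33)  # cap plus per-stratum rounding
})
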