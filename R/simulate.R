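#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators with defaults
#' mirroring the study design the package benchmarks against: a
#' two-subspecies population of 45 + 225 accessions, an inversion carried
#' by 69% of one group and 24% of the other, Balding-Nichols
#' allele-frequency divergence targeting F_ST 0.74 inside the inversion
#' and 0.10 outside, telomere caps of CCCTAAA repeats, and a centromeric
#' satellite array of 455-bp monomers with per-copy substitutions.
#' Chromosome and array sizes are Mb-scale benchmark sizes, not the full
#' genome.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param telomere_motif 5' telomere repeat unit; the 3' cap uses its
#'   reverse complement.
#' @param telomere_copies tandem copies per chromosome end.
#' @param monomer_length satellite monomer length (bp).
#' @param satellite_copies monomer copies per centromeric array.
#' @param satellite_div per-base substitution rate applied independently
#'   to each array copy.
#' @param n_te transposable-element annotation intervals per chromosome.
#' @param sd_length,sd_div segmental-duplication length (>= 1 kb) and
#'   per-base divergence of the duplicated copy (<= 0.10, so copies share
#'   >= 90% identity).
#' @param sd_at_breakpoints place one SD copy across each inversion
#'   breakpoint (emulating breakpoint-associated duplications).
#' @param inversion interval data frame with the true inversion (one row),
#'   or `NULL` for none.
#' @param pop_sizes named vector of accessions per group.
#' @param inv_freq per-group frequency of inversion carriers.
#' @param carrier_assignment `"exact"` (round(freq * n) carriers, positions
#'   permuted) or `"binomial"` (independent Bernoulli draws).
#' @param n_snp SNP count on the inversion chromosome.
#' @param fst_inside,fst_outside Balding-Nichols divergence targets for
#'   sites inside / outside the inversion.
#' @param depth_mean mean per-bin read depth (Poisson).
#' @param coverage_bin coverage bin size (bp).
#' @param void_fraction fraction of the inversion zeroed out in carriers,
#'   as breakpoint-anchored voids growing inward.
#' @param carrier_depth_factor depth multiplier for carriers over the
#'   inversion (reduced overall depth in addition to voids).
#' @param n_reads,read_length,aln_error_rate,improper_frac,mapping_rate
#'   alignment-summary simulation: read count and length, per-base error
#'   rate (NM ~ Binomial(length, rate)), fraction of improper pairs, and
#'   fraction of reads mapped.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr01 = 2e6, chr02 = 1e6,
                                         chr03 = 1e6),
                       telomere_motif = "CCCTAAA",
                       telomere_copies = 100,
                       monomer_length = 455,
                       satellite_copies = 200,
                       satellite_div = 0.02,
                       n_te = 20,
                       sd_length = 2000,
                       sd_div = 0.02,
                       sd_at_breakpoints = TRUE,
                       inversion = intervals("chr01", 1.3e6, 1.7e6),
                       pop_sizes = c(unguiculata = 45, sesquipedalis = 225),
                       inv_freq = c(unguiculata = 0.69,
                                    sesquipedalis = 0.24),
                       carrier_assignment = c("exact", "binomial"),
                       n_snp = 3000,
                       fst_inside = 0.74,
                       fst_outside = 0.10,
                       depth_mean = 12,
                       coverage_bin = 2000,
                       void_fraction = 0.20,
                       carrier_depth_factor = 0.8,
                       n_reads = 10000,
                       read_length = 150,
                       aln_error_rate = 0.01,
                       improper_frac = 0.05,
                       mapping_rate = 0.995) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              telomere_motif = toupper(telomere_motif),
              telomere_copies = telomere_copies,
              monomer_length = monomer_length,
              satellite_copies = satellite_copies,
              satellite_div = satellite_div, n_te = n_te,
              sd_length = sd_length, sd_div = sd_div,
              sd_at_breakpoints = sd_at_breakpoints,
              inversion = inversion, pop_sizes = pop_sizes,
              inv_freq = inv_freq,
              carrier_assignment = match.arg(carrier_assignment),
              n_snp = n_snp, fst_inside = fst_inside,
              fst_outside = fst_outside, depth_mean = depth_mean,
              coverage_bin = coverage_bin, void_fraction = void_fraction,
              carrier_depth_factor = carrier_depth_factor,
              n_reads = n_reads, read_length = read_length,
              aln_error_rate = aln_error_rate,
              improper_frac = improper_frac, mapping_rate = mapping_rate)
  rates <- c(cfg$satellite_div, cfg$sd_div, cfg$void_fraction,
             cfg$aln_error_rate, cfg$improper_frac, cfg$mapping_rate,
             cfg$inv_freq)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(cfg$pop_sizes <= 0)) stop("population sizes must be positive")
  if (cfg$fst_inside <= 0 || cfg$fst_inside >= 1 ||
      cfg$fst_outside < 0 || cfg$fst_outside >= 1)
    stop("target F_ST must lie in (0, 1) inside, [0, 1) outside")
  if (cfg$sd_length < 1000) stop("SD length must be >= 1 kb")
  if (!is.null(cfg$inversion)) {
    validate_intervals(cfg$inversion)
    if (nrow(cfg$inversion) != 1)
      stop("config supports a single inversion interval")
    ch <- cfg$inversion$chrom
    if (!ch %in% names(cfg$chrom_lengths) ||
        cfg$inversion$end > cfg$chrom_lengths[[ch]])
      stop("inversion interval must lie inside its chromosome")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_subs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  }
  paste(s, collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param seq character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Simulate a genome with known telomere, satellite, TE and SD truth
#'
#' Each chromosome is laid out as: 5' telomere cap (tandem motif), random
#' flank, centromeric satellite array (monomer repeated, each copy
#' independently substituted at `satellite_div`), random flank, 3'
#' telomere cap (reverse-complement motif). TE intervals are annotated in
#' the flanks; one segmental-duplication pair per chromosome is written
#' into the sequence (source + diverged copy, >= 90% identity). With
#' `sd_at_breakpoints`, extra SD copies are placed across the configured
#' inversion's breakpoints.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([genome_seq()]), `truth` (list: `monomer`,
#'   `telomeres`, `satellite_arrays`, `inversion`), and `tracks` (named
#'   list of annotation interval data frames: `telomere`, `satellite`,
#'   `TE`, `SD`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  motif <- config$telomere_motif
  tel_len <- nchar(motif) * config$telomere_copies
  arr_len <- config$monomer_length * config$satellite_copies
  monomer <- .rand_dna(config$monomer_length)
  seqs <- character(0)
  tel_iv <- sat_iv <- te_iv <- sd_iv <- NULL
  sat_hits <- NULL
  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    flank_total <- L - 2 * tel_len - arr_len
    if (flank_total < 2 * config$sd_length + 2000)
      stop("chromosome ", ch, " too short for configured features")
    f1 <- floor(flank_total / 2)
    f2 <- flank_total - f1
    copies <- vapply(seq_len(config$satellite_copies), function(i)
      .mutate_subs(monomer, config$satellite_div), character(1))
    chrom_seq <- paste0(strrep(motif, config$telomere_copies),
                        .rand_dna(f1), paste(copies, collapse = ""),
                        .rand_dna(f2),
                        strrep(revcomp(motif), config$telomere_copies))
    stopifnot(nchar(chrom_seq) == L)
    arr_start <- tel_len + f1
    tel_iv <- rbind(tel_iv, data.frame(
      chrom = ch, start = c(0, L - tel_len), end = c(tel_len, L),
      name = c("5prime", "3prime"), stringsAsFactors = FALSE))
    sat_iv <- rbind(sat_iv, data.frame(
      chrom = ch, start = arr_start, end = arr_start + arr_len,
      name = "satellite_array", stringsAsFactors = FALSE))
    sat_hits <- rbind(sat_hits, data.frame(
      chrom = ch,
      start = arr_start + (seq_len(config$satellite_copies) - 1) *
        config$monomer_length,
      end = arr_start + seq_len(config$satellite_copies) *
        config$monomer_length,
      name = "monomer", stringsAsFactors = FALSE))
    ## TE annotations in the flanks (never over telomeres)
    if (config$n_te > 0) {
      te_len <- pmin(round(runif(config$n_te, 2000, 8000)), f1 - 100)
      te_start <- vapply(te_len, function(l) {
        if (runif(1) < 0.5) tel_len + sample.int(f1 - l, 1) - 1
        else arr_start + arr_len + sample.int(f2 - l, 1) - 1
      }, numeric(1))
      te_iv <- rbind(te_iv, data.frame(
        chrom = ch, start = te_start, end = te_start + te_len,
        name = sample(c("LTR/Gypsy", "LTR/Copia", "DNA"), config$n_te,
                      replace = TRUE),
        stringsAsFactors = FALSE))
    }
    ## one SD pair: source in flank 1, diverged copy in flank 2
    sdl <- config$sd_length
    src <- tel_len + sample.int(f1 - sdl, 1) - 1
    dst <- arr_start + arr_len + sample.int(f2 - sdl, 1) - 1
    src_seq <- substr(chrom_seq, src + 1, src + sdl)
    chrom_seq <- paste0(substr(chrom_seq, 1, dst),
                        .mutate_subs(src_seq, config$sd_div),
                        substr(chrom_seq, dst + sdl + 1, L))
    sd_iv <- rbind(sd_iv, data.frame(
      chrom = ch, start = c(src, dst), end = c(src + sdl, dst + sdl),
      name = "SD", stringsAsFactors = FALSE))
    ## SD copies across inversion breakpoints
    inv <- config$inversion
    if (config$sd_at_breakpoints && !is.null(inv) && inv$chrom == ch) {
      for (bp in c(inv$start, inv$end)) {
        pos <- round(bp - sdl / 2)
        chrom_seq <- paste0(substr(chrom_seq, 1, pos),
                            .mutate_subs(src_seq, config$sd_div),
                            substr(chrom_seq, pos + sdl + 1, L))
        sd_iv <- rbind(sd_iv, data.frame(
          chrom = ch, start = pos, end = pos + sdl, name = "SD",
          stringsAsFactors = FALSE))
      }
    }
    seqs[ch] <- chrom_seq
  }
  genome <- genome_seq(seqs)
  tracks <- list(telomere = as_intervals(tel_iv),
                 satellite = as_intervals(sat_hits),
                 TE = as_intervals(te_iv[order(te_iv$chrom, te_iv$start), ]),
                 SD = as_intervals(sd_iv[order(sd_iv$chrom, sd_iv$start), ]))
  truth <- list(monomer = monomer,
                telomeres = as_intervals(tel_iv),
                satellite_arrays = as_intervals(sat_iv),
                inversion = config$inversion)
  list(genome = genome, truth = truth, tracks = tracks)
}

#' Apply an inversion to a genome
#'
#' Replaces the segment by its reverse complement. Applying the same
#' inversion twice restores the original sequence.
#'
#' @param genome a [genome_seq()].
#' @param interval one-row interval data frame within a single chromosome.
#' @return list with `genome` (modified) and `truth` (list: `interval`,
#'   `breakpoints` = the two boundary coordinates).
#' @export
apply_inversion <- function(genome, interval) {
  validate_intervals(interval, chrom_lengths(genome))
  stopifnot(nrow(interval) == 1)
  ch <- interval$chrom
  s <- interval$start; e <- interval$end
  seqs <- setNames(as.character(genome$seq), names(genome$seq))
  x <- seqs[[ch]]
  seqs[[ch]] <- paste0(substr(x, 1, s), revcomp(substr(x, s + 1, e)),
                       substr(x, e + 1, nchar(x)))
  list(genome = genome_seq(seqs, mask = genome$mask),
       truth = list(interval = interval, breakpoints = c(s, e)))
}

#' Simulate a syntenic anchor map between two related genomes
#'
#' Anchors are placed at regular spacing along each chromosome; target
#' coordinates equal query coordinates except inside recorded inversions,
#' where targets are mirrored (`t = s + e - q`) and orientation is `-`.
#' Optional noise anchors get random targets and orientations.
#'
#' @param chrom_lengths named vector of chromosome lengths (shared
#'   coordinate scaffold).
#' @param inversions interval data frame of inverted segments (or `NULL`).
#' @param spacing distance between anchor midpoints (bp).
#' @param anchor_len anchor (gene) length.
#' @param noise_rate fraction of anchors replaced by random-target noise.
#' @param seed optional seed.
#' @return anchor data frame (`q_chrom`, `q_start`, `q_end`, `t_chrom`,
#'   `t_start`, `t_end`, `orientation`), sorted by query position.
#' @export
simulate_anchor_map <- function(chrom_lengths, inversions = NULL,
                                spacing = 1e5, anchor_len = 1000,
                                noise_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spacing > max(chrom_lengths)) {
    warning("anchor spacing exceeds chromosome length; empty map")
    return(data.frame(q_chrom = character(), q_start = numeric(),
                      q_end = numeric(), t_chrom = character(),
                      t_start = numeric(), t_end = numeric(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(spacing / 2, L - anchor_len, by = spacing)
    an <- data.frame(q_chrom = ch, q_start = starts,
                     q_end = starts + anchor_len, t_chrom = ch,
                     t_start = starts, t_end = starts + anchor_len,
                     orientation = "+", stringsAsFactors = FALSE)
    if (!is.null(inversions)) {
      for (i in seq_len(nrow(inversions))) {
        if (inversions$chrom[i] != ch) next
        s <- inversions$start[i]; e <- inversions$end[i]
        inside <- an$q_start >= s & an$q_end <= e
        an$t_start[inside] <- s + e - an$q_end[inside]
        an$t_end[inside] <- s + e - an$q_start[inside]
        an$orientation[inside] <- "-"
      }
    }
    if (noise_rate > 0) {
      noisy <- runif(nrow(an)) < noise_rate
      n <- sum(noisy)
      if (n > 0) {
        ns <- round(runif(n, 0, L - anchor_len))
        an$t_start[noisy] <- ns
        an$t_end[noisy] <- ns + anchor_len
        an$orientation[noisy] <- sample(c("+", "-"), n, replace = TRUE)
      }
    }
    an
  })
  res <- do.call(rbind, out)
  res[order(res$q_chrom, res$q_start), , drop = FALSE]
}

## Balding-Nichols draw: subpopulation frequency given ancestral p and F
.bn_draw <- function(p_anc, fst) {
  if (fst <= 0) return(p_anc)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  rbeta(length(p_anc), a, b)
}

#' Simulate a two-group population with an inversion locus
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95). Outside the
#' inversion each group's frequency is an independent Balding-Nichols
#' draw at `fst_outside`. Inside the inversion, group-level frequencies
#' are Balding-Nichols draws at `fst_inside`, and the two inversion
#' haplotype classes get frequency vectors `p_ref`, `p_inv` solving
#' `p_group = c_group * p_inv + (1 - c_group) * p_ref` (projected onto
#' \[0, 1\] where infeasible), so carriers draw their genotypes from the
#' inverted-haplotype vector. Inversion carrier status is per accession at
#' the group carrier frequency. Diploid genotypes are binomial draws;
#' the inversion itself is a binary carrier state.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (a [variant_set()]) and `truth` (list:
#'   `groups`, `carrier`, `inside`, per-site frequency vectors).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  inv <- config$inversion
  ch <- if (!is.null(inv)) inv$chrom else names(config$chrom_lengths)[1]
  L <- config$chrom_lengths[[ch]]
  pos0 <- sort(sample.int(L - 2, config$n_snp))
  inside <- if (!is.null(inv)) pos0 >= inv$start & pos0 < inv$end
            else rep(FALSE, config$n_snp)
  n_groups <- length(config$pop_sizes)
  stopifnot(n_groups == 2)
  groups <- rep(names(config$pop_sizes), config$pop_sizes)
  n_acc <- length(groups)
  acc <- sprintf("acc%03d", seq_len(n_acc))
  ## carrier status
  cfreq <- config$inv_freq
  carrier <- logical(n_acc)
  for (g in names(config$pop_sizes)) {
    ix <- which(groups == g)
    if (config$carrier_assignment == "exact") {
      k <- round(cfreq[[g]] * length(ix))
      carrier[sample(ix, k)] <- TRUE
    } else {
      carrier[ix] <- runif(length(ix)) < cfreq[[g]]
    }
  }
  ## allele frequencies
  p_anc <- runif(config$n_snp, 0.05, 0.95)
  gnames <- names(config$pop_sizes)
  pA <- ifelse(inside, .bn_draw(p_anc, config$fst_inside),
               .bn_draw(p_anc, config$fst_outside))
  pB <- ifelse(inside, .bn_draw(p_anc, config$fst_inside),
               .bn_draw(p_anc, config$fst_outside))
  ## haplotype-class vectors for inside sites
  cA <- cfreq[[gnames[1]]]; cB <- cfreq[[gnames[2]]]
  p_ref <- p_inv <- rep(NA_real_, config$n_snp)
  if (any(inside)) {
    if (abs(cA - cB) < 1e-9) {
      p_ref[inside] <- p_inv[inside] <- (pA[inside] + pB[inside]) / 2
    } else {
      d <- (pA[inside] - pB[inside]) / (cA - cB)
      pr <- pmin(pmax(pA[inside] - cA * d, 0), 1)
      p_ref[inside] <- pr
      p_inv[inside] <- pmin(pmax(pr + d, 0), 1)
    }
  }
  ## genotypes: accessions x sites
  geno <- matrix(0L, nrow = n_acc, ncol = config$n_snp)
  pg <- rbind(pA, pB)[match(groups, gnames), , drop = FALSE]
  if (any(inside)) {
    pg[carrier, inside] <- matrix(p_inv[inside], nrow = sum(carrier),
                                  ncol = sum(inside), byrow = TRUE)
    pg[!carrier, inside] <- matrix(p_ref[inside], nrow = sum(!carrier),
                                   ncol = sum(inside), byrow = TRUE)
  }
  geno[] <- rbinom(length(pg), 2L, as.vector(pg))
  rownames(geno) <- acc
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_snp, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites <- data.frame(chrom = ch, pos0 = pos0, ref = ref, alt = alt,
                      QUAL = round(runif(config$n_snp, 100, 1000), 1),
                      QD = round(runif(config$n_snp, 20, 35), 2),
                      SOR = round(runif(config$n_snp, 0.5, 2), 3),
                      FS = round(runif(config$n_snp, 0, 10), 3),
                      MQ = 60,
                      MQRankSum = round(rnorm(config$n_snp), 3),
                      ReadPosRankSum = round(rnorm(config$n_snp), 3),
                      stringsAsFactors = FALSE)
  list(variants = variant_set(sites, geno),
       truth = list(groups = setNames(groups, acc),
                    carrier = setNames(carrier, acc),
                    inside = inside, p_anc = p_anc, pA = pA, pB = pB,
                    p_ref = p_ref, p_inv = p_inv))
}

#' Simulate per-accession coverage profiles over an inversion region
#'
#' Baseline depth is Poisson per bin. Accessions carrying the inversion
#' get zero-depth voids anchored at both breakpoints and growing inward,
#' totalling `void_fraction` of the inversion, plus an overall depth
#' reduction (`carrier_depth_factor`); non-carriers keep uniform coverage.
#'
#' @param carrier named logical vector of true carrier status per
#'   accession (e.g. from [simulate_population()]).
#' @param config a [sim_config()]; must define an inversion.
#' @param pad bases of flanking context either side of the inversion.
#' @return list with `profiles` (named list of data frames `chrom`,
#'   `start`, `end`, `depth`) and `region` (the profiled interval).
#' @export
simulate_coverage <- function(carrier, config, pad = NULL) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$inversion))
  set.seed(config$seed + 2L)
  inv <- config$inversion
  L <- config$chrom_lengths[[inv$chrom]]
  inv_len <- inv$end - inv$start
  bin <- config$coverage_bin
  if (bin > inv_len) stop("coverage bin larger than the inversion")
  if (is.null(pad)) pad <- round(inv_len / 4)
  r_start <- max(0, inv$start - pad)
  r_end <- min(L, inv$end + pad)
  starts <- seq(r_start, r_end - 1, by = bin)
  ends <- pmin(starts + bin, r_end)
  mids <- (starts + ends) / 2
  void_half <- config$void_fraction * inv_len / 2
  in_void <- (mids >= inv$start & mids < inv$start + void_half) |
    (mids >= inv$end - void_half & mids < inv$end)
  profiles <- lapply(seq_along(carrier), function(i) {
    mu <- config$depth_mean *
      if (carrier[i]) config$carrier_depth_factor else 1
    depth <- rpois(length(starts), mu)
    if (carrier[i]) depth[in_void] <- 0L
    data.frame(chrom = inv$chrom, start = starts, end = ends,
               depth = depth, stringsAsFactors = FALSE)
  })
  names(profiles) <- names(carrier)
  list(profiles = profiles,
       region = intervals(inv$chrom, r_start, r_end))
}

#' Simulate alignment summary records
#'
#' Per-read edit distance is Binomial(aligned length, error rate); an
#' exact fraction of reads is flagged as improperly paired and an exact
#' fraction left unmapped (both rounded to whole reads, positions
#' permuted).
#'
#' @param config a [sim_config()].
#' @return list with `records` (alignment data frame as in
#'   [read_alignment_tsv()]) and `truth` (totals used).
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- config$n_reads
  len <- config$read_length
  mapped <- rep(1L, n)
  n_unmapped <- round(n * (1 - config$mapping_rate))
  if (n_unmapped > 0) mapped[sample.int(n, n_unmapped)] <- 0L
  aligned <- ifelse(mapped == 1L, len, 0L)
  nm <- integer(n)
  nm[mapped == 1L] <- rbinom(sum(mapped), len, config$aln_error_rate)
  improper <- rep(0L, n)
  n_improper <- round(n * config$improper_frac)
  if (n_improper > 0) improper[sample.int(n, n_improper)] <- 1L
  records <- data.frame(read_id = sprintf("read%06d", seq_len(n)),
                        mapped = mapped, aligned_bases = aligned, nm = nm,
                        paired = 1L, proper_pair = 1L - improper,
                        stringsAsFactors = FALSE)
  list(records = records,
       truth = list(n_reads = n, n_unmapped = n_unmapped,
                    n_improper = n_improper, total_nm = sum(nm[mapped == 1]),
                    total_aligned = sum(aligned)))
}
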