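#' Variant set container
#'
#' Holds biallelic SNP sites plus a diploid genotype matrix. Site
#' coordinates are stored 0-based (`pos0`) internally and converted
#' to/from the 1-based VCF `POS` on read/write. Genotypes are coded as the
#' alternate-allele count 0/1/2, `NA` for missing.
#'
#' @param sites data frame with at least `chrom`, `pos0`, `ref`, `alt`;
#'   optional numeric annotation columns `QUAL`, `QD`, `SOR`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum`.
#' @param geno integer matrix, accessions x sites, entries in
#'   `{0, 1, 2, NA}`; row names are accession ids.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(sites, geno) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos0", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(sites))
    stop("geno must have one column per site")
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0/1/2/NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("acc%03d", seq_len(nrow(geno)))
  structure(list(sites = sites, geno = geno,
                 accessions = rownames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", nrow(x$geno),
      "accessions on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
`[.variant_set` <- function(x, sites_idx) {
  variant_set(x$sites[sites_idx, , drop = FALSE],
              x$geno[, sites_idx, drop = FALSE])
}

.info_keys <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Read a VCF into a variant_set
#'
#' Reads CHROM/POS/REF/ALT/QUAL, the INFO keys QD, SOR, FS, MQ, MQRankSum
#' and ReadPosRankSum, and per-sample GT fields. Multiallelic and
#' non-SNP records are dropped (with a message), consistent with a
#' high-confidence biallelic SNP set.
#'
#' @param path VCF v4.x file (plain text or gzipped).
#' @return a [variant_set()].
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1 & fix$ALT %in% c("A", "C", "G", "T")
  if (!all(keep))
    message("dropped ", sum(!keep), " multiallelic/non-SNP record(s)")
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos0 = as.numeric(fix$POS[keep]) - 1,
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      QUAL = suppressWarnings(as.numeric(fix$QUAL[keep])),
                      stringsAsFactors = FALSE)
  for (k in .info_keys) {
    v <- suppressWarnings(
      vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
    sites[[k]] <- if (is.null(v)) NA_real_ else v[keep]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  geno <- t(apply(gt, 2, code))  # accessions x sites
  if (nrow(gt) == 1) geno <- matrix(geno, ncol = 1)
  rownames(geno) <- colnames(gt)
  variant_set(sites, geno)
}

#' Write a variant_set as VCF v4.2
#'
#' @param vs a [variant_set()].
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_variants <- function(vs, path) {
  sites <- vs$sites
  geno <- vs$geno
  info <- vapply(seq_len(nrow(sites)), function(i) {
    kv <- vapply(.info_keys, function(k) {
      v <- sites[[k]][i]
      if (is.null(v) || is.na(v)) NA_character_ else paste0(k, "=", v)
    }, character(1))
    kv <- kv[!is.na(kv)]
    if (length(kv) == 0) "." else paste(kv, collapse = ";")
  }, character(1))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  gt_str[is.na(geno)] <- "./."
  qual <- if (is.null(sites$QUAL)) rep(".", nrow(sites)) else
    ifelse(is.na(sites$QUAL), ".", sites$QUAL)
  hdr <- c("##fileformat=VCFv4.2",
           vapply(.info_keys, function(k)
             sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
                     k, k), character(1)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], format(sites$pos0[i] + 1, scientific = FALSE),
            ".", sites$ref[i], sites$alt[i], qual[i], "PASS", info[i],
            "GT", gt_str[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
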