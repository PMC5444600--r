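#' Write genotypes as VCF
#'
#' Plain-text VCF 4.2 with a GT field; dosage 0/1/2 becomes 0/0, 0/1, 1/1 and
#' missing becomes ./. (unphased).
#'
#' @param g a [genotype_matrix()].
#' @param path output file path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=admixSMR",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  ), con)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g$dosage), ncol(g$dosage))
  ok <- !is.na(g$dosage)
  gt[ok] <- code[g$dosage[ok] + 1L]
  v <- g$variants
  lines <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Loads biallelic records of a VCF (possibly gzipped) as alternate-allele
#' dosages; multi-allelic records are skipped with a count in a warning.
#' Sample and variant order are preserved.
#'
#' @param path a `.vcf` or `.vcf.gz` file.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
    alt <- alt[!multi]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    pieces <- strsplit(x[ok], "[/|]")
    out[ok] <- vapply(pieces, function(p) sum(p == "1"), integer(1))
    out
  }
  dosage <- t(apply(gt, 1, count_alt))           # variants x samples -> keep
  dosage <- t(dosage)                            # samples x variants
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  genotype_matrix(
    dosage,
    samples = colnames(gt),
    variants = data.frame(
      chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
      id = ifelse(is.na(fx[, "ID"]) | fx[, "ID"] == ".",
                  paste0(fx[, "CHROM"], ":", fx[, "POS"]), fx[, "ID"]),
      ref = fx[, "REF"], alt = alt,
      stringsAsFactors = FALSE
    )
  )
}

#' Write genotypes as a PLINK bed/bim/fam triple
#'
#' SNP-major bed with the standard magic bytes; A1 is the alternate allele,
#' so bed code 0 (homozygous A1) encodes dosage 2, code 2 heterozygous,
#' code 3 homozygous reference and code 1 missing.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$samples); M <- nrow(g$variants)
  utils::write.table(
    data.frame(g$samples, g$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$alt, v$ref),  # A1 = alt, A2 = ref
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  # dosage -> 2-bit code: 2 alt = 00, het = 10, 0 alt = 11, missing = 01
  codes <- matrix(3L, n, M)
  codes[!is.na(g$dosage) & g$dosage == 2L] <- 0L
  codes[!is.na(g$dosage) & g$dosage == 1L] <- 2L
  codes[is.na(g$dosage)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (m in seq_len(M)) {
    cc <- c(codes[, m], rep(0L, pad))
    quads <- matrix(cc, nrow = 4)
    byte_vals <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' Read genotypes from a PLINK bed/bim/fam triple
#'
#' @param prefix path prefix of the `.bed`, `.bim`, `.fam` files.
#' @return A [genotype_matrix()] with dosages counting the A1 allele (written
#'   as the alternate allele by [write_plink()]).
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  n <- nrow(fam); M <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file", call. = FALSE)
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * M)
  if (length(raw) < bytes_per_snp * M) stop("truncated bed file", call. = FALSE)
  vals <- as.integer(raw)
  q1 <- vals %% 4L
  q2 <- (vals %/% 4L) %% 4L
  q3 <- (vals %/% 16L) %% 4L
  q4 <- (vals %/% 64L) %% 4L
  codes <- matrix(rbind(q1, q2, q3, q4), nrow = 4 * bytes_per_snp)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, M)
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  genotype_matrix(
    dosage,
    samples = fam[[2]],
    variants = data.frame(
      chrom = as.character(bim[[1]]), pos = bim[[4]], id = bim[[2]],
      ref = bim[[6]], alt = bim[[5]], stringsAsFactors = FALSE
    )
  )
}

#' Write ancestry estimates as CSV
#'
#' @param estimates data frame from [estimate_ancestry_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ancestry_csv <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override the defaults of [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
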