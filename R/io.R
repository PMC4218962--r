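# Plain-text interfaces: minimal phased VCF for the panel, TSV for read
# observations and reports, JSON for configs and manifests.

#' Write a reference panel as a minimal phased VCF
#'
#' One chromosome, biallelic SNPs, phased GT fields (`0|1` style), one
#' diploid sample per haplotype pair.
#'
#' @param panel A `reference_panel`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  H <- panel$haplotypes
  K <- nrow(H)
  M <- ncol(H)
  samples <- sprintf("S%03d", seq_len(K / 2))
  gt <- matrix("", nrow = M, ncol = K / 2)
  for (s in seq_len(K / 2)) {
    gt[, s] <- paste(H[2 * s - 1, ], H[2 * s, ], sep = "|")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(panel$chrom, panel$positions,
                sprintf("snp%d", seq_len(M)), panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased panel from a VCF
#'
#' Parses a phased, biallelic, single-chromosome VCF (as written by
#' [write_panel_vcf()] or any conforming phased VCF) into a
#' `reference_panel`. Uses \pkg{vcfR} for the VCF parsing.
#'
#' @param path VCF path (plain or gzipped).
#' @return A `reference_panel`.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF panels requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE)))
    stopf("panel VCF must be phased ('|' separators)")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  M <- nrow(gt)
  ns <- ncol(gt)
  H <- matrix(0L, nrow = 2 * ns, ncol = M)
  H[seq(1, 2 * ns, by = 2), ] <- t(matrix(as.integer(a1), nrow = M))
  H[seq(2, 2 * ns, by = 2), ] <- t(matrix(as.integer(a2), nrow = M))
  structure(list(haplotypes = H, positions = as.integer(fix[, "POS"]),
                 ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
                 chrom = unname(fix[1, "CHROM"]),
                 freq = colMeans(H)),
            class = "reference_panel")
}

#' Write read observations as TSV
#'
#' Columns: chrom, pos (1-based), base, phred, strand (+/-), dist5, dist3.
#' The hidden `contaminant` simulation flag is not written.
#'
#' @param reads A `read_observations` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  out <- reads[, c("chrom", "pos", "base", "phred", "strand", "dist5", "dist3")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a read-observation TSV
#'
#' @param path TSV path with the columns written by [write_reads_tsv()].
#' @param panel Optional `reference_panel`; when given, a `site` index
#'   column is added by matching positions (unmatched positions error).
#' @return A `read_observations` data.frame.
#' @export
read_reads_tsv <- function(path, panel = NULL) {
  reads <- read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "integer", "character",
                                     "numeric", "character", "integer",
                                     "integer"),
                      stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    site <- match(reads$pos, panel$positions)
    if (anyNA(site))
      stopf("%d read positions are absent from the panel", sum(is.na(site)))
    reads$site <- site
    attr(reads, "n_sites") <- length(panel$positions)
  }
  class(reads) <- c("read_observations", "data.frame")
  reads
}

#' Write a simulation config as JSON
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#' @param path JSON path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}
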