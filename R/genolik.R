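# Per-site linear-space genotype likelihoods at panel sites, the
# flat-likelihood rules for uncovered and deamination-prone sites, and read
# downsampling to coverage grids.

FLAT_GL <- rep(1 / 3, 3)

#' Genotype likelihoods for one site from a read stack
#'
#' Reads whose base is neither the ref nor the alt allele are discarded.
#' For read error probability `e = 10^(-Q/10)`, the per-read allele
#' likelihood is `1 - e` on a match and `e/3` otherwise; the likelihood of
#' a diploid genotype is the product over reads of the mean of its two
#' allele likelihoods. The triple (ref/ref, ref/alt, alt/alt) is
#' accumulated in log space and normalised to sum to 1. A site with no
#' usable reads gets the flat triple (1/3, 1/3, 1/3) and the uncovered
#' flag.
#'
#' @param bases Read base characters.
#' @param phreds Phred qualities (>= 0).
#' @param ref_allele,alt_allele Distinct single bases.
#' @return List with `gl` (normalised numeric triple), `uncovered`,
#'   `n_used`.
#' @examples
#' site_genotype_likelihoods("A", 20, "A", "C")
#' @export
site_genotype_likelihoods <- function(bases, phreds, ref_allele, alt_allele) {
  if (ref_allele == alt_allele) stopf("ref and alt alleles must differ")
  if (length(phreds) && any(phreds < 0)) stopf("invalid Phred quality < 0")
  keep <- bases == ref_allele | bases == alt_allele
  bases <- bases[keep]; phreds <- phreds[keep]
  if (!length(bases))
    return(list(gl = FLAT_GL, uncovered = TRUE, n_used = 0L))
  e <- phred_to_error(phreds)
  l_ref <- ifelse(bases == ref_allele, 1 - e, e / 3)
  l_alt <- ifelse(bases == alt_allele, 1 - e, e / 3)
  logl <- c(sum(log(l_ref)),
            sum(log((l_ref + l_alt) / 2)),
            sum(log(l_alt)))
  gl <- exp(logl - max(logl))
  list(gl = gl / sum(gl), uncovered = FALSE, n_used = length(bases))
}

#' Reset genotype likelihoods at deamination-prone sites
#'
#' Post-mortem deamination converts C to T (read as G to A on the opposite
#' strand), so at C/T and G/A sites the read data cannot be trusted. In the
#' default `"site-flat"` mode the whole likelihood triple at such sites is
#' reset to (1/3, 1/3, 1/3), deferring entirely to the haplotype-copying
#' prior. In `"genotype-flat"` mode only genotypes containing the
#' damage-product allele (T at C/T sites, A at G/A sites) are reset to 1/3
#' before renormalising. Masking is idempotent in both modes.
#'
#' @param gl A `gl_matrix` (see [build_gl_matrix()]) or a data.frame with
#'   columns `ref`, `alt`, `gl_rr`, `gl_ra`, `gl_aa`, `masked`.
#' @param mode `"site-flat"` (default) or `"genotype-flat"`.
#' @return The masked `gl_matrix` with the `masked` flag set at transition
#'   sites.
#' @export
apply_deamination_mask <- function(gl, mode = c("site-flat", "genotype-flat")) {
  mode <- match.arg(mode)
  # already-masked sites are skipped so masking is idempotent in both modes
  ts <- is_transition_site(gl$ref, gl$alt) & !gl$masked
  if (mode == "site-flat") {
    gl$gl_rr[ts] <- gl$gl_ra[ts] <- gl$gl_aa[ts] <- 1 / 3
  } else {
    # the damage product is T (from C) or A (from G); reset every genotype
    # containing that allele, then renormalise
    product <- ifelse(gl$ref %in% c("C", "G") & ts, gl$alt, gl$ref)
    has_prod_ra <- ts                               # het always carries it
    has_prod_rr <- ts & gl$ref == product
    has_prod_aa <- ts & gl$alt == product
    gl$gl_ra[has_prod_ra] <- 1 / 3
    gl$gl_rr[has_prod_rr] <- 1 / 3
    gl$gl_aa[has_prod_aa] <- 1 / 3
    s <- gl$gl_rr + gl$gl_ra + gl$gl_aa
    gl$gl_rr <- gl$gl_rr / s; gl$gl_ra <- gl$gl_ra / s; gl$gl_aa <- gl$gl_aa / s
  }
  gl$masked <- gl$masked | ts
  gl
}

#' Build the genotype-likelihood matrix over all panel sites
#'
#' Applies [site_genotype_likelihoods()] at every panel site (sites absent
#' from the reads are flat and flagged uncovered), then the deamination
#' mask.
#'
#' @param reads `read_observations` whose sites all lie in the panel.
#' @param panel A `reference_panel`.
#' @param mode Deamination-mask mode, see [apply_deamination_mask()];
#'   `"none"` skips masking.
#' @return A data.frame of class `gl_matrix` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gl_rr`, `gl_ra`, `gl_aa`, `uncovered`, `masked`. Each
#'   triple sums to 1.
#' @export
build_gl_matrix <- function(reads, panel,
                            mode = c("site-flat", "genotype-flat", "none")) {
  mode <- match.arg(mode)
  M <- length(panel$positions)
  site <- if ("site" %in% names(reads)) reads$site else match(reads$pos, panel$positions)
  if (anyNA(site) || (length(site) && (max(site) > M || min(site) < 1L)))
    stopf("reads contain sites absent from the panel")
  if (length(site) && any(reads$phred < 0)) stopf("invalid Phred quality < 0")

  gl_rr <- gl_ra <- gl_aa <- rep(1 / 3, M)
  uncovered <- rep(TRUE, M)
  if (length(site)) {
    ref_b <- panel$ref[site]; alt_b <- panel$alt[site]
    keep <- reads$base == ref_b | reads$base == alt_b
    s <- site[keep]
    if (length(s)) {
      e <- phred_to_error(reads$phred[keep])
      match_ref <- reads$base[keep] == ref_b[keep]
      l_ref <- ifelse(match_ref, 1 - e, e / 3)
      l_alt <- ifelse(!match_ref, 1 - e, e / 3)
      lr <- rowsum(log(l_ref), s)
      lh <- rowsum(log((l_ref + l_alt) / 2), s)
      la <- rowsum(log(l_alt), s)
      idx <- as.integer(rownames(lr))
      mx <- pmax(lr[, 1], lh[, 1], la[, 1])
      t_rr <- exp(lr[, 1] - mx); t_ra <- exp(lh[, 1] - mx); t_aa <- exp(la[, 1] - mx)
      tot <- t_rr + t_ra + t_aa
      gl_rr[idx] <- t_rr / tot
      gl_ra[idx] <- t_ra / tot
      gl_aa[idx] <- t_aa / tot
      uncovered[idx] <- FALSE
    }
  }
  gl <- data.frame(chrom = panel$chrom, pos = panel$positions,
                   ref = panel$ref, alt = panel$alt,
                   gl_rr = gl_rr, gl_ra = gl_ra, gl_aa = gl_aa,
                   uncovered = uncovered, masked = FALSE,
                   stringsAsFactors = FALSE)
  class(gl) <- c("gl_matrix", "data.frame")
  if (mode != "none") gl <- apply_deamination_mask(gl, mode)
  class(gl) <- c("gl_matrix", "data.frame")
  gl
}

#' Downsample reads by independent thinning
#'
#' Each read is kept independently with probability `fraction` (or
#' `target_coverage / attr(reads, "coverage")` when a target coverage is
#' given). Deterministic under `seed`.
#'
#' @param reads `read_observations`.
#' @param fraction Keep probability in (0, 1].
#' @param target_coverage Alternative to `fraction`: desired mean depth;
#'   requires `attr(reads, "n_sites")` to compute the current depth.
#' @param seed Integer seed.
#' @return The thinned `read_observations`.
#' @export
downsample_reads <- function(reads, fraction = NULL, target_coverage = NULL,
                             seed = 1L) {
  if (is.null(fraction)) {
    if (is.null(target_coverage)) stopf("give 'fraction' or 'target_coverage'")
    M <- attr(reads, "n_sites")
    if (is.null(M)) stopf("'target_coverage' needs attr(reads, \"n_sites\")")
    fraction <- min(1, target_coverage / (nrow(reads) / M))
  }
  if (fraction <= 0 || fraction > 1) stopf("'fraction' must be in (0, 1]")
  if (fraction == 1) return(reads)
  keep <- with_seed(seed, runif(nrow(reads)) < fraction)
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_sites") <- attr(reads, "n_sites")
  class(out) <- class(reads)
  out
}

#' Write a GL matrix as TSV (Beagle-like layout)
#' @param gl A `gl_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gl_tsv <- function(gl, path) {
  write.table(as.data.frame(gl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
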