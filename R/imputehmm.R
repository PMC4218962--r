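# Diploid Li-Stephens haplotype-copying HMM: genotype posteriors from a
# GL matrix and a phased panel, plus threshold calling and an exhaustive
# path-sum oracle for small instances.

#' Haplotype-copying HMM parameters
#'
#' @param copy_error Per-site miscopy probability epsilon in (0, 0.5).
#'   Default 0.002, small enough that a perfectly copied allele pair can
#'   carry a genotype probability above the 0.99 calling threshold
#'   ((1 - eps)^2 = 0.996) while still absorbing rare miscopies.
#' @param switch_rate Per-site recombination parameter rho (>= 0); when a
#'   map is used, interpreted per Mb of physical distance. Default 0.001,
#'   i.e. about 10 expected template switches per 10^4 sites.
#' @param use_map When `TRUE`, scale rho by the physical distance (Mb)
#'   between adjacent sites instead of treating sites as equidistant.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(copy_error = 0.002, switch_rate = 0.001,
                       use_map = FALSE) {
  if (copy_error <= 0 || copy_error >= 0.5)
    stopf("'copy_error' must be in (0, 0.5)")
  if (switch_rate < 0) stopf("'switch_rate' must be >= 0")
  structure(list(copy_error = copy_error, switch_rate = switch_rate,
                 use_map = isTRUE(use_map)),
            class = "hmm_params")
}

# Per-interval switch parameter vector for a panel.
interval_rho <- function(panel, params) {
  M <- length(panel$positions)
  if (M < 2L) return(numeric(0))
  if (params$use_map) {
    params$switch_rate * diff(panel$positions) / 1e6
  } else {
    rep(params$switch_rate, M - 1L)
  }
}

#' Posterior genotype probabilities by forward-backward
#'
#' Runs the diploid haplotype-copying forward-backward over the ordered-
#' pair state space (K^2 states, uniform start). Per-haplotype transitions
#' stay with probability `exp(-rho)` and otherwise jump uniformly over the
#' K panel haplotypes; emissions convolve the genotype likelihoods with
#' two independent miscopy-epsilon allele draws. Per-site rescaling keeps
#' desk-scale instances (M = 1e4, K = 100) free of underflow.
#'
#' @param gl A `gl_matrix` over exactly the panel sites, in order.
#' @param panel A `reference_panel`.
#' @param params An [hmm_params()].
#' @return A data.frame of class `genotype_posterior` with columns `chrom`,
#'   `pos`, `gp_rr`, `gp_ra`, `gp_aa` (each triple sums to 1) and
#'   attribute `loglik`, the log-likelihood of the data.
#' @export
forward_backward <- function(gl, panel, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  if (nrow(panel$haplotypes) < 1L) stopf("empty panel")
  if (!identical(as.integer(gl$pos), as.integer(panel$positions)))
    stopf("GL sites and panel sites differ (must be identical and ordered)")
  glm <- as.matrix(gl[, c("gl_rr", "gl_ra", "gl_aa")])
  res <- .fb_cpp(panel$haplotypes, glm, interval_rho(panel, params),
                 params$copy_error)
  out <- data.frame(chrom = panel$chrom, pos = panel$positions,
                    gp_rr = res$gp[, 1], gp_ra = res$gp[, 2],
                    gp_aa = res$gp[, 3], stringsAsFactors = FALSE)
  attr(out, "loglik") <- res$loglik
  class(out) <- c("genotype_posterior", "data.frame")
  out
}

#' Call genotypes at a genotype-probability threshold
#'
#' Per site the call is the argmax genotype when its posterior probability
#' reaches the threshold, otherwise missing; exact ties are missing.
#'
#' @param post A `genotype_posterior`.
#' @param threshold GP threshold in (1/3, 1]; 0.99 is the genome-wide
#'   default and 0.85 the single-locus one.
#' @return Integer dosage vector (0 = ref/ref, 1 = het, 2 = alt/alt,
#'   `NA` = no call) with attribute `threshold`.
#' @export
call_genotypes <- function(post, threshold = 0.99) {
  if (threshold <= 1 / 3 || threshold > 1)
    stopf("'threshold' must be in (1/3, 1]")
  gp <- as.matrix(post[, c("gp_rr", "gp_ra", "gp_aa")])
  best <- max.col(gp, ties.method = "first")
  mx <- gp[cbind(seq_len(nrow(gp)), best)]
  tie <- rowSums(gp == mx) > 1L
  call <- best - 1L
  call[mx < threshold | tie] <- NA_integer_
  attr(call, "threshold") <- threshold
  call
}

#' Exhaustive path-sum genotype posterior (test oracle)
#'
#' Enumerates every state path of the diploid copying HMM and sums path
#' probabilities directly. Exponential in the number of sites; guarded to
#' tiny instances. Exported for the test suite.
#'
#' @inheritParams forward_backward
#' @param max_paths Enumeration guard (default 1e6 paths).
#' @return A `genotype_posterior`, as [forward_backward()].
#' @export
brute_force_posterior <- function(gl, panel, params = hmm_params(),
                                  max_paths = 1e6) {
  K <- nrow(panel$haplotypes)
  M <- length(panel$positions)
  S <- K^2
  if (S * S^M > max_paths) stopf("instance too large for path enumeration")
  eps <- params$copy_error
  rho <- interval_rho(panel, params)
  glm <- as.matrix(gl[, c("gl_rr", "gl_ra", "gl_aa")])

  # allele-pair emission kernel A(g | a, b)
  Ak <- function(a, b) {
    p1 <- ifelse(a == 1L, 1 - eps, eps)
    p2 <- ifelse(b == 1L, 1 - eps, eps)
    c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
  }
  trans1 <- function(s) {
    # single-haplotype K x K transition for stay prob s
    s * diag(K) + (1 - s) / K
  }
  states <- expand.grid(j = seq_len(K), k = seq_len(K))
  paths <- do.call(expand.grid, rep(list(seq_len(S)), M))
  gp <- matrix(0, nrow = M, ncol = 3)
  total <- 0
  # ordered-pair transition = kronecker product of per-haplotype transitions
  # (state index s = (k - 1) * K + j, j varying fastest)
  Tm <- lapply(rho, function(r) kronecker(trans1(exp(-r)), trans1(exp(-r))))
  emis <- lapply(seq_len(M), function(m) {
    vapply(seq_len(S), function(s) {
      sum(glm[m, ] * Ak(panel$haplotypes[states$j[s], m],
                        panel$haplotypes[states$k[s], m]))
    }, 0)
  })
  for (p in seq_len(nrow(paths))) {
    path <- as.integer(paths[p, ])
    w <- 1 / S
    for (m in seq_len(M)) {
      if (m > 1L) w <- w * Tm[[m - 1L]][path[m - 1L], path[m]]
      w <- w * emis[[m]][path[m]]
    }
    if (w == 0) next
    total <- total + w
    for (m in seq_len(M)) {
      s <- path[m]
      contrib <- glm[m, ] * Ak(panel$haplotypes[states$j[s], m],
                               panel$haplotypes[states$k[s], m])
      gp[m, ] <- gp[m, ] + (w / emis[[m]][s]) * contrib
    }
  }
  gp <- gp / rowSums(gp)
  out <- data.frame(chrom = panel$chrom, pos = panel$positions,
                    gp_rr = gp[, 1], gp_ra = gp[, 2], gp_aa = gp[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- log(total)
  class(out) <- c("genotype_posterior", "data.frame")
  out
}

#' Write imputed genotypes as a simple VCF plus TSV mirror
#'
#' GT is emitted when the argmax genotype probability reaches the
#' threshold (missing `./.` otherwise); GP carries the posterior triple.
#'
#' @param post A `genotype_posterior`.
#' @param panel The matching `reference_panel` (for alleles).
#' @param path Output VCF path; the TSV mirror gets extension `.tsv`.
#' @param threshold GP calling threshold.
#' @param sample Sample name.
#' @return `path`, invisibly.
#' @export
write_posterior_vcf <- function(post, panel, path, threshold = 0.99,
                                sample = "sample1") {
  calls <- call_genotypes(post, threshold)
  gt <- c("0/0", "0/1", "1/1")[calls + 1L]
  gt[is.na(gt)] <- "./."
  gp <- sprintf("%.6f,%.6f,%.6f", post$gp_rr, post$gp_ra, post$gp_aa)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probability\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t")
  )
  body <- paste(panel$chrom, panel$positions, ".", panel$ref, panel$alt,
                ".", "PASS", ".", "GT:GP", paste(gt, gp, sep = ":"),
                sep = "\t")
  writeLines(c(header, body), path)
  mirror <- data.frame(chrom = panel$chrom, pos = panel$positions,
                       ref = panel$ref, alt = panel$alt,
                       gp_rr = post$gp_rr, gp_ra = post$gp_ra,
                       gp_aa = post$gp_aa, call = calls)
  write.table(mirror, sub("\\.vcf$", ".tsv", path), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
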