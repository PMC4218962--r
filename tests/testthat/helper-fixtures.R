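# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# A small, fast simulation configuration.
tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_haplotypes = 20L, n_sites = 200L, chrom_length = 4e5,
                   coverage = 2, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Noise-free settings: no deamination, no contamination, (near-)error-free
# bases. Phred Inf gives error probability exactly 0.
noise_free <- list(deam_amp_5p = 0, deam_amp_3p = 0, contamination_rate = 0,
                   base_error_law = list(dist = "constant", value = Inf))

# Hand-build a reference_panel from a haplotype matrix.
make_panel <- function(H, positions = NULL, ref = NULL, alt = NULL,
                       chrom = "1") {
  M <- ncol(H)
  structure(list(
    haplotypes = H,
    positions = if (is.null(positions)) seq_len(M) * 100L else positions,
    ref = if (is.null(ref)) rep("A", M) else ref,
    alt = if (is.null(alt)) rep("C", M) else alt,
    chrom = chrom, freq = colMeans(H)), class = "reference_panel")
}

# GL matrix from an M x 3 matrix of (possibly unnormalised) triples.
make_gl <- function(panel, triples) {
  triples <- matrix(triples, ncol = 3)
  triples <- triples / rowSums(triples)
  gl <- data.frame(chrom = panel$chrom, pos = panel$positions,
                   ref = panel$ref, alt = panel$alt,
                   gl_rr = triples[, 1], gl_ra = triples[, 2],
                   gl_aa = triples[, 3],
                   uncovered = FALSE, masked = FALSE,
                   stringsAsFactors = FALSE)
  class(gl) <- c("gl_matrix", "data.frame")
  gl
}

random_gl <- function(panel, seed = 1L) {
  set.seed(seed)
  make_gl(panel, matrix(runif(3 * length(panel$positions), 0.05, 1), ncol = 3))
}

# Random tiny panel for HMM oracle comparisons (K <= 3 haplotypes kept).
random_tiny_panel <- function(K, M, seed) {
  set.seed(seed)
  H <- matrix(rbinom(K * M, 1L, 0.5), nrow = K)
  make_panel(H)
}

# Read stack data.frame builder for likelihood/damage tests.
make_reads <- function(pos, base, phred = 30, strand = "+", dist5 = 10L,
                       dist3 = 10L, chrom = "1", site = NULL) {
  n <- length(base)
  df <- data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
                   base = base, phred = rep_len(phred, n),
                   strand = rep_len(strand, n),
                   dist5 = rep_len(dist5, n), dist3 = rep_len(dist3, n),
                   contaminant = rep_len(FALSE, n), stringsAsFactors = FALSE)
  if (!is.null(site)) df$site <- rep_len(site, n)
  class(df) <- c("read_observations", "data.frame")
  df
}

# Independent brute-force ROH detector implementing the same window
# definition with naive loops (test oracle for detect_roh).
naive_roh <- function(genotypes, positions, config, chrom = "1") {
  n <- length(genotypes)
  w <- config$window_snps
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_snps = integer(0), roh_class = character(0),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  nw <- n - w + 1L
  win_hom <- logical(nw)
  for (i in seq_len(nw)) {
    g <- genotypes[i:(i + w - 1L)]
    win_hom[i] <- sum(g == 1L, na.rm = TRUE) <= config$max_het_per_window &&
      sum(is.na(g)) <= config$max_missing_per_window
  }
  in_run <- logical(n)
  for (i in seq_len(n)) {
    spans <- max(1L, i - w + 1L):min(i, nw)
    in_run[i] <- mean(win_hom[spans]) >= config$hit_proportion
  }
  segs <- list()
  start <- NULL
  for (i in seq_len(n + 1L)) {
    gap_break <- !is.null(start) && i <= n && in_run[i] &&
      i > 1L && in_run[i - 1L] &&
      (positions[i] - positions[i - 1L]) > config$max_gap_kb * 1000
    if (i <= n && in_run[i] && is.null(start)) start <- i
    else if (!is.null(start) && (i > n || !in_run[i] || gap_break)) {
      segs[[length(segs) + 1L]] <- c(start, i - 1L)
      start <- if (i <= n && in_run[i]) i else NULL
    }
  }
  rows <- lapply(segs, function(se) {
    len <- positions[se[2]] - positions[se[1]] + 1L
    data.frame(chrom = chrom, start = positions[se[1]], end = positions[se[2]],
               length = len, n_snps = se[2] - se[1] + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$length >= config$min_length_kb * 1000 &
             out$n_snps >= config$min_snps, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$roh_class <- ifelse(out$length >= config$class_threshold_mb * 1e6,
                          "long", "short")
  rownames(out) <- NULL
  out
}
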