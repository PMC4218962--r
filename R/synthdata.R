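#' Simulation configuration for synthetic ancient-DNA data
#'
#' Bundles every parameter of the synthetic-data generator: panel shape,
#' allele-frequency law, mosaic structure of the target diploid, sequencing
#' coverage and error, post-mortem deamination, fragment lengths and
#' contamination. All generators are deterministic given `seed`.
#'
#' @param n_haplotypes Number of phased panel haplotypes K (even, >= 4).
#' @param n_sites Number of biallelic SNP sites M.
#' @param chrom_length Chromosome length in bp over which sites are placed.
#' @param founder_count Number of panel haplotypes usable as mosaic founders
#'   for the target diploid (defaults to all of them).
#' @param allele_freq_law Distribution spec for per-site derived-allele
#'   frequency, a list like `list(dist = "uniform", min = 0.05, max = 0.95)`
#'   or `list(dist = "beta", shape1, shape2)`.
#' @param transition_fraction Fraction of sites whose ref/alt pair is a
#'   transition (C/T or G/A). Default 0.66, the approximate transition share
#'   among human SNPs.
#' @param mosaic_switch_rate Per-bp probability that a target haplotype
#'   switches copying founder. Default 1e-6 (about ten switches per 10 Mb
#'   haplotype), so the target is an imperfect mosaic of the panel,
#'   emulating ancient haplotypes that a modern reference panel represents
#'   only approximately.
#' @param coverage Mean sequencing depth per site (x).
#' @param base_error_law Phred-quality spec, e.g. `list(dist = "constant",
#'   value = 30)` or `list(dist = "uniform", min = 20, max = 40)` (rounded).
#' @param deam_amp_5p Probability of C->T at the 5' terminal read position.
#' @param deam_amp_3p Probability of G->A at the 3' terminal read position.
#' @param deam_decay Exponential decay length (read positions) of deamination.
#' @param fragment_length_law Fragment-length spec; default discretised
#'   normal, mean 60, sd 15, truncated to \[30, 150\] bp.
#' @param contamination_rate Fraction of reads drawn from a modern-like
#'   contaminant (alleles sampled from panel frequencies).
#' @param n_sex_reads Total sex-chromosome reads drawn by
#'   [simulate_sex_counts()].
#' @param male_ry Expected Y fraction nY/(nX+nY) for an XY individual.
#' @param mt_depth Mean read depth per mtDNA diagnostic position.
#' @param n_diagnostic Number of mtDNA diagnostic positions.
#' @param chrom Chromosome name used in outputs.
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_haplotypes = 8, n_sites = 50, seed = 1)
#' panel <- simulate_panel(cfg)
#' @export
sim_config <- function(n_haplotypes = 100L,
                       n_sites = 5000L,
                       chrom_length = 1e7,
                       founder_count = n_haplotypes,
                       allele_freq_law = list(dist = "uniform", min = 0.05, max = 0.95),
                       transition_fraction = 0.66,
                       mosaic_switch_rate = 1e-6,
                       coverage = 1,
                       base_error_law = list(dist = "constant", value = 30),
                       deam_amp_5p = 0.2,
                       deam_amp_3p = 0.2,
                       deam_decay = 3,
                       fragment_length_law = list(dist = "norm", mean = 60, sd = 15,
                                                  min = 30, max = 150),
                       contamination_rate = 0.005,
                       n_sex_reads = 10000L,
                       male_ry = 0.09,
                       mt_depth = 100,
                       n_diagnostic = 50L,
                       chrom = "1",
                       seed = 1L) {
  K <- check_count(n_haplotypes, "n_haplotypes", min = 2L)
  if (K %% 2L != 0L) stopf("'n_haplotypes' must be even")
  M <- check_count(n_sites, "n_sites", min = 2L)
  if (chrom_length < M) stopf("'chrom_length' must be >= n_sites")
  founder_count <- check_count(founder_count, "founder_count", min = 1L)
  if (founder_count > K) stopf("'founder_count' cannot exceed n_haplotypes")
  check_prob(transition_fraction, "transition_fraction")
  check_prob(mosaic_switch_rate, "mosaic_switch_rate")
  check_prob(contamination_rate, "contamination_rate")
  check_prob(deam_amp_5p, "deam_amp_5p")
  check_prob(deam_amp_3p, "deam_amp_3p")
  check_prob(male_ry, "male_ry")
  if (coverage < 0) stopf("'coverage' must be >= 0")
  if (deam_decay <= 0) stopf("'deam_decay' must be > 0")
  cfg <- list(
    n_haplotypes = K, n_sites = M, chrom_length = chrom_length,
    founder_count = founder_count, allele_freq_law = allele_freq_law,
    transition_fraction = transition_fraction,
    mosaic_switch_rate = mosaic_switch_rate, coverage = coverage,
    base_error_law = base_error_law, deam_amp_5p = deam_amp_5p,
    deam_amp_3p = deam_amp_3p, deam_decay = deam_decay,
    fragment_length_law = fragment_length_law,
    contamination_rate = contamination_rate, n_sex_reads = n_sex_reads,
    male_ry = male_ry, mt_depth = mt_depth, n_diagnostic = n_diagnostic,
    chrom = as.character(chrom), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Draw n values from a distribution spec.
draw_law <- function(law, n) {
  switch(law$dist,
    uniform  = runif(n, law$min, law$max),
    beta     = rbeta(n, law$shape1, law$shape2),
    constant = rep(law$value, n),
    norm     = {
      x <- round(rnorm(n, law$mean, law$sd))
      lo <- if (is.null(law$min)) -Inf else law$min
      hi <- if (is.null(law$max)) Inf else law$max
      bad <- which(x < lo | x > hi)
      while (length(bad)) {
        x[bad] <- round(rnorm(length(bad), law$mean, law$sd))
        bad <- bad[x[bad] < lo | x[bad] > hi]
      }
      x
    },
    stopf("unknown distribution '%s'", law$dist)
  )
}

TRANSVERSION_PAIRS <- matrix(c("A", "C", "A", "T", "C", "G", "G", "T"),
                             ncol = 2, byrow = TRUE)

#' Simulate a phased reference panel
#'
#' Draws per-site derived-allele frequencies from the configured law, then
#' panel haplotype alleles as independent Bernoulli draws, enforcing a minor
#' allele count > 1 at every site by redrawing (bounded). Ref/alt base pairs
#' are assigned so that a configurable fraction of sites are transitions
#' (C/T or G/A), the sites later subject to deamination masking.
#'
#' @param config A [sim_config()].
#' @return An object of class `reference_panel`: list with `haplotypes`
#'   (K x M 0/1 integer matrix), `positions` (strictly increasing bp),
#'   `ref`, `alt` (base characters), `chrom`, and the drawn `freq`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_haplotypes
  M <- config$n_sites
  if (K < 4L)
    stopf("minor allele count > 1 requires at least 4 haplotypes (K = %d)", K)
  with_seed(derive_seed(config$seed, 0L), {
    positions <- sort(sample.int(config$chrom_length, M))
    freq <- draw_law(config$allele_freq_law, M)
    H <- matrix(rbinom(K * M, 1L, rep(freq, each = K)), nrow = K, ncol = M)
    # enforce MAC > 1 by jointly redrawing frequency and alleles at failing
    # sites (bounded); this ascertains sites conditional on MAC > 1, as a
    # polymorphism panel does
    for (try in seq_len(1000L)) {
      ac <- colSums(H)
      bad <- which(pmin(ac, K - ac) <= 1L)
      if (!length(bad)) break
      freq[bad] <- draw_law(config$allele_freq_law, length(bad))
      H[, bad] <- rbinom(K * length(bad), 1L, rep(freq[bad], each = K))
    }
    ac <- colSums(H)
    if (any(pmin(ac, K - ac) <= 1L))
      stopf("could not satisfy minor allele count > 1 after bounded redraws; %s",
            "frequencies too extreme for this panel size")
    is_ts <- runif(M) < config$transition_fraction
    ref <- alt <- character(M)
    n_ts <- sum(is_ts)
    if (n_ts) {
      pair <- sample(1:2, n_ts, replace = TRUE)        # C/T or G/A
      flip <- runif(n_ts) < 0.5                        # ref/alt orientation
      p1 <- c("C", "G")[pair]; p2 <- c("T", "A")[pair]
      ref[is_ts] <- ifelse(flip, p2, p1)
      alt[is_ts] <- ifelse(flip, p1, p2)
    }
    n_tv <- M - n_ts
    if (n_tv) {
      pair <- sample(nrow(TRANSVERSION_PAIRS), n_tv, replace = TRUE)
      flip <- runif(n_tv) < 0.5
      p1 <- TRANSVERSION_PAIRS[pair, 1]; p2 <- TRANSVERSION_PAIRS[pair, 2]
      ref[!is_ts] <- ifelse(flip, p2, p1)
      alt[!is_ts] <- ifelse(flip, p1, p2)
    }
    structure(list(haplotypes = H, positions = positions, ref = ref, alt = alt,
                   chrom = config$chrom, freq = freq),
              class = "reference_panel")
  })
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d phased haplotypes x %d sites (chrom %s, %d-%d bp)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$chrom,
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Simulate a diploid target genome as a panel mosaic
#'
#' Builds the two target haplotypes as recombination mosaics of panel
#' founder haplotypes: between consecutive sites separated by d bp the
#' copied founder switches with probability 1 - (1 - r)^d, where r is the
#' per-bp switch rate; at a switch a different founder is chosen uniformly.
#'
#' @param panel A `reference_panel`.
#' @param config A [sim_config()].
#' @return An object of class `diploid_truth`: list with `hap_a`, `hap_b`
#'   (0/1 vectors), `genotypes` (= hap_a + hap_b), and `source_tracks`
#'   (M x 2 founder indices).
#' @export
simulate_truth <- function(panel, config) {
  stopifnot(inherits(panel, "reference_panel"), inherits(config, "sim_config"))
  M <- ncol(panel$haplotypes)
  if (M < 1L) stopf("empty panel")
  nf <- config$founder_count
  with_seed(derive_seed(config$seed, 1L), {
    d <- diff(panel$positions)
    p_switch <- 1 - (1 - config$mosaic_switch_rate)^d
    tracks <- matrix(0L, nrow = M, ncol = 2)
    for (h in 1:2) {
      cur <- sample.int(nf, 1L)
      tr <- integer(M)
      tr[1] <- cur
      if (M > 1L) {
        sw <- runif(M - 1L) < p_switch
        for (m in 2:M) {
          if (sw[m - 1L] && nf > 1L) {
            cur <- sample(setdiff(seq_len(nf), cur), 1L)
          }
          tr[m] <- cur
        }
      }
      tracks[, h] <- tr
    }
    idx_a <- cbind(tracks[, 1], seq_len(M))
    idx_b <- cbind(tracks[, 2], seq_len(M))
    hap_a <- panel$haplotypes[idx_a]
    hap_b <- panel$haplotypes[idx_b]
    structure(list(hap_a = hap_a, hap_b = hap_b,
                   genotypes = hap_a + hap_b, source_tracks = tracks),
              class = "diploid_truth")
  })
}

# Apply terminal deamination and Phred sequencing error to true base calls,
# in place on a base vector. Deamination acts on the read strand: C->T
# decaying from the read 5' end, G->A from the 3' end; bases are stored in
# reference orientation, so on minus-strand reads the reference-G allele
# shows the 5'-driven lesion and reference-C the 3'-driven one.
apply_read_noise <- function(base, strand, dist5, dist3, phred, config) {
  n <- length(base)
  p5 <- config$deam_amp_5p * exp(-(dist5 - 1) / config$deam_decay)
  p3 <- config$deam_amp_3p * exp(-(dist3 - 1) / config$deam_decay)
  u <- runif(n)
  plus <- strand == "+"
  hit5 <- ifelse(plus, base == "C", base == "G") & u < p5
  hit3 <- ifelse(plus, base == "G", base == "C") & u < p3 & !hit5
  base[hit5] <- ifelse(plus[hit5], "T", "A")
  base[hit3] <- ifelse(plus[hit3], "A", "T")
  err <- runif(n) < phred_to_error(phred)
  if (any(err)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(base[err], bases)
    shift <- sample.int(3L, sum(err), replace = TRUE)
    base[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  base
}

#' Simulate per-site read observations
#'
#' Per panel site the read count is Poisson(coverage). Each read copies one
#' of the two target haplotypes uniformly, or (with the configured
#' contamination probability) carries an allele drawn from the panel sample
#' frequency (a modern-like contaminant). A fragment length is drawn per
#' read, the site placed uniformly within the fragment (giving distances
#' from both read ends), then terminal deamination and Phred base error are
#' applied.
#'
#' @param truth A `diploid_truth`.
#' @param panel The `reference_panel` the truth was drawn against.
#' @param config A [sim_config()].
#' @param coverage Optional mean depth override.
#' @param seed Optional seed override (defaults to a seed derived from the
#'   config seed).
#' @return A `data.frame` of class `read_observations` with columns
#'   `chrom`, `pos`, `site` (panel site index), `base`, `phred`, `strand`,
#'   `dist5`, `dist3` and the hidden simulation flag `contaminant`.
#' @export
simulate_reads <- function(truth, panel, config, coverage = NULL, seed = NULL) {
  stopifnot(inherits(truth, "diploid_truth"), inherits(panel, "reference_panel"),
            inherits(config, "sim_config"))
  cov <- if (is.null(coverage)) config$coverage else coverage
  if (cov <= 0) stopf("'coverage' must be > 0")
  if (is.null(seed)) seed <- derive_seed(config$seed, 2L)
  M <- ncol(panel$haplotypes)
  pfreq <- colMeans(panel$haplotypes)
  with_seed(seed, {
    n_per_site <- rpois(M, cov)
    site <- rep.int(seq_len(M), n_per_site)
    n <- length(site)
    if (n == 0L) {
      reads <- data.frame(chrom = character(0), pos = integer(0),
                          site = integer(0), base = character(0),
                          phred = numeric(0), strand = character(0),
                          dist5 = integer(0), dist3 = integer(0),
                          contaminant = logical(0),
                          stringsAsFactors = FALSE)
    } else {
      contaminant <- runif(n) < config$contamination_rate
      from_b <- runif(n) < 0.5
      allele <- ifelse(from_b, truth$hap_b[site], truth$hap_a[site])
      if (any(contaminant))
        allele[contaminant] <- rbinom(sum(contaminant), 1L, pfreq[site[contaminant]])
      base <- ifelse(allele == 1L, panel$alt[site], panel$ref[site])
      len <- draw_law(config$fragment_length_law, n)
      offset <- floor(runif(n) * len) + 1L          # uniform position in fragment
      dist5 <- as.integer(offset)
      dist3 <- as.integer(len - offset + 1L)
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      phred <- draw_law(config$base_error_law, n)
      base <- apply_read_noise(base, strand, dist5, dist3, phred, config)
      reads <- data.frame(chrom = panel$chrom, pos = panel$positions[site],
                          site = site, base = base, phred = phred,
                          strand = strand, dist5 = dist5, dist3 = dist3,
                          contaminant = contaminant, stringsAsFactors = FALSE)
    }
    attr(reads, "n_sites") <- M
    class(reads) <- c("read_observations", "data.frame")
    reads
  })
}

#' Simulate mtDNA reads over diagnostic positions
#'
#' Generates an endogenous mtDNA consensus and a contaminant haplotype that
#' differ at a set of diagnostic positions; reads at each position are
#' endogenous or contaminant (probability = contamination rate), with
#' fragment placement, deamination and Phred error as in [simulate_reads()].
#' Half of the diagnostic pairs are C/T (damage-confoundable) by default.
#'
#' @param config A [sim_config()].
#' @param transition_diag_fraction Fraction of diagnostic positions whose
#'   endogenous/contaminant pair is C->T (in the damage-prone orientation).
#' @return A `data.frame` of class `mt_read_set` (columns as in
#'   [simulate_reads()]), with attribute `diagnostics`: data.frame of
#'   `pos`, `endogenous`, `contaminant` alleles.
#' @export
simulate_mt_reads <- function(config, transition_diag_fraction = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  nd <- config$n_diagnostic
  with_seed(derive_seed(config$seed, 3L), {
    pos <- sort(sample.int(16569L, nd))
    is_ct <- runif(nd) < transition_diag_fraction
    endo <- ifelse(is_ct, "C", "G")
    cont <- ifelse(is_ct, "T", "T")                 # G->T transversion otherwise
    n_per <- rpois(nd, config$mt_depth)
    idx <- rep.int(seq_len(nd), n_per)
    n <- length(idx)
    contaminant <- runif(n) < config$contamination_rate
    base <- ifelse(contaminant, cont[idx], endo[idx])
    len <- draw_law(config$fragment_length_law, n)
    offset <- floor(runif(n) * len) + 1L
    dist5 <- as.integer(offset)
    dist3 <- as.integer(len - offset + 1L)
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    phred <- draw_law(config$base_error_law, n)
    base <- apply_read_noise(base, strand, dist5, dist3, phred, config)
    reads <- data.frame(chrom = "MT", pos = pos[idx], site = idx, base = base,
                        phred = phred, strand = strand, dist5 = dist5,
                        dist3 = dist3, contaminant = contaminant,
                        stringsAsFactors = FALSE)
    attr(reads, "diagnostics") <- data.frame(pos = pos, endogenous = endo,
                                             contaminant = cont,
                                             stringsAsFactors = FALSE)
    class(reads) <- c("mt_read_set", "read_observations", "data.frame")
    reads
  })
}

#' Simulate X/Y read counts for sex determination
#'
#' Draws the number of Y-aligned reads among `n_sex_reads` sex-chromosome
#' reads: expectation ~0 for an XX individual and the configured male Y
#' fraction for XY.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param config A [sim_config()].
#' @param y_misassign_rate Rate at which X-derived reads are misassigned to
#'   Y (0 = error-free).
#' @return Named integer vector `c(n_x = , n_y = )`.
#' @export
simulate_sex_counts <- function(sex, config, y_misassign_rate = 0) {
  sex <- match.arg(sex, c("XX", "XY"))
  stopifnot(inherits(config, "sim_config"))
  check_prob(y_misassign_rate, "y_misassign_rate")
  with_seed(derive_seed(config$seed, 4L), {
    n <- config$n_sex_reads
    p <- if (sex == "XY") config$male_ry else y_misassign_rate
    n_y <- rbinom(1L, n, p)
    c(n_x = n - n_y, n_y = n_y)
  })
}
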