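# Synthetic-data generator: shape/domain contracts, determinism, and
# agreement of generated data with the configured statistical laws.

test_that("simulate_panel obeys shape, domain, ordering and MAC > 1", {
  cfg <- sim_config(n_haplotypes = 4, n_sites = 10, chrom_length = 1e4,
                    seed = 1)
  panel <- simulate_panel(cfg)
  expect_equal(dim(panel$haplotypes), c(4L, 10L))
  expect_true(all(panel$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(panel$positions) > 0))
  ac <- colSums(panel$haplotypes)
  expect_true(all(pmin(ac, 4 - ac) > 1))
  expect_true(all(panel$ref %in% c("A", "C", "G", "T")))
  expect_true(all(panel$ref != panel$alt))

  # same seed -> bit-identical output
  expect_identical(panel, simulate_panel(cfg))

  # MAC > 1 unattainable with K = 2
  expect_error(simulate_panel(sim_config(n_haplotypes = 2, n_sites = 5,
                                         chrom_length = 100, seed = 1)),
               "at least 4 haplotypes")
})

test_that("panel MAC > 1 holds across configurations and frequency laws", {
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed,
                       allele_freq_law = list(dist = "beta", shape1 = 0.5,
                                              shape2 = 0.5))
    panel <- simulate_panel(cfg)
    ac <- colSums(panel$haplotypes)
    expect_true(all(pmin(ac, cfg$n_haplotypes - ac) > 1))
  }
})

test_that("panel sample frequencies track the drawn frequency law", {
  cfg <- sim_config(n_haplotypes = 100, n_sites = 5000, chrom_length = 1e7,
                    allele_freq_law = list(dist = "uniform", min = 0.05,
                                           max = 0.95), seed = 3)
  panel <- simulate_panel(cfg)
  drawn <- panel$freq                      # the frequency each site was drawn at
  fhat <- colMeans(panel$haplotypes)       # realised sample frequency
  se <- sqrt(drawn * (1 - drawn) / 100)
  z <- (fhat - drawn) / se
  # standardised deviations behave like binomial sampling error: mean ~ 0,
  # variance ~ 1, mean absolute deviation ~ sqrt(2/pi)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(mean(z^2) - 1), 0.1)
  expect_lt(abs(mean(abs(z)) - sqrt(2 / pi)), 0.05)
})

test_that("transition fraction of ref/alt pairs matches configuration", {
  cfg <- tiny_config(seed = 2, n_sites = 2000, chrom_length = 4e6,
                     transition_fraction = 0.66)
  panel <- simulate_panel(cfg)
  ts <- (panel$ref == "C" & panel$alt == "T") |
    (panel$ref == "T" & panel$alt == "C") |
    (panel$ref == "G" & panel$alt == "A") |
    (panel$ref == "A" & panel$alt == "G")
  expect_lt(abs(mean(ts) - 0.66), 3 * sqrt(0.66 * 0.34 / 2000))
})

test_that("zero-switch truth copies exactly one founder per haplotype", {
  cfg <- tiny_config(seed = 4, mosaic_switch_rate = 0)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  expect_equal(length(unique(truth$source_tracks[, 1])), 1L)
  expect_equal(length(unique(truth$source_tracks[, 2])), 1L)
  expect_identical(truth$hap_a,
                   unname(panel$haplotypes[truth$source_tracks[1, 1], ]))
  expect_identical(truth$genotypes, truth$hap_a + truth$hap_b)
})

test_that("mosaic switch counts follow the configured per-bp rate", {
  # rate 1e-6 over a 1e7 bp chromosome: expected switches per haplotype
  # ~ Poisson(10) restricted to the realised site span
  counts <- integer(0)
  expected <- numeric(0)
  for (seed in 1:100) {
    cfg <- sim_config(n_haplotypes = 8, n_sites = 500, chrom_length = 1e7,
                      mosaic_switch_rate = 1e-6, seed = seed)
    panel <- simulate_panel(cfg)
    truth <- simulate_truth(panel, cfg)
    counts <- c(counts, sum(diff(truth$source_tracks[, 1]) != 0),
                sum(diff(truth$source_tracks[, 2]) != 0))
    expected <- c(expected, sum(1 - (1 - 1e-6)^diff(panel$positions)))
  }
  mu <- mean(expected)
  se <- sqrt(mu / length(counts))   # Poisson-count standard error
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_gt(mu, 9)                  # sanity: the regime is ~10 switches
})

test_that("read counts are Poisson(coverage) and noise-free reads match truth", {
  cfg <- do.call(sim_config, c(list(n_haplotypes = 20, n_sites = 5000,
                                    chrom_length = 1e7, coverage = 2,
                                    seed = 5), noise_free))
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  mean_depth <- nrow(reads) / 5000
  expect_lt(abs(mean_depth - 2), 3 * sqrt(2 / 5000))
  truth_bases <- cbind(ifelse(truth$hap_a == 1, panel$alt, panel$ref),
                       ifelse(truth$hap_b == 1, panel$alt, panel$ref))
  ok <- reads$base == truth_bases[reads$site, 1] |
        reads$base == truth_bases[reads$site, 2]
  expect_true(all(ok))
  expect_true(all(reads$dist5 >= 1 & reads$dist3 >= 1))
  expect_true(all(reads$dist5 + reads$dist3 - 1 >= 30))
  # determinism
  expect_identical(reads, simulate_reads(truth, panel, cfg))
})

test_that("terminal deamination rate matches the configured amplitude", {
  cfg <- do.call(sim_config, c(list(n_haplotypes = 20, n_sites = 2000,
                                    chrom_length = 4e6, coverage = 10,
                                    seed = 6), noise_free))
  cfg$deam_amp_5p <- 0.3
  cfg$deam_decay <- 3
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  # counting oracle: among reads whose true base is unambiguously C (+) or
  # G (-) (homozygous sites), compare observed conversions at the 5' end
  # with the expected decaying rate
  hom <- truth$hap_a == truth$hap_b
  allele_base <- ifelse(truth$hap_a == 1, panel$alt, panel$ref)
  src <- ifelse(reads$strand == "+", "C", "G")
  sel <- hom[reads$site] & allele_base[reads$site] == src & reads$dist5 <= 6
  conv <- ifelse(reads$strand == "+", "T", "A")
  k <- sum(reads$base[sel] == conv[sel])
  p_exp <- 0.3 * exp(-(reads$dist5[sel] - 1) / 3)
  expect_gt(sum(sel), 200)
  expect_lt(abs(k - sum(p_exp)), 3 * sqrt(sum(p_exp * (1 - p_exp))))
})

test_that("mtDNA reads carry no contaminant alleles when alpha = 0, noise-free", {
  cfg <- do.call(sim_config, c(list(seed = 7, n_diagnostic = 20,
                                    mt_depth = 50), noise_free))
  mt <- simulate_mt_reads(cfg)
  diag <- attr(mt, "diagnostics")
  cont <- diag$contaminant[mt$site]
  expect_equal(sum(mt$base == cont), 0L)
  expect_false(any(mt$contaminant))
})

test_that("mtDNA contaminant read fraction matches alpha", {
  cfg <- do.call(sim_config, c(list(seed = 8, n_diagnostic = 50,
                                    mt_depth = 100), noise_free))
  cfg$contamination_rate <- 0.02
  mt <- simulate_mt_reads(cfg)
  frac <- mean(mt$contaminant)
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / nrow(mt)))
})

test_that("sex-chromosome read counts reflect the karyotype", {
  cfg <- sim_config(seed = 9, n_sex_reads = 10000, male_ry = 0.09)
  xx <- simulate_sex_counts("XX", cfg)
  expect_equal(unname(xx["n_y"]), 0L)
  expect_equal(sum(xx), 10000L)
  xy <- simulate_sex_counts("XY", cfg)
  ry <- xy["n_y"] / sum(xy)
  expect_lt(abs(ry - 0.09), 3 * sqrt(0.09 * 0.91 / 10000))
})

test_that("panel VCF and reads TSV round-trip through their readers", {
  skip_if_not_installed("vcfR")
  cfg <- tiny_config(seed = 10)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_panel_vcf(panel, vcf)
  panel2 <- read_panel_vcf(vcf)
  expect_equal(unname(panel2$haplotypes), unname(panel$haplotypes))
  expect_equal(panel2$positions, panel$positions)
  expect_equal(panel2$ref, panel$ref)
  expect_equal(panel2$alt, panel$alt)
  tsv <- tempfile(fileext = ".tsv")
  write_reads_tsv(reads, tsv)
  reads2 <- read_reads_tsv(tsv, panel)
  expect_equal(reads2$base, reads$base)
  expect_equal(reads2$site, reads$site)
  cfg_path <- tempfile(fileext = ".json")
  write_sim_config(cfg, cfg_path)
  expect_equal(read_sim_config(cfg_path), cfg)
})
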