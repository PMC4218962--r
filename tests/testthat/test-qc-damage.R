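# Endogenous-content arithmetic, damage-profile counting, and recovery of
# the deamination decay curve from simulated reads.

test_that("endogenous fraction is simple percentage arithmetic", {
  expect_equal(endogenous_fraction(500, 800), 62.5)
  expect_equal(endogenous_fraction(0, 1000), 0)
  expect_equal(endogenous_fraction(1000, 1000), 100)
  expect_error(endogenous_fraction(1, 0), "n_total")
  expect_error(endogenous_fraction(20, 10), "n_mapped_nonclonal")
})

test_that("damage profile counts match a constructed read stack", {
  # 1000 reference-C observations at dist5 = 1, 300 of them read T
  reads <- make_reads(pos = 100L,
                      base = c(rep("T", 300), rep("C", 700)),
                      dist5 = 1L, dist3 = 40L)
  sat <- data.frame(pos = 100L, ref = "C")
  prof <- damage_profile(reads, sat)
  expect_equal(prof$ct_5p$rate[1], 0.3)
  expect_equal(prof$ct_5p$numerator[1], 300L)
  expect_equal(prof$ct_5p$denominator[1], 1000L)
  # no reference-G observations: 3' curve undefined everywhere
  expect_true(all(prof$ga_3p$undefined))
  expect_true(all(is.na(prof$ga_3p$rate)))
})

test_that("minus-strand reads are complement-normalised before counting", {
  # a reference-G site observed A at dist5 = 2 on a minus-strand read is a
  # read-strand C->T lesion and belongs in the 5' C->T panel
  reads <- make_reads(pos = 1L, base = c("A", "G", "G", "G"), strand = "-",
                      dist5 = 2L, dist3 = 30L)
  prof <- damage_profile(reads, data.frame(pos = 1L, ref = "G"))
  expect_equal(prof$ct_5p$rate[2], 0.25)
  expect_equal(prof$ct_5p$denominator[2], 4L)
})

test_that("damage-free simulation yields all-zero rates", {
  cfg <- do.call(sim_config, c(list(seed = 21), noise_free,
                               list(n_haplotypes = 20, n_sites = 500,
                                    chrom_length = 1e6, coverage = 3)))
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  # restrict the accounting to homozygous-reference sites so genuine
  # polymorphism does not enter the mismatch counts
  hom_ref <- truth$genotypes == 0L
  sat <- data.frame(pos = panel$positions[hom_ref], ref = panel$ref[hom_ref])
  prof <- damage_profile(reads, sat)
  expect_true(all(prof$ct_5p$rate[!prof$ct_5p$undefined] == 0))
  expect_true(all(prof$ga_3p$rate[!prof$ga_3p$undefined] == 0))
})

test_that("empty input gives zero denominators, flagged not NaN", {
  prof <- damage_profile(make_reads(1L, character(0)),
                         data.frame(pos = 1L, ref = "C"))
  expect_true(all(prof$ct_5p$denominator == 0))
  expect_true(all(prof$ct_5p$undefined))
  expect_true(all(is.na(prof$ct_5p$rate)))
})

test_that("profiles are invariant to read order and merge by counts", {
  cfg <- tiny_config(seed = 22, deam_amp_5p = 0.3)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  sat <- data.frame(pos = panel$positions, ref = panel$ref)
  prof <- damage_profile(reads, sat)
  perm <- reads[sample(nrow(reads)), ]
  expect_equal(damage_profile(perm, sat), prof)
  # count-weighted merge of a partition equals the whole
  half <- seq_len(nrow(reads)) <= nrow(reads) / 2
  merged <- merge_damage_profiles(damage_profile(reads[half, ], sat),
                                  damage_profile(reads[!half, ], sat))
  expect_equal(merged$ct_5p, prof$ct_5p)
  expect_equal(merged$ga_3p, prof$ga_3p)
})

test_that("simulated deamination is recovered at the terminal position", {
  cfg <- do.call(sim_config, c(list(seed = 23), noise_free,
                               list(n_haplotypes = 20, n_sites = 2000,
                                    chrom_length = 4e6, coverage = 30)))
  cfg$deam_amp_5p <- 0.3
  cfg$deam_decay <- 3
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  hom_ref <- truth$genotypes == 0L
  sat <- data.frame(pos = panel$positions[hom_ref], ref = panel$ref[hom_ref])
  prof <- damage_profile(reads, sat)
  n1 <- prof$ct_5p$denominator[1]
  expect_gt(n1, 50)
  expect_lt(abs(prof$ct_5p$rate[1] - 0.3), 3 * sqrt(0.3 * 0.7 / n1))
  # monotone decreasing expectation over the first positions
  expect_gt(prof$ct_5p$rate[1], prof$ct_5p$rate[4])
  expect_gt(prof$ct_5p$rate[2], prof$ct_5p$rate[6])
})

test_that("fit_decay recovers exact exponential inputs to 1e-6", {
  rate <- 0.3 * exp(-(1:10 - 1) / 3)
  prof <- structure(list(
    ct_5p = list(numerator = round(rate * 1000), denominator = rep(1000L, 10),
                 rate = rate, undefined = rep(FALSE, 10)),
    ga_3p = list(numerator = rep(0L, 10), denominator = rep(0L, 10),
                 rate = rep(NA_real_, 10), undefined = rep(TRUE, 10)),
    fragment_length_hist = table(integer(0)), n_positions = 10L,
    n_reads = 0L), class = "damage_profile")
  fit <- fit_decay(prof, "5p")
  expect_lt(abs(fit$amplitude - 0.3), 1e-6)
  expect_lt(abs(fit$decay - 3), 1e-6)
  expect_false(fit$no_decay)
})

test_that("fit_decay flags flat and all-zero curves", {
  flat <- structure(list(
    ct_5p = list(numerator = rep(10L, 10), denominator = rep(1000L, 10),
                 rate = rep(0.01, 10), undefined = rep(FALSE, 10)),
    ga_3p = list(numerator = rep(0L, 10), denominator = rep(1000L, 10),
                 rate = rep(0, 10), undefined = rep(FALSE, 10)),
    fragment_length_hist = table(integer(0)), n_positions = 10L,
    n_reads = 0L), class = "damage_profile")
  f1 <- fit_decay(flat, "5p")
  expect_true(f1$no_decay)
  f0 <- fit_decay(flat, "3p")
  expect_true(f0$no_decay)
  expect_equal(f0$amplitude, 0)
  expect_true(is.na(f0$decay))
})

test_that("decay constant is recovered within 20% under noise", {
  # noisy rates around A = 0.3, lambda = 3 (sd 0.005): the median fitted
  # lambda over repeated draws stays within 20% of truth
  lambdas <- vapply(1:40, function(s) {
    set.seed(s)
    rate <- pmax(0, 0.3 * exp(-(1:15 - 1) / 3) + rnorm(15, 0, 0.005))
    prof <- structure(list(
      ct_5p = list(numerator = round(rate * 1000),
                   denominator = rep(1000L, 15), rate = rate,
                   undefined = rep(FALSE, 15)),
      ga_3p = list(numerator = rep(0L, 15), denominator = rep(0L, 15),
                   rate = rep(NA_real_, 15), undefined = rep(TRUE, 15)),
      fragment_length_hist = table(integer(0)), n_positions = 15L,
      n_reads = 0L), class = "damage_profile")
    fit_decay(prof, "5p")$decay
  }, 0)
  expect_lt(abs(median(lambdas) - 3) / 3, 0.2)
})
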