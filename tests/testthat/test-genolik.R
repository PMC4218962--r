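# Genotype likelihoods, the flat-likelihood rules, deamination masking and
# read downsampling.

test_that("empty read stack gives the flat triple and uncovered flag", {
  r <- site_genotype_likelihoods(character(0), numeric(0), "A", "C")
  expect_equal(r$gl, rep(1 / 3, 3))
  expect_true(r$uncovered)
  expect_equal(round(r$gl, 4), rep(0.3333, 3))
})

test_that("single-read likelihoods match the closed-form oracle", {
  # one read A at Q20 at an A/C site: e = 0.01, unnormalised likelihoods
  # (0.99, (0.99 + 0.01/3)/2, 0.01/3)
  r <- site_genotype_likelihoods("A", 20, "A", "C")
  e <- 0.01
  un <- c(1 - e, ((1 - e) + e / 3) / 2, e / 3)
  expect_equal(r$gl, un / sum(un), tolerance = 1e-12)
  expect_equal(round(un, 4), c(0.99, 0.4967, 0.0033))
  expect_false(r$uncovered)

  # reads that are neither allele are discarded
  r2 <- site_genotype_likelihoods(c("A", "G", "T"), c(20, 20, 20), "A", "C")
  expect_equal(r2$n_used, 1L)
  expect_equal(r2$gl, r$gl)
  r3 <- site_genotype_likelihoods(c("G", "T"), c(20, 20), "A", "C")
  expect_true(r3$uncovered)
  expect_equal(r3$gl, rep(1 / 3, 3))
})

test_that("likelihood concentrates with coverage and rejects bad quality", {
  r <- site_genotype_likelihoods(rep("A", 10), rep(40, 10), "A", "C")
  expect_gt(r$gl[1], 0.999)
  expect_error(site_genotype_likelihoods("A", -3, "A", "C"), "Phred")
  expect_error(site_genotype_likelihoods("A", 20, "A", "A"), "differ")
})

test_that("site-flat masking resets transition sites to 0.3333", {
  panel <- make_panel(matrix(c(0L, 0L, 1L, 1L), 4, 3),
                      ref = c("C", "A", "G"), alt = c("T", "C", "A"))
  reads <- make_reads(pos = panel$positions[1], base = rep("T", 5),
                      phred = 30, site = 1L)
  gl <- build_gl_matrix(reads, panel, mode = "site-flat")
  # C/T site with 5 T reads: masked flat despite strong data
  expect_equal(unlist(gl[1, c("gl_rr", "gl_ra", "gl_aa")], use.names = FALSE),
               rep(1 / 3, 3))
  expect_true(gl$masked[1])
  expect_equal(round(gl$gl_rr[1], 4), 0.3333)
  # A/C site untouched by the mask, G/A site masked
  expect_false(gl$masked[2])
  expect_true(gl$masked[3])
})

test_that("genotype-flat masking matches hand computation", {
  panel <- make_panel(matrix(c(0L, 0L, 1L, 1L), 4, 1), ref = "G", alt = "A")
  reads <- make_reads(pos = panel$positions[1], base = rep("G", 4),
                      phred = 30, site = 1L)
  raw <- build_gl_matrix(reads, panel, mode = "none")
  gl <- build_gl_matrix(reads, panel, mode = "genotype-flat")
  # damage product is A: genotypes G/A and A/A reset to 1/3, G/G kept,
  # then renormalised
  expected <- c(raw$gl_rr[1], 1 / 3, 1 / 3)
  expected <- expected / sum(expected)
  expect_equal(unlist(gl[1, c("gl_rr", "gl_ra", "gl_aa")], use.names = FALSE),
               expected, tolerance = 1e-12)
})

test_that("masking is idempotent in both modes", {
  cfg <- tiny_config(seed = 41)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  for (mode in c("site-flat", "genotype-flat")) {
    gl <- build_gl_matrix(reads, panel, mode = mode)
    expect_equal(apply_deamination_mask(gl, mode), gl)
  }
})

test_that("every emitted triple sums to 1 within 1e-12", {
  cfg <- tiny_config(seed = 42)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  for (mode in c("site-flat", "genotype-flat", "none")) {
    gl <- build_gl_matrix(reads, panel, mode = mode)
    expect_true(all(abs(gl$gl_rr + gl$gl_ra + gl$gl_aa - 1) < 1e-12))
  }
})

test_that("empty read set gives all-flat, all-uncovered GLs", {
  cfg <- tiny_config(seed = 43)
  panel <- simulate_panel(cfg)
  gl <- build_gl_matrix(make_reads(1L, character(0), site = integer(0)),
                        panel, mode = "none")
  expect_true(all(gl$uncovered))
  expect_true(all(gl$gl_rr == 1 / 3))
})

test_that("high-coverage error-free GLs recover truth at unmasked sites", {
  cfg <- do.call(sim_config, c(list(seed = 44, n_haplotypes = 20,
                                    n_sites = 300, chrom_length = 6e5,
                                    coverage = 30), noise_free))
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  gl <- build_gl_matrix(reads, panel, mode = "site-flat")
  use <- !gl$masked & !gl$uncovered
  argmax <- max.col(as.matrix(gl[, c("gl_rr", "gl_ra", "gl_aa")])) - 1L
  expect_gt(sum(use), 50)
  expect_equal(argmax[use], truth$genotypes[use])
})

test_that("an all-transition panel is fully masked under site-flat", {
  cfg <- tiny_config(seed = 45, transition_fraction = 1)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  gl <- build_gl_matrix(reads, panel)
  expect_true(all(gl$masked))
})

test_that("reads at sites outside the panel are rejected", {
  cfg <- tiny_config(seed = 46)
  panel <- simulate_panel(cfg)
  bad <- make_reads(pos = max(panel$positions) + 7L, base = "A", site = 9999L)
  expect_error(build_gl_matrix(bad, panel), "absent from the panel")
})

test_that("true-genotype likelihood grows with coverage in expectation", {
  cfg <- tiny_config(seed = 47, n_sites = 400, transition_fraction = 0)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  mean_gl_true <- vapply(c(0.5, 2, 8), function(cov) {
    reads <- simulate_reads(truth, panel, cfg, coverage = cov, seed = 470)
    gl <- build_gl_matrix(reads, panel, mode = "none")
    glm <- as.matrix(gl[, c("gl_rr", "gl_ra", "gl_aa")])
    mean(glm[cbind(seq_len(nrow(glm)), truth$genotypes + 1L)])
  }, 0)
  expect_true(all(diff(mean_gl_true) > 0))
})

test_that("downsampling thins binomially, deterministically", {
  cfg <- tiny_config(seed = 48, n_sites = 2000, chrom_length = 4e6,
                     coverage = 5)
  panel <- simulate_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  reads <- simulate_reads(truth, panel, cfg)
  expect_identical(downsample_reads(reads, fraction = 1), reads)
  half <- downsample_reads(reads, fraction = 0.5, seed = 7)
  expect_lt(abs(nrow(half) - nrow(reads) / 2),
            3 * sqrt(nrow(reads) * 0.25))
  expect_identical(half, downsample_reads(reads, fraction = 0.5, seed = 7))
  expect_error(downsample_reads(reads, fraction = 0), "fraction")
  expect_error(downsample_reads(reads, fraction = 1.2), "fraction")
  # target-coverage interface
  th <- downsample_reads(reads, target_coverage = 1, seed = 8)
  expect_lt(abs(nrow(th) / 2000 - 1), 0.1)
})
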