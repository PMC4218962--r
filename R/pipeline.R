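# End-to-end pipeline wiring: one validated configuration, deterministic
# per-stage seeds derived from a single global seed, a run manifest, and
# every stage's report written as plain text. Each stage is also an
# exported function, so any step can be re-run standalone with identical
# randomness.

#' Pipeline configuration
#'
#' Validates and assembles the parameter blocks of every stage. Unknown
#' keys in `sim`, `hmm` or `roh` are rejected, as are genotype-probability
#' thresholds outside (1/3, 1].
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; all stage seeds derive from it.
#' @param sim Named list of [sim_config()] overrides.
#' @param hmm Named list of [hmm_params()] overrides.
#' @param roh Named list of [roh_config()] overrides.
#' @param gp_threshold_genome Genome-wide GP calling threshold (default
#'   0.99).
#' @param gp_threshold_locus Single-locus GP threshold (default 0.85).
#' @param n_modern Number of modern diploid samples synthesised for the
#'   PCA context.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("paleoimpute_run_"),
                            seed = 1L, sim = list(), hmm = list(),
                            roh = list(), gp_threshold_genome = 0.99,
                            gp_threshold_locus = 0.85, n_modern = 50L) {
  for (t in c(gp_threshold_genome, gp_threshold_locus))
    if (t <= 1 / 3 || t > 1)
      stopf("genotype-probability thresholds must be in (1/3, 1]")
  check_named_subset <- function(x, allowed, what) {
    if (length(x) && (is.null(names(x)) || !all(names(x) %in% allowed)))
      stopf("unknown %s keys: %s", what,
            paste(setdiff(names(x), allowed), collapse = ", "))
  }
  check_named_subset(sim, names(formals(sim_config)), "sim")
  check_named_subset(hmm, names(formals(hmm_params)), "hmm")
  check_named_subset(roh, names(formals(roh_config)), "roh")
  sim$seed <- derive_seed(seed, 10L)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sim = do.call(sim_config, sim),
                 hmm = do.call(hmm_params, hmm),
                 roh = do.call(roh_config, roh),
                 gp_threshold_genome = gp_threshold_genome,
                 gp_threshold_locus = gp_threshold_locus,
                 n_modern = check_count(n_modern, "n_modern", 4L)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> damage QC -> sex/contamination -> genotype
#' likelihoods -> imputation -> concordance evaluation -> Procrustes PCA
#' -> ROH -> trait genotypes, writing every interface file plus a JSON run
#' manifest (package version, seed, parameter echo, file list). A stage
#' failure aborts with the failing stage named; files already written are
#' retained.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the principal in-memory results and
#'   `files`, the named vector of written artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  out <- function(name) file.path(config$out_dir, name)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- list(config = config)
  scfg <- config$sim

  stage("simulate", {
    say("simulate: panel %d x %d, coverage %.2fx",
        scfg$n_haplotypes, scfg$n_sites, scfg$coverage)
    res$panel <- simulate_panel(scfg)
    res$truth <- simulate_truth(res$panel, scfg)
    res$reads <- simulate_reads(res$truth, res$panel, scfg)
    files["panel_vcf"] <- write_panel_vcf(res$panel, out("panel.vcf"))
    files["reads_tsv"] <- write_reads_tsv(res$reads, out("reads.tsv"))
    files["sim_config"] <- write_sim_config(scfg, out("sim_config.json"))
  })
  stage("damage", {
    # profile mismatches only where the target is homozygous reference, so
    # genuine polymorphism does not enter the damage counts (the real-data
    # analogue is counting at monomorphic reference sites)
    hom_ref <- res$truth$genotypes == 0L
    sat <- data.frame(pos = res$panel$positions[hom_ref],
                      ref = res$panel$ref[hom_ref])
    res$damage <- damage_profile(res$reads, sat)
    res$decay_fit <- fit_decay(res$damage, "5p")
    files["damage_tsv"] <- write_damage_tsv(res$damage, out("damage.tsv"))
    say("damage: terminal C->T %.3f, fitted decay %.2f",
        res$damage$ct_5p$rate[1], res$decay_fit$decay)
  })
  stage("sex", {
    counts <- simulate_sex_counts("XY", scfg)
    res$sex <- determine_sex(counts["n_x"], counts["n_y"])
    say("sex: Ry = %.4f -> %s", res$sex$ry, res$sex$call)
  })
  stage("contam", {
    mt <- simulate_mt_reads(scfg)
    diag <- attr(mt, "diagnostics")
    res$mt_contam <- mt_contamination(mt, diag$pos, diag$contaminant,
                                      endogenous_alleles = diag$endogenous)
    # haploid X stand-in: a male target carries one X allele per site
    x_truth <- res$truth
    x_truth$hap_b <- x_truth$hap_a
    x_truth$genotypes <- 2L * x_truth$hap_a
    x_reads <- simulate_reads(x_truth, res$panel, scfg, coverage = 5,
                              seed = derive_seed(config$seed, 20L))
    res$x_contam <- x_contamination(
      x_reads, res$panel$freq,
      autosomal_error_rate = mean(phred_to_error(x_reads$phred)) / 3,
      site_alleles = data.frame(site = seq_along(res$panel$positions),
                                ref = res$panel$ref, alt = res$panel$alt),
      seed = derive_seed(config$seed, 21L))
    files["sexcontam_tsv"] <- write_sexcontam_tsv(
      list(res$sex, res$mt_contam, res$x_contam), out("sex_contamination.tsv"))
    say("contamination: mtDNA %.4f, X %.4f",
        res$mt_contam$estimate, res$x_contam$estimate)
  })
  stage("gl", {
    res$gl <- build_gl_matrix(res$reads, res$panel)
    files["gl_tsv"] <- write_gl_tsv(res$gl, out("genotype_likelihoods.tsv"))
  })
  stage("impute", {
    res$posterior <- forward_backward(res$gl, res$panel, config$hmm)
    res$calls <- call_genotypes(res$posterior, config$gp_threshold_genome)
    files["imputed_vcf"] <- write_posterior_vcf(
      res$posterior, res$panel, out("imputed.vcf"),
      threshold = config$gp_threshold_genome)
  })
  stage("evaluate", {
    res$concordance <- lapply(
      c(config$gp_threshold_genome, config$gp_threshold_locus),
      function(t) concordance(call_genotypes(res$posterior, t),
                              res$truth$genotypes, t))
    ev <- do.call(rbind, lapply(res$concordance, function(r)
      data.frame(threshold = r$threshold, call_rate = r$call_rate,
                 overall = r$overall_concordance, het = r$het_concordance,
                 het_callhet = r$het_concordance_callhet,
                 nonref_disc = r$nonref_discordance, n_loci = r$n_loci)))
    write.table(ev, out("concordance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files["concordance_tsv"] <- out("concordance.tsv")
    say("evaluate: call rate %.3f, concordance %.4f at GP >= %.2f",
        ev$call_rate[1], ev$overall[1], ev$threshold[1])
  })
  stage("pca", {
    # synthetic modern context: diploids drawn from panel haplotype pairs
    moderns <- with_seed(derive_seed(config$seed, 30L), {
      K <- nrow(res$panel$haplotypes)
      t(vapply(seq_len(config$n_modern), function(i) {
        pair <- sample.int(K, 2L)
        res$panel$haplotypes[pair[1], ] + res$panel$haplotypes[pair[2], ]
      }, integer(ncol(res$panel$haplotypes))))
    })
    res$pca <- reference_pca(moderns)
    ancient <- res$calls
    proj <- cosample_project(moderns, ancient, res$pca)
    res$ancient_coords <- proj$coords
    files["pca_tsv"] <- write_pca_tsv(res$pca, proj$coords,
                                      path = out("pca.tsv"))
  })
  stage("roh", {
    res$roh <- detect_roh(res$calls, res$panel$positions, config$roh,
                          chrom = res$panel$chrom)
    res$roh_totals <- classify_and_total(res$roh, config$roh)
    files["roh_bed"] <- write_roh_bed(res$roh, out("roh.bed"))
    write.table(res$roh_totals, out("roh_totals.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files["roh_totals_tsv"] <- out("roh_totals.tsv")
    say("roh: %d segments (%.2f Mb short, %.2f Mb long)", nrow(res$roh),
        res$roh_totals$short_mb[1], res$roh_totals$long_mb[1])
  })
  stage("traits", {
    # map the trait loci onto four synthetic panel sites (synthetic
    # stand-ins for the real coordinates, spread across the chromosome)
    M <- length(res$panel$positions)
    idx <- round(M * c(0.2, 0.4, 0.6, 0.8))
    traits <- default_trait_panel()
    traits$chrom <- res$panel$chrom
    traits$pos <- res$panel$positions[idx]
    traits$effect_allele <- res$panel$alt[idx]
    res$traits <- extract_trait_genotypes(res$posterior, res$panel, traits,
                                          threshold = config$gp_threshold_locus)
    write.table(res$traits, out("traits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files["traits_tsv"] <- out("traits.tsv")
  })
  stage("manifest", {
    manifest <- list(
      package = "paleoimpute",
      version = as.character(packageVersion("paleoimpute")),
      seed = config$seed,
      parameters = list(sim = unclass(config$sim),
                        hmm = unclass(config$hmm),
                        roh = unclass(config$roh),
                        gp_threshold_genome = config$gp_threshold_genome,
                        gp_threshold_locus = config$gp_threshold_locus,
                        n_modern = config$n_modern),
      files = as.list(files))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files["manifest"] <- out("manifest.json")
  })
  res$files <- files
  invisible(res)
}
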