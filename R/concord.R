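# Imputation validation: call-rate / concordance metrics against
# high-coverage truth, over coverages and GP thresholds.

#' Concordance of called genotypes against truth
#'
#' Truth-missing loci are excluded from every denominator. Heterozygote
#' concordance is conditioned on truth-heterozygous called loci (the
#' fraction of those called heterozygous-and-matching); the alternate
#' conditioning on call-heterozygous loci is also reported.
#'
#' @param calls Integer dosages with `NA` for no-call (as from
#'   [call_genotypes()]).
#' @param truth Integer truth dosages (`NA` allowed = truth-missing).
#' @param threshold The GP threshold used for `calls` (recorded in the
#'   report).
#' @return An object of class `concordance_report`: `threshold`,
#'   `call_rate`, `overall_concordance`, `het_concordance`,
#'   `het_concordance_callhet`, `nonref_discordance`, `n_loci`, `n_called`.
#' @export
concordance <- function(calls, truth, threshold = NA_real_) {
  if (length(calls) != length(truth))
    stopf("calls and truth cover different site sets")
  eval_i <- !is.na(truth)
  n_loci <- sum(eval_i)
  if (n_loci == 0L) stopf("no truth-called loci to evaluate")
  called <- eval_i & !is.na(calls)
  n_called <- sum(called)
  overall <- if (n_called) mean(calls[called] == truth[called]) else NA_real_
  th <- called & truth == 1L
  het <- if (any(th)) mean(calls[th] == 1L) else NA_real_
  ch <- called & calls == 1L
  het_call <- if (any(ch)) mean(truth[ch] == 1L) else NA_real_
  nr <- called & (truth != 0L | calls != 0L)
  nonref_disc <- if (any(nr)) mean(calls[nr] != truth[nr]) else NA_real_
  structure(list(threshold = threshold,
                 call_rate = n_called / n_loci,
                 overall_concordance = overall,
                 het_concordance = het,
                 het_concordance_callhet = het_call,
                 nonref_discordance = nonref_disc,
                 n_loci = n_loci, n_called = n_called),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("concordance_report (GP >= %s): call rate %.4f, ",
                     "overall %.4f, het %.4f (n = %d loci)\n"),
              format(x$threshold), x$call_rate, x$overall_concordance,
              x$het_concordance, x$n_loci))
  invisible(x)
}

#' Downsampling concordance sweep
#'
#' For each coverage x replicate: simulate reads from the truth at that
#' coverage, build masked genotype likelihoods, impute with the copying
#' HMM, then report call rate and concordance at each GP threshold. This
#' reproduces the validation design of downsampling a high-coverage genome
#' to a grid of coverages and comparing imputed calls with the directly
#' observed genotypes.
#'
#' @param truth A `diploid_truth` (stands in for the high-coverage calls).
#' @param panel The `reference_panel`.
#' @param config The [sim_config()] used for read simulation.
#' @param coverages Positive ascending coverages (x); default the study
#'   grid 0.1-5x.
#' @param thresholds GP thresholds to evaluate.
#' @param params [hmm_params()] for the imputation stage.
#' @param n_reps Replicates per coverage.
#' @param seed Seed from which per-replicate read seeds are derived.
#' @param mask_mode Deamination-mask mode for [build_gl_matrix()].
#' @return A tidy data.frame: coverage, replicate, threshold, call_rate,
#'   overall, het, het_callhet, nonref_disc, n_loci.
#' @export
coverage_sweep <- function(truth, panel, config,
                           coverages = c(0.1, 0.5, 1, 2, 5),
                           thresholds = c(0.99, 0.85),
                           params = hmm_params(), n_reps = 1L, seed = 1L,
                           mask_mode = "site-flat") {
  if (any(coverages <= 0) || is.unsorted(coverages, strictly = TRUE))
    stopf("'coverages' must be positive and ascending")
  rows <- list()
  for (ci in seq_along(coverages)) {
    for (rep_i in seq_len(n_reps)) {
      rseed <- derive_seed(seed, ci * 1000L + rep_i)
      reads <- simulate_reads(truth, panel, config,
                              coverage = coverages[ci], seed = rseed)
      gl <- build_gl_matrix(reads, panel, mode = mask_mode)
      post <- forward_backward(gl, panel, params)
      for (t in thresholds) {
        rep_row <- concordance(call_genotypes(post, t), truth$genotypes, t)
        rows[[length(rows) + 1L]] <- data.frame(
          coverage = coverages[ci], replicate = rep_i, threshold = t,
          call_rate = rep_row$call_rate,
          overall = rep_row$overall_concordance,
          het = rep_row$het_concordance,
          het_callhet = rep_row$het_concordance_callhet,
          nonref_disc = rep_row$nonref_discordance,
          n_loci = rep_row$n_loci)
      }
    }
  }
  do.call(rbind, rows)
}
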