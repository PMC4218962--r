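# Sex determination from X:Y read counts; contamination estimation from
# mtDNA diagnostic positions and X-chromosome polymorphisms in males.

#' Determine genetic sex from X and Y read counts
#'
#' Computes the Y fraction Ry = nY / (nX + nY) with a normal-approximation
#' binomial 95% confidence interval and calls XX when the whole interval
#' lies below `upper_xx_bound`, XY when it lies above `lower_xy_bound`, and
#' indeterminate otherwise. Default bounds follow the shotgun sex-typing
#' convention (0.016 / 0.075).
#'
#' @param n_x,n_y Read counts aligned to X and Y (sum > 0).
#' @param upper_xx_bound Ry upper bound consistent with XX.
#' @param lower_xy_bound Ry lower bound consistent with XY.
#' @return An object of class `sex_call`: list with `n_x`, `n_y`, `ry`,
#'   `ci_low`, `ci_high`, `call`.
#' @examples
#' determine_sex(8000, 800)
#' @export
determine_sex <- function(n_x, n_y, upper_xx_bound = 0.016,
                          lower_xy_bound = 0.075) {
  n_x <- check_count(n_x, "n_x"); n_y <- check_count(n_y, "n_y")
  n <- n_x + n_y
  if (n <= 0L) stopf("total read count must be > 0")
  ry <- n_y / n
  se <- sqrt(ry * (1 - ry) / n)
  ci <- c(max(0, ry - 1.96 * se), min(1, ry + 1.96 * se))
  call <- if (ci[2] < upper_xx_bound) "XX"
          else if (ci[1] > lower_xy_bound) "XY"
          else "indeterminate"
  structure(list(n_x = n_x, n_y = n_y, ry = ry,
                 ci_low = ci[1], ci_high = ci[2], call = call),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("sex_call: %s  (Ry = %.4f [%.4f, %.4f], nX = %d, nY = %d)\n",
              x$call, x$ry, x$ci_low, x$ci_high, x$n_x, x$n_y))
  invisible(x)
}

#' Mitochondrial contamination estimate from diagnostic positions
#'
#' The estimate is the fraction of reads carrying the contaminant allele
#' among all reads covering the diagnostic positions, with an exact
#' binomial 95% CI. When `exclude_damage_consistent` is on (the default),
#' diagnostic positions whose endogenous->contaminant mismatch could arise
#' by deamination (C->T or G->A) are dropped entirely, so deaminated
#' endogenous reads are not mistaken for contamination.
#'
#' @param mt_reads An `mt_read_set` (or any read data.frame with `pos`,
#'   `base`).
#' @param diagnostic_positions Positions where endogenous and contaminant
#'   haplotypes differ.
#' @param contaminant_alleles Contaminant base at each diagnostic position.
#' @param endogenous_alleles Endogenous base at each position; when `NULL`,
#'   the per-position majority read base is used as the consensus.
#' @param exclude_damage_consistent Drop C->T / G->A diagnostic pairs.
#' @return An object of class `contamination_estimate`: `estimate`,
#'   `ci_low`, `ci_high`, `method = "mtDNA"`, `n_informative` (read count).
#' @export
mt_contamination <- function(mt_reads, diagnostic_positions,
                             contaminant_alleles, endogenous_alleles = NULL,
                             exclude_damage_consistent = TRUE) {
  stopifnot(length(diagnostic_positions) == length(contaminant_alleles))
  keep_reads <- mt_reads[mt_reads$pos %in% diagnostic_positions, , drop = FALSE]
  if (nrow(keep_reads) == 0L) stopf("no covered diagnostic positions")
  if (is.null(endogenous_alleles)) {
    endogenous_alleles <- vapply(diagnostic_positions, function(p) {
      b <- keep_reads$base[keep_reads$pos == p]
      if (!length(b)) return(NA_character_)
      names(sort(table(b), decreasing = TRUE))[1]
    }, character(1))
  }
  use <- rep(TRUE, length(diagnostic_positions))
  if (exclude_damage_consistent) {
    dmg <- (endogenous_alleles == "C" & contaminant_alleles == "T") |
           (endogenous_alleles == "G" & contaminant_alleles == "A")
    use <- use & !dmg & !is.na(endogenous_alleles)
  }
  pos_use <- diagnostic_positions[use]
  if (!length(pos_use)) stopf("no usable diagnostic positions after exclusion")
  r <- keep_reads[keep_reads$pos %in% pos_use, , drop = FALSE]
  cont_allele <- contaminant_alleles[match(r$pos, diagnostic_positions)]
  k <- sum(r$base == cont_allele)
  n <- nrow(r)
  ci <- as.numeric(binom.test(k, n)$conf.int)
  structure(list(estimate = k / n, ci_low = ci[1], ci_high = ci[2],
                 method = "mtDNA", n_informative = n),
            class = "contamination_estimate")
}

#' X-chromosome contamination estimate in males
#'
#' A male carries a single X allele, so at panel-polymorphic X sites any
#' read disagreeing with the site's majority allele is sequencing error or
#' contamination. The moment estimator subtracts the supplied autosomal
#' error rate from the observed disagreement fraction and rescales by the
#' mean heterozygosity `2p(1-p)` over used sites (the chance a contaminant
#' read carries the non-endogenous allele), clipping to \[0, 1\]. The 95% CI
#' is a site-level bootstrap.
#'
#' @param x_reads `read_observations` over X sites (needs `site` or `pos`).
#' @param x_panel_freqs Panel alternate-allele frequency per X site (named
#'   by position when reads carry `pos` only).
#' @param autosomal_error_rate Probability that sequencing error turns a
#'   read into the site's other allele (estimated elsewhere from
#'   monomorphic sites; supplied, not re-estimated here).
#' @param site_alleles Optional data.frame with `site`, `ref`, `alt`; when
#'   given, only transversion sites are used and only reads carrying one
#'   of the two alleles are counted, so post-mortem deamination (C->T /
#'   G->A) cannot masquerade as contamination.
#' @param sex The sample's sex call; must be `"XY"`.
#' @param n_min Minimum number of polymorphic sites with depth >= 2.
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Seed for the bootstrap.
#' @return A `contamination_estimate` with `method = "X"`;
#'   `n_informative` is the number of sites used.
#' @export
x_contamination <- function(x_reads, x_panel_freqs, autosomal_error_rate,
                            site_alleles = NULL, sex = "XY", n_min = 20L,
                            n_boot = 200L, seed = 1L) {
  if (!identical(sex, "XY")) stopf("X contamination is estimated in males only")
  site <- if ("site" %in% names(x_reads)) x_reads$site else match(x_reads$pos, as.integer(names(x_panel_freqs)))
  base <- x_reads$base
  p <- x_panel_freqs
  poly <- which(p > 0 & p < 1)
  if (!length(poly)) stopf("too few informative sites: panel is monomorphic")
  if (!is.null(site_alleles)) {
    tv <- site_alleles$site[!is_transition_site(site_alleles$ref,
                                                site_alleles$alt)]
    poly <- intersect(poly, tv)
    allele_ok <- site %in% poly &
      (base == site_alleles$ref[match(site, site_alleles$site)] |
       base == site_alleles$alt[match(site, site_alleles$site)])
  } else {
    allele_ok <- site %in% poly
  }
  keep <- allele_ok & !is.na(allele_ok)
  site <- site[keep]
  base <- base[keep]
  depth <- table(site)
  used_sites <- as.integer(names(depth)[depth >= 2L])
  if (length(used_sites) < n_min)
    stopf("too few informative sites: %d polymorphic X sites with depth >= 2 (need %d)",
          length(used_sites), n_min)
  sel <- site %in% used_sites
  site <- site[sel]; base <- base[sel]
  # per-site majority allele and mismatch counts
  o <- order(site)
  site <- site[o]; base <- base[o]
  per_site <- function() {
    s <- split(seq_along(site), site)
    mm <- vapply(s, function(ii) {
      tab <- sort(table(base[ii]), decreasing = TRUE)
      length(ii) - as.integer(tab[1])
    }, 0L)
    nn <- lengths(s)
    list(mismatch = mm, n = nn, sites = as.integer(names(s)))
  }
  ps <- per_site()
  hbar <- mean(2 * p[ps$sites] * (1 - p[ps$sites]))
  est_fun <- function(mm, nn, h) {
    d_poly <- sum(mm) / sum(nn)
    min(1, max(0, (d_poly - autosomal_error_rate) / h))
  }
  est <- est_fun(ps$mismatch, ps$n, hbar)
  n_sites <- length(ps$sites)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    ii <- sample.int(n_sites, n_sites, replace = TRUE)
    h <- mean(2 * p[ps$sites[ii]] * (1 - p[ps$sites[ii]]))
    est_fun(ps$mismatch[ii], ps$n[ii], h)
  }, 0))
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  structure(list(estimate = est, ci_low = min(ci[1], est),
                 ci_high = max(ci[2], est), method = "X",
                 n_informative = n_sites),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf("contamination_estimate (%s): %.4f [%.4f, %.4f], n = %d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$n_informative))
  invisible(x)
}

#' Write sex / contamination reports as TSV
#'
#' @param x A `sex_call` or `contamination_estimate` (or list of them).
#' @param path Output path.
#' @param sample Sample label(s).
#' @return `path`, invisibly.
#' @export
write_sexcontam_tsv <- function(x, path, sample = "sample1") {
  if (inherits(x, "sex_call") || inherits(x, "contamination_estimate"))
    x <- list(x)
  rows <- lapply(seq_along(x), function(i) {
    xi <- x[[i]]
    if (inherits(xi, "sex_call"))
      data.frame(sample = sample[min(i, length(sample))], method = "sex",
                 estimate = xi$ry, ci_low = xi$ci_low, ci_high = xi$ci_high,
                 n_informative = xi$n_x + xi$n_y, call = xi$call)
    else
      data.frame(sample = sample[min(i, length(sample))], method = xi$method,
                 estimate = xi$estimate, ci_low = xi$ci_low,
                 ci_high = xi$ci_high, n_informative = xi$n_informative,
                 call = NA_character_)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
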