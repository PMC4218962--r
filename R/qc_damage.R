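# Endogenous-content accounting and post-mortem damage profiling.

#' Percentage of non-clonal endogenous DNA
#'
#' @param n_mapped_nonclonal Mapped, duplicate-removed read count.
#' @param n_total Total sequenced read count (> 0).
#' @return Percentage `100 * n_mapped_nonclonal / n_total`.
#' @examples
#' endogenous_fraction(500, 800) # 62.5
#' @export
endogenous_fraction <- function(n_mapped_nonclonal, n_total) {
  if (n_total <= 0) stopf("'n_total' must be > 0")
  if (n_mapped_nonclonal < 0 || n_mapped_nonclonal > n_total)
    stopf("'n_mapped_nonclonal' must be in [0, n_total]")
  100 * n_mapped_nonclonal / n_total
}

#' Terminal deamination damage profile
#'
#' Tallies C->T mismatch rates by distance from the 5' read end and G->A
#' rates by distance from the 3' end, against the reference allele at each
#' covered site. Minus-strand reads are complement-normalised before
#' counting: the read-strand C->T lesion on a minus-strand read appears as
#' a reference G->A, so such observations are counted in the 5' C->T panel
#' (and mirror-wise for the 3' panel). Only sites whose reference allele is
#' C (resp. G after normalisation) enter the denominators.
#'
#' @param reads A `read_observations` data.frame (needs `pos`, `base`,
#'   `strand`, `dist5`, `dist3`).
#' @param site_allele_table data.frame with columns `pos` and `ref` giving
#'   the reference base at each site.
#' @param n_positions Number of positions P tracked from each read end
#'   (default 25; the damage signal is terminal).
#' @return An object of class `damage_profile`: lists `ct_5p` and `ga_3p`
#'   each with `numerator`, `denominator`, `rate` per position 1..P (rate is
#'   `NA` where the denominator is 0, and flagged in `undefined`), plus
#'   `fragment_length_hist`.
#' @export
damage_profile <- function(reads, site_allele_table, n_positions = 25L) {
  P <- check_count(n_positions, "n_positions", min = 1L)
  ref <- site_allele_table$ref[match(reads$pos, site_allele_table$pos)]
  # reads at positions outside the table (e.g. polymorphic sites excluded
  # from the reference-allele accounting) are ignored
  reads <- reads[!is.na(ref), , drop = FALSE]
  ref <- ref[!is.na(ref)]
  minus <- reads$strand == "-"
  # complement-normalise to read-strand orientation
  ref_n <- ifelse(minus, unname(COMPLEMENT[ref]), ref)
  obs_n <- ifelse(minus, unname(COMPLEMENT[reads$base]), reads$base)

  tally <- function(ref_base, obs_base, dist) {
    sel <- ref_n == ref_base & dist <= P
    den <- tabulate(dist[sel], nbins = P)
    num <- tabulate(dist[sel & obs_n == obs_base], nbins = P)
    rate <- ifelse(den > 0, num / den, NA_real_)
    list(numerator = num, denominator = den, rate = rate,
         undefined = den == 0L)
  }
  frag_len <- reads$dist5 + reads$dist3 - 1L
  structure(list(
    ct_5p = tally("C", "T", reads$dist5),
    ga_3p = tally("G", "A", reads$dist3),
    fragment_length_hist = if (length(frag_len)) table(frag_len) else table(integer(0)),
    n_positions = P, n_reads = nrow(reads)
  ), class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("damage_profile over %d reads (P = %d)\n", x$n_reads, x$n_positions))
  cat(sprintf("  C->T at 5' position 1: %.4f (%d/%d)\n",
              x$ct_5p$rate[1], x$ct_5p$numerator[1], x$ct_5p$denominator[1]))
  cat(sprintf("  G->A at 3' position 1: %.4f (%d/%d)\n",
              x$ga_3p$rate[1], x$ga_3p$numerator[1], x$ga_3p$denominator[1]))
  invisible(x)
}

#' Merge damage profiles by count-weighted pooling
#'
#' @param ... `damage_profile` objects with equal `n_positions`.
#' @return A pooled `damage_profile` (without fragment-length histogram
#'   merging across different binnings; counts are summed).
#' @export
merge_damage_profiles <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) >= 1L, all(vapply(ps, inherits, TRUE, "damage_profile")))
  P <- ps[[1]]$n_positions
  if (any(vapply(ps, function(p) p$n_positions, 0L) != P))
    stopf("profiles track different numbers of positions")
  pool <- function(field) {
    num <- Reduce(`+`, lapply(ps, function(p) p[[field]]$numerator))
    den <- Reduce(`+`, lapply(ps, function(p) p[[field]]$denominator))
    list(numerator = num, denominator = den,
         rate = ifelse(den > 0, num / den, NA_real_), undefined = den == 0L)
  }
  lens <- sort(unique(unlist(lapply(ps, function(p) as.integer(names(p$fragment_length_hist))))))
  hist <- setNames(rep(0L, length(lens)), lens)
  for (p in ps) hist[names(p$fragment_length_hist)] <-
    hist[names(p$fragment_length_hist)] + as.integer(p$fragment_length_hist)
  structure(list(ct_5p = pool("ct_5p"), ga_3p = pool("ga_3p"),
                 fragment_length_hist = as.table(hist), n_positions = P,
                 n_reads = sum(vapply(ps, function(p) p$n_reads, 0L))),
            class = "damage_profile")
}

#' Fit an exponential decay to a damage curve
#'
#' Least-squares fit of `rate(i) = A * exp(-(i - 1) / lambda)` over read
#' positions with defined rates, via [stats::nls()] seeded from a
#' log-linear regression, with a direct [stats::optim()] fall-back.
#'
#' @param profile A `damage_profile`.
#' @param end Which curve to fit: `"5p"` (C->T) or `"3p"` (G->A).
#' @param flat_lambda Decay lengths above this are flagged as
#'   "no decay detected" (default 1e3 positions).
#' @return List with `amplitude`, `decay`, `rss`, `n_positions_used` and
#'   logical `no_decay` (flat or all-zero input; `decay` is `NA` when the
#'   curve is identically zero).
#' @export
fit_decay <- function(profile, end = c("5p", "3p"), flat_lambda = 1e3) {
  stopifnot(inherits(profile, "damage_profile"))
  end <- match.arg(end)
  curve <- if (end == "5p") profile$ct_5p else profile$ga_3p
  ok <- !curve$undefined
  i <- which(ok)
  y <- curve$rate[ok]
  if (length(y) < 3L) stopf("need at least 3 positions with defined rates")
  if (all(y == 0))
    return(list(amplitude = 0, decay = NA_real_, rss = 0,
                n_positions_used = length(y), no_decay = TRUE))
  # log-linear start values on the positive part
  pos <- y > 0
  start <- if (sum(pos) >= 2L) {
    f <- lm(log(y[pos]) ~ I(i[pos] - 1))
    b <- unname(coef(f))
    lam0 <- if (b[2] < 0) -1 / b[2] else flat_lambda
    c(A = unname(exp(b[1])), lambda = min(max(lam0, 0.1), 1e6))
  } else c(A = max(y), lambda = 3)
  fit <- tryCatch(suppressWarnings({
    m <- nls(y ~ A * exp(-(i - 1) / lambda),
             start = list(A = start[["A"]], lambda = start[["lambda"]]),
             control = list(maxiter = 200, warnOnly = TRUE))
    p <- coef(m)
    list(A = p[["A"]], lambda = p[["lambda"]],
         rss = sum((y - p[["A"]] * exp(-(i - 1) / p[["lambda"]]))^2))
  }), error = function(e) NULL)
  if (!is.null(fit) && (!is.finite(fit$lambda) || fit$lambda <= 0 ||
                        !is.finite(fit$A)))
    fit <- NULL                       # degenerate nls solution; refit
  if (is.null(fit)) {
    obj <- function(par) sum((y - exp(par[1]) * exp(-(i - 1) / exp(par[2])))^2)
    o <- optim(c(log(start[["A"]]), log(start[["lambda"]])), obj,
               control = list(reltol = 1e-14, maxit = 5000))
    fit <- list(A = exp(o$par[1]), lambda = exp(o$par[2]), rss = o$value)
  }
  list(amplitude = unname(fit$A), decay = unname(fit$lambda),
       rss = fit$rss, n_positions_used = length(y),
       no_decay = fit$lambda > flat_lambda)
}

#' Write a damage profile as a TSV report
#'
#' One row per position and end: `position`, `end`, `numerator`,
#' `denominator`, `rate`.
#'
#' @param profile A `damage_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_damage_tsv <- function(profile, path) {
  P <- profile$n_positions
  out <- rbind(
    data.frame(position = seq_len(P), end = "5p",
               numerator = profile$ct_5p$numerator,
               denominator = profile$ct_5p$denominator,
               rate = profile$ct_5p$rate),
    data.frame(position = seq_len(P), end = "3p",
               numerator = profile$ga_3p$numerator,
               denominator = profile$ga_3p$denominator,
               rate = profile$ga_3p$rate)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
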