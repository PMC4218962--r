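# Runs of homozygosity: sliding-window detection over called diploid
# genotypes, the short/long 1.6 Mb split, and the ROH-versus-age
# regression.

#' ROH detection configuration
#'
#' Sliding-window parameters in the PLINK tradition; the class threshold
#' separates short runs (older, small ancestral population size) from long
#' runs (recent endogamy). `min_snps` defaults to 50, matched to
#' desk-scale SNP densities.
#'
#' @param window_snps SNPs per sliding window.
#' @param max_het_per_window Maximum heterozygous calls per window for it
#'   to count as homozygous.
#' @param max_missing_per_window Maximum missing calls per window.
#' @param hit_proportion Minimum fraction of spanning windows that are
#'   homozygous for a SNP to be in-run.
#' @param min_length_kb Minimum segment length (kb).
#' @param min_snps Minimum SNPs per segment.
#' @param max_gap_kb Segments are split at inter-SNP gaps above this (kb).
#' @param class_threshold_mb Short/long split; length >= threshold is
#'   long.
#' @return An object of class `roh_config`.
#' @export
roh_config <- function(window_snps = 50L, max_het_per_window = 1L,
                       max_missing_per_window = 5L, hit_proportion = 0.05,
                       min_length_kb = 500, min_snps = 50L,
                       max_gap_kb = 1000, class_threshold_mb = 1.6) {
  cfg <- list(window_snps = check_count(window_snps, "window_snps", 1L),
              max_het_per_window = check_count(max_het_per_window,
                                               "max_het_per_window", 0L),
              max_missing_per_window = check_count(max_missing_per_window,
                                                   "max_missing_per_window", 0L),
              hit_proportion = hit_proportion, min_length_kb = min_length_kb,
              min_snps = check_count(min_snps, "min_snps", 1L),
              max_gap_kb = max_gap_kb, class_threshold_mb = class_threshold_mb)
  if (hit_proportion <= 0 || min_length_kb <= 0 || max_gap_kb <= 0 ||
      class_threshold_mb <= 0)
    stopf("all roh_config values must be positive")
  class(cfg) <- "roh_config"
  cfg
}

#' Detect runs of homozygosity
#'
#' Sliding windows of `window_snps` consecutive SNPs are homozygous when
#' they contain at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls. A SNP is in-run when the
#' fraction of windows spanning it that are homozygous reaches
#' `hit_proportion`. Maximal in-run stretches become segments, split at
#' physical gaps above `max_gap_kb`, then filtered by `min_length_kb` and
#' `min_snps`, and classed short/long at `class_threshold_mb` (boundary
#' length exactly at the threshold is long).
#'
#' @param genotypes Called dosages in \{0, 1, 2, NA\}.
#' @param positions Sorted 1-based bp positions.
#' @param config An [roh_config()].
#' @param chrom Chromosome label for the output.
#' @return data.frame of class `roh_segments`: `chrom`, `start`, `end`
#'   (1-based inclusive), `length`, `n_snps`, `roh_class`.
#' @export
detect_roh <- function(genotypes, positions, config = roh_config(),
                       chrom = "1") {
  stopifnot(inherits(config, "roh_config"))
  n <- length(genotypes)
  if (length(positions) != n) stopf("genotypes and positions differ in length")
  if (is.unsorted(positions, strictly = TRUE)) stopf("positions must be sorted")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_snps = integer(0), roh_class = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("roh_segments", "data.frame")
  w <- config$window_snps
  if (n < w) return(empty)
  het <- as.integer(!is.na(genotypes) & genotypes == 1L)
  mis <- as.integer(is.na(genotypes))
  # window i covers SNPs i .. i+w-1, i = 1..n-w+1
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  nw <- n - w + 1L
  win_hom <- (cs_het[(1:nw) + w] - cs_het[1:nw]) <= config$max_het_per_window &
             (cs_mis[(1:nw) + w] - cs_mis[1:nw]) <= config$max_missing_per_window
  # SNP i is spanned by windows max(1, i-w+1) .. min(i, nw)
  cs_hom <- c(0L, cumsum(as.integer(win_hom)))
  lo <- pmax(1L, (1:n) - w + 1L)
  hi <- pmin(1:n, nw)
  n_span <- hi - lo + 1L
  n_hom <- cs_hom[hi + 1L] - cs_hom[lo]
  in_run <- n_span > 0L & (n_hom / n_span) >= config$hit_proportion

  # maximal in-run stretches, split at large gaps
  idx <- which(in_run)
  if (!length(idx)) return(empty)
  brk <- c(TRUE, diff(idx) > 1L |
             diff(positions[idx]) > config$max_gap_kb * 1000)
  run_id <- cumsum(brk)
  segs <- lapply(split(idx, run_id), function(ii) {
    data.frame(chrom = chrom, start = positions[ii[1]],
               end = positions[ii[length(ii)]],
               length = positions[ii[length(ii)]] - positions[ii[1]] + 1L,
               n_snps = length(ii), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  out <- out[out$length >= config$min_length_kb * 1000 &
             out$n_snps >= config$min_snps, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$roh_class <- ifelse(out$length >= config$class_threshold_mb * 1e6,
                          "long", "short")
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Total short and long ROH per sample
#'
#' @param segments An `roh_segments` data.frame, optionally with a
#'   `sample` column.
#' @param config The [roh_config()] that defined the class threshold.
#' @return data.frame with `sample`, `short_mb`, `long_mb`, `total_mb`.
#' @export
classify_and_total <- function(segments, config = roh_config()) {
  sm <- if ("sample" %in% names(segments)) segments$sample
        else rep("sample1", nrow(segments))
  samples <- unique(sm)
  if (!length(samples)) samples <- "sample1"
  rows <- lapply(samples, function(s) {
    seg <- segments[sm == s, , drop = FALSE]
    long <- seg$length >= config$class_threshold_mb * 1e6
    data.frame(sample = s,
               short_mb = sum(seg$length[!long]) / 1e6,
               long_mb = sum(seg$length[long]) / 1e6,
               total_mb = sum(seg$length) / 1e6)
  })
  if (!nrow(segments))
    return(data.frame(sample = samples, short_mb = 0, long_mb = 0,
                      total_mb = 0))
  do.call(rbind, rows)
}

#' Regression of total ROH on sample age
#'
#' Ordinary least squares of total ROH (Mb) on median calibrated age,
#' reporting the slope, intercept, r-squared and two-sided slope p-value.
#'
#' @param total_roh_mb Total ROH per sample (Mb).
#' @param age_median Median age per sample (e.g. cal. BC years).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
roh_age_regression <- function(total_roh_mb, age_median) {
  if (length(total_roh_mb) != length(age_median))
    stopf("inputs differ in length")
  if (length(total_roh_mb) < 3L) stopf("need at least 3 samples")
  if (sd(age_median) == 0) stopf("zero variance in ages")
  if (sd(total_roh_mb) == 0)
    return(list(slope = 0, intercept = total_roh_mb[1], r_squared = 0,
                p_value = 1, n = length(total_roh_mb)))
  fit <- lm(total_roh_mb ~ age_median)
  sm <- suppressWarnings(summary(fit))  # silences the perfect-fit notice
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(total_roh_mb))
}

#' Write ROH segments as BED (0-based half-open) plus a TSV mirror
#'
#' @param segments An `roh_segments` data.frame.
#' @param path BED output path; the mirror gets extension `.tsv`.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start = segments$start - 1L,
                    end = segments$end, name = segments$roh_class)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(as.data.frame(segments), sub("\\.bed$", ".tsv", path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
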