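# Trait-locus genotype extraction from imputed posteriors at the
# single-locus threshold, and temporal trajectory tabulation.

#' Default trait-SNP panel
#'
#' The four loci followed through time: the pigmentation sweeps at
#' SLC24A5 (rs1426654), SLC45A2 (rs16891982) and TYRP1 (rs2733831), and
#' the European lactase-persistence allele, the T at rs4988235 upstream of
#' LCT. Positions are GRCh37.
#'
#' @return data.frame of class `trait_panel`: `rsid`, `chrom`, `pos`,
#'   `gene`, `effect_allele`, `trait`.
#' @export
default_trait_panel <- function() {
  tp <- data.frame(
    rsid = c("rs1426654", "rs16891982", "rs2733831", "rs4988235"),
    chrom = c("15", "5", "9", "2"),
    pos = c(48426484L, 33951693L, 12709305L, 136608646L),
    gene = c("SLC24A5", "SLC45A2", "TYRP1", "MCM6/LCT"),
    effect_allele = c("A", "G", "C", "T"),
    trait = c("light skin pigmentation", "light skin pigmentation",
              "iris/hair pigmentation", "lactase persistence"),
    stringsAsFactors = FALSE)
  class(tp) <- c("trait_panel", "data.frame")
  tp
}

#' Validate a trait panel table
#' @param traits data.frame with `rsid`, `chrom`, `pos`, `gene`,
#'   `effect_allele`, `trait`.
#' @return The validated `trait_panel`.
#' @export
as_trait_panel <- function(traits) {
  need <- c("rsid", "chrom", "pos", "gene", "effect_allele", "trait")
  if (!all(need %in% names(traits)))
    stopf("trait panel needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(traits$rsid)) stopf("rsids must be unique")
  class(traits) <- c("trait_panel", "data.frame")
  traits
}

#' Extract trait-locus genotypes from an imputed posterior
#'
#' Per locus: the called genotype is the argmax genotype probability when
#' it reaches the threshold (default 0.85, the single-locus threshold),
#' else no-call; the effect-allele dosage is oriented by matching the
#' effect allele to the site's ref or alt base. Loci absent from the
#' posterior's site set are reported `absent`, not errored.
#'
#' @param post A `genotype_posterior`.
#' @param panel The matching `reference_panel` (for ref/alt bases).
#' @param traits A `trait_panel` (default [default_trait_panel()]).
#' @param threshold GP threshold in (1/3, 1].
#' @return data.frame: `rsid`, `gene`, `status`
#'   (`called`/`no-call`/`absent`), `gp_max`, `genotype` (dosage of the
#'   alt allele), `effect_dosage` in \{0, 1, 2, NA\}, `label`.
#' @export
extract_trait_genotypes <- function(post, panel, traits = default_trait_panel(),
                                    threshold = 0.85) {
  if (threshold <= 1 / 3 || threshold > 1)
    stopf("'threshold' must be in (1/3, 1]")
  gp <- as.matrix(post[, c("gp_rr", "gp_ra", "gp_aa")])
  rows <- lapply(seq_len(nrow(traits)), function(i) {
    j <- which(panel$positions == traits$pos[i] &
               panel$chrom == traits$chrom[i])
    if (!length(j))
      return(data.frame(rsid = traits$rsid[i], gene = traits$gene[i],
                        status = "absent", gp_max = NA_real_,
                        genotype = NA_integer_, effect_dosage = NA_integer_,
                        label = NA_character_, stringsAsFactors = FALSE))
    j <- j[1]
    g <- gp[j, ]
    best <- which.max(g)
    called <- g[best] >= threshold && sum(g == g[best]) == 1L
    genotype <- if (called) best - 1L else NA_integer_
    eff <- traits$effect_allele[i]
    effect_dosage <- if (!called) NA_integer_
      else if (eff == panel$alt[j]) genotype
      else if (eff == panel$ref[j]) 2L - genotype
      else NA_integer_
    label <- if (!called) "no-call"
      else if (is.na(effect_dosage)) "effect allele not at this site"
      else if (effect_dosage == 2L) sprintf("%s effect-allele homozygote",
                                            traits$gene[i])
      else if (effect_dosage == 1L) "effect-allele heterozygote"
      else "no effect allele"
    data.frame(rsid = traits$rsid[i], gene = traits$gene[i],
               status = if (called) "called" else "no-call",
               gp_max = unname(g[best]), genotype = genotype,
               effect_dosage = effect_dosage, label = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Temporal trajectory of trait genotypes across samples
#'
#' Orders samples by median age (oldest first) and tabulates the
#' effect-allele dosage grid, with per-locus summaries: the age of the
#' first appearance of the effect allele and of the first homozygote among
#' called genotypes.
#'
#' @param reports Named list of per-sample reports from
#'   [extract_trait_genotypes()].
#' @param sample_ages Named numeric vector of median ages (years BC/BP;
#'   larger = older) for the same samples.
#' @return List: `grid` (locus x sample effect dosages, `NA` = no-call),
#'   `summary` (per locus: `first_appearance_age`, `first_homozygote_age`,
#'   `NA` when never observed).
#' @export
trait_trajectory <- function(reports, sample_ages) {
  if (!length(reports)) stopf("need at least one sample report")
  samples <- names(reports)
  if (is.null(samples) || !all(samples %in% names(sample_ages)))
    stopf("reports and sample_ages must share sample names")
  ord <- order(sample_ages[samples], decreasing = TRUE)  # oldest first
  samples <- samples[ord]
  rsids <- reports[[1]]$rsid
  grid <- sapply(samples, function(s) {
    r <- reports[[s]]
    r$effect_dosage[match(rsids, r$rsid)]
  })
  grid <- matrix(grid, nrow = length(rsids),
                 dimnames = list(rsids, samples))
  summ <- lapply(rsids, function(rs) {
    d <- grid[rs, ]
    appear <- which(!is.na(d) & d >= 1L)
    homo <- which(!is.na(d) & d == 2L)
    data.frame(
      rsid = rs,
      first_appearance_age = if (length(appear))
        unname(sample_ages[samples[appear[1]]]) else NA_real_,
      first_appearance_sample = if (length(appear)) samples[appear[1]]
        else NA_character_,
      first_homozygote_age = if (length(homo))
        unname(sample_ages[samples[homo[1]]]) else NA_real_,
      first_homozygote_sample = if (length(homo)) samples[homo[1]]
        else NA_character_,
      stringsAsFactors = FALSE)
  })
  list(grid = grid, summary = do.call(rbind, summ))
}
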