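# Patterson-normalised PCA of modern reference genotypes, with per-ancient-
# sample joint PCA combined onto the canonical axes by Procrustes
# transformation.

#' Patterson-normalised reference PCA
#'
#' Columns (sites) are centred by their mean dosage mu and scaled by
#' `sqrt((mu/2) * (1 - mu/2))`, the binomial standard deviation of a
#' diploid dosage at the estimated allele frequency; missing genotypes are
#' mean-imputed per site before decomposition; monomorphic sites are
#' dropped. Coordinates come from the singular value decomposition.
#'
#' @param genotypes Samples x sites matrix of dosages in \{0, 1, 2\} with
#'   `NA` allowed; at least 2 samples.
#' @param n_axes Number of retained axes D (default 2, matching
#'   two-dimensional summaries of genomic affinity).
#' @return An object of class `pca_model`: `coords` (samples x D),
#'   `loadings` (kept sites x D), `means`, `weights`, `kept` (kept site
#'   indices), `dropped` (monomorphic site indices), `sdev`.
#' @export
reference_pca <- function(genotypes, n_axes = 2L) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2L) stopf("need at least 2 samples")
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0L)) G[is.na(G[, j]), j] <- mu[j]
  keep <- which(!is.na(mu) & mu > 0 & mu < 2)
  if (length(keep) < 2L) stopf("fewer than 2 polymorphic sites")
  w <- 1 / sqrt((mu[keep] / 2) * (1 - mu[keep] / 2))
  X <- sweep(G[, keep, drop = FALSE], 2, mu[keep]) *
       rep(w, each = nrow(G))
  D <- min(n_axes, nrow(G) - 1L, length(keep))
  sv <- svd(X, nu = D, nv = D)
  coords <- sv$u %*% diag(sv$d[seq_len(D)], D, D)
  rownames(coords) <- rownames(genotypes)
  structure(list(coords = coords, loadings = sv$v, means = mu[keep],
                 weights = w, kept = keep,
                 dropped = setdiff(seq_len(ncol(G)), keep),
                 sdev = sv$d[seq_len(D)] / sqrt(max(1, nrow(G) - 1L)),
                 n_axes = D),
            class = "pca_model")
}

#' Least-squares Procrustes fit of one configuration onto another
#'
#' Finds the scale, orthogonal rotation (reflections allowed, since PCA
#' axes carry arbitrary sign) and translation minimising
#' `||X - (s * Y %*% R + t)||^2`, solved by singular value decomposition
#' of the cross-covariance of the centred configurations. Disparity is the
#' residual sum of squares normalised by the total centred variance of X.
#'
#' @param X Target coordinates (n x d, n >= 3).
#' @param Y Source coordinates (same dimensions).
#' @return An object of class `procrustes_fit`: `rotation` (d x d,
#'   det +-1), `scale` (> 0), `translation`, `disparity` in \[0, 1\].
#' @export
procrustes_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stopf("X and Y must have identical dimensions")
  if (nrow(X) < 3L) stopf("need at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ssY <- sum(Yc^2); ssX <- sum(Xc^2)
  if (ssY == 0) stopf("degenerate (zero-variance) source configuration")
  if (ssX == 0) stopf("degenerate (zero-variance) target configuration")
  sv <- svd(crossprod(Yc, Xc))          # t(Yc) %*% Xc
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / ssY
  t_vec <- cx - s * as.numeric(cy %*% R)
  resid <- ssX - sum(sv$d)^2 / ssY
  structure(list(rotation = R, scale = s, translation = t_vec,
                 disparity = max(0, resid / ssX)),
            class = "procrustes_fit")
}

#' Apply a Procrustes fit to coordinates
#' @param fit A `procrustes_fit`.
#' @param coords Matrix (or vector) of source-space coordinates.
#' @return Transformed coordinates in the target space.
#' @export
apply_procrustes <- function(fit, coords) {
  stopifnot(inherits(fit, "procrustes_fit"))
  cm <- matrix(coords, ncol = ncol(fit$rotation))
  sweep(fit$scale * cm %*% fit$rotation, 2, -fit$translation)
}

#' Project an ancient sample into the reference PCA by per-sample PCA plus
#' Procrustes
#'
#' Builds the per-sample configuration: a PCA of the modern samples
#' restricted to the ancient sample's non-missing sites (restricted, not
#' imputed), with the ancient sample's coordinates obtained on those same
#' axes. The modern coordinates of that configuration are then Procrustes-
#' fitted onto the canonical model's modern coordinates and the fitted
#' transform is applied to the ancient coordinates. The ancient sample
#' does not perturb the axes, so a copy of a modern individual with no
#' missingness lands exactly on its twin, and per-sample placements are
#' independent of processing order.
#'
#' @param modern_genotypes The modern dosage matrix used for the canonical
#'   model.
#' @param ancient_sample Dosage vector over the same sites (`NA` =
#'   missing).
#' @param pca_model The canonical [reference_pca()] model.
#' @param n_min Minimum shared non-missing sites.
#' @return List with `coords` (1 x D transformed ancient coordinates),
#'   `fit` (the `procrustes_fit`), `n_sites` used.
#' @export
cosample_project <- function(modern_genotypes, ancient_sample, pca_model,
                             n_min = 10L) {
  stopifnot(inherits(pca_model, "pca_model"))
  shared <- intersect(pca_model$kept, which(!is.na(ancient_sample)))
  if (length(shared) < n_min)
    stopf("insufficient overlap: %d shared sites (need %d)",
          length(shared), n_min)
  jp <- reference_pca(as.matrix(modern_genotypes)[, shared, drop = FALSE],
                      n_axes = pca_model$n_axes)
  # ancient coordinates on the restricted-site axes
  g <- ancient_sample[shared][jp$kept]
  anc_src <- ((g - jp$means) * jp$weights) %*% jp$loadings
  fit <- procrustes_fit(pca_model$coords, jp$coords)
  coords <- apply_procrustes(fit, anc_src)
  list(coords = coords, fit = fit, n_sites = length(shared))
}

#' Write combined PCA placements as TSV
#'
#' @param pca_model The canonical `pca_model` (modern samples).
#' @param ancient_coords Optional matrix of transformed ancient
#'   coordinates (rownames = sample names).
#' @param groups Optional group label per modern sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_tsv <- function(pca_model, ancient_coords = NULL, groups = NULL,
                          path) {
  n <- nrow(pca_model$coords)
  out <- data.frame(
    sample = if (is.null(rownames(pca_model$coords)))
      sprintf("modern%03d", seq_len(n)) else rownames(pca_model$coords),
    group = if (is.null(groups)) "modern" else groups,
    PC1 = pca_model$coords[, 1],
    PC2 = if (ncol(pca_model$coords) > 1) pca_model$coords[, 2] else NA_real_,
    transformed = FALSE)
  if (!is.null(ancient_coords)) {
    ac <- matrix(ancient_coords, ncol = ncol(pca_model$coords))
    out <- rbind(out, data.frame(
      sample = if (is.null(rownames(ancient_coords)))
        sprintf("ancient%03d", seq_len(nrow(ac))) else rownames(ancient_coords),
      group = "ancient", PC1 = ac[, 1],
      PC2 = if (ncol(ac) > 1) ac[, 2] else NA_real_,
      transformed = TRUE))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
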