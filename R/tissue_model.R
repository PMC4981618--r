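# Three-class (CSF/GM/WM) T1w intensity segmentation.
#
# Stand-in for an atlas-based tissue segmentation: a plain 3-component
# Gaussian mixture fitted by EM to the in-region T1 intensities, components
# assigned to CSF/GM/WM in ascending order of mean (the T1 contrast
# ordering). No spatial priors; the phantom contract only requires intensity
# separability, and externally produced probability maps can be substituted
# through the CLI.

#' Fit the three-class tissue mixture
#'
#' K-means initialization (centers at the 10th/50th/90th in-region intensity
#' percentiles, then Lloyd iterations) followed by Gaussian-mixture EM.
#' The procedure is fully deterministic; `seed` is part of the contract and
#' set for reproducibility of any future stochastic variant.
#'
#' @param t1 `wml_volume`, finite T1w intensities.
#' @param region non-empty `wml_mask`; the fit is restricted to it.
#' @param seed integer RNG seed (determinism contract).
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-5).
#' @return `wml_tissue_probs`: `csf`, `gm`, `wm` probability arrays summing
#'   to 1 inside the region and 0 outside, plus fitted `means`, `sds`,
#'   `weights`, `converged`, `region`, `spacing`.
#' @export
fit_three_class_em <- function(t1, region, seed = 1L, max_iter = 100L,
                               tol = 1e-5) {
  stopifnot(is_volume(t1), inherits(region, "wml_mask"))
  assert_coregistered(list(t1, region))
  if (any(!is.finite(t1$data))) stop("fit_three_class_em: non-finite T1 values")
  idx <- which(region$data == 1L)
  if (length(idx) == 0L) stop("fit_three_class_em: empty region")
  x <- t1$data[idx]
  if (length(unique(x)) < 3L)
    stop("fit_three_class_em: fewer than 3 distinct intensities in region ",
         "(degenerate input)")
  set.seed(seed)
  # Lloyd k-means on 1D intensities, percentile-seeded
  centers <- as.numeric(stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE))
  if (length(unique(centers)) < 3L)
    centers <- centers + c(-1, 0, 1) * 1e-6 * max(abs(centers), 1)
  for (it in 1:50) {
    d <- abs(outer(x, centers, "-"))
    assign <- max.col(-d, ties.method = "first")
    new_centers <- vapply(1:3, function(j) {
      xs <- x[assign == j]
      if (length(xs)) mean(xs) else centers[j]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-8) { centers <- new_centers; break }
    centers <- new_centers
  }
  mu <- centers
  sds <- vapply(1:3, function(j) {
    xs <- x[assign == j]
    if (length(xs) > 1L) stats::sd(xs) else stats::sd(x) / 3
  }, numeric(1))
  sds <- pmax(sds, 1e-6)
  w <- tabulate(assign, 3L) / length(x)
  w <- pmax(w, 1e-6); w <- w / sum(w)
  ll_old <- -Inf
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(j) w[j] * stats::dnorm(x, mu[j], sds[j]),
                   numeric(length(x)))
    tot <- rowSums(dens) + 1e-300
    ll <- sum(log(tot))
    post <- dens / tot
    nk <- colSums(post)
    w <- nk / length(x)
    mu <- colSums(post * x) / nk
    sds <- sqrt(pmax(colSums(post * (x - rep(mu, each = length(x)))^2) / nk,
                     1e-12))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("fit_three_class_em: EM did not converge in ", max_iter,
            " iterations; returning best estimate")
  ord <- order(mu)  # CSF < GM < WM on T1
  shape <- dim(t1$data)
  maps <- lapply(1:3, function(j) {
    a <- array(0, dim = shape)
    a[idx] <- post[, ord[j]]
    a
  })
  structure(list(csf = maps[[1]], gm = maps[[2]], wm = maps[[3]],
                 region = region, spacing = t1$spacing,
                 means = mu[ord], sds = sds[ord], weights = w[ord],
                 converged = converged, seed = seed),
            class = "wml_tissue_probs")
}

#' Tissue probability container from externally produced maps
#'
#' Accepts CSF/GM/WM probability volumes (e.g. from an atlas-based
#' segmentation), renormalizes them to sum to 1 wherever their sum is
#' positive, and returns the same container [fit_three_class_em()] produces.
#'
#' @param csf,gm,wm `wml_volume` probability maps on one grid.
#' @return `wml_tissue_probs`.
#' @export
tissue_probs_from_maps <- function(csf, gm, wm) {
  assert_coregistered(list(csf, gm, wm))
  s <- csf$data + gm$data + wm$data
  if (any(s < -1e-9) || any(csf$data < -1e-9 | gm$data < -1e-9 | wm$data < -1e-9))
    stop("tissue probabilities must be non-negative")
  inside <- s > 1e-9
  norm <- function(a) { a[inside] <- a[inside] / s[inside]; a[!inside] <- 0; a }
  region <- binary_mask(array(as.integer(inside), dim = dim(s)), csf$spacing)
  structure(list(csf = norm(csf$data), gm = norm(gm$data), wm = norm(wm$data),
                 region = region, spacing = csf$spacing,
                 means = NULL, sds = NULL, weights = NULL,
                 converged = NA, seed = NA_integer_),
            class = "wml_tissue_probs")
}

#' Hard tissue labels from probability maps
#'
#' Per voxel, the label of the maximal probability: 1 = CSF, 2 = GM,
#' 3 = WM; 0 = background where all probabilities are 0. Ties break toward
#' the higher label (WM > GM > CSF), so the white-matter neighborhood filter
#' is exercised conservatively.
#'
#' @param probs `wml_tissue_probs`.
#' @return `wml_tissue_labels`: integer label array + spacing.
#' @export
max_probability_labels <- function(probs) {
  stopifnot(inherits(probs, "wml_tissue_probs"))
  lab <- array(1L, dim = dim(probs$csf))
  lab[probs$gm >= probs$csf] <- 2L
  lab[probs$wm >= pmax(probs$csf, probs$gm)] <- 3L
  lab[(probs$csf + probs$gm + probs$wm) <= 0] <- 0L
  structure(list(labels = lab, spacing = probs$spacing),
            class = "wml_tissue_labels")
}

#' @export
print.wml_tissue_labels <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 4L)
  cat(sprintf("<wml_tissue_labels> background %d, CSF %d, GM %d, WM %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

tissue_labels_as_mask <- function(labels, which) {
  binary_mask(array(as.integer(labels$labels %in% which),
                    dim = dim(labels$labels)), labels$spacing)
}
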