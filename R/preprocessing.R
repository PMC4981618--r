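# FLAIR image enhancement and brain-mask construction.
#
# The FLAIR volume is denoised with one conservative pass of Perona-Malik
# anisotropic diffusion, then corrected for the smooth multiplicative bias
# field with an EM scheme (Gaussian mixture on log-intensities alternating
# with a low-order polynomial fit of the log-gain). The brain mask comes from
# the maximum tissue probability thresholded at 0.5, with interior holes
# filled.

#' Perona-Malik diffusion parameters
#'
#' Defaults are the conservative single-pass setting used for small focal
#' lesions: 1 iteration, conduction constant K = 50 (intensity units), and
#' the exponential conduction function that privileges high-contrast edges.
#' The time step `dt = 1/7` is the 3D explicit-scheme stability bound for the
#' 6-connected discretization.
#'
#' @param iterations number of explicit diffusion steps (>= 1).
#' @param K gradient-modulus conduction constant, intensity units (> 0).
#' @param conduction `"high-contrast"` (`exp(-(g/K)^2)`) or `"wide-region"`
#'   (`1/(1+(g/K)^2)`).
#' @param dt explicit time step, `0 < dt <= 1/7`.
#' @export
diffusion_params <- function(iterations = 1L, K = 50, conduction = "high-contrast",
                             dt = 1 / 7) {
  conduction <- match.arg(conduction, c("high-contrast", "wide-region"))
  if (iterations < 1L) stop("iterations must be >= 1")
  if (K <= 0) stop("K must be > 0")
  if (dt <= 0 || dt > 1 / 7 + 1e-12) stop("dt must be in (0, 1/7]")
  structure(list(iterations = as.integer(iterations), K = K,
                 conduction = conduction, dt = dt),
            class = "wml_diffusion_params")
}

# shift a 3D array by one voxel along `axis`, replicating the edge slab
# (replication makes the boundary difference zero => zero-flux boundaries)
shift_replicate <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  s <- seq_len(d[axis]) - by
  s[s < 1L] <- 1L
  s[s > d[axis]] <- d[axis]
  idx[[axis]] <- s
  do.call(`[`, c(list(a), idx))
}

#' 3D Perona-Malik anisotropic diffusion
#'
#' Explicit-Euler update in flux form with 6-neighbor fluxes and zero-flux
#' (Neumann) boundaries; conserves the total intensity sum exactly up to
#' floating-point rounding.
#'
#' @param vol `wml_volume` with finite values.
#' @param params [diffusion_params()].
#' @return diffused `wml_volume` on the same grid.
#' @export
perona_malik_3d <- function(vol, params = diffusion_params()) {
  stopifnot(is_volume(vol))
  a <- vol$data
  if (any(!is.finite(a))) stop("perona_malik_3d: input contains non-finite values")
  g <- if (params$conduction == "high-contrast")
    function(d) exp(-(d / params$K)^2)
  else
    function(d) 1 / (1 + (d / params$K)^2)
  for (it in seq_len(params$iterations)) {
    upd <- 0
    for (axis in 1:3) {
      dp <- shift_replicate(a, axis, -1L) - a  # forward neighbor difference
      dm <- shift_replicate(a, axis, +1L) - a  # backward neighbor difference
      upd <- upd + g(abs(dp)) * dp + g(abs(dm)) * dm
    }
    a <- a + params$dt * upd
  }
  volume(a, vol$spacing, vol$header)
}

# polynomial basis of total degree <= order on coordinates scaled to [-1,1]
poly_basis_3d <- function(coords, shape, order) {
  sc <- sweep(coords - 1, 2, pmax(shape - 1, 1), "/") * 2 - 1
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1L]] <- sc[, 1]^i * sc[, 2]^j * sc[, 3]^k
  do.call(cbind, cols)
}

# one-dimensional Gaussian mixture EM (shared helper); deterministic
# quantile initialization
fit_gmm_1d <- function(x, k = 3L, max_iter = 50L, tol = 1e-6) {
  qs <- seq(0.1, 0.9, length.out = k)
  mu <- as.numeric(stats::quantile(x, qs, names = FALSE))
  sd0 <- max(stats::sd(x) / k, 1e-6)
  sds <- rep(sd0, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  post <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sds[j]),
                   numeric(length(x)))
    tot <- rowSums(dens) + 1e-300
    ll <- sum(log(tot))
    post <- dens / tot
    nk <- colSums(post)
    alive <- nk > 1e-8
    w <- pmax(nk, 1e-8)
    w <- w / sum(w)
    mu[alive] <- (colSums(post * x) / nk)[alive]
    sds[alive] <- sqrt(pmax(
      (colSums(post * (x - rep(mu, each = length(x)))^2) / nk)[alive], 1e-12))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  post[!is.finite(post)] <- 0
  list(mu = mu, sd = sds, w = w, post = post, loglik = ll)
}

#' Estimate a multiplicative bias field
#'
#' EM alternation in the log domain: a k-class Gaussian mixture models the
#' tissue log-intensities inside the mask while a smooth 3D polynomial of the
#' given order absorbs the residual spatial trend (the log-gain). The
#' exponentiated field is mean-normalized to 1 inside the mask. Non-positive
#' intensities inside the mask are shifted by `1 - min` before the log
#' transform (and the shift undone on exit, it only affects fitting).
#'
#' @param vol `wml_volume`.
#' @param mask non-empty `wml_mask` restricting the fit (e.g. brain mask).
#' @param order total degree of the 3D polynomial log-gain (default 3).
#' @param max_iter maximum EM alternations (default 50).
#' @param tol relative log-likelihood change for convergence (default 1e-4).
#' @param k number of tissue classes in the mixture (default 3).
#' @return object of class `wml_bias_field`: `field` (a `wml_volume` of
#'   positive gains, 1 outside-mask semantics handled by
#'   [apply_bias_correction()]), `mask`, `converged`, `coef`.
#' @export
estimate_bias_field <- function(vol, mask, order = 3L, max_iter = 50L,
                                tol = 1e-4, k = 3L) {
  stopifnot(is_volume(vol), inherits(mask, "wml_mask"))
  assert_coregistered(list(vol, mask))
  idx <- which(mask$data == 1L)
  if (length(idx) == 0L) stop("estimate_bias_field: empty mask")
  v <- vol$data[idx]
  shift <- if (min(v) <= 0) 1 - min(v) else 0
  # mask out low-intensity voxels (CSF and near-background): their log
  # intensities are broad and skewed and would drag the field fit
  low_cut <- 0.33 * stats::quantile(v + shift, 0.95, names = FALSE)
  dark_idx <- idx[v + shift <= low_cut]
  bright <- idx[v + shift > low_cut]
  if (length(bright) >= 1000L) idx <- bright else dark_idx <- integer(0)
  v <- vol$data[idx]
  y <- log(v + shift)
  shape <- dim(vol$data)
  # work set: drop tissue-interface voxels (high local gradient) -- their
  # blended intensities carry a spatially organized signal that a smooth
  # basis would mistake for gain; then a deterministic subsample
  lv <- array(log(pmax(vol$data + shift, 1e-12)), dim = shape)
  gmax <- array(0, dim = shape)
  for (axis in 1:3) {
    gmax <- pmax(gmax, abs(shift_replicate(lv, axis, -1L) - lv),
                 abs(shift_replicate(lv, axis, +1L) - lv))
  }
  flat <- idx[gmax[idx] <= stats::quantile(gmax[idx], 0.75, names = FALSE)]
  if (length(flat) < 1000L) flat <- idx
  sel <- if (length(flat) > 30000L)
    flat[seq(1L, length(flat), length.out = 30000L)] else flat
  # dark (CSF-like) voxels re-enter the regression as one fixed broad class:
  # they anchor the fit at the brain rim against polynomial extrapolation
  # while their low precision keeps them from steering it
  dark_flat <- dark_idx[gmax[dark_idx] <=
                          stats::quantile(gmax[idx], 0.75, names = FALSE)]
  dark_sel <- if (length(dark_flat) > 8000L)
    dark_flat[seq(1L, length(dark_flat), length.out = 8000L)] else dark_flat
  ys <- log(vol$data[sel] + shift)
  B <- poly_basis_3d(arrayInd(sel, shape), shape, order)
  yd <- log(vol$data[dark_sel] + shift)
  Bd <- if (length(dark_sel)) poly_basis_3d(arrayInd(dark_sel, shape), shape,
                                            order) else NULL
  beta <- rep(0, ncol(B))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- ys - drop(B %*% beta)
    gm <- fit_gmm_1d(r, k = k, max_iter = 25L)
    # M-step for the field: precision-weighted least squares over all
    # classes, minimizing sum_ik post_ik (r_i - mu_k - B_i beta)^2 / sd_k^2.
    # The per-class precisions keep broad classes from dominating the fit,
    # and class-ambiguous boundary voxels contribute a near-zero effective
    # residual instead of a biased one.
    wik <- sweep(gm$post, 2, pmax(gm$sd, 1e-3)^2, "/")
    wsum <- rowSums(wik)
    bad <- !is.finite(wsum) | wsum <= 0
    wsum[bad] <- 1e-8
    target <- (r * wsum - drop(wik %*% gm$mu)) / wsum
    target[bad] <- 0
    Bfit <- B; tfit <- target; wfit <- wsum
    if (length(dark_sel) >= 100L) {
      rd <- yd - drop(Bd %*% beta)
      vd <- stats::var(rd)
      if (is.finite(vd)) {
        wd <- rep(1 / max(vd, 1e-4), length(rd))
        Bfit <- rbind(B, Bd)
        tfit <- c(target, rd - mean(rd))
        wfit <- c(wsum, wd)
      }
    }
    beta <- beta + stats::lm.wfit(Bfit, tfit, wfit)$coefficients
    beta[!is.finite(beta)] <- 0
    if (is.finite(ll_old) &&
        abs(gm$loglik - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- gm$loglik
  }
  if (!converged)
    warning("estimate_bias_field: EM did not converge in ", max_iter,
            " iterations; returning best estimate")
  all_idx <- seq_len(prod(shape))
  Bfull <- poly_basis_3d(arrayInd(all_idx, shape), shape, order)
  logf <- drop(Bfull %*% beta)
  field <- array(exp(logf), dim = shape)
  field <- field / mean(field[idx])
  structure(list(field = volume(field, vol$spacing), mask = mask,
                 converged = converged, coef = beta, shift = shift),
            class = "wml_bias_field")
}

#' Divide out a multiplicative bias field
#'
#' Inside the estimation mask the volume is divided by the gain field;
#' voxels outside the mask pass through unchanged.
#'
#' @param vol `wml_volume`.
#' @param bias `wml_bias_field` from [estimate_bias_field()].
#' @return corrected `wml_volume`.
#' @export
apply_bias_correction <- function(vol, bias) {
  stopifnot(is_volume(vol), inherits(bias, "wml_bias_field"))
  assert_coregistered(list(vol, bias$field, bias$mask))
  out <- vol$data
  inside <- bias$mask$data == 1L
  out[inside] <- vol$data[inside] / bias$field$data[inside]
  volume(out, vol$spacing, vol$header)
}

#' Brain mask from tissue probabilities
#'
#' A voxel is brain iff the maximum of its CSF/GM/WM probabilities is at
#' least 0.5; interior cavities (background unreachable from the array
#' border) are then filled, since lesion-induced misclassifications can
#' punch holes into the thresholded map.
#'
#' @param probs `wml_tissue_probs` (see [fit_three_class_em()]).
#' @return `wml_mask`.
#' @export
compute_brain_mask <- function(probs) {
  stopifnot(inherits(probs, "wml_tissue_probs"))
  mx <- pmax(probs$csf, probs$gm, probs$wm)
  m <- array(as.integer(mx >= 0.5), dim = dim(probs$csf))
  filled <- fill_holes_3d(as.integer(m), dim(m))
  binary_mask(array(as.integer(filled), dim = dim(m)), probs$spacing)
}
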