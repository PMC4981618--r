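# Core lesion segmentation: FLAIR hyperintense outliers of the GM intensity
# distribution, refined by size, WM-neighborhood and location rules.
#
# GM is the brightest normal tissue on FLAIR, so focal WM lesions are
# detected as outliers of the GM histogram: threshold = mu + alpha*sigma,
# where mu is the main histogram peak and sigma is derived from its FWHM
# (sigma = FWHM / (2*sqrt(2*ln 2))). Candidates are then filtered:
#   (1) size:        components below 3 mm^3 are removed;
#   (2) neighborhood: the 26-connected 1-voxel shell must be at least a
#                     fraction lambda white matter (over WM+GM+CSF);
#   (3) location:    voxels inside the posterior-fossa exclusion mask are
#                     never candidates (artifact-prone, rare lesion site).

#' Segmentation parameters
#'
#' Defaults are the tuned operating point: threshold multiplier
#' `alpha = 2.5` (placing the threshold above ~99.4% of a Gaussian GM
#' model), neighborhood WM fraction `lambda = 0.70`, and minimum lesion
#' volume 3 mm^3.
#'
#' @param alpha threshold multiplier (> 0).
#' @param lambda minimum WM fraction of the lesion shell, in [0, 1].
#' @param min_volume_mm3 minimum lesion volume in mm^3 (> 0).
#' @export
segmentation_params <- function(alpha = 2.5, lambda = 0.70, min_volume_mm3 = 3) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0,1]")
  if (min_volume_mm3 <= 0) stop("min_volume_mm3 must be > 0")
  structure(list(alpha = alpha, lambda = lambda,
                 min_volume_mm3 = min_volume_mm3),
            class = "wml_segmentation_params")
}

#' Locate the GM peak of the FLAIR histogram
#'
#' Builds a histogram of FLAIR intensities over the GM mask
#' (Freedman-Diaconis bin width, at least 64 bins), smooths it with a 3-bin
#' moving average, takes the global maximum as the main peak, refines the
#' peak location and height by 3-point parabolic interpolation, and measures
#' the FWHM from the outermost half-maximum crossings on each side (linear
#' interpolation between bins). `sigma = fwhm / (2*sqrt(2*ln 2))`.
#'
#' @param flair `wml_volume`.
#' @param gm_mask `wml_mask` of gray-matter voxels (a warning is issued
#'   below 1000 voxels).
#' @param bin_rule only `"fd"` (Freedman-Diaconis) is implemented.
#' @return `wml_gm_peak`: `mu`, `fwhm`, `sigma`, `bin_width`, `n`.
#' @export
estimate_gm_peak <- function(flair, gm_mask, bin_rule = "fd") {
  stopifnot(is_volume(flair), inherits(gm_mask, "wml_mask"))
  assert_coregistered(list(flair, gm_mask))
  bin_rule <- match.arg(bin_rule, "fd")
  x <- flair$data[gm_mask$data == 1L]
  if (length(x) == 0L) stop("estimate_gm_peak: empty GM mask")
  if (any(!is.finite(x))) stop("estimate_gm_peak: non-finite FLAIR values")
  if (length(x) < 1000L)
    warning("estimate_gm_peak: only ", length(x),
            " GM voxels; peak estimate may be unstable")
  n <- length(x)
  iqr <- stats::IQR(x)
  rng <- range(x)
  bw <- 2 * iqr / n^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(rng) / 64
  if (bw <= 0) stop("estimate_gm_peak: degenerate intensity distribution")
  nbins <- max(64L, ceiling(diff(rng) / bw))
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bw <- breaks[2] - breaks[1]
  counts <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                               1L), nbins), nbins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # 3-bin moving average; edges keep a 2-bin partial window
  s <- counts
  if (nbins >= 3L) {
    s <- (counts + c(counts[-1], counts[nbins]) +
            c(counts[1], counts[-nbins])) / 3
    s[1] <- (counts[1] + counts[2]) / 2
    s[nbins] <- (counts[nbins - 1] + counts[nbins]) / 2
  }
  p <- which.max(s)
  if (p == 1L || p == nbins)
    stop("estimate_gm_peak: histogram peak at the edge of the intensity ",
         "range; widen the range or check the GM mask")
  # parabolic refinement of peak position and apex height
  denom <- s[p - 1] - 2 * s[p] + s[p + 1]
  delta <- if (denom < 0) 0.5 * (s[p - 1] - s[p + 1]) / denom else 0
  mu <- centers[p] + delta * bw
  apex <- s[p] - 0.25 * (s[p - 1] - s[p + 1]) * delta
  half <- apex / 2
  # outermost upward crossing left of the peak
  left_below <- which(s[seq_len(p - 1L)] < half)
  if (length(left_below) == 0L)
    stop("estimate_gm_peak: no half-maximum crossing left of the peak ",
         "(edge peak); widen the intensity range")
  i <- min(left_below[s[left_below + 1L] >= half])
  if (!is.finite(i)) i <- max(left_below)
  xl <- centers[i] + (half - s[i]) / (s[i + 1L] - s[i]) * bw
  # outermost downward crossing right of the peak
  right_below <- which(s[seq(p + 1L, nbins)] < half) + p
  if (length(right_below) == 0L)
    stop("estimate_gm_peak: no half-maximum crossing right of the peak ",
         "(edge peak); widen the intensity range")
  j <- max(right_below[s[right_below - 1L] >= half])
  if (!is.finite(j)) j <- min(right_below)
  xr <- centers[j] - (half - s[j]) / (s[j - 1L] - s[j]) * bw
  fwhm <- xr - xl
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("estimate_gm_peak: degenerate FWHM estimate")
  # the half-maximum crossing midpoint is far more stable than the raw mode
  # (bin counts near a Gaussian peak are flat relative to count noise, the
  # crossings sit on the steep flanks); the parabolic vertex only picks the
  # basin and the apex height
  mu <- (xl + xr) / 2
  structure(list(mu = mu, fwhm = fwhm, sigma = fwhm / FWHM_TO_SIGMA,
                 bin_width = bw, n = n),
            class = "wml_gm_peak")
}

#' @export
print.wml_gm_peak <- function(x, ...) {
  cat(sprintf("<wml_gm_peak> mu = %.3f, FWHM = %.3f, sigma = %.3f (n = %d)\n",
              x$mu, x$fwhm, x$sigma, x$n))
  invisible(x)
}

#' Outlier threshold from the GM peak
#'
#' @param peak `wml_gm_peak`.
#' @param alpha threshold multiplier (> 0).
#' @return intensity scalar `mu + alpha * sigma`.
#' @export
compute_threshold <- function(peak, alpha = 2.5) {
  stopifnot(inherits(peak, "wml_gm_peak"))
  if (alpha <= 0) stop("alpha must be > 0")
  peak$mu + alpha * peak$sigma
}

#' Candidate lesion voxels
#'
#' A voxel is a candidate iff its FLAIR intensity is `>= threshold`, it lies
#' inside the brain mask, and (when an exclusion mask is given) outside the
#' posterior-fossa exclusion region. Exclusion is applied here, before
#' component labeling, so excluded hyperintensities never become candidates.
#'
#' @param flair `wml_volume`.
#' @param threshold intensity scalar.
#' @param brain_mask `wml_mask`.
#' @param exclusion optional `wml_mask` (posterior fossa), or NULL.
#' @return candidate `wml_mask`.
#' @export
detect_candidates <- function(flair, threshold, brain_mask, exclusion = NULL) {
  stopifnot(is_volume(flair), inherits(brain_mask, "wml_mask"))
  assert_coregistered(list(flair, brain_mask, exclusion))
  cand <- flair$data >= threshold & brain_mask$data == 1L
  if (!is.null(exclusion)) cand <- cand & exclusion$data == 0L
  binary_mask(array(as.integer(cand), dim = dim(flair$data)), flair$spacing)
}

new_lesions <- function(labels, spacing, connectivity) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(0L, max(labels))
  if (n > 0L) {
    nz <- which(labels > 0L)
    lab <- labels[nz]
    count <- tabulate(lab, n)
    co <- arrayInd(nz, dim(labels))
    cents <- rowsum(co, lab) / count
    comp <- data.frame(id = seq_len(n), n_voxels = count,
                       volume_mm3 = count * prod(spacing),
                       cx = cents[, 1], cy = cents[, 2], cz = cents[, 3],
                       wm_ratio = NA_real_, status = "candidate",
                       stringsAsFactors = FALSE)
  } else {
    comp <- data.frame(id = integer(), n_voxels = integer(),
                       volume_mm3 = numeric(), cx = numeric(), cy = numeric(),
                       cz = numeric(), wm_ratio = numeric(),
                       status = character(), stringsAsFactors = FALSE)
  }
  structure(list(labels = labels, components = comp, spacing = spacing,
                 connectivity = connectivity),
            class = "wml_lesions")
}

#' @export
print.wml_lesions <- function(x, ...) {
  cat(sprintf("<wml_lesions> %d components (%s-connectivity)\n",
              nrow(x$components), x$connectivity))
  if (nrow(x$components)) print(table(x$components$status))
  invisible(x)
}

#' Label connected candidate components
#'
#' @param mask `wml_mask` of candidate voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return `wml_lesions`: integer label array (ids contiguous from 1 in scan
#'   order) and a per-component table with voxel count, volume (mm^3),
#'   centroid, WM shell ratio (NA until computed) and status.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "wml_mask"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  lab <- cc_label_3d(as.integer(mask$data), dim(mask$data),
                     as.integer(connectivity))
  n <- attr(lab, "n_components")
  labels <- array(as.integer(lab), dim = dim(mask$data))
  attr(labels, "n_components") <- n
  new_lesions(labels, mask$spacing, as.integer(connectivity))
}

#' Remove components smaller than the minimum lesion volume
#'
#' Strict less-than: a component of exactly `min_volume_mm3` survives.
#'
#' @param lesions `wml_lesions`.
#' @param min_volume_mm3 minimum volume in mm^3 (default 3).
#' @return `wml_lesions` with `removed_size` statuses set.
#' @export
filter_by_size <- function(lesions, min_volume_mm3 = 3) {
  stopifnot(inherits(lesions, "wml_lesions"))
  small <- lesions$components$volume_mm3 < min_volume_mm3
  lesions$components$status[small & lesions$components$status == "candidate"] <-
    "removed_size"
  lesions
}

#' WM fraction of each component's neighborhood shell
#'
#' The neighborhood is the 26-connected 1-voxel shell (dilation minus the
#' component). The ratio is (#WM shell voxels) / (#WM+GM+CSF shell voxels);
#' background shell voxels are excluded from both counts; an empty
#' denominator yields 0.
#'
#' @param lesions `wml_lesions`.
#' @param tissue `wml_tissue_labels` on the same grid.
#' @return `wml_lesions` with the `wm_ratio` column filled for every
#'   component.
#' @export
neighborhood_wm_ratio <- function(lesions, tissue) {
  stopifnot(inherits(lesions, "wml_lesions"),
            inherits(tissue, "wml_tissue_labels"))
  if (!identical(dim(lesions$labels), dim(tissue$labels)))
    stop("lesion labels and tissue labels are on different grids")
  n <- nrow(lesions$components)
  if (n > 0L) {
    lesions$components$wm_ratio <-
      shell_wm_ratio_3d(as.integer(lesions$labels),
                        as.integer(tissue$labels),
                        dim(lesions$labels), n)
  }
  lesions
}

#' Remove components with insufficient WM neighborhood
#'
#' Surviving candidates whose shell WM ratio is `< lambda` become
#' `removed_neighborhood`; a ratio of exactly `lambda` survives. Ratios are
#' computed (and stored) for every component.
#'
#' @param lesions `wml_lesions`.
#' @param tissue `wml_tissue_labels`.
#' @param lambda minimum WM fraction (default 0.70).
#' @return `wml_lesions` with statuses updated.
#' @export
filter_by_neighborhood <- function(lesions, tissue, lambda = 0.70) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (any(is.na(lesions$components$wm_ratio)))
    lesions <- neighborhood_wm_ratio(lesions, tissue)
  bad <- lesions$components$wm_ratio < lambda
  lesions$components$status[bad & lesions$components$status == "candidate"] <-
    "removed_neighborhood"
  lesions
}

lesions_mask <- function(lesions, statuses = "kept") {
  ids <- lesions$components$id[lesions$components$status %in% statuses]
  keep <- array(as.integer(lesions$labels %in% ids), dim = dim(lesions$labels))
  binary_mask(keep, lesions$spacing)
}

#' Precompute the parameter-independent pipeline stages
#'
#' Runs every stage that does not depend on (alpha, lambda, min volume):
#' diffusion and bias correction of the FLAIR, tissue EM on the T1, brain
#' mask, and the GM peak estimate. [segment_lesions()] and [grid_search()]
#' reuse one context across many parameter settings.
#'
#' @param t1,flair co-registered `wml_volume`s.
#' @param exclusion optional posterior-fossa `wml_mask` or NULL.
#' @param diffusion [diffusion_params()].
#' @param seed integer seed for the tissue EM.
#' @param tissue_probs optional externally produced `wml_tissue_probs`
#'   (bypasses the EM), e.g. from [tissue_probs_from_maps()].
#' @param skip_diffusion,skip_bias logical switches for the two FLAIR
#'   enhancement stages.
#' @param bias_order polynomial order of the bias-field model.
#' @return `wml_seg_context`.
#' @export
segmentation_context <- function(t1, flair, exclusion = NULL,
                                 diffusion = diffusion_params(), seed = 1L,
                                 tissue_probs = NULL, skip_diffusion = FALSE,
                                 skip_bias = FALSE, bias_order = 3L) {
  stage <- "assert_coregistered"
  res <- tryCatch({
    assert_coregistered(list(t1, flair, exclusion))
    stage <- "perona_malik_3d"
    fl <- if (skip_diffusion) flair else perona_malik_3d(flair, diffusion)
    stage <- "fit_three_class_em"
    if (is.null(tissue_probs)) {
      head_thr <- 0.05 * stats::quantile(t1$data, 0.99, names = FALSE)
      head <- binary_mask(array(as.integer(t1$data > head_thr),
                                dim = dim(t1$data)), t1$spacing)
      tissue_probs <- fit_three_class_em(t1, head, seed = seed)
    }
    stage <- "compute_brain_mask"
    brain <- compute_brain_mask(tissue_probs)
    stage <- "estimate_bias_field"
    if (!skip_bias) {
      bias <- estimate_bias_field(fl, brain, order = bias_order)
      fl <- apply_bias_correction(fl, bias)
    }
    stage <- "max_probability_labels"
    tissue <- max_probability_labels(tissue_probs)
    stage <- "estimate_gm_peak"
    gm_mask <- tissue_labels_as_mask(tissue, 2L)
    peak <- estimate_gm_peak(fl, gm_mask)
    list(flair_corr = fl, brain_mask = brain, tissue = tissue,
         gm_peak = peak, exclusion = exclusion, spacing = flair$spacing,
         seed = seed)
  }, error = function(e) {
    stop("segmentation failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  structure(res, class = "wml_seg_context")
}

apply_segmentation <- function(ctx, params) {
  thr <- compute_threshold(ctx$gm_peak, params$alpha)
  cand <- detect_candidates(ctx$flair_corr, thr, ctx$brain_mask, ctx$exclusion)
  lesions <- label_components(cand, 26L)
  n_candidates <- nrow(lesions$components)
  lesions <- filter_by_size(lesions, params$min_volume_mm3)
  lesions <- filter_by_neighborhood(lesions, ctx$tissue, params$lambda)
  keep <- lesions$components$status == "candidate"
  lesions$components$status[keep] <- "kept"
  mask <- lesions_mask(lesions)
  report <- list(
    mu = ctx$gm_peak$mu, sigma = ctx$gm_peak$sigma, fwhm = ctx$gm_peak$fwhm,
    threshold = thr, alpha = params$alpha, lambda = params$lambda,
    min_volume_mm3 = params$min_volume_mm3, seed = ctx$seed,
    n_candidates = n_candidates,
    n_removed_size = sum(lesions$components$status == "removed_size"),
    n_removed_neighborhood =
      sum(lesions$components$status == "removed_neighborhood"),
    n_kept = sum(lesions$components$status == "kept"))
  list(mask = mask, lesions = lesions, report = report)
}

#' Full lesion segmentation pipeline
#'
#' Diffusion -> bias correction (FLAIR), tissue EM (T1) -> brain mask -> GM
#' peak -> threshold -> candidates (with posterior-fossa exclusion) ->
#' connected components -> size filter -> neighborhood filter. The final
#' mask is the union of the kept components.
#'
#' @inheritParams segmentation_context
#' @param params [segmentation_params()].
#' @param ... further arguments passed to [segmentation_context()].
#' @return list: `mask` (kept-lesion `wml_mask`), `lesions` (`wml_lesions`
#'   with per-component records), `report` (mu/sigma/threshold, stage
#'   counts, parameters, seed), `context`.
#' @export
segment_lesions <- function(t1, flair, exclusion = NULL,
                            params = segmentation_params(), seed = 1L, ...) {
  stopifnot(inherits(params, "wml_segmentation_params"))
  ctx <- segmentation_context(t1, flair, exclusion, seed = seed, ...)
  out <- apply_segmentation(ctx, params)
  out$context <- ctx
  out
}
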