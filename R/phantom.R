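# Synthetic co-registered T1w/FLAIR brain phantoms with ground truth.
#
# Geometry is three nested ellipsoids (WM core, GM ribbon, CSF rim) centered
# in the grid -- not anatomy, but enough structure to exercise every rule of
# the pipeline: focal hyperintense lesions embedded in WM (including
# juxtacortical ones that reproduce the method's false-negative regime),
# hyperintense non-lesion "artifacts" (deep-WM low-contrast, GM-border and
# posterior-fossa distractors emulating scanner artifacts), a smooth
# multiplicative bias field, Gaussian noise, and an inferior-slab
# "posterior fossa" label.
#
# Default contrasts: T1 CSF/GM/WM = 30/80/130 (sd 5), FLAIR CSF/GM/WM =
# 20/100/70 (sd 5) so GM is the brightest normal FLAIR tissue; lesions are
# set to GM mean + offset * GM sd. All tissue mean gaps are >= 6 sd
# (asserted at generation), the separability the tissue model assumes.

RHO_WM <- 0.75  # normalized radius of the WM core
RHO_GM <- 0.88  # outer edge of the GM ribbon

#' Phantom specification
#'
#' @param shape grid size, each axis >= 32 (default 64^3).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param t1_means,t1_sds CSF/GM/WM means and sds on T1 (CSF < GM < WM).
#' @param flair_means,flair_sds CSF/GM/WM means and sds on FLAIR (GM is the
#'   brightest normal tissue).
#' @param lesions list of lesion descriptors: `list(n_voxels =, offset =,
#'   sd = NULL, placement = "deep"|"juxtacortical", center = NULL)`.
#'   `offset` is the FLAIR intensity above the GM mean in GM-sd units;
#'   `center` (voxel coordinates) may be given explicitly and must lie in
#'   WM.
#' @param artifacts list of non-lesion hyperintensity descriptors with the
#'   same fields but `placement` in `"wm"`, `"gm_border"`, `"pf"`; these are
#'   recorded separately and never enter the ground truth.
#' @param bias_amplitude peak multiplicative deviation of the bias field
#'   (default 0, maximum 0.3).
#' @param noise_sd extra additive Gaussian noise applied to both volumes
#'   (default 0; the per-tissue sds already model acquisition noise).
#' @param pf_fraction fraction of the inferior brain slab labeled posterior
#'   fossa (default 0.2).
#' @param seed integer RNG seed.
#' @return `wml_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         t1_means = c(csf = 30, gm = 80, wm = 130),
                         t1_sds = c(5, 5, 5),
                         flair_means = c(csf = 20, gm = 100, wm = 70),
                         flair_sds = c(5, 5, 5),
                         lesions = list(), artifacts = list(),
                         bias_amplitude = 0, noise_sd = 0,
                         pf_fraction = 0.2, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom shape must be 3D with each axis >= 32")
  if (bias_amplitude < 0 || bias_amplitude > 0.3)
    stop("bias_amplitude must be in [0, 0.3]")
  if (pf_fraction < 0 || pf_fraction > 0.5)
    stop("pf_fraction must be in [0, 0.5]")
  # separability contract: mean gaps >= 6 sd in both modalities
  check_sep <- function(means, sds, what) {
    gaps <- diff(sort(means))
    if (any(gaps < 6 * max(sds)))
      stop("phantom ", what, " contrasts violate the separability contract ",
           "(mean gap < 6 sd)")
  }
  check_sep(t1_means, t1_sds, "T1")
  check_sep(flair_means, flair_sds, "FLAIR")
  for (les in lesions)
    if (!is.null(les$offset) && les$offset <= 0)
      stop("lesion FLAIR offset must be positive")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 t1_means = t1_means, t1_sds = t1_sds,
                 flair_means = flair_means, flair_sds = flair_sds,
                 lesions = lesions, artifacts = artifacts,
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 pf_fraction = pf_fraction, seed = as.integer(seed)),
            class = "wml_phantom_spec")
}

blob_radius <- function(n_voxels) (3 * n_voxels / (4 * pi))^(1 / 3)

# k nearest pool voxels to a center (deterministic tie-break by index)
blob_voxels <- function(center, pool_idx, coords, k) {
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
    (coords[, 3] - center[3])^2
  pool_idx[order(d2, pool_idx)[seq_len(k)]]
}

#' Generate one phantom case
#'
#' Deterministic given the spec seed. Lesion blobs are the `n_voxels`
#' nearest white-matter voxels to the chosen center, so inserted voxel
#' counts are exact and every lesion is contained in WM; `juxtacortical`
#' lesions are centered so they touch the GM ribbon. Artifacts use the same
#' construction on their own voxel pools.
#'
#' @param spec `wml_phantom_spec`.
#' @return `wml_phantom`: `t1`, `flair` (`wml_volume`), `tissue_gt`
#'   (`wml_tissue_labels`), `lesion_gt` (`wml_lesions`), `pf_mask`
#'   (`wml_mask`), `artifacts` (data frame), `spec`, `seed`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "wml_phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  ctr <- (shape + 1) / 2
  R <- shape / 2 - 2
  xs <- (seq_len(shape[1]) - ctr[1]) / R[1]
  ys <- (seq_len(shape[2]) - ctr[2]) / R[2]
  zs <- (seq_len(shape[3]) - ctr[3]) / R[3]
  rho <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  tissue <- array(0L, dim = shape)
  tissue[rho <= 1] <- 1L            # CSF rim
  tissue[rho <= RHO_GM] <- 2L       # GM ribbon
  tissue[rho <= RHO_WM] <- 3L       # WM core
  # posterior fossa: inferior slab of the brain
  brain <- tissue > 0L
  zidx <- which(apply(brain, 3, any))
  pf_zmax <- min(zidx) + floor(spec$pf_fraction * (max(zidx) - min(zidx)))
  pf <- brain
  pf[, , setdiff(seq_len(shape[3]), seq_len(pf_zmax))] <- FALSE
  # intensities
  draw <- function(means, sds) {
    a <- array(0, dim = shape)
    for (k in 1:3) {
      idx <- which(tissue == k)
      a[idx] <- stats::rnorm(length(idx), means[k], sds[k])
    }
    a
  }
  t1 <- draw(spec$t1_means, spec$t1_sds)
  flair <- draw(spec$flair_means, spec$flair_sds)
  gm_mu <- spec$flair_means[2]
  gm_sd <- spec$flair_sds[2]
  # voxel pools and geometry helpers for blob placement
  all_idx <- seq_len(prod(shape))
  wm_idx <- which(tissue == 3L)
  wm_coords <- arrayInd(wm_idx, shape)
  wmgm_idx <- which(tissue >= 2L)
  wmgm_coords <- arrayInd(wmgm_idx, shape)
  pf_wm_idx <- wm_idx[pf[wm_idx]]
  Rmin <- min(R)
  depth_vox <- (RHO_WM - rho) * Rmin  # approx. distance to the WM/GM border
  placed <- list()  # centers and radii already used, for separation
  pick_center <- function(pool, r, sep_extra = 3) {
    pool <- pool[sample.int(length(pool))]
    for (cand in utils::head(pool, 400L)) {
      co <- arrayInd(cand, shape)[1, ]
      ok <- TRUE
      for (p in placed) {
        if (sqrt(sum((co - p$center)^2)) < r + p$r + sep_extra) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(co)
    }
    NULL
  }
  # WM fraction of a blob's 26-shell against the ground-truth tissue labels
  gt_shell_ratio <- function(vox) {
    co <- arrayInd(vox, shape)
    nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    nb <- nb[rowSums(abs(nb)) > 0, ]
    shell <- integer(0)
    for (q in seq_len(nrow(nb))) {
      cc <- sweep(co, 2, as.numeric(nb[q, ]), "+")
      keep <- cc[, 1] >= 1 & cc[, 1] <= shape[1] & cc[, 2] >= 1 &
        cc[, 2] <= shape[2] & cc[, 3] >= 1 & cc[, 3] <= shape[3]
      cc <- cc[keep, , drop = FALSE]
      shell <- c(shell, cc[, 1] + shape[1] * ((cc[, 2] - 1) +
                                                shape[2] * (cc[, 3] - 1)))
    }
    shell <- setdiff(unique(shell), vox)
    t <- tissue[shell]
    denom <- sum(t >= 1L & t <= 3L)
    if (denom == 0) 0 else sum(t == 3L) / denom
  }
  resolve_blob <- function(b, what, i) {
    k <- b$n_voxels
    if (is.null(k) || k < 1L) stop(what, " ", i, ": n_voxels must be >= 1")
    r <- blob_radius(k)
    placement <- if (is.null(b$placement)) "deep" else b$placement
    pool_idx <- wm_idx
    pool_coords <- wm_coords
    away_from_pf <- !pf[wm_idx] & wm_coords[, 3] > pf_zmax + r + 2
    make_vox <- function(center) {
      if (placement == "gm_border") blob_voxels(center, wmgm_idx, wmgm_coords, k)
      else if (placement == "pf") {
        pool <- all_idx[pf & tissue == 3L]
        blob_voxels(center, pool, arrayInd(pool, shape), k)
      } else blob_voxels(center, wm_idx, wm_coords, k)
    }
    if (!is.null(b$center)) {
      center <- as.numeric(b$center)
      ci <- round(center)
      if (placement != "pf" && tissue[ci[1], ci[2], ci[3]] != 3L)
        stop(what, " ", i, " at (", paste(ci, collapse = ","),
             ") is outside the white matter")
      vox <- make_vox(center)
    } else if (placement %in% c("deep", "wm", "pf")) {
      pool <- if (placement == "pf") {
        p <- pf_wm_idx[depth_vox[pf_wm_idx] >= r]
        if (length(p) < 10L) pf_wm_idx else p  # small grids: any pf WM voxel
      } else wm_idx[depth_vox[wm_idx] >= r + 1 & away_from_pf]
      # progressively relax the inter-blob separation on crowded grids
      center <- NULL
      for (sep in c(3, 2, 1, 0)) {
        center <- pick_center(pool, r, sep_extra = sep)
        if (!is.null(center)) break
      }
      if (is.null(center))
        stop(what, " ", i, ": could not place a ", k,
             "-voxel blob (placement '", placement, "'); phantom too crowded")
      vox <- make_vox(center)
    } else if (placement %in% c("juxtacortical", "gm_border")) {
      # rejection sampling on the realized shell WM ratio: "juxtacortical"
      # lesions touch the ribbon but keep a mostly-WM shell, "gm_border"
      # distractors straddle it with a mixed shell
      band <- if (!is.null(b$ratio_band)) b$ratio_band
              else if (placement == "juxtacortical") c(0.75, 0.90)
              else c(0.55, 0.68)
      best <- NULL
      for (try in 1:60) {
        depth <- if (!is.null(b$depth)) b$depth
                 else if (placement == "juxtacortical")
                   r - stats::runif(1, 0, 0.5)
                 else stats::runif(1, 0.1, 0.5) * r
        pool <- wm_idx[abs(depth_vox[wm_idx] - max(depth, 0.2)) < 0.6 &
                         away_from_pf]
        cand <- pick_center(pool, r,
                            sep_extra = if (try <= 30) 3 else if (try <= 45) 2
                                        else 1)
        if (is.null(cand)) next
        vx <- make_vox(cand)
        ratio <- gt_shell_ratio(vx)
        miss <- max(band[1] - ratio, ratio - band[2], 0)
        if (is.null(best) || miss < best$miss)
          best <- list(center = cand, vox = vx, miss = miss)
        if (miss == 0) break
      }
      if (is.null(best))
        stop(what, " ", i, ": could not place a ", k,
             "-voxel blob (placement '", placement, "'); phantom too crowded")
      center <- best$center
      vox <- best$vox
    } else stop(what, " ", i, ": unknown placement '", placement, "'")
    placed[[length(placed) + 1L]] <<- list(center = center, r = r)
    sd_les <- if (is.null(b$sd)) gm_sd else b$sd
    offset <- if (is.null(b$offset)) 6 else b$offset
    list(vox = vox, center = center, k = k, offset = offset, sd = sd_les,
         placement = placement)
  }
  lesion_labels <- array(0L, dim = shape)
  les_records <- list()
  for (i in seq_along(spec$lesions)) {
    pl <- spec$lesions[[i]]$placement
    if (!is.null(pl) && !pl %in% c("deep", "juxtacortical"))
      stop("lesion ", i, ": placement must be 'deep' or 'juxtacortical' ",
           "(ground-truth lesions live in WM)")
    b <- resolve_blob(spec$lesions[[i]], "lesion", i)
    flair[b$vox] <- stats::rnorm(b$k, gm_mu + b$offset * gm_sd, b$sd)
    lesion_labels[b$vox] <- i
    les_records[[i]] <- b
  }
  art_records <- list()
  for (i in seq_along(spec$artifacts)) {
    b <- resolve_blob(spec$artifacts[[i]], "artifact", i)
    flair[b$vox] <- stats::rnorm(b$k, gm_mu + b$offset * gm_sd, b$sd)
    art_records[[i]] <- b
  }
  if (spec$noise_sd > 0) {
    t1 <- t1 + array(stats::rnorm(prod(shape), 0, spec$noise_sd), dim = shape)
    flair <- flair + array(stats::rnorm(prod(shape), 0, spec$noise_sd),
                           dim = shape)
  }
  if (spec$bias_amplitude > 0) {
    xn <- array(rep(xs, times = shape[2] * shape[3]), dim = shape)
    yn <- array(rep(rep(ys, each = shape[1]), times = shape[3]), dim = shape)
    field <- 1 + spec$bias_amplitude * (0.7 * xn + 0.3 * (yn^2 - 0.5))
    t1 <- t1 * field
    flair <- flair * field
  }
  attr(lesion_labels, "n_components") <- length(les_records)
  lesion_gt <- new_lesions(lesion_labels, spec$spacing, 26L)
  art_df <- if (length(art_records)) data.frame(
    id = seq_along(art_records),
    n_voxels = vapply(art_records, function(a) as.integer(a$k), integer(1)),
    offset = vapply(art_records, `[[`, numeric(1), "offset"),
    placement = vapply(art_records, `[[`, character(1), "placement"),
    stringsAsFactors = FALSE) else
    data.frame(id = integer(), n_voxels = integer(), offset = numeric(),
               placement = character(), stringsAsFactors = FALSE)
  structure(list(
    t1 = volume(t1, spec$spacing),
    flair = volume(flair, spec$spacing),
    tissue_gt = structure(list(labels = tissue, spacing = spec$spacing),
                          class = "wml_tissue_labels"),
    lesion_gt = lesion_gt,
    pf_mask = binary_mask(array(as.integer(pf), dim = shape), spec$spacing),
    artifacts = art_df,
    artifact_voxels = lapply(art_records, `[[`, "vox"),
    spec = spec, seed = spec$seed),
    class = "wml_phantom")
}

#' @export
print.wml_phantom <- function(x, ...) {
  cat(sprintf("<wml_phantom> %s, %d lesions, %d artifacts, seed %d\n",
              paste(x$spec$shape, collapse = "x"),
              nrow(x$lesion_gt$components), nrow(x$artifacts), x$seed))
  invisible(x)
}

# randomized lesion/artifact composition for one suite case
suite_case_spec <- function(n_lesions, shape, spacing, case_seed,
                            with_artifacts = TRUE) {
  set.seed(case_seed)
  lesions <- list()
  # at least one juxtacortical lesion per case: shell WM ratio typically in
  # [0.70, 0.90], so overly strict lambda settings start losing true lesions
  n_jux <- max(1L, min(if (n_lesions >= 6L) sample(1:2, 1) else 1L,
                       n_lesions))
  for (i in seq_len(n_jux))
    lesions[[length(lesions) + 1L]] <-
      list(n_voxels = sample(5:9, 1), offset = 6, placement = "juxtacortical")
  # one faint lesion per case: fully detected near the default threshold but
  # progressively clipped (and eventually size-filtered) as alpha grows,
  # giving the sweep its high-alpha penalty
  if (length(lesions) < n_lesions)
    lesions[[length(lesions) + 1L]] <-
      list(n_voxels = sample(5:8, 1), offset = stats::runif(1, 3.75, 4.0),
           sd = 0.5, placement = "deep")
  while (length(lesions) < n_lesions)
    lesions[[length(lesions) + 1L]] <-
      list(n_voxels = sample(4:15, 1), offset = stats::runif(1, 5, 8),
           placement = "deep")
  artifacts <- list()
  if (with_artifacts) {
    # low-contrast deep-WM distractors, large enough that diffusion keeps
    # their interior: below the default threshold, but false positives (with
    # an all-WM shell no lambda can reject) once alpha drops toward 2
    for (i in 1:3)
      artifacts[[length(artifacts) + 1L]] <-
        list(n_voxels = sample(15:25, 1), offset = stats::runif(1, 1.0, 1.3),
             sd = 1, placement = "wm")
    # bright GM-border distractors (shell WM ratio ~0.55-0.68): only the
    # neighborhood rule removes them
    for (i in 1:2)
      artifacts[[length(artifacts) + 1L]] <-
        list(n_voxels = sample(8:15, 1), offset = 6, placement = "gm_border")
    # bright posterior-fossa distractor: only the location rule removes it
    artifacts[[length(artifacts) + 1L]] <-
      list(n_voxels = sample(10:15, 1), offset = 6, placement = "pf")
  }
  phantom_spec(shape = shape, spacing = spacing, lesions = lesions,
               artifacts = artifacts, seed = case_seed)
}

#' Generate a suite of phantoms stratified by lesion burden
#'
#' Case lesion counts are drawn to hit the requested burden groups
#' (group 1: < 5 lesions, group 2: 5-25, group 3: > 25). Each case carries
#' the default distractor set (two low-contrast deep-WM, two bright
#' GM-border, one posterior-fossa artifact) so that the alpha, lambda and
#' location rules all have work to do; case seeds derive from the master
#' seed.
#'
#' @param n_cases number of cases (>= 1).
#' @param burden_mix integer vector of length 3, cases per burden group;
#'   must sum to `n_cases`.
#' @param shape,spacing grid geometry passed to every case.
#' @param seed master seed.
#' @param with_artifacts include the distractor set (default TRUE).
#' @return list of `wml_phantom`.
#' @export
generate_suite <- function(n_cases = 8L, burden_mix = c(3L, 3L, 2L),
                           shape = c(64, 64, 64), spacing = c(1, 1, 1),
                           seed = 1L, with_artifacts = TRUE) {
  if (n_cases < 1L) stop("n_cases must be >= 1")
  burden_mix <- as.integer(burden_mix)
  if (length(burden_mix) != 3L || any(burden_mix < 0L))
    stop("burden_mix must be 3 nonnegative counts")
  if (sum(burden_mix) != n_cases)
    stop("burden_mix must sum to n_cases")
  groups <- rep(1:3, times = burden_mix)
  base <- abs(seed) %% 1000000L
  lapply(seq_len(n_cases), function(i) {
    case_seed <- base + 7919L * i
    set.seed(case_seed)
    n_les <- switch(groups[i],
                    sample(2:4, 1), sample(6:12, 1), sample(26:30, 1))
    generate_phantom(suite_case_spec(n_les, shape, spacing, case_seed,
                                     with_artifacts))
  })
}
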