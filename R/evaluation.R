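# Evaluation metrics and the cross-validated alpha/lambda grid search.
#
# Voxel-wise accuracy is the Dice similarity coefficient; detection is
# lesion-wise with a >=1-voxel overlap rule (many-to-many, no one-to-one
# matching constraint); the combined score is
#   F = 3 * DSC * TPR * PPV / (DSC + TPR + PPV)
# which is implemented exactly as printed in its source (the true three-way
# harmonic mean 3abc/(ab+bc+ca) is available behind `variant`).

as_mask_array <- function(x) {
  if (inherits(x, "wml_lesions")) return(array(as.integer(x$labels > 0L),
                                               dim = dim(x$labels)))
  if (inherits(x, "wml_volume")) return(array(as.integer(x$data != 0),
                                              dim = dim(x$data)))
  if (is.array(x)) return(array(as.integer(x != 0), dim = dim(x)))
  stop("expected a mask, volume, lesion object or array")
}

lesion_labels_array <- function(x, kept_only = FALSE) {
  if (inherits(x, "wml_lesions")) {
    lab <- x$labels
    if (kept_only && nrow(x$components) &&
        any(x$components$status != "candidate")) {
      ids <- x$components$id[x$components$status == "kept"]
      lab <- array(ifelse(lab %in% ids, lab, 0L), dim = dim(lab))
    }
    return(lab)
  }
  if (inherits(x, "wml_volume")) return(array(as.integer(x$data), dim = dim(x$data)))
  if (is.array(x)) return(array(as.integer(x), dim = dim(x)))
  stop("expected labeled lesions")
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks agree perfectly (DSC = 1).
#'
#' @param a,b binary masks (`wml_mask`, `wml_lesions` or 0/1 arrays) on one
#'   grid.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  A <- as_mask_array(a)
  B <- as_mask_array(b)
  if (!identical(dim(A), dim(B)))
    stop("dice: masks on different grids (", paste(dim(A), collapse = "x"),
         " vs ", paste(dim(B), collapse = "x"), ")")
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Lesion-wise detection counts
#'
#' A ground-truth component counts as detected (TP) iff at least one of its
#' voxels overlaps any automatic component; an automatic component is a FP
#' iff it overlaps no ground-truth component. Overlap is many-to-many: one
#' automatic blob covering two GT lesions detects both.
#'
#' @param auto automatic segmentation (`wml_lesions`; if statuses are set,
#'   only `kept` components count) or a label array.
#' @param gt ground-truth `wml_lesions` or label array.
#' @return `wml_detection`: `tp`, `fp`, `fn`, `tpr`, `ppv`, `ppv_defined`
#'   (FALSE when there are no automatic lesions; `ppv` is then reported
#'   as 0), `n_auto`, `n_gt`.
#' @export
match_lesions <- function(auto, gt) {
  La <- lesion_labels_array(auto, kept_only = TRUE)
  Lg <- lesion_labels_array(gt)
  if (!identical(dim(La), dim(Lg)))
    stop("match_lesions: label maps on different grids")
  n_auto <- if (any(La > 0L)) length(unique(La[La > 0L])) else 0L
  n_gt <- if (any(Lg > 0L)) length(unique(Lg[Lg > 0L])) else 0L
  both <- La > 0L & Lg > 0L
  tp <- length(unique(Lg[both]))
  fn <- n_gt - tp
  fp <- n_auto - length(unique(La[both]))
  tpr <- if (n_gt > 0L) tp / n_gt else 1
  ppv_defined <- n_auto > 0L
  ppv <- if (ppv_defined) (n_auto - fp) / n_auto else 0
  structure(list(tp = tp, fp = fp, fn = fn, tpr = tpr, ppv = ppv,
                 ppv_defined = ppv_defined, n_auto = n_auto, n_gt = n_gt),
            class = "wml_detection")
}

#' False-negative lesion-volume fraction
#'
#' Total volume of the undetected ground-truth components divided by the
#' total ground-truth lesion volume; 0 when there are no GT lesions.
#'
#' @param auto automatic mask (any mask-like object).
#' @param gt ground-truth `wml_lesions`.
#' @return scalar in [0, 1].
#' @export
fn_volume_rate <- function(auto, gt) {
  stopifnot(inherits(gt, "wml_lesions"))
  A <- as_mask_array(auto)
  Lg <- gt$labels
  if (!identical(dim(A), dim(Lg)))
    stop("fn_volume_rate: masks on different grids")
  if (nrow(gt$components) == 0L) return(0)
  detected <- unique(Lg[Lg > 0L & A > 0L])
  vols <- gt$components$volume_mm3
  sum(vols[!gt$components$id %in% detected]) / sum(vols)
}

#' Combined detection/segmentation score
#'
#' `variant = "as-printed"` (default) evaluates
#' `3*DSC*TPR*PPV/(DSC+TPR+PPV)`; `variant = "harmonic"` evaluates the true
#' three-way harmonic mean `3*DSC*TPR*PPV/(DSC*TPR+TPR*PPV+DSC*PPV)`. All
#' inputs zero yields 0 by convention.
#'
#' @param dsc,tpr,ppv scalars in [0, 1].
#' @param variant `"as-printed"` or `"harmonic"`.
#' @return scalar in [0, 1].
#' @export
f_score <- function(dsc, tpr, ppv, variant = c("as-printed", "harmonic")) {
  variant <- match.arg(variant)
  vals <- c(dsc, tpr, ppv)
  if (any(vals < 0 | vals > 1)) stop("f_score inputs must be in [0,1]")
  if (all(vals == 0)) return(0)
  if (variant == "as-printed") 3 * dsc * tpr * ppv / (dsc + tpr + ppv)
  else {
    den <- dsc * tpr + tpr * ppv + dsc * ppv
    if (den == 0) 0 else 3 * dsc * tpr * ppv / den
  }
}

#' Lesion-burden group
#'
#' Group 1: fewer than 5 lesions; group 2: 5 to 25; group 3: more than 25.
#'
#' @param gt_lesion_count nonnegative integer.
#' @return 1, 2 or 3.
#' @export
stratify_burden <- function(gt_lesion_count) {
  if (gt_lesion_count < 0) stop("lesion count must be nonnegative")
  if (gt_lesion_count < 5) 1L else if (gt_lesion_count <= 25) 2L else 3L
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), computed
#' directly from the rank vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho: length mismatch")
  if (length(x) < 3L) stop("spearman_rho: need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("spearman_rho: undefined for a constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

#' Bland-Altman agreement of lesion volumes
#'
#' Differences are `d = gt - auto`, so a positive mean difference indicates
#' undersegmentation. Limits of agreement are `mean(d) +/- 1.96 sd(d)`.
#'
#' @param auto_vols,gt_vols per-case total lesion volumes (mm^3), equal
#'   length >= 2.
#' @return list: `mean_diff`, `sd_diff`, `loa` (lower, upper).
#' @export
bland_altman <- function(auto_vols, gt_vols) {
  if (length(auto_vols) != length(gt_vols))
    stop("bland_altman: length mismatch")
  if (length(auto_vols) < 2L) stop("bland_altman: need at least 2 cases")
  d <- gt_vols - auto_vols
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa = c(m - 1.96 * s, m + 1.96 * s))
}

#' Per-case evaluation report
#'
#' @param auto result of [segment_lesions()] (or a kept-lesion mask plus
#'   `wml_lesions`).
#' @param gt ground-truth `wml_lesions`.
#' @param variant F-score variant, see [f_score()].
#' @return `wml_eval_report`: `dsc`, `detection`, `fnr_volume`, `f_score`,
#'   `burden_group`, `volume_auto_mm3`, `volume_gt_mm3`, `n_auto`, `n_gt`.
#' @export
evaluate_case <- function(auto, gt, variant = "as-printed") {
  stopifnot(inherits(gt, "wml_lesions"))
  lesions <- if (is.list(auto) && !is.null(auto$lesions)) auto$lesions else auto
  mask <- if (is.list(auto) && !is.null(auto$mask)) auto$mask
          else lesions_mask(lesions)
  d <- dice(mask, gt)
  det <- match_lesions(lesions, gt)
  fnr <- fn_volume_rate(mask, gt)
  f <- f_score(d, det$tpr, det$ppv, variant)
  vox <- prod(gt$spacing)
  structure(list(dsc = d, detection = det, fnr_volume = fnr, f_score = f,
                 burden_group = stratify_burden(det$n_gt),
                 volume_auto_mm3 = sum(as_mask_array(mask)) * vox,
                 volume_gt_mm3 = sum(gt$components$volume_mm3),
                 n_auto = det$n_auto, n_gt = det$n_gt),
            class = "wml_eval_report")
}

# per-component statistics of one candidate labeling against ground truth;
# everything the lambda sweep needs, so lambda costs nothing to vary
component_sweep_stats <- function(cand_mask, ctx, gt_labels, min_volume_mm3) {
  lesions <- label_components(cand_mask, 26L)
  lesions <- neighborhood_wm_ratio(lesions, ctx$tissue)
  comp <- lesions$components
  n <- nrow(comp)
  gt_vox <- sum(gt_labels > 0L)
  if (n > 0L) {
    La <- lesions$labels
    both <- La > 0L & gt_labels > 0L
    overlap <- tabulate(La[both], n)
    pairs <- unique(cbind(La[both], gt_labels[both]))
    comp$gt_overlap <- overlap
    size_ok <- comp$volume_mm3 >= min_volume_mm3
  } else {
    pairs <- cbind(integer(), integer())
    comp$gt_overlap <- integer(0)
    size_ok <- logical(0)
  }
  list(comp = comp, pairs = pairs, size_ok = size_ok, gt_vox = gt_vox)
}

score_at_lambda <- function(st, lambda, n_gt, variant) {
  keep <- st$size_ok & st$comp$wm_ratio >= lambda
  kept_ids <- st$comp$id[keep]
  inter <- sum(st$comp$gt_overlap[keep])
  auto_vox <- sum(st$comp$n_voxels[keep])
  d <- if (auto_vox + st$gt_vox == 0) 1
       else 2 * inter / (auto_vox + st$gt_vox)
  tp <- length(unique(st$pairs[st$pairs[, 1] %in% kept_ids, 2]))
  fp <- sum(keep & st$comp$gt_overlap == 0L)
  n_auto <- length(kept_ids)
  tpr <- if (n_gt > 0L) tp / n_gt else 1
  ppv <- if (n_auto > 0L) (n_auto - fp) / n_auto else 0
  f_score(d, tpr, ppv, variant)
}

#' Two-fold cross-validated alpha/lambda grid search
#'
#' Cases are split at random into two halves; for each fold's training half
#' every case is segmented at every (alpha, lambda) pair and the mean
#' F-score selects the best pair (ties break toward the smallest alpha,
#' then the smallest lambda). The default grids are alpha 1.0 to 3.0 by 0.1
#' and lambda 0 to 1 by 0.05 (21 x 21). Parameter-independent pipeline
#' stages are computed once per case; a segmentation failure scores 0 for
#' that case/pair with a warning.
#'
#' @param cases list of `wml_phantom` cases (see [generate_phantom()]), or
#'   any list with `t1`, `flair`, `pf_mask`, `lesion_gt` entries.
#' @param alpha_grid,lambda_grid parameter vectors.
#' @param folds number of folds (2, per the two-fold protocol).
#' @param seed integer seed for the fold split.
#' @param min_volume_mm3 size-filter setting held fixed during the sweep.
#' @param variant F-score variant, see [f_score()].
#' @return `wml_grid_search`: `alpha_grid`, `lambda_grid`, `fold_scores`
#'   (list of mean-F matrices, |alpha| x |lambda|), `best_per_fold`,
#'   `best` (overall), `fold_cases`.
#' @export
grid_search <- function(cases, alpha_grid = seq(1, 3, by = 0.1),
                        lambda_grid = seq(0, 1, by = 0.05), folds = 2L,
                        seed = 1L, min_volume_mm3 = 3,
                        variant = "as-printed") {
  if (length(cases) < 2L) stop("grid_search: need at least 2 cases")
  if (!length(alpha_grid) || !length(lambda_grid))
    stop("grid_search: empty parameter grid")
  n <- length(cases)
  set.seed(seed)
  perm <- sample.int(n)
  half <- ceiling(n / 2)
  fold_cases <- list(perm[seq_len(half)], perm[seq(half + 1L, n)])
  if (folds != 2L) {
    fold_cases <- split(perm, rep_len(seq_len(folds), n))
    names(fold_cases) <- NULL
  }
  case_scores <- vector("list", n)
  for (ci in seq_len(n)) {
    cs <- cases[[ci]]
    mat <- matrix(0, length(alpha_grid), length(lambda_grid))
    ok <- tryCatch({
      ctx <- segmentation_context(cs$t1, cs$flair, cs$pf_mask, seed = seed)
      gt_labels <- cs$lesion_gt$labels
      n_gt <- nrow(cs$lesion_gt$components)
      for (ai in seq_along(alpha_grid)) {
        thr <- compute_threshold(ctx$gm_peak, alpha_grid[ai])
        cand <- detect_candidates(ctx$flair_corr, thr, ctx$brain_mask,
                                  ctx$exclusion)
        st <- component_sweep_stats(cand, ctx, gt_labels, min_volume_mm3)
        for (li in seq_along(lambda_grid))
          mat[ai, li] <- score_at_lambda(st, lambda_grid[li], n_gt, variant)
      }
      TRUE
    }, error = function(e) {
      warning("grid_search: case ", ci, " failed (", conditionMessage(e),
              "); scoring 0")
      FALSE
    })
    case_scores[[ci]] <- mat
  }
  fold_scores <- lapply(fold_cases, function(ids)
    Reduce(`+`, case_scores[ids]) / length(ids))
  pick_best <- function(m) {
    best <- which(m == max(m), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    list(alpha = alpha_grid[best[1]], lambda = lambda_grid[best[2]],
         f = max(m))
  }
  best_per_fold <- lapply(fold_scores, pick_best)
  overall <- pick_best(Reduce(`+`, fold_scores) / length(fold_scores))
  structure(list(alpha_grid = alpha_grid, lambda_grid = lambda_grid,
                 fold_scores = fold_scores, case_scores = case_scores,
                 best_per_fold = best_per_fold, best = overall,
                 fold_cases = fold_cases, seed = seed),
            class = "wml_grid_search")
}

#' @export
print.wml_grid_search <- function(x, ...) {
  cat(sprintf("<wml_grid_search> %dx%d grid, %d folds\n",
              length(x$alpha_grid), length(x$lambda_grid),
              length(x$fold_scores)))
  for (i in seq_along(x$best_per_fold))
    cat(sprintf("  fold %d best: alpha = %.2f, lambda = %.2f (F = %.3f)\n",
                i, x$best_per_fold[[i]]$alpha, x$best_per_fold[[i]]$lambda,
                x$best_per_fold[[i]]$f))
  cat(sprintf("  overall best: alpha = %.2f, lambda = %.2f (F = %.3f)\n",
              x$best$alpha, x$best$lambda, x$best$f))
  invisible(x)
}
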