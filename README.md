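# wmlseg

Unsupervised detection and segmentation of small focal white-matter lesions
(WML) from co-registered T1w and FLAIR brain MRI, for neuroimaging analysts
quantifying lesion burden — e.g. in neuropsychiatric lupus, where the number
and volume of WML stratify patients (<5 / 5–25 / >25 lesions).

## Method

On FLAIR, gray matter is the brightest normal tissue, so lesions are
detected as hyperintense outliers of the GM intensity distribution:

* the T1w volume is segmented into CSF/GM/WM by a three-class Gaussian
  mixture (EM); the brain mask is the maximum tissue probability
  thresholded at 0.5, holes filled;
* the FLAIR volume is denoised by one pass of Perona–Malik anisotropic
  diffusion (K = 50, high-contrast conduction) and corrected for the
  multiplicative bias field by a log-domain EM/polynomial model;
* the GM FLAIR histogram's main peak μ and its FWHM give
  σ = FWHM / (2√(2 ln 2)), and voxels with intensity ≥ μ + ασ (default
  α = 2.5, i.e. above ≈99.4% of a Gaussian GM model) become candidates;
* candidate components (26-connected) are refined by three rules: volume
  ≥ 3 mm³; ≥ λ (default 0.70) of the one-voxel 26-shell labeled WM; and no
  voxels inside a supplied posterior-fossa exclusion mask.

Evaluation is voxel-wise (Dice) and lesion-wise (TPR / PPV by ≥1-voxel
overlap; FNR by volume), combined as F = 3·DSC·TPR·PPV/(DSC+TPR+PPV), with
burden stratification, Spearman correlations, Bland–Altman volume agreement
(d = gt − auto), and a two-fold cross-validated grid search over
α ∈ {1.0,…,3.0} × λ ∈ {0,…,1.0}. A synthetic 3D phantom generator
(nested-ellipsoid brain, ground-truth tissue, lesions and distractors)
makes the whole pipeline testable without any data download.

## Worked example

```r
library(wmlseg)

spec <- phantom_spec(shape = c(64, 64, 64),
  lesions = lapply(c(4, 8, 15, 22, 30), function(k)
    list(n_voxels = k, offset = 6, placement = "deep")),
  seed = 3)
ph  <- generate_phantom(spec)
res <- segment_lesions(ph$t1, ph$flair, exclusion = ph$pf_mask, seed = 3)
str(res$report)
#> $ mu                    : num 99.5
#> $ sigma                 : num 2.28
#> $ threshold             : num 105
#> $ alpha                 : num 2.5
#> $ lambda                : num 0.7
#> $ n_candidates          : int 95
#> $ n_removed_size        : int 86
#> $ n_removed_neighborhood: int 4
#> $ n_kept                : int 5

ev <- evaluate_case(res, ph$lesion_gt)
cat(sprintf("DSC = %.3f  TPR = %.2f  PPV = %.2f  F = %.3f\n",
    ev$dsc, ev$detection$tpr, ev$detection$ppv, ev$f_score))
#> DSC = 1.000  TPR = 1.00  PPV = 1.00  F = 1.000
```

The report reads as follows: the GM peak of the preprocessed FLAIR sits at
μ ≈ 99.5 with σ ≈ 2.28 (one diffusion pass roughly halves the raw GM
spread), so the default threshold is ≈ 105. Of 95 raw candidate components,
86 are speckle below 3 mm³, 4 are cortex-attached (shell less than 70% WM),
and the 5 survivors are exactly the 5 implanted lesions — all found (TPR),
nothing false (PPV), voxel-perfect overlap (DSC).

The same pipeline is scriptable from the shell (`inst/cli/wmlseg`):

```sh
wmlseg phantom --out ph/ --seed 11
wmlseg segment --t1 ph/t1.nii.gz --flair ph/flair.nii.gz \
       --exclusion ph/pf_mask.nii.gz --out seg/ --seed 11
wmlseg evaluate --auto seg/lesion_mask.nii.gz --gt ph/lesion_gt.nii.gz \
       --out report.json
wmlseg sweep --cases auto --out sweep.csv --seed 7
```

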