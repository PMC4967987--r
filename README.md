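# fuzzyCT

Fuzzy clustering segmentation of thoracic CT for candidate-nodule ROI
detection.

Computer-aided detection of pulmonary nodules needs an early stage that
reduces a CT study to a small set of candidate regions of interest (ROIs)
with as many true nodule voxels and as few spurious ones as possible.
`fuzzyCT` implements that stage as a family of five related fuzzy
clustering algorithms over voxel attenuation values (Hounsfield Units),
together with everything needed to exercise and evaluate them without
clinical data: a synthetic CT phantom generator with ground-truth masks,
voxelwise TP/FP scoring, parameter sweeps tracing TP-vs-FP tradeoffs,
readers/writers for NIfTI/TIFF/PNG volumes and LIDC-dialect XML nodule
annotations, and a command-line pipeline.  It is aimed at medical image
analysis researchers who want a tested, reproducible reference
implementation of these algorithms and of the evaluation methodology
around them.

## The model family

All five algorithms partition voxel intensities $x_k$ into $c$ fuzzy
clusters with centroids $v_i$ via memberships $u_{ik} \in [0,1]$,
$\sum_i u_{ik} = 1$, fuzzifier $m > 1$, iterating membership and centroid
updates until the centroids move less than $\epsilon$:

| id | membership | centroid | extra parameters |
|----|------------|----------|------------------|
| `fcm` | $u_{ik} \propto \|x_k - v_i\|^{-2/(m-1)}$ | $\sum_k u^m x / \sum_k u^m$ | — |
| `kfcm` | $u_{ik} \propto (1 - K(x_k, v_i))^{-1/(m-1)}$ | kernel-weighted mean | Gaussian $\sigma$ |
| `sfcm` | FCM memberships reweighted by $u^p h^q$ | FCM form on $u'$ | window, $p$, $q$ |
| `skfcm` | kernel distance + $(\alpha/N_R)\sum_{r \in N_k}(1 - K(x_r, v_i))$ | penalized kernel mean | window, $\alpha$ |
| `mskfcm` | KFCM memberships reweighted by $u^p h^q$ | kernel form on $u'$ | window, $\sigma$, $p$, $q$ |

where $K(x, v) = \exp(-(x - v)^2 / 2\sigma^2)$ (a $\sigma^2$ denominator
convention is also supported), $h_{ij} = \sum_{k \in NB(x_j)} u_{ik}$ sums
the window neighbors' memberships, and $N_k$ is the window around voxel
$k$ excluding the voxel itself.  Windows are 2D in-slice squares or 3D
rectangular prisms spanning adjacent slices, truncated at volume
boundaries.  With three clusters the nodule is auto-selected as the
midrange cluster; the combined `mskfcm` keeps that assignment stable, which
is what makes unattended ROI detection possible.

## Worked example

```r
library(fuzzyCT)

ph  <- generate_phantom(phantom_spec())    # 64 x 64 x 3, nodule + vessels
fit <- fuzzy_cluster(ph$volume, "mskfcm", clusters = 3,
                     init = init_spec("samples", samples = list(-850, -50, 30)))
fit
#> Fuzzy clustering fit (MSKFCM)
#>   volume 64 x 64 x 3, 6852 eligible voxels, 3 clusters
#>   slice-wise fit over 3 slices; iterations: 4, 5, 4
#>   centroids (HU):
#>         [,1]    [,2]    [,3]
#> [1,] -849.66 -850.19 -849.87
#> [2,]  -49.59  -53.42  -51.41
#> [3,]   29.79   31.70   30.10

tp_fp_rates(roi_mask(fit), ph$truth, domain = ph$lung_mask)
#>   slice tp_count fp_count fn_count tp_pct fp_pct fp_denominator domain
#> 1    NA      139        0        0    100      0      predicted domain
```

The three centroids recover the phantom's generating intensities (lung
parenchyma -850 HU, nodule -50 HU, vessels 30 HU) per slice, and the
auto-selected midrange cluster covers all 139 ground-truth nodule voxels
with no false positives: `tp_pct` is the percentage of nodule voxels
labeled nodule, `fp_pct` the percentage of nodule-labeled voxels that are
not nodule.

The same pipeline is scriptable from a shell (`inst/cli/fuzzyct`):

```sh
fuzzyct phantom --out ph --seed 1
fuzzyct segment --input ph/volume.nii --lung-mask ph/lung_mask.nii \
        --algorithm mskfcm --clusters 3 --sigma 300 --seed 1 --out seg
fuzzyct evaluate --predicted seg/roi_mask.nii --truth ph/truth.nii \
        --lung-mask ph/lung_mask.nii --out eval.csv
```

## Scope notes

Lung isolation (removing the chest wall, diaphragm, airways) is a separate
preprocessing stage and is not implemented; the clustering accepts a
precomputed lung mask and the phantom supplies one.  Supported volume
formats are NIfTI (lossless), 16-bit TIFF (lossless for integer HU), and
PNG (8-bit, display only).  See the vignette
(`vignettes/fuzzy-ct-segmentation.Rmd`) for the full account of the
models, conventions, and limitations.
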