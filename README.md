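# tensorPheno

Tensor-based organ segmentation and morphological phenotyping of 3-D
plant point clouds, for early detection of sunflower broomrape
(*Orobanche cumana*) parasitism.

Broomrape is a root holoparasite whose damaging life-cycle stages happen
below the soil surface; by the time shoots emerge, the crop is already
compromised. Because the parasite drains water and nutrients from the
host root system, infection leaves a morphological signature on the host
plant early — in particular on plant height and the first internode
length. `tensorPheno` implements the analysis that turns a multi-view
stereo (MVS) reconstruction of a single potted plant into those
organ-level measurements, together with the thermal-time parasitism
dynamics model and the group-comparison statistics used to decide whether
control and infected plants differ.

## What it computes

For each point $x_i$ of a metric, cropped plant cloud, with neighborhood
$\sigma$ (default: 30 nearest neighbors):

- first-order tensor $t_i = \sum_{j\in\sigma}(x_i - x_j)$, whose
  magnitude flags asymmetric (boundary) neighborhoods;
- second-order tensor
  $T_i = \sum_{j\in\sigma}(x_j - x_i)(x_j - x_i)^\top$ with eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ and the stick / plate /
  sphere saliencies $(\lambda_1-\lambda_2,\ \lambda_2-\lambda_3,\
  \lambda_3)$.

Points are labeled **leaf** ($\lambda_2/\lambda_1 \ge 0.5$,
$\lambda_3/\lambda_1 \le 0.1$), **stem**
($\lambda_2/\lambda_1 \le 0.25$), or unassigned; a first-order
refinement pass recovers lamina-boundary misclassifications. From the
stem-related points, nodes (stem-petiole junctions) are detected as
regions of elevated $\lambda_2$ along the stem axis and internode lengths
are measured from their centroids. Whole-plant morphology comprises
height (z extent), width (planar diameter of the xy projection), and
voxel-occupancy volume with a five-cell connected-component noise filter.
The dynamics module converts hourly soil temperature to growing degree
days (GDD) and fits the three-parameter log-logistic
$y = a/(1+(x/x_0)^b)$ to attachment counts; the statistics module
provides one-way ANOVA with Tukey-HSD, estimated-vs-measured accuracy
regression, and the percent-difference reporting conventions.

A first-class synthetic generator (`generatePlant()`, `generateScene()`,
`generateCohort()`, `generateAttachments()`) produces labeled
sunflower-like clouds — bowed stem, petiole whorls, elliptical laminae,
Gaussian surface noise, reconstruction voids, pot/soil clutter — with
exact ground truth, so the entire pipeline is testable without field
data.

## Worked example

```r
library(tensorPheno)

g <- generatePlant(plantSpec(seed = 3))   # labeled synthetic plant
g$cloud
#> PointCloud: 3268 points [metric]
#>   extent x [-0.3491, 0.3531]  y [-0.3527, 0.3515]  z [0, 0.62]

res <- phenotypePlant(g$cloud, meta = list(plant_id = "demo", gdd = 940))
res$labels
#> OrganLabels [refined]: stem 214, leaf 2710, unassigned 344 (10.5%)
res$nodes
#> NodeSet: 3 nodes (lambda2/lambda1 >= 0.2)
#>   z (cm): 18.5, 30.3, 42.2
res$report
#> MorphologyReport: height 62.0 cm, width 74.7 cm, volume 0.00227 m^3,
#>   first internode 18.5 cm
100 * g$truth$firstInternode        # ground truth: 18.0 cm
```

The detected nodes sit within a few millimeters of the true junction
heights (18/30/42 cm), and the first internode (base to lowest node) is
recovered to 5 mm here. Dynamics and group statistics:

```r
fit <- fitLogLogistic(generateAttachments(c(6.62, 1000.18, -6.37),
  seq(550, 1120, by = 50), noiseSd = 0.3, seed = 2))
fit
#> Log-logistic fit  y = a / (1 + (x/x0)^b)
#>               a       x0       b
#> Estimate 6.6601 984.2823 -6.5956
#> SE       1.8518  90.4951  1.3780
#> R2 = 0.9743, RMSE = 0.2386, p < 0.0001

percentDifference(112, 82, reference = "infected")
#> $percent
#> [1] 36.58537
#> $display
#> [1] 36
```

The fit recovers the generating parameters within their standard errors;
the percent difference reproduces the convention used for reporting
height differences between control (112 cm) and infected (82 cm) groups.

A thin command-line wrapper ships in `inst/scripts/phyto3d.R`
(`crop`, `segment`, `phenotype`, `synth`, `fit-dynamics`, `compare`), for
example:

```sh
Rscript inst/scripts/phyto3d.R phenotype --in plant.ply --out report.json
```

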