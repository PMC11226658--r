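# shapejam

Cell-shape statistics and glassy dynamics of confluent monolayers.

In a confluent tissue — biological or synthetic — every cell is a polygon
pressed against its neighbours, and the distribution of cell *shapes* turns
out to be a remarkably universal readout of how close the layer is to
jamming. `shapejam` implements the statistical toolkit around that
observation:

- **Shape statistics** (`polygon_area`, `aspect_ratio`,
  `ensemble_aspect_ratios`, `rescale_ar`): second-moment aspect ratios of
  polygonal cells, with exact rigid-motion invariance and an exact-mean-1
  rescaling for distribution comparison.
- **Shape distributions** (`dkgamma`, `dmeanfield`, `fit_kgamma`,
  `fit_meanfield`, `sample_kgamma`, `sample_meanfield`): the one-parameter
  k-gamma law for rescaled areas/aspect ratios and the one-parameter
  mean-field aspect-ratio distribution, with maximum-likelihood fits and
  uniformly valid rejection samplers.
- **The universal scaling line** (`universal_line`, `collapse_pdfs`,
  `assess_scaling_deviation`): across the mean-field family the standard
  deviation of the aspect ratio is a linear function of its mean,
  SD(AR) ≈ 0.71·mean(AR) − 0.75; the package measures the line from the
  family itself and provides significance tests for data sitting on, above,
  or below it.
- **Glassy dynamics** (`msd`, `self_intermediate_scattering`,
  `relaxation_time`, `persistence_time`, `cage_time`, `mobility_subsets`):
  observables on cell-centre trajectories, including dynamical-heterogeneity
  tools (non-Gaussian parameter, fast/slow mobility subsets).
- **A thermal vertex model** (`init_tissue`, `vm_run`, `freeze_exterior`,
  `frozen_cluster_experiment`): an area–perimeter energy on a periodic
  disordered tissue with Brownian vertex dynamics and T1 topology changes,
  plus a frozen-cluster protocol in which only a compact cluster of n cells
  is mobile.
- **Synthetic generators** (`chiral_abp_trajectory`,
  `chiral_abp_msd_theory`, `polygons_with_ar`, `periodic_voronoi`): seeded
  generators with closed-form oracles, used throughout the test suite.
- **I/O** (`read_trajectory`, `write_polygons`, `write_fit_json`,
  `read_run_config`, pipelines `pipeline_shape_scaling`,
  `pipeline_heterogeneity`): validated CSV/JSON interchange and two
  end-to-end analysis pipelines.

## Worked example

Sample aspect ratios from the mean-field law, fit both one-parameter
families, and place the ensemble relative to the universal line:

```r
library(shapejam)

ar  <- sample_meanfield(5000, alpha = 2, seed = 42)
fit <- fit_meanfield(ar)
fit
#> mean-field AR fit: alpha = 1.9669 (n = 5000, logLik = -5126.09)

c(mean = mean(ar), sd = sd(ar))
#>      mean        sd
#> 2.1506574 0.8088910

x <- sample_kgamma(5000, k = 2.6, seed = 42)
fit_kgamma(x)
#> k-gamma fit: k = 2.5132 (n = 5000, logLik = -4059.36)

curve <- universal_line()
curve
#> universal scaling line: SD(AR) = 0.714 * mean(AR) -0.750  (fit on mean AR in [1.15, 2.50])

# the sampled ensemble sits on the line:
sd(ar) - (curve$slope * mean(ar) + curve$intercept)
#> [1] 0.023  (within the 0.05 band)
```

Run the frozen-cluster experiment (only a compact cluster of n cells is
mobile inside an otherwise frozen tissue) and find the cluster size at which
the shape statistics reach the universal line:

```r
fc <- frozen_cluster_experiment(n_values = c(1, 4, 12, 24),
                                T_values = c(0.004, 0.012), seeds = 1:3,
                                n_cells = 64, equil_steps = 6000,
                                prod_steps = 6000, snapshot_stride = 50)
scaling_onset(fc, universal_line(), band = 0.05)
#>       temperature onset_n
#> 0.004       0.004       1
#> 0.012       0.012       4
```

A single mobile cell (n = 1) has SD(AR) = 0 exactly — all its vertices are
shared with frozen neighbours — and SD(AR) rises monotonically onto the
line as n grows.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "shapejam", load_package = "installed")'
```

The suite includes one acceptance block per headline claim
(`tests/testthat/test-acceptance.R`) alongside unit suites for every module.
One acceptance expectation is a known red: at thermal equilibrium this
vertex model has no persistent dynamical heterogeneity, so its fast-mobility
subset is *not* significantly below the universal line (the subsets are
statistically identical). The assertion states the claim as written rather
than weakening it; see the methods vignette for the analysis.

## Reproducing headline numbers

```sh
Rscript scripts/acceptance.R --seed 1 --out results.json
```

writes JSON with `t1` (the fitted slope of the universal line, ≈ 0.71) and
`t3` (the SD of a single frozen-cluster cell's aspect-ratio series, 0
exactly), each with its sample size.

## Vignette

`vignettes/shapejam-methods.Rmd` documents the model assumptions, parameter
choices, numerical methods (rejection sampling in the transformed variable,
periodic Voronoi construction, adaptive time stepping, T1 handling), and
known limitations.
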