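# cochleogram

Longitudinal transduction-rate profiles for whole-mount cochleas.

Gene delivery to the inner ear (e.g. with AAV vectors) is mosaic: within
each cell type of the organ of Corti only a fraction of cells express the
transgene, and that fraction varies along the cochlea from base to apex.
`cochleogram` quantifies this for anyone who annotates whole-mount cochlear
images: it turns point annotations of transduced cells (clicked in
Fiji/ImageJ or stored as CSV) plus an operator-delineated cochlear axis
into per-cell-type **longitudinal transduction-rate profiles**, and
provides the statistics used to compare them between cochleas, ears, or
treatment groups.

## Method in brief

Given annotated cell centers and an ordered base-to-apex axis polyline:

1. an arc-length-parameterized cubic spline is fitted to the axis, giving
   every point on the curve a coordinate *s* ∈ [0, *L*] (base = 0);
2. each cell is projected to its globally nearest point on the curve
   (cells farther than a gate distance — e.g. mesenchymal cells or cells of
   an adjacent spiral turn — are rejected and counted, never misplaced);
3. the projected coordinates are smoothed with a unit-mass Gaussian kernel
   (σ = 250 µm by default, ~1/20 of the cochlear length), with kernels
   reflected at the domain ends so no mass is lost at base or apex:

   λ(x) = Σᵢ φ_σ(x − sᵢ)  (cells/µm, the "cochleogram");

4. dividing by the reference longitudinal density of each cell type
   (cells per 100 µm; P0 hair-cell defaults IHC 11.8, OHC1 13.7,
   OHC2 13.9, OHC3 14.1) gives the transduction rate
   f(x) = λ(x) / (ref/100).

Cochleas cut into fragments are merged by offsetting each fragment's
coordinates by the summed lengths of the fragments before it. Profiles are
compared with the two-sample Kolmogorov–Smirnov test on the underlying
cell coordinates (length-normalized by default), and mean values (segment
counts, peak rates) with Welch's *t*-test. A synthetic-cochlea generator
(Archimedean spiral, parallel cell rows, Bernoulli transduction with a
configurable probability profile p(s)) provides ground truth for
validating every stage.

See `vignettes/cochleogram-methods.Rmd` for the full model, parameter
choices and limitations.

## Worked example

Generate a synthetic cochlea with a basal-peaked transduction profile
(50 % at the base declining to 0 towards the apex), run the pipeline on
its annotation files, and summarize:

```r
library(cochleogram)

spec <- synthetic_cochlea_spec(
  profiles = profile_family("logistic", p_base = 0.5, p_apex = 0),
  seed = 42)
gen <- generate_cochlea(spec)
gen
#> <synthetic_cochlea> L = 5700 um, 1 fragment(s), 3050 cells (550 transduced)

dir <- file.path(tempdir(), "demo")
write_cochlea(gen, dir)

cfg <- run_config(
  annotations = file.path(dir, "annotations_frag1.csv"),
  axes        = file.path(dir, "axis_frag1.csv"),
  id = "pup1_left")
run <- run_profile(cfg)
#> Loaded 550 annotation(s) of 4 cell type(s) from annotations_frag1.csv
#> pup1_left: L = 5700 um, 550 cell(s) accepted, 0 rejected;
#>   peak fractions: IHC 0.58, OHC1 0.55, OHC2 0.47, OHC3 0.46

run$peaks
#> # A tibble: 4 x 5
#>   cell_type peak_fraction peak_position_um peak_position_rel cochlea_id
#>   <chr>             <dbl>            <dbl>             <dbl> <chr>
#> 1 IHC               0.585                0             0     pup1_left
#> 2 OHC1              0.553                0             0     pup1_left
#> 3 OHC2              0.473              690             0.121 pup1_left
#> 4 OHC3              0.463                0             0     pup1_left
```

The peaks sit at the cochlear base and recover the generating 50 % rate
(the IHC peak reads 0.585 on this 673-cell row; sampling noise at σ = 250 µm
is a few percent). Counts per base/mid/apex third show the basal bias
directly:

```r
segment_counts(run$coords, L = run$L)
#> # A tibble: 3 x 4
#>   segment start_um end_um count
#>     <int>    <dbl>  <dbl> <int>
#> 1       1       0   1900.   432
#> 2       2    1900.  3800.   109
#> 3       3    3800.  5700.     9
```

Comparing against a second cochlea generated from the same profile family
(a biological replicate under the null):

```r
gen2 <- generate_cochlea(synthetic_cochlea_spec(
  profiles = profile_family("logistic", p_base = 0.5, p_apex = 0),
  seed = 43))
ks <- compare_profiles_ks(
  run$coords, dplyr::filter(gen2$truth, transduced),
  L_a = run$L, L_b = gen2$L)
tidy(ks)
#> # A tibble: 1 x 6
#>   test                            statistic p_value   n_a   n_b grouping
#> 1 Kolmogorov-Smirnov (two-sample)    0.0342   0.905   550   551 <NA>
```

D = 0.034, p = 0.90: the two profiles are statistically indistinguishable,
as they should be. `autoplot(run$profile)` draws the profile figure;
`run_profile()` also writes the profile/peaks CSVs (with a config digest in
the header) and the figure when `out_dir` is set. A thin command-line
wrapper lives at `inst/scripts/cochleogram-cli.R` with `generate`,
`profile` and `compare` subcommands driven by YAML configs.

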