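# boneqct

Bone strength has two determinants: bone mass and bone quality — the
structural and material properties that mass alone does not capture.
Volumetric bone mineral density (BMD, mg/cm³) measures mass; it says
nothing about *where* the mineral sits in a cross-section, yet flexural
and torsional resistance depend on exactly that. `boneqct` is for
researchers analysing calibrated CT slice stacks of vertebral bodies
(small-animal in-vivo imaging in particular) who want, next to the
standard morphometry, the two density-weighted moment indices that make
mineral *distribution* measurable:

- the **minimum cross-sectional moment of inertia**
  `I_min = min over θ of ∬ r′² · BMD(x, y) dx dy` (mg·cm), with
  `r′ = |−sin θ (x − X_g) + cos θ (y − Y_g)|` the distance to the axis
  through the density-weighted centroid `(X_g, Y_g)` at angle `θ` — an
  index of bending strength, computed in closed form as the smaller
  eigenvalue of the density-weighted second-moment tensor;
- the **polar moment of inertia** `J = ∬ r² · BMD(x, y) dx dy` (mg·cm),
  `r` the radial distance to the centroid — an index of torsional
  strength, equal to the sum of the moments about any two perpendicular
  centroid axes.

Around these the package provides the full measurement chain: calibrated
16-bit TIFF + JSON sidecar stack IO, bone segmentation with a
cortical/cancellous shell split and replayable manual corrections,
volumetric BMD (`mineral / (d·ΣS(i))`), mean cortical thickness
(distance-transform local width), vertebral body height/width
(intermediate-value convention, averaged over L2–L4), and a per-day
two-group comparison (two-sided pooled-variance Student's t, α = 0.05).

Because no public imaging data accompanies the study design this package
emulates, everything is validated on **synthetic phantoms**: elliptical
cortical shells with textured cancellous interiors whose BMD, thickness,
dimensions, `I_min` and `J` are known analytically, generated as
longitudinal two-arm studies (5 control, 6 fasting subjects, 14 days,
imaging every other day) in which a 4-day fast suppresses density
accrual and triggers a persistent inward mineral redistribution. The
generator's headline property mirrors the motivating observation: after
refeeding, **BMD recovers within days while the moment indices do not**,
because redistribution changes the mineral distribution at conserved
mineral mass. See `vignettes/bone-quality-phantoms.Rmd` for the models,
parameter choices and limitations.

## Worked example

Simulate a small noiseless study, measure it, and compare the arms:

```r
library(boneqct)

params <- phantom_params(noise_sd = 0, blur_sigma = 0,
                         cancellous_texture_sd = 0, seed = 3L)
design <- study_design(n_control = 1L, n_fasting = 1L,
                       imaging_days = c(0L, 14L))
study  <- generate_study(params, design, render = TRUE)
tab    <- measure_study(study)
tab[, c("subject_id", "day", "bmd", "cortical_thickness", "min_moment",
        "polar_moment")]
#>   subject_id day      bmd cortical_thickness min_moment polar_moment
#> 1        C01   0 537.0932          0.3907331  0.4614745     1.280682
#> 2        C01  14 661.6317          0.4245766  0.7927479     2.203065
#> 3        F01   0 515.1282          0.3962712  0.4630280     1.294538
#> 4        F01  14 634.6282          0.8733325  0.5769778     1.649483
```

Reading the table: both animals nearly double their moments over 14
growth days; the fasted subject F01 ends with BMD back in the control
range (635 vs 662 mg/cm³, a gap within the between-subject spread — mass
recovered) but `I_min` and `J` about 25 % lower, with a
thicker-but-diluted cortical shell — the mineral redistribution the
moments are designed to detect. Ground truth for every value is in
`study$ground_truth`; at this resolution the measured table agrees with
it to better than 0.7 %.

The full study pipeline is driven by the numbered scripts:

```sh
Rscript analysis/01_simulate.R     # render the default 11-subject study
Rscript analysis/02_measure.R      # segment + morphometry -> results/morphometry.csv
Rscript analysis/03_compare.R      # per-day Student's t   -> results/timecourse.csv
Rscript analysis/04_calibration.R  # type-I error + dissociation frequency
```

On the default study (seed 20260922), `analysis/03_compare.R` prints,
for BMD, significant fasting deficits on days 2–6 (`***`) that vanish
from day 8 onward, while `min_moment` and `polar_moment` stay
significantly depressed through day 14 with a widening gap — the
density/quality dissociation as a generator-level property.

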