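# kinagree

Criterion-validity analysis for shoulder kinematics measured by a wearable
inertial sensor (IMU) against an optical motion-capture reference — as a
reusable, tested, fully synthetic pipeline.

## The problem

Clinicians and movement scientists increasingly use skin-mounted inertial
sensors to measure shoulder motion. Before an "off-the-shelf" IMU system
can replace laboratory motion capture, its agreement with the optical gold
standard has to be quantified: per movement and per outcome, how large is
the systematic error (bias), how wide are the 95% limits of agreement, how
well do the two systems rank subjects (ICC), and how large is the typical
error (RMSE)?

`kinagree` implements that whole analysis chain for active shoulder
movements, plus a synthetic-cohort generator so every stage can be tested
with known ground truth:

1. **simulate** — minimum-jerk movement trials for nine conditions
   (abduction/adduction, horizontal flexion/extension, vertical
   flexion/extension, external/internal rotation, and a multiplanar PNF
   pattern), observed by two imperfect systems: a 500 Hz optical reference
   and a 147 Hz wearable with configurable static offset, sensor-frame
   misalignment, amplitude scaling (soft-tissue artifact), random-walk
   drift, and additive noise;
2. **preprocess** — resample both streams to a common 200 Hz timebase
   (anti-alias low-pass before downsampling), synchronize by
   cross-correlation, remove baseline angle offsets;
3. **extract** — fragment each trial into outward phase, terminal dwell,
   and reverse phase by a sustained velocity threshold, then compute range
   of motion (ROM, °), total range of motion of opposing-movement arcs
   (TROM, °), peak angular velocity (PAV, °/s) and windowed mean angular
   velocity (MAV, °/s);
4. **agree** — Bland–Altman bias with limits of agreement
   `bias ± 1.96 × SD` of the paired differences (reference − test), the
   two-way mixed single-measures intraclass correlation
   `ICC(3,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E)` with interpretation
   bands (poor < 0.5 ≤ moderate < 0.7 ≤ good < 0.9 ≤ excellent),
   `RMSE = sqrt(mean(d²))`, and a Kendall-tau heteroscedasticity check on
   |difference| versus pair mean.

Angles are intrinsic XZ′Y″ Euler decompositions of the
humerus-relative-to-thorax rotation (X = abduction/adduction,
Z = vertical flexion/extension, Y = rotation and horizontal-plane
movements), the convention used in upper-limb motion analysis.

## Worked example

```r
library(kinagree)

# A wearable that attenuates the frontal-plane (X) channel by 30%
# and adds 1 degree of angle noise
cfg <- run_config(
  cohort     = cohort_spec(n_subjects = 24, movements = c("ABD", "ADD")),
  ref_model  = reference_model(),
  wear_model = wearable_model(amplitude_scale = c(0.7, 1, 1),
                              noise_sd_deg = 1))

rep <- run_pipeline(cfg, seed = 1, out_dir = "demo_run")
rep[rep$outcome == "ROM", c("movement", "ref_mean", "test_mean",
                            "rmse", "icc", "icc_band", "bias",
                            "loa_upper", "loa_lower")]
```

prints (seed 1):

```
  movement ref_mean test_mean  rmse    icc  icc_band  bias loa_upper loa_lower
1      ABD   163.29    114.14 49.28 0.9399 excellent 49.16     56.03    42.279
2      ADD    39.35     27.48 12.31 0.9403 excellent 11.87     18.39     5.345
```

Both frontal-plane movements recover the injected 30% attenuation: the
ABD bias is ≈ 0.3 × 163.3 ≈ 49° and the ADD bias ≈ 0.3 × 39.4 ≈ 12°.
Note the deliberately instructive contrast between the columns: the
Bland–Altman bias exposes the amplitude-proportional systematic error,
while the default *consistency* ICC stays "excellent" because pure
scaling preserves subject ranking — switch `icc_form = "agreement"` to
make the ICC absolute. `run_pipeline()` also
writes `trials/*.csv`, `manifest.csv`, `summaries.csv`,
`agreement_report.csv`, `agreement_report.txt` and `run.log` under the
output directory, and is byte-for-byte reproducible under a fixed seed.

A command-line front end with `simulate` / `extract` / `report` / `run`
subcommands is installed at `inst/cli/kinagree.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "kinagree.R", package = "kinagree"))')" \
    run --seed 1 --out demo_run
```

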