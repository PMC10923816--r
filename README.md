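# emibrain

Software pipeline for a portable electromagnetic (microwave) brain scanner
used in stroke triage. The device surrounds the head with 16 antennas in a
lossy coupling medium and sweeps 0.7–1.8 GHz; a vector network analyzer
records the complex 16 × 16 scattering matrix S(f) per frequency point.
Stroke changes tissue dielectrics — a hemorrhage (ICH) **raises**
permittivity and conductivity, an ischemia (IS) **lowers** both — and the
software must decide, within seconds, whether a stroke is present, of which
type, and in which head quadrant. Getting ICH vs IS right matters clinically
because the treatments are opposites.

`emibrain` implements the full chain in R:

* **Synthetic device model** — a 2-D Born-approximation solver,
  `S_ij(f) = k_b² Σ_p G(r_i, r_p) χ(r_p) G(r_p, r_j) ΔA`, with the
  background Green's function `G = (j/4) H₀⁽¹⁾(k_b |r − r′|)` (complex
  Hankel function in compiled code) over elliptical head phantoms with
  optional circular inclusions; plus the clinical acquisition protocol
  (20 scan replicates at 30 dB SNR, per-port drift, motion outliers, and
  two homogeneous calibration-phantom sweeps).
* **Calibration and gating** — exact per-channel complex affine two-phantom
  calibration, consecutive-scan stability gating, scan averaging.
* **Boundary estimation** — gradient-boosted regressor on reflection
  coefficients (ellipse out, ~2 mm held-out error).
* **Four detection/localization algorithms** — (II) horizontal visibility
  graph features of hemisphere-differential channels feeding a four-member
  classifier ensemble (random forest, kNN, naive Bayes, SVM) and a
  line-crossing map; (III) the Direct Mapping Method onto a polar grid with
  intensity detection and phase-based typing; (IV) beamography —
  distance-correlation side detection, symmetry + average clutter
  subtraction, and Green's-function back-propagation; (V) EVSLA —
  expected-value statistics over symmetric antenna patches.
* **Fusion** — image co-registration, K-of-N agreement masking,
  smoothing/dilation, red/blue rendering, and classifier-decision fusion
  into one verdict (healthy / ICH / IS) with a quadrant call.

The methods vignette (`vignettes/emibrain-methods.Rmd`) documents the model,
every tunable parameter, and what the synthetic world does and does not
share with real heads.

## Worked example

Train the model bundle on synthetic cohorts, simulate one hemorrhagic
patient, and run the pipeline (a short 21-point sweep keeps this example
fast; training takes a few minutes):

```r
library(emibrain)
sw <- frequency_sweep(n = 21L)
models <- train_models(seed = 7L, sweep = sw, n_train_ensemble = 24L,
                       n_boundary = 120L, n_dmm_null = 12L)
coh <- generate_cohort(1, c(ICH = 1), scans_per_patient = 20L, seed = 99L,
                       sweep = sw)
p <- coh$patients[[1]]
print(p$phantom)
#> <head_phantom> 79 x 92 mm ellipse, ICH r=24 mm at (-45, -22) mm

out <- run_pipeline(p$scans, p$cal, models)
print(out)
#> <fusion_output> ICH (certainty 0.88), posterior-right, peak (-56.0, -30.0) mm
cat(pipeline_report(out))
```

The report is canonical JSON (byte-identical on rerun with the same
inputs). For this patient it reads, in part:

```json
{
  "fused_class": "ICH",
  "certainty": 0.8822155343,
  "quadrant": "posterior-right",
  "peak_xy_m": [-0.056, -0.03],
  "dmm_detect": true,
  "dmm_type": "ICH",
  "affected_side": "right",
  "boundary_mm": [-2.57135, -0.531664, 78.616567, 97.777471],
  "scans_kept": 20
}
```

Reading it: the ensemble and the Direct Mapping Method both call a
hemorrhage; the affected hemisphere is the patient's right (the truth
inclusion sits at x = −45 mm, and +x is patient-left); the fused peak lands
14 mm from the true centre, in the correct posterior-right quadrant; the
boundary regressor recovered the 79 × 92 mm head to within ~6 mm; all 20
scans passed the stability gate. `render_fusion(out, "fused.png")` writes
the red (ICH) overlay, and `plot(out$images$beamography)` shows any single
modality.

A thin command-line wrapper over the same functions lives at
`inst/cli/emibrain.R` (`simulate`, `run`, `evaluate` verbs).

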