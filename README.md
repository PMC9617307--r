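# mrlap

Noninvasive, quantitative estimation of **left atrial pressure (LAP)** from
the continuous-wave Doppler spectrum of a **mitral regurgitation (MR)** jet.

Clinically, LAP is approximated by the pulmonary arteriolar wedge pressure
from a floating catheter — accurate but invasive. The MR jet offers a
noninvasive alternative: by the simplified Bernoulli relation
`ΔP = 4V²` the jet velocity is a pressure-difference recording. `mrlap`
implements two estimators built on it:

* **Sphygmomanometer method**: `LAP_BP = P_sys − 4·V_peak²`, using the
  arterial systolic pressure and the peak regurgitant velocity.
* **Equation method**: during isovolumic relaxation the ventricular pressure
  follows Weiss mono-exponential decay `P(t) = P₀·exp(−t/τ)`. The times
  `t3 < t2 < t1` at which the descending branch of the jet envelope falls
  through 3, 2 and 1 m/s mark ventricular pressures `LAP + 36`, `LAP + 16`
  and `LAP + 4` mmHg, giving two equations in the unknowns `(LAP, τ)`:

  ```
  t1 − t3 = τ · ln[(LAP + 36)/(LAP + 4)]
  t1 − t2 = τ · ln[(LAP + 16)/(LAP + 4)]
  ```

  The interval ratio determines LAP uniquely (the eliminant is strictly
  monotone); `mrlap` solves it by guaranteed-convergence bisection and
  recovers τ. The equation method reads only the *shape* of the pressure
  decline, which makes it far less sensitive than `LAP_BP` to eccentric
  jets that underestimate the measured velocity.

The package also provides the full measurement pipeline from calibrated
spectrogram images (edge detection, robust polynomial envelope refinement,
the calculability rules — no estimate when the peak is below 3 m/s or the
descending branch is incomplete — and sub-pixel landmark timing), a
ground-truthed synthetic spectrogram generator with speckle noise and
eccentric-jet underestimation, and a paired method-comparison statistics
harness (paired t, Fisher-z correlation intervals, the 10 % consistency
rule, chi-square, rank-sum, ICC).

## Worked example

Simulate one patient with known hemodynamics, render the spectrogram, and
run the estimation pipeline:

```r
library(mrlap)
truth <- patient_truth(lap_true = 14, tau = 0.05, v_peak = 4.8)
env   <- simulate_envelope(truth)
spec  <- render_spectrogram(env, seed = 7)
spec
#> Spectrogram: 553 velocity bins x 201 frames, dt = 0.001 s, dv = 0.01 m/s
#>   baseline row 1, jet below baseline; velocity span 0..5.52 m/s

estimate_lap(spec, id = "demo", p_systolic = truth$p_systolic)
#>     id        t1        t2        t3   lap_eq        tau   v_peak   lap_bp
#> 1 demo 0.1883428 0.1627002 0.1373319 13.39554 0.04887758 4.834611 12.66615
#>   calculable skip_reason
#> 1       TRUE        <NA>
```

Under default speckle noise the equation method recovers the true LAP of
14 mmHg to 13.4 mmHg (τ 0.049 s vs the true 0.05 s): `t1`, `t2`, `t3` are
the descending-branch crossing times (s), `lap_eq`/`tau` the equation-method
solution, and `lap_bp` the sphygmomanometer estimate from the measured peak
velocity. Non-calculable spectra return `calculable = FALSE` with the
violated rule in `skip_reason` instead of a number.

Batch use mirrors the same flow on directories of PNG/TIFF images with YAML
calibration sidecars (`cmd_estimate`), writes simulated cohorts to disk
(`cmd_simulate`), and compares estimate tables against catheter references
(`cmd_compare`). A thin command-line wrapper is installed at
`inst/cli/mrlap.R`:

```sh
Rscript inst/cli/mrlap.R simulate --out cohort --n 28 --seed 7
Rscript inst/cli/mrlap.R estimate --images cohort --out results --arterial cohort/truth.csv
Rscript inst/cli/mrlap.R compare  --estimates results/estimates.csv \
        --reference cohort/truth.csv --out report.json
```

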