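# bpvalidate

Accuracy evaluation of non-invasive blood-pressure (BP) devices under
**ISO 81060-2:2018** and the AAMI/ESH/ISO universal consensus protocol, as
used in clinical validation studies of cuff monitors and cuffless
estimators (e.g. smartphone photoplethysmography apps).

The package is aimed at statisticians and study teams running or auditing
such validations. It implements the full evaluation chain:

* **Reference derivation** — two blinded observers read the same cuff
  simultaneously; a round is valid when they agree within 4 mmHg on both
  arms and the test device produced a reading; the reference is their
  per-arm mean.
* **Exclusion cascade** — device failure → inter-nurse disagreement →
  subjects with < 3 valid pairs → subjects with excessive within-subject
  reference variability, applied in that fixed order with a conserved,
  per-record exclusion ledger.
* **Criterion 1** — pooled error `e = device − reference` must satisfy
  `−5 ≤ mean(e) ≤ 5` and `sd(e) ≤ 8` mmHg.
* **Criterion 2** — the between-subject SD of per-subject mean errors must
  not exceed the ceiling `s` solving
  `Φ((10 − |ē|)/s) − Φ((−10 − |ē|)/s) = 0.85`,
  i.e. a normal error model must keep 85% of errors within ±10 mmHg. The
  standard's printed lookup table for this ceiling is embedded and an
  optional *table mode* reproduces quoted thresholds exactly.
* **Sampling audits** — the protocol's BP-band, sex-fraction and cohort-size
  requirements (general population) and per-group minima (pregnant
  population, classified normotensive / hypertensive / pre-eclampsia).
* **Bland–Altman agreement** and pre-study **observer qualification**.
* A **synthetic-study simulator** (`generate_study()`, `scenario()`) with a
  documented error decomposition — mixture-distributed subject truth,
  shared round signal, quantized independent observer errors, device
  calibration anchoring, per-subject bias and a failure-mode mixture — so
  the entire pipeline is testable without field data.

## Worked example

Simulate a general-population community cohort and evaluate it:

```r
library(bpvalidate)

st <- generate_study(scenario("TZ_general", seed = 7))
report <- evaluate_study(st)
print(report)
#> Validation study report (general population): N = 103 subjects, M = 412 measurements
#>   SBP criterion 1: mean -0.3 (passed)  SD 7.0 (passed)
#>   SBP criterion 2: SD of subject means 6.2 <= 6.94  (passed)
#>   DBP criterion 1: mean -0.2 (passed)  SD 3.7 (passed)
#>   DBP criterion 2: SD of subject means 3.3 <= 6.94  (passed)

print(report$ledger)
#> Exclusion cascade: 520 measurements from 103 subjects
#>   device_failure            60 (55.6% of excluded)
#>   inter_nurse               48 (44.4% of excluded)
#>   insufficient_pairs         0 (0.0% of excluded)
#>   reference_variability      0 (0.0% of excluded)
#>   retained: 412 measurements, 103 subjects
#>   device-failure rounds also failing inter-nurse agreement: 5
```

Reading this: 103 subjects attempted 520 rounds; 60 rounds were lost to
device failures and 48 to nurse disagreement, leaving 412 valid paired
measurements (no subject fell below 3 pairs). The pooled SBP error is
−0.3 ± 7.0 mmHg, inside the criterion-1 box; the SD of the 103 per-subject
mean SBP errors is 6.2 mmHg, below the 6.94-mmHg ceiling that corresponds
to a pooled mean error of 0.3 mmHg — so the simulated device passes both
criteria on both arms.

The criterion-2 ceiling itself:

```r
round(max_permissible_sd(c(0, 2, 4.2)), 2)
#> [1] 6.95 6.65 5.49
```

`write_report(report, "out/")` emits `report.json`, a per-record exclusion
ledger, the criterion tables as text, and Bland–Altman point CSVs. CSV
inputs are read with `read_rounds_csv()` / `read_subjects_csv()`; a thin
command-line wrapper is installed at `exec/bpvalidate`
(`evaluate`, `simulate`, `table6` subcommands).

See the vignette `vignettes/device-validation.Rmd` for the model, the
design decisions behind the cascade interpretation, and what the simulator
does and does not emulate.

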