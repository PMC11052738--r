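# mirddose

Internal dosimetry in the MIRD schema for gamma-emitting
radiopharmaceuticals, starting from planar and SPECT **region count
tables** (not images) and ending at ICRP 103 / ICRP 60 effective dose.
Written for physicists and pharmacokineticists running first-in-human
biodistribution studies of Tc-99m-labelled tracers, where the protocol
is a handful of anterior/posterior whole-body sweeps plus a few SPECT/CT
acquisitions and the deliverable is a table of organ absorbed-dose
coefficients and an effective dose per MBq.

The chain, each stage an exported function:

| Stage | Core relation |
|---|---|
| Conjugate-view planar quantification | `fraction(t) = sqrt(C_ant * C_post) / CF / A_inj`, CF self-calibrated from the first pre-void whole-body image |
| SPECT VOI quantification | `fraction = (C - c_bg * V) / CF_spect / A_inj`; red marrow from L2–L4 at 6.7% |
| Mono-exponential kinetics | `A(t) = A0 * exp(-ln2 * t / T_eff)`, TIAC `= A0 * T_eff / ln2` hours |
| Voiding-bladder model | analytic integral of the bladder content between voids (default 1, 2, 4 h then every 3.5 h), driven by whole-body clearance |
| MIRD dose engine | `D(target) = sum_src TIAC_src * S(target <- src)` with remainder-of-body mass balance and patient-mass self-dose scaling |
| Effective dose | `E = sum_T w_T * H_T`, ICRP 103 and ICRP 60 weight sets with surrogate and remainder rules |

A synthetic-data generator (`ground_truth_kinetics()`,
`simulate_study()`) produces ground-truth biodistributions and
Poisson-noised planar/SPECT count tables under the same acquisition
schedule, so the entire chain is testable end to end without any image
data. The bundled S-value kernel is built from a clearly-labelled
**synthetic** adult-male phantom geometry; it reproduces the magnitude
and ranking of published Tc-99m S-values but is not a validated phantom
table (see the methods vignette).

## Worked example

Simulate a study, run the pipeline, read off the dose report:

```r
library(mirddose)

sim <- simulate_study(acq = acquisition_model(seed = 42))
dir <- tempfile(); dir.create(dir)
write.csv(sim$planar, file.path(dir, "planar.csv"), row.names = FALSE)
write.csv(sim$spect,  file.path(dir, "spect.csv"),  row.names = FALSE)

report <- run_pipeline(list(
  planar_csv   = file.path(dir, "planar.csv"),
  spect_csv    = file.path(dir, "spect.csv"),
  injected_mbq = list(SIM1 = 772),
  spect        = list(counts_per_mbq = 2000)))
print(report)
```

which prints (abridged):

```
Effective half-lives [h]:
                    organ SIM1 mean sd
                  kidneys 2.61 2.61 NA
                    liver 2.28 2.28 NA
               red_marrow 3.65 3.65 NA
 ...
Effective dose [mSv/MBq]:
  scheme   SIM1   mean sd
 ICRP103 0.0028 0.0028 NA
  ICRP60 0.0031 0.0031 NA
```

The recovered kidney half-life (2.61 h vs the generator's truth of
2.6 h) shows the quantification/fitting chain at realistic count
statistics; the ICRP 103 effective dose of ~0.0028 mSv/MBq is the level
expected for a fast renally-cleared Tc-99m tracer, dominated by the
bladder-wall term.

Individual stages are usable on their own, e.g. the bladder TIAC for a
whole-body effective half-life of 2.0 h:

```r
bladder_tiac(bladder_model_input(2.0), voiding_schedule(c(1, 2, 4), 3.5))
#> [1] 0.6443293
```

A thin command-line wrapper lives in
`inst/scripts/dosimetry-pipeline.R` (`simulate` and `report`
subcommands).

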