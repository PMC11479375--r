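# mear

Spatiotemporal gait segmentation from a single ear-worn accelerometer.

Walking leaves a characteristic signature in head acceleration: a
step-frequency oscillation punctuated by an impact transient at every
initial foot contact (IC, heel strike) and a weaker one at every final
contact (FC, toe off). `mear` turns a 100 Hz triaxial ear-acceleration
recording into:

* **gait events** — per-sample IC/FC probability traces from a temporal
  convolutional network (dilated convolutions, batch norm, ReLU,
  dropout; sigmoid only at inference), peak-picked into discrete events
  and assigned alternating foot sides;
* **stride parameters** — stride time, swing time and double support
  time from the bilateral event sequence; stride length and stride
  width (cm) regressed per gait cycle by causal residual TCNs with
  average pooling;
* **bout analytics** — mean, stride-to-stride variability
  (CV = 100·sd/mean, %) and left-right asymmetry
  (100·(1 − mean(smaller foot)/mean(larger foot)), %) per parameter;
* **agreement statistics** — event matching at a 250 ms tolerance with
  precision/recall/F1, signed time errors (t_annotated − t_predicted),
  absolute/relative RMSE, Pearson's r, two-way single-rater ICC
  (consistency and absolute-agreement variants, with the standard
  poor/moderate/good/excellent bands), and a repeated-measures ANOVA of
  relative RMSE across walking speeds.

Because real ear-worn walking datasets of this kind are not openly
available, the package includes a synthetic cohort simulator that
emulates a walkway protocol (repeated walks over a 6.7 m pressure mat at
slow/preferred/fast speeds, per-subject cadence and stride-length
distributions, stride-to-stride variability, left-right asymmetry, IC/FC
impact transients, per-subject sensor orientation, sensor noise). Every
stage of the pipeline is testable end-to-end against simulator ground
truth. The intended users are researchers in wearable gait analysis who
want a transparent, dependency-light reference implementation of this
kind of pipeline.

See `vignettes/gait-segmentation-methods.Rmd` for the model and
simulator details and the design decisions.

## Worked example

Simulate a small cohort, train the event detector, and segment a
held-out recording:

```r
library(mear)

config <- cohort_config(n_subjects = 6,
                        walks_per_speed = c(slow = 2, preferred = 2,
                                            fast = 2),
                        seed = 7)
cohort <- generate_cohort(config)
plan <- make_split_plan(cohort$manifest, test_fraction = 0.2, k = 4,
                        seed = 7)

subjects <- vapply(cohort$bouts, function(b) b$recording$subject_id, "")
train <- cohort$bouts[!(subjects %in% plan$test)]
test <- cohort$bouts[subjects %in% plan$test]

scaler <- fit_robust_scaler(lapply(train, `[[`, "recording"))
data <- temporal_training_data(train, scaler)
fit <- train_temporal(data, plan$folds[[1]]$train, plan$folds[[1]]$val,
                      epochs = 20, lr = 2e-3, seed = 7, scaler = scaler)

bout <- test[[1]]
events <- segment_recording(fit$model, bout$recording, scaler)
m <- match_events(events$time[events$kind == "IC"],
                  bout$events$time[bout$events$kind == "IC"])
detection_scores(m)[c("tp", "fn", "fp", "f1")]
#> $tp
#> [1] 18
#> $fn
#> [1] 0
#> $fp
#> [1] 0
#> $f1
#> [1] 1

strides <- strides_from_events(events)
s <- summarize_bout(strides, "stride_time")
round(c(mean_s = s$mean, cv_pct = s$cv, asym_pct = s$asymmetry), 3)
#>   mean_s   cv_pct asym_pct
#>    1.249    7.658    0.400
```

All 18 ground-truth ICs of the held-out (slow-walk) bout are recovered
within the 250 ms tolerance — no misses, no spurious detections,
F1 = 1 — and the mean stride time of ~1.25 s is the bout's true value.
The 7.7% stride-time CV is inflated relative to the simulated
stride-to-stride variability (~2.5%) because at 20 epochs on a
6-subject cohort the detected event *times* still jitter by tens of
milliseconds; the full recovery experiment below (12 subjects, 50
epochs) brings the mean timing error to a few milliseconds. FC
detection and stride-length regression likewise need the fuller
experiment.

The same pipeline is scriptable from a shell via the thin CLI at
`inst/cli/mear`:

```sh
mear simulate --config cohort.yaml --out data/
mear train    --task temporal --data data/ --out run/
mear segment  --model run/model_temporal.json --in rec.csv --out events.csv
mear metrics  --strides strides.csv --out summary.csv
mear evaluate --pred events.csv --truth truth.csv --out report/
```

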