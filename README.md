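# pdgait

Gait analysis and transmission quality control for wearable accelerometer
body-area networks, aimed at ambulatory monitoring of Parkinson's disease
(PD).

Home monitoring systems for PD strap five tri-axial accelerometers to the
patient (belt, both wrists, both legs), sample them at 62.5 Hz (one packet
every 16 ms, full scale ±6 g) and stream the packets wirelessly to a data
logger. Two analysis problems follow:

1. **Transmission QC.** The radios have no retransmission protocol; each
   packet only carries a unique timestamp. Lost packets appear as timestamp
   gaps, in bursts whose minimum length is the 64 ms logger reconnect time,
   with the longest bursts clustered at session start-up while the sensors
   connect. Before trusting any gait feature one must quantify data loss
   (percent lost, mean/modal burst length) and trim the unstable start-up
   period.
2. **Gait characterisation.** Once walking bouts are segmented out of the
   day's recording, each bout is summarised by:
   - **Sample entropy** `SampEn(m, r) = -ln(A/B)`, where `B` counts pairs of
     length-`m` templates within Chebyshev tolerance `r·sd` and `A` the same
     pairs extended by one point. Parkinsonian gait is less regular, so its
     SampEn is higher.
   - **Step frequency** `f = (n-1)/(t_n - t_1)` from peaks of the band-passed
     (0.5–3 Hz) cranio-caudal belt acceleration.
   - **Stride length** via the inverted-pendulum model: the vertical
     centre-of-mass excursion `h` per step (double-integrated vertical
     acceleration) gives step length `s = 2·sqrt(2·l·h - h²)` for leg length
     `l`.
   - **Velocity** `v = f·s̄` and the **stride-time coefficient of
     variation** (sd/mean of alternate-step intervals), the classic PD
     variability marker.

Because the clinical recordings behind such systems are not public, the
package ships a first-class synthetic-data generator (`simulate_session()`,
`apply_loss_model()`) that emulates healthy and PD-like gait plus the
packet-loss process with full ground truth, so the entire pipeline is
testable end to end.

## Worked example

```r
library(pdgait)

## a 5-minute session of a PD-like walker with two walking bouts,
## transmitted over a lossy network
sched <- activity_schedule(start_s = c(0, 120, 180),
                           end_s   = c(120, 180, 300),
                           label   = c("walking", "resting", "walking"))
session <- simulate_session(sched, pd_profile(), seed = 42)
lost    <- apply_loss_model(session, loss_model(seed = 43))

qc <- qc_report(lost$streams)   # detects gaps, trims start-up
print(qc)
#> Transmission quality report (window 60 s)
#> Sensor       Data loss (%)      Avg burst length (ms)    Modal (ms)
#> belt           0.91 +/- 0.15        97.78 +/- 34.66        64
#> left_wrist     0.97 +/- 0.39       104.89 +/- 45.74        64
#> right_wrist    0.96 +/- 0.42        89.00 +/- 29.65        64
#> left_leg       1.05 +/- 0.33        96.00 +/- 37.52        64
#> right_leg      0.82 +/- 0.33        94.15 +/- 41.94        64
#> Pooled: 0.94% loss (99.06% transmitted), modal burst 64 ms
```

About 1% of packets were lost; the most frequent burst is the 64 ms
reconnect minimum, as in real deployments. Gridding, gap handling,
segmentation and features:

```r
rec    <- as_recording(qc$trimmed[c("belt", "left_leg", "right_leg")])
pieces <- fill_gaps(rec)        # interpolate 64 ms bursts, split longer gaps
if (inherits(pieces, "recording")) pieces <- list(pieces)
feats <- do.call(rbind, unlist(lapply(pieces, function(p) {
  segs <- segment_walking(p)    # logistic window classifier on the legs
  lapply(seq_len(nrow(segs)), function(i)
    gait_features(p, segs[i, ], leg_length_m = 0.95))
}), recursive = FALSE))
feats[, c("start_s", "end_s", "n_steps", "sample_entropy",
          "step_frequency_hz", "stride_length_m", "velocity_m_s",
          "stride_time_cv")]
#>   start_s end_s n_steps sample_entropy step_frequency_hz stride_length_m
#> 1     0.0  10.2      16           1.65              1.65           0.600
#> 2    66.8  94.9      47           1.74              1.69           0.617
#> 3   186.0 202.6      28           1.74              1.67           0.601
#> 4   219.2 234.5      26           1.67              1.70           0.609
#> 5   254.3 264.5      18           1.75              1.73           0.544
#> 6   273.7 284.0      18           1.69              1.73           0.589
#>   velocity_m_s stride_time_cv
#> 1        0.989         0.1189
#> 2        1.039         0.0805
#> 3        1.003         0.1146
#> 4        1.036         0.0896
#> 5        0.944         0.1160
#> 6        1.018         0.1344
```

The walking bouts are fragmented by unfillable transmission gaps (the
policy never fabricates more than one 64 ms burst). The PD-like profile
(`pd_profile()`: 1.7 Hz cadence, stride-time CV 0.10, reduced and
asymmetric excursion, noisier signal) is recovered in the features: cadence
≈ 1.7 Hz, stride-time CV ≈ 0.08–0.13, and sample entropy around 1.7 —
clearly above the ≈ 0.85 a `healthy_profile()` walker produces under the
same analysis.

There is also a one-call orchestration (`run_pipeline(run_config(...))`)
and a command line (`exec/pdgait`): `pdgait simulate|qc|analyze|compare`,
configured by JSON with an explicit seed; outputs are CSV/JSON plus a run
manifest that makes every number reproducible.

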