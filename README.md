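# radarheart

Touch-free heart sound monitoring with a continuous-wave radar
interferometer, in R.

A 24 GHz Six-Port radar pointed at the chest resolves micrometre-scale
surface vibrations. Besides breathing (mm scale, 0.1–0.5 Hz) and the pulse
wave (tens of µm, 0.75–3 Hz), the displacement signal contains the first
and second heart sounds (S1, S2): ~10 µm bursts with 16–80 Hz content
caused by valve closure and isovolumetric contraction. `radarheart`
implements the full processing chain that turns four raw Six-Port baseband
voltages into segmented heart sounds and beat-timing statistics, plus a
synthetic scene generator so everything is testable without hardware:

* **Demodulation** — complex I/Q combination `Z = (b5−b6) + i(b3−b4)`,
  ellipse-fit compensation of baseband offset/gain/phase errors
  (Fitzgibbon-type algebraic conic fit), arctangent demodulation on
  `[−π, π)`, unwrapping, and `Δx = Δσ/(2π) · λ/2` displacement scaling.
* **Filter bank** — zero-phase fourth-order Butterworth bands for
  respiration (0.1–0.5 Hz), pulse wave (0.75–3 Hz), ECG (0.5–20 Hz) and
  heart sounds (variant A: 25–400 Hz, variant B: 16–80 Hz).
* **HSMM segmentation** — logistic-regression emissions over envelope
  features and a duration-dependent (extended) Viterbi decoder over the
  cyclic states S1 → systole → S2 → diastole, with S1/S2 durations
  modelled as 122 ± 22 ms and 92 ± 22 ms and the heart cycle estimated by
  envelope autocorrelation (variant B: 0.45–1.45 s, i.e. 41–133 bpm).
* **Cardiomechanical analyses** — radar/PCG morphology correlation (double
  integration + cross-correlation alignment + Pearson coefficient),
  per-beat segment SNR, respiratory peak-envelope (PPE) coupling, S2
  (A2–P2) split gap, propagation velocity.
* **Beat metrics** — tapping-based inter-sensor synchronisation,
  once-per-second median-of-five interbeat intervals,
  `RMSE = sqrt(mean((I_ECG − I)²))`, greedy ±100 ms event matching, and
  `F1 = 2pr/(p+r)` with full train/test subject-split enumeration
  (`choose(11, 6) = 462`).
* **Synthetic scenes** — ground-truth-labelled multichannel recordings
  (radar baseband, PCG, ECG, respiration at 2000 Hz) with configurable
  heart rate, coupling, S2 split, I/Q distortion and noise.

## Worked example

Train emission models on two synthetic subjects, then run the full
pipeline on a third, unseen scene:

```r
library(radarheart)

train <- lapply(1:2, function(s) {
  cfg  <- scene_config(duration = 30, seed = 100 + s, bpm = 66 + 6 * s)
  gr   <- generate_recording(cfg)
  disp <- demodulate(gr$recording)
  hs   <- extract_component(disp$displacement, "heart_sound_B", cfg$fs)
  fe   <- hs_features(hs, cfg$fs)
  list(fe = fe, lab = as.character(frame_labels(gr$truth, fe$time)))
})
emissions <- train_emissions(dplyr::bind_rows(lapply(train, `[[`, "fe")),
                             unlist(lapply(train, `[[`, "lab")))
glance(emissions)
#> # A tibble: 1 × 3
#>   train_accuracy n_frames n_features
#>            <dbl>    <int>      <int>
#> 1          0.834     6000          4

scene  <- generate_recording(scene_config(duration = 30, seed = 7))
report <- run_pipeline(scene$recording, emissions)
report
#> <rh_report> variant B: 35 S1 / 35 S2 segments
#>   S1 F1 = 1.000, S2 F1 = 1.000, IBI RMSE = 4.1 ms
#>   morphology: mean similarity 0.608 over 35 beats

head(report$segmentation, 5)
#> # A tibble: 5 × 3
#>   state    start   end
#>   <chr>    <dbl> <dbl>
#> 1 diastole  0     0.54
#> 2 S1        0.54  0.65
#> 3 systole   0.65  0.77
#> 4 S2        0.77  0.88
#> 5 diastole  0.88  1.37
```

Reading the output: every one of the 35 true beats was detected within
±100 ms (`F1 = 1`), the once-per-second interbeat-interval series deviates
from the ECG reference by 4.1 ms RMSE, and each decoded cycle follows the
fixed order S1 → systole → S2 → diastole with S1/S2 durations near their
122/92 ms physiological means. The per-beat `report$morphology` table holds
the radar-vs-PCG similarity of each S1 segment after double integration and
lag alignment.

`autoplot()` methods exist for recordings and segmentations, and
`plot_ibi_comparison()` overlays detected and reference IBI curves.

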