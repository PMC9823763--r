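# remotion

Contactless emotion recognition from FMCW radar vital signs and facial
video, end to end and fully testable on synthetic data.

A 77 GHz frequency-modulated continuous-wave (FMCW) radar pointed at a
seated person measures chest motion through the *phase* of its
intermediate-frequency (IF) signal: for a chest at range
`R = Δd + d(t)`,

```
f_IF = 2 B R / (c T_c)        (range lives in the IF frequency)
φ_IF = 4 π R / λ              (sub-wavelength motion lives in the phase)
```

A 0.1 mm displacement moves `f_IF` by ~33 Hz — about 0.001 cycles across
one 40 µs chirp, invisible in the spectrum — but rotates `φ_IF` by ~18°.
The package therefore recovers respiration and heartbeat from phase:
moving-target indication (MTI) removes static clutter, a range FFT and
target-bin phase extraction yield the chest displacement, and variational
mode decomposition (VMD) splits it into intrinsic mode functions that are
routed into the respiration band [0.1, 0.6] Hz and the cardiac band
[0.8, 3.3] Hz by mean instantaneous frequency. In parallel, face video is
reduced to stable keyframes (minimum chi-square histogram distance within
11-frame windows advancing by 8). A three-branch network — 1-D CNNs for
the respiration and heartbeat series, a 2-D CNN per keyframe, features
fused per time step into a 64-unit GRU with a softmax head — classifies
four emotional states: relaxed, happy, sad, angry.

Because no public recordings exist for this task, the package includes a
first-class synthetic-trial generator: a parametric chest-displacement
model (respiration + heartbeat + harmonic + noise) driving an IF cube
simulator with static reflectors, and a procedural face renderer with
per-emotion geometry presets. Every stage of the pipeline is validated
against that ground truth.

Who it is for: researchers and students in radar-based vital-sign
monitoring and affective computing who want a transparent, dependency-light
reference implementation of this pipeline that they can inspect, test and
extend.

## Worked example

```r
library(remotion)

cfg <- radar_profile("sim-small")          # 77 GHz, 4 GHz BW, 20 Hz frames
model <- displacement_model(resp_amplitude = 5, resp_freq = 0.28,
                            heart_amplitude = 0.5, heart_freq = 1.25,
                            noise_sd = 0.05)
chest <- make_displacement(model, duration = 60, rate = cfg$slow_rate, seed = 42)
cube  <- simulate_if_cube(cfg, chest,
                          statics = list(static_reflector(1.2, 0.8)),
                          baseline_range = 0.5, seed = 43)
cube
#> <radar_cube> 1200 frames x 2 chirps x 256 samples (real)

displacement <- extract_displacement(cube)   # MTI -> FFT -> phase -> mm
vitals <- extract_vitals(displacement, k = 6)
vitals
#> <vital_signs> breathing 16.8 /min, heart 75.0 bpm (k = 6)
cor(displacement$values, chest$values - mean(chest$values))
#> 0.9999
```

The model was built with breathing at 0.28 Hz (16.8 breaths/min) and a
heartbeat at 1.25 Hz (75 bpm); both come back exactly, and the recovered
waveform tracks the true chest motion at correlation 0.9999 despite the
stronger static reflector in the scene.

Training the classifier on a balanced synthetic dataset:

```r
ds  <- make_dataset(50, image_size = 32, n_keyframes = 4, seed = 11)
sp  <- split_protocols(ds$manifest, "person_dependent",
                       val_frac = 0.15, test_frac = 0.15, seed = 11)
net <- emotion_net(input_length = 1200, image_size = 32, n_keyframes = 4, seed = 11)
net <- train_emotion_net(net, ds$samples[sp$train], ds$samples[sp$val],
                         epochs = 12, seed = 11)
pred  <- predict_emotion(net, ds$samples[sp$test])
truth <- sapply(ds$samples[sp$test], `[[`, "label")
mean(pred$labels == truth)
#> 1
```

A command-line front end over the same functions lives in
`inst/cli/remotion.R` (subcommands `simulate`, `extract`, `keyframes`,
`e2e`).

See `vignettes/remotion-methods.Rmd` for the model assumptions, parameter
defaults and their rationale, the synthetic generator's scope, and known
limitations.

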