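# gammatrio

Visual cortex does not produce a single broadband gamma rhythm: grating
stimuli of varying spatial frequency (SF) can drive up to **three
distinct narrowband gamma components** in the local field potential —
low gamma (LG, 25–45 Hz), medium gamma (MG, 45–65 Hz) and high gamma
(HG, 65–100 Hz) — with different SF preferences, different cortical
depths, and different information content about object structure.
`gammatrio` is an R package plus a scripted analysis workflow for
multi-trial LFP/spike recordings organized by stimulus condition. It is
aimed at electrophysiologists who want to separate, quantify and decode
these rhythms, and it ships a synthetic-data generator with known ground
truth so every estimator in the chain is testable.

## The model at the core

The trial-averaged SF × frequency power surface is decomposed as

    Power(s, f) = k/(f^a + b) + c                       (aperiodic baseline)
                + Σᵢ Wᵢ(s) · exp(−(f − μᵢ(s))² / 2σᵢ²)   (3 gamma components)

    μᵢ(s) = K₀ᵢ + Kᵢ · sⁿⁱ / (sⁿⁱ + s₀ⁿⁱ)               (Naka–Rushton peak drift)
    Wᵢ(s) = A₁ᵢ e^(−s²/2σ₁ᵢ²) − A₂ᵢ e^(−s²/2σ₂ᵢ²)       (difference of Gaussians, ≥ 0)

fitted by bounded multi-start least squares with each μᵢ confined to its
band window. A component counts as present when its SNR — peak weight
over SF divided by mean blank-condition power in the band — strictly
exceeds 3. Around this sit multitaper spectra (time–bandwidth 3, 5
Slepian tapers, 0.3–2.0 s window), SF-tuning metrics (cutoff SF = the
largest SF at half-maximum; selectivity = 1 − response(lowest
SF)/response(peak)), relative-depth laminar alignment with a
session-resampling bootstrap, spike–field coherence with trial-shuffle
controls, and an L1-regularized logistic edge/surface decoder
(60/15/25 split, λ from 20 log-spaced values in [0.001, 40]).

## Worked example

The analysis is organized as numbered drivers under `analysis/`, each a
thin script over package functions that prints what it finds and writes
tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1      # synthetic study data, seed 1
Rscript analysis/02_fit_spectra.R 1   # multitaper spectra + model fit
Rscript analysis/03_tuning.R 1        # cutoff SF and selectivity per band
Rscript analysis/04_laminar.R 1       # relative-depth peaks + bootstrap
Rscript analysis/05_decode.R 1        # edge/surface decoding
```

Step 2 fits the two-dimensional model to the simulated site and prints:

```
spectrum grid: 10 SFs x 171 frequencies
Two-dimensional gamma spectrum fit
  goodness of fit: 0.9928
  component SNR: LG=5.63, MG=5.97, HG=5.72
  components counted (SNR > 3): 3
goodness of fit 0.9928 with 3 components counted; wrote results/fit_site1.json
```

All three injected components are recovered (the generator scales them
to SNR 6) and the surface is explained almost perfectly. Step 3 then
quantifies their SF tuning:

```
 band cutoff_sf_cpd censored sf_selectivity peak_weight
   LG    0.70637074    FALSE      0.7896774    8.707011
   MG    0.32774275    FALSE      0.5644785    6.082248
   HG    0.09529028    FALSE      0.0000000    4.464275
```

LG prefers fine spatial detail (cutoff ≈ 0.7 cycles/degree, high
selectivity), HG is low-pass (cutoff ≈ 0.095 cpd, selectivity 0) and MG
sits between — the ordering that lets the three rhythms multiplex
different SF channels. Step 4 localizes them in depth (mean peak ReD
0.21 for LG, 0.40 for MG, 0.51 for HG — LG above the input layer, HG
inside it; bootstrap p(LG above MG) = 0 at 10000 draws) and step 5 shows
gamma power out-decodes MUA rates at every site count (single-site test
accuracy 82.0% vs 61.0% under the default effect sizes).

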