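# behavrec

Classify the effect of daily behaviors on health from multimodal
wearable-style time series, and derive corrective-behavior
recommendations — for researchers prototyping digital-health analytics
who need an end-to-end, fully seeded, dependency-light reference
pipeline.

One record is one subject: uniformly sampled series for several
behavioral categories (sleep, heart-rate variability, motion, activity,
blood markers). The pipeline:

1. **Multidomain feature bank** — Fourier components
   (literal 1-based `DFT_i = Σ_j x_j [cos(2πij/N_f) − i·sin(2πij/N_f)]`),
   cosine features, ramp-kernel windowed convolutions
   `Conv_i = Σ_a x_{i−a} · LReLU((m+2a)/2)`, Gabor filter energies over
   a 2-D signal embedding, and pairwise average/difference wavelet
   components — concatenated into a provenance-tagged Behavioral
   Feature Vector (BFV).
2. **Firefly feature selection** — candidate subsets scored by the
   brightness statistic `f_b = Σ_i (v_i − v̄)² / (N+1)` summed over
   selected feature columns; dim fireflies respawn, bright ones
   attract, and the final set is the union of members with
   `f_b > 2·f_th`, `f_th = L_r · mean(f_b)`.
3. **LSTM classifier** — standard gates
   `i, f, o = σ(xU + hW)`, `C' = tanh(xU_g + hW_g)`,
   `T_out = f⊙T_out_prev + i⊙C'`, `h_out = tanh(T_out)⊙o`, iterated on
   the selected features until `e = ‖ΔT_out‖∞ < 0.01`, with a softmax
   head `SoftMax(Σ f_i w_i + b)` and quantization into Low/Medium/High
   Effect (LE/ME/HE).
4. **Recommendation engine** — Pearson linkage map between categories,
   fuzzy c-means over the correlation values, automatic minimum support
   `Minsup = min(SD,VAR)/max(SD,VAR) · M_intra/M_inter`, Apriori
   frequent-itemset mining, and red (health-affecting) vs blue category
   flagging with per-subject templated suggestions.
5. **Metrics** — recommendation accuracy, precision, the model's
   printed recall (`tp/(tp+tn+fp+fn)`) alongside conventional recall
   (`tp/(tp+fn)`), both labelled, and mean delay.

A seeded synthetic-data generator plants spectral class structure and
cross-category correlations so every stage is testable offline; see the
vignette (`vignettes/behavioral-recommendation.Rmd`) for the model,
assumptions and design decisions.

## Worked example

```r
library(behavrec)

# 400 subjects, 3 classes encoded spectrally in the sleep channel,
# planted sleep~hrv correlation 0.9, noise sd 0.3
run <- run_pipeline(synth = synth_config(n_subjects = 400), n_test = 100, seed = 1)
print(run)
#> <behavrec_run>
#>   held-out accuracy: 0.980
#>   recommendation metrics: A=1.000 P=1.000 R_paper=0.400 R_standard=1.000 d=0.160s
#>   red: sleep, hrv
```

Reading the numbers: the classifier labels 98 of 100 held-out subjects
with the correct health-condition class; the recommender flags exactly
the two categories whose series actually depend on the class (`sleep`
carries the planted class frequency and `hrv` copies it through the
planted correlation), so recommendation accuracy and precision are 1.
`R_paper = 0.40` is the model's printed recall — true positives over
*all four* confusion counts (2 of 5 categories are planted) — while
conventional recall is 1; `d` is the wall-clock recommendation delay.

The same stages are available piecemeal — `generate_dataset()`,
`build_bfv()`, `ffo_select()`, `train_classifier()`, `fcm()`,
`apriori()` — and as a fitted-model interface:

```r
ds  <- generate_dataset(synth_config(n_subjects = 120), seed = 7)
fit <- behavrec(ds, seed = 7)       # extract -> select -> train
predict(fit, ds)[1:3, c("class", "effect_label")]
recommend(fit, ds)                  # linkage -> FCM -> Apriori -> red/blue
```

A thin command-line wrapper ships in `inst/cli/behavrec.R`
(`simulate`, `run`, `sweep` subcommands), and `sweep_ffo()` re-runs the
pipeline over firefly hyperparameter grids (population 10–50,
iterations 100–1000, learning rate 0.1–1.0).

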