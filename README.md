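# affectkit

Affective-state recognition from wearable physiological signals, as a
reusable R toolkit. Two complementary models form its core:

1. **Stress classification with transfer learning.** A 1D convolutional
   network — Conv1D(64, k=3) → BatchNorm → MaxPool → Dropout(0.4) →
   Conv1D(128, k=3) → BatchNorm → MaxPool → Dropout → GlobalAveragePooling →
   Dense(64) → softmax — classifies tabular HRV-style feature rows
   (consumed as a length-62, one-channel sequence) into baseline / stress /
   amusement. Its weights transfer to activity recognition by rebuilding
   the output head and fine-tuning at a reduced learning rate with balanced
   class weights `w_c = n / (k n_c)` and optional focal loss
   `-α_y (1 - p_y)^γ log p_y` against heavy class imbalance.
2. **Continuous emotion regression.** A Temporal Conformer — two 1D
   convolutions (32, 64 filters), a position-wise projection to d = 64, two
   transformer encoder blocks (4 heads, residual + layer norm + dropout),
   and a dense 3-output head — regresses normalized valence–arousal–
   dominance (VAD ∈ [0,1]³) from 33 features per 5-s ECG window
   (11 statistical + 12 Daubechies-4 wavelet + 10 STFT band powers), under
   Smooth-L1 (Huber) loss.

Both models run on a small, fully deterministic neural-network engine
written in base R (im2col convolutions, hand-derived backpropagation,
Adam, early stopping, reduce-on-plateau), with gradients verified against
finite differences in the test suite.

Around the models: EDF and MAT v5 (DREAMER-style nested container) readers
and writers, CSV feature tables, versioned single-file weight checkpoints,
z-score/split/window preprocessing, explainability (1D Grad-CAM, Integrated
Gradients, attention maps, exact t-SNE of pooled embeddings), rule-based
emotional-state diagnostics (six states, Fatigue Index `1 - arousal`,
Motion Quality `valence * dominance`, k-means profiling), and seeded
synthetic-data generators that emulate all three data sources so the whole
framework trains and tests with no external downloads.

## Worked example

Train the stress classifier on a synthetic separable table and read its
report:

```r
library(affectkit)

tab <- gen_stress_table(3000, effect_size = 3, seed = 7)
sp  <- stratified_split(tab, seed = 7)           # 70 / 15 / 15, stratified
zs  <- zscore_fit(sp$train$values)

fit <- train_classifier(build_cnn(62, 3, seed = 11),
                        zscore_apply(sp$train$values, zs), sp$train$labels,
                        zscore_apply(sp$val$values, zs),   sp$val$labels,
                        train_config(max_epochs = 15,
                                     class_weights = "balanced", seed = 11))
pred <- predict_classes(fit$model, zscore_apply(sp$test$values, zs))
mean(pred$labels == sp$test$labels)
#> [1] 0.98
```

0.98 is the held-out accuracy on the 450-row test part: with a 3-SD
class-mean separation the network recovers the planted structure almost
perfectly. The diagnostics stage turns predicted VAD triples into the
printed table format:

```r
vad <- rbind(c(0.56, 0.54, 0.38),   # valence, arousal, dominance
             c(0.93, 0.09, 0.38),
             c(0.09, 0.63, 0.04))
diagnose(vad, k = 3, display = TRUE)[, c("arousal", "valence", "dominance",
                                         "state", "fatigue_index",
                                         "motion_quality")]
#>   arousal valence dominance    state fatigue_index motion_quality
#> 1    0.54    0.56      0.38  Neutral          0.46           0.21
#> 2    0.09    0.93      0.38  Relaxed          0.91           0.35
#> 3    0.63    0.09      0.04 Stressed          0.37           0.00
```

Low-arousal/high-valence rows read as Relaxed, high-arousal/low-valence as
Stressed; the Fatigue Index is the arousal complement and Motion Quality
the valence-dominance product, rounded half away from zero for display.

A command-line wrapper over the same pipelines ships at
`inst/cli/affectkit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","affectkit.R",package="affectkit"))')" \
    simulate --what stress --n 3000 --effect-size 3 --seed 7 --out sim/
```

with subcommands `simulate`, `train-stress`, `finetune-activity`,
`train-vad`, `diagnose`, `evaluate`.

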