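# dualseq

Trial-level decoding of cognitive-operation sequences in dual-task EEG.

## The problem

In the psychological refractory period (PRP) paradigm, two speeded tasks are
presented with a stimulus-onset asynchrony (SOA) of either 300 ms (Short) or
1200 ms (Long). Averaged reaction times hide *how* the two tasks' latent
processing stages — Encoding (E), Central (C), Response (R) — interleave on
individual trials. `dualseq` reconstructs that interleaving trial by trial:

1. **Event decomposition.** Each task's epochs are decomposed into
   probabilistic onsets of K latent operations: every onset is marked by a
   brief half-sine multivariate event, and an EM algorithm jointly estimates
   per-event channel patterns `m_k` and gamma-distributed (shape 2) stage
   durations, with an exact forward–backward E-step over (event × time).
   The event width is tuned by stability of the estimated event count over
   20–60 ms, and the fit is restricted to Long-SOA trials, where the tasks
   do not overlap.
2. **Sequence labeling.** A causal spatiotemporal network (pointwise spatial
   mix → temporal dropout → causal convolutions at 12/36 ms → relative
   positional encoding → five causal state-space layers → task-specific
   softmax heads) is trained on the EM onset posteriors as soft labels with
   a KL loss (NAdam, jittered windows, early stopping on by-participant
   validation loss).
3. **Cross-condition embeddings.** Operation embeddings (mean latent vector
   over 13 samples around each predicted peak) are compared across SOA
   conditions by resampled mean pairwise cosine distances.
4. **Sequence posteriors.** Per-trial onsets are repeatedly sampled from the
   predicted probability traces (Task 2 shifted by the SOA), draws violating
   within-task order are rejected, and the retained draws — weighted by
   their predicted probability — yield a posterior over the six valid
   cross-task sequences A–F (plus INVALID).
5. **Behavior.** Sequence uncertainty is propagated into
   `RT ~ sequence + (1 | participant)` (and a logistic accuracy analog) by
   multiple imputation (100 draws) with Rubin's-rules pooling and
   Holm-adjusted pairwise contrasts.

A synthetic-data generator produces dual-task EEG with known onsets,
sequence strategies and behavioral effects, so the whole chain is validated
end to end. See the methods vignette
(`vignettes/dualseq-methods.Rmd`) for the models, assumptions and design
decisions.

## Worked example

```r
library(dualseq)

# the cross-task sequence taxonomy, by brute force
en <- enumerate_valid_sequences()
en$n_all      # 20 order-preserving interleavings
en$n_valid    # 6 that begin with E1 and end with R2
vapply(en$valid, paste, "", collapse = " -> ")
#>                                  A                                  B
#> "E1 -> C1 -> R1 -> E2 -> C2 -> R2" "E1 -> C1 -> E2 -> R1 -> C2 -> R2"
#>                                  C                                  D
#> "E1 -> E2 -> C1 -> R1 -> C2 -> R2" "E1 -> C1 -> E2 -> C2 -> R1 -> R2"
#>                                  E                                  F
#> "E1 -> E2 -> C1 -> C2 -> R1 -> R2" "E1 -> E2 -> C2 -> C1 -> R1 -> R2"

# classify one trial's onsets (ms on the Task 1 clock)
classify_sequence(c(E1 = 120, C1 = 260, E2 = 380, C2 = 470,
                    R1 = 610, R2 = 700))
#> [1] "D"

# Rubin's-rules pooling of multiply-imputed estimates
pool_rubin(c(1, 2, 3), c(1, 1, 1))[c("estimate", "u_within",
                                     "b_between", "t_total", "df")]
#>   estimate u_within b_between t_total    df
#> 1        2        1         1  2.3333 6.125
holm_adjust(c(0.01, 0.04, 0.03))
#> [1] 0.03 0.06 0.06

# a synthetic dual-task study with known ground truth
ds <- generate_dataset(sim_config(n_participants = 2,
                                  trials_per_condition = 6, seed = 3))
ds
#> <dualseq_dataset> 24 trials (2 participants), 32 channels @ 250 Hz
#>          label
#> condition  A  B  C
#>     Long  12  0  0
#>     Short  5  5  2
```

The full chain on a realistic problem size (minutes on one CPU):

```r
ds  <- generate_dataset(sim_config(n_participants = 6,
                                   trials_per_condition = 36, seed = 42))
res <- run_pipeline(ds, seed = 1)        # tune widths, fit, train, decode
res$decomp[[1]]$width_ms                 # tuned event width (ms)
res$decomp[[1]]$fit$k_events             # 3 events per task
res$similarity                           # cross-condition embedding stats
res$posteriors                           # per-trial sequence posteriors
res$pooled_rt                            # pooled RT effects vs sequence A
res$contrasts_rt                         # Holm-adjusted pairwise contrasts
```

On data of this size the decomposition recovers planted onsets with a
median error of a few milliseconds, the width-tuning profile plateaus at
three events per task, held-out model onset errors stay well under one
event width (50 ms), Short-condition posterior modes agree with the
planted strategy on roughly three quarters of trials, and Long-condition
trials decode to the serial sequence A essentially always.

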