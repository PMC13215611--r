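# End-to-end pipeline fixture: one moderate synthetic study, decomposed,
# trained and decoded once per test session and shared by the acceptance
# tests. The generator keeps the default study conditions; only the trial
# count is scaled for a desk-speed run. The event width and count come
# from the pipeline's own stability tuning over 20-60 ms.

pipeline_fixture <- function() {
  memo("pipeline_fixture", function() {
    ds <- generate_dataset(sim_config(n_participants = 6,
                                      trials_per_condition = 36,
                                      seed = 42))
    res <- run_pipeline(ds, seed = 1, tune = TRUE, tune_max_trials = 80,
                        k_max = 5, lr = 2e-3, max_epochs = 60,
                        finetune_epochs = 40, m_imputations = 40,
                        n_decode = 1000, n_iter_sim = 400,
                        n_samp_sim = 600)
    list(ds = ds, res = res)
  })
}

fixture_z <- function(fx, task) {
  mad_zscore(fx$ds[[paste0("task", task)]], fx$res$norm[[task]])
}
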