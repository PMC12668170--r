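# Shared fixtures. Everything is generated in code; the heavyweight trained
# model used by the end-to-end checks is built once per test run and
# memoized here.

noise_free_sim <- function(n_patients = 2, breaths = 100, asynchrony = 0,
                           artifact = 0, seed = 5) {
  sim_config(n_patients = n_patients, breaths_per_patient = breaths,
             asynchrony_fraction = asynchrony, artifact_fraction = artifact,
             noise_sd_flow = 0, noise_sd_pressure = 0,
             baseline_wander_amplitude = c(flow = 0, pressure = 0),
             seed = seed)
}

# Tiny architecture for fast unit tests of the network machinery.
tiny_model_config <- function() {
  model_config(depth = 2, base_filters = 3, kernel_size = 3,
               convs_per_block = 2, bottleneck_dilations = c(1, 2),
               dropout_bottleneck = 0, dropout_head = 0,
               input_len = 32, output_len = 16, channels_in = 2)
}

# The validation-scale experiment: a 13-patient cohort (~2,200 breaths,
# ~1,400 training windows) with flow noise sd 3 L/min, and a reduced
# (depth-3, 8-filter) U-Net trained at most 30 epochs. Memoized: training
# runs once and is shared by the end-to-end tests.
.fixture_env <- new.env(parent = emptyenv())
validation_experiment <- function() {
  if (is.null(.fixture_env$report)) {
    cfg <- experiment_config(
      sim = sim_config(n_patients = 13, breaths_per_patient = 170,
                       asynchrony_fraction = 0.3, artifact_fraction = 0.05,
                       noise_sd_flow = 3, seed = 101),
      model = model_config(depth = 3, base_filters = 8, kernel_size = 5,
                           bottleneck_dilations = c(1, 2),
                           dropout_bottleneck = 0.15, dropout_head = 0.1),
      train = train_config(max_epochs = 30, seed = 202),
      seed = 303)
    .fixture_env$report <- run_experiment(cfg)
  }
  .fixture_env$report
}

# A separate ~1,000-breath test cohort (5 patients x 200 breaths, same
# conditions as the validation experiment) with the trained model's
# segmentation of every record. Memoized alongside the experiment.
pva_testset <- function(model) {
  if (is.null(.fixture_env$pva_testset)) {
    cohort <- synth_cohort(sim_config(n_patients = 5, breaths_per_patient = 200,
                                      asynchrony_fraction = 0.3,
                                      artifact_fraction = 0.05,
                                      noise_sd_flow = 3, seed = 404))
    events <- lapply(cohort, function(r) predict_record(model, r)$events)
    .fixture_env$pva_testset <- list(records = cohort, events = events)
  }
  .fixture_env$pva_testset
}
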