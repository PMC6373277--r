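# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env()

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

tiny_cfg <- function(seed = 42, ...) {
  args <- list(n_families = 12, n_controls = 80, n_reference = 150,
               n_common_markers = 60, n_causal_markers = 15, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

tiny_cohort <- function() fixture("tiny_cohort", function() {
  simulate_cohort(tiny_cfg())
})

tiny_reference <- function() fixture("tiny_reference", function() {
  simulate_reference(tiny_cfg())
})

# a small trained risk model on the tiny cohort's training samples
tiny_model <- function() fixture("tiny_model", function() {
  co <- tiny_cohort()
  train <- common_genotypes(co, c("control_training", "case_training"))
  train_risk_model(train, rep(0:1, each = co$config$n_controls),
                   ntree = 150, seed = 7)
})
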