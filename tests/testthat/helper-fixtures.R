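# Shared fixtures, all generated in code.

# tiny deterministic record table for filter tests
make_filter_fixture <- function() {
  data.frame(
    participant_id = 1L,
    trial = 1:6,
    response = c("smile", "smile", "frown", "smile", NA, "frown"),
    rt_ms = c(600, 626, 700, 5100, NA, 4999),
    stringsAsFactors = FALSE
  )
}

# a 4-trial single-subject schedule for exhaustive likelihood checks
make_tiny_schedule <- function() {
  sch <- data.frame(
    participant_id = 1L,
    trial = 1:4,
    block = 1L,
    interactant = c(1L, 2L, 1L, 2L),
    target_expression = c("smile", "frown", "frown", "smile"),
    stringsAsFactors = FALSE
  )
  cmap <- contingency_map()
  sch$condition <- ifelse(contingency_rule(cmap, sch$interactant, sch$block) ==
                            "copy", "congruent", "incongruent")
  sch$correct_response <- correct_response(sch$interactant,
                                           sch$target_expression, sch$block,
                                           cmap)
  sch
}

# cache expensive fixtures across tests within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small clean rl_choices dataset (choices only, no artifacts)
small_rl_dataset <- function() {
  cached("small_rl", generate_dataset(
    generator_config(n_participants = 8L, p_fast_noncompliance = 0,
                     p_no_response = 0, seed = 301L),
    mode = "rl_choices", rts = FALSE))
}

# small rl fit shared by rl-fit tests
small_rl_fit <- function() {
  cached("small_rl_fit", suppressWarnings(fit_rl_hierarchical(
    small_rl_dataset()$records, rl_model_spec("copy_bias"),
    rl_sampler_config(chains = 2L, iter = 700L, warmup = 300L, seed = 42L))))
}
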