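# Shared fixtures, built lazily and cached for the whole test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

test_dims <- function() fixture("dims", function() model_dims())

test_gen <- function() {
  fixture("gen", function() {
    generate_synthetic_economy(test_dims(), seed = 42, noise_level = 0.05)
  })
}

# Full model with the study-size lookup simulation; shared by the CGE,
# scenario and acceptance tests.
test_model <- function() {
  fixture("model", function() {
    build_model(test_gen()$truth, seed = 42, lookup_n = 10000L)
  })
}

test_tax <- function() {
  fixture("tax", function() {
    elapsed <- system.time(
      sol <- find_tax_rate(test_model(), scenario_options(target = 0.5))
    )[["elapsed"]]
    sol$elapsed <- elapsed
    sol
  })
}

test_policy_run <- function() {
  fixture("policy_run", function() {
    suppressWarnings(run_scenario(test_model(), test_tax()$tax_rate))
  })
}

test_decomposition <- function() {
  fixture("decomposition", function() {
    suppressWarnings(decompose_pathways(test_model(), test_tax()$tax_rate))
  })
}

# A small fast model for structural tests that rebuild or re-run often.
small_model <- function() {
  fixture("small_model", function() {
    gen <- generate_synthetic_economy(test_dims(), seed = 7)
    build_model(gen$truth, seed = 7, lookup_n = 500L, horizon = 5L)
  })
}
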