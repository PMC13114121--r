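# Shared fixtures. Everything is generated in code; expensive objects are
# built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Tiny network configuration used by closed-form and gradient tests.
tiny_config <- function(...) {
  pvae_config(input_dim = 7, latent_dim = 8, hidden_dim = 6, prior_dim = 5,
              n_heads = 2, classifier_dims = c(5, 4), seed = 11, ...)
}

tiny_model <- function(cfg = tiny_config(), p_rows = 3) {
  set.seed(99)
  pvae_model(cfg, matrix(rnorm(p_rows * cfg$prior_dim), p_rows, cfg$prior_dim))
}

# Small separable cohort + a short cross-validated run reused across
# training/attribution tests (n = 120, M = 120, 30 epochs).
small_cv_bundle <- function() {
  fixture("small_cv", function() {
    spec <- synthetic_spec(n = 120, m = 120, k_inf = 12, delta = 2, pi0 = 0.6,
                           p_prior = 16, e_dim = 32, seed = 42)
    co <- generate_cohort(spec)
    prior <- generate_prior(spec)
    cfg <- pvae_config(latent_dim = 64, hidden_dim = 96, prior_dim = 32,
                       n_heads = 4, classifier_dims = c(32, 16))
    cv <- suppressMessages(run_cv(co$abundance, co$labels, prior, config = cfg,
                                  settings = pvae_train_settings(epochs = 30, seed = 42)))
    list(spec = spec, cohort = co, prior = prior, config = cfg, cv = cv)
  })
}

# A trained small model (single split) for IG completeness-style checks.
small_trained_model <- function() {
  fixture("small_model", function() {
    b <- small_cv_bundle()
    sc <- fit_scaler(b$cohort$abundance)
    ab <- apply_scaler(b$cohort$abundance, sc)
    m <- pvae_train(ab, b$cohort$labels, b$prior, b$config,
                    pvae_train_settings(epochs = 30, seed = 7))
    list(model = m, ab_std = ab, scaler = sc, labels = b$cohort$labels)
  })
}
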