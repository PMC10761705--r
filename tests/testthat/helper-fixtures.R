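# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small world/ensemble for fast unit tests
small_world <- function() cached("small_world", gen_world(12, 12, seed = 7))
small_ensemble <- function() {
  cached("small_ensemble",
         gen_esm_ensemble(small_world(), n_models = 2,
                          scenarios = c("ssp126", "ssp585"), seed = 8))
}
small_ctx <- function() {
  cached("small_ctx", suppressWarnings(
    build_pipeline(small_world(), small_ensemble(), n_sites = 200,
                   cv_config = list(eta = 0.1, max_depth = 3, nrounds = 300,
                                    nfold = 5),
                   seed = 9)))
}

# desk-scale world/ensemble at the sizes the calibration studies use
accept_world <- function() cached("accept_world", gen_world(20, 20, seed = 1))
accept_ensemble <- function() {
  cached("accept_ensemble", gen_esm_ensemble(accept_world(), n_models = 3,
                                             seed = 2))
}
accept_ctx <- function() {
  cached("accept_ctx", suppressWarnings(
    build_pipeline(accept_world(), accept_ensemble(), n_sites = 300,
                   site_noise = 0.1, seed = 3)))
}

# reference three-pool parameter set used across kinetics tests
ref_params <- function() pool_params(k = c(0.05, 4e-3, 8e-6),
                                     f = c(0.05, 0.42, 0.53))
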