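# Shared small fixtures, built once per test run. Everything is generated
# in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_config <- function() make_fixture("tiny_grid")

tiny_grid <- function() cached("tiny_grid", build_grid(tiny_config()$geometry))

tiny_absorption <- function() {
  cached("tiny_absorption", {
    cfg <- tiny_config()
    run_transport(tiny_grid(), make_synthetic_spectrum(), cfg$n_photons,
                  seed = 42)
  })
}

# uniform-medium helper for solver oracles: constant properties, no tissue
# structure
uniform_medium <- function(n = 100, k = 0.5, rhoc = 1200 * 3600) {
  list(n = n, k = matrix(k, n, n), rhoc = matrix(rhoc, n, n),
       alpha = k / rhoc)
}
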