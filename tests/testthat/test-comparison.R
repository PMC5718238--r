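# End-to-end driver, fixtures, report round trips, configuration file.

test_that("tiny fixture runs the full pipeline quickly and deterministically", {
  cfg <- tiny_config()
  t0 <- Sys.time()
  rep1 <- run_comparison(cfg)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_s3_class(rep1, "comparison_report")
  expect_equal(nrow(rep1$metrics$table), 4)
  expect_true(all(c("seed", "n_photons", "spectrum_sha1", "schema_version")
                  %in% names(rep1$provenance)))
  # same config + seed -> identical numeric content
  rep2 <- run_comparison(cfg)
  expect_identical(rep1$metrics$table, rep2$metrics$table)
  expect_identical(rep1$absorption$deposited, rep2$absorption$deposited)
  expect_identical(rep1$histories$SQUARE_PULSE$follicle_trace,
                   rep2$histories$SQUARE_PULSE$follicle_trace)
})

test_that("absorption is pulse-shape independent (transport runs once)", {
  # computing the transport separately per category with the same seed gives
  # the same grid each time, so a single transport serves all four trains
  grid <- tiny_grid()
  spec <- make_synthetic_spectrum()
  a1 <- run_transport(grid, spec, 1e4, seed = 3)
  a2 <- run_transport(grid, spec, 1e4, seed = 3)
  expect_identical(a1$deposited, a2$deposited)
})

test_that("single-category report has no excess matrix", {
  cfg <- tiny_config()
  cfg$categories <- "SQUARE_PULSE"
  rep <- run_comparison(cfg)
  expect_equal(nrow(rep$metrics$table), 1)
  expect_null(rep$metrics$excess_rise_pct)
})

test_that("fixture kinds behave as documented", {
  slab <- make_fixture("homogeneous_slab")
  g <- build_grid(slab$geometry)
  expect_false(any(g$class_map == "HAIR"))
  expect_true(all(g$class_map == "DERMIS"))
  nf <- make_fixture("no_follicle")
  expect_error(run_comparison(nf), "no HAIR cells")
})

test_that("reports round-trip through the on-disk format", {
  rep <- run_comparison(tiny_config())
  dir <- withr::local_tempdir()
  out <- file.path(dir, "does", "not", "exist", "yet")
  expect_message(write_report(rep, out), "created")
  body <- read_report(out)
  expect_equal(body$schema_version, 1L)
  expect_equal(body$peaks$peak_follicle, rep$metrics$table$peak_follicle)
  expect_equal(body$provenance$seed, rep$provenance$seed)
  # traces: one file per category, 1 + two probe columns
  tr <- read.table(file.path(out, "trace_square_pulse.tsv"), header = TRUE,
                   comment.char = "#")
  expect_equal(ncol(tr), 3)
  expect_equal(nrow(tr), length(rep$histories$SQUARE_PULSE$times))
  # absorption matrix round-trips through the array container
  arr <- read_grid_array(file.path(out, "absorption.tsv"))
  expect_equal(arr$data, rep$absorption$deposited, tolerance = 1e-10)
  expect_equal(arr$meta$seed, rep$absorption$rng_seed)
})

test_that("grid-array container preserves data and metadata", {
  m <- matrix(rnorm(30), 5, 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_array(m, path, meta = list(cell_size_m = 5e-6, origin = "test"))
  back <- read_grid_array(path)
  expect_equal(back$data, m, tolerance = 1e-14)
  expect_equal(back$meta$cell_size_m, 5e-6)
  expect_equal(back$meta$dim, c(5L, 6L))
})

test_that("run configuration round-trips through YAML", {
  cfg <- run_config(n_photons = 5e4, seed = 77, fluence = 12,
                    spectrum_cutoff_nm = 615,
                    geometry = geometry_config(domain_width = 1000e-6),
                    categories = c("SQUARE_PULSE", "FREE_DISCHARGE"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$seed, 77)
  expect_equal(cfg2$fluence, 12)
  expect_equal(cfg2$spectrum_cutoff_nm, 615)
  expect_equal(cfg2$geometry$domain_width, 1000e-6)
  expect_equal(cfg2$categories, c("SQUARE_PULSE", "FREE_DISCHARGE"))
  expect_equal(cfg2$optics$melanin_anchor_694, cfg$optics$melanin_anchor_694)
  # a partial file falls back to defaults
  writeLines("transport:\n  seed: 5\n  n_photons: 20000", path)
  cfg3 <- read_run_config(path)
  expect_equal(cfg3$seed, 5)
  expect_equal(cfg3$n_photons, 20000)
  expect_equal(cfg3$geometry$cell_size, 5e-6)
})

test_that("config validation", {
  expect_error(run_config(fluence = -1), "positive")
  expect_warning(run_config(n_photons = 100), "1e4")
})
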