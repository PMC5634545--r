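test_that("session write/read round-trips bit for bit and validates against the atlas", {
  atlas <- atlas_table(c("alpha", "beta", "gamma"))
  set.seed(11)
  ts <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, atlas$region_name))
  mt <- 2 * exp(-0.4 * (0:9)) + 1
  ses <- session_record("sub01", "ses01", ts, sampling_interval = 2,
                        movement_times = mt)
  tsf <- withr::local_tempfile(fileext = ".tsv")
  bf <- withr::local_tempfile(fileext = ".tsv")
  write_session(ses, tsf, bf)
  back <- read_session(tsf, bf, subject_id = "sub01", session_id = "ses01",
                       atlas = atlas)
  expect_identical(unname(back$timeseries), unname(ses$timeseries))
  expect_identical(back$movement_times, ses$movement_times)
  expect_equal(nrow(back$timeseries), 10L)
  expect_equal(ncol(back$timeseries), 3L)

  # header region absent from atlas -> error naming the region
  colnames(ts)[2] <- "delta"
  write_session(session_record("s", "s", ts), tsf)
  expect_error(read_session(tsf, atlas = atlas), "delta")

  # behavior omitted -> record without movement times
  back2 <- read_session(tsf)
  expect_null(back2$movement_times)
})

test_that("invalid sessions and atlases are rejected", {
  expect_error(session_record("s", "s", matrix(c(1, NA, 2, 3), 2, 2,
                                               dimnames = list(NULL, c("a", "b")))),
               "non-finite")
  expect_error(session_record("s", "s", matrix(1:4, 2, 2,
                                               dimnames = list(NULL, c("a", "b"))),
                              movement_times = c(1, -2, 3, 4)),
               "positive")
  expect_error(atlas_table(c("a", "a", "b")), "unique")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("region_id\tregion_name\n0\ta\n2\tb", f)
  expect_error(read_atlas(f), "contiguous")
})

test_that("atlas and config round-trip through their on-disk formats", {
  atlas <- atlas_table(c("L planum temporale", "R planum temporale", "L occipital pole"),
                       hemisphere = c("L", "R", "L"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(atlas, f)
  expect_equal(read_atlas(f), atlas)

  cfg <- study_config(cv_folds = 4L, cv_repeats = 2L, rng_seed = 99L,
                      lam_grid = c(0.5, 2), k_grid = c(3L, 6L))
  yf <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, yf)
  expect_equal(read_config(yf), cfg)
  expect_error(study_config(frequency_band = c(0.12, 0.06)), "frequency_band")
  expect_error(study_config(q_threshold = 0), "q_threshold")
})

test_that("biomarker reports round-trip and reference regions only via the atlas", {
  dual <- to_edge_dual(4L)
  atlas <- atlas_table(sprintf("area_%d", 1:4))
  cands <- list(
    structure(list(edges = c(1L, 2L), support = 5L, accuracy = 0.9,
                   p_value = 0.002, q_value = 0.01), class = "subgraph_candidate"),
    structure(list(edges = 4L, support = 3L, accuracy = 0.7,
                   p_value = 0.2, q_value = 0.4), class = "subgraph_candidate"))
  out <- withr::local_tempdir()
  write_biomarker_report(cands, atlas, out, dual = dual)
  back <- read_biomarker_report(file.path(out, "subgraphs.json"), dual)
  expect_equal(lapply(back, `[[`, "edges"), lapply(cands, `[[`, "edges"))
  expect_equal(vapply(back, `[[`, integer(1), "support"),
               vapply(cands, `[[`, integer(1), "support"))
  expect_equal(vapply(back, `[[`, numeric(1), "q_value"),
               vapply(cands, `[[`, numeric(1), "q_value"))
  txt <- readLines(file.path(out, "subgraphs.json"))
  expect_true(any(grepl("area_1 / area_2", txt)))

  # one single-edge candidate -> JSON array of length 1 with one edge
  write_biomarker_report(cands[2], atlas, out, dual = dual)
  expect_length(jsonlite::read_json(file.path(out, "subgraphs.json")), 1L)
  # a study-sized candidate list (21 subgraphs) -> JSON array of length 21
  many <- lapply(rep(1:6, length.out = 21), function(e)
    structure(list(edges = as.integer(e), support = 2L, accuracy = 0.8,
                   p_value = 0.01, q_value = 0.01),
              class = "subgraph_candidate"))
  write_biomarker_report(many, atlas, out, dual = dual)
  expect_length(jsonlite::read_json(file.path(out, "subgraphs.json")), 21L)
  # empty candidate list -> valid empty report
  write_biomarker_report(list(), atlas, out, dual = dual)
  expect_length(read_biomarker_report(file.path(out, "subgraphs.json"), dual), 0L)
})

test_that("run ledgers round-trip through JSON", {
  st <- small_study()
  dual <- to_edge_dual(8L)
  cfg <- study_config(cv_folds = 2L, cv_repeats = 1L, inner_folds = 2L,
                      lam_grid = 0.1, k_grid = c(2L, 4L), rng_seed = 5L)
  led <- run_repeated_cv(small_V(), st$labels, dual, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_run_ledger(led, f)
  expect_equal(read_run_ledger(f), led)
})
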