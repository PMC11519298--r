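fast_proto <- function() {
  protocol_preset("desk", strain_limit = 0.22, equil_steps = 2000)
}

test_that("a density-zero-only spec yields one reference run with unit normalizations", {
  spec <- sweep_spec(k1 = 8, rbreak = 31.72, n_age = 0, preset = "mini",
                     include_glucosepane = FALSE)
  res <- run_sweep(spec, protocol = fast_proto(), quiet = TRUE)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_age, 0)
  expect_equal(res$e_slide_norm, 1)
  expect_equal(res$e_stretch_norm, 1)
  expect_equal(res$status, "ok")
  expect_gt(attr(res, "wtc"), 0)
})

test_that("sweep caching: identical spec re-runs from cache, changed config recomputes", {
  dir <- withr::local_tempdir()
  spec <- sweep_spec(k1 = 6, rbreak = 25, n_age = c(0, 2), preset = "mini",
                     include_glucosepane = FALSE)
  res1 <- run_sweep(spec, out_dir = dir, protocol = fast_proto(),
                    quiet = TRUE)
  expect_true(file.exists(file.path(dir, "results.csv")))
  n_cache <- length(list.files(dir, pattern = "^mini_.*json$"))
  expect_equal(n_cache, nrow(res1))
  # resume: every cell is a cache hit
  msgs <- character(0)
  res2 <- withCallingHandlers(
    run_sweep(spec, out_dir = dir, protocol = fast_proto()),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  expect_equal(sum(grepl("cache hit", msgs)), nrow(res1))
  expect_equal(res2$sigma_peak, res1$sigma_peak)
  # any parameter change invalidates the key comparison: no cache hits
  msgs3 <- character(0)
  res3 <- withCallingHandlers(
    run_sweep(spec, out_dir = dir,
              protocol = protocol_preset("desk", strain_limit = 0.24,
                                         equil_steps = 2000)),
    message = function(m) {
      msgs3 <<- c(msgs3, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  expect_equal(sum(grepl("cache hit", msgs3)), 0L)
  expect_gt(max(res3$eps_peak, na.rm = TRUE), 0)
})

test_that("cross-link placements are shared across mechanical variants within a sweep", {
  m <- build_fibril(fibril_preset("mini"))
  a <- insert_age_crosslinks(m, crosslink_spec(2, seed = 4))
  b <- insert_age_crosslinks(m, crosslink_spec(2, seed = 4))
  expect_identical(a$bonds[a$bonds$type == "age", c("i", "j")],
                   b$bonds[b$bonds$type == "age", c("i", "j")])
})
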