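test_that("sampled parameters stay inside their design ranges", {
  spec <- sampling_spec(n_draws = 200, seed = 9)
  draws <- lapply(1:200, function(d) sample_parameters(spec, d))
  kms <- unlist(lapply(draws, `[[`, "km"))
  vms <- unlist(lapply(draws, function(b) b$vmax[-1]))
  expect_true(all(kms >= 0.5 & kms <= 2))
  expect_true(all(vms >= 0.6 & vms <= 1))
  expect_true(all(vapply(draws, function(b) b$vmax[["v1"]], 1) == 0.5))
  kas <- vapply(draws, `[[`, 1, "ka")
  kis <- vapply(draws, `[[`, 1, "ki")
  expect_true(all(kas >= 0.01 & kas <= 1 & kis >= 0.01 & kis <= 1))
  ns <- vapply(draws, function(b) unname(b$hill_n), 1)
  expect_true(all(ns >= 1e-6 & ns <= 4))
})

test_that("the sampled Km distribution centres on the interval midpoint", {
  spec <- sampling_spec(n_draws = 10000, seed = 2)
  kms <- unlist(lapply(1:10000, function(d) sample_parameters(spec, d)$km))
  expect_gt(mean(kms), 1.2)
  expect_lt(mean(kms), 1.3)
})

test_that("draws are deterministic and independent of ensemble size", {
  s1 <- sampling_spec(n_draws = 5, seed = 4)
  s2 <- sampling_spec(n_draws = 50, seed = 4)
  d1 <- sample_parameters(s1, 3)
  d2 <- sample_parameters(s2, 3)
  d1$draw <- d2$draw <- NULL
  expect_identical(d1, d2)
  expect_identical(sample_parameters(s1, 3), sample_parameters(s1, 3))
  expect_false(identical(sample_parameters(s1, 3)$km,
                         sample_parameters(s1, 4)$km))
})

test_that("invalid sampling ranges are rejected", {
  expect_error(sampling_spec(km_nonphos_range = c(2, 0.5)),
               class = "phosflux_config_error")
  expect_error(sampling_spec(n_draws = 0), class = "phosflux_config_error")
})

test_that("the smallest ensemble yields one finite summary row", {
  ens <- run_ensemble(sampling_spec(n_draws = 1, seed = 5),
                      variants = "WT", n_grid = 201, horizon = 100)
  s <- tidy(ens)
  expect_identical(nrow(s), 1L)
  expect_identical(s$status, "ok")
  expect_true(all(is.finite(unlist(s[, 3:8]))))
  expect_true(all(unlist(s[, 3:8]) >= 0))
})

test_that("ensembles rerun bit-identically under the same seed", {
  spec <- sampling_spec(n_draws = 4, seed = 11)
  e1 <- run_ensemble(spec, variants = c("WT", "M1"), n_grid = 201,
                     horizon = 100)
  e2 <- run_ensemble(spec, variants = c("WT", "M1"), n_grid = 201,
                     horizon = 100)
  expect_identical(tidy(e1), tidy(e2))
  expect_identical(nrow(tidy(e1)), 8L)
})

test_that("variants share base draws: identical ratios give identical outcomes", {
  ratios <- default_ratio_table()
  wt_rows <- ratios[ratios$variant == "WT", ]
  cloned <- dplyr::bind_rows(
    wt_rows,
    dplyr::mutate(wt_rows, variant = "cloneA"),
    dplyr::mutate(wt_rows, variant = "cloneB"))
  ens <- run_ensemble(sampling_spec(n_draws = 6, seed = 8),
                      variants = c("WT", "cloneA", "cloneB"),
                      ratios = cloned, n_grid = 201, horizon = 100)
  s <- tidy(ens)
  by_draw <- split(s$final_product, s$draw)
  for (fp in by_draw) expect_equal(max(fp) - min(fp), 0)
  cmp <- compare_variants(ens, reference = "WT")
  expect_equal(cmp$win_fraction, rep(0.5, 3))
  expect_equal(cmp$median_paired_diff, rep(0, 3))
})

test_that("comparison requires the reference and orders variants as given", {
  ens <- run_ensemble(sampling_spec(n_draws = 2, seed = 3),
                      variants = c("WT", "M3"), n_grid = 201, horizon = 100)
  expect_error(compare_variants(ens, reference = "M9"),
               class = "phosflux_config_error")
  cmp <- compare_variants(ens)
  expect_identical(cmp$variant, c("WT", "M3"))
  expect_identical(glance(ens)$n_failed, 0L)
})

test_that("unresolvable variants are rejected before any simulation", {
  expect_error(
    run_ensemble(sampling_spec(n_draws = 1), variants = c("WT", "M4")),
    class = "phosflux_config_error")
})
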