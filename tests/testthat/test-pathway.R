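test_that("core rates follow the substrate mapping", {
  p <- make_params(vmax = c(v1 = 0.5))
  v0 <- core_rates(zero_state, p)
  expect_equal(v0[["v1"]], 0.5)
  expect_equal(unname(v0[paste0("v", 2:12)]), rep(0, 11))
  # half-saturation of the isomerase step: x2 = Km3
  s <- zero_state; s["x2"] <- 1
  expect_equal(core_rates(s, p)[["v3"]], p$vmax[["v3"]] / 2)
  # and of the fructose kinase step: x5 = Km12
  s <- zero_state; s["x5"] <- 1
  expect_equal(core_rates(s, p)[["v12"]], p$vmax[["v12"]] / 2)
  expect_error(core_rates(c(-1, rep(0, 7)), p),
               class = "phosflux_invalid_state")
})

test_that("v10 draws on GlcN6P by default and on GlcNAc in literal mode", {
  s <- zero_state; s["x4"] <- 1; s["x8"] <- 3
  p4 <- make_params()
  p8 <- make_params(v10_substrate = "x8")
  expect_equal(core_rates(s, p4)[["v10"]], 0.8 * 1 / 2)
  expect_equal(core_rates(s, p8)[["v10"]], 0.8 * 3 / 4)
})

test_that("regulated rates: biosensor induction and uptake inhibition", {
  p <- make_params(p = c(v5 = 0.3, v6 = 0.3, v7 = 0.3, v11 = 0.3))
  # no inducer: activation term vanishes, only basal expression remains
  s <- zero_state; s["x2"] <- 1  # x2 = Km5
  expect_equal(regulated_rates(s, p)[["v5"]], 0.3 / 2)
  # phosphosugar pool at Ki gives half-maximal uptake for any n_t > 0
  for (nt in c(0.5, 1, 3)) {
    pn <- make_params(transport_n = nt, vmax = c(v1 = 0.5))
    s <- zero_state; s["x2"] <- 0.25; s["x3"] <- 0.25
    expect_equal(regulated_rates(s, pn)[["v1"]], 0.25)
  }
  # saturating inducer: prefactor approaches p + vmax
  for (n in c(1, 2, 4)) {
    pn <- make_params(hill_n = n, ka = 0.3,
                      p = c(v5 = 0.2, v6 = 0, v7 = 0, v11 = 0))
    s <- zero_state; s["x2"] <- 1; s["x7"] <- 1e6 * 0.3
    v5 <- regulated_rates(s, pn)[["v5"]]
    expect_equal(v5, (0.2 + pn$vmax[["v5"]]) * 1 / 2, tolerance = 1e-4)
  }
})

test_that("regulation is monotone: activating in x7, inhibiting in the pool", {
  withr::with_seed(7, {
    for (i in 1:10) {
      p <- make_params(hill_n = runif(1, 0.1, 4), ka = runif(1, 0.05, 1),
                       ki = runif(1, 0.05, 1),
                       transport_n = runif(1, 0.1, 4),
                       p = c(v5 = 0.4, v6 = 0.4, v7 = 0.4, v11 = 0.4))
      x7s <- seq(0, 3, length.out = 25)
      v5 <- vapply(x7s, function(x7) {
        s <- zero_state; s["x2"] <- 1; s["x7"] <- x7
        regulated_rates(s, p)[["v5"]] # fixed substrate, rising inducer
      }, numeric(1))
      # v5 shares substrate x2 but responds to x7 only via the prefactor
      expect_true(all(diff(v5) >= -1e-12))
      v1 <- vapply(seq(0, 3, length.out = 25), function(pool) {
        s <- zero_state; s["x3"] <- pool
        regulated_rates(s, p)[["v1"]]
      }, numeric(1))
      expect_true(all(diff(v1) <= 1e-12))
    }
  })
})

test_that("zero Hill exponents reduce regulated to core rates with constant prefactors", {
  p0 <- make_params(hill_n = 0, transport_n = 0,
                    p = c(v5 = 0.3, v6 = 0.2, v7 = 0.1, v11 = 0.4))
  # equivalent unregulated model: vmax_r -> p_r + vmax_r / 2, v1 -> v1max / 2
  veq <- stats::setNames(rep(0.8, 12), paste0("v", 1:12))
  veq["v1"] <- 0.8 / 2
  veq[c("v5", "v6", "v7", "v11")] <-
    c(0.3, 0.2, 0.1, 0.4) + 0.8 / 2
  peq <- make_params(vmax = veq)
  withr::with_seed(13, {
    for (i in 1:10) {
      s <- random_state()
      expect_equal(regulated_rates(s, p0), core_rates(s, peq),
                   tolerance = 1e-12)
    }
  })
})

test_that("mass balances conserve everything except uptake", {
  v <- stats::setNames(rep(0, 12), paste0("v", 1:12))
  v["v1"] <- 1
  dx <- mass_balance(v)
  expect_equal(dx[["x1"]], 1)
  expect_equal(sum(abs(dx[paste0("x", 2:8)])), 0)
  v2 <- stats::setNames(rep(0, 12), paste0("v", 1:12))
  v2["v2"] <- 1
  dx2 <- mass_balance(v2)
  expect_equal(unname(dx2[c("x1", "x2")]), c(-1, 1))
  withr::with_seed(5, {
    for (i in 1:20) {
      vr <- stats::setNames(runif(12), paste0("v", 1:12))
      expect_equal(sum(mass_balance(vr)), vr[["v1"]])
    }
  })
  expect_error(mass_balance(c(v[1:11], NA)), class = "phosflux_invalid_state")
})

test_that("pure uptake accumulates linearly and the product needs its reaction", {
  # everything off but uptake at 0.5: x1(10) = 5
  p <- make_params(vmax_val = 0, vmax = c(v1 = 0.5))
  tr <- simulate_pathway(p, horizon = 10, n_grid = 101)
  expect_equal(unname(tr$states[101, "x1"]), 5, tolerance = 1e-6)
  expect_equal(sum(tr$states[101, paste0("x", 2:8)]), 0)
  # no GlcNAc without its phosphatase step
  p2 <- make_params(vmax = c(v11 = 0))  # p defaults to zero
  tr2 <- simulate_pathway(p2, horizon = 50, n_grid = 201)
  expect_equal(max(tr2$states[, "x8"]), 0)
})

test_that("trajectories satisfy the source-balance identity and stay non-negative", {
  spec <- sampling_spec(n_draws = 3, seed = 7)
  ratios <- default_ratio_table()
  for (d in 1:3) {
    base <- sample_parameters(spec, d)
    params <- build_variant_params(ratios, base, "WT")
    tr <- simulate_pathway(params, horizon = 200)
    expect_lt(flux_balance_error(tr), 1e-4)
    expect_gte(min(tr$states), 0)
  }
})

test_that("without the GlcNAc6P phosphatase, x7 rises whenever v10 exceeds v8", {
  base <- sample_parameters(sampling_spec(n_draws = 1, seed = 3), 1)
  params <- build_variant_params(default_ratio_table(), base, "WT")
  params$vmax[["v11"]] <- 0
  params$p[["v11"]] <- 0
  tr <- simulate_pathway(params, horizon = 100, n_grid = 401)
  growing <- tr$rates[, "v10"] > tr$rates[, "v8"]
  idx <- which(growing[-length(growing)] & growing[-1])
  expect_true(all(diff(tr$states[, "x7"])[idx] >= -1e-8))
})

test_that("variant parameters scale from the measured ratio table", {
  base <- list(
    vmax = c(v1 = 0.5, v2 = 0.8, v3 = 0.8, v4 = 0.8, v8 = 0.8, v9 = 0.8,
             v10 = 0.8, v12 = 0.8),
    km = c(Km2 = 1, Km3 = 1, Km4 = 1, Km8 = 1, Km9 = 1, Km10 = 1, Km12 = 1),
    km_wt_glc6p = 1.3, hill_n = 2, ka = 0.5, ki = 0.5, transport_n = 2)
  ratios <- default_ratio_table()
  wt <- build_variant_params(ratios, base, "WT")
  expect_equal(wt$vmax[["v5"]], 0.5)  # the anchored wild-type Glc6P reaction
  expect_equal(wt$km[["Km5"]], 1.3)
  expect_equal(wt$vmax[["v11"]], 0.5 * 13.28 / 30.98)
  # doubling a vmax ratio doubles the reaction's ceiling
  r2 <- ratios
  r2$vmax_ratio[r2$variant == "WT" & r2$substrate == "GlcNAc6P"] <- 2
  expect_equal(build_variant_params(r2, base, "WT")$vmax[["v11"]], 1)
  # basal expression follows the variant-scaled vmax
  expect_equal(wt$p[["v5"]], wt$vmax[["v5"]])
  expect_equal(build_variant_params(ratios, base, "WT",
                                    basal_mult = 0.5)$p[["v5"]], 0.25)
})

test_that("variants with unmeasured substrates need an explicit imputation policy", {
  base <- sample_parameters(sampling_spec(n_draws = 1, seed = 1), 1)
  err <- expect_error(
    build_variant_params(default_ratio_table(), base, "M4"),
    class = "phosflux_config_error")
  expect_match(conditionMessage(err), "(M4, Fru6P)", fixed = TRUE)
  expect_match(conditionMessage(err), "(M4, GlcN6P)", fixed = TRUE)
  imputed <- default_ratio_table(impute = c(M4 = "M3"))
  p <- build_variant_params(imputed, base, "M4")
  expect_equal(p$vmax[["v6"]], 0.5 * 1.47 / 30.98)  # inherited from M3
  expect_identical(
    sort(unique(imputed$provenance[imputed$variant == "M4"])),
    c("imputed", "measured"))
})

test_that("parameter validation catches out-of-range regulation constants", {
  expect_error(make_params(hill_n = 5), class = "phosflux_config_error")
  expect_error(make_params(ka = 0), class = "phosflux_config_error")
  expect_error(make_params(ki = 1.5), class = "phosflux_config_error")
  expect_error(make_params(km_val = 0), class = "phosflux_config_error")
})
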