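test_that("treatment specs validate their inputs", {
  expect_error(ad_treatment("aspirin", 1), "etanercept")
  expect_error(ad_treatment("etanercept", -1), "nonnegative")
  expect_error(ad_treatment("mtc", 2), "multiplier")
  expect_error(ad_treatment("etanercept", 1, start_day = -5), "nonnegative")
  spec <- ad_treatment("etanercept", 10)
  expect_s3_class(spec, "ad_treatment")
  expect_equal(spec$start_day, 300)
})

test_that("standard parameterisation maps folds onto the drug channels", {
  p <- ad_parameters()
  ch <- alzsim:::.treatment_channels(list(ad_treatment("etanercept", 10)), 400, p)
  expect_equal(ch$f, 10 * 55.45)  # 554.5/day
  ch <- alzsim:::.treatment_channels(list(ad_treatment("tgf_beta", 10)), 400, p)
  expect_equal(ch$g, 10 * p$d_Tb * p$K_Tb)
  ch <- alzsim:::.treatment_channels(list(ad_treatment("aducanumab", 5),
                                          ad_treatment("bindarit", 10),
                                          ad_treatment("mtc", 0.1)), 400, p)
  expect_equal(ch$h, 5)
  expect_equal(ch$k, 10)
  expect_equal(ch$tau_factor, 0.1)
  # inactive before the start day
  ch <- alzsim:::.treatment_channels(list(ad_treatment("etanercept", 10)), 100, p)
  expect_equal(ch$f, 0)
})

test_that("derivatives are unchanged before start day and modified after", {
  y <- random_state(3)
  trt <- list(ad_treatment("etanercept", 10), ad_treatment("aducanumab", 5))
  expect_identical(ad_derivatives(100, y, treatment = trt),
                   ad_derivatives(100, y))
  d_trt <- ad_derivatives(400, y, treatment = trt)
  d_un <- ad_derivatives(400, y)
  expect_lt(d_trt[["Ta"]], d_un[["Ta"]])
  expect_lt(d_trt[["Abo"]], d_un[["Abo"]])
  # only the targeted equations change
  unchanged <- setdiff(species_names, c("Ta", "Abo"))
  expect_identical(d_trt[unchanged], d_un[unchanged])
})

test_that("apply_treatment reproduces the treated right-hand side, composing drugs", {
  p <- ad_parameters()
  for (s in 1:4) {
    y <- random_state(s)
    trt <- list(ad_treatment("etanercept", 7), ad_treatment("aducanumab", 3),
                ad_treatment("bindarit", 2), ad_treatment("tgf_beta", 5),
                ad_treatment("mtc", 0.2))
    base <- ad_derivatives(500, y, p)
    expect_equal(apply_treatment(trt, 500, base, y, p),
                 ad_derivatives(500, y, p, treatment = trt), tolerance = 1e-12)
    expect_identical(apply_treatment(NULL, 500, base, y, p), base)
  }
})

test_that("TNF-alpha inhibitor at 10-fold reduces the steady level elevenfold", {
  # linear balance of the TNF-alpha equation at fixed macrophage densities:
  # Ta* = (lam_M1 M1 + lam_Mh1 Mh1) / (d_Ta + f); f = 10 d_Ta gives 1/11
  p <- ad_parameters()
  y <- random_state(8)
  ta_star_untreated <- (p$lambda_TaM1 * y[["M1"]] + p$lambda_TaMh1 * y[["Mh1"]]) / p$d_Ta
  y_t <- y; y_t["Ta"] <- ta_star_untreated / 11
  d <- ad_derivatives(400, y_t, p, treatment = ad_treatment("etanercept", 10))
  expect_lt(abs(d[["Ta"]]), 1e-16)
})

test_that("zero-dose treatment reproduces the untreated trajectory bit for bit", {
  tt <- seq(0, 800, by = 50)
  treated <- simulate_ad(treatment = ad_treatment("etanercept", 0),
                         horizon = 800, times = tt)
  untreated <- simulate_ad(horizon = 800, times = tt, restart_at = 300)
  expect_identical(traj_values(treated), traj_values(untreated))
})

test_that("treatment leaves the pre-treatment window untouched", {
  tt <- seq(0, 600, by = 25)
  treated <- simulate_ad(treatment = ad_treatment("etanercept", 10),
                         horizon = 600, times = tt)
  untreated <- simulate_ad(horizon = 600, times = tt, restart_at = 300)
  pre <- tt < 300
  expect_identical(lapply(traj_values(treated), `[`, pre),
                   lapply(traj_values(untreated), `[`, pre))
  expect_false(identical(treated$Ta[!pre], untreated$Ta[!pre]))
})

test_that("dose-response directions: f lowers TNF-alpha, h lowers amyloid, mtc lowers tau", {
  endpoint <- function(trt) {
    traj <- simulate_ad(treatment = trt, times = c(0, 300, 3650),
                        restart_at = 300)
    traj[nrow(traj), ]
  }
  base <- endpoint(NULL)
  ta_ends <- vapply(c(2, 10, 50), function(f) {
    endpoint(ad_treatment("etanercept", f))$Ta
  }, numeric(1))
  expect_true(all(diff(c(base$Ta, ta_ends)) < 0))
  abo_ends <- vapply(c(2, 10), function(h) {
    endpoint(ad_treatment("aducanumab", h))$Abo
  }, numeric(1))
  expect_true(all(diff(c(base$Abo, abo_ends)) < 0))
  # tau-aggregation inhibitor lowers tau and intracellular NFT
  mtc <- endpoint(ad_treatment("mtc", 0.1))
  expect_lt(mtc$tau, base$tau)
  expect_lt(mtc$Fi, base$Fi)
  # MCP-1 inhibitor lowers MCP-1 and the macrophage load
  bin <- endpoint(ad_treatment("bindarit", 10))
  expect_lt(bin$P, base$P)
  expect_lt(bin$Mh1, base$Mh1)
})
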