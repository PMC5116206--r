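test_that("ROS forcing ramps linearly for 100 days, then holds its amplitude", {
  expect_equal(ros_forcing(0, 6), 0)
  expect_equal(ros_forcing(50, 6), 3)
  expect_equal(ros_forcing(100, 6), 6)
  expect_equal(ros_forcing(200, 6), 6)
  expect_equal(ros_forcing(c(25, 1000), 4), c(1, 4))
  expect_error(ros_forcing(-1), "nonnegative")
})

test_that("initial state matches the prescribed disease-stage values", {
  y <- ad_initial_state()
  expect_equal(y[["Abi"]], 1e-6)
  expect_equal(y[["N"]], 0.14)
  expect_equal(y[["A"]], 0.14)
  expect_equal(y[["M1"]], 0.02)
  expect_equal(y[["M2"]], 0.02)
  expect_equal(unname(y[c("Mh1", "Mh2", "Nd")]), c(0, 0, 0))
  expect_equal(y[["P"]], 5e-9)
  expect_equal(y[["tau"]], 1.37e-10)
  expect_length(y, 18)
  expect_error(ad_initial_state(XX = 1), "unknown species")
})

test_that("phenotype fractions follow the weighted saturation split", {
  p <- ad_parameters()
  # both signals at half-saturation: fractions beta/(beta+1), 1/(beta+1)
  fr <- phenotype_fractions(p$K_Ta, p$K_I10, p)
  expect_equal(fr$pro, 10 / 11)
  expect_equal(fr$anti, 1 / 11)
  # pure proinflammatory limit
  fr <- phenotype_fractions(1e3, 0, p)
  expect_equal(fr$pro, 1)
  expect_equal(fr$anti, 0)
  # no signal at all: no activation cue
  fr <- phenotype_fractions(0, 0, p)
  expect_equal(unlist(fr), c(pro = 0, anti = 0))
  # hand evaluation at the initial state: e1 = 1/3, e2 = 4/5
  fr <- phenotype_fractions(2e-5, 1e-5, p)
  expect_equal(fr$pro, 25 / 31)
  expect_equal(fr$anti, 6 / 31)
  # fractions always sum to 1 when any signal is present
  set.seed(42)
  Ta <- stats::runif(50, 0, 1e-3)
  I10 <- stats::runif(50, 0, 1e-4)
  fr <- phenotype_fractions(Ta, I10, p)
  expect_equal(fr$pro + fr$anti, rep(1, 50))
})

test_that("neuronal death rate vanishes without neurons or without drivers", {
  y <- ad_initial_state()
  y0 <- y; y0["N"] <- 0
  expect_equal(neuronal_death_rate(y0), 0)
  y0 <- y; y0["Fi"] <- 0; y0["Ta"] <- 0
  expect_equal(neuronal_death_rate(y0), 0)
  # hand evaluation at the initial state:
  # 3.4e-4 * 1/2 * 0.14  +  1.7e-4 * 1/3 * 1/5 * 0.14
  expect_equal(neuronal_death_rate(y), 2.38e-5 + 1.586667e-6, tolerance = 1e-6)
})

test_that("derivative identities: tau steady state, neuron loss, dead-neuron balance", {
  p0 <- ad_parameters(R_0 = 0)  # no forcing
  y <- ad_initial_state(tau = ad_parameters()$lambda_tau0 / ad_parameters()$d_tau)
  d <- ad_derivatives(200, y, p0)
  expect_equal(d[["tau"]], 0, tolerance = 1e-24)
  # N can only decline, for any admissible state
  for (s in 1:5) {
    y <- random_state(s)
    d <- ad_derivatives(500, y)
    expect_lte(d[["N"]], 0)
    # neuron loss reappears as dead-neuron production: with clearance turned
    # off, dN/dt + dNd/dt = 0 identically
    d2 <- ad_derivatives(500, y, ad_parameters(d_NdM = 1e-300, d_NdMh = 1e-300))
    expect_equal(d2[["N"]] + d2[["Nd"]], 0, tolerance = 1e-20)
    # and the production term equals the analytic death rate
    expect_equal(-d[["N"]], neuronal_death_rate(y), tolerance = 1e-12)
  }
  expect_error(ad_derivatives(0, ad_initial_state() - 1e-3), "negative")
})

test_that("with production silenced every species decays at its linear rate", {
  lam <- grep("^lambda_", names(ad_parameters()), value = TRUE)
  zeros <- stats::setNames(as.list(rep(0, length(lam))), lam)
  p <- do.call(ad_parameters, c(zeros, list(
    R_0 = 1e-300, d_NF = 1e-300, d_NT = 1e-300,
    d_AboM = 1e-300, d_AboMh = 1e-300, d_NdM = 1e-300, d_NdMh = 1e-300,
    alpha = 1e-300)))
  y0 <- ad_initial_state(Nd = 1e-5, Mh1 = 0.01, Mh2 = 0.01, AO = 1e-7)
  rates <- c(Abi = p$d_Abi, tau = p$d_tau, Fi = p$d_Fi, Fo = p$d_Fo,
             A = p$d_A, AO = p$d_AO, H = p$d_H, M1 = p$d_M1, M2 = p$d_M2,
             Mh1 = p$d_Mh1, Mh2 = p$d_Mh2, Tb = p$d_Tb, I10 = p$d_I10,
             Ta = p$d_Ta, P = p$d_P)
  for (tt in c(0.01, 100)) {
    traj <- simulate_ad(params = p, state = y0, horizon = tt, times = c(0, tt))
    fin <- traj[nrow(traj), ]
    for (sp in names(rates)) {
      expected <- y0[[sp]] * exp(-rates[[sp]] * tt)
      if (expected > 1e-10) {
        expect_equal(fin[[sp]], expected, tolerance = 1e-4,
                     label = paste0(sp, "(t=", tt, ")"))
      }
    }
    # N frozen, and pools whose only sinks are phagocytic stay put
    expect_equal(fin$N, y0[["N"]], tolerance = 1e-8)
    expect_equal(fin$Abo, y0[["Abo"]], tolerance = 1e-6)
    expect_equal(fin$Nd, y0[["Nd"]], tolerance = 1e-6)
  }
})

test_that("baseline ten-year run stays nonnegative with monotone neuron loss", {
  traj <- baseline_trajectory()
  vals <- as.matrix(traj[, species_names])
  expect_true(all(vals >= 0))
  expect_true(all(diff(traj$N) <= 0))
  expect_true(all(diff(traj$time) > 0))
})

test_that("cumulative neuron loss equals the integrated death rate", {
  traj <- baseline_trajectory()
  rate <- vapply(seq_len(nrow(traj)), function(i) {
    neuronal_death_rate(unlist(traj[i, species_names]))
  }, numeric(1))
  dt <- diff(traj$time)
  integral <- sum((rate[-1] + rate[-length(rate)]) / 2 * dt)
  loss <- traj$N[1] - traj$N[nrow(traj)]
  expect_equal(integral, loss, tolerance = 1e-3)
})

test_that("trajectory tidiers expose long format and endpoint summaries", {
  traj <- baseline_trajectory()
  long <- tidy(traj)
  expect_setequal(unique(long$species), species_names)
  expect_equal(nrow(long), nrow(traj) * 18)
  expect_true(all(c("units", "description") %in% names(long)))
  g <- glance(traj)
  expect_equal(g$horizon_days, 3650)
  expect_equal(g$neuron_loss, 1 - traj$N[nrow(traj)] / 0.14)
})
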