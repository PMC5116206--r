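# Coordinates of cell centres for building analytic test fields.
grid_xy <- function(grid) {
  x <- (seq_len(grid$n) - 0.5) * grid$dx
  list(X = matrix(x, grid$n, grid$n), Y = matrix(x, grid$n, grid$n, byrow = TRUE))
}

test_that("periodic Laplacian: constants, eigenmodes, discrete conservation", {
  g <- ad_grid(16)
  xy <- grid_xy(g)
  expect_equal(laplacian_periodic(matrix(3.7, g$n, g$n), g),
               matrix(0, g$n, g$n))
  # sin(2*pi*x) is an eigenfunction; eigenvalue -> -(2*pi)^2 as dx -> 0
  f16 <- sin(2 * pi * xy$X)
  err16 <- max(abs(laplacian_periodic(f16, g) - (-(2 * pi)^2) * f16))
  expect_lt(err16, (2 * pi)^2 * (2 * pi * g$dx)^2)  # O(dx^2) bound
  g32 <- ad_grid(32)
  xy32 <- grid_xy(g32)
  f32 <- sin(2 * pi * xy32$X)
  err32 <- max(abs(laplacian_periodic(f32, g32) - (-(2 * pi)^2) * f32))
  expect_lt(err32, err16 / 3.5)  # second-order convergence
  # domain sum zero to machine precision
  set.seed(11)
  r <- matrix(stats::runif(g$n^2), g$n, g$n)
  expect_lt(abs(sum(laplacian_periodic(r, g))), 1e-9 * sum(abs(r)) / g$dx^2)
  expect_error(laplacian_periodic(matrix(0, 4, 4), g), "matrix")
})

test_that("chemotaxis flux: no taxis without gradient, exact mass conservation", {
  g <- ad_grid(16)
  set.seed(12)
  cells <- matrix(stats::runif(g$n^2, 1, 2), g$n, g$n)
  expect_equal(chemotaxis_divergence(cells, matrix(5, g$n, g$n), g),
               matrix(0, g$n, g$n))
  attr_field <- matrix(stats::runif(g$n^2), g$n, g$n)
  div <- chemotaxis_divergence(cells, attr_field, g)
  expect_lt(abs(sum(div)), 1e-10 * sum(abs(div)))
  expect_error(chemotaxis_divergence(cells[1:4, 1:4], attr_field, g), "matrix")
})

test_that("chemotaxis flux converges to the analytic divergence on smooth fields", {
  # C = 2 + sin(2 pi x) cos(2 pi y), A = cos(2 pi x):
  # div(C grad A) = d/dx(C * -2 pi sin(2 pi x))
  analytic <- function(X, Y) {
    -(2 * pi)^2 * (2 + sin(2 * pi * X) * cos(2 * pi * Y)) * cos(2 * pi * X) -
      (2 * pi)^2 * cos(2 * pi * X) * cos(2 * pi * Y) * sin(2 * pi * X)
  }
  errs <- vapply(c(16, 32, 64), function(n) {
    g <- ad_grid(n)
    xy <- grid_xy(g)
    C <- 2 + sin(2 * pi * xy$X) * cos(2 * pi * xy$Y)
    A <- cos(2 * pi * xy$X)
    max(abs(chemotaxis_divergence(C, A, g) - analytic(xy$X, xy$Y)))
  }, numeric(1))
  # donor-cell upwinding is first-order accurate
  expect_lt(errs[2], errs[1] / 1.7)
  expect_lt(errs[3], errs[2] / 1.7)
  expect_lt(errs[3] / max(abs(analytic(grid_xy(ad_grid(64))$X,
                                       grid_xy(ad_grid(64))$Y))), 0.08)
})

test_that("uniform-field spatial run matches the well-mixed run", {
  tt <- c(0, 300, 1000)
  sp <- simulate_ad_spatial(grid = ad_grid(8), times = tt)
  wm <- simulate_ad(times = tt)
  for (s in species_names) {
    expect_equal(sp[[s]], wm[[s]], tolerance = 1e-4, label = s)
  }
})

test_that("with reactions off, diffusion conserves mass and damps modes at D (2 pi)^2", {
  lam <- grep("^lambda_", names(ad_parameters()), value = TRUE)
  zeros <- stats::setNames(as.list(rep(0, length(lam))), lam)
  p <- do.call(ad_parameters, c(zeros, list(
    R_0 = 1e-300, d_NF = 1e-300, d_NT = 1e-300, d_AboM = 1e-300,
    d_AboMh = 1e-300, d_NdM = 1e-300, d_NdMh = 1e-300, alpha = 1e-300,
    d_AO = 1e-300, d_P = 1e-300)))
  g <- ad_grid(16)
  xy <- grid_xy(g)
  fields <- ad_initial_fields(g)
  # single-mode perturbations on two diffusible species with zeroed kinetics
  fields$AO <- 1e-7 * (1 + 0.5 * sin(2 * pi * xy$X))
  fields$P <- 5e-9 * (1 + 0.5 * sin(2 * pi * xy$Y))
  tt <- 1
  traj <- simulate_ad_spatial(params = p, grid = g, times = c(0, tt),
                              fields = fields, keep_fields = "final")
  fin <- attr(traj, "fields")[[1]]
  # mass conserved (domain mean unchanged)
  expect_equal(mean(fin$AO), 1e-7, tolerance = 1e-6)
  expect_equal(mean(fin$P), 5e-9, tolerance = 1e-6)
  # mode amplitude decays at D * (2 pi)^2; tight agreement against the exact
  # eigenvalue of the discrete operator, 10% against the continuum rate
  amp <- function(M, mode) 2 * mean(M * mode)
  k2_disc <- (2 - 2 * cos(2 * pi * g$dx)) / g$dx^2
  p_ad <- ad_parameters()
  for (cfg in list(list(M = fin$AO, mode = sin(2 * pi * xy$X),
                        a0 = 1e-7 * 0.5, D = p_ad$D_AO),
                   list(M = fin$P, mode = sin(2 * pi * xy$Y),
                        a0 = 5e-9 * 0.5, D = p_ad$D_P))) {
    ratio <- amp(cfg$M, cfg$mode) / cfg$a0
    expect_equal(ratio, exp(-cfg$D * k2_disc * tt), tolerance = 1e-3)
    expect_equal(ratio, exp(-cfg$D * (2 * pi)^2 * tt), tolerance = 0.1)
  }
})

test_that("grid refinement leaves ten-year domain means nearly unchanged", {
  mk_fields <- function(g) {
    xy <- grid_xy(g)
    fields <- ad_initial_fields(g)
    bump <- 1 + 0.2 * sin(2 * pi * xy$X) * cos(2 * pi * xy$Y)
    for (s in c("Abo", "M1", "M2", "Ta", "I10")) fields[[s]] <- fields[[s]] * bump
    fields
  }
  tt <- c(0, 3650)
  s8 <- simulate_ad_spatial(grid = ad_grid(8), times = tt,
                            fields = mk_fields(ad_grid(8)))
  s16 <- simulate_ad_spatial(grid = ad_grid(16), times = tt,
                             fields = mk_fields(ad_grid(16)))
  for (s in c("N", "Abo", "Ta", "M1", "Nd")) {
    expect_equal(s16[[s]][2], s8[[s]][2], tolerance = 0.01, label = s)
  }
})

test_that("field snapshots export with a readable header", {
  g <- ad_grid(8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field_snapshot(matrix(1:64 / 64, 8, 8), "AO", 10, g, path)
  lines <- readLines(path)
  expect_match(lines[1], "species: AO")
  expect_equal(length(lines), 3 + 8)
})
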