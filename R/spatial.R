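# 2-D periodic-domain mode: diffusion and chemotaxis on the unit square, with
# the well-mixed mode as its uniform-field limit.

#' Spatial grid on the unit square
#'
#' A regular n-by-n grid on the domain \[0,1\] x \[0,1\] (cm) with periodic
#' wrap in both axes.
#'
#' @param n grid resolution per axis (at least 8; default 32).
#' @return A list of class `ad_grid` with fields `n` and `dx = 1/n`.
#' @export
ad_grid <- function(n = 32) {
  n <- as.integer(n)
  if (is.na(n) || n < 8) stop("grid resolution must be at least 8", call. = FALSE)
  structure(list(n = n, dx = 1 / n), class = "ad_grid")
}

.check_field <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$n || ncol(field) != grid$n) {
    stop("field must be a ", grid$n, " x ", grid$n, " matrix", call. = FALSE)
  }
}

# periodic shifts
.shift <- function(M, di, dj) {
  n <- nrow(M)
  M[(seq_len(n) - 1 + di) %% n + 1, (seq_len(n) - 1 + dj) %% n + 1, drop = FALSE]
}

#' Discrete periodic Laplacian
#'
#' Second-order central five-point Laplacian with periodic wrap; its domain
#' sum is zero to machine precision, so pure diffusion conserves mass.
#'
#' @param field an n-by-n matrix.
#' @param grid the matching [ad_grid()].
#' @return Matrix of the same shape.
#' @export
laplacian_periodic <- function(field, grid) {
  .check_field(field, grid)
  (.shift(field, 1, 0) + .shift(field, -1, 0) +
     .shift(field, 0, 1) + .shift(field, 0, -1) - 4 * field) / grid$dx^2
}

#' Conservative chemotactic flux divergence
#'
#' Computes the divergence of the advective chemotaxis flux
#' `cells * grad(attractant)` in conservative flux form with donor-cell
#' upwinding (the face velocity is the central gradient of the attractant; the
#' transported cell density is taken from the upwind side).  Upwinding keeps
#' cell densities nonnegative under advection; the flux form makes the domain
#' sum of the divergence exactly zero on the periodic domain.
#'
#' The term enters the cell equations on the left-hand side, so the
#' right-hand-side contribution is the negative of this function's value
#' (cells drift up the attractant gradient).
#'
#' @param cells n-by-n cell-density matrix.
#' @param attractant n-by-n attractant-concentration matrix.
#' @param grid the matching [ad_grid()].
#' @return Matrix of the same shape (domain sum 0).
#' @export
chemotaxis_divergence <- function(cells, attractant, grid) {
  .check_field(cells, grid)
  .check_field(attractant, grid)
  dx <- grid$dx
  # faces in +row direction between i and i+1
  u_x <- (.shift(attractant, 1, 0) - attractant) / dx
  Fx <- ifelse(u_x > 0, cells, .shift(cells, 1, 0)) * u_x
  u_y <- (.shift(attractant, 0, 1) - attractant) / dx
  Fy <- ifelse(u_y > 0, cells, .shift(cells, 0, 1)) * u_y
  (Fx - .shift(Fx, -1, 0)) / dx + (Fy - .shift(Fy, 0, -1)) / dx
}

#' Initial fields for the spatial mode
#'
#' Uniform fields at the well-mixed initial values by default, optionally with
#' a seeded multiplicative random perturbation for exploring pattern
#' formation.
#'
#' @param grid an [ad_grid()].
#' @param state named initial state (see [ad_initial_state()]).
#' @param perturb relative perturbation amplitude (0 = uniform); each grid
#'   value is multiplied by `1 + perturb * u` with `u` uniform on \[-1, 1\].
#' @param seed RNG seed for the perturbation.
#' @return Named list of n-by-n matrices, one per species.
#' @export
ad_initial_fields <- function(grid = ad_grid(), state = ad_initial_state(),
                              perturb = 0, seed = NULL) {
  state <- state[.ad_species]
  fields <- lapply(as.list(state), function(v) matrix(v, grid$n, grid$n))
  if (perturb > 0) {
    if (!is.null(seed)) set.seed(seed)
    fields <- lapply(fields, function(M) {
      M * (1 + perturb * matrix(stats::runif(grid$n^2, -1, 1), grid$n, grid$n))
    })
  }
  fields
}

.spatial_rhs <- function(t, y, parms) {
  n <- parms$grid$n
  nx <- n * n
  S <- lapply(seq_along(.ad_species), function(k) {
    matrix(y[((k - 1) * nx + 1):(k * nx)], n, n)
  })
  names(S) <- .ad_species
  ch <- .treatment_channels(parms$treatment, t, parms$p)
  d <- .ad_reaction_terms(t, S, parms$p, ch, parms$abeta_clearance)
  p <- parms$p
  g <- parms$grid
  d$AO <- d$AO + p$D_AO * laplacian_periodic(S$AO, g)
  d$H <- d$H + p$D_H * laplacian_periodic(S$H, g)
  d$Tb <- d$Tb + p$D_Tb * laplacian_periodic(S$Tb, g)
  d$I10 <- d$I10 + p$D_I10 * laplacian_periodic(S$I10, g)
  d$Ta <- d$Ta + p$D_Ta * laplacian_periodic(S$Ta, g)
  d$P <- d$P + p$D_P * laplacian_periodic(S$P, g)
  d$M1 <- d$M1 - chemotaxis_divergence(S$M1, S$H, g)
  d$M2 <- d$M2 - chemotaxis_divergence(S$M2, S$H, g)
  d$Mh1 <- d$Mh1 - chemotaxis_divergence(S$Mh1, S$AO, g)
  d$Mh2 <- d$Mh2 - chemotaxis_divergence(S$Mh2, S$AO, g)
  list(unlist(lapply(d[.ad_species], as.vector), use.names = FALSE))
}

#' Simulate the spatial reaction-diffusion-chemotaxis system
#'
#' Method-of-lines integration of the full 2-D periodic system: the six
#' diffusible species (oligomer, HMGB-1, TGF-beta, IL-10, TNF-alpha, MCP-1)
#' carry a central-difference Laplacian; activated microglia are advected up
#' the HMGB-1 gradient and peripheral macrophages up the oligomer gradient via
#' the conservative upwind flux of [chemotaxis_divergence()]; macrophages do
#' not diffuse (blood-brain-barrier assumption).  The semi-discrete system is
#' integrated with the sparse stiff solver `lsodes`.
#'
#' With uniform initial fields both operators vanish identically and the
#' domain-mean trajectory coincides with [simulate_ad()], which serves as the
#' primary correctness oracle for this mode.
#'
#' @param params an [ad_parameters()] set.
#' @param treatment an [ad_treatment()], a list of them, or `NULL`.
#' @param grid an [ad_grid()].
#' @param horizon end of the simulation (days).
#' @param times output time grid (days).
#' @param fields initial fields from [ad_initial_fields()].
#' @param abeta_clearance as in [ad_derivatives()].
#' @param keep_fields `"none"`, `"final"` or `"all"`: store field snapshots at
#'   no, the last, or every output time (attribute `"fields"`).
#' @param rtol,atol solver tolerances.
#' @return An `ad_trajectory` tibble of domain means per species.
#' @export
simulate_ad_spatial <- function(params = ad_parameters(), treatment = NULL,
                                grid = ad_grid(), horizon = 3650,
                                times = seq(0, horizon, by = 5),
                                fields = ad_initial_fields(grid),
                                abeta_clearance = c("mass_action", "saturating"),
                                keep_fields = c("none", "final", "all"),
                                rtol = 1e-6, atol = 1e-12) {
  abeta_clearance <- match.arg(abeta_clearance)
  keep_fields <- match.arg(keep_fields)
  stopifnot(inherits(params, "ad_parameters"), inherits(grid, "ad_grid"))
  treatment <- .as_treatment_list(treatment)
  for (sp in .ad_species) .check_field(fields[[sp]], grid)
  y0 <- unlist(lapply(fields[.ad_species], as.vector), use.names = FALSE)
  times <- sort(unique(as.numeric(times)))
  breaks <- vapply(treatment, `[[`, numeric(1), "start_day")
  breaks <- sort(unique(breaks[breaks > min(times) & breaks < max(times)]))
  parms <- list(p = params, treatment = treatment, grid = grid,
                abeta_clearance = abeta_clearance)
  segs <- c(min(times), breaks, max(times))
  sols <- list()
  y <- y0
  for (i in seq_len(length(segs) - 1)) {
    seg_times <- sort(unique(c(segs[i], times[times >= segs[i] & times <= segs[i + 1]],
                               segs[i + 1])))
    sol <- deSolve::ode(y, seg_times, .spatial_rhs, parms, method = "lsodes",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("spatial integration failed at t = ", utils::tail(sol[, 1], 1),
           "; consider a finer grid or looser tolerances", call. = FALSE)
    }
    keep <- sol[, 1] %in% times
    if (i > 1) keep[1] <- FALSE
    sols[[i]] <- sol[keep, , drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  sol <- do.call(rbind, sols)
  nx <- grid$n^2
  means <- vapply(seq_along(.ad_species), function(k) {
    rowMeans(sol[, 1 + ((k - 1) * nx + 1):(k * nx), drop = FALSE])
  }, numeric(nrow(sol)))
  colnames(means) <- .ad_species
  out <- tibble::as_tibble(as.data.frame(cbind(time = sol[, 1], means)))
  out <- dplyr::mutate(out, years = .data$time / 365, .after = "time")
  snap <- NULL
  to_fields <- function(row) {
    fl <- lapply(seq_along(.ad_species), function(k) {
      matrix(row[((k - 1) * nx + 1):(k * nx)], grid$n, grid$n)
    })
    stats::setNames(fl, .ad_species)
  }
  if (keep_fields == "final") {
    snap <- stats::setNames(list(to_fields(sol[nrow(sol), -1])),
                            as.character(sol[nrow(sol), 1]))
  } else if (keep_fields == "all") {
    snap <- stats::setNames(lapply(seq_len(nrow(sol)), function(i) to_fields(sol[i, -1])),
                            as.character(sol[, 1]))
  }
  structure(out,
            class = c("ad_trajectory", class(out)),
            params_hash = rlang::hash(unclass(params)),
            treatment = treatment,
            abeta_clearance = abeta_clearance,
            grid = grid, fields = snap,
            solver = list(method = "lsodes", rtol = rtol, atol = atol))
}

#' Export a field snapshot as a delimited text file
#'
#' Writes one species' field with a small header (species, time, grid) and the
#' dense matrix of values.
#'
#' @param field n-by-n matrix.
#' @param species species name.
#' @param time snapshot time (days).
#' @param grid the matching [ad_grid()].
#' @param path output path.
#' @export
write_field_snapshot <- function(field, species, time, grid, path) {
  .check_field(field, grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# species:", species),
               paste("# time_days:", time),
               paste("# grid:", grid$n, "x", grid$n, "dx", grid$dx)), con)
  utils::write.table(field, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
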