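# State representation and right-hand side of the 18-species network.

# Species order is fixed throughout the package.
.ad_species <- c("Abi", "Abo", "tau", "Fi", "Fo", "N", "A", "Nd", "AO", "H",
                 "M1", "M2", "Mh1", "Mh2", "Tb", "I10", "Ta", "P")

.ad_species_info <- function() {
  tibble::tibble(
    species = .ad_species,
    units = c(rep("g/ml", 5), rep("g/cm^3", 3), rep("g/ml", 2),
              rep("g/cm^3", 4), rep("g/ml", 4)),
    description = c(
      "amyloid-beta inside neurons", "amyloid-beta outside neurons",
      "hyperphosphorylated tau", "intracellular NFT", "extracellular NFT",
      "live neurons", "astrocytes", "dead neurons",
      "soluble amyloid-beta oligomer", "HMGB-1",
      "proinflammatory microglia", "anti-inflammatory microglia",
      "proinflammatory peripheral macrophages",
      "anti-inflammatory peripheral macrophages",
      "TGF-beta", "IL-10", "TNF-alpha", "MCP-1"))
}

#' Disease-stage initial state
#'
#' The default initial values of the 18 species: a diagnosed disease state with
#' each variable below (above) its expected long-run level if it grows (falls)
#' as the disease progresses.  Peripheral macrophages and dead neurons start at
#' zero; the soluble oligomer pool, which is not assigned a published starting
#' value, also starts at zero and equilibrates with the plaque pool within
#' days.
#'
#' @param ... named overrides, e.g. `ad_initial_state(Abo = 2e-8)`.
#' @return A named numeric vector over the 18 species (g/ml; cell densities
#'   g/cm^3, numerically identical).
#' @examples
#' ad_initial_state()[["N"]]
#' @export
ad_initial_state <- function(...) {
  y <- c(Abi = 1e-6, Abo = 1e-8, tau = 1.37e-10, Fi = 3.36e-10, Fo = 3.36e-11,
         N = 0.14, A = 0.14, Nd = 0, AO = 0, H = 1.3e-11,
         M1 = 0.02, M2 = 0.02, Mh1 = 0, Mh2 = 0,
         Tb = 1e-6, I10 = 1e-5, Ta = 2e-5, P = 5e-9)
  ov <- list(...)
  if (length(ov) > 0) {
    bad <- setdiff(names(ov), names(y))
    if (length(bad) > 0) stop("unknown species: ", paste(bad, collapse = ", "))
    y[names(ov)] <- vapply(ov, as.numeric, numeric(1))
    if (any(y < 0)) stop("initial state must be nonnegative")
  }
  y
}

#' Reactive-oxygen-species forcing signal
#'
#' The dimensionless ROS signal driving intraneuronal amyloid-beta and tau
#' overproduction: a linear ramp from 0 to the amplitude `R_0` over the first
#' 100 days, constant afterwards.
#'
#' @param t time in days (vectorised); must be nonnegative.
#' @param R_0 forcing amplitude (dimensionless).
#' @return The forcing value(s).
#' @examples
#' ros_forcing(c(0, 50, 200))
#' @export
ros_forcing <- function(t, R_0 = 6) {
  if (any(t < 0)) stop("time must be nonnegative", call. = FALSE)
  ifelse(t <= 100, R_0 * t / 100, R_0)
}

# saturating activation X/(X+K), defined as 0 at X = 0 and clamped for
# transiently negative solver states
.sat <- function(x, K) {
  x <- pmax(x, 0)
  x / (x + K)
}

#' Phenotype split of newly activated cells
#'
#' Newly activated microglia (and incoming peripheral macrophages) divide into
#' pro- and anti-inflammatory phenotypes according to the saturated TNF-alpha
#' and IL-10 signals: with `e1 = Ta/(Ta+K_Ta)` and `e2 = I10/(I10+K_I10)`, the
#' proinflammatory fraction is `beta*e1 / (beta*e1 + e2)` and the
#' anti-inflammatory fraction is `e2 / (beta*e1 + e2)`.  When both signals are
#' zero there is no activation cue and both fractions are 0.
#'
#' @param Ta TNF-alpha concentration (g/ml), vectorised.
#' @param I10 IL-10 concentration (g/ml), vectorised.
#' @param params an [ad_parameters()] set.
#' @return A tibble with columns `pro` and `anti` (summing to 1 wherever a
#'   signal is present).
#' @export
phenotype_fractions <- function(Ta, I10, params = ad_parameters()) {
  e1 <- .sat(Ta, params$K_Ta)
  e2 <- .sat(I10, params$K_I10)
  den <- params$beta * e1 + e2
  pro <- ifelse(den > 0, params$beta * e1 / den, 0)
  anti <- ifelse(den > 0, e2 / den, 0)
  tibble::tibble(pro = pro, anti = anti)
}

#' Instantaneous neuronal death rate
#'
#' The magnitude of dN/dt: NFT-mediated death saturating in intracellular
#' tangles plus TNF-alpha-mediated death saturating in TNF-alpha and inhibited
#' by IL-10.  The same quantity feeds the release terms of the extracellular
#' amyloid-beta and NFT pools and the production of dead neurons, so it is
#' evaluated analytically from the current state rather than by differencing.
#'
#' @param state named state vector (or list of fields) over the 18 species.
#' @param params an [ad_parameters()] set.
#' @return Death rate in g/ml/day (nonnegative).
#' @export
neuronal_death_rate <- function(state, params = ad_parameters()) {
  p <- params
  inhib <- 1 / (1 + p$gamma * pmax(state[["I10"]], 0) / p$K_I10)
  p$d_NF * .sat(state[["Fi"]], p$K_Fi) * state[["N"]] +
    p$d_NT * .sat(state[["Ta"]], p$K_Ta) * inhib * state[["N"]]
}

# Reaction terms shared by the well-mixed and spatial modes.  `S` is a named
# list whose elements are scalars (well-mixed) or matrices (one field per
# species); `ch` holds the resolved treatment channels at time t.
# `abeta_clearance` selects the phagocytosis law for the plaque pool:
# "mass_action" (default; the law the constant set is derived under) or
# "saturating" (Michaelis form with Kbar_Abo).
.ad_reaction_terms <- function(t, S, p, ch, abeta_clearance = "mass_action") {
  R <- ros_forcing(t, p$R_0)
  e1 <- .sat(S$Ta, p$K_Ta)
  e2 <- .sat(S$I10, p$K_I10)
  den <- p$beta * e1 + e2
  pro <- ifelse(den > 0, p$beta * e1 / den, 0)
  anti <- ifelse(den > 0, e2 / den, 0)
  inhib <- 1 / (1 + p$gamma * pmax(S$I10, 0) / p$K_I10)
  death <- p$d_NF * .sat(S$Fi, p$K_Fi) * S$N +
    p$d_NT * e1 * inhib * S$N
  act <- p$MG0 * (p$lambda_MF * .sat(S$Fo, p$K_Fo) +
                  p$lambda_MA * .sat(S$AO, p$K_AO))
  Mh <- S$Mh1 + S$Mh2
  influx <- p$alpha * .sat(S$P, p$K_P) * pmax(p$M_0 - Mh, 0)
  trans_M <- p$lambda_M1Tb * .sat(S$Tb, p$K_Tb) * S$M1
  trans_Mh <- p$lambda_Mh1Tb * .sat(S$Tb, p$K_Tb) * S$Mh1
  abo_drive <- if (identical(abeta_clearance, "mass_action")) {
    pmax(S$Abo, 0)
  } else {
    .sat(S$Abo, p$Kbar_Abo)
  }
  list(
    Abi = (p$lambda_Bi * (1 + R) - p$d_Abi * S$Abi) * S$N / p$N_0,
    Abo = S$Abi * death + p$lambda_N * S$N / p$N_0 + p$lambda_A * S$A / p$A_0 -
      (p$d_AboMh * (S$Mh1 + p$theta * S$Mh2) +
         p$d_AboM * (S$M1 + p$theta * S$M2) * (1 + ch$h)) * abo_drive,
    tau = (ch$tau_factor * (p$lambda_tau0 + p$lambda_tau * R) -
             p$d_tau * S$tau) * S$N / p$N_0,
    Fi = (p$lambda_F * S$tau - p$d_Fi * S$Fi) * S$N / p$N_0,
    Fo = S$Fi * death - p$d_Fo * S$Fo,
    N = -death,
    A = p$lambda_AAbo * S$Abo + p$lambda_ATa * S$Ta - p$d_A * S$A,
    Nd = death - (p$d_NdM * (S$M1 + S$M2) + p$d_NdMh * Mh) * .sat(S$Nd, p$Kbar_Nd),
    AO = p$lambda_AO * S$Abo - p$d_AO * S$AO,
    H = p$lambda_H * S$Nd - p$d_H * S$H,
    M1 = act * pro - trans_M - p$d_M1 * S$M1,
    M2 = act * anti + trans_M - p$d_M2 * S$M2,
    Mh1 = influx * pro - trans_Mh - p$d_Mh1 * S$Mh1,
    Mh2 = influx * anti + trans_Mh - p$d_Mh2 * S$Mh2,
    Tb = p$lambda_TbM * S$M2 + p$lambda_TbMh * S$Mh2 - p$d_Tb * S$Tb + ch$g,
    I10 = p$lambda_I10M2 * S$M2 + p$lambda_I10Mh2 * S$Mh2 - p$d_I10 * S$I10,
    Ta = p$lambda_TaM1 * S$M1 + p$lambda_TaMh1 * S$Mh1 - p$d_Ta * S$Ta -
      ch$f * S$Ta,
    P = p$lambda_PA * S$A + p$lambda_PM2 * S$M2 - p$d_P * S$P * (1 + ch$k)
  )
}

#' Time derivative of the well-mixed system
#'
#' Evaluates the right-hand side of the 18-species system in spatially
#' homogeneous form, with treatment modifications applied if a treatment is
#' active at time `t`.
#'
#' @param t time in days.
#' @param state named state vector over the 18 species.
#' @param params an [ad_parameters()] set.
#' @param treatment an [ad_treatment()], a list of them, or `NULL`.
#' @param abeta_clearance phagocytosis law for the extracellular amyloid-beta
#'   pool: `"mass_action"` (default) or `"saturating"`.
#' @return Named numeric vector of derivatives (per day).
#' @export
ad_derivatives <- function(t, state, params = ad_parameters(), treatment = NULL,
                           abeta_clearance = c("mass_action", "saturating")) {
  abeta_clearance <- match.arg(abeta_clearance)
  if (any(state < -1e-7 * max(abs(state), 1e-12))) {
    stop("state has a negative component beyond tolerance", call. = FALSE)
  }
  S <- as.list(state[.ad_species])
  ch <- .treatment_channels(.as_treatment_list(treatment), t, params)
  d <- .ad_reaction_terms(t, S, params, ch, abeta_clearance)
  unlist(d[.ad_species])
}

# deSolve-facing RHS (no per-call validation)
.ad_rhs <- function(t, y, parms) {
  S <- as.list(y)
  names(S) <- .ad_species
  ch <- .treatment_channels(parms$treatment, t, parms$p)
  d <- .ad_reaction_terms(t, S, parms$p, ch, parms$abeta_clearance)
  list(unlist(d, use.names = FALSE))
}

#' Simulate the well-mixed disease course
#'
#' Integrates the 18-species system with the stiff adaptive `lsoda` solver
#' (relative tolerance 1e-6, absolute tolerance 1e-12 by default; the state
#' spans roughly 1e-11 to 1e-1 g/ml and the rate constants span five orders of
#' magnitude).  When a treatment is supplied the integration restarts at each
#' treatment start day so the switch is resolved as a hard discontinuity; the
#' same restart grid can be imposed on an untreated reference run via
#' `restart_at` to make treated/untreated arms step-for-step comparable.
#'
#' @param params an [ad_parameters()] set.
#' @param treatment an [ad_treatment()], a list of them, or `NULL`.
#' @param horizon end of the simulation in days (default 3650 = 10 years).
#' @param times output time grid in days (default every 5 days).
#' @param state initial state, from [ad_initial_state()].
#' @param abeta_clearance `"mass_action"` (default) or `"saturating"`; see
#'   [ad_derivatives()].
#' @param restart_at additional integrator restart times (days); treatment
#'   start days are always included.
#' @param rtol,atol solver tolerances.
#' @param method a [deSolve::ode()] method; default `"lsoda"`.
#' @return A tibble of class `ad_trajectory`: columns `time` (days), `years`,
#'   and one column per species, with the parameter hash, treatment and solver
#'   settings stored as attributes.
#' @examples
#' traj <- simulate_ad(horizon = 365, times = seq(0, 365, by = 73))
#' traj[nrow(traj), c("time", "N", "Abo")]
#' @export
simulate_ad <- function(params = ad_parameters(), treatment = NULL,
                        horizon = 3650, times = seq(0, horizon, by = 5),
                        state = ad_initial_state(),
                        abeta_clearance = c("mass_action", "saturating"),
                        restart_at = NULL, rtol = 1e-6, atol = 1e-12,
                        method = "lsoda") {
  abeta_clearance <- match.arg(abeta_clearance)
  stopifnot(inherits(params, "ad_parameters"), horizon > 0)
  treatment <- .as_treatment_list(treatment)
  state <- state[.ad_species]
  if (any(is.na(state))) stop("initial state must cover all 18 species")
  times <- sort(unique(as.numeric(times)))
  breaks <- sort(unique(c(
    vapply(treatment, `[[`, numeric(1), "start_day"), restart_at)))
  breaks <- breaks[breaks > min(times) & breaks < max(times)]
  parms <- list(p = params, treatment = treatment,
                abeta_clearance = abeta_clearance)
  segs <- c(min(times), breaks, max(times))
  out_rows <- list()
  y <- state
  for (i in seq_len(length(segs) - 1)) {
    seg_times <- sort(unique(c(segs[i], times[times >= segs[i] & times <= segs[i + 1]],
                               segs[i + 1])))
    sol <- deSolve::ode(y, seg_times, .ad_rhs, parms, method = method,
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed at t = ", utils::tail(sol[, 1], 1), call. = FALSE)
    }
    keep <- sol[, 1] %in% times
    if (i > 1) keep[1] <- FALSE  # segment start already emitted
    out_rows[[i]] <- sol[keep, , drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  m <- do.call(rbind, out_rows)
  colnames(m) <- c("time", .ad_species)
  lo <- min(m[, .ad_species])
  if (lo < -1e3 * atol) {
    stop("solution left the nonnegative cone (min = ", signif(lo, 3), ")")
  }
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::mutate(out, years = .data$time / 365, .after = "time")
  structure(out,
            class = c("ad_trajectory", class(out)),
            params_hash = rlang::hash(unclass(params)),
            treatment = treatment,
            abeta_clearance = abeta_clearance,
            solver = list(method = method, rtol = rtol, atol = atol))
}

#' @export
print.ad_trajectory <- function(x, ...) {
  trt <- attr(x, "treatment")
  cat("<ad_trajectory> ", nrow(x), " time points over ",
      round(max(x$time)), " days; ",
      if (length(trt) == 0) "untreated" else
        paste(vapply(trt, function(s) s$drug, ""), collapse = " + "),
      "\n", sep = "")
  NextMethod()
}

#' Long-format trajectory
#'
#' @param x an `ad_trajectory`.
#' @param ... unused.
#' @return Tibble with columns `time`, `years`, `species`, `value`, `units`.
#' @export
tidy.ad_trajectory <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), cols = -c("time", "years"),
                              names_to = "species", values_to = "value")
  dplyr::left_join(long, .ad_species_info(), by = "species")
}

#' Trajectory endpoint summary
#'
#' @param x an `ad_trajectory`.
#' @param ... unused.
#' @return One-row tibble: horizon, final live-neuron density, final
#'   extracellular amyloid-beta, total neuron loss fraction and the average
#'   annual percentage decline of `N`.
#' @export
glance.ad_trajectory <- function(x, ...) {
  n0 <- x$N[1]
  nT <- x$N[nrow(x)]
  tibble::tibble(
    horizon_days = max(x$time),
    N_final = nT,
    Abo_final = x$Abo[nrow(x)],
    neuron_loss = (n0 - nT) / n0,
    annual_decline_pct = 100 * (n0 - nT) / n0 / (max(x$time) / 365))
}
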