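# Treatment efficacy measures, (f, h) efficacy maps, and the synergy index
# for etanercept + aducanumab combination therapy.

# one trial arm: returns the final state row of a 10-year run with the trial
# protocol (restart at start_day in every arm, so arms are step-comparable)
.trial_run <- function(f, h, params, horizon, start_day, ...) {
  treatment <- list()
  if (f > 0) treatment <- c(treatment, list(ad_treatment("etanercept", f, start_day)))
  if (h > 0) treatment <- c(treatment, list(ad_treatment("aducanumab", h, start_day)))
  traj <- simulate_ad(params = params,
                      treatment = if (length(treatment)) treatment else NULL,
                      horizon = horizon,
                      times = c(0, start_day, horizon),
                      restart_at = start_day, ...)
  traj[nrow(traj), ]
}

#' Efficacy of combined etanercept/aducanumab treatment
#'
#' Runs treated and untreated ten-year simulations (continuous treatment from
#' `start_day`) and reports, at the horizon:
#'
#' * `E_N = (N(f,h) - N(0,0)) / N(0,0)` — relative improvement in live-neuron
#'   density;
#' * `E_Abeta = (Abo(0,0) - Abo(f,h)) / Abo(0,0)` — relative reduction in
#'   extracellular amyloid-beta;
#' * `death_reduction = (loss(0,0) - loss(f,h)) / loss(0,0)` with
#'   `loss = N(0) - N(horizon)` — relative reduction in cumulative neuronal
#'   death.  With roughly half the neurons lost over ten years this closely
#'   tracks `E_N`.
#'
#' @param f etanercept fold number (the removal rate added to the TNF-alpha
#'   equation is `f * d_Ta`).
#' @param h aducanumab fold number.
#' @param params an [ad_parameters()] set.
#' @param horizon trial horizon in days (includes the pre-treatment window).
#' @param start_day treatment start (day of diagnosis).
#' @param reference optional precomputed untreated endpoint (from a previous
#'   call's `reference` attribute) to avoid re-running the control arm.
#' @param ... further arguments to [simulate_ad()].
#' @return A one-row tibble with `f`, `h`, `E_N`, `E_Abeta`,
#'   `death_reduction`, `N_final`, `Abo_final`; the untreated endpoint is
#'   attached as attribute `"reference"`.
#' @examples
#' \donttest{
#' treatment_efficacy(10, 5)
#' }
#' @export
treatment_efficacy <- function(f, h, params = ad_parameters(), horizon = 3650,
                               start_day = 300, reference = NULL, ...) {
  stopifnot(f >= 0, h >= 0)
  if (is.null(reference)) {
    reference <- .trial_run(0, 0, params, horizon, start_day, ...)
  }
  fin <- if (f == 0 && h == 0) reference else {
    .trial_run(f, h, params, horizon, start_day, ...)
  }
  n0 <- ad_initial_state()[["N"]]
  loss_u <- n0 - reference$N
  loss_t <- n0 - fin$N
  out <- tibble::tibble(
    f = f, h = h,
    E_N = (fin$N - reference$N) / reference$N,
    E_Abeta = (reference$Abo - fin$Abo) / reference$Abo,
    death_reduction = (loss_u - loss_t) / loss_u,
    N_final = fin$N, Abo_final = fin$Abo)
  attr(out, "reference") <- reference
  out
}

#' Efficacy map over the (f, h) dose plane
#'
#' Dense efficacy evaluation over a rectangular grid of etanercept and
#' aducanumab fold numbers, sharing one untreated reference run.  Cells whose
#' simulation fails are flagged (`failed = TRUE`) and the map is completed.
#'
#' @param f_max,h_max upper fold limits (published map: 50 and 25).
#' @param n_f,n_h number of grid values per axis, 0 to the maximum inclusive.
#' @param params an [ad_parameters()] set.
#' @param horizon,start_day trial protocol, as in [treatment_efficacy()].
#' @param ... further arguments to [simulate_ad()].
#' @return A tibble of class `ad_efficacy_map` in long format: `f`, `h`,
#'   `E_N`, `E_Abeta`, `death_reduction`, `failed`.
#' @export
efficacy_map <- function(f_max = 50, h_max = 25, n_f = 11, n_h = 11,
                         params = ad_parameters(), horizon = 3650,
                         start_day = 300, ...) {
  stopifnot(n_f >= 2, n_h >= 2, f_max > 0, h_max > 0)
  grid <- tidyr::expand_grid(f = seq(0, f_max, length.out = n_f),
                             h = seq(0, h_max, length.out = n_h))
  reference <- .trial_run(0, 0, params, horizon, start_day, ...)
  rows <- purrr::pmap(grid, function(f, h) {
    tryCatch({
      r <- treatment_efficacy(f, h, params, horizon, start_day,
                              reference = reference, ...)
      dplyr::mutate(r[, c("f", "h", "E_N", "E_Abeta", "death_reduction")],
                    failed = FALSE)
    }, error = function(e) {
      tibble::tibble(f = f, h = h, E_N = NA_real_, E_Abeta = NA_real_,
                     death_reduction = NA_real_, failed = TRUE)
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ad_efficacy_map", class(out)),
            horizon = horizon, reference = reference)
}

#' Synergy index of a dose pair
#'
#' `sigma_N(f, g) = E_N(f, g) / max(E_N(2f, 0), E_N(0, 2g))`: the efficacy of
#' the combination against the better of the two same-total-dose
#' monotherapies.  `sigma_N > 1` indicates positive synergy, `sigma_N < 1`
#' negative synergy.  Where the denominator is not positive the index is
#' undefined and returned as `NA` with `defined = FALSE`.  The analogous
#' index for the amyloid endpoint is returned as `sigma_Abeta`.
#'
#' @param f etanercept fold number.
#' @param g aducanumab fold number.
#' @inheritParams treatment_efficacy
#' @param cache optional environment used to share single-arm runs across
#'   calls (used by [synergy_map()]).
#' @return One-row tibble: `f`, `g`, `sigma_N`, `sigma_Abeta`, `defined`.
#' @export
synergy_index <- function(f, g, params = ad_parameters(), horizon = 3650,
                          start_day = 300, reference = NULL, cache = NULL, ...) {
  stopifnot(f >= 0, g >= 0)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(reference)) {
    reference <- .trial_run(0, 0, params, horizon, start_day, ...)
  }
  eff <- function(ff, hh) {
    key <- paste(ff, hh, sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- treatment_efficacy(ff, hh, params, horizon, start_day,
                                         reference = reference, ...)
    }
    cache[[key]]
  }
  comb <- eff(f, g)
  mono_f <- eff(2 * f, 0)
  mono_g <- eff(0, 2 * g)
  den_N <- max(mono_f$E_N, mono_g$E_N)
  den_A <- max(mono_f$E_Abeta, mono_g$E_Abeta)
  tibble::tibble(
    f = f, g = g,
    sigma_N = if (den_N > 0) comb$E_N / den_N else NA_real_,
    sigma_Abeta = if (den_A > 0) comb$E_Abeta / den_A else NA_real_,
    defined = den_N > 0)
}

#' Synergy map over the (f, g) dose plane
#'
#' Evaluates [synergy_index()] on a rectangular grid of fold numbers, sharing
#' the untreated reference and all single-arm runs across cells.
#'
#' @param f_max,g_max upper fold limits.
#' @param n_f,n_g grid sizes (values 0 to the maximum inclusive; the zero
#'   row/column is undefined by construction).
#' @inheritParams treatment_efficacy
#' @return A tibble of class `ad_synergy_map` in long format.
#' @export
synergy_map <- function(f_max = 50, g_max = 25, n_f = 6, n_g = 6,
                        params = ad_parameters(), horizon = 3650,
                        start_day = 300, ...) {
  cache <- new.env(parent = emptyenv())
  reference <- .trial_run(0, 0, params, horizon, start_day, ...)
  grid <- tidyr::expand_grid(f = seq(0, f_max, length.out = n_f),
                             g = seq(0, g_max, length.out = n_g))
  rows <- purrr::pmap(grid, function(f, g) {
    synergy_index(f, g, params, horizon, start_day,
                  reference = reference, cache = cache, ...)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ad_synergy_map", class(out)), horizon = horizon)
}
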