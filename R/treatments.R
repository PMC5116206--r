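# In silico interventions: modifications of the right-hand side from a start
# day onward.

.ad_drugs <- c("etanercept", "tgf_beta", "aducanumab", "bindarit", "mtc")

#' Specify an in silico treatment
#'
#' The five supported interventions act on the network as follows, from
#' `start_day` (default 300, the diagnosis point of the trial protocol) to the
#' end of the simulation:
#'
#' * `etanercept` (TNF-alpha inhibitor): adds a removal term `-f * Ta` to the
#'   TNF-alpha equation with `f = fold * d_Ta`.
#' * `tgf_beta` (TGF-beta injection): adds a constant source
#'   `g = fold * d_Tb * K_Tb` to the TGF-beta equation.
#' * `aducanumab` (anti-amyloid antibody): scales the microglial clearance
#'   term of the extracellular amyloid-beta pool by `(1 + fold)`.
#' * `bindarit` (MCP-1 inhibitor): scales MCP-1 degradation by `(1 + fold)`.
#' * `mtc` (tau-aggregation inhibitor): multiplies both tau production rates
#'   by `fold`, which must lie in (0, 1] (default published dose 1/10).
#'
#' Combination therapy is a list of treatments; their modifications compose.
#'
#' @param drug one of `"etanercept"`, `"tgf_beta"`, `"aducanumab"`,
#'   `"bindarit"`, `"mtc"`.
#' @param fold nonnegative fold number (for `mtc`, the production multiplier
#'   in (0, 1]).
#' @param start_day first day of (continuous) treatment.
#' @return A list of class `ad_treatment`.
#' @examples
#' ad_treatment("etanercept", 10)
#' list(ad_treatment("etanercept", 50), ad_treatment("aducanumab", 25))
#' @export
ad_treatment <- function(drug, fold, start_day = 300) {
  if (!is.character(drug) || length(drug) != 1 || !(drug %in% .ad_drugs)) {
    stop("unknown drug; valid names: ", paste(.ad_drugs, collapse = ", "),
         call. = FALSE)
  }
  fold <- as.numeric(fold)
  if (!is.finite(fold) || fold < 0) stop("fold must be nonnegative", call. = FALSE)
  if (drug == "mtc" && (fold <= 0 || fold > 1)) {
    stop("mtc fold is a production multiplier in (0, 1]", call. = FALSE)
  }
  if (start_day < 0) stop("start_day must be nonnegative", call. = FALSE)
  structure(list(drug = drug, fold = fold, start_day = as.numeric(start_day)),
            class = "ad_treatment")
}

#' @export
print.ad_treatment <- function(x, ...) {
  cat("<ad_treatment> ", x$drug, " fold ", x$fold,
      " from day ", x$start_day, "\n", sep = "")
  invisible(x)
}

.as_treatment_list <- function(treatment) {
  if (is.null(treatment)) return(list())
  if (inherits(treatment, "ad_treatment")) return(list(treatment))
  if (is.list(treatment) && all(vapply(treatment, inherits, logical(1), "ad_treatment"))) {
    return(treatment)
  }
  stop("treatment must be an ad_treatment, a list of them, or NULL",
       call. = FALSE)
}

# Resolve the composed treatment channels active at time t:
# f (1/day, TNF-alpha removal), g (g/ml/day, TGF-beta source),
# h (fold on microglial amyloid clearance), k (fold on MCP-1 degradation),
# tau_factor (multiplier on tau production).
.treatment_channels <- function(treatment, t, params) {
  ch <- list(f = 0, g = 0, h = 0, k = 0, tau_factor = 1)
  for (spec in treatment) {
    if (t < spec$start_day) next
    switch(spec$drug,
      etanercept = ch$f <- ch$f + spec$fold * params$d_Ta,
      tgf_beta   = ch$g <- ch$g + spec$fold * params$d_Tb * params$K_Tb,
      aducanumab = ch$h <- ch$h + spec$fold,
      bindarit   = ch$k <- ch$k + spec$fold,
      mtc        = ch$tau_factor <- ch$tau_factor * spec$fold)
  }
  ch
}

#' Apply treatment modifications to a base derivative
#'
#' Adds the per-equation treatment terms to an untreated derivative
#' evaluation.  Before any treatment's start day the derivative is returned
#' unchanged; afterwards the modifications of all active treatments compose.
#' Consistent with evaluating [ad_derivatives()] with the treatment attached.
#'
#' @param treatment an [ad_treatment()], a list of them, or `NULL`.
#' @param t time in days.
#' @param deriv untreated derivative (named vector from [ad_derivatives()]).
#' @param state the state at which `deriv` was evaluated.
#' @param params an [ad_parameters()] set.
#' @param abeta_clearance clearance law, as in [ad_derivatives()].
#' @return Modified derivative vector.
#' @export
apply_treatment <- function(treatment, t, deriv, state,
                            params = ad_parameters(),
                            abeta_clearance = c("mass_action", "saturating")) {
  abeta_clearance <- match.arg(abeta_clearance)
  ch <- .treatment_channels(.as_treatment_list(treatment), t, params)
  p <- params
  drive <- if (abeta_clearance == "mass_action") {
    max(state[["Abo"]], 0)
  } else {
    .sat(state[["Abo"]], p$Kbar_Abo)
  }
  deriv[["Ta"]] <- deriv[["Ta"]] - ch$f * state[["Ta"]]
  deriv[["Tb"]] <- deriv[["Tb"]] + ch$g
  deriv[["Abo"]] <- deriv[["Abo"]] -
    ch$h * p$d_AboM * (state[["M1"]] + p$theta * state[["M2"]]) * drive
  deriv[["P"]] <- deriv[["P"]] - ch$k * p$d_P * state[["P"]]
  deriv[["tau"]] <- deriv[["tau"]] - (1 - ch$tau_factor) *
    (p$lambda_tau0 + p$lambda_tau * ros_forcing(t, p$R_0)) * state[["N"]] / p$N_0
  deriv
}
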