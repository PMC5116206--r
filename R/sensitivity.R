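# Latin hypercube sensitivity analysis with partial rank correlation
# coefficients against the ten-year neuron and amyloid endpoints.

#' Perturbation factors for the sensitivity analysis
#'
#' The eight perturbed quantities: the individual rates `lambda_N`,
#' `lambda_A`, `d_NF`, `d_NT`, each varied between half and twice its default,
#' and four group multipliers varied between 1/2 and 2 that jointly scale
#' parameter pairs: `gamma_tilde` the TNF-alpha production rates
#' (`lambda_TaM1`, `lambda_TaMh1`), `delta` the TGF-beta production rates
#' (`lambda_TbM`, `lambda_TbMh`), `xi` the MCP-1 production rates
#' (`lambda_PA`, `lambda_PM2`), and `epsilon` the amyloid-beta clearance rates
#' (`d_AboM`, `d_AboMh`).  (`gamma_tilde` is named to avoid collision with the
#' IL-10 inhibition ratio `gamma`.)
#'
#' @param params an [ad_parameters()] set supplying the central values.
#' @return Tibble with columns `factor`, `kind` (`"parameter"` or
#'   `"multiplier"`), `lower`, `upper`.
#' @export
sensitivity_factors <- function(params = ad_parameters()) {
  tibble::tibble(
    factor = c("lambda_N", "lambda_A", "d_NF", "d_NT",
               "gamma_tilde", "delta", "xi", "epsilon"),
    kind = c(rep("parameter", 4), rep("multiplier", 4)),
    lower = c(0.5 * params$lambda_N, 0.5 * params$lambda_A,
              0.5 * params$d_NF, 0.5 * params$d_NT, rep(0.5, 4)),
    upper = c(2 * params$lambda_N, 2 * params$lambda_A,
              2 * params$d_NF, 2 * params$d_NT, rep(2, 4)))
}

#' Latin hypercube sample
#'
#' Stratified uniform design: for each factor the n sampled values occupy each
#' of the n equal-probability strata of its range exactly once, with the
#' stratum order randomised independently per factor.  Reproducible under
#' `seed`.
#'
#' @param n number of samples.
#' @param ranges a tibble with columns `factor`, `lower`, `upper` (e.g.
#'   [sensitivity_factors()]), or a named list of `c(lower, upper)` pairs.
#' @param seed RNG seed.
#' @return An n-row tibble, one column per factor.
#' @examples
#' lhs_sample(4, list(a = c(0, 1), b = c(10, 20)), seed = 1)
#' @export
lhs_sample <- function(n, ranges, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (is.data.frame(ranges)) {
    nm <- ranges$factor
    lo <- ranges$lower
    hi <- ranges$upper
  } else {
    nm <- names(ranges)
    lo <- vapply(ranges, `[`, numeric(1), 1)
    hi <- vapply(ranges, `[`, numeric(1), 2)
  }
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo)) {
    stop("each range must be a finite interval with upper > lower", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, length(nm))
  x <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(x) <- nm
  tibble::as_tibble(x)
}

# apply one design row to a parameter set
.apply_factors <- function(params, row) {
  p <- params
  p$lambda_N <- row[["lambda_N"]]
  p$lambda_A <- row[["lambda_A"]]
  p$d_NF <- row[["d_NF"]]
  p$d_NT <- row[["d_NT"]]
  p$lambda_TaM1 <- p$lambda_TaM1 * row[["gamma_tilde"]]
  p$lambda_TaMh1 <- p$lambda_TaMh1 * row[["gamma_tilde"]]
  p$lambda_TbM <- p$lambda_TbM * row[["delta"]]
  p$lambda_TbMh <- p$lambda_TbMh * row[["delta"]]
  p$lambda_PA <- p$lambda_PA * row[["xi"]]
  p$lambda_PM2 <- p$lambda_PM2 * row[["xi"]]
  p$d_AboM <- p$d_AboM * row[["epsilon"]]
  p$d_AboMh <- p$d_AboMh * row[["epsilon"]]
  p
}

#' Partial rank correlation coefficients
#'
#' For each design factor, ranks all columns and the output (midranks on
#' ties), removes the influence of the other factors from both the factor and
#' the output by linear regression on the ranks, and correlates the two
#' residual vectors.  Significance is assessed through
#' `t = r * sqrt((n - 2 - p) / (1 - r^2))` with `p` the number of conditioning
#' factors, referred to a t distribution with `n - 2 - p` degrees of freedom.
#'
#' @param design an n-by-k data frame or matrix of sampled factor values.
#' @param output length-n numeric outcome vector.
#' @return Tibble with columns `factor`, `estimate` (PRCC in \[-1, 1\]),
#'   `statistic`, `p_value`.
#' @examples
#' d <- lhs_sample(50, list(a = c(0, 1), b = c(0, 1)), seed = 2)
#' prcc(d, d$a^3 + 0.01 * d$b)
#' @export
prcc <- function(design, output) {
  X <- as.matrix(design)
  if (nrow(X) != length(output)) stop("design and output sizes differ", call. = FALSE)
  cst <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(cst)) {
    stop("constant design column(s): ",
         paste(colnames(X)[cst], collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 3) stop("need at least k + 3 samples for k factors", call. = FALSE)
  Rx <- apply(X, 2, rank)
  Ry <- rank(output)
  res <- lapply(seq_len(k), function(j) {
    Z <- cbind(1, Rx[, -j, drop = FALSE])
    q <- qr(Z)
    rj <- qr.resid(q, Rx[, j])
    ry <- qr.resid(q, Ry)
    r <- sum(rj * ry) / sqrt(sum(rj^2) * sum(ry^2))
    df <- n - 2 - (k - 1)
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(factor = colnames(X)[j], estimate = r, statistic = tval,
                   p_value = 2 * stats::pt(-abs(tval), df))
  })
  dplyr::bind_rows(res)
}

#' Run the Latin hypercube / PRCC sensitivity analysis
#'
#' Draws an LHS design over the eight perturbation factors, simulates the
#' untreated ten-year disease course for every sample, and computes PRCC and
#' p-values of each factor against the final live-neuron density `N` and the
#' final extracellular amyloid-beta concentration `Abo`.  Samples whose
#' simulation fails or returns non-finite endpoints are excluded listwise and
#' counted.
#'
#' @param n number of samples (published analysis: 2000).
#' @param params an [ad_parameters()] set.
#' @param seed RNG seed for the design.
#' @param horizon endpoint time in days.
#' @param factors factor table, see [sensitivity_factors()].
#' @param ... further arguments to [simulate_ad()].
#' @return An object of class `ad_sensitivity`: list with `design` (the
#'   realised sample), `outputs` (endpoint tibble), `prcc` (tidy PRCC table),
#'   `n`, `n_failed`, `seed`.  Use [tidy()] / [glance()] / `autoplot()`.
#' @examples
#' \donttest{
#' s <- run_sensitivity(n = 25, seed = 1)
#' tidy(s)
#' }
#' @export
run_sensitivity <- function(n = 2000, params = ad_parameters(), seed = 1,
                            horizon = 3650, factors = sensitivity_factors(params),
                            ...) {
  design <- lhs_sample(n, factors, seed = seed)
  sim_args <- list(...)
  sims <- purrr::map(seq_len(nrow(design)), function(i) {
    tryCatch({
      p <- .apply_factors(params, unlist(design[i, ]))
      traj <- do.call(simulate_ad, c(list(params = p, horizon = horizon,
                                          times = c(0, horizon)), sim_args))
      fin <- traj[nrow(traj), ]
      c(N = fin$N, Abo = fin$Abo)
    }, error = function(e) c(N = NA_real_, Abo = NA_real_))
  })
  outputs <- tibble::as_tibble(do.call(rbind, sims))
  ok <- stats::complete.cases(outputs) & is.finite(outputs$N) & is.finite(outputs$Abo)
  n_failed <- sum(!ok)
  if (sum(ok) < nrow(factors) + 3) {
    stop("too few successful simulations for PRCC (", sum(ok), ")", call. = FALSE)
  }
  tab <- dplyr::bind_rows(
    dplyr::mutate(prcc(design[ok, ], outputs$N[ok]), output = "N"),
    dplyr::mutate(prcc(design[ok, ], outputs$Abo[ok]), output = "Abo"))
  tab <- dplyr::relocate(tab, "output", .after = "factor")
  structure(list(design = design, outputs = outputs, prcc = tab,
                 n = n, n_failed = n_failed, seed = seed, horizon = horizon),
            class = "ad_sensitivity")
}

#' @export
print.ad_sensitivity <- function(x, ...) {
  cat("<ad_sensitivity> n = ", x$n, " (", x$n_failed, " failed), seed ",
      x$seed, "\n", sep = "")
  print(x$prcc, n = 16)
  invisible(x)
}

#' @rdname run_sensitivity
#' @param x an `ad_sensitivity` object.
#' @param ... unused.
#' @export
tidy.ad_sensitivity <- function(x, ...) x$prcc

#' @rdname run_sensitivity
#' @export
glance.ad_sensitivity <- function(x, ...) {
  tibble::tibble(n = x$n, n_failed = x$n_failed, seed = x$seed,
                 horizon_days = x$horizon,
                 max_p_value = max(x$prcc$p_value))
}
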