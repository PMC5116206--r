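# Run configuration, artifact serialization, and the config-driven driver
# behind the command-line front-end.

#' Write a trajectory as a delimited table
#'
#' Tab-separated, full double precision (17 significant digits) so that
#' re-reading reproduces the in-memory values exactly; species units are
#' recorded in `#` header lines.
#'
#' @param x an `ad_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "ad_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  info <- .ad_species_info()
  writeLines(c("# time: days; years: time/365",
               paste0("# ", info$species, ": ", info$description,
                      " [", info$units, "]")), con)
  df <- as.data.frame(x)
  num <- vapply(df, function(col) formatC(col, digits = 17, format = "g"),
                character(nrow(df)))
  utils::write.table(num, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path input path.
#' @return An `ad_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "numeric")
  out <- tibble::as_tibble(df)
  structure(out, class = c("ad_trajectory", class(out)))
}

.default_run_config <- function() {
  list(
    analysis = "simulate",   # simulate | trial | map | synergy | sensitivity | derive_params
    mode = "wellmixed",      # wellmixed | spatial
    horizon = 3650,
    save_every = 5,
    grid_n = 32,
    abeta_clearance = "mass_action",
    treatments = list(),     # list of {drug, fold, start_day}
    start_day = 300,
    f_max = 50, h_max = 25, n_f = 11, n_h = 11,
    sensitivity_n = 2000,
    seed = 1,
    out_dir = "alzsim-run",
    parameters = list())
}

#' Read a run configuration file
#'
#' A flat YAML file; omitted keys take the published defaults, so an empty
#' file reproduces the baseline untreated run.
#'
#' @param path YAML file path.
#' @return A run-config list.
#' @export
read_run_config <- function(path) {
  cfg <- .default_run_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (length(user) == 0) return(cfg)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .merge_config(cfg, user)
}

# modifyList drops unnamed nested entries, so the treatment list (a list of
# unnamed specs) is carried over verbatim
.merge_config <- function(cfg, user) {
  out <- utils::modifyList(cfg, user[setdiff(names(user), "treatments")])
  if (!is.null(user$treatments)) out$treatments <- user$treatments
  out
}

#' Execute a configured analysis and write its artifacts
#'
#' Runs one of the package's workflows — a baseline or treated simulation, a
#' single-drug trial, the efficacy or synergy map, the sensitivity analysis,
#' or the parameter-derivation table — and writes the resulting delimited
#' tables plus a YAML manifest (parameter hash, seed, package and R versions)
#' sufficient to reproduce the artifacts.
#'
#' @param config a run-config list (see [read_run_config()]), or a path to a
#'   YAML config file.
#' @return Invisibly, a named list of the objects written.
#' @export
ad_run <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- .merge_config(.default_run_config(), config)
  params <- do.call(ad_parameters, cfg$parameters)
  treatment <- lapply(cfg$treatments, function(s) {
    ad_treatment(s$drug, s$fold,
                 if (is.null(s$start_day)) cfg$start_day else s$start_day)
  })
  if (length(treatment) == 0) treatment <- NULL
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(cfg$out_dir, name)
  set.seed(cfg$seed)
  times <- seq(0, cfg$horizon, by = cfg$save_every)
  out <- list()

  if (cfg$analysis %in% c("simulate", "trial")) {
    simulate_fn <- function(trt) {
      if (cfg$mode == "spatial") {
        simulate_ad_spatial(params, trt, grid = ad_grid(cfg$grid_n),
                            horizon = cfg$horizon, times = times,
                            abeta_clearance = cfg$abeta_clearance)
      } else {
        simulate_ad(params, trt, horizon = cfg$horizon, times = times,
                    abeta_clearance = cfg$abeta_clearance,
                    restart_at = cfg$start_day)
      }
    }
    if (cfg$analysis == "simulate") {
      out$trajectory <- simulate_fn(treatment)
      write_trajectory(out$trajectory, art("trajectory.tsv"))
    } else {
      if (length(treatment) == 0) stop("trial analysis needs treatments", call. = FALSE)
      out$untreated <- simulate_fn(NULL)
      out$treated <- simulate_fn(treatment)
      write_trajectory(out$untreated, art("untreated.tsv"))
      write_trajectory(out$treated, art("treated.tsv"))
      fu <- out$untreated[nrow(out$untreated), ]
      ft <- out$treated[nrow(out$treated), ]
      n0 <- out$untreated$N[1]
      out$summary <- tibble::tibble(
        E_N = (ft$N - fu$N) / fu$N,
        E_Abeta = (fu$Abo - ft$Abo) / fu$Abo,
        death_reduction = ((n0 - fu$N) - (n0 - ft$N)) / (n0 - fu$N))
      utils::write.table(out$summary, art("efficacy_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else if (cfg$analysis == "map") {
    out$map <- efficacy_map(cfg$f_max, cfg$h_max, cfg$n_f, cfg$n_h,
                            params = params, horizon = cfg$horizon,
                            start_day = cfg$start_day,
                            abeta_clearance = cfg$abeta_clearance)
    utils::write.table(as.data.frame(out$map), art("efficacy_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (cfg$analysis == "synergy") {
    out$synergy <- synergy_map(cfg$f_max, cfg$h_max, cfg$n_f, cfg$n_h,
                               params = params, horizon = cfg$horizon,
                               start_day = cfg$start_day,
                               abeta_clearance = cfg$abeta_clearance)
    utils::write.table(as.data.frame(out$synergy), art("synergy_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (cfg$analysis == "sensitivity") {
    out$sensitivity <- run_sensitivity(cfg$sensitivity_n, params,
                                       seed = cfg$seed, horizon = cfg$horizon,
                                       abeta_clearance = cfg$abeta_clearance)
    utils::write.table(as.data.frame(tidy(out$sensitivity)),
                       art("prcc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(out$sensitivity$design),
                       art("design.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (cfg$analysis == "derive_params") {
    out$derivations <- derive_appendix_parameters()
    utils::write.table(as.data.frame(out$derivations), art("derivations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_parameters(params, art("parameters.tsv"))
  } else {
    stop("unknown analysis: ", cfg$analysis, call. = FALSE)
  }

  manifest <- list(
    analysis = cfg$analysis, mode = cfg$mode, seed = cfg$seed,
    horizon = cfg$horizon, abeta_clearance = cfg$abeta_clearance,
    params_hash = rlang::hash(unclass(params)),
    config = cfg,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("alzsim")))
  yaml::write_yaml(manifest, art("manifest.yaml"))
  invisible(out)
}
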