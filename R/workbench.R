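#' Read an experiment configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Write an experiment configuration
#'
#' @param config named list.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

config_keys <- list(
  common = c("experiment", "seed", "out_dir", "tau_m", "gamma", "phi_max",
             "mechanism", "g_w", "tau_w", "tau_s"),
  connectivity = c("N", "C_E", "C_I", "J", "g", "radius", "allow_self"),
  filters = character(),
  phase_diagram_popavg = c("j_eff_grid", "g_w_grid"),
  phase_diagram_hetero = c("g_w_grid", "tau_w_grid"),
  simulate = c("N", "C_E", "C_I", "J", "g", "radius", "allow_self", "T", "dt",
               "sigma_eta", "store_every", "perturbation"),
  dmft = c("J_eff", "J_cs", "sigma_eta", "alpha", "tol", "max_iter", "T",
           "dt", "trials"),
  timescale = c("autocorr_csv"),
  make_fixtures = character()
)

validate_config <- function(config) {
  if (is.null(config$experiment) ||
      !config$experiment %in% names(config_keys)[-1])
    abort(paste("config needs an `experiment` key, one of:",
                paste(names(config_keys)[-1], collapse = ", ")))
  allowed <- c(config_keys$common, config_keys[[config$experiment]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0)
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  invisible(config)
}

params_from_config <- function(config) {
  unit_params(mechanism = config$mechanism %||% "adaptation",
              tau_m = config$tau_m %||% 1,
              g_w = config$g_w, tau_w = config$tau_w, tau_s = config$tau_s,
              gamma = config$gamma %||% -0.5,
              phi_max = config$phi_max %||% 2)
}

spec_from_config <- function(config, seed) {
  connectivity_spec(N = config$N %||% 3000, C_E = config$C_E %||% 80,
                    C_I = config$C_I %||% 20, J = config$J,
                    g = config$g %||% 4.1, radius = config$radius,
                    seed = seed, allow_self = isTRUE(config$allow_self))
}

#' Run a configured experiment and write its artifacts
#'
#' Dispatches on `config$experiment` (one of `connectivity`, `filters`,
#' `phase_diagram_popavg`, `phase_diagram_hetero`, `simulate`, `dmft`,
#' `timescale`, `make_fixtures`), writes delimited-text/JSON/MatrixMarket
#' artifacts into `out_dir` and a `manifest.json` recording the seed, package
#' version and a hash of the canonical configuration. Unknown configuration
#' keys are rejected.
#'
#' @param config named list (see [read_config()]) or a path to a config file.
#' @param out_dir output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return invisibly, a character vector of the files written.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  exp_ <- config$experiment
  files <- character()
  out <- function(name) file.path(out_dir, name)

  if (exp_ == "connectivity") {
    W <- build_connectivity(spec_from_config(config,
                                             derive_seed(seed, "connectivity")))
    write_connectivity(W, out("W.mtx"))
    files <- c(out("W.mtx"), out("W.mtx.json"))
  } else if (exp_ == "filters") {
    p <- params_from_config(config)
    h <- if (p$mechanism == "adaptation")
      adaptive_filter(p$tau_m, p$tau_w, p$g_w)
    else synaptic_filter(p$tau_m, p$tau_s)
    t <- seq(0, 8 * max(-1 / Re(h$lambda)), length.out = 500)
    utils::write.csv(data.frame(t = t, h = filter_evaluate(h, t)),
                     out("filter.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(tau_corr = filter_timescale(h)$tau_corr,
           area = filter_area(h),
           variance_gain = white_noise_variance_gain(h)),
      out("filter_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(out("filter.csv"), out("filter_summary.json"))
  } else if (exp_ == "phase_diagram_popavg") {
    p <- params_from_config(config)
    pd <- popavg_phase_diagram(p, config$j_eff_grid,
                               g_w_grid = config$g_w_grid)
    utils::write.csv(pd, out("popavg_diagram.csv"), row.names = FALSE)
    files <- out("popavg_diagram.csv")
  } else if (exp_ == "phase_diagram_hetero") {
    p <- params_from_config(config)
    pd <- hetero_phase_diagram(config$g_w_grid, config$tau_w_grid,
                               tau_m = p$tau_m, gamma = p$gamma,
                               phi_max = p$phi_max)
    utils::write.csv(pd, out("hetero_diagram.csv"), row.names = FALSE)
    files <- out("hetero_diagram.csv")
  } else if (exp_ == "simulate") {
    p <- params_from_config(config)
    W <- build_connectivity(spec_from_config(config,
                                             derive_seed(seed, "connectivity")))
    tr <- simulate_network(W, p,
                           noise = noise_params(config$sigma_eta %||% 0),
                           T = config$T %||% 100,
                           dt = config$dt %||% 0.05 * p$tau_m,
                           perturbation = config$perturbation %||% 0.01,
                           seed = derive_seed(seed, "simulate"),
                           store_every = config$store_every %||% 1L)
    pa <- population_average(tr)
    utils::write.csv(pa, out("population_rate.csv"), row.names = FALSE)
    if (nrow(tr$x) <= 200)
      utils::write.csv(as.data.frame(t(unit_rates(tr))), out("rates.csv"),
                       row.names = FALSE)
    files <- out("population_rate.csv")
  } else if (exp_ == "dmft") {
    p <- params_from_config(config)
    st <- dmft_solve(p, J_eff = config$J_eff, J_cs = config$J_cs,
                     sigma_eta = config$sigma_eta %||% 0,
                     alpha = config$alpha %||% 0.6,
                     tol = config$tol %||% 5e-3,
                     max_iter = config$max_iter %||% 40,
                     T = config$T, dt = config$dt,
                     trials = config$trials %||% 32,
                     seed = derive_seed(seed, "dmft"))
    ts <- envelope_timescale(st$estimate)
    ac <- tidy(st)
    ac$envelope <- ts$envelope$envelope
    utils::write.csv(ac, out("autocorr.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(glance(st)), out("state.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(out("autocorr.csv"), out("state.json"))
  } else if (exp_ == "timescale") {
    ac <- utils::read.csv(config$autocorr_csv)
    ts <- envelope_timescale(ac$C, ac$lag)
    jsonlite::write_json(list(tau_corr = ts$tau_corr, method = ts$method,
                              failed = ts$failed),
                         out("timescale.json"), auto_unbox = TRUE, digits = NA)
    files <- out("timescale.json")
  } else if (exp_ == "make_fixtures") {
    files <- make_fixtures(out_dir, seed = seed)
  }

  cfg_path <- out("config.yaml")
  write_config(config[order(names(config))], cfg_path)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("ratenet")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   experiment = exp_)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, cfg_path, out("manifest.json")))
}

#' Generate the small fixtures used by the test-suite and demos
#'
#' Writes an N = 50 connectivity matrix (MatrixMarket + JSON sidecar) and a
#' 500-step synaptic-network trajectory (CSV of rates) into `dir`.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return character vector of files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- connectivity_spec(N = 50, C_E = 8, C_I = 2, radius = 0.8, g = 4.1,
                            seed = derive_seed(seed, "fixture-W"))
  W <- build_connectivity(spec)
  write_connectivity(W, file.path(dir, "fixture_W.mtx"))
  p <- unit_params("synaptic", tau_s = 2)
  tr <- simulate_network(W, p, T = 25, dt = 0.05,
                         seed = derive_seed(seed, "fixture-traj"))
  utils::write.csv(round(t(unit_rates(tr)), 6),
                   file.path(dir, "fixture_trajectory.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, c("fixture_W.mtx", "fixture_W.mtx.json",
                             "fixture_trajectory.csv")))
}
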