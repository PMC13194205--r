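# Configuration, structured outputs, seeded fixtures and the command-line
# entry points.  Configs are flat sectioned YAML; manifests and spectral
# summaries are JSON; trajectory/sweep summaries are CSV.

config_defaults <- list(
  model = list(figure = NULL, q = NULL, mu = NULL, sigma = NULL, m = NULL),
  grid = list(half_width = 150, n_nodes = 3001),
  run = list(n_gens = NULL, dt = NULL, record_every = 50, initial = "u1"),
  spectral = list(radii = NULL, plateau_tol = 1e-3),
  output = list(directory = ".", formats = c("csv", "json"))
)

#' Read and validate a run configuration
#'
#' Reads a sectioned YAML configuration (sections \code{model}, \code{grid},
#' \code{run}, \code{spectral}, \code{output}), rejects unknown sections or
#' keys by name, materialises every default, and builds the scenario it
#' describes.  The materialised configuration is echoed back so a written
#' copy re-reads identically.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class \code{"run_config"}: the materialised
#'   \code{config} list and the built \code{scenario}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- config_defaults
  for (section in names(raw)) {
    if (!section %in% names(cfg))
      stop("unknown config section: '", section, "'", call. = FALSE)
    for (key in names(raw[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key: '", section, ".", key, "'", call. = FALSE)
      cfg[[section]][[key]] <- raw[[section]][[key]]
    }
  }
  if (is.null(cfg$model$figure))
    stop("config must name 'model.figure'", call. = FALSE)
  scenario <- build_scenario(
    figure = cfg$model$figure,
    q = cfg$model$q, mu = cfg$model$mu, sigma = cfg$model$sigma,
    m = cfg$model$m,
    initial = cfg$run$initial,
    half_width = cfg$grid$half_width, n_nodes = cfg$grid$n_nodes,
    n_gens = cfg$run$n_gens, dt = cfg$run$dt)
  cfg$run$n_gens <- scenario$n_gens
  cfg$run$dt <- scenario$dt
  # drop unset placeholders so a written config re-reads identically
  cfg <- lapply(cfg, function(sec) sec[!vapply(sec, is.null, logical(1))])
  structure(list(config = cfg, scenario = scenario), class = "run_config")
}

#' Write a materialised configuration back to YAML
#'
#' @param rc A \code{"run_config"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  yaml::write_yaml(rc$config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Long-running commands write a manifest first (parameters, package
#' version, defaults) so any output can be reproduced from the manifest
#' alone.
#'
#' @param settings Named list of run settings.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(settings, path) {
  settings$package <- "impulseRAD"
  settings$version <- as.character(utils::packageVersion("impulseRAD"))
  jsonlite::write_json(settings, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Seeded fixtures for property tests
#'
#' Generates, deterministically from \code{seed}: (a) 20 ordered field pairs
#' phi <= psi, with psi a smooth nonnegative Gaussian-bump mixture and phi a
#' pointwise-scaled copy; (b) 5 smooth random fields for operator
#' consistency checks; (c) randomised plateau profiles with scale in
#' [2, 30].  The caller's RNG state is saved and restored, so fixture
#' generation is the only randomness in the package and leaks nowhere.
#'
#' @param seed Integer seed.
#' @param grid A \code{\link{spatial_grid}} (default half-width 50, 501
#'   nodes).
#' @return An object of class \code{"fixture"}: \code{seed}, \code{pairs}
#'   (list of \code{list(phi, psi)}), \code{fields}, \code{profiles}.
#' @export
generate_fixtures <- function(seed, grid = spatial_grid(50, 501)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  x <- grid$nodes
  smooth_field <- function() {
    n_bumps <- sample(2:5, 1)
    centers <- stats::runif(n_bumps, -grid$half_width / 2, grid$half_width / 2)
    widths <- stats::runif(n_bumps, 1, 5)   # widths >= 1 bound the curvature
    amps <- stats::runif(n_bumps, 0.2, 2)
    v <- numeric(grid$n_nodes)
    for (b in seq_len(n_bumps))
      v <- v + amps[b] * exp(-(x - centers[b])^2 / (2 * widths[b]^2))
    density_field(grid, v)
  }
  pairs <- lapply(seq_len(20), function(i) {
    psi <- smooth_field()
    phi <- density_field(grid, psi$values * stats::runif(grid$n_nodes))
    list(phi = phi, psi = psi)
  })
  fields <- lapply(seq_len(5), function(i) smooth_field())
  profiles <- lapply(seq_len(4), function(i) {
    role <- if (i %% 2 == 0) "reproduction" else "mortality"
    plateau_profile(role, stats::runif(1, 2, 30))
  })
  structure(list(seed = as.integer(seed), grid = grid, pairs = pairs,
                 fields = fields, profiles = profiles),
            class = "fixture")
}

log_decision_notes <- function(scenario) {
  notes <- c("diffusivity default D = 1 (not stated in the source scenarios)")
  r <- scenario$model$reaction
  b <- scenario$model$birth
  if (r$family == "logistic_mortality" &&
      startsWith(r$alpha_profile$kind, "periodic"))
    notes <- c(notes, "periodic mortality ascending branch uses the continuity-corrected ramp")
  if (b$family %in% c("beverton_holt", "logistic_nonmonotone") &&
      !is.null(b$r_profile) && startsWith(b$r_profile$kind, "periodic"))
    notes <- c(notes, "periodic reproduction ascending branch uses the continuity-corrected ramp")
  for (msg in notes) warning(msg, call. = FALSE)
  invisible(notes)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, used by the
#' \code{inst/cli/impulseRAD.R} wrapper script.  Commands:
#' \describe{
#'   \item{simulate}{\code{--config <yaml>} or \code{--figure <figN>} plus
#'     variant flags; runs the scenario and writes a manifest, a trajectory
#'     CSV and the final field CSV into \code{--out <dir>}.}
#'   \item{rho}{same scenario flags; writes the spectral sweep CSV and a
#'     JSON summary.}
#'   \item{sweep}{\code{--figure <figN>}; runs the full printed variant grid
#'     of that figure and writes a tidy sweep CSV.}
#'   \item{classify}{\code{--trajectory <csv>}; classifies a saved
#'     trajectory summary.}
#'   \item{fixtures}{\code{--seed <int>}; writes the seeded fixture fields
#'     as CSV.}
#' }
#'
#' @param args Character vector of command-line arguments (default
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return Integer exit status, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L)
      stop("usage: impulseRAD <simulate|rho|sweep|classify|fixtures> [flags]",
           call. = FALSE)
    command <- args[[1L]]
    flags <- parse_flags(args[-1L])
    out_dir <- flags$out %||% "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    switch(command,
      simulate = cli_simulate(flags, out_dir),
      rho = cli_rho(flags, out_dir),
      sweep = cli_sweep(flags, out_dir),
      classify = cli_classify(flags),
      fixtures = cli_fixtures(flags, out_dir),
      stop("unknown command: ", command, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("expected a --flag, got: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    val <- args[[i + 1L]]
    num <- suppressWarnings(as.numeric(val))
    flags[[key]] <- if (!is.na(num)) num else val
    i <- i + 2L
  }
  flags
}

cli_scenario <- function(flags) {
  if (!is.null(flags$config)) return(read_config(flags$config)$scenario)
  if (is.null(flags$figure))
    stop("supply --config <yaml> or --figure <figN>", call. = FALSE)
  build_scenario(figure = flags$figure, q = flags$q, mu = flags$mu,
                 sigma = flags$sigma, m = flags$m,
                 initial = flags$initial %||% "u1",
                 half_width = flags$half_width %||% 150,
                 n_nodes = flags$n_nodes %||% 3001,
                 n_gens = flags$n_gens, dt = flags$dt)
}

scenario_settings <- function(sc, command) {
  list(command = command, scenario = sc$name, figure = sc$figure,
       q = sc$model$q, D = sc$model$D, tau = sc$model$tau,
       kernel_mean = sc$model$kernel$mean, kernel_sd = sc$model$kernel$sd,
       half_width = sc$grid$half_width, n_nodes = sc$grid$n_nodes,
       n_gens = sc$n_gens, dt = sc$dt, initial = sc$initial_kind)
}

cli_simulate <- function(flags, out_dir) {
  sc <- cli_scenario(flags)
  log_decision_notes(sc)
  write_manifest(scenario_settings(sc, "simulate"),
                 file.path(out_dir, paste0(sc$name, "_manifest.json")))
  traj <- run_scenario(sc)
  tab <- trajectory_table(traj)
  tab[] <- lapply(tab, function(col) signif(col, 10))
  utils::write.csv(tab, file.path(out_dir, paste0(sc$name, "_trajectory.csv")),
                   row.names = FALSE)
  fin <- trajectory_final(traj)
  utils::write.csv(
    data.frame(position = signif(sc$grid$nodes, 10),
               density = signif(fin$values, 10)),
    file.path(out_dir, paste0(sc$name, "_final_field.csv")),
    row.names = FALSE)
  rep <- classify_outcome(traj)
  message(sc$name, ": ", rep$classification,
          " (final sup ", signif(rep$final_sup_norm, 4), ")")
}

cli_rho <- function(flags, out_dir) {
  sc <- cli_scenario(flags)
  log_decision_notes(sc)
  sw <- scenario_rho_L(sc)
  utils::write.csv(sweep_table(sw),
                   file.path(out_dir, paste0(sc$name, "_rho_sweep.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = sc$name, rho_L_estimate = sw$rho_L_estimate,
         plateaued = sw$plateaued, rel_change_tail = sw$rel_change_tail,
         settings = sw$settings),
    file.path(out_dir, paste0(sc$name, "_rho_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sc$name, ": rho_L ~ ", signif(sw$rho_L_estimate, 6))
}

figure_grid <- function(figure, ...) {
  variants <- switch(figure,
    fig1 = lapply(c(0.1, 1, 10), function(q) list(q = q)),
    fig2 = do.call(c, lapply(c(0.1, 1, 10), function(q)
      lapply(c(-2, 0, 2), function(mu) list(q = q, mu = mu)))),
    fig3 = do.call(c, lapply(c(1, 2, 5), function(q)
      lapply(c(1, 2, 3), function(s) list(q = q, sigma = s)))),
    fig4 = lapply(c(5, 10, 15, 20, 25), function(m) list(m = m)),
    fig5 = lapply(c(10, 15, 18, 20, 25, 30), function(m) list(m = m)),
    fig6 = do.call(c, lapply(c(1, 2, 5), function(q)
      lapply(c(1, 2, 3), function(s) list(q = q, sigma = s)))),
    stop("unknown figure: ", figure, call. = FALSE))
  lapply(variants, function(v) do.call(build_scenario,
                                       c(list(figure = figure), v, list(...))))
}

cli_sweep <- function(flags, out_dir) {
  if (is.null(flags$figure)) stop("sweep needs --figure", call. = FALSE)
  extra <- flags[names(flags) %in% c("half_width", "n_nodes", "n_gens", "dt")]
  scenarios <- do.call(figure_grid, c(list(figure = flags$figure), extra))
  log_decision_notes(scenarios[[1L]])
  write_manifest(list(command = "sweep", figure = flags$figure,
                      n_scenarios = length(scenarios)),
                 file.path(out_dir, paste0(flags$figure, "_sweep_manifest.json")))
  tab <- run_sweep(scenarios, with_rho = isTRUE(flags$with_rho == 1))
  utils::write.csv(tab, file.path(out_dir, paste0(flags$figure, "_sweep.csv")),
                   row.names = FALSE)
  message("sweep of ", nrow(tab), " scenarios written")
}

cli_classify <- function(flags) {
  if (is.null(flags$trajectory)) stop("classify needs --trajectory",
                                      call. = FALSE)
  tab <- utils::read.csv(flags$trajectory)
  if (!all(c("generation", "sup_norm") %in% names(tab)))
    stop("trajectory CSV needs 'generation' and 'sup_norm' columns",
         call. = FALSE)
  s <- tab$sup_norm
  fake <- structure(list(sup_norms = s, n_total = length(s) - 1L,
                         fields = list(), gens_recorded = integer(0)),
                    class = "generation_trajectory")
  final <- s[length(s)]
  window <- min(100L, length(s) - 1L)
  tail_s <- s[seq(length(s) - window + 1L, length(s))]
  cls <- if (final < 1e-6) "extinct"
         else if ((max(tail_s) - min(tail_s)) / max(tail_s) < 0.01 &&
                  final > 1e-3) "persistent"
         else "undetermined"
  message("classification: ", cls, " (final sup ", signif(final, 4), ")")
}

cli_fixtures <- function(flags, out_dir) {
  seed <- flags$seed %||% 0
  fx <- generate_fixtures(seed)
  mat <- do.call(cbind, lapply(fx$fields, function(f) f$values))
  colnames(mat) <- paste0("field", seq_len(ncol(mat)))
  utils::write.csv(
    cbind(data.frame(position = fx$grid$nodes), as.data.frame(mat)),
    file.path(out_dir, sprintf("fixtures_seed%d.csv", as.integer(seed))),
    row.names = FALSE)
  message("fixtures for seed ", as.integer(seed), " written")
}
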