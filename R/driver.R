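# ---- genotype presets --------------------------------------------------------

#' Genotype presets
#'
#' The four modelled genotypes differ only in the amplitude of the auxin
#' production noise and in whether CUC1 is produced: wild type
#' (`sd_aux = 0.1`, `prod_cuc = 1`), `cuc1` (0.1, 0), `drmy1` (1, 1) and
#' `drmy1_cuc1` (1, 0).
#'
#' @param name one of `"WT"`, `"cuc1"`, `"drmy1"`, `"drmy1_cuc1"`
#' @return a list with `name`, `sd_aux`, `prod_cuc`
#' @export
genotype_preset <- function(name) {
  presets <- list(
    WT         = list(sd_aux = 0.1, prod_cuc = 1),
    cuc1       = list(sd_aux = 0.1, prod_cuc = 0),
    drmy1      = list(sd_aux = 1,   prod_cuc = 1),
    drmy1_cuc1 = list(sd_aux = 1,   prod_cuc = 0))
  name <- gsub("[ -]", "_", name)
  if (!name %in% names(presets))
    stop("unknown genotype '", name, "'; valid names: ",
         paste(names(presets), collapse = ", "))
  c(list(name = name), presets[[name]])
}

# ---- configuration -----------------------------------------------------------

#' Simulation configuration
#'
#' Assembles the full parameter set of a run. The genotype preset fixes the
#' noise amplitude and CUC1 production; any chemistry or mechanics field can
#' still be overridden explicitly through `chemistry` / `mechanics`.
#'
#' @param genotype genotype name or the result of [genotype_preset()]
#' @param growth_rate wall extensibility g (0.4 low, 0.8 reference, 1.2 high)
#' @param n_iterations number of driver iterations
#' @param seed integer seed; fully determines the run
#' @param snapshot_every snapshot interval in iterations
#' @param mechanics a [mechanics_params()] list
#' @param chemistry a [chem_params()] list (its `sd_aux`/`prod_cuc` are
#'   overwritten by the genotype preset unless `apply_genotype = FALSE`)
#' @param division_area_thres cell division area threshold (um^2)
#' @param max_wall_len maximum wall segment length (um)
#' @param frozen_noise draw the production noise once at initialisation only
#' @param apply_genotype whether the genotype preset overrides
#'   `chemistry$sd_aux` and `chemistry$prod_cuc`
#' @return a `sim_config` list
#' @export
sim_config <- function(genotype = "WT", growth_rate = 0.8,
                       n_iterations = 100L, seed = 1L, snapshot_every = 10L,
                       mechanics = mechanics_params(),
                       chemistry = chem_params(),
                       division_area_thres = 50, max_wall_len = 1,
                       frozen_noise = FALSE, apply_genotype = TRUE) {
  stopifnot(n_iterations >= 1, snapshot_every >= 1, growth_rate >= 0,
            division_area_thres > 0, max_wall_len > 0)
  if (is.character(genotype)) genotype <- genotype_preset(genotype)
  if (apply_genotype) {
    chemistry$sd_aux <- genotype$sd_aux
    chemistry$prod_cuc <- genotype$prod_cuc
  }
  chemistry$frozen_noise <- isTRUE(frozen_noise)
  structure(list(genotype = genotype, growth_rate = growth_rate,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every),
                 mechanics = mechanics, chemistry = chemistry,
                 division_area_thres = division_area_thres,
                 max_wall_len = max_wall_len,
                 frozen_noise = isTRUE(frozen_noise)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> genotype ", x$genotype$name,
      " (sd_aux ", x$chemistry$sd_aux, ", prod_cuc ", x$chemistry$prod_cuc,
      "), g = ", x$growth_rate, ", ", x$n_iterations, " iterations, seed ",
      x$seed, if (x$frozen_noise) ", frozen noise" else "", "\n", sep = "")
  invisible(x)
}

# ---- one iteration -----------------------------------------------------------

#' Run one simulation iteration
#'
#' Executes, in order: (1) relaxation of the wall network to mechanical
#' equilibrium; (2) dilution of auxin and CUC1 by the relaxation-induced area
#' changes; (3) redraw of the auxin production noise; (4) the chemistry pass
#' (`n_substeps` substeps); (5) a division pass over every cell whose area
#' exceeds the threshold; (6) subdivision of over-long walls; (7) rest-length
#' growth; (8) reinitialisation of cached adjacency structures; (9) data
#' output (snapshot flag). The executed stage names are recorded in
#' `attr(, "stage_log")`.
#'
#' @param state a list with elements `mesh` and `areas` (cell areas at the end
#'   of the previous iteration), as produced by this function
#' @param config a [sim_config()]
#' @return the updated state list
#' @export
run_iteration <- function(state, config) {
  mesh <- state$mesh
  log <- character(0)

  mesh <- relax_to_equilibrium(mesh, config$mechanics)
  log <- c(log, "relax_to_equilibrium")

  areas_now <- cell_areas(mesh)
  mesh <- dilute_concentrations(mesh, state$areas, areas_now)
  log <- c(log, "dilute_concentrations")

  mesh <- draw_noise(mesh, config$chemistry$sd_aux,
                     frozen = config$chemistry$frozen_noise, at_init = FALSE)
  log <- c(log, "draw_noise")

  mesh <- run_chemistry(mesh, config$chemistry)
  log <- c(log, sprintf("run_chemistry[%d]", config$chemistry$n_substeps))

  over <- which(areas_now > config$division_area_thres)
  for (cc in over) mesh <- divide_cell(mesh, cc)   # one division per cell
  log <- c(log, "division_pass")

  mesh <- split_long_walls(mesh, config$max_wall_len)
  log <- c(log, "split_long_walls")

  mesh <- grow_rest_lengths(mesh, growth_params(g = config$growth_rate))
  log <- c(log, "grow_rest_lengths")

  # reinitialisation: rebuild cached adjacency; state-neutral by construction
  pairs <- cell_pairs(mesh)
  log <- c(log, "reinitialize")

  mesh$iteration <- mesh$iteration + 1L
  due <- mesh$iteration %% config$snapshot_every == 0L
  log <- c(log, "data_output")

  state$mesh <- mesh
  state$areas <- cell_areas(mesh)
  state$snapshot_due <- due
  state$pairs <- pairs
  attr(state, "stage_log") <- log
  state
}

# ---- full simulation ---------------------------------------------------------

#' Run a full simulation
#'
#' Starts from the packaged disk (or a supplied mesh) with `aux = cuc = 0`,
#' apolar length-proportional PIN and freshly drawn production noise, then
#' runs `n_iterations` of [run_iteration()]. Snapshots are kept at iteration
#' 0, every `snapshot_every` iterations, and the final iteration. The run is
#' fully reproducible from the configuration (including its seed).
#'
#' @param config a [sim_config()]
#' @param mesh optional starting `tissue_mesh` (defaults to the packaged disk)
#' @return a `trajectory`: list with `snapshots` (named by iteration),
#'   `config` and `diagnostics`
#' @export
run_simulation <- function(config = sim_config(), mesh = NULL) {
  set.seed(config$seed)
  if (is.null(mesh)) mesh <- load_default_disk()
  mesh$aux <- numeric(n_cells(mesh))
  mesh$cuc <- numeric(n_cells(mesh))
  mesh$iteration <- 0L
  mesh <- init_pin(mesh)
  mesh <- draw_noise(mesh, config$chemistry$sd_aux,
                     frozen = config$chemistry$frozen_noise, at_init = TRUE)
  state <- list(mesh = mesh, areas = cell_areas(mesh))
  snapshots <- list("0" = mesh)
  diag <- data.frame(iteration = integer(0), cells = integer(0),
                     relax_steps = integer(0), relax_residual = numeric(0))
  last_good <- mesh
  for (it in seq_len(config$n_iterations)) {
    state <- tryCatch(run_iteration(state, config), error = function(e) e)
    if (inherits(state, "error")) {
      snapshots[[as.character(it - 1L)]] <- last_good
      out <- structure(list(snapshots = snapshots, config = config,
                            diagnostics = diag, error = conditionMessage(state)),
                       class = "trajectory")
      stop("simulation aborted at iteration ", it, ": ",
           conditionMessage(state))
    }
    rl <- attr(state$mesh, "relax")
    diag <- rbind(diag, data.frame(iteration = it, cells = n_cells(state$mesh),
                                   relax_steps = rl$steps,
                                   relax_residual = rl$residual))
    if (state$snapshot_due || it == config$n_iterations)
      snapshots[[as.character(it)]] <- state$mesh
    last_good <- state$mesh
  }
  structure(list(snapshots = snapshots, config = config, diagnostics = diag),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  fin <- final_snapshot(x)
  cat("<trajectory> ", x$config$genotype$name, ", g = ", x$config$growth_rate,
      ", ", x$config$n_iterations, " iterations, seed ", x$config$seed, "\n",
      "  ", length(x$snapshots), " snapshots; final tissue: ", n_cells(fin),
      " cells, max aux ", format(max(fin$aux), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Final snapshot of a trajectory
#' @param trajectory a `trajectory` from [run_simulation()]
#' @return a `tissue_mesh`
#' @export
final_snapshot <- function(trajectory) {
  its <- as.integer(names(trajectory$snapshots))
  trajectory$snapshots[[which.max(its)]]
}

# ---- ensembles ---------------------------------------------------------------

#' Run an ensemble of simulations
#'
#' Runs `n_runs` simulations with seeds `base_seed ... base_seed + n_runs - 1`
#' and collects per-run robustness summaries of the final snapshot. Individual
#' run failures are recorded and skipped; more than 10% failures abort the
#' ensemble.
#'
#' @param config_template a [sim_config()]; its seed is replaced per run
#' @param n_runs number of runs
#' @param base_seed first seed
#' @param mesh optional starting mesh passed to every run
#' @return a data.frame with one row per run: `seed`, `genotype`,
#'   `growth_rate`, `frozen_noise`, `maxima_count`, `mean_max_aux`,
#'   `angular_cv`, `n_cells`
#' @export
run_ensemble <- function(config_template, n_runs, base_seed = 1L, mesh = NULL) {
  stopifnot(n_runs >= 1)
  rows <- vector("list", n_runs)
  failures <- character(0)
  for (r in seq_len(n_runs)) {
    cfg <- config_template
    cfg$seed <- as.integer(base_seed + r - 1L)
    cfg$snapshot_every <- cfg$n_iterations   # summaries need the final state only
    res <- tryCatch({
      traj <- run_simulation(cfg, mesh = mesh)
      s <- summarize_run(traj)
      data.frame(seed = cfg$seed, genotype = cfg$genotype$name,
                 growth_rate = cfg$growth_rate,
                 frozen_noise = cfg$frozen_noise,
                 maxima_count = s$maxima_count,
                 mean_max_aux = s$mean_max_aux,
                 angular_cv = s$angular_cv,
                 n_cells = n_cells(final_snapshot(traj)))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures <- c(failures, sprintf("seed %d: %s", cfg$seed, res))
    else rows[[r]] <- res
  }
  if (length(failures) > 0.1 * n_runs)
    stop("ensemble failed: ", length(failures), "/", n_runs, " runs errored; first: ",
         failures[1L])
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
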