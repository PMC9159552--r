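#' Run configuration
#'
#' Reads and validates a YAML run configuration with one section per stage:
#' `tiling` (kind, nx or n/L/d_min, seeds), `model` (k, gamma_p_ratio, a0,
#' gamma, p0 list), `predeform` (a), `protocol` (mode, eps0,
#' samples_per_cycle, cycles_per_block, max_blocks, steady_rel_tol),
#' `frequencies` (omega list), and `output` (dir). Defaults are the study
#' conditions: `eps0 = 1e-7`, 25 samples per cycle, `Gamma/(K A0) = 0.289`,
#' kick `sigma = 1.5e-4 sqrt(A0)`.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    tiling = list(kind = "hexagonal", nx = 15, n = 200, L = 15,
                  d_min = NULL, seeds = 1L),
    model = list(k = 1, gamma_p_ratio = 0.289, a0 = NULL, gamma = 1,
                 p0 = 3.65, sigma_kick = NULL),
    predeform = list(a = 1),
    protocol = list(mode = "shear", eps0 = 1e-7, samples_per_cycle = 25,
                    cycles_per_block = 3, max_blocks = 40,
                    steady_rel_tol = 1e-3),
    frequencies = list(omega = 10^seq(-2, 2, length.out = 5)),
    fit = list(model = "auto"),
    phase = list(p0_grid = seq(3.6, 3.8, by = 0.01), a = 1),
    output = list(dir = tempfile("vertexrheo_run_"))
  )
  for (sec in names(defaults)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
    for (key in names(defaults[[sec]])) {
      if (is.null(cfg[[sec]][[key]])) cfg[[sec]][[key]] <- defaults[[sec]][[key]]
    }
  }
  stopifnot(cfg$tiling$kind %in% c("hexagonal", "disordered"),
            all(unlist(cfg$model$p0) >= 0),
            cfg$protocol$eps0 > 0,
            all(unlist(cfg$frequencies$omega) > 0),
            cfg$predeform$a > 0)
  structure(cfg, class = c("run_config", "list"))
}

cfg_params <- function(cfg, p0, a0) {
  model_params(p0 = p0, k = cfg$model$k,
               gamma_p = cfg$model$gamma_p_ratio * cfg$model$k * a0,
               a0 = a0, gamma = cfg$model$gamma)
}

cfg_build_one <- function(cfg, seed) {
  if (cfg$tiling$kind == "hexagonal") {
    mesh <- hex_tiling(cfg$tiling$nx, a0 = cfg$model$a0 %||% 1)
  } else {
    mesh <- disordered_tiling(n = cfg$tiling$n, L = cfg$tiling$L,
                              d_min = cfg$tiling$d_min %||%
                                (0.5 * sqrt(cfg$tiling$L^2 / cfg$tiling$n)),
                              seed = seed)
  }
  mesh
}

cfg_a0 <- function(cfg, mesh) cfg$model$a0 %||% mesh$meta$a0 %||% 1

#' Pipeline stages
#'
#' `cmd_generate()` builds (and, when needed, relaxes) the configured
#' tilings and writes mesh JSON + VTK files. `cmd_sweep()` runs frequency
#' sweeps for every configured `p0` and seed and writes modulus-curve CSVs.
#' `cmd_fit()` fits the configured spring-dashpot model to each curve CSV
#' and writes fit JSONs plus a tidy CSV of fitted constants vs `p0`.
#' `cmd_phase()` scans the lowest nontranslational Hessian eigenvalue of the
#' hexagonal lattice over `p0` (and pre-deformation `a`) and writes a phase
#' CSV. All outputs embed the config and seeds; a fixed config reproduces
#' identical files.
#'
#' @param cfg a [run_config()] (or path to one).
#' @return Invisibly, the paths written.
#' @export
cmd_generate <- function(cfg) {
  cfg <- as_config(cfg)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (seed in cfg$tiling$seeds) {
    mesh <- cfg_build_one(cfg, seed)
    a0 <- cfg_a0(cfg, mesh)
    p0 <- cfg$model$p0[[1]]
    params <- cfg_params(cfg, p0, a0)
    if (cfg$tiling$kind == "disordered" || p0 > p_c_hex()) {
      sig <- cfg$model$sigma_kick %||% (1.5e-4 * sqrt(a0))
      mesh <- prepare_fluid_state(mesh, params, sigma = sig, seed = seed)$mesh
    }
    base <- file.path(cfg$output$dir,
                      sprintf("mesh_%s_seed%03d", cfg$tiling$kind, seed))
    write_mesh_json(mesh, paste0(base, ".json"))
    write_mesh_vtk(mesh, paste0(base, ".vtk"))
    paths <- c(paths, paste0(base, c(".json", ".vtk")))
  }
  invisible(paths)
}

as_config <- function(cfg) {
  if (inherits(cfg, "run_config")) cfg else run_config(cfg)
}

#' @rdname cmd_generate
#' @export
cmd_sweep <- function(cfg) {
  cfg <- as_config(cfg)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (seed in cfg$tiling$seeds) {
    mesh0 <- cfg_build_one(cfg, seed)
    a0 <- cfg_a0(cfg, mesh0)
    for (p0 in unlist(cfg$model$p0)) {
      params <- cfg_params(cfg, p0, a0)
      mesh <- mesh0
      if (cfg$predeform$a != 1) {
        mesh <- apply_predeformation(mesh, cfg$predeform$a)
      }
      if (cfg$tiling$kind == "disordered" || p0 > p_c_hex()) {
        sig <- cfg$model$sigma_kick %||% (1.5e-4 * sqrt(a0))
        mesh <- prepare_fluid_state(mesh, params, sigma = sig, seed = seed)$mesh
      }
      curve <- frequency_sweep(
        mesh, params, mode = cfg$protocol$mode,
        omega = unlist(cfg$frequencies$omega) / params$t_star,
        eps0 = cfg$protocol$eps0,
        samples_per_cycle = cfg$protocol$samples_per_cycle,
        cycles_per_block = cfg$protocol$cycles_per_block,
        max_blocks = cfg$protocol$max_blocks,
        steady_rel_tol = cfg$protocol$steady_rel_tol)
      path <- file.path(cfg$output$dir,
                        sprintf("moduli_%s_p0_%.3f_seed%03d.csv",
                                cfg$protocol$mode, p0, seed))
      write_modulus_curve(curve, path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' @rdname cmd_generate
#' @export
cmd_fit <- function(cfg) {
  cfg <- as_config(cfg)
  files <- list.files(cfg$output$dir, pattern = "^moduli_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no modulus curves found; run cmd_sweep first")
  rows <- list()
  paths <- c()
  for (f in files) {
    curve <- read_modulus_curve(f)
    p0 <- attr(curve, "meta")$p0 %||% NA_real_
    kind <- cfg$fit$model
    if (kind == "auto") {
      kind <- if (!is.na(p0) && p0 > p_c_hex()) "burgers" else "sls"
    }
    fit <- try(fit_viscoelastic(curve, model = kind), silent = TRUE)
    if (inherits(fit, "try-error")) next
    out <- sub("\\.csv$", "_fit.json", f)
    jsonlite::write_json(
      list(model = fit$model, coefficients = as.list(coef(fit)),
           timescales = fit$timescales, ssr = fit$ssr,
           converged = fit$converged),
      out, digits = NA, auto_unbox = TRUE)
    paths <- c(paths, out)
    rows[[f]] <- data.frame(file = basename(f), p0 = p0, model = fit$model,
                            t(coef(fit)), ssr = fit$ssr)
  }
  if (length(rows)) {
    tidy <- do.call(rbind, lapply(rows, function(r) {
      miss <- setdiff(c("E2", "E1", "eta1", "eta2"), names(r))
      for (mcol in miss) r[[mcol]] <- NA_real_
      r[c("file", "p0", "model", "E2", "E1", "eta1", "eta2", "ssr")]
    }))
    tp <- file.path(cfg$output$dir, "fitted_constants.csv")
    utils::write.csv(tidy, tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' @rdname cmd_generate
#' @export
cmd_phase <- function(cfg) {
  cfg <- as_config(cfg)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (a in unlist(cfg$phase$a)) {
    base <- hex_tiling(cfg$tiling$nx)
    if (a != 1) base <- apply_predeformation(base, a)
    for (p0 in unlist(cfg$phase$p0_grid)) {
      params <- cfg_params(cfg, p0, 1)
      rep <- suppressWarnings(hessian_spectrum(base, params))
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, p0 = p0, lowest_nontrivial = rep$lowest_nontrivial,
        n_zero_modes = rep$n_nontrivial_zero,
        phase = if (rep$lowest_nontrivial > 0) "solid" else "fluid")
    }
  }
  out <- do.call(rbind, rows)
  path <- file.path(cfg$output$dir, "phase_scan.csv")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run pipeline stages in order
#'
#' @param cfg a [run_config()] or path.
#' @param stages subset of `c("generate", "sweep", "fit", "phase")`.
#' @return Invisibly, a named list of written paths per stage.
#' @export
run_pipeline <- function(cfg, stages = c("generate", "sweep", "fit")) {
  cfg <- as_config(cfg)
  out <- list()
  for (s in stages) {
    out[[s]] <- switch(s,
      generate = cmd_generate(cfg),
      sweep = cmd_sweep(cfg),
      fit = cmd_fit(cfg),
      phase = cmd_phase(cfg),
      stop("unknown stage: ", s))
  }
  invisible(out)
}
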