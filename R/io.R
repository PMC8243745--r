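#' Default run configuration
#'
#' The complete configuration of a run as a plain named list, suitable for
#' JSON serialisation. Unspecified fields in a user config resolve to these
#' values, which are the model's standard parameterisation.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  p <- simulation_params()
  list(
    beta_N = p$beta_N, beta_D = p$beta_D, beta_R = p$beta_R,
    m = p$m, n = p$n, k_t = p$k_t, k_c = p$k_c,
    gamma = p$gamma, gamma_R = p$gamma_R, k_RS = p$k_RS,
    pv_delta = p$pv_delta, dt = p$dt, residual_tol = p$residual_tol,
    max_steps = p$max_steps,
    width = p$lattice$width, height = p$lattice$height,
    init_mean = p$init_mean, init_sd = p$init_sd,
    diff_threshold = p$diff_threshold,
    pv_freeze_NR = p$pv_freeze_NR, residual_type = p$residual_type,
    seed = 1L,
    pv = list(c(ceiling(p$lattice$height / 2),
                ceiling(p$lattice$width / 2))),
    outdir = "limipv-out",
    images = FALSE,
    snapshot_every = 0L,
    sweep = NULL
  )
}

#' Read a JSON run configuration
#'
#' Fields absent from the file fall back to [default_run_config()]; unknown
#' fields are an error (they are almost always typos).
#'
#' @param path Path to a JSON file, or a named list already in memory.
#' @return A complete configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) {
    path
  } else {
    stop("config must be a file path or a named list", call. = FALSE)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  # the default PV cell is the centre of the *configured* lattice
  if (!"pv" %in% names(user)) {
    cfg$pv <- list(c(ceiling(cfg$height / 2), ceiling(cfg$width / 2)))
  }
  # normalise PV list to a matrix (or NULL)
  cfg$pv <- normalize_pv(cfg$pv)
  cfg
}

normalize_pv <- function(pv) {
  if (is.null(pv) || length(pv) == 0L) return(NULL)
  if (is.matrix(pv)) {
    m <- pv
  } else if (is.list(pv)) {
    m <- do.call(rbind, lapply(pv, function(x) as.integer(unlist(x))))
  } else {
    m <- matrix(as.integer(pv), ncol = 2L, byrow = TRUE)
  }
  if (ncol(m) != 2L) stop("pv entries must be (row, col) pairs",
                          call. = FALSE)
  colnames(m) <- c("row", "col")
  m
}

#' Write a run configuration to JSON
#'
#' @param config A configuration list (see [read_run_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$pv)) {
    cfg$pv <- lapply(seq_len(nrow(cfg$pv)),
                     function(i) as.integer(cfg$pv[i, ]))
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  invisible(path)
}

config_to_params <- function(config) {
  simulation_params(
    beta_N = config$beta_N, beta_D = config$beta_D, beta_R = config$beta_R,
    m = config$m, n = config$n, k_t = config$k_t, k_c = config$k_c,
    gamma = config$gamma, gamma_R = config$gamma_R, k_RS = config$k_RS,
    pv_delta = config$pv_delta, dt = config$dt,
    residual_tol = config$residual_tol, max_steps = config$max_steps,
    lattice = lattice_spec(config$width, config$height),
    init_mean = config$init_mean, init_sd = config$init_sd,
    diff_threshold = config$diff_threshold,
    pv_freeze_NR = config$pv_freeze_NR,
    residual_type = config$residual_type
  )
}

write_field_csv <- function(field, path) {
  utils::write.table(field, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a field matrix written by [run_single()]
#' @param path CSV path.
#' @return A numeric matrix.
#' @export
read_field_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

report_to_list <- function(report) {
  if (is.null(report)) return(NULL)
  list(
    ave = report$ave, sd = report$sd,
    neighbor_cells = lapply(seq_len(nrow(report$neighbor_cells)),
                            function(i) as.integer(report$neighbor_cells[i, ])),
    neighbor_diffs = report$neighbor_diffs,
    mean_diff = report$mean_diff,
    log2_mean_diff = report$log2_mean_diff,
    sentinel = report$sentinel,
    cholangiocyte_calls = report$cholangiocyte_calls
  )
}

#' Run a single simulation from a configuration
#'
#' Executes the full pipeline described by the config and writes the
#' artifacts to the output directory: the equilibrium `D`, `N`, `R` fields
#' as three CSV matrices, a JSON summary (`summary.json`) with the seed,
#' step count, residual, convergence flag, the diff report (when PV cells
#' are present) and the resolved configuration, and — when
#' `config$images` is true — grayscale PNG images of the three fields with
#' PV cells cross-marked.
#'
#' @param config A config list or JSON path (passed to
#'   [read_run_config()]).
#' @param outdir Output directory; defaults to `config$outdir`.
#' @param quiet Suppress the progress message.
#' @return Invisibly, a list with the `pv_run` object and the paths written.
#' @export
run_single <- function(config, outdir = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(outdir)) outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- config_to_params(cfg)

  t0 <- Sys.time()
  run <- simulate_pv_case(params, seed = cfg$seed,
                          pv_cells = if (is.null(cfg$pv)) NULL else cfg$pv)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  st <- run$trajectory$final_state

  paths <- c(D = file.path(outdir, "D.csv"),
             N = file.path(outdir, "N.csv"),
             R = file.path(outdir, "R.csv"))
  write_field_csv(st$D, paths[["D"]])
  write_field_csv(st$N, paths[["N"]])
  write_field_csv(st$R, paths[["R"]])

  summary <- list(
    seed = cfg$seed,
    steps = run$trajectory$steps,
    final_residual = run$trajectory$final_residual,
    converged = run$trajectory$converged,
    elapsed_seconds = elapsed,
    diff_report = report_to_list(run$report),
    config = {
      c2 <- cfg
      if (!is.null(c2$pv)) {
        c2$pv <- lapply(seq_len(nrow(c2$pv)),
                        function(i) as.integer(c2$pv[i, ]))
      }
      c2
    }
  )
  spath <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)

  if (isTRUE(cfg$images)) {
    for (f in c("D", "N", "R")) {
      grDevices::png(file.path(outdir, paste0(f, ".png")),
                     width = 480L, height = 480L)
      plot_field(st, f)
      grDevices::dev.off()
    }
  }
  if (!quiet) {
    message(sprintf(
      "run_single: seed %s, %g steps, residual %.3g, %s (%.1fs) -> %s",
      format(cfg$seed), run$trajectory$steps, run$trajectory$final_residual,
      if (run$trajectory$converged) "converged" else "NOT converged",
      elapsed, outdir))
  }
  invisible(list(run = run, paths = paths, summary_path = spath,
                 outdir = outdir))
}

sweep_cell_key <- function(i, j) sprintf("%d,%d", i, j)

#' Run a (possibly multi-panel) 2-D sweep from a configuration
#'
#' The config's `sweep` entry holds `beta_N_values`, `beta_D_values`, a list
#' of `panels` (each an `(m, n)` pair), and optionally `master_seed` and
#' `seed_policy`. For each panel this writes a grid CSV (axes as header row
#' and first column; sentinel cells as the token `"CROSS"`, non-converged as
#' `"NOCONV"`), a JSON sidecar with the full config and every per-cell
#' record (seed, value, code, steps), and a heatmap PNG with sentinel cells
#' cross-marked. Reruns are resumable: cells already present in the sidecar
#' are not recomputed.
#'
#' @param config Config list or JSON path with a `sweep` entry.
#' @param outdir Output directory; defaults to `config$outdir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of `sweep_grid` objects, one per panel.
#' @export
run_sweep <- function(config, outdir = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(cfg$sweep)) stop("config has no 'sweep' entry", call. = FALSE)
  if (is.null(outdir)) outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sw <- cfg$sweep
  bn <- as.numeric(sw$beta_N_values %||% log_axis(1, 1000, 10L))
  bd <- as.numeric(sw$beta_D_values %||% log_axis(1, 1000, 10L))
  panels <- sw$panels %||% list(c(1, 1), c(1, 3), c(2, 1), c(2, 3))
  if (is.matrix(panels)) panels <- asplit(panels, 1L)
  master_seed <- as.integer(sw$master_seed %||% cfg$seed)
  seed_policy <- sw$seed_policy %||% "derived"

  nr <- length(bn); ncl <- length(bd)
  seeds <- if (seed_policy == "derived") {
    matrix(derive_seeds(master_seed, nr * ncl), nr, ncl)
  } else {
    matrix(master_seed, nr, ncl)
  }

  grids <- list()
  for (panel in panels) {
    m <- as.numeric(panel[[1L]])
    n <- as.numeric(panel[[2L]])
    tag <- sprintf("m%g_n%g", m, n)
    sidecar <- file.path(outdir, sprintf("sweep_%s.json", tag))

    records <- list()
    if (file.exists(sidecar)) {
      prev <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
      records <- prev$cells %||% list()
    }
    for (i in seq_len(nr)) {
      for (j in seq_len(ncl)) {
        key <- sweep_cell_key(i, j)
        if (!is.null(records[[key]])) next
        p <- update_params(config_to_params(cfg), beta_N = bn[i],
                           beta_D = bd[j], m = m, n = n)
        cell <- run_sweep_cell(p, seeds[i, j])
        records[[key]] <- cell
        sidecar_obj <- list(config = {
          c2 <- cfg
          c2$pv <- NULL  # sweep places its own central PV cell
          c2$sweep <- list(beta_N_values = bn, beta_D_values = bd,
                           panels = lapply(panels, as.numeric),
                           master_seed = master_seed,
                           seed_policy = seed_policy)
          c2
        }, panel = c(m = m, n = n), cells = records)
        jsonlite::write_json(sidecar_obj, sidecar, auto_unbox = TRUE,
                             digits = NA, na = "null", null = "null",
                             pretty = TRUE)
        if (!quiet) {
          message(sprintf("sweep %s [%d,%d] beta_N=%.3g beta_D=%.3g -> %s",
                          tag, i, j, bn[i], bd[j],
                          records[[key]]$code))
        }
      }
    }

    log2m <- matrix(NA_real_, nr, ncl)
    codem <- matrix(NA_character_, nr, ncl)
    stepsm <- matrix(NA_real_, nr, ncl)
    for (i in seq_len(nr)) for (j in seq_len(ncl)) {
      rec <- records[[sweep_cell_key(i, j)]]
      log2m[i, j] <- if (is.null(rec$log2) || is.na(rec$log2))
        NA_real_ else as.numeric(rec$log2)
      codem[i, j] <- rec$code
      stepsm[i, j] <- if (is.null(rec$steps) || is.na(rec$steps))
        NA_real_ else as.numeric(rec$steps)
    }
    grid <- structure(list(beta_N_values = bn, beta_D_values = bd,
                           panel_params = c(m = m, n = n),
                           log2 = log2m, code = codem, seeds = seeds,
                           steps = stepsm),
                      class = "sweep_grid")
    grids[[tag]] <- grid

    write_sweep_csv(grid, file.path(outdir, sprintf("sweep_%s.csv", tag)))
    grDevices::png(file.path(outdir, sprintf("sweep_%s.png", tag)),
                   width = 560L, height = 520L)
    plot(grid)
    grDevices::dev.off()
  }
  invisible(grids)
}

#' Write a sweep grid as CSV
#'
#' Header row holds the `beta_D` axis, the first column the `beta_N` axis;
#' sentinel cells become `"CROSS"` (`"NOCONV"` for non-converged runs).
#'
#' @param grid A `sweep_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(grid, path) {
  chr <- matrix(format(grid$log2, trim = TRUE), nrow(grid$log2))
  chr[grid$code == "nonconverged"] <- "NOCONV"
  chr[is.na(grid$log2) & grid$code != "nonconverged"] <- "CROSS"
  out <- cbind(beta_N = format(grid$beta_N_values, trim = TRUE), chr)
  colnames(out) <- c("beta_N", format(grid$beta_D_values, trim = TRUE))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
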