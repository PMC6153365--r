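# Scenario orchestration: reproducible runs tying model computations to
# on-disk CSV artifacts. Pure plumbing -- all numerics live in the model,
# phase-plane, bifurcation and population modules.

#' Run a named analysis scenario and write its artifacts
#'
#' Executes one of the package's standard analyses and writes the result as
#' CSV under `out_dir`. Every file carries a comment header recording the
#' parameter checksum, seed and package version, so outputs are traceable
#' and deterministic scenarios are byte-reproducible.
#'
#' Supported kinds and their artifacts:
#' \describe{
#'   \item{`trajectory`}{`trajectory.csv`: time course at `dose` from the
#'     naive state (or `initial`).}
#'   \item{`nullclines`}{`nullclines.csv`: both nullclines at `dose`.}
#'   \item{`steady_states`}{`steady_states.csv`: fixed-point census at
#'     `dose`.}
#'   \item{`bifurcation`}{`branch.csv`: branch continued from the naive
#'     state (or `seed_state`) over `range` of `parameter`.}
#'   \item{`population`}{`composition.csv`: composition table over
#'     `values` of `parameter`.}
#'   \item{`heatmap`}{`heatmap.csv` and `heatmap.ppm` over a 2-D grid.}
#'   \item{`hysteresis`}{`hysteresis.csv`: up/back endpoints.}
#' }
#'
#' @param config Named list. Common fields: `kind`, `out_dir`, `seed`
#'   (default 1), `params_file` (default: packaged parameters), `dose`
#'   (length-3 vector), `n`, `t_end`; kind-specific fields as described
#'   above.
#' @return Character vector of files written, invisibly.
#' @export
run_scenario <- function(config) {
  kinds <- c("trajectory", "nullclines", "steady_states", "bifurcation",
             "population", "heatmap", "hysteresis")
  if (is.null(config$kind) || !(config$kind %in% kinds))
    stop("config$kind must be one of: ", paste(kinds, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  params <- if (!is.null(config$params_file))
    load_parameters(config$params_file) else default_parameters()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dose <- if (is.null(config$dose)) cytokine_dose() else as_dose(config$dose)
  n <- if (is.null(config$n)) 500L else as.integer(config$n)
  t_end <- if (is.null(config$t_end)) 300 else config$t_end
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  header <- c(
    sprintf("# gmpfate %s scenario", config$kind),
    sprintf("# params_checksum: %s", params$checksum),
    sprintf("# seed: %d", seed),
    sprintf("# version: %s",
            as.character(utils::packageVersion("gmpfate"))))
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(as.data.frame(df), con, row.names = FALSE)
    close(con)
    path
  }

  written <- switch(
    config$kind,
    trajectory = {
      x0 <- if (!is.null(config$initial)) as_state(config$initial)
      else naive_steady_state(params)
      tr <- integrate_model(x0, dose, params, t_end = t_end,
                            pre_period = if (is.null(config$pre_period)) 0
                            else config$pre_period)
      df <- as.data.frame(tr)
      df$MCSF <- dose[["MCSF"]]; df$GCSF <- dose[["GCSF"]]
      df$GMCSF <- dose[["GMCSF"]]
      emit(df, "trajectory.csv")
    },
    nullclines = {
      ng <- if (is.null(config$n_grid)) 200L else as.integer(config$n_grid)
      nc <- rbind(nullcline("PU1", dose, params, n_grid = ng),
                  nullcline("CEBP", dose, params, n_grid = ng))
      emit(nc, "nullclines.csv")
    },
    steady_states = {
      emit(find_steady_states(dose, params), "steady_states.csv")
    },
    bifurcation = {
      if (is.null(config$parameter)) stop("bifurcation needs a parameter")
      rng <- if (is.null(config$range)) c(0, 1.5) else config$range
      x0 <- if (!is.null(config$seed_state)) as_state(config$seed_state)
      else naive_steady_state(params)
      sv <- if (is.null(config$seed_value)) 0 else config$seed_value
      br <- continue_branch(x0, config$parameter, sv, rng, params = params)
      emit(br, "branch.csv")
    },
    population = {
      if (is.null(config$parameter)) stop("population needs a parameter")
      vals <- if (is.null(config$values)) seq(0, 1.4, by = 0.2)
      else config$values
      tab <- composition_table(config$parameter, vals, params,
                               base_dose = dose, n = n, seed = seed,
                               t_end = t_end)
      emit(tab, "composition.csv")
    },
    heatmap = {
      hm <- fate_heatmap(config$x_axis, config$y_axis, config$x_values,
                         config$y_values, params, n = n, seed = seed,
                         t_end = t_end)
      p1 <- emit(hm, "heatmap.csv")
      p2 <- write_heatmap_ppm(hm, file.path(config$out_dir, "heatmap.ppm"))
      c(p1, p2)
    },
    hysteresis = {
      if (is.null(config$parameter)) stop("hysteresis needs a parameter")
      uv <- if (is.null(config$up_value)) 1 else config$up_value
      hy <- hysteresis_scan(config$parameter, uv, params, t_end = t_end)
      df <- data.frame(leg = c("up", "back"),
                       rbind(hy$up, hy$back),
                       phenotype = c(hy$phenotype_up, hy$phenotype_back),
                       reversible = hy$reversible)
      emit(df, "hysteresis.csv")
    })
  invisible(written)
}
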