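# Stochastic population simulation: cells differ only in their initial
# conditions, drawn by perturbing the naive steady state multiplicatively.

#' Sample stochastic initial conditions
#'
#' Each cell starts from the naive steady state with every component
#' multiplied by an independent factor drawn from Normal(mean 1, sd 0.2)
#' (configurable), then clamped to `[0, 1]`.
#'
#' @param n Number of cells (>= 1).
#' @param base Base state (typically [naive_steady_state()]).
#' @param seed RNG seed; fixed seed gives a bit-identical sample.
#' @param mean_factor,sd_factor Parameters of the Normal factor
#'   distribution.
#' @return `n x 8` matrix of states, one row per cell.
#' @export
sample_initial_conditions <- function(n, base, seed = NULL,
                                      mean_factor = 1, sd_factor = 0.2) {
  if (n < 1) stop("n must be at least 1")
  if (sd_factor <= 0) stop("sd_factor must be positive")
  base <- as_state(base)
  if (!is.null(seed)) set.seed(seed)
  factors <- matrix(stats::rnorm(n * 8, mean_factor, sd_factor), nrow = n)
  states <- sweep(factors, 2, base, `*`)
  states <- pmin(pmax(states, 0), 1)
  colnames(states) <- PROTEINS
  states
}

#' Classify a trajectory endpoint against the attractors of its dose
#'
#' Assigns the label of the nearest attractor in eight-dimensional Euclidean
#' distance, where each attractor carries the quadrant label of
#' [phenotype_label()]. Endpoints farther than `max_dist` from every
#' attractor are labelled `"other"` with a warning.
#'
#' @param endpoint Converged state vector.
#' @param attractors `gmp_steady_states` data frame (only rows with
#'   `stability == "stable"` are used) computed at the same dose.
#' @param threshold Low/high activity threshold for quadrant labels.
#' @param max_dist Maximum accepted distance to the nearest attractor.
#' @return Phenotype label.
#' @export
classify_phenotype <- function(endpoint, attractors, threshold = 0.5,
                               max_dist = 0.2) {
  endpoint <- as_state(endpoint)
  att <- attractors[attractors$stability == "stable", , drop = FALSE]
  if (nrow(att) == 0) stop("no stable attractors supplied")
  dists <- vapply(seq_len(nrow(att)), function(i)
    sqrt(sum((endpoint - unlist(att[i, PROTEINS]))^2)), 0)
  i <- which.min(dists)
  if (dists[i] > max_dist) {
    warning(sprintf(
      "endpoint is %.3f away from the nearest attractor; labelling 'other'",
      dists[i]))
    return("other")
  }
  phenotype_label(unlist(att[i, PROTEINS]), threshold = threshold)
}

#' Composition of a stochastic cell population under one dose
#'
#' Simulates `n` cells with stochastically perturbed initial conditions to
#' convergence (or `t_end`), classifies every endpoint against the stable
#' attractors at the dose, and tabulates phenotype fractions.
#'
#' @param dose Cytokine dose.
#' @param params Model parameters.
#' @param n Number of cells.
#' @param seed RNG seed (recorded in the result).
#' @param t_end Per-cell integration horizon.
#' @param sd_factor Initial-condition noise level.
#' @param attractors Optional precomputed steady states at `dose`.
#' @param max_nonconverged Error when more than this fraction of cells fails
#'   to converge.
#' @return One-row data frame of class `gmp_composition` with columns
#'   `MCSF`, `GCSF`, `GMCSF`, fractions `GMP`, `GP`, `MO`, `MMDSC`, `other`,
#'   plus `n`, `seed`, `n_nonconverged`. Fractions are integer counts over
#'   `n` and sum to one exactly.
#' @export
population_composition <- function(dose, params, n = 500, seed = 1,
                                   t_end = 300, sd_factor = 0.2,
                                   attractors = NULL,
                                   max_nonconverged = 0.01) {
  dose <- as_dose(dose)
  if (is.null(attractors)) attractors <- find_steady_states(dose, params)
  naive <- naive_steady_state(params)
  ics <- sample_initial_conditions(n, naive, seed = seed,
                                   sd_factor = sd_factor)
  counts <- c(GMP = 0L, GP = 0L, MO = 0L, MMDSC = 0L, other = 0L)
  nonconv <- 0L
  for (i in seq_len(n)) {
    tr <- integrate_model(ics[i, ], dose, params, t_end = t_end,
                          dt = t_end, rtol = 1e-6, atol = 1e-8)
    if (!attr(tr, "converged")) nonconv <- nonconv + 1L
    lab <- suppressWarnings(
      classify_phenotype(final_state(tr), attractors))
    counts[lab] <- counts[lab] + 1L
  }
  if (nonconv > max_nonconverged * n)
    stop(sprintf("%d of %d cells failed to converge by t = %g", nonconv,
                 n, t_end))
  out <- data.frame(t(dose), t(counts / n), n = n, seed = seed,
                    n_nonconverged = nonconv)
  class(out) <- c("gmp_composition", "data.frame")
  out
}

#' Composition table over a dose grid
#'
#' [population_composition()] applied along one cytokine axis; the other
#' two cytokines are held at `base_dose`.
#'
#' @param parameter Cytokine id to sweep.
#' @param values Dose values.
#' @param params Model parameters.
#' @param base_dose Dose of the other cytokines.
#' @inheritParams population_composition
#' @return `gmp_composition` data frame with one row per dose.
#' @export
composition_table <- function(parameter, values, params,
                              base_dose = cytokine_dose(), n = 500,
                              seed = 1, t_end = 300) {
  stopifnot(parameter %in% CYTOKINES)
  rows <- lapply(values, function(v) {
    d <- as_dose(base_dose); d[parameter] <- v
    population_composition(d, params, n = n, seed = seed, t_end = t_end)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gmp_composition", "data.frame")
  out
}

#' RGB color encoding of a population composition
#'
#' Each channel is the cube root of the corresponding phenotype fraction
#' over the largest category: red = granulocyte progenitors, green =
#' M-MDSCs, blue = monocytes, all divided by
#' `phi = max(GP, MMDSC, MO, GMP)`. All-naive populations map to black.
#'
#' @param gp,mmdsc,mo,gmp Phenotype fractions (non-negative, summing to at
#'   most 1).
#' @return Named numeric vector `c(r, g, b)`, each channel in `[0, 1]`.
#' @examples
#' rgb_from_fractions(1, 0, 0, 0)            # pure red
#' rgb_from_fractions(0, 0, 0, 1)            # black
#' @export
rgb_from_fractions <- function(gp, mmdsc, mo, gmp) {
  if (any(c(gp, mmdsc, mo, gmp) < 0)) stop("fractions must be non-negative")
  phi <- max(gp, mmdsc, mo, gmp)
  if (phi <= 0) return(c(r = 0, g = 0, b = 0))
  c(r = (gp / phi)^(1 / 3), g = (mmdsc / phi)^(1 / 3),
    b = (mo / phi)^(1 / 3))
}

#' Fate heat map over a two-cytokine dose grid
#'
#' Simulates a stochastic population at every grid point of a
#' two-dimensional dose plane and colors each pixel with
#' [rgb_from_fractions()]. Either axis may be a single cytokine or an
#' equal-concentration pair (e.g. `"GMCSF+MCSF"`), in which case the axis
#' value is applied to both.
#'
#' @param x_axis,y_axis Cytokine id or `"A+B"` pair.
#' @param x_values,y_values Dose grids.
#' @param params Model parameters.
#' @param n Cells per pixel.
#' @param seed Master seed; each pixel derives its own substream seed so
#'   results do not depend on evaluation order.
#' @param t_end Per-cell integration horizon.
#' @return Data frame of class `gmp_heatmap`: one row per pixel with the
#'   axis values, full dose triple, phenotype fractions, and `r`, `g`, `b`
#'   channels.
#' @export
fate_heatmap <- function(x_axis, y_axis, x_values, y_values, params,
                         n = 500, seed = 1, t_end = 300) {
  parse_axis <- function(a) {
    ids <- strsplit(a, "+", fixed = TRUE)[[1]]
    if (!all(ids %in% CYTOKINES))
      stop("axis must name cytokines from: ", paste(CYTOKINES, collapse = ", "))
    ids
  }
  xs <- parse_axis(x_axis); ys <- parse_axis(y_axis)
  rows <- list()
  k <- 0
  for (yi in seq_along(y_values)) {
    for (xi in seq_along(x_values)) {
      k <- k + 1
      d <- cytokine_dose()
      d[xs] <- x_values[xi]
      d[ys] <- y_values[yi]
      pixel_seed <- (seed * 10007 + k * 101) %% 2147483647
      comp <- population_composition(d, params, n = n, seed = pixel_seed,
                                     t_end = t_end)
      rgb <- rgb_from_fractions(comp$GP, comp$MMDSC, comp$MO, comp$GMP)
      rows[[k]] <- data.frame(x = x_values[xi], y = y_values[yi],
                              comp[, c(CYTOKINES, "GMP", "GP", "MO",
                                       "MMDSC", "other")],
                              r = rgb[["r"]], g = rgb[["g"]], b = rgb[["b"]],
                              n = n, seed = pixel_seed)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gmp_heatmap", "data.frame")
  attr(out, "x_axis") <- x_axis
  attr(out, "y_axis") <- y_axis
  out
}

#' Write a heat map as a plain PPM raster
#'
#' Portable pixmap (P3, plain text) with one pixel per grid cell; rows of
#' the image run from the largest y value (top) to the smallest.
#'
#' @param hm A `gmp_heatmap`.
#' @param path Output file path.
#' @param maxval Color depth.
#' @return `path`, invisibly.
#' @export
write_heatmap_ppm <- function(hm, path, maxval = 255) {
  stopifnot(inherits(hm, "gmp_heatmap"))
  xs <- sort(unique(hm$x)); ys <- sort(unique(hm$y), decreasing = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(length(xs), length(ys)), as.character(maxval)),
             con)
  for (y in ys) {
    row <- hm[hm$y == y, ]
    row <- row[match(xs, row$x), ]
    writeLines(paste(round(row$r * maxval), round(row$g * maxval),
                     round(row$b * maxval), collapse = " "), con)
  }
  invisible(path)
}

#' Minimal GM-CSF dose producing substantial monopoiesis
#'
#' Scans a GM-CSF dose grid (optionally on top of a fixed background dose of
#' the other cytokines) and returns the smallest dose at which the combined
#' monocyte-lineage fraction (MO + M-MDSC) reaches `cutoff`. Used to
#' quantify the G-CSF/GM-CSF crosstalk that lowers the monopoiesis
#' threshold.
#'
#' @param params Model parameters.
#' @param base_dose Background dose (e.g. a small G-CSF level).
#' @param values GM-CSF grid (default a 0.05-spaced grid to 0.6).
#' @param cutoff Monocyte-lineage fraction counted as "substantial"
#'   (default 10%).
#' @param n,seed,t_end Population simulation settings.
#' @return The threshold dose, or `NA` if never reached on the grid.
#' @export
monopoiesis_threshold <- function(params, base_dose = cytokine_dose(),
                                  values = seq(0.05, 0.6, by = 0.05),
                                  cutoff = 0.1, n = 200, seed = 1,
                                  t_end = 300) {
  for (v in values) {
    d <- as_dose(base_dose); d["GMCSF"] <- v
    comp <- population_composition(d, params, n = n, seed = seed,
                                   t_end = t_end)
    if (comp$MO + comp$MMDSC >= cutoff) return(v)
  }
  NA_real_
}
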