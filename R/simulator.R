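#' Simulation parameters
#'
#' The full parameter set of the biofilm growth model plus run controls.
#' Defaults follow the model's reference configuration: a 128 x 40 grid
#' (one cell = 1 um x 1 um), placement block \code{N = 11}, and cutoff
#' \code{a_max = 1e12}.
#'
#' @param w,d Grid width and depth in cells.
#' @param s Inoculation separation distance (cells).
#' @param b Boundary-layer thickness (cells).
#' @param r Nutrient uptake-diffusion ratio (1/cell^2).
#' @param p Characteristic light penetration depth (cells); only used in
#'   light-dependent mode.
#' @param light_dependent Whether division also requires light.
#' @param i_half Light Monod parameter.
#' @param n_half Nutrient Monod parameter.
#' @param N,alpha,beta,a_max Daughter-placement parameters (see
#'   \code{\link{placement_params}}).
#' @param target_biomass Stop once total biomass reaches this count
#'   (exact-target truncation). \code{Inf} disables.
#' @param max_steps Hard cap on time steps.
#' @param p_negligible Stop when the maximum division probability over all
#'   cells falls below this threshold (default 1e-6).
#' @param seed Integer seed; every random draw in a run (division
#'   variates, placement order, placement sampling) consumes one R stream
#'   seeded from it.
#' @param record_states If \code{TRUE}, keep a snapshot state per step.
#' @param validate_ranges If \code{TRUE} (default), error when a parameter
#'   leaves the explored model ranges (s in [1,64], b in [1,16], r in
#'   [0,5], p in [0,30], Monod parameters in [0,1], alpha and beta in
#'   [0,3]); disable to explore wider ranges.
#' @return An object of class \code{"simulation_params"}.
#' @export
simulation_params <- function(w = 128L, d = 40L, s = 32L, b = 7, r = 0.25,
                              p = 2, light_dependent = FALSE, i_half = 0,
                              n_half = 0.25, N = 11L, alpha = 2, beta = 1,
                              a_max = 1e12, target_biomass = 2000,
                              max_steps = 10000L, p_negligible = 1e-6,
                              seed = 1L, record_states = FALSE,
                              validate_ranges = TRUE) {
  if (validate_ranges) {
    chk <- function(val, lo, hi, nm) {
      if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
          val < lo || val > hi)
        stop(sprintf("%s must be in [%g, %g]", nm, lo, hi), call. = FALSE)
    }
    chk(s, 1, 64, "s"); chk(b, 1, 16, "b"); chk(r, 0, 5, "r")
    chk(p, 0, 30, "p"); chk(i_half, 0, 1, "i_half")
    chk(n_half, 0, 1, "n_half"); chk(alpha, 0, 3, "alpha")
    chk(beta, 0, 3, "beta")
  }
  structure(list(config = grid_config(w, d), s = as.integer(s), b = b,
                 r = r, p = p,
                 kinetics = kinetics_params(n_half, i_half, light_dependent),
                 placement = placement_params(N, alpha, beta, a_max),
                 target_biomass = target_biomass,
                 max_steps = as.integer(max_steps),
                 p_negligible = p_negligible, seed = as.integer(seed),
                 record_states = isTRUE(record_states)),
            class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf(paste0("<simulation_params> %dx%d grid, s=%d, b=%g, r=%g, ",
                     "light=%s (p=%g, I1/2=%g), n1/2=%g, alpha=%g, beta=%g, ",
                     "target=%g, seed=%d\n"),
              x$config$w, x$config$d, x$s, x$b, x$r,
              if (x$kinetics$light_dependent) "on" else "off", x$p,
              x$kinetics$i_half, x$kinetics$n_half, x$placement$alpha,
              x$placement$beta, x$target_biomass, x$seed))
  invisible(x)
}

#' Advance the biofilm one time step
#'
#' A time step has two phases: (1) the domain mask, equilibrium nutrient
#' field, and — in light-dependent mode — the light field are computed
#' from the pre-step state; (2) dividing cells are drawn from the Monod
#' division probabilities and daughters are placed sequentially in random
#' order. Uses (and advances) the current R random stream; callers wanting
#' reproducibility seed it (as \code{\link{run_biofilm}} does).
#'
#' @param state A \code{"biofilm_state"}.
#' @param params A \code{\link{simulation_params}}.
#' @param biomass_cap Optional exact-target truncation passed to
#'   \code{\link{place_daughters}}.
#' @return A list: \code{state}, \code{events} (placement events),
#'   \code{max_p} (maximum division probability this step).
#' @export
biofilm_step <- function(state, params, biomass_cap = NULL) {
  stopifnot(inherits(state, "biofilm_state"),
            inherits(params, "simulation_params"))
  mask <- compute_domain_mask(state, params$b)
  nutrient <- solve_nutrient_field(state, mask, params$r)
  light <- if (params$kinetics$light_dependent)
    compute_light_field(state, params$p) else NULL
  prob <- division_probabilities(state, nutrient, light, params$kinetics)
  dividing <- draw_dividing_cells(prob)
  placed <- place_daughters(state, dividing, params$placement,
                            biomass_cap = biomass_cap)
  st <- placed$state
  st$step <- st$step + 1L
  list(state = st, events = placed$events, max_p = max(prob$values))
}

#' Run a biofilm growth simulation
#'
#' Inoculates the lattice and steps the model until the target biomass is
#' reached (exact-target truncation: the final count equals the target),
#' the maximum division probability is negligible, or the step cap is hit.
#' The run is fully deterministic given \code{params$seed}.
#'
#' @param params A \code{\link{simulation_params}}.
#' @return A \code{"biofilm_trajectory"}: final \code{state},
#'   \code{metrics} (one row per recorded step: step, biomass,
#'   mean_thickness, mean_cell_depth, max_p), \code{stop_reason} (one of
#'   \code{"target_biomass"}, \code{"negligible_probability"},
#'   \code{"max_steps"}), and (if requested) \code{states}.
#' @export
run_biofilm <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  state <- inoculate(params$config, params$s)
  cap <- params$target_biomass
  rows <- list()
  states <- if (params$record_states) list(state) else NULL
  record <- function(st, max_p) {
    data.frame(step = st$step, biomass = total_biomass(st),
               mean_thickness = mean_thickness(st),
               mean_cell_depth = mean_cell_depth(st), max_p = max_p)
  }
  rows[[1L]] <- record(state, NA_real_)
  stop_reason <- "max_steps"
  if (total_biomass(state) >= cap) {
    stop_reason <- "target_biomass"
  } else {
    for (i in seq_len(params$max_steps)) {
      stepped <- biofilm_step(state, params,
                              biomass_cap = if (is.finite(cap)) cap else NULL)
      state <- stepped$state
      rows[[length(rows) + 1L]] <- record(state, stepped$max_p)
      if (params$record_states) states[[length(states) + 1L]] <- state
      if (total_biomass(state) >= cap) { stop_reason <- "target_biomass"; break }
      if (stepped$max_p < params$p_negligible) {
        stop_reason <- "negligible_probability"; break
      }
    }
  }
  structure(list(state = state, metrics = do.call(rbind, rows),
                 stop_reason = stop_reason, states = states,
                 params = params),
            class = "biofilm_trajectory")
}

#' @export
print.biofilm_trajectory <- function(x, ...) {
  cat(sprintf("<biofilm_trajectory> %d steps, %d biomass cells, stopped: %s\n",
              x$state$step, total_biomass(x$state), x$stop_reason))
  invisible(x)
}

#' Sweep the model parameter space
#'
#' Draws parameter samples, runs the model on each, and returns one row
#' per sample with the drawn parameters, derived inverse nutrient scarcity
#' \code{b^2 r}, final morphology metrics, and the coverage-versus-depth
#' profile (as columns \code{cov_0 ... cov_{d-1}}). Reproducible from
#' \code{seed}: sample parameters are drawn from one seeded stream, and
#' each run is seeded with its own derived seed.
#'
#' @param n_samples Number of parameter samples.
#' @param seed Integer master seed.
#' @param ranges Named list of \code{c(lo, hi)} ranges to sample uniformly
#'   per parameter; supported names: \code{s}, \code{b}, \code{r},
#'   \code{p}, \code{i_half}, \code{n_half}, \code{alpha}, \code{beta},
#'   \code{inv_ns}, \code{target_biomass}. \code{s} is rounded to an
#'   integer. If \code{inv_ns} is given, \code{1/n_s = b^2 r} is sampled
#'   log-uniformly over its range and \code{r} derived as
#'   \code{inv_ns/b^2} (the nutrient-rich-to-scarce axis is logarithmic);
#'   a plain \code{r} range samples uniformly.
#' @param fixed Named list of parameters held fixed (passed to
#'   \code{\link{simulation_params}}).
#' @param target_biomass Default growth target when not sampled.
#' @param validate_ranges Passed through to
#'   \code{\link{simulation_params}}.
#' @return A data frame with class \code{"biofilm_sweep"}; failed samples
#'   carry \code{ok = FALSE} and NA metrics.
#' @export
sweep_biofilm <- function(n_samples, seed = 1L,
                          ranges = list(b = c(1, 16),
                                        inv_ns = c(1 / 30, 300)),
                          fixed = list(), target_biomass = 2000,
                          validate_ranges = FALSE) {
  stopifnot(n_samples >= 0)
  set.seed(seed)
  draw <- function(nm) stats::runif(n_samples, ranges[[nm]][1L],
                                    ranges[[nm]][2L])
  samp <- list()
  for (nm in setdiff(names(ranges), "inv_ns")) samp[[nm]] <- draw(nm)
  if (!is.null(ranges$inv_ns)) {
    lo <- log(ranges$inv_ns[1L]); hi <- log(ranges$inv_ns[2L])
    inv_ns <- exp(stats::runif(n_samples, lo, hi))
    if (is.null(samp$b)) stop("sampling inv_ns requires a b range")
    samp$r <- inv_ns / samp$b^2
  }
  if (!is.null(samp$s)) samp$s <- pmax(1L, as.integer(round(samp$s)))
  run_seeds <- sample.int(.Machine$integer.max, max(n_samples, 1L))
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    args <- c(list(seed = run_seeds[i], target_biomass = target_biomass,
                   validate_ranges = validate_ranges), fixed)
    for (nm in names(samp)) args[[nm]] <- samp[[nm]][i]
    par_row <- data.frame(
      sample = i, seed = run_seeds[i],
      s = if (is.null(args$s)) formals(simulation_params)$s else args$s,
      b = args$b %||% eval(formals(simulation_params)$b),
      r = args$r %||% eval(formals(simulation_params)$r),
      p = args$p %||% eval(formals(simulation_params)$p),
      i_half = args$i_half %||% eval(formals(simulation_params)$i_half),
      n_half = args$n_half %||% eval(formals(simulation_params)$n_half),
      alpha = args$alpha %||% eval(formals(simulation_params)$alpha),
      beta = args$beta %||% eval(formals(simulation_params)$beta),
      target_biomass = args$target_biomass)
    par_row$inv_ns <- inverse_nutrient_scarcity(par_row$b, par_row$r)
    res <- tryCatch({
      traj <- run_biofilm(do.call(simulation_params, args))
      st <- traj$state
      cov <- coverage_by_depth(st)$coverage
      cbind(par_row,
            data.frame(ok = TRUE, stop_reason = traj$stop_reason,
                       steps = st$step, biomass = total_biomass(st),
                       mean_thickness = mean_thickness(st),
                       mean_cell_depth = mean_cell_depth(st),
                       hull_density = convex_hull_density(st)),
            stats::setNames(as.data.frame(as.list(cov)),
                            paste0("cov_", seq_along(cov) - 1L)))
    }, error = function(e) {
      cbind(par_row, data.frame(ok = FALSE, stop_reason = conditionMessage(e),
                                steps = NA_integer_, biomass = NA_integer_,
                                mean_thickness = NA_real_,
                                mean_cell_depth = NA_real_,
                                hull_density = NA_real_))
    })
    rows[[i]] <- res
  }
  if (n_samples == 0L) {
    out <- data.frame(sample = integer(0), seed = integer(0), s = integer(0),
                      b = numeric(0), r = numeric(0), p = numeric(0),
                      i_half = numeric(0), n_half = numeric(0),
                      alpha = numeric(0), beta = numeric(0),
                      target_biomass = numeric(0), inv_ns = numeric(0),
                      ok = logical(0), stop_reason = character(0),
                      steps = integer(0), biomass = integer(0),
                      mean_thickness = numeric(0),
                      mean_cell_depth = numeric(0), hull_density = numeric(0))
  } else {
    all_names <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(rw) {
      rw[setdiff(all_names, names(rw))] <- NA
      rw[all_names]
    })
    out <- do.call(rbind, rows)
  }
  class(out) <- c("biofilm_sweep", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
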