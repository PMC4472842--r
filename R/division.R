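#' Monod probability factor
#'
#' Saturating Monod kinetics \code{K(y, y_half) = y / (y + y_half)}: the
#' division-probability factor contributed by a resource at level \code{y}
#' with half-saturation \code{y_half}. At \code{y = y_half} a cell divides
#' with probability 1/2 per time step (all other factors unity). With
#' \code{y_half = 0} the resource is non-limiting and the factor is 1 for
#' any \code{y > 0}.
#'
#' @param y Resource level(s), \code{y >= 0}. Vectorized.
#' @param y_half Half-saturation parameter, \code{y_half >= 0}.
#' @return Numeric factor(s) in [0, 1].
#' @export
#' @examples
#' monod(0.25, 0.25) # 0.5
monod <- function(y, y_half) {
  if (any(y < 0) || any(y_half < 0))
    stop("Monod arguments must be non-negative", call. = FALSE)
  if (any(y == 0 & y_half == 0))
    stop("Monod factor undefined at y = y_half = 0", call. = FALSE)
  y / (y + y_half)
}

#' Kinetics parameters for cell division
#'
#' @param n_half Nutrient Monod parameter (relative concentration, [0,1]).
#' @param i_half Light Monod parameter (relative intensity, [0,1]); the
#'   source intensity is absorbed into it.
#' @param light_dependent If \code{TRUE}, division requires light as well
#'   as nutrient.
#' @return An object of class \code{"kinetics_params"}.
#' @export
kinetics_params <- function(n_half = 0.25, i_half = 0,
                            light_dependent = FALSE) {
  stopifnot(is.numeric(n_half), n_half >= 0, n_half <= 1,
            is.numeric(i_half), i_half >= 0, i_half <= 1,
            is.logical(light_dependent))
  structure(list(n_half = n_half, i_half = i_half,
                 light_dependent = light_dependent),
            class = "kinetics_params")
}

#' Per-cell division probabilities
#'
#' For every biomass cell, the per-step division probability is the Monod
#' nutrient factor \code{K(n, n_half)}, multiplied in light-dependent mode
#' by the Monod light factor \code{K(I, i_half)}. Media cells get
#' probability 0.
#'
#' @param state A \code{"biofilm_state"}.
#' @param nutrient_field Nutrient \code{"scalar_field"} for this state.
#' @param light_field Light \code{"scalar_field"}; required in
#'   light-dependent mode, ignored otherwise.
#' @param kinetics A \code{\link{kinetics_params}}.
#' @return A probability \code{"scalar_field"}.
#' @export
division_probabilities <- function(state, nutrient_field,
                                   light_field = NULL, kinetics) {
  stopifnot(inherits(state, "biofilm_state"),
            inherits(nutrient_field, "scalar_field"),
            inherits(kinetics, "kinetics_params"))
  if (nutrient_field$kind != "nutrient")
    stop("nutrient_field must be a nutrient field", call. = FALSE)
  P <- monod(nutrient_field$values, kinetics$n_half)
  if (kinetics$light_dependent) {
    if (is.null(light_field))
      stop("light-dependent mode requires a light field", call. = FALSE)
    stopifnot(inherits(light_field, "scalar_field"))
    P <- P * monod(light_field$values, kinetics$i_half)
  }
  P[state$occ == 0L] <- 0
  scalar_field(P, state$config, "probability")
}

#' Draw the set of dividing cells
#'
#' Each biomass cell divides this step iff \code{P > V} with \code{V}
#' drawn independently, uniform on [0, 1] (strict inequality). Consumes
#' the current R random stream; cells are visited in column-major grid
#' order.
#'
#' @param prob_field Probability \code{"scalar_field"} (media cells 0).
#' @return Integer matrix with columns \code{x}, \code{z} (0-based), one
#'   row per dividing cell.
#' @export
draw_dividing_cells <- function(prob_field) {
  stopifnot(inherits(prob_field, "scalar_field"),
            prob_field$kind == "probability")
  P <- prob_field$values
  w <- nrow(P)
  cand <- which(P > 0)
  if (length(cand) == 0L)
    return(cbind(x = integer(0), z = integer(0)))
  V <- stats::runif(length(cand))
  div <- cand[P[cand] > V]
  cbind(x = as.integer((div - 1L) %% w), z = as.integer((div - 1L) %/% w))
}

#' Daughter-placement parameters
#'
#' @param N Odd block length (cells) of the candidate neighborhood
#'   centered on the parent; default 11.
#' @param alpha Weighting of the placement distance factor (the 1/2 power
#'   of the Euclidean distance is folded into \code{alpha}).
#' @param beta Weighting of the surface-energy factor (surface tension and
#'   kT folded into \code{beta}).
#' @param a_max Normalization cutoff: if the normalization factor
#'   \code{A = 1/sum(R^alpha * S^beta)} exceeds \code{a_max}, no daughter
#'   is placed. Default 1e12.
#' @return An object of class \code{"placement_params"}.
#' @export
placement_params <- function(N = 11L, alpha = 2, beta = 1, a_max = 1e12) {
  N <- as.integer(N)
  stopifnot(length(N) == 1L, N >= 3L, N %% 2L == 1L,
            is.numeric(alpha), alpha >= 0,
            is.numeric(beta), beta >= 0,
            is.numeric(a_max), a_max > 0)
  structure(list(N = N, alpha = alpha, beta = beta, a_max = a_max),
            class = "placement_params")
}

# Internal workhorse: candidate coordinates, weights and probabilities for
# one parent against an occupancy matrix. Returns NULL when skipped.
.placement_raw <- function(occ, w, d, px, pz, params) {
  half <- (params$N - 1L) %/% 2L
  xs <- max(0L, px - half):min(w - 1L, px + half)
  zs <- max(0L, pz - half):min(d - 1L, pz + half)
  cx <- rep(xs, times = length(zs))
  cz <- rep(zs, each = length(xs))
  ci <- cx + 1L + w * cz
  media <- occ[ci] == 0L
  cx <- cx[media]; cz <- cz[media]; ci <- ci[media]
  if (length(ci) == 0L) return(NULL)
  # biomass 4-neighbor count k and in-grid degree per candidate
  k <- integer(length(ci)); deg <- integer(length(ci))
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nx <- cx + s[1L]; nz <- cz + s[2L]
    ok <- nx >= 0L & nx < w & nz >= 0L & nz < d
    deg <- deg + ok
    kk <- integer(length(ci))
    kk[ok] <- occ[nx[ok] + 1L + w * nz[ok]]
    k <- k + kk
  }
  valid <- k > 0L
  if (!any(valid)) return(NULL)
  cx <- cx[valid]; cz <- cz[valid]; ci <- ci[valid]
  dL <- deg[valid] - 2L * k[valid]
  R <- 1 / ((cx - px)^2 + (cz - pz)^2)
  wt <- R^params$alpha * exp(-params$beta * dL)
  tot <- sum(wt)
  if (!is.finite(tot) || tot <= 0 || 1 / tot > params$a_max) return(NULL)
  list(x = cx, z = cz, idx = ci, delta_L = as.integer(dL), weight = wt,
       prob = wt / tot, A = 1 / tot)
}

#' Daughter-cell placement distribution for a dividing cell
#'
#' Over the \code{N x N} block centered on the parent (clipped at grid
#' borders), biomass cells and media cells with no biomass 4-neighbor get
#' probability 0; each remaining candidate at offset (dx, dz) gets
#' probability proportional to \code{R^alpha * S^beta} with distance
#' factor \code{R = 1/(dx^2 + dz^2)} and surface-energy factor
#' \code{S = exp(-dL)}, \code{dL} the perimeter change of placing the
#' daughter there. The distribution is skipped (no daughter) when there
#' are no candidates or the normalization factor \code{A} exceeds
#' \code{a_max}, which corresponds to divisions deep inside the biofilm.
#'
#' @param state A \code{"biofilm_state"}.
#' @param parent Length-2 vector \code{c(x, z)}, 0-based; must be biomass.
#' @param params A \code{\link{placement_params}}.
#' @return A \code{"placement_distribution"}: parent, data frame of
#'   candidates (\code{x}, \code{z}, \code{delta_L}, \code{weight},
#'   \code{prob}), normalization \code{A}, and \code{skipped} flag.
#' @export
placement_distribution <- function(state, parent, params) {
  stopifnot(inherits(state, "biofilm_state"),
            inherits(params, "placement_params"))
  px <- as.integer(parent[[1L]]); pz <- as.integer(parent[[2L]])
  w <- state$config$w; d <- state$config$d
  if (px < 0L || px >= w || pz < 0L || pz >= d ||
      state$occ[px + 1L, pz + 1L] != 1L)
    stop("parent must be a biomass-filled cell", call. = FALSE)
  raw <- .placement_raw(state$occ, w, d, px, pz, params)
  if (is.null(raw)) {
    return(structure(list(parent = c(x = px, z = pz),
                          candidates = data.frame(x = integer(0),
                                                  z = integer(0),
                                                  delta_L = integer(0),
                                                  weight = numeric(0),
                                                  prob = numeric(0)),
                          A = NA_real_, skipped = TRUE),
                     class = "placement_distribution"))
  }
  structure(list(parent = c(x = px, z = pz),
                 candidates = data.frame(x = raw$x, z = raw$z,
                                         delta_L = raw$delta_L,
                                         weight = raw$weight,
                                         prob = raw$prob),
                 A = raw$A, skipped = FALSE),
            class = "placement_distribution")
}

#' @export
print.placement_distribution <- function(x, ...) {
  if (x$skipped)
    cat(sprintf("<placement_distribution> parent (%d,%d): skipped\n",
                x$parent[1L], x$parent[2L]))
  else
    cat(sprintf("<placement_distribution> parent (%d,%d): %d candidates, A = %.4g\n",
                x$parent[1L], x$parent[2L], nrow(x$candidates), x$A))
  invisible(x)
}

#' Place daughter cells for a set of dividing cells
#'
#' Processes the dividing cells in a uniformly random order. For each, the
#' placement distribution is computed against the current state (daughters
#' placed earlier in the same step are visible to later parents) and one
#' daughter cell is sampled and set to biomass. Parents whose distribution
#' is skipped produce no daughter. If \code{biomass_cap} is given,
#' processing stops once total biomass reaches the cap, so runs grown to a
#' prescribed total mass terminate at exactly that count.
#'
#' @param state A \code{"biofilm_state"}.
#' @param dividing Integer matrix with columns \code{x}, \code{z}
#'   (0-based), as returned by \code{\link{draw_dividing_cells}}.
#' @param params A \code{\link{placement_params}}.
#' @param biomass_cap Optional integer: stop placing once total biomass
#'   reaches this count.
#' @return A list: \code{state} (updated) and \code{events}, a data frame
#'   with one row per processed parent (\code{parent_x}, \code{parent_z},
#'   \code{daughter_x}, \code{daughter_z}, \code{skipped}).
#' @export
place_daughters <- function(state, dividing, params, biomass_cap = NULL) {
  stopifnot(inherits(state, "biofilm_state"),
            inherits(params, "placement_params"))
  occ <- state$occ
  w <- state$config$w; d <- state$config$d
  nd <- nrow(dividing)
  ev_px <- ev_pz <- ev_dx <- ev_dz <- integer(0)
  ev_skip <- logical(0)
  if (nd > 0L) {
    ord <- if (nd == 1L) 1L else sample.int(nd)
    total <- sum(occ)
    ev_px <- ev_pz <- ev_dx <- ev_dz <- integer(nd)
    ev_skip <- logical(nd)
    used <- 0L
    for (i in ord) {
      if (!is.null(biomass_cap) && total >= biomass_cap) break
      used <- used + 1L
      px <- dividing[i, 1L]; pz <- dividing[i, 2L]
      ev_px[used] <- px; ev_pz[used] <- pz
      raw <- .placement_raw(occ, w, d, px, pz, params)
      if (is.null(raw)) {
        ev_skip[used] <- TRUE
        ev_dx[used] <- NA_integer_; ev_dz[used] <- NA_integer_
        next
      }
      pick <- if (length(raw$idx) == 1L) 1L
              else sample.int(length(raw$idx), 1L, prob = raw$prob)
      occ[raw$idx[pick]] <- 1L
      total <- total + 1L
      ev_dx[used] <- raw$x[pick]; ev_dz[used] <- raw$z[pick]
    }
    keep <- seq_len(used)
    ev_px <- ev_px[keep]; ev_pz <- ev_pz[keep]
    ev_dx <- ev_dx[keep]; ev_dz <- ev_dz[keep]; ev_skip <- ev_skip[keep]
  }
  state$occ <- occ
  list(state = state,
       events = data.frame(parent_x = ev_px, parent_z = ev_pz,
                           daughter_x = ev_dx, daughter_z = ev_dz,
                           skipped = ev_skip))
}
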