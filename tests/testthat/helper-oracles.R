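# Independent brute-force oracles used to validate the fast implementations.

# Random small biofilm state grown downward from the coverslip so the
# connectivity invariant holds: start from a random coverslip row and
# repeatedly attach random media cells adjacent to biomass.
random_state <- function(w, d, n_extra, seed) {
  set.seed(seed)
  st <- inoculate(grid_config(w, d), s = sample(1:max(1, w %/% 2), 1))
  for (i in seq_len(n_extra)) {
    occ <- st$occ
    cand <- which(occ == 0L)
    if (length(cand) == 0L) break
    adj <- vapply(cand, function(idx) {
      x <- (idx - 1L) %% w; z <- (idx - 1L) %/% w
      nb <- neighbors4(c(x, z), st$config)
      any(occ[nb[, 1L] + 1L + w * nb[, 2L]] == 1L)
    }, logical(1))
    cand <- cand[adj]
    if (length(cand) == 0L) break
    st$occ[cand[sample.int(length(cand), 1L)]] <- 1L
  }
  st
}

# Global-recompute perimeter difference for a hypothetical placement.
oracle_delta_perimeter <- function(state, cell) {
  before <- perimeter(state)
  st2 <- state
  st2$occ[cell[1L] + 1L, cell[2L] + 1L] <- 1L
  perimeter(st2) - before
}

# Exhaustive enumeration of the daughter-placement distribution: loops
# over every cell of the N x N block, applies the candidate rules
# directly, and computes delta-L by global perimeter recomputation.
oracle_placement <- function(state, parent, params) {
  w <- state$config$w; d <- state$config$d
  px <- parent[1L]; pz <- parent[2L]
  half <- (params$N - 1L) %/% 2L
  rows <- list()
  for (x in (px - half):(px + half)) {
    for (z in (pz - half):(pz + half)) {
      if (x < 0L || x >= w || z < 0L || z >= d) next
      if (state$occ[x + 1L, z + 1L] == 1L) next
      nb <- neighbors4(c(x, z), state$config)
      if (!any(state$occ[nb[, 1L] + 1L + w * nb[, 2L]] == 1L)) next
      dL <- oracle_delta_perimeter(state, c(x, z))
      R <- 1 / ((x - px)^2 + (z - pz)^2)
      wt <- R^params$alpha * exp(-dL)^params$beta
      rows[[length(rows) + 1L]] <- data.frame(x = x, z = z, weight = wt)
    }
  }
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)
  tot <- sum(df$weight)
  if (1 / tot > params$a_max) return(NULL)
  df$prob <- df$weight / tot
  df
}

# 1D two-region closed form for a laterally uniform film of height h with
# boundary layer b and uptake-diffusion ratio r: analytic solution of
# n'' = r n in the film (zero flux at z = 0) matched to a linear profile
# across the boundary layer with n = 1 at its outer edge.
uniform_film_closed_form <- function(z, h, r, b) {
  sq <- sqrt(r)
  cosh(sq * z) / (cosh(sq * h) + b * sq * sinh(sq * h))
}

# Laterally uniform film state of height h cells.
uniform_film_state <- function(w, d, h) {
  st <- inoculate(grid_config(w, d), 1L)
  st$occ[, seq_len(h)] <- 1L
  st
}
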