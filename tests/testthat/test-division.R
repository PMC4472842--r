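test_that("Monod factor has the half-saturation and limiting behaviors", {
  expect_identical(monod(0.25, 0.25), 0.5)
  expect_identical(monod(0, 0.3), 0)
  expect_identical(monod(3, 1), 0.75)
  expect_identical(monod(0.7, 0), 1)        # non-limiting resource
  expect_error(monod(0, 0), "undefined")
  expect_error(monod(-1, 0.5), "non-negative")
})

test_that("division probabilities combine nutrient and light Monod factors", {
  st <- inoculate(grid_config(8, 6), 8)
  nf <- scalar_field(matrix(1, 8, 6), st$config, "nutrient")

  # light-independent, n = 1, n1/2 = 0.25 -> P = 0.8 on biomass
  k <- kinetics_params(n_half = 0.25)
  P <- division_probabilities(st, nf, kinetics = k)$values
  expect_equal(P[1, 1], 0.8)
  expect_true(all(P[st$occ == 0L] == 0))

  # light-dependent with I1/2 = 0 reduces to light-independent
  lf <- compute_light_field(st, p = 2)
  k0 <- kinetics_params(n_half = 0.25, i_half = 0, light_dependent = TRUE)
  expect_equal(division_probabilities(st, nf, lf, k0)$values,
               P)

  # single inoculated cell, p = 2, I1/2 = 0.5: P = K(e^-.5, .5) * 0.8
  k1 <- kinetics_params(n_half = 0.25, i_half = 0.5, light_dependent = TRUE)
  P1 <- division_probabilities(st, nf, lf, k1)$values
  expect_equal(P1[1, 1], monod(exp(-0.5), 0.5) * 0.8)

  expect_error(division_probabilities(st, nf, NULL, k1), "light field")
})

test_that("dividing cells are drawn by strict P > V comparison", {
  st <- inoculate(grid_config(100, 100), 1)
  st$occ[] <- 1L
  mk <- function(p) scalar_field(matrix(p, 100, 100), st$config,
                                 "probability")
  set.seed(1)
  expect_equal(nrow(draw_dividing_cells(mk(0))), 0L)
  expect_equal(nrow(draw_dividing_cells(mk(1))), 10000L)
  frac <- nrow(draw_dividing_cells(mk(0.5))) / 1e4
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("placement distribution is symmetric for isolated parents", {
  st <- inoculate(grid_config(21, 21), 21); st$occ[] <- 0L
  st$occ[11, 11] <- 1L
  pd <- placement_distribution(st, c(10, 10), placement_params(alpha = 2,
                                                               beta = 1))
  expect_false(pd$skipped)
  expect_equal(nrow(pd$candidates), 4L)      # only the 4-neighbors qualify
  expect_equal(pd$candidates$prob, rep(0.25, 4))
  expect_equal(sum(pd$candidates$prob), 1)

  # parent on the coverslip: 3 candidates; with beta = 0 all three sit at
  # distance 1 and the distribution is exactly uniform (with beta > 0 the
  # two lateral candidates touch the reflective coverslip border and have
  # a smaller perimeter change than the candidate above, so symmetry is a
  # beta = 0 property)
  st$occ[] <- 0L; st$occ[11, 1] <- 1L
  pd <- placement_distribution(st, c(10, 0),
                               placement_params(alpha = 2, beta = 0))
  expect_equal(nrow(pd$candidates), 3L)
  expect_equal(pd$candidates$prob, rep(1 / 3, 3))

  expect_error(placement_distribution(st, c(0, 5), placement_params()),
               "biomass")
})

test_that("placement distribution equals exhaustive enumeration", {
  # two-cell horizontal biofilm: a hand-checkable asymmetric case
  st <- inoculate(grid_config(15, 15), 15); st$occ[] <- 0L
  st$occ[7, 8] <- st$occ[8, 8] <- 1L
  prm <- placement_params(N = 11, alpha = 2, beta = 1)
  pd <- placement_distribution(st, c(6, 7), prm)
  orc <- oracle_placement(st, c(6, 7), prm)
  key <- function(df) df[order(df$x, df$z), ]
  expect_equal(key(pd$candidates[, c("x", "z", "prob")])$prob,
               key(orc)$prob, tolerance = 1e-12)

  # randomized states and parameter draws
  for (seed in 1:10) {
    st <- random_state(13, 11, 22, seed = 100 + seed)
    prm <- placement_params(N = 11, alpha = stats::runif(1, 0, 3),
                            beta = stats::runif(1, 0, 3))
    bio <- which(st$occ == 1L)
    parent <- bio[sample.int(length(bio), 1L)]
    pxz <- c((parent - 1L) %% 13L, (parent - 1L) %/% 13L)
    pd <- placement_distribution(st, pxz, prm)
    orc <- oracle_placement(st, pxz, prm)
    if (pd$skipped) {
      expect_null(orc)
    } else {
      expect_equal(key(pd$candidates[, c("x", "z", "prob")])$prob,
                   key(orc)$prob, tolerance = 1e-12)
      expect_equal(sum(pd$candidates$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("degenerate weights give a uniform distribution", {
  st <- random_state(13, 11, 25, seed = 7)
  prm <- placement_params(alpha = 0, beta = 0)
  bio <- which(st$occ == 1L)
  pxz <- c((bio[3] - 1L) %% 13L, (bio[3] - 1L) %/% 13L)
  pd <- placement_distribution(st, pxz, prm)
  if (!pd$skipped)
    expect_equal(pd$candidates$prob,
                 rep(1 / nrow(pd$candidates), nrow(pd$candidates)))
})

test_that("larger beta shifts probability toward smaller delta-L", {
  # fixed configuration with candidates of differing delta-L
  st <- inoculate(grid_config(15, 15), 15); st$occ[] <- 0L
  st$occ[7, 8] <- st$occ[8, 8] <- st$occ[7, 7] <- 1L
  p_at <- function(beta) {
    pd <- placement_distribution(st, c(6, 7),
                                 placement_params(alpha = 1, beta = beta))
    stats::aggregate(prob ~ delta_L, pd$candidates, sum)
  }
  lo <- p_at(0.2); hi <- p_at(2.5)
  # total mass on the smallest delta-L strictly grows with beta
  expect_gt(hi$prob[1], lo$prob[1])
  expect_equal(lo$delta_L[1], min(lo$delta_L))
})

test_that("sampling frequencies match the exact distribution", {
  st <- inoculate(grid_config(15, 15), 15); st$occ[] <- 0L
  st$occ[7, 8] <- st$occ[8, 8] <- 1L
  prm <- placement_params(N = 11, alpha = 2, beta = 1)
  pd <- placement_distribution(st, c(6, 7), prm)
  n_draws <- 1e5
  set.seed(11)
  counts <- integer(nrow(pd$candidates))
  for (rep in seq_len(n_draws)) {
    out <- place_daughters(st, cbind(x = 6L, z = 7L), prm)
    ev <- out$events
    hit <- which(pd$candidates$x == ev$daughter_x &
                 pd$candidates$z == ev$daughter_z)
    counts[hit] <- counts[hit] + 1L
  }
  p <- pd$candidates$prob
  sigma <- sqrt(n_draws * p * (1 - p))
  expect_true(all(abs(counts - n_draws * p) <= 3 * sigma + 1))
})

test_that("daughter placement bookkeeping and caps are exact", {
  st <- random_state(13, 11, 20, seed = 3)
  prm <- placement_params()
  # empty dividing set: unchanged
  out <- place_daughters(st, cbind(x = integer(0), z = integer(0)), prm)
  expect_identical(out$state$occ, st$occ)

  # k dividing cells, none skipped: biomass grows by exactly k
  set.seed(21)
  for (rep in 1:5) {
    st <- random_state(13, 11, 15, seed = 30 + rep)
    bio <- which(st$occ == 1L)
    pick <- bio[sample.int(length(bio), min(4L, length(bio)))]
    div <- cbind(x = (pick - 1L) %% 13L, z = (pick - 1L) %/% 13L)
    out <- place_daughters(st, div, prm)
    n_placed <- sum(!out$events$skipped)
    expect_equal(total_biomass(out$state), total_biomass(st) + n_placed)
    # every daughter is 4-adjacent to pre-existing-or-earlier biomass and
    # the updated state remains coverslip-connected
    expect_true(is_connected_to_coverslip(out$state))
  }

  # exact-target truncation
  st <- inoculate(grid_config(16, 8), 2)
  div <- cbind(x = seq(0L, 14L, 2L), z = 0L)
  out <- place_daughters(st, div, prm, biomass_cap = total_biomass(st) + 3L)
  expect_equal(total_biomass(out$state), total_biomass(st) + 3L)
})
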