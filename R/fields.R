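#' Scalar fields on the biofilm grid
#'
#' A scalar field holds one real value per grid cell, aligned with the
#' occupancy lattice, plus a semantic tag: nutrient concentration
#' (relative to bulk, in [0,1]), light intensity (relative to the source,
#' in (0,1]), or division probability.
#'
#' @param values Numeric \code{w x d} matrix, \code{values[x+1, z+1]}.
#' @param config A \code{\link{grid_config}}.
#' @param kind One of \code{"nutrient"}, \code{"light"},
#'   \code{"probability"}.
#' @return An object of class \code{"scalar_field"}.
#' @export
scalar_field <- function(values, config, kind = c("nutrient", "light",
                                                  "probability")) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "grid_config"),
            is.matrix(values),
            nrow(values) == config$w, ncol(values) == config$d,
            all(is.finite(values)))
  structure(list(values = values, config = config, kind = kind),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field: %s> %d x %d, range [%.4g, %.4g]\n", x$kind,
              x$config$w, x$config$d, min(x$values), max(x$values)))
  invisible(x)
}

#' Write a scalar field as a CSV matrix aligned with the state grid
#'
#' @param field A \code{"scalar_field"}.
#' @param path Output file path. Rows are depths (row 1 = coverslip),
#'   columns are x positions, matching \code{\link{write_state_csv}}.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  utils::write.table(t(field$values), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Integer region codes used in the domain mask.
MASK_BULK <- 0L
MASK_BOUNDARY <- 1L
MASK_BIOMASS <- 2L

#' Partition the grid into biomass, boundary-layer, and bulk media
#'
#' The diffusive boundary layer is the circular dilation of the biomass by
#' radius \code{b}: media cells whose Euclidean center-to-center distance
#' to the nearest biomass cell is at most \code{b}. All remaining media
#' cells are well-mixed bulk, where the nutrient concentration is pinned
#' at the bulk value.
#'
#' @param state A \code{"biofilm_state"}.
#' @param b Boundary-layer thickness (dilation radius) in cells,
#'   \code{b >= 1}.
#' @return A \code{"domain_mask"}: integer \code{w x d} matrix with values
#'   0 (bulk), 1 (boundary layer), 2 (biomass), plus the grid config.
#' @export
compute_domain_mask <- function(state, b) {
  stopifnot(inherits(state, "biofilm_state"))
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 1)
    stop("boundary-layer thickness b must be >= 1", call. = FALSE)
  occ <- state$occ
  w <- nrow(occ); d <- ncol(occ)
  dil <- matrix(FALSE, w, d)
  if (any(occ == 1L)) {
    bi <- as.integer(floor(b))
    # shift-OR dilation over all integer offsets inside the radius-b disk
    for (dx in -bi:bi) {
      x0 <- max(1L, 1L + dx); x1 <- min(w, w + dx)
      if (x0 > x1) next
      zmax <- floor(sqrt(b * b - dx * dx))
      for (dz in -zmax:zmax) {
        z0 <- max(1L, 1L + dz); z1 <- min(d, d + dz)
        if (z0 > z1) next
        xs <- x0:x1; zs <- z0:z1
        dil[xs, zs] <- dil[xs, zs] | (occ[xs - dx, zs - dz] == 1L)
      }
    }
  }
  m <- matrix(MASK_BULK, w, d)
  m[dil] <- MASK_BOUNDARY
  m[occ == 1L] <- MASK_BIOMASS
  structure(list(mask = m, config = state$config), class = "domain_mask")
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("<domain_mask> biomass %d, boundary layer %d, bulk %d cells\n",
              sum(x$mask == MASK_BIOMASS), sum(x$mask == MASK_BOUNDARY),
              sum(x$mask == MASK_BULK)))
  invisible(x)
}

#' Solve the equilibrium nutrient field
#'
#' Solves the discrete equilibrium uptake-diffusion equation
#' \code{lap(n) = r * c * n} (5-point stencil, unit spacing) over biomass
#' and boundary-layer cells, with Dirichlet \code{n = 1} on bulk media and
#' zero-flux (mirrored ghost cell) conditions at the coverslip, sides, and
#' top border. \code{r = u0/D} is the nutrient uptake-diffusion ratio and
#' \code{c} the 0/1 occupancy. Assembled as a sparse symmetric system and
#' solved directly (CHOLMOD via the Matrix package).
#'
#' @param state A \code{"biofilm_state"}.
#' @param mask A \code{"domain_mask"} for the same state (see
#'   \code{\link{compute_domain_mask}}).
#' @param r Uptake-diffusion ratio, \code{r >= 0} (units 1/length^2).
#' @return A nutrient \code{"scalar_field"} with values in [0, 1].
#' @export
solve_nutrient_field <- function(state, mask, r) {
  stopifnot(inherits(state, "biofilm_state"), inherits(mask, "domain_mask"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("uptake-diffusion ratio r must be >= 0", call. = FALSE)
  w <- state$config$w; d <- state$config$d
  m <- mask$mask
  vals <- matrix(1, w, d)
  unk <- which(m != MASK_BULK)            # linear indices of unknown cells
  nu <- length(unk)
  if (nu == 0L || r == 0)
    return(scalar_field(vals, state$config, "nutrient"))

  idx <- matrix(0L, w, d)                 # unknown index lookup, 0 = bulk
  idx[unk] <- seq_len(nu)
  ux <- (unk - 1L) %% w + 1L              # 1-based coords of unknowns
  uz <- (unk - 1L) %/% w + 1L

  deg <- integer(nu)                      # in-grid neighbor count
  rhs <- numeric(nu)                      # Dirichlet contributions
  ti <- tj <- vector("list", 4L)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in seq_along(shifts)) {
    nx <- ux + shifts[[s]][1L]; nz <- uz + shifts[[s]][2L]
    ok <- nx >= 1L & nx <= w & nz >= 1L & nz <= d
    deg <- deg + ok
    nidx <- integer(nu)
    nidx[ok] <- idx[cbind(nx[ok], nz[ok])]
    to_unknown <- ok & nidx > 0L
    rhs <- rhs + (ok & nidx == 0L)        # bulk neighbor contributes n = 1
    ti[[s]] <- which(to_unknown)
    tj[[s]] <- nidx[to_unknown]
  }
  i <- c(seq_len(nu), unlist(ti))
  j <- c(seq_len(nu), unlist(tj))
  xv <- c(deg + r * (m[unk] == MASK_BIOMASS), rep(-1, length(i) - nu))
  A <- Matrix::sparseMatrix(i = i, j = j, x = xv, dims = c(nu, nu))
  sol <- as.numeric(Matrix::solve(A, rhs))
  # clip solver roundoff; the discrete maximum principle bounds n in [0,1]
  vals[unk] <- pmin(pmax(sol, 0), 1)
  scalar_field(vals, state$config, "nutrient")
}

#' Compute the attenuated light field
#'
#' Light enters at the coverslip pointing away from it and attenuates
#' exponentially through biomass (Beer-Lambert):
#' \code{I[x,z] = exp(-(1/p) * sum(c[x, 0..z]))} with source intensity 1
#' (absorbed into the light Monod parameter). The column sum includes row
#' \code{z} itself, so a biomass cell shades itself.
#'
#' @param state A \code{"biofilm_state"}.
#' @param p Characteristic light penetration depth in cells, \code{p > 0}.
#' @return A light \code{"scalar_field"} with values in (0, 1].
#' @export
compute_light_field <- function(state, p) {
  stopifnot(inherits(state, "biofilm_state"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop("light penetration depth p must be > 0", call. = FALSE)
  cum <- t(apply(state$occ, 1L, cumsum))
  if (state$config$d == 1L) cum <- matrix(cum, ncol = 1L)
  scalar_field(exp(-cum / p), state$config, "light")
}
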