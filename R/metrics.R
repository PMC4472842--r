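#' Coverage as a function of depth
#'
#' Fraction of cells at each depth row that are biomass: the model analog
#' of the per-slice area coverage computed from confocal stacks, used to
#' characterize depth-dependent biofilm structure.
#'
#' @param state A \code{"biofilm_state"}.
#' @return A \code{"coverage_profile"}: data frame with columns
#'   \code{depth} (um, 0-based row index) and \code{coverage} (in [0,1]),
#'   with attribute \code{spacing} (um between rows, 1 for the lattice).
#' @export
coverage_by_depth <- function(state) {
  stopifnot(inherits(state, "biofilm_state"))
  cov <- colMeans(state$occ)
  coverage_profile(cov, spacing = 1)
}

#' Construct a coverage profile
#'
#' @param coverage Numeric vector of per-depth coverage fractions in
#'   [0, 1], ordered from the coverslip outward.
#' @param spacing Depth spacing between successive values, in um.
#' @return A \code{"coverage_profile"} data frame.
#' @export
coverage_profile <- function(coverage, spacing = 1) {
  stopifnot(is.numeric(coverage), all(coverage >= 0), all(coverage <= 1),
            is.numeric(spacing), spacing > 0)
  structure(data.frame(depth = (seq_along(coverage) - 1) * spacing,
                       coverage = as.numeric(coverage)),
            spacing = spacing,
            class = c("coverage_profile", "data.frame"))
}

#' Total biomass and mean thickness
#'
#' \code{total_biomass} is the biomass cell count;
#' \code{mean_thickness} divides by the grid width, giving mean biofilm
#' thickness in um-equivalents (the simulation analog of the COMSTAT
#' biomass statistic: biovolume per substratum area).
#'
#' @param state A \code{"biofilm_state"}.
#' @return Integer count, or numeric thickness in um.
#' @export
total_biomass <- function(state) {
  stopifnot(inherits(state, "biofilm_state"))
  as.integer(sum(state$occ))
}

#' @rdname total_biomass
#' @export
mean_thickness <- function(state) {
  stopifnot(inherits(state, "biofilm_state"))
  sum(state$occ) / state$config$w
}

#' Mean biomass cell depth
#'
#' Mean distance from the coverslip (z, in um) over all biomass cells.
#'
#' @param state A \code{"biofilm_state"} with at least one biomass cell.
#' @return Numeric mean depth in um.
#' @export
mean_cell_depth <- function(state) {
  stopifnot(inherits(state, "biofilm_state"))
  tot <- sum(state$occ)
  if (tot == 0L)
    stop("mean cell depth undefined for an empty biofilm", call. = FALSE)
  z <- col(state$occ) - 1L
  sum(z[state$occ == 1L]) / tot
}

#' Convex-hull density of a biofilm
#'
#' Biomass cell count divided by the area of the convex hull of the
#' biomass, an inverse proxy for porosity: dense laminar biofilms score
#' near 1, porous columnar biofilms score low. The hull is taken over the
#' four corners of each occupied unit cell (not the centers), so solid
#' convex shapes — including a single cell — score exactly 1.
#'
#' @param state A \code{"biofilm_state"} with at least one biomass cell.
#' @return Numeric density in (0, 1].
#' @export
convex_hull_density <- function(state) {
  stopifnot(inherits(state, "biofilm_state"))
  idx <- which(state$occ == 1L)
  if (length(idx) == 0L)
    stop("convex-hull density undefined for an empty biofilm", call. = FALSE)
  w <- nrow(state$occ)
  x <- (idx - 1L) %% w
  z <- (idx - 1L) %/% w
  px <- c(x, x + 1L, x, x + 1L)
  pz <- c(z, z, z + 1L, z + 1L)
  hull <- grDevices::chull(px, pz)
  hx <- px[hull]; hz <- pz[hull]
  # shoelace formula
  area <- abs(sum(hx * c(hz[-1L], hz[1L]) - c(hx[-1L], hx[1L]) * hz)) / 2
  length(idx) / area
}

#' Nutrient scarcity
#'
#' The dimensionless nutrient scarcity \code{n_s = 1/(b^2 r)}:
#' approximately the equilibrium nutrient concentration experienced by an
#' isolated cell relative to the bulk, small when diffusion is slow
#' (large r) and the boundary layer thick (large b). Its inverse
#' \code{1/n_s = b^2 r} is large in nutrient-deprived regimes.
#'
#' @param b Boundary-layer thickness (cells), \code{b >= 1}.
#' @param r Uptake-diffusion ratio, \code{r > 0} for \code{n_s}
#'   (\code{r = 0} is allowed for the inverse, which is then 0).
#' @return \code{nutrient_scarcity}: \code{n_s};
#'   \code{inverse_nutrient_scarcity}: \code{b^2 r}.
#' @export
#' @examples
#' nutrient_scarcity(1, 1)            # 1
#' inverse_nutrient_scarcity(7, 0.04) # 1.96
nutrient_scarcity <- function(b, r) {
  stopifnot(is.numeric(b), all(b >= 1), is.numeric(r), all(r >= 0))
  if (any(r == 0))
    stop("nutrient scarcity undefined at r = 0", call. = FALSE)
  1 / (b^2 * r)
}

#' @rdname nutrient_scarcity
#' @export
inverse_nutrient_scarcity <- function(b, r) {
  stopifnot(is.numeric(b), all(b >= 1), is.numeric(r), all(r >= 0))
  b^2 * r
}
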