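#' Grid configuration for the biofilm lattice
#'
#' Defines the rectangular cellular-automaton grid on which biofilms grow.
#' Coordinates are 0-based: \code{x} runs along the coverslip in
#' \code{[0, w)}, \code{z} runs away from the coverslip in \code{[0, d)},
#' and \code{z = 0} is the coverslip row. One grid cell maps to
#' 1 um x 1 um.
#'
#' @param w Grid width in cells (default 128).
#' @param d Grid depth in cells (default 40).
#' @return An object of class \code{"grid_config"}.
#' @export
#' @examples
#' cfg <- grid_config(16, 8)
grid_config <- function(w = 128L, d = 40L) {
  w <- as.integer(w); d <- as.integer(d)
  if (length(w) != 1L || length(d) != 1L || is.na(w) || is.na(d) ||
      w < 1L || d < 1L)
    stop("grid dimensions must be integers >= 1", call. = FALSE)
  structure(list(w = w, d = d), class = "grid_config")
}

#' @export
print.grid_config <- function(x, ...) {
  cat(sprintf("<grid_config> %d x %d cells (z = 0 at the coverslip)\n",
              x$w, x$d))
  invisible(x)
}

new_biofilm_state <- function(config, occ, step = 0L) {
  structure(list(config = config, occ = occ, step = as.integer(step)),
            class = "biofilm_state")
}

#' Inoculate a biofilm lattice
#'
#' Creates an initial biofilm state with biomass cells on the coverslip row
#' (\code{z = 0}) at \code{x = 0, s, 2s, ...}, i.e. separated by an integer
#' distance \code{s}, all other cells media-filled.
#'
#' @param config A \code{\link{grid_config}}.
#' @param s Integer separation between inoculated cells, \code{1 <= s <= w}.
#' @return A \code{"biofilm_state"}: the grid config, a \code{w x d}
#'   integer occupancy matrix (\code{occ[x+1, z+1]}, 1 = biomass,
#'   0 = media), and a step counter starting at 0.
#' @export
#' @examples
#' st <- inoculate(grid_config(128, 40), s = 64)
#' total_biomass(st) # 2
inoculate <- function(config, s) {
  stopifnot(inherits(config, "grid_config"))
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L || s > config$w)
    stop("inoculation separation s must satisfy 1 <= s <= w", call. = FALSE)
  occ <- matrix(0L, nrow = config$w, ncol = config$d)
  occ[seq.int(1L, config$w, by = s), 1L] <- 1L
  new_biofilm_state(config, occ)
}

#' @export
print.biofilm_state <- function(x, ...) {
  cat(sprintf("<biofilm_state> %d x %d grid, %d biomass cells, step %d\n",
              x$config$w, x$config$d, sum(x$occ), x$step))
  invisible(x)
}

#' In-grid 4-neighbors of a lattice cell
#'
#' Edge-adjacent (von Neumann) neighbors of a cell, clipped at the grid
#' borders. Adjacency everywhere in the model (daughter connectivity,
#' perimeter edges) is 4-connectivity.
#'
#' @param coord Length-2 integer vector \code{c(x, z)}, 0-based.
#' @param config A \code{\link{grid_config}}.
#' @return An integer matrix with columns \code{x}, \code{z}; one row per
#'   in-grid neighbor (4 in the interior, fewer at borders).
#' @export
neighbors4 <- function(coord, config) {
  stopifnot(inherits(config, "grid_config"), length(coord) == 2L)
  x <- as.integer(coord[[1L]]); z <- as.integer(coord[[2L]])
  if (x < 0L || x >= config$w || z < 0L || z >= config$d)
    stop("coordinate outside the grid", call. = FALSE)
  nb <- cbind(x = x + c(-1L, 1L, 0L, 0L), z = z + c(0L, 0L, -1L, 1L))
  nb[nb[, 1L] >= 0L & nb[, 1L] < config$w &
     nb[, 2L] >= 0L & nb[, 2L] < config$d, , drop = FALSE]
}

#' Biomass-media perimeter of a lattice region
#'
#' Counts grid-cell edges separating a biomass-filled cell from a
#' media-filled cell. Edges on the grid border do not count: borders are
#' reflective, so no biomass-media interface exists there.
#'
#' @param state A \code{"biofilm_state"}.
#' @param region Optional rectangular block, a list/vector
#'   \code{c(x0, x1, z0, z1)} of 0-based inclusive bounds; only edges with
#'   both incident cells inside the block are counted. Default: whole grid.
#' @return Integer edge count \code{L}.
#' @export
perimeter <- function(state, region = NULL) {
  stopifnot(inherits(state, "biofilm_state"))
  occ <- state$occ
  if (!is.null(region)) {
    region <- as.integer(unlist(region))
    x0 <- region[1L] + 1L; x1 <- region[2L] + 1L
    z0 <- region[3L] + 1L; z1 <- region[4L] + 1L
    occ <- occ[x0:x1, z0:z1, drop = FALSE]
  }
  w <- nrow(occ); d <- ncol(occ)
  edges <- 0L
  if (w > 1L)
    edges <- edges + sum(occ[-w, , drop = FALSE] != occ[-1L, , drop = FALSE])
  if (d > 1L)
    edges <- edges + sum(occ[, -d, drop = FALSE] != occ[, -1L, drop = FALSE])
  as.integer(edges)
}

#' Perimeter change from placing a daughter cell
#'
#' Local, exact evaluation of the perimeter change \code{dL} produced by
#' converting a media-filled candidate cell to biomass:
#' \code{dL = 4 - 2k - e}, where \code{k} is the number of biomass
#' 4-neighbors and \code{e} the number of candidate edges lying on the grid
#' border (border edges never count toward the perimeter). Equals the
#' global perimeter recomputed after the hypothetical placement minus the
#' perimeter before.
#'
#' @param state A \code{"biofilm_state"}.
#' @param cell Length-2 vector \code{c(x, z)}, 0-based; must be
#'   media-filled.
#' @return Integer \code{dL}.
#' @export
delta_perimeter <- function(state, cell) {
  stopifnot(inherits(state, "biofilm_state"))
  x <- as.integer(cell[[1L]]); z <- as.integer(cell[[2L]])
  if (state$occ[x + 1L, z + 1L] != 0L)
    stop("candidate cell is already biomass-filled", call. = FALSE)
  nb <- neighbors4(c(x, z), state$config)
  deg <- nrow(nb)
  k <- sum(state$occ[nb[, 1L] + 1L + nrow(state$occ) * nb[, 2L]])
  as.integer(deg - 2L * k)
}

#' Serialize a biofilm state to a plain-text CSV matrix
#'
#' Writes the occupancy lattice as a d-row, w-column 0/1 CSV (row 1 is the
#' coverslip row z = 0). \code{read_state_csv} round-trips exactly.
#'
#' @param state A \code{"biofilm_state"}.
#' @param path Output file path.
#' @export
write_state_csv <- function(state, path) {
  stopifnot(inherits(state, "biofilm_state"))
  utils::write.table(t(state$occ), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @param step Step counter to attach to the restored state (default 0).
#' @return \code{read_state_csv} returns a \code{"biofilm_state"}.
#' @export
read_state_csv <- function(path, step = 0L) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  occ <- t(m)
  storage.mode(occ) <- "integer"
  dimnames(occ) <- NULL
  new_biofilm_state(grid_config(nrow(occ), ncol(occ)), occ, step = step)
}

# Flood fill from the coverslip row through biomass; TRUE iff every biomass
# cell is 4-connected to z = 0. Used by invariant tests.
#' Check biofilm connectivity to the coverslip
#'
#' Verifies by flood fill that every biomass cell is 4-connected through
#' biomass to the coverslip row \code{z = 0}. Holds for any state grown
#' from an inoculated lattice, since daughters are always placed adjacent
#' to existing biomass and biomass never reverts to media.
#'
#' @param state A \code{"biofilm_state"}.
#' @return Logical scalar.
#' @export
is_connected_to_coverslip <- function(state) {
  occ <- state$occ
  w <- nrow(occ); d <- ncol(occ)
  total <- sum(occ)
  if (total == 0L) return(TRUE)
  seen <- matrix(FALSE, w, d)
  frontier <- which(occ[, 1L] == 1L)
  seen[frontier, 1L] <- TRUE
  frontier <- cbind(frontier, 1L)
  while (nrow(frontier) > 0L) {
    nxt <- rbind(
      cbind(frontier[, 1L] - 1L, frontier[, 2L]),
      cbind(frontier[, 1L] + 1L, frontier[, 2L]),
      cbind(frontier[, 1L], frontier[, 2L] - 1L),
      cbind(frontier[, 1L], frontier[, 2L] + 1L))
    ok <- nxt[, 1L] >= 1L & nxt[, 1L] <= w & nxt[, 2L] >= 1L & nxt[, 2L] <= d
    nxt <- nxt[ok, , drop = FALSE]
    idx <- nxt[, 1L] + w * (nxt[, 2L] - 1L)
    keep <- occ[idx] == 1L & !seen[idx]
    idx <- unique(idx[keep])
    if (length(idx) == 0L) break
    seen[idx] <- TRUE
    frontier <- cbind((idx - 1L) %% w + 1L, (idx - 1L) %/% w + 1L)
  }
  sum(seen) == total
}
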