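#' Confocal-style image stack
#'
#' An ordered set of grayscale 2D slices, slice 1 at the coverslip, with
#' physical voxel dimensions. Intensities live in the image's native units
#' (e.g. [0,1] for normalized TIFF data).
#'
#' @param data 3D numeric array \code{[x, y, slice]} of intensities.
#' @param voxel Numeric length-3 vector: voxel size in um along x, y, z
#'   (z = slice spacing). All > 0.
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(data, voxel = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[3L] >= 1L,
            is.numeric(voxel), length(voxel) == 3L, all(voxel > 0),
            all(is.finite(data)))
  structure(list(data = data, voxel = as.numeric(voxel)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d slices; voxel %.3g x %.3g x %.3g um\n",
    dm[1L], dm[2L], dm[3L], x$voxel[1L], x$voxel[2L], x$voxel[3L]))
  invisible(x)
}

#' Depth-adaptive threshold schedule
#'
#' Confocal reflectance signal attenuates with imaging depth, so a single
#' global threshold under-segments deep slices. A threshold schedule fixes
#' anchor thresholds at user-chosen depths and linearly interpolates for
#' all intermediate slices, with constant extrapolation beyond the first
#' and last anchors.
#'
#' @param anchors Data frame or 2-column matrix: \code{depth} (slice
#'   index, 0-based) and \code{threshold} (intensity). Depths must be
#'   unique; any order.
#' @return An object of class \code{"threshold_schedule"}.
#' @export
#' @examples
#' sch <- make_threshold_schedule(cbind(depth = c(0, 40),
#'                                      threshold = c(10, 20)))
#' schedule_thresholds(sch, slices = 0:40)[21] # 15 at slice 20
make_threshold_schedule <- function(anchors) {
  a <- as.data.frame(anchors)
  names(a) <- c("depth", "threshold")
  stopifnot(nrow(a) >= 1L, is.numeric(a$depth), is.numeric(a$threshold))
  if (anyDuplicated(a$depth))
    stop("threshold anchors must have unique depths", call. = FALSE)
  a <- a[order(a$depth), , drop = FALSE]
  rownames(a) <- NULL
  structure(list(anchors = a), class = "threshold_schedule")
}

#' @rdname make_threshold_schedule
#' @param schedule A \code{"threshold_schedule"}.
#' @param slices Integer vector of 0-based slice indices.
#' @return \code{schedule_thresholds} returns one threshold per slice.
#' @export
schedule_thresholds <- function(schedule, slices) {
  stopifnot(inherits(schedule, "threshold_schedule"))
  a <- schedule$anchors
  if (nrow(a) == 1L) return(rep(a$threshold, length(slices)))
  stats::approx(a$depth, a$threshold, xout = slices, rule = 2)$y
}

#' Binarize an image stack with a threshold schedule
#'
#' A voxel is foreground (biomass) iff its intensity is strictly greater
#' than its slice's threshold.
#'
#' @param stack An \code{"image_stack"}.
#' @param schedule A \code{"threshold_schedule"}.
#' @return A \code{"binary_stack"}: logical array plus voxel dims.
#' @export
binarize_stack <- function(stack, schedule) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(schedule, "threshold_schedule"))
  nz <- dim(stack$data)[3L]
  thr <- schedule_thresholds(schedule, seq_len(nz) - 1L)
  bin <- stack$data > rep(thr, each = prod(dim(stack$data)[1:2]))
  dim(bin) <- dim(stack$data)
  structure(list(data = bin, voxel = stack$voxel), class = "binary_stack")
}

#' COMSTAT biomass of a binarized stack
#'
#' Foreground biovolume divided by substratum area: mean biofilm thickness
#' in um (the COMSTAT biomass statistic).
#'
#' @param bin A \code{"binary_stack"}.
#' @return Numeric biomass in um.
#' @export
stack_biomass <- function(bin) {
  stopifnot(inherits(bin, "binary_stack"))
  dm <- dim(bin$data)
  vol <- sum(bin$data) * prod(bin$voxel)
  vol / (dm[1L] * dm[2L] * bin$voxel[1L] * bin$voxel[2L])
}

#' Coverage versus depth for a binarized stack
#'
#' Per-slice foreground fraction, depth in um via the z voxel spacing.
#'
#' @param bin A \code{"binary_stack"}.
#' @return A \code{\link{coverage_profile}}.
#' @export
stack_coverage_by_depth <- function(bin) {
  stopifnot(inherits(bin, "binary_stack"))
  cov <- apply(bin$data, 3L, mean)
  coverage_profile(cov, spacing = bin$voxel[3L])
}

#' Extract vertical sections from a binarized stack
#'
#' Samples \code{count} vertical (x-z or y-z) sections of a requested
#' physical size, starting at and perpendicular to the coverslip, each
#' carrying its own coverage-versus-depth curve — the 2D slice dataset
#' used for slice-level morphology classification. Positions and
#' orientations are drawn from a dedicated stream seeded by \code{seed},
#' so the slice dataset is reproducible.
#'
#' @param bin A \code{"binary_stack"}.
#' @param length_um Section length along the coverslip (default 96).
#' @param depth_um Section depth from the coverslip (default 20).
#' @param count Number of sections.
#' @param seed Integer seed for the sampling positions.
#' @return A list of sections; each is a list with \code{mask} (length x
#'   depth logical matrix), \code{orientation}, \code{offset}, and
#'   \code{coverage} (a \code{\link{coverage_profile}}).
#' @export
extract_slices <- function(bin, length_um = 96, depth_um = 20, count = 100,
                           seed = 1L) {
  stopifnot(inherits(bin, "binary_stack"), count >= 0)
  dm <- dim(bin$data)
  npx_x <- round(length_um / bin$voxel[1L])
  npx_y <- round(length_um / bin$voxel[2L])
  nsl <- round(depth_um / bin$voxel[3L]) + 1L
  if (npx_x > dm[1L] || npx_y > dm[2L])
    stop("stack lateral extent smaller than the requested section length",
         call. = FALSE)
  if (nsl > dm[3L])
    stop("stack depth smaller than the requested section depth",
         call. = FALSE)
  if (count == 0L) return(list())
  rng <- local({ set.seed(seed); list(
    orient = sample(c("xz", "yz"), count, replace = TRUE),
    pos = stats::runif(count), lane = stats::runif(count)) })
  out <- vector("list", count)
  for (i in seq_len(count)) {
    if (rng$orient[i] == "xz") {
      x0 <- 1L + floor(rng$pos[i] * (dm[1L] - npx_x + 1L))
      y <- 1L + floor(rng$lane[i] * dm[2L])
      mask <- bin$data[x0:(x0 + npx_x - 1L), y, seq_len(nsl)]
      sp <- bin$voxel[3L]
    } else {
      y0 <- 1L + floor(rng$pos[i] * (dm[2L] - npx_y + 1L))
      x <- 1L + floor(rng$lane[i] * dm[1L])
      mask <- bin$data[x, y0:(y0 + npx_y - 1L), seq_len(nsl)]
      sp <- bin$voxel[3L]
    }
    out[[i]] <- list(mask = mask, orientation = rng$orient[i],
                     offset = c(rng$pos[i], rng$lane[i]),
                     coverage = coverage_profile(colMeans(mask),
                                                 spacing = sp))
  }
  out
}

#' Synthesize a confocal reflectance stack
#'
#' Renders an image stack from a parametric binary biomass phantom:
#' a base layer covering the coverslip plus vertical columns that either
#' taper with height (\code{"columnar"}, coverage decreasing monotonically
#' beyond the base layer, the heterotrophic signature), widen into a cap
#' (\code{"mushroom"}, a local coverage maximum above the base layer, the
#' photoheterotrophic signature), or stay uniform (\code{"laminar"}, a
#' thick dense slab). Rendered intensity (signal and stray background)
#' decays exponentially with depth (characteristic length
#' \code{attenuation}) to emulate confocal signal loss, with additive
#' depth-independent Gaussian detector noise. The ground-truth phantom is
#' returned alongside the rendered stack.
#'
#' @param morphology One of \code{"laminar"}, \code{"columnar"},
#'   \code{"mushroom"}.
#' @param nx,ny Lateral size in pixels (default 128).
#' @param nz Number of slices (default 26).
#' @param voxel Voxel size in um (default 1 x 1 x 1).
#' @param n_columns Number of columns (laminar: ignored).
#' @param base_height Base-layer thickness in slices (default 2).
#' @param column_height Column height in slices above the coverslip.
#' @param column_radius Column radius in pixels at the base.
#' @param cap_radius Mushroom cap radius in pixels (>= column_radius).
#' @param cap_start Slice index where the cap begins widening (mushroom).
#' @param fg,bg Mean foreground/background intensity before attenuation.
#' @param noise_sd Gaussian noise standard deviation (0 for noiseless).
#' @param attenuation Characteristic intensity decay length in slices;
#'   \code{Inf} disables attenuation.
#' @param seed Integer seed (column positions and noise).
#' @return A list: \code{stack} (an \code{\link{image_stack}}),
#'   \code{phantom} (logical ground-truth array), and the generation
#'   parameters.
#' @export
synth_stack <- function(morphology = c("columnar", "mushroom", "laminar"),
                        nx = 128L, ny = 128L, nz = 26L, voxel = c(1, 1, 1),
                        n_columns = 6L, base_height = 2L,
                        column_height = 18L, column_radius = 10,
                        cap_radius = 16, cap_start = 8L, fg = 0.8,
                        bg = 0.05, noise_sd = 0.02, attenuation = 12,
                        seed = 1L) {
  morphology <- match.arg(morphology)
  set.seed(seed)
  phantom <- array(FALSE, dim = c(nx, ny, nz))
  if (base_height > 0L) phantom[, , seq_len(min(base_height, nz))] <- TRUE
  if (morphology == "laminar") {
    phantom[, , seq_len(min(column_height, nz))] <- TRUE
  } else if (n_columns > 0L && column_height > base_height) {
    cx <- stats::runif(n_columns, 1, nx)
    cy <- stats::runif(n_columns, 1, ny)
    xs <- matrix(seq_len(nx), nx, ny)
    ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    top <- min(column_height, nz)
    for (z in (base_height + 1L):top) {
      frac <- (z - base_height) / max(top - base_height, 1L)
      rad <- if (morphology == "columnar") {
        column_radius * (1 - 0.75 * frac)     # taper toward the top
      } else if (z <= cap_start) {
        column_radius * 0.6                   # narrow stem
      } else {
        # rounded cap: widen from the stem to the full cap radius at 70%
        # of the cap height, then close back toward the top, so the
        # coverage maximum sits strictly inside the cap
        cfrac <- (z - cap_start) / max(top - cap_start, 1L)
        shape <- if (cfrac <= 0.7) cfrac / 0.7 else 1 - (cfrac - 0.7)
        stem <- column_radius * 0.6
        stem + (cap_radius - stem) * shape
      }
      sl <- matrix(FALSE, nx, ny)
      for (k in seq_len(n_columns)) {
        # toroidal distance so columns near edges stay whole
        ddx <- pmin(abs(xs - cx[k]), nx - abs(xs - cx[k]))
        ddy <- pmin(abs(ys - cy[k]), ny - abs(ys - cy[k]))
        sl <- sl | (ddx^2 + ddy^2 <= rad^2)
      }
      phantom[, , z] <- phantom[, , z] | sl
    }
  }
  depth_fac <- if (is.finite(attenuation))
    exp(-(seq_len(nz) - 1L) / attenuation) else rep(1, nz)
  # signal and stray background both attenuate with depth; detector noise
  # is additive and depth-independent
  img <- (bg + (fg - bg) * phantom) * rep(depth_fac, each = nx * ny)
  dim(img) <- dim(phantom)
  if (noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  list(stack = image_stack(img, voxel), phantom = phantom,
       morphology = morphology, fg = fg, bg = bg, noise_sd = noise_sd,
       attenuation = attenuation, seed = seed)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Thin wrappers over the tiff package (a Suggests dependency) mapping
#' between multi-page grayscale TIFF files and \code{"image_stack"}
#' objects. Intensities are the tiff package's normalized [0,1] values.
#'
#' @param path TIFF file path.
#' @param voxel Voxel dimensions in um to attach on read.
#' @return \code{read_stack_tiff} returns an \code{"image_stack"}.
#' @export
read_stack_tiff <- function(path, voxel = c(1, 1, 1)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) if (length(dim(pg)) == 3L)
    pg[, , 1L] else pg)
  arr <- array(0, dim = c(ncol(pages[[1L]]), nrow(pages[[1L]]),
                          length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- t(pages[[i]])
  image_stack(arr, voxel)
}

#' @rdname read_stack_tiff
#' @param stack An \code{"image_stack"} with intensities in [0, 1].
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF stacks requires the 'tiff' package", call. = FALSE)
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(dim(stack$data)[3L]), function(i)
    t(pmin(pmax(stack$data[, , i], 0), 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
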