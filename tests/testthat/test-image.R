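test_that("threshold schedules interpolate linearly and clamp outside", {
  sch <- make_threshold_schedule(cbind(depth = c(0, 40),
                                       threshold = c(10, 20)))
  expect_equal(schedule_thresholds(sch, 20), 15)
  expect_equal(schedule_thresholds(sch, c(0, 40)), c(10, 20))
  expect_equal(schedule_thresholds(sch, 50), 20)     # beyond last anchor
  expect_equal(schedule_thresholds(sch, -5), 10)     # before first anchor

  one <- make_threshold_schedule(cbind(5, 12))
  expect_equal(schedule_thresholds(one, c(0, 5, 99)), rep(12, 3))

  expect_error(make_threshold_schedule(cbind(c(1, 1), c(2, 3))), "unique")
})

test_that("binarization is a strict per-slice threshold test", {
  arr <- array(0, dim = c(4, 4, 3))
  stk <- image_stack(arr)
  sch <- make_threshold_schedule(cbind(0, 0.5))
  expect_equal(sum(binarize_stack(stk, sch)$data), 0)

  arr[] <- 1
  expect_equal(sum(binarize_stack(image_stack(arr), sch)$data), 48)

  # gradient slice split at its midpoint: foreground fraction 0.5
  arr <- array(rep(seq(0, 1, length.out = 16), 3), dim = c(4, 4, 3))
  bin <- binarize_stack(image_stack(arr), sch)
  expect_equal(mean(bin$data[, , 1]), 0.5)

  # strictness: intensity exactly at the threshold is background
  arr[] <- 0.5
  expect_equal(sum(binarize_stack(image_stack(arr), sch)$data), 0)
})

test_that("stack biomass is mean thickness in um", {
  full <- structure(list(data = array(TRUE, dim = c(5, 5, 30)),
                         voxel = c(1, 1, 1)), class = "binary_stack")
  expect_equal(stack_biomass(full), 30)

  none <- structure(list(data = array(FALSE, dim = c(5, 5, 3)),
                         voxel = c(1, 1, 1)), class = "binary_stack")
  expect_equal(stack_biomass(none), 0)

  half <- array(FALSE, dim = c(4, 4, 10))
  half[1:2, , ] <- TRUE
  hb <- structure(list(data = half, voxel = c(1, 1, 0.5)),
                  class = "binary_stack")
  expect_equal(stack_biomass(hb), 2.5)

  # identity: biomass equals mean coverage times total depth
  prof <- stack_coverage_by_depth(hb)
  expect_equal(stack_biomass(hb), mean(prof$coverage) * 10 * 0.5)
})

test_that("vertical section extraction is deterministic geometry bookkeeping", {
  syn <- synth_stack("columnar", nx = 128, ny = 128, nz = 26,
                     noise_sd = 0, attenuation = Inf, seed = 4)
  bin <- binarize_stack(syn$stack,
                        make_threshold_schedule(cbind(0, 0.4)))
  expect_equal(length(extract_slices(bin, count = 0)), 0L)

  sl <- extract_slices(bin, length_um = 96, depth_um = 20, count = 100,
                       seed = 2)
  expect_equal(length(sl), 100L)
  for (i in c(1, 50, 100)) {
    expect_equal(dim(sl[[i]]$mask), c(96L, 21L))
    expect_true(all(sl[[i]]$coverage$coverage >= 0 &
                    sl[[i]]$coverage$coverage <= 1))
  }
  # deterministic given the seed
  sl2 <- extract_slices(bin, length_um = 96, depth_um = 20, count = 100,
                        seed = 2)
  expect_identical(sl[[37]]$mask, sl2[[37]]$mask)

  # homogeneous stack: every section has the same coverage curve
  hom <- structure(list(data = array(TRUE, dim = c(100, 100, 21)),
                        voxel = c(1, 1, 1)), class = "binary_stack")
  hsl <- extract_slices(hom, count = 5, seed = 1)
  expect_true(all(vapply(hsl, function(s)
    all(s$coverage$coverage == 1), logical(1))))

  small <- structure(list(data = array(TRUE, dim = c(50, 50, 21)),
                          voxel = c(1, 1, 1)), class = "binary_stack")
  expect_error(extract_slices(small, count = 1), "lateral")
})

test_that("noiseless synthetic stacks round-trip exactly through binarize", {
  for (morph in c("laminar", "columnar", "mushroom")) {
    syn <- synth_stack(morph, nx = 64, ny = 64, nz = 24, noise_sd = 0,
                       attenuation = Inf, fg = 0.8, bg = 0.05, seed = 9)
    bin <- binarize_stack(syn$stack, make_threshold_schedule(cbind(0, 0.4)))
    expect_identical(bin$data, syn$phantom)
  }
})

test_that("phantom coverage curves have the designed depth structure", {
  mush <- synth_stack("mushroom", nx = 96, ny = 96, nz = 24,
                      base_height = 2, column_height = 20, cap_start = 6,
                      noise_sd = 0, attenuation = Inf, seed = 3)
  cov <- apply(mush$phantom, 3, mean)
  inner <- cov[4:21]                       # above the base layer
  peak <- which.max(inner)
  expect_gt(peak, 1)                       # local maximum at depth,
  expect_lt(peak, length(inner))           # not at either end
  expect_gt(max(inner), inner[1])

  col <- synth_stack("columnar", nx = 96, ny = 96, nz = 24,
                     base_height = 2, column_height = 20, noise_sd = 0,
                     attenuation = Inf, seed = 3)
  ccov <- apply(col$phantom, 3, mean)
  expect_true(all(diff(ccov[3:20]) <= 1e-12))  # monotone beyond the base
})

test_that("adaptive thresholds recover attenuated stacks, constant ones do not", {
  # columns deep enough that the attenuated signal falls below the
  # shallow background level: no single threshold can work at all depths
  syn <- synth_stack("mushroom", nx = 96, ny = 96, nz = 24,
                     column_height = 22, fg = 0.9, bg = 0.05,
                     noise_sd = 0.01, attenuation = 8, seed = 5)
  truth <- apply(syn$phantom, 3, mean)
  # anchors track the attenuated midpoint between background and signal
  anchor_z <- seq(0, 23, by = 4)
  adaptive <- make_threshold_schedule(cbind(
    depth = anchor_z,
    threshold = (0.05 + 0.9) / 2 * exp(-anchor_z / 8)))
  cov_a <- stack_coverage_by_depth(binarize_stack(syn$stack, adaptive))
  err_a <- mean(abs(cov_a$coverage - truth))
  expect_lt(err_a, 0.02)

  # best constant threshold still under-counts deep slices
  errs_c <- vapply(seq(0.05, 0.5, by = 0.01), function(thr) {
    cc <- stack_coverage_by_depth(
      binarize_stack(syn$stack, make_threshold_schedule(cbind(0, thr))))
    mean(abs(cc$coverage - truth))
  }, numeric(1))
  expect_gt(min(errs_c), err_a)
})

test_that("stacks round-trip through multi-page TIFF", {
  skip_if_not_installed("tiff")
  syn <- synth_stack("columnar", nx = 32, ny = 32, nz = 8, noise_sd = 0,
                     attenuation = Inf, seed = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(syn$stack, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back$data), dim(syn$stack$data))
  # 16-bit quantization error only
  expect_lt(max(abs(back$data - syn$stack$data)), 1 / 65535 + 1e-9)
})
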