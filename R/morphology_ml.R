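#' Morphology feature vector from a coverage curve
#'
#' Builds the classifier features used for slice- and stack-level
#' morphology classification. Variant \code{"age"}: the sample age plus 21
#' coverage samples taken every 1 um from the coverslip up to 20 um.
#' Variant \code{"biomass"}: total biomass (um, the COMSTAT statistic)
#' plus coverage sampled every 1 um from 2 to 20 um inclusive (the first
#' 2 um are dropped because model and experiment differ most near the
#' coverslip), 20 features in total; \code{drop_20um = TRUE} drops the
#' final 20 um sample, giving 19. In both variants the coverage block is
#' normalized to sum to 1 so that slices of different biomass are directly
#' comparable; an all-zero coverage block is undefined and raises an error
#' (such slices are excluded from datasets).
#'
#' @param coverage A \code{\link{coverage_profile}} (or data frame with
#'   \code{depth} and \code{coverage} columns, depths in um). Values at
#'   the sampling depths are linearly interpolated.
#' @param scalar The leading scalar feature: age in days (variant
#'   \code{"age"}) or biomass in um (variant \code{"biomass"}).
#' @param variant \code{"age"} or \code{"biomass"}.
#' @param drop_20um Drop the 20 um coverage sample (variant
#'   \code{"biomass"} only).
#' @return Named numeric feature vector; the coverage block sums to 1.
#' @export
slice_features <- function(coverage, scalar,
                           variant = c("biomass", "age"),
                           drop_20um = FALSE) {
  variant <- match.arg(variant)
  cv <- as.data.frame(coverage)
  stopifnot(all(c("depth", "coverage") %in% names(cv)),
            is.numeric(scalar), length(scalar) == 1L)
  depths <- if (variant == "age") 0:20 else 2:(if (drop_20um) 19 else 20)
  if (max(cv$depth) < max(depths) || min(cv$depth) > min(depths))
    stop("coverage curve does not cover the required depth range",
         call. = FALSE)
  samp <- stats::approx(cv$depth, cv$coverage, xout = depths)$y
  tot <- sum(samp)
  if (tot <= 0)
    stop("all-zero coverage block: slice excluded from feature extraction",
         call. = FALSE)
  out <- c(scalar, samp / tot)
  names(out) <- c(if (variant == "age") "age" else "biomass",
                  paste0("cov_", depths))
  out
}

#' Random-forest specification
#'
#' Defaults follow the morphology classification setup: classification
#' uses 1000 trees, the Gini impurity criterion, and at most 5 features
#' per split; regression uses 500 trees and the mean-squared-error
#' criterion (the randomForest package's criteria for each task).
#'
#' @param task \code{"classify"} or \code{"regress"}.
#' @param n_estimators Number of trees (default 1000 classify,
#'   500 regress).
#' @param max_features Features considered per split (\code{mtry});
#'   default 5 for classification, the randomForest regression default
#'   (p/3) otherwise.
#' @return An object of class \code{"forest_spec"}.
#' @export
forest_spec <- function(task = c("classify", "regress"),
                        n_estimators = NULL, max_features = NULL) {
  task <- match.arg(task)
  if (is.null(n_estimators))
    n_estimators <- if (task == "classify") 1000L else 500L
  if (is.null(max_features) && task == "classify") max_features <- 5L
  structure(list(task = task, n_estimators = as.integer(n_estimators),
                 max_features = max_features),
            class = "forest_spec")
}

#' Train a random forest with an out-of-bag estimate
#'
#' @param features Numeric matrix or data frame of features (rows =
#'   samples).
#' @param response Factor labels (classification; at least 2 classes
#'   present) or numeric targets (regression).
#' @param spec A \code{\link{forest_spec}}.
#' @param seed Integer seed; training is deterministic given it.
#' @return A \code{"morphology_forest"}: the fitted randomForest
#'   \code{model}, \code{oob_error} (classification misclassification
#'   rate) or \code{oob_r2} (regression OOB R^2), and the spec.
#' @export
train_forest <- function(features, response, spec = forest_spec(),
                         seed = 1L) {
  stopifnot(inherits(spec, "forest_spec"))
  x <- as.data.frame(features)
  if (spec$task == "classify") {
    y <- factor(response)
    if (nlevels(droplevels(y)) < 2L)
      stop("classification requires at least two classes", call. = FALSE)
    y <- droplevels(y)
    mtry <- min(spec$max_features, ncol(x))
    set.seed(seed)
    model <- randomForest::randomForest(x = x, y = y,
                                        ntree = spec$n_estimators,
                                        mtry = mtry, importance = TRUE)
    oob <- as.numeric(model$err.rate[spec$n_estimators, "OOB"])
    structure(list(model = model, oob_error = oob, oob_r2 = NULL,
                   spec = spec, levels = levels(y)),
              class = "morphology_forest")
  } else {
    y <- as.numeric(response)
    set.seed(seed)
    args <- list(x = x, y = y, ntree = spec$n_estimators,
                 importance = TRUE)
    if (!is.null(spec$max_features))
      args$mtry <- min(spec$max_features, ncol(x))
    model <- suppressWarnings(do.call(randomForest::randomForest, args))
    # a constant response has no explainable variance: report R^2 = 0
    r2 <- if (stats::var(y) == 0) 0 else model$rsq[spec$n_estimators]
    structure(list(model = model, oob_error = NULL, oob_r2 = r2,
                   spec = spec, levels = NULL),
              class = "morphology_forest")
  }
}

#' @export
print.morphology_forest <- function(x, ...) {
  if (x$spec$task == "classify")
    cat(sprintf("<morphology_forest> classifier, %d trees, OOB error %.3f\n",
                x$spec$n_estimators, x$oob_error))
  else
    cat(sprintf("<morphology_forest> regressor, %d trees, OOB R2 %.3f\n",
                x$spec$n_estimators, x$oob_r2))
  invisible(x)
}

#' Naive baseline classification accuracy
#'
#' Accuracy of a classifier that guesses the majority class, i.e. the
#' largest class proportion in the labels. The reference point against
#' which forest accuracy is judged.
#'
#' @param labels Vector or factor of class labels.
#' @return Numeric accuracy in (0, 1].
#' @export
naive_baseline <- function(labels) {
  stopifnot(length(labels) >= 1L)
  max(table(labels)) / length(labels)
}

#' Heterotrophic classification probability of model output
#'
#' Applies a trained morphology classifier to feature vectors derived from
#' simulator output (biomass-variant features), returning the per-sample
#' probability of displaying heterotrophic-like morphology.
#'
#' @param forest A classification \code{"morphology_forest"} whose
#'   positive class label is \code{"heterotrophic"}.
#' @param features Feature matrix/data frame matching the training
#'   features.
#' @return A list: \code{prob} (per-sample probability, in [0,1]),
#'   \code{mean}, \code{sd}.
#' @export
classify_model_output <- function(forest, features) {
  stopifnot(inherits(forest, "morphology_forest"),
            forest$spec$task == "classify",
            "heterotrophic" %in% forest$levels)
  pr <- stats::predict(forest$model, newdata = as.data.frame(features),
                       type = "prob")[, "heterotrophic"]
  list(prob = as.numeric(pr), mean = mean(pr), sd = stats::sd(pr))
}

#' Biomass-variant features for every row of a parameter sweep
#'
#' Convenience extraction of \code{\link{slice_features}} (variant
#' \code{"biomass"}) from the coverage columns of a
#' \code{\link{sweep_biofilm}} table. Rows with failed runs or all-zero
#' coverage blocks are excluded.
#'
#' @param sweep A \code{"biofilm_sweep"} data frame.
#' @param drop_20um Passed to \code{\link{slice_features}}.
#' @return A list: \code{features} (data frame) and \code{rows} (indices
#'   of the sweep rows retained).
#' @export
sweep_features <- function(sweep, drop_20um = FALSE) {
  covcols <- grep("^cov_", names(sweep), value = TRUE)
  depths <- as.integer(sub("^cov_", "", covcols))
  ord <- order(depths)
  covcols <- covcols[ord]; depths <- depths[ord]
  keep <- integer(0); feats <- list()
  for (i in seq_len(nrow(sweep))) {
    if (!isTRUE(sweep$ok[i])) next
    prof <- data.frame(depth = depths,
                       coverage = as.numeric(sweep[i, covcols]))
    fv <- tryCatch(slice_features(prof, sweep$mean_thickness[i],
                                  variant = "biomass",
                                  drop_20um = drop_20um),
                   error = function(e) NULL)
    if (is.null(fv)) next
    keep <- c(keep, i)
    feats[[length(feats) + 1L]] <- fv
  }
  list(features = as.data.frame(do.call(rbind, feats)), rows = keep)
}

#' Synthetic morphology training set from rendered confocal stacks
#'
#' Builds a labeled feature table for the morphology classifier by running
#' the full image path end to end: synthetic stacks are rendered with
#' randomized geometry (\code{\link{synth_stack}}), binarized with a
#' depth-adaptive threshold schedule tracking the known attenuation, and
#' quantified into biomass-variant features
#' (\code{\link{slice_features}}). Tapering columnar stacks are labeled
#' \code{"heterotrophic"} (coverage decreasing monotonically away from the
#' coverslip) and mushroom-capped stacks \code{"photoheterotrophic"}
#' (a localized coverage peak above the base layer) — the two
#' experimentally observed morphology classes.
#'
#' @param n_per_class Stacks rendered per class.
#' @param seed Integer seed for geometry, rendering, and thresholds.
#' @param nx,ny,nz Stack dimensions in voxels (1 um voxels).
#' @param drop_20um Passed to \code{\link{slice_features}}.
#' @return A list: \code{features} (data frame), \code{labels} (factor
#'   with levels heterotrophic/photoheterotrophic).
#' @export
synth_training_set <- function(n_per_class = 60, seed = 1L, nx = 96L,
                               ny = 96L, nz = 24L, drop_20um = FALSE) {
  set.seed(seed)
  n <- 2L * n_per_class
  morphology <- rep(c("columnar", "mushroom"), each = n_per_class)
  # heterotrophic-like stacks carry a thick dense base layer with columns
  # tapering above it (coverage monotone non-increasing with depth);
  # photoheterotrophic-like stacks have a thin base and capped columns
  # whose rounded heads put a localized coverage peak at depth
  base_height <- ifelse(morphology == "columnar",
                        sample(5:14, n, replace = TRUE),
                        sample(1:4, n, replace = TRUE))
  column_height <- pmin(base_height + sample(6:14, n, replace = TRUE),
                        nz - 2L)
  cap_start <- pmin(base_height + sample(2:6, n, replace = TRUE),
                    column_height - 3L)
  geo <- data.frame(
    morphology = morphology,
    n_columns = sample(6:14, n, replace = TRUE),
    base_height = base_height,
    column_height = column_height,
    column_radius = stats::runif(n, 10, 20),
    cap_start = cap_start,
    cap_factor = stats::runif(n, 1.5, 2.1),
    fg = stats::runif(n, 0.7, 0.95),
    bg = stats::runif(n, 0.03, 0.08),
    noise_sd = stats::runif(n, 0.01, 0.03),
    attenuation = stats::runif(n, 6, 14),
    seed = sample.int(.Machine$integer.max, n))
  feats <- list(); labels <- character(0)
  for (i in seq_len(n)) {
    g <- geo[i, ]
    syn <- synth_stack(g$morphology, nx = nx, ny = ny, nz = nz,
                       n_columns = g$n_columns,
                       base_height = g$base_height,
                       column_height = g$column_height,
                       column_radius = g$column_radius,
                       cap_radius = g$column_radius * g$cap_factor,
                       cap_start = g$cap_start, fg = g$fg, bg = g$bg,
                       noise_sd = g$noise_sd, attenuation = g$attenuation,
                       seed = g$seed)
    anchor_z <- seq(0, nz - 1, by = 4)
    sch <- make_threshold_schedule(cbind(
      depth = anchor_z,
      threshold = (g$fg + g$bg) / 2 * exp(-anchor_z / g$attenuation)))
    bin <- binarize_stack(syn$stack, sch)
    fv <- tryCatch(slice_features(stack_coverage_by_depth(bin),
                                  stack_biomass(bin),
                                  variant = "biomass",
                                  drop_20um = drop_20um),
                   error = function(e) NULL)
    if (is.null(fv)) next
    feats[[length(feats) + 1L]] <- fv
    labels <- c(labels,
                if (g$morphology == "columnar") "heterotrophic"
                else "photoheterotrophic")
  }
  list(features = as.data.frame(do.call(rbind, feats)),
       labels = factor(labels,
                       levels = c("heterotrophic", "photoheterotrophic")))
}

#' Parameter-importance regression
#'
#' Fits a random-forest regression of the heterotrophic classification
#' probability on the model parameters (s, b, r, p, I1/2, n1/2, alpha,
#' beta) plus the derived inverse nutrient scarcity \code{b^2 r}, and
#' reports relative feature importances (normalized to sum to 1) and the
#' out-of-bag R^2.
#'
#' @param sweep A \code{"biofilm_sweep"} table (or data frame with the
#'   parameter columns and \code{inv_ns}).
#' @param probabilities Numeric response, one per sweep row used.
#' @param spec A regression \code{\link{forest_spec}}.
#' @param seed Integer seed.
#' @return A list: \code{importance} (named, sums to 1), \code{oob_r2},
#'   and the fitted \code{forest}.
#' @export
importance_regression <- function(sweep, probabilities,
                                  spec = forest_spec("regress"),
                                  seed = 1L) {
  stopifnot(spec$task == "regress")
  feats <- c("s", "b", "r", "p", "i_half", "n_half", "alpha", "beta",
             "inv_ns")
  feats <- intersect(feats, names(sweep))
  x <- as.data.frame(sweep)[, feats, drop = FALSE]
  stopifnot(nrow(x) == length(probabilities))
  fit <- train_forest(x, probabilities, spec, seed = seed)
  imp <- randomForest::importance(fit$model, type = 2)[, 1L]
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(NA_real_, length(imp)), names(imp))
  list(importance = imp, oob_r2 = fit$oob_r2, forest = fit)
}
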