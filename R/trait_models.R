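# Trait-level models: multi-temporal lodging scores, green-band leaf-type
# classification, standardized linear AGBM presets, and Lasso model fitting
# with the 85%-split / cross-validation protocol.

#' Multi-temporal lodging score
#'
#' When a plot lodges its canopy height drops while its canopy coverage
#' spreads. The score between an early timepoint 1 and a later timepoint k
#' is \code{(CH_1 - CH_k) * (CC_1 - CC_k)} when canopy coverage is included
#' (the two-date form used between flowering and the last flight), or just
#' the CH difference otherwise. The sign is kept as defined: lodged plots
#' (height down, cover up) score negative under the CC form.
#'
#' @param featT1,featTk feature-table rows (equal length, matched by
#'   plot_id) at the earlier and later ADD; need columns plot_id, add,
#'   CH_uas and (if \code{includeCC}) CC.
#' @param includeCC multiply the CH difference by the CC difference
#'   (default TRUE).
#' @return data.frame with columns plot_id, score, add1, addk.
#' @export
lodgingScore <- function(featT1, featTk, includeCC = TRUE) {
  if (!all(featT1$plot_id == featTk$plot_id))
    stop("mismatched plot ids between the two timepoints")
  if (any(featT1$add >= featTk$add))
    stop("the first timepoint must precede the second (ADD1 < ADDk)")
  dch <- featT1$CH_uas - featTk$CH_uas
  score <- if (includeCC) dch * (featT1$CC - featTk$CC) else dch
  data.frame(plot_id = featT1$plot_id, score = score,
             add1 = featT1$add, addk = featTk$add,
             stringsAsFactors = FALSE)
}

#' Fit a one-dimensional leaf-type threshold classifier
#'
#' Semi-leafless (af) and normal (Af) pea entries differ in plot-mean green
#' reflectance. The classifier is a single threshold chosen by exhaustive
#' search over the midpoints between consecutive sorted training values,
#' minimizing training misclassification; ties break toward the lower
#' threshold. Both orientations (af above or below) are considered.
#'
#' @param greenMeans per-plot mean green reflectance.
#' @param labels leaf-type labels, two classes (typically "af" / "Af").
#' @return a \linkS4class{LeafTypeModel}.
#' @export
fitLeafType <- function(greenMeans, labels) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2)
    stop("training labels must contain exactly two classes; got ",
         paste(cls, collapse = ", "))
  svals <- sort(unique(greenMeans))
  cand <- if (length(svals) > 1)
    (svals[-1] + svals[-length(svals)]) / 2 else svals  # degenerate: all equal
  best <- NULL
  for (up in cls) {
    lo <- setdiff(cls, up)
    for (th in cand) {
      pred <- ifelse(greenMeans > th, up, lo)
      acc <- mean(pred == labels)
      better <- is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 && th < best$th)
      if (better) best <- list(th = th, up = up, lo = lo, acc = acc)
    }
  }
  stats <- do.call(rbind, lapply(cls, function(cl) {
    v <- greenMeans[labels == cl]
    data.frame(class = cl, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  new("LeafTypeModel", threshold = best$th, upperClass = best$up,
      lowerClass = best$lo, classStats = stats, accuracy = best$acc)
}

#' Classify leaf types with a fitted threshold model
#'
#' @param model a \linkS4class{LeafTypeModel}.
#' @param greenMeans per-plot mean green reflectance.
#' @param labels optional true labels; when given, accuracy is reported.
#' @return list with elements labels (predicted) and accuracy (NA when true
#'   labels are not supplied).
#' @export
classifyLeafType <- function(model, greenMeans, labels = NULL) {
  pred <- ifelse(greenMeans > model@threshold, model@upperClass,
                 model@lowerClass)
  acc <- if (is.null(labels)) NA_real_ else mean(pred == as.character(labels))
  list(labels = pred, accuracy = acc)
}

#' Center and scale feature columns
#'
#' Each feature becomes (x - mean) / SD. The means and SDs are returned so
#' they can be frozen into a fitted model; a zero-SD feature is rejected
#' naming the column.
#'
#' @param table data.frame containing the features.
#' @param featureNames columns to standardize.
#' @return list with elements table (standardized copy), centers, scales.
#' @export
standardizeFeatures <- function(table, featureNames) {
  centers <- numeric(0); scales <- numeric(0)
  out <- table
  for (f in featureNames) {
    v <- table[[f]]
    if (is.null(v)) stop("missing feature column: ", f)
    mu <- mean(v); sdv <- stats::sd(v)
    if (!is.finite(sdv) || sdv == 0)
      stop("feature ", f, " has zero standard deviation; cannot standardize")
    out[[f]] <- (v - mu) / sdv
    centers[f] <- mu; scales[f] <- sdv
  }
  list(table = out, centers = centers, scales = scales)
}

#' Frozen literature presets of the linear AGBM equations
#'
#' \code{"winter_1268"}: the four-feature winter-pea model at 1268 ADD
#' (flowering), coefficients on standardized GRVI_sum (1.56), NDVI_sum
#' (-0.83), NDRE_sum (0.75) and CC (-0.01), intercept 8.85, divisor 1.5e4;
#' AGBM in kg fresh weight. \code{"spring_1231"}: the five-feature spring
#' model at 1231 ADD, GRVI_sum (7.80), NDVI_sum (2.46), NDVI_mean (4.98),
#' NDRE_sum (4.98), PV (10.73), intercept 87.83, divisor 1.0e3; AGBM in g
#' dry weight. The presets carry no standardization parameters (the
#' originating trial's feature means/SDs are unpublished), so they apply to
#' features standardized on the current dataset; absolute estimates are
#' therefore not comparable across datasets, rankings are.
#'
#' @param name "winter_1268" or "spring_1231".
#' @return an \linkS4class{AGBMModel}.
#' @export
agbmPreset <- function(name = c("winter_1268", "spring_1231")) {
  name <- match.arg(name)
  switch(name,
    winter_1268 = AGBMModel(
      coefficients = c(GRVI_sum = 1.56, NDVI_sum = -0.83, NDRE_sum = 0.75,
                       CC = -0.01),
      intercept = 8.85, divisor = 1.5e4),
    spring_1231 = AGBMModel(
      coefficients = c(GRVI_sum = 7.80, NDVI_sum = 2.46, NDVI_mean = 4.98,
                       NDRE_sum = 4.98, PV = 10.73),
      intercept = 87.83, divisor = 1.0e3))
}

#' Apply a linear AGBM model to feature rows
#'
#' Computes \code{(sum_i coef_i x_i + intercept) / divisor} per row. When
#' the model carries standardization parameters the raw features are
#' centered and scaled with them first; models without them (the frozen
#' presets) require pre-standardized input.
#'
#' @param model an \linkS4class{AGBMModel}.
#' @param features data.frame covering the model's feature columns.
#' @param standardized set TRUE if \code{features} are already standardized;
#'   default uses the model's own parameters when present.
#' @return numeric vector of AGBM estimates.
#' @export
applyAGBMModel <- function(model, features, standardized = NA) {
  missing <- setdiff(model@featureNames, names(features))
  if (length(missing))
    stop("feature row is missing model feature(s): ",
         paste(missing, collapse = ", "))
  hasStd <- !any(is.na(model@scales))
  if (is.na(standardized)) standardized <- !hasStd
  x <- as.matrix(features[model@featureNames])
  if (!standardized) {
    if (!hasStd)
      stop("model carries no standardization parameters; supply standardized features")
    x <- sweep(sweep(x, 2, model@centers[model@featureNames]), 2,
               model@scales[model@featureNames], "/")
  }
  as.numeric(x %*% model@coefficients + model@intercept) / model@divisor
}

#' Fit a Lasso AGBM model with the 85%-split protocol
#'
#' Features are standardized (zero mean, unit SD on the matched dataset),
#' a seeded random 85% of the rows forms the training split, the L1 penalty
#' is chosen by k-fold cross-validation on that split (seeded fold
#' assignment, lambda at the CV minimum), and the fitted model is validated
#' against the complete dataset: Pearson r and mean absolute error between
#' estimated and actual AGBM, plus the training-split R-squared of the
#' penalized fit.
#'
#' @param features feature table at one ADD, keyed by plot_id.
#' @param agbm data.frame with columns plot_id and agbm (ground truth).
#' @param featureNames model features (columns of \code{features}).
#' @param trainFrac training fraction in (0, 1), default 0.85.
#' @param nFolds cross-validation folds, default 5.
#' @param seed integer seed (split and folds).
#' @return list with elements model (\linkS4class{AGBMModel}, divisor 1),
#'   validation_r, mae, train_r2, lambda and n.
#' @export
fitLassoAGBM <- function(features, agbm, featureNames, trainFrac = 0.85,
                         nFolds = 5, seed = 1) {
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("trainFrac must lie strictly between 0 and 1")
  dat <- merge(features, agbm[c("plot_id", "agbm")], by = "plot_id")
  n <- nrow(dat)
  if (n < 10) stop("need at least 10 matched rows to fit; got ", n)
  std <- standardizeFeatures(dat, featureNames)
  x <- as.matrix(std$table[featureNames])
  y <- dat$agbm

  nTrain <- max(2L, round(trainFrac * n))
  train <- withSeed(deriveSeed(seed, "lasso-split"), sample.int(n, nTrain))
  nFolds <- max(3L, min(as.integer(nFolds), nTrain %/% 3L))
  foldid <- withSeed(deriveSeed(seed, "lasso-folds"),
                     sample(rep_len(seq_len(nFolds), nTrain)))
  # logarithmic penalty grid from the null-model lambda down six decades,
  # so the cross-validated minimum is not truncated by path early-exit
  xt <- x[train, , drop = FALSE]; yt <- y[train]
  lmax <- max(abs(crossprod(xt, yt - mean(yt)))) / length(yt)
  grid <- exp(seq(log(lmax), log(lmax * 1e-6), length.out = 100))
  cv <- glmnet::cv.glmnet(xt, yt, alpha = 1, foldid = foldid,
                          lambda = grid, standardize = FALSE)
  fit <- glmnet::glmnet(xt, yt, alpha = 1, lambda = cv$lambda.min,
                        standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  model <- AGBMModel(coefficients = beta[featureNames],
                     intercept = as.numeric(fit$a0), divisor = 1,
                     centers = std$centers, scales = std$scales)
  # validation with the complete dataset
  pred <- applyAGBMModel(model, std$table, standardized = TRUE)
  predTrain <- pred[train]
  list(model = model,
       # an all-shrunk (constant) estimator has no defined correlation
       validation_r = if (stats::sd(pred) == 0) NA_real_
                      else stats::cor(y, pred),
       mae = mean(abs(y - pred)),
       train_r2 = 1 - sum((y[train] - predTrain)^2) /
         sum((y[train] - mean(y[train]))^2),
       lambda = cv$lambda.min, n = n)
}

#' Entry-level AGBM predictions
#'
#' Applies the model per plot, averages the estimates per entry, and flags
#' entries above the experiment mean.
#'
#' @param model an \linkS4class{AGBMModel}.
#' @param features feature table keyed by plot_id covering the model
#'   features.
#' @param plots \linkS4class{PlotSet} supplying the plot -> entry map.
#' @param standardized passed to \code{\link{applyAGBMModel}}.
#' @return data.frame with columns entry, agbm_est, n_plots, above_mean.
#' @export
predictEntries <- function(model, features, plots, standardized = NA) {
  m <- plotMeta(plots)
  pm <- m[m$role == "plot", ]
  missing <- setdiff(pm$plot_id, features$plot_id)
  if (length(missing))
    stop("missing features for plot(s): ", paste(missing, collapse = ", "))
  feats <- features[match(pm$plot_id, features$plot_id), , drop = FALSE]
  est <- applyAGBMModel(model, feats, standardized = standardized)
  agg <- stats::aggregate(list(agbm_est = est), by = list(entry = pm$entry),
                          FUN = mean)
  cnt <- stats::aggregate(list(n_plots = est), by = list(entry = pm$entry),
                          FUN = length)
  out <- merge(agg, cnt, by = "entry")
  out$above_mean <- out$agbm_est > mean(out$agbm_est)
  out[order(out$entry), , drop = FALSE]
}

#' Serialize and restore AGBM models as JSON
#'
#' @param model an \linkS4class{AGBMModel}.
#' @param path file path (.json).
#' @return \code{writeAGBMModel}: the path, invisibly;
#'   \code{readAGBMModel}: an \linkS4class{AGBMModel}.
#' @export
writeAGBMModel <- function(model, path) {
  jsonlite::write_json(list(
    feature_names = model@featureNames,
    coefficients = as.list(model@coefficients),
    intercept = model@intercept,
    divisor = model@divisor,
    centers = as.list(model@centers),
    scales = as.list(model@scales)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAGBMModel
#' @export
readAGBMModel <- function(path) {
  j <- jsonlite::read_json(path)
  fn <- unlist(j$feature_names)
  num <- function(lst) stats::setNames(vapply(lst, function(v) {
    if (is.null(v)) return(NA_real_)
    suppressWarnings(as.numeric(v))   # JSON null / "NA" -> NA
  }, numeric(1)), names(lst))[fn]
  AGBMModel(coefficients = num(j$coefficients), intercept = j$intercept,
            divisor = j$divisor, centers = num(j$centers),
            scales = num(j$scales))
}
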