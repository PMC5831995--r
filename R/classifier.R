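#' Training configuration for the lincRNA/PCT SVM
#'
#' Defaults follow standard libSVM practice for RBF grid search:
#' C over \code{2^seq(-5, 15, 2)} and gamma over \code{2^seq(-15, 3, 2)},
#' 10-fold cross-validation, and a stratified 80/20 train/test split.
#'
#' @param gridC Candidate values for the cost parameter C.
#' @param gridGamma Candidate values for the RBF width gamma.
#' @param folds Number of cross-validation folds (>= 2).
#' @param testFraction Fraction of each class held out for testing,
#'   in (0, 1).
#' @param seed Integer seed fixing balancing, split and folds.
#' @return A validated list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(gridC = 2^seq(-5, 15, by = 2),
                        gridGamma = 2^seq(-15, 3, by = 2),
                        folds = 10L, testFraction = 0.2, seed = 1L) {
  stopifnot(length(gridC) >= 1, all(gridC > 0),
            length(gridGamma) >= 1, all(gridGamma > 0),
            folds >= 2, testFraction > 0, testFraction < 1)
  structure(list(gridC = gridC, gridGamma = gridGamma,
                 folds = as.integer(folds), testFraction = testFraction,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

POS_LABEL <- "lincRNA_like"
NEG_LABEL <- "PCT_like"

.checkFeatureMatrix <- function(m, what) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rn <- rownames(m)
    id <- if (is.null(rn)) as.character(bad[1, 1]) else rn[bad[1, 1]]
    stop("non-finite value in ", what, " features: transcript '", id,
         "', column '", colnames(m)[bad[1, 2]], "'")
  }
}

.scaleFeatures <- function(m, scaling) {
  stopifnot(identical(colnames(m), scaling$feature))
  sdv <- ifelse(scaling$constant, 1, scaling$sd)
  sweep(sweep(m, 2, scaling$mean, "-"), 2, sdv, "/")
}

#' Train the lincRNA/PCT SVM discriminator
#'
#' Builds an RBF-kernel SVM from positive (lincRNA-like) and negative
#' (PCT-like) feature matrices: classes are balanced to equal size by
#' seeded down-sampling of the larger; a stratified, seeded
#' \code{testFraction} split holds out the test set; features are z-scored
#' with training-split statistics only; every (C, gamma) pair in the grid
#' is assessed by mean \code{folds}-fold cross-validation accuracy on the
#' training split; the winner (ties broken by smallest C, then smallest
#' gamma) is refit on the full training split and evaluated once on the
#' hold-out.
#'
#' @param posFeatures Numeric matrix of positive-class features (as from
#'   [buildFeatureMatrix()]).
#' @param negFeatures Numeric matrix of negative-class features with the
#'   same columns.
#' @param config A [trainConfig()].
#' @param patterns Pattern list to embed in the model; defaults to the
#'   feature column names minus the two ORF columns.
#' @return A [LincModel-class].
#' @export
trainLincModel <- function(posFeatures, negFeatures, config = trainConfig(),
                           patterns = NULL) {
  stopifnot(inherits(config, "trainConfig"))
  if (nrow(posFeatures) == 0 || nrow(negFeatures) == 0)
    stop("both classes must be non-empty")
  if (!identical(colnames(posFeatures), colnames(negFeatures)))
    stop("positive and negative feature matrices must share the same columns")
  .checkFeatureMatrix(posFeatures, "positive")
  .checkFeatureMatrix(negFeatures, "negative")
  if (is.null(patterns))
    patterns <- setdiff(colnames(posFeatures),
                        c("orf_length", "orf_proportion"))

  set.seed(config$seed)
  # balance classes by down-sampling the larger
  n <- min(nrow(posFeatures), nrow(negFeatures))
  if (nrow(posFeatures) > n)
    posFeatures <- posFeatures[sort(sample.int(nrow(posFeatures), n)), , drop = FALSE]
  if (nrow(negFeatures) > n)
    negFeatures <- negFeatures[sort(sample.int(nrow(negFeatures), n)), , drop = FALSE]

  nTest <- max(1L, floor(n * config$testFraction))
  if (n - nTest < config$folds)
    stop("class size after balancing and splitting (", n - nTest,
         ") is smaller than the number of folds (", config$folds, ")")

  posTest <- sort(sample.int(n, nTest))
  negTest <- sort(sample.int(n, nTest))
  trainX <- rbind(posFeatures[-posTest, , drop = FALSE],
                  negFeatures[-negTest, , drop = FALSE])
  trainY <- factor(rep(c(POS_LABEL, NEG_LABEL), each = n - nTest),
                   levels = c(POS_LABEL, NEG_LABEL))
  testX <- rbind(posFeatures[posTest, , drop = FALSE],
                 negFeatures[negTest, , drop = FALSE])
  testY <- factor(rep(c(POS_LABEL, NEG_LABEL), each = nTest),
                  levels = c(POS_LABEL, NEG_LABEL))

  mu <- colMeans(trainX)
  sdv <- apply(trainX, 2, sd)
  scaling <- data.frame(feature = colnames(trainX), mean = mu, sd = sdv,
                        constant = sdv == 0, row.names = NULL,
                        stringsAsFactors = FALSE)
  trainZ <- .scaleFeatures(trainX, scaling)
  testZ <- .scaleFeatures(testX, scaling)

  # stratified fold assignment over the training split
  nTrainClass <- n - nTest
  foldOne <- sample(rep_len(seq_len(config$folds), nTrainClass))
  foldTwo <- sample(rep_len(seq_len(config$folds), nTrainClass))
  foldId <- c(foldOne, foldTwo)

  grid <- expand.grid(cost = config$gridC, gamma = config$gridGamma,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cvAccuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(config$folds)) {
      inFold <- foldId == f
      fit <- e1071::svm(trainZ[!inFold, , drop = FALSE], trainY[!inFold],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- predict(fit, trainZ[inFold, , drop = FALSE])
      correct <- correct + sum(pred == trainY[inFold])
    }
    grid$cvAccuracy[g] <- correct / length(trainY)
  }
  best <- with(grid, order(-cvAccuracy, cost, gamma))[1]

  fit <- e1071::svm(trainZ, trainY, kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE)
  testAcc <- mean(predict(fit, testZ) == testY)
  testIds <- rownames(testZ)
  if (is.null(testIds)) testIds <- character(0)

  new("LincModel", kernel = "RBF", cost = grid$cost[best],
      gamma = grid$gamma[best], scaling = scaling,
      patterns = as.character(patterns), fit = fit,
      cvAccuracy = grid$cvAccuracy[best], testAccuracy = testAcc,
      testIds = testIds, grid = grid, seed = config$seed,
      version = MODEL_FORMAT_VERSION)
}

.predictFeatures <- function(model, features) {
  z <- .scaleFeatures(features, model@scaling)
  as.character(predict(model@fit, z))
}

#' Predict lincRNA-like vs PCT-like labels for transcripts
#'
#' Features are extracted with the model's own pattern list and scaled
#' with its stored training statistics, so predictions are reproducible
#' from the model archive alone. Transcripts shorter than 4 nt cannot
#' support feature extraction and are labeled \code{"too_short"}; they
#' must be excluded from downstream positive sets.
#'
#' @param object A [LincModel-class].
#' @param transcripts A named \code{DNAStringSet}.
#' @return Named character vector over transcript ids with values
#'   \code{"lincRNA_like"}, \code{"PCT_like"} or \code{"too_short"}.
#' @export
setMethod("predict", "LincModel", function(object, transcripts) {
  if (length(transcripts) == 0)
    return(stats::setNames(character(0), character(0)))
  ids <- names(transcripts)
  if (is.null(ids)) stop("transcripts must be named")
  out <- stats::setNames(rep(NA_character_, length(transcripts)), ids)
  short <- Biostrings::width(transcripts) < 4
  out[short] <- "too_short"
  if (any(!short)) {
    feats <- buildFeatureMatrix(transcripts[!short], object@patterns)
    out[!short] <- .predictFeatures(object, feats)
  }
  out
})

#' Evaluate a model on labeled feature data
#'
#' @param model A [LincModel-class].
#' @param features Numeric feature matrix matching the model's columns.
#' @param labels Character/factor vector of true labels,
#'   \code{"pos"}/\code{"neg"} (or the model's own
#'   \code{"lincRNA_like"}/\code{"PCT_like"}).
#' @return Named numeric vector: \code{accuracy} ((TP+TN)/N),
#'   \code{sensitivity} (TP/(TP+FN)), \code{specificity} (TN/(TN+FP)).
#'   A metric whose denominator is empty is \code{NaN}, with a warning.
#' @export
evaluateModel <- function(model, features, labels) {
  stopifnot(is(model, "LincModel"))
  if (nrow(features) == 0) stop("empty input")
  if (length(labels) != nrow(features))
    stop("labels must match feature rows")
  labels <- as.character(labels)
  labels[labels == "pos"] <- POS_LABEL
  labels[labels == "neg"] <- NEG_LABEL
  if (!all(labels %in% c(POS_LABEL, NEG_LABEL)))
    stop("labels must be pos/neg or lincRNA_like/PCT_like")
  pred <- .predictFeatures(model, features)
  tp <- sum(pred == POS_LABEL & labels == POS_LABEL)
  tn <- sum(pred == NEG_LABEL & labels == NEG_LABEL)
  fp <- sum(pred == POS_LABEL & labels == NEG_LABEL)
  fn <- sum(pred == NEG_LABEL & labels == POS_LABEL)
  sens <- if (tp + fn == 0) {
    warning("no positive examples: sensitivity undefined"); NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative examples: specificity undefined"); NaN
  } else tn / (tn + fp)
  c(accuracy = (tp + tn) / length(labels), sensitivity = sens,
    specificity = spec)
}
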