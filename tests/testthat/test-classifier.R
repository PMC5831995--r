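test_that("training configuration is validated", {
  expect_error(trainConfig(gridC = numeric(0)))
  expect_error(trainConfig(gridC = -1))
  expect_error(trainConfig(folds = 1))
  expect_error(trainConfig(testFraction = 0))
  expect_error(trainConfig(testFraction = 1))
})

test_that("a separable synthetic set trains to high hold-out accuracy", {
  m <- sharedModel()
  expect_gte(testAccuracy(m), 0.9)
  expect_gte(cvAccuracy(m), 0.9)
  expect_identical(m@kernel, "RBF")
  # grid winner dominates every other grid point by construction
  expect_true(all(searchGrid(m)$cvAccuracy <= cvAccuracy(m)))
})

test_that("training is deterministic given seed and inputs", {
  g <- sharedTrainingSet()
  pats <- patternPreset("sugarcane")
  fp <- buildFeatureMatrix(g$pos, pats)
  fn <- buildFeatureMatrix(g$neg, pats)
  cfg <- trainConfig(gridC = 2^c(-1, 3, 7), gridGamma = 2^c(-7, -3, 1),
                     folds = 5, seed = 421)
  m2 <- trainLincModel(fp, fn, cfg)
  m1 <- sharedModel()
  expect_identical(m1@cost, m2@cost)
  expect_identical(m1@gamma, m2@gamma)
  expect_identical(m1@testAccuracy, m2@testAccuracy)
  expect_identical(m1@grid, m2@grid)
  expect_identical(m1@scaling, m2@scaling)
})

test_that("stored hold-out accuracy is reproduced from the stored test ids", {
  m <- sharedModel()
  g <- sharedTrainingSet()
  pats <- patternPreset("sugarcane")
  feats <- rbind(buildFeatureMatrix(g$pos, pats),
                 buildFeatureMatrix(g$neg, pats))
  truth <- stats::setNames(rep(c("pos", "neg"),
                               c(length(g$pos), length(g$neg))),
                           c(names(g$pos), names(g$neg)))
  ids <- m@testIds
  expect_gt(length(ids), 0)
  metrics <- evaluateModel(m, feats[ids, , drop = FALSE], truth[ids])
  expect_equal(unname(metrics["accuracy"]), testAccuracy(m))
})

test_that("scaling parameters never see the held-out split", {
  g <- sharedTrainingSet()
  pats <- patternPreset("sugarcane")
  fp <- buildFeatureMatrix(g$pos, pats)
  fn <- buildFeatureMatrix(g$neg, pats)
  cfg <- trainConfig(gridC = 2, gridGamma = 2^-3, folds = 5, seed = 421)
  m <- trainLincModel(fp, fn, cfg)
  # poison exactly the rows that end up in the hold-out split
  fp2 <- fp; fn2 <- fn
  poison <- m@testIds
  fp2[rownames(fp2) %in% poison, ] <- 1e6
  fn2[rownames(fn2) %in% poison, ] <- 1e6
  m2 <- trainLincModel(fp2, fn2, cfg)
  expect_identical(m@scaling, m2@scaling)
})

test_that("prediction uses the model's own pattern list and flags short input", {
  m <- sharedModel()
  g <- sharedTrainingSet()
  ts <- c(g$pos[1:5], Biostrings::DNAStringSet(c(tiny = "ACG")))
  lab <- predict(m, ts)
  expect_equal(unname(lab["tiny"]), "too_short")
  expect_true(all(lab[names(g$pos)[1:5]] %in% c("lincRNA_like", "PCT_like")))
  expect_identical(predict(m, Biostrings::DNAStringSet()),
                   stats::setNames(character(0), character(0)))
})

test_that("a pure PCT-like batch is predominantly labeled PCT_like", {
  m <- sharedModel()
  batch <- simulateLabeledTranscripts(generatorConfig(77, 0, 100))$neg
  lab <- predict(m, batch)
  expect_gte(mean(lab == "PCT_like"), 0.95)
})

test_that("degenerate training inputs raise informative errors", {
  pats <- c("AA", "CC")
  f <- matrix(rnorm(40), 10,
              dimnames = list(paste0("t", 1:10),
                              c("orf_length", "orf_proportion", pats)))
  expect_error(trainLincModel(f[0, , drop = FALSE], f), "non-empty")
  expect_error(trainLincModel(f, f[, c(1, 3, 2, 4)]), "same columns")
  g <- f; g["t3", "AA"] <- NaN
  expect_error(trainLincModel(f, g, trainConfig(folds = 2)), "t3.*AA")
  expect_error(trainLincModel(f, f, trainConfig(folds = 10)),
               "smaller than the number of folds")
})

test_that("unequal classes are balanced by down-sampling", {
  set.seed(1)
  mk <- function(n, shift) matrix(rnorm(n * 4, shift), n,
    dimnames = list(paste0("x", seq_len(n), "_", shift),
                    c("orf_length", "orf_proportion", "AA", "CC")))
  cfg <- trainConfig(gridC = 1, gridGamma = 0.1, folds = 3,
                     testFraction = 0.25, seed = 5)
  m <- trainLincModel(mk(40, 0), mk(80, 3), cfg)
  # balanced to 40 per class, 25% of each class held out
  expect_length(m@testIds, 2 * 10)
})

test_that("the no-signal null stays near chance accuracy", {
  # no signal: both classes drawn independently from the same distribution
  set.seed(2)
  cols <- c("orf_length", "orf_proportion", "AA", "CC")
  acc <- vapply(1:3, function(s) {
    f <- matrix(rnorm(200 * 4), 200, dimnames = list(paste0("p", 1:200), cols))
    g <- matrix(rnorm(200 * 4), 200, dimnames = list(paste0("n", 1:200), cols))
    cfg <- trainConfig(gridC = 2^c(0, 4), gridGamma = 2^c(-3, 0),
                       folds = 5, seed = s)
    testAccuracy(trainLincModel(f, g, cfg))
  }, numeric(1))
  expect_true(all(abs(acc - 0.5) < 0.2))
  expect_lt(abs(mean(acc) - 0.5), 0.1)
})

test_that("evaluation metrics follow the confusion-matrix definitions", {
  m <- sharedModel()
  g <- sharedTrainingSet()
  pats <- patternPreset("sugarcane")
  # pick 4 transcripts the model calls lincRNA-like and 1 it calls PCT-like
  lab <- predict(m, c(g$pos, g$neg))
  posIds <- names(lab)[lab == "lincRNA_like"][1:4]
  negIds <- names(lab)[lab == "PCT_like"][1]
  ts <- c(g$pos, g$neg)[c(posIds, negIds)]
  feats <- buildFeatureMatrix(ts, pats)

  perfect <- evaluateModel(m, feats, c(rep("pos", 4), "neg"))
  expect_equal(unname(perfect), c(1, 1, 1))

  # truth: 3 TP, 1 FP (predicted pos, truth neg), 1 TN -> accuracy 0.8
  mixed <- evaluateModel(m, feats, c("pos", "pos", "pos", "neg", "neg"))
  expect_equal(unname(mixed["accuracy"]), 0.8)
  expect_equal(unname(mixed["sensitivity"]), 1)
  expect_equal(unname(mixed["specificity"]), 0.5)

  expect_warning(onlyPos <- evaluateModel(m, feats, rep("pos", 5)),
                 "specificity undefined")
  expect_true(is.nan(onlyPos["specificity"]))
  expect_error(evaluateModel(m, feats[0, , drop = FALSE], character(0)),
               "empty")
})
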