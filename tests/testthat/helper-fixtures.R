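suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# Brute-force longest-ORF oracle, independent of the package implementation:
# enumerate every ATG position, pair it with the first downstream in-frame
# stop, and take the longest candidate (ties: smallest start, then frame).
oracleLongestOrf <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  codonAt <- function(i) paste(chars[i:(i + 2)], collapse = "")
  best <- NULL
  for (start in seq_len(max(L - 5, 0))) {
    if (codonAt(start) != "ATG") next
    j <- start + 3
    while (j + 2 <= L) {
      if (codonAt(j) %in% c("TAA", "TAG", "TGA")) {
        nt <- j + 2 - start + 1
        cand <- c(start0 = start - 1, nt = nt, frame = (start - 1) %% 3)
        if (is.null(best) || cand["nt"] > best["nt"] ||
            (cand["nt"] == best["nt"] &&
             (cand["start0"] < best["start0"] ||
              (cand["start0"] == best["start0"] &&
               cand["frame"] < best["frame"]))))
          best <- cand
        break
      }
      j <- j + 3
    }
  }
  best
}

randomDna <- function(len, withN = FALSE) {
  alpha <- if (withN) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alpha, len, replace = TRUE, prob = prob), collapse = "")
}

# Brute-force differential-expression rule, row by row.
oracleDifferential <- function(mat, condition) {
  treated <- names(condition)[condition == "treated"]
  control <- names(condition)[condition == "control"]
  out <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    t <- any(mat[i, treated]); c <- any(mat[i, control])
    out[i] <- (t && !c) || (c && !t)
  }
  out
}

# One small separable model shared across test files (trained lazily once).
.shared <- new.env(parent = emptyenv())
sharedModel <- function() {
  if (is.null(.shared$model)) {
    g <- simulateLabeledTranscripts(generatorConfig(421, nPos = 250, nNeg = 250))
    pats <- patternPreset("sugarcane")
    cfg <- trainConfig(gridC = 2^c(-1, 3, 7), gridGamma = 2^c(-7, -3, 1),
                       folds = 5, seed = 421)
    .shared$model <- trainLincModel(buildFeatureMatrix(g$pos, pats),
                                    buildFeatureMatrix(g$neg, pats), cfg)
    .shared$train <- g
  }
  .shared$model
}
sharedTrainingSet <- function() { sharedModel(); .shared$train }

# A PresenceMatrix built directly from a given logical matrix (self-presence
# forced), for randomized rule tests.
makePresence <- function(mat, home, condition) {
  mat[cbind(seq_len(nrow(mat)), match(home, colnames(mat)))] <- TRUE
  new("PresenceMatrix", presence = mat, homeLibrary = home,
      condition = condition)
}
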