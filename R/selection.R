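#' Select class-discriminative nucleotide patterns by PCA
#'
#' Identifies, from all 336 possible 2-/3-/4-mer frequency features
#' computed on a labeled training set, the patterns most discriminative
#' between lincRNAs (positives) and protein-coding transcripts
#' (negatives). The procedure: (1) compute all 336 k-mer frequencies per
#' transcript; (2) z-score standardize each feature over the pooled set
#' (zero-variance features are excluded and score 0); (3) run PCA on the
#' standardized pooled matrix; (4) pick the component whose sample scores
#' have maximal absolute point-biserial correlation with the class label;
#' (5) score every feature by the absolute value of its loading on that
#' component; (6) return the top \code{nSelect}. The component is
#' oriented so the positive class has a positive mean score. The result
#' is deterministic given the input.
#'
#' When no component correlates with the label (e.g. the two classes are
#' identical), a warning is raised and the top loadings of PC1 are
#' returned.
#'
#' @param pos \code{DNAStringSet} of positive-class (lincRNA) transcripts.
#' @param neg \code{DNAStringSet} of negative-class (PCT) transcripts.
#' @param nSelect Number of patterns to select (default 10).
#' @param seed Unused for computation (the procedure is deterministic);
#'   accepted for interface symmetry with the stochastic steps of the
#'   workflow and stored nowhere.
#' @return A [PatternSelection-class] object.
#' @export
selectPatterns <- function(pos, neg, nSelect = 10, seed = NULL) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("each class needs at least 2 transcripts (covariance undefined)")
  pats <- candidatePatterns()
  if (nSelect > length(pats))
    stop("nSelect must be <= ", length(pats))
  M <- do.call(cbind, lapply(2:4, function(k)
    rbind(kmerFrequencies(pos, k), kmerFrequencies(neg, k))))
  M <- M[, pats, drop = FALSE]
  label <- rep(c(1, 0), c(length(pos), length(neg)))

  sdv <- apply(M, 2, sd)
  keep <- sdv > 0
  Z <- scale(M[, keep, drop = FALSE])
  pr <- prcomp(Z, center = FALSE, scale. = FALSE)

  usable <- pr$sdev > 1e-12
  corr <- rep(0, ncol(pr$x))
  corr[usable] <- suppressWarnings(
    as.vector(cor(pr$x[, usable, drop = FALSE], label)))
  corr[is.na(corr)] <- 0

  if (max(abs(corr)) < 1e-8) {
    warning("no discriminative component: classes are indistinguishable; ",
            "returning top loadings of PC1")
    pc <- 1L
  } else {
    pc <- which.max(abs(corr))
  }
  # orient so the positive class has positive mean score
  orient <- if (mean(pr$x[label == 1, pc]) >= mean(pr$x[label == 0, pc])) 1 else -1

  scores <- stats::setNames(rep(0, length(pats)), pats)
  scores[colnames(Z)] <- abs(orient * pr$rotation[, pc])
  ord <- order(-scores, seq_along(scores))
  selected <- pats[ord][seq_len(nSelect)]

  new("PatternSelection",
      selectedPatterns = selected,
      scores = scores,
      pcIndex = as.integer(pc),
      explainedVariance = pr$sdev[pc]^2 / sum(pr$sdev^2))
}
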