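#' @describeIn PatternSelection Ordered selected patterns.
#' @param object A \code{PatternSelection}, \code{LincModel},
#'   \code{StageReport}, \code{LibrarySet} or \code{PresenceMatrix}.
#' @export
setGeneric("selectedPatterns", function(object) standardGeneric("selectedPatterns"))

#' @export
setMethod("selectedPatterns", "PatternSelection", function(object)
  object@selectedPatterns)

#' Discrimination scores over all candidate patterns
#' @param object A \code{PatternSelection}.
#' @return Named numeric vector over the 336 candidate patterns.
#' @export
setGeneric("patternScores", function(object) standardGeneric("patternScores"))

#' @export
setMethod("patternScores", "PatternSelection", function(object) object@scores)

#' Pattern list carried by a trained model
#' @param object A \code{LincModel}.
#' @export
setGeneric("modelPatterns", function(object) standardGeneric("modelPatterns"))

#' @export
setMethod("modelPatterns", "LincModel", function(object) object@patterns)

#' Cross-validation accuracy of the winning grid point
#' @param object A \code{LincModel}.
#' @export
setGeneric("cvAccuracy", function(object) standardGeneric("cvAccuracy"))

#' @export
setMethod("cvAccuracy", "LincModel", function(object) object@cvAccuracy)

#' Hold-out test accuracy stored at training time
#' @param object A \code{LincModel}.
#' @export
setGeneric("testAccuracy", function(object) standardGeneric("testAccuracy"))

#' @export
setMethod("testAccuracy", "LincModel", function(object) object@testAccuracy)

#' Grid-search results
#' @param object A \code{LincModel}.
#' @return \code{data.frame} with columns cost, gamma, cvAccuracy.
#' @export
setGeneric("searchGrid", function(object) standardGeneric("searchGrid"))

#' @export
setMethod("searchGrid", "LincModel", function(object) object@grid)

#' Per-stage counts of a pipeline run
#' @param object A \code{StageReport}.
#' @return \code{data.frame} with columns stage, input, output.
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @export
setMethod("stageCounts", "StageReport", function(object) object@stages)

#' Final predicted lincRNA ids of a pipeline run
#' @param object A \code{StageReport}.
#' @export
setGeneric("finalIds", function(object) standardGeneric("finalIds"))

#' @export
setMethod("finalIds", "StageReport", function(object) object@finalIds)

#' Library ids of a LibrarySet or PresenceMatrix
#' @param object A \code{LibrarySet} or \code{PresenceMatrix}.
#' @export
setGeneric("libraryIds", function(object) standardGeneric("libraryIds"))

#' @export
setMethod("libraryIds", "LibrarySet", function(object) names(object@libraries))

#' @export
setMethod("libraryIds", "PresenceMatrix", function(object)
  colnames(object@presence))

#' Treatment condition of each library
#' @param object A \code{LibrarySet} or \code{PresenceMatrix}.
#' @return Named character vector over library ids.
#' @export
setGeneric("libraryCondition", function(object) standardGeneric("libraryCondition"))

#' @export
setMethod("libraryCondition", "LibrarySet", function(object) object@condition)

#' @export
setMethod("libraryCondition", "PresenceMatrix", function(object)
  object@condition)

#' Presence matrix as a plain logical matrix
#' @param object A \code{PresenceMatrix}.
#' @export
setGeneric("presence", function(object) standardGeneric("presence"))

#' @export
setMethod("presence", "PresenceMatrix", function(object) object@presence)

setMethod("show", "LincModel", function(object) {
  cat("LincModel (RBF SVM)\n")
  cat(sprintf("  features  : orf_length, orf_proportion + %d patterns (%s, ...)\n",
              length(object@patterns),
              paste(head(object@patterns, 4), collapse = ", ")))
  cat(sprintf("  C = %g, gamma = %g\n", object@cost, object@gamma))
  cat(sprintf("  CV accuracy = %.4f, hold-out accuracy = %.4f (seed %d)\n",
              object@cvAccuracy, object@testAccuracy, object@seed))
})

setMethod("show", "PatternSelection", function(object) {
  cat("PatternSelection\n")
  cat(sprintf("  selected (%d): %s\n", length(object@selectedPatterns),
              paste(object@selectedPatterns, collapse = ", ")))
  cat(sprintf("  discriminative component: PC%d (%.1f%% of variance)\n",
              object@pcIndex, 100 * object@explainedVariance))
})

setMethod("show", "StageReport", function(object) {
  cat("StageReport\n")
  df <- object@stages
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-22s %6d -> %6d\n", df$stage[i], df$input[i], df$output[i]))
  cat(sprintf("  final ids: %d\n", length(object@finalIds)))
})

setMethod("show", "LibrarySet", function(object) {
  cat("LibrarySet of", length(object@libraries), "libraries\n")
  for (id in names(object@libraries))
    cat(sprintf("  %s (%s): %d sequences\n", id, object@condition[[id]],
                length(object@libraries[[id]])))
})

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d pooled sequences x %d libraries\n",
              nrow(object@presence), ncol(object@presence)))
  cat(sprintf("  treated: %s | control: %s\n",
              paste(names(object@condition)[object@condition == "treated"],
                    collapse = ", "),
              paste(names(object@condition)[object@condition == "control"],
                    collapse = ", ")))
})
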