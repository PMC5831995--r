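#' @import methods
#' @importFrom stats prcomp predict sd cor setNames runif
#' @importFrom e1071 svm
#' @importFrom utils head
NULL

MODEL_FORMAT_VERSION <- "plantlincs-model-1"

#' Trained lincRNA/PCT discriminator
#'
#' An RBF-kernel support vector machine together with everything needed to
#' reproduce its predictions: the ordered nucleotide-pattern list used at
#' feature extraction, the per-feature scaling statistics estimated on the
#' training split, the tuned hyperparameters, and the cross-validation and
#' hold-out accuracies observed during training. Carrying the pattern list
#' and scaling inside the model guarantees predict-time feature extraction
#' cannot diverge from train-time.
#'
#' @slot kernel Kernel name; always \code{"RBF"}.
#' @slot cost Tuned SVM cost parameter C (> 0).
#' @slot gamma Tuned RBF kernel width gamma (> 0).
#' @slot scaling \code{data.frame} with columns \code{feature}, \code{mean},
#'   \code{sd}, \code{constant}: z-scoring statistics estimated on the
#'   training split only. Constant features (sd == 0) are flagged and left
#'   unscaled.
#' @slot patterns Ordered character vector of nucleotide patterns (k in
#'   2..4) appended to the two ORF features.
#' @slot fit The underlying \code{e1071::svm} object.
#' @slot cvAccuracy Mean 10-fold cross-validation accuracy of the winning
#'   grid point, on the training split.
#' @slot testAccuracy Accuracy on the held-out test split (disjoint from
#'   all training folds).
#' @slot testIds Row names of the held-out feature rows (empty when the
#'   training matrices were unnamed), so the stored hold-out accuracy can
#'   be reproduced.
#' @slot grid \code{data.frame} of all evaluated (cost, gamma) pairs and
#'   their cross-validation accuracies.
#' @slot seed Integer seed that fixed the class balancing, split and fold
#'   assignment.
#' @slot version Model format version tag.
#'
#' @seealso [trainLincModel()], [saveModel()], [loadModel()]
#' @export
setClass("LincModel",
  representation(
    kernel = "character",
    cost = "numeric",
    gamma = "numeric",
    scaling = "data.frame",
    patterns = "character",
    fit = "ANY",
    cvAccuracy = "numeric",
    testAccuracy = "numeric",
    testIds = "character",
    grid = "data.frame",
    seed = "integer",
    version = "character"
  )
)

setValidity("LincModel", function(object) {
  msg <- character()
  if (!identical(object@kernel, "RBF"))
    msg <- c(msg, "kernel must be \"RBF\"")
  if (length(object@cost) != 1 || object@cost <= 0)
    msg <- c(msg, "cost must be a single positive number")
  if (length(object@gamma) != 1 || object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive number")
  if (length(object@patterns) == 0)
    msg <- c(msg, "patterns must be non-empty")
  need <- c("feature", "mean", "sd", "constant")
  if (!all(need %in% names(object@scaling)))
    msg <- c(msg, "scaling must have columns feature, mean, sd, constant")
  else {
    if (nrow(object@scaling) != length(object@patterns) + 2L)
      msg <- c(msg, "scaling must have one row per feature column")
    bad <- !object@scaling$constant & object@scaling$sd <= 0
    if (any(bad))
      msg <- c(msg, "non-constant features must have sd > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Result of PCA-based nucleotide-pattern selection
#'
#' @slot selectedPatterns Ordered character vector of the selected patterns
#'   (descending discrimination score).
#' @slot scores Named numeric vector of discrimination scores for all 336
#'   candidate 2-/3-/4-mers (absolute loading on the class-separating
#'   principal component; zero-variance features score 0).
#' @slot pcIndex Index of the principal component whose scores correlate
#'   most with the class label.
#' @slot explainedVariance Fraction of total variance explained by that
#'   component.
#'
#' @seealso [selectPatterns()]
#' @export
setClass("PatternSelection",
  representation(
    selectedPatterns = "character",
    scores = "numeric",
    pcIndex = "integer",
    explainedVariance = "numeric"
  )
)

setValidity("PatternSelection", function(object) {
  msg <- character()
  if (anyDuplicated(object@selectedPatterns))
    msg <- c(msg, "selected patterns must be unique")
  if (length(object@scores) != 336 || is.null(names(object@scores)))
    msg <- c(msg, "scores must be a named vector over all 336 candidates")
  if (length(object@explainedVariance) == 1 &&
      (object@explainedVariance < 0 || object@explainedVariance > 1))
    msg <- c(msg, "explainedVariance must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Per-stage survivor counts of the prediction cascade
#'
#' Mirrors the per-stage tables the workflow reports: each filtering stage
#' with its input and output transcript counts, plus the final set of
#' predicted lincRNA ids. The SVM-positive and lncRNA-annotation stages are
#' parallel branches over the same survivor set; the final stage is their
#' intersection.
#'
#' @slot stages \code{data.frame} with columns \code{stage},
#'   \code{input}, \code{output}.
#' @slot finalIds Character vector of transcript ids in the final output.
#'
#' @seealso [runPipeline()]
#' @export
setClass("StageReport",
  representation(stages = "data.frame", finalIds = "character")
)

setValidity("StageReport", function(object) {
  msg <- character()
  need <- c("stage", "input", "output")
  if (!all(need %in% names(object@stages)))
    msg <- c(msg, "stages must have columns stage, input, output")
  else if (any(object@stages$output > object@stages$input))
    msg <- c(msg, "every stage must satisfy output <= input")
  if (nrow(object@stages) > 0 &&
      length(object@finalIds) != object@stages$output[nrow(object@stages)])
    msg <- c(msg, "finalIds length must equal the last stage's output count")
  if (length(msg)) msg else TRUE
})

#' A set of per-library predicted lincRNAs with treatment conditions
#'
#' @slot libraries Named list of \code{DNAStringSet}, one per sequencing
#'   library; names are library ids.
#' @slot condition Named character vector mapping each library id to
#'   \code{"treated"} or \code{"control"}.
#'
#' @seealso [buildPresenceMatrix()]
#' @export
setClass("LibrarySet",
  representation(libraries = "list", condition = "character")
)

setValidity("LibrarySet", function(object) {
  msg <- character()
  ids <- names(object@libraries)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    msg <- c(msg, "libraries must be uniquely named")
  if (!all(vapply(object@libraries, inherits, logical(1), "DNAStringSet")))
    msg <- c(msg, "each library must be a DNAStringSet")
  if (!setequal(names(object@condition), ids))
    msg <- c(msg, "condition must name every library exactly once")
  if (!all(object@condition %in% c("treated", "control")))
    msg <- c(msg, "condition values must be \"treated\" or \"control\"")
  if (length(msg) == 0) {
    if (sum(object@condition == "treated") < 1 ||
        sum(object@condition == "control") < 1)
      msg <- c(msg, "need at least one treated and one control library")
  }
  if (length(msg)) msg else TRUE
})

#' Presence/absence matrix of pooled lincRNAs across libraries
#'
#' Rows are library-qualified predicted lincRNAs (id
#' \code{"library:transcript"}) pooled over all libraries; columns are
#' libraries. A cell is \code{TRUE} when the row's sequence is present in
#' (similar to a sequence of) that library. Self-presence in the home
#' library is always \code{TRUE}.
#'
#' @slot presence Logical matrix, pooled sequences x libraries.
#' @slot homeLibrary Character vector giving each row's library of origin.
#' @slot condition Named character vector over columns
#'   (\code{"treated"}/\code{"control"}).
#'
#' @seealso [buildPresenceMatrix()], [callDifferential()]
#' @export
setClass("PresenceMatrix",
  representation(
    presence = "matrix",
    homeLibrary = "character",
    condition = "character"
  )
)

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  m <- object@presence
  if (!is.logical(m)) msg <- c(msg, "presence must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "presence must have row and column names")
  if (length(object@homeLibrary) != nrow(m))
    msg <- c(msg, "homeLibrary must have one entry per row")
  else if (!all(object@homeLibrary %in% colnames(m)))
    msg <- c(msg, "homeLibrary entries must be matrix columns")
  else if (nrow(m) > 0 &&
           !all(m[cbind(seq_len(nrow(m)), match(object@homeLibrary, colnames(m)))]))
    msg <- c(msg, "self-presence must hold: each row TRUE in its home library")
  if (!setequal(names(object@condition), colnames(m)))
    msg <- c(msg, "condition must cover every library column")
  if (length(msg)) msg else TRUE
})
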