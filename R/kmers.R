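#' Overlapping k-mer frequencies of transcripts
#'
#' Counts overlapping windows of width \code{k} and converts them to
#' frequencies over the valid windows. Windows containing any non-ACGT
#' character are excluded from both numerator and denominator; when a
#' sequence has no valid window all its frequencies are 0. All \code{4^k}
#' patterns are present in the output (zero-filled).
#'
#' @param x A \code{DNAStringSet} (or single sequence).
#' @param k Window width, one of 2, 3 or 4.
#' @return Numeric matrix, transcripts x \code{4^k} patterns, rows
#'   ordered as the input, columns in lexicographic pattern order.
#' @examples
#' kmerFrequencies(Biostrings::DNAStringSet(c(a = "ACGT")), 2)
#' @export
kmerFrequencies <- function(x, k) {
  if (!(length(k) == 1 && k %in% 2:4))
    stop("k must be one of 2, 3, 4")
  if (!inherits(x, "DNAStringSet"))
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  counts <- Biostrings::oligonucleotideFrequency(x, width = k)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  valid <- rowSums(counts)
  freq <- counts / pmax(valid, 1)
  rownames(freq) <- names(x)
  freq
}

#' All candidate nucleotide patterns
#'
#' The full candidate universe for pattern selection: all 16 dimers, 64
#' trimers and 256 tetramers, lexicographic within each width, widths
#' ascending (336 patterns in total).
#'
#' @return Character vector of length 336, first element \code{"AA"},
#'   last \code{"TTTT"}.
#' @export
candidatePatterns <- function() {
  unlist(lapply(2:4, function(k)
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)), use.names = FALSE)
}

#' Case-study pattern presets
#'
#' The per-organism lists of the 10 most discriminative nucleotide
#' patterns used by the two published case studies, shippable so that
#' prediction can bypass selection.
#'
#' @param organism \code{"sugarcane"} or \code{"maize"}.
#' @return Character vector of 10 patterns.
#' @export
patternPreset <- function(organism = c("sugarcane", "maize")) {
  organism <- match.arg(organism)
  switch(organism,
    sugarcane = c("AA", "AT", "CA", "CC", "CG", "GA", "GC", "GG", "TG", "TT"),
    maize = c("AA", "AC", "CA", "CC", "CCC", "CG", "GA", "GC", "GG", "TG"))
}

.validatePatterns <- function(patterns) {
  if (length(patterns) == 0) stop("patterns must be non-empty")
  bad <- patterns[!grepl("^[ACGT]{2,4}$", patterns)]
  if (length(bad))
    stop("invalid pattern(s): ", paste(bad, collapse = ", "),
         " (must be strings over ACGT of length 2-4)")
  invisible(patterns)
}

#' Assemble the SVM feature matrix
#'
#' Rows are transcripts (input order preserved), columns are
#' \code{orf_length}, \code{orf_proportion}, then the supplied patterns
#' in their given order. Pattern frequencies are normalized per width
#' over valid windows, so a dimer and a trimer column are on comparable
#' scales.
#'
#' @param x A \code{DNAStringSet}.
#' @param patterns Ordered character vector of patterns over ACGT with
#'   lengths in 2..4.
#' @param allowOpenEnded Passed to [findLongestOrf()].
#' @return Numeric matrix with \code{length(patterns) + 2} columns and
#'   transcript ids as row names.
#' @examples
#' ts <- Biostrings::DNAStringSet(c(t1 = "ATGAAATAACCCC"))
#' buildFeatureMatrix(ts, patternPreset("sugarcane"))
#' @export
buildFeatureMatrix <- function(x, patterns, allowOpenEnded = FALSE) {
  .validatePatterns(patterns)
  cols <- c("orf_length", "orf_proportion", patterns)
  if (length(x) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = length(cols),
                  dimnames = list(NULL, cols)))
  orf <- orfFeatures(x, allowOpenEnded = allowOpenEnded)
  out <- matrix(0, nrow = length(x), ncol = length(cols),
                dimnames = list(orf$id, cols))
  out[, "orf_length"] <- orf$orf_length
  out[, "orf_proportion"] <- orf$orf_proportion
  for (k in sort(unique(nchar(patterns)))) {
    pk <- patterns[nchar(patterns) == k]
    freq <- kmerFrequencies(x, k)
    out[, pk] <- freq[, pk, drop = FALSE]
  }
  out
}
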