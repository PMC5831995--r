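#' Find the longest open reading frame of a transcript
#'
#' Scans the given strand only, in all three reading frames, for spans
#' starting at an ATG and ending at the first downstream in-frame stop
#' codon (TAA, TAG or TGA). The stop codon is included in the reported
#' nucleotide length. Ties on length are broken by smallest start
#' position, then smallest frame. Codons containing ambiguous bases match
#' neither ATG nor a stop.
#'
#' Transcripts are assumed to be oriented (assembled transcript
#' sequences), so the reverse strand is not scanned. An ORF requires a
#' terminating stop codon: an ATG running to the end of the sequence
#' without a stop does not count unless \code{allowOpenEnded = TRUE}.
#'
#' @param x A single sequence: \code{DNAString}, length-1
#'   \code{DNAStringSet}, or character string.
#' @param allowOpenEnded If \code{TRUE}, an ATG with no downstream
#'   in-frame stop yields an open-ended ORF running to the last complete
#'   codon. Default \code{FALSE}.
#' @return A list with elements \code{start} (0-based offset of the A of
#'   the start codon), \code{end} (exclusive offset one past the stop
#'   codon), \code{frame} (0, 1 or 2), \code{ntLength} and
#'   \code{aaLength} (\code{ntLength/3 - 1}; the stop contributes no
#'   residue), or \code{NULL} when no ORF exists.
#' @examples
#' findLongestOrf("ATGAAATAA")  # start 0, ntLength 9, aaLength 2
#' findLongestOrf("CCCCCC")     # NULL
#' @export
findLongestOrf <- function(x, allowOpenEnded = FALSE) {
  s <- .asSequence(x)
  L <- nchar(s)
  best <- NULL
  if (L < 6L) return(NULL)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (L - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, starts, starts + 2L)
    isStart <- codons == "ATG"
    isStop <- codons %in% stops
    open <- NA_integer_
    for (i in seq_len(ncod)) {
      if (isStop[i]) {
        if (!is.na(open)) {
          nt <- 3L * (i - open + 1L)
          cand <- list(start = starts[open] - 1L, end = starts[i] + 2L,
                       frame = frame, ntLength = nt, aaLength = nt %/% 3L - 1L)
          best <- .betterOrf(best, cand)
          open <- NA_integer_
        }
      } else if (isStart[i] && is.na(open)) {
        open <- i
      }
    }
    if (allowOpenEnded && !is.na(open)) {
      nt <- 3L * (ncod - open + 1L)
      if (nt >= 6L) {
        cand <- list(start = starts[open] - 1L, end = starts[ncod] + 2L,
                     frame = frame, ntLength = nt, aaLength = nt %/% 3L - 1L)
        best <- .betterOrf(best, cand)
      }
    }
  }
  best
}

.betterOrf <- function(best, cand) {
  if (is.null(best)) return(cand)
  if (cand$ntLength > best$ntLength) return(cand)
  if (cand$ntLength == best$ntLength &&
      (cand$start < best$start ||
       (cand$start == best$start && cand$frame < best$frame)))
    return(cand)
  best
}

.asSequence <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    x <- x[[1L]]
  }
  toupper(as.character(x))
}

#' ORF-derived coding-potential features
#'
#' For each transcript, the length in nucleotides of its longest ORF
#' (0 when none exists) and the proportion of the transcript covered by
#' it (\code{orf_length / transcript length}), the two ORF features used
#' by the lincRNA/PCT discriminator. A lincRNA is expected to have a
#' longest ORF under 100 amino acids; the residue count is reported
#' alongside for that landmark.
#'
#' @param x A \code{DNAStringSet} (or single sequence).
#' @param allowOpenEnded Passed to [findLongestOrf()].
#' @return \code{data.frame} with columns \code{id}, \code{orf_length},
#'   \code{orf_proportion}, \code{aa_length}.
#' @examples
#' orfFeatures(Biostrings::DNAStringSet(c(t1 = "ATGAAATAA")))
#' @export
orfFeatures <- function(x, allowOpenEnded = FALSE) {
  if (!inherits(x, "DNAStringSet"))
    x <- Biostrings::DNAStringSet(.asSequence(x))
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  seqs <- as.character(x)
  n <- length(x)
  orfLen <- integer(n)
  aaLen <- integer(n)
  for (i in seq_len(n)) {
    o <- findLongestOrf(seqs[[i]], allowOpenEnded = allowOpenEnded)
    if (!is.null(o)) {
      orfLen[i] <- o$ntLength
      aaLen[i] <- o$aaLength
    }
  }
  w <- Biostrings::width(x)
  data.frame(id = ids, orf_length = orfLen,
             orf_proportion = ifelse(w > 0, orfLen / w, 0),
             aa_length = aaLen, stringsAsFactors = FALSE)
}
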