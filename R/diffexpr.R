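#' Construct a LibrarySet
#'
#' Bundles per-library predicted lincRNA sequences with their treatment
#' conditions for the presence/absence differential-expression
#' procedure. Pooled sequences are identified as
#' \code{"library:transcript"}; the colon separates the library id, so
#' library ids must not contain one.
#'
#' @param libraries Named list of \code{DNAStringSet}, one per library.
#' @param condition Named character vector over library ids with values
#'   \code{"treated"} or \code{"control"}; at least one of each.
#' @return A [LibrarySet-class].
#' @export
LibrarySet <- function(libraries, condition) {
  if (any(grepl(":", names(libraries), fixed = TRUE)))
    stop("library ids must not contain ':'")
  new("LibrarySet", libraries = libraries,
      condition = condition[names(libraries)])
}

.pooledIds <- function(ls) {
  unlist(lapply(names(ls@libraries), function(lib) {
    ids <- names(ls@libraries[[lib]])
    if (is.null(ids)) stop("library '", lib, "' has unnamed sequences")
    paste0(lib, ":", ids)
  }), use.names = FALSE)
}

.libOf <- function(pooledId) sub(":.*$", "", pooledId)

#' Build the presence/absence matrix from similarity hits
#'
#' Rows are all predicted lincRNAs pooled over the libraries
#' (library-qualified ids); columns are libraries. A cell (r, L) is
#' \code{TRUE} iff L is r's home library, or r has a similarity hit
#' (query = r, subject in L) with e-value <= \code{evalueMax}. Two
#' sequences are considered similar when their e-value is less than or
#' equal to the threshold (inclusive; default 1e-12). Self-presence is
#' forced regardless of whether self-hits appear in the hit table.
#'
#' @param ls A [LibrarySet-class].
#' @param hits BLAST hit table of pooled lincRNAs queried against the
#'   pooled lincRNA database; query and subject ids use the
#'   library-qualified \code{"library:transcript"} convention.
#' @param evalueMax Inclusive similarity threshold (default 1e-12).
#' @return A [PresenceMatrix-class]. Hits naming unknown sequences are
#'   ignored with a warning.
#' @export
buildPresenceMatrix <- function(ls, hits, evalueMax = 1e-12) {
  stopifnot(is(ls, "LibrarySet"))
  rows <- .pooledIds(ls)
  libs <- names(ls@libraries)
  m <- matrix(FALSE, nrow = length(rows), ncol = length(libs),
              dimnames = list(rows, libs))
  home <- .libOf(rows)
  m[cbind(seq_along(rows), match(home, libs))] <- TRUE
  if (nrow(hits) > 0) {
    sig <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    known <- sig$qseqid %in% rows & sig$sseqid %in% rows
    if (any(!known))
      warning(sum(!known), " hit(s) reference sequences absent from all ",
              "libraries (ignored)")
    sig <- sig[known, , drop = FALSE]
    if (nrow(sig) > 0)
      m[cbind(match(sig$qseqid, rows), match(.libOf(sig$sseqid), libs))] <- TRUE
  }
  new("PresenceMatrix", presence = m, homeLibrary = home,
      condition = ls@condition[libs])
}

#' Call presence/absence differential expression
#'
#' A pooled sequence is differentially expressed iff it is present in at
#' least one treated library and absent from every control library, or
#' vice-versa (present in at least one control and absent from every
#' treated library). The rule is symmetric under swapping the condition
#' labels.
#'
#' @param pm A [PresenceMatrix-class].
#' @param condition Optional named condition vector overriding the one
#'   stored in \code{pm} (must cover every library column).
#' @return List with elements \code{ids} (character vector of
#'   differential row ids) and \code{n} (their count).
#' @export
callDifferential <- function(pm, condition = NULL) {
  stopifnot(is(pm, "PresenceMatrix"))
  m <- pm@presence
  if (is.null(condition)) condition <- pm@condition
  if (!setequal(names(condition), colnames(m)))
    stop("condition must cover every library column")
  treated <- colnames(m)[condition[colnames(m)] == "treated"]
  control <- colnames(m)[condition[colnames(m)] == "control"]
  anyT <- rowSums(m[, treated, drop = FALSE]) > 0
  anyC <- rowSums(m[, control, drop = FALSE]) > 0
  diff <- (anyT & !anyC) | (anyC & !anyT)
  list(ids = rownames(m)[diff], n = sum(diff))
}

#' Synthetic similarity hits from exact shared substrings
#'
#' A deliberately naive stand-in for an external similarity search, used
#' by fixtures and tests: for every ordered pair of pooled sequences
#' (including self-pairs) sharing at least one exact substring of length
#' >= \code{minSharedKmerLen}, emits a hit with e-value 1e-30. Quadratic
#' in the number of sequences; intended only for small test sets.
#'
#' @param ls A [LibrarySet-class].
#' @param minSharedKmerLen Minimum exact shared substring length.
#' @return BLAST-tabular-shaped \code{data.frame} of hits with
#'   library-qualified ids.
#' @export
naiveSimilarityHits <- function(ls, minSharedKmerLen) {
  stopifnot(is(ls, "LibrarySet"), minSharedKmerLen >= 1)
  ids <- .pooledIds(ls)
  seqs <- unlist(lapply(ls@libraries, as.character), use.names = FALSE)
  L <- minSharedKmerLen
  subs <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < L) character(0)
    else unique(substring(s, 1:(n - L + 1), L:n))
  })
  qs <- character(0); ss <- character(0)
  for (i in seq_along(ids)) {
    if (length(subs[[i]]) == 0) next
    for (j in seq_along(ids)) {
      if (nchar(seqs[[j]]) < L) next
      shared <- if (i == j) TRUE
                else any(vapply(subs[[i]], function(p)
                  grepl(p, seqs[[j]], fixed = TRUE), logical(1)))
      if (shared) { qs <- c(qs, ids[i]); ss <- c(ss, ids[j]) }
    }
  }
  n <- length(qs)
  data.frame(qseqid = qs, sseqid = ss,
             pident = rep(100, n), length = rep(L, n),
             mismatch = rep(0, n), gapopen = rep(0, n),
             qstart = rep(1, n), qend = rep(L, n),
             sstart = rep(1, n), send = rep(L, n),
             evalue = rep(1e-30, n), bitscore = rep(200, n),
             stringsAsFactors = FALSE)
}
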