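#' Pipeline configuration
#'
#' Thresholds and layout for the prediction cascade. The e-value
#' thresholds default to 1e-10 for the coding filter and 1e-12 for
#' lncRNA annotation (the latter matching the similarity threshold of the
#' differential-expression procedure); both are deliberately exposed here
#' rather than hard-coded.
#'
#' @param minLength Minimum transcript length in nt (default 200; kept
#'   when length >= minLength).
#' @param codingEvalueMax A transcript with any coding-database hit at
#'   e-value <= this is called protein-coding and removed.
#' @param lncEvalueMax A transcript with any lncRNA-database hit at
#'   e-value <= this is annotated as lncRNA.
#' @param layout Stage ordering: \code{"generic"} and \code{"sugarcane"}
#'   apply coding filter, then length, then intergenic;
#'   \code{"maize"} (where upstream read mapping and consensus assembly
#'   have already produced the input transcripts) enters at the length
#'   filter, then coding, then intergenic. The filters commute, so the
#'   layouts differ only in stage ordering of the report.
#' @param minGeneDistance Minimum distance in bp between an alignment and
#'   the nearest gene body for the transcript to count as intergenic
#'   (default 0: any non-overlap qualifies).
#' @return A validated list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(minLength = 200L, codingEvalueMax = 1e-10,
                           lncEvalueMax = 1e-12,
                           layout = c("generic", "sugarcane", "maize"),
                           minGeneDistance = 0L) {
  layout <- match.arg(layout)
  stopifnot(minLength >= 1, codingEvalueMax > 0, lncEvalueMax > 0,
            minGeneDistance >= 0)
  structure(list(minLength = as.integer(minLength),
                 codingEvalueMax = codingEvalueMax,
                 lncEvalueMax = lncEvalueMax, layout = layout,
                 minGeneDistance = as.integer(minGeneDistance)),
            class = "pipelineConfig")
}

.hitIds <- function(transcripts, hits, evalueMax, what) {
  unknown <- setdiff(unique(hits$qseqid), names(transcripts))
  if (length(unknown))
    warning(length(unknown), " ", what,
            " hit query id(s) not among the transcripts (ignored): ",
            paste(head(unknown, 5), collapse = ", "))
  unique(hits$qseqid[hits$evalue <= evalueMax &
                       hits$qseqid %in% names(transcripts)])
}

#' Remove transcripts with protein-coding similarity
#'
#' A transcript is removed iff it has at least one hit against the
#' protein-coding database with e-value <= \code{evalueMax} (inclusive).
#' Order is preserved. Hits whose query id matches no transcript are
#' ignored with a warning.
#'
#' @param transcripts A named \code{DNAStringSet}.
#' @param hits BLAST hit table (see [readBlastTab()]) against a
#'   PCT/protein database.
#' @param evalueMax Inclusive e-value threshold.
#' @return The surviving \code{DNAStringSet}.
#' @export
filterCoding <- function(transcripts, hits, evalueMax = 1e-10) {
  coding <- .hitIds(transcripts, hits, evalueMax, "coding")
  transcripts[!names(transcripts) %in% coding]
}

#' Keep transcripts of at least a minimum length
#'
#' lncRNAs are by definition longer than 200 nt, so the cascade keeps
#' transcripts with length greater than or equal to the threshold.
#'
#' @param transcripts A \code{DNAStringSet}.
#' @param minLength Minimum length in nt (inclusive; default 200).
#' @return The surviving \code{DNAStringSet}, order preserved.
#' @export
filterLength <- function(transcripts, minLength = 200L) {
  transcripts[Biostrings::width(transcripts) >= minLength]
}

#' Keep transcripts whose genome alignments are all intergenic
#'
#' A transcript survives iff it has at least one genome alignment AND
#' none of its alignments overlaps any annotated gene body by >= 1 bp
#' (strand-agnostic). Unmapped transcripts are dropped; alignments naming
#' unknown transcripts are ignored with a warning. An alignment merely
#' touching a gene boundary (zero shared bases) is intergenic.
#'
#' @param transcripts A named \code{DNAStringSet}.
#' @param alignments \code{GRanges} of transcript-to-genome alignments
#'   with transcript ids in the \code{name} metadata column (see
#'   [readBedIntervals()]); a transcript may have several alignments.
#' @param genes \code{GRanges} of gene bodies (see [readGffGenes()]).
#' @param minGeneDistance Required minimum distance in bp to the nearest
#'   gene (default 0: adjacency allowed).
#' @return The surviving \code{DNAStringSet}, order preserved.
#' @export
filterIntergenic <- function(transcripts, alignments, genes,
                             minGeneDistance = 0L) {
  alnNames <- alignments$name
  if (is.null(alnNames)) stop("alignments must carry a name column")
  unknown <- setdiff(unique(alnNames), names(transcripts))
  if (length(unknown)) {
    warning(length(unknown),
            " alignment(s) reference unknown transcript ids (ignored): ",
            paste(head(unknown, 5), collapse = ", "))
    keepAln <- alnNames %in% names(transcripts)
    alignments <- alignments[keepAln]
    alnNames <- alnNames[keepAln]
  }
  if (length(genes) > 0 && length(alignments) > 0) {
    ov <- GenomicRanges::findOverlaps(
      alignments, genes, ignore.strand = TRUE,
      maxgap = if (minGeneDistance > 0) minGeneDistance - 1L else -1L)
    genic <- unique(alnNames[S4Vectors::queryHits(ov)])
  } else {
    genic <- character(0)
  }
  mapped <- unique(alnNames)
  keep <- setdiff(mapped, genic)
  transcripts[names(transcripts) %in% keep]
}

#' Transcripts annotated as lncRNA by database similarity
#'
#' @param transcripts A named \code{DNAStringSet}.
#' @param hits BLAST hit table against a lncRNA database.
#' @param evalueMax Inclusive e-value threshold (default 1e-12).
#' @return Character vector of annotated transcript ids (any-hit rule).
#' @export
annotateLnc <- function(transcripts, hits, evalueMax = 1e-12) {
  .hitIds(transcripts, hits, evalueMax, "lncRNA-annotation")
}

#' Intersect SVM-positive and lncRNA-annotated calls
#'
#' The workflow's final output: transcripts that appear in both the
#' SVM-positive set and the lncRNA-annotation set.
#'
#' @param svmPositive Character vector of SVM-positive ids.
#' @param lncAnnotated Character vector of annotation-positive ids.
#' @return Their exact intersection.
#' @export
intersectCalls <- function(svmPositive, lncAnnotated) {
  intersect(svmPositive, lncAnnotated)
}

#' Run the full lincRNA prediction cascade
#'
#' Applies, in the order set by \code{config$layout}, the coding-removal
#' filter, the minimum-length filter and the intergenic filter; then, on
#' the survivors, SVM prediction and lncRNA-database annotation in
#' parallel; the final calls are their intersection. Any stage collapsing
#' to zero survivors yields an empty final set with a warning, not an
#' error.
#'
#' @param transcripts Named \code{DNAStringSet} of input transcripts.
#' @param codingHits BLAST hit table vs a protein-coding database.
#' @param lncHits BLAST hit table vs a lncRNA database.
#' @param alignments \code{GRanges} of transcript-to-genome alignments
#'   (name column = transcript id).
#' @param genes \code{GRanges} of gene bodies.
#' @param model A [LincModel-class] (or a path to one saved with
#'   [saveModel()]).
#' @param config A [pipelineConfig()].
#' @return A [StageReport-class] with per-stage counts and the final id
#'   set.
#' @export
runPipeline <- function(transcripts, codingHits, lncHits, alignments,
                        genes, model, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.character(model)) model <- loadModel(model)
  stopifnot(is(model, "LincModel"))

  # validate references against the full input once; later stages then see
  # only ids that were known at entry, so removals do not re-trigger warnings
  codingHits <- codingHits[codingHits$qseqid %in%
    .hitIds(transcripts, codingHits, Inf, "coding"), , drop = FALSE]
  lncHits <- lncHits[lncHits$qseqid %in%
    .hitIds(transcripts, lncHits, Inf, "lncRNA-annotation"), , drop = FALSE]
  alnKnown <- alignments$name %in% names(transcripts)
  if (any(!alnKnown))
    warning(sum(!alnKnown),
            " alignment(s) reference unknown transcript ids (ignored): ",
            paste(head(unique(alignments$name[!alnKnown]), 5),
                  collapse = ", "))
  alignments <- alignments[alnKnown]

  stageDefs <- list(
    coding_filter = function(ts)
      filterCoding(ts, codingHits[codingHits$qseqid %in% names(ts), ,
                                  drop = FALSE],
                   config$codingEvalueMax),
    length_filter = function(ts) filterLength(ts, config$minLength),
    intergenic_filter = function(ts)
      filterIntergenic(ts, alignments[alignments$name %in% names(ts)],
                       genes, config$minGeneDistance))
  order <- switch(config$layout,
    generic = ,
    sugarcane = c("coding_filter", "length_filter", "intergenic_filter"),
    maize = c("length_filter", "coding_filter", "intergenic_filter"))

  stages <- data.frame(stage = character(), input = integer(),
                       output = integer(), stringsAsFactors = FALSE)
  current <- transcripts
  for (s in order) {
    nin <- length(current)
    current <- stageDefs[[s]](current)
    stages <- rbind(stages, data.frame(stage = s, input = nin,
                                       output = length(current)))
    if (length(current) == 0)
      warning("stage '", s, "' left no survivors")
  }

  nSurv <- length(current)
  labels <- predict(model, current)
  svmPositive <- names(labels)[labels == POS_LABEL]
  lncAnnotated <- annotateLnc(current,
                              lncHits[lncHits$qseqid %in% names(current), ,
                                      drop = FALSE],
                              config$lncEvalueMax)
  final <- intersectCalls(svmPositive, lncAnnotated)
  stages <- rbind(stages,
    data.frame(stage = "svm_predict", input = nSurv,
               output = length(svmPositive)),
    data.frame(stage = "lnc_annotate", input = nSurv,
               output = length(lncAnnotated)),
    data.frame(stage = "intersection",
               input = min(length(svmPositive), length(lncAnnotated)),
               output = length(final)))
  if (length(final) == 0 && nSurv > 0)
    warning("no transcript is both SVM-positive and lncRNA-annotated")

  new("StageReport", stages = stages, finalIds = final)
}
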