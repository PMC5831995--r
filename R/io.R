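#' Read transcript sequences from a FASTA file
#'
#' Reads a (wrapped or single-line) FASTA file into a \code{DNAStringSet}.
#' The id of each transcript is the header token before the first
#' whitespace; sequences are uppercase-normalized. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 some description", "ac", "gt", ">t2", "AAA"), fa)
#' readTranscripts(fa)
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  empty <- ids[Biostrings::width(x) == 0]
  if (length(empty))
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  names(x) <- ids
  # readDNAStringSet already maps lowercase bases to uppercase
  x
}

#' Write transcripts to a FASTA file
#'
#' @param x A named \code{DNAStringSet}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeTranscripts <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the standard 12-column whitespace/tab-delimited dialect
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore). Comment lines starting with \code{#}
#' are skipped; extra columns are tolerated and ignored. Rows with fewer
#' than 12 columns or unparseable numeric fields raise an error naming the
#' line.
#'
#' @param path Path to a BLAST tabular file.
#' @return \code{data.frame} with the 12 standard columns.
#' @export
readBlastTab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0) {
    out <- c(list(qseqid = character(), sseqid = character()),
             stats::setNames(rep(list(numeric()), 10), BLAST_COLUMNS[3:12]))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  short <- lengths(fields) < 12
  if (any(short))
    stop("BLAST tabular row with fewer than 12 columns at line ",
         lineno[which(short)[1]], " of ", path)
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    stringsAsFactors = FALSE)
  numcols <- 3:12
  for (j in numcols) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) & m[, j] != "NA")
    if (length(bad))
      stop("unparseable numeric field '", m[bad[1], j], "' (column ",
           BLAST_COLUMNS[j], ") at line ", lineno[bad[1]], " of ", path)
    out[[BLAST_COLUMNS[j]]] <- v
  }
  if (any(out$evalue < 0))
    stop("negative e-value in ", path)
  out
}

#' Write a hit table in BLAST tabular (outfmt 6) format
#'
#' @param hits \code{data.frame} with at least the 12 standard columns
#'   (as returned by [readBlastTab()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeBlastTab <- function(hits, path) {
  stopifnot(all(BLAST_COLUMNS %in% names(hits)))
  df <- hits[, BLAST_COLUMNS, drop = FALSE]
  for (j in 3:12) df[[j]] <- vapply(df[[j]], format, character(1), digits = 15)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein-coding gene bodies from a GFF3 annotation
#'
#' Imports records of feature type \code{"gene"} as a \code{GRanges}
#' (1-based closed coordinates, as in GFF3). When a biotype attribute
#' (\code{biotype}, \code{gene_biotype} or \code{gene_type}) is present
#' and some gene carries \code{"protein_coding"}, only protein-coding
#' genes are kept; otherwise all gene records are used. A gene id is taken
#' from \code{ID}, \code{Name} or \code{gene_id}, in that order.
#'
#' @param path Path to a GFF3 file.
#' @return \code{GRanges} of gene bodies with a \code{name} metadata
#'   column. Warns when the file has no gene records.
#' @export
readGffGenes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(genes) == 0) {
    warning("no gene records in ", path)
    out <- GenomicRanges::GRanges()
    out$name <- character(0)
    return(out)
  }
  mc <- S4Vectors::mcols(genes)
  biocol <- intersect(c("biotype", "gene_biotype", "gene_type"), names(mc))
  if (length(biocol)) {
    bt <- as.character(mc[[biocol[1]]])
    if (any(bt == "protein_coding", na.rm = TRUE))
      genes <- genes[!is.na(bt) & bt == "protein_coding"]
  }
  mc <- S4Vectors::mcols(genes)
  idcol <- intersect(c("ID", "Name", "gene_id"), names(mc))
  nm <- if (length(idcol)) as.character(mc[[idcol[1]]])
        else paste0("gene", seq_along(genes))
  out <- GenomicRanges::granges(genes)
  out$name <- nm
  out
}

#' Read transcript-to-genome alignments from a BED file
#'
#' Reads BED4+ rows (0-based half-open, converted to the 1-based closed
#' \code{GRanges} convention on import). Column 4 must hold the transcript
#' id; column 6 (strand) is optional and defaults to \code{"*"}. Rows with
#' \code{start >= end} and files with fewer than 4 columns are rejected.
#'
#' @param path Path to a BED file.
#' @return \code{GRanges} with a \code{name} metadata column.
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track|browser)", lines)
  fields <- strsplit(lines[keep], "\t")
  if (length(fields)) {
    ncol <- lengths(fields)
    if (any(ncol < 4))
      stop("BED row with fewer than 4 columns at line ",
           which(keep)[which(ncol < 4)[1]], " of ", path,
           "; 4-column input (chrom, start, end, name) is required")
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
    if (any(is.na(s)) || any(is.na(e)))
      stop("non-numeric BED coordinates in ", path)
    bad <- which(s >= e)
    if (length(bad))
      stop("empty or inverted BED interval (start >= end) at line ",
           which(keep)[bad[1]], " of ", path)
  }
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop("BED name column (column 4) required in ", path)
  gr
}

#' Save a trained model to disk
#'
#' Writes a self-describing single-file archive embedding the selected
#' pattern list, scaling parameters, kernel parameters and a format
#' version tag, so that predict-time feature extraction cannot diverge
#' from train-time.
#'
#' @param model A \code{LincModel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "LincModel"))
  validObject(model)
  payload <- list(format = MODEL_FORMAT_VERSION, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a trained model from disk
#'
#' Counterpart of [saveModel()]. A loaded model reproduces identical
#' predictions on any feature matrix. Version mismatches, truncated files
#' and archives missing required components raise errors rather than
#' returning a default model.
#'
#' @param path Path to a model archive written by [saveModel()].
#' @return A \code{LincModel}.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model archive ", path, ": ", conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$format))
    stop("not a model archive: ", path)
  if (!identical(payload$format, MODEL_FORMAT_VERSION))
    stop("model format version mismatch in ", path, ": found '",
         payload$format, "', expected '", MODEL_FORMAT_VERSION, "'")
  model <- payload$model
  if (!is(model, "LincModel"))
    stop("model archive ", path, " does not contain a LincModel")
  validObject(model)
  model
}
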