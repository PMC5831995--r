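#' Configuration for the labeled-transcript generator
#'
#' The generator emulates the statistical structure the discriminator's
#' features assume: negatives (PCT-like) carry a long sampled-codon ORF
#' of at least \code{pctOrfMinAa} residues covering at least 60\% of the
#' transcript; positives (lincRNA-like) are uniform-background sequences
#' with class-specific nucleotide-pattern enrichments and a longest ORF
#' of at most \code{lincOrfMaxAa} residues, i.e. the two classes sit on
#' opposite sides of the 100-amino-acid lincRNA landmark.
#'
#' Patterns are planted by seeded motif insertion. A multiplier m for a
#' width-k pattern inserts approximately \code{(m-1) * windows / 4^k}
#' occurrences, raising the pattern's expected frequency by the factor m.
#' The default planted set is ten tetramers (multiplier 3.5 each) chosen
#' so that their twenty sub-trimers are pairwise distinct, every one of
#' the sixteen dimers appears in the motif content (1-2 sub-dimer slots
#' each), and motif letters and boundary letters are balanced. Under
#' those constraints a sub- or super-pattern of an inserted motif
#' receives at most about half the planted pattern's standardized shift,
#' and -- because motif content is compositionally background-like -- no
#' unplanted pattern is systematically crowded out. Short planted motifs
#' are deliberately avoided: inserting enough copies of a dimer to shift
#' its frequency would crowd out background occurrences of every other
#' pattern, making unplanted dimers spuriously discriminative.
#'
#' @param seed Integer seed; all outputs are pure functions of the
#'   config including the seed.
#' @param nPos,nNeg Class sizes.
#' @param lengthRange Transcript length range in nt (min, max); the
#'   maximum must accommodate the minimum PCT ORF.
#' @param plantedPatterns Named numeric vector: pattern -> positive-class
#'   frequency multiplier (> 0).
#' @param pctOrfMinAa Minimum ORF residues of a negative (default 100).
#' @param lincOrfMaxAa Maximum longest-ORF residues of a positive
#'   (default 99).
#' @param enforceLincCeiling When \code{FALSE}, positives skip the ORF
#'   ceiling (emulating a looser lncRNA positive set, as used when no
#'   lincRNA-labeled training data exist).
#' @param classMode \code{"orf"} (default): negatives carry the long
#'   codon-structured ORF and positives the ORF ceiling, so the classes
#'   differ in coding structure as well as planted composition -- the
#'   regime the classifier is trained in. \code{"composition"}: both
#'   classes are the same uniform background and differ \emph{only} in
#'   the planted pattern insertions -- the regime in which
#'   planted-pattern recovery by [selectPatterns()] is well-posed,
#'   because coding structure would otherwise add real class signal
#'   beyond the planted truth.
#' @return A validated list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(seed, nPos, nNeg, lengthRange = c(200L, 600L),
                            plantedPatterns = c(
                              AATT = 3.5, ATAA = 3.5, CACT = 3.5,
                              CGTG = 3.5, CTGC = 3.5, GAGG = 3.5,
                              CGCC = 3.5, GTCC = 3.5, TAGA = 3.5,
                              TTCA = 3.5),
                            pctOrfMinAa = 100L, lincOrfMaxAa = 99L,
                            enforceLincCeiling = TRUE,
                            classMode = c("orf", "composition")) {
  classMode <- match.arg(classMode)
  stopifnot(length(lengthRange) == 2, lengthRange[1] >= 1,
            lengthRange[1] <= lengthRange[2],
            nPos >= 0, nNeg >= 0, all(plantedPatterns > 0))
  if (length(plantedPatterns)) .validatePatterns(names(plantedPatterns))
  if (enforceLincCeiling && pctOrfMinAa <= lincOrfMaxAa)
    stop("pctOrfMinAa must exceed lincOrfMaxAa (class boundary)")
  if (3 * (pctOrfMinAa + 1) > lengthRange[2])
    stop("lengthRange[2] too short for a ", pctOrfMinAa,
         "-residue ORF (needs >= ", 3 * (pctOrfMinAa + 1), " nt)")
  structure(list(seed = as.integer(seed), nPos = as.integer(nPos),
                 nNeg = as.integer(nNeg),
                 lengthRange = as.integer(lengthRange),
                 plantedPatterns = plantedPatterns,
                 pctOrfMinAa = as.integer(pctOrfMinAa),
                 lincOrfMaxAa = as.integer(lincOrfMaxAa),
                 enforceLincCeiling = enforceLincCeiling,
                 classMode = classMode),
            class = "generatorConfig")
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0)),
  c("TAA", "TAG", "TGA"))

.randomSeq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# sample one integer uniformly from lo:hi (safe when lo == hi)
.sampleBetween <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

.plantMotifs <- function(s, planted) {
  len <- nchar(s)
  # widest motifs first, so later short insertions rarely destroy them
  planted <- planted[order(-nchar(names(planted)))]
  for (p in names(planted)) {
    k <- nchar(p)
    nWin <- len - k + 1L
    if (nWin < 1) next
    c0 <- (planted[[p]] - 1) * nWin / 4^k
    nIns <- floor(c0) + (runif(1) < c0 - floor(c0))
    if (nIns < 1) next
    pos <- sample.int(nWin, min(nIns, nWin))
    for (q in pos) substr(s, q, q + k - 1L) <- p
  }
  s
}

.capOrf <- function(s, maxAa) {
  for (iter in 1:500) {
    o <- findLongestOrf(s)
    if (is.null(o) || o$aaLength <= maxAa) return(s)
    # knock out the ORF with an in-frame stop near its middle
    codonOffset <- max(1L, o$aaLength %/% 2L)
    at <- o$start + 3L * codonOffset + 1L   # 1-based
    substr(s, at, at + 2L) <- sample(STOP_CODONS, 1)
  }
  stop("failed to cap ORF length")  # unreachable for sane inputs
}

#' Generate a labeled synthetic training set
#'
#' Produces lincRNA-like positives and PCT-like negatives per the
#' generator config (see [generatorConfig()]), plus a truth manifest.
#' Negatives are a uniformly sampled sense-codon ORF (ATG ... stop, at
#' least \code{pctOrfMinAa} residues) flanked by uniform UTR-like
#' sequence with ORF proportion >= 0.6; positives are uniform background
#' with planted pattern insertions, post-edited with in-frame stops so
#' the longest ORF stays at or below \code{lincOrfMaxAa} residues. The
#' class-boundary guarantee (every negative at or above
#' \code{pctOrfMinAa} residues, every positive at or below the ceiling)
#' is asserted on the generated batch.
#'
#' @param cfg A [generatorConfig()].
#' @return List with \code{pos} and \code{neg} (\code{DNAStringSet}) and
#'   \code{truth} (\code{data.frame}: id, class, length, orf_aa).
#' @export
simulateLabeledTranscripts <- function(cfg) {
  stopifnot(inherits(cfg, "generatorConfig"))
  set.seed(cfg$seed)
  minL <- cfg$lengthRange[1]; maxL <- cfg$lengthRange[2]

  composition <- identical(cfg$classMode, "composition")
  neg <- character(cfg$nNeg)
  if (composition) {
    for (i in seq_len(cfg$nNeg))
      neg[i] <- .randomSeq(.sampleBetween(minL, maxL))
  } else for (i in seq_len(cfg$nNeg)) {
    aaMax <- maxL %/% 3L - 1L
    aa <- .sampleBetween(cfg$pctOrfMinAa, aaMax)
    orf <- paste0("ATG",
                  paste(sample(SENSE_CODONS, aa - 1L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1))
    orfNt <- nchar(orf)                      # 3 * (aa + 1)
    total <- .sampleBetween(max(orfNt, minL),
                            max(orfNt, min(maxL, floor(orfNt / 0.6))))
    pre <- .sampleBetween(0L, total - orfNt)
    neg[i] <- paste0(.randomSeq(pre), orf,
                     .randomSeq(total - orfNt - pre))
  }

  pos <- character(cfg$nPos)
  for (i in seq_len(cfg$nPos)) {
    s <- .plantMotifs(.randomSeq(.sampleBetween(minL, maxL)),
                      cfg$plantedPatterns)
    if (!composition && cfg$enforceLincCeiling)
      s <- .capOrf(s, cfg$lincOrfMaxAa)
    pos[i] <- s
  }

  posSet <- Biostrings::DNAStringSet(pos)
  names(posSet) <- sprintf("linc%04d", seq_len(cfg$nPos))
  negSet <- Biostrings::DNAStringSet(neg)
  names(negSet) <- sprintf("pct%04d", seq_len(cfg$nNeg))

  orfP <- orfFeatures(posSet); orfN <- orfFeatures(negSet)
  if (!composition) {
    if (cfg$enforceLincCeiling && any(orfP$aa_length > cfg$lincOrfMaxAa))
      stop("internal error: positive violates the ORF ceiling")
    if (any(orfN$aa_length < cfg$pctOrfMinAa))
      stop("internal error: negative violates the ORF floor")
  }

  truth <- data.frame(
    id = c(names(posSet), names(negSet)),
    class = rep(c("lincRNA_like", "PCT_like"), c(cfg$nPos, cfg$nNeg)),
    length = c(Biostrings::width(posSet), Biostrings::width(negSet)),
    orf_aa = c(orfP$aa_length, orfN$aa_length),
    stringsAsFactors = FALSE)
  list(pos = posSet, neg = negSet, truth = truth)
}

#' Generate a toy genome with genes and placed transcripts
#'
#' Places \code{nGenes} non-overlapping genes on a single chromosome
#' separated by intergenic gaps, then assigns each of
#' \code{nTranscripts} transcripts a genomic placement either overlapping
#' a gene body (genic) or strictly within a gap (intergenic), with
#' exactly \code{round(genicFraction * nTranscripts)} genic placements.
#' Transcript sequences are the corresponding genome substrings.
#'
#' @param seed Integer seed.
#' @param nGenes Number of genes.
#' @param nTranscripts Number of transcripts.
#' @param genicFraction Fraction of transcripts placed genic, in [0, 1].
#' @param geneLength Gene body length in bp.
#' @param txLength Transcript (and alignment) length in bp.
#' @return List: \code{genome} (\code{DNAStringSet}), \code{genes} and
#'   \code{alignments} (\code{GRanges}, each with a \code{name} column),
#'   \code{transcripts} (\code{DNAStringSet}) and \code{truth}
#'   (\code{data.frame}: id, placement).
#' @export
simulateToyGenome <- function(seed, nGenes = 8L, nTranscripts = 50L,
                              genicFraction = 0.3, geneLength = 400L,
                              txLength = 250L) {
  stopifnot(genicFraction >= 0, genicFraction <= 1, nGenes >= 1,
            txLength >= 1, geneLength >= 1)
  set.seed(seed)
  gap <- 3L * txLength
  geneStarts <- gap + (seq_len(nGenes) - 1L) * (geneLength + gap) + 1L
  geneEnds <- geneStarts + geneLength - 1L
  chromLen <- geneEnds[nGenes] + gap
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(geneStarts, geneEnds), strand = "+")
  genes$name <- sprintf("g%02d", seq_len(nGenes))

  nGenic <- round(genicFraction * nTranscripts)
  placement <- rep(c("genic", "intergenic"),
                   c(nGenic, nTranscripts - nGenic))
  starts <- integer(nTranscripts)
  for (i in seq_len(nTranscripts)) {
    if (placement[i] == "genic") {
      g <- sample.int(nGenes, 1)
      # overlap the gene body by at least 1 bp
      lo <- max(1L, geneStarts[g] - txLength + 1L)
      starts[i] <- .sampleBetween(lo, geneEnds[g])
    } else {
      # strictly inside a gap: no gene-body overlap
      g <- sample.int(nGenes + 1L, 1)
      gapStart <- if (g == 1L) 1L else geneEnds[g - 1L] + 1L
      gapEnd <- if (g > nGenes) chromLen else geneStarts[g] - 1L
      starts[i] <- .sampleBetween(gapStart, gapEnd - txLength + 1L)
    }
  }
  genomeSeq <- .randomSeq(chromLen)
  genome <- Biostrings::DNAStringSet(genomeSeq)
  names(genome) <- "chr1"
  ids <- sprintf("tx%04d", seq_len(nTranscripts))
  aln <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, width = txLength), strand = "+")
  aln$name <- ids
  tx <- Biostrings::DNAStringSet(
    substring(genomeSeq, starts, starts + txLength - 1L))
  names(tx) <- ids
  list(genome = genome, genes = genes, alignments = aln, transcripts = tx,
       truth = data.frame(id = ids, placement = placement,
                          stringsAsFactors = FALSE))
}

#' Write a gene annotation as GFF3
#'
#' @param genes \code{GRanges} with a \code{name} metadata column.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotation <- function(genes, path) {
  lines <- c("##gff-version 3",
    sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=protein_coding",
            as.character(GenomicRanges::seqnames(genes)),
            GenomicRanges::start(genes), GenomicRanges::end(genes),
            as.character(GenomicRanges::strand(genes)), genes$name))
  writeLines(lines, path)
  invisible(path)
}

#' Build a synthetic BLAST-tabular hit table
#'
#' Expands (query, subject, evalue) triples into a full 12-column hit
#' table with plausible filler columns; written files round-trip through
#' [readBlastTab()] exactly.
#'
#' @param pairs \code{data.frame} with columns \code{qseqid},
#'   \code{sseqid}, \code{evalue} (> 0, or 0 for maximal significance).
#' @param path Optional output path; when given the table is also
#'   written in outfmt-6 format.
#' @return The hit table \code{data.frame}.
#' @export
simulateHitTable <- function(pairs, path = NULL) {
  stopifnot(all(c("qseqid", "sseqid", "evalue") %in% names(pairs)),
            all(pairs$evalue >= 0))
  n <- nrow(pairs)
  hits <- data.frame(qseqid = as.character(pairs$qseqid),
                     sseqid = as.character(pairs$sseqid),
                     pident = rep(98, n), length = rep(120, n),
                     mismatch = rep(2, n), gapopen = rep(0, n),
                     qstart = rep(1, n), qend = rep(120, n),
                     sstart = rep(1, n), send = rep(120, n),
                     evalue = pairs$evalue, bitscore = rep(180, n),
                     stringsAsFactors = FALSE)
  if (!is.null(path)) writeBlastTab(hits, path)
  hits
}

#' Construct an end-to-end cascade fixture with forced stage counts
#'
#' Builds a transcript set partitioned into disjoint categories --
#' coding-hit, too-short, genic, and clean survivors with prescribed
#' SVM-positive / lncRNA-annotated / overlap counts -- so that every
#' stage count of [runPipeline()] is known by construction. The SVM
#' labels are forced by drawing clean survivors from a pool of labeled
#' generator output and keeping only candidates the model labels as
#' intended; an error is raised when the model agrees with the generator
#' too rarely to fill the requested counts.
#'
#' @param model A [LincModel-class] trained on [simulateLabeledTranscripts()]
#'   output.
#' @param seed Integer seed.
#' @param nCoding,nShort,nGenic Category sizes.
#' @param nSvmPos Clean survivors intended lincRNA-like.
#' @param nSvmNeg Clean survivors intended PCT-like.
#' @param nLncAnnotated Clean survivors given a lncRNA-database hit.
#' @param nOverlap How many of the lncRNA-annotated are also SVM-positive
#'   (the forced final count); requires \code{nOverlap <= min(nSvmPos,
#'   nLncAnnotated)} and \code{nLncAnnotated - nOverlap <= nSvmNeg}.
#' @return List with pipeline inputs (\code{transcripts},
#'   \code{codingHits}, \code{lncHits}, \code{alignments}, \code{genes})
#'   and \code{expected} counts per stage.
#' @export
simulateCascadeFixture <- function(model, seed, nCoding = 40L, nShort = 10L,
                                   nGenic = 20L, nSvmPos = 18L, nSvmNeg = 12L,
                                   nLncAnnotated = 12L, nOverlap = 9L) {
  stopifnot(is(model, "LincModel"),
            nOverlap <= min(nSvmPos, nLncAnnotated),
            nLncAnnotated - nOverlap <= nSvmNeg)
  set.seed(seed)
  nClean <- nSvmPos + nSvmNeg
  seedLinc <- sample.int(1e6, 1); seedPct <- sample.int(1e6, 1)
  # clean survivors are drawn from a candidate pool, keeping only those the
  # model labels as intended, so the SVM stage counts hold by construction
  lincPool <- simulateLabeledTranscripts(
    generatorConfig(seedLinc, nPos = 2L * nSvmPos + nGenic + 20L,
                    nNeg = nCoding))
  pctPool <- simulateLabeledTranscripts(
    generatorConfig(seedPct, nPos = 0, nNeg = 2L * nSvmNeg + 20L))$neg
  pickLabeled <- function(pool, label, n, what) {
    if (n == 0L) return(pool[0])
    lab <- predict(model, pool)
    hit <- which(lab == label)
    if (length(hit) < n)
      stop("cascade fixture construction failed: only ", length(hit),
           " of ", length(pool), " candidates are labeled ", label,
           " by the model; use a model trained on the labeled generator")
    pool[hit[seq_len(n)]]
  }
  cleanPos <- pickLabeled(lincPool$pos, POS_LABEL, nSvmPos, "positive")
  remaining <- lincPool$pos[!names(lincPool$pos) %in% names(cleanPos)]
  genicTx <- remaining[seq_len(nGenic)]
  codingTx <- lincPool$neg
  cleanNeg <- pickLabeled(pctPool, NEG_LABEL, nSvmNeg, "negative")
  shortTx <- Biostrings::DNAStringSet(
    vapply(seq_len(nShort), function(i) .randomSeq(.sampleBetween(100L, 199L)),
           character(1)))

  rename <- function(x, prefix) {
    names(x) <- sprintf("%s%04d", prefix, seq_along(x)); x
  }
  codingTx <- rename(codingTx, "cod")
  shortTx <- rename(shortTx, "sho")
  genicTx <- rename(genicTx, "gen")
  cleanPos <- rename(cleanPos, "clp")
  cleanNeg <- rename(cleanNeg, "cln")
  transcripts <- c(codingTx, shortTx, genicTx, cleanPos, cleanNeg)

  codingHits <- simulateHitTable(data.frame(
    qseqid = names(codingTx),
    sseqid = rep("protDB", length(codingTx)),
    evalue = rep(1e-40, length(codingTx))))
  lncTargets <- c(head(names(cleanPos), nOverlap),
                  head(names(cleanNeg), nLncAnnotated - nOverlap))
  lncHits <- simulateHitTable(data.frame(
    qseqid = lncTargets,
    sseqid = rep("lncDB", length(lncTargets)),
    evalue = rep(1e-30, length(lncTargets))))

  # toy coordinates: genic transcripts overlap a gene, everything else
  # sits in gaps
  nGenes <- max(1L, nGenic)
  nOthers <- nCoding + nShort + nClean
  geneLen <- 400L
  gap <- 400L + 10L * (nOthers %/% nGenes + 1L)
  geneStarts <- gap + (seq_len(nGenes) - 1L) * (geneLen + gap) + 1L
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(geneStarts, width = geneLen), strand = "+")
  genes$name <- sprintf("g%03d", seq_len(nGenes))
  others <- c(names(codingTx), names(shortTx), names(cleanPos),
              names(cleanNeg))
  gapAnchors <- geneStarts[((seq_along(others) - 1L) %% nGenes) + 1L] -
    gap + 50L + 10L * ((seq_along(others) - 1L) %/% nGenes)
  aln <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(geneStarts[seq_len(nGenic)] + 10L, gapAnchors),
    width = 200L), strand = "+")
  aln$name <- c(names(genicTx), others)

  list(transcripts = transcripts, codingHits = codingHits,
       lncHits = lncHits, alignments = aln, genes = genes,
       expected = list(
         input = length(transcripts),
         afterCoding = length(transcripts) - nCoding,
         afterLength = length(transcripts) - nCoding - nShort,
         afterIntergenic = nClean,
         svmPositive = nSvmPos, lncAnnotated = nLncAnnotated,
         final = nOverlap))
}
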