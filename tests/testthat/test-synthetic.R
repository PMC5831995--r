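test_that("generator configs are validated", {
  expect_error(generatorConfig(1, 10, 10, lengthRange = c(200, 250)),
               "too short")
  expect_error(generatorConfig(1, 10, 10, pctOrfMinAa = 50, lincOrfMaxAa = 80),
               "class boundary")
  expect_error(generatorConfig(1, 10, 10,
                               plantedPatterns = c(AAAAA = 2)), "AAAAA")
  expect_error(generatorConfig(1, 10, 10, plantedPatterns = c(AA = -1)))
})

test_that("labeled generation is a pure function of its config", {
  cfg <- generatorConfig(3, nPos = 10, nNeg = 10)
  g1 <- simulateLabeledTranscripts(cfg)
  g2 <- simulateLabeledTranscripts(cfg)
  expect_identical(as.character(g1$pos), as.character(g2$pos))
  expect_identical(as.character(g1$neg), as.character(g2$neg))
  expect_identical(g1$truth, g2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeTranscripts(c(g1$pos, g1$neg), f1)
  writeTranscripts(c(g2$pos, g2$neg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated classes sit on opposite sides of the 100-residue boundary", {
  g <- simulateLabeledTranscripts(generatorConfig(13, 40, 40))
  orfP <- orfFeatures(g$pos)
  orfN <- orfFeatures(g$neg)
  expect_true(all(orfN$aa_length >= 100))
  expect_true(all(orfP$aa_length <= 99))
  expect_true(all(orfN$orf_length / orfN$length >= 0.6))
  expect_equal(g$truth$class, rep(c("lincRNA_like", "PCT_like"), each = 40))
  # relaxed ceiling: positives may exceed the cap
  loose <- simulateLabeledTranscripts(
    generatorConfig(13, 40, 0, enforceLincCeiling = FALSE))
  expect_true(is.numeric(orfFeatures(loose$pos)$aa_length))
})

test_that("planted patterns are enriched in the positive class", {
  cfg <- generatorConfig(3, 300, 300, classMode = "composition")
  g <- simulateLabeledTranscripts(cfg)
  fp <- kmerFrequencies(g$pos, 4)
  fn <- kmerFrequencies(g$neg, 4)
  for (p in names(cfg$plantedPatterns)) {
    w <- stats::wilcox.test(fp[, p], fn[, p], alternative = "greater")
    expect_lt(w$p.value, 1e-6)
  }
})

test_that("toy genomes place transcripts exactly as the manifest says", {
  all0 <- simulateToyGenome(5, genicFraction = 0)
  kept <- filterIntergenic(all0$transcripts, all0$alignments, all0$genes)
  expect_equal(length(kept), length(all0$transcripts))

  all1 <- simulateToyGenome(5, genicFraction = 1)
  expect_length(filterIntergenic(all1$transcripts, all1$alignments,
                                 all1$genes), 0)

  mix <- simulateToyGenome(5, nTranscripts = 200, genicFraction = 0.35)
  kept <- filterIntergenic(mix$transcripts, mix$alignments, mix$genes)
  wantKept <- mix$truth$id[mix$truth$placement == "intergenic"]
  expect_setequal(names(kept), wantKept)
  expect_equal(sum(mix$truth$placement == "genic"), round(0.35 * 200))
})

test_that("toy genome files survive the annotation and alignment round-trips", {
  toy <- simulateToyGenome(8, nTranscripts = 20, genicFraction = 0.5)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeGeneAnnotation(toy$genes, gff)
  genes2 <- readGffGenes(gff)
  expect_equal(start(genes2), start(toy$genes))
  expect_equal(end(genes2), end(toy$genes))
  expect_equal(genes2$name, toy$genes$name)

  bed <- withr::local_tempfile(fileext = ".bed")
  rtracklayer::export(toy$alignments, bed, format = "bed")
  aln2 <- readBedIntervals(bed)
  expect_equal(start(aln2), start(toy$alignments))
  expect_equal(end(aln2), end(toy$alignments))
  expect_equal(aln2$name, toy$alignments$name)

  fa <- withr::local_tempfile(fileext = ".fa")
  writeTranscripts(toy$transcripts, fa)
  expect_identical(as.character(readTranscripts(fa)),
                   as.character(toy$transcripts))
})

test_that("synthetic hit tables round-trip through the tabular format", {
  pairs <- data.frame(qseqid = c("a", "b", "c"),
                      sseqid = c("x", "y", "z"),
                      evalue = c(1e-12, 0, 3.5e-40))
  f <- withr::local_tempfile(fileext = ".tsv")
  simulateHitTable(pairs, f)
  h <- readBlastTab(f)
  expect_equal(h$qseqid, pairs$qseqid)
  expect_equal(h$sseqid, pairs$sseqid)
  expect_identical(h$evalue, pairs$evalue)  # 1e-12 survives exactly

  empty <- simulateHitTable(pairs[0, ], f)
  expect_equal(nrow(readBlastTab(f)), 0L)
})

test_that("the cascade fixture rejects a model that cannot force its labels", {
  g <- simulateLabeledTranscripts(generatorConfig(19, 60, 60))
  pats <- patternPreset("sugarcane")
  cfg <- trainConfig(gridC = 1, gridGamma = 0.1, folds = 3, seed = 19)
  # deliberately swap the classes so the model mislabels the generator output
  swapped <- trainLincModel(buildFeatureMatrix(g$neg, pats),
                            buildFeatureMatrix(g$pos, pats), cfg)
  expect_error(simulateCascadeFixture(swapped, seed = 2), "construction failed")
})
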