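mkLibs <- function(nPer = 2, seqLen = 60, seed = 1) {
  set.seed(seed)
  libs <- lapply(1:4, function(i) {
    x <- Biostrings::DNAStringSet(vapply(seq_len(nPer), function(j)
      randomDna(seqLen), character(1)))
    names(x) <- paste0("tx", seq_len(nPer))
    x
  })
  names(libs) <- c("id9", "id10", "id11", "id12")
  LibrarySet(libs, c(id9 = "control", id10 = "treated",
                     id11 = "control", id12 = "treated"))
}

test_that("the worked example row pattern is present and called differential", {
  ls <- mkLibs()
  # a sequence from library id10 similar to one in id12, no other hits
  hits <- simulateHitTable(data.frame(
    qseqid = "id10:tx1", sseqid = "id12:tx2", evalue = 1e-20))
  pm <- buildPresenceMatrix(ls, hits)
  row <- presence(pm)["id10:tx1", c("id9", "id10", "id11", "id12")]
  expect_equal(unname(row), c(FALSE, TRUE, FALSE, TRUE))
  call <- callDifferential(pm)
  expect_true("id10:tx1" %in% call$ids)
})

test_that("e-value similarity is inclusive at the 1e-12 boundary", {
  ls <- mkLibs()
  mk <- function(ev) buildPresenceMatrix(ls, simulateHitTable(data.frame(
    qseqid = "id10:tx1", sseqid = "id9:tx1", evalue = ev)))
  expect_true(presence(mk(1e-12))["id10:tx1", "id9"])
  expect_false(presence(mk(2e-12))["id10:tx1", "id9"])
})

test_that("with no hits the matrix is the identity pattern and every row differential", {
  ls <- mkLibs()
  pm <- buildPresenceMatrix(ls, simulateHitTable(data.frame(
    qseqid = character(0), sseqid = character(0), evalue = numeric(0))))
  m <- presence(pm)
  expect_equal(sum(m), nrow(m))  # each row present only at home
  call <- callDifferential(pm)
  expect_equal(call$n, nrow(m))  # maximal-count bound
})

test_that("all-present and cross-condition rows are not differential", {
  ls <- mkLibs()
  libs <- libraryIds(ls)
  m <- matrix(FALSE, 3, 4, dimnames = list(
    c("id9:tx1", "id10:tx1", "id10:tx2"), libs))
  m["id9:tx1", ] <- TRUE                          # everywhere
  m["id10:tx1", c("id10", "id9")] <- TRUE         # one treated, one control
  m["id10:tx2", c("id10", "id12")] <- TRUE        # treated only
  pm <- makePresence(m, c("id9", "id10", "id10"),
                     c(id9 = "control", id10 = "treated",
                       id11 = "control", id12 = "treated"))
  call <- callDifferential(pm)
  expect_identical(call$ids, "id10:tx2")
})

test_that("differential calls are invariant to column order and label swap", {
  set.seed(31)
  cond <- c(id9 = "control", id10 = "treated", id11 = "control",
            id12 = "treated")
  for (i in 1:20) {
    m <- matrix(runif(40) < 0.4, 10, 4,
                dimnames = list(paste0("id9:r", 1:10), names(cond)))
    pm <- makePresence(m, rep("id9", 10), cond)
    base <- callDifferential(pm)
    perm <- sample(4)
    pmPerm <- makePresence(m[, perm], rep("id9", 10), cond)
    expect_equal(callDifferential(pmPerm)$n, base$n)
    swapped <- ifelse(cond == "treated", "control", "treated")
    names(swapped) <- names(cond)
    expect_equal(callDifferential(pm, swapped)$n, base$n)
    # brute-force re-evaluation agrees
    expect_equal(sort(base$ids),
                 sort(rownames(m)[oracleDifferential(presence(pm), cond)]))
  }
})

test_that("cross-condition hits can only remove differential calls", {
  set.seed(55)
  ls <- mkLibs(nPer = 3)
  for (i in 1:10) {
    pool <- paste0(rep(libraryIds(ls), each = 3), ":tx", 1:3)
    pick <- function() sample(pool, sample(2:6, 1), replace = TRUE)
    q <- pick()
    hits <- simulateHitTable(data.frame(
      qseqid = q, sseqid = sample(pool, length(q), replace = TRUE),
      evalue = 1e-20))
    base <- callDifferential(buildPresenceMatrix(ls, hits))$n
    cond <- libraryCondition(ls)
    libOf <- function(x) sub(":.*", "", x)
    treatedPool <- pool[cond[libOf(pool)] == "treated"]
    controlPool <- pool[cond[libOf(pool)] == "control"]
    cross <- simulateHitTable(data.frame(
      qseqid = sample(treatedPool, 1), sseqid = sample(controlPool, 1),
      evalue = 1e-20))
    withCross <- callDifferential(
      buildPresenceMatrix(ls, rbind(hits, cross)))$n
    expect_lte(withCross, base)
    within <- simulateHitTable(data.frame(
      qseqid = sample(treatedPool, 1), sseqid = sample(treatedPool, 1),
      evalue = 1e-20))
    withWithin <- callDifferential(
      buildPresenceMatrix(ls, rbind(hits, within)))$n
    expect_gte(withWithin, base)
  }
})

test_that("hits naming unknown sequences are ignored with a warning", {
  ls <- mkLibs()
  hits <- simulateHitTable(data.frame(
    qseqid = c("id10:tx1", "nowhere:tx9"),
    sseqid = c("id12:tx1", "id9:tx1"), evalue = 1e-20))
  expect_warning(pm <- buildPresenceMatrix(ls, hits), "absent")
  expect_true(presence(pm)["id10:tx1", "id12"])
})

test_that("library sets validate ids and conditions", {
  x <- Biostrings::DNAStringSet(c(a = "ACGT"))
  expect_error(LibrarySet(list(`a:b` = x),
                          c(`a:b` = "treated")), ":")
  expect_error(LibrarySet(list(l1 = x, l2 = x),
                          c(l1 = "treated", l2 = "treated")),
               "control")
  expect_error(LibrarySet(list(l1 = x, l2 = x), c(l1 = "treated")),
               "condition")
})

test_that("the naive shared-substring matcher behaves as a similarity stand-in", {
  s <- randomDna(300)
  libs <- list(
    L1 = Biostrings::DNAStringSet(c(a = s, b = randomDna(300))),
    L2 = Biostrings::DNAStringSet(c(c = s)))
  ls <- LibrarySet(libs, c(L1 = "treated", L2 = "control"))
  hits <- naiveSimilarityHits(ls, minSharedKmerLen = 100)
  key <- paste(hits$qseqid, hits$sseqid)
  expect_true("L1:a L2:c" %in% key)   # reciprocal hits for identical seqs
  expect_true("L2:c L1:a" %in% key)
  expect_true("L1:a L1:a" %in% key)   # self-hit emitted
  expect_false(any(grepl("L1:b L2:c", key)))  # independent sequences
  expect_true(all(hits$evalue == 1e-30))
})
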