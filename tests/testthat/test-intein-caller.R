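models <- splicingBlockModels()
henModels <- henBlockModels()
lens <- blockLens(models)

test_that("compatible hits form a unique four-block chain", {
  hits <- data.frame(block = c("A", "B", "F", "G"), protein_id = "p",
                     start = c(10L, 80L, 200L, 230L),
                     score = c(20, 30, 25, 22), stringsAsFactors = FALSE)
  chains <- chainBlocks(hits, models)
  expect_length(chains, 1)
  expect_equal(chains[[1]]$block, c("A", "B", "F", "G"))
})

test_that("spacing violations reject a chain", {
  # B-F gap above max_gap
  hits <- data.frame(block = c("B", "F", "G"), protein_id = "p",
                     start = c(10L, 600L, 630L),
                     score = c(30, 25, 22), stringsAsFactors = FALSE)
  expect_length(chainBlocks(hits, models), 0)
})

test_that("two interleaved candidate inteins yield two complete chains", {
  hits <- data.frame(block = rep(c("B", "F", "G"), 2), protein_id = "p",
                     start = c(10L, 120L, 160L, 300L, 420L, 460L),
                     score = rep(c(30, 25, 22), 2), stringsAsFactors = FALSE)
  chains <- chainBlocks(hits, models)
  expect_length(chains, 2)
  for (ch in chains) expect_true(all(c("B", "F", "G") %in% ch$block))
  want <- oracleChainSet(hits, lens, spacingDefaults())
  expect_length(want, 2)
})

test_that("DP chaining equals exhaustive enumeration on random hit sets", {
  set.seed(808)
  for (rep in 1:60) {
    hits <- randomHitSet(sample(2:12, 1), lens)
    got <- chainBlocks(hits, models)
    want <- oracleChainSet(hits, lens, spacingDefaults())
    expect_length(got, length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$block, want[[k]]$block)
      expect_equal(got[[k]]$start, want[[k]]$start)
    }
  }
})

test_that("a planted intein is called with exact boundaries and residues", {
  set.seed(12)
  refs <- referenceExteins()
  it <- buildIntein("class1", hen = FALSE, penultimate = "H", divergence = 0)
  pl <- plantIntein(refs$RecB$seq, 124, it)
  hits <- scanBlocks(pl$precursor, models, minScore = 8, proteinId = "p")
  chains <- chainBlocks(hits, models)
  expect_length(chains, 1)
  call <- callIntein(pl$precursor, chains[[1]], models, proteinId = "p")
  expect_equal(unname(inteinRange(call)), c(pl$start, pl$end))
  k <- keyResidues(call)
  expect_equal(unname(k[c("a1", "terminal", "plus_one")]), c("C", "N", "C"))
  expect_equal(inteinClass(call), "class1")
  expect_equal(callStatus(call), "ok")
  # splicing simulation: excision restores the extein and the +1 junction
  sp <- spliceIntein(pl$precursor, call)
  expect_equal(nchar(sp$exteins), nchar(pl$precursor) - (call@end - call@start + 1))
  expect_equal(sp$exteins, refs$RecB$seq)
  expect_equal(substr(sp$exteins, call@start, call@start), k[["plus_one"]])
})

test_that("a chain with no room for the +1 extein residue is rejected", {
  set.seed(3)
  it <- buildIntein("class1", hen = FALSE, divergence = 0)
  prot <- paste0(randomProtein(30), it$seq)   # protein ends with the intein
  bl <- it$blocks
  chain <- data.frame(block = c("B", "F", "G"), protein_id = "p",
                      start = bl$start[match(c("B", "F", "G"), bl$block)] + 30L,
                      score = c(30, 25, 20), stringsAsFactors = FALSE)
  chain$end <- chain$start + lens[chain$block] - 1L
  # G columns 1-7 are the intein tail; column 8 (the +1) is past the end
  expect_null(callIntein(prot, chain, models))
})

test_that("a non-Asn/Gln terminal demotes the call to warning status", {
  set.seed(4)
  refs <- referenceExteins()
  it <- buildIntein("class1", hen = FALSE, divergence = 0)
  # corrupt the terminal residue after building
  itSeq <- it$seq
  substr(itSeq, nchar(itSeq), nchar(itSeq)) <- "A"
  it$seq <- itSeq
  pl <- plantIntein(refs$RecB$seq, 124, it)
  hits <- scanBlocks(pl$precursor, models, minScore = 8, proteinId = "p")
  chains <- chainBlocks(hits, models)
  call <- callIntein(pl$precursor, chains[[1]], models, proteinId = "p")
  expect_equal(callStatus(call), "warning")
  expect_true("noncanonical_terminal" %in% call@notes)
  # excluded from the default report
  expect_equal(nrow(callsTable(list(call))), 0)
  expect_equal(nrow(callsTable(list(call), includeWarnings = TRUE)), 1)
})

test_that("class assignment follows the WCT-then-nucleophile rules", {
  key <- function(a1, b12, f4, g5) c(a1 = a1, b12 = b12, f4 = f4, g5 = g5)
  expect_equal(assignClass(key("A", "W", "C", "T")), "class3")
  expect_equal(assignClass(key("C", "G", "V", "T")), "class1")
  # noncanonical penultimate does not affect class 1 assignment
  expect_equal(assignClass(key("C", "G", "V", "A")), "class1")
  expect_equal(assignClass(key("A", "G", "V", "T")), "unknown")
  # WCT wins even with a nucleophilic position 1
  expect_equal(assignClass(key("C", "W", "C", "T")), "class3")
})

test_that("HEN detection is restricted to the B-F region", {
  set.seed(21)
  refs <- referenceExteins()
  scanCall <- function(it) {
    pl <- plantIntein(refs$RecB$seq, 124, it)
    hits <- scanBlocks(pl$precursor, models, minScore = 8, proteinId = "p")
    chains <- chainBlocks(hits, models)
    call <- callIntein(pl$precursor, chains[[1]], models, proteinId = "p")
    detectHen(pl$precursor, call, henModels)
  }
  withHen <- scanCall(buildIntein("class1", hen = TRUE, divergence = 0))
  expect_true(withHen@henPresent)
  expect_false(withHen@miniIntein)
  mini <- scanCall(buildIntein("class1", hen = FALSE, divergence = 0))
  expect_false(mini@henPresent)
  expect_true(mini@miniIntein)   # B-F linker 15 < miniGap 50
})

test_that("HEN consensus outside the B-F region is ignored", {
  set.seed(22)
  refs <- referenceExteins()
  it <- buildIntein("class1", hen = FALSE, divergence = 0)
  pl <- plantIntein(refs$RecB$seq, 124, it)
  # append the HEN blocks downstream of the intein (C-extein side)
  henSeq <- paste0(paste(AA20h[apply(logOdds(henModels$C), 1, which.max)], collapse = ""),
                   randomProtein(10),
                   paste(AA20h[apply(logOdds(henModels$E), 1, which.max)], collapse = ""))
  prot <- paste0(pl$precursor, henSeq)
  hits <- scanBlocks(prot, models, minScore = 8, proteinId = "p")
  chains <- chainBlocks(hits, models)
  call <- callIntein(prot, chains[[1]], models, proteinId = "p")
  call <- detectHen(prot, call, henModels)
  expect_false(call@henPresent)
})

test_that("background-only proteins yield essentially no intein calls", {
  set.seed(555)
  nCalls <- 0
  for (i in 1:200) {
    scan <- runScan(proteins = c(bg = randomProtein(500)))
    nCalls <- nCalls + nrow(scan$table)
  }
  expect_lte(nCalls / 200, 0.01)
})
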