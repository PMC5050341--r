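test_that("global alignment handles identity and a single deletion", {
  pa <- globalAlign(paste(rep("ACDEFGHIKL", 3), collapse = ""),
                    paste(rep("ACDEFGHIKL", 3), collapse = ""))
  expect_equal(percentIdentity(pa), 100)
  expect_false(grepl("-", as.character(Biostrings::alignedPattern(pa))))
  pa2 <- globalAlign("ACDEFG", "ACEFG")
  aligned <- as.character(Biostrings::alignedSubject(pa2))
  expect_equal(nchar(aligned), 6)
  expect_equal(sum(strsplit(aligned, "")[[1]] == "-"), 1)
})

test_that("alignment scores match an independent affine-gap DP", {
  set.seed(404)
  for (i in 1:15) {
    a <- randomProtein(sample(15:35, 1))
    b <- randomProtein(sample(15:35, 1))
    got <- Biostrings::score(globalAlign(a, b))
    expect_equal(got, oracleAlignScore(a, b), tolerance = 1e-9)
  }
})

test_that("percent identity uses the declared denominator convention", {
  expect_equal(percentIdentity(list(pattern = "ACDEFGHIKL",
                                    subject = "AxDxFxHxKx")), 50)
  # 40-nt flanks differing at 10 positions: 75% identity
  set.seed(8)
  f1 <- randomDna(40)
  ch <- strsplit(f1, "")[[1]]
  pos <- sample(40, 10)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  f2 <- paste(ch, collapse = "")
  expect_equal(percentIdentity(globalAlign(f1, f2, type = "dna")), 75)
  # terminal overhangs are excluded from the denominator
  expect_equal(percentIdentity(list(pattern = "--ACDEF", subject = "KLACDEF")), 100)
})

test_that("splicing-domain excision removes exactly the B-F region", {
  set.seed(9)
  models <- splicingBlockModels()
  refs <- referenceExteins()
  for (hen in c(TRUE, FALSE)) {
    it <- buildIntein("class1", hen = hen, divergence = 0)
    pl <- plantIntein(refs$RecB$seq, 124, it)
    hits <- scanBlocks(pl$precursor, models, minScore = 8, proteinId = "p")
    call <- callIntein(pl$precursor, chainBlocks(hits, models)[[1]], models,
                       proteinId = "p")
    sp <- exciseSplicingDomain(call, spliceIntein(pl$precursor, call)$intein)
    bl <- it$blocks
    bEnd <- bl$end[bl$block == "B"]; fStart <- bl$start[bl$block == "F"]
    linker <- fStart - bEnd - 1L
    expect_equal(nchar(sp), nchar(it$seq) - linker)
  }
})

test_that("splicing-only identity of siblings exceeds full-length identity
           when the HEN regions are independently randomized", {
  set.seed(10)
  backbone <- buildIntein("class1", hen = TRUE, divergence = 0)
  bl <- backbone$blocks
  bEnd <- bl$end[bl$block == "B"]; fStart <- bl$start[bl$block == "F"]
  region <- (bEnd + 1):(fStart - 1)
  mkSib <- function() {             # shared splicing domains, random HEN region
    ch <- strsplit(backbone$seq, "")[[1]]
    ch[region] <- sample(AA20h, length(region), replace = TRUE)
    paste(ch, collapse = "")
  }
  a <- mkSib(); b <- mkSib()
  full <- percentIdentity(globalAlign(a, b))
  spliceOnly <- function(s) paste0(substr(s, 1, bEnd),
                                   substr(s, fStart, nchar(s)))
  spOnly <- percentIdentity(globalAlign(spliceOnly(a), spliceOnly(b)))
  expect_gte(spOnly, full - 1e-9)
})

test_that("transfer flagging separates reported identity regimes", {
  res <- data.frame(id_a = c("TerL1-e", "TerL1-a"),
                    id_b = c("Msm_prophage", "Krh_prophage"),
                    percent_identity = c(30.8, 39.9))
  flags <- flagTransferCandidates(res)
  expect_equal(flags$flagged, c(FALSE, TRUE))
  expect_equal(nrow(flagTransferCandidates(res[0, ])), 0)
  # sweep monotonicity: raising the threshold never adds flags
  prev <- sum(flagTransferCandidates(res, threshold = 25)$flagged)
  for (thr in c(30, 35, 40, 45)) {
    cur <- sum(flagTransferCandidates(res, threshold = thr)$flagged)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("NJ recovers additive topologies exactly", {
  # unique unrooted 3-taxon topology
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(d3)
  expect_equal(sort(t3$tip.label), c("A", "B", "C"))
  # additive 4-taxon matrix from ((A,B),(C,D)) with internal edge 3
  tx <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(tx, tx))
  ext <- c(A = 1, B = 2, C = 1.5, D = 2.5)
  for (i in 1:3) for (j in (i + 1):4) {
    within <- (i <= 2 && j <= 2) || (i >= 3 && j >= 3)
    d4[i, j] <- d4[j, i] <- ext[i] + ext[j] + if (within) 0 else 3
  }
  t4 <- njTree(d4)
  expect_equal(rfDistance(t4, ape::read.tree(text = "((A,B),(C,D));")), 0)
  # random additive matrices, 4-8 taxa
  set.seed(777)
  for (n in 4:8) for (rep in 1:5) {
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    expect_equal(rfDistance(njTree(d), tr), 0)
  }
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "square|taxa")
  dAsym <- d4; dAsym[1, 2] <- dAsym[1, 2] + 1
  expect_error(njTree(dAsym), "asymmetric")
})

test_that("RF distance counts one-sided bipartitions", {
  q1 <- ape::read.tree(text = "((A,B),(C,D));")
  q2 <- ape::read.tree(text = "((A,C),(B,D));")
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(rfDistance(q1, q1), 0)
  expect_equal(rfDistance(q1, q2), 2)
  expect_equal(rfDistance(star, q1), 1)
  expect_error(rfDistance(q1, ape::read.tree(text = "((A,B),(C,E));")),
               "taxon sets")
})

test_that("incongruence requires monophyly in exactly one tree", {
  it <- ape::read.tree(text = "((D,R),(X,(Y,Z)));")
  et <- ape::read.tree(text = "((D,X),(R,(Y,Z)));")
  inc <- detectIncongruence(it, et, c("D", "R"))
  expect_true(inc$incongruent)
  expect_true(inc$monophyletic_intein)
  expect_false(inc$monophyletic_extein)
  same <- detectIncongruence(it, it, c("D", "R"))
  expect_false(same$incongruent)
  none <- detectIncongruence(et, et, c("D", "R"))
  expect_equal(none$signal, "no signal")
  expect_error(detectIncongruence(it, et, "D"), "focal")
})

test_that("a simulated recent transfer is detected; controls are not", {
  s1 <- simulateHgt(seed = 42, transfer = TRUE)
  a1 <- suppressWarnings(hgtAnalyze(s1))
  expect_true(a1$transfer_detected)
  expect_gt(a1$identity, 80)
  s0 <- simulateHgt(seed = 42, transfer = FALSE)
  a0 <- suppressWarnings(hgtAnalyze(s0))
  expect_false(a0$transfer_detected)
})
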