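refs <- referenceExteins()

test_that("extein simulation respects divergence and frozen motifs", {
  set.seed(301)
  expect_equal(simulateExtein(refs$TerL1, 0), refs$TerL1$seq)
  # frozen motifs: zero substitutions inside motif intervals
  for (i in 1:5) {
    mut <- simulateExtein(refs$TerL1, 0.3)
    for (r in seq_len(nrow(refs$TerL1$motifs))) {
      m <- refs$TerL1$motifs[r, ]
      expect_equal(substr(mut, m$start, m$end),
                   substr(refs$TerL1$seq, m$start, m$end))
    }
  }
  expect_error(simulateExtein(refs$TerL1, 0.9), "divergence")
})

test_that("observed differences follow Binomial(L, d)", {
  set.seed(302)
  ref <- refs$PORT
  d <- 0.12
  L <- nchar(ref$seq)
  protected <- sum(vapply(seq_len(nrow(ref$motifs)), function(i)
    ref$motifs$end[i] - ref$motifs$start[i] + 1L, integer(1))) +
    nrow(ref$sites) + 1L
  nFree <- L - protected
  diffs <- vapply(1:100, function(i) {
    mut <- simulateExtein(ref, d)
    sum(strsplit(mut, "")[[1]] != strsplit(ref$seq, "")[[1]])
  }, numeric(1))
  ci <- qbinom(c(0.005, 0.995), nFree * 100, d)
  expect_gte(sum(diffs), ci[1])
  expect_lte(sum(diffs), ci[2])
})

test_that("built inteins carry the class-defining residues exactly", {
  set.seed(303)
  for (cls in c("class1", "class3")) for (hen in c(TRUE, FALSE)) {
    it <- buildIntein(cls, hen = hen, penultimate = "G", divergence = 0.2)
    ch <- strsplit(it$seq, "")[[1]]
    bl <- it$blocks
    at <- function(b, off) ch[bl$start[bl$block == b] + off - 1L]
    if (cls == "class3") {
      expect_equal(c(at("B", 12), at("F", 4), at("G", 5)), c("W", "C", "T"))
      expect_false(at("A", 1) %in% c("C", "S", "T"))
    } else {
      expect_equal(at("A", 1), "C")
      expect_false(identical(c(at("B", 12), at("F", 4), at("G", 5)),
                             c("W", "C", "T")))
    }
    expect_equal(at("G", 6), "G")       # requested penultimate
    expect_equal(at("G", 7), "N")       # terminal Asn
    expect_equal(bl$end[bl$block == "G"], nchar(it$seq))
    henBlocks <- c("C", "D", "E", "H")
    expect_equal(all(henBlocks %in% bl$block), hen)
  }
})

test_that("planting conserves length and round-trips by excision", {
  set.seed(304)
  it <- buildIntein("class1", hen = FALSE, divergence = 0.1)
  ext <- refs$RDF$seq
  pl <- plantIntein(ext, 95, it)
  expect_equal(nchar(pl$precursor), nchar(ext) + nchar(it$seq))
  back <- paste0(substr(pl$precursor, 1, pl$start - 1),
                 substr(pl$precursor, pl$end + 1, nchar(pl$precursor)))
  expect_equal(back, ext)
  expect_equal(substr(pl$precursor, pl$start, pl$end), it$seq)
  # +1 validation: the residue after the insertion must be a nucleophile
  nonNuc <- which(!strsplit(ext, "")[[1]] %in% c("C", "S", "T"))
  rc <- nonNuc[nonNuc >= 2][1] - 1L
  expect_error(plantIntein(ext, rc, it), "nucleophile")
  it3 <- buildIntein("class3", hen = FALSE, divergence = 0)
  expect_error(plantIntein(paste0("MA", "STSTST"), 3, it3), "nucleophile")
})

test_that("survey simulation is deterministic and truth-consistent", {
  cfg <- simConfig(seed = 42, clusters = c(C = 6L, B = 6L),
                   inteinRate = c(C = 0.9, B = 0.2))
  s1 <- simulateSurvey(cfg)
  s2 <- simulateSurvey(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  # every truth row is consistent with the emitted protein
  for (i in seq_len(nrow(s1$truth))) {
    tr <- s1$truth[i, ]
    prot <- s1$proteins[[tr$protein_id]]
    expect_equal(substr(prot, tr$start, tr$end), tr$intein_seq)
  }
  expect_equal(s1$manifest$cds_count, rep(cfg$genesPerGenome, 12))
  expect_equal(sum(s1$manifest$intein_count), nrow(s1$truth))
})

test_that("a zero-rate survey yields an empty truth and 0% prevalence", {
  cfg <- simConfig(seed = 5, clusters = c(A = 5L), inteinRate = c(A = 0))
  sim <- simulateSurvey(cfg)
  expect_equal(nrow(sim$truth), 0)
  prev <- clusterPrevalence(sim$manifest)
  expect_equal(prev$percent_positive[prev$cluster == "ALL"], 0)
})

test_that("genome ORFs reproduce the emitted proteins", {
  cfg <- simConfig(seed = 88, clusters = c(A = 3L), inteinRate = c(A = 1))
  sim <- simulateSurvey(cfg)
  for (gid in names(sim$genomes)) {
    orfs <- longestOrfs(findOrfs(sim$genomes[[gid]], minAa = 50, genomeId = gid))
    emitted <- sim$proteins[startsWith(names(sim$proteins), paste0(gid, "_"))]
    # each emitted protein is the suffix of some ORF (upstream spacer starts
    # may legitimately extend the ORF)
    for (p in emitted)
      expect_true(any(vapply(orfs$protein, function(o)
        endsWith(o, p), logical(1))))
  }
})

test_that("HGT simulation is deterministic with tree-consistent controls", {
  s1 <- simulateHgt(seed = 9, transfer = TRUE)
  s2 <- simulateHgt(seed = 9, transfer = TRUE)
  expect_identical(s1$inteins, s2$inteins)
  expect_identical(s1$exteins, s2$exteins)
  # transferred intein is near-identical to the donor's; controls are not
  idT <- 100 * mean(strsplit(s1$inteins[[s1$donor]], "")[[1]] ==
                    strsplit(s1$inteins[[s1$recipient]], "")[[1]])
  s0 <- simulateHgt(seed = 9, transfer = FALSE)
  id0 <- 100 * mean(strsplit(s0$inteins[[s0$donor]], "")[[1]] ==
                    strsplit(s0$inteins[[s0$recipient]], "")[[1]])
  expect_gt(idT, 80)
  expect_lt(id0, 50)
})
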