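test_that("FASTA reading preserves records, ids, descriptions and joins lines", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 first protein", "ACGT", "ACGT",
               ">p2", "MKLV"), f)
  recs <- readFastaRecords(f)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$description, c("first protein", ""))
  expect_equal(recs$seq[1], "ACGTACGT")
})

test_that("FASTA format errors are reported", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(readFastaRecords(f), "empty|FASTA")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(readFastaRecords(f), "duplicate id.*a")
})

test_that("translation follows genetic code 11 with ambiguity to X", {
  expect_equal(translateDna("ATGAAA"), "MK")
  expect_equal(translateDna("NNNATG"), "XM")
  expect_error(translateDna("ATGA"), "divisible")
})

test_that("all 64 codons match an independent code-11 table", {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  got <- translateDna(paste(codons, collapse = ""))
  want <- paste(vapply(codons, function(cd)
    toupper(seqinr::translate(strsplit(cd, "")[[1]], numcode = 11)),
    character(1)), collapse = "")
  expect_equal(got, want)
})

test_that("toy ORFs are found and boundary cases handled", {
  orfs <- findOrfs("ATGAAATAA", minAa = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$protein, "MK")
  expect_equal(c(orfs$start, orfs$end), c(1, 9))
  # no in-frame stop anywhere: open-ended ORFs excluded by default
  expect_equal(nrow(findOrfs("ATGAAAAAAAAA", minAa = 1)), 0)
  expect_error(findOrfs("MKLV", minAa = 1), "DNA")
})

test_that("ORF finding matches a brute-force six-frame scanner", {
  set.seed(421)
  for (rep in 1:5) {
    g <- randomDna(300)
    got <- findOrfs(g, minAa = 5)
    want <- oracleFindOrfs(g, minAa = 5)
    expect_equal(got[, c("start", "end", "strand", "frame")],
                 want, ignore_attr = TRUE)
  }
})

test_that("ORF proteins re-translate from genome coordinates", {
  set.seed(99)
  g <- randomDna(400)
  orfs <- findOrfs(g, minAa = 5)
  for (i in seq_len(nrow(orfs))) {
    sub <- substr(g, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") sub <- revcompStr(sub)
    expect_equal(translateDna(sub), paste0(orfs$protein[i], "*"))
  }
})

test_that("reverse complement mirrors the ORF set", {
  set.seed(17)
  g <- randomDna(350)
  rc <- revcompStr(g)
  a <- findOrfs(g, minAa = 5)
  b <- findOrfs(rc, minAa = 5)
  L <- nchar(g)
  mirrored <- data.frame(start = L - b$end + 1, end = L - b$start + 1,
                         strand = ifelse(b$strand == "+", "-", "+"),
                         protein = b$protein, stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$start, mirrored$end, mirrored$strand), ]
  orig <- a[order(a$start, a$end, a$strand), c("start", "end", "strand", "protein")]
  expect_equal(orig, mirrored, ignore_attr = TRUE)
})

test_that("longestOrfs keeps one ORF per stop", {
  # nested starts sharing a stop
  g <- paste0("ATGAAAATGAAATAA")  # starts at 1 and 7, same stop
  orfs <- findOrfs(g, minAa = 2)
  expect_gte(nrow(orfs), 2)
  keep <- longestOrfs(orfs)
  plus <- keep[keep$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 1)
})

test_that("GenBank-lite reader extracts CDS translations only", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       TESTPHAGE 900 bp DNA linear",
    "FEATURES             Location/Qualifiers",
    "     source          1..900",
    "     gene            1..300",
    "     CDS             1..300",
    '                     /protein_id="gp1"',
    '                     /translation="MKLVVT',
    '                     GHRR"',
    "     CDS             400..600",
    '                     /note="no translation"',
    "ORIGIN",
    "//"), f)
  expect_warning(cds <- readGenBankCds(f), "ignored")
  expect_equal(nrow(cds), 1)
  expect_equal(cds$translation, "MKLVVTGHRR")
  expect_equal(cds$protein_id, "gp1")
})

test_that("survey manifest validation enforces required columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcluster\tgenome_length_bp\tcds_count",
               "phage1\tA\t50000\t90", "phage2\tB\t70000\t"), f)
  m <- readSurveyManifest(f)
  expect_equal(nrow(m), 2)
  writeLines(c("genome_id\tcluster", "p\tA"), f)
  expect_error(readSurveyManifest(f), "lacks columns")
})
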