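# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms (brute force / enumeration) and
# never call the code paths they verify.

AA20h <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

randomProtein <- function(n) paste(sample(AA20h, n, replace = TRUE), collapse = "")
randomDna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

revcompStr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# --- brute-force six-frame ORF scanner (start codon -> next in-frame stop) ---
oracleFindOrfs <- function(s, minAa, startCodons = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else revcompStr(s)
    for (b in seq_len(L - 2)) {
      if (!substr(str, b, b + 2) %in% startCodons) next
      p <- b + 3
      found <- FALSE
      while (p + 2 <= L) {
        if (substr(str, p, p + 2) %in% stops) { found <- TRUE; break }
        p <- p + 3
      }
      if (!found) next
      nAa <- (p - b) / 3
      if (nAa < minAa) next
      e <- p + 2
      if (strand == "-") { fb <- L - e + 1; fe <- L - b + 1 } else { fb <- b; fe <- e }
      rows[[length(rows) + 1]] <- data.frame(
        start = fb, end = fe, strand = strand,
        frame = (b - 1) %% 3, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       strand = character(0), frame = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# --- naive PSSM window scan -------------------------------------------------
oracleScan <- function(protein, model, minScore) {
  ch <- strsplit(toupper(protein), "")[[1]]
  lo <- logOdds(model)
  m <- nrow(lo)
  hits <- list()
  for (s in seq_len(max(0, length(ch) - m + 1))) {
    sc <- 0
    for (j in seq_len(m)) {
      a <- match(ch[s + j - 1], AA20h)
      sc <- sc + if (is.na(a)) 0 else lo[j, a]
    }
    if (sc >= minScore)
      hits[[length(hits) + 1]] <- data.frame(start = s, score = sc)
  }
  if (!length(hits)) return(data.frame(start = integer(0), score = numeric(0)))
  do.call(rbind, hits)
}

# --- quadratic-space affine-gap global alignment score (Gotoh) --------------
# gap of length k costs open + k * ext; end gaps penalized
oracleAlignScore <- function(a, b, open = 11, ext = 1, submat = NULL) {
  if (is.null(submat)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
  }
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- submat[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- exhaustive chain enumeration ------------------------------------------
# every combination of (optional A) x B x F x G hits satisfying order and
# spacing; best-first with greedy non-overlap removal
oracleChainSet <- function(hits, lens, constraints) {
  hits$end <- hits$start + lens[hits$block] - 1L
  gapOk <- function(pe, ns, lim) { g <- ns - pe - 1; g >= lim[1] && g <= lim[2] }
  enumerate <- function(pool) {
    hA <- pool[pool$block == "A", , drop = FALSE]
    hB <- pool[pool$block == "B", , drop = FALSE]
    hF <- pool[pool$block == "F", , drop = FALSE]
    hG <- pool[pool$block == "G", , drop = FALSE]
    chains <- list()
    for (bi in seq_len(nrow(hB))) for (fi in seq_len(nrow(hF)))
      for (gi in seq_len(nrow(hG))) {
        if (!gapOk(hB$end[bi], hF$start[fi], constraints$B_F)) next
        if (!gapOk(hF$end[fi], hG$start[gi], constraints$F_G)) next
        base <- rbind(hB[bi, ], hF[fi, ], hG[gi, ])
        chains[[length(chains) + 1]] <- base
        for (ai in seq_len(nrow(hA))) {
          if (!gapOk(hA$end[ai], hB$start[bi], constraints$A_B)) next
          chains[[length(chains) + 1]] <- rbind(hA[ai, ], base)
        }
      }
    chains
  }
  pick <- function(chains) {
    if (!length(chains)) return(NULL)
    sc <- vapply(chains, function(c) sum(c$score), numeric(1))
    st <- vapply(chains, function(c) min(c$start), numeric(1))
    bs <- vapply(chains, function(c) paste(sort(c$block), collapse = ""), character(1))
    chains[[order(-sc, st, bs)[1]]]
  }
  out <- list()
  pool <- hits
  repeat {
    best <- pick(enumerate(pool))
    if (is.null(best)) break
    out[[length(out) + 1]] <- best
    span <- c(min(best$start), max(best$end))
    pool <- pool[pool$end < span[1] | pool$start > span[2], , drop = FALSE]
    if (!nrow(pool)) break
  }
  out
}

randomHitSet <- function(n, lens) {
  blocks <- sample(c("A", "B", "F", "G"), n, replace = TRUE)
  data.frame(block = blocks, protein_id = "p",
             start = sample.int(600, n, replace = TRUE),
             score = round(runif(n, 8, 40), 3), stringsAsFactors = FALSE)
}

blockLens <- function(models) vapply(models, modelLength, integer(1))
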