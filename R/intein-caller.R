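# Chain block hits into intein calls, fix boundaries and key residues,
# assign splicing class, and detect the homing endonuclease.

#' Default block spacing constraints
#'
#' Gaps are counted as residues strictly between consecutive block windows
#' (next start - previous end - 1). The defaults bracket known intein
#' architectures: a 30-120 residue A-B region, up to 450 residues between B
#' and F (room for a LAGLIDADG endonuclease), and a short 5-60 residue F-G
#' linker. They are configuration constants, not biological claims.
#' @return named list of c(min, max) gaps for A_B, B_F, F_G
#' @export
spacingDefaults <- function() {
  list(A_B = c(30L, 120L), B_F = c(0L, 450L), F_G = c(5L, 60L))
}

#' @keywords internal
.blockLengths <- function(models) {
  vapply(models, modelLength, integer(1))
}

#' @keywords internal
.gapOk <- function(prevEnd, nextStart, lim) {
  g <- nextStart - prevEnd - 1L
  g >= lim[1] && g <= lim[2]
}

#' Chain block hits into candidate inteins
#'
#' Dynamic programming over hits sorted by position finds the
#' maximum-total-score chain respecting block order (A < B < F < G) and the
#' spacing constraints; blocks B, F and G are required, block A optional
#' (class 3 block A diverges, so its absence only makes the N-terminus
#' approximate). Non-overlapping chains are returned best-first: after each
#' chain is accepted, hits overlapping its span are removed and the DP is
#' rerun. Ties break toward the leftmost start, then the lexicographically
#' smallest block set.
#'
#' @param hits data.frame from \code{\link{scanBlocks}} (one protein)
#' @param models named list of models (block lengths are needed to place ends)
#' @param constraints spacing table as from \code{\link{spacingDefaults}}
#' @return list of chains; each chain is a data.frame of hits (block, start,
#'   end, score) in block order
#' @export
chainBlocks <- function(hits, models, constraints = spacingDefaults()) {
  if (nrow(hits) == 0) return(list())
  lens <- .blockLengths(models)
  hits$end <- hits$start + lens[hits$block] - 1L
  chains <- list()
  pool <- hits
  repeat {
    best <- .bestChain(pool, constraints)
    if (is.null(best)) break
    chains[[length(chains) + 1L]] <- best
    span <- c(min(best$start), max(best$end))
    pool <- pool[pool$end < span[1] | pool$start > span[2], , drop = FALSE]
    if (nrow(pool) == 0) break
  }
  chains
}

#' Single best chain by DP; NULL if no complete chain exists
#' @keywords internal
.bestChain <- function(hits, constraints) {
  hA <- hits[hits$block == "A", , drop = FALSE]
  hB <- hits[hits$block == "B", , drop = FALSE]
  hF <- hits[hits$block == "F", , drop = FALSE]
  hG <- hits[hits$block == "G", , drop = FALSE]
  if (nrow(hB) == 0 || nrow(hF) == 0 || nrow(hG) == 0) return(NULL)

  # best prefix ending at each B hit (optionally through an A hit)
  bScore <- numeric(nrow(hB)); bPrev <- rep(NA_integer_, nrow(hB))
  for (i in seq_len(nrow(hB))) {
    bScore[i] <- hB$score[i]
    if (nrow(hA)) {
      ok <- which(vapply(seq_len(nrow(hA)), function(a)
        .gapOk(hA$end[a], hB$start[i], constraints$A_B), logical(1)))
      if (length(ok)) {
        cand <- hA$score[ok]
        pick <- ok[order(-cand, hA$start[ok])][1]
        bScore[i] <- hB$score[i] + hA$score[pick]
        bPrev[i] <- pick
      }
    }
  }
  fScore <- rep(-Inf, nrow(hF)); fPrev <- rep(NA_integer_, nrow(hF))
  for (i in seq_len(nrow(hF))) {
    ok <- which(vapply(seq_len(nrow(hB)), function(b)
      .gapOk(hB$end[b], hF$start[i], constraints$B_F), logical(1)))
    if (length(ok)) {
      pick <- ok[order(-bScore[ok], hB$start[ok])][1]
      fScore[i] <- hF$score[i] + bScore[pick]
      fPrev[i] <- pick
    }
  }
  gScore <- rep(-Inf, nrow(hG)); gPrev <- rep(NA_integer_, nrow(hG))
  for (i in seq_len(nrow(hG))) {
    ok <- which(vapply(seq_len(nrow(hF)), function(f)
      is.finite(fScore[f]) && .gapOk(hF$end[f], hG$start[i], constraints$F_G),
      logical(1)))
    if (length(ok)) {
      pick <- ok[order(-fScore[ok], hF$start[ok])][1]
      gScore[i] <- hG$score[i] + fScore[pick]
      gPrev[i] <- pick
    }
  }
  if (all(!is.finite(gScore))) return(NULL)
  gi <- order(-gScore, hG$start)[1]
  fi <- gPrev[gi]; bi <- fPrev[fi]; ai <- bPrev[bi]
  rows <- rbind(if (!is.na(ai)) hA[ai, ], hB[bi, ], hF[fi, ], hG[gi, ])
  rows <- rows[, c("block", "protein_id", "start", "end", "score")]
  rownames(rows) <- NULL
  rows
}

#' Fix boundaries and key residues for a chained candidate
#'
#' Intein position 1 is block A column 1 when block A is present; otherwise a
#' heuristic N-terminus is placed \code{approxOffset} residues upstream of
#' block B and the call is flagged \code{approximate_n_terminus}. The intein
#' ends at block G column 7 (terminal Asn/Gln); block G column 8 is the +1
#' C-extein nucleophile. Calls whose terminal residue is not Asn or Gln are
#' demoted to warning status rather than dropped.
#'
#' @param protein protein sequence (character) or record row
#' @param chain one chain from \code{\link{chainBlocks}}
#' @param models named list of \code{\linkS4class{BlockModel}} (needs G key positions)
#' @param approxOffset N-terminus offset used when block A is absent
#' @param proteinId id recorded in the call
#' @return an \code{\linkS4class{InteinCall}}, or NULL if no +1 residue exists
#' @export
callIntein <- function(protein, chain, models, approxOffset = 10L,
                       proteinId = "protein") {
  if (is.data.frame(protein)) { proteinId <- protein$id; protein <- protein$seq }
  ch <- .chars(protein)
  blocks <- chain$block
  if (is.unsorted(match(blocks, c("A", "B", "F", "G")), strictly = TRUE))
    .stopf("chain blocks out of order: %s", paste(blocks, collapse = ","))
  if (!all(c("B", "F", "G") %in% blocks))
    .stopf("chain must contain blocks B, F and G")
  g <- chain[chain$block == "G", ]
  kpG <- keyPositions(models[["G"]])
  endPos <- g$start + kpG[["terminal"]] - 1L
  plusPos <- g$start + kpG[["plus_one"]] - 1L
  if (plusPos > length(ch)) return(NULL)   # no +1 extein residue exists
  notes <- character(0)
  if ("A" %in% blocks) {
    startPos <- chain$start[chain$block == "A"]
  } else {
    startPos <- max(1L, chain$start[chain$block == "B"] - approxOffset)
    notes <- c(notes, "approximate_n_terminus")
  }
  b <- chain[chain$block == "B", ]
  f <- chain[chain$block == "F", ]
  key <- c(
    a1 = ch[startPos],
    b12 = ch[b$start + keyPositions(models[["B"]])[["triplet_W"]] - 1L],
    f4 = ch[f$start + keyPositions(models[["F"]])[["triplet_C"]] - 1L],
    g5 = ch[g$start + kpG[["triplet_T"]] - 1L],
    penultimate = ch[g$start + kpG[["penultimate"]] - 1L],
    terminal = ch[endPos],
    plus_one = ch[plusPos])
  status <- "ok"
  if (!key[["terminal"]] %in% c("N", "Q")) {
    status <- "warning"
    notes <- c(notes, "noncanonical_terminal")
  }
  if (length(notes) && "approximate_n_terminus" %in% notes && status == "ok")
    status <- "warning"
  nFlank <- if (startPos > 1)
    paste(ch[max(1L, startPos - 10L):(startPos - 1L)], collapse = "") else ""
  cFlank <- paste(ch[plusPos:min(length(ch), endPos + 10L)], collapse = "")
  call <- methods::new("InteinCall",
    proteinId = proteinId, start = as.integer(startPos), end = as.integer(endPos),
    blocks = chain[, c("block", "start", "end", "score")],
    keyResidues = key, inteinClass = "unknown",
    henPresent = FALSE, miniIntein = FALSE,
    nFlank = nFlank, cFlank = cFlank, status = status, notes = notes)
  call@inteinClass <- assignClass(call)
  call
}

#' Assign the splicing class from key residues
#'
#' Class 3 iff the Trp-Cys-Thr (WCT) triplet occupies block positions
#' B12/F4/G5; otherwise class 1 iff position 1 carries a nucleophile
#' (Cys/Ser/Thr); otherwise unknown.
#'
#' @param call an \code{\linkS4class{InteinCall}} or a named character vector
#'   of key residues (a1, b12, f4, g5)
#' @return "class1", "class3" or "unknown"
#' @export
assignClass <- function(call) {
  k <- if (methods::is(call, "InteinCall")) call@keyResidues else call
  if (identical(unname(k[c("b12", "f4", "g5")]), c("W", "C", "T"))) return("class3")
  if (k[["a1"]] %in% c("C", "S", "T")) return("class1")
  "unknown"
}

#' Detect a LAGLIDADG homing endonuclease inside a call
#'
#' Scans only the region between the end of block B and the start of block F.
#' The HEN is called present iff blocks C and E (which carry the actual
#' LAGLIDADG motifs) both hit with C before E; a HEN-less intein whose B-F
#' region is shorter than \code{miniGap} is a mini-intein.
#'
#' @param protein protein sequence (character) or record row
#' @param call an \code{\linkS4class{InteinCall}}
#' @param henModels list of C/D/E/H models
#' @param miniGap mini-intein linker threshold in residues (default 50)
#' @param minScore bit threshold for HEN block hits
#' @return the call with \code{henPresent}/\code{miniIntein} set and HEN hits
#'   appended to \code{notes}-free slot \code{blocks} attribute "hen_hits"
#' @export
detectHen <- function(protein, call, henModels, miniGap = 50L, minScore = 8) {
  if (is.data.frame(protein)) protein <- protein$seq
  b <- call@blocks[call@blocks$block == "B", ]
  f <- call@blocks[call@blocks$block == "F", ]
  if (nrow(b) == 0 || nrow(f) == 0) .stopf("call lacks located blocks B and F")
  lo <- b$end + 1L
  hi <- f$start - 1L
  regionLen <- hi - lo + 1L
  present <- FALSE
  henHits <- data.frame(block = character(0), protein_id = character(0),
                        start = integer(0), score = numeric(0),
                        stringsAsFactors = FALSE)
  if (regionLen >= min(vapply(henModels, modelLength, integer(1)))) {
    region <- substr(protein, lo, hi)
    henHits <- scanBlocks(region, henModels, minScore = minScore,
                          proteinId = call@proteinId)
    if (nrow(henHits)) henHits$start <- henHits$start + lo - 1L
    cs <- henHits$start[henHits$block == "C"]
    es <- henHits$start[henHits$block == "E"]
    present <- length(cs) > 0 && length(es) > 0 && min(cs) < max(es)
  }
  call@henPresent <- present
  call@miniIntein <- (!present) && regionLen < miniGap
  attr(call@blocks, "hen_hits") <- henHits
  call
}

#' Excise an intein from its host protein
#'
#' Returns the ligated exteins: the protein with \code{[start, end]} removed.
#' For an accepted call the residue at the former junction is the +1
#' nucleophile.
#' @param protein host protein sequence
#' @param call an \code{\linkS4class{InteinCall}}
#' @return list(exteins, intein) of character strings
#' @export
spliceIntein <- function(protein, call) {
  if (is.data.frame(protein)) protein <- protein$seq
  L <- nchar(protein)
  list(
    exteins = paste0(substr(protein, 1, call@start - 1L),
                     substr(protein, call@end + 1L, L)),
    intein = substr(protein, call@start, call@end))
}

# ---- call set reporting ----------------------------------------------------

#' Tabulate a list of intein calls
#'
#' @param calls list of \code{\linkS4class{InteinCall}}
#' @param includeWarnings include warning-status calls (default FALSE,
#'   mirroring default reports)
#' @return data.frame with 1-based inclusive coordinates, class, key residues
#'   and HEN flags
#' @export
callsTable <- function(calls, includeWarnings = FALSE) {
  cols <- c("protein_id", "start", "end", "intein_class", "a1", "b12", "f4",
            "g5", "penultimate", "terminal", "plus_one", "hen", "mini_intein",
            "status", "notes")
  if (length(calls) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  rows <- lapply(calls, function(x) data.frame(
    protein_id = x@proteinId, start = x@start, end = x@end,
    intein_class = x@inteinClass,
    a1 = x@keyResidues[["a1"]], b12 = x@keyResidues[["b12"]],
    f4 = x@keyResidues[["f4"]], g5 = x@keyResidues[["g5"]],
    penultimate = x@keyResidues[["penultimate"]],
    terminal = x@keyResidues[["terminal"]],
    plus_one = x@keyResidues[["plus_one"]],
    hen = x@henPresent, mini_intein = x@miniIntein, status = x@status,
    notes = paste(x@notes, collapse = ";"), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (!includeWarnings) df <- df[df$status == "ok", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intein calls as a TSV table
#' @param calls list of \code{\linkS4class{InteinCall}}
#' @param path output path
#' @param params named list echoed into the header comment
#' @param includeWarnings include warning-status calls
#' @export
writeCallsTsv <- function(calls, path, params = list(), includeWarnings = FALSE) {
  df <- callsTable(calls, includeWarnings = includeWarnings)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params))
    writeLines(sprintf("# %s", paste(names(params), unlist(params), sep = "=",
                                     collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intein calls as GFF3 on the protein coordinate system
#' @param calls list of \code{\linkS4class{InteinCall}}
#' @param path output path
#' @export
writeCallsGff3 <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (x in calls) {
    attrs <- sprintf("ID=intein_%s_%d;class=%s;hen=%s;mini=%s;status=%s",
                     x@proteinId, x@start, x@inteinClass,
                     tolower(x@henPresent), tolower(x@miniIntein), x@status)
    score <- sum(x@blocks$score)
    writeLines(paste(x@proteinId, "inteinscan", "intein", x@start, x@end,
                     sprintf("%.2f", score), ".", ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Extract intein sequences from calls as a named character vector
#' @param calls list of \code{\linkS4class{InteinCall}}
#' @param proteins named character vector of host proteins
#' @export
inteinSequences <- function(calls, proteins) {
  out <- character(0)
  for (x in calls) {
    s <- proteins[[x@proteinId]]
    out[sprintf("%s_intein_%d_%d", x@proteinId, x@start, x@end)] <-
      substr(s, x@start, x@end)
  }
  out
}
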