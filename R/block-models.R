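# Position-specific scoring models for the intein splicing blocks (A, B, F, G)
# and the LAGLIDADG endonuclease blocks (C, D, E, H).

#' Build a position-specific scoring model from a seed alignment
#'
#' Log-odds in bits with pseudocounts proportional to the background:
#' \deqn{S_{c,a} = \log_2 \frac{n_{c,a} + \kappa\, b_a}{(N + \kappa)\, b_a}}
#' where \eqn{n_{c,a}} counts residue \eqn{a} in column \eqn{c}, \eqn{N} is
#' the number of seed sequences and \eqn{\kappa} the pseudocount mass.
#' Columns with more than 50\% gap characters are removed and key positions
#' re-indexed onto the remaining columns.
#'
#' @param seedAlignment character vector of equal-length aligned sequences
#'   (gaps as \code{-} or \code{.})
#' @param name block name (A, B, F, G, C, D, E, H)
#' @param keyPositions named integer vector of role -> column in the
#'   original alignment numbering
#' @param pseudocount positive pseudocount mass (default 2)
#' @param background 20-vector of background frequencies (default uniform)
#' @return a \code{\linkS4class{BlockModel}}
#' @export
buildPssm <- function(seedAlignment, name, keyPositions = integer(0),
                      pseudocount = 2, background = rep(1 / 20, 20)) {
  if (length(seedAlignment) < 2)
    .stopf("seed alignment needs >= 2 sequences (got %d)", length(seedAlignment))
  lens <- nchar(seedAlignment)
  if (length(unique(lens)) != 1)
    .stopf("ragged seed alignment: lengths %s", paste(unique(lens), collapse = ", "))
  if (pseudocount <= 0) .stopf("pseudocount must be > 0")
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-9)
    .stopf("background must be 20 frequencies summing to 1")
  keyPositions <- if (length(keyPositions))
    stats::setNames(as.integer(keyPositions), names(keyPositions)) else integer(0)

  mat <- do.call(rbind, lapply(seedAlignment, .chars))
  gapFrac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gapFrac <= 0.5)
  if (length(keep) == 0) .stopf("all alignment columns are majority-gap")
  if (length(keyPositions)) {
    lost <- setdiff(keyPositions, keep)
    if (length(lost))
      .stopf("key position(s) %s fall in removed gap columns",
             paste(lost, collapse = ", "))
    keyPositions <- stats::setNames(match(keyPositions, keep), names(keyPositions))
  }
  mat <- mat[, keep, drop = FALSE]

  N <- nrow(mat)
  lo <- matrix(0, nrow = ncol(mat), ncol = 20, dimnames = list(NULL, AA20))
  for (c in seq_len(ncol(mat))) {
    col <- mat[, c]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    lo[c, ] <- log2((as.numeric(cnt) + pseudocount * background) /
                      ((N + pseudocount) * background))
  }
  methods::new("BlockModel", name = name, logOdds = lo,
               keyPositions = keyPositions, background = background)
}

#' Score a protein window under a model
#' @keywords internal
.scoreWindows <- function(proteinChars, model) {
  m <- modelLength(model)
  L <- length(proteinChars)
  W <- L - m + 1L
  if (W < 1) return(numeric(0))
  S <- cbind(logOdds(model), 0)    # 21st column: unknown residue scores 0
  idx <- .aaIndex(proteinChars)
  sc <- numeric(W)
  for (j in seq_len(m)) sc <- sc + S[j, idx[j:(j + W - 1L)]]
  sc
}

#' Scan a protein for block hits
#'
#' Every window position is scored under every model; windows at or above
#' \code{minScore} bits are returned sorted by (position, block name).
#' Residues outside the 20-letter alphabet (e.g. \code{X}) contribute the
#' background-expected score of 0 bits. A protein shorter than a model
#' simply yields no hits for that model.
#'
#' @param protein a protein sequence (character) or a record row from
#'   \code{\link{readFastaRecords}}
#' @param models list of \code{\linkS4class{BlockModel}}
#' @param minScore minimum score in bits (default 8)
#' @param proteinId id recorded in the hits
#' @return data.frame: block, protein_id, start (1-based), score
#' @export
scanBlocks <- function(protein, models, minScore = 8, proteinId = "protein") {
  if (is.data.frame(protein)) {
    if (protein$alphabet != "protein") .stopf("scanBlocks requires a protein sequence")
    proteinId <- protein$id
    protein <- protein$seq
  }
  if (!is.finite(minScore)) .stopf("minScore must be finite")
  ch <- .chars(protein)
  out <- list()
  for (model in models) {
    sc <- .scoreWindows(ch, model)
    hit <- which(sc >= minScore)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        block = modelName(model), protein_id = proteinId,
        start = hit, score = sc[hit], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(block = character(0), protein_id = character(0),
                      start = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$block), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Empirical background amino-acid frequencies of a protein set
#' @param proteins character vector of protein sequences
#' @return named 20-vector of frequencies
#' @export
backgroundFrequencies <- function(proteins) {
  ch <- unlist(lapply(proteins, .chars))
  ch <- ch[ch %in% AA20]
  cnt <- table(factor(ch, levels = AA20))
  stats::setNames(as.numeric(cnt) / sum(cnt), AA20)
}

# ---- packaged seed alignments ----------------------------------------------

.BLOCK_KEYPOS <- list(
  A = c(nucleophile = 1L),
  B = c(triplet_W = 12L),
  F = c(triplet_C = 4L),
  G = c(triplet_T = 5L, penultimate = 6L, terminal = 7L, plus_one = 8L),
  C = c(laglidadg = 2L),
  D = integer(0),
  E = c(laglidadg = 2L),
  H = integer(0)
)

#' Read a packaged seed alignment for one block
#'
#' The packaged seeds are synthetic, consensus-anchored alignments encoding
#' the canonical residue logic of the splicing and LAGLIDADG blocks; they are
#' stand-ins for unpublished profile seeds, not database-derived alignments.
#'
#' @param block block name
#' @return character vector of aligned sequences
#' @export
seedAlignment <- function(block) {
  recs <- readFastaRecords(.extdata(sprintf("seed_block_%s_synthetic.fasta", block)))
  recs$seq
}

#' Build the full packaged model set
#'
#' @param blocks which blocks to build (default all eight)
#' @param pseudocount,background passed to \code{\link{buildPssm}}
#' @return named list of \code{\linkS4class{BlockModel}}
#' @export
inteinBlockModels <- function(blocks = c("A", "B", "F", "G", "C", "D", "E", "H"),
                              pseudocount = 2, background = rep(1 / 20, 20)) {
  stats::setNames(lapply(blocks, function(b)
    buildPssm(seedAlignment(b), name = b, keyPositions = .BLOCK_KEYPOS[[b]],
              pseudocount = pseudocount, background = background)), blocks)
}

#' @describeIn inteinBlockModels the four splicing-block models (A, B, F, G)
#' @export
splicingBlockModels <- function(pseudocount = 2, background = rep(1 / 20, 20))
  inteinBlockModels(c("A", "B", "F", "G"), pseudocount, background)

#' @describeIn inteinBlockModels the four HEN-block models (C, D, E, H)
#' @export
henBlockModels <- function(pseudocount = 2, background = rep(1 / 20, 20))
  inteinBlockModels(c("C", "D", "E", "H"), pseudocount, background)

# ---- serialization ---------------------------------------------------------

#' Write / read a BlockModel as JSON text
#'
#' @param model a \code{\linkS4class{BlockModel}}
#' @param path file path
#' @export
writeBlockModel <- function(model, path) {
  obj <- list(name = modelName(model), length = modelLength(model),
              key_positions = as.list(keyPositions(model)),
              background = model@background,
              alphabet = AA20,
              matrix = unname(apply(logOdds(model), 1, as.numeric, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBlockModel
#' @export
readBlockModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- if (is.list(obj$matrix))
    do.call(rbind, lapply(obj$matrix, as.numeric)) else as.matrix(obj$matrix)
  dimnames(lo) <- list(NULL, AA20)
  kp <- stats::setNames(as.integer(unlist(obj$key_positions)), names(obj$key_positions))
  methods::new("BlockModel", name = obj$name, logOdds = lo,
               keyPositions = kp, background = as.numeric(obj$background))
}
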