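#' @import methods
NULL

#' BlockModel: a position-specific scoring model for one conserved block
#'
#' Inteins carry four conserved protein-splicing blocks (A, B, F, G) and,
#' when a homing endonuclease (HEN) is present, four LAGLIDADG blocks
#' (C, D, E, H) between blocks B and F. A \code{BlockModel} is a log-odds
#' matrix (bits) over the 20 amino acids built from a seed alignment, with
#' named key positions (e.g. the block A nucleophile at column 1, the class 3
#' WCT triplet at B12/F4/G5, the penultimate residue at G6, the terminal
#' Asn/Gln at G7 and the +1 extein nucleophile at G8).
#'
#' @slot name single letter block name (A, B, F, G, C, D, E, H)
#' @slot logOdds numeric matrix, length x 20 (columns in \code{AA20} order), bits
#' @slot keyPositions named integer vector of role -> column (1-based)
#' @slot background numeric vector of 20 background frequencies (sums to 1)
#' @export
setClass("BlockModel",
  representation(
    name = "character",
    logOdds = "matrix",
    keyPositions = "integer",
    background = "numeric"
  )
)

setValidity("BlockModel", function(object) {
  msg <- character(0)
  if (length(object@name) != 1 || !object@name %in% c("A", "B", "F", "G", "C", "D", "E", "H"))
    msg <- c(msg, "name must be one of A, B, F, G, C, D, E, H")
  if (ncol(object@logOdds) != 20)
    msg <- c(msg, "logOdds must have 20 columns")
  if (length(object@background) != 20 ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 20 frequencies summing to 1")
  L <- nrow(object@logOdds)
  kp <- object@keyPositions
  if (length(kp) && (any(kp < 1) || any(kp > L)))
    msg <- c(msg, "keyPositions must lie within [1, length]")
  if (identical(object@name, "G") && L < 8)
    msg <- c(msg, "block G must have length >= 8 (columns up to the +1 residue)")
  if (any(!is.finite(object@logOdds)))
    msg <- c(msg, "logOdds must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn BlockModel block name
#' @param object,x a \code{BlockModel}
#' @export
modelName <- function(x) x@name

#' @describeIn BlockModel number of model columns
#' @export
modelLength <- function(x) nrow(x@logOdds)

#' @describeIn BlockModel named key positions (role -> column)
#' @export
keyPositions <- function(x) x@keyPositions

#' @describeIn BlockModel the log-odds matrix in bits
#' @export
logOdds <- function(x) x@logOdds

setMethod("show", "BlockModel", function(object) {
  cat(sprintf("BlockModel %s: %d columns, key positions: %s\n",
              object@name, nrow(object@logOdds),
              if (length(object@keyPositions))
                paste(names(object@keyPositions), object@keyPositions,
                      sep = "=", collapse = ", ")
              else "none"))
})

#' InteinCall: one detected intein on a protein
#'
#' Coordinates are 1-based inclusive on the host protein: \code{start} is
#' intein position 1 (the block A nucleophile for class 1) and \code{end} is
#' the terminal Asn/Gln (block G column 7). The +1 residue (first C-extein
#' residue, block G column 8) sits at \code{end + 1}.
#'
#' @slot proteinId host protein identifier
#' @slot start,end 1-based inclusive intein boundaries on the protein
#' @slot blocks data.frame of chained block hits (block, start, score)
#' @slot keyResidues named character: a1, b12, f4, g5, penultimate, terminal, plus_one
#' @slot inteinClass "class1", "class3" or "unknown"
#' @slot henPresent logical; LAGLIDADG endonuclease found between B and F
#' @slot miniIntein logical; HEN-less intein with a short B-F linker
#' @slot nFlank,cFlank up to 10 flanking extein residues on each side
#' @slot status "ok" or "warning" (e.g. non-canonical terminal residue,
#'   approximate N-terminus when block A was not located)
#' @slot notes character vector of warning annotations
#' @export
setClass("InteinCall",
  representation(
    proteinId = "character",
    start = "integer",
    end = "integer",
    blocks = "data.frame",
    keyResidues = "character",
    inteinClass = "character",
    henPresent = "logical",
    miniIntein = "logical",
    nFlank = "character",
    cFlank = "character",
    status = "character",
    notes = "character"
  )
)

setValidity("InteinCall", function(object) {
  msg <- character(0)
  if (object@start >= object@end)
    msg <- c(msg, "start must be < end")
  b <- object@blocks
  if (nrow(b)) {
    ord <- match(b$block, c("A", "B", "F", "G"))
    if (any(is.na(ord)) || any(diff(ord) <= 0) || any(diff(b$start) <= 0))
      msg <- c(msg, "chained blocks must appear in protein order A < B < F < G")
  }
  need <- c("a1", "b12", "f4", "g5", "penultimate", "terminal", "plus_one")
  if (!all(need %in% names(object@keyResidues)))
    msg <- c(msg, "keyResidues must name a1, b12, f4, g5, penultimate, terminal, plus_one")
  if (!object@inteinClass %in% c("class1", "class3", "unknown"))
    msg <- c(msg, "inteinClass must be class1, class3 or unknown")
  if (length(msg)) msg else TRUE
})

#' @describeIn InteinCall splicing class of a call
#' @param x an \code{InteinCall}
#' @export
inteinClass <- function(x) x@inteinClass

#' @describeIn InteinCall named key catalytic residues
#' @export
keyResidues <- function(x) x@keyResidues

#' @describeIn InteinCall 1-based inclusive boundaries as c(start, end)
#' @export
inteinRange <- function(x) c(start = x@start, end = x@end)

#' @describeIn InteinCall call status ("ok" or "warning")
#' @export
callStatus <- function(x) x@status

setMethod("show", "InteinCall", function(object) {
  cat(sprintf(
    "InteinCall on %s [%d-%d] %s%s%s status=%s\n  key residues: %s\n",
    object@proteinId, object@start, object@end, object@inteinClass,
    if (object@henPresent) " +HEN" else "",
    if (object@miniIntein) " (mini)" else "",
    object@status,
    paste(names(object@keyResidues), object@keyResidues,
          sep = "=", collapse = " ")))
})
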