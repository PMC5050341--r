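# Pairwise intein identity, intein/extein trees, incongruence, and
# horizontal-transfer flagging.

#' Optimal global alignment of two amino-acid or nucleotide strings
#'
#' Affine-gap global (Needleman-Wunsch) alignment via
#' \code{Biostrings::pairwiseAlignment}. Protein pairs use BLOSUM62; DNA
#' pairs a +2/-2 match/mismatch matrix. A gap of length k costs
#' \code{gapOpening + k * gapExtension}. Tie-breaking is deterministic
#' (single optimal traceback).
#'
#' @param a,b non-empty sequences
#' @param type "protein" or "dna"
#' @param gapOpening,gapExtension affine gap penalties (non-negative)
#' @return a \code{PairwiseAlignments} object
#' @export
globalAlign <- function(a, b, type = c("protein", "dna"),
                        gapOpening = 11, gapExtension = 1) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) .stopf("globalAlign requires non-empty sequences")
  if (type == "protein") {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
      substitutionMatrix = "BLOSUM62", gapOpening = gapOpening,
      gapExtension = gapExtension, type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
      substitutionMatrix = mat, gapOpening = gapOpening,
      gapExtension = gapExtension, type = "global")
  }
}

#' Percent identity of an alignment
#'
#' 100 x identical columns / denominator. The default denominator is the
#' number of aligned columns excluding terminal gap overhangs; this
#' convention is stated in every report header because published identity
#' values are only comparable under a declared denominator.
#'
#' @param alignment a \code{PairwiseAlignments} (from \code{\link{globalAlign}})
#'   or a list(pattern, subject) of equal-length aligned strings
#' @return percent identity in [0, 100]
#' @export
percentIdentity <- function(alignment) {
  if (methods::is(alignment, "PairwiseAlignments"))
    return(.alignedIdentity(alignment)$identity)
  p <- .chars(alignment$pattern); s <- .chars(alignment$subject)
  if (length(p) != length(s)) .stopf("aligned strings differ in length")
  .alignedIdentityChars(p, s)
}

#' @keywords internal
.alignedIdentityChars <- function(p, s) {
  cols <- .nonOverhangColumns(p, s)
  100 * sum(p[cols] == s[cols] & p[cols] != "-") / length(cols)
}

#' All pairwise percent identities of a sequence set
#'
#' @param seqs named character vector of sequences
#' @param align align each pair globally (TRUE) or compare position-wise
#'   (requires equal lengths; the natural mode for simulated, indel-free sets)
#' @param type passed to \code{\link{globalAlign}}
#' @return symmetric matrix of percent identities (diagonal 100)
#' @export
pairwiseIdentityMatrix <- function(seqs, align = TRUE, type = "protein") {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pid <- if (align)
      percentIdentity(globalAlign(seqs[[i]], seqs[[j]], type = type))
    else {
      a <- .chars(seqs[[i]]); b <- .chars(seqs[[j]])
      if (length(a) != length(b)) .stopf("unequal lengths; use align = TRUE")
      100 * mean(a == b)
    }
    m[i, j] <- m[j, i] <- pid
  }
  m
}

#' Excise the endonuclease region, keeping only the splicing domains
#'
#' Removes the region between the end of block B and the start of block F
#' from the intein sequence (N-terminal splicing domain + C-terminal
#' splicing region concatenated) — the mode used to compare HEN-less inteins
#' with HEN-bearing relatives.
#'
#' @param call an \code{\linkS4class{InteinCall}} with blocks B and F located
#' @param inteinSeq the intein sequence (coordinates as in the call)
#' @return amino-acid string
#' @export
exciseSplicingDomain <- function(call, inteinSeq) {
  b <- call@blocks[call@blocks$block == "B", ]
  f <- call@blocks[call@blocks$block == "F", ]
  if (nrow(b) == 0 || nrow(f) == 0) .stopf("call lacks located blocks B and F")
  # block coordinates are on the host protein; shift into intein coordinates
  off <- call@start - 1L
  bEnd <- b$end - off
  fStart <- f$start - off
  paste0(substr(inteinSeq, 1, bEnd), substr(inteinSeq, fStart, nchar(inteinSeq)))
}

#' Flag horizontal-transfer candidate pairs by identity
#'
#' Typical unrelated inteins share at most ~30\% identity; pairs above the
#' threshold (default 35\%) are flagged as transfer candidates. The default
#' separates reported background-consistent values (~31\%) from
#' transfer-suggestive ones (~40-55\%).
#'
#' @param identities symmetric percent-identity matrix or a data.frame with
#'   columns id_a, id_b, percent_identity
#' @param threshold flagging threshold (percent)
#' @return data.frame: id_a, id_b, percent_identity, threshold, flagged
#' @export
flagTransferCandidates <- function(identities, threshold = 35) {
  if (is.matrix(identities)) {
    nm <- rownames(identities)
    idx <- which(upper.tri(identities), arr.ind = TRUE)
    identities <- data.frame(id_a = nm[idx[, 1]], id_b = nm[idx[, 2]],
                             percent_identity = identities[idx],
                             stringsAsFactors = FALSE)
  }
  if (nrow(identities) == 0)
    return(data.frame(id_a = character(0), id_b = character(0),
                      percent_identity = numeric(0), threshold = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  identities$threshold <- threshold
  identities$flagged <- identities$percent_identity > threshold
  identities
}

#' Poisson-corrected distance matrix from sequences
#'
#' p-distance (fraction of differing positions, equal-length sets) with
#' Poisson correction \eqn{d = -\ln(1 - p)}; p is capped just below 1.
#' @param seqs named character vector of equal-length sequences
#' @return symmetric distance matrix
#' @export
poissonDistances <- function(seqs) {
  idm <- pairwiseIdentityMatrix(seqs, align = FALSE)
  p <- pmin(1 - idm / 100, 0.95)
  d <- -log(1 - p)
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' \code{ape::nj} on a validated symmetric matrix; negative branch lengths
#' are clamped to 0 with a warning.
#' @param distances symmetric matrix with zero diagonal, >= 3 taxa
#' @return an \code{ape::phylo} tree (unrooted)
#' @export
njTree <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    .stopf("distances must be a square matrix")
  if (nrow(distances) < 3) .stopf("need >= 3 taxa")
  if (max(abs(distances - t(distances))) > 1e-9)
    .stopf("asymmetric distance matrix")
  tr <- ape::nj(stats::as.dist(distances))
  if (any(tr$edge.length < 0)) {
    .warnf("clamping %d negative NJ branch length(s) to 0",
           sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Count of bipartitions present in exactly one tree (same taxon sets
#' required). Delegates to \code{phangorn::RF.dist}.
#' @param t1,t2 \code{phylo} trees or Newick strings
#' @return integer RF distance
#' @export
rfDistance <- function(t1, t2) {
  if (is.character(t1)) t1 <- ape::read.tree(text = t1)
  if (is.character(t2)) t2 <- ape::read.tree(text = t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    .stopf("taxon sets differ between trees")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Is a taxon set an unrooted cluster of a tree?
#'
#' TRUE iff some edge's removal separates exactly the focal taxa from the
#' rest (pendant edges included, so singletons and (n-1)-sets are trivially
#' monophyletic).
#' @param tree a \code{phylo}
#' @param taxa character vector of tip labels
#' @export
isMonophyleticUnrooted <- function(tree, taxa) {
  tips <- tree$tip.label
  if (!all(taxa %in% tips)) .stopf("taxa not in tree: %s",
                                   paste(setdiff(taxa, tips), collapse = ", "))
  k <- length(taxa)
  if (k <= 1 || k >= length(tips) - 1) return(TRUE)
  parts <- ape::prop.part(tree)
  for (cl in parts) {
    set <- tips[cl]
    if (setequal(set, taxa) || setequal(setdiff(tips, set), taxa)) return(TRUE)
  }
  FALSE
}

#' Detect intein/extein tree incongruence for a focal taxon set
#'
#' The focal taxa (e.g. a putative donor/recipient pair) are tested for
#' monophyly, as an unrooted cluster, in the intein tree and in the extein
#' tree. Incongruent iff they are monophyletic (grouped with each other,
#' apart from the outgroup taxa) in exactly one tree; monophyletic in
#' neither tree is reported as "no signal".
#'
#' @param inteinTree,exteinTree \code{phylo} trees over the same taxa
#' @param focalTaxa character vector, >= 2 tip labels
#' @return list(incongruent, monophyletic_intein, monophyletic_extein, signal)
#' @export
detectIncongruence <- function(inteinTree, exteinTree, focalTaxa) {
  if (length(focalTaxa) < 2) .stopf("need >= 2 focal taxa")
  mi <- isMonophyleticUnrooted(inteinTree, focalTaxa)
  me <- isMonophyleticUnrooted(exteinTree, focalTaxa)
  list(incongruent = xor(mi, me),
       monophyletic_intein = mi,
       monophyletic_extein = me,
       signal = if (!mi && !me) "no signal" else if (xor(mi, me))
         "incongruent" else "congruent")
}
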