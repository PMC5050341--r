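# Synthetic phage-survey generator with ground truth: extein families with
# motifs, planted class 1/3 inteins with controllable divergence and HEN
# content, multi-cluster genome sets, and HGT scenarios.

# most-common-codon reverse translation map (genetic code 11)
.CODON_OF <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
               G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
               M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGC",
               S = "TCC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

#' Reverse-translate a protein with the most common codon per residue
#' @param protein amino-acid string
#' @param stop append a TAA stop codon
#' @return DNA string
#' @export
reverseTranslate <- function(protein, stop = TRUE) {
  ch <- .chars(protein)
  bad <- setdiff(unique(ch), names(.CODON_OF))
  if (length(bad)) .stopf("cannot reverse-translate residue(s): %s",
                          paste(bad, collapse = ""))
  paste0(paste(.CODON_OF[ch], collapse = ""), if (stop) "TAA" else "")
}

#' Survey simulation configuration
#'
#' Defaults are the package's fixed study conditions: a small survey
#' contrasting an intein-rich cluster (60 genomes at rate 0.9) with an
#' intein-poor one (140 genomes at rate 0.05); planted inteins diverge 0.15
#' substitutions/site from the block consensus outside key positions, host
#' exteins 0.05 from their reference; 30\% of inteins are class 3; half of
#' all inteins carry a HEN; class 1 penultimate residues are drawn
#' H/G/K/S at 0.5/0.25/0.15/0.1.
#'
#' @param seed integer RNG seed (all randomness flows from it)
#' @param clusters named integer vector: genomes per cluster
#' @param inteinRate named numeric vector: per-cluster probability that a
#'   genome carries one intein
#' @param classMix fraction of planted inteins that are class 3
#' @param henFraction fraction of planted inteins carrying a HEN
#' @param divergence intein substitutions/site from block consensus, in [0, 0.5]
#' @param exteinDivergence host extein substitutions/site from the reference
#' @param penultimateMix named probabilities of class 1 penultimate residues
#' @param genesPerGenome protein-coding genes per genome
#' @param spacerLen intergenic spacer length (nt)
#' @return a list of class "simConfig"
#' @export
simConfig <- function(seed = 1L,
                      clusters = c(C = 60L, B = 140L),
                      inteinRate = c(C = 0.9, B = 0.05),
                      classMix = 0.3,
                      henFraction = 0.5,
                      divergence = 0.15,
                      exteinDivergence = 0.05,
                      penultimateMix = c(H = 0.5, G = 0.25, K = 0.15, S = 0.1),
                      genesPerGenome = 4L,
                      spacerLen = 60L) {
  stopifnot(all(names(clusters) == names(inteinRate)),
            all(inteinRate >= 0 & inteinRate <= 1),
            divergence >= 0, divergence <= 0.5,
            classMix >= 0, classMix <= 1,
            henFraction >= 0, henFraction <= 1,
            abs(sum(penultimateMix) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), clusters = clusters,
                 inteinRate = inteinRate, classMix = classMix,
                 henFraction = henFraction, divergence = divergence,
                 exteinDivergence = exteinDivergence,
                 penultimateMix = penultimateMix,
                 genesPerGenome = as.integer(genesPerGenome),
                 spacerLen = as.integer(spacerLen)),
            class = "simConfig")
}

#' Simulate a diverged extein from a reference family
#'
#' Per-site substitution with the given probability, replacements uniform
#' over the 19 alternatives. With \code{freezeMotifs} (default) the motif
#' intervals, the designated insertion-site +1 nucleophiles, and the leading
#' Met (the ORF start) are protected from substitution.
#'
#' @param reference one element of \code{\link{referenceExteins}}
#' @param divergence substitution probability per site, in [0, 0.5]
#' @param freezeMotifs protect motif intervals and site nucleophiles
#' @return amino-acid string
#' @export
simulateExtein <- function(reference, divergence, freezeMotifs = TRUE) {
  if (divergence < 0 || divergence > 0.5) .stopf("divergence must be in [0, 0.5]")
  protect <- integer(0)
  if (freezeMotifs) {
    m <- reference$motifs
    if (nrow(m))
      protect <- unlist(lapply(seq_len(nrow(m)), function(i) m$start[i]:m$end[i]))
    protect <- c(protect, 1L, reference$sites$ref_column + 1L)
  }
  .mutateAA(reference$seq, divergence, protect = unique(protect))
}

# fixed architecture linkers (residues between consecutive blocks)
.LINKERS <- list(A_B = 60L, B_F_mini = 15L,
                 hen = c(pre = 15L, C_D = 10L, D_E = 12L, E_H = 10L, post = 15L),
                 F_G = 20L)

#' Construct a synthetic intein with exact key residues
#'
#' Concatenates the block consensus sequences (from the packaged seeds) with
#' random linkers following the package's spacing defaults, applies the
#' requested divergence outside key positions, then sets the key positions
#' exactly: class 1 gets a Cys nucleophile at position 1; class 3 gets a
#' non-nucleophilic position 1 and the WCT triplet at B12/F4/G5; both end
#' in (penultimate, Asn). A HEN-bearing intein embeds the C/D/E/H LAGLIDADG
#' block consensus between B and F; otherwise the B-F linker is short
#' (mini-intein).
#'
#' @param inteinClass "class1" or "class3"
#' @param hen embed a homing endonuclease
#' @param penultimate residue at block G column 6
#' @param divergence substitutions/site outside key positions
#' @param models optional cached \code{\link{inteinBlockModels}} seed consensus
#' @return list(seq, blocks (data.frame block/start/end in intein
#'   coordinates), class, hen, penultimate)
#' @export
buildIntein <- function(inteinClass = c("class1", "class3"), hen = TRUE,
                        penultimate = "H", divergence = 0.15,
                        models = NULL) {
  inteinClass <- match.arg(inteinClass)
  cons <- .blockConsensusSet()
  lk <- .LINKERS
  parts <- list(); blocks <- list(); pos <- 0L
  addBlock <- function(name, seq) {
    parts[[length(parts) + 1L]] <<- seq
    blocks[[length(blocks) + 1L]] <<- data.frame(
      block = name, start = pos + 1L, end = pos + nchar(seq),
      stringsAsFactors = FALSE)
    pos <<- pos + nchar(seq)
  }
  addLinker <- function(n) {
    parts[[length(parts) + 1L]] <<- .randomAA(n)
    pos <<- pos + n
  }
  addBlock("A", cons[["A"]])
  addLinker(lk$A_B)
  addBlock("B", cons[["B"]])
  if (hen) {
    addLinker(lk$hen[["pre"]])
    addBlock("C", cons[["C"]])
    addLinker(lk$hen[["C_D"]])
    addBlock("D", cons[["D"]])
    addLinker(lk$hen[["D_E"]])
    addBlock("E", cons[["E"]])
    addLinker(lk$hen[["E_H"]])
    addBlock("H", cons[["H"]])
    addLinker(lk$hen[["post"]])
  } else {
    addLinker(lk$B_F_mini)
  }
  addBlock("F", cons[["F"]])
  addLinker(lk$F_G)
  # block G contributes columns 1-7 to the intein; column 8 (+1) is extein
  addBlock("G", substr(cons[["G"]], 1, 7))

  seq <- paste(unlist(parts), collapse = "")
  blocks <- do.call(rbind, blocks)
  bStart <- function(b) blocks$start[blocks$block == b]
  keyPos <- c(a1 = 1L,
              b12 = bStart("B") + 11L,
              f4 = bStart("F") + 3L,
              g5 = bStart("G") + 4L,
              penult = bStart("G") + 5L,
              terminal = bStart("G") + 6L)
  seq <- .mutateAA(seq, divergence, protect = keyPos)
  ch <- .chars(seq)
  if (inteinClass == "class1") {
    ch[keyPos[["a1"]]] <- "C"
    ch[keyPos[["b12"]]] <- "G"
    ch[keyPos[["f4"]]] <- "V"
    ch[keyPos[["g5"]]] <- "T"
  } else {
    ch[keyPos[["a1"]]] <- "A"
    ch[keyPos[["b12"]]] <- "W"
    ch[keyPos[["f4"]]] <- "C"
    ch[keyPos[["g5"]]] <- "T"
  }
  ch[keyPos[["penult"]]] <- penultimate
  ch[keyPos[["terminal"]]] <- "N"
  list(seq = paste(ch, collapse = ""), blocks = blocks,
       class = inteinClass, hen = hen, penultimate = penultimate)
}

# consensus (majority residue per column) of each packaged seed alignment,
# cached per session
.blockConsensusSet <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    out <- lapply(c("A", "B", "F", "G", "C", "D", "E", "H"), function(b) {
      mat <- do.call(rbind, lapply(seedAlignment(b), .chars))
      paste(apply(mat, 2, function(col) {
        col <- col[col %in% AA20]
        names(sort(table(col), decreasing = TRUE))[1]
      }), collapse = "")
    })
    cache <<- stats::setNames(out, c("A", "B", "F", "G", "C", "D", "E", "H"))
    cache
  }
})

#' Plant an intein into an extein at a reference column
#'
#' The intein is inserted after extein position \code{refColumn}; the extein
#' residue at \code{refColumn + 1} becomes the +1 nucleophile and must be
#' Cys/Ser/Thr for class 1 planting, Cys for class 3.
#'
#' @param exteinSeq host extein amino-acid string
#' @param refColumn 1-based position of the last N-extein residue
#' @param intein result of \code{\link{buildIntein}}
#' @return list(precursor, start, end) with 1-based inclusive intein
#'   boundaries in the precursor
#' @export
plantIntein <- function(exteinSeq, refColumn, intein) {
  L <- nchar(exteinSeq)
  if (refColumn < 1 || refColumn >= L)
    .stopf("refColumn must lie strictly inside the extein")
  plusOne <- substr(exteinSeq, refColumn + 1L, refColumn + 1L)
  okSet <- if (intein$class == "class3") "C" else c("C", "S", "T")
  if (!plusOne %in% okSet)
    .stopf("+1 residue '%s' is not an allowed nucleophile for %s planting",
           plusOne, intein$class)
  precursor <- paste0(substr(exteinSeq, 1, refColumn), intein$seq,
                      substr(exteinSeq, refColumn + 1L, L))
  list(precursor = precursor, start = refColumn + 1L,
       end = refColumn + nchar(intein$seq))
}

#' Simulate a multi-cluster phage survey with planted inteins
#'
#' Each genome carries \code{genesPerGenome} protein-coding genes drawn from
#' the reference extein families, diverged by \code{exteinDivergence}; with
#' the cluster's intein rate, one gene receives a planted intein. Proteins
#' are reverse-translated (most common codon, genetic code 11) and embedded
#' in random intergenic spacers on the forward strand. Identical
#' configurations (including seed) give byte-identical output.
#'
#' @param config a \code{\link{simConfig}}
#' @return list(genomes, proteins, manifest, truth, config): named character
#'   vectors of genome DNA and precursor proteins; the survey manifest with
#'   true intein_count; and the truth manifest (one row per planted intein:
#'   genome_id, protein_id, family, ref_column, class, hen, penultimate,
#'   start, end, intein_seq)
#' @export
simulateSurvey <- function(config = simConfig()) {
  set.seed(config$seed)
  refs <- referenceExteins()
  genomes <- character(0); proteins <- character(0)
  manifest <- list(); truth <- list()
  for (cl in names(config$clusters)) {
    for (g in seq_len(config$clusters[[cl]])) {
      gid <- sprintf("%s_phage%03d", cl, g)
      fams <- sample(names(refs), config$genesPerGenome)
      prots <- vapply(fams, function(f)
        simulateExtein(refs[[f]], config$exteinDivergence), character(1))
      nIntein <- 0L
      if (stats::runif(1) < config$inteinRate[[cl]]) {
        cls <- if (stats::runif(1) < config$classMix) "class3" else "class1"
        siteOk <- function(f) {
          p1 <- refs[[f]]$sites$plus_one
          if (cls == "class3") p1 == "C" else p1 %in% c("C", "S", "T")
        }
        compat <- which(vapply(fams, function(f) any(siteOk(f)), logical(1)))
        if (length(compat) == 0) {  # no class 3 compatible (+1 Cys) gene drawn
          cls <- "class1"
          compat <- seq_along(fams)
        }
        gi <- compat[sample.int(length(compat), 1)]
        fam <- fams[gi]
        ok <- which(siteOk(fam))
        site <- refs[[fam]]$sites$ref_column[ok[sample.int(length(ok), 1)]]
        pen <- if (cls == "class3") "H" else
          sample(names(config$penultimateMix), 1, prob = config$penultimateMix)
        hen <- stats::runif(1) < config$henFraction
        it <- buildIntein(cls, hen = hen, penultimate = pen,
                          divergence = config$divergence)
        pl <- plantIntein(prots[gi], site, it)
        prots[gi] <- pl$precursor
        nIntein <- 1L
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = gid, protein_id = sprintf("%s_g%d", gid, gi),
          family = fam, ref_column = site, class = cls, hen = hen,
          penultimate = pen, start = pl$start, end = pl$end,
          intein_seq = it$seq, stringsAsFactors = FALSE)
      }
      names(prots) <- sprintf("%s_g%d", gid, seq_along(prots))
      proteins <- c(proteins, prots)
      dna <- vapply(prots, reverseTranslate, character(1))
      spacers <- vapply(seq_len(length(dna) + 1L), function(i)
        paste(sample(c("A", "C", "G", "T"), config$spacerLen, replace = TRUE),
              collapse = ""), character(1))
      genome <- paste0(spacers[1],
                       paste0(dna, spacers[-1], collapse = ""))
      genomes[[gid]] <- genome
      manifest[[length(manifest) + 1L]] <- data.frame(
        genome_id = gid, cluster = cl, genome_length_bp = nchar(genome),
        cds_count = config$genesPerGenome, intein_count = nIntein,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome_id = character(0), protein_id = character(0),
               family = character(0), ref_column = integer(0),
               class = character(0), hen = logical(0),
               penultimate = character(0), start = integer(0),
               end = integer(0), intein_seq = character(0),
               stringsAsFactors = FALSE)
  list(genomes = genomes, proteins = proteins,
       manifest = do.call(rbind, manifest), truth = truth, config = config)
}

#' Simulate an intein/extein pair of alignments with an optional HGT event
#'
#' Exteins evolve along one fixed random tree (per-edge substitution
#' probability \eqn{1 - e^{-\ell}}, JC-like uniform replacement); inteins
#' evolve along the same tree, except that with \code{transfer} the
#' recipient lineage's intein is replaced by a copy of the donor's intein
#' diverged by \code{eventDivergence}. Donor and recipient are the most
#' distant tip pair on the tree, so the transfer signal is maximally
#' discordant with the extein history.
#'
#' @param seed RNG seed
#' @param nTaxa number of tips (>= 6)
#' @param transfer simulate one recent transfer event (else a no-transfer
#'   control)
#' @param exteinLen,inteinLen sequence lengths (intein defaults to a
#'   HEN-less splicing-domain construct from \code{\link{buildIntein}})
#' @param depth mean root-to-tip path length (substitutions/site)
#' @param eventDivergence divergence of the transferred intein copy
#' @return list(exteins, inteins, donor, recipient, transfer, tree)
#' @export
simulateHgt <- function(seed = 1L, nTaxa = 8L, transfer = TRUE,
                        exteinLen = 300L, inteinLen = NULL, depth = 0.75,
                        eventDivergence = 0.05) {
  if (nTaxa < 6) .stopf("need >= 6 taxa")
  set.seed(seed)
  tree <- ape::rtree(nTaxa)
  tipDepths <- ape::node.depth.edgelength(tree)[seq_len(nTaxa)]
  tree$edge.length <- tree$edge.length * depth / mean(tipDepths)
  rootExtein <- .randomAA(exteinLen)
  rootIntein <- buildIntein("class3", hen = FALSE, penultimate = "H",
                            divergence = 0)$seq
  if (!is.null(inteinLen)) rootIntein <- substr(rootIntein, 1, inteinLen)
  exteins <- .evolveAlongTree(tree, rootExtein)
  inteins <- .evolveAlongTree(tree, rootIntein)
  coph <- ape::cophenetic.phylo(tree)
  idx <- which(coph == max(coph), arr.ind = TRUE)[1, ]
  donor <- rownames(coph)[idx[1]]
  recipient <- colnames(coph)[idx[2]]
  if (transfer)
    inteins[[recipient]] <- .mutateAA(inteins[[donor]], eventDivergence)
  list(exteins = exteins, inteins = inteins, donor = donor,
       recipient = recipient, transfer = transfer, tree = tree)
}

#' Evolve a root sequence along a tree, returning tip sequences
#' @keywords internal
.evolveAlongTree <- function(tree, rootSeq) {
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  seqs <- vector("list", nTip + tree$Nnode)
  seqs[[root]] <- rootSeq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    p <- 1 - exp(-ord$edge.length[k])
    seqs[[child]] <- .mutateAA(seqs[[par]], p)
  }
  stats::setNames(unlist(seqs[seq_len(nTip)]), tree$tip.label)
}

#' Analyze an HGT simulation: trees, incongruence, identity flag
#'
#' Builds neighbor-joining trees from Poisson-corrected distances for the
#' intein and extein sets, tests donor/recipient monophyly in both, and
#' flags the pair when its intein identity exceeds the transfer threshold.
#' The transfer verdict requires both lines of evidence (identity above
#' threshold and tree incongruence).
#'
#' @param sim result of \code{\link{simulateHgt}}
#' @param threshold percent-identity transfer threshold (default 35)
#' @return list(intein_tree, extein_tree, incongruence, identity, flagged,
#'   transfer_detected)
#' @export
hgtAnalyze <- function(sim, threshold = 35) {
  it <- njTree(poissonDistances(sim$inteins))
  et <- njTree(poissonDistances(sim$exteins))
  inc <- detectIncongruence(it, et, c(sim$donor, sim$recipient))
  a <- .chars(sim$inteins[[sim$donor]]); b <- .chars(sim$inteins[[sim$recipient]])
  pid <- 100 * mean(a == b)
  flagged <- pid > threshold
  list(intein_tree = it, extein_tree = et, incongruence = inc,
       identity = pid, flagged = flagged,
       transfer_detected = flagged && inc$incongruent)
}
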