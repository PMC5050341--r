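# Insertion-site classification in reference-extein coordinates, functional
# motif context, and extein functional-category tallies.

#' Load the packaged reference extein families
#'
#' Twelve synthetic reference extein families (TerL1, TerL6, Pham3880, RecB,
#' RDF, TOPRIM, NT, DNMT1, DNMT2, PORT, HEL, TdS) with functional-motif
#' intervals (Walker A/B, C-motif, PD-(D/E)xK, metallophosphoesterase,
#' active sites). The sequences are synthetic stand-ins that encode the
#' qualitative motif layout of terminase-like and related phage proteins;
#' they make no residue-level claim about any real phage. Motif intervals are
#' 1-based inclusive; the planting-site registry lists, per family, the
#' reference columns where the generator may insert an intein (each followed
#' by a +1 nucleophile).
#'
#' @return named list; each element has fields family, seq, motifs
#'   (data.frame label/start/end) and sites (data.frame ref_column/plus_one)
#' @export
referenceExteins <- function() {
  fa <- readFastaRecords(.extdata("ref_exteins_synthetic.fasta"))
  motifs <- utils::read.delim(.extdata("ref_extein_motifs.tsv"),
                              stringsAsFactors = FALSE)
  sites <- utils::read.delim(.extdata("ref_extein_sites.tsv"),
                             stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(fa)), function(i) {
    fam <- fa$id[i]
    m <- motifs[motifs$family == fam, c("label", "start", "end"), drop = FALSE]
    rownames(m) <- NULL
    st <- sites[sites$family == fam, c("ref_column", "plus_one"), drop = FALSE]
    rownames(st) <- NULL
    list(family = fam, seq = fa$seq[i], motifs = m, sites = st)
  })
  stats::setNames(out, fa$id)
}

#' Static extein family -> functional category mapping
#'
#' A packaged, editable table standing in for live GO/InterPro annotation;
#' one family may carry several categories.
#' @return data.frame: family, category
#' @export
exteinCategoryMap <- function() {
  utils::read.delim(.extdata("extein_categories.tsv"), stringsAsFactors = FALSE)
}

#' Aligned identity with terminal overhangs excluded from the denominator
#' @keywords internal
.alignedIdentity <- function(pa) {
  p <- .chars(as.character(Biostrings::alignedPattern(pa)))
  s <- .chars(as.character(Biostrings::alignedSubject(pa)))
  cols <- .nonOverhangColumns(p, s)
  ident <- sum(p[cols] == s[cols] & p[cols] != "-")
  list(identity = 100 * ident / length(cols), columns = length(cols),
       pattern = p, subject = s)
}

#' Columns outside terminal gap overhangs (a gap run anchored at either
#' terminus in either sequence)
#' @keywords internal
.nonOverhangColumns <- function(p, s) {
  n <- length(p)
  lead <- 0L
  while (lead < n && (p[lead + 1L] == "-" || s[lead + 1L] == "-") &&
         (all(p[seq_len(lead + 1L)] == "-") || all(s[seq_len(lead + 1L)] == "-")))
    lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead &&
         (all(p[(n - trail):n] == "-") || all(s[(n - trail):n] == "-")))
    trail <- trail + 1L
  seq.int(lead + 1L, n - trail)
}

#' Map an intein insertion site into reference-extein coordinates
#'
#' The inteinless host protein (intein excised) is globally aligned to the
#' reference (BLOSUM62, affine gaps); the site is the reference column
#' aligned to the last N-extein residue, i.e. the residue immediately
#' preceding the insertion. The motif context is the motif interval
#' containing that column, else "none". Padding the host protein upstream
#' does not change the mapped column.
#'
#' @param call an \code{\linkS4class{InteinCall}}
#' @param hostProtein the intact host protein sequence (with intein)
#' @param reference one element of \code{\link{referenceExteins}}
#' @param identityFloor minimum percent identity to accept the family (25)
#' @param minColumns minimum aligned columns (50)
#' @param gapOpening,gapExtension affine gap penalties
#' @return list(family, ref_column, motif_context, identity, columns)
#' @export
mapInsertion <- function(call, hostProtein, reference,
                         identityFloor = 25, minColumns = 50,
                         gapOpening = 11, gapExtension = 1) {
  if (is.data.frame(hostProtein)) hostProtein <- hostProtein$seq
  sp <- spliceIntein(hostProtein, call)
  inteinless <- sp$exteins
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(inteinless), Biostrings::AAString(reference$seq),
    substitutionMatrix = "BLOSUM62", gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  ai <- .alignedIdentity(pa)
  if (ai$columns < minColumns || ai$identity < identityFloor)
    .stopf("unassignable family: best identity %.1f%% over %d columns (floor %s%%/%d)",
           ai$identity, ai$columns, identityFloor, minColumns)
  lastN <- call@start - 1L          # last N-extein residue in the inteinless protein
  refCol <- .patternToSubject(ai$pattern, ai$subject, lastN)
  motif <- "none"
  m <- reference$motifs
  if (nrow(m)) {
    hitM <- which(m$start <= refCol & refCol <= m$end)
    if (length(hitM)) motif <- m$label[hitM[1]]
  }
  list(family = reference$family, ref_column = refCol, motif_context = motif,
       identity = ai$identity, columns = ai$columns)
}

#' Map a pattern residue index to the subject residue index it aligns to
#' (or the last subject residue seen before it, if aligned to a gap).
#' @keywords internal
.patternToSubject <- function(p, s, patternPos) {
  pi <- 0L; si <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (s[k] != "-") si <- si + 1L
    if (pi == patternPos && p[k] != "-") return(si)
  }
  si
}

#' Pick the best-matching reference family for an inteinless extein
#'
#' @param inteinless extein sequence with the intein excised
#' @param references list from \code{\link{referenceExteins}}
#' @param identityFloor,minColumns acceptance thresholds
#' @return list(family, identity) of the best hit at or above the floor
#' @export
assignFamily <- function(inteinless, references, identityFloor = 25,
                         minColumns = 50) {
  best <- list(family = NA_character_, identity = -Inf)
  for (ref in references) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(inteinless), Biostrings::AAString(ref$seq),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global")
    ai <- .alignedIdentity(pa)
    if (ai$identity > best$identity && ai$columns >= minColumns)
      best <- list(family = ref$family, identity = ai$identity)
  }
  if (!is.finite(best$identity) || best$identity < identityFloor)
    .stopf("unassignable family: best identity %.1f%%", best$identity)
  best
}

#' Assign per-family insertion-site letters
#'
#' Within each family, distinct reference columns sorted ascending receive
#' letters a, b, c, ... — deterministic across runs. Two calls share a letter
#' iff they share family and reference column (tolerance 0: sites one residue
#' apart are distinct).
#'
#' @param sites data.frame with columns family, ref_column
#' @return the input with a \code{label} column added
#' @export
assignSiteLabels <- function(sites) {
  if (nrow(sites) == 0) { sites$label <- character(0); return(sites) }
  sites$label <- NA_character_
  for (fam in unique(sites$family)) {
    i <- which(sites$family == fam)
    cols <- sort(unique(sites$ref_column[i]))
    sites$label[i] <- letters[match(sites$ref_column[i], cols)]
  }
  sites
}

#' Tally extein functional categories
#'
#' For each category, the percentage of intein-containing proteins annotated
#' with it; multi-label families make percentages sum above 100. Families
#' absent from the mapping are tallied as "unmapped".
#'
#' @param families character vector, one family per intein-containing protein
#' @param mapping data.frame family/category (default packaged table)
#' @return data.frame: category, n, percent
#' @export
categorizeExteins <- function(families, mapping = exteinCategoryMap()) {
  if (length(families) == 0)
    return(data.frame(category = character(0), n = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  nTot <- length(families)
  cats <- unique(mapping$category)
  rows <- lapply(cats, function(cat) {
    fams <- mapping$family[mapping$category == cat]
    n <- sum(families %in% fams)
    data.frame(category = cat, n = n, percent = 100 * n / nTot,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  unmapped <- sum(!families %in% mapping$family)
  if (unmapped > 0)
    res <- rbind(res, data.frame(category = "unmapped", n = unmapped,
                                 percent = 100 * unmapped / nTot,
                                 stringsAsFactors = FALSE))
  res[res$n > 0 | res$category == "unmapped", , drop = FALSE]
}
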