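#' Read a FASTA file into sequence records
#'
#' Wraps \code{Biostrings::readBStringSet} and enforces the package's record
#' conventions: the id is the first whitespace-delimited token of the header,
#' the remainder is the description, ids must be unique within a file, and the
#' file must contain at least one record. Sequences keep their case on read
#' and are compared case-insensitively downstream.
#'
#' @param path path to a FASTA file (wrapped or unwrapped)
#' @param alphabet "auto" (default), "dna" or "protein"
#' @return a data.frame with columns id, description, seq, alphabet
#' @export
readFastaRecords <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) .stopf("not FASTA-formatted: %s (%s)",
                                             path, conditionMessage(e)))
  if (length(set) == 0) .stopf("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate id in %s: %s", path, dup[1])
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) .stopf("empty sequence for id %s", ids[!nzchar(seqs)][1])
  alpha <- vapply(seqs, function(s) .guessAlphabet(s, alphabet), character(1),
                  USE.NAMES = FALSE)
  data.frame(id = ids, description = desc, seq = unname(seqs),
             alphabet = alpha, stringsAsFactors = FALSE)
}

#' @keywords internal
.guessAlphabet <- function(s, alphabet) {
  ch <- unique(.chars(s))
  if (alphabet == "dna" || (alphabet == "auto" && all(ch %in% .DNA_CHARS))) {
    if (!all(ch %in% .DNA_CHARS))
      .stopf("non-IUPAC DNA characters: %s", paste(setdiff(ch, .DNA_CHARS), collapse = ""))
    "dna"
  } else {
    if (!all(ch %in% .AA_CHARS))
      .stopf("non-IUPAC protein characters: %s", paste(setdiff(ch, .AA_CHARS), collapse = ""))
    "protein"
  }
}

#' Write named sequences to a FASTA file
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line wrap width
#' @export
writeFastaRecords <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a DNA string with genetic code 11
#'
#' Standard bacterial/plastid code (translation table 11). Codons containing
#' ambiguity characters translate to the residue they unambiguously encode
#' when possible, otherwise to \code{X}.
#'
#' @param dna a DNA string whose length is divisible by 3
#' @return amino-acid string (stops as \code{*})
#' @export
translateDna <- function(dna) {
  if (nchar(dna) %% 3 != 0)
    .stopf("sequence length (%d) not divisible by 3", nchar(dna))
  if (nchar(dna) == 0) return("")
  aa <- Biostrings::translate(Biostrings::DNAString(toupper(dna)),
                              genetic.code = Biostrings::getGeneticCode("11"),
                              if.fuzzy.codon = "solve", no.init.codon = TRUE)
  as.character(aa)
}

# plain-codon lookup for fast in-frame translation (genetic code 11);
# ambiguous codons fall back to X via the vectorized path in findOrfs
.GC11 <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::getGeneticCode("11")
    gc
  }
})

#' Find open reading frames on both strands
#'
#' Every start codon (default ATG/GTG/TTG, the common mycobacteriophage
#' annotation set) paired with its next in-frame stop yields an ORF, so
#' nested ORFs sharing a stop are all reported. ORFs lacking an in-frame stop
#' before the sequence end are dropped unless \code{allowOpenEnded}.
#' Reverse-strand ORFs are reported in forward-strand coordinates
#' (1-based inclusive, \code{end >= start}).
#'
#' @param genome a single DNA sequence (character) or one row of
#'   \code{readFastaRecords} output
#' @param minAa minimum protein length (stop excluded)
#' @param startCodons character vector of start codons
#' @param allowOpenEnded keep ORFs running off the sequence end
#' @param genomeId id recorded in the output
#' @return data.frame: genome_id, start, end, strand, frame, protein;
#'   sorted by start
#' @export
findOrfs <- function(genome, minAa = 50,
                     startCodons = c("ATG", "GTG", "TTG"),
                     allowOpenEnded = FALSE, genomeId = "genome") {
  if (is.data.frame(genome)) {
    if (nrow(genome) != 1) .stopf("findOrfs expects a single genome record")
    if (genome$alphabet != "dna") .stopf("findOrfs requires a DNA sequence")
    genomeId <- genome$id
    genome <- genome$seq
  }
  s <- toupper(genome)
  if (!all(unique(.chars(s)) %in% .DNA_CHARS))
    .stopf("findOrfs requires a DNA sequence")
  if (minAa < 1) .stopf("minAa must be >= 1")
  L <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (frame in 0:2) {
      npos <- seq(1 + frame, L - 2, by = 3)
      if (length(npos) == 0) next
      codons <- substring(str, npos, npos + 2)
      aa <- unname(.GC11()[codons])
      aa[is.na(aa)] <- "X"        # ambiguous codons
      isStop <- codons %in% stops
      isStart <- codons %in% startCodons
      stopIdx <- which(isStop)
      for (i in which(isStart)) {
        nxt <- stopIdx[stopIdx > i]
        if (length(nxt) == 0) {
          if (!allowOpenEnded) next else j <- length(codons) + 1L
        } else j <- nxt[1]
        nAa <- j - i               # protein length, stop excluded
        if (nAa < minAa) next
        e <- if (j <= length(codons)) npos[j] + 2L else npos[length(codons)] + 2L
        b <- npos[i]
        prot <- paste(aa[i:(j - 1L)], collapse = "")
        if (strand == "-") { fb <- L - e + 1L; fe <- L - b + 1L } else { fb <- b; fe <- e }
        out[[length(out) + 1L]] <- data.frame(
          genome_id = genomeId, start = fb, end = fe, strand = strand,
          frame = frame, protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep the longest ORF per (strand, frame, stop position)
#'
#' Nested ORFs share a stop; for scanning purposes the longest (earliest
#' start) is the representative gene model.
#' @param orfs output of \code{\link{findOrfs}}
#' @export
longestOrfs <- function(orfs) {
  if (nrow(orfs) == 0) return(orfs)
  stopPos <- ifelse(orfs$strand == "+", orfs$end, orfs$start)
  key <- paste(orfs$genome_id, orfs$strand, orfs$frame, stopPos)
  len <- orfs$end - orfs$start + 1L
  keep <- unlist(lapply(split(seq_len(nrow(orfs)), key), function(i)
    i[which.max(len[i])]), use.names = FALSE)
  res <- orfs[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read CDS features with /translation from a GenBank-like flat file
#'
#' Deliberately minimal: only CDS features carrying a /translation qualifier
#' are returned; all other features are counted and reported in a warning.
#'
#' @param path path to a GenBank flat file
#' @return data.frame: locus, protein_id, translation
#' @export
readGenBankCds <- function(path) {
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  locus <- sub("^LOCUS\\s+(\\S+).*$", "\\1", grep("^LOCUS", lines, value = TRUE)[1])
  featStart <- grep("^FEATURES", lines)
  if (length(featStart) == 0) .stopf("no FEATURES table in %s", path)
  body <- lines[(featStart[1] + 1):length(lines)]
  body <- body[!grepl("^ORIGIN|^//", body)]
  isFeat <- grepl("^ {5}\\S", body)
  featIdx <- which(isFeat)
  skipped <- 0L
  res <- list()
  for (k in seq_along(featIdx)) {
    i <- featIdx[k]
    j <- if (k < length(featIdx)) featIdx[k + 1] - 1L else length(body)
    ftype <- sub("^ +(\\S+).*$", "\\1", body[i])
    if (ftype != "CDS") { skipped <- skipped + 1L; next }
    block <- paste(sub("^ +", "", body[i:j]), collapse = " ")
    pid <- if (grepl('/protein_id="', block))
      sub('.*?/protein_id="([^"]*)".*', "\\1", block) else NA_character_
    if (!grepl('/translation="', block)) { skipped <- skipped + 1L; next }
    tr <- sub('.*?/translation="([^"]*)".*', "\\1", block)
    tr <- gsub("\\s", "", tr)
    res[[length(res) + 1L]] <- data.frame(locus = locus, protein_id = pid,
                                          translation = tr,
                                          stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    .warnf("ignored %d non-CDS or translation-less features in %s", skipped, path)
  if (length(res) == 0)
    return(data.frame(locus = character(0), protein_id = character(0),
                      translation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Read a tab-separated survey manifest
#'
#' Required columns: genome_id, cluster, genome_length_bp, cds_count
#' (cds_count entries may be empty). An intein_count column is optional
#' and is filled by the pipeline.
#'
#' @param path path to a TSV file (lines starting with \code{#} are comments)
#' @return data.frame
#' @export
readSurveyManifest <- function(path) {
  m <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("genome_id", "cluster", "genome_length_bp", "cds_count")
  miss <- setdiff(need, names(m))
  if (length(miss)) .stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (any(duplicated(m$genome_id))) .stopf("duplicate genome_id in manifest")
  if (any(!is.na(m$genome_length_bp) & m$genome_length_bp <= 0))
    .stopf("genome_length_bp must be > 0")
  m
}
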