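# Orchestration: scan -> calls, survey tables, transfer analysis.
# These functions are the package-level equivalents of the command-line
# subcommands in inst/scripts/intein-survey.R.

#' Scan proteins (or genomes) for inteins
#'
#' Genome input is first translated to candidate proteins via
#' \code{\link{findOrfs}} (longest ORF per stop). Every protein is scanned
#' with the splicing-block models, hits are chained, boundaries and key
#' residues fixed, and the HEN region annotated. Warning-status calls
#' (non-canonical terminal residue, approximate N-terminus) are retained in
#' the call list but excluded from the default table.
#'
#' @param proteins named character vector of protein sequences (or NULL)
#' @param genomes named character vector of genome DNA sequences (or NULL)
#' @param models model set from \code{\link{inteinBlockModels}}
#' @param minScore block score threshold in bits (default 8)
#' @param minAa minimum ORF protein length for genome input
#' @param miniGap mini-intein threshold (residues)
#' @param constraints block spacing table
#' @return list(calls, table, proteins): accepted + warning calls, the
#'   default (ok-only) call table, and the scanned protein set
#' @export
runScan <- function(proteins = NULL, genomes = NULL,
                    models = inteinBlockModels(), minScore = 8,
                    minAa = 50, miniGap = 50L,
                    constraints = spacingDefaults()) {
  if (is.null(proteins) && is.null(genomes))
    .stopf("provide proteins or genomes")
  if (!is.null(genomes)) {
    orfProts <- character(0)
    for (gid in names(genomes)) {
      orfs <- longestOrfs(findOrfs(genomes[[gid]], minAa = minAa, genomeId = gid))
      if (nrow(orfs))
        orfProts[sprintf("%s_orf%d", gid, seq_len(nrow(orfs)))] <- orfs$protein
    }
    proteins <- c(proteins, orfProts)
  }
  splicing <- models[intersect(c("A", "B", "F", "G"), names(models))]
  hen <- models[intersect(c("C", "D", "E", "H"), names(models))]
  calls <- list()
  for (pid in names(proteins)) {
    seq <- proteins[[pid]]
    hits <- scanBlocks(seq, splicing, minScore = minScore, proteinId = pid)
    chains <- chainBlocks(hits, splicing, constraints)
    for (chain in chains) {
      call <- callIntein(seq, chain, splicing, proteinId = pid)
      if (is.null(call)) next
      if (length(hen))
        call <- detectHen(seq, call, hen, miniGap = miniGap, minScore = minScore)
      calls[[length(calls) + 1L]] <- call
    }
  }
  list(calls = calls, table = callsTable(calls), proteins = proteins)
}

#' Survey-level statistics from a manifest and intein calls
#'
#' Fills intein_count from the calls (matched by genome id prefix of the
#' protein ids) when the manifest lacks it, then computes per-cluster
#' prevalence, intein frequency per 100 CDS, and the genome-size versus
#' intein-frequency R^2.
#'
#' @param manifest survey manifest data.frame
#' @param callTable call table from \code{\link{runScan}} (optional when the
#'   manifest already has intein_count)
#' @return list(prevalence, frequency, r2_size_frequency)
#' @export
runSurvey <- function(manifest, callTable = NULL) {
  if (!"intein_count" %in% names(manifest)) {
    if (is.null(callTable)) .stopf("need a call table or an intein_count column")
    counts <- vapply(manifest$genome_id, function(gid)
      sum(startsWith(callTable$protein_id, paste0(gid, "_"))), integer(1))
    manifest$intein_count <- counts
  }
  prevalence <- clusterPrevalence(manifest)
  frequency <- tryCatch(inteinFrequency(manifest), error = function(e) {
    .warnf("frequency table unavailable: %s", conditionMessage(e))
    data.frame(genome_id = character(0), inteins_per_100_cds = numeric(0))
  })
  r2 <- NA_real_
  if (nrow(frequency) >= 3) {
    m <- manifest[match(frequency$genome_id, manifest$genome_id), ]
    if (stats::sd(m$genome_length_bp) > 0 &&
        stats::sd(frequency$inteins_per_100_cds) > 0)
      r2 <- linearR2(m$genome_length_bp, frequency$inteins_per_100_cds)
  }
  list(prevalence = prevalence, frequency = frequency, r2_size_frequency = r2)
}

#' Transfer analysis over a set of intein sequences
#'
#' Computes the full pairwise identity matrix (global alignment,
#' overhang-excluded denominator), flags candidate pairs above the
#' threshold, and — given at least three sequences — builds a
#' neighbor-joining tree from Poisson-corrected distances.
#'
#' @param inteins named character vector of >= 2 intein sequences
#' @param threshold transfer flagging threshold (percent identity)
#' @param align use global alignment (TRUE) or position-wise comparison
#' @return list(identities, flags, tree (phylo or NULL), newick)
#' @export
runTransfer <- function(inteins, threshold = 35, align = TRUE) {
  if (length(inteins) < 2) .stopf("need >= 2 intein sequences")
  idm <- pairwiseIdentityMatrix(inteins, align = align)
  flags <- flagTransferCandidates(idm, threshold = threshold)
  tree <- NULL; newick <- NULL
  if (length(inteins) >= 3) {
    p <- pmin(1 - idm / 100, 0.95)
    d <- -log(1 - p); diag(d) <- 0
    tree <- njTree(d)
    newick <- ape::write.tree(tree)
  }
  list(identities = idm, flags = flags, tree = tree, newick = newick)
}

#' Match intein calls against a simulation truth manifest
#'
#' A planted intein is recovered (exact boundaries) when some accepted call
#' in the same genome excises exactly the planted intein string — a
#' padding-invariant criterion that tolerates legitimate upstream ORF
#' extension through the random intergenic spacers. Class accuracy is scored
#' on the recovered calls.
#'
#' @param scan result of \code{\link{runScan}} (genome input)
#' @param truth truth manifest from \code{\link{simulateSurvey}}
#' @return list(recall, class_accuracy, n_truth, n_recovered, matches)
#' @export
scoreRecovery <- function(scan, truth) {
  tab <- scan$table
  inteinSeqs <- substr(scan$proteins[tab$protein_id], tab$start, tab$end)
  recovered <- logical(nrow(truth))
  classOk <- logical(nrow(truth))
  matchIdx <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    gid <- truth$genome_id[i]
    inGenome <- startsWith(tab$protein_id, paste0(gid, "_"))
    hit <- which(inGenome & inteinSeqs == truth$intein_seq[i])
    if (length(hit)) {
      recovered[i] <- TRUE
      matchIdx[i] <- hit[1]
      classOk[i] <- tab$intein_class[hit[1]] == truth$class[i]
    }
  }
  list(recall = mean(recovered),
       class_accuracy = if (any(recovered)) mean(classOk[recovered]) else NA_real_,
       n_truth = nrow(truth), n_recovered = sum(recovered),
       matches = data.frame(truth_row = seq_len(nrow(truth)),
                            recovered = recovered, call_row = matchIdx,
                            class_ok = classOk))
}

#' Map recovered calls to insertion sites and score exact-column recovery
#'
#' @param scan result of \code{\link{runScan}}
#' @param truth truth manifest
#' @param recovery result of \code{\link{scoreRecovery}}
#' @param references reference extein list
#' @return list(site_exact_rate, sites): per-recovered-call mapped sites with
#'   truth columns alongside
#' @export
scoreSiteRecovery <- function(scan, truth, recovery,
                              references = referenceExteins()) {
  tab <- scan$table
  rows <- list()
  exact <- logical(0)
  for (i in which(recovery$matches$recovered)) {
    j <- recovery$matches$call_row[i]
    call <- methods::new("InteinCall",
      proteinId = tab$protein_id[j], start = as.integer(tab$start[j]),
      end = as.integer(tab$end[j]),
      blocks = data.frame(block = character(0), start = integer(0),
                          end = integer(0), score = numeric(0)),
      keyResidues = c(a1 = tab$a1[j], b12 = tab$b12[j], f4 = tab$f4[j],
                      g5 = tab$g5[j], penultimate = tab$penultimate[j],
                      terminal = tab$terminal[j], plus_one = tab$plus_one[j]),
      inteinClass = tab$intein_class[j], henPresent = tab$hen[j],
      miniIntein = tab$mini_intein[j], nFlank = "", cFlank = "",
      status = tab$status[j], notes = character(0))
    ref <- references[[truth$family[i]]]
    site <- tryCatch(
      mapInsertion(call, scan$proteins[[tab$protein_id[j]]], ref),
      error = function(e) NULL)
    ok <- !is.null(site) && site$ref_column == truth$ref_column[i]
    exact <- c(exact, ok)
    rows[[length(rows) + 1L]] <- data.frame(
      truth_row = i, family = truth$family[i],
      truth_column = truth$ref_column[i],
      mapped_column = if (is.null(site)) NA_integer_ else site$ref_column,
      motif_context = if (is.null(site)) NA_character_ else site$motif_context,
      exact = ok, stringsAsFactors = FALSE)
  }
  list(site_exact_rate = if (length(exact)) mean(exact) else NA_real_,
       sites = if (length(rows)) do.call(rbind, rows) else NULL)
}
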