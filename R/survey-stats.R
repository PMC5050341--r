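# Survey-level tables and statistics: prevalence, intein frequency,
# genome-size regression, conservation logos, penultimate-residue report.

#' Per-cluster intein prevalence
#'
#' A genome is intein-positive when its intein_count exceeds 0. Percentages
#' are kept at full precision in \code{percent_positive} and half-up rounded
#' to one decimal in \code{percent_display} (the survey reporting style, e.g.
#' 88.7). An "ALL" row aggregates every genome.
#'
#' @param manifest data.frame with columns genome_id, cluster, intein_count
#' @return data.frame: cluster, n_total, n_positive, percent_positive,
#'   percent_display
#' @export
clusterPrevalence <- function(manifest) {
  if (nrow(manifest) == 0) .stopf("empty manifest")
  if (!"intein_count" %in% names(manifest))
    .stopf("manifest lacks intein_count (run the scan first)")
  tab <- lapply(split(manifest, manifest$cluster), function(m)
    data.frame(cluster = m$cluster[1], n_total = nrow(m),
               n_positive = sum(m$intein_count > 0), stringsAsFactors = FALSE))
  res <- do.call(rbind, tab)
  res <- rbind(res, data.frame(cluster = "ALL", n_total = nrow(manifest),
                               n_positive = sum(manifest$intein_count > 0),
                               stringsAsFactors = FALSE))
  res$percent_positive <- 100 * res$n_positive / res$n_total
  res$percent_display <- .roundHalfUp(res$percent_positive, 1)
  rownames(res) <- NULL
  res
}

#' Inteins per 100 protein-coding sequences
#'
#' Rows lacking a cds_count are skipped (their number is reported in a
#' message, mirroring surveys where CDS counts are only partly available);
#' a cds_count of zero is a row error.
#'
#' @param manifest data.frame with genome_id, cds_count, intein_count
#' @return data.frame: genome_id, inteins_per_100_cds
#' @export
inteinFrequency <- function(manifest) {
  has <- !is.na(manifest$cds_count) & manifest$cds_count != ""
  skipped <- sum(!has)
  if (skipped > 0)
    message(sprintf("inteinFrequency: skipped %d genomes lacking cds_count", skipped))
  m <- manifest[has, , drop = FALSE]
  cds <- as.numeric(m$cds_count)
  if (any(cds == 0))
    .stopf("cds_count == 0 for genome(s): %s",
           paste(m$genome_id[cds == 0], collapse = ", "))
  data.frame(genome_id = m$genome_id,
             inteins_per_100_cds = 100 * m$intein_count / cds,
             stringsAsFactors = FALSE)
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return R^2, or NaN with a warning when either variable is constant
#' @export
linearR2 <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  if (length(x) < 3) .stopf("need >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .warnf("R^2 undefined for constant input; returning NaN")
    return(NaN)
  }
  stats::cor(x, y)^2
}

#' Residue-conservation logo columns from aligned block sequences
#'
#' Per column: residue frequencies with gaps excluded from the denominator,
#' and information content \eqn{\log_2 20 - H} bits (Shannon entropy H; no
#' small-sample correction by default, as group sizes vary wildly between
#' sets). An all-gap column is reported with information 0 and a flag.
#'
#' @param aligned character vector of equal-length aligned sequences (>= 2)
#' @param smallSampleCorrection apply the Miller-Madow correction
#' @return data.frame with position, information, n (non-gap count),
#'   all_gap flag, and one frequency column per amino acid
#' @export
conservationLogo <- function(aligned, smallSampleCorrection = FALSE) {
  if (length(aligned) < 2) .stopf("need >= 2 sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) .stopf("ragged alignment")
  mat <- do.call(rbind, lapply(aligned, .chars))
  L <- ncol(mat)
  freq <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  info <- numeric(L)
  nEff <- integer(L)
  allGap <- logical(L)
  for (c in seq_len(L)) {
    col <- mat[, c]
    col <- col[col %in% AA20]
    nEff[c] <- length(col)
    if (length(col) == 0) { allGap[c] <- TRUE; info[c] <- 0; next }
    f <- as.numeric(table(factor(col, levels = AA20))) / length(col)
    freq[c, ] <- f
    h <- .entropyBits(f)
    if (smallSampleCorrection) h <- h + (sum(f > 0) - 1) / (2 * length(col) * log(2))
    info[c] <- max(0, log2(20) - h)
  }
  cbind(data.frame(position = seq_len(L), information = info, n = nEff,
                   all_gap = allGap, stringsAsFactors = FALSE),
        as.data.frame(freq))
}

#' Penultimate-residue (block G column 6) frequency report
#'
#' The penultimate His assists terminal Asn cyclization; phage inteins often
#' replace it (Gly, Lys, Ser). Class 1 calls are reported here; class 3
#' calls should be tabulated separately by the caller.
#'
#' @param calls list of \code{\linkS4class{InteinCall}} (class 1)
#' @param group optional character vector of group labels (one per call)
#' @return data.frame: group, residue, count, fraction
#' @export
penultimateReport <- function(calls, group = NULL) {
  if (length(calls) == 0)
    return(data.frame(group = character(0), residue = character(0),
                      count = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  if (is.null(group)) group <- rep("all", length(calls))
  pen <- vapply(calls, function(x) x@keyResidues[["penultimate"]], character(1))
  rows <- lapply(unique(group), function(g) {
    p <- pen[group == g]
    cnt <- table(p)
    data.frame(group = g, residue = names(cnt), count = as.integer(cnt),
               fraction = as.numeric(cnt) / length(p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a table as TSV with a parameter-recording header comment
#' @param df data.frame
#' @param path output path
#' @param params named list echoed as a \code{#} header line
#' @export
writeTsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params))
    writeLines(sprintf("# %s", paste(names(params), unlist(params), sep = "=",
                                     collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
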