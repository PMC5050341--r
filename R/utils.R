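# Shared constants and small helpers.

#' The 20 standard amino acids, alphabetical one-letter codes
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# IUPAC sets used for input validation (ambiguity codes allowed)
.DNA_CHARS <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
.AA_CHARS  <- c(AA20, "B", "Z", "X", "J", "U", "O", "*", "-")

#' Split a sequence string into single characters (uppercased)
#' @keywords internal
.chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

#' Map residues to 1..20 indices; unknown/ambiguous residues become 21
#' (scored as the background expectation, 0 bits, by the scanner).
#' @keywords internal
.aaIndex <- function(chars) {
  i <- match(chars, AA20)
  i[is.na(i)] <- 21L
  i
}

#' Half-up rounding to `digits` decimals (display convention: 19.1, 88.7)
#' @keywords internal
.roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Shannon entropy (bits) of a frequency vector; 0 log 0 = 0
#' @keywords internal
.entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Draw random amino acids from a background distribution
#' @keywords internal
.randomAA <- function(n, background = rep(1 / 20, 20)) {
  paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

#' Substitute residues of `s` with probability `rate`, uniformly among the 19
#' alternatives; positions in `protect` are never touched.
#' @keywords internal
.mutateAA <- function(s, rate, protect = integer(0)) {
  if (rate <= 0) return(s)
  ch <- .chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    repl <- sample(AA20, length(hit), replace = TRUE)
    clash <- which(repl == ch[hit])
    while (length(clash)) {       # redraw until different from the original
      repl[clash] <- sample(AA20, length(clash), replace = TRUE)
      clash <- clash[repl[clash] == ch[hit][clash]]
    }
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

#' Substitute nucleotides with probability `rate` (uniform among alternatives)
#' @keywords internal
.mutateDNA <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- .chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

#' Path to a packaged data file
#' @keywords internal
.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "inteinscan", mustWork = FALSE)
  if (!nzchar(p)) .stopf("packaged data file not found: %s", file.path(...))
  p
}
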