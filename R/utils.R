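#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' all reported spacings and site lengths. Base `round()` rounds half to even,
#' which would print 81.92 -> 81.9 but 60.25 -> 60.2; half-up is applied once,
#' at presentation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Reverse complement of a DNA string
#'
#' Byte-level complement-and-reverse for character vectors (full IUPAC
#' alphabet), avoiding XString construction in per-molecule inner loops.
#' Agrees with [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (ACGT and IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVacgtryswkmbdhv",
                 "TGCAYRSWMKVHDBtgcayrswmkvhdb", x)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), "", USE.NAMES = FALSE)
}

# Assert a substrate is plain ACGT; report the first offending position.
check_acgt <- function(seq, what = "substrate") {
  bad <- regexpr("[^ACGT]", seq)[1]
  if (bad > 0) {
    stop(sprintf("%s contains a non-ACGT character ('%s') at position %d",
                 what, substr(seq, bad, bad), bad), call. = FALSE)
  }
  invisible(TRUE)
}

# One string from a DNAString/DNAStringSet/character scalar.
as_dna_string <- function(x) {
  if (is.character(x)) return(toupper(x[[1L]]))
  as.character(x)[[1L]]
}

#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail read.delim write.table
NULL

# IUPAC nucleotide code -> base set
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
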