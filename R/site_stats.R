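#' Mean spacing between recognition events
#'
#' The average distance between cleavable positions implied by a recognized
#' word set: `4^word_len / (n_relaxed + n_canonical)` bp, i.e. one event per
#' so many bp of random sequence (both strands of a site count as one event
#' since the word set is scanned on both). Reported half-up rounded to one
#' decimal; with 48 relaxed + 2 canonical 6-mers this is 81.9 bp, with 66 + 2
#' it is 60.2 bp.
#'
#' @param n_relaxed number of distinct relaxed (>= 1 mismatch) words.
#' @param n_canonical number of distinct canonical words observed.
#' @param word_len recognition word length (default 6).
#' @param rounded return the presentation value (half-up, 1 decimal) or the
#'   exact value.
#' @return spacing in bp.
#' @export
mean_spacing <- function(n_relaxed, n_canonical, word_len = 6L, rounded = TRUE) {
  total <- n_relaxed + n_canonical
  if (total < 1) stop("need at least one recognized word", call. = FALSE)
  x <- 4^word_len / total
  if (rounded) round_half_up(x, 1L) else x
}

#' Theoretical (effective) recognition-site length
#'
#' The statistical equivalent length of the recognized set: `log4` of the
#' *unrounded* mean spacing, presented half-up rounded to one decimal. A
#' single fully specific `w`-mer gives `w`; the full 4^w set gives 0. For
#' 48 relaxed + 2 canonical 6-mers this is 3.2 bp; for 66 + 2 it is 3.0 bp.
#'
#' @inheritParams mean_spacing
#' @return effective site length in bp.
#' @export
theoretical_site_length <- function(n_relaxed, n_canonical, word_len = 6L,
                                    rounded = TRUE) {
  x <- log(mean_spacing(n_relaxed, n_canonical, word_len, rounded = FALSE),
           base = 4)
  if (rounded) round_half_up(x, 1L) else x
}

#' Count mismatches of concrete words against the cognate IUPAC pattern
#'
#' A position matches when the word's base is in the pattern's IUPAC set
#' (R matches A or G), so both canonical words score 0.
#'
#' @param hexamer character vector of concrete words (same length as
#'   `pattern`).
#' @param pattern IUPAC pattern (default `"CAARCA"`).
#' @return list with `count` (integer vector) and `positions`
#'   (comma-separated 1-based mismatch positions, `""` for canonical).
#' @export
classify_mismatches <- function(hexamer, pattern = "CAARCA") {
  chars <- strsplit(toupper(pattern), "")[[1L]]
  w <- length(chars)
  hexamer <- toupper(hexamer)
  if (any(nchar(hexamer) != w)) {
    stop("words must have the pattern's width (", w, ")", call. = FALSE)
  }
  sets <- IUPAC_SETS[chars]
  mat <- vapply(seq_len(w), function(i) {
    !substring(hexamer, i, i) %in% sets[[i]]
  }, logical(length(hexamer)))
  if (length(hexamer) == 1L) mat <- matrix(mat, nrow = 1L)
  count <- as.integer(rowSums(mat))
  positions <- apply(mat, 1L, function(r) paste(which(r), collapse = ","))
  list(count = count, positions = positions)
}

#' Build a variant table from decoded junction hexamers
#'
#' Aggregates hexamer observations into one row per distinct word with its
#' observation count and mismatch classification, split canonical vs relaxed.
#'
#' @param hexamers character vector of observed words (one entry per
#'   junction observation; `NA`s dropped).
#' @param counts optional per-entry weights (default 1 each).
#' @param pattern cognate IUPAC pattern.
#' @return data.frame of class `variant_table`: `hexamer`, `count`,
#'   `mismatches`, `positions`, `class` (`canonical`/`relaxed`), sorted by
#'   mismatches then decreasing count. Attributes `n_relaxed_variants`,
#'   `n_canonical`, `pattern`.
#' @export
variant_table <- function(hexamers, counts = NULL, pattern = "CAARCA") {
  keep <- !is.na(hexamers)
  hexamers <- hexamers[keep]
  if (is.null(counts)) counts <- rep(1L, length(hexamers)) else counts <- counts[keep]
  agg <- tapply(counts, hexamers, sum)
  hex <- names(agg)
  if (is.null(hex)) hex <- character(0)
  if (length(hex)) {
    mm <- classify_mismatches(hex, pattern)
    out <- data.frame(hexamer = hex, count = as.integer(agg),
                      mismatches = mm$count, positions = mm$positions,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(hexamer = character(0), count = integer(0),
                      mismatches = integer(0), positions = character(0),
                      stringsAsFactors = FALSE)
  }
  out$class <- ifelse(out$mismatches == 0L, "canonical", "relaxed")
  out <- out[order(out$mismatches, -out$count, out$hexamer), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_relaxed_variants") <- sum(out$class == "relaxed")
  attr(out, "n_canonical") <- sum(out$class == "canonical")
  attr(out, "pattern") <- pattern
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Position frequency matrix and information content of observed sites
#'
#' Stacks the observed recognition words into a 4 x w position count matrix
#' and derives per-position base frequencies and Shannon information content
#' `IC_i = 2 - H_i` bits (no small-sample correction). Count-weighted by
#' default — each junction observation is one sequence, as in a logo built
#' from all observed sites; `weighting = "unweighted"` counts each distinct
#' variant once.
#'
#' @param x a `variant_table` or a character vector of words.
#' @param weighting `"count"` (default) or `"unweighted"`.
#' @return list of class `pfm`: `counts` (4 x w), `freq`, `ic` (bits per
#'   position), `n` (total sequences).
#' @export
build_pfm <- function(x, weighting = c("count", "unweighted")) {
  weighting <- match.arg(weighting)
  if (inherits(x, "variant_table")) {
    words <- x$hexamer
    wts <- if (weighting == "count") x$count else rep(1L, nrow(x))
  } else {
    words <- as.character(x)
    wts <- rep(1L, length(words))
    if (weighting == "unweighted") {
      words <- unique(words)
      wts <- rep(1L, length(words))
    }
  }
  if (!length(words)) stop("need at least one sequence", call. = FALSE)
  w <- nchar(words[1L])
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4L, ncol = w, dimnames = list(bases, seq_len(w)))
  for (i in seq_len(w)) {
    tab <- tapply(wts, substring(words, i, i), sum)
    counts[names(tab), i] <- tab
  }
  freq <- sweep(counts, 2L, colSums(counts), "/")
  ic <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(counts = counts, freq = freq, ic = ic, n = sum(wts)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d sequence(s), %d position(s); IC (bits): %s\n",
              x$n, ncol(x$counts), paste(round(x$ic, 2), collapse = ", ")))
  invisible(x)
}

#' Insert-length histogram
#'
#' Right-open bins `[0, bin_width)`, `[bin_width, 2*bin_width)`, ..., up to
#' `max_bin`, plus an overflow bin for lengths >= `max_bin`.
#'
#' @param lengths positive insert lengths (bp).
#' @param bin_width bin width (bp).
#' @param max_bin lower edge of the overflow bin.
#' @return data.frame `lower`, `upper` (`Inf` for overflow), `count`; counts
#'   sum to `length(lengths)`.
#' @export
insert_length_histogram <- function(lengths, bin_width = 100L, max_bin = 1000L) {
  stopifnot(all(lengths > 0))
  lower <- seq(0L, max_bin, by = bin_width)
  upper <- c(lower[-1L], Inf)
  idx <- pmin(lengths %/% bin_width, max_bin %/% bin_width) + 1L
  count <- tabulate(idx, nbins = length(lower))
  data.frame(lower = lower, upper = upper, count = count)
}
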