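#' Generate a random reference sequence, optionally free of given motifs
#'
#' Draws an i.i.d. ACGT sequence at the requested GC content and, if `forbid`
#' is given, rejects/resamples windows until none of the forbidden motifs
#' occurs on either strand. Stands in for the genomic substrates (phage
#' lambda, *E. coli*) used as digestion targets.
#'
#' @param length sequence length (>= 100).
#' @param gc GC content in (0, 1).
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param forbid optional character vector of motifs that must be absent from
#'   both strands.
#' @param max_iter resampling rounds before giving up on `forbid`.
#' @return a single character string.
#' @export
make_reference <- function(length, gc = 0.5, seed, forbid = NULL, max_iter = 200L) {
  stopifnot(length >= 100, gc > 0, gc < 1, !missing(seed))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  if (is.null(forbid) || !base::length(forbid)) return(paste(bases, collapse = ""))
  forbid <- toupper(forbid)
  both <- unique(c(forbid, revcomp(forbid)))
  w <- max(nchar(both))
  for (iter in seq_len(max_iter)) {
    seq <- paste(bases, collapse = "")
    hit_pos <- integer(0)
    for (m in both) {
      g <- gregexpr(m, seq, fixed = TRUE)[[1L]]
      if (g[1L] > 0) {
        hit_pos <- c(hit_pos, unlist(lapply(g, function(s) s:(s + nchar(m) - 1L))))
      }
    }
    if (!base::length(hit_pos)) return(seq)
    hit_pos <- unique(hit_pos)
    bases[hit_pos] <- sample(names(p), base::length(hit_pos), replace = TRUE, prob = p)
  }
  stop("could not generate a sequence of length ", length,
       " avoiding the forbidden motifs within ", max_iter, " rounds", call. = FALSE)
}

#' The two-site worked-example substrate (1789 bp)
#'
#' A 1789-bp linear sequence carrying two convergent cognate TthHB27I sites —
#' a top-strand CAAACA at positions 297-302 and a bottom-strand site spanning
#' top coordinates 927-932 (reading CAAGCA on the bottom strand) — on a random
#' background free of any other CAARCA occurrence on either strand. Site
#' positions are derived from the printed complete-digest core lengths
#' 311/602/872 under 11/9-nt cleavage with 2-nt 3' overhangs, assuming
#' fragment order 311 | 602 | 872; digestion results should therefore be
#' compared as length *multisets*, not orders. The sequence is synthetic (the
#' real substrate is a plasmid amplicon) and deterministic.
#'
#' @return character string of length 1789.
#' @export
make_worked_example_substrate <- function() {
  L <- 1789L
  words <- expand_iupac("CAARCA")
  for (sub_seed in 571L + 0:49) {
    bg <- make_reference(L, gc = 0.5, seed = sub_seed, forbid = words)
    seq <- paste0(substr(bg, 1L, 296L), "CAAACA", substr(bg, 303L, 926L),
                  revcomp("CAAGCA"), substr(bg, 933L, L))
    hits <- scan_sites(seq, tthHB27I())
    if (nrow(hits) == 2L && all(hits$start == c(297L, 927L)) &&
        all(hits$strand == c("+", "-")) &&
        all(hits$hexamer == c("CAAACA", "CAAGCA"))) {
      return(seq)
    }
  }
  stop("failed to construct the worked-example substrate")  # nocov
}

#' The cognate-free control substrate (1850 bp)
#'
#' A 1850-bp random sequence with no CAARCA occurrence on either strand,
#' emulating the control amplicon used to show that relaxed ('star') cleavage
#' does not require cognate sites. Synthetic and deterministic.
#'
#' @return character string of length 1850.
#' @export
make_nosite_substrate <- function() {
  make_reference(1850L, gc = 0.5, seed = 967L, forbid = expand_iupac("CAARCA"))
}
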