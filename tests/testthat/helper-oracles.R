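# Independent oracles and shared fixtures for the suite.

# Naive sliding-window matcher: every window on the top strand is compared
# against the word set and (via reverse complement) against the bottom-strand
# hypothesis. Independent of the PDict-based scanner.
naive_scan <- function(seq, words) {
  w <- nchar(words[1L])
  L <- nchar(seq)
  if (L < w) {
    return(data.frame(start = integer(), strand = character(),
                      hexamer = character(), stringsAsFactors = FALSE))
  }
  windows <- substring(seq, 1:(L - w + 1L), w:L)
  plus <- which(windows %in% words)
  rc <- revcomp(windows)
  minus <- which(rc %in% words)
  out <- rbind(
    data.frame(start = plus, strand = rep("+", length(plus)),
               hexamer = windows[plus], stringsAsFactors = FALSE),
    data.frame(start = minus, strand = rep("-", length(minus)),
               hexamer = rc[minus], stringsAsFactors = FALSE))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force partial-digest enumeration: digest every subset of the cuts and
# pool the resulting fragments; distinct species are distinct core spans.
# Exercises none of the run-length arithmetic under test.
brute_force_species <- function(L, cuts, enzyme) {
  k <- nrow(cuts)
  frames <- list()
  for (mask in 0:(2^k - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    cd <- complete_digest(L, cuts[sel, , drop = FALSE], enzyme)
    frames[[mask + 1L]] <- cd$fragments[, c("core_start", "core_end", "core_len")]
  }
  unique(do.call(rbind, frames))
}

# Synthetic, geometrically valid cut tables for conservation properties:
# bottom cut positions spaced >= 3 apart so cores never overlap, top cut
# always bottom + overhang (as the 11/9 geometry implies on either strand).
random_cuts <- function(L, k, enzyme, seed) {
  set.seed(seed)
  repeat {
    bot <- sort(sample(seq(2L, L - 4L), k))
    if (k < 2L || all(diff(bot) >= 3L)) break
  }
  data.frame(top_cut_after = bot + enzyme$overhang, bottom_cut_after = bot,
             start = rep(NA_integer_, k), strand = rep("+", k),
             hexamer = rep("CAAACA", k), stringsAsFactors = FALSE)
}

# Shared large-scale library runs (built once per session, reused across
# files): lambda-scale reference, K planted relaxed variants, 2000 clones.
.shared <- new.env(parent = emptyenv())
shared_report <- function(K) {
  key <- paste0("K", K)
  if (is.null(.shared[[key]])) {
    cfg <- default_config(n_relaxed = as.integer(K), n_clones = 2000L,
                          seed = 101L + as.integer(K))
    .shared[[key]] <- run_end_to_end(cfg)
  }
  .shared[[key]]
}

worked_substrate <- function() {
  if (is.null(.shared$worked)) .shared$worked <- make_worked_example_substrate()
  .shared$worked
}
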