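#' Complete digestion of a linear substrate
#'
#' Applies every cut and returns the resulting fragments with duplex-core
#' length accounting. Each double-strand cut converts 2 bp of duplex (for a
#' 2-nt overhang enzyme) into one protruding 3' single-stranded extension on
#' each daughter fragment; reported fragment extents are the *duplex core*
#' (both strands paired), so for `k` cuts the core lengths sum to
#' `L - overhang * k`. Molecule termini of a linear substrate are blunt; ends
#' created by a cut carry a 3' overhang of `enzyme$overhang` nt.
#'
#' @param L substrate length in bp (or the substrate sequence itself, from
#'   which the length is taken).
#' @param cuts data.frame of cut coordinates from [cut_positions()].
#' @param enzyme an [enzyme_spec()] (supplies the overhang length).
#' @param substrate_id identifier recorded on fragments.
#' @param circular treat the substrate as a circle: `k` cuts give `k`
#'   fragments (the wrap-around fragment spans the origin), and an uncut
#'   circle is one unbroken molecule with no ends.
#' @return object of class `digest_result`: a list with `fragments` (data.frame
#'   `core_start`, `core_end`, `core_len`, `left_end`, `right_end`,
#'   `left_ext`, `right_ext`, `species_label`), `cuts`, `mode`, `L`,
#'   `overhang`.
#' @export
complete_digest <- function(L, cuts, enzyme, substrate_id = "substrate",
                            circular = FALSE) {
  if (is.character(L) || inherits(L, "DNAString")) L <- nchar(as_dna_string(L))
  L <- as.integer(L)
  ov <- enzyme$overhang
  if (nrow(cuts)) {
    if (any(cuts$top_cut_after < 1L | cuts$top_cut_after > L - 1L |
            cuts$bottom_cut_after < 1L | cuts$bottom_cut_after > L - 1L)) {
      stop("cut coordinate outside the molecule [1, L-1]", call. = FALSE)
    }
  }
  # per cut: duplex core ends at min(top, bottom); resumes after max(top, bottom)
  left_end <- pmin(cuts$top_cut_after, cuts$bottom_cut_after)
  right_start <- pmax(cuts$top_cut_after, cuts$bottom_cut_after) + 1L
  keep <- !duplicated(paste(left_end, right_start))
  o <- order(left_end[keep])
  left_end <- left_end[keep][o]
  right_start <- right_start[keep][o]
  k <- length(left_end)
  if (k > 1L && any(right_start[-k] > left_end[-1L])) {
    stop("overlapping cuts: adjacent cut sites closer than the overhang width",
         call. = FALSE)
  }
  if (circular) {
    if (k == 0L) {
      frags <- data.frame(
        substrate_id = substrate_id, core_start = 1L, core_end = L,
        core_len = L, left_end = "none", right_end = "none",
        left_ext = 0L, right_ext = 0L, species_label = "1-1",
        stringsAsFactors = FALSE)
    } else {
      # fragment i runs from cut i's resumption to cut i+1's core end;
      # the last wraps across the origin
      nxt <- c(seq_len(k)[-1L], 1L)
      core_start <- right_start
      core_end <- left_end[nxt]
      core_len <- ifelse(nxt == 1L, (L - core_start + 1L) + core_end,
                         core_end - core_start + 1L)
      frags <- data.frame(
        substrate_id = substrate_id, core_start = core_start,
        core_end = core_end, core_len = as.integer(core_len),
        left_end = "overhang3p", right_end = "overhang3p",
        left_ext = ov, right_ext = ov,
        species_label = paste0(seq_len(k), "-", seq_len(k)),
        stringsAsFactors = FALSE)
    }
    return(structure(list(fragments = frags,
                          cuts = data.frame(left_end = left_end,
                                            right_start = right_start),
                          mode = "complete", L = L, overhang = ov),
                     class = "digest_result"))
  }
  core_start <- c(1L, right_start)
  core_end <- c(left_end, L)
  frags <- data.frame(
    substrate_id = substrate_id,
    core_start = core_start, core_end = core_end,
    core_len = core_end - core_start + 1L,
    left_end = c("blunt", rep("overhang3p", k)),
    right_end = c(rep("overhang3p", k), "blunt"),
    left_ext = c(0L, rep(ov, k)),
    right_ext = c(rep(ov, k), 0L),
    species_label = paste0(seq_len(k + 1L), "-", seq_len(k + 1L)),
    stringsAsFactors = FALSE
  )
  structure(list(fragments = frags,
                 cuts = data.frame(left_end = left_end, right_start = right_start),
                 mode = "complete", L = L, overhang = ov),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> mode=%s, L=%d, %d fragment(s): %s\n",
              x$mode, x$L, nrow(x$fragments),
              paste(x$fragments$core_len, collapse = ", ")))
  invisible(x)
}

#' Enumerate all partial-digest species
#'
#' In a partial digest every subset of cut sites is realized by some molecule,
#' so the distinct species are exactly the contiguous runs of complete-digest
#' fragments. A run spanning complete cores `i..j` has length
#' `sum(core_i..core_j) + overhang * (j - i)`: each internal site left uncut
#' retains its `overhang` bp of duplex. With `k` cuts and all run lengths
#' distinct there are `(k+1)(k+2)/2` species, including the `k+1` complete
#' fragments and the uncut full-length molecule.
#'
#' @inheritParams complete_digest
#' @return data.frame with one row per contiguous run: `species_label`
#'   (`"i-j"`), `length` (bp), sorted by decreasing length.
#' @export
partial_digest_species <- function(L, cuts, enzyme, substrate_id = "substrate") {
  cd <- complete_digest(L, cuts, enzyme, substrate_id)
  cores <- cd$fragments$core_len
  n <- length(cores)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i <= idx$j, , drop = FALSE]
  cs <- c(0L, cumsum(cores))
  len <- cs[idx$j + 1L] - cs[idx$i] + cd$overhang * (idx$j - idx$i)
  out <- data.frame(species_label = paste0(idx$i, "-", idx$j),
                    length = as.integer(len), stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$species_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample fragment lengths from stochastic partial digests
#'
#' Each molecule cuts every eligible site independently with probability
#' `cut_prob` (the package's abstraction of the experimental partial-digestion
#' control knobs: temperature, time, enzyme amount). Returns the pooled
#' fragment-length multiset over `n_molecules` molecules.
#'
#' @inheritParams complete_digest
#' @param cut_prob per-site cut probability in \[0, 1\]; scalar or one value
#'   per cut site.
#' @param n_molecules number of molecules to simulate.
#' @param seed mandatory integer seed.
#' @return data.frame `length`, `count` (pooled over molecules), sorted by
#'   decreasing length; attribute `n_molecules`.
#' @export
sample_partial_digest <- function(L, cuts, enzyme, cut_prob, n_molecules, seed,
                                  substrate_id = "substrate") {
  stopifnot(all(cut_prob >= 0), all(cut_prob <= 1), !missing(seed))
  cd <- complete_digest(L, cuts, enzyme, substrate_id)
  k <- nrow(cd$cuts)
  cut_prob <- rep_len(cut_prob, k)
  cores <- cd$fragments$core_len
  cs <- c(0L, cumsum(cores))
  ov <- cd$overhang
  set.seed(seed)
  pool <- integer(0)
  for (m in seq_len(n_molecules)) {
    sel <- which(runif(k) < cut_prob)
    i <- c(1L, sel + 1L)              # run start fragment indices
    j <- c(sel, k + 1L)               # run end fragment indices
    pool <- c(pool, cs[j + 1L] - cs[i] + ov * (j - i))
  }
  tab <- table(pool)
  out <- data.frame(length = as.integer(names(tab)), count = as.integer(tab))
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_molecules") <- n_molecules
  out
}

#' Group fragment lengths into electrophoretic bands
#'
#' Orders unique lengths descending and merges lengths that would co-migrate:
#' consecutive lengths closer than `min_separation_bp` join the same band
#' (single-linkage).
#'
#' @param lengths numeric vector of fragment lengths (a `digest_result` is
#'   also accepted).
#' @param min_separation_bp minimum resolvable length difference; `0` keeps
#'   every unique length as its own band.
#' @return data.frame `band` (1 = slowest/largest), `lengths`
#'   (comma-separated members), `representative` (largest member).
#' @export
band_pattern <- function(lengths, min_separation_bp = 0) {
  if (inherits(lengths, "digest_result")) lengths <- lengths$fragments$core_len
  u <- sort(unique(as.numeric(lengths)), decreasing = TRUE)
  if (!length(u)) {
    return(data.frame(band = integer(), lengths = character(),
                      representative = numeric(), stringsAsFactors = FALSE))
  }
  gap <- c(Inf, -diff(u))
  band <- cumsum(gap >= min_separation_bp | gap == Inf)
  if (min_separation_bp == 0) band <- seq_along(u)
  data.frame(
    band = unique(band),
    lengths = vapply(split(u, band), function(v) paste(v, collapse = ","), ""),
    representative = vapply(split(u, band), max, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
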