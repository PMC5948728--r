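#' Reconstruct candidate recognition hexamers from a blunt junction
#'
#' Given a mapped blunt junction (a duplex-core boundary on the reference),
#' inverts the cleavage geometry to recover the up-to-two recognition hexamers
#' that could have produced the cut. For an insert-START junction at 1-based
#' `p` (the cut's right duplex-core start) the two hypotheses are: a site on
#' the top strand upstream, outside the insert (`reference[p-17 .. p-12]` for
#' 11/9 cleavage of a 6-mer), or a site on the bottom strand inside the insert
#' (`revcomp(reference[p+9 .. p+14])`). Insert-END junctions use the mirror
#' arithmetic. Candidates whose context runs off the reference are dropped.
#'
#' @param p junction coordinate(s): duplex-core start (side `"start"`) or
#'   duplex-core end (side `"end"`).
#' @param side `"start"` or `"end"`, recycled against `p`.
#' @param reference reference sequence.
#' @param enzyme an [enzyme_spec()].
#' @param pattern IUPAC pattern mismatches are counted against (default: the
#'   enzyme's recognition sequence).
#' @return data.frame with one row per surviving candidate: `junction_index`
#'   (position in `p`), `hypothesis` (`"outside"`/`"inside"` the insert),
#'   `hexamer`, `site_strand`, `site_start` (top-strand span start),
#'   `mismatches`, `positions` (comma-separated, 1-based in the hexamer).
#' @export
reconstruct_hexamers <- function(p, side, reference, enzyme,
                                 pattern = enzyme$recognition) {
  reference <- as_dna_string(reference)
  L <- nchar(reference)
  w <- nchar(enzyme$recognition)
  side <- rep_len(side, length(p))
  stopifnot(all(side %in% c("start", "end")))
  start_j <- side == "start"
  # site span start for each hypothesis (top-strand coordinates)
  s_out <- ifelse(start_j, p - w - enzyme$top_offset, p + 1L + enzyme$top_offset)
  s_in  <- ifelse(start_j, p + enzyme$bottom_offset, p - w + 1L - enzyme$bottom_offset)
  strand_out <- ifelse(start_j, "+", "-")
  strand_in  <- ifelse(start_j, "-", "+")
  cand <- data.frame(
    junction_index = rep(seq_along(p), 2L),
    hypothesis = rep(c("outside", "inside"), each = length(p)),
    site_start = as.integer(c(s_out, s_in)),
    site_strand = c(strand_out, strand_in),
    stringsAsFactors = FALSE)
  cand <- cand[cand$site_start >= 1L & cand$site_start + w - 1L <= L, , drop = FALSE]
  top_word <- substring(reference, cand$site_start, cand$site_start + w - 1L)
  cand$hexamer <- ifelse(cand$site_strand == "-", revcomp(top_word), top_word)
  mm <- classify_mismatches(cand$hexamer, pattern)
  cand$mismatches <- mm$count
  cand$positions <- mm$positions
  cand <- cand[order(cand$junction_index, cand$hypothesis == "inside"), ]
  rownames(cand) <- NULL
  cand
}

#' Locate the insert junction of one read on the reference
#'
#' Strips the known vector flank from the read start and maps the first
#' `min_anchor` nt of the insert by exact search against both reference
#' strands. A unique hit yields the blunt-junction coordinate and side; no hit
#' or multiple hits yield `unmapped` / `ambiguous`.
#'
#' @param read read sequence (character).
#' @param flanks vector flank pair ([make_vector_flanks()]).
#' @param reference reference sequence.
#' @param vector_flank_len vector prefix length in the read.
#' @param min_anchor anchor length (>= 15).
#' @return list: `status` (`mapped`, `unmapped`, `multi_mapped`, `no_vector`,
#'   `short_insert`), and for mapped reads `coord` and `side`.
#' @export
locate_insert <- function(read, flanks, reference, vector_flank_len = 30L,
                          min_anchor = 20L) {
  d <- decode_junctions(setNames(read, "read"), reference, flanks,
                        enzyme = tthHB27I(), vector_flank_len = vector_flank_len,
                        min_anchor = min_anchor, reconstruct = FALSE)
  list(status = d$status[1L], coord = d$coord[1L], side = d$side[1L])
}

#' Decode vector-insert junction reads against a reference
#'
#' For every read: verifies and strips the vector prefix, maps the insert
#' anchor (exact, both strands, unique-hit requirement), converts the hit into
#' a blunt-junction coordinate and side, and reconstructs the candidate
#' recognition hexamers via [reconstruct_hexamers()]. Reads whose anchor
#' crosses into a second insert of a concatemer clone fail the exact match and
#' are reported `unmapped`.
#'
#' @param reads named character vector of reads.
#' @param reference reference sequence.
#' @param flanks vector flank pair used in cloning.
#' @param enzyme an [enzyme_spec()].
#' @param vector_flank_len vector prefix length in each read.
#' @param min_anchor exact-match anchor length (>= 15).
#' @param reconstruct set `FALSE` to skip hexamer reconstruction (mapping
#'   only).
#' @return data.frame, one row per read: `read_id`, `status`, `side`, `coord`,
#'   and candidate columns `out_hexamer`, `out_strand`, `out_start`, `out_mm`,
#'   `out_pos`, `in_hexamer`, `in_strand`, `in_start`, `in_mm`, `in_pos` (NA
#'   where a hypothesis was dropped).
#' @export
decode_junctions <- function(reads, reference, flanks, enzyme = tthHB27I(),
                             vector_flank_len = 30L, min_anchor = 20L,
                             reconstruct = TRUE) {
  stopifnot(min_anchor >= 15L)
  reference <- as_dna_string(reference)
  n <- length(reads)
  out <- data.frame(
    read_id = if (is.null(names(reads))) paste0("read", seq_len(n)) else names(reads),
    status = rep("unmapped", n), side = NA_character_, coord = NA_integer_,
    out_hexamer = NA_character_, out_strand = NA_character_,
    out_start = NA_integer_, out_mm = NA_integer_, out_pos = NA_character_,
    in_hexamer = NA_character_, in_strand = NA_character_,
    in_start = NA_integer_, in_mm = NA_integer_, in_pos = NA_character_,
    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  v <- vector_flank_len
  expect_left <- substr(flanks$left, nchar(flanks$left) - v + 1L, nchar(flanks$left))
  expect_right <- revcomp(substr(flanks$right, 1L, v))
  prefix <- substr(reads, 1L, v)
  has_vector <- prefix == expect_left | prefix == expect_right
  out$status[!has_vector] <- "no_vector"

  anchor <- substr(reads, v + 1L, v + min_anchor)
  too_short <- has_vector & nchar(anchor) < min_anchor
  out$status[too_short] <- "short_insert"
  usable <- which(has_vector & !too_short)
  if (!length(usable)) return(out)

  subject <- Biostrings::DNAString(reference)
  anc_set <- Biostrings::DNAStringSet(anchor[usable])
  fwd <- Biostrings::matchPDict(Biostrings::PDict(anc_set), subject)
  rev <- Biostrings::matchPDict(
    Biostrings::PDict(Biostrings::reverseComplement(anc_set)), subject)
  n_fwd <- S4Vectors::elementNROWS(fwd)
  n_rev <- S4Vectors::elementNROWS(rev)
  total <- n_fwd + n_rev
  for (ii in seq_along(usable)) {
    i <- usable[ii]
    if (total[ii] == 0L) { out$status[i] <- "unmapped"; next }
    if (total[ii] > 1L) { out$status[i] <- "multi_mapped"; next }
    out$status[i] <- "mapped"
    if (n_fwd[ii] == 1L) {
      out$side[i] <- "start"
      out$coord[i] <- BiocGenerics::start(fwd[[ii]])[1L]
    } else {
      out$side[i] <- "end"
      out$coord[i] <- BiocGenerics::start(rev[[ii]])[1L] + min_anchor - 1L
    }
  }

  if (reconstruct) {
    mapped <- which(out$status == "mapped")
    if (length(mapped)) {
      cand <- reconstruct_hexamers(out$coord[mapped], out$side[mapped],
                                   reference, enzyme)
      for (hyp in c("outside", "inside")) {
        h <- cand[cand$hypothesis == hyp, , drop = FALSE]
        idx <- mapped[h$junction_index]
        pre <- if (hyp == "outside") "out" else "in"
        out[[paste0(pre, "_hexamer")]][idx] <- h$hexamer
        out[[paste0(pre, "_strand")]][idx] <- h$site_strand
        out[[paste0(pre, "_start")]][idx] <- h$site_start
        out[[paste0(pre, "_mm")]][idx] <- h$mismatches
        out[[paste0(pre, "_pos")]][idx] <- h$positions
      }
    }
  }
  out
}

#' Resolve junction candidates and aggregate a variant table
#'
#' Each mapped junction carries up to two candidate hexamers (site outside vs
#' inside the insert). Two resolution policies:
#'
#' * `"conservative"` (default): a candidate is *plausible* if it has at most
#'   `max_mismatch` mismatches to the cognate pattern. A junction is counted
#'   only when exactly one candidate is plausible; two plausible candidates
#'   make it `ambiguous` and none make it `unresolved`. This never lets a
#'   background hexamer outcompete a true relaxed site.
#' * `"min_mismatch"`: the candidate with fewer mismatches wins; ties are
#'   `ambiguous`.
#'
#' Ambiguous/unresolved junctions are reported in the output but excluded
#' from variant counts.
#'
#' @param decoded data.frame from [decode_junctions()].
#' @param policy resolution policy (see above).
#' @param max_mismatch plausibility cutoff for the conservative policy; the
#'   default 2 reflects the observed relaxation spectrum (variants carry one
#'   or two changes within the 6-bp site).
#' @param pattern cognate IUPAC pattern.
#' @return list of class `variant_calls`: `junctions` (the input plus
#'   `resolution`, `hexamer`, `site_strand`, `mismatches`, `positions`),
#'   `variants` (a [variant_table()]), and counts `n_relaxed_variants`,
#'   `n_canonical`, `n_ambiguous`, `n_unresolved`, `n_unmapped`,
#'   `total_junctions` (resolved junction observations).
#' @export
resolve_and_aggregate <- function(decoded, policy = c("conservative", "min_mismatch"),
                                  max_mismatch = 2L, pattern = "CAARCA") {
  policy <- match.arg(policy)
  d <- decoded
  d$resolution <- ifelse(d$status == "mapped", "unresolved", d$status)
  d$hexamer <- NA_character_
  d$site_strand <- NA_character_
  d$mismatches <- NA_integer_
  d$positions <- NA_character_

  mapped <- which(d$status == "mapped")
  for (i in mapped) {
    mm <- c(out = d$out_mm[i], inn = d$in_mm[i])
    avail <- !is.na(mm)
    if (policy == "conservative") {
      ok <- avail & mm <= max_mismatch
      if (sum(ok) == 1L) pick <- names(mm)[ok]
      else if (sum(ok) == 2L) { d$resolution[i] <- "ambiguous"; next }
      else { d$resolution[i] <- "unresolved"; next }
    } else {
      if (!any(avail)) { d$resolution[i] <- "unresolved"; next }
      if (all(avail) && mm[1L] == mm[2L]) { d$resolution[i] <- "ambiguous"; next }
      pick <- names(mm)[which.min(mm)]
    }
    pre <- if (pick == "out") "out" else "in"
    d$resolution[i] <- "unique"
    d$hexamer[i] <- d[[paste0(pre, "_hexamer")]][i]
    d$site_strand[i] <- d[[paste0(pre, "_strand")]][i]
    d$mismatches[i] <- d[[paste0(pre, "_mm")]][i]
    d$positions[i] <- d[[paste0(pre, "_pos")]][i]
  }

  uniq <- d[d$resolution == "unique", , drop = FALSE]
  vt <- variant_table(uniq$hexamer, pattern = pattern)
  structure(list(
    junctions = d,
    variants = vt,
    n_relaxed_variants = attr(vt, "n_relaxed_variants"),
    n_canonical = attr(vt, "n_canonical"),
    n_ambiguous = sum(d$resolution == "ambiguous"),
    n_unresolved = sum(d$resolution == "unresolved"),
    n_unmapped = sum(d$resolution %in% c("unmapped", "multi_mapped",
                                         "no_vector", "short_insert")),
    total_junctions = nrow(uniq)), class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf(paste0("<variant_calls> %d resolved junction(s): %d canonical word(s), ",
                     "%d relaxed variant(s); %d ambiguous, %d unresolved, %d unusable\n"),
              x$total_junctions, x$n_canonical, x$n_relaxed_variants,
              x$n_ambiguous, x$n_unresolved, x$n_unmapped))
  invisible(x)
}
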