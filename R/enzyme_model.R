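#' Define a Type IIS enzyme with degenerate recognition and downstream cleavage
#'
#' An `enzyme_spec` describes an endonuclease that recognizes a (possibly
#' degenerate, IUPAC-coded) sequence and cleaves both strands at fixed
#' distances *downstream* of the site on the recognition strand. Distances are
#' counted from the last base of the recognition sequence, exclusive: the
#' recognition strand is cut after the `top_offset`-th spacer nucleotide and
#' the complementary strand after the `bottom_offset`-th. With
#' `top_offset > bottom_offset` the two scissions leave `overhang`-nt
#' protruding 3' single-stranded ends on both daughter fragments.
#'
#' @param name enzyme name.
#' @param recognition recognition sequence, IUPAC codes allowed
#'   (e.g. `"CAARCA"`, R = A or G).
#' @param top_offset cut distance (nt) on the recognition strand, downstream of
#'   the site.
#' @param bottom_offset cut distance (nt) on the complementary strand.
#' @param overhang length (nt) of the protruding 3' ends; must equal
#'   `top_offset - bottom_offset`.
#' @return an object of class `enzyme_spec`.
#' @examples
#' tthHB27I()
#' @export
enzyme_spec <- function(name, recognition, top_offset, bottom_offset,
                        overhang = top_offset - bottom_offset) {
  recognition <- toupper(recognition)
  expand_iupac(recognition)  # validates characters
  stopifnot(length(top_offset) == 1L, length(bottom_offset) == 1L)
  if (top_offset - bottom_offset != overhang) {
    stop("top_offset - bottom_offset must equal overhang (",
         top_offset, " - ", bottom_offset, " != ", overhang, ")",
         call. = FALSE)
  }
  if (overhang < 0) stop("5'-recessed geometry not supported: overhang < 0", call. = FALSE)
  structure(
    list(name = name, recognition = recognition,
         top_offset = as.integer(top_offset),
         bottom_offset = as.integer(bottom_offset),
         overhang = as.integer(overhang)),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: %s (%d/%d nt downstream, %d-nt 3' overhang)\n",
              x$name, x$recognition, x$top_offset, x$bottom_offset, x$overhang))
  invisible(x)
}

#' Built-in TthHB27I preset
#'
#' TthHB27I (from *Thermus thermophilus* HB27) recognizes the degenerate 6-bp
#' sequence 5'-CAARCA-3' (two concrete words, CAAACA and CAAGCA) and cleaves
#' 11/9 nt downstream, leaving 2-nt 3' cohesive ends.
#'
#' @return an [enzyme_spec()].
#' @export
tthHB27I <- function() {
  enzyme_spec("TthHB27I", "CAARCA", top_offset = 11L, bottom_offset = 9L)
}

#' Read an enzyme definition from a YAML config file
#'
#' The file must provide `name`, `recognition`, `top_offset`, `bottom_offset`
#' and optionally `overhang`. A copy of the TthHB27I preset ships in
#' `system.file("extdata", "tthHB27I.yaml", package = "starcutter")`.
#'
#' @param path path to a YAML file.
#' @return an [enzyme_spec()].
#' @export
read_enzyme <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "recognition", "top_offset", "bottom_offset")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("enzyme config ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  enzyme_spec(cfg$name, cfg$recognition, cfg$top_offset, cfg$bottom_offset,
              overhang = if (is.null(cfg$overhang)) cfg$top_offset - cfg$bottom_offset
                         else cfg$overhang)
}

#' Expand an IUPAC pattern into its concrete DNA words
#'
#' @param pattern IUPAC-coded DNA string, e.g. `"CAARCA"`.
#' @return character vector of all concrete ACGT words matching the pattern
#'   (length = product of per-position degeneracies).
#' @examples
#' expand_iupac("CAARCA")  # CAAACA, CAAGCA
#' @export
expand_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    stop("pattern must be a single nonempty string", call. = FALSE)
  }
  chars <- strsplit(toupper(pattern), "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d", chars[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  sets <- IUPAC_SETS[chars]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  words <- do.call(paste0, rev(grid))
  sort(words)
}

#' Scan a substrate for recognition sites on both strands
#'
#' Locates every occurrence of the enzyme's recognition words (or an explicit
#' replacement word set) on both strands of an ACGT substrate. Coordinates are
#' 1-based and always refer to the top strand: a hit on the minus strand at
#' `start` means the *reverse complement* of the top-strand hexamer at
#' `[start, start + w - 1]` is a recognition word. Overlapping occurrences are
#' all reported.
#'
#' @param seq substrate sequence (character or `DNAString`); ACGT only.
#' @param enzyme an [enzyme_spec()].
#' @param variants optional character vector of concrete words that *replaces*
#'   the cognate expansion (used for relaxed/'star' site sets).
#' @param substrate_id identifier recorded in the output.
#' @return data.frame with columns `substrate_id`, `start`, `strand`
#'   (`"+"`/`"-"`), `hexamer` (the word as read on the recognition strand) and
#'   `methylated` (all `FALSE`; callers may flag sites to mask them from
#'   cleavage), sorted by `start`.
#' @export
scan_sites <- function(seq, enzyme, variants = NULL, substrate_id = "substrate") {
  seq <- as_dna_string(seq)
  if (nchar(seq) == 0L) {
    return(data.frame(substrate_id = character(), start = integer(),
                      strand = character(), hexamer = character(),
                      methylated = logical(), stringsAsFactors = FALSE))
  }
  check_acgt(seq)
  words <- if (is.null(variants)) expand_iupac(enzyme$recognition) else toupper(unique(variants))
  stopifnot(all(nchar(words) == nchar(words[1L])))
  subject <- Biostrings::DNAString(seq)

  match_words <- function(wset) {
    # PDict needs >= 1 pattern and constant width
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(wset))
    hits <- Biostrings::matchPDict(pd, subject)
    starts <- lapply(seq_along(wset), function(i) BiocGenerics::start(hits[[i]]))
    data.frame(start = unlist(starts),
               word = rep(wset, lengths(starts)),
               stringsAsFactors = FALSE)
  }

  fwd <- match_words(words)
  rev <- match_words(unique(revcomp(words)))
  out <- rbind(
    if (nrow(fwd)) data.frame(substrate_id = substrate_id, start = fwd$start,
                              strand = "+", hexamer = fwd$word,
                              methylated = FALSE, stringsAsFactors = FALSE),
    if (nrow(rev)) data.frame(substrate_id = substrate_id, start = rev$start,
                              strand = "-", hexamer = revcomp(rev$word),
                              methylated = FALSE, stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(substrate_id = character(), start = integer(),
                      strand = character(), hexamer = character(),
                      methylated = logical(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive double-strand cut coordinates from located sites
#'
#' Converts site hits into cut coordinates under the "cut after coordinate c"
#' convention: coordinate `c` denotes the phosphodiester bond between
#' top-strand positions `c` and `c + 1` (on either strand, bonds are indexed by
#' the top-strand base to their left). For a plus-strand site whose word spans
#' `[s, s + w - 1]`, the recognition (top) strand is cut after
#' `s + w - 1 + top_offset` and the bottom strand after
#' `s + w - 1 + bottom_offset`. Minus-strand sites use the mirror-symmetric
#' positions (downstream runs leftward): bottom cut after `s - 1 - top_offset`,
#' top cut after `s - 1 - bottom_offset`. Sites flagged `methylated` and sites
#' whose cut coordinates fall outside `[1, L - 1]` (too close to a molecule
#' end to be cleavable) yield no cut.
#'
#' @param hits data.frame of site hits from [scan_sites()].
#' @param enzyme an [enzyme_spec()].
#' @param L substrate length (bp).
#' @return data.frame with one row per cleavable site: `top_cut_after`,
#'   `bottom_cut_after`, plus the originating `start`, `strand`, `hexamer`.
#'   Dropped (uncleavable/methylated) sites are simply absent.
#' @export
cut_positions <- function(hits, enzyme, L) {
  if (nrow(hits) == 0L) {
    return(data.frame(top_cut_after = integer(), bottom_cut_after = integer(),
                      start = integer(), strand = character(),
                      hexamer = character(), stringsAsFactors = FALSE))
  }
  w <- nchar(enzyme$recognition)
  s <- hits$start
  plus <- hits$strand == "+"
  top <- ifelse(plus, s + w - 1L + enzyme$top_offset, s - 1L - enzyme$bottom_offset)
  bot <- ifelse(plus, s + w - 1L + enzyme$bottom_offset, s - 1L - enzyme$top_offset)
  ok <- !hits$methylated & top >= 1L & top <= L - 1L & bot >= 1L & bot <= L - 1L &
        s >= 1L & s + w - 1L <= L
  out <- data.frame(top_cut_after = as.integer(top[ok]),
                    bottom_cut_after = as.integer(bot[ok]),
                    start = hits$start[ok], strand = hits$strand[ok],
                    hexamer = hits$hexamer[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export site hits as BED-like TSV
#'
#' Five columns: substrate id, 0-based start, end, word, strand.
#'
#' @param hits data.frame from [scan_sites()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(hits, path) {
  w <- nchar(hits$hexamer)
  bed <- data.frame(chrom = hits$substrate_id, start = hits$start - 1L,
                    end = hits$start - 1L + w, name = hits$hexamer,
                    strand = hits$strand, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
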