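#' Build a relaxed-specificity ('star') cleavage model
#'
#' A star model is a named probability vector mapping concrete recognition
#' 6-mers to per-site cut probabilities. The default generator emulates the
#' observed relaxation spectrum: besides the two canonical words, it draws
#' `n_relaxed` distinct variants with one or two mismatches to the cognate
#' IUPAC pattern (roughly half each), with mismatch positions enriched at
#' positions 1, 3 and 6 (the 2nd and 4th-5th bp core is relatively conserved).
#' Per-variant cut efficiencies are not known quantitatively, so a synthetic
#' two-tier model is used: canonical sites cut at `p_canonical`, relaxed sites
#' at `p_relaxed`.
#'
#' @param n_relaxed number of distinct relaxed (>= 1 mismatch) variants.
#' @param seed integer seed.
#' @param pattern cognate IUPAC pattern (default `"CAARCA"`).
#' @param p_canonical cut probability at canonical sites.
#' @param p_relaxed cut probability at relaxed sites.
#' @param position_weights relative mismatch-position weights, length =
#'   pattern width; default favors positions 1, 3, 6.
#' @param mismatch_probs probabilities of drawing a 1- vs 2-mismatch variant.
#' @return named numeric vector of class `star_model` (names: 6-mers; values:
#'   cut probabilities), canonical words first.
#' @export
make_star_model <- function(n_relaxed, seed, pattern = "CAARCA",
                            p_canonical = 0.9, p_relaxed = 0.5,
                            position_weights = c(3, 1, 3, 1, 1, 3),
                            mismatch_probs = c(0.5, 0.5)) {
  stopifnot(!missing(seed), n_relaxed >= 0,
            p_canonical > 0, p_canonical <= 1, p_relaxed > 0, p_relaxed <= 1)
  canonical <- expand_iupac(pattern)
  chars <- strsplit(toupper(pattern), "")[[1L]]
  w <- length(chars)
  stopifnot(length(position_weights) == w)
  set.seed(seed)
  variants <- character(0)
  guard <- 0L
  while (length(variants) < n_relaxed) {
    guard <- guard + 1L
    if (guard > 50000L) stop("could not draw ", n_relaxed, " distinct variants")
    k <- sample(seq_along(mismatch_probs), 1L, prob = mismatch_probs)
    pos <- sample(seq_len(w), k, prob = position_weights)
    word <- vapply(seq_len(w), function(i) {
      allowed <- IUPAC_SETS[[chars[i]]]
      if (i %in% pos) sample(setdiff(c("A", "C", "G", "T"), allowed), 1L)
      else sample(allowed, 1L)
    }, "")
    word <- paste(word, collapse = "")
    if (!word %in% c(canonical, variants)) variants <- c(variants, word)
  }
  probs <- c(rep(p_canonical, length(canonical)), rep(p_relaxed, length(variants)))
  structure(setNames(probs, c(canonical, variants)), class = "star_model")
}

#' Canonical-only cleavage model
#'
#' @param cut_prob cut probability at cognate sites.
#' @param pattern cognate IUPAC pattern.
#' @return a `star_model` containing only the cognate expansion.
#' @export
cognate_model <- function(cut_prob = 1, pattern = "CAARCA") {
  canonical <- expand_iupac(pattern)
  structure(setNames(rep(cut_prob, length(canonical)), canonical),
            class = "star_model")
}

#' Synthetic cloning-vector flank pair
#'
#' A deterministic pair of 300-bp random flanks emulating the vector sequence
#' on each side of a blunt (SmaI-style) cloning point; both flanks are free of
#' the cognate pattern on either strand. A real vector sequence may be
#' supplied to the simulator/decoder instead.
#'
#' @param flank_len flank length in bp.
#' @param seed integer seed.
#' @return list with elements `left` and `right` (character strings). A clone
#'   is modeled as `left + insert(s) + right`.
#' @export
make_vector_flanks <- function(flank_len = 300L, seed = 20L) {
  list(left = make_reference(max(100L, flank_len), gc = 0.5, seed = seed,
                             forbid = expand_iupac("CAARCA")),
       right = make_reference(max(100L, flank_len), gc = 0.5, seed = seed + 1L,
                              forbid = expand_iupac("CAARCA")))
}

#' Simulate a shotgun junction-sequencing library under star cleavage
#'
#' Emulates the shotgun experiment end to end: each clone corresponds to one
#' molecule of the reference digested at star-model word occurrences (each
#' eligible site cut independently with its per-variant probability), 3'
#' overhangs blunted back to the duplex core, one size-selected insert
#' blunt-ligated into the vector in a random orientation, and both vector-insert
#' junction reads emitted. With probability `concatemer_rate` a clone carries
#' two inserts (multi-insert recombinants). Every read is linked to ground
#' truth in the manifest.
#'
#' By default only inserts bounded by two cuts are cloned
#' (`include_terminal = FALSE`): a molecule-end fragment has one terminus with
#' no responsible recognition site, which is uninformative for junction
#' decoding.
#'
#' @param reference reference sequence (character or `DNAString`).
#' @param star a `star_model` (named cut-probability vector).
#' @param enzyme an [enzyme_spec()].
#' @param n_clones number of clones to emit.
#' @param insert_min,insert_max size-selection window on duplex-core length
#'   (bp); clones are inserts in `[insert_min, insert_max]`.
#' @param vector_flank_len vector sequence length (nt) at the start of each
#'   read.
#' @param read_len total read length (nt); the read covers the vector flank
#'   tail plus the start of the cloned region.
#' @param concatemer_rate probability that a clone carries two inserts.
#' @param seed mandatory integer seed; identical seeds give byte-identical
#'   output.
#' @param flanks vector flank pair from [make_vector_flanks()].
#' @param include_terminal also clone molecule-end fragments.
#' @param reference_id identifier recorded in the manifest.
#' @param max_retries digestion retries per clone before counting a failure.
#' @return list of class `star_library`: `reads` (named character vector,
#'   2 per clone), `manifest` (data.frame, one row per read; see
#'   [write_manifest()]), `n_failed` (clones abandoned because no eligible
#'   insert was found), `n_concatemer`.
#' @export
simulate_star_library <- function(reference, star, enzyme, n_clones,
                                  insert_min = 20L, insert_max = 1000L,
                                  vector_flank_len = 30L, read_len = 120L,
                                  concatemer_rate = 0, seed,
                                  flanks = make_vector_flanks(),
                                  include_terminal = FALSE,
                                  reference_id = "reference",
                                  max_retries = 20L) {
  stopifnot(!missing(seed), inherits(star, "star_model"),
            insert_min >= 1L, insert_max >= insert_min,
            concatemer_rate >= 0, concatemer_rate <= 1,
            vector_flank_len <= nchar(flanks$left),
            vector_flank_len <= nchar(flanks$right))
  reference <- as_dna_string(reference)
  L <- nchar(reference)
  hits <- scan_sites(reference, enzyme, variants = names(star),
                     substrate_id = reference_id)
  cuts <- cut_positions(hits, enzyme, L)
  k <- nrow(cuts)
  # per-site boundaries and probabilities, ordered along the molecule
  le <- pmin(cuts$top_cut_after, cuts$bottom_cut_after)
  rs <- pmax(cuts$top_cut_after, cuts$bottom_cut_after) + 1L
  o <- order(le)
  le <- le[o]; rs <- rs[o]
  site <- cuts[o, c("start", "strand", "hexamer"), drop = FALSE]
  pcut <- unname(star[site$hexamer])

  set.seed(seed)
  empty_manifest <- data.frame(
    read_id = character(), clone_id = character(), which_end = character(),
    junction_coord = integer(), junction_side = character(),
    site_start = integer(), site_strand = character(), site_hexamer = character(),
    ins_start = integer(), ins_end = integer(), ins_orient = character(),
    n_inserts = integer(), clone_inserts = character(), stringsAsFactors = FALSE)
  if (n_clones == 0L) {
    out <- list(reads = setNames(character(0), character(0)),
                manifest = empty_manifest, n_failed = 0L, n_concatemer = 0L)
    return(finish_library(out, reference_id, seed, n_clones,
                          vector_flank_len, read_len))
  }
  if (k == 0L && !include_terminal) {
    stop("no cleavable sites on the reference: no cut-bounded inserts exist",
         call. = FALSE)
  }

  # sample one digestion; return eligible fragments as parallel vectors
  digest_once <- function() {
    sel <- which(runif(k) < pcut)
    if (length(sel) > 1L) {
      # drop later members of overlapping cut pairs (sites closer than overhang)
      keep <- c(TRUE, rs[sel][-length(sel)] <= le[sel][-1L])
      while (!all(keep)) {
        sel <- sel[keep]
        if (length(sel) <= 1L) break
        keep <- c(TRUE, rs[sel][-length(sel)] <= le[sel][-1L])
      }
    }
    a <- c(1L, rs[sel])
    b <- c(le[sel], L)
    lcut <- c(NA_integer_, sel)  # cut index bounding the fragment's left end
    rcut <- c(sel, NA_integer_)  # cut index at its right end
    ok <- (b - a + 1L) >= insert_min & (b - a + 1L) <= insert_max
    if (!include_terminal) ok <- ok & !is.na(lcut) & !is.na(rcut)
    list(a = a[ok], b = b[ok], lcut = lcut[ok], rcut = rcut[ok])
  }

  nr <- 2L * n_clones
  reads <- character(nr)
  M <- list(read_id = character(nr), clone_id = character(nr),
            which_end = character(nr), junction_coord = integer(nr),
            junction_side = character(nr), site_start = integer(nr),
            site_strand = character(nr), site_hexamer = character(nr),
            ins_start = integer(nr), ins_end = integer(nr),
            ins_orient = character(nr), n_inserts = integer(nr),
            clone_inserts = character(nr))
  n_failed <- 0L
  n_concatemer <- 0L

  for (ci in seq_len(n_clones)) {
    frags <- NULL
    for (r in seq_len(max_retries)) {
      f <- digest_once()
      if (length(f$a)) { frags <- f; break }
    }
    clone_id <- sprintf("clone%05d", ci)
    if (is.null(frags)) {
      n_failed <- n_failed + 1L
      next
    }
    nf <- length(frags$a)
    n_ins <- if (runif(1L) < concatemer_rate && nf >= 2L) 2L else 1L
    if (n_ins == 2L) n_concatemer <- n_concatemer + 1L
    pick <- sample.int(nf, n_ins)
    a <- frags$a[pick]; b <- frags$b[pick]
    lcut <- frags$lcut[pick]; rcut <- frags$rcut[pick]
    orient <- sample(c("+", "-"), n_ins, replace = TRUE)
    seqs <- substring(reference, a, b)
    flip <- orient == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    clone <- paste0(flanks$left, paste(seqs, collapse = ""), flanks$right)
    inserts_code <- paste(sprintf("%d-%d:%s", a, b, orient), collapse = ";")

    left_read <- substr(clone, nchar(flanks$left) - vector_flank_len + 1L,
                        nchar(flanks$left) - vector_flank_len + read_len)
    rc_clone <- revcomp(clone)
    right_read <- substr(rc_clone, nchar(flanks$right) - vector_flank_len + 1L,
                         nchar(flanks$right) - vector_flank_len + read_len)

    for (e in 1:2) {
      # e = 1: left read (junction at clone-orientation start of first insert)
      # e = 2: right read (junction at clone-orientation end of last insert)
      i <- if (e == 1L) 1L else n_ins
      read_is_start <- e == 1L
      at_start <- (orient[i] == "+") == read_is_start
      cut_i <- if (at_start) lcut[i] else rcut[i]
      slot <- 2L * ci - 2L + e
      reads[slot] <- if (e == 1L) left_read else right_read
      M$read_id[slot] <- paste0(clone_id, "_", c("left", "right")[e])
      M$clone_id[slot] <- clone_id
      M$which_end[slot] <- c("left", "right")[e]
      M$junction_coord[slot] <- if (at_start) a[i] else b[i]
      M$junction_side[slot] <- if (is.na(cut_i)) "terminus" else
                               if (at_start) "start" else "end"
      M$site_start[slot] <- if (is.na(cut_i)) NA_integer_ else site$start[cut_i]
      M$site_strand[slot] <- if (is.na(cut_i)) NA_character_ else site$strand[cut_i]
      M$site_hexamer[slot] <- if (is.na(cut_i)) NA_character_ else site$hexamer[cut_i]
      M$ins_start[slot] <- a[i]
      M$ins_end[slot] <- b[i]
      M$ins_orient[slot] <- orient[i]
      M$n_inserts[slot] <- n_ins
      M$clone_inserts[slot] <- inserts_code
    }
  }

  keep <- nzchar(M$read_id)
  manifest <- as.data.frame(lapply(M, function(v) v[keep]),
                            stringsAsFactors = FALSE)
  if (!nrow(manifest)) manifest <- empty_manifest
  out <- list(reads = setNames(reads[keep], M$read_id[keep]),
              manifest = manifest,
              n_failed = n_failed, n_concatemer = n_concatemer)
  finish_library(out, reference_id, seed, n_clones, vector_flank_len, read_len)
}

finish_library <- function(out, reference_id, seed, n_clones,
                           vector_flank_len, read_len) {
  rownames(out$manifest) <- NULL
  attr(out$manifest, "reference_id") <- reference_id
  attr(out$manifest, "seed") <- as.integer(seed)
  attr(out$manifest, "n_clones") <- as.integer(n_clones)
  attr(out$manifest, "vector_flank_len") <- as.integer(vector_flank_len)
  attr(out$manifest, "read_len") <- as.integer(read_len)
  class(out) <- "star_library"
  out
}

#' @export
print.star_library <- function(x, ...) {
  cat(sprintf("<star_library> %d read(s) from %d clone(s); %d failed, %d concatemer\n",
              length(x$reads), attr(x$manifest, "n_clones"), x$n_failed,
              x$n_concatemer))
  invisible(x)
}

#' Write simulated reads as FASTA
#'
#' @param reads named character vector (e.g. `lib$reads`).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

MANIFEST_COLS <- c("read_id", "clone_id", "which_end", "junction_coord",
                   "junction_side", "site_start", "site_strand", "site_hexamer",
                   "ins_start", "ins_end", "ins_orient", "n_inserts",
                   "clone_inserts")

#' Write / read a ground-truth manifest (lossless TSV round trip)
#'
#' The TSV carries global metadata (`reference_id`, `seed`, `n_clones`,
#' `vector_flank_len`, `read_len`) as `#key=value` header lines, then one row
#' per read.
#'
#' @param manifest manifest data.frame (from [simulate_star_library()]).
#' @param path file path.
#' @return `write_manifest`: `path`, invisibly. `read_manifest`: the manifest
#'   data.frame with metadata attributes restored.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("reference_id", "seed", "n_clones", "vector_flank_len", "read_len")) {
    writeLines(sprintf("#%s=%s", key, attr(manifest, key)), con)
  }
  writeLines(paste(MANIFEST_COLS, collapse = "\t"), con)
  if (nrow(manifest)) {
    df <- manifest[, MANIFEST_COLS]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' @param reference_length optional; if given, junction and insert coordinates
#'   are validated against it.
#' @rdname write_manifest
#' @export
read_manifest <- function(path, reference_length = NULL) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[meta_idx]), "=", fixed = TRUE)
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (!length(body)) stop("manifest ", path, ": no header line", call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, MANIFEST_COLS)) {
    stop("manifest ", path, ": schema mismatch at line ",
         setdiff(seq_along(lines), meta_idx)[1L], call. = FALSE)
  }
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(MANIFEST_COLS))) {
    bad <- which(nf != length(MANIFEST_COLS))[1L]
    stop("manifest ", path, ": malformed record at line ",
         setdiff(seq_along(lines), meta_idx)[bad + 1L],
         " (", nf[bad], " fields, expected ", length(MANIFEST_COLS), ")",
         call. = FALSE)
  }
  m <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!length(rows)) {
    m <- as.data.frame(setNames(rep(list(character(0)), length(MANIFEST_COLS)),
                                MANIFEST_COLS), stringsAsFactors = FALSE)
  }
  names(m) <- MANIFEST_COLS
  for (col in c("junction_coord", "site_start", "ins_start", "ins_end", "n_inserts")) {
    m[[col]] <- suppressWarnings(as.integer(ifelse(m[[col]] == "NA", NA, m[[col]])))
  }
  for (col in c("site_strand", "site_hexamer")) {
    m[[col]][m[[col]] == "NA"] <- NA_character_
  }
  for (kv in meta) attr(m, kv[1L]) <- type.convert(kv[2L], as.is = TRUE)
  if (!is.null(reference_length)) validate_manifest(m, reference_length)
  m
}

#' Validate manifest coordinates against a reference length
#'
#' @param manifest manifest data.frame.
#' @param reference_length reference length in bp.
#' @return `TRUE` invisibly; errors on the first out-of-range coordinate.
#' @export
validate_manifest <- function(manifest, reference_length) {
  bad <- which(manifest$ins_start < 1L | manifest$ins_end > reference_length |
               manifest$junction_coord < 1L |
               manifest$junction_coord > reference_length)
  if (length(bad)) {
    stop("manifest record ", bad[1L], " (read ", manifest$read_id[bad[1L]],
         "): coordinate off the reference (length ", reference_length, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reconstruct a read from its manifest truth record
#'
#' Rebuilds the clone from the reference, the vector flanks and the manifest's
#' insert fields, then re-derives the read; on an intact manifest this
#' round-trips exactly to the emitted read.
#'
#' @param record one manifest row.
#' @param reference reference sequence.
#' @param flanks vector flank pair.
#' @param vector_flank_len,read_len read composition (defaults from manifest
#'   attributes if the full manifest is passed as `record`'s parent).
#' @return the reconstructed read (character).
#' @export
reconstruct_read <- function(record, reference, flanks,
                             vector_flank_len = 30L, read_len = 120L) {
  reference <- as_dna_string(reference)
  parts <- strsplit(record$clone_inserts, ";", fixed = TRUE)[[1L]]
  seqs <- vapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)-(\\d+):([+-])$", p))[[1L]]
    s <- substr(reference, as.integer(m[2L]), as.integer(m[3L]))
    if (m[4L] == "-") revcomp(s) else s
  }, "")
  clone <- paste0(flanks$left, paste(seqs, collapse = ""), flanks$right)
  if (record$which_end == "right") clone <- revcomp(clone)
  flank <- if (record$which_end == "right") flanks$right else flanks$left
  substr(clone, nchar(flank) - vector_flank_len + 1L,
         nchar(flank) - vector_flank_len + read_len)
}
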