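#' Default end-to-end run configuration
#'
#' All tunable parameters of the simulate -> decode -> aggregate -> stats
#' chain with their defaults. Any subset can be overridden via `...` or a
#' YAML file ([read_run_config()]). A run is a pure function of
#' (config, seed): the same pair reproduces outputs byte-identically.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    reference_length = 48502L,  # lambda-genome scale
    reference_gc = 0.5,
    n_relaxed = 48L,
    p_canonical = 0.9,
    p_relaxed = 0.5,
    n_clones = 2000L,
    insert_min = 20L,
    insert_max = 1000L,
    vector_flank_len = 30L,
    read_len = 120L,
    concatemer_rate = 0.05,
    min_anchor = 20L,
    policy = "conservative",
    max_mismatch = 2L,
    weighting = "count",
    bin_width = 100L,
    max_bin = 1000L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` (or plain named list).
#' @return `cfg` invisibly; errors with an actionable message on the first
#'   invalid field.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$reference_length >= 100, "reference_length must be >= 100")
  chk(cfg$p_canonical > 0 && cfg$p_canonical <= 1,
      "p_canonical must be a probability in (0, 1]")
  chk(cfg$p_relaxed > 0 && cfg$p_relaxed <= 1,
      "p_relaxed must be a probability in (0, 1]")
  chk(cfg$concatemer_rate >= 0 && cfg$concatemer_rate <= 1,
      "concatemer_rate must be a probability in [0, 1]")
  chk(cfg$insert_min >= 1 && cfg$insert_max >= cfg$insert_min,
      "insert size window must satisfy 1 <= insert_min <= insert_max")
  chk(cfg$insert_min >= cfg$min_anchor,
      "insert_min must be >= min_anchor (inserts must be mappable)")
  chk(cfg$min_anchor >= 15, "min_anchor must be >= 15")
  chk(cfg$n_relaxed >= 0, "n_relaxed must be >= 0")
  chk(cfg$n_clones >= 0, "n_clones must be >= 0")
  chk(cfg$policy %in% c("conservative", "min_mismatch"), "unknown policy")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of [default_config()] fields.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full simulate -> decode -> stats chain
#'
#' Generates (or accepts) a reference and a star model, simulates the shotgun
#' junction library, decodes every read, aggregates the variant table and
#' computes the summary statistics: recovered variant counts, mean
#' recognition spacing, theoretical site length, mismatch spectrum, position
#' frequency matrix and insert-length histogram. Optionally writes reads,
#' manifest and result tables under `out_dir`.
#'
#' @param cfg a `run_config` from [default_config()] / [read_run_config()].
#' @param enzyme an [enzyme_spec()].
#' @param reference optional explicit reference sequence (else generated from
#'   the config).
#' @param star optional explicit `star_model` (else generated).
#' @param out_dir optional output directory for TSV/FASTA artifacts.
#' @return list of class `star_report`: `config`, `library` stats,
#'   `variants`, `n_relaxed_recovered`, `n_canonical_recovered`,
#'   `mean_spacing`, `site_length`, `mismatch_spectrum`, `pfm`, `histogram`,
#'   `decode_counts`.
#' @export
run_end_to_end <- function(cfg = default_config(), enzyme = tthHB27I(),
                           reference = NULL, star = NULL, out_dir = NULL) {
  validate_config(cfg)
  seed <- as.integer(cfg$seed)
  if (is.null(reference)) {
    reference <- make_reference(cfg$reference_length, cfg$reference_gc,
                                seed = seed)
  }
  if (is.null(star)) {
    star <- make_star_model(cfg$n_relaxed, seed = seed + 1L,
                            pattern = enzyme$recognition,
                            p_canonical = cfg$p_canonical,
                            p_relaxed = cfg$p_relaxed)
  }
  flanks <- make_vector_flanks(seed = 20L)
  lib <- simulate_star_library(
    reference, star, enzyme, n_clones = cfg$n_clones,
    insert_min = cfg$insert_min, insert_max = cfg$insert_max,
    vector_flank_len = cfg$vector_flank_len, read_len = cfg$read_len,
    concatemer_rate = cfg$concatemer_rate, seed = seed + 2L, flanks = flanks)
  decoded <- decode_junctions(lib$reads, reference, flanks, enzyme,
                              vector_flank_len = cfg$vector_flank_len,
                              min_anchor = cfg$min_anchor)
  calls <- resolve_and_aggregate(decoded, policy = cfg$policy,
                                 max_mismatch = cfg$max_mismatch,
                                 pattern = enzyme$recognition)
  n_rel <- calls$n_relaxed_variants
  n_can <- calls$n_canonical
  uniq <- calls$junctions[calls$junctions$resolution == "unique", , drop = FALSE]
  spectrum <- table(factor(uniq$mismatches, levels = 0:nchar(enzyme$recognition)))
  ins_len <- abs(lib$manifest$ins_end - lib$manifest$ins_start) + 1L
  ins_len <- ins_len[!duplicated(paste(lib$manifest$clone_id, lib$manifest$ins_start))]
  report <- structure(list(
    config = cfg,
    library = list(n_reads = length(lib$reads), n_failed = lib$n_failed,
                   n_concatemer = lib$n_concatemer),
    variants = calls$variants,
    n_relaxed_recovered = n_rel,
    n_canonical_recovered = n_can,
    mean_spacing = if (n_rel + n_can >= 1) mean_spacing(n_rel, n_can) else NA_real_,
    site_length = if (n_rel + n_can >= 1) theoretical_site_length(n_rel, n_can) else NA_real_,
    mismatch_spectrum = spectrum,
    pfm = if (nrow(calls$variants)) build_pfm(calls$variants, cfg$weighting) else NULL,
    histogram = insert_length_histogram(ins_len, cfg$bin_width, cfg$max_bin),
    decode_counts = list(ambiguous = calls$n_ambiguous,
                         unresolved = calls$n_unresolved,
                         unusable = calls$n_unmapped,
                         resolved = calls$total_junctions)
  ), class = "star_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reads_fasta(lib$reads, file.path(out_dir, "reads.fasta"))
    write_manifest(lib$manifest, file.path(out_dir, "manifest.tsv"))
    write.table(calls$variants, file.path(out_dir, "variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$histogram, file.path(out_dir, "insert_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$pfm)) {
      write.table(report$pfm$counts, file.path(out_dir, "pfm_counts.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  report
}

#' @export
print.star_report <- function(x, ...) {
  cat("<star_report>\n")
  cat(sprintf("  reads: %d (failed clones %d, concatemer %d)\n",
              x$library$n_reads, x$library$n_failed, x$library$n_concatemer))
  cat(sprintf("  resolved junctions: %d (ambiguous %d, unresolved %d, unusable %d)\n",
              x$decode_counts$resolved, x$decode_counts$ambiguous,
              x$decode_counts$unresolved, x$decode_counts$unusable))
  cat(sprintf("  recovered: %d relaxed variant(s) + %d canonical word(s)\n",
              x$n_relaxed_recovered, x$n_canonical_recovered))
  cat(sprintf("  mean spacing: %.1f bp; theoretical site length: %.1f bp\n",
              x$mean_spacing, x$site_length))
  invisible(x)
}
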