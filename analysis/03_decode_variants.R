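#!/usr/bin/env Rscript
# Decode the junction reads of both simulated libraries: map each read's
# insert anchor, invert the 11/9 cleavage geometry into candidate recognition
# hexamers, resolve, and aggregate per-condition variant tables under
# results/variants/. Requires 02_simulate_libraries.R to have run.

suppressPackageStartupMessages({library(starcutter); library(Biostrings)})
libdir <- "results/libraries"
out <- "results/variants"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

enz <- tthHB27I()
ref <- as.character(readDNAStringSet(file.path(libdir, "reference.fasta"))[[1L]])
flanks <- make_vector_flanks()

for (tag in c("sam48", "sin66")) {
  reads_set <- readDNAStringSet(file.path(libdir, paste0(tag, ".reads.fasta")))
  reads <- setNames(as.character(reads_set), names(reads_set))
  manifest <- read_manifest(file.path(libdir, paste0(tag, ".manifest.tsv")),
                            reference_length = nchar(ref))
  decoded <- decode_junctions(reads, ref, flanks, enz)
  calls <- resolve_and_aggregate(decoded)
  truth <- manifest$site_hexamer[match(calls$junctions$read_id, manifest$read_id)]
  uniq <- calls$junctions$resolution == "unique"
  message(sprintf(
    "%s: %d/%d junctions resolved; %d relaxed + %d canonical variants; %.1f%% agree with truth",
    tag, calls$total_junctions, nrow(decoded), calls$n_relaxed_variants,
    calls$n_canonical, 100 * mean(calls$junctions$hexamer[uniq] == truth[uniq])))
  write.table(calls$variants, file.path(out, paste0(tag, ".variants.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(calls$junctions, file.path(out, paste0(tag, ".junctions.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("done; variant tables under ", out)
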