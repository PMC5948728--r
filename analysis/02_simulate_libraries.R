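#!/usr/bin/env Rscript
# Simulate the two shotgun junction libraries on a lambda-scale (48.5-kb)
# synthetic reference: one star model with 48 relaxed variants (SAM-like
# condition) and one with 66 (SIN-like condition), 2000 clones each under
# saturating digestion. Reads + ground-truth manifests go to
# results/libraries/.

suppressPackageStartupMessages(library(starcutter))
out <- "results/libraries"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

enz <- tthHB27I()
ref <- make_reference(48502L, gc = 0.5, seed = 2026L)
writeLines(c(">lambda_like_48502", ref), file.path(out, "reference.fasta"))

for (cond in list(list(tag = "sam48", K = 48L, seed = 310L),
                  list(tag = "sin66", K = 66L, seed = 320L))) {
  star <- make_star_model(cond$K, seed = cond$seed)
  lib <- simulate_star_library(ref, star, enz, n_clones = 2000L,
                               concatemer_rate = 0.05, seed = cond$seed + 1L)
  write_reads_fasta(lib$reads, file.path(out, paste0(cond$tag, ".reads.fasta")))
  write_manifest(lib$manifest, file.path(out, paste0(cond$tag, ".manifest.tsv")))
  write.table(data.frame(hexamer = names(star), probability = as.numeric(star)),
              file.path(out, paste0(cond$tag, ".star_model.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(cond$tag, ": ", length(lib$reads), " reads from 2000 clones (",
          lib$n_concatemer, " concatemer, ", lib$n_failed, " failed)")
}
message("done; libraries under ", out)
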