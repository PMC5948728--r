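#!/usr/bin/env Rscript
# Headline statistics per condition: recovered variant counts, mean
# recognition spacing, theoretical site length, mismatch spectrum, position
# frequency matrix / information content, and the insert-length histogram.
# Requires 02 and 03 to have run. Tables go to results/stats/.

suppressPackageStartupMessages(library(starcutter))
out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

summary_rows <- list()
for (tag in c("sam48", "sin66")) {
  vt <- read.delim(file.path("results/variants", paste0(tag, ".variants.tsv")),
                   colClasses = c(hexamer = "character", positions = "character"))
  vt <- variant_table(rep(vt$hexamer, vt$count))
  n_rel <- attr(vt, "n_relaxed_variants")
  n_can <- attr(vt, "n_canonical")
  sp <- mean_spacing(n_rel, n_can)
  sl <- theoretical_site_length(n_rel, n_can)
  message(sprintf("%s: %d relaxed + %d canonical -> spacing %.1f bp, site length %.1f bp",
                  tag, n_rel, n_can, sp, sl))

  pfm <- build_pfm(vt, weighting = "count")
  write.table(pfm$counts, file.path(out, paste0(tag, ".pfm_counts.tsv")),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(data.frame(position = seq_along(pfm$ic), ic_bits = pfm$ic),
              file.path(out, paste0(tag, ".information_content.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- read_manifest(file.path("results/libraries",
                                      paste0(tag, ".manifest.tsv")))
  ins <- abs(manifest$ins_end - manifest$ins_start) + 1L
  ins <- ins[!duplicated(paste(manifest$clone_id, manifest$ins_start))]
  hist <- insert_length_histogram(ins)
  write.table(hist, file.path(out, paste0(tag, ".insert_histogram.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- table(factor(vt$mismatches, levels = 0:6))
  summary_rows[[tag]] <- data.frame(
    condition = tag, n_relaxed = n_rel, n_canonical = n_can,
    spacing_bp = sp, site_length_bp = sl,
    one_mismatch = as.integer(spec["1"]), two_mismatch = as.integer(spec["2"]),
    frac_inserts_lt_200 = round(mean(ins < 200), 3))
}
summary <- do.call(rbind, summary_rows)
write.table(summary, file.path(out, "summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("done; summary:")
print(summary, row.names = FALSE)
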