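enz <- tthHB27I()

small_library <- function(seed = 5, n_clones = 120L, concatemer_rate = 0.1) {
  ref <- make_reference(6000, gc = 0.5, seed = 1234)
  star <- make_star_model(8L, seed = 55)
  lib <- simulate_star_library(ref, star, enz, n_clones = n_clones,
                               concatemer_rate = concatemer_rate, seed = seed)
  list(ref = ref, star = star, lib = lib)
}

test_that("make_reference honors length, determinism and forbidden motifs", {
  a <- make_reference(1850, gc = 0.5, seed = 3)
  b <- make_reference(1850, gc = 0.5, seed = 3)
  expect_identical(a, b)
  expect_identical(nchar(a), 1850L)
  clean <- make_reference(1850, gc = 0.5, seed = 3,
                          forbid = c("CAAACA", "CAAGCA"))
  expect_identical(nrow(scan_sites(clean, enz)), 0L)
})

test_that("random-sequence word density matches the Poisson-binomial expectation", {
  word <- "ACGTAC"
  hits <- vapply(1:200, function(s) {
    nrow(scan_sites(make_reference(2000, gc = 0.5, seed = 2200 + s), enz,
                    variants = word))
  }, 0L)
  expected <- 2 * (2000 - 5) / 4^6   # both strands
  se <- sqrt(expected / 200)         # ~Poisson
  expect_lt(abs(mean(hits) - expected), 4 * se)
})

test_that("star-model generator plants distinct variants within the spectrum", {
  star <- make_star_model(48L, seed = 9)
  words <- names(star)
  expect_identical(anyDuplicated(words), 0L)
  canonical <- expand_iupac("CAARCA")
  relaxed <- setdiff(words, canonical)
  expect_length(relaxed, 48L)
  mm <- classify_mismatches(relaxed)
  expect_true(all(mm$count %in% 1:2))
  expect_true(all(star[canonical] > star[relaxed]))
  expect_identical(star, make_star_model(48L, seed = 9))
})

test_that("canonical-only full cleavage yields inserts from the printed cores", {
  sub <- worked_substrate()
  lib <- simulate_star_library(sub, cognate_model(1), enz, n_clones = 50L,
                               seed = 21, include_terminal = TRUE)
  ins_len <- abs(lib$manifest$ins_end - lib$manifest$ins_start) + 1L
  expect_true(all(ins_len %in% c(311L, 602L, 872L)))
  # default: only cut-bounded inserts, i.e. the 602-bp middle fragment
  lib2 <- simulate_star_library(sub, cognate_model(1), enz, n_clones = 20L,
                                seed = 21)
  ins_len2 <- abs(lib2$manifest$ins_end - lib2$manifest$ins_start) + 1L
  expect_true(all(ins_len2 == 602L))
})

test_that("an empty library is a valid library", {
  lib <- simulate_star_library(make_reference(2000, 0.5, seed = 2),
                               make_star_model(5L, seed = 3), enz,
                               n_clones = 0L, seed = 1)
  expect_identical(length(lib$reads), 0L)
  expect_identical(nrow(lib$manifest), 0L)
})

test_that("planted per-strand site spacing approaches 4096/(K+2) bp", {
  ref <- make_reference(48502, gc = 0.5, seed = 77)
  star <- make_star_model(48L, seed = 78)
  hits <- scan_sites(ref, enz, variants = names(star))
  per_strand <- sum(hits$strand == "+")
  spacing <- nchar(ref) / per_strand
  expect_lt(abs(spacing - 81.9) / 81.9, 0.15)
})

test_that("junction truth coincides with digestion-module core boundaries", {
  x <- small_library()
  hits <- scan_sites(x$ref, enz, variants = names(x$star))
  cuts <- cut_positions(hits, enz, nchar(x$ref))
  left_ends <- pmin(cuts$top_cut_after, cuts$bottom_cut_after)
  right_starts <- pmax(cuts$top_cut_after, cuts$bottom_cut_after) + 1L
  m <- x$lib$manifest
  starts <- m[m$junction_side == "start", ]
  ends <- m[m$junction_side == "end", ]
  expect_true(all(starts$junction_coord %in% right_starts))
  expect_true(all(ends$junction_coord %in% left_ends))
  # and the recorded responsible site reproduces that exact coordinate
  for (i in seq_len(nrow(m))) {
    h <- data.frame(substrate_id = "r", start = m$site_start[i],
                    strand = m$site_strand[i], hexamer = m$site_hexamer[i],
                    methylated = FALSE)
    cc <- cut_positions(h, enz, nchar(x$ref))
    bound <- if (m$junction_side[i] == "start")
      pmax(cc$top_cut_after, cc$bottom_cut_after) + 1L
    else pmin(cc$top_cut_after, cc$bottom_cut_after)
    expect_identical(m$junction_coord[i], bound)
  }
})

test_that("every read round-trips from its manifest truth record", {
  x <- small_library(concatemer_rate = 0.3)
  flanks <- make_vector_flanks()
  for (i in seq_len(nrow(x$lib$manifest))) {
    rec <- x$lib$manifest[i, ]
    expect_identical(reconstruct_read(rec, x$ref, flanks),
                     unname(x$lib$reads[rec$read_id]))
  }
})

test_that("manifests round-trip losslessly through TSV", {
  x <- small_library()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(x$lib$manifest, path)
  back <- read_manifest(path, reference_length = nchar(x$ref))
  expect_identical(back[, names(back)], x$lib$manifest[, names(back)])
  for (key in c("reference_id", "seed", "n_clones")) {
    expect_equal(attr(back, key), attr(x$lib$manifest, key))
  }
})

test_that("malformed and off-reference manifests are rejected with a line", {
  x <- small_library(n_clones = 10L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(x$lib$manifest, path)
  lines <- readLines(path)
  truncated <- c(lines[1:8], substr(lines[9], 1, 20))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(truncated, path2)
  expect_error(read_manifest(path2), "line 9")

  m <- x$lib$manifest
  m$junction_coord[2] <- nchar(x$ref) + 50L
  expect_error(validate_manifest(m, nchar(x$ref)), "record 2")
})

test_that("identical seeds give byte-identical FASTA and manifest", {
  ref <- make_reference(5000, 0.5, seed = 10)
  star <- make_star_model(6L, seed = 11)
  fa <- withr::local_tempfile(fileext = ".fasta")
  mf <- withr::local_tempfile(fileext = ".tsv")
  f <- lapply(1:2, function(i) {
    lib <- simulate_star_library(ref, star, enz, n_clones = 40L, seed = 500)
    write_reads_fasta(lib$reads, fa)
    write_manifest(lib$manifest, mf)
    list(fa = readLines(fa), mf = readLines(mf))
  })
  expect_identical(f[[1]], f[[2]])
})

test_that("saturating digestion concentrates insert lengths below 200 bp", {
  rep48 <- shared_report(48)
  hist <- rep48$histogram
  expect_identical(hist$lower[which.max(hist$count)], 0L)
  expect_gt(sum(hist$count[hist$lower < 200]) / sum(hist$count), 0.5)
})
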