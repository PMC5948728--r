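enz <- tthHB27I()
flanks <- make_vector_flanks()

# a read as the simulator would emit it: 30 nt of vector then the insert
fake_read <- function(insert_prefix, side = "left") {
  v <- if (side == "left") {
    substr(flanks$left, nchar(flanks$left) - 29L, nchar(flanks$left))
  } else {
    revcomp(substr(flanks$right, 1L, 30L))
  }
  paste0(v, insert_prefix)
}

test_that("junction arithmetic inverts the cleavage geometry on the worked substrate", {
  sub <- worked_substrate()
  # plus-strand site at 297 cuts 313/311: start junction at 314, end at 311
  c1 <- reconstruct_hexamers(314L, "start", sub, enz)
  out1 <- c1[c1$hypothesis == "outside", ]
  expect_identical(out1$hexamer, "CAAACA")
  expect_identical(out1$site_start, 297L)
  expect_identical(out1$site_strand, "+")
  c2 <- reconstruct_hexamers(311L, "end", sub, enz)
  expect_identical(c2$hexamer[c2$hypothesis == "inside"], "CAAACA")
  # minus-strand site at 927 cuts 917/915: end junction at 915, start at 918
  c3 <- reconstruct_hexamers(915L, "end", sub, enz)
  out3 <- c3[c3$hypothesis == "outside", ]
  expect_identical(out3$hexamer, "CAAGCA")
  expect_identical(out3$site_start, 927L)
  expect_identical(out3$site_strand, "-")
  c4 <- reconstruct_hexamers(918L, "start", sub, enz)
  expect_identical(c4$hexamer[c4$hypothesis == "inside"], "CAAGCA")
})

test_that("candidates without reference context are dropped, not fabricated", {
  sub <- worked_substrate()
  c1 <- reconstruct_hexamers(10L, "start", sub, enz)
  expect_identical(c1$hypothesis, "inside")  # upstream hypothesis off the end
  c2 <- reconstruct_hexamers(nchar(sub) - 5L, "end", sub, enz)
  expect_identical(c2$hypothesis, "inside")
})

test_that("reconstructed hexamers are re-extractable at their claimed position", {
  ref <- make_reference(8000, 0.5, seed = 40)
  set.seed(41)
  p <- sample(100:7900, 50)
  side <- sample(c("start", "end"), 50, replace = TRUE)
  cand <- reconstruct_hexamers(p, side, ref, enz)
  top <- substring(ref, cand$site_start, cand$site_start + 5L)
  expect_identical(cand$hexamer,
                   ifelse(cand$site_strand == "-", revcomp(top), top))
})

test_that("reads map back to their manifest truth", {
  ref <- make_reference(6000, 0.5, seed = 1234)
  star <- make_star_model(8L, seed = 55)
  lib <- simulate_star_library(ref, star, enz, n_clones = 150L, seed = 5,
                               concatemer_rate = 0.1, flanks = flanks)
  d <- decode_junctions(lib$reads, ref, flanks, enz)
  m <- lib$manifest[match(d$read_id, lib$manifest$read_id), ]
  mapped <- d$status == "mapped"
  expect_gt(mean(mapped), 0.95)
  expect_identical(d$coord[mapped], m$junction_coord[mapped])
  expect_identical(d$side[mapped], m$junction_side[mapped])

  calls <- resolve_and_aggregate(d)
  j <- calls$junctions
  uniq <- j$resolution == "unique"
  # round-trip completeness: nearly every resolved junction names the planted hexamer
  agree <- j$hexamer[uniq] == m$site_hexamer[uniq]
  expect_gte(mean(agree), 0.99)
  expect_identical(j$hexamer[uniq][j$mismatches[uniq] <= 2],
                   m$site_hexamer[uniq][j$mismatches[uniq] <= 2])
})

test_that("vector-only, unanchored and repeated-prefix reads are flagged", {
  ref <- make_reference(4000, 0.5, seed = 17)
  vec_read <- substr(paste0(flanks$left, flanks$right), nchar(flanks$left) - 29L,
                     nchar(flanks$left) + 90L)
  expect_identical(locate_insert(vec_read, flanks, ref)$status, "unmapped")

  alien <- fake_read(substr(make_reference(200, 0.5, seed = 99), 1, 60))
  expect_identical(locate_insert(alien, flanks, ref)$status, "unmapped")

  expect_identical(locate_insert("ACGTACGT", flanks, ref)$status, "no_vector")

  # plant the same 40-mer twice -> ambiguous mapping
  dup <- substr(ref, 101, 140)
  ref2 <- paste0(substr(ref, 1, 2000), dup, substr(ref, 2041, 4000))
  expect_identical(locate_insert(fake_read(dup), flanks, ref2)$status,
                   "multi_mapped")
})

test_that("conservative policy surfaces two-plausible-candidate junctions as ambiguous", {
  # build context where both hypotheses are 1 mismatch from CAARCA
  set.seed(7)
  ref <- make_reference(200, 0.5, seed = 31, forbid = expand_iupac("CAARCA"))
  p <- 100L
  substr(ref, p - 17L, p - 12L) <- "AAAACA"            # outside: 1 mismatch
  substr(ref, p + 9L, p + 14L) <- revcomp("CAATCA")    # inside: 1 mismatch
  cand <- reconstruct_hexamers(p, "start", ref, enz)
  expect_setequal(cand$mismatches, c(1L, 1L))

  d <- data.frame(read_id = "r1", status = "mapped", side = "start", coord = p,
                  out_hexamer = cand$hexamer[cand$hypothesis == "outside"],
                  out_strand = "+", out_start = p - 17L, out_mm = 1L, out_pos = "1",
                  in_hexamer = cand$hexamer[cand$hypothesis == "inside"],
                  in_strand = "-", in_start = p + 9L, in_mm = 1L, in_pos = "4",
                  stringsAsFactors = FALSE)
  for (pol in c("conservative", "min_mismatch")) {
    calls <- resolve_and_aggregate(d, policy = pol)
    expect_identical(calls$n_ambiguous, 1L)
    expect_identical(nrow(calls$variants), 0L)
  }
})

test_that("min-mismatch policy picks the closer candidate when unequal", {
  d <- data.frame(read_id = "r1", status = "mapped", side = "start", coord = 50L,
                  out_hexamer = "CAAACA", out_strand = "+", out_start = 33L,
                  out_mm = 0L, out_pos = "",
                  in_hexamer = "TTTTTT", in_strand = "-", in_start = 59L,
                  in_mm = 5L, in_pos = "1,2,3,4,5,6",
                  stringsAsFactors = FALSE)
  calls <- resolve_and_aggregate(d, policy = "min_mismatch")
  expect_identical(calls$junctions$hexamer, "CAAACA")
  # conservative agrees here: only one candidate is plausible
  calls2 <- resolve_and_aggregate(d, policy = "conservative")
  expect_identical(calls2$junctions$hexamer, "CAAACA")
})

test_that("canonical-only libraries aggregate to zero relaxed variants", {
  sub <- worked_substrate()
  lib <- simulate_star_library(sub, cognate_model(1), enz, n_clones = 60L,
                               seed = 3, include_terminal = TRUE, flanks = flanks)
  d <- decode_junctions(lib$reads, sub, flanks, enz)
  calls <- resolve_and_aggregate(d)
  expect_identical(calls$n_relaxed_variants, 0L)
  expect_identical(calls$n_canonical, 2L)
  expect_setequal(calls$variants$hexamer, c("CAAACA", "CAAGCA"))
})

test_that("aggregation is order-independent", {
  ref <- make_reference(6000, 0.5, seed = 1234)
  star <- make_star_model(8L, seed = 55)
  lib <- simulate_star_library(ref, star, enz, n_clones = 80L, seed = 5,
                               flanks = flanks)
  d <- decode_junctions(lib$reads, ref, flanks, enz)
  set.seed(1)
  perm <- d[sample(nrow(d)), ]
  a <- resolve_and_aggregate(d)$variants
  b <- resolve_and_aggregate(perm)$variants
  attributes(a) <- attributes(a)[c("names", "class")]
  attributes(b) <- attributes(b)[c("names", "class")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
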