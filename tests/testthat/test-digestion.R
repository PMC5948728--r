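enz <- tthHB27I()

worked_cuts <- function(sub = worked_substrate()) {
  cut_positions(scan_sites(sub, enz), enz, nchar(sub))
}

test_that("complete digestion of the two-site substrate gives the printed cores", {
  sub <- worked_substrate()
  cd <- complete_digest(sub, worked_cuts(sub), enz)
  expect_setequal(cd$fragments$core_len, c(311L, 602L, 872L))
  expect_identical(nrow(cd$fragments), 3L)
  # termini blunt, cut ends 3'-protruding
  expect_identical(cd$fragments$left_end, c("blunt", "overhang3p", "overhang3p"))
  expect_identical(cd$fragments$right_end, c("overhang3p", "overhang3p", "blunt"))
})

test_that("zero cuts return the intact molecule", {
  cd <- complete_digest(1789L, worked_cuts()[0, ], enz)
  expect_identical(cd$fragments$core_len, 1789L)
  expect_identical(cd$fragments$left_end, "blunt")
  expect_identical(cd$fragments$right_end, "blunt")
})

test_that("cuts outside the molecule are rejected", {
  bad <- data.frame(top_cut_after = 5002L, bottom_cut_after = 5000L,
                    start = NA, strand = "+", hexamer = "CAAACA")
  expect_error(complete_digest(5000L, bad, enz), "outside")
})

test_that("duplex-core conservation holds on randomized inputs", {
  for (s in 1:25) {
    L <- sample(1000:8000, 1)
    k <- sample(0:8, 1)
    cuts <- random_cuts(L, k, enz, seed = 700 + s)
    cd <- complete_digest(L, cuts, enz)
    expect_identical(nrow(cd$fragments), k + 1L)
    expect_identical(sum(cd$fragments$core_len), L - 2L * k)
  }
})

test_that("methylated cognate sites contribute no cuts", {
  sub <- worked_substrate()
  hits <- scan_sites(sub, enz)
  hits$methylated <- TRUE
  expect_identical(nrow(cut_positions(hits, enz, nchar(sub))), 0L)
  cd <- complete_digest(sub, cut_positions(hits, enz, nchar(sub)), enz)
  expect_identical(cd$fragments$core_len, 1789L)
  # one site masked: the remaining site still cuts
  hits$methylated <- c(TRUE, FALSE)
  cd1 <- complete_digest(sub, cut_positions(hits, enz, nchar(sub)), enz)
  expect_setequal(cd1$fragments$core_len, c(915L, 872L))
})

test_that("partial-digest species reproduce the six printed lengths", {
  sub <- worked_substrate()
  sp <- partial_digest_species(sub, worked_cuts(sub), enz)
  expect_identical(nrow(sp), 6L)
  expect_setequal(sp$length, c(311L, 602L, 872L, 915L, 1476L, 1789L))
  # partial species regain the 2 bp of each spanned uncut site
  expect_true(915L %in% sp$length)   # 311 + 602 + 2
  expect_true(1476L %in% sp$length)  # 602 + 872 + 2
})

test_that("species enumeration matches brute-force subset digestion", {
  for (k in 0:6) {
    L <- 3000L
    cuts <- random_cuts(L, k, enz, seed = 900 + k)
    sp <- partial_digest_species(L, cuts, enz)
    bf <- brute_force_species(L, cuts, enz)
    expect_identical(nrow(sp), nrow(bf))
    expect_identical(sort(sp$length), sort(bf$core_len))
    # species-count law when all run lengths are distinct
    if (!anyDuplicated(sp$length)) {
      expect_identical(nrow(sp), ((k + 1L) * (k + 2L)) %/% 2L)
    }
  }
})

test_that("sampled partial digests hit the binomial closed forms", {
  sub <- worked_substrate()
  cuts <- worked_cuts(sub)
  full <- sample_partial_digest(sub, cuts, enz, cut_prob = 1, n_molecules = 50,
                                seed = 1)
  expect_setequal(full$length, c(311L, 602L, 872L))
  expect_identical(sum(full$count), 150L)

  none <- sample_partial_digest(sub, cuts, enz, cut_prob = 0, n_molecules = 50,
                                seed = 1)
  expect_identical(none$length, 1789L)

  n <- 10000L
  half <- sample_partial_digest(sub, cuts, enz, cut_prob = 0.5, n_molecules = n,
                                seed = 42)
  frac_full <- half$count[half$length == 1789L] / n
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(frac_full - 0.25), 3 * se)
})

test_that("expected fragment count is non-decreasing in cut probability", {
  L <- 6000L
  cuts <- random_cuts(L, 6L, enz, seed = 31)
  mean_frags <- vapply(c(0.2, 0.5, 0.8), function(p) {
    d <- sample_partial_digest(L, cuts, enz, cut_prob = p,
                               n_molecules = 10000L, seed = 99)
    sum(d$count) / 10000
  }, 0)
  expect_true(all(diff(mean_frags) > 0))
})

test_that("identical seeds reproduce sampled digests exactly", {
  cuts <- random_cuts(4000L, 4L, enz, seed = 8)
  a <- sample_partial_digest(4000L, cuts, enz, 0.4, 500L, seed = 77)
  b <- sample_partial_digest(4000L, cuts, enz, 0.4, 500L, seed = 77)
  expect_identical(a, b)
})

test_that("band patterns group co-migrating lengths", {
  six <- c(311, 602, 872, 915, 1476, 1789)
  expect_identical(nrow(band_pattern(six, 0)), 6L)
  bp <- band_pattern(c(872, 915), 50)
  expect_identical(nrow(bp), 1L)
  expect_identical(bp$lengths, "915,872")
  # complete digest of the worked substrate resolves into 3 bands
  cd <- complete_digest(worked_substrate(), worked_cuts(), enz)
  expect_identical(nrow(band_pattern(cd, 20)), 3L)
})

test_that("circular substrates give k fragments whose cores sum to L - 2k", {
  L <- 4000L
  for (k in c(0L, 1L, 3L, 6L)) {
    cuts <- random_cuts(L, k, enz, seed = 1300 + k)
    cd <- complete_digest(L, cuts, enz, circular = TRUE)
    expect_identical(nrow(cd$fragments), max(k, 1L))
    if (k == 0L) {
      expect_identical(cd$fragments$core_len, L)
      expect_identical(cd$fragments$left_end, "none")
    } else {
      expect_identical(sum(cd$fragments$core_len), L - 2L * k)
      expect_true(all(cd$fragments$left_end == "overhang3p"))
      # one fragment wraps the origin
      expect_identical(sum(cd$fragments$core_end < cd$fragments$core_start), 1L)
    }
  }
})
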