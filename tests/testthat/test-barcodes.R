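test_that("generated barcodes have the designed architecture", {
  set.seed(1)
  for (w in 1:2) {
    bc <- random_barcodes(50, which = w)
    expect_length(unique(bc), 50)
    expect_true(all(nchar(bc) == 38))
    pat <- if (w == 1) BC1_PATTERN else BC2_PATTERN
    expect_true(all(grepl(pat, bc, perl = TRUE)))
  }
})

test_that("reads built from library barcodes parse cleanly at high quality", {
  lib <- tiny_library()
  reads <- make_read(lib, quality = 40)
  p <- parse_double_barcode(reads$sequence, reads$quality)
  expect_true(all(p$reason == "ok"))
  expect_identical(p$barcode1, lib$barcode1)
  expect_identical(p$barcode2, lib$barcode2)
})

test_that("mean barcode quality must be strictly greater than the floor", {
  lib <- tiny_library(n = 3)
  q29 <- make_read(lib, quality = 29)
  p <- parse_double_barcode(q29$sequence, q29$quality, min_mean_quality = 30)
  expect_true(all(p$reason == "quality_fail"))
  # boundary: exactly 30 is still a rejection ("greater than 30")
  q30 <- make_read(lib, quality = 30)
  p30 <- parse_double_barcode(q30$sequence, q30$quality, min_mean_quality = 30)
  expect_true(all(p30$reason == "quality_fail"))
})

test_that("regions without the internal spacer structure are rejected", {
  lib <- tiny_library(n = 1)
  # oracle: direct regular-expression evaluation of the printed pattern
  bad1 <- strrep("G", 38)
  expect_false(grepl(BC1_PATTERN, bad1, perl = TRUE))
  read <- make_read(lib)
  seq_bad1 <- paste0(substr(read$sequence, 1, 6), bad1,
                     substr(read$sequence, 45, nchar(read$sequence)))
  p <- parse_double_barcode(seq_bad1, read$quality)
  expect_equal(p$reason, "pattern1_fail")

  bad2 <- strrep("G", 38)
  seq_bad2 <- paste0(substr(read$sequence, 1, 78), bad2,
                     substr(read$sequence, 117, nchar(read$sequence)))
  p2 <- parse_double_barcode(seq_bad2, read$quality)
  expect_equal(p2$reason, "pattern2_fail")
})

test_that("the alternate first-barcode flank is accepted", {
  lib <- tiny_library(n = 1)
  read <- make_read(lib)
  alt_region <- paste0(BC1_ALT_FLANK,
                       substr(strrep("G", 38), 1, 38 - nchar(BC1_ALT_FLANK)))
  expect_false(grepl(BC1_PATTERN, alt_region, perl = TRUE))
  seq_alt <- paste0(substr(read$sequence, 1, 6), alt_region,
                    substr(read$sequence, 45, nchar(read$sequence)))
  p <- parse_double_barcode(seq_alt, read$quality)
  expect_equal(p$reason, "ok")
})

test_that("short reads are tagged malformed and parsing is idempotent", {
  lib <- tiny_library(n = 4)
  reads <- make_read(lib)
  p <- parse_double_barcode(substr(reads$sequence[1], 1, 50),
                            substr(reads$quality[1], 1, 50))
  expect_equal(p$reason, "malformed_read")

  once <- parse_double_barcode(reads$sequence, reads$quality)
  again <- parse_double_barcode(reads$sequence, reads$quality)
  expect_identical(once, again)
})

test_that("library matching finds exact and near pairs, with oracle", {
  lib <- tiny_library(n = 10)
  # exact
  expect_identical(match_to_library(lib$barcode1, lib$barcode2, lib),
                   lib$entry_id)
  # two substitutions inside barcode1 still match the same entry
  mut <- substitute_bases(lib$barcode1[4], c(10, 20))
  d <- hamming_to_library(paste0(mut, lib$barcode2[4]), lib)
  expect_equal(min(d), 2)
  expect_identical(match_to_library(mut, lib$barcode2[4], lib), lib$entry_id[4])
  # a pair at distance >= 3 from everything is unmatched
  far1 <- substitute_bases(lib$barcode1[5], c(8, 16, 24, 33))
  far2 <- substitute_bases(lib$barcode2[5], c(8, 16, 24, 33))
  d <- hamming_to_library(paste0(far1, far2), lib)
  expect_true(min(d) >= 3)
  expect_true(is.na(match_to_library(far1, far2, lib)))
})

test_that("ambiguous ties at the minimal distance are unmatched", {
  set.seed(9)
  b1 <- random_barcodes(1, which = 1)
  b2 <- random_barcodes(2, which = 2)
  # two entries share barcode1; query barcode2 is 1 substitution from each
  q2 <- b2[1]
  entry2 <- substitute_bases(q2, c(12, 22))          # distance 2 from q2
  alt2 <- substitute_bases(q2, 12)                   # distance 1
  other <- substitute_bases(q2, 22)                  # distance 1
  lib <- data.frame(entry_id = c("E1", "E2"), barcode1 = b1,
                    barcode2 = c(alt2, other), bait = "x", prey = "y",
                    is_control = FALSE, stringsAsFactors = FALSE)
  expect_true(is.na(match_to_library(b1, q2, lib)))
  # but a unique best match within budget is returned
  lib$barcode2[2] <- entry2
  expect_identical(match_to_library(b1, q2, lib), "E1")
})

test_that("matching is invariant under library row permutation", {
  set.seed(5)
  lib <- tiny_library(n = 12)
  q1 <- c(lib$barcode1[3], substitute_bases(lib$barcode1[7], c(4, 30)))
  q2 <- c(lib$barcode2[3], lib$barcode2[7])
  base <- match_to_library(q1, q2, lib)
  for (i in 1:5) {
    perm <- lib[sample(nrow(lib)), ]
    expect_identical(match_to_library(q1, q2, perm), base)
  }
})

test_that("an empty library is a configuration error", {
  lib <- tiny_library(n = 2)[0, ]
  expect_error(match_to_library("A", "C", lib), "empty")
})
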