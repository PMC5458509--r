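#' Structural regular expressions for the two barcode halves
#'
#' Each 38-bp barcode half carries four fixed anchor blocks (a 4-bp flank,
#' two internal `AA` spacers, one internal `TT` spacer, and a closing 4-bp
#' flank) separated by random fill of 4-7 bases. The flank alternations admit
#' one sequencing error in the 4-bp flanks. Barcode 1 additionally admits a
#' fixed alternate flank sequence (`GTACTAACGGCTAATTTGGTGCCCA`) found in a
#' subset of designed constructs.
#'
#' @format Character scalars, PCRE syntax, anchored to the isolated 38-bp
#'   region.
#' @keywords internal
#' @name barcode_patterns
NULL

.bc_core <- ".{4,7}?AA.{4,7}?AA.{4,7}?TT.{4,7}?"

#' @rdname barcode_patterns
#' @export
BC1_PATTERN <- paste0("^(.ACC|T.CC|TA.C|TAC.)", .bc_core, "(.TAA|A.AA|AT.A|ATA.)$")

#' @rdname barcode_patterns
#' @export
BC1_ALT_FLANK <- "GTACTAACGGCTAATTTGGTGCCCA"

#' @rdname barcode_patterns
#' @export
BC2_PATTERN <- paste0("^(.TAT|T.AT|TT.T|TTA.)", .bc_core, "(.GTA|G.TA|GG.A|GGT.)$")

#' Default amplicon layout
#'
#' Positions (1-based, inclusive) of the sample multiplexing tags and the two
#' 38-bp barcode regions within a read. The default places a 6-bp tag at each
#' end and the 34-bp loxP scar between the two barcode halves, giving a 122-bp
#' read. The true amplicon geometry of a given library preparation is
#' configuration; any layout with fixed offsets is accepted.
#'
#' @return A list with integer ranges `tag1`, `bc1`, `bc2`, `tag2` and the
#'   scalar `read_length`.
#' @export
#' @examples
#' default_read_layout()
default_read_layout <- function() {
  list(
    tag1 = c(1L, 6L),
    bc1 = c(7L, 44L),
    bc2 = c(79L, 116L),
    tag2 = c(117L, 122L),
    read_length = 122L
  )
}

# loxP site separating the two halves on the recombined chromosome
LOXP_SEQ <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"

#' Generate random barcode halves matching the structural patterns
#'
#' Draws barcodes of the designed architecture: flank, four random fill
#' blocks, the AA/AA/TT spacers, closing flank. Used by the simulator and by
#' test fixtures. Candidates are rejection-sampled until they match the
#' corresponding structural pattern and are unique.
#'
#' @param n number of barcodes.
#' @param which `1` or `2`, selecting the barcode-half architecture.
#' @return Character vector of `n` distinct 38-bp barcodes.
#' @export
random_barcodes <- function(n, which = 1) {
  which <- match.arg(as.character(which), c("1", "2"))
  open <- if (which == "1") "TACC" else "TTAT"
  close <- if (which == "1") "ATAA" else "GGTA"
  pat <- if (which == "1") BC1_PATTERN else BC2_PATTERN
  out <- character(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 4L
    fills <- vapply(seq_len(m), function(i) {
      paste(vapply(1:4, function(j)
        paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
        character(1)), collapse = "|")
    }, character(1))
    parts <- strsplit(fills, "|", fixed = TRUE)
    cand <- vapply(parts, function(p)
      paste0(open, p[1], "AA", p[2], "AA", p[3], "TT", p[4], close),
      character(1))
    ok <- grepl(pat, cand, perl = TRUE)
    out <- unique(c(out, cand[ok]))
  }
  out[seq_len(n)]
}

#' Parse a read into its two barcode regions
#'
#' Applies the three read filters: (1) mean Phred quality over each barcode
#' region must exceed `min_mean_quality`; (2) barcode region 1 must match
#' [BC1_PATTERN] (or contain the alternate flank [BC1_ALT_FLANK]); (3) barcode
#' region 2 must match [BC2_PATTERN]. Filters are applied in that order and
#' the first failure is reported.
#'
#' @param sequence character vector of read sequences.
#' @param quality integer matrix/list or character vector of Phred+33 quality
#'   strings, parallel to `sequence`.
#' @param layout amplicon layout, see [default_read_layout()].
#' @param min_mean_quality reads whose mean barcode-region quality is not
#'   strictly greater than this are rejected (default 30).
#' @return A data.frame with columns `barcode1`, `barcode2` (NA when
#'   rejected) and `reason` (`"ok"`, `"malformed_read"`, `"quality_fail"`,
#'   `"pattern1_fail"`, `"pattern2_fail"`).
#' @export
parse_double_barcode <- function(sequence, quality, layout = default_read_layout(),
                                 min_mean_quality = 30) {
  n <- length(sequence)
  stopifnot(length(quality) == n)
  reason <- rep("ok", n)
  bc1 <- bc2 <- rep(NA_character_, n)

  too_short <- nchar(sequence) < layout$read_length
  reason[too_short] <- "malformed_read"
  live <- !too_short

  if (any(live)) {
    q <- .phred_matrix(quality[live], layout$read_length)
    q1 <- rowMeans(q[, layout$bc1[1]:layout$bc1[2], drop = FALSE])
    q2 <- rowMeans(q[, layout$bc2[1]:layout$bc2[2], drop = FALSE])
    qfail <- !(q1 > min_mean_quality & q2 > min_mean_quality)
    reason[which(live)[qfail]] <- "quality_fail"
    live[live] <- !qfail
  }

  if (any(live)) {
    r1 <- substr(sequence[live], layout$bc1[1], layout$bc1[2])
    ok1 <- grepl(BC1_PATTERN, r1, perl = TRUE) |
      grepl(BC1_ALT_FLANK, r1, fixed = TRUE)
    reason[which(live)[!ok1]] <- "pattern1_fail"
    live[live] <- ok1
  }

  if (any(live)) {
    r2 <- substr(sequence[live], layout$bc2[1], layout$bc2[2])
    ok2 <- grepl(BC2_PATTERN, r2, perl = TRUE)
    reason[which(live)[!ok2]] <- "pattern2_fail"
    live[live] <- ok2
  }

  idx <- which(live)
  bc1[idx] <- substr(sequence[idx], layout$bc1[1], layout$bc1[2])
  bc2[idx] <- substr(sequence[idx], layout$bc2[1], layout$bc2[2])
  data.frame(barcode1 = bc1, barcode2 = bc2, reason = reason,
             stringsAsFactors = FALSE)
}

# Phred+33 quality strings (or an integer matrix already) -> integer matrix,
# truncated to the first `len` cycles.
.phred_matrix <- function(quality, len) {
  if (is.matrix(quality)) return(quality[, seq_len(len), drop = FALSE])
  chars <- lapply(quality, function(s) utf8ToInt(substr(s, 1, len)) - 33L)
  do.call(rbind, chars)
}

#' Match parsed double barcodes to the designed library
#'
#' Assigns each (barcode1, barcode2) pair to the unique library entry whose
#' concatenated 76-bp double barcode lies within Hamming distance
#' `max_mismatch`. Pairs at distance > `max_mismatch` from every entry, or
#' tied between two entries at the minimal distance, are unmatched. This is
#' the sequence-similarity criterion used for read assignment (about two
#' mismatches across the 76 bases); barcode regions are fixed-length so
#' substitutions, not indels, are the error model.
#'
#' @param barcode1,barcode2 character vectors of parsed 38-bp halves.
#' @param library a barcode library data.frame, see [read_barcode_library()].
#' @param max_mismatch maximum Hamming distance (default 2).
#' @return Character vector of `entry_id`s, `NA` where unmatched.
#' @export
match_to_library <- function(barcode1, barcode2, library, max_mismatch = 2) {
  if (nrow(library) == 0) stop("empty barcode library")
  query <- paste0(barcode1, barcode2)
  ref <- paste0(library$barcode1, library$barcode2)
  out <- library$entry_id[match(query, ref)]
  miss <- which(is.na(out) & !is.na(barcode1) & !is.na(barcode2))
  if (length(miss) > 0 && max_mismatch > 0) {
    refmat <- .char_matrix(ref)
    for (i in miss) {
      qc <- strsplit(query[i], "")[[1]]
      if (length(qc) != ncol(refmat)) next
      d <- rowSums(refmat != matrix(qc, nrow(refmat), ncol(refmat), byrow = TRUE))
      dmin <- min(d)
      if (dmin <= max_mismatch && sum(d == dmin) == 1L)
        out[i] <- library$entry_id[which.min(d)]
    }
  }
  out
}

.char_matrix <- function(x) {
  do.call(rbind, strsplit(x, ""))
}

#' Both-halves membership in the library
#'
#' Identifies pairs whose two halves each occur somewhere in the library but
#' whose combination is not a designed entry. Such pairs can only arise from
#' PCR chimerism (or residual matching error) and drive rate estimation in
#' [estimate_chimera_rate()].
#'
#' @inheritParams match_to_library
#' @return Logical vector: both halves known, pair not designed.
#' @keywords internal
.is_off_target <- function(barcode1, barcode2, library) {
  pair <- paste0(barcode1, barcode2)
  designed <- paste0(library$barcode1, library$barcode2)
  !is.na(barcode1) & !is.na(barcode2) &
    barcode1 %in% library$barcode1 & barcode2 %in% library$barcode2 &
    !(pair %in% designed)
}
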