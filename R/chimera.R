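#' Estimate the PCR chimera rate from off-target double barcodes
#'
#' Chimeric amplicons form when the two barcode halves of a read stem from
#' different template molecules. Under random re-pairing, a chimera carries
#' half 1 of template i with probability equal to the read-marginal frequency
#' of half i, independently of half 2. When the designed library does not
#' occupy the full cross of observed halves, chimeras land on undesigned
#' (off-target) pairs at a predictable rate, and the chimera fraction is
#'
#'   epsilon-hat = O / (E x N)
#'
#' where O is the number of off-target reads, N the total parsed reads whose
#' halves are both known, and E the probability that a random re-pairing
#' falls outside the designed set (computed from the marginal half
#' frequencies).
#'
#' When the library IS a complete cross of its barcode halves, every chimera
#' lands on a designed pair, nothing is observable, and the rate must be
#' supplied from an external calibration; this is signalled as an error.
#'
#' @param x a `ppiseq_counts` object (with its `off_target` ledger).
#' @param per_sample estimate one rate per sample (`TRUE`) or one global rate
#'   (default, `FALSE`).
#' @return Named numeric vector of chimera-rate estimates (one element,
#'   `"global"`, unless `per_sample`).
#' @export
estimate_chimera_rate <- function(x, per_sample = FALSE) {
  stopifnot(inherits(x, "ppiseq_counts"))
  lib <- x$library
  sids <- colnames(x$counts)
  off <- x$off_target

  est_one <- function(cols) {
    in_lib <- rowSums(x$counts[, cols, drop = FALSE])
    o <- off[off$sample_id %in% cols, , drop = FALSE]
    # marginal read frequencies of each half, pooling designed and off-target
    h1 <- c(tapply(in_lib, lib$barcode1, sum))
    h2 <- c(tapply(in_lib, lib$barcode2, sum))
    if (nrow(o) > 0) {
      o1 <- tapply(o$count, o$barcode1, sum)
      h1[names(o1)] <- ifelse(is.na(h1[names(o1)]), 0, h1[names(o1)]) + o1
      o2 <- tapply(o$count, o$barcode2, sum)
      h2[names(o2)] <- ifelse(is.na(h2[names(o2)]), 0, h2[names(o2)]) + o2
    }
    total <- sum(in_lib) + sum(o$count)
    if (total == 0) return(0)
    p <- h1 / sum(h1)
    q <- h2 / sum(h2)
    inside <- sum(p[lib$barcode1] * q[lib$barcode2], na.rm = TRUE)
    e_out <- 1 - inside
    if (e_out <= 0) {
      if (sum(o$count) == 0)
        stop("library is a complete cross of its barcode halves: ",
             "chimeras are unobservable; supply the rate explicitly ",
             "(e.g. correct_counts(..., rate = <calibrated value>))")
      e_out <- 1e-12
    }
    min(sum(o$count) / (e_out * total), 1 - 1e-12)
  }

  if (per_sample) {
    out <- vapply(sids, function(s) est_one(s), numeric(1))
    names(out) <- sids
    out
  } else {
    c(global = est_one(sids))
  }
}

#' Subtract expected PCR-chimera reads from double-barcode counts
#'
#' For pair (i, j) in a sample with total reads `R..`, half-1 marginal `Ri.`
#' and half-2 marginal `R.j`, the expected chimeric contribution is
#' `rate * Ri. * R.j / R..`; the corrected count is the raw count minus this
#' expectation, floored at zero and rounded to the nearest integer (counts
#' are read tallies, and downstream Poisson likelihoods expect integers).
#'
#' @param x a `ppiseq_counts` object or a trajectory data.frame
#'   (see [as_trajectory_table()]).
#' @param rate chimera fraction: a single number, a per-sample named vector,
#'   or `"auto"` to call [estimate_chimera_rate()].
#' @return Same class as `x`; matrix input gains a `corrected` matrix,
#'   trajectory input gains `Reads_<g>_generations_corrected` columns.
#' @export
correct_counts <- function(x, rate = "auto") {
  UseMethod("correct_counts")
}

.check_rate <- function(rate) {
  if (any(rate < 0 | rate >= 1)) stop("chimera rate must lie in [0, 1)")
  rate
}

# expected chimeric reads for one sample's count vector, given half labels
.expected_chimeras <- function(counts, half1, half2, rate) {
  tot <- sum(counts)
  if (tot == 0 || rate == 0) return(numeric(length(counts)))
  m1 <- c(tapply(counts, half1, sum))[half1]
  m2 <- c(tapply(counts, half2, sum))[half2]
  rate * m1 * m2 / tot
}

#' @rdname correct_counts
#' @export
correct_counts.ppiseq_counts <- function(x, rate = "auto") {
  if (identical(rate, "auto")) rate <- estimate_chimera_rate(x)
  .check_rate(rate)
  sids <- colnames(x$counts)
  if (length(rate) == 1 && is.null(names(rate))) rate <- c(global = rate)
  corrected <- x$counts
  for (s in sids) {
    r <- if (s %in% names(rate)) rate[[s]] else rate[[1]]
    ch <- .expected_chimeras(x$counts[, s], x$library$barcode1,
                             x$library$barcode2, r)
    corrected[, s] <- as.integer(round(pmax(0, x$counts[, s] - ch)))
  }
  x$corrected <- corrected
  x$chimera_rate <- rate
  x
}

#' @rdname correct_counts
#' @export
correct_counts.data.frame <- function(x, rate = "auto") {
  if (identical(rate, "auto"))
    stop("rate = \"auto\" needs the off-target ledger of a ppiseq_counts ",
         "object; trajectory tables carry designed pairs only")
  if (length(rate) != 1)
    stop("trajectory-table correction takes a single global rate")
  .check_rate(rate)
  need <- c("Bait_barcode", "Prey_barcode", "Condition",
            "Methotrexate_selection", "Replicate")
  if (!all(need %in% names(x)))
    stop("trajectory table must carry columns: ", paste(need, collapse = ", "))
  cols <- reads_columns(x)
  pool <- paste(x$Condition, x$Methotrexate_selection, x$Replicate)
  for (g in names(cols)) {
    col <- cols[[g]]
    out <- numeric(nrow(x))
    for (p in unique(pool)) {
      i <- pool == p
      ch <- .expected_chimeras(x[[col]][i], x$Bait_barcode[i],
                               x$Prey_barcode[i], rate)
      out[i] <- pmax(0, x[[col]][i] - ch)
    }
    x[[paste0(col, "_corrected")]] <- as.integer(round(out))
  }
  attr(x, "chimera_rate") <- rate
  x
}
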