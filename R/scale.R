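#' Expected unique double-barcoded diploids from pooled mating
#'
#' Library complexity bound for bulk mating on agar plates: cells per plate
#' times the mating efficiency times the loxP recombination efficiency,
#' times the number of plates. At the measured lower-bound efficiencies
#' (8.1\% mating, 2.7\% recombination) a single 1e10-cell plate yields at
#' least 2e7 unique double barcodes.
#'
#' @param cells_per_plate haploid cells mated per plate.
#' @param mating_efficiency,recombination_efficiency fractions in (0, 1].
#' @param n_plates number of plates (default 1).
#' @return Expected number of unique double-barcoded diploids.
#' @export
#' @examples
#' predicted_complexity(1e10, 0.081, 0.027)          # one plate
#' predicted_complexity(1e10, 0.081, 0.027, n_plates = 50)
predicted_complexity <- function(cells_per_plate, mating_efficiency,
                                 recombination_efficiency, n_plates = 1) {
  stopifnot(cells_per_plate > 0, n_plates > 0)
  if (mating_efficiency <= 0 || mating_efficiency > 1 ||
      recombination_efficiency <= 0 || recombination_efficiency > 1)
    stop("efficiencies must lie in (0, 1]")
  cells_per_plate * mating_efficiency * recombination_efficiency * n_plates
}

#' Expected fraction of barcodes detected at a sequencing depth
#'
#' Under Poisson read sampling (the many-barcodes, small-frequencies limit
#' of multinomial sequencing), barcode b with frequency f_b receives at
#' least k reads with probability `P(Poisson(depth * f_b) >= k)`; the
#' detection fraction is the mean over barcodes. Monotone increasing in
#' depth and decreasing in k.
#'
#' @param frequencies barcode frequency vector (must sum to 1 within
#'   tolerance).
#' @param depth total reads sequenced.
#' @param k minimum reads for a barcode to count as detected (default 1).
#' @return Expected detected fraction in `[0, 1]`.
#' @export
#' @examples
#' detection_fraction(rep(1 / 2500, 2500), depth = 67 * 2500, k = 1)
#' detection_fraction(rep(1 / 2500, 2500), depth = 67 * 2500, k = 10)
detection_fraction <- function(frequencies, depth, k = 1) {
  if (k < 0) stop("k must be non-negative")
  stopifnot(depth > 0, all(frequencies >= 0))
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  if (k == 0) return(1)
  mean(stats::ppois(k - 1, depth * frequencies, lower.tail = FALSE))
}
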