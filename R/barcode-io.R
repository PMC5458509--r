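#' Read a designed double-barcode library table
#'
#' The library maps each designed (barcode1, barcode2) pair to its genotype
#' pair. Tab-separated with header columns `entry_id`, `barcode1`,
#' `barcode2`, `bait`, `prey`, `is_control`.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_barcode_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_barcode_library(lib)
}

#' @rdname read_barcode_library
#' @param lib a library data.frame to validate in place.
#' @export
validate_barcode_library <- function(lib) {
  need <- c("entry_id", "barcode1", "barcode2", "bait", "prey", "is_control")
  if (!all(need %in% names(lib)))
    stop("library table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste0(lib$barcode1, lib$barcode2)))
    stop("duplicate (barcode1, barcode2) pairs in library")
  if (anyDuplicated(lib$entry_id))
    stop("duplicate entry_id in library")
  lib$is_control <- as.logical(lib$is_control)
  lib
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `tag1`, `tag2`, `condition`, `mtx`,
#' `replicate`, `generation`. One row per sequenced sample; the tag pair is
#' the double index that identifies the sample.
#'
#' @param path TSV file path.
#' @return data.frame with an added `sample_id` column.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tag1", "tag2", "condition", "mtx", "replicate", "generation")
  if (!all(need %in% names(s)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  s$mtx <- as.logical(s$mtx)
  s$sample_id <- make_sample_id(s$condition, s$mtx, s$replicate, s$generation)
  if (anyDuplicated(paste(s$tag1, s$tag2))) stop("duplicate tag pairs")
  s
}

#' @rdname read_sample_sheet
#' @param condition,mtx,replicate,generation sample descriptors.
#' @export
make_sample_id <- function(condition, mtx, replicate, generation) {
  paste(condition, ifelse(mtx, "MTXplus", "MTXminus"),
        paste0("R", replicate), paste0("G", generation), sep = ".")
}

#' Read a FASTQ file into sequences and quality strings
#'
#' Thin wrapper over `Biostrings` FASTQ input (plain or gzip).
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `sequence` and `quality` (Phred+33).
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Demultiplex reads and tabulate double-barcode counts
#'
#' Full read-to-count pipeline: sample assignment by the multiplexing tag
#' pair, barcode-region parsing and quality/pattern filtering
#' ([parse_double_barcode()]), library assignment by unique-best Hamming
#' matching ([match_to_library()]), and tallying. Reads whose two halves are
#' each known to the library but whose combination is undesigned are recorded
#' separately as off-target observations (putative PCR chimeras) for
#' [estimate_chimera_rate()].
#'
#' Conservation holds per sample: matched reads plus all rejection reasons
#' equal reads processed.
#'
#' @param reads data.frame with columns `sequence`, `quality` (see
#'   [read_fastq_reads()]), or a character vector of FASTQ paths.
#' @param library designed library, see [read_barcode_library()].
#' @param samples sample sheet, see [read_sample_sheet()].
#' @param layout amplicon layout, see [default_read_layout()].
#' @param max_mismatch Hamming budget for library matching (default 2).
#' @param min_mean_quality barcode-region quality floor (default 30).
#' @return An object of class `ppiseq_counts`: list with `counts` (integer
#'   matrix, library entries x samples), `samples`, `library`, `unmatched`
#'   (integer matrix, rejection reason x samples plus an `unassigned` column
#'   for tag failures) and `off_target` (data.frame of undesigned pairs).
#' @export
demultiplex_and_tabulate <- function(reads, library, samples,
                                     layout = default_read_layout(),
                                     max_mismatch = 2, min_mean_quality = 30) {
  library <- validate_barcode_library(library)
  if (is.character(reads))
    reads <- do.call(rbind, lapply(reads, read_fastq_reads))
  stopifnot(all(c("sequence", "quality") %in% names(reads)))

  sample_ids <- samples$sample_id
  reasons <- c("malformed_read", "tag_fail", "quality_fail",
               "pattern1_fail", "pattern2_fail", "library_fail")
  counts <- matrix(0L, nrow(library), length(sample_ids),
                   dimnames = list(library$entry_id, sample_ids))
  unmatched <- matrix(0L, length(reasons), length(sample_ids) + 1L,
                      dimnames = list(reasons, c(sample_ids, "unassigned")))
  off <- data.frame(sample_id = character(0), barcode1 = character(0),
                    barcode2 = character(0), count = integer(0),
                    stringsAsFactors = FALSE)
  res <- list(counts = counts, samples = samples, library = library,
              unmatched = unmatched, off_target = off, reads_processed = 0L)
  class(res) <- "ppiseq_counts"
  n <- nrow(reads)
  res$reads_processed <- n
  if (n == 0) return(res)

  seqs <- reads$sequence
  too_short <- nchar(seqs) < layout$read_length
  res$unmatched["malformed_read", "unassigned"] <-
    res$unmatched["malformed_read", "unassigned"] + sum(too_short)

  live <- which(!too_short)
  tag <- paste0(substr(seqs[live], layout$tag1[1], layout$tag1[2]),
                substr(seqs[live], layout$tag2[1], layout$tag2[2]))
  samp <- sample_ids[match(tag, paste0(samples$tag1, samples$tag2))]
  bad_tag <- is.na(samp)
  res$unmatched["tag_fail", "unassigned"] <-
    res$unmatched["tag_fail", "unassigned"] + sum(bad_tag)
  live <- live[!bad_tag]
  samp <- samp[!bad_tag]
  if (length(live) == 0) return(res)

  parsed <- parse_double_barcode(seqs[live], reads$quality[live],
                                 layout = layout,
                                 min_mean_quality = min_mean_quality)
  for (r in c("quality_fail", "pattern1_fail", "pattern2_fail")) {
    tab <- table(factor(samp[parsed$reason == r], levels = sample_ids))
    res$unmatched[r, sample_ids] <- res$unmatched[r, sample_ids] + as.integer(tab)
  }
  ok <- parsed$reason == "ok"
  if (!any(ok)) return(res)
  samp <- samp[ok]
  parsed <- parsed[ok, , drop = FALSE]

  # match unique pairs once, then spread assignments back over reads
  key <- paste0(parsed$barcode1, parsed$barcode2)
  uk <- !duplicated(key)
  entry <- match_to_library(parsed$barcode1[uk], parsed$barcode2[uk],
                            library, max_mismatch = max_mismatch)
  entry_all <- entry[match(key, key[uk])]

  hit <- !is.na(entry_all)
  if (any(hit)) {
    tab <- table(factor(entry_all[hit], levels = library$entry_id),
                 factor(samp[hit], levels = sample_ids))
    res$counts <- res$counts + matrix(as.integer(tab), nrow(library),
                                      length(sample_ids),
                                      dimnames = dimnames(res$counts))
  }
  if (any(!hit)) {
    tab <- table(factor(samp[!hit], levels = sample_ids))
    res$unmatched["library_fail", sample_ids] <-
      res$unmatched["library_fail", sample_ids] + as.integer(tab)
    offt <- .is_off_target(parsed$barcode1[!hit], parsed$barcode2[!hit], library)
    if (any(offt)) {
      agg <- stats::aggregate(
        list(count = rep(1L, sum(offt))),
        by = list(sample_id = samp[!hit][offt],
                  barcode1 = parsed$barcode1[!hit][offt],
                  barcode2 = parsed$barcode2[!hit][offt]),
        FUN = sum)
      res$off_target <- agg[, c("sample_id", "barcode1", "barcode2", "count")]
    }
  }
  res
}

#' @export
print.ppiseq_counts <- function(x, ...) {
  cat("Double-barcode count table:", nrow(x$counts), "library entries x",
      ncol(x$counts), "samples\n")
  cat("  reads processed:", x$reads_processed,
      "| matched:", sum(x$counts),
      "| rejected:", sum(x$unmatched), "\n")
  if (sum(x$unmatched) > 0) {
    by_reason <- rowSums(x$unmatched)
    by_reason <- by_reason[by_reason > 0]
    cat("  rejections:", paste(names(by_reason), by_reason, sep = "=",
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pivot a count table to long trajectory form
#'
#' One row per library entry per growth culture (condition x methotrexate x
#' replicate) with one read-count column per generation, following the
#' standard published column schema (`PPI_pair`, `barcode_pair`, `Bait`,
#' `Prey`, `Bait_barcode`, `Prey_barcode`, `Condition`,
#' `Methotrexate_selection`, `Replicate`, `Reads_<g>_generations`).
#'
#' @param x a `ppiseq_counts` object (or a `sim_result`, which is converted
#'   via [as_ppiseq_counts()]).
#' @return data.frame in trajectory form.
#' @export
as_trajectory_table <- function(x) {
  UseMethod("as_trajectory_table")
}

#' @rdname as_trajectory_table
#' @export
as_trajectory_table.ppiseq_counts <- function(x) {
  stopifnot(inherits(x, "ppiseq_counts"))
  s <- x$samples
  gens <- sort(unique(s$generation))
  pools <- unique(s[, c("condition", "mtx", "replicate")])
  lib <- x$library
  out <- do.call(rbind, lapply(seq_len(nrow(pools)), function(i) {
    p <- pools[i, ]
    df <- data.frame(
      PPI_pair = paste(lib$bait, lib$prey, sep = ":"),
      barcode_pair = lib$entry_id,
      Bait = lib$bait, Prey = lib$prey,
      Bait_barcode = lib$barcode1, Prey_barcode = lib$barcode2,
      Condition = p$condition,
      Methotrexate_selection = p$mtx,
      Replicate = p$replicate,
      stringsAsFactors = FALSE)
    for (g in gens) {
      sid <- make_sample_id(p$condition, p$mtx, p$replicate, g)
      df[[sprintf("Reads_%d_generations", g)]] <-
        if (sid %in% colnames(x$counts)) x$counts[, sid] else NA_integer_
    }
    df
  }))
  rownames(out) <- NULL
  out
}

#' Read or write trajectory tables
#'
#' Trajectory tables are TSVs in the long schema produced by
#' [as_trajectory_table()]; `read_trajectory_table()` accepts any table with
#' the `Reads_<g>_generations` columns (raw and/or `_corrected`).
#'
#' @param path TSV file path.
#' @param x trajectory data.frame.
#' @return `read_trajectory_table()`: data.frame; `write_trajectory_table()`:
#'   `path`, invisibly.
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (length(reads_columns(df)) < 2)
    stop("no Reads_<g>_generations columns found in ", path)
  df
}

#' @rdname read_trajectory_table
#' @export
write_trajectory_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generations covered by a trajectory table
#'
#' @param df trajectory data.frame.
#' @param corrected if `TRUE`, look at the `_corrected` columns.
#' @return Named integer vector: generation -> column name.
#' @export
reads_columns <- function(df, corrected = FALSE) {
  suf <- if (corrected) "_corrected" else ""
  pat <- paste0("^Reads_([0-9]+)_generations", suf, "$")
  cols <- grep(pat, names(df), value = TRUE)
  g <- as.integer(sub(pat, "\\1", cols))
  names(cols) <- g
  cols[order(g)]
}
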