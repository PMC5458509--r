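#' Configure a pooled double-barcode growth simulation
#'
#' The generative model of the pooled competition assay: deterministic
#' exponential growth between transfers, a multinomial bottleneck at each
#' serial dilution, multinomial read sampling at each sequencing time point,
#' and PCR chimera formation by random re-pairing of barcode halves in
#' proportion to their marginal frequencies.
#'
#' The default configuration mirrors the bench experiment: 10 x 10 genotype
#' pairs (one bait and one prey slot reserved for the reporter-free control),
#' 25 barcode pairs per genotype pair (5 bait barcodes x 5 prey barcodes),
#' triplicate cultures diluted 1:8 (about 3 generations) for 4 cycles, so
#' sequencing at generations 0/3/6/9/12, and a mean read depth of 67 reads
#' per barcode per sample. True fitness spans 0 to about 0.4 per generation:
#' genotype pairs involving a control half sit at 0 (no reporter can
#' reconstitute) and the genuine bait x prey pairs take evenly spaced values
#' across the range, mirroring the graded fitness spread of the bench assay.
#'
#' @param n_bait,n_prey genotype counts per mating type, including the
#'   control slot (default 10 each).
#' @param barcodes_per_genotype barcode pairs per genotype pair; must be a
#'   perfect square under the `"cross"` scheme (default 25 = 5 x 5).
#' @param barcode_scheme `"cross"` (each bait/prey genotype gets
#'   `sqrt(barcodes_per_genotype)` barcode halves, and the library is the
#'   complete cross of halves, as in the pairwise-mated pool) or `"unique"`
#'   (every lineage gets its own two halves, leaving the cross space almost
#'   empty, so chimeras are observable off target).
#' @param fitness_map data.frame (`bait`, `prey`, `s`) of true per-generation
#'   fitnesses; defaults as described.
#' @param max_fitness top of the default fitness range (default 0.4).
#' @param bottleneck_size cells transferred at each dilution (default 1e6).
#' @param dilution_factor fold dilution per cycle (default 8); coupled to
#'   `generations_per_cycle` by `2^generations_per_cycle` (a warning is
#'   issued when violated).
#' @param generations_per_cycle doublings per growth cycle (default 3).
#' @param n_cycles dilution cycles (default 4, so 5 time points).
#' @param n_replicates growth replicates (default 3).
#' @param read_depth reads per sample; default 67 per lineage.
#' @param chimera_rate fraction of reads that are chimeric (default 0.002).
#' @param seed RNG seed stored in the config; every simulation from the same
#'   config is bit-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_bait = 10, n_prey = 10, barcodes_per_genotype = 25,
                       barcode_scheme = c("cross", "unique"),
                       fitness_map = NULL,
                       max_fitness = 0.4, bottleneck_size = 1e6,
                       dilution_factor = 8, generations_per_cycle = 3,
                       n_cycles = 4, n_replicates = 3, read_depth = NULL,
                       chimera_rate = 0.002, seed = 1) {
  barcode_scheme <- match.arg(barcode_scheme)
  stopifnot(n_bait >= 1, n_prey >= 1, barcodes_per_genotype >= 1,
            bottleneck_size >= 1, n_cycles >= 1, n_replicates >= 1)
  if (chimera_rate < 0 || chimera_rate >= 1)
    stop("chimera_rate must lie in [0, 1)")
  if (abs(dilution_factor - 2^generations_per_cycle) > 1e-8)
    warning("dilution_factor != 2^generations_per_cycle: ",
            "dilution and generation bookkeeping are inconsistent")
  if (barcode_scheme == "cross" &&
      (sqrt(barcodes_per_genotype) %% 1) != 0)
    stop("cross scheme needs a square barcodes_per_genotype")
  baits <- c(paste0("bait", seq_len(n_bait - 1)), "control")
  preys <- c(paste0("prey", seq_len(n_prey - 1)), "control")
  if (is.null(fitness_map)) {
    fitness_map <- expand.grid(bait = baits, prey = preys,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
    fitness_map$s <- 0
    genuine <- which(fitness_map$bait != "control" &
                       fitness_map$prey != "control")
    fitness_map$s[genuine] <- seq(0, max_fitness,
                                  length.out = length(genuine))
  }
  n_lineages <- nrow(fitness_map) * barcodes_per_genotype
  if (is.null(read_depth)) read_depth <- 67 * n_lineages
  structure(list(
    baits = baits, preys = preys, fitness_map = fitness_map,
    barcodes_per_genotype = barcodes_per_genotype,
    barcode_scheme = barcode_scheme,
    bottleneck_size = bottleneck_size, dilution_factor = dilution_factor,
    generations_per_cycle = generations_per_cycle, n_cycles = n_cycles,
    n_replicates = n_replicates, read_depth = read_depth,
    chimera_rate = chimera_rate, seed = seed,
    n_lineages = n_lineages), class = "sim_config")
}

#' The experiment-scale default configuration
#'
#' 2,500 lineages (100 genotype pairs x 25 barcode pairs), five time points
#' at generations 0/3/6/9/12, triplicate cultures, about 67 reads per barcode
#' per sample, chimera rate 0.2\%.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_experiment_config <- function(seed = 1, ...) {
  sim_config(seed = seed, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pooled-growth simulation config:\n")
  cat(sprintf("  %d x %d genotypes, %d barcode pairs each (%s scheme): %d lineages\n",
              length(x$baits), length(x$preys), x$barcodes_per_genotype,
              x$barcode_scheme, x$n_lineages))
  cat(sprintf("  %d cycles x %g generations, 1:%g dilution, bottleneck %g cells, %d replicate(s)\n",
              x$n_cycles, x$generations_per_cycle, x$dilution_factor,
              x$bottleneck_size, x$n_replicates))
  cat(sprintf("  read depth %g/sample (%.1f per barcode), chimera rate %g, seed %d\n",
              x$read_depth, x$read_depth / x$n_lineages, x$chimera_rate,
              x$seed))
  invisible(x)
}

# Build the designed library for a config (deterministic given the seed).
.sim_library <- function(config) {
  fm <- config$fitness_map
  if (config$barcode_scheme == "cross") {
    k <- as.integer(sqrt(config$barcodes_per_genotype))
    bc1 <- random_barcodes(length(config$baits) * k, which = 1)
    bc2 <- random_barcodes(length(config$preys) * k, which = 2)
    bait_bc <- split(bc1, rep(config$baits, each = k))
    prey_bc <- split(bc2, rep(config$preys, each = k))
    lib <- do.call(rbind, lapply(seq_len(nrow(fm)), function(i) {
      expand.grid(barcode1 = bait_bc[[fm$bait[i]]],
                  barcode2 = prey_bc[[fm$prey[i]]],
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    lib$bait <- rep(fm$bait, each = config$barcodes_per_genotype)
    lib$prey <- rep(fm$prey, each = config$barcodes_per_genotype)
    lib$s_true <- rep(fm$s, each = config$barcodes_per_genotype)
  } else {
    n <- config$n_lineages
    lib <- data.frame(barcode1 = random_barcodes(n, which = 1),
                      barcode2 = random_barcodes(n, which = 2),
                      bait = rep(fm$bait, each = config$barcodes_per_genotype),
                      prey = rep(fm$prey, each = config$barcodes_per_genotype),
                      s_true = rep(fm$s, each = config$barcodes_per_genotype),
                      stringsAsFactors = FALSE)
  }
  lib$is_control <- lib$bait == "control" & lib$prey == "control"
  lib$entry_id <- sprintf("BC%05d", seq_len(nrow(lib)))
  lib[, c("entry_id", "barcode1", "barcode2", "bait", "prey", "is_control",
          "s_true")]
}

#' Simulate the pooled competition experiment
#'
#' Runs the generative model of [sim_config()]: each replicate culture starts
#' from a multinomial draw of `bottleneck_size` cells over lineages (uniform
#' expected frequencies), grows deterministically - lineage cells multiply by
#' `exp(g * (ln 2 + s))` per cycle of `g` generations (a neutral lineage
#' doubles once per generation; fitness `s` is the per-generation advantage
#' on the natural-log scale, the same parameterization the estimator fits),
#' normalized to the culture capacity - and is bottlenecked by multinomial
#' sampling at each
#' 1:`dilution_factor` transfer. At every time point (including generation 0)
#' reads are drawn multinomially over lineage frequencies; a binomial share
#' `chimera_rate` of reads instead re-pairs barcode halves at random from the
#' two marginal half distributions. Chimeric reads landing on designed pairs
#' inflate their counts; those landing outside are recorded in the off-target
#' ledger.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_result`: list with `library` (designed
#'   entries + `s_true`), `truth` (per-lineage true fitness), `cells`
#'   (lineage x time point x replicate), `reads_clean` and `reads_observed`
#'   (lineage x sample count matrices, before/after chimerism), `off_target`
#'   ledger, `chimera_reads` per sample, `samples`, and `config`.
#' @export
simulate_pool <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lib <- .sim_library(config)
  n <- nrow(lib)
  if (config$bottleneck_size < n)
    warning("bottleneck smaller than lineage count: heavy extinction expected")
  g <- config$generations_per_cycle
  gens <- seq(0, by = g, length.out = config$n_cycles + 1)
  # neutral lineages double once per generation; fitness s is the
  # per-generation advantage on the natural-log scale, matching the
  # estimator's frequency model exactly
  growth <- exp(g * (log(2) + lib$s_true))

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         generation = gens, KEEP.OUT.ATTRS = FALSE)
  samples <- samples[order(samples$replicate, samples$generation), ]
  samples$condition <- "DMSO"
  samples$mtx <- TRUE
  tags <- .sample_tags(nrow(samples))
  samples$tag1 <- tags$tag1
  samples$tag2 <- tags$tag2
  samples$sample_id <- make_sample_id(samples$condition, samples$mtx,
                                      samples$replicate, samples$generation)
  rownames(samples) <- NULL

  cells <- array(0, dim = c(n, length(gens), config$n_replicates),
                 dimnames = list(lib$entry_id, gens, NULL))
  reads_clean <- reads_obs <- matrix(
    0L, n, nrow(samples), dimnames = list(lib$entry_id, samples$sample_id))
  off_all <- list()
  chim_reads <- stats::setNames(integer(nrow(samples)), samples$sample_id)

  for (r in seq_len(config$n_replicates)) {
    cur <- as.numeric(stats::rmultinom(1, config$bottleneck_size, rep(1, n)))
    for (ti in seq_along(gens)) {
      cells[, ti, r] <- cur
      sid <- samples$sample_id[samples$replicate == r &
                                 samples$generation == gens[ti]]
      freq <- cur / sum(cur)
      seqd <- .sequence_sample(freq, lib, config$read_depth,
                               config$chimera_rate)
      reads_clean[, sid] <- seqd$clean
      reads_obs[, sid] <- seqd$observed
      chim_reads[sid] <- seqd$n_chimeric
      if (nrow(seqd$off_target) > 0) {
        seqd$off_target$sample_id <- sid
        off_all[[sid]] <- seqd$off_target
      }
      if (ti < length(gens)) {
        grown <- cur * growth
        cur <- as.numeric(stats::rmultinom(1, config$bottleneck_size,
                                           grown / sum(grown)))
      }
    }
  }
  off <- if (length(off_all) > 0) {
    o <- do.call(rbind, off_all)
    rownames(o) <- NULL
    o[, c("sample_id", "barcode1", "barcode2", "count")]
  } else {
    data.frame(sample_id = character(0), barcode1 = character(0),
               barcode2 = character(0), count = integer(0))
  }
  structure(list(
    library = lib,
    truth = data.frame(entry_id = lib$entry_id, bait = lib$bait,
                       prey = lib$prey, is_control = lib$is_control,
                       s_true = lib$s_true, stringsAsFactors = FALSE),
    cells = cells, reads_clean = reads_clean, reads_observed = reads_obs,
    off_target = off, chimera_reads = chim_reads,
    samples = samples, generations = gens, config = config),
    class = "sim_result")
}

# one sample's sequencing: clean multinomial reads plus chimeric re-pairing
.sequence_sample <- function(freq, lib, depth, eps) {
  n_chim <- stats::rbinom(1, depth, eps)
  clean <- as.integer(stats::rmultinom(1, depth - n_chim, freq))
  observed <- clean
  off <- data.frame(barcode1 = character(0), barcode2 = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  if (n_chim > 0) {
    p1 <- c(tapply(freq, lib$barcode1, sum))
    p2 <- c(tapply(freq, lib$barcode2, sum))
    h1 <- sample(names(p1), n_chim, replace = TRUE, prob = p1)
    h2 <- sample(names(p2), n_chim, replace = TRUE, prob = p2)
    pair <- paste0(h1, h2)
    designed <- paste0(lib$barcode1, lib$barcode2)
    idx <- match(pair, designed)
    hit <- !is.na(idx)
    if (any(hit)) {
      add <- tabulate(idx[hit], nbins = nrow(lib))
      observed <- observed + add
    }
    if (any(!hit)) {
      agg <- stats::aggregate(list(count = rep(1L, sum(!hit))),
                              by = list(barcode1 = h1[!hit],
                                        barcode2 = h2[!hit]), FUN = sum)
      off <- agg
    }
  }
  list(clean = clean, observed = as.integer(observed), off_target = off,
       n_chimeric = n_chim)
}

# short multiplexing tags, unique as pairs
.sample_tags <- function(n) {
  bases <- c("A", "C", "G", "T")
  make <- function(m) vapply(seq_len(m), function(i)
    paste(sample(bases, 6, replace = TRUE), collapse = ""), character(1))
  repeat {
    t1 <- make(n); t2 <- make(n)
    if (!anyDuplicated(paste(t1, t2))) return(list(tag1 = t1, tag2 = t2))
  }
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated pooled-growth experiment:\n")
  cat(sprintf("  %d lineages, %d samples (%d replicates x %d time points)\n",
              nrow(x$library), nrow(x$samples), x$config$n_replicates,
              length(x$generations)))
  cat(sprintf("  total reads %g (chimeric %g, %.3f%%)\n",
              sum(x$reads_observed) + sum(x$off_target$count),
              sum(x$chimera_reads),
              100 * sum(x$chimera_reads) /
                (sum(x$reads_observed) + sum(x$off_target$count))))
  invisible(x)
}

#' Convert a simulation to a count table or trajectory table
#'
#' `as_ppiseq_counts()` packages the simulator's observed (chimera-inflated)
#' counts and off-target ledger as the `ppiseq_counts` object that
#' [demultiplex_and_tabulate()] would produce from its reads.
#'
#' @param sim a `sim_result`.
#' @return `ppiseq_counts` object.
#' @export
as_ppiseq_counts <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  reasons <- c("malformed_read", "tag_fail", "quality_fail",
               "pattern1_fail", "pattern2_fail", "library_fail")
  unmatched <- matrix(0L, length(reasons), nrow(sim$samples) + 1L,
                      dimnames = list(reasons,
                                      c(sim$samples$sample_id, "unassigned")))
  if (nrow(sim$off_target) > 0) {
    t <- tapply(sim$off_target$count, sim$off_target$sample_id, sum)
    unmatched["library_fail", names(t)] <- as.integer(t)
  }
  structure(list(counts = sim$reads_observed,
                 samples = sim$samples,
                 library = sim$library[, c("entry_id", "barcode1", "barcode2",
                                           "bait", "prey", "is_control")],
                 unmatched = unmatched, off_target = sim$off_target,
                 reads_processed = sum(sim$reads_observed) +
                   sum(sim$off_target$count)),
            class = "ppiseq_counts")
}

#' @rdname as_ppiseq_counts
#' @param x a `sim_result`.
#' @export
as_trajectory_table.sim_result <- function(x) {
  as_trajectory_table(as_ppiseq_counts(x))
}

#' Write synthetic FASTQ for a simulation
#'
#' Emits one FASTQ file per sample containing the observed reads
#' (tag1 + barcode1 + loxP + barcode2 + tag2), including the off-target
#' chimeric pairs, at a constant quality. Error-free output round-trips
#' through [demultiplex_and_tabulate()] to the simulator's observed count
#' matrix exactly.
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @param quality constant Phred quality per base (default 40).
#' @param layout amplicon layout, see [default_read_layout()].
#' @param samples subset of sample ids to write (default all).
#' @return Named character vector of file paths.
#' @export
emit_fastq <- function(sim, dir, quality = 40,
                       layout = default_read_layout(), samples = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qchar <- rawToChar(as.raw(quality + 33L))
  sids <- samples %||% sim$samples$sample_id
  out <- character(0)
  for (sid in sids) {
    srow <- sim$samples[sim$samples$sample_id == sid, ]
    cnt <- sim$reads_observed[, sid]
    b1 <- rep(sim$library$barcode1, cnt)
    b2 <- rep(sim$library$barcode2, cnt)
    off <- sim$off_target[sim$off_target$sample_id == sid, , drop = FALSE]
    if (nrow(off) > 0) {
      b1 <- c(b1, rep(off$barcode1, off$count))
      b2 <- c(b2, rep(off$barcode2, off$count))
    }
    seqs <- paste0(srow$tag1, b1, LOXP_SEQ, b2, srow$tag2)
    path <- file.path(dir, paste0(sid, ".fastq"))
    if (length(seqs) == 0) {
      file.create(path)
    } else {
      qual <- strrep(qchar, nchar(seqs[1]))
      writeLines(rbind(paste0("@read", seq_along(seqs)), seqs,
                       "+", rep(qual, length(seqs))), path)
    }
    out[sid] <- path
  }
  out
}
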