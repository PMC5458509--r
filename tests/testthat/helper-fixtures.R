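# Shared fixtures: all synthetic, built in code at test time.

# a small designed library with well-separated barcodes
tiny_library <- function(n = 10, seed = 42) {
  set.seed(seed)
  data.frame(entry_id = sprintf("BC%03d", seq_len(n)),
             barcode1 = random_barcodes(n, which = 1),
             barcode2 = random_barcodes(n, which = 2),
             bait = rep(c("baitA", "baitB"), length.out = n),
             prey = rep(c("preyA", "preyB"), length.out = n),
             is_control = FALSE,
             stringsAsFactors = FALSE)
}

# assemble synthetic reads for a library entry under the default layout
make_read <- function(lib_row, tag1 = "AAAAAA", tag2 = "CCCCCC",
                      quality = 40) {
  seqs <- paste0(tag1, lib_row$barcode1,
                 "ATAACTTCGTATAATGTATGCTATACGAAGTTAT",
                 lib_row$barcode2, tag2)
  data.frame(sequence = seqs,
             quality = strrep(rawToChar(as.raw(quality + 33L)),
                              nchar(seqs)),
             stringsAsFactors = FALSE)
}

one_sample_sheet <- function(tag1 = "AAAAAA", tag2 = "CCCCCC") {
  s <- data.frame(tag1 = tag1, tag2 = tag2, condition = "DMSO", mtx = TRUE,
                  replicate = 1L, generation = 0L, stringsAsFactors = FALSE)
  s$sample_id <- make_sample_id(s$condition, s$mtx, s$replicate, s$generation)
  s
}

# substitute k bases of a sequence at fixed positions, avoiding no-ops
substitute_bases <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- swap[chars[positions]]
  paste(chars, collapse = "")
}

# exhaustive Hamming distances of a 76-mer to every library entry (oracle)
hamming_to_library <- function(query, lib) {
  ref <- paste0(lib$barcode1, lib$barcode2)
  vapply(ref, function(r) {
    sum(strsplit(r, "")[[1]] != strsplit(query, "")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
}

# a fast, small but non-trivial simulated experiment
small_sim <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(n_bait = 4, n_prey = 4, barcodes_per_genotype = 4,
         read_depth = 6000, n_replicates = 2, seed = seed),
    list(...))
  simulate_pool(do.call(sim_config, args))
}
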