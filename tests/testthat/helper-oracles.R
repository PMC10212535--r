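# independent reference implementations used as oracles

# naive O(W * n) sliding extremum
naive_sliding <- function(v, W, fun = min) {
  vapply(seq_len(length(v) - W + 1L),
         function(i) fun(v[i:(i + W - 1L)]), numeric(1))
}

# base-R reverse complement, independent of the package's C++ path
revcomp_r <- function(x) {
  vapply(x, function(w) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(w, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_words <- function(n, len) {
  codes <- sample.int(4L, n * len, replace = TRUE) - 1L
  kamq:::cpp_codes_to_dna(codes, len)
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force s-abundance: for every distinct s-mer, scan all k-mers for
# substring containment (quadratic, independent of expand/tapply)
brute_sab <- function(kmers, counts, s, canonicalize = FALSE) {
  get_smers <- function(km) {
    sm <- substring(km, 1:(nchar(km) - s + 1L), s:nchar(km))
    if (canonicalize) sm <- canonical(sm)
    sm
  }
  all_smers <- unique(unlist(lapply(kmers, get_smers)))
  out <- vapply(all_smers, function(sm) {
    max(counts[vapply(kmers, function(km) sm %in% get_smers(km), logical(1))])
  }, numeric(1))
  storage.mode(out) <- "integer"
  out
}

# instrumented fixed-window minimum: counts comparisons to verify the O(n)
# bound empirically (no W factor)
fixed_window_min_count <- function(v, W) {
  n <- length(v)
  comparisons <- 0L
  run <- v[1]
  block_start <- 1L
  v <- as.numeric(v)
  for (t in seq_len(n)) {
    o <- t - block_start
    if (o == 0L) run <- v[t]
    else { run <- min(run, v[t]); comparisons <- comparisons + 1L }
    i <- t - W + 1L
    if (i >= 1L) {
      if (o == W - 1L) v[i] <- run
      else { v[i] <- min(run, v[i]); comparisons <- comparisons + 1L }
    }
    if (o == W - 1L || t == n) {
      u <- t - 1L
      while (u >= block_start) {
        v[u] <- min(v[u], v[u + 1L]); comparisons <- comparisons + 1L
        u <- u - 1L
      }
      block_start <- t + 1L
    }
  }
  list(r = v[seq_len(n - W + 1L)], comparisons = comparisons)
}

# tiny scenario shared by several tests (fast to build)
tiny_scenario <- function(seed = 7, ...) {
  synthetic_scenario(seed = seed, genome_length = 2000L, k = 21L, z = 3L,
                     b = 5L, read_count = 20L, read_length = 60L, ...)
}
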