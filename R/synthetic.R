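#' @section Reproducibility:
#' All generators draw exclusively from R's RNG, seeded per operation by a
#' label-specific derivation from the scenario seed, so adding operations
#' never perturbs earlier draws and every artifact is bit-reproducible from
#' `(seed, parameters)`.
#' @name synthetic-data
NULL

# temporary seed scope: restores the caller's RNG state on exit
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# label-split substreams of a scenario seed; fixed offsets keep streams
# stable as operations are added, and the result stays below 2^31
sub_seed <- function(seed, label) {
  offsets <- c(genome = 11L, absent_genome = 23L, abundance = 37L,
               reads = 51L, absent_kmers = 67L, probes = 83L)
  if (!label %in% names(offsets)) stop("unknown seed label: ", label)
  (as.numeric(seed) %% 1000003) * 2011 + offsets[[label]]
}

#' Generate a random genome
#'
#' Uniform i.i.d. bases over ACGT; deterministic per seed.
#'
#' @param length genome length in bases.
#' @param seed integer seed.
#' @return A single DNA string.
#' @export
generate_genome <- function(length, seed) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1")
  codes <- with_seed(seed, sample.int(4L, length, replace = TRUE) - 1L)
  cpp_codes_to_dna(codes, length)
}

#' Sample reads from a genome
#'
#' Reads are substrings at uniform start positions, reverse-complemented
#' with probability `revcomp_prob`.
#'
#' @param genome a DNA string.
#' @param n number of reads.
#' @param read_length read length in bases (`<= nchar(genome)`).
#' @param revcomp_prob probability a read is reverse-complemented.
#' @param seed integer seed.
#' @param id_prefix read identifier prefix.
#' @return A `data.frame` with columns `id`, `seq`, `qual` (all `NA`).
#' @export
sample_reads <- function(genome, n, read_length, revcomp_prob = 0, seed = 1L,
                         id_prefix = "read") {
  L <- nchar(genome)
  if (read_length > L) stop("read_length exceeds the genome length")
  if (n < 0) stop("n must be >= 0")
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    rc <- runif(n) < revcomp_prob
  })
  seqs <- substring(genome, starts, starts + read_length - 1L)
  if (any(rc)) seqs[rc] <- reverse_complement(seqs[rc])
  data.frame(id = paste0(id_prefix, "_", seq_len(n)), seq = seqs,
             qual = NA_character_)
}

default_abundance_profile <- function(mean = 3, cap = 31L) {
  # geometric on {1, 2, ...} with the given mean, capped pre-discretization
  p <- 1 / mean
  function(n) pmin(1L + stats::rgeom(n, prob = p), as.integer(cap))
}

#' Exact counted k-mers of a genome with a planted abundance profile
#'
#' Enumerates the distinct (optionally canonical) k-mers of the genome by
#' exact substring scan — no sketching — and assigns each a count drawn from
#' the abundance profile (default: geometric with mean 3, capped at 31).
#'
#' @param genome a DNA string.
#' @param k k-mer length.
#' @param abundance_profile `NULL` for the default, or a `function(n)`
#'   returning `n` counts `>= 1`.
#' @param canonical collapse to canonical k-mers.
#' @param seed integer seed (for the abundance draw).
#' @return A [counted_kmers()] table.
#' @export
counted_kmers_from_genome <- function(genome, k, abundance_profile = NULL,
                                      canonical = FALSE, seed = 1L) {
  L <- nchar(genome)
  if (L < k) stop("genome shorter than k")
  kmers <- substring(genome, 1:(L - k + 1L), k:L)
  if (canonical) kmers <- canonical(kmers)
  kmers <- unique(kmers)
  if (is.null(abundance_profile)) abundance_profile <- default_abundance_profile()
  counts <- with_seed(seed, abundance_profile(length(kmers)))
  if (any(counts < 1)) stop("abundance profile produced counts < 1")
  counted_kmers(kmers, counts)
}

#' Random k-mers verified absent from the truth
#'
#' Rejection-sampling of uniform random k-mers, keeping those with true
#' abundance 0 (canonical-consistent). For realistic `k` the acceptance rate
#' is essentially 1 (collision probability at most `|truth| / 4^k`).
#'
#' @param truth a [ground_truth()] object.
#' @param n number of absent k-mers wanted.
#' @param seed integer seed.
#' @param max_tries bound on rejection rounds before giving up (a truth
#'   table saturating the k-mer space cannot be probed this way).
#' @return Character vector of `n` absent k-mers.
#' @export
generate_absent_kmers <- function(truth, n, seed = 1L, max_tries = 100L) {
  stopifnot(inherits(truth, "kamq_truth"))
  n <- as.integer(n)
  if (n == 0L) return(character())
  k <- truth$config$k
  out <- character(0)
  with_seed(seed, {
    for (round in seq_len(max_tries)) {
      m <- max(n - length(out), 1L)
      codes <- sample.int(4L, m * k, replace = TRUE) - 1L
      cand <- cpp_codes_to_dna(codes, k)
      cand <- cand[truth_count(truth, cand) == 0L]
      out <- c(out, cand)
      if (length(out) >= n) break
    }
  })
  if (length(out) < n)
    stop("could not find ", n, " absent k-mers after ", max_tries,
         " rounds; the truth saturates the k-mer space")
  out[seq_len(n)]
}

#' A reproducible index/query scenario
#'
#' Describes a complete synthetic experiment: an indexed random genome with
#' a planted abundance profile, a disjoint "absent" genome supplying
#' negative query material, a read sample mixing the two, and the index
#' parameters. `nb_slots = NULL` sizes the filter so that the per-s-mer
#' false positive rate at the scenario's `z` equals `target_smer_fpr`
#' (solving `1 - (1 - 1/m)^n = p` for `m` with `n` the distinct s-mer
#' count), mirroring index sizings quoted as a per-element false positive
#' rate.
#'
#' @param seed master seed; every derived artifact is reproducible from it.
#' @param genome_length indexed genome length in bases.
#' @param k,z,b,nb_slots index parameters (see [kamq_config()]).
#' @param discretization,canonical index parameters (see [kamq_config()]).
#' @param read_count,read_length query read sample shape.
#' @param fraction_absent_reads proportion of query reads drawn from the
#'   disjoint genome.
#' @param revcomp_prob probability a query read is reverse-complemented.
#' @param target_smer_fpr per-s-mer false positive rate used to size the
#'   filter when `nb_slots` is `NULL`.
#' @param abundance_profile `NULL` or a `function(n)` (see
#'   [counted_kmers_from_genome()]).
#' @return An object of class `kamq_scenario` (a parameter list).
#' @export
synthetic_scenario <- function(seed = 1L, genome_length = 20000L, k = 31L,
                               z = 3L, b = 5L, nb_slots = NULL,
                               discretization = "log2", canonical = FALSE,
                               read_count = 100L, read_length = 100L,
                               fraction_absent_reads = 0.5, revcomp_prob = 0,
                               target_smer_fpr = 0.25,
                               abundance_profile = NULL) {
  structure(
    list(seed = seed, genome_length = as.integer(genome_length),
         k = as.integer(k), z = as.integer(z), b = as.integer(b),
         nb_slots = nb_slots, discretization = discretization,
         canonical = isTRUE(canonical), read_count = as.integer(read_count),
         read_length = as.integer(read_length),
         fraction_absent_reads = fraction_absent_reads,
         revcomp_prob = revcomp_prob, target_smer_fpr = target_smer_fpr,
         abundance_profile = abundance_profile),
    class = "kamq_scenario")
}

#' Materialize a scenario's data
#'
#' Generates the indexed genome, a disjoint absent genome (regenerated with
#' a shifted seed until the two share no k-mer), the counted k-mer table,
#' the ground truth, the read sample (present reads from the indexed
#' genome, absent reads from the disjoint one), and the built index.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A list with elements `scenario`, `config`, `genome`,
#'   `absent_genome`, `table`, `truth`, `reads` (with a logical
#'   `from_absent` column), and `index`.
#' @export
build_scenario_data <- function(scenario) {
  stopifnot(inherits(scenario, "kamq_scenario"))
  sc <- scenario
  genome <- generate_genome(sc$genome_length, sub_seed(sc$seed, "genome"))
  kmer_set <- function(g) {
    ks <- substring(g, 1:(nchar(g) - sc$k + 1L), sc$k:nchar(g))
    if (sc$canonical) ks <- canonical(ks)
    unique(ks)
  }
  indexed_set <- kmer_set(genome)
  absent_genome <- NULL
  for (attempt in 0:20) {
    cand <- generate_genome(sc$genome_length,
                            sub_seed(sc$seed, "absent_genome") + attempt)
    if (!any(kmer_set(cand) %in% indexed_set)) { absent_genome <- cand; break }
  }
  if (is.null(absent_genome))
    stop("could not generate a k-mer-disjoint absent genome")

  table <- counted_kmers_from_genome(
    genome, sc$k, abundance_profile = sc$abundance_profile,
    canonical = sc$canonical, seed = sub_seed(sc$seed, "abundance"))

  nb_slots <- sc$nb_slots
  if (is.null(nb_slots)) {
    n_smers <- length(compute_sab(table, sc$k - sc$z,
                                  canonical = sc$canonical))
    nb_slots <- ceiling(n_smers / -log1p(-sc$target_smer_fpr))
  }
  config <- kamq_config(k = sc$k, z = sc$z, b = sc$b, nb_slots = nb_slots,
                        discretization = sc$discretization,
                        canonical = sc$canonical)
  truth <- ground_truth(table, config)

  n_absent <- round(sc$read_count * sc$fraction_absent_reads)
  n_present <- sc$read_count - n_absent
  reads_p <- sample_reads(genome, n_present, sc$read_length,
                          revcomp_prob = sc$revcomp_prob,
                          seed = sub_seed(sc$seed, "reads"),
                          id_prefix = "present")
  reads_a <- sample_reads(absent_genome, n_absent, sc$read_length,
                          revcomp_prob = sc$revcomp_prob,
                          seed = sub_seed(sc$seed, "reads") + 1,
                          id_prefix = "absent")
  reads <- rbind(reads_p, reads_a)
  reads$from_absent <- rep(c(FALSE, TRUE), c(n_present, n_absent))

  list(scenario = sc, config = config, genome = genome,
       absent_genome = absent_genome, table = table, truth = truth,
       reads = reads, index = build_index(table, config))
}

#' False-positive-rate experiment across z values
#'
#' For each `z`, builds an index at a *fixed* filter size from the
#' scenario's table, probes `n_probes` uniform random absent k-mers and all
#' indexed k-mers, classifies every call against the exact truth, and
#' tabulates the empirical false positive rate, the construction share of
#' the false positives, and the incorrect-abundance rate over true
#' positives. The analytic s-mer saturation probability
#' `1 - (1 - 1/4^s)^n` (with `n` the indexed genome length) is reported per
#' row. Absent probes are i.i.d. uniform, so the independence model
#' `p^(z+1)` applies to them.
#'
#' @param scenario a [synthetic_scenario()]; its `nb_slots` (or the size
#'   derived from its own `z` and `target_smer_fpr`) is held fixed across
#'   the sweep.
#' @param z_values integer vector of shrinkage values to sweep.
#' @param n_probes number of absent k-mer probes per row.
#' @return A `data.frame` with one row per `z`: `z`, `s`, `nb_slots`,
#'   `load_factor`, `empirical_fpr`, `construction_fp_share`,
#'   `incorrect_abundance_rate`, `saturation_prob`.
#' @export
fpr_experiment <- function(scenario, z_values = c(0L, 1L, 2L, 3L),
                           n_probes = 20000L) {
  stopifnot(inherits(scenario, "kamq_scenario"))
  data <- build_scenario_data(scenario)
  nb_slots <- data$config$nb_slots
  rows <- lapply(as.integer(z_values), function(z) {
    cfg <- kamq_config(k = scenario$k, z = z, b = scenario$b,
                       nb_slots = nb_slots,
                       discretization = scenario$discretization,
                       canonical = scenario$canonical)
    idx <- build_index(data$table, cfg)
    truth <- ground_truth(data$table, cfg)
    absent <- generate_absent_kmers(truth, n_probes,
                                    seed = sub_seed(scenario$seed, "probes"))
    indexed <- names(truth$kmer_abundance)
    probes <- c(absent, indexed)
    reported <- query_kmers(idx, probes, report = "stored")
    cls <- classify_calls(probes, reported, truth)
    sm <- summarize_calls(cls)
    data.frame(z = z, s = cfg$s, nb_slots = nb_slots,
               load_factor = load_factor(idx$filter),
               empirical_fpr = sm$fpr,
               construction_fp_share = sm$construction_fp_share,
               incorrect_abundance_rate = sm$incorrect_abundance_rate,
               saturation_prob = smer_saturation_prob(
                 cfg$s, scenario$genome_length))
  })
  do.call(rbind, rows)
}

#' Query a batch of k-mers
#'
#' Reports the rank of each k-mer queried on its own (each word is one
#' window of `z + 1` s-mer responses).
#'
#' @param index a `kamq_index`.
#' @param kmers character vector of words of length `k`.
#' @param optimize use the absent-s-mer skipping path.
#' @param report `"rank"` or `"stored"` (see [query_sequence()]).
#' @return Integer vector of reported ranks (or stored codes).
#' @export
query_kmers <- function(index, kmers, optimize = TRUE,
                        report = c("rank", "stored")) {
  report <- match.arg(report)
  vapply(kmers, function(s) {
    r <- query_sequence(index, s, optimize = optimize, report = report)
    if (length(r) != 1L) stop("query_kmers expects words of length k")
    r[[1L]]
  }, integer(1), USE.NAMES = FALSE)
}
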