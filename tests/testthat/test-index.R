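test_that("discretization maps abundances to ranks and decodes intervals", {
  sp <- discretization_spec("log2", b = 5)
  expect_equal(discretize(8, sp), 3L)
  expect_equal(unlist(decode_rank(3, sp)[c("lo", "hi")]), c(lo = 8, hi = 15))
  expect_equal(discretize(1, sp), 0L)
  expect_equal(discretize(2^40, sp), 31L)       # cap at 2^b - 1
  expect_equal(discretize(c(1, 2, 3, 4, 1023, 1024), sp),
               c(0L, 1L, 1L, 2L, 9L, 10L))
  expect_true(is.infinite(decode_rank(31, sp)$hi))

  sp10 <- discretization_spec("log10", b = 3)
  expect_equal(discretize(c(1, 9, 10, 99, 1e9), sp10), c(0L, 0L, 1L, 1L, 7L))

  spi <- discretization_spec("identity", b = 5)
  expect_equal(discretize(c(1, 30, 31, 99), spi), c(1L, 30L, 31L, 31L))
  expect_equal(decode_rank(7, spi)$lo, 7)

  expect_error(discretize(0, sp), "must be >= 1")
  expect_error(decode_rank(32, sp), "out of range")
})

test_that("index-effective rank caps one bin below 2^b - 1 under log modes", {
  sp <- discretization_spec("log2", b = 3)
  # stored codes are rank + 1 (absence sentinel), saturating at 7: rank <= 6
  expect_equal(index_rank(c(1, 2, 63, 64, 1e9), sp), c(0L, 1L, 5L, 6L, 6L))
  spi <- discretization_spec("identity", b = 3)
  expect_equal(index_rank(c(1, 6, 7, 99), spi), c(1L, 6L, 7L, 7L))
})

test_that("s-abundance is the max count over k-mers containing each s-mer", {
  tab <- counted_kmers(c("ACGTA", "CGTAC"), c(5, 3))
  sab <- compute_sab(tab, 4)
  expect_equal(sab[c("ACGT", "CGTA", "GTAC")],
               c(ACGT = 5L, CGTA = 5L, GTAC = 3L))
  expect_length(sab, 3L)

  one <- compute_sab(counted_kmers("ACGTA", 7), 4)
  expect_equal(unname(one), c(7L, 7L))

  expect_error(compute_sab(tab, 6), "exceeds")
})

test_that("s-abundance agrees with quadratic substring-containment brute force", {
  set.seed(601)
  g <- random_seq(320)
  kmers <- unique(substring(g, 1:314, 7:320))
  counts <- sample(1:50, length(kmers), replace = TRUE)
  tab <- counted_kmers(kmers, counts)
  for (canon in c(FALSE, TRUE)) {
    sab <- compute_sab(tab, 4, canonical = canon)
    oracle <- brute_sab(kmers, counts, 4, canonicalize = canon)
    expect_identical(sab[sort(names(sab))], oracle[sort(names(oracle))])
  }
})

test_that("collision-free build stores the discretized s-abundance exactly", {
  tab <- counted_kmers(c("ACGTA", "CGTAC"), c(5, 3))
  cfg <- kamq_config(k = 5, z = 1, b = 8, nb_slots = 2^20,
                     discretization = "identity")
  idx <- build_index(tab, cfg)
  expect_equal(lookup(idx$filter, "CGTA"), 5L)  # shared s-mer: max(5, 3)
  expect_equal(lookup(idx$filter, "GTAC"), 3L)
  expect_equal(as.integer(query_sequence(idx, "ACGTAC")), c(5L, 3L))

  set.seed(607)
  g <- random_seq(2000)
  tab2 <- counted_kmers_from_genome(g, 21, seed = 11)
  cfg2 <- kamq_config(k = 21, z = 3, b = 5, nb_slots = 2^22)
  idx2 <- build_index(tab2, cfg2)
  sab <- compute_sab(tab2, cfg2$s)
  smers <- names(sab)
  h <- hash_smer(smers, cfg2$nb_slots)
  clash <- h %in% h[duplicated(h)]
  spec <- discretization_spec(cfg2$discretization, cfg2$b)
  want_stored <- kamq:::rank_to_stored(discretize(unname(sab), spec), spec)
  got <- lookup(idx2$filter, smers)
  expect_true(all(got >= want_stored))          # never underestimates
  expect_identical(got[!clash], want_stored[!clash])  # exact without collisions
})

test_that("z = 0 build is exactly a plain counting Bloom filter on k-mers", {
  set.seed(613)
  g <- random_seq(1500)
  tab <- counted_kmers_from_genome(g, 21, seed = 3)
  cfg <- kamq_config(k = 21, z = 0, b = 5, nb_slots = 5000)
  idx <- build_index(tab, cfg)

  spec <- discretization_spec(cfg$discretization, cfg$b)
  plain <- counting_filter(cfg$nb_slots, cfg$b)
  insert_max(plain, tab$kmer,
             kamq:::rank_to_stored(discretize(tab$count, spec), spec))
  expect_identical(idx$filter$slots, plain$slots)

  probes <- c(tab$kmer[1:50], random_words(200, 21))
  expect_identical(query_kmers(idx, probes, report = "stored"),
                   lookup(plain, probes))
})

test_that("raw abundance mode indexes a counted s-mer table directly", {
  smers <- c("ACGT", "CGTA", "GGGG")
  tab <- counted_kmers(smers, c(9, 2, 4))
  cfg <- kamq_config(k = 6, z = 2, b = 8, nb_slots = 2^16,
                     discretization = "identity", abundance_mode = "raw")
  idx <- build_index(tab, cfg)
  expect_equal(lookup(idx$filter, smers), c(9L, 2L, 4L))
  # a k-mer table is rejected in raw mode
  expect_error(build_index(counted_kmers("ACGTAA", 1), cfg), "raw mode")
})

test_that("query ranks are the window minimum of s-mer responses", {
  set.seed(617)
  g <- random_seq(800)
  k <- 21; z <- 3
  tab <- counted_kmers_from_genome(g, k, seed = 5)
  cfg <- kamq_config(k = k, z = z, b = 5, nb_slots = 2^22)
  idx <- build_index(tab, cfg)
  sab <- compute_sab(tab, cfg$s)
  spec <- discretization_spec(cfg$discretization, cfg$b)

  reads <- sample_reads(g, 20, 80, seed = 21)
  for (rs in reads$seq) {
    got <- query_sequence(idx, rs, report = "stored")
    attributes(got) <- NULL
    sm <- substring(rs, 1:(nchar(rs) - cfg$s + 1), cfg$s:nchar(rs))
    sab_true <- unname(sab[sm]); sab_true[is.na(sab_true)] <- 0L
    stored_true <- ifelse(sab_true == 0, 0L,
                          kamq:::rank_to_stored(discretize(pmax(sab_true, 1), spec), spec))
    oracle <- as.integer(naive_sliding(stored_true, z + 1, min))
    expect_identical(got, oracle)
  }

  # sequences shorter than k yield an empty vector
  expect_length(query_sequence(idx, substr(g, 1, k - 1)), 0L)
  # non-ACGT characters force rank 0 on every covering k-mer
  read <- substr(g, 1, 60)
  substr(read, 30, 30) <- "N"
  r <- query_sequence(idx, read, report = "stored")
  expect_true(all(r[(30 - k + 1):30] == 0L))
})

test_that("optimized query is bit-identical to the unoptimized path", {
  set.seed(619)
  g <- random_seq(3000)
  tab <- counted_kmers_from_genome(g, 21, seed = 9)
  cfg <- kamq_config(k = 21, z = 3, b = 5, nb_slots = 6000)
  idx <- build_index(tab, cfg)
  lookups_saved <- FALSE
  for (i in 1:300) {
    # mix of present stretches, absent stretches, and chimeras
    kind <- i %% 3
    rs <- if (kind == 0) sample_reads(g, 1, 90, seed = i)$seq
          else if (kind == 1) random_seq(90)
          else paste0(sample_reads(g, 1, 45, seed = i)$seq, random_seq(45))
    fast <- query_sequence(idx, rs, optimize = TRUE)
    slow <- query_sequence(idx, rs, optimize = FALSE)
    expect_identical(as.integer(fast), as.integer(slow))
    expect_lte(attr(fast, "lookups"), attr(slow, "lookups"))
    if (attr(fast, "lookups") < attr(slow, "lookups")) lookups_saved <- TRUE
  }
  expect_true(lookups_saved)  # skipping engaged on absent stretches
})

test_that("canonical indexing answers strand-flipped queries identically", {
  set.seed(623)
  g <- random_seq(1200)
  tab <- counted_kmers_from_genome(g, 21, canonical = TRUE, seed = 13)
  cfg <- kamq_config(k = 21, z = 3, b = 5, nb_slots = 2^20, canonical = TRUE)
  idx <- build_index(tab, cfg)
  read <- substr(g, 101, 200)
  fwd <- query_sequence(idx, read, report = "stored")
  bwd <- query_sequence(idx, revcomp_r(read), report = "stored")
  attributes(fwd) <- NULL; attributes(bwd) <- NULL
  expect_identical(bwd, rev(fwd))
  expect_true(all(fwd > 0))
})

test_that("file queries honor output modes and tally skipped reads", {
  set.seed(629)
  g <- random_seq(1000)
  k <- 21
  tab <- counted_kmers_from_genome(g, k,
                                   abundance_profile = function(n) rep(4L, n),
                                   seed = 17)
  cfg <- kamq_config(k = k, z = 2, b = 5, nb_slots = 2^20)
  idx <- build_index(tab, cfg)

  fa <- tempfile(fileext = ".fa")
  reads <- rbind(sample_reads(g, 2, 60, seed = 31),
                 data.frame(id = "short", seq = "ACGT", qual = NA))
  write_sequences(reads[, c("id", "seq")], fa)

  rep_k <- query_file(idx, fa, output = "per_kmer")
  expect_equal(nrow(rep_k$data), 3L)
  expect_equal(lengths(rep_k$data$ranks), c(60 - k + 1, 60 - k + 1, 0))
  expect_equal(rep_k$skipped, 1L)

  # every k-mer has count 4 -> rank floor(log2 4) = 2 everywhere
  rep_m <- query_file(idx, fa, output = "mean")
  expect_equal(nrow(rep_m$data), 2L)
  expect_equal(rep_m$data$mean_rank, c(2, 2))

  rep_t <- query_file(idx, fa, output = "threshold", threshold = 2)
  expect_equal(nrow(rep_t$data), 0L)  # mean must strictly exceed t
  rep_t1 <- query_file(idx, fa, output = "threshold", threshold = 1.5)
  expect_equal(nrow(rep_t1$data), 2L)

  out <- tempfile(fileext = ".tsv")
  write_report(rep_k, out)
  lines <- readLines(out)
  expect_length(lines, 3L)
  expect_match(lines[1], "^read_1\t[0-9]+( [0-9]+)*$")

  # absent reads under a threshold of 0: nothing passes
  fa2 <- tempfile(fileext = ".fa")
  write_sequences(data.frame(id = paste0("a", 1:5),
                             seq = replicate(5, random_seq(60))), fa2)
  idx_cf <- build_index(tab, kamq_config(k = k, z = 2, b = 5, nb_slots = 2^24))
  rep0 <- query_file(idx_cf, fa2, output = "threshold", threshold = 0)
  expect_equal(nrow(rep0$data), 0L)
})

test_that("a saved index reloads with identical query behavior", {
  set.seed(631)
  g <- random_seq(900)
  tab <- counted_kmers_from_genome(g, 21, seed = 19)
  cfg <- kamq_config(k = 21, z = 3, b = 5, nb_slots = 4000)
  idx <- build_index(tab, cfg)
  tf <- tempfile(fileext = ".kamq")
  save_index(idx, tf)
  idx2 <- load_index(tf)
  expect_equal(idx2$config, cfg)
  read <- sample_reads(g, 1, 100, seed = 37)$seq
  expect_identical(query_sequence(idx2, read), query_sequence(idx, read))
})
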