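# small planted truth used across the classification tests: k = 5, z = 1,
# identity discretization, collision-free filter
planted_setup <- function() {
  tab <- counted_kmers(c("GAAAA", "AAAAG", "AAAGC"), c(9, 2, 7))
  cfg <- kamq_config(k = 5, z = 1, b = 8, nb_slots = 2^20,
                     discretization = "identity")
  list(tab = tab, cfg = cfg, idx = build_index(tab, cfg),
       truth = ground_truth(tab, cfg))
}

test_that("calls are labeled by the exact-oracle taxonomy", {
  p <- planted_setup()
  # TAAAG is absent but both its 4-mers (TAAA? no: AAAG, AAGC...) --
  # use GAAAG: s-mers GAAA (s_ab 9) and AAAG (s_ab 7) both truly present
  probes <- c(
    "GAAAA",  # present, s-mers GAAA/AAAA both s_ab 9 -> reported 9 = truth
    "AAAAG",  # present count 2; window min s_ab = min(9, 7) = 7 > 2
    "GAAAG",  # absent, all s-mers with s_ab > 0: construction FP
    "TTTTT")  # absent, s-mers unknown: true negative (collision-free filter)
  reported <- query_kmers(p$idx, probes, report = "stored")
  cls <- classify_calls(probes, reported, p$truth)
  expect_equal(cls$label,
               c("TP_correct", "TP_overestimated_construction",
                 "FP_construction", "TN"))
  expect_equal(cls$truth_count, c(9L, 2L, 0L, 0L))
  expect_equal(cls$reported_rank, c(9L, 7L, 7L, 0L))

  # a collision FP needs at least one s-mer with true s_ab = 0: plant one by
  # inserting the probe's s-mer directly into the filter (simulating a clash)
  insert_max(p$idx$filter, c("TTTT", "TTTA"), 3)
  rep2 <- query_kmers(p$idx, "TTTTA", report = "stored")
  cls2 <- classify_calls("TTTTA", rep2, p$truth)
  expect_equal(cls2$label, "FP_collision")

  # mismatched lengths are refused
  expect_error(classify_calls(probes, reported[1:2], p$truth), "length")
})

test_that("collision overestimation is separated from construction effects", {
  p <- planted_setup()
  # AAAGC has truth 7 and its window min s_ab is 7: any overestimate must
  # come from a filter collision; force one at its s-mer AAGC
  insert_max(p$idx$filter, "AAGC", 200)
  insert_max(p$idx$filter, "AAAG", 200)
  rep <- query_kmers(p$idx, "AAAGC", report = "stored")
  cls <- classify_calls("AAAGC", rep, p$truth)
  expect_equal(cls$label, "TP_overestimated_collision")
})

test_that("classification matches a direct per-call reimplementation", {
  set.seed(701)
  sc <- tiny_scenario(seed = 31)
  d <- build_scenario_data(sc)
  truth <- d$truth
  cfg <- d$config
  spec <- discretization_spec(cfg$discretization, cfg$b)
  absent <- generate_absent_kmers(truth, 800, seed = 5)
  probes <- c(absent, names(truth$kmer_abundance)[1:800])
  reported <- query_kmers(d$index, probes, report = "stored")
  cls <- classify_calls(probes, reported, truth)

  relabel <- vapply(seq_along(probes), function(i) {
    km <- probes[i]; rep <- reported[i]
    tc <- unname(truth$kmer_abundance[km]); if (is.na(tc)) tc <- 0L
    sm <- substring(km, 1:(cfg$k - cfg$s + 1), cfg$s:cfg$k)
    sab <- unname(truth$sab[sm]); sab[is.na(sab)] <- 0L
    stored_of <- function(x) min(floor(log2(x)) + 1, 2^cfg$b - 1)
    if (tc == 0L) {
      if (rep == 0L) return("TN")
      return(if (all(sab > 0)) "FP_construction" else "FP_collision")
    }
    if (rep == stored_of(tc)) return("TP_correct")
    if (stored_of(min(sab)) > stored_of(tc)) "TP_overestimated_construction"
    else "TP_overestimated_collision"
  }, character(1))
  expect_identical(cls$label, relabel)
})

test_that("summary rates follow their definitions, with NA for empty denominators", {
  calls <- structure(
    data.frame(
      kmer = c("A", "B", "C", "D", "E", "F", "G"),
      truth_count = c(0L, 0L, 0L, 0L, 8L, 8L, 2L),
      truth_rank = c(0L, 0L, 0L, 0L, 3L, 3L, 1L),
      reported = c(0L, 0L, 0L, 5L, 4L, 6L, 2L),
      reported_rank = c(0L, 0L, 0L, 4L, 3L, 5L, 1L),
      label = c("TN", "TN", "TN", "FP_collision", "TP_correct",
                "TP_overestimated_collision", "TP_correct")),
    class = c("kamq_calls", "data.frame"))
  s <- summarize_calls(calls)
  expect_equal(s$fpr, 1 / 4)                        # FP / (FP + TN)
  expect_equal(s$incorrect_abundance_rate, 1 / 3)   # over TP only
  expect_equal(s$construction_fp_share, 0)
  expect_equal(s$construction_overest_share, 0)
  expect_equal(s$mean_error_distance, 2)            # rank units
  expect_equal(s$overestimation_score, 4^2 + 2^2)

  all_tn <- calls[calls$label == "TN", ]
  class(all_tn) <- class(calls)
  s2 <- summarize_calls(all_tn)
  expect_equal(s2$fpr, 0)
  expect_true(is.na(s2$incorrect_abundance_rate))
  expect_true(is.na(s2$construction_fp_share))
  expect_equal(s2$overestimation_score, 0)
})

test_that("overestimation score is the sum of squared errors", {
  expect_equal(overestimation_score(c(3, 2), c(1, 2)), 4)
  expect_equal(overestimation_score(1:5, 1:5), 0)
  set.seed(11)
  a <- rpois(100, 6); b <- rpois(100, 6)
  expect_equal(overestimation_score(a, b),
               sum(vapply(seq_along(a), function(i) (a[i] - b[i])^2, 1)))
  expect_error(overestimation_score(1:3, 1:4), "length")
})

test_that("true positives are never underestimated across random campaigns", {
  for (seed in c(3, 17, 91)) {
    d <- build_scenario_data(tiny_scenario(seed = seed))
    spec <- discretization_spec(d$config$discretization, d$config$b)
    kmers <- names(d$truth$kmer_abundance)
    reported <- query_kmers(d$index, kmers, report = "stored")
    truth_stored <- kamq:::rank_to_stored(
      discretize(unname(d$truth$kmer_abundance), spec), spec)
    expect_true(all(reported >= truth_stored))
    # and the classifier agrees: no label is missing
    cls <- classify_calls(kmers, reported, d$truth)
    expect_true(all(cls$label %in% c("TP_correct",
                                     "TP_overestimated_construction",
                                     "TP_overestimated_collision")))
  }
})

test_that("construction false positives are independent of the filter size", {
  sc <- tiny_scenario(seed = 57)
  d <- build_scenario_data(sc)
  # force a regime with real construction FPs: tiny s saturates the s-mer space
  cfg_small <- kamq_config(k = sc$k, z = sc$k - 5L, b = 5,
                           nb_slots = 50000)
  cfg_large <- kamq_config(k = sc$k, z = sc$k - 5L, b = 5,
                           nb_slots = 2^22)
  truth_s <- ground_truth(d$table, cfg_small)
  truth_l <- ground_truth(d$table, cfg_large)
  probes <- generate_absent_kmers(truth_s, 400, seed = 13)
  cls_s <- classify_calls(probes,
                          query_kmers(build_index(d$table, cfg_small), probes,
                                      report = "stored"), truth_s)
  cls_l <- classify_calls(probes,
                          query_kmers(build_index(d$table, cfg_large), probes,
                                      report = "stored"), truth_l)
  cfp_s <- probes[cls_s$label == "FP_construction"]
  cfp_l <- probes[cls_l$label == "FP_construction"]
  expect_gt(length(cfp_s), 0)
  expect_identical(cfp_s, cfp_l)
})

test_that("closed-form rates evaluate correctly", {
  expect_equal(kmer_fpr(0.25, 3), 0.25^4)
  expect_equal(single_hash_fpr(1, 2), 0.5)
  expect_equal(single_hash_fpr(2, 2), 0.75)
  expect_equal(smer_saturation_prob(1, 1), 0.25)
  # complement identity on moderate arguments
  expect_equal(single_hash_fpr(1e4, 1e6), 1 - (1 - 1e-6)^1e4)
})
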