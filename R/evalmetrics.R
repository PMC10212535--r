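#' Exact ground truth for evaluation
#'
#' Bundles the exact k-mer abundance map and the exact s-abundance map
#' derived from the same counted k-mer table, under the configuration's
#' canonical flag and discretization. Evaluation classifies calls against
#' this oracle, independently of the filter.
#'
#' @param table the [counted_kmers()] table that was (or will be) indexed.
#' @param config the [kamq_config()] in force.
#' @return An object of class `kamq_truth`.
#' @export
ground_truth <- function(table, config) {
  stopifnot(inherits(table, "counted_kmers"), inherits(config, "kamq_config"))
  if (nrow(table) > 0 && attr(table, "k") != config$k)
    stop("table word length does not match config k")
  kmers <- table$kmer
  counts <- table$count
  if (config$canonical && nrow(table) > 0) {
    kmers <- canonical(kmers)
    agg <- tapply(counts, kmers, max)
    kmers <- names(agg)
    counts <- as.integer(agg)
  }
  kmap <- counts
  names(kmap) <- kmers
  structure(
    list(kmer_abundance = kmap,
         sab = compute_sab(table, config$s, canonical = config$canonical),
         config = config),
    class = "kamq_truth")
}

#' @export
print.kamq_truth <- function(x, ...) {
  cat(sprintf("<kamq_truth> %d k-mers, %d s-mers (k=%d, s=%d%s)\n",
              length(x$kmer_abundance), length(x$sab), x$config$k,
              x$config$s, if (x$config$canonical) ", canonical" else ""))
  invisible(x)
}

#' True abundance of query k-mers
#'
#' Looks k-mers up in the exact truth map (canonical-aware); absent k-mers
#' and k-mers containing non-ACGT characters have abundance 0.
#'
#' @param truth a [ground_truth()] object.
#' @param kmers character vector of query k-mers.
#' @return Integer abundances (0 = absent).
#' @export
truth_count <- function(truth, kmers) {
  stopifnot(inherits(truth, "kamq_truth"))
  out <- integer(length(kmers))
  ok <- !grepl("[^ACGTacgt]", kmers)
  key <- toupper(kmers[ok])
  if (truth$config$canonical && length(key)) key <- canonical(key)
  hit <- truth$kmer_abundance[key]
  hit[is.na(hit)] <- 0L
  out[ok] <- as.integer(hit)
  out
}

# exact s_ab of each s-mer window of each query k-mer: matrix with one row
# per k-mer and one column per offset 0..z
sab_window_matrix <- function(truth, kmers) {
  cfg <- truth$config
  offs <- 0:(cfg$k - cfg$s)
  m <- matrix(0L, nrow = length(kmers), ncol = length(offs))
  ok <- !grepl("[^ACGTacgt]", kmers)
  up <- toupper(kmers)
  for (j in seq_along(offs)) {
    sm <- substring(up[ok], offs[j] + 1L, offs[j] + cfg$s)
    if (cfg$canonical && length(sm)) sm <- canonical(sm)
    v <- truth$sab[sm]
    v[is.na(v)] <- 0L
    m[ok, j] <- as.integer(v)
  }
  m
}

#' Classify query calls against the exact truth
#'
#' Each queried k-mer gets one label:
#' \describe{
#'   \item{TN}{absent from the truth, reported 0.}
#'   \item{FP_construction}{absent, reported > 0, and *every* constituent
#'     s-mer truly has s-abundance > 0 — an error the s-mer decomposition
#'     creates independently of the underlying filter.}
#'   \item{FP_collision}{absent, reported > 0, at least one s-mer with true
#'     s-abundance 0 (hash collisions in the filter caused the call).}
#'   \item{TP_correct}{present, reported rank equals the index-effective
#'     rank of the true abundance.}
#'   \item{TP_overestimated_construction}{present and overestimated, with
#'     the minimum discretized true s-abundance over the window already
#'     above the true rank (s-mer sharing between k-mers of different
#'     abundance; filter-independent). Mixed cases where collisions also
#'     occurred count here, matching the filter-independent definition.}
#'   \item{TP_overestimated_collision}{present and overestimated purely by
#'     filter collisions.}
#' }
#' Underestimation cannot occur and is asserted against.
#'
#' Calls are classified on the filter-response (`"stored"`) scale, where 0
#' unambiguously encodes absence (see [query_sequence()]): pass the output
#' of `query_sequence(..., report = "stored")` or
#' `query_kmers(..., report = "stored")`. Rank-scale columns are derived in
#' the returned table.
#'
#' @param kmers character vector of queried k-mers.
#' @param reported integer vector of stored-scale responses (same length).
#' @param truth a [ground_truth()] built with the same configuration as the
#'   index that produced `reported`.
#' @return A `data.frame` of class `kamq_calls` with columns `kmer`,
#'   `truth_count`, `truth_rank`, `reported` (stored scale),
#'   `reported_rank`, `label`.
#' @export
classify_calls <- function(kmers, reported, truth) {
  stopifnot(inherits(truth, "kamq_truth"))
  if (length(kmers) != length(reported))
    stop("kmers and reported must have the same length")
  cfg <- truth$config
  spec <- as_discretization(cfg)
  tc <- truth_count(truth, kmers)
  tstored <- integer(length(tc))
  tstored[tc > 0] <- rank_to_stored(discretize(tc[tc > 0], spec), spec)
  reported <- as.integer(reported)

  sabm <- sab_window_matrix(truth, kmers)
  all_smers_present <- rowSums(sabm == 0L) == 0L
  # stored code of the window-minimum true s-abundance: what a collision-free
  # filter would report for this k-mer
  min_sab <- apply(sabm, 1L, min)
  min_sab_stored <- integer(length(min_sab))
  pos <- min_sab > 0
  min_sab_stored[pos] <- rank_to_stored(discretize(min_sab[pos], spec), spec)

  label <- character(length(kmers))
  absent <- tc == 0L
  label[absent & reported == 0L] <- "TN"
  label[absent & reported > 0L & all_smers_present] <- "FP_construction"
  label[absent & reported > 0L & !all_smers_present] <- "FP_collision"
  present <- !absent
  if (any(present & reported < tstored))
    stop("internal error: underestimated true-positive call detected")
  label[present & reported == tstored] <- "TP_correct"
  over <- present & reported > tstored
  label[over & min_sab_stored > tstored] <- "TP_overestimated_construction"
  label[over & min_sab_stored <= tstored] <- "TP_overestimated_collision"

  structure(
    data.frame(kmer = kmers, truth_count = tc,
               truth_rank = stored_to_rank(tstored, spec),
               reported = reported,
               reported_rank = stored_to_rank(reported, spec),
               label = label),
    class = c("kamq_calls", "data.frame"))
}

#' Summarize classified calls
#'
#' Computes the evaluation metrics: false positive rate
#' `#FP / (#FP + #TN)`; the incorrect-abundance rate over true-positive
#' calls only; the construction shares of false positives and of
#' overestimated true positives; the mean error distance (reported minus
#' true rank, in discretized rank units, over erroneous true positives);
#' and the overestimation score (sum of squared rank errors over all
#' calls). Undefined ratios (zero denominators) are reported as `NA`, not 0.
#'
#' @param calls a `kamq_calls` table from [classify_calls()].
#' @return An object of class `kamq_eval` (a one-row `data.frame`).
#' @export
summarize_calls <- function(calls) {
  stopifnot(inherits(calls, "kamq_calls"))
  if (nrow(calls) == 0) stop("no calls to summarize")
  n <- table(factor(calls$label,
                    levels = c("TN", "FP_construction", "FP_collision",
                               "TP_correct", "TP_overestimated_construction",
                               "TP_overestimated_collision")))
  fp <- n[["FP_construction"]] + n[["FP_collision"]]
  tn <- n[["TN"]]
  tp <- n[["TP_correct"]] + n[["TP_overestimated_construction"]] +
    n[["TP_overestimated_collision"]]
  tp_over <- n[["TP_overestimated_construction"]] +
    n[["TP_overestimated_collision"]]
  # error distance in discretized rank units
  err <- calls$reported_rank - calls$truth_rank
  over_tp <- calls$truth_count > 0 & err > 0
  res <- data.frame(
    n_calls = nrow(calls),
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    incorrect_abundance_rate = if (tp > 0) tp_over / tp else NA_real_,
    construction_fp_share = if (fp > 0) n[["FP_construction"]] / fp else NA_real_,
    construction_overest_share =
      if (tp_over > 0) n[["TP_overestimated_construction"]] / tp_over
      else NA_real_,
    mean_error_distance = if (any(over_tp)) mean(err[over_tp]) else NA_real_,
    overestimation_score = sum(as.numeric(err)^2))
  class(res) <- c("kamq_eval", "data.frame")
  res
}

#' Sum of squared abundance errors
#'
#' The overestimation score comparing reported against true values: the sum
#' of squared differences, applied per k-mer or per read mean depending on
#' the experiment. Zero iff every call is exact; errors close to the truth
#' are penalized less than distant ones.
#'
#' @param reported numeric vector of reported values.
#' @param truth numeric vector of true values, same length.
#' @return A non-negative number.
#' @examples
#' overestimation_score(c(3, 2), c(1, 2))  # 4
#' @export
overestimation_score <- function(reported, truth) {
  if (length(reported) != length(truth))
    stop("reported and truth must have the same length")
  sum((as.numeric(reported) - as.numeric(truth))^2)
}

#' Closed-form error rates
#'
#' `single_hash_fpr()` is the false positive rate of a single-hash filter
#' holding `n` distinct keys in `m` slots: `1 - (1 - 1/m)^n` (evaluated
#' stably). `kmer_fpr()` is the independence-model false positive rate of a
#' k-mer query through `z + 1` s-mer lookups, `p^(z + 1)`, for per-s-mer
#' false positive rate `p`. `smer_saturation_prob()` is the probability that
#' a fixed s-mer occurs by chance in a random sequence of `n` characters
#' over a 4-letter alphabet: `1 - (1 - 1/4^s)^n` — the regime in which small
#' `s` makes every s-mer present and floods queries with construction false
#' positives.
#'
#' @param n number of distinct inserted keys (resp. indexed characters).
#' @param m number of slots.
#' @return A probability.
#' @examples
#' single_hash_fpr(2.38e8, 3.48e9)   # ~0.0661
#' kmer_fpr(0.25, 3)                 # 0.25^4 = 0.00390625
#' smer_saturation_prob(11, 2e7)     # > 0.99
#' @export
single_hash_fpr <- function(n, m) -expm1(n * log1p(-1 / m))

#' @rdname single_hash_fpr
#' @param smer_fpr per-s-mer false positive rate.
#' @param z shrinkage (a k-mer spans `z + 1` s-mers).
#' @export
kmer_fpr <- function(smer_fpr, z) smer_fpr^(z + 1)

#' @rdname single_hash_fpr
#' @param s s-mer length.
#' @export
smer_saturation_prob <- function(s, n) -expm1(n * log1p(-4^(-s)))
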