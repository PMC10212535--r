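#' Index configuration
#'
#' Bundles the parameters governing an abundance index: the k-mer length `k`,
#' the shrinkage `z` (the filter stores s-mers of length `s = k - z`; each
#' k-mer is represented by its `z + 1` constituent s-mers), the counter width
#' `b` in bits, the filter size in slots, the abundance discretization, and
#' whether words are canonicalized (replaced by the lexicographic minimum of
#' the word and its reverse complement).
#'
#' `z = 0` makes the index degenerate exactly into a plain counting Bloom
#' filter over k-mers. `abundance_mode = "sab"` derives, for every s-mer, the
#' maximum abundance over the indexed k-mers containing it (the s-abundance);
#' `"raw"` expects a counted s-mer table as build input instead.
#'
#' @param k k-mer length in bases (`k >= 1`). Default 31.
#' @param z shrinkage; `0 <= z < k`. Default 3.
#' @param b bits per counter slot, 1..8. `b = 1` degenerates to a plain
#'   presence/absence Bloom filter. Default 5.
#' @param nb_slots number of counter slots in the backing filter (total size
#'   is `nb_slots * b` bits).
#' @param discretization abundance-to-rank map: `"log2"` (`min(floor(log2 x),
#'   2^b - 1)`), `"log10"` analogously, or `"identity"` (`min(x, 2^b - 1)`).
#' @param canonical logical; canonicalize s-mers at build and query time.
#' @param abundance_mode `"sab"` or `"raw"` (see Details).
#' @return An object of class `kamq_config`.
#' @examples
#' kamq_config(k = 31, z = 3, b = 5, nb_slots = 1e5)
#' @export
kamq_config <- function(k = 31L, z = 3L, b = 5L, nb_slots,
                        discretization = c("log2", "identity", "log10"),
                        canonical = FALSE,
                        abundance_mode = c("sab", "raw")) {
  discretization <- match.arg(discretization)
  abundance_mode <- match.arg(abundance_mode)
  k <- as.integer(k); z <- as.integer(z); b <- as.integer(b)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (is.na(z) || z < 0L || z >= k) stop("z must satisfy 0 <= z < k")
  if (is.na(b) || b < 1L || b > 8L) stop("b must be in 1..8")
  nb_slots <- as.numeric(nb_slots)
  if (length(nb_slots) != 1L || is.na(nb_slots) || nb_slots < 1)
    stop("nb_slots must be a positive number")
  nb_slots <- floor(nb_slots)
  structure(
    list(k = k, z = z, s = k - z, b = b, nb_slots = nb_slots,
         discretization = discretization, canonical = isTRUE(canonical),
         abundance_mode = abundance_mode),
    class = "kamq_config")
}

#' @export
print.kamq_config <- function(x, ...) {
  cat(sprintf(
    "<kamq_config> k=%d z=%d (s=%d) b=%d nb_slots=%s %s%s mode=%s\n",
    x$k, x$z, x$s, x$b, format(x$nb_slots, big.mark = ","),
    x$discretization, if (x$canonical) " canonical" else "", x$abundance_mode))
  invisible(x)
}

#' Abundance discretization
#'
#' A discretization maps an abundance `x >= 1` to a rank `y` in
#' `[0, 2^b - 1]` so that large counts fit in `b`-bit filter slots.
#' `floor_log2` uses `y = min(floor(log2 x), 2^b - 1)` (mode `"log2"`),
#' `floor_log10` analogously, and `"identity"` stores `min(x, 2^b - 1)`.
#' `decode_rank()` inverts a rank to the abundance interval it covers; the top
#' rank is open-ended.
#'
#' @param mode `"log2"`, `"log10"`, or `"identity"`.
#' @param b bits per slot, 1..8.
#' @return `discretization_spec()`: an object of class `kamq_discretization`.
#' @examples
#' sp <- discretization_spec("log2", b = 5)
#' discretize(8, sp)        # 3
#' decode_rank(3, sp)       # [8, 15]
#' @export
discretization_spec <- function(mode = c("log2", "identity", "log10"), b = 5L) {
  mode <- match.arg(mode)
  b <- as.integer(b)
  if (is.na(b) || b < 1L || b > 8L) stop("b must be in 1..8")
  structure(
    list(mode = mode, b = b, max_rank = 2L^b - 1L,
         # log modes can emit rank 0 for indexed abundances, which would
         # collide with 0-means-absent in the filter; their stored values are
         # therefore shifted up by one (see rank_to_stored)
         zero_based = mode != "identity"),
    class = "kamq_discretization")
}

as_discretization <- function(x) {
  if (inherits(x, "kamq_discretization")) return(x)
  if (inherits(x, "kamq_config"))
    return(discretization_spec(x$discretization, x$b))
  stop("expected a kamq_discretization or kamq_config")
}

#' @rdname discretization_spec
#' @param x abundance values, all `>= 1`.
#' @param spec a `kamq_discretization` (or a `kamq_config`, whose
#'   discretization is used).
#' @export
discretize <- function(x, spec) {
  spec <- as_discretization(spec)
  if (any(is.na(x)) || any(x < 1)) stop("abundances must be >= 1")
  y <- switch(spec$mode,
    log2 = floor(log2(x)),
    log10 = floor(log10(x)),
    identity = x)
  as.integer(pmin(y, spec$max_rank))
}

#' @rdname discretization_spec
#' @param rank ranks in `[0, 2^b - 1]`.
#' @export
decode_rank <- function(rank, spec) {
  spec <- as_discretization(spec)
  if (any(rank < 0) || any(rank > spec$max_rank)) stop("rank out of range")
  base <- switch(spec$mode, log2 = 2, log10 = 10, identity = NA)
  if (spec$mode == "identity") {
    lo <- rank
    hi <- ifelse(rank == spec$max_rank, Inf, rank)
  } else {
    lo <- base^rank
    hi <- ifelse(rank == spec$max_rank, Inf, base^(rank + 1) - 1)
  }
  data.frame(rank = rank, lo = lo, hi = hi)
}

# Stored-value encoding: 0 always means "absent" in the filter.  Log-mode
# ranks start at 0, so they are stored shifted by +1 (saturating at 2^b - 1)
# and shifted back on report; identity-mode values are stored as-is.
rank_to_stored <- function(rank, spec) {
  if (spec$zero_based) as.integer(pmin(rank + 1L, spec$max_rank))
  else as.integer(pmin(rank, spec$max_rank))
}

stored_to_rank <- function(stored, spec) {
  if (spec$zero_based) as.integer(pmax(stored - 1L, 0L))
  else as.integer(stored)
}

#' Index-effective rank of a true abundance
#'
#' The rank an index reports for a k-mer whose abundance is stored without
#' collisions or construction effects: discretize, encode to the stored value
#' (saturating at `2^b - 1`, with the absence-sentinel shift under log
#' modes), decode back. Under log modes the largest reportable rank is
#' `2^b - 2`. Evaluation compares reported ranks against this quantity.
#'
#' @param x true abundances (`>= 1`).
#' @param spec a `kamq_discretization`, `kamq_config`, or `kamq_index`.
#' @return integer ranks.
#' @export
index_rank <- function(x, spec) {
  if (inherits(spec, "kamq_index")) spec <- spec$config
  spec <- as_discretization(spec)
  stored_to_rank(rank_to_stored(discretize(x, spec), spec), spec)
}
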