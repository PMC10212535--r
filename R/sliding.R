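#' Sliding-window minimum and maximum in linear time
#'
#' Computes `r[i] = min(v[i], ..., v[i + W - 1])` (resp. `max`) for every
#' window start `i`, using the fixed-window algorithm: the vector is split
#' into non-overlapping blocks of size `W`; block prefix minima (`minL`) are
#' kept in a single running scalar and block suffix minima (`minR`) are
#' materialized inside the queried vector itself, which is safe because
#' `r[i] <= minR[i] <= v[i]`. Each element is visited at most twice, so the
#' runtime is `O(length(v))` with no dependence on `W` and the auxiliary
#' state is a constant number of scalars — no heap allocation proportional to
#' the input. A trailing block shorter than `W` is handled as a shorter fixed
#' window.
#'
#' With `in_place = TRUE` the result is written over the input vector's
#' prefix: **the vector passed in is mutated**, which departs from R's usual
#' copy-on-modify semantics and is intended for hot inner loops where the
#' caller owns the buffer. The function still returns the result window.
#' The input must already be a double vector for the mutation to be
#' observable (integer input is coerced, i.e. copied, first).
#'
#' @param v numeric vector of totally ordered values.
#' @param W window size, `1 <= W <= length(v)`.
#' @param in_place logical; overwrite the input's prefix with the result.
#' @param details logical; also return the `minL`/`minR` decomposition
#'   (computed by a plain reference pass, for inspection and testing).
#' @return Numeric vector of length `length(v) - W + 1`; with
#'   `details = TRUE`, a list with elements `r`, `minL`, `minR`, `W`.
#' @examples
#' sliding_window_min(c(5, 3, 7, 1, 4, 5, 3, 2, 2, 3), 3)
#' # 3 1 1 1 3 2 2 2
#' @export
sliding_window_min <- function(v, W, in_place = FALSE, details = FALSE) {
  if (details) return(sliding_details(v, W, maximum = FALSE))
  cpp_sliding_extreme(as.numeric(v), check_window(v, W), FALSE, isTRUE(in_place))
}

#' @rdname sliding_window_min
#' @export
sliding_window_max <- function(v, W, in_place = FALSE, details = FALSE) {
  if (details) return(sliding_details(v, W, maximum = TRUE))
  cpp_sliding_extreme(as.numeric(v), check_window(v, W), TRUE, isTRUE(in_place))
}

check_window <- function(v, W) {
  W <- as.numeric(W)
  if (length(W) != 1L || is.na(W) || W < 1 || W > length(v))
    stop("window size must satisfy 1 <= W <= length(v)")
  floor(W)
}

# Reference pass materializing the block decomposition: minL[i] is the
# prefix extremum of i's block up to i, minR[i] the suffix extremum from i to
# the block end, and r[i] = extreme(minL[i + W - 1], minR[i]).
sliding_details <- function(v, W, maximum = FALSE) {
  v <- as.numeric(v)
  W <- check_window(v, W)
  ext <- if (maximum) max else min
  n <- length(v)
  minL <- numeric(n); minR <- numeric(n)
  for (i in seq_len(n)) {
    o <- (i - 1L) %% W
    minL[i] <- if (o == 0) v[i] else ext(minL[i - 1L], v[i])
  }
  for (i in rev(seq_len(n))) {
    o <- (i - 1L) %% W
    last_of_block <- o == W - 1L || i == n
    minR[i] <- if (last_of_block) v[i] else ext(minR[i + 1L], v[i])
  }
  r <- vapply(seq_len(n - W + 1L),
              function(i) ext(minL[i + W - 1L], minR[i]), numeric(1))
  list(r = r, minL = minL, minR = minR, W = W)
}
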