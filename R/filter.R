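#' Single-hash counting Bloom filter
#'
#' A counting approximate-membership-query (cAMQ) structure: `nb_slots`
#' saturating counters of `b` bits each, bit-packed into a raw byte array.
#' Every word is hashed (one seed-free hash of its 2-bit encoding) to a
#' single slot. Insertion stores the maximum of the colliding values,
#' saturating at `2^b - 1`; lookup returns the slot value, so a response is
#' always either correct or an overestimate — never an underestimate — and
#' `0` signals absence. `b = 1` degenerates to a plain Bloom filter.
#'
#' The filter is an environment, so [insert_max()] updates it in place and
#' returns it invisibly.
#'
#' @param nb_slots number of counter slots (total size `nb_slots * b` bits).
#' @param b bits per slot, 1..8.
#' @return An object of class `counting_filter`.
#' @examples
#' f <- counting_filter(1024, b = 5)
#' insert_max(f, "ACGTACGTAC", 7)
#' lookup(f, "ACGTACGTAC")  # 7
#' @export
counting_filter <- function(nb_slots, b = 5L) {
  b <- as.integer(b)
  if (is.na(b) || b < 1L || b > 8L) stop("b must be in 1..8")
  nb_slots <- floor(as.numeric(nb_slots))
  if (length(nb_slots) != 1L || is.na(nb_slots) || nb_slots < 1)
    stop("nb_slots must be a positive number")
  f <- new.env(parent = emptyenv())
  f$nb_slots <- nb_slots
  f$b <- b
  f$hash_name <- "fnv1a-splitmix64-2bit"
  f$slots <- raw(ceiling(nb_slots * b / 8))
  class(f) <- "counting_filter"
  f
}

#' @export
print.counting_filter <- function(x, ...) {
  cat(sprintf("<counting_filter> %s slots x %d bits (%s), load %.3f\n",
              format(x$nb_slots, big.mark = ","), x$b, x$hash_name,
              load_factor(x)))
  invisible(x)
}

#' Insert words with saturating max semantics
#'
#' Sets `slot[hash(word)] <- min(max(slot, value), 2^b - 1)` for each
#' (word, value) pair. Monotone non-decreasing: a lookup never returns less
#' than the largest value ever inserted at that slot.
#'
#' @param filter a [counting_filter()].
#' @param words character vector of ACGT words (case-insensitive).
#' @param values non-negative integer values, recycled to `length(words)`.
#' @return The filter, invisibly (mutated in place).
#' @export
insert_max <- function(filter, words, values) {
  stopifnot(inherits(filter, "counting_filter"))
  values <- as.integer(rep_len(values, length(words)))
  cpp_cf_insert_max(filter$slots, filter$nb_slots, filter$b,
                    as.character(words), values)
  invisible(filter)
}

#' Look up words in a counting filter
#'
#' @inheritParams insert_max
#' @return Integer vector of slot values in `[0, 2^b - 1]`; `0` means the
#'   word was never inserted (or only with value 0) — possibly a true
#'   negative, possibly an unprobed collision-free slot.
#' @export
lookup <- function(filter, words) {
  stopifnot(inherits(filter, "counting_filter"))
  cpp_cf_lookup(filter$slots, filter$nb_slots, filter$b, as.character(words))
}

#' Slot index of a word
#'
#' Deterministic, seed-free slot assignment: FNV-1a over the word's 2-bit
#' encoding with a splitmix64 finalizer, reduced modulo `nb_slots`. Identical
#' across runs and platforms.
#'
#' @param words character vector of ACGT words.
#' @param nb_slots number of slots.
#' @return 0-based slot indices (as doubles; slot counts may exceed the
#'   integer range).
#' @export
hash_smer <- function(words, nb_slots) {
  cpp_hash_smer(as.character(words), floor(as.numeric(nb_slots)))
}

#' Fraction of non-zero slots
#'
#' @param filter a [counting_filter()].
#' @return The load factor in `[0, 1]`.
#' @export
load_factor <- function(filter) {
  stopifnot(inherits(filter, "counting_filter"))
  cpp_count_nonzero_slots(filter$slots, filter$nb_slots, filter$b) /
    filter$nb_slots
}

KAMQ_MAGIC <- "KAMQCBF1"
KAMQ_FORMAT_VERSION <- 1L

disc_codes <- c(identity = 1L, log2 = 2L, log10 = 3L)
mode_codes <- c(sab = 1L, raw = 2L)

#' Serialize a counting filter
#'
#' Writes a self-describing little-endian binary file: magic bytes, format
#' version, filter geometry and hash name, the owning index configuration
#' when present, the bit-packed slot payload, and an FNV-1a checksum of the
#' payload. [load_filter()] verifies magic, version, completeness, and
#' checksum, and reproduces the filter bit-exactly.
#'
#' @param filter a [counting_filter()].
#' @param path file path to write to / read from.
#' @param config optional [kamq_config()] recorded in the header (always
#'   present when saving a whole index).
#' @return `save_filter()`: `path`, invisibly. `load_filter()`: the filter,
#'   with the stored config (or `NULL`) in `attr(, "config")`.
#' @export
save_filter <- function(filter, path, config = NULL) {
  stopifnot(inherits(filter, "counting_filter"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(KAMQ_MAGIC), con)
  writeBin(KAMQ_FORMAT_VERSION, con, size = 4L, endian = "little")
  writeBin(as.numeric(filter$nb_slots), con, endian = "little")
  writeBin(filter$b, con, size = 4L, endian = "little")
  hn <- charToRaw(filter$hash_name)
  writeBin(length(hn), con, size = 4L, endian = "little")
  writeBin(hn, con)
  writeBin(if (is.null(config)) 0L else 1L, con, size = 4L, endian = "little")
  if (!is.null(config)) {
    stopifnot(inherits(config, "kamq_config"))
    writeBin(c(config$k, config$z, config$b,
               disc_codes[[config$discretization]],
               as.integer(config$canonical),
               mode_codes[[config$abundance_mode]]),
             con, size = 4L, endian = "little")
    writeBin(as.numeric(config$nb_slots), con, endian = "little")
  }
  writeBin(as.numeric(length(filter$slots)), con, endian = "little")
  writeBin(filter$slots, con)
  writeBin(charToRaw(cpp_checksum(filter$slots)), con)
  invisible(path)
}

#' @rdname save_filter
#' @export
load_filter <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  need <- function(x, n, what) {
    if (length(x) < n) stop("truncated or corrupt filter file: missing ", what)
    x
  }
  magic <- need(readBin(con, "raw", 8L), 8L, "magic")
  if (!identical(rawToChar(magic), KAMQ_MAGIC))
    stop("not a kamq filter file (bad magic bytes)")
  version <- need(readBin(con, "integer", 1L, size = 4L, endian = "little"),
                  1L, "version")
  if (version != KAMQ_FORMAT_VERSION)
    stop("unsupported filter format version: ", version)
  nb_slots <- need(readBin(con, "numeric", 1L, endian = "little"), 1L, "nb_slots")
  b <- need(readBin(con, "integer", 1L, size = 4L, endian = "little"), 1L, "b")
  hn_len <- need(readBin(con, "integer", 1L, size = 4L, endian = "little"),
                 1L, "hash name length")
  hash_name <- rawToChar(need(readBin(con, "raw", hn_len), hn_len, "hash name"))
  has_config <- need(readBin(con, "integer", 1L, size = 4L, endian = "little"),
                     1L, "config flag")
  config <- NULL
  if (has_config == 1L) {
    hdr <- need(readBin(con, "integer", 6L, size = 4L, endian = "little"),
                6L, "config header")
    cfg_slots <- need(readBin(con, "numeric", 1L, endian = "little"),
                      1L, "config nb_slots")
    config <- kamq_config(
      k = hdr[1L], z = hdr[2L], b = hdr[3L], nb_slots = cfg_slots,
      discretization = names(disc_codes)[hdr[4L]],
      canonical = hdr[5L] == 1L,
      abundance_mode = names(mode_codes)[hdr[6L]])
  }
  payload_len <- need(readBin(con, "numeric", 1L, endian = "little"),
                      1L, "payload length")
  slots <- readBin(con, "raw", payload_len)
  if (length(slots) != payload_len)
    stop("truncated filter file: payload shorter than declared")
  stored_sum <- readBin(con, "raw", 16L)
  if (length(stored_sum) != 16L)
    stop("truncated filter file: missing checksum")
  if (!identical(rawToChar(stored_sum), cpp_checksum(slots)))
    stop("filter file checksum mismatch")
  f <- counting_filter(nb_slots, b)
  f$hash_name <- hash_name
  f$slots <- slots
  attr(f, "config") <- config
  f
}
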