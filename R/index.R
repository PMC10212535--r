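#' s-abundance of every s-mer in a counted k-mer table
#'
#' The s-abundance (`s_ab`) of an s-mer is the maximum abundance over all
#' indexed k-mers containing it. This is what the index stores per s-mer:
#' taking the window minimum of s-abundances at query time can then only
#' return the true k-mer abundance or an overestimate, never an
#' underestimate.
#'
#' @param table a [counted_kmers()] table.
#' @param s s-mer length, `1 <= s <= k`.
#' @param canonical aggregate over canonical s-mer forms.
#' @return A named integer vector mapping each distinct s-mer to its
#'   s-abundance.
#' @examples
#' tab <- counted_kmers(c("ACGTA", "CGTAC"), c(5, 3))
#' compute_sab(tab, 4)  # ACGT: 5, CGTA: 5, GTAC: 3
#' @export
compute_sab <- function(table, s, canonical = FALSE) {
  stopifnot(inherits(table, "counted_kmers"))
  k <- attr(table, "k")
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("s must be >= 1")
  if (nrow(table) == 0) return(structure(integer(), names = character()))
  if (s > k) stop("s (", s, ") exceeds the table's k (", k, ")")
  exp <- expand_smers(table$kmer, table$count, k, s, canonical)
  res <- tapply(exp$count, exp$smer, max)
  out <- as.integer(res)
  names(out) <- names(res)
  out
}

# one row per (k-mer, s-mer offset): k - s + 1 offsets per k-mer
expand_smers <- function(kmers, counts, k, s, canonical) {
  offs <- 0:(k - s)
  smers <- unlist(lapply(offs, function(o) substring(kmers, o + 1L, o + s)),
                  use.names = FALSE)
  if (canonical) smers <- canonical(smers)
  list(smer = smers, count = rep.int(counts, length(offs)))
}

#' Build an abundance index from a counted k-mer table
#'
#' Splits every k-mer into its `z + 1` constituent s-mers and inserts each
#' s-mer into a single-hash counting Bloom filter with the (discretized,
#' sentinel-shifted) abundance of that k-mer, under saturating-max
#' semantics. Max-on-collision makes the stored value of every s-mer at
#' least its discretized s-abundance, so queries never underestimate. With
#' `z = 0` the k-mers themselves are indexed and the structure is exactly a
#' plain counting Bloom filter.
#'
#' In `abundance_mode = "raw"` the input must be a counted *s*-mer table
#' (word length `k - z`) whose counts are inserted directly, skipping the
#' s-abundance derivation.
#'
#' @param table a [counted_kmers()] table (k-mers in `"sab"` mode, s-mers in
#'   `"raw"` mode).
#' @param config a [kamq_config()].
#' @return An object of class `kamq_index` (environment with the backing
#'   [counting_filter()] and the config).
#' @export
build_index <- function(table, config) {
  stopifnot(inherits(table, "counted_kmers"), inherits(config, "kamq_config"))
  spec <- as_discretization(config)
  filter <- counting_filter(config$nb_slots, config$b)
  if (nrow(table) > 0) {
    tab_k <- attr(table, "k")
    if (config$abundance_mode == "raw") {
      if (tab_k != config$s)
        stop("raw mode expects a counted s-mer table with word length s = ",
             config$s, ", got ", tab_k)
      words <- if (config$canonical) canonical(table$kmer) else table$kmer
      stored <- rank_to_stored(discretize(table$count, spec), spec)
      insert_max(filter, words, stored)
    } else {
      if (tab_k != config$k)
        stop("table word length ", tab_k, " does not match config k = ",
             config$k)
      exp <- expand_smers(table$kmer, table$count, config$k, config$s,
                          config$canonical)
      stored <- rank_to_stored(discretize(exp$count, spec), spec)
      insert_max(filter, exp$smer, stored)
    }
  }
  idx <- new.env(parent = emptyenv())
  idx$filter <- filter
  idx$config <- config
  class(idx) <- "kamq_index"
  idx
}

#' @export
print.kamq_index <- function(x, ...) {
  cat("<kamq_index>\n")
  print(x$config)
  print(x$filter)
  invisible(x)
}

#' Save / load a whole index
#'
#' Thin wrappers over [save_filter()] / [load_filter()] that always record
#' the configuration in the file header.
#'
#' @param index a `kamq_index`.
#' @param path file path.
#' @return `save_index()`: `path`, invisibly; `load_index()`: the index.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "kamq_index"))
  save_filter(index$filter, path, config = index$config)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  f <- load_filter(path)
  config <- attr(f, "config")
  if (is.null(config)) stop("file carries no index configuration: ", path)
  attr(f, "config") <- NULL
  idx <- new.env(parent = emptyenv())
  idx$filter <- f
  idx$config <- config
  class(idx) <- "kamq_index"
  idx
}

#' Query a sequence for per-k-mer abundance ranks
#'
#' Two-step query: the filter response of every s-mer window of the sequence
#' is gathered (invalid windows — those containing a non-ACGT character —
#' respond 0), then the reported rank of the k-mer starting at position `p`
#' is the minimum response over the `z + 1` s-mer windows `p .. p + z`,
#' computed with the fixed-window sliding minimum. A rank of 0 means absent
#' (or, under log-mode discretization, the lowest abundance bin).
#'
#' With `optimize = TRUE`, an s-mer response of 0 immediately zeroes every
#' k-mer spanning it and unneeded filter probes are skipped; the output is
#' bit-identical to the unoptimized path (the probe count actually used is
#' attached as attribute `"lookups"`).
#'
#' Two report scales are offered. `"stored"` returns the filter-level
#' response: 0 unambiguously means absent and positive values are the
#' b-bit stored codes (under log-mode discretization these are ranks
#' shifted up by one, the absence sentinel; under identity mode they are
#' the capped abundances themselves). `"rank"` shifts log-mode codes back
#' to ranks; note that a present k-mer in the lowest abundance bin then
#' reports rank 0, indistinguishable from absence. Evaluation against
#' ground truth is done on the `"stored"` scale for exactly this reason.
#'
#' @param index a `kamq_index` from [build_index()] or [load_index()].
#' @param seq a single sequence string; sequences shorter than `k` yield an
#'   empty vector.
#' @param optimize use the absent-s-mer skipping fast path.
#' @param report `"rank"` (default) or `"stored"` (see Details).
#' @return Integer vector of length `max(0, nchar(seq) - k + 1)` of reported
#'   abundance ranks (or stored codes).
#' @export
query_sequence <- function(index, seq, optimize = TRUE,
                           report = c("rank", "stored")) {
  stopifnot(inherits(index, "kamq_index"), length(seq) == 1L)
  report <- match.arg(report)
  cfg <- index$config
  spec <- as_discretization(cfg)
  stored <- cpp_query_ranks(index$filter$slots, index$filter$nb_slots,
                            index$filter$b, as.character(seq), cfg$s,
                            cfg$z + 1L, cfg$canonical, isTRUE(optimize))
  lookups <- attr(stored, "lookups")
  out <- if (report == "stored") as.integer(stored)
         else stored_to_rank(stored, spec)
  attr(out, "lookups") <- lookups
  out
}

#' Raw s-mer filter responses along a sequence
#'
#' Step one of the query in isolation: the stored filter value for every
#' s-mer window of the sequence (0 for invalid windows). Mainly useful for
#' inspection and testing; [query_sequence()] fuses both steps.
#'
#' @inheritParams query_sequence
#' @return Integer vector of length `max(0, nchar(seq) - s + 1)` of stored
#'   slot values.
#' @export
smer_responses <- function(index, seq) {
  stopifnot(inherits(index, "kamq_index"), length(seq) == 1L)
  cfg <- index$config
  cpp_query_responses(index$filter$slots, index$filter$nb_slots,
                      index$filter$b, as.character(seq), cfg$s, cfg$canonical)
}

#' Query every sequence of a FASTA/FASTQ file
#'
#' Streams the file through [stream_sequences()] and queries each record.
#' Output modes: `"per_kmer"` keeps the full rank vector per record;
#' `"mean"` reports the arithmetic mean rank per record (records shorter
#' than `k` emit no value); `"threshold"` keeps only records whose mean rank
#' exceeds `threshold`.
#'
#' @inheritParams query_sequence
#' @param path query file (FASTA/FASTQ, optionally gzipped).
#' @param output one of `"per_kmer"`, `"mean"`, `"threshold"`.
#' @param threshold mean-rank cutoff for `output = "threshold"`.
#' @param chunk_size records read per chunk.
#' @param verbose log parameters and the skipped-read tally via [message()].
#' @return An object of class `kamq_report`: a list with `output`, `data`
#'   (a `data.frame`; for `"per_kmer"` the `ranks` column is a list of
#'   integer vectors), and `skipped` (number of reads shorter than `k`).
#' @export
query_file <- function(index, path, output = c("per_kmer", "mean", "threshold"),
                       threshold = 0, optimize = TRUE, chunk_size = 1000L,
                       verbose = FALSE) {
  stopifnot(inherits(index, "kamq_index"))
  output <- match.arg(output)
  cfg <- index$config
  if (verbose)
    message(sprintf("query: k=%d z=%d b=%d nb_slots=%g load=%.3f output=%s",
                    cfg$k, cfg$z, cfg$b, cfg$nb_slots,
                    load_factor(index$filter), output))
  it <- stream_sequences(path, chunk_size = chunk_size)
  ids <- character(0); ranks <- list(); skipped <- 0L
  while (!is.null(chunk <- it())) {
    short <- nchar(chunk$seq) < cfg$k
    skipped <- skipped + sum(short)
    res <- lapply(chunk$seq, function(s) {
      r <- query_sequence(index, s, optimize = optimize)
      attributes(r) <- NULL
      r
    })
    ids <- c(ids, chunk$id)
    ranks <- c(ranks, res)
  }
  if (verbose && skipped > 0)
    message(sprintf("skipped %d read(s) shorter than k", skipped))
  data <- switch(output,
    per_kmer = {
      d <- data.frame(id = ids)
      d$ranks <- ranks
      d
    },
    mean = {
      keep <- lengths(ranks) > 0
      data.frame(id = ids[keep],
                 mean_rank = vapply(ranks[keep], mean, numeric(1)))
    },
    threshold = {
      keep <- lengths(ranks) > 0
      m <- vapply(ranks[keep], mean, numeric(1))
      data.frame(id = ids[keep][m > threshold], mean_rank = m[m > threshold])
    })
  structure(list(output = output, data = data, skipped = skipped,
                 threshold = if (output == "threshold") threshold else NULL),
            class = "kamq_report")
}

#' @export
print.kamq_report <- function(x, ...) {
  cat(sprintf("<kamq_report> output=%s records=%d skipped=%d\n",
              x$output, nrow(x$data), x$skipped))
  print(head(x$data))
  invisible(x)
}

#' Write a query report as TSV
#'
#' `per_kmer` reports are written as `<read_id>TAB<rank_1> <rank_2> ...`;
#' mean/threshold reports as `<read_id>TAB<mean_rank>`.
#'
#' @param report a `kamq_report` from [query_file()].
#' @param path output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "kamq_report"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  lines <- if (report$output == "per_kmer") {
    paste(report$data$id,
          vapply(report$data$ranks, paste, character(1), collapse = " "),
          sep = "\t")
  } else {
    paste(report$data$id, format(report$data$mean_rank, trim = TRUE),
          sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}
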