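#' Counted k-mer tables
#'
#' The indexing input: a table of distinct k-mers with positive counts, as
#' produced by k-mer counters (KMC dump dialect: one `<kmer>TAB<count>` per
#' line, no header). All words must share one length `k`; counts must be
#' `>= 1`.
#'
#' @param kmer character vector of ACGT words of identical length.
#' @param count positive integer counts, one per k-mer.
#' @return A `data.frame` of class `counted_kmers` with columns `kmer` and
#'   `count` and the word length in `attr(, "k")`.
#' @export
counted_kmers <- function(kmer, count) {
  kmer <- toupper(as.character(kmer))
  count <- as.integer(count)
  if (length(kmer) != length(count)) stop("kmer and count lengths differ")
  if (length(kmer) > 0) {
    lens <- unique(nchar(kmer))
    if (length(lens) > 1)
      stop("inconsistent word lengths: ", paste(lens, collapse = ", "))
    if (any(is.na(count)) || any(count < 1L)) stop("all counts must be >= 1")
    if (any(grepl("[^ACGT]", kmer))) stop("k-mers must be ACGT-only")
    k <- lens
  } else {
    k <- NA_integer_
  }
  structure(data.frame(kmer = kmer, count = count),
            k = as.integer(k), class = c("counted_kmers", "data.frame"))
}

#' Read / write counted k-mer TSV files
#'
#' Parses the KMC dump dialect (`<kmer>TAB<count>` per line). Gzipped input
#' is decompressed transparently. Lowercase bases are uppercased. Malformed
#' lines (no tab, non-integer or non-positive count) raise an error naming
#' the offending line; inconsistent word lengths raise a format error.
#'
#' @param path file path (plain or `.gz`).
#' @param expected_k optional word length to enforce.
#' @return `read_counted_kmers()`: a [counted_kmers()] table.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ACGTA\t5", "CGTAC\t3"), tf)
#' read_counted_kmers(tf)
#' @export
read_counted_kmers <- function(path, expected_k = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    tab <- counted_kmers(character(), integer())
    if (!is.null(expected_k)) attr(tab, "k") <- as.integer(expected_k)
    return(tab)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("malformed counted k-mer line ", lineno[which(nf != 2L)[1]],
         ": expected '<kmer>\\t<count>'")
  words <- vapply(parts, `[[`, character(1), 1L)
  counts_chr <- vapply(parts, `[[`, character(1), 2L)
  counts <- suppressWarnings(as.integer(counts_chr))
  bad <- is.na(counts) | counts_chr != as.character(counts) | counts < 1L
  if (any(bad))
    stop("malformed count on line ", lineno[which(bad)[1]],
         ": '", counts_chr[which(bad)[1]], "' (need an integer >= 1)")
  tab <- counted_kmers(words, counts)
  if (!is.null(expected_k) && attr(tab, "k") != as.integer(expected_k))
    stop("word length ", attr(tab, "k"), " does not match expected_k = ",
         expected_k)
  tab
}

#' @rdname read_counted_kmers
#' @param table a [counted_kmers()] table.
#' @return `write_counted_kmers()`: `path`, invisibly.
#' @export
write_counted_kmers <- function(table, path) {
  stopifnot(inherits(table, "counted_kmers"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(table$kmer, table$count, sep = "\t"), con)
  invisible(path)
}

#' Stream sequences from FASTA/FASTQ files
#'
#' Opens a FASTA or FASTQ file (plain or gzipped; format auto-detected from
#' the first byte after decompression, `>` vs `@`) and returns an iterator
#' that yields successive chunks of records without loading the whole file.
#' Multi-line FASTA is supported; FASTQ must be 4-line records. Sequences are
#' uppercased on read.
#'
#' @param path file path.
#' @param chunk_size maximum number of records per chunk.
#' @return A function: each call returns a `data.frame` with columns `id`,
#'   `seq`, `qual` (`NA` for FASTA) holding up to `chunk_size` records, or
#'   `NULL` once the file is exhausted (the connection is then closed).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT", ">r2", "TTTT"), tf)
#' it <- stream_sequences(tf)
#' it()
#' @export
stream_sequences <- function(path, chunk_size = 1000L) {
  if (!file.exists(path)) stop("no such file: ", path)
  st <- new.env(parent = emptyenv())
  st$con <- gzfile(path, "rt")
  st$open <- TRUE
  st$pending <- character()  # pushback buffer of unconsumed lines
  close_st <- function() {
    if (st$open) { close(st$con); st$open <- FALSE }
  }
  reg.finalizer(st, function(e) if (e$open) close(e$con))
  get_line <- function() {
    if (length(st$pending)) {
      ln <- st$pending[[1L]]
      st$pending <- st$pending[-1L]
      return(ln)
    }
    ln <- readLines(st$con, n = 1L)
    if (length(ln) == 0) NULL else ln
  }
  push_back <- function(ln) st$pending <- c(ln, st$pending)

  first <- get_line()
  if (is.null(first)) {
    fmt <- "empty"
  } else if (startsWith(first, ">")) {
    fmt <- "fasta"; push_back(first)
  } else if (startsWith(first, "@")) {
    fmt <- "fastq"; push_back(first)
  } else {
    close_st()
    stop("unrecognized sequence format: file starts with '",
         substr(first, 1, 1), "' (expected '>' or '@')")
  }

  next_fasta <- function() {
    hdr <- get_line()
    if (is.null(hdr)) return(NULL)
    if (!startsWith(hdr, ">")) stop("malformed FASTA: expected '>' header")
    seq <- character()
    repeat {
      ln <- get_line()
      if (is.null(ln)) break
      if (startsWith(ln, ">")) { push_back(ln); break }
      seq <- c(seq, ln)
    }
    list(id = sub("^>\\s*", "", hdr) , seq = toupper(paste(seq, collapse = "")),
         qual = NA_character_)
  }
  next_fastq <- function() {
    hdr <- get_line()
    if (is.null(hdr)) return(NULL)
    if (!startsWith(hdr, "@")) stop("malformed FASTQ: expected '@' header")
    seq <- get_line(); plus <- get_line(); qual <- get_line()
    if (is.null(seq) || is.null(plus) || is.null(qual))
      stop("truncated FASTQ record: '", hdr, "'")
    if (!startsWith(plus, "+"))
      stop("malformed FASTQ record (missing '+' line): '", hdr, "'")
    if (nchar(qual) != nchar(seq))
      stop("FASTQ quality length differs from sequence length: '", hdr, "'")
    list(id = sub("^@\\s*", "", hdr), seq = toupper(seq), qual = qual)
  }
  next_record <- switch(fmt, fasta = next_fasta, fastq = next_fastq,
                        empty = function() NULL)

  function() {
    if (!st$open) return(NULL)
    ids <- character(0); seqs <- character(0); quals <- character(0)
    while (length(ids) < chunk_size) {
      rec <- next_record()
      if (is.null(rec)) break
      ids <- c(ids, rec$id); seqs <- c(seqs, rec$seq); quals <- c(quals, rec$qual)
    }
    if (length(ids) == 0) { close_st(); return(NULL) }
    # ids keep only the token up to the first whitespace
    data.frame(id = sub("\\s.*$", "", ids), seq = seqs, qual = quals)
  }
}

#' Read all sequences from a FASTA/FASTQ file
#'
#' Convenience wrapper collecting every chunk from [stream_sequences()].
#'
#' @inheritParams stream_sequences
#' @return A `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_sequences <- function(path) {
  it <- stream_sequences(path, chunk_size = 10000L)
  out <- list()
  while (!is.null(chunk <- it())) out[[length(out) + 1L]] <- chunk
  if (length(out) == 0)
    return(data.frame(id = character(), seq = character(), qual = character()))
  do.call(rbind, out)
}

#' Write sequence records to FASTA or FASTQ
#'
#' Format is chosen from the file extension (`.fq`/`.fastq` write FASTQ,
#' anything else FASTA); `.gz` compresses. FASTQ records with missing
#' qualities get a constant placeholder quality string.
#'
#' @param records a `data.frame` with columns `id`, `seq`, and optionally
#'   `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (fastq) {
    qual <- if ("qual" %in% names(records)) records$qual else NA_character_
    qual <- ifelse(is.na(qual),
                   vapply(nchar(records$seq),
                          function(n) strrep("I", n), character(1)),
                   qual)
    writeLines(rbind("@" %p% records$id, records$seq, "+", qual), con)
  } else {
    writeLines(rbind(">" %p% records$id, records$seq), con)
  }
  invisible(path)
}

`%p%` <- function(a, b) paste0(a, b)

#' Canonical form and reverse complement
#'
#' `canonical()` returns the lexicographic minimum (A < C < G < T) of each
#' word and its reverse complement, making indexing strand-insensitive; it is
#' idempotent and strand-symmetric: `canonical(x) == canonical(revcomp(x))`.
#' Words must be ACGT-only (case-insensitive).
#'
#' @param words character vector of DNA words.
#' @return Character vector of the same length.
#' @examples
#' canonical(c("ACGT", "TTTT"))  # "ACGT" "AAAA"
#' @export
canonical <- function(words) cpp_canonical(as.character(words))

#' @rdname canonical
#' @export
reverse_complement <- function(words) cpp_revcomp(as.character(words))

#' Enumerate the s-mers of a sequence
#'
#' One entry per start position `0 .. nchar(seq) - s` (0-based, half-open
#' windows). Windows containing a non-ACGT character are flagged invalid
#' rather than dropped, so positional arithmetic downstream stays aligned.
#'
#' @param seq a single sequence string.
#' @param s word length, `>= 1`.
#' @param canonicalize replace each valid s-mer by its canonical form.
#' @return A `data.frame` with columns `position` (0-based), `smer`, `valid`.
#' @examples
#' enumerate_smers("ACGNACGT", 4)  # positions 0..4; only position 4 is valid
#' @export
enumerate_smers <- function(seq, s, canonicalize = FALSE) {
  stopifnot(length(seq) == 1L)
  res <- cpp_enumerate_smers(as.character(seq), as.integer(s),
                             isTRUE(canonicalize))
  n <- length(res$smers)
  data.frame(position = seq_len(n) - 1L, smer = as.character(res$smers),
             valid = as.logical(res$valid))
}
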