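# FASTA and reference-order-table readers/writers, plus the seeded fixture
# generator. FASTA goes through Biostrings; the reference table is a small
# LF-terminated TSV with a comment header.

#' Write or read an encoded pool as FASTA
#'
#' One record per sequence, header `<id> len=<nt> group=<ordinal>`
#' (informative only -- the decoder identifies sequences solely by their
#' index fragment), 80-column wrapping, uppercase bases.
#'
#' @param pool An `encoded_pool` or a tibble with `ordinal`, `id`, `bases`.
#' @param path File path.
#' @return `write_pool_fasta()` returns `path` invisibly;
#'   `read_pool_fasta()` returns a tibble with `id` and `bases` (lowercase
#'   input is folded to uppercase).
#' @export
write_pool_fasta <- function(pool, path) {
  rec <- if (inherits(pool, "encoded_pool")) pool$records else pool
  seqs <- Biostrings::DNAStringSet(rec$bases)
  names(seqs) <- sprintf("%s len=%d group=%d", rec$id, nchar(rec$bases),
                         rec$ordinal)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(seqs)),
                 bases = unname(toupper(as.character(seqs))))
}

#' Write or read a reference-order table
#'
#' The decode-side map from index fragment to group ordinal: a TSV with
#' comment header lines `#length=<bytes>` and `#config=<fingerprint>`, then
#' `index_fragment<TAB>ordinal` rows ordered by ordinal. LF line endings;
#' bit-exact across platforms.
#'
#' @param table A `ref_order_table` (from [encode_file()]).
#' @param path File path.
#' @return `write_ref_table()` returns `path` invisibly;
#'   `read_ref_table()` returns a `ref_order_table`.
#' @export
write_ref_table <- function(table, path) {
  stopifnot(inherits(table, "ref_order_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#length=%d", table$original_length),
               sprintf("#config=%s", table$fingerprint),
               sprintf("%s\t%d", table$rows$index_fragment,
                       table$rows$ordinal)),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_ref_table
#' @export
read_ref_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  len <- sub("^#length=", "", grep("^#length=", hdr, value = TRUE))
  fp <- sub("^#config=", "", grep("^#config=", hdr, value = TRUE))
  if (length(len) != 1L || length(fp) != 1L)
    stop("malformed reference table: need one #length= and one #config= ",
         "header line", call. = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed reference table row", call. = FALSE)
  rows <- tibble::tibble(
    index_fragment = toupper(vapply(parts, `[[`, character(1), 1L)),
    ordinal = as.integer(vapply(parts, `[[`, character(1), 2L))
  )
  if (anyNA(rows$ordinal))
    stop("malformed reference table: non-numeric ordinal", call. = FALSE)
  if (anyDuplicated(rows$index_fragment))
    stop("malformed reference table: duplicate index fragment", call. = FALSE)
  structure(list(original_length = as.integer(len), fingerprint = fp,
                 rows = rows[order(rows$ordinal), ]),
            class = "ref_order_table")
}

#' Deterministic pseudo-random fixture bytes
#'
#' A seeded byte stream from the package's pinned linear congruential
#' generator: the same `(size, seed)` always produces the same bytes, on
#' every platform. Stands in for real payload files in tests and examples.
#'
#' @param size Number of bytes (>= 1).
#' @param seed Integer seed (>= 0).
#' @return A raw vector of `size` bytes.
#' @examples
#' identical(fixture_bytes(36, 7), fixture_bytes(36, 7))
#' @export
fixture_bytes <- function(size, seed = 1L) {
  if (length(size) != 1L || is.na(size) || size < 1)
    stop("size must be >= 1", call. = FALSE)
  s <- as.numeric(seed) %% 2147483648
  out <- integer(size)
  for (i in seq_len(size)) {
    s <- lcg_next(s)
    out[i] <- (s %/% 65536) %% 256
  }
  as.raw(out)
}
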