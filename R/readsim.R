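# Simplified Illumina-like single-end read simulator: uniform start
# positions, iid substitution errors, no indels, constant quality. Used to
# measure the per-sequence detected-base (coverage) fraction.

#' Simulate single-end sequencing reads
#'
#' For each source sequence of length `L`, draws
#' `ceiling(coverage * L / read_nt)` reads with start positions uniform over
#' the valid range, then substitutes each base independently with
#' probability `sub_rate` (to a uniformly chosen different base). Sequences
#' shorter than `read_nt` yield whole-sequence reads (amplicon behaviour).
#' Deterministic given `rng_seed`.
#'
#' @param records Source sequences: an `encoded_pool`, a tibble with `id`
#'   and `bases` columns, or a named character vector.
#' @param read_nt Read length in nucleotides (default 150).
#' @param coverage Mean per-base coverage (default 20).
#' @param sub_rate Per-base substitution probability (default 0.01, the
#'   short-read platform ballpark).
#' @param rng_seed Integer seed for all randomness.
#' @return A `read_set`: list with `reads` (tibble of `source`, `start`
#'   -- 0-based --, `bases`, `quality`), `read_nt` and
#'   `per_sequence_detected` (tibble of `source`, `detected`: fraction of
#'   source positions covered by at least one read).
#' @export
simulate_reads <- function(records, read_nt = 150L, coverage = 20,
                           sub_rate = 0.01, rng_seed = 1L) {
  if (inherits(records, "encoded_pool")) records <- records$records
  if (is.data.frame(records)) {
    src <- stats::setNames(records$bases, records$id)
  } else {
    src <- records
    if (is.null(names(src))) names(src) <- sprintf("seq%06d", seq_along(src))
  }
  if (length(src) == 0L) stop("no sequences to simulate from", call. = FALSE)
  stopifnot(read_nt >= 1L, coverage > 0, sub_rate >= 0, sub_rate < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  all_reads <- vector("list", length(src))
  detected <- numeric(length(src))
  for (i in seq_along(src)) {
    L <- nchar(src[i])
    rl <- min(read_nt, L)
    n_reads <- ceiling(coverage * L / read_nt)
    starts <- if (L <= read_nt) rep(0L, n_reads)
              else sample.int(L - read_nt + 1L, n_reads, replace = TRUE) - 1L
    bases <- substring(src[i], starts + 1L, starts + rl)
    if (sub_rate > 0) {
      chars <- matrix(unlist(strsplit(bases, ""), use.names = FALSE),
                      nrow = rl)
      err <- stats::runif(length(chars)) < sub_rate
      if (any(err)) {
        cur <- match(chars[err], .BASES)
        shift <- sample.int(3L, sum(err), replace = TRUE)
        chars[err] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
        bases <- apply(chars, 2, paste, collapse = "")
      }
    }
    covered <- logical(L)
    for (s in unique(starts)) covered[(s + 1L):(s + rl)] <- TRUE
    detected[i] <- mean(covered)
    all_reads[[i]] <- tibble::tibble(source = names(src)[i],
                                     start = as.integer(starts),
                                     bases = bases,
                                     quality = strrep("I", rl))
  }
  structure(list(reads = do.call(rbind, all_reads),
                 read_nt = as.integer(read_nt),
                 per_sequence_detected = tibble::tibble(
                   source = names(src), detected = detected)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads of %d nt over %d sequences; mean detected %.2f%%\n",
              nrow(x$reads), x$read_nt, nrow(x$per_sequence_detected),
              100 * mean(x$per_sequence_detected$detected)))
  invisible(x)
}

#' Fraction of a sequence covered by reads
#'
#' Coverage-based detection: the fraction of the source's positions covered
#' by at least one read (substitution errors do not remove coverage).
#'
#' @param record The source: a list/tibble row with `bases`, or a sequence
#'   string.
#' @param reads A tibble of reads (with `start` and `bases` columns)
#'   attributed to this source, e.g. a filtered `read_set$reads`.
#' @return A fraction in `[0, 1]`.
#' @export
detected_fraction <- function(record, reads) {
  bases <- if (is.character(record)) record else record$bases
  L <- nchar(bases)
  covered <- logical(L)
  if (nrow(reads) > 0L) {
    for (r in seq_len(nrow(reads))) {
      s <- reads$start[r]
      covered[(s + 1L):min(L, s + nchar(reads$bases[r]))] <- TRUE
    }
  }
  mean(covered)
}

#' Write or read simulated reads as FASTQ
#'
#' Four-line records with Phred+33 qualities and `@<source>:<start>`
#' headers.
#'
#' @param rs A `read_set` from [simulate_reads()].
#' @param path File path.
#' @return `write_reads_fastq()` returns `path` invisibly;
#'   `read_reads_fastq()` returns a tibble of `source`, `start`, `bases`,
#'   `quality`.
#' @export
write_reads_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  lines <- character(4L * nrow(rs$reads))
  lines[seq(1L, length(lines), 4L)] <- sprintf("@%s:%d", rs$reads$source,
                                               rs$reads$start)
  lines[seq(2L, length(lines), 4L)] <- rs$reads$bases
  lines[seq(3L, length(lines), 4L)] <- "+"
  lines[seq(4L, length(lines), 4L)] <- rs$reads$quality
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  heads <- lines[seq(1L, length(lines), 4L)]
  if (!all(startsWith(heads, "@")))
    stop("malformed FASTQ: header lines must start with '@'", call. = FALSE)
  src <- sub(":[0-9]+$", "", substring(heads, 2L))
  start <- as.integer(sub("^.*:", "", heads))
  tibble::tibble(source = src, start = start,
                 bases = toupper(lines[seq(2L, length(lines), 4L)]),
                 quality = lines[seq(4L, length(lines), 4L)])
}

#' Per-sequence coverage report
#'
#' @param rs A `read_set`.
#' @return A tibble of `source` and `detected` (fraction of positions
#'   covered by at least one read).
#' @export
coverage_report <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  rs$per_sequence_detected
}
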