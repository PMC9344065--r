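# Binary <-> nucleotide mapping and the biochemical constraint filter.
# Canonical 2-bit map, used in BOTH directions: A=00, C=01, G=10, T=11.

.BASES <- c("A", "C", "G", "T")

#' Convert bits to nucleotides
#'
#' Consecutive bit pairs map 00->A, 01->C, 10->G, 11->T.
#'
#' @param bits Integer 0/1 vector of even length.
#' @return A nucleotide string of `length(bits)/2` bases.
#' @examples
#' bits_to_bases(c(0,0, 0,1, 1,0, 1,1))  # "ACGT"
#' @export
bits_to_bases <- function(bits) {
  if (length(bits) %% 2L != 0L)
    stop("bit vector must have even width", call. = FALSE)
  if (length(bits) == 0L) return("")
  b <- as.integer(bits)
  odd <- seq(1L, length(b), by = 2L)
  paste(.BASES[2L * b[odd] + b[odd + 1L] + 1L], collapse = "")
}

#' Convert nucleotides to bits
#'
#' Exact inverse of [bits_to_bases()].
#'
#' @param dna A string over A, C, G, T.
#' @return An integer 0/1 vector of `2 * nchar(dna)` bits.
#' @export
bases_to_bits <- function(dna) {
  if (nchar(dna) == 0L) return(integer(0))
  codes <- base_codes(dna)
  as.integer(rbind(codes %/% 2L, codes %% 2L))
}

# base letters -> integer codes 0..3, with position-naming error
base_codes <- function(dna) {
  chars <- utf8ToInt(dna)
  codes <- match(chars, utf8ToInt(paste(.BASES, collapse = "")))
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1L]
    stop("invalid base '", substr(dna, pos, pos), "' at position ", pos,
         call. = FALSE)
  }
  codes - 1L
}

#' GC content of a sequence
#'
#' Fraction of bases that are G or C.
#'
#' @param dna A non-empty string over A, C, G, T.
#' @return A fraction in `[0, 1]`.
#' @examples
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(dna) {
  if (nchar(dna) == 0L) stop("empty sequence", call. = FALSE)
  codes <- base_codes(dna)
  sum(codes == 1L | codes == 2L) / length(codes)
}

#' Longest homopolymer run
#'
#' Length of the longest run of one repeated base.
#'
#' @param dna A non-empty string over A, C, G, T.
#' @return An integer count.
#' @examples
#' max_run("ACCCCAT")  # 4
#' @export
max_run <- function(dna) {
  if (nchar(dna) == 0L) stop("empty sequence", call. = FALSE)
  max(rle(base_codes(dna))$lengths)
}

#' Biochemical constraint filter
#'
#' A fragment passes iff its GC content lies in `[gc_lo, gc_hi]`
#' (inclusive) and its longest homopolymer run is at most
#' `max_homopolymer`. The filter is applied to the full fragment, seed
#' bases included. At the default 23-nt geometry the GC bound admits
#' exactly 11 or 12 G+C bases.
#'
#' @param dna A string of exactly `fragment_nt` bases.
#' @param cfg A [storage_config()].
#' @return `TRUE` or `FALSE`.
#' @export
passes_constraints <- function(dna, cfg = storage_config()) {
  if (nchar(dna) != cfg$fragment_nt)
    stop("fragment must be ", cfg$fragment_nt, " nt, got ", nchar(dna),
         call. = FALSE)
  gc <- gc_content(dna)
  gc >= cfg$gc_lo && gc <= cfg$gc_hi && max_run(dna) <= cfg$max_homopolymer
}

#' Render a droplet as a DNA fragment
#'
#' Concatenates the big-endian seed bits with the payload bits and maps the
#' result to bases. Renderings that violate the constraint filter are
#' rejected (`NULL`), which is a normal outcome: the fountain simply moves
#' on to the next seed.
#'
#' @param droplet A droplet from [make_droplet()].
#' @param cfg A [storage_config()].
#' @return A fragment (list with `bases`, `seed`, `droplet`, class
#'   `dna_fragment`) or `NULL` if the rendering fails the filter.
#' @export
droplet_to_fragment <- function(droplet, cfg = storage_config()) {
  bits <- c(int_to_bits(droplet$seed, cfg$seed_bits), droplet$payload)
  bases <- bits_to_bases(bits)
  if (!passes_constraints(bases, cfg)) return(NULL)
  structure(list(bases = bases, seed = droplet$seed, droplet = droplet),
            class = "dna_fragment")
}

#' @export
print.dna_fragment <- function(x, ...) {
  cat(sprintf("<dna_fragment> seed %d, degree %d: %s\n",
              x$seed, x$droplet$degree, x$bases))
  invisible(x)
}
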