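# Evaluation statistics: k-mer Jaccard similarity, word-match dotplots,
# windowed GC statistics, and the redundancy / net-information-density
# closed forms of the sequence geometry.

#' k-mer set of a sequence
#'
#' All distinct contiguous length-`k` substrings.
#'
#' @param seq A nucleotide string.
#' @param k k-mer length (>= 1).
#' @return A character vector (the set, first-occurrence order); empty when
#'   `nchar(seq) < k`.
#' @examples
#' kmer_set("ACGTTAGGC", 5)
#' @export
kmer_set <- function(seq, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' k-mer Jaccard similarity of two sequences
#'
#' \eqn{|A \cap B| / |A \cup B|} over the two k-mer sets; defined whenever
#' at least one set is non-empty.
#'
#' @param a,b Nucleotide strings.
#' @param k k-mer length.
#' @return A fraction in `[0, 1]`.
#' @examples
#' jaccard_kmer("ACGTTAGGC", "GTACCTTAGG", 5)  # 0.1
#' @export
jaccard_kmer <- function(a, b, k) {
  sa <- kmer_set(a, k)
  sb <- kmer_set(b, k)
  if (length(sa) == 0L && length(sb) == 0L)
    stop("both k-mer sets are empty", call. = FALSE)
  inter <- length(intersect(sa, sb))
  inter / (length(sa) + length(sb) - inter)
}

#' Pairwise Jaccard sums over a sequence set
#'
#' For each sequence, the sum of its Jaccard coefficients against every
#' other sequence; the grand total sums these row sums (so each unordered
#' pair contributes twice, once per row).
#'
#' @param seqs A character vector of at least two sequences.
#' @param k k-mer length.
#' @return A `jaccard_report`: list with `per_seq` (tibble of `seq` index
#'   and `jaccard_sum`) and `total`.
#' @export
jaccard_total <- function(seqs, k) {
  m <- length(seqs)
  if (m < 2L) stop("need at least two sequences", call. = FALSE)
  sets <- lapply(seqs, kmer_set, k = k)
  sums <- numeric(m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(sets[[i]]) + length(sets[[j]]) - inter
      if (uni == 0L) stop("both k-mer sets are empty for pair (", i, ", ", j,
                          ")", call. = FALSE)
      jc <- inter / uni
      sums[i] <- sums[i] + jc
      sums[j] <- sums[j] + jc
    }
  }
  structure(list(per_seq = tibble::tibble(seq = seq_len(m),
                                          jaccard_sum = sums),
                 total = sum(sums)),
            class = "jaccard_report")
}

#' @export
print.jaccard_report <- function(x, ...) {
  cat(sprintf("<jaccard_report> %d sequences, grand total %.4g\n",
              nrow(x$per_seq), x$total))
  invisible(x)
}

#' Word-match dotplot
#'
#' A dot at `(i, j)` (0-based) marks every position pair where `a` and `b`
#' share an exact word of length `word`. In a self-comparison the main
#' diagonal is always fully present; off-diagonal dots indicate internal
#' repeats.
#'
#' @param a,b Nucleotide strings.
#' @param word Word length (>= 1).
#' @return A `dotplot_result`: list with `word_nt`, `dots` (tibble of `i`,
#'   `j`), `off_diagonal_count` (excludes `i == j` when `a` and `b` are the
#'   same string) and `density` (dots over valid position pairs).
#' @export
dotplot <- function(a, b, word) {
  if (word < 1) stop("word must be >= 1", call. = FALSE)
  na <- nchar(a) - word + 1L
  nb <- nchar(b) - word + 1L
  if (na < 1L || nb < 1L) {
    dots <- tibble::tibble(i = integer(0), j = integer(0))
  } else {
    wa <- substring(a, 1:na, word:(na + word - 1L))
    wb <- substring(b, 1:nb, word:(nb + word - 1L))
    shared <- intersect(wa, wb)
    pairs <- lapply(shared, function(w) {
      expand.grid(i = which(wa == w) - 1L, j = which(wb == w) - 1L)
    })
    dots <- if (length(pairs) == 0L) {
      tibble::tibble(i = integer(0), j = integer(0))
    } else {
      d <- do.call(rbind, pairs)
      d <- d[order(d$i, d$j), , drop = FALSE]
      tibble::tibble(i = as.integer(d$i), j = as.integer(d$j))
    }
  }
  self <- identical(a, b)
  offd <- if (self) sum(dots$i != dots$j) else nrow(dots)
  structure(list(word_nt = as.integer(word), dots = dots,
                 off_diagonal_count = as.integer(offd),
                 density = if (na >= 1L && nb >= 1L)
                   nrow(dots) / (as.numeric(na) * nb) else 0),
            class = "dotplot_result")
}

#' @export
print.dotplot_result <- function(x, ...) {
  cat(sprintf("<dotplot_result> word %d: %d dots, %d off-diagonal, density %.4g\n",
              x$word_nt, nrow(x$dots), x$off_diagonal_count, x$density))
  invisible(x)
}

#' Plot a dotplot
#'
#' @param dp A [dotplot()] result.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(dp) {
  stopifnot(inherits(dp, "dotplot_result"))
  ggplot2::ggplot(dp$dots, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position in sequence A", y = "position in sequence B",
                  title = sprintf("word length %d", dp$word_nt)) +
    ggplot2::theme_minimal()
}

#' Windowed GC statistics
#'
#' Splits every sequence into non-overlapping windows of `window` bases
#' (trailing partial windows dropped) and reports the GC fraction of each
#' window together with the mean and population variance over all windows
#' of all sequences.
#'
#' @param seqs A character vector of sequences.
#' @param window Window width in nucleotides.
#' @return A `gc_stats`: list with `window_nt`, `per_window` (tibble of
#'   `seq`, `window`, `gc`), `mean` and `variance` (population variance).
#' @export
gc_window_stats <- function(seqs, window) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  rows <- lapply(seq_along(seqs), function(s) {
    n <- nchar(seqs[s]) %/% window
    if (n == 0L) return(NULL)
    starts <- (seq_len(n) - 1L) * window + 1L
    gc <- vapply(substring(seqs[s], starts, starts + window - 1L),
                 gc_content, numeric(1), USE.NAMES = FALSE)
    tibble::tibble(seq = s, window = seq_len(n) - 1L, gc = gc)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no complete window in any sequence", call. = FALSE)
  mu <- mean(rows$gc)
  structure(list(window_nt = as.integer(window), per_window = rows,
                 mean = mu, variance = mean((rows$gc - mu)^2)),
            class = "gc_stats")
}

#' @export
print.gc_stats <- function(x, ...) {
  cat(sprintf("<gc_stats> %d windows of %d nt: mean %.4f, population variance %.3g\n",
              nrow(x$per_window), x$window_nt, x$mean, x$variance))
  invisible(x)
}

#' Plot windowed GC fractions
#'
#' @param stats A [gc_window_stats()] result.
#' @return A ggplot object.
#' @export
plot_gc_windows <- function(stats) {
  stopifnot(inherits(stats, "gc_stats"))
  ggplot2::ggplot(stats$per_window,
                  ggplot2::aes(x = .data$window, y = .data$gc,
                               group = .data$seq)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_hline(yintercept = stats$mean, linetype = 2) +
    ggplot2::labs(x = sprintf("window (%d nt)", stats$window_nt),
                  y = "GC fraction") +
    ggplot2::theme_minimal()
}

#' Per-sequence redundancy of the geometry
#'
#' Fraction of the fragment region spent on addressing and error
#' correction: `(seed_nt * fragments_per_sequence + rs_nt) / region_nt`,
#' where the denominator is the fragment region (the parity suffix is
#' appended after it). At the defaults this is 48/184, i.e. 26%.
#'
#' @param cfg A [storage_config()].
#' @return A fraction.
#' @examples
#' round(100 * redundancy(storage_config()))  # 26
#' @export
redundancy <- function(cfg = storage_config()) {
  (seed_nt(cfg) * cfg$fragments_per_sequence + 4 * cfg$rs_parity_bytes) /
    region_nt(cfg)
}

#' Net information density
#'
#' Payload bits stored per nucleotide: `2 * (1 - redundancy)`, against the
#' 2 bit/nt ceiling of a four-letter alphabet. 1.48 at the defaults.
#'
#' @param cfg A [storage_config()].
#' @return Bits per nucleotide.
#' @export
net_information_density <- function(cfg = storage_config()) {
  2 * (1 - redundancy(cfg))
}
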