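#' Encoding configuration
#'
#' Bundles every tunable of the codec: sequence geometry, biochemical
#' constraint bounds, soliton distribution parameters and index-selection
#' thresholds. The defaults describe the reference geometry: eight 36-bit
#' segments per group, 23-nt fragments carrying a 5-nt (10-bit) seed, eight
#' fragments per sequence (one index + seven payload) and two Reed-Solomon
#' parity bytes rendered as 8 nt, for a 192-nt sequence with a 184-nt
#' fragment region.
#'
#' @param segments_per_group Number of fixed-width segments per data group
#'   (`n` of the Luby transform). Default 8.
#' @param segment_bits Width of one segment in bits. Must equal
#'   `2 * (fragment_nt - seed_bits / 2)` so a droplet renders to exactly one
#'   fragment. Default 36.
#' @param seed_bits Width of the droplet seed in bits; rendered as
#'   `seed_bits / 2` nucleotides at the start of each fragment. Must be even.
#'   Default 10 (5 nt, 1023 usable seeds).
#' @param fragment_nt Fragment length in nucleotides. Default 23.
#' @param fragments_per_sequence Fragments concatenated into one sequence:
#'   one index fragment plus payload fragments. Default 8.
#' @param gc_lo,gc_hi Inclusive GC-content bounds applied to every fragment.
#'   Defaults 0.45 and 0.55.
#' @param max_homopolymer Longest allowed run of one base; runs of
#'   `max_homopolymer + 1` or more are rejected. Default 2.
#' @param rs_parity_bytes Reed-Solomon parity bytes appended per sequence
#'   (each byte is 4 nt). Default 2.
#' @param soliton_c,soliton_delta Robust soliton parameters `c` and `delta`.
#'   Defaults 0.025 and 0.001.
#' @param index_k k-mer length used when screening candidate index fragments
#'   for cross-group similarity. Default 10.
#' @param index_jaccard_max Maximum allowed k-mer Jaccard coefficient between
#'   a new index fragment and every previously chosen one. Default 0.2.
#' @param master_seed Integer seed recorded in the configuration; encoding
#'   itself is fully deterministic, so this only seeds auxiliary stochastic
#'   helpers that default to it.
#'
#' @return An object of class `storage_config` (a validated named list).
#' @examples
#' cfg <- storage_config()
#' cfg$fragment_nt
#' @export
storage_config <- function(segments_per_group = 8L,
                           segment_bits = 36L,
                           seed_bits = 10L,
                           fragment_nt = 23L,
                           fragments_per_sequence = 8L,
                           gc_lo = 0.45,
                           gc_hi = 0.55,
                           max_homopolymer = 2L,
                           rs_parity_bytes = 2L,
                           soliton_c = 0.025,
                           soliton_delta = 0.001,
                           index_k = 10L,
                           index_jaccard_max = 0.2,
                           master_seed = 1L) {
  cfg <- list(
    segments_per_group = as.integer(segments_per_group),
    segment_bits = as.integer(segment_bits),
    seed_bits = as.integer(seed_bits),
    fragment_nt = as.integer(fragment_nt),
    fragments_per_sequence = as.integer(fragments_per_sequence),
    gc_lo = as.numeric(gc_lo),
    gc_hi = as.numeric(gc_hi),
    max_homopolymer = as.integer(max_homopolymer),
    rs_parity_bytes = as.integer(rs_parity_bytes),
    soliton_c = as.numeric(soliton_c),
    soliton_delta = as.numeric(soliton_delta),
    index_k = as.integer(index_k),
    index_jaccard_max = as.numeric(index_jaccard_max),
    master_seed = as.integer(master_seed)
  )
  class(cfg) <- "storage_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c("segments_per_group", "segment_bits", "seed_bits", "fragment_nt",
              "fragments_per_sequence", "max_homopolymer")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("'", f, "' must be a positive count", call. = FALSE)
  }
  if (cfg$rs_parity_bytes < 0L)
    stop("'rs_parity_bytes' must be non-negative", call. = FALSE)
  if (cfg$seed_bits %% 2L != 0L)
    stop("'seed_bits' must be even (2 bits per seed nucleotide)", call. = FALSE)
  if (cfg$seed_bits < 2L || cfg$seed_bits > 16L)
    stop("'seed_bits' must be between 2 and 16", call. = FALSE)
  if (cfg$segment_bits != 2L * (cfg$fragment_nt - cfg$seed_bits %/% 2L))
    stop("'segment_bits' must equal 2*(fragment_nt - seed_bits/2); got ",
         cfg$segment_bits, " for a ", cfg$fragment_nt, "-nt fragment with a ",
         cfg$seed_bits %/% 2L, "-nt seed", call. = FALSE)
  if ((cfg$segments_per_group * cfg$segment_bits) %% 8L != 0L)
    stop("segments_per_group * segment_bits must be divisible by 8 ",
         "(groups are byte-aligned)", call. = FALSE)
  if (!(cfg$gc_lo >= 0 && cfg$gc_lo <= cfg$gc_hi && cfg$gc_hi <= 1))
    stop("need 0 <= gc_lo <= gc_hi <= 1", call. = FALSE)
  if (cfg$soliton_c <= 0 || cfg$soliton_delta <= 0 || cfg$soliton_delta >= 1)
    stop("need soliton_c > 0 and 0 < soliton_delta < 1", call. = FALSE)
  if (region_nt(cfg) %% 4L != 0L)
    stop("fragment region must pack to whole bytes (length divisible by 4 nt)",
         call. = FALSE)
  if (region_bytes(cfg) + cfg$rs_parity_bytes > 255L)
    stop("fragment region bytes + parity exceed the Reed-Solomon block ",
         "limit of 255", call. = FALSE)
  invisible(cfg)
}

# geometry helpers -----------------------------------------------------------

group_bytes <- function(cfg) (cfg$segments_per_group * cfg$segment_bits) %/% 8L

seed_nt <- function(cfg) cfg$seed_bits %/% 2L

region_nt <- function(cfg) cfg$fragments_per_sequence * cfg$fragment_nt

region_bytes <- function(cfg) region_nt(cfg) %/% 4L

sequence_nt <- function(cfg) region_nt(cfg) + 4L * cfg$rs_parity_bytes

#' @export
print.storage_config <- function(x, ...) {
  cat("<storage_config>\n")
  cat(sprintf("  group: %d segments x %d bits (%d bytes)\n",
              x$segments_per_group, x$segment_bits, group_bytes(x)))
  cat(sprintf("  fragment: %d nt (%d-nt seed + %d-nt payload)\n",
              x$fragment_nt, seed_nt(x), x$fragment_nt - seed_nt(x)))
  cat(sprintf("  sequence: %d nt region + %d nt RS parity = %d nt\n",
              region_nt(x), 4L * x$rs_parity_bytes, sequence_nt(x)))
  cat(sprintf("  constraints: GC in [%.2f, %.2f], max run %d\n",
              x$gc_lo, x$gc_hi, x$max_homopolymer))
  cat(sprintf("  soliton: c = %g, delta = %g; index screen: %d-mer Jaccard <= %g\n",
              x$soliton_c, x$soliton_delta, x$index_k, x$index_jaccard_max))
  invisible(x)
}

#' Configuration fingerprint
#'
#' A short text fingerprint of the geometry-critical fields, stored in the
#' reference-order table header so a decode run can detect a mismatched
#' configuration.
#'
#' @param cfg A [storage_config()].
#' @return A single character string.
#' @export
config_fingerprint <- function(cfg) {
  sprintf("n%d.b%d.s%d.f%d.x%d.gc%g-%g.h%d.rs%d.c%g.d%g",
          cfg$segments_per_group, cfg$segment_bits, cfg$seed_bits,
          cfg$fragment_nt, cfg$fragments_per_sequence,
          cfg$gc_lo, cfg$gc_hi, cfg$max_homopolymer, cfg$rs_parity_bytes,
          cfg$soliton_c, cfg$soliton_delta)
}

#' Read or write a configuration file
#'
#' Plain-text (YAML) serialization of a [storage_config()]. Unknown keys are
#' rejected rather than ignored so typos cannot silently fall back to
#' defaults.
#'
#' @param path File path.
#' @param cfg A [storage_config()].
#' @return `read_config()` returns a [storage_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(storage_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(storage_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "storage_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
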