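#' Split a byte payload into data groups
#'
#' File preprocessing: the payload is padded to a whole number of groups and
#' cut into groups of `segments_per_group` fixed-width bit segments. Groups
#' are mutually independent, which is what makes per-group random access
#' possible downstream.
#'
#' Padding uses a fixed deterministic pseudo-random byte stream rather than
#' zeros: the constraint filter needs roughly balanced base composition, and
#' an all-zero tail would render every candidate fragment of the last group
#' as a long A run that no seed can rescue. The padding bytes are the same
#' on every platform and are discarded by [ungroup_payload()], which
#' truncates to `original_length`.
#'
#' @param payload A non-empty raw vector.
#' @param cfg A [storage_config()].
#' @return A list with elements `groups` (a list of data groups, each a list
#'   with `ordinal` -- 0-based -- and `segments`, an integer 0/1 matrix of
#'   `segments_per_group` rows by `segment_bits` columns) and
#'   `original_length` (bytes before padding).
#' @examples
#' pg <- pad_and_group(as.raw(1:40), storage_config())
#' length(pg$groups)   # 2 groups of 36 bytes
#' @seealso [ungroup_payload()]
#' @export
pad_and_group <- function(payload, cfg = storage_config()) {
  stopifnot(is.raw(payload), inherits(cfg, "storage_config"))
  if (length(payload) == 0L) stop("nothing to encode", call. = FALSE)
  gb <- group_bytes(cfg)
  n_groups <- ceiling(length(payload) / gb)
  n_pad <- n_groups * gb - length(payload)
  padded <- c(payload, padding_bytes(n_pad))
  bits <- bytes_to_bits(padded)
  per_group <- cfg$segments_per_group * cfg$segment_bits
  groups <- lapply(seq_len(n_groups), function(g) {
    seg <- matrix(bits[((g - 1L) * per_group + 1L):(g * per_group)],
                  nrow = cfg$segments_per_group, ncol = cfg$segment_bits,
                  byrow = TRUE)
    list(ordinal = g - 1L, segments = seg)
  })
  list(groups = groups, original_length = length(payload))
}

# fixed keystream used to pad the final group; any constant seed works, it
# only has to be identical for every encoder and platform
padding_bytes <- function(n) {
  if (n == 0L) return(raw(0))
  fixture_bytes(n, seed = 305419896)
}

#' Reassemble bytes from recovered data groups
#'
#' Inverse of [pad_and_group()]: concatenates the segment bits of the
#' complete, ordered group set and truncates the padding.
#'
#' @param groups A list of data groups as produced by [pad_and_group()] (or
#'   recovered by the decoder); all ordinals `0..N-1` must be present.
#' @param original_length Payload length in bytes before padding.
#' @return A raw vector of `original_length` bytes.
#' @export
ungroup_payload <- function(groups, original_length) {
  stopifnot(length(groups) > 0L, original_length >= 0L)
  ords <- vapply(groups, function(g) g$ordinal, integer(1))
  gbytes <- length(groups[[1L]]$segments) %/% 8L
  n_expected <- max(ceiling(original_length / gbytes), max(ords) + 1L)
  missing <- setdiff(0:(n_expected - 1L), ords)
  if (length(missing) > 0L)
    stop("missing group ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ords))
    stop("duplicate group ordinals", call. = FALSE)
  groups <- groups[order(ords)]
  bits <- unlist(lapply(groups, function(g) as.integer(t(g$segments))),
                 use.names = FALSE)
  bytes <- bits_to_bytes(bits)
  if (original_length > length(bytes))
    stop("groups hold only ", length(bytes), " bytes but original_length is ",
         original_length, call. = FALSE)
  bytes[seq_len(original_length)]
}
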