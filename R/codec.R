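# Sequence assembly and pool decoding. A sequence is
#   index fragment || 7 payload fragments || RS parity bases
# and identity comes solely from the index fragment looked up in the
# reference-order table -- never from FASTA headers.

#' Assemble a sequence record from a selection result
#'
#' Concatenates the index and payload fragments, packs the region to bytes
#' (4 bases per byte), computes Reed-Solomon parity over those bytes and
#' appends the parity rendered as bases.
#'
#' @param sel A `selection_result` from [select_payload()].
#' @param cfg A [storage_config()].
#' @return A list with `ordinal`, `id` and `bases` (full sequence,
#'   `sequence_nt` long).
#' @export
assemble <- function(sel, cfg = storage_config()) {
  stopifnot(inherits(sel, "selection_result"), isTRUE(sel$rank_certificate))
  region <- paste0(sel$index$bases, paste(sel$payload$bases, collapse = ""))
  msg <- bits_to_bytes(bases_to_bits(region))
  if (cfg$rs_parity_bytes > 0L) {
    cw <- rs_protect(msg, cfg$rs_parity_bytes)
    parity <- cw[(length(msg) + 1L):length(cw)]
    bases <- paste0(region, bits_to_bases(bytes_to_bits(parity)))
  } else {
    bases <- region
  }
  list(ordinal = sel$ordinal,
       id = sprintf("oligo%06d", sel$ordinal),
       bases = bases)
}

#' Encode a byte payload into a pool of DNA sequences
#'
#' The full pipeline: preprocessing ([pad_and_group()]), fountain encoding
#' and constraint filtering ([build_pool()]), hidden-addressing selection
#' ([select_index()], [select_payload()]) and assembly with parity
#' ([assemble()]). Deterministic: the same payload and configuration always
#' produce byte-identical output.
#'
#' @param payload A non-empty raw vector.
#' @param cfg A [storage_config()].
#' @return An `encoded_pool`: list with `records` (tibble of `ordinal`,
#'   `id`, `bases`, one row per group) and `ref_table` (a
#'   `ref_order_table`: list with `original_length`, `fingerprint` and
#'   `rows`, a tibble of `index_fragment`, `ordinal`).
#' @examples
#' pool <- encode_file(fixture_bytes(72, seed = 7))
#' pool$records$bases
#' @export
encode_file <- function(payload, cfg = storage_config()) {
  pg <- pad_and_group(payload, cfg)
  pools <- lapply(pg$groups, build_pool, cfg = cfg)
  idx <- select_index(pools, cfg)
  records <- vector("list", length(pools))
  for (g in seq_along(pools)) {
    sel <- select_payload(pools[[g]], idx$pool_row[g], cfg)
    records[[g]] <- assemble(sel, cfg)
  }
  rec <- tibble::tibble(
    ordinal = vapply(records, `[[`, integer(1), "ordinal"),
    id = vapply(records, `[[`, character(1), "id"),
    bases = vapply(records, `[[`, character(1), "bases")
  )
  tab <- structure(list(original_length = pg$original_length,
                        fingerprint = config_fingerprint(cfg),
                        rows = tibble::tibble(index_fragment = idx$bases,
                                              ordinal = idx$ordinal)),
                   class = "ref_order_table")
  structure(list(records = rec, ref_table = tab), class = "encoded_pool")
}

#' @export
print.encoded_pool <- function(x, ...) {
  cat(sprintf("<encoded_pool> %d sequences of %d nt, payload %d bytes\n",
              nrow(x$records), nchar(x$records$bases[1L]),
              x$ref_table$original_length))
  invisible(x)
}

#' @export
print.ref_order_table <- function(x, ...) {
  cat(sprintf("<ref_order_table> %d groups, payload %d bytes, config %s\n",
              nrow(x$rows), x$original_length, x$fingerprint))
  invisible(x)
}

#' Disassemble one sequence into its droplets
#'
#' Applies Reed-Solomon recovery, splits the corrected fragment region into
#' fragments, re-derives each droplet's plan from its seed field and looks
#' the index fragment up in the reference-order table. As an integrity
#' check every decoded fragment is re-validated against the constraint
#' filter (all emitted fragments satisfy it by construction), which catches
#' most miscorrections of error patterns beyond the parity budget.
#'
#' @param bases A sequence string of exactly `sequence_nt` bases.
#' @param table A `ref_order_table`.
#' @param cfg A [storage_config()].
#' @return A list with `ordinal`, `droplets` (list of
#'   `fragments_per_sequence` droplets, index droplet first) and
#'   `corrected` (bytes fixed by RS).
#' @export
disassemble <- function(bases, table, cfg = storage_config()) {
  if (nchar(bases) != sequence_nt(cfg))
    stop("sequence must be ", sequence_nt(cfg), " nt, got ", nchar(bases),
         call. = FALSE)
  corrected <- 0L
  if (cfg$rs_parity_bytes > 0L) {
    cw <- bits_to_bytes(bases_to_bits(bases))
    rec <- rs_recover(cw, cfg$rs_parity_bytes)
    if (!rec$ok) stop("uncorrectable sequence", call. = FALSE)
    corrected <- rec$corrected
    region <- bits_to_bases(bytes_to_bits(rec$message))
  } else {
    region <- bases
  }
  frags <- substring(region,
                     (seq_len(cfg$fragments_per_sequence) - 1L) * cfg$fragment_nt + 1L,
                     seq_len(cfg$fragments_per_sequence) * cfg$fragment_nt)
  ord <- match(frags[1L], table$rows$index_fragment)
  if (is.na(ord)) stop("unknown index fragment", call. = FALSE)
  dist <- robust_soliton(cfg$segments_per_group, cfg$soliton_c,
                         cfg$soliton_delta)
  droplets <- lapply(frags, function(f) {
    if (!passes_constraints(f, cfg))
      stop("uncorrectable sequence (fragment fails constraint filter)",
           call. = FALSE)
    bits <- bases_to_bits(f)
    seed <- bits_to_int(bits[seq_len(cfg$seed_bits)])
    if (seed == 0) stop("uncorrectable sequence (reserved seed 0)",
                        call. = FALSE)
    plan <- droplet_plan(seed, cfg$segments_per_group, dist)
    list(seed = as.integer(seed), degree = plan$degree,
         members = plan$members,
         payload = bits[(cfg$seed_bits + 1L):length(bits)])
  })
  list(ordinal = table$rows$ordinal[ord], droplets = droplets,
       corrected = corrected)
}

#' Solve a group from its droplets
#'
#' Gaussian elimination over GF(2) on the droplet membership matrix with
#' the droplet payloads as right-hand sides, with a peeling fast path that
#' repeatedly substitutes degree-1 rows first.
#'
#' @param droplets A list of droplets (with `members` and `payload`).
#' @param n Number of segments to recover.
#' @return An integer 0/1 matrix of `n` rows (the segments in order).
#' @export
solve_group <- function(droplets, n) {
  width <- length(droplets[[1L]]$payload)
  A <- t(vapply(droplets, function(d) {
    row <- integer(n)
    row[d$members] <- 1L
    row
  }, integer(n)))
  B <- t(vapply(droplets, function(d) as.integer(d$payload), integer(width)))
  segs <- matrix(NA_integer_, nrow = n, ncol = width)
  known <- logical(n)
  # peeling fast path: propagate degree-1 rows until quiescent
  repeat {
    deg <- rowSums(A)
    i <- which(deg == 1L)[1L]
    if (is.na(i)) break
    s <- which(A[i, ] == 1L)
    if (!known[s]) {
      segs[s, ] <- B[i, ]
      known[s] <- TRUE
    }
    hit <- which(A[, s] == 1L)
    A[hit, s] <- 0L
    B[hit, ] <- (B[hit, , drop = FALSE] + rep(segs[s, ], each = length(hit))) %% 2L
  }
  # Gauss-Jordan on whatever peeling left behind: clearing the full pivot
  # column each time leaves every pivot row as a unit row, so the
  # right-hand side is the segment directly
  free_row <- rep(TRUE, nrow(A))
  pivot_of <- rep(NA_integer_, n)
  for (s in which(!known)) {
    cand <- which(A[, s] == 1L & free_row)
    if (length(cand) == 0L)
      stop("undecodable group (rank below ", n, ")", call. = FALSE)
    piv <- cand[1L]
    free_row[piv] <- FALSE
    pivot_of[s] <- piv
    others <- setdiff(which(A[, s] == 1L), piv)
    if (length(others) > 0L) {
      A[others, ] <- (A[others, , drop = FALSE] +
                        rep(A[piv, ], each = length(others))) %% 2L
      B[others, ] <- (B[others, , drop = FALSE] +
                        rep(B[piv, ], each = length(others))) %% 2L
    }
  }
  for (s in which(!known)) {
    segs[s, ] <- B[pivot_of[s], ]
  }
  segs
}

#' Decode a pool of sequences back to bytes
#'
#' Order-independent decoding: exact duplicates (after RS recovery) are
#' collapsed, each sequence is mapped to its group through the
#' reference-order table, every group is solved and the payload is
#' reassembled and truncated to the original length. Sequences that cannot
#' be recovered (uncorrectable, unknown index) are skipped with a warning;
#' if that leaves any group without a usable sequence the decode fails and
#' names the missing groups.
#'
#' @param records Sequences to decode: a character vector of bases, a
#'   tibble with a `bases` column, or an `encoded_pool`.
#' @param table A `ref_order_table` (defaults to the pool's own when
#'   `records` is an `encoded_pool`).
#' @param cfg A [storage_config()].
#' @param groups Optional integer vector of group ordinals for random
#'   access: only these groups are solved and their bytes returned (a slice
#'   of the padded payload, not truncated to `original_length`).
#' @return A raw vector: the original payload, or the selected groups'
#'   bytes when `groups` is given.
#' @examples
#' pool <- encode_file(fixture_bytes(72, seed = 7))
#' identical(decode_pool(pool), fixture_bytes(72, seed = 7))
#' @export
decode_pool <- function(records, table = NULL, cfg = storage_config(),
                        groups = NULL) {
  if (inherits(records, "encoded_pool")) {
    if (is.null(table)) table <- records$ref_table
    records <- records$records
  }
  if (is.data.frame(records)) records <- records$bases
  stopifnot(is.character(records), inherits(table, "ref_order_table"))
  fp <- config_fingerprint(cfg)
  if (!identical(fp, table$fingerprint))
    stop("configuration fingerprint mismatch: table has '", table$fingerprint,
         "', decoder has '", fp, "'", call. = FALSE)
  n <- cfg$segments_per_group
  solved <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  n_skipped <- 0L
  for (bases in records) {
    dis <- tryCatch(disassemble(bases, table, cfg), error = function(e) e)
    if (inherits(dis, "error")) {
      n_skipped <- n_skipped + 1L
      next
    }
    key <- as.character(dis$ordinal)
    if (!is.null(groups) && !(dis$ordinal %in% groups)) next
    sig <- paste0(key, ":", bases)
    if (!is.null(seen[[sig]])) next   # exact duplicate
    seen[[sig]] <- TRUE
    if (!is.null(solved[[key]])) next # first verifiable solve wins
    segs <- tryCatch(solve_group(dis$droplets, n), error = function(e) NULL)
    if (is.null(segs)) next
    # verification identity: re-XOR the solution through every droplet
    ok <- all(vapply(dis$droplets, function(d) {
      xr <- colSums(segs[d$members, , drop = FALSE]) %% 2L
      all(xr == d$payload)
    }, logical(1)))
    if (ok) solved[[key]] <- segs
  }
  if (n_skipped > 0L)
    warning(n_skipped, " sequence(s) could not be recovered and were skipped",
            call. = FALSE)
  wanted <- if (is.null(groups)) table$rows$ordinal else sort(unique(groups))
  missing <- wanted[!vapply(as.character(wanted),
                            function(k) !is.null(solved[[k]]), logical(1))]
  if (length(missing) > 0L)
    stop("undecodable pool: missing group(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  grps <- lapply(wanted, function(o) list(ordinal = 0L,
                                          segments = solved[[as.character(o)]]))
  # reuse ungroup's bit plumbing with local ordinals 0..k-1
  for (i in seq_along(grps)) grps[[i]]$ordinal <- i - 1L
  if (is.null(groups)) {
    ungroup_payload(grps, table$original_length)
  } else {
    ungroup_payload(grps, length(grps) * group_bytes(cfg))
  }
}
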