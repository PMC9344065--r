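# Fragment pool construction and the hidden-addressing selection step:
# one index fragment per group (screened for cross-group similarity) plus
# seven payload fragments whose droplets, together with the index droplet,
# span the group over GF(2).

#' Build the constraint-passing fragment pool for a group
#'
#' Runs the fountain over the full seed stream: every seed's droplet is
#' rendered and filtered, and all survivors are kept in seed-stream order.
#' The whole stream is evaluated as one set of matrix operations, so
#' building a pool costs a few milliseconds rather than a loop over
#' thousands of seeds.
#'
#' @param group A data group from [pad_and_group()].
#' @param cfg A [storage_config()].
#' @return A `fragment_pool`: a [tibble::tibble()] with columns `seed`,
#'   `bases`, `degree`, `members` (list of 1-based index vectors) and
#'   `payload` (list of 0/1 bit vectors), plus attribute `ordinal`.
#' @export
build_pool <- function(group, cfg = storage_config()) {
  pt <- plan_table(cfg)
  n_seeds <- length(pt$seeds)
  # payload bits for every seed at once: membership (seeds x n) . segments
  P <- pt$membership %*% group$segments %% 2
  odd <- seq(1L, cfg$segment_bits, by = 2L)
  V <- cbind(pt$seed_codes, 2 * P[, odd, drop = FALSE] + P[, odd + 1L, drop = FALSE])
  gc_count <- rowSums(V == 1 | V == 2)
  gc <- gc_count / cfg$fragment_nt
  eq <- V[, -1L, drop = FALSE] == V[, -ncol(V), drop = FALSE]
  h <- cfg$max_homopolymer
  # a run of h+1 bases means h consecutive equalities
  if (h >= ncol(eq)) {
    run_bad <- rep(FALSE, n_seeds)
  } else {
    acc <- eq[, seq_len(ncol(eq) - h + 1L), drop = FALSE]
    if (h > 1L) for (j in seq_len(h - 1L)) {
      acc <- acc & eq[, seq_len(ncol(eq) - h + 1L) + j, drop = FALSE]
    }
    run_bad <- rowSums(acc) > 0
  }
  pass <- which(gc >= cfg$gc_lo & gc <= cfg$gc_hi & !run_bad)
  if (length(pass) < cfg$fragments_per_sequence)
    stop("group ", group$ordinal, ": only ", length(pass),
         " constraint-passing fragments for ", cfg$fragments_per_sequence,
         " slots; increase seed_bits", call. = FALSE)
  codes <- V[pass, , drop = FALSE] + 1L
  letters <- utf8ToInt("ACGT")
  bases <- vapply(seq_along(pass),
                  function(i) intToUtf8(letters[codes[i, ]]), character(1))
  pool <- tibble::tibble(
    seed = pt$seeds[pass],
    bases = bases,
    degree = pt$degree[pass],
    members = pt$members[pass],
    payload = lapply(pass, function(i) as.integer(P[i, ]))
  )
  attr(pool, "ordinal") <- group$ordinal
  class(pool) <- c("fragment_pool", class(pool))
  pool
}

#' GF(2) rank of a droplet membership matrix
#'
#' Rank over GF(2) of the droplets-by-segments membership matrix, by
#' elimination on bit-packed rows. Full rank (`== n`) certifies that the
#' droplet set determines every segment of the group.
#'
#' @param droplets A list of droplets (anything with a `members` element) or
#'   a list of 1-based member-index vectors.
#' @param n Number of segments (matrix columns).
#' @return The rank, an integer in `[0, min(length(droplets), n)]`.
#' @export
gf2_rank <- function(droplets, n) {
  masks <- members_to_masks(droplets)
  basis <- numeric(0)
  rank <- 0L
  for (m in masks) {
    m <- reduce_mask(m, basis)
    if (m != 0) {
      basis <- c(basis, m)
      rank <- rank + 1L
    }
  }
  rank
}

members_to_masks <- function(droplets) {
  vapply(droplets, function(d) {
    mem <- if (is.list(d)) d$members else d
    sum(2^(mem - 1))
  }, numeric(1))
}

# XOR for small nonneg doubles used as bit masks (n <= 31 segments)
xor_mask <- function(a, b) {
  r <- 0
  bit <- 1
  while (a > 0 || b > 0) {
    if ((a %% 2) != (b %% 2)) r <- r + bit
    a <- a %/% 2; b <- b %/% 2; bit <- bit * 2
  }
  r
}

reduce_mask <- function(m, basis) {
  for (b in basis) {
    # eliminate using the basis row's highest set bit
    hb <- 2^floor(log2(b))
    if (m >= hb && (m %/% hb) %% 2 == 1) m <- xor_mask(m, b)
  }
  m
}

#' Select index fragments across groups
#'
#' Hidden addressing: each group's index is one of its own data droplets.
#' Groups are processed in ascending ordinal; for each, the first pool
#' fragment (seed-stream order) is taken whose bases differ from every
#' previously chosen index and whose k-mer Jaccard coefficient
#' (`k = index_k`) against every previous index is at most
#' `index_jaccard_max`. If no candidate qualifies, the threshold is relaxed
#' to the non-duplicate candidate minimising the maximum pairwise Jaccard,
#' with a warning.
#'
#' Only candidates that share at least one k-mer with a previous index can
#' have a nonzero Jaccard, so the scan is driven by a k-mer occurrence map
#' and stays near-linear in the number of groups.
#'
#' @param pools List of [build_pool()] results, one per group, any order.
#' @param cfg A [storage_config()].
#' @return A [tibble::tibble()] with columns `ordinal`, `seed`, `bases` and
#'   `pool_row` (the row of the group's pool that was chosen), ordered by
#'   ordinal.
#' @export
select_index <- function(pools, cfg = storage_config()) {
  ords <- vapply(pools, function(p) attr(p, "ordinal"), integer(1))
  pools <- pools[order(ords)]
  n_groups <- length(pools)
  chosen_bases <- new.env(parent = emptyenv())   # exact-duplicate set
  kmer_map <- new.env(parent = emptyenv())       # k-mer -> group ids
  kmer_sets <- vector("list", n_groups)
  out_seed <- integer(n_groups)
  out_bases <- character(n_groups)
  out_row <- integer(n_groups)
  for (g in seq_len(n_groups)) {
    pool <- pools[[g]]
    best_row <- NA_integer_
    best_j <- Inf
    pick <- NA_integer_
    cand_kmers <- NULL
    for (r in seq_len(nrow(pool))) {
      b <- pool$bases[r]
      if (!is.null(chosen_bases[[b]])) next
      km <- kmer_set(b, cfg$index_k)
      near <- unique(unlist(lapply(km, function(x) kmer_map[[x]]),
                            use.names = FALSE))
      max_j <- 0
      for (other in near) {
        inter <- length(intersect(km, kmer_sets[[other]]))
        uni <- length(km) + length(kmer_sets[[other]]) - inter
        max_j <- max(max_j, inter / uni)
      }
      if (max_j <= cfg$index_jaccard_max) {
        pick <- r
        cand_kmers <- km
        break
      }
      if (max_j < best_j) {
        best_j <- max_j
        best_row <- r
      }
    }
    if (is.na(pick)) {
      if (is.na(best_row))
        stop("group ", attr(pool, "ordinal"),
             ": no index candidate distinct from earlier groups", call. = FALSE)
      warning("group ", attr(pool, "ordinal"),
              ": index similarity threshold relaxed (max Jaccard ",
              signif(best_j, 3), ")", call. = FALSE)
      pick <- best_row
      cand_kmers <- kmer_set(pool$bases[pick], cfg$index_k)
    }
    b <- pool$bases[pick]
    chosen_bases[[b]] <- TRUE
    kmer_sets[[g]] <- cand_kmers
    for (x in cand_kmers) kmer_map[[x]] <- c(kmer_map[[x]], g)
    out_seed[g] <- pool$seed[pick]
    out_bases[g] <- b
    out_row[g] <- pick
  }
  tibble::tibble(ordinal = sort(ords), seed = out_seed, bases = out_bases,
                 pool_row = out_row)
}

#' Select the payload fragments for a group
#'
#' Greedy scan of the pool in seed-stream order, starting from the index
#' droplet's membership row: a fragment is appended iff it strictly
#' increases the GF(2) rank of the accumulated membership matrix and its
#' junction with the previously placed fragment creates no homopolymer run
#' longer than `max_homopolymer`. The scan must end with
#' `fragments_per_sequence - 1` fragments and full rank, so the eight
#' droplets of the sequence are guaranteed decodable.
#'
#' @param pool A [build_pool()] result.
#' @param index_row Row index of the chosen index fragment within `pool`
#'   (from [select_index()]'s `pool_row`).
#' @param cfg A [storage_config()].
#' @return A `selection_result`: list with `ordinal`, `index` (one-row
#'   tibble slice of the pool), `payload` (tibble of
#'   `fragments_per_sequence - 1` pool rows in placement order) and
#'   `rank_certificate` (`TRUE`).
#' @export
select_payload <- function(pool, index_row, cfg = storage_config()) {
  n <- cfg$segments_per_group
  need <- cfg$fragments_per_sequence - 1L
  h <- cfg$max_homopolymer
  masks <- members_to_masks(pool$members)
  basis <- numeric(0)
  m0 <- reduce_mask(masks[index_row], basis)
  basis <- c(basis, m0)
  rank <- 1L
  prev_bases <- pool$bases[index_row]
  taken <- integer(0)
  for (r in seq_len(nrow(pool))) {
    if (length(taken) == need) break
    if (r == index_row) next
    red <- reduce_mask(masks[r], basis)
    if (red == 0) next
    junction <- paste0(substr(prev_bases, cfg$fragment_nt - h + 1L,
                              cfg$fragment_nt),
                       substr(pool$bases[r], 1L, h))
    if (max_run(junction) > h) next
    basis <- c(basis, red)
    rank <- rank + 1L
    taken <- c(taken, r)
    prev_bases <- pool$bases[r]
  }
  if (length(taken) < need || rank < n)
    stop("group ", attr(pool, "ordinal"),
         ": undecodable with available seeds (rank ", rank, " of ", n, ")",
         call. = FALSE)
  structure(list(ordinal = attr(pool, "ordinal"),
                 index = pool[index_row, ],
                 payload = pool[taken, ],
                 rank_certificate = TRUE),
            class = "selection_result")
}
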