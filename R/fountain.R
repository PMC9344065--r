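# Luby-transform engine: degree distribution, seed enumeration and the
# deterministic seed -> (degree, members) mapping shared by encoder and
# decoder.

#' Robust soliton degree distribution
#'
#' The robust soliton distribution over droplet degrees `1..n`: the ideal
#' soliton \eqn{\rho} plus the tail/spike term \eqn{\tau} with
#' \eqn{R = c \ln(n/\delta) \sqrt{n}}, normalised by
#' \eqn{\beta = \sum_d (\rho(d) + \tau(d))}. When the spike index
#' \eqn{\lfloor n/R \rfloor} exceeds `n` (common at small `n`), the tail
#' simply extends through degree `n` and the spike never occurs.
#'
#' @param n Number of segments in a group.
#' @param c,delta Soliton parameters; `c > 0`, `0 < delta < 1`.
#' @return An object of class `degree_distribution`: a list with `n` and
#'   `probs`, where `probs[d]` is the probability of degree `d`.
#' @examples
#' d <- robust_soliton(8, 0.025, 0.001)
#' sum(d$probs)
#' @export
robust_soliton <- function(n, c = 0.025, delta = 0.001) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive count", call. = FALSE)
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)", call. = FALSE)
  if (n == 1L) {
    return(structure(list(n = 1L, probs = 1), class = "degree_distribution"))
  }
  d <- seq_len(n)
  rho <- c(1 / n, 1 / (d[-1L] * (d[-1L] - 1)))
  R <- c * log(n / delta) * sqrt(n)
  M <- floor(n / R)
  tau <- numeric(n)
  tail_idx <- d[d < M]
  tau[tail_idx] <- R / (tail_idx * n)
  if (M >= 1 && M <= n) tau[M] <- R * log(R / delta) / n
  beta <- sum(rho + tau)
  structure(list(n = n, probs = (rho + tau) / beta),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("<degree_distribution> n =", x$n, "\n")
  print(round(x$probs, 4))
  invisible(x)
}

# Pinned linear congruential generator (glibc constants, modulus 2^31).
# All seed -> plan randomness flows through this so encoder and decoder
# agree bit-for-bit across platforms. Exact in doubles: the split multiply
# keeps every intermediate below 2^53.
lcg_next <- function(state) {
  s1 <- state %/% 65536
  s0 <- state %% 65536
  (((1103515245 * s1) %% 32768) * 65536 + 1103515245 * s0 + 12345) %% 2147483648
}

# Primitive feedback polynomials (low part, leading x^k term implied) for
# Galois LFSRs of width 2..16.
lfsr_polys <- c(`2` = 3L, `3` = 3L, `4` = 3L, `5` = 5L, `6` = 3L, `7` = 3L,
                `8` = 29L, `9` = 17L, `10` = 129L, `11` = 5L, `12` = 83L,
                `13` = 27L, `14` = 1091L, `15` = 3L, `16` = 4107L)

#' Enumerate droplet seeds with a Galois LFSR
#'
#' A Galois linear-feedback shift register of width `seed_bits` with a
#' primitive feedback polynomial, started at state 1, visits every nonzero
#' state exactly once per period. Its state sequence is the canonical seed
#' order: pools, selection and decoding all refer to it. Seed 0 is reserved
#' (it would render as an all-A seed field and the LFSR never reaches it).
#'
#' @param cfg A [storage_config()] (only `seed_bits` is used).
#' @return An integer vector of `2^seed_bits - 1` distinct nonzero seeds,
#'   first element 1.
#' @examples
#' s <- seed_stream(storage_config())
#' length(s)   # 1023
#' @export
seed_stream <- function(cfg = storage_config()) {
  k <- cfg$seed_bits
  poly <- lfsr_polys[[as.character(k)]]
  if (is.null(poly)) stop("no feedback polynomial for width ", k, call. = FALSE)
  mask <- bitwShiftL(1L, k) - 1L
  out <- integer(mask)
  s <- 1L
  for (i in seq_len(mask)) {
    out[i] <- s
    carry <- bitwAnd(bitwShiftR(s, k - 1L), 1L)
    s <- bitwAnd(bitwShiftL(s, 1L), mask)
    if (carry == 1L) s <- bitwXor(s, poly)
  }
  out
}

#' Deterministic droplet plan for a seed
#'
#' Maps a seed to the droplet's degree and member segments. A pinned linear
#' congruential generator is seeded with the seed value; the degree is drawn
#' by inverse-CDF over the degree distribution, then `degree` distinct
#' member indices are drawn uniformly (redrawing on collision). The mapping
#' is a pure function of `(seed, n, dist)`, which is what lets the decoder
#' rebuild the XOR equations from the 5-nt seed field alone.
#'
#' @param seed Nonzero integer seed (seed 0 is reserved).
#' @param n Number of segments in the group.
#' @param dist A [robust_soliton()] distribution with `dist$n == n`.
#' @return A list with `degree` and `members` (sorted 1-based segment
#'   indices, `length(members) == degree`).
#' @export
droplet_plan <- function(seed, n, dist) {
  if (length(seed) != 1L || is.na(seed) || seed == 0)
    stop("seed 0 is reserved; seeds must be nonzero", call. = FALSE)
  stopifnot(inherits(dist, "degree_distribution"), dist$n == n)
  if (n == 1L) return(list(degree = 1L, members = 1L))
  cum <- cumsum(dist$probs)
  st <- lcg_next(seed)
  degree <- min(findInterval(st / 2147483648, cum) + 1L, n)
  members <- integer(0)
  while (length(members) < degree) {
    st <- lcg_next(st)
    idx <- floor((st / 2147483648) * n) + 1L
    if (!(idx %in% members)) members <- c(members, idx)
  }
  list(degree = as.integer(degree), members = sort(as.integer(members)))
}

# Plans for every seed in stream order, cached per configuration. Columns of
# $membership are segments; rows follow seed_stream order.
.oligostore_cache <- new.env(parent = emptyenv())

plan_table <- function(cfg, dist = NULL) {
  key <- sprintf("plans.%d.%d.%g.%g", cfg$seed_bits, cfg$segments_per_group,
                 cfg$soliton_c, cfg$soliton_delta)
  hit <- .oligostore_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- cfg$segments_per_group
  if (is.null(dist)) dist <- robust_soliton(n, cfg$soliton_c, cfg$soliton_delta)
  seeds <- seed_stream(cfg)
  membership <- matrix(0, nrow = length(seeds), ncol = n)
  degree <- integer(length(seeds))
  members <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    p <- droplet_plan(seeds[i], n, dist)
    degree[i] <- p$degree
    members[[i]] <- p$members
    membership[i, p$members] <- 1
  }
  # seed field rendered as base codes 0..3 (A,C,G,T), one row per seed
  seed_codes <- t(vapply(seeds, function(s) {
    b <- int_to_bits(s, cfg$seed_bits)
    odd <- seq(1L, cfg$seed_bits, by = 2L)
    2L * b[odd] + b[odd + 1L]
  }, integer(seed_nt(cfg))))
  res <- list(seeds = seeds, degree = degree, members = members,
              membership = membership, seed_codes = seed_codes, dist = dist)
  .oligostore_cache[[key]] <- res
  res
}

#' Build a droplet from a group
#'
#' Executes the plan for `seed` on a data group: XORs the member segments
#' into the droplet payload.
#'
#' @param group A data group from [pad_and_group()].
#' @param seed Nonzero integer seed.
#' @param dist A [robust_soliton()] distribution for the group size.
#' @return A droplet: list with `seed`, `degree`, `members` and `payload`
#'   (an integer 0/1 vector of `segment_bits`).
#' @export
make_droplet <- function(group, seed, dist) {
  plan <- droplet_plan(seed, nrow(group$segments), dist)
  payload <- colSums(group$segments[plan$members, , drop = FALSE]) %% 2L
  list(seed = as.integer(seed), degree = plan$degree, members = plan$members,
       payload = as.integer(payload))
}
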