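# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; no binary fixtures.

default_cfg <- storage_config()

# a data group filled with seeded pseudo-random bytes
random_group <- function(seed, cfg = default_cfg) {
  gb <- (cfg$segments_per_group * cfg$segment_bits) %/% 8L
  pad_and_group(fixture_bytes(gb, seed), cfg)$groups[[1L]]
}

random_dna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute one base of `seq` at `pos` with a different base
substitute_base <- function(seq, pos, to = NULL) {
  cur <- substr(seq, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  paste0(substr(seq, 1L, pos - 1L), to, substr(seq, pos + 1L, nchar(seq)))
}

# independent GF(2) rank oracle: dense logical elimination, written without
# reference to the package's bit-mask implementation
gf2_rank_oracle <- function(mat) {
  mat <- mat %% 2L
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(mat))) {
    if (row > nrow(mat)) break
    piv <- which(mat[row:nrow(mat), col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) mat[c(row, piv), ] <- mat[c(piv, row), ]
    for (r in seq_len(nrow(mat))) {
      if (r != row && mat[r, col] == 1L) mat[r, ] <- (mat[r, ] + mat[row, ]) %% 2L
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

# independent two-pass population variance
pop_var_oracle <- function(x) {
  mu <- sum(x) / length(x)
  sum((x - mu)^2) / length(x)
}

# a hand-rolled fragment pool for selection unit tests: degree-1 droplets
# with chosen bases, bypassing the fountain
fake_pool <- function(bases, members, ordinal = 0L, cfg = default_cfg) {
  stopifnot(length(bases) == length(members))
  pool <- tibble::tibble(
    seed = seq_along(bases),
    bases = bases,
    degree = lengths(members),
    members = members,
    payload = replicate(length(bases), integer(cfg$segment_bits),
                        simplify = FALSE)
  )
  attr(pool, "ordinal") <- ordinal
  class(pool) <- c("fragment_pool", class(pool))
  pool
}
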