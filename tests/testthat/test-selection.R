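test_that("pools hold every constraint-passing fragment in seed order", {
  cfg <- default_cfg
  grp <- random_group(21)
  pool <- build_pool(grp, cfg)
  expect_gte(nrow(pool), cfg$fragments_per_sequence)
  expect_false(anyDuplicated(pool$seed) > 0)
  expect_true(all(vapply(pool$bases, passes_constraints, logical(1),
                         cfg = cfg)))
  # seed order follows the stream, and rebuilding reproduces the pool
  stream <- seed_stream(cfg)
  expect_identical(pool$seed, stream[sort(match(pool$seed, stream))])
  expect_identical(build_pool(grp, cfg), pool)

  # pool contents agree with the scalar path droplet-by-droplet
  dist <- robust_soliton(8, cfg$soliton_c, cfg$soliton_delta)
  for (r in c(1L, nrow(pool) %/% 2L, nrow(pool))) {
    d <- make_droplet(grp, pool$seed[r], dist)
    expect_identical(d$members, pool$members[[r]])
    expect_identical(d$payload, pool$payload[[r]])
    expect_identical(droplet_to_fragment(d, cfg)$bases, pool$bases[r])
  }
})

test_that("a group no seed can render constraint-clean is refused", {
  # the all-zero group: every droplet payload is zero, so every fragment
  # ends in 18 A's and fails the run limit
  zero <- pad_and_group(raw(36), default_cfg)$groups[[1L]]
  expect_error(build_pool(zero, default_cfg), "constraint-passing fragments")
})

test_that("GF(2) rank agrees with a brute-force elimination oracle", {
  # identity and duplicate-row cases
  expect_identical(gf2_rank(as.list(1:8), 8L), 8L)
  dup <- c(as.list(1:6), list(c(1L, 3L)), list(c(1L, 3L)))
  expect_lte(gf2_rank(dup, 8L), 7L)

  set.seed(77)
  for (i in 1:100) {
    mat <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    members <- apply(mat, 1, function(r) which(r == 1L), simplify = FALSE)
    if (any(lengths(members) == 0L)) next  # empty rows have no droplet form
    expect_identical(gf2_rank(members, 8L), gf2_rank_oracle(mat))
  }
})

test_that("index selection skips duplicates and enforces the similarity cap", {
  cfg <- default_cfg
  a <- random_dna(23, 1)
  b <- random_dna(23, 2)
  c3 <- random_dna(23, 3)
  pool1 <- fake_pool(c(a, b), list(1L, 2L), ordinal = 0L)
  pool2 <- fake_pool(c(a, c3), list(1L, 2L), ordinal = 1L)  # first is a dup
  idx <- select_index(list(pool1, pool2), cfg)
  expect_identical(idx$bases, c(a, c3))
  expect_identical(idx$pool_row, c(1L, 2L))

  # real pools: chosen indices are unique and pairwise dissimilar
  pools <- lapply(1:12, function(i) {
    p <- build_pool(random_group(100 + i), cfg)
    attr(p, "ordinal") <- i - 1L
    p
  })
  idx <- select_index(pools, cfg)
  expect_identical(idx$ordinal, 0:11)
  expect_false(anyDuplicated(idx$bases) > 0)
  pairs <- utils::combn(nrow(idx), 2)
  jmax <- max(apply(pairs, 2, function(p)
    jaccard_kmer(idx$bases[p[1]], idx$bases[p[2]], cfg$index_k)))
  expect_lte(jmax, cfg$index_jaccard_max)
})

test_that("payload selection skips junctions that would create a long run", {
  cfg <- default_cfg
  # degree-1 pool covering all 8 segments; the first candidate for segment 2
  # would butt a T against the index's TT tail (run of 3), the last row is
  # the clean alternative for segment 2
  idx_bases <- paste0(strrep("GA", 10), "CTT")     # ends TT
  bad <- paste0("T", strrep("GA", 11))             # starts T -> TTT junction
  f <- paste0(strrep("AC", 11), "G")               # junction-safe filler
  clean2 <- paste0("G", strrep("CA", 11))          # clean segment-2 carrier
  pool <- fake_pool(c(idx_bases, bad, rep(f, 6), clean2),
                    members = c(list(1L, 2L), as.list(3:8), list(2L)),
                    ordinal = 0L)
  sel <- select_payload(pool, index_row = 1L, cfg)
  expect_identical(nrow(sel$payload), 7L)
  expect_false(bad %in% sel$payload$bases)         # junction run of 3 skipped
  expect_true(clean2 %in% sel$payload$bases)       # replacement used
  expect_true(sel$rank_certificate)
})

test_that("selection always certifies full rank on random groups", {
  cfg <- default_cfg
  for (i in 1:40) {
    pool <- build_pool(random_group(400 + i), cfg)
    sel <- select_payload(pool, index_row = 1L, cfg)
    droplets <- c(list(sel$index$members[[1L]]),
                  sel$payload$members)
    expect_identical(gf2_rank(droplets, cfg$segments_per_group), 8L)
    # oracle agreement on the same membership matrix
    mat <- t(vapply(droplets, function(m) {
      r <- integer(8); r[m] <- 1L; r
    }, integer(8)))
    expect_identical(gf2_rank_oracle(mat), 8L)
    # the assembled fragment region is homopolymer-clean across junctions
    region <- paste0(sel$index$bases, paste(sel$payload$bases, collapse = ""))
    expect_identical(nchar(region), 184L)
    expect_lte(max_run(region), cfg$max_homopolymer)
    expect_false(anyDuplicated(c(sel$index$seed, sel$payload$seed)) > 0)
  }
})
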