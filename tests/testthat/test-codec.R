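cfg <- default_cfg
small_pool <- encode_file(fixture_bytes(360, seed = 7), cfg)

test_that("assembled sequences have the reference geometry", {
  expect_identical(unique(nchar(small_pool$records$bases)), 192L)
  # first 23 bases are the index fragment verbatim
  expect_identical(substr(small_pool$records$bases, 1, 23),
                   small_pool$ref_table$rows$index_fragment)
  # region bits re-pack to the RS message exactly
  b <- small_pool$records$bases[1L]
  region <- substr(b, 1, 184)
  parity_bases <- substr(b, 185, 192)
  msg <- bits_to_bytes(bases_to_bits(region))
  expect_length(msg, 46L)
  cw <- rs_protect(msg, cfg$rs_parity_bytes)
  expect_identical(bits_to_bases(bytes_to_bits(cw[47:48])), parity_bases)
})

test_that("encoding is deterministic", {
  again <- encode_file(fixture_bytes(360, seed = 7), cfg)
  expect_identical(again$records, small_pool$records)
  expect_identical(again$ref_table$rows, small_pool$ref_table$rows)
})

test_that("disassembly inverts assembly and survives any single substitution", {
  b <- small_pool$records$bases[3L]
  truth <- disassemble(b, small_pool$ref_table, cfg)
  expect_identical(truth$ordinal, small_pool$records$ordinal[3L])
  expect_length(truth$droplets, 8L)
  expect_identical(truth$corrected, 0L)

  for (pos in seq_len(192L)) {
    for (to in setdiff(c("A", "C", "G", "T"), substr(b, pos, pos))) {
      dis <- disassemble(substitute_base(b, pos, to), small_pool$ref_table,
                         cfg)
      expect_identical(dis$ordinal, truth$ordinal)
      expect_identical(dis$droplets, truth$droplets)
      expect_identical(dis$corrected, 1L)
    }
  }
})

test_that("a fabricated index fragment is rejected by name", {
  b <- small_pool$records$bases[1L]
  # splice in a constraint-clean fragment that is in no table row
  alien <- paste0(strrep("AC", 5), "G", strrep("TG", 6))
  expect_identical(nchar(alien), 23L)
  fake <- paste0(alien, substr(b, 24, 192))
  # parity must match for RS to accept the altered region
  msg <- bits_to_bytes(bases_to_bits(substr(fake, 1, 184)))
  cw <- rs_protect(msg, cfg$rs_parity_bytes)
  fake <- paste0(substr(fake, 1, 184), bits_to_bases(bytes_to_bits(cw[47:48])))
  expect_error(disassemble(fake, small_pool$ref_table, cfg),
               "unknown index fragment")
})

test_that("group solving inverts the fountain", {
  dist <- robust_soliton(8, cfg$soliton_c, cfg$soliton_delta)
  grp <- random_group(33)

  # eight degree-1 droplets: segments read off directly
  ident <- lapply(1:8, function(s)
    list(seed = s, degree = 1L, members = s,
         payload = as.integer(grp$segments[s, ])))
  expect_identical(solve_group(ident, 8L), grp$segments)

  # real droplets from a full-rank selection
  pool <- build_pool(grp, cfg)
  sel <- select_payload(pool, 1L, cfg)
  rows <- rbind(sel$index, sel$payload)
  droplets <- lapply(seq_len(8L), function(i)
    list(seed = rows$seed[i], degree = rows$degree[i],
         members = rows$members[[i]], payload = rows$payload[[i]]))
  segs <- solve_group(droplets, 8L)
  expect_identical(segs, grp$segments)
  # verification identity: the solution re-XORs to every payload
  for (d in droplets) {
    expect_identical(as.integer(colSums(segs[d$members, , drop = FALSE]) %% 2L),
                     as.integer(d$payload))
  }

  # rank-deficient sets are refused
  degenerate <- ident[c(1:7, 7)]
  expect_error(solve_group(degenerate, 8L), "undecodable group")
})

test_that("pools decode regardless of order, duplication and corruption", {
  for (size in c(1L, 37L, 1000L, 5000L)) {
    payload <- fixture_bytes(size, seed = size + 100L)
    pool <- encode_file(payload, cfg)
    set.seed(size)
    shuffled <- sample(pool$records$bases)
    expect_identical(decode_pool(shuffled, pool$ref_table, cfg), payload)
    # duplicated reads collapse harmlessly
    expect_identical(decode_pool(c(shuffled, shuffled[1L]), pool$ref_table,
                                 cfg),
                     payload)
  }

  # one random substitution per sequence
  payload <- fixture_bytes(2000, seed = 55)
  pool <- encode_file(payload, cfg)
  set.seed(55)
  mutated <- vapply(sample(pool$records$bases), function(b) {
    substitute_base(b, sample(192L, 1L))
  }, character(1), USE.NAMES = FALSE)
  expect_identical(decode_pool(mutated, pool$ref_table, cfg), payload)
})

test_that("a missing sequence fails the decode and is named", {
  payload <- fixture_bytes(150, seed = 8)
  pool <- encode_file(payload, cfg)   # 5 groups
  keep <- pool$records$bases[pool$records$ordinal != 2L]
  expect_error(decode_pool(keep, pool$ref_table, cfg),
               "missing group\\(s\\) 2")
})

test_that("random access decodes only the requested group range", {
  payload <- fixture_bytes(1800, seed = 12)   # 50 groups
  pool <- encode_file(payload, cfg)
  for (rng in list(c(0L, 5L), c(10L, 11L), c(47L, 50L))) {
    groups <- rng[1L]:(rng[2L] - 1L)
    bytes <- decode_pool(pool$records$bases, pool$ref_table, cfg,
                         groups = groups)
    expect_identical(bytes,
                     fixture_bytes(1800, seed = 12)[(rng[1L] * 36L + 1L):
                                                      (rng[2L] * 36L)])
  }
})

test_that("double substitutions are overwhelmingly detected, never trusted", {
  b <- small_pool$records$bases[2L]
  truth <- disassemble(b, small_pool$ref_table, cfg)
  set.seed(99)
  outcomes <- c(detected = 0L, recovered = 0L, silent = 0L)
  for (i in 1:150) {
    pos <- sample(192L, 2L)
    bad <- b
    for (p in pos) {
      bad <- substitute_base(bad, p,
                             sample(setdiff(c("A", "C", "G", "T"),
                                            substr(bad, p, p)), 1L))
    }
    dis <- tryCatch(disassemble(bad, small_pool$ref_table, cfg),
                    error = function(e) e)
    if (inherits(dis, "error")) {
      outcomes["detected"] <- outcomes["detected"] + 1L
    } else if (identical(dis$droplets, truth$droplets)) {
      # both hits in one byte: a 1-byte error, legitimately corrected
      outcomes["recovered"] <- outcomes["recovered"] + 1L
    } else {
      outcomes["silent"] <- outcomes["silent"] + 1L
    }
  }
  expect_gte(outcomes[["detected"]], 120L)
  expect_lte(outcomes[["silent"]], 5L)
})
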