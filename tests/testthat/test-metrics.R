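test_that("k-mer sets and the Jaccard coefficient match the worked example", {
  expect_setequal(kmer_set("ACGTTAGGC", 5),
                  c("ACGTT", "CGTTA", "GTTAG", "TTAGG", "TAGGC"))
  expect_setequal(kmer_set("GTACCTTAGG", 5),
                  c("GTACC", "TACCT", "ACCTT", "CCTTA", "CTTAG", "TTAGG"))
  expect_identical(kmer_set("ACG", 5), character(0))
  expect_error(kmer_set("ACG", 0), "k must be")

  # the two sequences share exactly one 5-mer (TTAGG): 1/10
  expect_identical(jaccard_kmer("ACGTTAGGC", "GTACCTTAGG", 5), 1 / 10)
  expect_identical(jaccard_kmer("ACGTTAGGC", "ACGTTAGGC", 5), 1)
  expect_identical(jaccard_kmer("AAAA", "CCCC", 2), 0)
  expect_identical(jaccard_kmer("GTACCTTAGG", "ACGTTAGGC", 5), 1 / 10)
  expect_error(jaccard_kmer("AC", "GT", 5), "empty")
})

test_that("pairwise Jaccard sums follow the row-sum convention", {
  # hand-computed: s1 and s2 have identical 3-mer sets (J = 1), s3 shares
  # nothing; row sums 1, 1, 0; grand total 2 (each pair counted twice)
  rep3 <- jaccard_total(c("ACGTAC", "CGTACG", "TTTTTT"), 3)
  expect_equal(rep3$per_seq$jaccard_sum, c(1, 1, 0))
  expect_equal(rep3$total, 2)

  # m identical sequences: row sums m-1, total m(m-1)
  rep4 <- jaccard_total(rep("ACGTACGT", 4), 4)
  expect_equal(rep4$per_seq$jaccard_sum, rep(3, 4))
  expect_equal(rep4$total, 12)

  expect_equal(jaccard_total(c("AAAA", "CCCC", "GGGG"), 3)$total, 0)
  expect_error(jaccard_total("ACGT", 2), "at least two")
})

test_that("dotplots mark exact word matches, diagonal included", {
  # ACGTACGT vs itself at word 4: five positions, period-4 repeat at
  # (0,4) and (4,0), hand-enumerated
  dp <- dotplot("ACGTACGT", "ACGTACGT", 4)
  expect_identical(dp$dots,
                   tibble::tibble(i = c(0L, 0L, 1L, 2L, 3L, 4L, 4L),
                                  j = c(0L, 4L, 1L, 2L, 3L, 0L, 4L)))
  expect_identical(dp$off_diagonal_count, 2L)
  expect_equal(dp$density, 7 / 25)

  expect_identical(nrow(dotplot("AAAA", "CCCC", 3)$dots), 0L)

  for (seed in 1:5) {
    a <- random_dna(40, seed)
    b <- random_dna(30, seed + 50)
    dp_self <- dotplot(a, a, 8)
    diag_dots <- dp_self$dots[dp_self$dots$i == dp_self$dots$j, ]
    expect_identical(diag_dots$i, 0:(40 - 8))   # full main diagonal
    # transpose symmetry
    ab <- dotplot(a, b, 6)$dots
    ba <- dotplot(b, a, 6)$dots
    expect_setequal(paste(ab$j, ab$i), paste(ba$i, ba$j))
  }
})

test_that("windowed GC statistics use population variance", {
  flat <- gc_window_stats(rep(strrep("AC", 30), 3), 20)
  expect_equal(flat$variance, 0)
  expect_equal(flat$mean, 0.5)

  # two windows at 0.45 and 0.55: variance 0.0025 in closed form
  w1 <- paste0(strrep("GC", 4), "G", strrep("AT", 5), "A")   # 9 GC of 20
  w2 <- paste0(strrep("GC", 5), "G", strrep("AT", 4), "A")   # 11 GC of 20
  expect_identical(c(nchar(w1), nchar(w2)), c(20L, 20L))
  st <- gc_window_stats(paste0(w1, w2), 20)
  expect_equal(st$per_window$gc, c(0.45, 0.55))
  expect_equal(st$mean, 0.5)
  expect_equal(st$variance, 0.0025)

  # trailing partial windows are dropped; empty input is an error
  expect_identical(nrow(gc_window_stats("ACGTACGTA", 4)$per_window), 2L)
  expect_error(gc_window_stats(c("ACG", "T"), 10), "no complete window")

  # two-pass oracle agreement on random sequences
  seqs <- vapply(1:6, function(i) random_dna(100, 600 + i), character(1))
  st <- gc_window_stats(seqs, 23)
  expect_equal(st$variance, pop_var_oracle(st$per_window$gc))
  expect_equal(st$mean, mean(st$per_window$gc))
})

test_that("redundancy and net information density follow the geometry", {
  cfg <- default_cfg
  expect_equal(redundancy(cfg), 48 / 184)
  expect_identical(round(100 * redundancy(cfg)), 26)
  expect_equal(net_information_density(cfg), 2 * 136 / 184)
  expect_identical(round(net_information_density(cfg), 2), 1.48)

  # doubling the fragment length halves the ratio
  cfg2 <- storage_config(fragment_nt = 46L, segment_bits = 82L)
  expect_equal(redundancy(cfg2), redundancy(cfg) / 2)
  # NID identity across geometries
  for (c0 in list(cfg, cfg2)) {
    expect_equal(net_information_density(c0), 2 - 2 * redundancy(c0))
  }
})
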