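test_that("encode_binary produces one-hot blocks in A,C,G,T order", {
  expect_equal(encode_binary("A"), c(1, 0, 0, 0))
  expect_equal(encode_binary("ACGT"),
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  expect_length(encode_binary(rand_seqs(1, 41, 2)), 164L)
  expect_equal(encode_binary("ACGU"), encode_binary("ACGT"))
  expect_error(encode_binary("ACGN"), "invalid character")
})

test_that("encode_kmer matches hand-derived frequencies and sums to 1", {
  v <- encode_kmer("AAAA", 2)
  expect_equal(v[1], 1)
  expect_equal(sum(v), 1)
  # single-nucleotide composition of the benchmark A. thaliana sequence
  expect_equal(encode_kmer("ATAAGAGAAAAGAAAACCTT", 1),
               c(0.60, 0.10, 0.15, 0.15))
  # "ACGT": 2-mers AC, CG, GT each once over 3 windows
  v2 <- setNames(encode_kmer("ACGT", 2), oracle_levels[[2]])
  expect_equal(unname(v2[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(v2 != 0), 3)
  expect_error(encode_kmer("ACG", 4), "sequence-too-short")
})

test_that("encode_enac emits per-window frequency blocks", {
  expect_equal(encode_enac("AAAA", 2), rep(c(1, 0, 0, 0), 3))
  expect_equal(encode_enac("ACGT", 4), rep(0.25, 4))
  expect_equal(encode_enac("AACC", 2),
               c(1, 0, 0, 0, 0.5, 0.5, 0, 0, 0, 1, 0, 0))
  expect_error(encode_enac("ACG", 5), "sequence-too-short")
})

test_that("encode_cksnap tabulates gap-spaced pairs per printed pair order", {
  v0 <- encode_cksnap("AAAA", 0)
  expect_equal(v0[1], 1)
  expect_equal(sum(v0), 1)
  v1 <- encode_cksnap("ACAC", 1)
  gap0 <- setNames(v1[1:16], oracle_levels[[2]])
  gap1 <- setNames(v1[17:32], oracle_levels[[2]])
  expect_equal(unname(gap0[c("AC", "CA")]), c(2 / 3, 1 / 3))
  expect_equal(unname(gap1[c("AA", "CC")]), c(0.5, 0.5))
  expect_length(encode_cksnap(rand_seqs(1, 41, 3), 5), 96L)
  expect_error(encode_cksnap("ACG", 2), "sequence-too-short")
})

test_that("encode_ncp emits the printed chemical-property triples", {
  expect_equal(encode_ncp("A"), c(1, 1, 1))
  expect_equal(encode_ncp("C"), c(0, 1, 0))
  expect_equal(encode_ncp("ACGU"),
               c(1, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(encode_ncp("T"), encode_ncp("U"))
})

test_that("encoders match the brute-force oracles on random sequences", {
  seqs <- rand_seqs(120, 8, seed = 21)
  for (s in c(seqs, rand_seqs(60, 5, seed = 22))) {
    L <- nchar(s)
    expect_equal(encode_binary(s), oracle_binary(s))
    expect_equal(encode_ncp(s), oracle_ncp(s))
    for (k in 1:3) expect_equal(encode_kmer(s, k), oracle_kmer(s, k))
    for (w in 1:3) expect_equal(encode_enac(s, w), oracle_enac(s, w))
    for (g in 0:3) expect_equal(encode_cksnap(s, g), oracle_cksnap(s, g))
  }
})

test_that("alphabet normalization never changes an encoding", {
  recs <- rand_records(15, 15, seed = 31)
  rna <- normalize_alphabet(recs, "RNA")
  for (scheme in list(encoding_scheme("binary"), encoding_scheme("kmer", 2),
                      encoding_scheme("enac", 3), encoding_scheme("cksnap", 2),
                      encoding_scheme("ncp"))) {
    expect_equal(encode_dataset(recs, scheme)$values,
                 encode_dataset(rna, scheme)$values,
                 info = scheme_label(scheme))
  }
})

test_that("enumerate_schemes returns the fifteen-scheme grid in order", {
  grid <- enumerate_schemes()
  expect_length(grid, 15L)
  labels <- vapply(grid, scheme_label, "")
  expect_equal(labels[1], "binary")
  expect_equal(labels[15], "ncp")
  expect_equal(labels[2:5], paste0("kmer-", 2:5))
  expect_equal(labels[6:9], paste0("enac-", 2:5))
  expect_equal(labels[10:14], paste0("cksnap-", 1:5))
  expect_equal(sum(labels == "kmer-4"), 1L)
})

test_that("scheme construction validates family and parameter", {
  expect_error(encoding_scheme("pseknc"), "arg")
  expect_error(encoding_scheme("kmer"), "parameter")
  expect_error(encoding_scheme("kmer", 0), ">= 1")
  expect_equal(encoding_scheme("cksnap", 0)$param, 0L)
  expect_true(is.na(encoding_scheme("binary", 3)$param))
})

test_that("encode_dataset builds labeled matrices with feature names", {
  recs <- rand_records(2, 4, seed = 41, label = c(1L, 0L))
  fm <- encode_dataset(recs, encoding_scheme("binary"))
  expect_equal(dim(fm$values), c(2L, 16L))
  expect_equal(fm$labels, c(1L, 0L))
  expect_equal(fm$record_ids, recs$id)
  expect_equal(fm$feature_names[1:4], paste0("pos1_", c("A", "C", "G", "T")))

  fme <- encode_dataset(recs[0, ], encoding_scheme("kmer", 3), length = 41)
  expect_equal(dim(fme$values), c(0L, 64L))

  het <- seq_records(c("a", "b"), c("ACGT", "ACGTA"), c(1, 0))
  expect_error(encode_dataset(het, encoding_scheme("binary")),
               "heterogeneous-length")

  short <- seq_records(c("a", "b"), c("ACG", "AAA"), c(1, 0))
  expect_error(encode_dataset(short, encoding_scheme("cksnap", 5)),
               "incompatible")

  named <- encode_dataset(rand_records(3, 9, 43), encoding_scheme("cksnap", 1))
  expect_equal(named$feature_names[17], "gap1_AA")
})

test_that("feature CSV export/import round-trips matrix and metadata", {
  recs <- rand_records(6, 11, seed = 51)
  fm <- encode_dataset(recs, encoding_scheme("enac", 3))
  path <- tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_feature_csv(path)
  expect_equal(back$values, fm$values)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$scheme$family, "enac")
  expect_equal(back$scheme$param, 3L)
  expect_equal(back$length, 11L)
})
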