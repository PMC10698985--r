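test_that("one-hot encodings are orthonormal indicators; 'X' is zero", {
  vecs <- vapply(AA_ALPHABET, encode_one_hot, numeric(20))
  expect_equal(unname(vecs), diag(20))   # exhaustive: orthogonal units
  expect_equal(encode_one_hot("X"), numeric(20))
  expect_error(encode_one_hot("Z"), "unknown residue")
})

test_that("entropy density matches its definition", {
  expect_equal(encode_entropy_density("AAAA"), numeric(20),
               ignore_attr = TRUE)
  v <- encode_entropy_density(paste(AA_ALPHABET, collapse = ""))
  expect_equal(unname(v), rep(log2(20) / 20, 20))
  # random 200-mer against a direct count-then-formula oracle
  seqs <- vapply(1:5, function(s) {
    ppistack:::with_seed(s, paste(sample(AA_ALPHABET, 200, replace = TRUE),
                                  collapse = ""))
  }, "")
  for (sq in seqs) {
    ch <- strsplit(sq, "")[[1]]
    oracle <- vapply(AA_ALPHABET, function(a) {
      p <- mean(ch == a)
      if (p == 0) 0 else -p * log2(p)
    }, 0)
    expect_equal(unname(encode_entropy_density(sq)), unname(oracle),
                 tolerance = 1e-12)
  }
  expect_error(encode_entropy_density(""), "empty")
})

test_that("property lookups are pure, dimensioned and zero for 'X'", {
  expect_identical(encode_phychem("W"), encode_phychem("W"))
  expect_length(encode_phychem("A"), 21)
  expect_equal(encode_phychem("X"), numeric(21))
  expect_length(encode_hyin("K"), 2)
  expect_equal(encode_hyin("X"), numeric(2))
  # exhaustive structural validation of the bundled tables
  pc <- phychem_table()
  expect_identical(dim(pc), c(20L, 21L))
  expect_true(all(is.finite(pc)))
  hy <- hyin_table()
  expect_identical(dim(hy), c(20L, 2L))
  expect_true(all(is.finite(hy)))
  # distinct residues have distinct descriptor rows
  expect_identical(anyDuplicated(apply(pc, 1, paste, collapse = ",")), 0L)
})

test_that("PSSM rows squash through the logistic to (0,1)", {
  m <- matrix(0, 3, 20)
  expect_equal(encode_pssm_row(m, 2), rep(0.5, 20))
  rnd <- ppistack:::with_seed(2, matrix(rnorm(60, sd = 4), 3, 20))
  for (i in 1:3) {
    v <- encode_pssm_row(rnd, i)
    expect_true(all(v > 0 & v < 1))
    expect_equal(v, 1 / (1 + exp(-rnd[i, ])), tolerance = 1e-12)
  }
  expect_error(encode_pssm_row(m, 4), "out of range")
})

test_that("windowed pseudo amino acid composition follows the formula", {
  # homopolymer: all correlation factors vanish, composition is a point mass
  v <- encode_kpseaa(strrep("A", 25), 13)
  expect_equal(v[1], 1)
  expect_equal(v[-1], numeric(29))

  # components are non-negative and sum to 1 for random sequences/positions
  for (s in 1:8) {
    sq <- ppistack:::with_seed(s, paste(sample(AA_ALPHABET, 40,
                                               replace = TRUE),
                                        collapse = ""))
    i <- ppistack:::with_seed(s + 100, sample(40, 1))
    v <- encode_kpseaa(sq, i)
    expect_length(v, 30)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }

  # interior length-21 subsequence against direct theta summation
  sq <- ppistack:::with_seed(9, paste(sample(AA_ALPHABET, 41,
                                             replace = TRUE),
                                      collapse = ""))
  K <- 10; lambda <- 10; w <- 0.05
  v <- encode_kpseaa(sq, 21, K, lambda, w)
  sub <- strsplit(substr(sq, 11, 31), "")[[1]]
  props <- ppistack:::pseaa_properties()$scales
  Theta <- function(a, b) mean((props[a, ] - props[b, ])^2)
  Ls <- length(sub)
  theta <- vapply(seq_len(lambda), function(j) {
    sum(vapply(seq_len(Ls - j), function(i) Theta(sub[i], sub[i + j]), 0)) /
      (Ls - j)
  }, 0)
  counts <- vapply(AA_ALPHABET, function(a) sum(sub == a), 0)
  oracle <- c(counts, w * theta) / (sum(counts) + w * sum(theta))
  expect_equal(v, unname(oracle), tolerance = 1e-10)

  expect_error(encode_kpseaa(sq, 0), "out of range")
})

test_that("edge subsequences clamp short-range correlations to zero", {
  sq <- "ACDEFGHIKL"
  v <- encode_kpseaa(sq, 1, K = 2, lambda = 10)  # subsequence length 3
  expect_equal(v[20 + 3:10], numeric(8))         # theta_j = 0 for j >= 3
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("targeted features pair the right encoders at the right dims", {
  rec <- tiny_records()[[1]]
  expect_length(build_targeted_feature(rec, 3, 0), 40)
  expect_length(build_targeted_feature(rec, 3, 1), 23)
  rec$pssm <- matrix(0, 10, 20)
  expect_length(build_targeted_feature(rec, 3, 2), 50)
  expect_error(build_targeted_feature(rec, 3, 3), "0, 1 or 2")
  rec$pssm <- NULL
  expect_error(build_targeted_feature(rec, 3, 2), "requires a PSSM")
  # module 0 content check: one-hot of residue 3 ('D') then entropy density
  f <- build_targeted_feature(rec, 3, 0)
  expect_equal(f[1:20], encode_one_hot("D"))
  expect_equal(f[21:40], unname(encode_entropy_density(rec$sequence)))
})

test_that("context matrices pad with zero rows at sequence ends", {
  rec <- random_record("ctx", 30, 42)
  ctx <- build_context_matrix(rec, 1, W = 8, fmod = 0)
  expect_identical(dim(ctx$f_ctx), c(17L, 40L))
  expect_identical(ctx$pad_mask, c(rep(TRUE, 8), rep(FALSE, 9)))
  expect_true(all(ctx$f_ctx[1:8, ] == 0))

  mid <- build_context_matrix(rec, 15, W = 8, fmod = 0)
  expect_false(any(mid$pad_mask))
  expect_equal(mid$f_ctx[9, ], build_targeted_feature(rec, 15, 0))

  # random positions against a naive slice-and-pad oracle
  feat <- t(vapply(1:30, function(i) build_targeted_feature(rec, i, 0),
                   numeric(40)))
  for (i in c(2, 7, 16, 29, 30)) {
    got <- build_context_matrix(rec, i, W = 5, fmod = 0)
    oracle <- matrix(0, 11, 40)
    for (o in -5:5) {
      if (i + o >= 1 && i + o <= 30) oracle[o + 6, ] <- feat[i + o, ]
    }
    expect_equal(got$f_ctx, oracle)
    expect_identical(got$pad_mask, (i + (-5:5)) < 1 | (i + (-5:5)) > 30)
    expect_equal(sum(got$pad_mask),
                 max(0, 5 - i + 1) + max(0, i + 5 - 30))
  }
})

test_that("featurized arrays agree with per-residue construction", {
  recs <- tiny_records()
  feats <- featurize_records(recs, 0, W = 3)
  expect_identical(dim(feats$X), c(28L, 7L, 40L))
  # spot-check a few residues against the single-residue path
  for (k in c(1, 5, 11, 28)) {
    rec <- recs[[match(feats$id[k], vapply(recs, `[[`, "", "id"))]]
    fs <- build_residue_feature_set(rec, feats$position[k], 3, 0)
    expect_equal(feats$X[k, , ], fs$f_ctx)
    expect_identical(feats$mask[k, ], fs$pad_mask)
    expect_equal(feats$ftr[k, ], fs$f_tr)
  }
  expect_identical(feats$y,
                   unlist(lapply(recs, `[[`, "labels"), use.names = FALSE))
})
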