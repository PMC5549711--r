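tabs <- aa_property_tables()

test_that("frequency descriptor counts residues in fixed order", {
  f <- frequency_descriptor("AAAA")
  expect_equal(unname(f[["freq.A"]]), 1)
  expect_equal(sum(f), 1)
  f2 <- frequency_descriptor("ACAC")
  expect_equal(unname(f2[c("freq.A", "freq.C")]), c(0.5, 0.5))
  expect_equal(sum(f2 != 0), 2L)
  set.seed(3)
  expect_equal(sum(frequency_descriptor(random_protein(211))), 1)
})

test_that("composition is the per-group fraction and sums to one", {
  expect_equal(ctd_composition(rep(1L, 7)), c(1, 0, 0))
  expect_equal(ctd_composition(c(1L, 2L, 3L, 1L)), c(0.5, 0.25, 0.25))
  set.seed(4)
  g <- sample(1:3, 50, replace = TRUE)
  expect_equal(sum(ctd_composition(g)), 1)
})

test_that("transition counts unordered adjacent group changes as percents", {
  expect_equal(ctd_transition(rep(2L, 9)), c(0, 0, 0))
  expect_equal(ctd_transition(c(1L, 2L, 1L, 2L)), c(100, 0, 0))
  expect_equal(ctd_transition(c(1L, 3L, 2L)), c(0, 50, 50))
  expect_error(ctd_transition(1L), "length >= 2")
})

test_that("distribution reports percent positions of occurrence quantiles", {
  d <- ctd_distribution(rep(1L, 4))
  expect_equal(d[1:5], c(25, 25, 50, 75, 100))
  expect_equal(d[6:15], rep(0, 10))      # absent groups
  set.seed(5)
  g <- sample(1:3, 80, replace = TRUE)
  d <- ctd_distribution(g)
  expect_true(all(d >= 0 & d <= 100))
  for (k in 1:3) {
    expect_true(all(diff(d[(k - 1) * 5 + 1:5]) >= 0))  # non-decreasing
  }
})

test_that("auto-covariance matches its definition and invariances", {
  expect_equal(auto_covariance(rep(2.2, 40), max_lag = 5), rep(0, 5))
  v <- c(1, -1, 1, -1, 1)
  expect_equal(auto_covariance(v, max_lag = 2),
               oracle_auto_covariance(v, max_lag = 2))
  set.seed(6)
  w <- rnorm(60)
  expect_equal(auto_covariance(w + 17.3, max_lag = 30),
               auto_covariance(w, max_lag = 30), tolerance = 1e-9)
  expect_error(auto_covariance(rnorm(30), max_lag = 30), "at least 31")
})

test_that("optimized CTD and AC agree with literal-loop oracles on random sequences", {
  set.seed(101)
  h_scales <- lapply(tabs$quantitative, normalize_property_scale)
  for (rep_i in 1:200) {
    seq_i <- random_protein(sample(31:500, 1))
    prop <- tabs$qualitative[[sample(names(tabs$qualitative), 1)]]
    g <- encode_qualitative(seq_i, prop)
    expect_equal(ctd_composition(g), oracle_composition(g), tolerance = 1e-10)
    expect_equal(ctd_transition(g), oracle_transition(g), tolerance = 1e-10)
    expect_equal(ctd_distribution(g), oracle_distribution(g), tolerance = 1e-10)
    scale_i <- h_scales[[sample(names(h_scales), 1)]]
    v <- encode_quantitative(seq_i, scale_i)
    expect_equal(auto_covariance(v), oracle_auto_covariance(v),
                 tolerance = 1e-10)
  }
})

test_that("protein descriptor vector has the documented layout and invariants", {
  set.seed(7)
  s <- random_protein(120)
  v <- protein_features(s, tabs)
  expect_length(v, 347L)
  nm <- names(v)
  expect_equal(sum(startsWith(nm, "freq.")), 20L)
  ctd_block <- sum(startsWith(nm, "c.") | startsWith(nm, "t.") |
                     startsWith(nm, "d."))
  expect_equal(ctd_block, 147L)
  expect_equal(sum(startsWith(nm, "ac.")), 180L)
  expect_equal(sum(startsWith(nm, "ac.H.")), 30L)
  expect_true(all(is.finite(v)))
  expect_equal(sum(v[startsWith(nm, "freq.")]), 1, tolerance = 1e-9)
  for (p in names(tabs$qualitative)) {
    expect_equal(sum(v[startsWith(nm, paste0("c.", p, "."))]), 1,
                 tolerance = 1e-9)
  }
  d_vals <- v[startsWith(nm, "d.")]
  expect_true(all(d_vals >= 0 & d_vals <= 100))
  expect_error(protein_features(random_protein(30)), "longer than")
})

test_that("frequency and composition are permutation-invariant; T, D and AC are not", {
  s <- "AAAAACCCCCDDDDDEEEEEFFFFFGGGGGHHHHH"
  perm <- "ACDEFGHACDEFGHACDEFGHACDEFGHACDEFGH"
  expect_equal(sort(strsplit(s, "")[[1]]), sort(strsplit(perm, "")[[1]]))
  expect_equal(frequency_descriptor(s), frequency_descriptor(perm))
  prop <- tabs$qualitative$hydrophobicity
  g1 <- encode_qualitative(s, prop); g2 <- encode_qualitative(perm, prop)
  expect_equal(ctd_composition(g1), ctd_composition(g2))
  expect_false(isTRUE(all.equal(ctd_transition(g1), ctd_transition(g2))))
  expect_false(isTRUE(all.equal(ctd_distribution(g1), ctd_distribution(g2))))
  h <- normalize_property_scale(tabs$quantitative$H)
  expect_false(isTRUE(all.equal(
    auto_covariance(encode_quantitative(s, h), max_lag = 10),
    auto_covariance(encode_quantitative(perm, h), max_lag = 10))))
})

test_that("pair vectors concatenate the two protein vectors in order", {
  set.seed(8)
  fa <- protein_features(random_protein(60), tabs)
  fb <- protein_features(random_protein(90), tabs)
  pv <- pair_features(fa, fb)
  expect_length(pv, 694L)
  expect_equal(unname(pv[1:347]), unname(fa))
  expect_equal(unname(pv[348:694]), unname(fb))
  same <- pair_features(fa, fa)
  expect_equal(unname(same[1:347]), unname(same[348:694]))
  expect_equal(sort(unname(pair_features(fa, fb))),
               sort(unname(pair_features(fb, fa))))
  expect_error(pair_features(fa, fb[-1]), "different lengths")
})

test_that("pair_feature_matrix assembles rows per pair and can augment symmetrically", {
  set.seed(9)
  seqs <- c(a = random_protein(50), b = random_protein(60),
            c = random_protein(70))
  pairs <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                      label = c(1L, 0L), stringsAsFactors = FALSE)
  fm <- pair_feature_matrix(pairs, seqs)
  expect_equal(dim(fm$x), c(2L, 694L))
  expect_equal(fm$y, c(1L, 0L))
  expect_equal(unname(fm$x[1, 1:347]), unname(protein_features(seqs[["a"]])))
  aug <- pair_feature_matrix(pairs, seqs, augment_symmetric = TRUE)
  expect_equal(dim(aug$x), c(4L, 694L))
  expect_equal(unname(aug$x[3, 348:694]), unname(fm$x[1, 1:347]))
  expect_equal(aug$y, c(1L, 0L, 1L, 0L))
  expect_error(pair_feature_matrix(data.frame(id_a = "a", id_b = "zz",
                                              label = 1L), seqs), "zz")
})

test_that("feature matrices survive a CSV round trip", {
  set.seed(10)
  seqs <- c(s1 = random_protein(45), s2 = random_protein(55))
  m <- protein_feature_matrix(seqs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(m, path)
  m2 <- read_feature_csv(path)
  expect_equal(m2, m, tolerance = 1e-12)
})
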