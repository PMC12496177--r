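# Fixed-point torus emulation: encoding, normalization, comparison
# circuits, LUT sigmoid, thresholding, end-to-end concordance.

test_that("fixed-point encode/decode round-trips within half an encoding unit", {
  p <- default_params()
  expect_equal(encode_fixed(0, p), 0)
  expect_equal(encode_fixed(1.25, fp_params(Q = 2^32, scale = 2^20, B = 10)),
               1310720)
  # negative values wrap onto the top of the torus
  expect_equal(encode_fixed(-1, p), p$Q - p$scale)
  set.seed(2)
  v <- runif(1e4, -100, 100)
  err <- abs(decode_fixed(encode_fixed(v, p), p) - v)
  expect_lte(max(err), 1 / (2 * p$scale))
  expect_error(encode_fixed(p$Q, p), "overflow")
})

test_that("linear_he matches the plaintext linear scores up to rounding", {
  m <- structure(list(gene = "G", alleles = c("a", "b"),
                      weights = rbind(c(1, -1), c(0.25, 0.5)),
                      intercepts = c(0.5, 0), flagged = c(FALSE, FALSE),
                      snp_ids = c("rs1", "rs2"), threshold_t = 2L,
                      bound_B = 10, config = NULL), class = "gene_model")
  p <- default_params()
  tv <- linear_he(m, c(2, 0), p)
  expect_equal(decode_fixed(tv, p), c(2.5, 0.5), tolerance = 3 / p$scale)
  # all-zero input returns the encoded intercepts exactly
  expect_equal(linear_he(m, c(0, 0), p),
               encode_fixed(c(0.5, 0), p))
  # chunking never changes the result: integer accumulation is exact
  set.seed(33)
  W <- matrix(rnorm(3 * 101), 3, 101)
  mm <- structure(list(gene = "G", alleles = c("a", "b", "c"),
                       weights = W, intercepts = rnorm(3),
                       flagged = rep(FALSE, 3),
                       snp_ids = sprintf("rs%d", 1:101), threshold_t = 2L,
                       bound_B = 50, config = NULL), class = "gene_model")
  x <- sample(0:2, 101, TRUE)
  p1 <- fp_params(B = 50, T_norm = -50, pack_size = 2)
  p2 <- fp_params(B = 50, T_norm = -50, pack_size = 1e6)
  expect_identical(linear_he(mm, x, p1), linear_he(mm, x, p2))
  # plaintext oracle across random models
  expect_equal(decode_fixed(linear_he(mm, x, p1), p1),
               unname(linear_scores(mm, x)),
               tolerance = 102 / (2 * p1$scale))
})

test_that("normalize_t maps [T, B] onto [0, Q/4], clamping above B", {
  p <- default_params(B = 10)   # T_norm = -10
  expect_equal(normalize_t(-10, p), 0)
  expect_equal(normalize_t(-25, p), 0)           # below T collapses to 0
  expect_equal(normalize_t(10, p), p$Q / 4)
  expect_equal(normalize_t(0, p), 2^30 / 2)      # midpoint, Q = 2^32
  expect_message(v <- normalize_t(99, p), "clamped")
  expect_equal(v, p$Q / 4)
  x <- seq(-12, 10, length.out = 500)
  expect_true(all(diff(normalize_t(x, p)) >= 0))  # non-decreasing
})

test_that("cmpbit equals signed comparison on every residue of a toy modulus", {
  p <- toy_params(Q = 2^16)
  x <- 0:(p$Q - 1)
  signed <- ifelse(x >= p$Q / 2, x - p$Q, x)
  expect_identical(cmpbit(x, p), ifelse(signed >= 0, p$Q / 2, 0))
  expect_equal(cmpbit(0, p), p$Q / 2)   # boundary: x = 0 is >= 0
  expect_equal(cmpbit(p$Q - 1, p), 0)   # encodes -1
})

test_that("mux follows the printed piecewise definition at the boundaries", {
  p <- toy_params()
  expect_equal(mux(p$Q / 2 + 7, p), 7)
  expect_equal(mux(7, p), 0)
  expect_equal(mux(p$Q / 2, p), 0)      # joint: x - Q/2 = 0
  expect_equal(mux(p$Q - 1, p), p$Q / 2 - 1)
})

test_that("the mux selection identity returns one of its payloads", {
  p <- toy_params(Q = 2^12)
  set.seed(6)
  for (i in 1:500) {
    a <- sample(0:(p$Q / 4 - 1), 1)
    b <- sample(0:(p$Q / 4 - 1), 1)
    ctc <- sample(c(0, p$Q / 2), 1)
    out <- mux(ctc + a, p) + mux(p$Q / 2 - ctc + b, p)
    expect_equal(out, if (ctc == p$Q / 2) a else b)
  }
})

test_that("he_max follows the worked example and ties keep the left payload", {
  p <- toy_params(Q = 2^16)
  r <- he_max(indexed_value(3, 1L), indexed_value(5, 2L), p)
  expect_equal(r$value, 5)
  expect_equal(r$index, 2L)
  tie <- he_max(indexed_value(4, 1L), indexed_value(4, 2L), p)
  expect_equal(tie$index, 1L)           # cmpbit(0) = Q/2, left branch wins
  expect_error(he_max(indexed_value(p$Q / 4, 1L), indexed_value(0, 2L), p),
               "Q/4")
})

test_that("he_min is a + b - max with the complementary index", {
  p <- toy_params(Q = 2^16)
  r <- he_min(indexed_value(3, 1L), indexed_value(5, 2L), p)
  expect_equal(r$value, 3)
  expect_equal(r$index, 1L)
  same <- he_min(indexed_value(4, 1L), indexed_value(4, 2L), p)
  expect_equal(same$value, 4)
})

test_that("he_top2 matches the plaintext top2 on random vectors", {
  p <- default_params()
  expect_error(he_top2(list(indexed_value(1, 1L)), p), "at least 2")
  vals <- lapply(seq_along(c(10, 900, 880, 5)),
                 function(k) indexed_value(c(10, 900, 880, 5)[k], k))
  r <- he_top2(vals, p)
  expect_equal(c(r$first$index, r$second$index), c(2, 3))
  two <- he_top2(vals[1:2], p)
  expect_equal(two$first$value, 900)
  expect_equal(two$second$value, 10)
  set.seed(44)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    v <- sample.int(p$Q / 4, n) - 1     # distinct values
    r <- he_top2(lapply(seq_len(n), function(k) indexed_value(v[k], k)), p)
    o <- top2(v)
    expect_equal(c(r$first$index, r$second$index), c(o$index_f, o$index_s))
    expect_equal(c(r$first$value, r$second$value), c(o$score_f, o$score_s))
  }
})

test_that("lut_sigmoid stays within the quantization bound of exact sigmoid", {
  p <- default_params(B = 10)
  # the score 0 sits mid-range: decodes to ~0.5
  tv0 <- normalize_t(0, p)
  expect_equal(decode_fixed(lut_sigmoid(tv0, p), p), 0.5, tolerance = 1e-2)
  # the saturated low end decodes to sigmoid(-10)
  expect_equal(decode_fixed(lut_sigmoid(0, p), p), plogis(-10),
               tolerance = 1e-3)
  expect_error(lut_sigmoid(p$Q / 4 + 1, p), "outside")
  # sweep: |LUT path - exact| <= max-slope * cell width + encoding error
  cell_score <- (p$B - p$T_norm) / p$lut_size
  bound <- cell_score / 4 + 1 / (2 * p$scale)
  set.seed(19)
  x <- runif(1e4, p$T_norm, p$B)
  lut <- decode_fixed(lut_sigmoid(normalize_t(x, p), p), p)
  expect_lte(max(abs(lut - plogis(x))), bound)
})

test_that("he_threshold divides pf by t and selects a2 through the mux identity", {
  p <- default_params()
  enc <- function(v) encode_fixed(v, p)
  hom <- he_threshold(indexed_value(enc(0.8), 3L), indexed_value(enc(0.1), 7L),
                      2L, p)
  expect_equal(c(hom$a1, hom$a2), c(3L, 3L))
  expect_true(hom$homozygous)
  het <- he_threshold(indexed_value(enc(0.8), 3L), indexed_value(enc(0.1), 7L),
                      17L, p)
  expect_equal(c(het$a1, het$a2), c(3L, 7L))
  expect_false(het$homozygous)
  expect_error(he_threshold(indexed_value(1, 1L), indexed_value(0, 2L), 1L, p),
               "t must be")
  # random triples agree with the plaintext rule away from the boundary
  set.seed(55)
  for (i in 1:300) {
    ps <- runif(1, 1e-4, 0.5); pf <- min(ps + runif(1, 0, 0.5), 0.999)
    t <- sample(2:20, 1)
    if (abs(pf - ps * t) < t / p$scale) next  # within one encoding unit
    d_he <- he_threshold(indexed_value(enc(pf), 1L), indexed_value(enc(ps), 2L),
                         t, p)
    d_pl <- threshold_decision(pf, ps, t, 1L, 2L)
    expect_equal(d_he$a2, d_pl$a2)
  }
})

test_that("impute_he agrees with impute_plain away from decision boundaries", {
  ss <- shared_sim()
  m <- ss$models[["HLA-A"]]
  p <- fp_params_for_model(m)
  for (i in 1:30) {
    x <- ss$sim$target_dosage[i, m$snp_ids]
    r_he <- impute_he(m, x, p)
    r_pl <- impute_plain(m, x)
    expect_equal(c(r_he$a1, r_he$a2), c(r_pl$a1, r_pl$a2))
  }
})
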