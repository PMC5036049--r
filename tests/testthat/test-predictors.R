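test_that("configuration objects validate their parameters", {
  cfg <- svm_config()
  expect_equal(cfg$C, 2)
  expect_equal(cfg$gamma, 0.03125)
  expect_equal(cfg$neg_pos_ratio, 6)
  expect_error(svm_config(C = -1))
  expect_error(svm_config(gamma = 0))
  fus <- fusion_config()
  expect_equal(fus$alpha, 0.55)
  expect_equal(fus$sp_cutoff, 0.6)
  expect_equal(fus$beta, 0.57)
  expect_equal(fus$hh_cutoff, 0.87)
  expect_error(fusion_config(alpha = 1.2))
})

test_that("structural vectors stack the target block and neighbor blocks", {
  st <- rand_structure(8, atoms_per_res = 4, seed = 19)
  graph <- contact_graph(st, tessellate(st))
  me <- rep(0.1, 8)
  netf <- network_features(graph, 9)
  ln <- laplacian_norms(st)
  pssm <- cr_pssm(matrix(0, 8, 20))
  x <- build_structural_vectors(st, graph, me, netf, ln, pssm, window = 2,
                                cutoff = 9)
  expect_identical(dim(x), c(8L, 30L + 2L * 31L))
  cls <- attr(x, "feature_class")
  expect_identical(sum(cls == "pssm"), 60L)     # 3 blocks x 20
  expect_identical(sum(cls == "binary"), 2L)    # one pad bit per neighbor slot
  # a residue with fewer than `window` neighbors gets pad bits set
  env_sizes <- vapply(1:8, function(r) nrow(microenvironment(graph, r, 9)),
                      integer(1))
  for (r in 1:8) {
    pads <- x[r, c("nb1_pad", "nb2_pad")]
    expect_equal(unname(pads), as.numeric(seq_len(2) > env_sizes[r]))
  }
  # the first 30 columns are the residue's own block
  expect_equal(unname(x[3, "t_me"]), me[3])
  expect_equal(unname(x[3, "t_degree"]), netf$degree[3])
  expect_error(build_structural_vectors(st, graph, me[-1], netf, ln, pssm),
               "length mismatch")
  expect_error(build_structural_vectors(st, graph, me, netf, ln,
                                        cr_pssm(matrix(0, 5, 20))),
               "does not match")
})

test_that("sequence vectors window the per-position block and append globals", {
  st <- rand_structure(6, seed = 23)
  pssm <- cr_pssm(matrix(rnorm(120), 6, 20))
  msa <- matrix(rep(st$aa, each = 3), 3, 6)
  cons <- conservation(msa)
  static <- static_features(st$aa)
  x <- build_sequence_vectors(st, pssm, cons, static, window = 2)
  # per-position block: 20 pssm + 3 conservation + 20 one-hot + 4 scales,
  # plus a terminal bit, times 5 positions, plus 22 globals
  expect_identical(ncol(x), 5L * 48L + 22L)
  expect_identical(nrow(x), 6L)
  cls <- attr(x, "feature_class")
  expect_identical(sum(cls == "pssm"), 100L)
  expect_identical(sum(cls == "binary"), 5L * 21L)
  # centre block of residue 3 carries its own pssm row
  expect_equal(unname(x[3, "w0_pssm_A"]), pssm$matrix[3, "A"], ignore_attr = TRUE)
  expect_equal(unname(x[1, "w-1_term"]), 1)
  expect_equal(unname(x[1, "w1_term"]), 0)
})

test_that("the SVM predictor is deterministic and learns a separable toy", {
  set.seed(31)
  n <- 320
  y <- rep(c(1, 0), c(40, 280))
  x <- cbind(f1 = rnorm(n, mean = 2 * y), f2 = rnorm(n, mean = -1.5 * y))
  colnames(x) <- c("f1", "f2")
  cfg <- svm_config(seed = 9)
  m1 <- train_feature_predictor(x, y, cfg)
  m2 <- train_feature_predictor(x, y, cfg)
  p1 <- predict(m1, x); p2 <- predict(m2, x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gt(auc_score(p1, y), 0.95)
  # calibrated scores are oriented: positives score higher on average
  expect_gt(mean(p1[y == 1]), mean(p1[y == 0]))
  # the negative subsample honours the 1:6 ratio
  expect_identical(length(m1$subsample), 40L + 40L * 6L)
  expect_error(train_feature_predictor(x, rep(0, n), cfg), "no positive")
})

test_that("fusion gates on the similarity cutoff", {
  f <- c(0.8, 0.2, 0.5)
  t <- c(1, 0, 1)
  expect_identical(fuse(f, t, 0.59, weight = 0.55, cutoff = 0.6), f)
  expect_identical(fuse(f, t, -Inf, weight = 0.55, cutoff = 0.6), f)
  expect_equal(fuse(f, t, 0.6, weight = 0.55, cutoff = 0.6),
               0.55 * f + 0.45 * t)
  expect_error(fuse(f, t[1:2], 1, 0.5, 0.5), "length mismatch")
})

test_that("channel blending is the stated convex combination", {
  expect_equal(crhunter_score(c(1, 0), c(0, 1), gamma = 0.5), c(0.5, 0.5))
  expect_equal(crhunter_score(0.8, 0.4, gamma = 0.25), 0.25 * 0.8 + 0.75 * 0.4)
  expect_error(crhunter_score(1, c(1, 2)), "length mismatch")
  expect_error(crhunter_score(1, 1, gamma = 1.5))
})
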