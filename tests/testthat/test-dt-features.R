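# hand-built 4-residue graph: 1-2 strong, 1-3 strong, 1-4 weak, 2-3 weak
toy_graph <- function() {
  graph_from_facets(4, data.frame(i = c(1L, 1L, 1L, 2L),
                                  j = c(2L, 3L, 4L, 3L),
                                  count = c(12L, 10L, 3L, 2L)))
}
toy_structure <- function(aa = c("H", "D", "D", "A")) {
  ca <- matrix(seq_len(12), 4, 3)
  atoms <- data.frame(res = 1:4, name = "CA", element = "C",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3])
  cr_structure("toy", aa, atoms, ca)
}

test_that("pair_frequency counts neighbor types on the query row only", {
  st <- toy_structure()
  f <- pair_frequency(st, toy_graph(), 1, cutoff = 9)
  expect_identical(dim(f), c(20L, 20L))
  expect_equal(f["H", "D"], 2)   # residues 2 and 3 at cutoff 9
  expect_equal(sum(f), 2)
  expect_equal(sum(f[setdiff(AA_ALPHABET, "H"), ]), 0)
  # isolated residue gives an all-zero matrix
  expect_equal(sum(pair_frequency(st, toy_graph(), 4, cutoff = 9)), 0)
})

test_that("train_pair_weights matches the hand-computed normalization", {
  st <- toy_structure()
  ann <- cr_annotation("toy", 1L)
  w <- train_pair_weights(list(st), list(toy_graph()), list(ann), cutoff = 9)
  # neighborhood of residue 1: types D, D; with the query H included the
  # type counts are H = 1, D = 2; pair counts N_HD = 2
  pc <- 0.5
  expect_equal(w$values["H", "D"], 2 / ((1 + pc) * (2 + pc)))
  expect_equal(w$values["H", "A"], 0)
  expect_equal(sum(w$values[setdiff(AA_ALPHABET, "H"), ]), 0)
  expect_identical(w$n_catalytic, 1L)
  expect_identical(w$n_skipped, 0L)
})

test_that("train_pair_weights averages, skips empty neighborhoods, errors when all empty", {
  st <- toy_structure()
  g <- toy_graph()
  ann2 <- cr_annotation("toy", c(1L, 4L))   # residue 4 has no contacts >= 9
  w2 <- train_pair_weights(list(st), list(g), list(ann2), cutoff = 9)
  expect_identical(w2$n_catalytic, 1L)
  expect_identical(w2$n_skipped, 1L)
  w1 <- train_pair_weights(list(st), list(g), list(cr_annotation("toy", 1L)),
                           cutoff = 9)
  expect_equal(w2$values, w1$values)
  expect_error(
    train_pair_weights(list(st), list(g), list(cr_annotation("toy", 4L)),
                       cutoff = 9),
    "no catalytic residue")
  # annotation beyond the chain is rejected
  expect_error(
    train_pair_weights(list(st), list(g), list(cr_annotation("toy", 11L))),
    "exceeds chain length")
})

test_that("a custom weight_fun replaces the default normalization", {
  st <- toy_structure()
  ann <- cr_annotation("toy", 1L)
  w <- train_pair_weights(list(st), list(toy_graph()), list(ann), cutoff = 9,
                          weight_fun = function(pair_counts, type_counts, m, pc) {
                            out <- matrix(0, 20, 20,
                                          dimnames = list(AA_ALPHABET, AA_ALPHABET))
                            out[m, ] <- pair_counts
                            out
                          })
  expect_equal(w$values["H", "D"], 2)
})

test_that("me_score is the plain inner product and me_scores maps the chain", {
  st <- toy_structure()
  g <- toy_graph()
  w <- train_pair_weights(list(st), list(g), list(cr_annotation("toy", 1L)))
  f1 <- pair_frequency(st, g, 1)
  expect_equal(me_score(f1, w), sum(f1 * w$values))
  expect_equal(me_scores(st, g, w)[1], me_score(f1, w))
  expect_equal(me_scores(st, g, w)[4], 0)
  expect_error(me_score(matrix(0, 3, 3), w), "20 x 20")
})

test_that("network centralities match the brute-force oracle on small graphs", {
  set.seed(42)
  for (trial in 1:10) {
    n <- sample(3:12, 1)
    all_pairs <- t(combn(n, 2))
    m <- sample(0:nrow(all_pairs), 1)
    e <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
    g <- graph_from_facets(n, data.frame(i = e[, 1], j = e[, 2],
                                         count = rep(1L, m)))
    got <- network_features(g, cutoff = 1)
    want <- oracle_centralities(n, e)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
  }
})

test_that("pair weights round trip through TSV", {
  st <- toy_structure()
  w <- train_pair_weights(list(st), list(toy_graph()),
                          list(cr_annotation("toy", 1L)))
  path <- tempfile()
  write_pair_weights(w, path)
  back <- read_pair_weights(path)
  expect_equal(back$values, w$values, tolerance = 1e-12)
})
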