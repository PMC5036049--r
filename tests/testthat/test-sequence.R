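test_that("PSSM write/read round trips and canonicalizes column order", {
  set.seed(8)
  m <- matrix(sample(-10:12, 6 * 20, replace = TRUE), 6, 20)
  pssm <- cr_pssm(m, sequence = strsplit("HDKLMA", "")[[1]])
  path <- tempfile()
  write_pssm(pssm, path)
  back <- read_pssm(path)
  expect_equal(unname(back$matrix), unname(m))
  expect_identical(colnames(back$matrix), AA_ALPHABET)
  expect_identical(back$sequence, pssm$sequence)
})

test_that("read_pssm reports malformed input with line numbers", {
  expect_error(read_pssm(tempfile()), "not found")
  path <- tempfile()
  writeLines(c("", "junk header", "more junk"), path)
  expect_error(read_pssm(path), "no amino-acid header")
  hdr <- paste(PSIBLAST_ORDER, collapse = " ")
  writeLines(c(hdr, paste(c("1", "A", rep("0", 19)), collapse = " ")), path)
  expect_error(read_pssm(path), "line 2")
  writeLines(c(hdr, paste(c("1", "A", rep("0", 19), "xx"), collapse = " ")), path)
  expect_error(read_pssm(path), "non-numeric")
})

test_that("conservation entropies behave on known columns", {
  # column 1: perfectly conserved; column 2: two equiprobable letters;
  # column 3: query gap (dropped); column 4: > 90% gaps (flagged)
  msa <- rbind(c("A", "C", "-", "H"),
               matrix(rep(c("A", "D", "K", "-"), each = 6), 6, 4),
               matrix(rep(c("A", "C", "K", "-"), each = 5), 5, 4))
  cons <- conservation(msa)
  expect_identical(nrow(cons), 3L)        # query-gap column dropped
  expect_equal(cons$shannon[1], 0)
  expect_equal(cons$relative_entropy[1], log2(20))
  expect_equal(cons$shannon[2], 1)        # C and D at 6/12 each
  expect_true(cons$gappy[3])              # 11 of 12 entries are gaps
  expect_false(any(cons$gappy[1:2]))
  expect_true(all(cons$jsd >= 0 & cons$jsd <= 1))
})

test_that("conservation uses the supplied background for relative entropy", {
  msa <- rbind("H", "H", "H")
  bg <- rep(1 / 20, 20); names(bg) <- AA_ALPHABET
  bg["H"] <- 0.5; bg <- bg / sum(bg)
  cons <- conservation(msa, background = bg)
  expect_equal(cons$relative_entropy[1], log2(1 / bg["H"]), ignore_attr = TRUE)
  expect_error(conservation(msa, background = rep(1, 3)), "20 entries")
  expect_error(conservation(matrix(character(0), 0, 0)), "empty alignment")
  expect_error(conservation(c("AC", "ACD")), "differ in length")
})

test_that("MSA files round trip through FASTA", {
  msa <- rbind(q = c("A", "C", "-"), h = c("A", "D", "K"))
  path <- tempfile(fileext = ".fasta")
  write_msa(msa, path)
  back <- read_msa(path)
  expect_identical(unname(back), unname(msa))
  expect_identical(rownames(back), c("q", "h"))
})

test_that("static features encode type, scales, propensity and position", {
  tab <- static_features("HDA")
  expect_identical(dim(tab), c(3L, 46L))
  expect_equal(unname(tab[1, "rt_H"]), 1)
  expect_equal(sum(tab[1, paste0("rt_", AA_ALPHABET)]), 1)
  expect_equal(unname(tab[2, "hydropathy"]), -3.5)   # aspartate, Kyte-Doolittle
  expect_equal(unname(tab[2, "charge"]), -1)
  expect_equal(unname(tab[, "relpos"]), c(0, 0.5, 1))
  expect_equal(unname(tab[, "length"]), rep(3, 3))
  expect_equal(unname(tab[1, "aac_A"]), 1 / 3)
  cls <- attr(tab, "feature_class")
  expect_identical(unname(cls[paste0("rt_", AA_ALPHABET)]), rep("binary", 20))
  expect_identical(unname(cls["hydropathy"]), "other")
  expect_error(static_features("HBX"), "non-standard")
  # a trained propensity replaces the generic prior
  prop <- setNames(seq(0, 1.9, by = 0.1), AA_ALPHABET)
  tab2 <- static_features("HDA", propensity = prop)
  expect_equal(unname(tab2[, "propensity"]), unname(prop[c("H", "D", "A")]))
})

test_that("trained propensity is the smoothed log2 enrichment", {
  st <- ca_structure(matrix(rnorm(12), 4, 3))
  st$aa <- c("H", "H", "A", "G"); st$sequence <- "HHAG"
  prop <- train_propensity(list(st), list(cr_annotation(st$id, 1L)),
                           pseudocount = 0.5)
  nc <- rep(0.5, 20); names(nc) <- AA_ALPHABET; nc["H"] <- 1.5
  nb <- rep(0.5, 20); names(nb) <- AA_ALPHABET
  nb[c("A", "G")] <- 1.5; nb["H"] <- 2.5
  want <- log2((nc / sum(nc)) / (nb / sum(nb)))
  expect_equal(prop, want)
  bg <- train_background(list(st))
  expect_equal(sum(bg), 1)
  expect_gt(bg["H"], bg["C"])
})

test_that("window features pad out-of-chain positions with a terminal bit", {
  tab <- matrix(1:12, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  v <- window_features(tab, center = 1, half_width = 1)
  expect_length(v, 3 * 4)
  # left pad: zeros + terminal bit
  expect_equal(unname(v[1:4]), c(0, 0, 0, 1))
  expect_equal(unname(v[5:8]), c(tab[1, ], 0), ignore_attr = TRUE)
  expect_equal(unname(v[9:12]), c(tab[2, ], 0), ignore_attr = TRUE)
  expect_identical(names(v)[1:4], c("w-1_a", "w-1_b", "w-1_c", "w-1_term"))
  # interior window has no terminal bits
  v2 <- window_features(tab, center = 2, half_width = 1)
  expect_equal(unname(v2[c(4, 8, 12)]), c(0, 0, 0))
  expect_error(window_features(tab, 0, 1), "invalid center")
  expect_error(window_features(tab, 5, 1), "invalid center")
})
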