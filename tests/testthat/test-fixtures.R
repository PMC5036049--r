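test_that("the generator is deterministic for a fixed spec", {
  spec <- fixture_spec(n_structures = 3, seed = 41)
  b1 <- make_benchmark(spec)
  b2 <- make_benchmark(spec)
  expect_identical(b1$structures, b2$structures)
  expect_identical(b1$msas, b2$msas)
  expect_identical(b1$pssms, b2$pssms)
  expect_identical(b1$hits_str, b2$hits_str)
  # a different seed changes the structures
  b3 <- make_benchmark(fixture_spec(n_structures = 3, seed = 42))
  expect_false(identical(b1$structures[[1]]$ca, b3$structures[[1]]$ca))
})

test_that("generated chains have protein-like geometry and valid annotations", {
  spec <- fixture_spec(seed = 43)
  for (i in 1:3) {
    g <- make_structure(spec, i)
    st <- g$structure
    L <- n_residues(st)
    expect_true(L >= spec$length_range[1] && L <= spec$length_range[2])
    steps <- sqrt(rowSums((st$ca[-1, ] - st$ca[-L, ])^2))
    expect_true(abs(mean(steps) - 3.8) < 0.5)
    idx <- g$annotation$catalytic_indices
    expect_identical(length(idx), max(2L, as.integer(round(spec$catalytic_fraction * L))))
    expect_true(all(idx >= 1 & idx <= L))
    # catalytic residues sit in the pocket: closer to the center than average
    rad <- sqrt(rowSums(st$ca^2))
    expect_lt(mean(rad[idx]), mean(rad[-idx]))
  }
})

test_that("a zero-depth pocket removes the geometric signal", {
  spec <- fixture_spec(pocket_depth = 0, seed = 47)
  g <- make_structure(spec, 1)
  rad <- sqrt(rowSums(g$structure$ca^2))
  # all residues on the shell: radial spread is tiny
  expect_lt(sd(rad), 0.5)
  expect_error(fixture_backbone(60, pocket_depth = 1e4), "infeasible geometry")
})

test_that("catalytic residues draw from the biased alphabet", {
  spec <- fixture_spec(n_structures = 25, seed = 53)
  bm <- make_benchmark(spec, with_templates = FALSE)
  hot <- c("H", "D", "R", "E", "K", "C", "Y")
  cat_aa <- unlist(lapply(seq_along(bm$structures), function(i)
    bm$structures[[i]]$aa[bm$annotations[[i]]$catalytic_indices]))
  # expected hot fraction is 6*7 / (6*7 + 0.5*13) ~ 0.87 vs 0.35 uniform
  expect_gt(mean(cat_aa %in% hot), 0.6)
})

test_that("alignments are deeper-conserved at catalytic columns", {
  spec <- fixture_spec(n_structures = 6, seed = 59)
  bm <- make_benchmark(spec, with_templates = FALSE)
  sh_cat <- c(); sh_other <- c()
  for (i in seq_along(bm$structures)) {
    msa <- bm$msas[[i]]
    expect_equal(nrow(msa), spec$msa_depth)
    expect_identical(unname(msa[1, ]), bm$structures[[i]]$aa)
    cons <- conservation(msa)
    idx <- bm$annotations[[i]]$catalytic_indices
    sh_cat <- c(sh_cat, cons$shannon[idx])
    sh_other <- c(sh_other, cons$shannon[-idx])
  }
  expect_lt(mean(sh_cat), mean(sh_other) - 0.5)
})

test_that("PSSMs align with the chain and favor the query residue", {
  spec <- fixture_spec(n_structures = 4, seed = 61)
  bm <- make_benchmark(spec, with_templates = FALSE)
  for (i in seq_along(bm$structures)) {
    p <- bm$pssms[[i]]
    L <- n_residues(bm$structures[[i]])
    expect_identical(nrow(p$matrix), L)
    own <- vapply(seq_len(L), function(r)
      p$matrix[r, bm$structures[[i]]$aa[r]], numeric(1))
    expect_gt(mean(own), mean(p$matrix))
  }
})

test_that("the related template tops each hit list above the fusion cutoffs", {
  spec <- fixture_spec(n_structures = 8, seed = 67)
  bm <- make_benchmark(spec)
  fus <- fusion_config()
  for (i in seq_along(bm$structures)) {
    id <- bm$structures[[i]]$id
    hs <- bm$hits_str[[id]]; hq <- bm$hits_seq[[id]]
    expect_identical(hs[[1]]$template_id, paste0("t_", id))
    expect_identical(hq[[1]]$template_id, paste0("t_", id))
    expect_gte(hs[[1]]$similarity, fus$sp_cutoff)
    expect_gte(hq[[1]]$similarity, fus$hh_cutoff)
    # decoys stay below the related template
    expect_true(all(vapply(hs[-1], function(h) h$similarity, numeric(1)) <
                      hs[[1]]$similarity))
  }
  # template bookkeeping is consistent
  expect_identical(unname(bm$template_source[paste0("t_", bm$structures[[1]]$id)]),
                   bm$structures[[1]]$id)
  expect_identical(bm$template_annotations[[paste0("t_", bm$structures[[2]]$id)]],
                   bm$annotations[[2]]$catalytic_indices)
  off <- make_benchmark(fixture_spec(n_structures = 3, seed = 67),
                        with_templates = FALSE)
  expect_true(all(lengths(off$hits_str) == 0))
  expect_true(all(lengths(off$hits_seq) == 0))
})

test_that("a benchmark round trips through its directory layout", {
  spec <- fixture_spec(n_structures = 3, seed = 71)
  bm <- make_benchmark(spec)
  dir <- tempfile("bench")
  write_benchmark(bm, dir)
  back <- read_benchmark(dir)
  ids <- vapply(bm$structures, function(s) s$id, character(1))
  expect_identical(vapply(back$structures, function(s) s$id, character(1)), ids)
  for (i in seq_along(ids)) {
    expect_identical(back$structures[[i]]$aa, bm$structures[[i]]$aa)
    expect_lt(max(abs(back$structures[[i]]$ca - bm$structures[[i]]$ca)), 1e-3)
    expect_identical(back$annotations[[i]]$catalytic_indices,
                     bm$annotations[[i]]$catalytic_indices)
    # PSSM files carry 2 decimals
    expect_lt(max(abs(back$pssms[[i]]$matrix - bm$pssms[[i]]$matrix)), 0.0051)
    expect_identical(unname(back$msas[[i]]), unname(bm$msas[[i]]))
    expect_length(back$hits_str[[ids[i]]], length(bm$hits_str[[ids[i]]]))
  }
  expect_identical(back$template_source, bm$template_source)
  expect_identical(back$template_annotations[names(bm$template_annotations)],
                   bm$template_annotations)
})
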