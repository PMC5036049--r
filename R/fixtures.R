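# Synthetic benchmark generator: compact globular chains folded on a
# sphere shell with a pocket-like indentation, catalytic residues planted
# at the pocket bottom with enriched charged/hydrophilic neighborhoods,
# alignments with elevated conservation at catalytic columns, and
# template libraries of perturbed copies with known annotations.

#' Specification for the synthetic benchmark generator
#'
#' Defaults emulate the statistical signatures the predictor exploits:
#' catalytic sites sit at the bottom of a surface pocket (small
#' large-scale Laplacian norm), are enriched in H/D/R/E/K/C/Y together
#' with their contact neighbors (microenvironment signal), and are
#' strongly conserved in the alignment (profile signal). Related
#' templates are perturbed copies of each query.
#'
#' @param n_structures number of chains to generate.
#' @param length_range inclusive range of chain lengths.
#' @param pocket_depth pocket indentation depth in Angstrom (0 gives a
#'   null fixture with no geometric signal).
#' @param catalytic_fraction fraction of residues planted as catalytic.
#' @param alphabet_bias named length-20 sampling weight vector for
#'   catalytic residues and their neighbors.
#' @param conservation_boost in [0, 1]: fractional reduction of the
#'   substitution rate at catalytic columns (1 = absolute conservation,
#'   0 = no conservation signal).
#' @param template_noise coordinate noise (Angstrom, sd) applied to the
#'   perturbed-copy templates.
#' @param msa_depth number of sequences per alignment.
#' @param mutation_rate baseline per-column substitution rate.
#' @param seed master seed; fixed seed gives byte-identical outputs.
#' @return list of class `cr_fixture_spec`.
#' @export
fixture_spec <- function(n_structures = 40, length_range = c(50, 70),
                         pocket_depth = 6, catalytic_fraction = 0.06,
                         alphabet_bias = NULL, conservation_boost = 0.9,
                         template_noise = 1.0, msa_depth = 50,
                         mutation_rate = 0.35, seed = 1) {
  stopifnot(n_structures >= 1, catalytic_fraction > 0, catalytic_fraction < 1,
            conservation_boost >= 0, conservation_boost <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (is.null(alphabet_bias)) {
    alphabet_bias <- setNames(rep(0.5, 20), AA_ALPHABET)
    alphabet_bias[c("H", "D", "R", "E", "K", "C", "Y")] <- 6
  }
  structure(list(n_structures = n_structures, length_range = length_range,
                 pocket_depth = pocket_depth,
                 catalytic_fraction = catalytic_fraction,
                 alphabet_bias = alphabet_bias,
                 conservation_boost = conservation_boost,
                 template_noise = template_noise, msa_depth = msa_depth,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "cr_fixture_spec")
}

# unit vectors
unitv <- function(v) v / sqrt(sum(v^2))

# alpha-carbon trace: spherical spiral resampled to ~3.8 A spacing, then
# indented by a spherical-cap pocket around a random axis
fixture_backbone <- function(L, pocket_depth) {
  R0 <- 3.8 * sqrt(L / (4 * pi))
  m <- max(3, pi * R0 / 4.5)
  t <- seq(0.02, 0.98, length.out = 6000)
  th <- pi * t; ph <- 2 * pi * m * t
  pts <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  seg <- sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2))
  arc <- c(0, cumsum(seg))
  want <- seq(0, arc[length(arc)], length.out = L)
  idx <- findInterval(want, arc, all.inside = TRUE)
  ca <- pts[idx, ]
  ca <- ca * (3.8 / mean(sqrt(rowSums((ca[-1, ] - ca[-L, ])^2))))
  R <- sqrt(sum(ca[1, ]^2))
  if (pocket_depth >= R)
    stop("infeasible geometry: pocket deeper than the sphere radius (",
         round(R, 1), " A)")
  axis <- unitv(ca[round(L * 0.45), ])
  ang <- acos(pmin(1, pmax(-1, (ca %*% axis) / sqrt(rowSums(ca^2)))))
  psi <- acos(1 - 2 * 0.10) # cap covering ~10% of the sphere
  depth <- ifelse(ang < psi, pocket_depth * cos(pi * ang / (2 * psi))^2, 0)
  ca <- ca * (1 - depth / R)
  list(ca = ca, axis = axis, angle = as.numeric(ang), depth = depth, R = R)
}

#' Generate one synthetic structure with planted catalytic residues
#'
#' @param spec a [fixture_spec()].
#' @param index structure index (also seeds the generator).
#' @return list with `structure` (a [cr_structure()]) and `annotation`
#'   (a [cr_annotation()]).
#' @export
make_structure <- function(spec, index) {
  seed <- (spec$seed * 7919 + index * 104729) %% 2147480000
  with_seed(seed, {
    L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    bb <- fixture_backbone(L, spec$pocket_depth)
    ca <- bb$ca
    n_cat <- max(2, round(spec$catalytic_fraction * L))
    cat_idx <- sort(order(bb$angle)[seq_len(n_cat)])

    # sequence: catalytic and pocket-contacting residues from the biased
    # alphabet, the rest uniform
    bias <- spec$alphabet_bias / sum(spec$alphabet_bias)
    aa <- sample(AA_ALPHABET, L, replace = TRUE)
    d2cat <- apply(ca, 1, function(p)
      min(sqrt(colSums((t(ca[cat_idx, , drop = FALSE]) - p)^2))))
    nb_idx <- setdiff(which(d2cat < 8), cat_idx)
    aa[cat_idx] <- sample(AA_ALPHABET, n_cat, replace = TRUE, prob = bias)
    if (length(nb_idx)) {
      half <- sqrt(spec$alphabet_bias) # milder enrichment for neighbors
      aa[nb_idx] <- sample(AA_ALPHABET, length(nb_idx), replace = TRUE,
                           prob = half / sum(half))
    }

    # heavy-atom decoration: backbone N, C, O around each CA plus 0-4
    # side-chain pseudo-atoms along the outward normal
    rows <- list()
    for (i in seq_len(L)) {
      out <- unitv(ca[i, ])
      prev <- if (i > 1) unitv(ca[i - 1, ] - ca[i, ]) else unitv(ca[i, ] - ca[min(i + 1, L), ])
      nxt <- if (i < L) unitv(ca[i + 1, ] - ca[i, ]) else unitv(ca[i, ] - ca[i - 1, ])
      jit <- function() rnorm(3, 0, 0.15)
      pos <- rbind(N = ca[i, ] + 1.25 * prev + jit(),
                   CA = ca[i, ],
                   C = ca[i, ] + 1.25 * nxt + jit(),
                   O = ca[i, ] + 1.25 * nxt + 1.1 * out + jit())
      nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
      nsc <- SIDECHAIN_ATOMS[aa[i]]
      scnames <- c("CB", "CG", "CD", "CE")
      for (k in seq_len(nsc)) {
        pos <- rbind(pos, ca[i, ] + (1.0 + 1.4 * k) * out + rnorm(3, 0, 0.35))
        nm <- c(nm, scnames[k]); el <- c(el, "C")
      }
      rows[[i]] <- data.frame(res = i, name = nm, element = el,
                              x = pos[, 1], y = pos[, 2], z = pos[, 3],
                              stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    rownames(atoms) <- NULL
    id <- sprintf("syn%03d", index)
    list(structure = cr_structure(id, aa, atoms, ca),
         annotation = cr_annotation(id, cat_idx))
  })
}

#' Generate a synthetic alignment and PSSM for a structure
#'
#' The alignment holds `msa_depth` mutated copies of the sequence; the
#' per-column substitution rate is reduced by `conservation_boost` at
#' catalytic columns. The PSSM holds log2 odds of smoothed column
#' frequencies against the uniform background.
#'
#' @param structure a [cr_structure()].
#' @param annotation the matching [cr_annotation()].
#' @param spec a [fixture_spec()].
#' @return list with `msa` (character matrix, query first) and `pssm`
#'   (a `cr_pssm` tagged synthetic).
#' @export
make_msa_and_pssm <- function(structure, annotation, spec) {
  seed <- (string_seed(structure$id) + spec$seed * 31) %% 2147480000
  with_seed(seed, {
    L <- n_residues(structure)
    aa <- structure$aa
    rate <- rep(spec$mutation_rate, L)
    rate[annotation$catalytic_indices] <-
      spec$mutation_rate * (1 - spec$conservation_boost)
    n <- spec$msa_depth
    msa <- matrix(rep(aa, each = n), n, L)
    for (j in seq_len(L)) {
      mut <- which(runif(n - 1) < rate[j]) + 1L
      if (length(mut))
        msa[mut, j] <- sample(setdiff(AA_ALPHABET, aa[j]), length(mut),
                              replace = TRUE)
      if (rate[j] > 0) {
        gap <- which(runif(n - 1) < 0.02) + 1L
        msa[gap, j] <- "-"
      }
    }
    msa[1, ] <- aa
    rownames(msa) <- c("query", sprintf("hom%02d", seq_len(n - 1)))

    counts <- apply(msa, 2, function(col)
      as.numeric(table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))))
    freqs <- t(t(counts + 0.5) / (colSums(counts) + 10))
    pssm <- cr_pssm(t(log2(freqs / 0.05)), sequence = aa, source = "synthetic")
    list(msa = msa, pssm = pssm)
  })
}

#' Generate ranked template hits for a query against a library
#'
#' The library entry related to the query (a perturbed copy) receives a
#' similarity drawn from `high_range` and an identity mapping with a small
#' fraction of simulated gap positions; unrelated entries receive
#' similarities from `low_range` and partial mappings.
#'
#' @param query a [cr_structure()].
#' @param library list of entries, each
#'   `list(id, length, related_to)` (see [make_benchmark()]).
#' @param spec a [fixture_spec()].
#' @param high_range similarity range for the related template.
#' @param low_range similarity range for unrelated templates.
#' @param salt integer mixed into the seed so the structure- and
#'   profile-alignment channels draw independent similarities.
#' @return list of [template_hit()] objects, ranked by similarity
#'   descending.
#' @export
make_template_hits <- function(query, library, spec,
                               high_range = c(0.65, 0.95),
                               low_range = c(0.2, 0.5), salt = 0L) {
  if (length(library) == 0) stop("empty template library")
  seed <- (string_seed(query$id) + spec$seed * 17 + salt * 7) %% 2147480000
  with_seed(seed, {
    L <- n_residues(query)
    hits <- lapply(library, function(entry) {
      if (identical(entry$related_to, query$id)) {
        sim <- runif(1, high_range[1], high_range[2])
        keep <- which(runif(L) > 0.05)
        template_hit(entry$id, sim, setNames(keep, keep))
      } else {
        sim <- runif(1, low_range[1], low_range[2])
        k <- min(L, entry$length)
        keep <- sort(sample(seq_len(k), max(1, round(0.6 * k))))
        template_hit(entry$id, sim, setNames(keep, keep))
      }
    })
    sims <- vapply(hits, function(h) h$similarity, numeric(1))
    hits[order(-sims)]
  })
}

#' Generate a complete synthetic benchmark
#'
#' Produces structures with planted catalytic residues, alignments and
#' PSSMs, a template library of perturbed copies (one related template
#' per query plus unrelated decoys), and ranked structure- and
#' profile-alignment hit lists whose related similarities clear the
#' respective fusion cutoffs.
#'
#' @param spec a [fixture_spec()].
#' @param with_templates if `FALSE`, hit lists are empty (the regime where
#'   fusion must reduce to the feature predictors).
#' @return object of class `cr_benchmark` with fields `structures`,
#'   `annotations`, `msas`, `pssms`, `hits_str`, `hits_seq`,
#'   `template_structures`, `template_annotations`, `template_lengths`,
#'   `template_source`, `spec`.
#' @export
make_benchmark <- function(spec = fixture_spec(), with_templates = TRUE) {
  gen <- lapply(seq_len(spec$n_structures), function(i) make_structure(spec, i))
  structures <- lapply(gen, `[[`, "structure")
  annotations <- lapply(gen, `[[`, "annotation")
  prof <- lapply(seq_along(gen), function(i)
    make_msa_and_pssm(structures[[i]], annotations[[i]], spec))
  msas <- lapply(prof, `[[`, "msa")
  pssms <- lapply(prof, `[[`, "pssm")
  ids <- vapply(structures, function(s) s$id, character(1))

  # template library: one perturbed copy per query
  template_structures <- lapply(seq_along(structures), function(i) {
    st <- structures[[i]]
    seed <- (string_seed(st$id) + spec$seed * 13 + 5) %% 2147480000
    with_seed(seed, {
      at <- st$atoms
      at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
        matrix(rnorm(3 * nrow(at), 0, spec$template_noise), ncol = 3)
      ca <- st$ca + matrix(rnorm(3 * nrow(st$ca), 0, spec$template_noise), ncol = 3)
      cr_structure(paste0("t_", st$id), st$aa, at, ca)
    })
  })
  template_annotations <- setNames(
    lapply(annotations, function(a) a$catalytic_indices),
    paste0("t_", ids))
  template_lengths <- setNames(vapply(structures, n_residues, integer(1)),
                               paste0("t_", ids))
  template_source <- setNames(ids, paste0("t_", ids))

  library <- lapply(seq_along(ids), function(i)
    list(id = paste0("t_", ids[i]), length = template_lengths[[i]],
         related_to = ids[i]))

  hits_str <- hits_seq <- setNames(vector("list", length(ids)), ids)
  if (with_templates) {
    for (i in seq_along(ids)) {
      # a handful of decoys plus the related template, per channel
      decoys <- library[setdiff(
        with_seed(spec$seed + i, sample(seq_along(library), min(6, length(library)))),
        i)]
      hits_str[[i]] <- make_template_hits(structures[[i]], c(library[i], decoys),
                                          spec, high_range = c(0.65, 0.95),
                                          salt = 1L)
      hits_seq[[i]] <- make_template_hits(structures[[i]], c(library[i], decoys),
                                          spec, high_range = c(0.88, 0.97),
                                          salt = 2L)
    }
  } else {
    for (i in seq_along(ids)) { hits_str[[i]] <- list(); hits_seq[[i]] <- list() }
  }

  structure(list(structures = structures, annotations = annotations,
                 msas = msas, pssms = pssms,
                 hits_str = hits_str, hits_seq = hits_seq,
                 template_structures = template_structures,
                 template_annotations = template_annotations,
                 template_lengths = template_lengths,
                 template_source = template_source, spec = spec),
            class = "cr_benchmark")
}

#' @export
print.cr_benchmark <- function(x, ...) {
  cat(sprintf("<cr_benchmark> %d structures (seed %d), %d templates\n",
              length(x$structures), x$spec$seed, length(x$template_structures)))
  invisible(x)
}

#' Write a benchmark to a self-contained directory
#'
#' Layout: `pdb/<id>.pdb`, `templates/<id>.pdb`, `msa/<id>.fasta`,
#' `pssm/<id>.pssm`, `annotations.tsv`, `template_annotations.tsv`,
#' `hits_str.tsv`, `hits_seq.tsv`, `manifest.json`.
#'
#' @param benchmark a [make_benchmark()] object.
#' @param dir output directory (created if needed).
#' @export
write_benchmark <- function(benchmark, dir) {
  for (d in c("", "pdb", "templates", "msa", "pssm"))
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  for (st in benchmark$structures)
    write_structure_pdb(st, file.path(dir, "pdb", paste0(st$id, ".pdb")))
  for (st in benchmark$template_structures)
    write_structure_pdb(st, file.path(dir, "templates", paste0(st$id, ".pdb")))
  for (i in seq_along(benchmark$structures)) {
    id <- benchmark$structures[[i]]$id
    write_msa(benchmark$msas[[i]], file.path(dir, "msa", paste0(id, ".fasta")))
    write_pssm(benchmark$pssms[[i]], file.path(dir, "pssm", paste0(id, ".pssm")))
  }
  write_annotations(benchmark$annotations, file.path(dir, "annotations.tsv"))
  tmpl_ann <- lapply(names(benchmark$template_annotations), function(id)
    cr_annotation(id, benchmark$template_annotations[[id]]))
  write_annotations(tmpl_ann, file.path(dir, "template_annotations.tsv"))
  write_template_hits(benchmark$hits_str, file.path(dir, "hits_str.tsv"))
  write_template_hits(benchmark$hits_seq, file.path(dir, "hits_seq.tsv"))
  jsonlite::write_json(
    list(n_structures = length(benchmark$structures),
         seed = benchmark$spec$seed,
         template_source = as.list(benchmark$template_source)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a benchmark directory written by [write_benchmark()]
#' @param dir benchmark directory.
#' @return a `cr_benchmark` object (template structures are not reloaded).
#' @export
read_benchmark <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  ids <- names(ann)
  structures <- lapply(ids, function(id) {
    st <- read_structure(file.path(dir, "pdb", paste0(id, ".pdb")), chain = "A")
    st$id <- id
    st
  })
  msas <- lapply(ids, function(id) read_msa(file.path(dir, "msa", paste0(id, ".fasta"))))
  pssms <- lapply(ids, function(id) read_pssm(file.path(dir, "pssm", paste0(id, ".pssm"))))
  tmpl <- read_annotations(file.path(dir, "template_annotations.tsv"))
  template_annotations <- lapply(tmpl, function(a) a$catalytic_indices)
  hits_str <- read_template_hits(file.path(dir, "hits_str.tsv"))
  hits_seq <- read_template_hits(file.path(dir, "hits_seq.tsv"))
  structure(list(structures = structures, annotations = ann[ids],
                 msas = msas, pssms = pssms,
                 hits_str = hits_str[ids], hits_seq = hits_seq[ids],
                 template_structures = NULL,
                 template_annotations = template_annotations,
                 template_lengths = NULL,
                 template_source = unlist(manifest$template_source),
                 spec = NULL),
            class = "cr_benchmark")
}
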