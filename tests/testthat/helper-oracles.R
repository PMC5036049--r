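# Shared fixtures and independent oracles used across the suite.

# a random multi-residue "structure" with one pseudo-atom cloud per
# residue, for tessellation/contact-graph tests
rand_structure <- function(n_res, atoms_per_res = 3, seed = 1, sd = 6) {
  set.seed(seed)
  aa <- sample(AA_ALPHABET, n_res, replace = TRUE)
  centers <- matrix(rnorm(3 * n_res, sd = sd), ncol = 3)
  rows <- list()
  for (r in seq_len(n_res)) {
    k <- atoms_per_res
    pos <- sweep(matrix(rnorm(3 * k, sd = 1), ncol = 3), 2, centers[r, ], "+")
    rows[[r]] <- data.frame(res = r,
                            name = c("CA", paste0("C", seq_len(k - 1)))[seq_len(k)],
                            element = "C",
                            x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  cr_structure(paste0("rnd", seed, "_", n_res), aa, do.call(rbind, rows),
               centers)
}

# minimal structure from bare CA coordinates (one atom per residue)
ca_structure <- function(ca, id = "ca_fix") {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  atoms <- data.frame(res = seq_len(n), name = "CA", element = "C",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3])
  cr_structure(id, rep("A", n), atoms, ca)
}

# explicit Voronoi ridge oracle: brute-force empty-circumsphere
# enumeration of atom 4-subsets (numpy); returns a 2-column matrix of
# 1-based atom pairs. `point_sets` is a list of n x 3 matrices.
oracle_voronoi_pairs <- function(point_sets) {
  script <- system.file("oracle", "voronoi_pairs.py", package = "crhunter")
  paths <- vapply(seq_along(point_sets), function(i) {
    p <- tempfile(fileext = ".txt")
    write.table(point_sets[[i]], p, row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  out <- system2("python", c(script, paths), stdout = TRUE)
  on.exit(unlink(paths))
  heads <- grep("^## ", out)
  res <- vector("list", length(point_sets))
  bounds <- c(heads, length(out) + 1)
  for (k in seq_along(heads)) {
    block <- out[seq(bounds[k] + 1, bounds[k + 1] - 1)]
    block <- block[nzchar(block)]
    m <- if (length(block))
      do.call(rbind, lapply(strsplit(block, " ", fixed = TRUE), as.integer))
    else matrix(integer(0), 0, 2)
    res[[k]] <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  res
}

# inter-residue facet counts recomputed by direct enumeration of the six
# edges of every tetrahedron (independent of the contact_graph code path)
oracle_facet_counts <- function(tess) {
  pairs <- list()
  comb <- utils::combn(4, 2)
  for (t in seq_len(nrow(tess$simplices))) {
    v <- tess$simplices[t, ]
    for (k in 1:6) {
      a <- v[comb[1, k]]; b <- v[comb[2, k]]
      pairs[[length(pairs) + 1]] <- c(min(a, b), max(a, b))
    }
  }
  e <- unique(do.call(rbind, pairs))
  ri <- tess$atom_res[e[, 1]]; rj <- tess$atom_res[e[, 2]]
  keep <- ri != rj
  key <- paste(pmin(ri, rj)[keep], pmax(ri, rj)[keep])
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  df <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                   count = as.integer(tab))
  df[order(df$i, df$j), ]
}

# brute-force network centralities: Floyd-Warshall distances and path
# counting, triangle enumeration for clustering
oracle_centralities <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]

  # shortest-path counts sigma[s, t]
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(A[, t] & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  deg <- rowSums(A)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- if (n > 2) tot * 2 / ((n - 1) * (n - 2)) else 0
  }
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, numeric(1))
  clu <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k))
      if (A[nb[a], nb[b]]) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
  data.frame(degree = deg, closeness = clo, betweenness = btw, clustering = clu)
}

# O(n^2) AUC: fraction of positive-negative pairs ranked correctly,
# ties counting one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# build a contact-graph object directly from a facet table (for feeding
# arbitrary graphs into network_features)
graph_from_facets <- function(n, facets) {
  structure(list(n_residues = n, facets = facets), class = "cr_contact_graph")
}

# a tiny deterministic benchmark shared by slower tests
small_benchmark <- function(n = 8, seed = 7, ...) {
  make_benchmark(fixture_spec(n_structures = n, seed = seed, ...))
}
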