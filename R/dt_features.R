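# Microenvironment score on the Delaunay contact graph and residue
# interaction network centralities.

#' Residue-pair frequency matrix of one residue's microenvironment
#'
#' Row `m` (the type of the query residue) holds the counts of each
#' neighbor type in the facet-count microenvironment; all other rows are
#' zero. Flattened, this is the 400-entry pair frequency vector that the
#' microenvironment score contracts against the pair weight matrix.
#'
#' @param structure a [cr_structure()].
#' @param graph the matching [contact_graph()].
#' @param residue 1-based residue index.
#' @param cutoff minimum shared-facet count (default 9).
#' @return 20 x 20 matrix (query type x neighbor type, alphabetical).
#' @export
pair_frequency <- function(structure, graph, residue, cutoff = 9) {
  env <- microenvironment(graph, residue, cutoff)
  f <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m <- structure$aa[residue]
  if (nrow(env)) {
    tab <- table(factor(structure$aa[env$neighbor], levels = AA_ALPHABET))
    f[m, ] <- as.numeric(tab)
  }
  f
}

# default pair weighting: pair count normalized by smoothed marginal type
# counts of the neighborhood, W(m,n) = N_mn / ((N_m + pc) (N_n + pc))
default_pair_weight <- function(pair_counts, type_counts, m, pseudocount) {
  w <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  nm <- type_counts[m] + pseudocount
  w[m, ] <- pair_counts / (nm * (type_counts + pseudocount))
  w
}

#' Train the residue-pair weight matrix from catalytic neighborhoods
#'
#' For each catalytic residue of type `m` with a non-empty
#' microenvironment, a weight matrix is formed whose row `m` holds
#' `N_mn / ((N_m + pc) * (N_n + pc))`, where `N_mn` is the count of
#' neighbors of type `n` and `N_m`, `N_n` are the type counts in the
#' neighborhood (query residue included by default). The overall weight
#' matrix is the elementwise mean over all catalytic residues. Catalytic
#' residues with empty neighborhoods are skipped and counted.
#'
#' @param structures list of [cr_structure()] objects.
#' @param graphs list of matching [contact_graph()] objects.
#' @param annotations list of [cr_annotation()] objects (same order).
#' @param cutoff minimum shared-facet count (default 9).
#' @param pseudocount additive smoothing for the marginal counts
#'   (default 0.5).
#' @param weight_fun optional alternative weighting
#'   `function(pair_counts, type_counts, m, pseudocount)` returning a
#'   20 x 20 matrix, replacing the default normalization.
#' @param include_query whether the query residue itself enters the
#'   neighborhood type counts (default TRUE).
#' @return object of class `cr_pair_weights` with fields `values`
#'   (20 x 20), `n_catalytic`, `n_skipped`.
#' @export
train_pair_weights <- function(structures, graphs, annotations, cutoff = 9,
                               pseudocount = 0.5, weight_fun = NULL,
                               include_query = TRUE) {
  if (is.null(weight_fun)) weight_fun <- default_pair_weight
  acc <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  used <- 0L; skipped <- 0L
  for (s in seq_along(structures)) {
    st <- structures[[s]]; gr <- graphs[[s]]; an <- annotations[[s]]
    for (r in an$catalytic_indices) {
      if (r > n_residues(st)) stop("annotation index ", r, " exceeds chain length")
      env <- microenvironment(gr, r, cutoff)
      if (nrow(env) == 0) { skipped <- skipped + 1L; next }
      m <- st$aa[r]
      nb_types <- factor(st$aa[env$neighbor], levels = AA_ALPHABET)
      pair_counts <- as.numeric(table(nb_types))
      names(pair_counts) <- AA_ALPHABET
      members <- c(if (include_query) m, st$aa[env$neighbor])
      type_counts <- as.numeric(table(factor(members, levels = AA_ALPHABET)))
      names(type_counts) <- AA_ALPHABET
      acc <- acc + weight_fun(pair_counts, type_counts, m, pseudocount)
      used <- used + 1L
    }
  }
  if (used == 0L) stop("no catalytic residue with a non-empty microenvironment")
  structure(list(values = acc / used, n_catalytic = used, n_skipped = skipped),
            class = "cr_pair_weights")
}

#' @export
print.cr_pair_weights <- function(x, ...) {
  cat(sprintf("<cr_pair_weights> averaged over %d catalytic residues (%d skipped)\n",
              x$n_catalytic, x$n_skipped))
  invisible(x)
}

#' Microenvironment score of one residue
#'
#' Inner product of the residue's pair frequency matrix with the trained
#' pair weight matrix.
#'
#' @param fvec 20 x 20 pair frequency matrix from [pair_frequency()].
#' @param weights a [train_pair_weights()] result (or bare 20 x 20 matrix).
#' @return scalar microenvironment score.
#' @export
me_score <- function(fvec, weights) {
  w <- if (inherits(weights, "cr_pair_weights")) weights$values else weights
  if (!all(dim(fvec) == c(20, 20)) || !all(dim(w) == c(20, 20)))
    stop("incompatible shapes: expected 20 x 20 matrices")
  sum(fvec * w)
}

#' Microenvironment scores for every residue of a structure
#'
#' @inheritParams pair_frequency
#' @param weights a [train_pair_weights()] result.
#' @return numeric vector of per-residue scores.
#' @export
me_scores <- function(structure, graph, weights, cutoff = 9) {
  vapply(seq_len(n_residues(structure)), function(r)
    me_score(pair_frequency(structure, graph, r, cutoff), weights),
    numeric(1))
}

#' Residue interaction network centralities
#'
#' Builds the residue network at the given facet-count cutoff and returns
#' per-residue degree, closeness (Wasserman-Faust correction for
#' disconnected graphs: `(r / sum of distances) * (r / (n - 1))` with `r`
#' the number of reachable vertices), betweenness (shortest-path
#' betweenness normalized by `2 / ((n - 1) (n - 2))`), and local
#' clustering coefficient (`2 * triangles / (k (k - 1))`, zero when
#' degree < 2). Isolated residues score zero on all measures.
#'
#' @param graph a [contact_graph()] result.
#' @param cutoff minimum shared-facet count for an edge (default 9).
#' @return data frame with columns `degree`, `closeness`, `betweenness`,
#'   `clustering`, one row per residue.
#' @export
network_features <- function(graph, cutoff = 9) {
  n <- graph$n_residues
  ed <- graph_edges(graph, cutoff)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ed)) g <- igraph::add_edges(g, t(ed))
  deg <- igraph::degree(g)

  D <- igraph::distances(g)
  closeness <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d) & d > 0
    r <- sum(reach)
    if (r == 0 || n < 2) return(0)
    (r / sum(d[reach])) * (r / (n - 1))
  }, numeric(1))

  btw <- if (n > 2) igraph::betweenness(g, directed = FALSE, normalized = TRUE)
         else rep(0, n)
  clu <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  clu[deg < 2] <- 0

  data.frame(degree = as.integer(deg), closeness = closeness,
             betweenness = as.numeric(btw), clustering = as.numeric(clu))
}

#' Write a pair weight matrix as TSV
#' @param weights a [train_pair_weights()] result.
#' @param path output path.
#' @export
write_pair_weights <- function(weights, path) {
  m <- weights$values
  df <- data.frame(aa = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair weight matrix from TSV
#' @param path path written by [write_pair_weights()].
#' @return a `cr_pair_weights` object (counts unknown, set to NA).
#' @export
read_pair_weights <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$aa
  if (!identical(rownames(m), AA_ALPHABET) || !identical(colnames(m), AA_ALPHABET))
    stop("malformed pair weight file: expected alphabetical 20 x 20 layout")
  structure(list(values = m, n_catalytic = NA_integer_, n_skipped = NA_integer_),
            class = "cr_pair_weights")
}
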