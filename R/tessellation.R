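# Delaunay tessellation of heavy atoms and the residue contact graph
# weighted by shared Voronoi facet counts.

#' Delaunay tessellation of a structure's heavy atoms
#'
#' Tetrahedralizes all heavy-atom coordinates. Two atoms share a Voronoi
#' facet exactly when they are joined by a Delaunay edge (geometric
#' duality), so the tessellation carries the full atom contact relation.
#' Coordinates are joggled by a small deterministic perturbation (seeded
#' from the structure id) before tessellation, resolving the cospherical
#' degeneracies that are routine at PDB coordinate precision; the joggled
#' points are stored on the result so that any oracle can be fed the exact
#' input used.
#'
#' @param structure a [cr_structure()].
#' @param jitter joggle amplitude in Angstrom (default 1e-6).
#' @return an object of class `cr_tessellation` with fields `points`
#'   (joggled m x 3 coordinates), `atom_res` (residue index per atom),
#'   `simplices` (t x 4 matrix of 1-based atom indices), and `edges`
#'   (e x 2 matrix of unique Delaunay atom pairs, i < j).
#' @export
tessellate <- function(structure, jitter = 1e-6) {
  at <- structure$atoms
  if (nrow(at) < 4)
    stop("tessellation requires at least 4 atoms, got ", nrow(at))
  pts <- as.matrix(at[, c("x", "y", "z")])
  seed <- string_seed(structure$id)
  simp <- NULL
  amp <- jitter
  for (attempt in 1:4) {
    jpts <- with_seed(seed + attempt - 1L, {
      pts + matrix(runif(length(pts), -amp, amp), ncol = 3)
    })
    simp <- tryCatch(.delaunay3d(jpts), error = function(e) NULL)
    if (!is.null(simp)) break
    amp <- amp * 100
  }
  if (is.null(simp))
    stop("tessellation failed: irrecoverably degenerate atom geometry")
  simp <- simp + 1L
  pair_idx <- combn(4, 2)
  e <- matrix(0L, nrow(simp) * 6, 2)
  for (k in 1:6) {
    a <- simp[, pair_idx[1, k]]
    b <- simp[, pair_idx[2, k]]
    e[seq_len(nrow(simp)) + (k - 1) * nrow(simp), ] <-
      cbind(pmin(a, b), pmax(a, b))
  }
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  structure(
    list(points = jpts, atom_res = at$res, simplices = simp, edges = e),
    class = "cr_tessellation")
}

#' @export
print.cr_tessellation <- function(x, ...) {
  cat(sprintf("<cr_tessellation> %d atoms, %d tetrahedra, %d Delaunay edges\n",
              nrow(x$points), nrow(x$simplices), nrow(x$edges)))
  invisible(x)
}

#' Residue contact graph weighted by shared Voronoi facet counts
#'
#' The facet count of a residue pair is the number of heavy-atom pairs
#' (one atom from each residue) that share a Voronoi facet, i.e. that are
#' joined by a Delaunay edge.
#'
#' @param structure the [cr_structure()] the tessellation was built from.
#' @param tess a [tessellate()] result for `structure`.
#' @return an object of class `cr_contact_graph` with fields `n_residues`
#'   and `facets` (data frame `i`, `j`, `count` with `i < j`).
#' @export
contact_graph <- function(structure, tess) {
  if (length(tess$atom_res) != nrow(structure$atoms))
    stop("tessellation was not built from this structure")
  ri <- tess$atom_res[tess$edges[, 1]]
  rj <- tess$atom_res[tess$edges[, 2]]
  inter <- ri != rj
  a <- pmin(ri[inter], rj[inter])
  b <- pmax(ri[inter], rj[inter])
  key <- paste(a, b)
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  facets <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                       count = as.integer(tab))
  facets <- facets[order(facets$i, facets$j), , drop = FALSE]
  rownames(facets) <- NULL
  structure(list(n_residues = n_residues(structure), facets = facets),
            class = "cr_contact_graph")
}

#' @export
print.cr_contact_graph <- function(x, ...) {
  cat(sprintf("<cr_contact_graph> %d residues, %d contacting pairs\n",
              x$n_residues, nrow(x$facets)))
  invisible(x)
}

#' Residue pairs in contact at a facet-count cutoff
#'
#' @param graph a [contact_graph()] result.
#' @param cutoff minimum shared-facet count for an edge (default 9, the
#'   value at which the microenvironment score is most informative).
#' @return two-column integer matrix of residue pairs (i < j).
#' @export
graph_edges <- function(graph, cutoff = 9) {
  f <- graph$facets[graph$facets$count >= cutoff, , drop = FALSE]
  cbind(i = f$i, j = f$j)
}

#' Symmetric facet-count lookup
#'
#' @param graph a [contact_graph()] result.
#' @return an n x n symmetric integer matrix of shared-facet counts
#'   (zero diagonal).
#' @export
facet_matrix <- function(graph) {
  n <- graph$n_residues
  m <- matrix(0L, n, n)
  f <- graph$facets
  m[cbind(f$i, f$j)] <- f$count
  m[cbind(f$j, f$i)] <- f$count
  m
}

#' Microenvironment of a residue
#'
#' Neighbors sharing at least `cutoff` Voronoi facets with the target,
#' sorted by facet count descending with ties broken by residue index
#' ascending (the ordering used to assemble structural feature windows).
#'
#' @param graph a [contact_graph()] result.
#' @param residue 1-based residue index.
#' @param cutoff minimum shared-facet count (default 9).
#' @return data frame with columns `neighbor` and `facets`.
#' @export
microenvironment <- function(graph, residue, cutoff = 9) {
  if (length(residue) != 1 || residue < 1 || residue > graph$n_residues)
    stop("invalid residue index: ", residue)
  if (cutoff < 1) stop("cutoff must be >= 1")
  f <- graph$facets
  sel <- (f$i == residue | f$j == residue) & f$count >= cutoff
  nb <- ifelse(f$i[sel] == residue, f$j[sel], f$i[sel])
  cnt <- f$count[sel]
  ord <- order(-cnt, nb)
  data.frame(neighbor = nb[ord], facets = cnt[ord])
}

#' Dump facet counts to TSV
#' @param graph a [contact_graph()] result.
#' @param path output path.
#' @export
write_facet_counts <- function(graph, path) {
  write.table(graph$facets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
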