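# Multi-scale Laplacian norms: distance from each alpha carbon to the
# Gaussian-weighted center of all other alpha carbons.

# quantile positions of the pairwise CA-distance distribution used as
# scale factors: minimum, 2^-6, 2^-4, 2^-2, maximum
LN_QUANTILES <- c(0, 2^-6, 2^-4, 2^-2, 1)

#' Scale factors from the pairwise alpha-carbon distance distribution
#'
#' Empirical quantiles (linear interpolation between order statistics) of
#' all n(n-1)/2 CA-CA distances at positions 0, 2^-6, 2^-4, 2^-2 and 1.
#' The smallest scale localizes the weighting to nearest neighbors; the
#' largest extends it to the whole chain.
#'
#' @param structure a [cr_structure()].
#' @return named numeric vector of 5 non-decreasing scale factors
#'   (Angstrom), names `q0`, `q2^-6`, `q2^-4`, `q2^-2`, `q1`.
#' @export
scale_factors <- function(structure) {
  if (n_residues(structure) < 2)
    stop("scale factors require at least 2 residues")
  d <- as.numeric(dist(structure$ca))
  q <- quantile(d, probs = LN_QUANTILES, type = 7, names = FALSE)
  setNames(q, c("q0", "q2^-6", "q2^-4", "q2^-2", "q1"))
}

#' Multi-scale Laplacian norms
#'
#' For residue `i` at scale `sigma`, neighbor weights are
#' `w_ij = exp(-||p_i - p_j||^2 / sigma^2)` over all `j != i`; the
#' Laplacian coordinate is `p_i` minus the weighted mean of the neighbor
#' coordinates, and the Laplacian norm is its Euclidean length. Small
#' norms at large scales indicate concave (pocket-like) locations.
#' Weights below 1e-12 are truncated for speed; if every weight
#' underflows (tiny sigma, remote residue) the weighted center degenerates
#' to the nearest neighbor, which is the exact small-sigma limit.
#'
#' @param structure a [cr_structure()].
#' @param sigmas positive scale factors (default [scale_factors()]).
#' @return n x length(sigmas) matrix of Laplacian norms (Angstrom).
#' @export
laplacian_norms <- function(structure, sigmas = scale_factors(structure)) {
  if (any(sigmas <= 0)) stop("scale factors must be positive")
  p <- structure$ca
  n <- nrow(p)
  D2 <- as.matrix(dist(p))^2
  out <- matrix(NA_real_, n, length(sigmas))
  colnames(out) <- names(sigmas) %||% paste0("s", seq_along(sigmas))
  for (k in seq_along(sigmas)) {
    w <- exp(-D2 / sigmas[k]^2)
    diag(w) <- 0
    w[w < 1e-12] <- 0
    sw <- rowSums(w)
    ctr <- matrix(NA_real_, n, 3)
    ok <- sw > 0
    if (any(ok)) ctr[ok, ] <- (w[ok, , drop = FALSE] %*% p) / sw[ok]
    if (any(!ok)) {
      for (i in which(!ok)) {
        d2i <- D2[i, ]; d2i[i] <- Inf
        ctr[i, ] <- p[which.min(d2i), ]
      }
    }
    out[, k] <- sqrt(rowSums((p - ctr)^2))
  }
  out
}

#' Write per-residue Laplacian norms as TSV
#' @param ln matrix from [laplacian_norms()].
#' @param path output path.
#' @export
write_laplacian_norms <- function(ln, path) {
  df <- data.frame(residue = seq_len(nrow(ln)), ln, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
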