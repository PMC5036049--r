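# Sequence-derived descriptors: PSSM ingestion, conservation entropies,
# physicochemical properties, catalytic propensity and window assembly.

# PSI-BLAST's native column order
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the `-out_ascii_pssm` layout: a header line naming the 20
#' amino-acid columns followed by one row per position (`index`, residue
#' letter, 20 log-odds integers, optionally followed by percentages that
#' are ignored). Columns are canonicalized to alphabetical order.
#'
#' @param path path to the PSSM file.
#' @return object of class `cr_pssm`: list with `matrix` (L x 20 log-odds,
#'   alphabetical columns), `sequence` (query letters), `source`.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  hdr <- which(vapply(toks, function(t)
    length(t) >= 20 && all(t[1:20] %in% AA_ALPHABET) &&
      length(unique(t[1:20])) == 20, logical(1)))
  if (length(hdr) == 0) stop("malformed PSSM: no amino-acid header line found")
  order20 <- toks[[hdr[1]]][1:20]
  rows <- list(); seq <- character(0)
  for (li in seq(hdr[1] + 1, length(lines))) {
    t <- toks[[li]]
    if (length(t) == 0) break
    if (is.na(suppressWarnings(as.integer(t[1])))) break
    if (length(t) < 22)
      stop("malformed PSSM row at line ", li, ": expected 20 scores")
    v <- suppressWarnings(as.numeric(t[3:22]))
    if (any(is.na(v)))
      stop("malformed PSSM row at line ", li, ": non-numeric score")
    rows[[length(rows) + 1]] <- v
    seq <- c(seq, t[2])
  }
  if (length(rows) == 0) stop("malformed PSSM: no data rows")
  m <- do.call(rbind, rows)
  colnames(m) <- order20
  m <- m[, AA_ALPHABET, drop = FALSE]
  structure(list(matrix = m, sequence = seq, source = "file"),
            class = "cr_pssm")
}

#' Construct a PSSM object from a matrix
#' @param matrix L x 20 numeric matrix, columns in alphabetical order.
#' @param sequence query letters (optional).
#' @param source provenance tag, `"file"` or `"synthetic"`.
#' @export
cr_pssm <- function(matrix, sequence = NULL, source = "synthetic") {
  if (ncol(matrix) != 20) stop("PSSM must have 20 columns")
  colnames(matrix) <- AA_ALPHABET
  structure(list(matrix = matrix, sequence = sequence, source = source),
            class = "cr_pssm")
}

#' @export
print.cr_pssm <- function(x, ...) {
  cat(sprintf("<cr_pssm> %d positions (%s)\n", nrow(x$matrix), x$source))
  invisible(x)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#' @param pssm a `cr_pssm`.
#' @param path output path.
#' @export
write_pssm <- function(pssm, path) {
  m <- pssm$matrix[, PSIBLAST_ORDER, drop = FALSE]
  seq <- pssm$sequence %||% rep("X", nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed", con)
  writeLines(paste0("            ", paste(sprintf("%6s", PSIBLAST_ORDER), collapse = " ")), con)
  for (i in seq_len(nrow(m)))
    writeLines(sprintf("%5d %s %s", i, seq[i],
                       paste(sprintf("%6.2f", m[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Read an aligned FASTA file as a character matrix
#' @param path FASTA path; sequences must have equal lengths.
#' @return character matrix, one row per sequence, rownames from headers.
#' @export
read_msa <- function(path) {
  fa <- bio3d::read.fasta(path)
  m <- fa$ali
  rownames(m) <- fa$id
  m
}

#' Write an alignment matrix as FASTA
#' @param msa character matrix (rows = sequences).
#' @param path output path.
#' @export
write_msa <- function(msa, path) {
  ids <- rownames(msa) %||% paste0("seq", seq_len(nrow(msa)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(msa))) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(paste(msa[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Per-column conservation scores from a multiple sequence alignment
#'
#' The first sequence is the query; columns where the query has a gap are
#' dropped, so the profile aligns with the query positions. Per column,
#' amino-acid frequencies exclude gaps. Shannon entropy is in bits;
#' relative entropy is the Kullback-Leibler divergence against the
#' background; the Jensen-Shannon divergence uses mixing weight 0.5 and is
#' bounded in [0, 1] (bits). Columns with more than 90% gaps are flagged.
#'
#' @param msa character matrix (rows = aligned sequences) or character
#'   vector of equal-length strings; `-` and `.` are gaps.
#' @param background length-20 background distribution (default uniform).
#' @return object of class `cr_conservation`: data frame with columns
#'   `shannon`, `relative_entropy`, `jsd`, `gappy`.
#' @export
conservation <- function(msa, background = NULL) {
  if (is.character(msa) && is.null(dim(msa))) {
    if (length(unique(nchar(msa))) != 1) stop("aligned sequences differ in length")
    msa <- do.call(rbind, strsplit(msa, ""))
  }
  if (nrow(msa) == 0 || ncol(msa) == 0) stop("empty alignment")
  msa <- toupper(msa)
  bg <- background %||% rep(1 / 20, 20)
  if (length(bg) != 20) stop("background must have 20 entries")
  bg <- bg / sum(bg)
  keep <- !(msa[1, ] %in% c("-", "."))
  msa <- msa[, keep, drop = FALSE]
  L <- ncol(msa)
  sh <- re <- js <- numeric(L)
  gappy <- logical(L)
  xlogy <- function(x, y) ifelse(x > 0, x * log2(x / y), 0)
  for (j in seq_len(L)) {
    col <- msa[, j]
    isgap <- col %in% c("-", ".")
    gappy[j] <- mean(isgap) > 0.9
    col <- col[!isgap & col %in% AA_ALPHABET]
    if (length(col) == 0) { sh[j] <- 0; re[j] <- 0; js[j] <- 0; next }
    p <- as.numeric(table(factor(col, levels = AA_ALPHABET))) / length(col)
    sh[j] <- -sum(xlogy(p, 1))
    re[j] <- sum(xlogy(p, bg))
    m <- (p + bg) / 2
    js[j] <- 0.5 * sum(xlogy(p, m)) + 0.5 * sum(xlogy(bg, m))
  }
  structure(data.frame(shannon = sh, relative_entropy = re, jsd = js,
                       gappy = gappy),
            class = c("cr_conservation", "data.frame"))
}

# synthetic generic prior favouring the residue types enriched at
# catalytic sites (H, D, R, E, K, C, Y); replaced by a trained table
# whenever annotations are available
DEFAULT_PROPENSITY <- local({
  p <- setNames(rep(-0.5, 20), AA_ALPHABET)
  p[c("H", "D", "R", "E", "K", "C", "Y")] <- c(2.0, 1.2, 0.8, 1.0, 0.7, 0.9, 0.6)
  p
})

#' Train per-type catalytic propensity from annotations
#'
#' Log2 ratio of the amino-acid frequency among catalytic residues to the
#' frequency over all residues, with additive smoothing.
#'
#' @param structures list of [cr_structure()] objects.
#' @param annotations matching list of [cr_annotation()] objects.
#' @param pseudocount additive smoothing (default 0.5).
#' @return named length-20 numeric vector (log2 scale).
#' @export
train_propensity <- function(structures, annotations, pseudocount = 0.5) {
  cat_aa <- character(0); all_aa <- character(0)
  for (s in seq_along(structures)) {
    all_aa <- c(all_aa, structures[[s]]$aa)
    cat_aa <- c(cat_aa, structures[[s]]$aa[annotations[[s]]$catalytic_indices])
  }
  nc <- as.numeric(table(factor(cat_aa, levels = AA_ALPHABET))) + pseudocount
  nb <- as.numeric(table(factor(all_aa, levels = AA_ALPHABET))) + pseudocount
  setNames(log2((nc / sum(nc)) / (nb / sum(nb))), AA_ALPHABET)
}

#' Amino-acid background frequencies of a training corpus
#' @inheritParams train_propensity
#' @return named length-20 frequency vector summing to 1.
#' @export
train_background <- function(structures, pseudocount = 0.5) {
  all_aa <- unlist(lapply(structures, function(s) s$aa))
  n <- as.numeric(table(factor(all_aa, levels = AA_ALPHABET))) + pseudocount
  setNames(n / sum(n), AA_ALPHABET)
}

#' Static per-residue sequence descriptors
#'
#' Residue type one-hot encoding, physicochemical scales (Kyte-Doolittle
#' hydropathy, net charge at pH 7, Grantham polarity), catalytic
#' propensity, relative sequential position `i / (L - 1)`, chain length,
#' and the global amino-acid composition (identical for all rows).
#'
#' @param sequence amino-acid string or character vector of letters.
#' @param propensity named length-20 propensity vector (default: generic
#'   synthetic prior; train one with [train_propensity()]).
#' @return numeric matrix (n x 46) with an attribute `feature_class`
#'   labelling each column `binary` or `other`.
#' @export
static_features <- function(sequence, propensity = NULL) {
  aa <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  if (!all(aa %in% AA_ALPHABET))
    stop("non-standard amino acid letter: ",
         paste(unique(aa[!aa %in% AA_ALPHABET]), collapse = ", "))
  prop <- propensity %||% DEFAULT_PROPENSITY
  n <- length(aa)
  onehot <- outer(aa, AA_ALPHABET, "==") * 1
  colnames(onehot) <- paste0("rt_", AA_ALPHABET)
  comp <- as.numeric(table(factor(aa, levels = AA_ALPHABET))) / n
  compm <- matrix(comp, n, 20, byrow = TRUE,
                  dimnames = list(NULL, paste0("aac_", AA_ALPHABET)))
  relpos <- if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n)
  tab <- cbind(onehot,
               hydropathy = unname(HYDROPATHY[aa]),
               charge = unname(CHARGE[aa]),
               polarity = unname(POLARITY[aa]),
               propensity = unname(prop[aa]),
               relpos = relpos,
               length = rep(n, n),
               compm)
  cls <- c(rep("binary", 20), rep("other", 6), rep("other", 20))
  names(cls) <- colnames(tab)
  attr(tab, "feature_class") <- cls
  tab
}

#' Sliding-window feature vector around one position
#'
#' Concatenates the feature rows for positions `center - half_width` to
#' `center + half_width`. Out-of-chain positions are zero-padded and
#' flagged by a per-position terminal-indicator bit (1 = outside the
#' chain).
#'
#' @param per_residue numeric matrix (rows = positions).
#' @param center 1-based center position.
#' @param half_width window half width (window covers `2 * half_width + 1`
#'   positions).
#' @return numeric vector of length `(2 * half_width + 1) * (ncol + 1)`.
#' @export
window_features <- function(per_residue, center, half_width) {
  n <- nrow(per_residue)
  if (center < 1 || center > n) stop("invalid center position: ", center)
  nf <- ncol(per_residue)
  out <- numeric(0)
  for (pos in (center - half_width):(center + half_width)) {
    if (pos < 1 || pos > n) block <- c(rep(0, nf), 1)
    else block <- c(per_residue[pos, ], 0)
    out <- c(out, block)
  }
  offs <- -half_width:half_width
  base <- colnames(per_residue) %||% paste0("f", seq_len(nf))
  names(out) <- unlist(lapply(offs, function(o)
    c(paste0("w", o, "_", base), paste0("w", o, "_term"))))
  out
}
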