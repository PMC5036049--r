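# Structure model: parsed protein chains and catalytic annotations.

#' Construct a protein structure object
#'
#' A `cr_structure` holds one chain: an ordered residue list with heavy-atom
#' coordinates and alpha-carbon positions. Residue indices are 1-based and
#' contiguous; author residue numbers are retained for reporting only.
#'
#' @param id chain identifier string.
#' @param aa character vector of one-letter amino-acid codes.
#' @param atoms data frame with columns `res` (1-based residue index),
#'   `name`, `element`, `x`, `y`, `z`.
#' @param ca n x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @param seq_id integer vector of author residue numbers (optional).
#' @return an object of class `cr_structure` with fields `id`, `aa`,
#'   `sequence`, `atoms`, `ca`, `seq_id`.
#' @export
cr_structure <- function(id, aa, atoms, ca, seq_id = seq_along(aa)) {
  stopifnot(is.character(id), length(id) == 1)
  aa <- as.character(aa)
  if (!all(aa %in% AA_ALPHABET))
    stop("non-standard amino acid code(s): ",
         paste(unique(aa[!aa %in% AA_ALPHABET]), collapse = ", "))
  ca <- as.matrix(ca)
  if (nrow(ca) != length(aa) || ncol(ca) != 3)
    stop("ca must be an n x 3 matrix matching the residue count")
  if (!all(is.finite(ca))) stop("non-finite alpha-carbon coordinates")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (!all(atoms$res >= 1 & atoms$res <= length(aa)))
    stop("atom residue indices out of range")
  structure(
    list(id = id, aa = aa, sequence = paste(aa, collapse = ""),
         atoms = as.data.frame(atoms), ca = unname(ca),
         seq_id = as.integer(seq_id)),
    class = "cr_structure"
  )
}

#' @export
print.cr_structure <- function(x, ...) {
  cat(sprintf("<cr_structure> %s: %d residues, %d heavy atoms\n",
              x$id, length(x$aa), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `cr_structure`.
#' @export
n_residues <- function(structure) length(structure$aa)

#' Read a single protein chain from a PDB file
#'
#' Parses ATOM records (plus MSE/SEC HETATM records, mapped to M/C),
#' drops hydrogens, resolves alternate locations to the highest-occupancy
#' copy (ties broken by altloc label order), and excludes residues lacking
#' an alpha carbon or with a non-standard residue name (with a warning).
#' Only the first model of multi-model files is used.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` takes the first chain in the file.
#' @return a [cr_structure()].
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% c("MSE", "SEC"))
  at <- at[keep, , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  if (!any(at$chain %in% chain, na.rm = TRUE))
    stop("chain '", chain, "' not present in ", path)
  at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]

  # element symbol: prefer the PDB element column, fall back to the first
  # alphabetic character of the atom name
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[^A-Za-z].*$", "",
                            gsub("^[0-9]*", "", at$elety[miss])), 1, 1)
  at$element <- elem
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]

  # altloc resolution: within (residue, atom name), keep highest occupancy,
  # ties broken by altloc label order; file order is preserved
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  key <- paste(at$resno, ins, at$elety, sep = "|")
  pick <- order(key, -occ, alt)
  keep <- sort(pick[!duplicated(key[pick])])
  at <- at[keep, , drop = FALSE]
  ins <- ins[keep]

  reskey <- paste(at$resno, ins, sep = "|")
  ures <- unique(reskey)
  aa1 <- character(0); seq_id <- integer(0); ca <- NULL
  rows <- list(); dropped <- character(0)
  for (rk in ures) {
    sub <- at[reskey == rk, , drop = FALSE]
    code <- AA_321[sub$resid[1]]
    if (is.na(code)) { dropped <- c(dropped, sub$resid[1]); next }
    cai <- which(sub$elety == "CA")
    if (length(cai) == 0) { dropped <- c(dropped, paste0(sub$resid[1], sub$resno[1])); next }
    aa1 <- c(aa1, unname(code))
    seq_id <- c(seq_id, sub$resno[1])
    ca <- rbind(ca, c(sub$x[cai[1]], sub$y[cai[1]], sub$z[cai[1]]))
    rows[[length(rows) + 1]] <- data.frame(
      res = length(aa1), name = sub$elety, element = sub$element,
      x = sub$x, y = sub$y, z = sub$z, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("dropped residues (non-standard or missing CA): ",
            paste(unique(dropped), collapse = ", "))
  if (length(aa1) == 0) stop("no standard residues in chain '", chain, "'")
  atoms <- do.call(rbind, rows)
  id <- paste0(sub("\\.[^.]*$", "", basename(path)), "_", chain)
  cr_structure(id, aa1, atoms, ca, seq_id)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM records (single chain A, occupancy 1, B-factor 0)
#' so that a generated structure can be round-tripped through
#' [read_structure()]. Output bytes are deterministic.
#'
#' @param structure a [cr_structure()].
#' @param path output file path.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  aa3 <- names(AA_321)[match(structure$aa, AA_321[1:20])]
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- character(nrow(at) + 1)
  for (i in seq_len(nrow(at))) {
    r <- at$res[i]
    nm <- at$name[i]
    padded <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    lines[i] <- sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, padded, aa3[r], structure$seq_id[r],
      at$x[i], at$y[i], at$z[i], 1, 0, at$element[i])
  }
  lines[length(lines)] <- "END"
  writeLines(lines, con)
  invisible(path)
}

#' Construct a catalytic annotation
#'
#' @param structure_id identifier of the annotated structure.
#' @param catalytic_indices integer vector of 1-based residue indices.
#' @return an object of class `cr_annotation`.
#' @export
cr_annotation <- function(structure_id, catalytic_indices) {
  idx <- sort(unique(as.integer(catalytic_indices)))
  if (length(idx) && any(idx < 1)) stop("catalytic indices must be >= 1")
  structure(list(structure_id = structure_id, catalytic_indices = idx),
            class = "cr_annotation")
}

#' @export
print.cr_annotation <- function(x, ...) {
  cat(sprintf("<cr_annotation> %s: %d catalytic residues\n",
              x$structure_id, length(x$catalytic_indices)))
  invisible(x)
}

#' Read catalytic annotations from a TSV file
#'
#' One record per line: `structure_id<TAB>i1,i2,...` with 1-based residue
#' indices. Duplicate indices are deduplicated.
#'
#' @param path path to the annotation file.
#' @return a named list of [cr_annotation()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed annotation line ", ln, ": expected 2 tab-separated fields")
    idx <- suppressWarnings(as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
    if (any(is.na(idx)))
      stop("malformed annotation line ", ln, ": non-integer residue index")
    out[[parts[1]]] <- cr_annotation(parts[1], idx)
  }
  out
}

#' Write catalytic annotations to a TSV file
#' @param annotations list of [cr_annotation()] objects.
#' @param path output file path.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(annotations, function(a)
    paste0(a$structure_id, "\t", paste(a$catalytic_indices, collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
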