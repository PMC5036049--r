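# Feature scaling: PSSM columns through the logistic function, other
# non-binary columns through Z-score + logistic, binary columns untouched.

#' Scale a feature table to (0, 1)
#'
#' PSSM (log-odds) columns are mapped by the logistic function; all other
#' non-binary columns are standardized with training mean and standard
#' deviation and then mapped by the logistic function; binary columns pass
#' through. Zero-variance columns map to the constant 0.5. When `stats`
#' is supplied (prediction time), its training means and standard
#' deviations are reused; otherwise they are computed from `table`.
#'
#' @param table numeric matrix with named columns.
#' @param pssm_columns character vector of PSSM column names.
#' @param binary_columns character vector of binary column names.
#' @param stats optional list `(mean, sd)` from a previous call.
#' @return list with `table` (scaled matrix) and `stats`.
#' @export
scale_features <- function(table, pssm_columns = character(0),
                           binary_columns = character(0), stats = NULL) {
  cn <- colnames(table)
  if (is.null(cn)) stop("feature table must have column names")
  unknown <- setdiff(c(pssm_columns, binary_columns), cn)
  if (length(unknown))
    stop("unknown column(s) in sets: ", paste(unknown, collapse = ", "))
  other <- setdiff(cn, c(pssm_columns, binary_columns))

  out <- table
  if (length(pssm_columns))
    out[, pssm_columns] <- logistic(table[, pssm_columns, drop = FALSE])

  if (is.null(stats)) {
    mu <- apply(table[, other, drop = FALSE], 2, mean)
    sg <- apply(table[, other, drop = FALSE], 2, sd)
    stats <- list(mean = mu, sd = sg)
  }
  if (length(other)) {
    mu <- stats$mean[other]; sg <- stats$sd[other]
    zerovar <- !is.finite(sg) | sg == 0
    z <- sweep(table[, other, drop = FALSE], 2, mu, "-")
    z <- sweep(z, 2, ifelse(zerovar, 1, sg), "/")
    z[, zerovar] <- 0
    out[, other] <- logistic(z)
  }
  list(table = out, stats = stats)
}

# derive the column-class sets from a feature_class attribute
feature_class_sets <- function(cls) {
  list(pssm = names(cls)[cls == "pssm"],
       binary = names(cls)[cls == "binary"])
}
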