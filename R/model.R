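# The fitted predictor: crhunter() trains the pair weight matrix, the
# catalytic propensity, the feature scalers and the two SVMs; predict()
# scores a query and fuses the four component predictors.

# compute all per-residue feature channels for one structure
featurize_structure <- function(structure, pssm, msa, weights, propensity,
                                background, config, facet_cutoff) {
  tess <- tessellate(structure)
  graph <- contact_graph(structure, tess)
  me <- me_scores(structure, graph, weights, facet_cutoff)
  netf <- network_features(graph, facet_cutoff)
  ln <- laplacian_norms(structure)
  cons <- conservation(msa, background)
  static <- static_features(structure$aa, propensity)
  xs <- build_structural_vectors(structure, graph, me, netf, ln, pssm,
                                 window = config$window_structure,
                                 cutoff = facet_cutoff)
  xq <- build_sequence_vectors(structure, pssm, cons, static,
                               window = config$window_sequence)
  list(str = xs, seq = xq)
}

#' Fit a catalytic-residue prediction model
#'
#' Trains, on a set of annotated structures: the residue-pair weight
#' matrix of the microenvironment score, the catalytic propensity and
#' background frequencies, the feature scaling statistics, and the two
#' calibrated RBF SVM feature predictors (structural and sequence).
#' Template transfer requires no training; template hits are supplied at
#' prediction time.
#'
#' @param structures list of [cr_structure()] objects.
#' @param annotations list of [cr_annotation()] objects (same order).
#' @param pssms list of `cr_pssm` objects (same order).
#' @param msas list of alignment matrices (same order, query first row).
#' @param config an [svm_config()].
#' @param fusion a [fusion_config()].
#' @param facet_cutoff minimum shared Voronoi facets for a contact
#'   (default 9).
#' @param pseudocount additive smoothing for pair weights and propensity.
#' @return an object of class `crhunter`.
#' @export
crhunter <- function(structures, annotations, pssms, msas,
                     config = svm_config(), fusion = fusion_config(),
                     facet_cutoff = 9, pseudocount = 0.5) {
  ns <- length(structures)
  stopifnot(ns >= 1, length(annotations) == ns, length(pssms) == ns,
            length(msas) == ns)
  graphs <- vector("list", ns)
  for (s in seq_len(ns))
    graphs[[s]] <- contact_graph(structures[[s]], tessellate(structures[[s]]))
  weights <- train_pair_weights(structures, graphs, annotations,
                                cutoff = facet_cutoff,
                                pseudocount = pseudocount)
  propensity <- train_propensity(structures, annotations, pseudocount)
  background <- train_background(structures, pseudocount)

  xs_list <- vector("list", ns); xq_list <- vector("list", ns)
  labels <- vector("list", ns)
  cls_str <- cls_seq <- NULL
  for (s in seq_len(ns)) {
    feats <- featurize_structure(structures[[s]], pssms[[s]], msas[[s]],
                                 weights, propensity, background,
                                 config, facet_cutoff)
    xs_list[[s]] <- feats$str
    xq_list[[s]] <- feats$seq
    cls_str <- cls_str %||% attr(feats$str, "feature_class")
    cls_seq <- cls_seq %||% attr(feats$seq, "feature_class")
    lab <- integer(n_residues(structures[[s]]))
    lab[annotations[[s]]$catalytic_indices] <- 1L
    labels[[s]] <- lab
  }
  xs <- do.call(rbind, xs_list)
  xq <- do.call(rbind, xq_list)
  y <- unlist(labels)

  sets_str <- feature_class_sets(cls_str)
  sets_seq <- feature_class_sets(cls_seq)
  sc_str <- scale_features(xs, sets_str$pssm, sets_str$binary)
  sc_seq <- scale_features(xq, sets_seq$pssm, sets_seq$binary)

  svm_str <- train_feature_predictor(sc_str$table, y, config)
  svm_seq <- train_feature_predictor(sc_seq$table, y, config)

  structure(list(
    weights = weights, propensity = propensity, background = background,
    scaler_str = sc_str$stats, scaler_seq = sc_seq$stats,
    class_str = cls_str, class_seq = cls_seq,
    svm_str = svm_str, svm_seq = svm_seq,
    config = config, fusion = fusion, facet_cutoff = facet_cutoff,
    n_structures = ns, n_residues = length(y), n_catalytic = sum(y)),
    class = "crhunter")
}

#' @export
print.crhunter <- function(x, ...) {
  cat(sprintf(paste0("<crhunter> fitted on %d structures ",
                     "(%d residues, %d catalytic)\n"),
              x$n_structures, x$n_residues, x$n_catalytic))
  cat(sprintf("  facet cutoff %d; SVM C=%g gamma=%g ratio 1:%g\n",
              x$facet_cutoff, x$config$C, x$config$gamma,
              x$config$neg_pos_ratio))
  cat(sprintf("  fusion alpha=%.2f (SP>=%.2f), beta=%.2f (HH>=%.2f), gamma=%.2f\n",
              x$fusion$alpha, x$fusion$sp_cutoff, x$fusion$beta,
              x$fusion$hh_cutoff, x$fusion$gamma))
  invisible(x)
}

#' @export
summary.crhunter <- function(object, ...) {
  print(object)
  w <- object$weights$values
  rs <- sort(rowSums(w), decreasing = TRUE)
  cat("  strongest pair-weight rows (query residue types): ",
      paste(names(head(rs, 7)), collapse = " "), "\n")
  p <- sort(object$propensity, decreasing = TRUE)
  cat("  highest catalytic propensity: ",
      paste(names(head(p, 7)), collapse = " "), "\n")
  invisible(object)
}

#' Score the residues of a query structure
#'
#' Computes the two feature predictor probabilities, transfers
#' annotations from the top structure and profile templates, fuses each
#' channel (template gated by its similarity cutoff) and blends the two
#' channels into the final score.
#'
#' @param object a fitted [crhunter()] model.
#' @param structure query [cr_structure()].
#' @param pssm query `cr_pssm`.
#' @param msa query alignment matrix (query first row).
#' @param hits_str list of [template_hit()] from structure alignment.
#' @param hits_seq list of [template_hit()] from profile alignment.
#' @param template_annotations named list: template id -> catalytic indices.
#' @param template_lengths optional named template lengths for validation.
#' @param ... unused.
#' @return data frame with one row per residue: `index`, `aa`,
#'   `fscore_str`, `tscore_str`, `fscore_seq`, `tscore_seq`, `strhunter`,
#'   `seqhunter`, `crhunter`.
#' @export
predict.crhunter <- function(object, structure, pssm, msa,
                             hits_str = list(), hits_seq = list(),
                             template_annotations = list(),
                             template_lengths = NULL, ...) {
  feats <- featurize_structure(structure, pssm, msa, object$weights,
                               object$propensity, object$background,
                               object$config, object$facet_cutoff)
  sets_str <- feature_class_sets(object$class_str)
  sets_seq <- feature_class_sets(object$class_seq)
  xs <- scale_features(feats$str, sets_str$pssm, sets_str$binary,
                       stats = object$scaler_str)$table
  xq <- scale_features(feats$seq, sets_seq$pssm, sets_seq$binary,
                       stats = object$scaler_seq)$table
  fscore_str <- predict(object$svm_str, xs)
  fscore_seq <- predict(object$svm_seq, xq)

  n <- n_residues(structure)
  tp_str <- template_predict(n, hits_str, template_annotations, template_lengths)
  tp_seq <- template_predict(n, hits_seq, template_annotations, template_lengths)

  strhunter <- fuse(fscore_str, tp_str$scores, tp_str$best_similarity,
                    object$fusion$alpha, object$fusion$sp_cutoff)
  seqhunter <- fuse(fscore_seq, tp_seq$scores, tp_seq$best_similarity,
                    object$fusion$beta, object$fusion$hh_cutoff)
  final <- crhunter_score(strhunter, seqhunter, object$fusion$gamma)

  data.frame(index = seq_len(n), aa = structure$aa,
             fscore_str = fscore_str, tscore_str = tp_str$scores,
             fscore_seq = fscore_seq, tscore_seq = tp_seq$scores,
             strhunter = strhunter, seqhunter = seqhunter,
             crhunter = final)
}

#' Write per-residue scores as TSV
#' @param scores data frame from [predict.crhunter()].
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 12, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
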