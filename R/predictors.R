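# Feature predictors (RBF SVMs with class rebalancing and seeded Platt
# calibration), structural/sequence vector assembly, and score fusion.

#' SVM predictor configuration
#'
#' Defaults are the method's standard operating point: RBF kernel with C = 2
#' and gamma = 2^-5 = 0.03125, negatives subsampled to 6 per positive,
#' structural window of 4 microenvironment neighbors and sequence window
#' half-width 9 (19 positions).
#'
#' @param C soft-margin cost (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param neg_pos_ratio negatives kept per positive during training (>= 1).
#' @param window_structure number of top facet-count neighbors appended to
#'   the target block.
#' @param window_sequence sliding-window half-width.
#' @param seed seed for negative subsampling and calibration folds.
#' @return list of class `cr_svm_config`.
#' @export
svm_config <- function(C = 2, gamma = 0.03125, neg_pos_ratio = 6,
                       window_structure = 4, window_sequence = 9, seed = 1) {
  stopifnot(C > 0, gamma > 0, neg_pos_ratio >= 1,
            window_structure >= 0, window_sequence >= 0)
  structure(list(C = C, gamma = gamma, neg_pos_ratio = neg_pos_ratio,
                 window_structure = window_structure,
                 window_sequence = window_sequence, seed = as.integer(seed)),
            class = "cr_svm_config")
}

#' Fusion configuration
#'
#' Default weights and reliability cutoffs: within the structural
#' channel the feature and template scores are blended with alpha = 0.55
#' when the structure-alignment score reaches 0.6; within the sequence
#' channel with beta = 0.57 when the profile-alignment score reaches
#' 0.87; the two channels are then blended with equal weight gamma = 0.5.
#'
#' @param alpha structural-channel feature weight in [0, 1].
#' @param sp_cutoff structure-alignment reliability cutoff.
#' @param beta sequence-channel feature weight in [0, 1].
#' @param hh_cutoff profile-alignment reliability cutoff.
#' @param gamma structural-channel weight in the final blend.
#' @return list of class `cr_fusion_config`.
#' @export
fusion_config <- function(alpha = 0.55, sp_cutoff = 0.6, beta = 0.57,
                          hh_cutoff = 0.87, gamma = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            gamma >= 0, gamma <= 1, is.finite(sp_cutoff), is.finite(hh_cutoff))
  structure(list(alpha = alpha, sp_cutoff = sp_cutoff, beta = beta,
                 hh_cutoff = hh_cutoff, gamma = gamma),
            class = "cr_fusion_config")
}

# per-residue structural feature block: microenvironment score, four
# network centralities, five Laplacian norms, 20 PSSM log-odds
structural_block <- function(me, netf, ln, pssm) {
  tab <- cbind(me = me,
               degree = netf$degree, closeness = netf$closeness,
               betweenness = netf$betweenness, clustering = netf$clustering,
               ln,
               pssm)
  colnames(tab) <- c("me", "degree", "closeness", "betweenness", "clustering",
                     paste0("ln_", seq_len(ncol(ln))),
                     paste0("pssm_", AA_ALPHABET))
  tab
}

#' Assemble per-residue structural SVM vectors
#'
#' Each residue's vector is its own feature block followed by the blocks
#' of its `window` highest-facet-count microenvironment neighbors (in
#' [microenvironment()] order); missing neighbor slots are zero-padded and
#' flagged by an indicator bit.
#'
#' @param structure a [cr_structure()].
#' @param graph the matching [contact_graph()].
#' @param me per-residue microenvironment scores ([me_scores()]).
#' @param netf per-residue network features ([network_features()]).
#' @param ln per-residue Laplacian norms ([laplacian_norms()]).
#' @param pssm a `cr_pssm` aligned with the chain.
#' @param window number of neighbor blocks (default 4).
#' @param cutoff facet-count cutoff for the microenvironment (default 9).
#' @return numeric matrix (n x (30 + window * 31)) with a `feature_class`
#'   attribute labelling columns `pssm`, `binary` or `other`.
#' @export
build_structural_vectors <- function(structure, graph, me, netf, ln, pssm,
                                     window = 4, cutoff = 9) {
  n <- n_residues(structure)
  if (nrow(pssm$matrix) != n)
    stop("PSSM length does not match the chain (", nrow(pssm$matrix),
         " vs ", n, ")")
  if (length(me) != n || nrow(netf) != n || nrow(ln) != n)
    stop("feature channel length mismatch")
  blk <- structural_block(me, netf, ln, pssm$matrix)
  nb <- ncol(blk)
  out <- matrix(0, n, nb + window * (nb + 1))
  base <- colnames(blk)
  cn <- c(paste0("t_", base),
          unlist(lapply(seq_len(window), function(k)
            c(paste0("nb", k, "_", base), paste0("nb", k, "_pad")))))
  colnames(out) <- cn
  for (r in seq_len(n)) {
    env <- microenvironment(graph, r, cutoff)
    v <- blk[r, ]
    for (k in seq_len(window)) {
      if (k <= nrow(env)) v <- c(v, blk[env$neighbor[k], ], 0)
      else v <- c(v, rep(0, nb), 1)
    }
    out[r, ] <- v
  }
  cls <- rep("other", ncol(out))
  names(cls) <- cn
  cls[grepl("_pssm_", cn)] <- "pssm"
  cls[grepl("_pad$", cn)] <- "binary"
  attr(out, "feature_class") <- cls
  out
}

#' Assemble per-residue sequence SVM vectors
#'
#' The sliding window (half-width `window`) concatenates per-position
#' blocks of PSSM log-odds, conservation scores (Shannon, relative
#' entropy, Jensen-Shannon), residue one-hot, physicochemical scales and
#' catalytic propensity; chain-level descriptors (relative position,
#' length, composition) are appended once for the center residue.
#'
#' @param structure a [cr_structure()] (only the sequence is used).
#' @param pssm a `cr_pssm` aligned with the chain.
#' @param cons a [conservation()] profile aligned with the chain.
#' @param static per-residue table from [static_features()].
#' @param window sliding-window half-width (default 9).
#' @return numeric matrix with a `feature_class` attribute.
#' @export
build_sequence_vectors <- function(structure, pssm, cons, static, window = 9) {
  n <- n_residues(structure)
  if (nrow(pssm$matrix) != n || nrow(cons) != n || nrow(static) != n)
    stop("feature channel length mismatch")
  percol <- cbind(pssm$matrix,
                  shannon = cons$shannon, re = cons$relative_entropy,
                  jsd = cons$jsd,
                  static[, c(paste0("rt_", AA_ALPHABET), "hydropathy",
                             "charge", "polarity", "propensity")])
  colnames(percol)[1:20] <- paste0("pssm_", AA_ALPHABET)
  global <- static[, c("relpos", "length", paste0("aac_", AA_ALPHABET)), drop = FALSE]
  wmat <- t(vapply(seq_len(n), function(r)
    window_features(percol, r, window), numeric((2 * window + 1) * (ncol(percol) + 1))))
  out <- cbind(wmat, global)
  cn <- colnames(out)
  cls <- rep("other", ncol(out))
  names(cls) <- cn
  cls[grepl("_pssm_", cn)] <- "pssm"
  cls[grepl("_rt_", cn) | grepl("_term$", cn)] <- "binary"
  attr(out, "feature_class") <- cls
  out
}

#' Train a calibrated RBF SVM feature predictor
#'
#' Negatives are subsampled uniformly at random (seeded) to
#' `neg_pos_ratio` negatives per positive; an RBF SVM is trained on the
#' balanced subsample; probabilities are calibrated by Platt scaling (a
#' logistic fit to out-of-fold decision values from a seeded 5-fold split
#' of the training subsample).
#'
#' @param x scaled feature matrix (rows = residues).
#' @param y binary labels (1 = catalytic).
#' @param config an [svm_config()].
#' @return object of class `cr_svm`: the fitted SVM, Platt coefficients
#'   and the subsample row indices.
#' @export
train_feature_predictor <- function(x, y, config = svm_config()) {
  y <- as.integer(y)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0) stop("no positive examples")
  nneg <- min(length(neg), ceiling(length(pos) * config$neg_pos_ratio))
  keep_neg <- with_seed(config$seed, sort(sample(neg, nneg)))
  idx <- c(pos, keep_neg)
  xs <- x[idx, , drop = FALSE]
  ys <- factor(y[idx], levels = c(0, 1))

  fit <- e1071::svm(xs, ys, kernel = "radial", cost = config$C,
                    gamma = config$gamma, scale = FALSE)

  # seeded Platt calibration on out-of-fold decision values
  nfold <- 5
  folds <- with_seed(config$seed + 1L, sample(rep_len(seq_len(nfold), nrow(xs))))
  dv <- numeric(nrow(xs))
  for (f in seq_len(nfold)) {
    tr <- folds != f
    if (length(unique(ys[tr])) < 2) { dv[!tr] <- 0; next }
    sub <- e1071::svm(xs[tr, , drop = FALSE], ys[tr], kernel = "radial",
                      cost = config$C, gamma = config$gamma, scale = FALSE)
    p <- predict(sub, xs[!tr, , drop = FALSE], decision.values = TRUE)
    d <- attr(p, "decision.values")[, 1]
    # orient decision values as "positive class high" regardless of the
    # level order libsvm happened to use
    if (grepl("^0/", colnames(attr(p, "decision.values"))[1])) d <- -d
    dv[!tr] <- d
  }
  platt <- suppressWarnings(
    glm((ys == "1") ~ dv, family = binomial()))

  structure(list(fit = fit, platt = coef(platt), subsample = idx,
                 config = config, n_features = ncol(x)),
            class = "cr_svm")
}

#' @export
print.cr_svm <- function(x, ...) {
  cat(sprintf("<cr_svm> %d support vectors, %d features, C=%g gamma=%g\n",
              x$fit$tot.nSV, x$n_features, x$config$C, x$config$gamma))
  invisible(x)
}

#' Predict calibrated catalytic probabilities
#' @param object a [train_feature_predictor()] model.
#' @param newdata scaled feature matrix.
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict.cr_svm <- function(object, newdata, ...) {
  p <- predict(object$fit, newdata, decision.values = TRUE)
  d <- attr(p, "decision.values")[, 1]
  if (grepl("^0/", colnames(attr(p, "decision.values"))[1])) d <- -d
  unname(logistic(object$platt[1] + object$platt[2] * d))
}

#' Fuse a feature score with a template score
#'
#' When the best template similarity reaches the reliability cutoff the
#' fused score is the convex combination
#' `weight * fscore + (1 - weight) * tscore`; otherwise the template
#' channel is suppressed and the feature score passes through unchanged.
#'
#' @param fscore per-residue feature predictor scores in [0, 1].
#' @param tscore per-residue template scores (0/1).
#' @param best_similarity top template similarity (`-Inf` if no template).
#' @param weight feature weight in [0, 1].
#' @param cutoff similarity reliability cutoff.
#' @return per-residue fused scores.
#' @export
fuse <- function(fscore, tscore, best_similarity, weight, cutoff) {
  if (length(fscore) != length(tscore)) stop("score length mismatch")
  if (is.finite(best_similarity) && best_similarity >= cutoff)
    weight * fscore + (1 - weight) * tscore
  else
    fscore
}

#' Blend the structural and sequence channel scores
#'
#' @param str_fused structural-channel fused scores.
#' @param seq_fused sequence-channel fused scores.
#' @param gamma structural weight in [0, 1] (default 0.5, equal weight).
#' @return per-residue combined scores.
#' @export
crhunter_score <- function(str_fused, seq_fused, gamma = 0.5) {
  if (length(str_fused) != length(seq_fused)) stop("score length mismatch")
  stopifnot(gamma >= 0, gamma <= 1)
  gamma * str_fused + (1 - gamma) * seq_fused
}
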