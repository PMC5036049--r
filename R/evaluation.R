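# Evaluation: threshold metrics, rank-based ROC AUC, and k-fold
# cross-validation grouped by structure so no chain straddles folds.

#' Confusion-matrix metrics at a score threshold
#'
#' Predictions are `score >= threshold`. The Matthews correlation
#' coefficient is defined as 0 when its denominator vanishes.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = catalytic).
#' @param threshold classification threshold (default 0.5).
#' @return list with `recall`, `precision`, `f1`, `acc`, `mcc`, `tp`,
#'   `fp`, `fn`, `tn`, `threshold`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input")
  if (length(scores) != length(labels)) stop("length mismatch")
  pred <- scores >= threshold
  lab <- labels == 1
  tp <- sum(pred & lab); fp <- sum(pred & !lab)
  fn <- sum(!pred & lab); tn <- sum(!pred & !lab)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  acc <- (tp + tn) / length(scores)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(recall = recall, precision = precision, f1 = f1, acc = acc,
       mcc = mcc, tp = tp, fp = fp, fn = fn, tn = tn, threshold = threshold)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator; tied scores contribute 1/2.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  lab <- labels == 1
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0 || nn == 0) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[lab]) - np * (np + 1) / 2) / (np * nn)
}

#' Structure-grouped k-fold cross-validation of the full pipeline
#'
#' Folds partition structures (never residues). Within each fold the pair
#' weight matrix, propensity, background, scalers and both SVMs are re-fit
#' on the training structures only; the fold's test structures are then
#' scored with their template hits. Template hits whose template derives
#' from a test structure other than the query itself are excluded from
#' that query's hit list (a chain never benefits from a fold-mate).
#'
#' @param benchmark a [make_benchmark()] object (or a list with the same
#'   fields: `structures`, `annotations`, `pssms`, `msas`, `hits_str`,
#'   `hits_seq`, `template_annotations`, `template_lengths`,
#'   `template_source`).
#' @param k number of folds (default 5).
#' @param config an [svm_config()].
#' @param fusion a [fusion_config()].
#' @param facet_cutoff contact cutoff (default 9).
#' @param seed fold-assignment seed.
#' @return object of class `cr_evaluation`: pooled per-residue scores with
#'   labels and fold ids, pooled AUC per predictor, per-fold AUC matrix
#'   and fold standard errors.
#' @export
cross_validate <- function(benchmark, k = 5, config = svm_config(),
                           fusion = fusion_config(), facet_cutoff = 9,
                           seed = 1) {
  ns <- length(benchmark$structures)
  if (k < 2) stop("k must be >= 2")
  if (ns < k) stop("fewer structures than folds")
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k), ns)))
  score_cols <- c("fscore_str", "tscore_str", "fscore_seq", "tscore_seq",
                  "strhunter", "seqhunter", "crhunter")
  pooled <- list()
  fold_auc <- matrix(NA_real_, k, length(score_cols),
                     dimnames = list(NULL, score_cols))
  ids <- vapply(benchmark$structures, function(s) s$id, character(1))
  tsrc <- benchmark$template_source %||% setNames(character(0), character(0))

  for (f in seq_len(k)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    model <- crhunter(benchmark$structures[tr], benchmark$annotations[tr],
                      benchmark$pssms[tr], benchmark$msas[tr],
                      config = config, fusion = fusion,
                      facet_cutoff = facet_cutoff)
    for (q in te) {
      qid <- ids[q]
      drop_tmpl <- function(hits) {
        Filter(function(h) {
          src <- tsrc[h$template_id]
          is.na(src) || src == qid || !(src %in% ids[te])
        }, hits)
      }
      sc <- predict(model, benchmark$structures[[q]], benchmark$pssms[[q]],
                    benchmark$msas[[q]],
                    hits_str = drop_tmpl(benchmark$hits_str[[qid]] %||% list()),
                    hits_seq = drop_tmpl(benchmark$hits_seq[[qid]] %||% list()),
                    template_annotations = benchmark$template_annotations,
                    template_lengths = benchmark$template_lengths)
      lab <- integer(nrow(sc))
      lab[benchmark$annotations[[q]]$catalytic_indices] <- 1L
      sc$label <- lab
      sc$structure <- qid
      sc$fold <- f
      pooled[[length(pooled) + 1]] <- sc
    }
    fsc <- do.call(rbind, pooled[vapply(pooled, function(p) p$fold[1] == f, logical(1))])
    for (col in score_cols)
      fold_auc[f, col] <- tryCatch(auc_score(fsc[[col]], fsc$label),
                                   error = function(e) NA_real_)
  }
  pooled <- do.call(rbind, pooled)
  pooled_auc <- vapply(score_cols, function(col)
    auc_score(pooled[[col]], pooled$label), numeric(1))
  se <- apply(fold_auc, 2, function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  structure(list(scores = pooled, pooled_auc = pooled_auc,
                 fold_auc = fold_auc, fold_se = se, k = k, seed = seed),
            class = "cr_evaluation")
}

#' @export
print.cr_evaluation <- function(x, ...) {
  cat(sprintf("<cr_evaluation> %d-fold CV, %d residues\n", x$k, nrow(x$scores)))
  for (col in names(x$pooled_auc))
    cat(sprintf("  %-11s AUC %.3f (fold SE %.3f)\n", col,
                x$pooled_auc[col], x$fold_se[col]))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param evaluation a [cross_validate()] result.
#' @param path output path.
#' @export
write_evaluation <- function(evaluation, path) {
  rep <- list(pooled_auc = as.list(evaluation$pooled_auc),
              fold_se = as.list(evaluation$fold_se),
              k = evaluation$k, seed = evaluation$seed,
              n_residues = nrow(evaluation$scores),
              n_catalytic = sum(evaluation$scores$label))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
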