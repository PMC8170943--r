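#' Sample negative drug-disease pairs
#'
#' Draws `floor(ratio * #positives)` distinct zero cells of the interaction
#' matrix uniformly without replacement, as presumed non-interactions for
#' training and evaluation. Reproducible by seed.
#'
#' @param I binary interaction matrix or a [benchmark_dataset()].
#' @param ratio negatives per positive (default 1, matching the positives).
#' @param seed integer seed.
#' @return Two-column integer matrix of (drug index, disease index).
#' @export
sample_negatives <- function(I, ratio = 1, seed = 1) {
  if (inherits(I, "benchmark_dataset")) I <- I$interactions
  I <- as.matrix(I)
  npos <- sum(I == 1)
  nneg <- floor(ratio * npos)
  zeros <- which(I == 0)
  if (nneg > length(zeros))
    fail("requested %d negatives but only %d zero cells available",
         nneg, length(zeros))
  if (nneg < 1) fail("no negatives requested (no positives in I?)")
  chosen <- with_seed(seed, sample(zeros, nneg))
  arrayInd(chosen, dim(I))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, true positive rate (sensitivity), true negative rate
#' (specificity), positive predictive value (precision) and the Matthews
#' correlation coefficient:
#' \deqn{MCC = (TP TN - FP FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' A zero denominator (PPV or MCC) yields a defined 0 and sets the
#' `degenerate` flag rather than erroring.
#'
#' @param TP,TN,FP,FN non-negative confusion counts. Alternatively pass a
#'   list/vector with those names as `TP`.
#' @return A list with `acc`, `tpr`, `tnr`, `ppv`, `mcc`, `degenerate`.
#' @examples
#' metrics_from_counts(3, 3, 1, 1) # mcc = 0.5
#' @export
metrics_from_counts <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP) || (is.numeric(TP) && length(TP) == 4L && !is.null(names(TP)))) {
    c0 <- TP; TP <- c0[["TP"]]; TN <- c0[["TN"]]; FP <- c0[["FP"]]; FN <- c0[["FN"]]
  }
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  if (any(c(TP, TN, FP, FN) < 0)) fail("confusion counts must be non-negative")
  degenerate <- FALSE
  total <- TP + TN + FP + FN
  acc <- if (total > 0) (TP + TN) / total else { degenerate <- TRUE; 0 }
  tpr <- if (TP + FN > 0) TP / (TP + FN) else { degenerate <- TRUE; 0 }
  tnr <- if (TN + FP > 0) TN / (TN + FP) else { degenerate <- TRUE; 0 }
  ppv <- if (TP + FP > 0) TP / (TP + FP) else { degenerate <- TRUE; 0 }
  mden <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (mden > 0) (TP * TN - FP * FN) / sqrt(mden) else { degenerate <- TRUE; 0 }
  list(acc = acc, tpr = tpr, tnr = tnr, ppv = ppv, mcc = mcc,
       degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney statistic
#' `P(score+ > score-) + 0.5 P(tie)` via average ranks, so it is exact under
#' ties and invariant under strictly monotone transforms of the scores. ROC
#' points are emitted at every distinct threshold, from (0, 0) to (1, 1).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes must be present).
#' @return A list with `auc` and `roc` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores); labels <- as.numeric(labels)
  if (length(scores) != length(labels)) fail("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) fail("labels must be binary")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) fail("both classes must be present to compute ROC/AUC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; l_sorted <- labels[ord]
  last_of_threshold <- c(diff(s_sorted) != 0, TRUE)
  tp <- cumsum(l_sorted)[last_of_threshold]
  fp <- cumsum(1 - l_sorted)[last_of_threshold]
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(auc = auc, roc = roc)
}

#' Tenfold cross-validation of the full prediction pipeline
#'
#' Positives (all known interactions) and sampled negatives are pooled,
#' shuffled once, and split into `folds` near-equal parts; each fold in turn
#' is held out for testing while the model is fitted on the remainder. To
#' prevent the test labels leaking through the interaction-derived features,
#' the GIP kernels and the cluster boosting are, by default, recomputed per
#' fold from the training interactions only (test-fold positive cells zeroed
#' out); `refit_per_fold = FALSE` reproduces the naive variant.
#'
#' Per fold the report carries thresholded confusion metrics
#' ([metrics_from_counts()]) and the ROC/AUC; the summary rows are the mean
#' and the population standard deviation over folds. A pooled AUC over the
#' concatenated test scores is also recorded.
#'
#' @param ds a [benchmark_dataset()].
#' @param config pipeline configuration from [ddi_config()].
#' @param folds number of folds (default 10).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param refit_per_fold recompute interaction-derived features per fold
#'   (default; see above).
#' @param verbose print per-fold progress.
#' @return An object of class `ddi_cv`: list with `per_fold` (data frame),
#'   `mean`, `sd`, `auc_pooled`, `roc` (per-fold ROC points), `folds`,
#'   `seed`, `config`, plus the pair/fold assignment.
#' @export
ddi_cv <- function(ds, config = ddi_config(), folds = 10, seed = 1,
                   refit_per_fold = TRUE, verbose = FALSE) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  I <- ds$interactions
  pos <- which(I == 1)
  if (length(pos) < folds)
    fail("need at least %d positives for %d-fold CV", folds, folds)
  pos_pairs <- arrayInd(pos, dim(I))
  neg_pairs <- sample_negatives(I, config$negative_ratio,
                                seed = derive_seed(seed, "negatives"))
  if (nrow(neg_pairs) < folds)
    fail("need at least %d negatives for %d-fold CV", folds, folds)
  pairs <- rbind(pos_pairs, neg_pairs)
  labels <- c(rep(1, nrow(pos_pairs)), rep(0, nrow(neg_pairs)))
  N <- nrow(pairs)
  fold_id <- with_seed(derive_seed(seed, "folds"),
                       sample(rep(seq_len(folds), length.out = N)))

  per_fold <- vector("list", folds)
  rocs <- vector("list", folds)
  all_scores <- numeric(N)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    I_train <- I
    if (refit_per_fold) {
      test_pos <- pairs[test & labels == 1, , drop = FALSE]
      I_train[test_pos] <- 0
    }
    fit <- ddi_fit(ds, config = config,
                   seed = derive_seed(seed, paste0("fold", f)),
                   pairs = pairs[!test, , drop = FALSE],
                   labels = labels[!test], I_train = I_train)
    sc <- predict(fit, pairs = pairs[test, , drop = FALSE])
    all_scores[test] <- sc
    cm <- confusion_at(sc, labels[test], config$threshold)
    met <- metrics_from_counts(cm)
    ra <- roc_auc(sc, labels[test])
    rocs[[f]] <- ra$roc
    per_fold[[f]] <- data.frame(fold = f, n_test = sum(test),
                                acc = met$acc, tpr = met$tpr, tnr = met$tnr,
                                ppv = met$ppv, mcc = met$mcc, auc = ra$auc)
    if (verbose)
      message(sprintf("fold %d/%d: acc %.3f auc %.3f", f, folds,
                      met$acc, ra$auc))
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("acc", "tpr", "tnr", "ppv", "mcc", "auc")
  mu <- colMeans(per_fold[metric_cols])
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sdv <- vapply(per_fold[metric_cols], pop_sd, numeric(1))
  structure(
    list(per_fold = per_fold, mean = mu, sd = sdv,
         auc_pooled = roc_auc(all_scores, labels)$auc,
         roc = rocs, folds = folds, seed = seed, config = config,
         pairs = pairs, labels = labels, fold_id = fold_id,
         scores = all_scores),
    class = "ddi_cv"
  )
}

confusion_at <- function(scores, labels, threshold) {
  pred <- as.numeric(scores >= threshold)
  list(TP = sum(pred == 1 & labels == 1), TN = sum(pred == 0 & labels == 0),
       FP = sum(pred == 1 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

#' @export
print.ddi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d pairs, seed %d)\n",
              x$folds, nrow(x$pairs), x$seed))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  cat(sprintf("pooled AUC: %.4f\n", x$auc_pooled))
  invisible(x)
}

#' @export
summary.ddi_cv <- function(object, ...) {
  out <- rbind(object$per_fold[, c("acc", "tpr", "tnr", "ppv", "mcc", "auc")],
               mean = object$mean, sd = object$sd)
  rownames(out)[seq_len(object$folds)] <- paste0("fold", seq_len(object$folds))
  out
}

#' Write a cross-validation report to TSV/CSV files
#'
#' Writes `report.tsv` (per-fold rows plus mean and sd rows) and
#' `roc.csv` (per-fold ROC points) into a directory.
#'
#' @param cv a `ddi_cv` object.
#' @param directory output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cv_report <- function(cv, directory) {
  stopifnot(inherits(cv, "ddi_cv"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tab <- summary(cv)
  utils::write.table(data.frame(set = rownames(tab), round(tab, 6)),
                     file.path(directory, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  roc <- do.call(rbind, lapply(seq_along(cv$roc), function(f)
    data.frame(fold = f, cv$roc[[f]])))
  utils::write.csv(roc, file.path(directory, "roc.csv"), row.names = FALSE)
  invisible(directory)
}

#' Rank candidate partners for a query drug or disease
#'
#' Scores every entity on the other axis against the query with a fitted
#' model and ranks candidates by decreasing score, ties broken by candidate
#' ID. Known interactions are flagged, not removed, so confirmed indications
#' can be recognized among the top ranks.
#'
#' @param fit a fitted model from [ddi_fit()].
#' @param query a drug ID or disease ID present in the fitted dataset.
#' @return An object of class `ranked_list`: data frame with `rank`,
#'   `candidate`, `score`, `known`; the query and its axis as attributes.
#' @export
rank_candidates <- function(fit, query) {
  stopifnot(inherits(fit, "ddi_fit"))
  ds <- fit$ds
  if (query %in% ds$drugs) {
    qi <- match(query, ds$drugs)
    pairs <- cbind(qi, seq_along(ds$diseases))
    cand <- ds$diseases
    known <- ds$interactions[qi, ]
    axis <- "drug"
  } else if (query %in% ds$diseases) {
    qj <- match(query, ds$diseases)
    pairs <- cbind(seq_along(ds$drugs), qj)
    cand <- ds$drugs
    known <- ds$interactions[, qj]
    axis <- "disease"
  } else {
    fail("query ID '%s' not found among drugs or diseases", query)
  }
  sc <- predict(fit, pairs = pairs)
  ord <- order(-sc, cand)
  out <- data.frame(rank = seq_along(cand), candidate = cand[ord],
                    score = sc[ord], known = as.integer(known[ord]),
                    row.names = NULL)
  attr(out, "query") <- query
  attr(out, "query_axis") <- axis
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat(sprintf("Candidates ranked for %s '%s' (%d candidates, %d known)\n",
              attr(x, "query_axis"), attr(x, "query"), nrow(x), sum(x$known)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Known interactions retrieved in the top N ranks
#'
#' @param ranked a `ranked_list` from [rank_candidates()].
#' @param n number of top ranks to inspect; clamped to the candidate count
#'   with a warning when larger.
#' @return Integer count of known interactions among the top `n`.
#' @export
top_n_retrieval <- function(ranked, n) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n < 1) fail("n must be >= 1")
  if (n > nrow(ranked)) {
    warning(sprintf("n = %d exceeds %d candidates; clamped", n, nrow(ranked)),
            call. = FALSE)
    n <- nrow(ranked)
  }
  sum(ranked$known[seq_len(n)])
}
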