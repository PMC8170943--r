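#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline with its default.
#' Stages: (1) logistic adjustment of the drug similarity; (2)
#' interaction-based clustering of drugs and cluster-informed restoration of
#' raw similarities; (3) GIP kernel for diseases, fused with the phenotype
#' similarity; (4) per-pair feature assembly and truncated-SVD reduction;
#' (5) GRU training.
#'
#' @param logistic_a,logistic_b logistic adjustment coefficients; the
#'   defaults send a similarity of 0 to 1e-4 and of 1 to ~0.997.
#' @param cluster_boost apply the cluster-informed similarity restoration.
#' @param cluster_edge_floor drug-axis GIP kernel entries below this are
#'   treated as non-edges when building the clustering graph.
#' @param cluster_min_size,cluster_min_density,cluster_overlap,cluster_penalty
#'   passed to [cluster_one()] (`cluster_penalty = NULL` = auto).
#' @param alpha_prime GIP bandwidth scale (default 0.5).
#' @param disease_fusion_weight weight of the GIP kernel vs the phenotype
#'   similarity in the disease representation (default 0.5).
#' @param use_drug_gip append drug-axis GIP features to the drug
#'   representation (default off: similarity carries the drug side).
#' @param tsvd_dim truncated-SVD dimension (default 64); capped at the
#'   feature-matrix rank at run time.
#' @param tsvd_stage `"pairs"` reduces the assembled per-pair feature matrix
#'   (default), `"representations"` reduces the drug and disease
#'   representations separately before pairing, `"none"` skips the SVD.
#' @param hidden,dropout,epochs,batch_size,learning_rate,timesteps GRU
#'   training settings, see [gru_train()].
#' @param negative_ratio negatives sampled per positive (default 1).
#' @param threshold score threshold for confusion-based metrics.
#' @return A named list of class `ddi_config`.
#' @export
ddi_config <- function(logistic_a = -15, logistic_b = log(9999),
                       cluster_boost = TRUE, cluster_edge_floor = 0.1,
                       cluster_min_size = 3, cluster_min_density = 0.3,
                       cluster_overlap = 0.8, cluster_penalty = NULL,
                       alpha_prime = 0.5, disease_fusion_weight = 0.5,
                       use_drug_gip = FALSE,
                       tsvd_dim = 64, tsvd_stage = c("pairs", "representations", "none"),
                       hidden = 128, dropout = 0.25, epochs = 50,
                       batch_size = 64, learning_rate = 1e-3, timesteps = 1,
                       negative_ratio = 1, threshold = 0.5) {
  tsvd_stage <- match.arg(tsvd_stage)
  structure(
    list(logistic_a = logistic_a, logistic_b = logistic_b,
         cluster_boost = cluster_boost, cluster_edge_floor = cluster_edge_floor,
         cluster_min_size = cluster_min_size,
         cluster_min_density = cluster_min_density,
         cluster_overlap = cluster_overlap, cluster_penalty = cluster_penalty,
         alpha_prime = alpha_prime,
         disease_fusion_weight = disease_fusion_weight,
         use_drug_gip = use_drug_gip,
         tsvd_dim = tsvd_dim, tsvd_stage = tsvd_stage,
         hidden = hidden, dropout = dropout, epochs = epochs,
         batch_size = batch_size, learning_rate = learning_rate,
         timesteps = timesteps, negative_ratio = negative_ratio,
         threshold = threshold),
    class = "ddi_config"
  )
}

# Build per-drug and per-disease representations from a dataset and a
# (possibly fold-restricted) interaction matrix.
build_representations <- function(ds, I_train, cfg) {
  S_adj <- logistic_adjust(ds$drug_sim, cfg$logistic_a, cfg$logistic_b)
  clusters <- list()
  S_drug <- S_adj
  if (cfg$cluster_boost) {
    K_drug <- gip_kernel(I_train, "drugs", cfg$alpha_prime)
    W <- unclass(K_drug)
    attr(W, "bandwidth") <- NULL
    W[W < cfg$cluster_edge_floor] <- 0
    clusters <- cluster_one(W, penalty_per_node = cfg$cluster_penalty,
                            min_size = cfg$cluster_min_size,
                            min_density = cfg$cluster_min_density,
                            overlap_merge_threshold = cfg$cluster_overlap)
    S_drug <- boost_with_clusters(ds$drug_sim, S_adj, clusters)
  }
  K_gip <- gip_kernel(I_train, "diseases", cfg$alpha_prime)
  disease_repr <- cfg$disease_fusion_weight * unclass(K_gip) +
    (1 - cfg$disease_fusion_weight) * ds$disease_sim
  attr(disease_repr, "bandwidth") <- NULL
  drug_repr <- S_drug
  if (cfg$use_drug_gip)
    drug_repr <- cbind(drug_repr, gip_kernel(I_train, "drugs", cfg$alpha_prime))
  rownames(drug_repr) <- ds$drugs
  rownames(disease_repr) <- ds$diseases
  list(drug_repr = drug_repr, disease_repr = disease_repr,
       clusters = clusters)
}

#' Fit the drug-disease association prediction model
#'
#' The central fitting function. Given a benchmark dataset it (1) sharpens
#' the drug similarity with [logistic_adjust()] and, guided by
#' interaction-based [cluster_one()] modules, restores raw similarities for
#' co-clustered drugs ([boost_with_clusters()]); (2) builds disease features
#' by fusing the [gip_kernel()] over interaction profiles with the phenotype
#' similarity; (3) assembles one feature row per (drug, disease) training
#' pair and reduces it with [tsvd_reduce()]; (4) trains the GRU classifier
#' ([gru_train()]) on positive pairs versus sampled negative pairs.
#'
#' When `pairs`/`labels` are omitted, all known interactions are taken as
#' positives and an equal number of zero cells (times
#' `config$negative_ratio`) is sampled as negatives. `I_train` lets
#' cross-validation supply an interaction matrix with held-out cells zeroed,
#' so interaction-derived features never see test labels.
#'
#' @param ds a [benchmark_dataset()].
#' @param config a [ddi_config()].
#' @param seed global seed; stage seeds (negative sampling, GRU) derive
#'   from it deterministically.
#' @param pairs optional two-column integer matrix of training pairs.
#' @param labels binary labels for `pairs`.
#' @param I_train optional interaction matrix to derive features from
#'   (defaults to `ds$interactions`).
#' @return An object of class `ddi_fit` with elements `gru` (the trained
#'   [gru_train()] fit), `drug_repr`, `disease_repr`, `clusters`, `tsvd`
#'   (projection basis or `NULL`), `pairs`, `labels`, `fitted` (training
#'   scores), `config`, `seed`, `ds`.
#' @examples
#' sim <- synthetic_benchmark(m = 40, n = 30, k_blocks = 2, seed = 1)
#' cfg <- ddi_config(epochs = 3, hidden = 8, tsvd_dim = 10)
#' fit <- ddi_fit(sim$dataset, cfg, seed = 1)
#' head(predict(fit))
#' @export
ddi_fit <- function(ds, config = ddi_config(), seed = 1,
                    pairs = NULL, labels = NULL, I_train = NULL) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  cfg <- config
  if (is.null(I_train)) I_train <- ds$interactions
  if (is.null(pairs)) {
    pos <- arrayInd(which(ds$interactions == 1), dim(ds$interactions))
    neg <- sample_negatives(ds$interactions, cfg$negative_ratio,
                            seed = derive_seed(seed, "negatives"))
    pairs <- rbind(pos, neg)
    labels <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (length(labels) != nrow(pairs)) fail("labels length must match pairs")

  repr <- build_representations(ds, I_train, cfg)
  if (cfg$tsvd_stage == "representations") {
    kd <- min(cfg$tsvd_dim, dim(repr$drug_repr))
    ks <- min(cfg$tsvd_dim, dim(repr$disease_repr))
    td <- tsvd_reduce(repr$drug_repr, kd)
    ts <- tsvd_reduce(repr$disease_repr, ks)
    repr$drug_repr <- td$scores; rownames(repr$drug_repr) <- ds$drugs
    repr$disease_repr <- ts$scores; rownames(repr$disease_repr) <- ds$diseases
  }
  pf <- assemble_pairs(repr$drug_repr, repr$disease_repr, pairs, labels)
  tsvd <- NULL
  x <- pf$x
  if (cfg$tsvd_stage == "pairs") {
    k <- min(cfg$tsvd_dim, dim(x))
    tsvd <- tsvd_reduce(x, k)
    x <- tsvd$scores
  }
  gru <- gru_train(x, labels, hidden = cfg$hidden, dropout = cfg$dropout,
                   epochs = cfg$epochs, batch_size = cfg$batch_size,
                   learning_rate = cfg$learning_rate,
                   timesteps = cfg$timesteps,
                   seed = derive_seed(seed, "gru"))
  fitted <- predict(gru, x)
  structure(
    list(gru = gru, drug_repr = repr$drug_repr,
         disease_repr = repr$disease_repr, clusters = repr$clusters,
         tsvd = tsvd, pairs = pairs, labels = labels, fitted = fitted,
         config = cfg, seed = seed, ds = ds),
    class = "ddi_fit"
  )
}

# Feature rows for arbitrary pairs under a fitted model's representations
# and SVD basis.
featurize_pairs <- function(fit, pairs) {
  pf <- assemble_pairs(fit$drug_repr, fit$disease_repr, pairs)
  x <- pf$x
  if (!is.null(fit$tsvd)) x <- x %*% fit$tsvd$v
  x
}

#' Predict association scores from a fitted model
#'
#' @param object a `ddi_fit`.
#' @param pairs two-column integer matrix of (drug index, disease index);
#'   `NULL` (default) scores the training pairs.
#' @param ... unused.
#' @return A probability per pair, in (0, 1).
#' @export
predict.ddi_fit <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(object$fitted)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  predict(object$gru, featurize_pairs(object, pairs))
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat(sprintf("Drug-disease association model: %d drugs x %d diseases, %d training pairs\n",
              length(x$ds$drugs), length(x$ds$diseases), nrow(x$pairs)))
  cat(sprintf("features: drug width %d + disease width %d%s; %d drug clusters\n",
              ncol(x$drug_repr), ncol(x$disease_repr),
              if (is.null(x$tsvd)) "" else
                sprintf(" -> TSVD %d", length(x$tsvd$d)),
              length(x$clusters)))
  print(x$gru)
  invisible(x)
}

#' @export
summary.ddi_fit <- function(object, ...) {
  cm <- confusion_at(object$fitted, object$labels, object$config$threshold)
  met <- metrics_from_counts(cm)
  ra <- roc_auc(object$fitted, object$labels)
  out <- list(
    n_drugs = length(object$ds$drugs), n_diseases = length(object$ds$diseases),
    n_pairs = nrow(object$pairs),
    n_clusters = length(object$clusters),
    singular_values = object$tsvd$d,
    train_metrics = c(acc = met$acc, tpr = met$tpr, tnr = met$tnr,
                      ppv = met$ppv, mcc = met$mcc, auc = ra$auc),
    loss = object$gru$history
  )
  class(out) <- "summary.ddi_fit"
  out
}

#' @export
print.summary.ddi_fit <- function(x, ...) {
  cat(sprintf("%d drugs x %d diseases, %d training pairs, %d drug clusters\n",
              x$n_drugs, x$n_diseases, x$n_pairs, x$n_clusters))
  cat("training-set metrics (in-sample, optimistic):\n")
  print(round(x$train_metrics, 4))
  invisible(x)
}

#' @export
coef.ddi_fit <- function(object, ...) object$gru$params

#' @export
residuals.ddi_fit <- function(object, ...) object$labels - object$fitted

#' @export
fitted.ddi_fit <- function(object, ...) object$fitted

#' Plot the training loss curve
#'
#' @param x a `ddi_fit`.
#' @param ... passed to [plot()].
#' @export
plot.ddi_fit <- function(x, ...) {
  h <- x$gru$history
  if (!length(h)) fail("model has no training history")
  plot(seq_along(h), h, type = "l", xlab = "epoch",
       ylab = "mean training loss", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' The model (GRU parameter arrays, representations, SVD basis and
#' configuration) is serialized as a single RDS container, loadable across
#' sessions.
#'
#' @param fit a `ddi_fit`.
#' @param path file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   `ddi_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "ddi_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "ddi_fit")) fail("file does not contain a ddi_fit model")
  fit
}

#' Write predicted scores for pairs as TSV
#'
#' Columns: `drug_id`, `disease_id`, `score`, `known_flag`, `rank` (dense
#' rank by descending score).
#'
#' @param fit a `ddi_fit`.
#' @param pairs two-column integer matrix; default all cells.
#' @param path output file.
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(fit, pairs = NULL, path) {
  ds <- fit$ds
  if (is.null(pairs))
    pairs <- as.matrix(expand.grid(seq_along(ds$drugs), seq_along(ds$diseases)))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  sc <- predict(fit, pairs = pairs)
  df <- data.frame(drug_id = ds$drugs[pairs[, 1]],
                   disease_id = ds$diseases[pairs[, 2]],
                   score = sc,
                   known_flag = as.integer(ds$interactions[pairs]),
                   rank = rank(-sc, ties.method = "min"))
  df <- df[order(df$rank), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
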