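#' Booster configuration
#'
#' Hyperparameters of the gradient-boosted tree classifier.
#'
#' @param nrounds number of boosting rounds (default 500).
#' @param max_depth tree depth (default 6).
#' @param eta learning rate (default 0.1).
#' @param subsample row subsample fraction per round (default 0.8).
#' @param scale_pos_weight class weight on positives (default 1; raise for
#'   imbalanced data).
#' @param nthread threads used by the booster; kept at 1 so refits with the
#'   same seed are bitwise reproducible.
#' @return an object of class \code{m5u_booster_config}.
#' @export
booster_config <- function(nrounds = 500L, max_depth = 6L, eta = 0.1,
                           subsample = 0.8, scale_pos_weight = 1,
                           nthread = 1L) {
  stopifnot(nrounds >= 1L, max_depth >= 1L, eta > 0, subsample > 0,
            subsample <= 1)
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 subsample = subsample, scale_pos_weight = scale_pos_weight,
                 nthread = as.integer(nthread)),
            class = "m5u_booster_config")
}

# Deterministic sub-seed derivation from the single run seed.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 2654435761 + 97 * k) %% 2147483647
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into disjoint, exhaustive train and test parts,
#' stratified by label, deterministically under \code{seed}.
#'
#' @param ds a labeled \code{m5u_dataset}.
#' @param ratio training fraction (default 0.8, the 8:2 protocol).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} datasets.
#' @export
split_dataset <- function(ds, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  lab <- ds$label
  if (any(lab == "unknown")) stop("split requires fully labeled data")
  if (any(table(lab) < 2L))
    stop("stratified split requires >= 2 members per class")
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(unique(lab), function(cl) {
      i <- which(lab == cl)
      sample(i, round(ratio * length(i)))
    }))
  })
  train_idx <- sort(train_idx)
  list(train = ds[train_idx], test = ds[setdiff(seq_along(lab), train_idx)])
}

#' Fit the m5U site classifier
#'
#' Runs the full training pipeline on a labeled dataset: fit per-position
#' profiles, encode the seven sequence feature schemes, z-standardize,
#' learn the FLNSA similarity graph, embed its nodes with the configured
#' methods, fuse sequence and embedding blocks, and fit the gradient
#' boosted tree classifier. All fitted state (profiles, scaler, graph,
#' embeddings) derives from the training samples only, so prediction on
#' new data is inductive (new samples are projected onto the training
#' graph, see \code{\link{project_new_nodes}}).
#'
#' @param train a labeled \code{m5u_dataset} containing both classes.
#' @param encoder an \code{\link{encoder_config}}.
#' @param flnsa an \code{\link{flnsa_config}}.
#' @param embed an \code{\link{embed_config}} (its seed is re-derived from
#'   \code{seed}).
#' @param booster a \code{\link{booster_config}}.
#' @param encoders sequence encoders to use (see
#'   \code{\link{encode_dataset}}).
#' @param seed single integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return an object of class \code{m5u_model}.
#' @export
m5u_fit <- function(train, encoder = encoder_config(),
                    flnsa = flnsa_config(), embed = embed_config(),
                    booster = booster_config(),
                    encoders = c("nps", "ctd", "bpb", "eiip", "pseknc",
                                 "ncpnd", "npps"),
                    seed = 1L) {
  lab <- train$label
  if (!any(lab == "positive") || !any(lab == "negative"))
    stop("training requires both positive and negative windows")
  profiles <- fit_profiles(train, encoder)
  seqfeat <- encode_dataset(train, encoder, profiles, encoders = encoders)
  mu_x <- colMeans(seqfeat$X)
  sd_x <- apply(seqfeat$X, 2L, sd)
  sd_x[sd_x < 1e-12] <- 1
  Xs <- scale(seqfeat$X, center = mu_x, scale = sd_x)
  C <- select_neighbors(Xs, flnsa$K)
  W <- fit_weights(Xs, C, flnsa)
  graph <- build_graph(W, flnsa, ids = train$id)
  embed$seed <- as.integer(derive_seed(seed, 1L))
  emb <- embed_all(graph, embed)
  fused <- fuse_features(list(seqfeat, emb))
  y <- as.integer(lab == "positive")
  dtrain <- xgboost::xgb.DMatrix(fused$X, label = y, nthread = booster$nthread)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = booster$max_depth, eta = booster$eta,
                  subsample = booster$subsample,
                  scale_pos_weight = booster$scale_pos_weight,
                  nthread = booster$nthread,
                  seed = as.integer(derive_seed(seed, 2L))),
    data = dtrain, nrounds = booster$nrounds, verbose = 0)
  structure(list(booster = bst, schema = fused$blocks,
                 feature_names = colnames(fused$X), X_fused = fused$X,
                 profiles = profiles, scaler = list(center = mu_x, scale = sd_x),
                 flnsa = flnsa, graph = graph, X_train = unclass(Xs),
                 E_train = emb$X, embed = embed, encoder = encoder,
                 encoders = encoders, booster_cfg = booster,
                 train_ids = train$id, train_labels = lab, L = train$L,
                 seed = as.integer(seed)),
            class = "m5u_model")
}

#' @export
print.m5u_model <- function(x, ...) {
  cat("m5U site classifier (gradient-boosted trees over sequence +",
      "graph-embedding features)\n")
  cat("  trained on ", length(x$train_ids), " windows of length ", x$L,
      " (", sum(x$train_labels == "positive"), " positive)\n", sep = "")
  cat("  feature blocks:", paste0(x$schema$name, "(", x$schema$n_cols, ")",
                                  collapse = " "), "\n")
  cat("  booster: ", x$booster_cfg$nrounds, " rounds, depth ",
      x$booster_cfg$max_depth, ", eta ", x$booster_cfg$eta, "\n", sep = "")
  invisible(x)
}

#' @export
summary.m5u_model <- function(object, ...) {
  dmat <- xgboost::xgb.DMatrix(object$X_fused,
                               nthread = object$booster_cfg$nthread)
  rep <- evaluate(object$train_labels, predict(object$booster, dmat))
  print(object)
  cat("Training-set (resubstitution) performance:\n")
  print(rep)
  invisible(rep)
}

#' Predict m5U probabilities for new windows
#'
#' Encodes new windows with the model's fitted profiles and scaler,
#' projects them onto the training similarity graph to obtain embedding
#' features, and scores them with the trained booster.
#'
#' @param object an \code{m5u_model}.
#' @param newdata an \code{m5u_dataset} (or, internally, a pre-built
#'   feature matrix).
#' @param cutoff probability cutoff for the hard call (default 0.5).
#' @param ... unused.
#' @return data.frame with columns \code{id}, \code{prob}, \code{call}.
#' @export
predict.m5u_model <- function(object, newdata, cutoff = 0.5, ...) {
  stopifnot(inherits(newdata, "m5u_dataset"))
  if (newdata$L != object$L)
    stop("window length ", newdata$L, " does not match model L = ", object$L)
  seqfeat <- encode_dataset(newdata, object$encoder, object$profiles,
                            encoders = object$encoders)
  Xs <- scale(seqfeat$X, center = object$scaler$center,
              scale = object$scaler$scale)
  E_new <- project_new_nodes(object$E_train, Xs, object$X_train,
                             object$flnsa, ids = newdata$id)
  X <- cbind(seqfeat$X, E_new)
  ids <- newdata$id
  colnames(X) <- object$feature_names
  dmat <- xgboost::xgb.DMatrix(X, nthread = object$booster_cfg$nthread)
  prob <- predict(object$booster, dmat)
  data.frame(id = ids, prob = prob,
             call = ifelse(prob > cutoff, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Feature-importance plot
#'
#' @param x an \code{m5u_model}.
#' @param top_n number of features to show.
#' @param ... passed to \code{barplot}.
#' @export
plot.m5u_model <- function(x, top_n = 20L, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  imp <- utils::head(imp, top_n)
  graphics::barplot(rev(imp$Gain), names.arg = rev(imp$Feature), horiz = TRUE,
                    las = 1, xlab = "Gain", main = "Feature importance", ...)
  invisible(imp)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("positive", "negative"))
    if (length(bad)) stop("labels must be positive/negative or 0/1")
    as.integer(labels == "positive")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    labels
  }
}

#' Rank-statistic AUROC (midrank ties)
#'
#' @param labels 0/1 or positive/negative labels.
#' @param scores numeric scores.
#' @return AUROC in [0, 1], or \code{NA} when only one class is present.
#' @export
auroc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)                       # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate scores against labels
#'
#' Confusion counts at the cutoff, sensitivity/specificity/accuracy in
#' percent, Matthews correlation coefficient (0 when its denominator is 0)
#' and the rank-statistic AUROC.
#'
#' @param labels 0/1 or positive/negative labels.
#' @param scores numeric scores in [0, 1].
#' @param cutoff hard-call threshold (call positive when score > cutoff).
#' @param protocol free-text protocol tag stored in the report.
#' @return an object of class \code{m5u_eval}.
#' @export
evaluate <- function(labels, scores, cutoff = 0.5, protocol = "holdout") {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores), length(y) >= 1L)
  pred <- as.integer(scores > cutoff)
  TP <- sum(pred == 1L & y == 1L)
  TN <- sum(pred == 0L & y == 0L)
  FP <- sum(pred == 1L & y == 0L)
  FN <- sum(pred == 0L & y == 1L)
  n <- length(y)
  sn <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  acc <- 100 * (TP + TN) / n
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, n = n,
                 Sn = sn, Sp = sp, ACC = acc, MCC = mcc,
                 AUROC = auroc(y, scores), cutoff = cutoff,
                 protocol = protocol),
            class = "m5u_eval")
}

#' @export
print.m5u_eval <- function(x, ...) {
  cat("m5u_eval [", x$protocol, "] n = ", x$n,
      " (TP ", x$TP, ", TN ", x$TN, ", FP ", x$FP, ", FN ", x$FN, ")\n",
      sep = "")
  cat(sprintf("  Sn %.2f%%  Sp %.2f%%  ACC %.2f%%  MCC %.3f  AUROC %s\n",
              x$Sn, x$Sp, x$ACC, x$MCC,
              if (is.na(x$AUROC)) "NA" else sprintf("%.3f", x$AUROC)))
  invisible(x)
}

stratified_folds <- function(labels, k, seed) {
  y <- as_binary_labels(labels)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      i <- sample(which(y == cl))
      fold[i] <- rep_len(seq_len(k), length(i))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' All fitted state (profiles, scaler, similarity graph, embeddings,
#' booster) is re-fit inside each training fold; held-out folds are scored
#' inductively.
#'
#' @param ds a labeled \code{m5u_dataset}.
#' @param k number of folds (default 5).
#' @param cutoff hard-call threshold.
#' @param seed integer seed (folds and per-fold fits derive from it).
#' @inheritParams m5u_fit
#' @return list with \code{folds} (list of \code{m5u_eval}) and
#'   \code{mean} (metric means across folds; counts summed).
#' @export
cross_validate <- function(ds, k = 5L, encoder = encoder_config(),
                           flnsa = flnsa_config(), embed = embed_config(),
                           booster = booster_config(),
                           encoders = c("nps", "ctd", "bpb", "eiip",
                                        "pseknc", "ncpnd", "npps"),
                           cutoff = 0.5, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (length(ds) < k) stop("fewer samples than folds")
  fold <- stratified_folds(ds$label, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    tr <- ds[fold != f]
    te <- ds[fold == f]
    model <- m5u_fit(tr, encoder, flnsa, embed, booster,
                     encoders = encoders, seed = derive_seed(seed, 10L + f))
    pred <- predict(model, te, cutoff = cutoff)
    evaluate(te$label, pred$prob, cutoff = cutoff, protocol = "cv")
  })
  list(folds = reports, mean = mean_report(reports, "cv_mean"))
}

mean_report <- function(reports, protocol) {
  agg <- function(f) mean(vapply(reports, function(r) r[[f]], numeric(1L)),
                          na.rm = TRUE)
  tot <- function(f) sum(vapply(reports, function(r) r[[f]], numeric(1L)))
  structure(list(TP = tot("TP"), TN = tot("TN"), FP = tot("FP"),
                 FN = tot("FN"), n = tot("n"),
                 Sn = agg("Sn"), Sp = agg("Sp"), ACC = agg("ACC"),
                 MCC = agg("MCC"), AUROC = agg("AUROC"),
                 cutoff = reports[[1L]]$cutoff, protocol = protocol),
            class = "m5u_eval")
}

#' Cross-group (cross-technique / cross-cell-type) evaluation
#'
#' Trains on the samples carrying \code{train_value} for the given group
#' tag and tests on those carrying \code{test_value}; fitting is fully
#' inductive, so no test-group information enters the model.
#'
#' @param ds a labeled \code{m5u_dataset} with group tags.
#' @param group_tag name of the group column (e.g. \code{"technique"}).
#' @param train_value,test_value group values for training and testing.
#' @param cutoff hard-call threshold.
#' @param seed integer seed.
#' @inheritParams m5u_fit
#' @return an \code{m5u_eval} (protocol \code{"cross_group"}).
#' @export
cross_group_evaluate <- function(ds, group_tag, train_value, test_value,
                                 encoder = encoder_config(),
                                 flnsa = flnsa_config(),
                                 embed = embed_config(),
                                 booster = booster_config(),
                                 encoders = c("nps", "ctd", "bpb", "eiip",
                                              "pseknc", "ncpnd", "npps"),
                                 cutoff = 0.5, seed = 1L) {
  if (is.null(ds$groups) || !group_tag %in% names(ds$groups))
    stop("dataset has no group tag '", group_tag, "'")
  gv <- ds$groups[[group_tag]]
  for (v in c(train_value, test_value))
    if (!any(gv == v))
      stop("no samples with ", group_tag, " = '", v, "'")
  tr <- ds[gv == train_value]
  te <- ds[gv == test_value]
  model <- m5u_fit(tr, encoder, flnsa, embed, booster, encoders = encoders,
                   seed = seed)
  pred <- predict(model, te, cutoff = cutoff)
  rep <- evaluate(te$label, pred$prob, cutoff = cutoff,
                  protocol = "cross_group")
  rep
}

#' Transductive fit-and-score
#'
#' Reproduces the construction in which the similarity network spans the
#' entire dataset (training and test nodes together): supervised state
#' (profiles, scaler, booster) is fitted on the training rows only, but
#' the FLNSA graph and embeddings are learned over all samples, so test
#' nodes contribute to the graph. Use the default inductive
#' \code{\link{m5u_fit}} + \code{predict} for leakage-free evaluation.
#'
#' @param ds a labeled \code{m5u_dataset}.
#' @param train_idx integer indices of the training rows.
#' @param cutoff hard-call threshold.
#' @param seed integer seed.
#' @inheritParams m5u_fit
#' @return list with \code{scores} (data.frame id/prob/call for the test
#'   rows) and \code{report} (an \code{m5u_eval}).
#' @export
transductive_evaluate <- function(ds, train_idx, encoder = encoder_config(),
                                  flnsa = flnsa_config(),
                                  embed = embed_config(),
                                  booster = booster_config(),
                                  encoders = c("nps", "ctd", "bpb", "eiip",
                                               "pseknc", "ncpnd", "npps"),
                                  cutoff = 0.5, seed = 1L) {
  train_idx <- sort(unique(as.integer(train_idx)))
  test_idx <- setdiff(seq_along(ds$label), train_idx)
  tr <- ds[train_idx]
  profiles <- fit_profiles(tr, encoder)
  seqfeat <- encode_dataset(ds, encoder, profiles, encoders = encoders)
  mu_x <- colMeans(seqfeat$X[train_idx, , drop = FALSE])
  sd_x <- apply(seqfeat$X[train_idx, , drop = FALSE], 2L, sd)
  sd_x[sd_x < 1e-12] <- 1
  Xs <- scale(seqfeat$X, center = mu_x, scale = sd_x)
  C <- select_neighbors(Xs, flnsa$K)
  W <- fit_weights(Xs, C, flnsa)
  graph <- build_graph(W, flnsa, ids = ds$id)
  embed$seed <- as.integer(derive_seed(seed, 1L))
  emb <- embed_all(graph, embed)
  fused <- fuse_features(list(seqfeat, emb))
  y <- as.integer(ds$label == "positive")
  bcfg <- booster
  dtrain <- xgboost::xgb.DMatrix(fused$X[train_idx, , drop = FALSE],
                                 label = y[train_idx], nthread = bcfg$nthread)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = bcfg$max_depth,
                  eta = bcfg$eta, subsample = bcfg$subsample,
                  scale_pos_weight = bcfg$scale_pos_weight,
                  nthread = bcfg$nthread,
                  seed = as.integer(derive_seed(seed, 2L))),
    data = dtrain, nrounds = bcfg$nrounds, verbose = 0)
  dtest <- xgboost::xgb.DMatrix(fused$X[test_idx, , drop = FALSE],
                                nthread = bcfg$nthread)
  prob <- predict(bst, dtest)
  scores <- data.frame(id = ds$id[test_idx], prob = prob,
                       call = ifelse(prob > cutoff, "positive", "negative"),
                       stringsAsFactors = FALSE)
  list(scores = scores,
       report = evaluate(ds$label[test_idx], prob, cutoff = cutoff,
                         protocol = "transductive_holdout"))
}
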