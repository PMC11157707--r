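## Two-layer stacked ensemble. Layer 1: per feature type (FSP, CNV, NCP,
## SNS), a random search over four algorithms (elastic-net logistic
## regression, gradient boosting, random forest, single-hidden-layer neural
## network) scored by k-fold cross-validated AUROC; the five best
## algorithm-hyperparameter combinations per type are kept, 4 x 5 = 20 base
## models. Layer 2: the base models' out-of-fold scores are stacked with a
## second random search (elastic net, boosting, forest); the five best
## stacked models are kept and their predictions averaged.

.BASE_ALGOS <- c("glm", "xgb", "rf", "nn")
.STACK_ALGOS <- c("glm", "xgb", "rf")

.makeFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

.sampleParams <- function(algo) {
  switch(algo,
    glm = list(alpha = stats::runif(1),
               lambda = 10^stats::runif(1, -3, 0)),
    xgb = list(nrounds = sample(30:150, 1),
               eta = 10^stats::runif(1, -2, -0.3),
               max_depth = sample(2:6, 1),
               subsample = stats::runif(1, 0.6, 1),
               colsample_bytree = stats::runif(1, 0.5, 1),
               min_child_weight = sample(1:5, 1)),
    rf  = list(ntree = sample(c(100L, 200L, 300L), 1),
               mtryFrac = stats::runif(1, 0.1, 0.9),
               nodesize = sample(1:5, 1)),
    nn  = list(size = sample(1:8, 1),
               decay = 10^stats::runif(1, -3, 0),
               maxit = 200L),
    stop("unknown algorithm: ", algo))
}

.fitModel <- function(algo, params, x, y) {
  x <- as.matrix(x)
  out <- list(algo = algo, params = params, colnames = colnames(x))
  if (algo == "glm") {
    out$colSd <- apply(x, 2, stats::sd)
    out$fit <- glmnet::glmnet(x, y, family = "binomial",
                              alpha = params$alpha, standardize = TRUE,
                              lambda = 10^seq(0.5, -3.5, length.out = 60))
  } else if (algo == "xgb") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    out$fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    min_child_weight = params$min_child_weight,
                    nthread = 1),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
  } else if (algo == "rf") {
    out$fit <- randomForest::randomForest(
      x, factor(y, levels = c(0, 1)),
      ntree = params$ntree,
      mtry = max(1L, round(params$mtryFrac * ncol(x))),
      nodesize = params$nodesize)
  } else if (algo == "nn") {
    mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
    out$mu <- mu; out$sd <- sdv
    xs <- scale(x, mu, sdv)
    out$fit <- nnet::nnet(xs, y, size = params$size, decay = params$decay,
                          maxit = params$maxit, entropy = TRUE,
                          trace = FALSE, MaxNWts = 5000L)
  }
  out
}

.predictModel <- function(model, x) {
  x <- as.matrix(x)[, model$colnames, drop = FALSE]
  p <- switch(model$algo,
    glm = as.numeric(stats::predict(model$fit, x, s = model$params$lambda,
                                    type = "response")),
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x))),
    rf  = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"]),
    nn  = as.numeric(stats::predict(model$fit,
                                    scale(x, model$mu, model$sd))))
  pmin(pmax(p, 0), 1)
}

## default variable importance on the model's own scale (only ranks are used
## downstream): |coef|*sd for the elastic net, gain for boosting, Gini
## decrease for the forest, Garson-style |w_in|.|w_out| products for the net
.importanceOf <- function(model) {
  vars <- model$colnames
  imp <- switch(model$algo,
    glm = {
      b <- as.numeric(stats::coef(model$fit, s = model$params$lambda))[-1]
      abs(b) * model$colSd
    },
    xgb = {
      tab <- xgboost::xgb.importance(model = model$fit)
      v <- stats::setNames(rep(0, length(vars)), vars)
      if (nrow(tab)) v[tab$Feature] <- tab$Gain
      as.numeric(v)
    },
    rf  = as.numeric(model$fit$importance[, "MeanDecreaseGini"]),
    nn  = {
      p <- length(vars); h <- model$params$size
      w <- model$fit$wts
      w1 <- matrix(w[seq_len(h * (p + 1))], nrow = p + 1)[-1, , drop = FALSE]
      w2 <- w[h * (p + 1) + 1 + seq_len(h)]
      as.numeric(abs(w1) %*% abs(w2))
    })
  stats::setNames(imp, vars)
}

## cross-validate one candidate: out-of-fold predictions over all rows
.oofPredict <- function(algo, params, x, y, foldIds) {
  oof <- numeric(length(y))
  for (f in sort(unique(foldIds))) {
    tr <- foldIds != f
    m <- .fitModel(algo, params, x[tr, , drop = FALSE], y[tr])
    oof[!tr] <- .predictModel(m, x[!tr, , drop = FALSE])
  }
  oof
}

#' Train the first (base) layer
#'
#' Per feature type, draws `nSearch` random hyperparameter sets for each of
#' the four algorithms, scores every candidate by `nFolds`-fold
#' cross-validated AUROC on that type's features, and keeps the top five
#' regardless of algorithm (ties broken by draw order). Out-of-fold
#' predictions of all candidates are retained for stacking and for
#' fold-honest evaluation. Deterministic given `seed`.
#'
#' @param features Named list of four sample x variable matrices (`FSP`,
#'   `CNV`, `NCP`, `SNS` — any names are accepted; one model block per
#'   element).
#' @param labels Binary labels (1 = cancer); both classes required.
#' @param nFolds Cross-validation folds (default 5).
#' @param nSearch Random-search draws per algorithm per feature type
#'   (default 13, i.e. 52 candidates per type, >200 models over 4 types).
#' @param seed RNG seed.
#' @param foldIds Optional pre-computed fold assignment.
#' @return List with `selected` (20 base model specs with full-data refits
#'   and default importances), `oof` (n x 20 matrix), `candidates` (per-type
#'   candidate store for fold-honest evaluation), `foldIds`, `labels`.
#' @export
trainBaseLayer <- function(features, labels, nFolds = 5L, nSearch = 13L,
                           seed = 1L, foldIds = NULL) {
  labels <- as.numeric(labels > 0)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  stopifnot(is.list(features), length(features) >= 1L)
  .withSeed(seed, {
    if (is.null(foldIds)) foldIds <- .makeFolds(labels, nFolds)
    candidates <- list()
    for (type in names(features)) {
      x <- as.matrix(features[[type]])
      if (is.null(colnames(x)))
        colnames(x) <- paste0(tolower(type), "_v", seq_len(ncol(x)))
      cand <- list()
      for (algo in .BASE_ALGOS) {
        for (k in seq_len(nSearch)) {
          params <- .sampleParams(algo)
          oof <- .oofPredict(algo, params, x, labels, foldIds)
          cand[[length(cand) + 1L]] <- list(
            type = type, algo = algo, params = params, oof = oof,
            cvAuroc = aurocScore(oof, labels))
        }
      }
      candidates[[type]] <- cand
    }
    selected <- list()
    for (type in names(features)) {
      sc <- vapply(candidates[[type]], `[[`, numeric(1), "cvAuroc")
      top <- order(-sc)[seq_len(min(5L, length(sc)))]  # ties: draw order
      x <- as.matrix(features[[type]])
      if (is.null(colnames(x)))
        colnames(x) <- paste0(tolower(type), "_v", seq_len(ncol(x)))
      for (k in top) {
        cd <- candidates[[type]][[k]]
        full <- .fitModel(cd$algo, cd$params, x, labels)
        selected[[length(selected) + 1L]] <- list(
          type = type, algo = cd$algo, params = cd$params,
          cvAuroc = cd$cvAuroc, oof = cd$oof, fit = full,
          importance = .importanceOf(full))
      }
    }
    oof <- vapply(selected, `[[`, numeric(length(labels)), "oof")
    colnames(oof) <- vapply(seq_along(selected), function(i)
      sprintf("%s_%s_%d", selected[[i]]$type, selected[[i]]$algo, i),
      character(1))
    list(selected = selected, oof = oof, candidates = candidates,
         foldIds = foldIds, labels = labels)
  })
}

#' Train the second (stacking) layer
#'
#' Random search over elastic net, gradient boosting and random forest on
#' the 20-column out-of-fold score matrix, scored by the same
#' cross-validation folds; the five best stacked models are kept and refit
#' on the full matrix.
#'
#' @param oof n x 20 matrix of base out-of-fold scores.
#' @param labels Binary labels.
#' @param foldIds Fold assignment (reuse the base layer's).
#' @param nSearch Draws per algorithm (default 12, i.e. 36 candidates).
#' @param seed RNG seed.
#' @return List with `selected` (5 stacked model specs with fits, per-model
#'   importance over the 20 base columns, and stack out-of-fold scores) and
#'   `params` (the drawn candidate grid, reused by fold-honest evaluation).
#' @export
trainStackLayer <- function(oof, labels, foldIds, nSearch = 12L, seed = 1L) {
  if (ncol(oof) != 20L)
    stop("stacking expects exactly 20 base model columns, got ", ncol(oof))
  labels <- as.numeric(labels > 0)
  .withSeed(seed + 1L, {
    grid <- list()
    for (algo in .STACK_ALGOS)
      for (k in seq_len(nSearch))
        grid[[length(grid) + 1L]] <- list(algo = algo,
                                          params = .sampleParams(algo))
    cand <- lapply(grid, function(g) {
      so <- .oofPredict(g$algo, g$params, oof, labels, foldIds)
      list(algo = g$algo, params = g$params, oof = so,
           cvAuroc = aurocScore(so, labels))
    })
    sc <- vapply(cand, `[[`, numeric(1), "cvAuroc")
    top <- order(-sc)[seq_len(5L)]
    selected <- lapply(top, function(k) {
      cd <- cand[[k]]
      full <- .fitModel(cd$algo, cd$params, oof, labels)
      c(cd, list(fit = full, importance = .importanceOf(full)))
    })
    list(selected = selected, params = grid)
  })
}

## fold-honest cross-validated ensemble scores: base-model selection redone
## per evaluated fold without that fold's labels, stack-model selection by
## inner CV on the remaining rows — the evaluated fold's labels touch
## nothing upstream of its own predictions
.honestCvScores <- function(base, stackGrid, nInner = 4L, seed = 1L) {
  labels <- base$labels
  foldIds <- base$foldIds
  n <- length(labels)
  scores <- numeric(n)
  .withSeed(seed + 2L, {
    for (f in sort(unique(foldIds))) {
      tr <- foldIds != f
      cols <- list()
      for (type in names(base$candidates)) {
        sc <- vapply(base$candidates[[type]], function(cd)
          aurocScore(cd$oof[tr], labels[tr]), numeric(1))
        top <- order(-sc)[seq_len(min(5L, length(sc)))]
        cols <- c(cols, lapply(base$candidates[[type]][top], `[[`, "oof"))
      }
      Z <- do.call(cbind, cols)
      colnames(Z) <- paste0("base", seq_len(ncol(Z)))
      inner <- .makeFolds(labels[tr], nInner)
      innerAuroc <- vapply(stackGrid, function(g)
        aurocScore(.oofPredict(g$algo, g$params, Z[tr, , drop = FALSE],
                               labels[tr], inner), labels[tr]),
        numeric(1))
      top5 <- order(-innerAuroc)[seq_len(5L)]
      preds <- vapply(stackGrid[top5], function(g) {
        m <- .fitModel(g$algo, g$params, Z[tr, , drop = FALSE], labels[tr])
        .predictModel(m, Z[!tr, , drop = FALSE])
      }, numeric(sum(!tr)))
      scores[!tr] <- rowMeans(preds)
    }
  })
  scores
}

#' Train the full two-layer ensemble
#'
#' Runs [trainBaseLayer()] and [trainStackLayer()], computes fold-honest
#' cross-validated ensemble scores (base and stack model selection redone
#' without the evaluated fold), and chooses the Youden-index decision
#' threshold on those scores.
#'
#' @inheritParams trainBaseLayer
#' @param nSearchStack Stack-layer draws per algorithm.
#' @return A [CfdnaEnsemble-class].
#' @export
trainEnsemble <- function(features, labels, nFolds = 5L, nSearch = 13L,
                          nSearchStack = 12L, seed = 1L) {
  labels <- as.numeric(labels > 0)
  base <- trainBaseLayer(features, labels, nFolds = nFolds, nSearch = nSearch,
                         seed = seed)
  stack <- trainStackLayer(base$oof, labels, base$foldIds,
                           nSearch = nSearchStack, seed = seed)
  cvScores <- .honestCvScores(base, stack$params, seed = seed)
  methods::new("CfdnaEnsemble",
    baseModels = base$selected, stackModels = stack$selected,
    foldIds = base$foldIds, oof = base$oof,
    cvScores = cvScores, cvAuroc = aurocScore(cvScores, labels),
    threshold = as.numeric(youdenThreshold(cvScores, labels)),
    labels = labels,
    featureNames = lapply(features, function(m) {
      cn <- colnames(as.matrix(m))
      if (is.null(cn)) character(0) else cn
    }),
    seed = as.integer(seed))
}

#' Predict ensemble cancer scores for new samples
#'
#' Runs the 20 full-data base models on their feature blocks and averages
#' the five stacked models' outputs on the resulting 20 base scores.
#'
#' @param model A [CfdnaEnsemble-class].
#' @param features Named list of feature matrices covering every feature
#'   type the model was trained on (same columns).
#' @return Numeric scores in \[0, 1\], one per row.
#' @export
predictEnsemble <- function(model, features) {
  types <- unique(vapply(model@baseModels, `[[`, character(1), "type"))
  missing <- setdiff(types, names(features))
  if (length(missing))
    stop("missing feature block(s): ", paste(missing, collapse = ", "))
  n <- nrow(as.matrix(features[[types[1]]]))
  baseScores <- vapply(model@baseModels, function(b)
    .predictModel(b$fit, features[[b$type]]), numeric(n))
  colnames(baseScores) <- colnames(model@oof)
  stackPred <- vapply(model@stackModels, function(s)
    .predictModel(s$fit, baseScores), numeric(n))
  rowMeans(stackPred)
}
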