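# Base learners behind a uniform train/predict surface.
#
# RF is a ranger forest (Gini splitting, probability leaves) so the fitted
# trees expose per-node structure for impurity-based importance. GB is
# xgboost with prior log-odds as base margin, which makes it behave as a
# stagewise additive model starting from the class prior (learning rate 0
# degrades to the majority class). LR is elastic-net multinomial regression
# (glmnet), SVM is e1071. KNN (Manhattan/Euclidean, uniform/distance
# weights) and AdaBoost (SAMME over depth-limited CART trees) are
# implemented here: no installed package offers those exact
# parameterizations.

LEARNERS <- c("RF", "GB", "LR", "SVM", "KNN", "ADA")

#' Train a single base learner
#'
#' @param kind One of `"RF"`, `"GB"`, `"LR"`, `"SVM"`, `"KNN"`, `"ADA"`.
#' @param config Named list of hyperparameters; must lie inside the
#'   learner's search space (see [rf_space()] and friends).
#' @param train A `labeled_dataset`.
#' @param seed Integer seed for any training-time randomness.
#' @return A fitted `sw_model` recording its configuration.
#' @export
train_learner <- function(kind, config, train, seed = 1L) {
  kind <- match.arg(kind, LEARNERS)
  validate_config(kind, config)
  X <- ld_matrix(train)
  y <- train$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    sw_abort("training data must contain at least 2 classes", "sw_validation_error")
  fit <- switch(kind,
    RF = fit_rf(X, y, classes, config, seed),
    GB = fit_gb(X, y, classes, config, seed),
    LR = fit_lr(X, y, classes, config, seed),
    SVM = fit_svm(X, y, classes, config, seed),
    KNN = list(X = X, y = y),
    ADA = fit_ada(X, y, classes, config, seed)
  )
  structure(list(kind = kind, config = config, fit = fit, classes = classes,
                 feature_names = colnames(X), X = X, y = y, seed = seed),
            class = c(paste0("sw_", tolower(kind)), "sw_model"))
}

#' @export
print.sw_model <- function(x, ...) {
  cfg <- paste(names(x$config), unlist(lapply(x$config, format)),
               sep = "=", collapse = ", ")
  cat(sprintf("<sw_model:%s> classes {%s}; %s\n", x$kind,
              paste(x$classes, collapse = ","), cfg))
  invisible(x)
}

as_feature_matrix <- function(model, newdata) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[model$feature_names])
  newdata
}

#' Predict stress classes
#'
#' @param object A fitted `sw_model`.
#' @param newdata Feature table, matrix, or `labeled_dataset`.
#' @param ... Unused.
#' @return Integer class labels.
#' @export
predict.sw_model <- function(object, newdata, ...) {
  P <- predict_proba(object, newdata)
  object$classes[max.col(P, ties.method = "first")]
}

# Class-probability matrix (columns ordered as model$classes).
predict_proba <- function(model, newdata) {
  X <- as_feature_matrix(model, newdata)
  P <- switch(model$kind,
    RF = {
      p <- stats::predict(model$fit, data = X, num.threads = 1L)$predictions
      p[, as.character(model$classes), drop = FALSE]
    },
    GB = {
      dm <- xgboost::xgb.DMatrix(X)
      xgboost::setinfo(dm, "base_margin",
                       matrix(rep(model$fit$log_prior, each = nrow(X)),
                              nrow(X), length(model$classes)))
      p <- stats::predict(model$fit$booster, dm)
      if (is.matrix(p)) p
      else matrix(p, nrow(X), length(model$classes), byrow = TRUE)
    },
    LR = {
      p <- stats::predict(model$fit, newx = X, type = "response",
                          s = model$fit$sw_lambda)
      p[, , 1L][, as.character(model$classes), drop = FALSE]
    },
    SVM = {
      d <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                "decision.values")
      # one-vs-one votes -> pseudo-probabilities by normalized vote share
      vote_probs(d, model$classes)
    },
    KNN = knn_proba(model, X),
    ADA = ada_proba(model, X)
  )
  colnames(P) <- as.character(model$classes)
  P
}

vote_probs <- function(decision, classes) {
  K <- length(classes)
  votes <- matrix(0, nrow(decision), K, dimnames = list(NULL, as.character(classes)))
  pairs <- strsplit(colnames(decision), "/")
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1L]; b <- pairs[[j]][2L]
    pos <- decision[, j] > 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
  }
  votes / rowSums(votes)
}

# ---- Random forest (ranger) -------------------------------------------------

fit_rf <- function(X, y, classes, config, seed) {
  p <- ncol(X)
  mtry <- switch(config$max_features,
                 sqrt = max(1L, floor(sqrt(p))),
                 log2 = max(1L, floor(log2(p))))
  ranger::ranger(
    x = X, y = factor(y, levels = classes),
    num.trees = config$n_estimators,
    mtry = mtry,
    max.depth = config$max_depth,
    min.node.size = config$min_samples_split,
    min.bucket = config$min_samples_leaf,
    replace = isTRUE(config$bootstrap),
    sample.fraction = 1,
    probability = TRUE,
    keep.inbag = TRUE,
    num.threads = 1L,
    seed = seed
  )
}

# ---- Gradient boosting (xgboost, prior-initialized) -------------------------

fit_gb <- function(X, y, classes, config, seed) {
  K <- length(classes)
  yidx <- match(y, classes) - 1L
  prior <- as.numeric(table(factor(y, levels = classes))) / length(y)
  log_prior <- log(pmax(prior, 1e-12))
  dtr <- xgboost::xgb.DMatrix(X, label = yidx)
  xgboost::setinfo(dtr, "base_margin",
                   matrix(rep(log_prior, each = nrow(X)), nrow(X), K))
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = K,
                  eta = config$learning_rate, max_depth = config$max_depth,
                  lambda = 0, subsample = 1, colsample_bytree = 1,
                  nthread = 1L, seed = seed),
    data = dtr, nrounds = config$n_estimators, verbose = 0
  )
  list(booster = booster, log_prior = log_prior)
}

# ---- Logistic regression (glmnet elastic net) -------------------------------

fit_lr <- function(X, y, classes, config, seed) {
  # map the cost parameter C to glmnet's per-observation penalty scale;
  # fit a short decreasing path down to the target for warm starts
  lambda <- 1 / (config$C * nrow(X))
  yf <- factor(y, levels = classes)
  fit_path <- function(path, maxit) suppressWarnings(
    glmnet::glmnet(X, yf, family = "multinomial", alpha = config$alpha,
                   lambda = path, maxit = maxit, standardize = FALSE))
  # glmnet hard-errors when no path point converges within maxit; widen the
  # warm-start path, then lift the cap, so a usable solution is always
  # returned (the iteration cap is advisory, as in reference solvers that
  # return the current iterate with a convergence warning)
  fit <- tryCatch(
    fit_path(lambda * c(16, 8, 4, 2, 1), config$max_iter),
    error = function(e) tryCatch(
      fit_path(lambda * 2^(8:0), config$max_iter * 10),
      error = function(e2) fit_path(lambda * 2^(8:0), 1e6)))
  fit$sw_lambda <- max(lambda, min(fit$lambda))
  fit
}

# ---- Support vector machine (e1071) -----------------------------------------

fit_svm <- function(X, y, classes, config, seed) {
  gamma <- switch(as.character(config$gamma),
                  scale = 1 / (ncol(X) * max(pop_var(X), 1e-12)),
                  auto = 1 / ncol(X),
                  as.numeric(config$gamma))
  e1071::svm(x = X, y = factor(y, levels = classes), cost = config$C,
             kernel = config$kernel, gamma = gamma, scale = FALSE)
}

pop_var <- function(X) mean((X - mean(X))^2)

# ---- K-nearest neighbours ---------------------------------------------------

knn_proba <- function(model, Xte) {
  Xtr <- model$fit$X
  ytr <- model$fit$y
  k <- model$config$n_neighbors
  K <- length(model$classes)
  D <- if (model$config$metric == "euclidean") {
    sq <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
      outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * Xte %*% t(Xtr)
    sqrt(pmax(sq, 0))
  } else {
    D0 <- matrix(0, nrow(Xte), nrow(Xtr))
    for (j in seq_len(ncol(Xtr)))
      D0 <- D0 + abs(outer(Xte[, j], Xtr[, j], `-`))
    D0
  }
  P <- matrix(0, nrow(Xte), K)
  for (i in seq_len(nrow(Xte))) {
    nn <- order(D[i, ])[seq_len(min(k, ncol(D)))]
    w <- if (model$config$weights == "uniform") rep(1, length(nn)) else {
      d <- D[i, nn]
      if (any(d == 0)) as.numeric(d == 0) else 1 / d
    }
    for (j in seq_along(nn)) {
      cls <- match(ytr[nn[j]], model$classes)
      P[i, cls] <- P[i, cls] + w[j]
    }
  }
  P / rowSums(P)
}

# ---- AdaBoost (SAMME over rpart trees) --------------------------------------

fit_ada <- function(X, y, classes, config, seed) {
  n <- nrow(X)
  K <- length(classes)
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = classes)
  w <- rep(1 / n, n)
  stages <- list()
  ctrl <- rpart::rpart.control(maxdepth = config$max_depth, cp = 0, xval = 0,
                               minsplit = 2, minbucket = 1)
  with_rng(seed, {
    for (m in seq_len(config$n_estimators)) {
      tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                           control = ctrl)
      pred <- stats::predict(tree, df, type = "class")
      miss <- pred != df$.y
      err <- sum(w[miss])
      if (err <= 0) {            # perfect stage: take it with full weight, stop
        stages[[m]] <- list(tree = tree, alpha = 1)
        break
      }
      if (err >= 1 - 1 / K) break  # no better than chance: discard and stop
      alpha <- config$learning_rate * (log((1 - err) / err) + log(K - 1))
      stages[[m]] <- list(tree = tree, alpha = alpha)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  })
  list(stages = stages, prior = as.numeric(table(df$.y)) / n)
}

ada_proba <- function(model, Xte) {
  K <- length(model$classes)
  stages <- model$fit$stages
  score <- matrix(0, nrow(Xte), K)
  df <- as.data.frame(Xte)
  for (st in stages) {
    pred <- stats::predict(st$tree, df, type = "class")
    idx <- match(as.character(pred), as.character(model$classes))
    score[cbind(seq_len(nrow(Xte)), idx)] <-
      score[cbind(seq_len(nrow(Xte)), idx)] + st$alpha
  }
  if (length(stages) == 0L || all(score == 0))  # learning rate 0: class prior
    return(matrix(rep(model$fit$prior, each = nrow(Xte)), nrow(Xte), K))
  score / rowSums(score)
}
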