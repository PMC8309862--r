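# The nine-classifier bank. Hyperparameters live in a registry (data, not
# code) so specs can be inspected, serialized and extended. Backends:
# class::knn, e1071::svm, rpart, randomForest, nnet, e1071::naiveBayes,
# MASS::qda, plus an in-package Real AdaBoost over depth-1 rpart stumps.

model_registry <- function() {
  list(
    list(name = "K-Nearest Neighbors",
         hyperparameters = list(n_neighbors = 3, weights = "uniform",
                                algorithm = "auto", leaf_size = 30,
                                metric = "minkowski", p = 2)),
    list(name = "Poly SVM",
         hyperparameters = list(C = 10, degree = 3, gamma = "scale",
                                break_ties = FALSE, cache_size = 200,
                                decision_function_shape = "ovr",
                                kernel = "poly")),
    list(name = "RBF SVM",
         hyperparameters = list(C = 1, degree = 3, gamma = 2,
                                break_ties = FALSE, cache_size = 200,
                                decision_function_shape = "ovr",
                                kernel = "rbf")),
    list(name = "Decision Tree",
         hyperparameters = list(criterion = "gini", splitter = "best",
                                max_depth = 5, min_samples_split = 2,
                                min_samples_leaf = 1, class_weight = NULL)),
    list(name = "Random Forest",
         hyperparameters = list(n_estimators = 10, criterion = "gini",
                                max_depth = 5, min_samples_split = 2,
                                min_samples_leaf = 1, class_weight = NULL)),
    list(name = "Neural Net",
         hyperparameters = list(hidden_layer_sizes = 100,
                                activation = "relu", solver = "adam",
                                alpha = 1, batch_size = "auto",
                                learning_rate = "constant", power_t = 0.5,
                                learning_rate_init = 0.001, max_iter = 1000,
                                shuffle = TRUE, early_stopping = FALSE)),
    list(name = "AdaBoost",
         hyperparameters = list(algorithm = "SAMME.R",
                                base_estimator = "stump",
                                learning_rate = 1.0, n_estimators = 50)),
    list(name = "G Naive Bayes",
         hyperparameters = list(priors = NULL, var_smoothing = 1e-9)),
    list(name = "QDA",
         hyperparameters = list(priors = NULL, reg_param = 0.0,
                                store_covariance = FALSE, tol = 1e-4))
  )
}

#' The nine default classifier specifications
#'
#' Returns the model bank in stable order with its reference
#' hyperparameters: 3-nearest neighbours; polynomial-kernel SVM (C = 10,
#' degree 3, scale gamma); RBF SVM (C = 1, gamma = 2); Gini decision tree
#' of depth 5; random forest of 10 depth-5 trees; a one-hidden-layer
#' perceptron of width 100 (alpha = 1, up to 1000 iterations); Real
#' AdaBoost over 50 decision stumps; Gaussian naive Bayes; and quadratic
#' discriminant analysis. Stochastic learners carry a fixed default seed
#' so runs are reproducible.
#'
#' @param seed integer seed stored in every spec (default 0).
#' @return a list of nine `model_spec` objects.
#' @export
list_models <- function(seed = 0L) {
  lapply(model_registry(), function(m) {
    m$seed <- as.integer(seed)
    class(m) <- "model_spec"
    m
  })
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- vapply(names(x$hyperparameters), function(k) {
    v <- x$hyperparameters[[k]]
    paste0(k, " = ", if (is.null(v)) "NULL" else format(v))
  }, "")
  cat("<model_spec> ", x$name, "\n  ", paste(hp, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Serialize the model registry to YAML
#'
#' Writes every spec's name and hyperparameters so a bank configuration
#' can be inspected or versioned outside R.
#'
#' @param path output YAML file.
#' @param specs list of `model_spec`s; defaults to the full bank.
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(path, specs = list_models()) {
  yaml::write_yaml(lapply(specs, unclass), path)
  invisible(path)
}

model_spec_by_name <- function(name, seed = 0L) {
  specs <- list_models(seed)
  hit <- which(vapply(specs, `[[`, "", "name") == name)
  if (!length(hit)) stop("unknown model name: ", name, call. = FALSE)
  specs[[hit]]
}

feature_frame <- function(matrix) {
  as.data.frame(matrix)[, feature_cols(), drop = FALSE]
}

# sklearn-style 'scale' kernel coefficient: 1 / (p * Var(X)), with Var the
# population variance over all matrix entries
gamma_scale <- function(X) {
  v <- mean((as.matrix(X) - mean(as.matrix(X)))^2)
  1 / (ncol(X) * v)
}

fingerprint_matrix <- function(X, y) {
  paste(nrow(X), ncol(X),
        format(sum(as.matrix(X)), digits = 12),
        sum(y == 1), sep = ":")
}

#' Train one classifier of the bank
#'
#' Fits `spec` on the 21 feature columns of `train`. Stochastic learners
#' (random forest, neural net) are seeded from `spec$seed`, so repeated
#' training is bit-reproducible. The returned model records its training
#' fingerprint and training accuracy.
#'
#' @param spec a `model_spec` from [list_models()].
#' @param train a non-empty `feature_matrix` containing both classes
#'   (single-class data is an error for the probabilistic/discriminant
#'   models, which cannot estimate a class-conditional density from it).
#' @return a `pest_model` object.
#' @export
train_model <- function(spec, train) {
  stopifnot(inherits(spec, "model_spec"), inherits(train, "feature_matrix"))
  if (nrow(train) == 0) stop("empty training matrix", call. = FALSE)
  X <- feature_frame(train)
  y <- factor(train$label, levels = c(0, 1))
  hp <- spec$hyperparameters
  if (length(unique(train$label)) < 2 &&
      spec$name %in% c("G Naive Bayes", "QDA"))
    stop("degenerate training data: only one class present, cannot fit ",
         spec$name, call. = FALSE)
  state <- withr::with_seed(spec$seed, switch(
    spec$name,
    "K-Nearest Neighbors" = list(X = as.matrix(X), y = y,
                                 k = hp$n_neighbors),
    "Poly SVM" = e1071::svm(x = as.matrix(X), y = y, scale = FALSE,
                            kernel = "polynomial", cost = hp$C,
                            degree = hp$degree, gamma = gamma_scale(X),
                            coef0 = 0, cachesize = hp$cache_size),
    "RBF SVM" = e1071::svm(x = as.matrix(X), y = y, scale = FALSE,
                           kernel = "radial", cost = hp$C,
                           gamma = hp$gamma, cachesize = hp$cache_size),
    "Decision Tree" = rpart::rpart(
      .label ~ ., data = cbind(X, .label = y), method = "class",
      parms = list(split = "gini"),
      control = rpart::rpart.control(maxdepth = hp$max_depth,
                                     minsplit = hp$min_samples_split,
                                     minbucket = hp$min_samples_leaf,
                                     cp = 0, xval = 0)),
    "Random Forest" = randomForest::randomForest(
      x = as.matrix(X), y = y, ntree = hp$n_estimators,
      maxnodes = 2^hp$max_depth, nodesize = hp$min_samples_leaf),
    "Neural Net" = fit_mlp(X, y, hp),
    "AdaBoost" = fit_real_adaboost(X, y,
                                   n_estimators = hp$n_estimators,
                                   learning_rate = hp$learning_rate),
    "G Naive Bayes" = e1071::naiveBayes(x = X, y = y),
    "QDA" = MASS::qda(x = as.matrix(X), grouping = y),
    stop("unknown model name: ", spec$name, call. = FALSE)))
  model <- structure(list(spec = spec, state = state,
                          feature_names = feature_cols(),
                          training_fingerprint = fingerprint_matrix(X, y)),
                     class = "pest_model")
  train_pred <- predict(model, train)
  model$training_accuracy <- mean(train_pred$predicted == train_pred$actual)
  model
}

# One-hidden-layer perceptron via nnet (logistic hidden units, BFGS
# optimizer); width, weight decay and iteration cap come from the spec.
fit_mlp <- function(X, y, hp) {
  width <- hp$hidden_layer_sizes[1]
  nw <- (ncol(X) + 1) * width + (width + 1)
  fit <- nnet::nnet(x = as.matrix(X), y = as.numeric(y == "1"),
                    size = width, decay = hp$alpha,
                    maxit = hp$max_iter, MaxNWts = nw + 10,
                    entropy = TRUE, trace = FALSE)
  if (fit$convergence != 0)
    warning("neural net did not converge within ", hp$max_iter,
            " iterations; returning the final iterate", call. = FALSE)
  fit
}

#' Predict occurrence labels for a feature matrix
#'
#' Hard 0/1 labels through each classifier's native decision rule (no
#' custom threshold), aligned with the matrix rows.
#'
#' @param object a `pest_model`.
#' @param matrix a `feature_matrix` with the training schema.
#' @param ... unused.
#' @return a `prediction_series` data frame with columns `location_id`,
#'   `series_id`, `date`, `actual`, `predicted`.
#' @export
predict.pest_model <- function(object, matrix, ...) {
  stopifnot(inherits(matrix, "feature_matrix"))
  missing_cols <- setdiff(object$feature_names, names(matrix))
  if (length(missing_cols))
    stop("feature matrix lacks training column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(matrix) == 0) {
    out <- data.frame(location_id = character(0), series_id = integer(0),
                      date = as.Date(character(0)), actual = integer(0),
                      predicted = integer(0))
    class(out) <- c("prediction_series", "data.frame")
    return(out)
  }
  X <- feature_frame(matrix)
  st <- object$state
  pred <- switch(
    object$spec$name,
    "K-Nearest Neighbors" = withr::with_seed(
      object$spec$seed,
      as.integer(as.character(class::knn(st$X, as.matrix(X), st$y,
                                         k = st$k)))),
    "Poly SVM" = ,
    "RBF SVM" = as.integer(as.character(predict(st, as.matrix(X)))),
    "Decision Tree" = as.integer(as.character(
      predict(st, X, type = "class"))),
    "Random Forest" = as.integer(as.character(predict(st, as.matrix(X)))),
    "Neural Net" = as.integer(predict(st, as.matrix(X)) > 0.5),
    "AdaBoost" = predict_real_adaboost(st, X),
    "G Naive Bayes" = as.integer(as.character(predict(st, X))),
    "QDA" = as.integer(as.character(predict(st, as.matrix(X))$class)),
    stop("unknown model name: ", object$spec$name, call. = FALSE))
  out <- data.frame(location_id = matrix$location_id,
                    series_id = matrix$series_id,
                    date = matrix$date,
                    actual = as.integer(matrix$label),
                    predicted = pred,
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_series", "data.frame")
  out
}

# ---- Real AdaBoost (two-class SAMME.R) over depth-1 rpart stumps -------
# Each round fits a weighted stump, converts its class-1 probability to a
# half-log-odds score, and reweights misclassified samples exponentially.
# The committee predicts the sign of the summed scores.

fit_real_adaboost <- function(X, y, n_estimators = 50, learning_rate = 1) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  ypm <- ifelse(y == "1", 1, -1)
  df <- cbind(X, .label = y)
  stumps <- vector("list", n_estimators)
  eps <- .Machine$double.eps
  used <- 0L
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.label ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       minbucket = 1,
                                                       cp = -1, xval = 0))
    p1 <- pmin(pmax(predict(fit, df)[, "1"], eps), 1 - eps)
    h <- 0.5 * log(p1 / (1 - p1))
    stumps[[m]] <- fit
    used <- m
    w <- w * exp(-learning_rate * ypm * h)
    s <- sum(w)
    if (!is.finite(s) || s <= 0) break
    w <- w / s
  }
  structure(list(stumps = stumps[seq_len(used)],
                 learning_rate = learning_rate),
            class = "real_adaboost")
}

predict_real_adaboost <- function(object, X) {
  eps <- .Machine$double.eps
  score <- numeric(nrow(X))
  for (fit in object$stumps) {
    p1 <- pmin(pmax(predict(fit, X)[, "1"], eps), 1 - eps)
    score <- score + 0.5 * log(p1 / (1 - p1))
  }
  as.integer(score > 0)
}

#' Apply the model-exclusion rule to validation confusion counts
#'
#' Two-part rule mirroring how a practitioner prunes a classifier bank on
#' imbalanced validation data: a model is excluded when its false
#' positives exceed its true positives (it raises more false alarms than
#' real detections), or when its true-positive count is "low" -- below a
#' configurable fraction (default 0.5) of the best model's TP.
#'
#' @param validation_results data frame with columns `model`, `TN`, `FP`,
#'   `FN`, `TP` (one row per model).
#' @param low_tp_fraction models with `TP < low_tp_fraction * max(TP)` are
#'   excluded; default 0.5.
#' @return list with `retained` (character vector of model names) and
#'   `excluded` (data frame of model/reason pairs).
#' @export
select_models <- function(validation_results, low_tp_fraction = 0.5) {
  vr <- as.data.frame(validation_results)
  if (nrow(vr) == 0) stop("empty validation results", call. = FALSE)
  stopifnot(all(c("model", "FP", "TP") %in% names(vr)))
  best_tp <- max(vr$TP)
  reasons <- character(nrow(vr))
  fp_rule <- vr$FP > vr$TP
  tp_rule <- vr$TP < low_tp_fraction * best_tp
  reasons[tp_rule] <- "low TP"
  reasons[fp_rule] <- ifelse(tp_rule[fp_rule],
                             "FP exceeds TP; low TP", "FP exceeds TP")
  excluded <- data.frame(model = vr$model[fp_rule | tp_rule],
                         reason = reasons[fp_rule | tp_rule],
                         stringsAsFactors = FALSE)
  list(retained = vr$model[!(fp_rule | tp_rule)], excluded = excluded)
}
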