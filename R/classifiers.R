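# Classifier backends behind a uniform fit/predict contract. Each config is
# list(kind, label, info, params); fit_classifier() returns a closure that
# predicts class labels for new rows. Backend internals are pluggable: any
# implementation honouring the hyperparameter notes qualifies.

#' The default ten-classifier suite
#'
#' Two depth-limited decision trees (at most 10 and 5 splits), linear
#' discriminant analysis, Gaussian naive Bayes, a linear-kernel SVM, two
#' Euclidean k-nearest-neighbour classifiers (k = 20, k = 5), a bagging
#' decision forest, a boosting decision forest (shallow trees) and a
#' single-hidden-layer neural network with 10 hidden neurons.
#'
#' @return List of classifier configs for [run_benchmark()].
#' @export
default_classifier_suite <- function() {
  list(
    list(kind = "decision_tree", label = "decision tree (max 10 splits)",
         info = "max. 10 splits", params = list(max_splits = 10L)),
    list(kind = "decision_tree", label = "decision tree (max 5 splits)",
         info = "max. 5 splits", params = list(max_splits = 5L)),
    list(kind = "discriminant_analysis", label = "discriminant analysis",
         info = "", params = list()),
    list(kind = "naive_bayes", label = "naive Bayes", info = "", params = list()),
    list(kind = "svm_linear", label = "support vector machine",
         info = "linear kernel", params = list()),
    list(kind = "knn", label = "k nearest neighbors (k = 20)",
         info = "k = 20, euclidean distance", params = list(k = 20L)),
    list(kind = "knn", label = "k nearest neighbors (k = 5)",
         info = "k = 5, euclidean distance", params = list(k = 5L)),
    list(kind = "decision_forest_bagging", label = "decision forest (bagging)",
         info = "bagging", params = list(n_trees = 100L)),
    list(kind = "decision_forest_boosting", label = "decision forest (boosting)",
         info = "boosting, max 10 splits",
         params = list(max_splits = 10L, n_rounds = 30L)),
    list(kind = "neural_network", label = "neural network",
         info = "10 hidden neurons, tansig function",
         params = list(hidden = 10L))
  )
}

# Grow an unpruned tree, then prune back to the largest subtree whose split
# count does not exceed max_splits (the cptable enumerates the nested
# optimal subtrees by split count).
fit_tree_limited <- function(df, max_splits) {
  fit <- rpart::rpart(label ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = 0, minsplit = 2L,
                                                     xval = 0L))
  tab <- fit$cptable
  ok <- tab[tab[, "nsplit"] <= max_splits, , drop = FALSE]
  if (nrow(ok) < nrow(tab)) {
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"] + 1e-12)
  }
  fit
}

majority_class <- function(y) {
  names(which.max(table(y)))
}

fit_classifier <- function(config, x_train, y_train) {
  df <- as.data.frame(x_train)
  names(df) <- paste0("V", seq_len(ncol(x_train)))
  df$label <- y_train
  lvls <- levels(y_train)
  wrap_df <- function(x_new) {
    nd <- as.data.frame(x_new)
    names(nd) <- paste0("V", seq_len(ncol(x_new)))
    nd
  }
  fallback <- majority_class(y_train)
  switch(config$kind,
    decision_tree = {
      fit <- fit_tree_limited(df, config$params$max_splits)
      function(x_new) as.character(predict(fit, wrap_df(x_new), type = "class"))
    },
    discriminant_analysis = {
      fit <- tryCatch(MASS::lda(label ~ ., data = df), error = function(e) NULL)
      function(x_new) {
        if (is.null(fit)) return(rep(fallback, nrow(x_new)))
        as.character(stats::predict(fit, wrap_df(x_new))$class)
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(label ~ ., data = df)
      function(x_new) as.character(predict(fit, wrap_df(x_new)))
    },
    svm_linear = {
      fit <- e1071::svm(label ~ ., data = df, kernel = "linear")
      function(x_new) as.character(predict(fit, wrap_df(x_new)))
    },
    knn = {
      k <- min(config$params$k, nrow(df))
      function(x_new) {
        as.character(class::knn(as.matrix(df[, -ncol(df), drop = FALSE]),
                                as.matrix(x_new), df$label, k = k))
      }
    },
    decision_forest_bagging = {
      fit <- randomForest::randomForest(
        x = df[, -ncol(df), drop = FALSE], y = df$label,
        ntree = config$params$n_trees)
      function(x_new) as.character(predict(fit, wrap_df(x_new)))
    },
    decision_forest_boosting = {
      # "max splits" maps to a leaf budget: a tree with s splits has s + 1 leaves
      fit <- xgboost::xgboost(
        as.matrix(x_train), droplevels(y_train),
        nrounds = config$params$n_rounds,
        max_leaves = config$params$max_splits + 1L,
        grow_policy = "lossguide", tree_method = "hist",
        nthreads = 1L, verbosity = 0
      )
      lvls_present <- levels(droplevels(y_train))
      function(x_new) {
        p <- predict(fit, as.matrix(x_new))
        if (is.null(dim(p))) {
          # binary fit: single column of probabilities for the second level
          lvls_present[1L + (p > 0.5)]
        } else {
          colnames(p)[max.col(p, ties.method = "first")]
        }
      }
    },
    neural_network = {
      fit <- tryCatch(
        nnet::nnet(label ~ ., data = df, size = config$params$hidden,
                   decay = 1e-3, maxit = 200L, trace = FALSE,
                   MaxNWts = 5000L),
        error = function(e) NULL)
      function(x_new) {
        if (is.null(fit)) return(rep(fallback, nrow(x_new)))
        as.character(predict(fit, wrap_df(x_new), type = "class"))
      }
    },
    vag_stop(sprintf("unknown classifier kind '%s'", config$kind))
  )
}
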