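# Overlap classification: decision tree (rpart, information gain, cost-
# complexity pruned), naive Bayes with Gaussian or kernel-density class-
# conditional densities (own implementation, so that a missing comparative
# score simply drops that feature's likelihood term), and random forest.

ALGORITHMS <- c("decision_tree", "naive_bayes_gaussian", "naive_bayes_kde",
                "random_forest")

#' OverlapClassifier
#'
#' A fitted overlap classifier with its feature schema.  Inputs to
#' [predictLabels()] must carry exactly the training feature columns.
#'
#' @slot algorithm One of `decision_tree`, `naive_bayes_gaussian`,
#'   `naive_bayes_kde`, `random_forest`.
#' @slot fit The fitted model object.
#' @slot schema Character vector of feature column names.
#' @slot seed Integer training seed.
#' @slot extra List of algorithm-specific state (e.g. random-forest
#'   imputation medians).
#' @aliases OverlapClassifier
#' @exportClass OverlapClassifier
setClass("OverlapClassifier",
         representation(algorithm = "character", fit = "ANY",
                        schema = "character", seed = "integer",
                        extra = "list"))

setValidity("OverlapClassifier", function(object) {
  if (!object@algorithm %in% ALGORITHMS)
    return(paste("unknown algorithm:", object@algorithm))
  if (!length(object@schema)) return("empty feature schema")
  TRUE
})

setMethod("show", "OverlapClassifier", function(object) {
  cat("OverlapClassifier\n")
  cat(sprintf("  algorithm: %s\n", object@algorithm))
  cat(sprintf("  features (%d): %s\n", length(object@schema),
              paste(object@schema, collapse = ", ")))
  cat(sprintf("  training seed: %d\n", object@seed))
})

KEY_COLUMNS <- c("readA", "readB", "orientation", "label")

# Numeric feature columns of a feature table (keys and label dropped).
feature_matrix <- function(features, schema = NULL) {
  features <- as.data.frame(features)
  if (is.null(schema))
    schema <- setdiff(names(features), KEY_COLUMNS)
  miss <- setdiff(schema, names(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- features[schema]
  for (nm in schema) x[[nm]] <- as.numeric(x[[nm]])
  x
}

as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "true", "false")
  bad <- setdiff(unique(labels), c("true", "false"))
  if (length(bad))
    stop("labels must be 'true' or 'false', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  factor(labels, levels = c("true", "false"))
}

# --- naive Bayes engine -----------------------------------------------------

nb_fit <- function(x, y, kernel) {
  classes <- levels(y)
  prior <- table(y) / length(y)
  dens <- lapply(classes, function(cl) {
    lapply(x, function(col) {
      v <- col[y == cl & !is.na(col)]
      if (length(v) < 2L || sd(v) == 0) {
        m <- if (length(v)) mean(v) else 0
        s <- max(sd(v), 1e-6, na.rm = TRUE)
        if (is.na(s)) s <- 1e-6
        list(type = "gaussian", mean = m, sd = s)
      } else if (kernel) {
        d <- stats::density(v, n = 512)
        list(type = "kde", x = d$x, y = pmax(d$y, 1e-12))
      } else {
        list(type = "gaussian", mean = mean(v), sd = max(sd(v), 1e-9))
      }
    })
  })
  names(dens) <- classes
  list(prior = prior, dens = dens, classes = classes)
}

nb_loglik <- function(fit, x, cl) {
  n <- nrow(x)
  ll <- rep(log(as.numeric(fit$prior[cl])), n)
  for (nm in names(x)) {
    d <- fit$dens[[cl]][[nm]]
    v <- x[[nm]]
    ok <- !is.na(v)
    if (!any(ok)) next
    lk <- if (d$type == "gaussian")
      stats::dnorm(v[ok], d$mean, d$sd)
    else
      stats::approx(d$x, d$y, xout = v[ok], rule = 2)$y
    ll[ok] <- ll[ok] + log(pmax(lk, 1e-300))
  }
  ll
}

nb_predict <- function(fit, x) {
  ll <- vapply(fit$classes, function(cl) nb_loglik(fit, x, cl),
               numeric(nrow(x)))
  if (nrow(x) == 1L) ll <- matrix(ll, nrow = 1L,
                                  dimnames = list(NULL, fit$classes))
  fit$classes[max.col(ll, ties.method = "first")]
}

# --- training ---------------------------------------------------------------

#' Train an overlap classifier
#'
#' Trains on a labelled feature table.  Missing feature values (e.g. an
#' undefined comparative score) are supported natively: the decision tree
#' uses surrogate splits, naive Bayes omits the feature's likelihood term,
#' and the random forest imputes training medians alongside a missingness
#' indicator column.  All algorithms are deterministic given `seed`.
#'
#' @param features Feature table (data.frame); key columns `readA, readB,
#'   orientation` and `label` are ignored as predictors.
#' @param labels Labels (`"true"`/`"false"`, factor or logical); if
#'   omitted, taken from the `label` column of `features`.
#' @param algorithm One of `"decision_tree"`, `"naive_bayes_gaussian"`,
#'   `"naive_bayes_kde"`, `"random_forest"`.
#' @param seed Integer training seed.
#' @param hyperparams Optional list: `minbucket` and `cp` for the tree,
#'   `ntree` for the forest.
#' @return An [OverlapClassifier-class].
#' @export
trainClassifier <- function(features, labels = NULL,
                            algorithm = "decision_tree", seed = 1L,
                            hyperparams = list()) {
  if (!is.character(algorithm) || !algorithm %in% ALGORITHMS)
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  if (is.null(labels)) {
    if (!"label" %in% names(as.data.frame(features)))
      stop("no labels given and no 'label' column present", call. = FALSE)
    labels <- as.data.frame(features)$label
  }
  y <- as_label_factor(labels)
  x <- feature_matrix(features)
  if (nrow(x) != length(y))
    stop("features and labels differ in length", call. = FALSE)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("training set contains a single class", call. = FALSE)
  drop_all_na <- vapply(x, function(col) all(is.na(col)), TRUE)
  x <- x[!drop_all_na]
  if (!ncol(x)) stop("no usable feature columns", call. = FALSE)
  seed <- as.integer(seed)
  extra <- list()
  fit <- with_seed(seed, switch(
    algorithm,
    decision_tree = {
      ctrl <- rpart::rpart.control(
        minbucket = hyperparams$minbucket %||% 2L,
        cp = hyperparams$cp %||% 0,
        xval = 10L, maxsurrogate = 5L, usesurrogate = 2L)
      df <- cbind(x, .label = y)
      tree <- rpart::rpart(.label ~ ., data = df, method = "class",
                           parms = list(split = "information"),
                           control = ctrl)
      cptab <- tree$cptable
      best <- cptab[which.min(cptab[, "xerror"]), "CP"]
      rpart::prune(tree, cp = best)
    },
    naive_bayes_gaussian = nb_fit(x, y, kernel = FALSE),
    naive_bayes_kde = nb_fit(x, y, kernel = TRUE),
    random_forest = {
      med <- vapply(x, function(col) {
        m <- median(col, na.rm = TRUE)
        if (is.na(m)) 0 else m
      }, 0)
      xi <- x
      for (nm in names(xi)) {
        nas <- is.na(xi[[nm]])
        if (any(nas)) {
          xi[[paste0(nm, "_missing")]] <- as.numeric(nas)
          xi[[nm]][nas] <- med[[nm]]
        }
      }
      extra <- list(medians = med, indicator = grep("_missing$", names(xi),
                                                    value = TRUE))
      randomForest::randomForest(x = xi, y = y,
                                 ntree = hyperparams$ntree %||% 100L)
    }))
  methods::new("OverlapClassifier", algorithm = algorithm, fit = fit,
               schema = names(x), seed = seed, extra = extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict overlap labels
#'
#' @param model An [OverlapClassifier-class].
#' @param features Feature table with exactly the model's schema columns
#'   (key columns are ignored).
#' @return Factor of predictions with levels `true, false`, one per row.
#' @export
predictLabels <- function(model, features) {
  stopifnot(methods::is(model, "OverlapClassifier"))
  features <- as.data.frame(features)
  extra_cols <- setdiff(setdiff(names(features), KEY_COLUMNS), model@schema)
  miss <- setdiff(model@schema, names(features))
  if (length(miss))
    stop("feature table lacks model features: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(extra_cols))
    stop("feature table has unknown feature columns: ",
         paste(extra_cols, collapse = ", "), call. = FALSE)
  x <- feature_matrix(features, model@schema)
  if (!nrow(x)) return(factor(character(0), levels = c("true", "false")))
  pred <- switch(
    model@algorithm,
    decision_tree = as.character(predict(model@fit, newdata = x,
                                         type = "class")),
    naive_bayes_gaussian = nb_predict(model@fit, x),
    naive_bayes_kde = nb_predict(model@fit, x),
    random_forest = {
      med <- model@extra$medians
      for (nm in names(x)) {
        nas <- is.na(x[[nm]])
        ind <- paste0(nm, "_missing")
        if (ind %in% model@extra$indicator)
          x[[ind]] <- as.numeric(nas)
        if (any(nas)) x[[nm]][nas] <- med[[nm]]
      }
      as.character(predict(model@fit, newdata = x))
    })
  factor(pred, levels = c("true", "false"))
}

#' Classification metrics for overlap predictions
#'
#' `true` is the positive class.  Accuracy is correct predictions over all
#' overlaps; the false positive rate is actual-false overlaps predicted
#' true over all actual-false overlaps; the false negative rate is
#' actual-true overlaps predicted false over all actual-true overlaps.
#'
#' @param predicted,actual Label vectors (`"true"`/`"false"`) of equal
#'   length.
#' @return A list of class `occMetrics` with counts `n_true, n_false, TP,
#'   FP, TN, FN` and rates `accuracy, false_positive_rate,
#'   false_negative_rate`.
#' @export
evaluateClassification <- function(predicted, actual) {
  p <- as_label_factor(predicted)
  a <- as_label_factor(actual)
  if (length(p) != length(a))
    stop("predicted and actual differ in length", call. = FALSE)
  if (!length(p)) stop("empty label vectors", call. = FALSE)
  TP <- sum(p == "true" & a == "true")
  FP <- sum(p == "true" & a == "false")
  TN <- sum(p == "false" & a == "false")
  FN <- sum(p == "false" & a == "true")
  out <- list(n_true = TP + FN, n_false = FP + TN,
              TP = TP, FP = FP, TN = TN, FN = FN,
              accuracy = (TP + TN) / length(p),
              false_positive_rate = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
              false_negative_rate = if (FN + TP > 0) FN / (FN + TP) else NA_real_)
  class(out) <- "occMetrics"
  out
}

#' @export
print.occMetrics <- function(x, ...) {
  cat("Overlap classification metrics\n")
  cat(sprintf("  actual true/false: %d / %d\n", x$n_true, x$n_false))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy: %.4f\n", x$accuracy))
  cat(sprintf("  false positive rate: %.4f\n", x$false_positive_rate))
  cat(sprintf("  false negative rate: %.4f\n", x$false_negative_rate))
  invisible(x)
}
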