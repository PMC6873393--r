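#' Trainer contract
#'
#' A trainer is any pair of functions `fit(x, labels) -> model` and
#' `predict(model, newdata) -> labels`.  The cross-validation harness and the
#' tuning loop consume classifiers only through this contract, so any method
#' (including external decision-tree / neural-network / SVM implementations)
#' can be benchmarked by wrapping it.
#'
#' @param fit function of `(x, labels)` returning a fitted model.
#' @param predict function of `(model, newdata)` returning one label per row.
#' @param name method label used in reports.
#' @return a `trainer` object.
#' @export
trainer <- function(fit, predict, name = "custom") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, name = name),
            class = "trainer")
}

#' Rule-classifier trainer
#' @param max_error,max_bins,top_k passed to [llm_train()].
#' @return a `trainer`.
#' @export
llm_trainer <- function(max_error = 0.05, max_bins = 4L, top_k = NULL) {
  trainer(fit = function(x, labels) {
            llm_train(x, labels, max_error = max_error,
                      max_bins = max_bins, top_k = top_k)
          },
          predict = function(model, newdata) predict(model, newdata),
          name = sprintf("llm(max_error=%g)", max_error))
}

#' k-nearest-neighbour trainer
#'
#' Euclidean distance after per-feature standardization (training mean and
#' standard deviation; constant features get scale 1), majority vote among
#' the k nearest training samples.  Vote ties are broken by the class of the
#' nearest neighbour among the tied classes, then lexicographically.
#'
#' @param k number of neighbours.
#' @return a `trainer`.
#' @export
knn_trainer <- function(k = 3L) {
  trainer(
    fit = function(x, labels) {
      x <- as_expression_matrix(x)
      mu <- colMeans(x)
      sd <- apply(x, 2L, stats::sd)
      sd[sd == 0 | is.na(sd)] <- 1
      list(x = sweep(sweep(x, 2L, mu), 2L, sd, "/"),
           labels = as.character(labels), mu = mu, sd = sd, k = k)
    },
    predict = function(model, newdata) {
      if (is.null(dim(newdata))) {
        newdata <- matrix(newdata, nrow = 1L,
                          dimnames = list(NULL, names(newdata)))
      }
      newdata <- newdata[, colnames(model$x), drop = FALSE]
      z <- sweep(sweep(newdata, 2L, model$mu), 2L, model$sd, "/")
      apply(z, 1L, function(row) {
        d <- sqrt(colSums((t(model$x) - row)^2))
        nb <- order(d)[seq_len(min(model$k, length(d)))]
        votes <- table(model$labels[nb])
        top <- names(votes)[votes == max(votes)]
        if (length(top) == 1L) return(top)
        first <- model$labels[nb][model$labels[nb] %in% top][1L]
        if (!is.na(first)) first else sort(top)[1L]
      })
    },
    name = sprintf("knn(k=%d)", k))
}

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a model trained on the remaining n-1 samples.
#' All preprocessing a trainer performs (discretization, filtering, scaling)
#' is refit inside each fold, so no information from the held-out sample can
#' leak into its own prediction.
#'
#' @param x expression matrix, samples in rows.
#' @param labels class label per sample.
#' @param tr a `trainer`.
#' @return a `loocv_result`: list with `predictions` (one per sample, in
#'   input order), `confusion` (rows true), and `accuracy`.
#' @export
loocv <- function(x, labels, tr) {
  stopifnot(inherits(tr, "trainer"))
  x <- as_expression_matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples")
  preds <- character(n)
  for (i in seq_len(n)) {
    preds[i] <- tryCatch({
      model <- tr$fit(x[-i, , drop = FALSE], labels[-i])
      as.character(tr$predict(model, x[i, , drop = FALSE]))[1L]
    }, error = function(e) {
      stop("fold ", i, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  cm <- confusion_matrix(labels, preds, classes = sort(unique(labels)))
  structure(list(predictions = preds, confusion = cm,
                 accuracy = mean(preds == labels), method = tr$name),
            class = "loocv_result")
}

#' Published parameter-tuning grids
#'
#' Returns the tuning grid for one of the five benchmarked methods, exactly
#' as published: the rule classifier varies its admissible error `E(r)` from
#' 2.5% to 7.5% in steps of 0.5% (11 values); kNN varies k from 1 to 10; the
#' neural network varies hidden layers 0-1, neurons 2-6 and learning rate
#' 0.25-0.75 (step 0.05); the decision tree compares pessimistic, none and
#' cost-complexity pruning with maximum node impurity 0.0-0.1 (step 0.01);
#' the SVM compares linear and RBF kernels with kernel degree 1-10.
#' Row order is deterministic and is the tie-breaking order for [tune_loocv()].
#'
#' @param method one of `"llm"`, `"dt"`, `"ann"`, `"svm"`, `"knn"`.
#' @return data.frame, one row per grid point.
#' @export
tuning_grid <- function(method = c("llm", "dt", "ann", "svm", "knn")) {
  method <- match.arg(method)
  switch(method,
    llm = data.frame(max_error = seq(0.025, 0.075, by = 0.005)),
    knn = data.frame(k = 1:10),
    ann = expand.grid(hidden_layers = 0:1, neurons = 2:6,
                      learning_rate = seq(0.25, 0.75, by = 0.05),
                      KEEP.OUT.ATTRS = FALSE),
    dt = expand.grid(pruning = c("pessimistic", "none", "cost-complexity"),
                     max_impurity = seq(0, 0.1, by = 0.01),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    svm = expand.grid(kernel = c("linear", "rbf"), degree = 1:10,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}

#' Grid tuning on LOOCV kappa
#'
#' Runs [loocv()] at every grid point and retains the point with the highest
#' Cohen kappa (multi-class kappa of the LOOCV confusion matrix); ties go to
#' the first point in grid order.  This replicates the published non-nested
#' tuning protocol, whose scores are therefore an upper limit of the expected
#' accuracy; for an unbiased estimate wrap the tuning itself inside an outer
#' validation loop (`nested = TRUE`) and report the outer predictions.
#'
#' @param x,labels dataset.
#' @param trainer_factory function mapping one grid row (as a named list) to
#'   a `trainer`, e.g. `function(max_error) llm_trainer(max_error)`.
#' @param grid data.frame of grid points, e.g. from [tuning_grid()].
#' @param nested if `TRUE`, each sample's reported prediction comes from a
#'   tuning run performed with that sample held out entirely (leakage-free,
#'   substantially slower).
#' @return list with `best` (grid row), `kappa`, `result` (the selected
#'   `loocv_result`) and `kappas` (per grid point).  In nested mode, `result`
#'   holds the outer-loop predictions instead.
#' @export
tune_loocv <- function(x, labels, trainer_factory, grid, nested = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0L)
  x <- as_expression_matrix(x)
  labels <- as.character(labels)
  inner <- function(xs, ys) {
    kappas <- numeric(nrow(grid))
    results <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      tr <- do.call(trainer_factory, as.list(grid[g, , drop = FALSE]))
      results[[g]] <- loocv(xs, ys, tr)
      kappas[g] <- kappa_multiclass(results[[g]]$confusion)
    }
    best <- which.max(kappas)  # first maximum in grid order
    list(best = best, kappas = kappas, results = results)
  }
  if (!nested) {
    fit <- inner(x, labels)
    return(list(best = grid[fit$best, , drop = FALSE],
                kappa = fit$kappas[fit$best],
                result = fit$results[[fit$best]],
                kappas = fit$kappas))
  }
  n <- nrow(x)
  preds <- character(n)
  for (i in seq_len(n)) {
    fit <- inner(x[-i, , drop = FALSE], labels[-i])
    tr <- do.call(trainer_factory, as.list(grid[fit$best, , drop = FALSE]))
    model <- tr$fit(x[-i, , drop = FALSE], labels[-i])
    preds[i] <- as.character(tr$predict(model, x[i, , drop = FALSE]))[1L]
  }
  cm <- confusion_matrix(labels, preds, classes = sort(unique(labels)))
  outer_fit <- inner(x, labels)
  list(best = grid[outer_fit$best, , drop = FALSE],
       kappa = kappa_multiclass(cm),
       result = structure(list(predictions = preds, confusion = cm,
                               accuracy = mean(preds == labels),
                               method = "nested"),
                          class = "loocv_result"),
       kappas = outer_fit$kappas)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV [%s]: accuracy %s%%, kappa %s%%\n", x$method,
              format_pct(x$accuracy), format_pct(kappa_multiclass(x$confusion))))
  invisible(x)
}
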