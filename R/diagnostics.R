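#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes (this orientation is
#' fixed throughout the package).  For binary tasks the first class is the
#' positive one, so `a11 = TP`, `a12 = FN`, `a21 = FP`, `a22 = TN`.
#'
#' @param truth,predicted class labels per sample.
#' @param classes optional class ordering; defaults to sorted union.
#' @return integer m x m matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(union(truth, predicted))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

check_cm <- function(cm, square = TRUE) {
  if (!is.matrix(cm) || !is.numeric(cm)) stop("confusion matrix must be a numeric matrix")
  if (square && nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  if (nrow(cm) < 2L) stop("need at least 2 classes")
  cm
}

#' Accuracy measures for a 2x2 confusion matrix
#'
#' Computes sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' Youden index `Y = SE + SP - 1`, empirical accuracy `(TP+TN)/N`, and the
#' binary Cohen kappa
#' `K = 2(TP*TN - FP*FN) / ((TP+FP)(TN+FP) + (TN+FN)(TP+FN))`.
#'
#' @param cm 2x2 matrix, rows true (first row = positive class), columns
#'   predicted.
#' @return a `study_accuracy` object: list with `se`, `sp`, `youden`,
#'   `accuracy`, `kappa` (all fractions), the four cells and `n`.
#' @export
binary_metrics <- function(cm) {
  check_cm(cm)
  if (nrow(cm) != 2L) stop("binary_metrics requires a 2x2 matrix")
  if (any(rowSums(cm) == 0)) stop("empty true class")
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  structure(list(se = se, sp = sp, youden = se + sp - 1,
                 accuracy = (tp + tn) / sum(cm),
                 kappa = 2 * (tp * tn - fp * fn) /
                   ((tp + fp) * (tn + fp) + (tn + fn) * (tp + fn)),
                 tp = tp, fn = fn, tn = tn, fp = fp, n = sum(cm)),
            class = "study_accuracy")
}

#' Log diagnostic odds ratio and its asymptotic variance
#'
#' `OR = SE*SP / ((1-SE)(1-SP)) = TP*TN / (FN*FP)`; the asymptotic variance of
#' `log(OR)` is `1/TP + 1/FN + 1/TN + 1/FP`.  When any cell is zero the
#' continuity correction adds 0.5 to all four cells before computing both the
#' odds ratio and the variance.
#'
#' @param cm 2x2 matrix, rows true, columns predicted.
#' @return list with `log_or`, `var`, and `corrected` (logical).
#' @export
log_odds_ratio <- function(cm) {
  check_cm(cm)
  if (nrow(cm) != 2L) stop("log_odds_ratio requires a 2x2 matrix")
  if (any(rowSums(cm) == 0) || any(colSums(cm) == 0)) {
    stop("two empty cells in the same margin: odds ratio undefined")
  }
  cells <- c(tp = cm[1, 1], fn = cm[1, 2], fp = cm[2, 1], tn = cm[2, 2])
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(log_or = log(cells[["tp"]] * cells[["tn"]] /
                      (cells[["fn"]] * cells[["fp"]])),
       var = sum(1 / cells),
       corrected = corrected)
}

#' Multi-class Cohen kappa
#'
#' Chance-corrected agreement
#' `K = (sum a_ii - sum e_ii) / (sum a_ij - sum e_ii)` with expected diagonal
#' counts `e_ii = (row_i * col_i) / N` under random assignment.  Reduces to
#' the binary kappa formula for m = 2.
#'
#' @param cm m x m matrix, rows true, columns predicted.
#' @return scalar kappa in `[-1, 1]`.
#' @export
kappa_multiclass <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  if (n == 0) stop("all-zero confusion matrix")
  e_ii <- rowSums(cm) * colSums(cm) / n
  (sum(diag(cm)) - sum(e_ii)) / (n - sum(e_ii))
}

#' Mantel-Haenszel pooled log odds ratio over a multi-class confusion matrix
#'
#' The m x m matrix is collapsed into m-1 two-by-two tables against the
#' reference category (row/column 1 after reordering): table i has cells
#' `a11, a1i, ai1, aii`.  The MH estimate is
#' `log( sum_i a11*aii/n_i / sum_i a1i*ai1/n_i )` with
#' `n_i = a11 + a1i + ai1 + aii`, and the asymptotic variance is the
#' Robins-Breslow-Greenland-type expression printed alongside it:
#' `sum_i (a11+a1i)(ai1+aii)(a11+ai1)(a1i+aii) / ((n_i-1) n_i^2)` divided by
#' the product of the two MH sums.  The continuity correction (+0.5 on all
#' four cells) is applied per collapsed table whenever one of its cells is
#' zero.
#'
#' @param cm m x m matrix, rows true, columns predicted.
#' @param reference index of the reference category (moved to position 1).
#' @return list with `log_or` and `var`.
#' @export
mh_log_or <- function(cm, reference = 1L) {
  check_cm(cm)
  m <- nrow(cm)
  if (reference != 1L) {
    ord <- c(reference, setdiff(seq_len(m), reference))
    cm <- cm[ord, ord, drop = FALSE]
  }
  num <- den <- vterm <- 0
  for (i in 2:m) {
    cells <- c(cm[1, 1], cm[1, i], cm[i, 1], cm[i, i])
    if (any(cells == 0)) cells <- cells + 0.5
    a11 <- cells[1]; a1i <- cells[2]; ai1 <- cells[3]; aii <- cells[4]
    ni <- a11 + a1i + ai1 + aii
    num <- num + a11 * aii / ni
    den <- den + a1i * ai1 / ni
    vterm <- vterm +
      (a11 + a1i) * (ai1 + aii) * (a11 + ai1) * (a1i + aii) /
      ((ni - 1) * ni^2)
  }
  if (num <= 0 || den <= 0) stop("degenerate tables")
  list(log_or = log(num / den), var = vterm / (num * den))
}

#' Multi-class sensitivity and specificity conventions
#'
#' The multi-class specificity is the proportion of correctly classified
#' samples inside the reference category, `SP = a11 / sum_j a1j`.  The
#' multi-class sensitivity is recovered by inverting the odds-ratio identity:
#' `SE = OR(1-SP) / (SP + OR(1-SP))`.  When `SP = 1` with a finite OR the
#' inversion degenerates and `SE = 0` is returned with a flag.
#'
#' @param cm m x m matrix, rows true, columns predicted (reference first).
#' @param log_or pooled log odds ratio, e.g. from [mh_log_or()].
#' @param reference index of the reference category.
#' @return list with `se`, `sp` and `degenerate` (logical).
#' @export
multiclass_se_sp <- function(cm, log_or, reference = 1L) {
  check_cm(cm)
  if (rowSums(cm)[reference] == 0) stop("empty reference category")
  sp <- cm[reference, reference] / sum(cm[reference, ])
  or <- exp(log_or)
  if (sp >= 1) {
    return(list(se = 0, sp = sp, degenerate = TRUE))
  }
  se <- or * (1 - sp) / (sp + or * (1 - sp))
  list(se = se, sp = sp, degenerate = FALSE)
}

#' Choose the reference category for multi-class accuracy measures
#'
#' The reference is the healthy (disease-free) class when one exists, else
#' the class with the lowest severity rank, else the largest class; remaining
#' ties go to the lexicographically first class name.
#'
#' @param classes character vector of class names.
#' @param healthy optional logical vector flagging disease-free classes.
#' @param severity optional numeric severity rank (lower = less severe).
#' @param sizes optional class sizes.
#' @return index into `classes`.
#' @export
select_reference <- function(classes, healthy = NULL, severity = NULL,
                             sizes = NULL) {
  if (length(classes) < 2L) stop("need at least 2 classes")
  pick <- function(idx, key, decreasing = FALSE) {
    k <- key[idx]
    best <- if (decreasing) idx[k == max(k)] else idx[k == min(k)]
    best
  }
  cand <- seq_along(classes)
  if (!is.null(healthy) && any(healthy)) {
    cand <- which(healthy)
  } else if (!is.null(severity)) {
    cand <- pick(cand, severity)
  } else if (!is.null(sizes)) {
    cand <- pick(cand, sizes, decreasing = TRUE)
  }
  if (length(cand) > 1L && !is.null(sizes)) {
    cand <- pick(cand, sizes, decreasing = TRUE)
  }
  cand[order(classes[cand])][1L]
}

#' Per-study accuracy summary from a confusion matrix
#'
#' For 2x2 matrices this is [binary_metrics()] plus [log_odds_ratio()].  For
#' m > 2 the matrix is reordered so the reference category comes first, and
#' the measures follow the multi-class conventions: multi-class kappa,
#' Mantel-Haenszel pooled log odds ratio with its asymptotic variance,
#' reference-category specificity and the odds-ratio-inverted sensitivity.
#'
#' @param cm m x m matrix, rows true, columns predicted.
#' @param reference reference category index (default: chosen by
#'   [select_reference()] on class sizes unless `m == 2`).
#' @param healthy,severity optional class metadata passed to
#'   [select_reference()].
#' @return a `study_accuracy` object with `se`, `sp`, `youden`, `accuracy`,
#'   `kappa`, `log_or`, `var`, `n`, `m`, `reference`.
#' @export
study_accuracy <- function(cm, reference = NULL, healthy = NULL,
                           severity = NULL) {
  check_cm(cm)
  m <- nrow(cm)
  if (m == 2L) {
    out <- binary_metrics(cm)
    lo <- log_odds_ratio(cm)
    out$log_or <- lo$log_or
    out$var <- lo$var
    out$corrected <- lo$corrected
    out$m <- 2L
    out$reference <- 2L
    return(out)
  }
  if (is.null(reference)) {
    reference <- select_reference(rownames(cm), healthy = healthy,
                                  severity = severity, sizes = rowSums(cm))
  }
  ord <- c(reference, setdiff(seq_len(m), reference))
  cmr <- cm[ord, ord, drop = FALSE]
  mh <- mh_log_or(cmr, reference = 1L)
  sesp <- multiclass_se_sp(cmr, mh$log_or, reference = 1L)
  structure(list(se = sesp$se, sp = sesp$sp,
                 youden = sesp$se + sesp$sp - 1,
                 accuracy = sum(diag(cm)) / sum(cm),
                 kappa = kappa_multiclass(cm),
                 log_or = mh$log_or, var = mh$var,
                 degenerate = sesp$degenerate,
                 n = sum(cm), m = m, reference = reference),
            class = "study_accuracy")
}

#' @export
print.study_accuracy <- function(x, ...) {
  cat(sprintf("SE %s%%  SP %s%%  Youden %s%%  Accuracy %s%%  Kappa %s%%\n",
              format_pct(x$se), format_pct(x$sp), format_pct(x$youden),
              format_pct(x$accuracy), format_pct(x$kappa)))
  if (!is.null(x$log_or)) {
    cat(sprintf("log(OR) %.4f  var %.4f\n", x$log_or, x$var))
  }
  invisible(x)
}

#' Tabulate study accuracies as a report
#'
#' Produces the standard method-by-metric report (one row per analysis;
#' Sens., Spec., Youden, Empirical Accuracy and Cohen kappa as percentages
#' with one decimal).
#'
#' @param studies named list of `study_accuracy` objects (names become the
#'   first column, e.g. method or dataset labels).
#' @return data.frame with formatted percent columns.
#' @export
accuracy_report <- function(studies) {
  stopifnot(length(studies) > 0L)
  rows <- lapply(names(studies), function(nm) {
    s <- studies[[nm]]
    data.frame(analysis = nm,
               sens_pct = format_pct(s$se),
               spec_pct = format_pct(s$sp),
               youden_pct = format_pct(s$youden),
               accuracy_pct = format_pct(s$accuracy),
               kappa_pct = format_pct(s$kappa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
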