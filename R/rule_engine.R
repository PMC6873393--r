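#' Generate implicants for one class by greedy covering
#'
#' An implicant is a set of admitted bins per feature (equivalently a binary
#' mask over the concatenated pattern bits with one contiguous run of
#' admitted bits per block); a sample satisfies it when every feature's bin
#' is admitted.  Implicants are grown by sequential covering: a seed (the
#' first still-uncovered target sample, in data order) anchors a premise
#' that is specialized condition by condition — each condition a bin run
#' containing the seed's bin, chosen by FOIL gain (target samples retained
#' times log-precision improvement) — until the covered false-positive
#' fraction is at or below `max_error`.  Exact premise-level passes then
#' drop redundant conditions and widen the remaining runs as far as the
#' error budget allows.  Seeding repeats until every target sample is
#' covered or provably uncoverable at this budget.
#'
#' @param patterns a `binary_pattern` from [binarize()].
#' @param labels class label per sample.
#' @param target_class the class whose samples the implicants must cover.
#' @param max_error maximum admissible false-positive fraction in `[0, 0.5]`
#'   (fraction of non-target samples an implicant may cover).
#' @return an object of class `implicant_set`: a list of implicants, each with
#'   `admitted` (logical over pattern bits), `covered` (sample indices),
#'   `error`, and `seed`.  Attribute `uncovered` lists target samples no
#'   admissible implicant could cover.
#' @export
generate_implicants <- function(patterns, labels, target_class, max_error = 0.05) {
  stopifnot(inherits(patterns, "binary_pattern"))
  labels <- as.character(labels)
  if (!target_class %in% labels) {
    stop("target class '", target_class, "' absent from labels")
  }
  if (max_error < 0 || max_error > 0.5) stop("max_error must be in [0, 0.5]")
  bins <- patterns$bins
  q <- patterns$bin_count
  off <- patterns$block_offsets
  n <- nrow(bins)
  L <- sum(q)
  y_pos <- labels == target_class
  n_neg <- sum(!y_pos)
  if (n_neg == 0L) stop("no non-target samples: error fraction undefined")
  budget <- floor(max_error * n_neg + 1e-9)

  # univariate quality of each feature's binning (entropy gain of the bin
  # partition w.r.t. target-vs-rest): the static generalization priority —
  # uninformative features are relaxed first, discriminative ones last
  h0 <- class_entropy(table(y_pos))
  feature_gain <- vapply(seq_len(ncol(bins)), function(f) {
    tab <- table(bins[, f], y_pos)
    h0 - sum(apply(tab, 1L, function(cnt) class_entropy(cnt) * sum(cnt))) / n
  }, numeric(1))

  covered_global <- rep(FALSE, n)
  uncoverable <- integer(0)
  implicants <- list()
  repeat {
    seeds <- which(y_pos & !covered_global)
    seeds <- setdiff(seeds, uncoverable)
    if (length(seeds) == 0L) break
    imp <- build_implicant(bins, q, y_pos, y_pos & !covered_global,
                           seeds[1L], budget, feature_gain)
    if (is.null(imp)) {
      uncoverable <- c(uncoverable, seeds[1L])
      next
    }
    # admitted-bit mask over the concatenated pattern
    admitted <- rep(TRUE, L)
    for (f in which(imp$restricted)) {
      block <- off[f] + seq_len(q[f])
      admitted[block] <- FALSE
      admitted[off[f] + imp$run_lo[f]:imp$run_hi[f]] <- TRUE
    }
    imp$admitted <- admitted
    imp$error <- sum(!y_pos[imp$covered]) / n_neg
    covered_global[imp$covered[y_pos[imp$covered]]] <- TRUE
    implicants[[length(implicants) + 1L]] <- imp
  }
  structure(implicants, class = "implicant_set",
            uncovered = sort(uncoverable),
            bin_count = q, block_offsets = off)
}

# Build one implicant anchored at a seed sample by top-down specialization.
# Returns NULL when no premise within the error budget can cover the seed.
#
# Conditions are contiguous bin runs that contain the seed's bin (the
# ordinal reading of the inverse only-one code: an implicant's admitted bits
# form one run per feature).  Starting from the empty premise, the condition
# retaining the most still-uncovered target samples while reducing the
# number of covered non-target samples is added until that number is within
# the error budget; candidates already inside the budget are preferred, then
# larger positive retention, then fewer negatives, then larger univariate
# entropy gain of the feature, then wider runs, then lower feature index.
# Two exact premise-level passes follow: conditions whose removal keeps the
# error within budget are dropped (least informative feature first), and
# remaining runs are widened bin by bin as far as the budget allows.  All
# evaluation is on the premise itself, so no interaction with the hundreds
# of unrestricted features can mask a negative.
build_implicant <- function(bins, q, y_pos, eligible, seed, budget,
                            feature_gain) {
  n <- nrow(bins)
  nf <- ncol(bins)
  run_lo <- rep(1L, nf)
  run_hi <- q
  restricted <- rep(FALSE, nf)
  active <- rep(TRUE, n)
  cur_neg <- sum(!y_pos)
  sb <- bins[seed, ]

  while (cur_neg > budget) {
    cur_pos <- sum(active & eligible)
    prec0 <- cur_pos / max(cur_pos + cur_neg, 1L)
    best <- NULL
    for (f in seq_len(nf)) {
      if (restricted[f] || q[f] == 1L) next
      act_f <- bins[, f]
      pos_cnt <- tabulate2(act_f[active & eligible], q[f])
      neg_cnt <- tabulate2(act_f[active & !y_pos], q[f])
      cpos <- cumsum(pos_cnt)
      cneg <- cumsum(neg_cnt)
      b <- sb[f]
      for (lo in 1:b) {
        for (hi in b:q[f]) {
          if (lo == 1L && hi == q[f]) next
          pk <- cpos[hi] - if (lo > 1L) cpos[lo - 1L] else 0L
          nk <- cneg[hi] - if (lo > 1L) cneg[lo - 1L] else 0L
          if (nk >= cur_neg || pk == 0L) next   # must reduce the error
          # FOIL gain: positives retained, weighted by the log-precision
          # improvement of the specialized premise
          gain <- pk * (log2(pk / (pk + nk)) - log2(max(prec0, 1e-12)))
          key <- c(gain, -nk, feature_gain[f], hi - lo, -f, -lo)
          if (is.null(best) || key_gt(key, best$key)) {
            best <- list(key = key, f = f, lo = lo, hi = hi, nk = nk)
          }
        }
      }
    }
    if (is.null(best)) return(NULL)
    f <- best$f
    restricted[f] <- TRUE
    run_lo[f] <- best$lo
    run_hi[f] <- best$hi
    active <- active & bins[, f] >= best$lo & bins[, f] <= best$hi
    cur_neg <- best$nk
  }

  premise_neg <- function(skip = 0L) {
    keep <- rep(TRUE, n)
    for (f in which(restricted)) {
      if (f == skip) next
      keep <- keep & bins[, f] >= run_lo[f] & bins[, f] <= run_hi[f]
    }
    keep
  }

  # drop pass: least informative condition first, exact re-evaluation
  for (f in order(feature_gain, seq_len(nf))) {
    if (!restricted[f]) next
    keep <- premise_neg(skip = f)
    if (sum(keep & !y_pos) <= budget) {
      restricted[f] <- FALSE
      run_lo[f] <- 1L
      run_hi[f] <- q[f]
    }
  }

  # relax pass: widen each remaining run while the budget holds
  for (f in order(feature_gain, seq_len(nf))) {
    if (!restricted[f]) next
    others <- premise_neg(skip = f)
    vb <- bins[, f]
    repeat {
      ext <- FALSE
      if (run_lo[f] > 1L) {
        lo2 <- run_lo[f] - 1L
        covered <- others & vb >= lo2 & vb <= run_hi[f]
        if (sum(covered & !y_pos) <= budget) {
          run_lo[f] <- lo2
          ext <- TRUE
        }
      }
      if (run_hi[f] < q[f]) {
        hi2 <- run_hi[f] + 1L
        covered <- others & vb >= run_lo[f] & vb <= hi2
        if (sum(covered & !y_pos) <= budget) {
          run_hi[f] <- hi2
          ext <- TRUE
        }
      }
      if (!ext) break
    }
    if (run_lo[f] == 1L && run_hi[f] == q[f]) restricted[f] <- FALSE
  }

  covered <- which(premise_neg())
  list(run_lo = run_lo, run_hi = run_hi, restricted = restricted,
       covered = covered, seed = seed)
}

# lexicographic "a > b" over numeric keys
key_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(a[i] > b[i])
  }
  FALSE
}

# tabulate that tolerates empty input
tabulate2 <- function(x, nbins) {
  if (length(x) == 0L) integer(nbins) else tabulate(x, nbins)
}

#' Convert implicants to intelligible threshold rules
#'
#' Per feature block, the admitted bins are translated into a threshold
#' condition: a leading run of bins becomes `x <= c`, a trailing run `x > c`,
#' and an inner run an interval `a < x <= b`; a fully admitted block
#' contributes no condition.  If a block's admitted bins are non-contiguous,
#' the implicant is split into one rule per combination of contiguous runs
#' (with a warning).  Covering and error are evaluated on the supplied
#' training data.
#'
#' @param implicants an `implicant_set` from [generate_implicants()].
#' @param map the `disc_map` the patterns were binarized with.
#' @param target_class class label attached as the rules' consequence.
#' @param x,labels training data used to attach covering and error.
#' @return list of `llm_rule` objects.
#' @export
implicants_to_rules <- function(implicants, map, target_class, x, labels) {
  stopifnot(inherits(implicants, "implicant_set"), inherits(map, "disc_map"))
  q <- bin_counts(map)
  off <- cumsum(c(0L, q[-length(q)]))
  x <- as_expression_matrix(x)
  rules <- list()
  for (imp in implicants) {
    runs_by_feature <- list()
    for (j in seq_along(map$features)) {
      if (q[j] == 1L) next
      adm <- which(imp$admitted[off[j] + seq_len(q[j])])
      if (length(adm) == q[j]) next
      runs <- unname(split(adm, cumsum(c(1L, diff(adm) != 1L))))
      runs_by_feature[[map$features[j]]] <- runs
    }
    split_imp <- any(vapply(runs_by_feature, length, integer(1)) > 1L)
    if (split_imp) {
      warning("non-contiguous admitted bins: implicant split into ",
              prod(vapply(runs_by_feature, length, integer(1))), " rules")
    }
    combos <- expand_runs(runs_by_feature)
    for (combo in combos) {
      premise <- lapply(names(combo), function(f) {
        run_to_condition(f, combo[[f]], map$cutoffs[[f]])
      })
      rule <- new_rule(premise, target_class)
      ce <- rule_quality(rule, x, labels, target_class)
      rule$covering <- ce[["covering"]]
      rule$error <- ce[["error"]]
      # run-splitting can manufacture combinations covering no sample of the
      # class at all; those are artifacts of the split, not trained rules
      if (split_imp && rule$covering == 0) next
      rules[[length(rules) + 1L]] <- rule
    }
  }
  rules
}

# cartesian product over features of their contiguous runs
expand_runs <- function(runs_by_feature) {
  if (length(runs_by_feature) == 0L) return(list(stats::setNames(list(), character(0))))
  idx <- expand.grid(lapply(runs_by_feature, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    stats::setNames(
      lapply(seq_along(runs_by_feature), function(j) {
        runs_by_feature[[j]][[idx[i, j]]]
      }),
      names(runs_by_feature))
  })
}

run_to_condition <- function(feature, run, cutoffs) {
  qf <- length(cutoffs) + 1L
  lo <- min(run)
  hi <- max(run)
  if (lo == 1L && hi < qf) {
    new_condition(feature, "<=", high = cutoffs[hi])
  } else if (lo > 1L && hi == qf) {
    new_condition(feature, ">", low = cutoffs[lo - 1L])
  } else {
    new_condition(feature, "in", low = cutoffs[lo - 1L], high = cutoffs[hi])
  }
}

new_condition <- function(feature, op, low = NA_real_, high = NA_real_) {
  structure(list(feature = feature, op = op, low = low, high = high),
            class = "condition")
}

#' Threshold condition constructor
#' @param feature feature id.
#' @param op one of `"<="`, `">"`, `"in"` (interval `(low, high]`).
#' @param low,high thresholds in expression units.
#' @return a `condition` object.
#' @export
condition <- function(feature, op = c("<=", ">", "in"), low = NULL, high = NULL) {
  op <- match.arg(op)
  if (op == "in" && (is.null(low) || is.null(high) || low >= high)) {
    stop("interval condition requires low < high")
  }
  new_condition(feature, op,
                low = if (is.null(low)) NA_real_ else low,
                high = if (is.null(high)) NA_real_ else high)
}

new_rule <- function(premise, class, covering = NA_real_, error = NA_real_) {
  structure(list(premise = premise, class = class,
                 covering = covering, error = error),
            class = "llm_rule")
}

condition_holds <- function(cond, v) {
  switch(cond$op,
         "<=" = v <= cond$high,
         ">"  = v > cond$low,
         "in" = v > cond$low & v <= cond$high)
}

#' Which samples does a rule fire on?
#' @param rule an `llm_rule`.
#' @param x expression matrix (samples x features).
#' @return logical vector over samples; an empty premise fires everywhere.
#' @export
rule_fires <- function(rule, x) {
  x <- as_expression_matrix(x)
  fires <- rep(TRUE, nrow(x))
  for (cond in rule$premise) {
    if (!cond$feature %in% colnames(x)) {
      stop("missing feature value: ", cond$feature)
    }
    fires <- fires & condition_holds(cond, x[, cond$feature])
  }
  fires
}

#' Covering and error of a rule
#'
#' Covering `C(r)` is the fraction of the rule's own class captured by the
#' premise; error `E(r)` is the false-positive fraction, i.e. the fraction of
#' all other classes wrongly captured.  In a binary task these correspond to
#' the sensitivity (or specificity) of the rule.
#'
#' @param rule an `llm_rule`.
#' @param x,labels evaluation data.
#' @param positives class treated as the rule's own; defaults to the rule's
#'   consequence.
#' @return named numeric `c(covering =, error =)`.
#' @export
rule_quality <- function(rule, x, labels, positives = rule$class) {
  labels <- as.character(labels)
  pos <- labels == positives
  if (sum(pos) == 0L) stop("no samples of the positive class")
  if (sum(!pos) == 0L) stop("no samples outside the positive class")
  fires <- rule_fires(rule, x)
  c(covering = sum(fires & pos) / sum(pos),
    error = sum(fires & !pos) / sum(!pos))
}

#' Relevance of a single condition
#'
#' The relevance of condition `c` in rule `r` is `R(c) = dE(c) * C(r)` where
#' `dE(c) = E(r') - E(r)` and `r'` is `r` with the condition removed: the
#' error increase the condition prevents, weighted by the rule's covering.
#' Negative differences (possible for non-greedy rules) are clipped at 0 so
#' that the per-variable aggregate stays in `[0, 1]`.
#'
#' @param rule an `llm_rule`.
#' @param index position of the condition in the premise.
#' @param x,labels evaluation data.
#' @return non-negative scalar `R(c)`.
#' @export
condition_relevance <- function(rule, index, x, labels) {
  if (index < 1L || index > length(rule$premise)) stop("invalid condition index")
  ce <- rule_quality(rule, x, labels)
  reduced <- rule
  reduced$premise <- rule$premise[-index]
  e_prime <- rule_quality(reduced, x, labels)[["error"]]
  max(e_prime - ce[["error"]], 0) * ce[["covering"]]
}

#' Per-variable relevance across a rule model
#'
#' Aggregates the condition relevances of all conditions on each variable
#' across all rules as `R_v(x) = 1 - prod(1 - R(c))`.  Variables absent from
#' every rule score 0.  As a rule of thumb a variable with `R_v <= 10%`
#' contributes only marginally to the classifier; those are flagged in the
#' `"marginal"` attribute.
#'
#' @param model an `llm_model`.
#' @param x,labels evaluation data (typically the training data).
#' @param features subset of features to score (default: all model features).
#' @return named numeric vector of `R_v` values in `[0, 1]`, with attribute
#'   `marginal` (logical, `R_v <= 0.10`).
#' @export
variable_relevance <- function(model, x, labels, features = NULL) {
  stopifnot(inherits(model, "llm_model"))
  if (is.null(features)) features <- model$discretization$features
  unknown <- setdiff(features, model$discretization$features)
  if (length(unknown) > 0L) {
    stop("feature(s) unknown to the discretization: ",
         paste(unknown, collapse = ", "))
  }
  rv <- stats::setNames(rep(0, length(features)), features)
  for (rule in model$rules) {
    for (i in seq_along(rule$premise)) {
      f <- rule$premise[[i]]$feature
      if (f %in% features) {
        r <- condition_relevance(rule, i, x, labels)
        rv[f] <- 1 - (1 - rv[f]) * (1 - r)
      }
    }
  }
  attr(rv, "marginal") <- rv <= 0.10
  rv
}

#' Train a threshold-rule classifier
#'
#' Full training pipeline: supervised discretization, latticization, greedy
#' implicant generation one-vs-rest per class, and conversion to threshold
#' rules.  Rules are sorted by decreasing covering within each class.  The
#' default class (predicted when no rule fires) is the largest training
#' class.
#'
#' @param x numeric expression matrix, samples in rows.
#' @param labels class label per sample.
#' @param max_error maximum admissible false-positive fraction per rule on
#'   training data; the published tuning range is 2.5\% to 7.5\%, default 5\%.
#' @param max_bins maximum discretization bins per feature.
#' @param top_k optional univariate feature pre-filter (see
#'   [fit_discretizer()]).
#' @param discretization optional prefit `disc_map`.  The discretization does
#'   not depend on `max_error`, so a tuning loop over the error grid can fit
#'   it once per training set and reuse it; leave `NULL` to fit from `x` and
#'   `labels`.
#' @return an `llm_model`: list with `discretization`, `rules`, `default_class`,
#'   `class_sizes`, `uncovered` (per-class uncoverable training samples) and
#'   `params`.
#' @export
llm_train <- function(x, labels, max_error = 0.05, max_bins = 4L,
                      top_k = NULL, discretization = NULL) {
  x <- as_expression_matrix(x)
  labels <- as.character(labels)
  map <- discretization %||%
    fit_discretizer(x, labels, max_bins = max_bins, top_k = top_k)
  patterns <- binarize(x, map)
  classes <- sort(unique(labels))
  rules <- list()
  uncovered <- list()
  for (cls in classes) {
    imps <- generate_implicants(patterns, labels, cls, max_error = max_error)
    cls_rules <- implicants_to_rules(imps, map, cls, x, labels)
    ord <- order(vapply(cls_rules, function(r) r$covering, numeric(1)),
                 decreasing = TRUE)
    rules <- c(rules, cls_rules[ord])
    unc <- attr(imps, "uncovered")
    if (length(unc) > 0L) uncovered[[cls]] <- unc
  }
  for (i in seq_along(rules)) rules[[i]]$id <- i
  sizes <- table(labels)
  default_class <- names(sizes)[order(-as.integer(sizes), names(sizes))][1L]
  structure(list(discretization = map,
                 rules = rules,
                 default_class = default_class,
                 class_sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 uncovered = uncovered,
                 params = list(max_error = max_error, max_bins = max_bins,
                               top_k = top_k)),
            class = "llm_model")
}

#' Classify samples with a rule model
#'
#' Covering-weighted vote: each fired rule contributes its covering to its
#' class's score; the class with the largest score wins.  Ties are broken by
#' the larger training class, then lexicographic class order.  Samples firing
#' no rule receive the default class.
#'
#' @param object an `llm_model`.
#' @param newdata expression matrix or single named numeric vector; must
#'   contain every model feature.
#' @param type `"class"` for labels (default), `"score"` for the per-class
#'   score matrix.
#' @param ... unused.
#' @return character vector of classes, or a numeric score matrix.
#' @export
predict.llm_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  }
  newdata <- as_expression_matrix(newdata)
  missing <- setdiff(object$discretization$features, colnames(newdata))
  if (length(missing) > 0L) {
    stop("missing feature value(s): ", paste(missing, collapse = ", "))
  }
  classes <- sort(names(object$class_sizes))
  scores <- matrix(0, nrow(newdata), length(classes),
                   dimnames = list(rownames(newdata), classes))
  for (rule in object$rules) {
    fires <- rule_fires(rule, newdata)
    scores[fires, rule$class] <- scores[fires, rule$class] + rule$covering
  }
  if (type == "score") return(scores)
  sizes <- object$class_sizes[classes]
  pref <- order(-sizes, classes)  # tie-break preference order
  apply(scores, 1L, function(s) {
    if (all(s == 0)) return(object$default_class)
    top <- which(s == max(s))
    classes[pref[pref %in% top][1L]]
  })
}

#' Rules fired by a single sample
#' @param model an `llm_model`.
#' @param sample named numeric vector or 1-row matrix.
#' @return integer rule ids.
#' @export
fired_rules <- function(model, sample) {
  if (is.null(dim(sample))) {
    sample <- matrix(sample, nrow = 1L, dimnames = list(NULL, names(sample)))
  }
  fired <- vapply(model$rules, function(r) rule_fires(r, sample), logical(1))
  vapply(model$rules[fired], function(r) r$id, integer(1))
}

#' Flag rules that likely cover outliers
#'
#' A rule with `C(r) * (1 - E(r)) <= 10%` often covers samples with anomalous
#' values; such rules are flagged for review.
#'
#' @param model an `llm_model`.
#' @param x,labels optional data on which to recompute covering/error;
#'   defaults to the values stored at training time.
#' @return integer ids of flagged rules.
#' @export
flag_outlier_rules <- function(model, x = NULL, labels = NULL) {
  stopifnot(inherits(model, "llm_model"))
  score <- vapply(model$rules, function(r) {
    if (!is.null(x)) {
      ce <- rule_quality(r, x, labels)
      ce[["covering"]] * (1 - ce[["error"]])
    } else {
      r$covering * (1 - r$error)
    }
  }, numeric(1))
  vapply(model$rules[score <= 0.10], function(r) r$id, integer(1))
}

#' @export
print.llm_model <- function(x, ...) {
  cat("Threshold-rule classifier:", length(x$rules), "rules,",
      length(x$class_sizes), "classes; default class:", x$default_class, "\n")
  cat(render_rules(x), sep = "\n")
  if (length(x$uncovered) > 0L) {
    for (cls in names(x$uncovered)) {
      cat("# uncovered training samples in class ", cls, ": ",
          paste(x$uncovered[[cls]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
print.llm_rule <- function(x, ...) {
  cat(render_rule(x), "\n")
  invisible(x)
}
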