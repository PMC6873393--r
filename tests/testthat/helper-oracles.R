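# Independent oracles the tests compare the implementation against.
# Everything here is deliberately written in the most direct way possible
# (plain formula evaluation, exhaustive enumeration) and shares no code with
# the package internals.

# direct evaluation of the 2x2 accuracy formulas
oracle_binary <- function(tp, fn, fp, tn) {
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(se = se, sp = sp, youden = se + sp - 1,
       accuracy = (tp + tn) / (tp + fn + fp + tn),
       kappa = 2 * (tp * tn - fp * fn) /
         ((tp + fp) * (tn + fp) + (tn + fn) * (tp + fn)))
}

# direct log odds ratio with the continuity-correction rule
oracle_log_or <- function(tp, fn, fp, tn) {
  cells <- c(tp, fn, fp, tn)
  if (any(cells == 0)) cells <- cells + 0.5
  list(log_or = log(cells[1] * cells[4] / (cells[2] * cells[3])),
       var = sum(1 / cells))
}

cm2 <- function(tp, fn, fp, tn) {
  matrix(c(tp, fp, fn, tn), 2, 2,
         dimnames = list(true = c("pos", "neg"),
                         predicted = c("pos", "neg")))
}

# exhaustive implicant enumeration for binary-feature datasets:
# every implicant is a choice, per feature, of admitted bins {1}, {2} or
# {1,2}; returns for each the covered sample set and the false-positive
# fraction.  Used to certify coverage feasibility and greedy validity on
# datasets of <= 8 samples x 4 binary features.
oracle_enumerate_implicants <- function(bins, y_pos) {
  nf <- ncol(bins)
  choices <- list(1L, 2L, c(1L, 2L))
  grid <- do.call(expand.grid, rep(list(seq_along(choices)), nf))
  n_neg <- sum(!y_pos)
  lapply(seq_len(nrow(grid)), function(i) {
    admit <- lapply(unlist(grid[i, ]), function(k) choices[[k]])
    sat <- rep(TRUE, nrow(bins))
    for (f in seq_len(nf)) sat <- sat & bins[, f] %in% admit[[f]]
    list(admitted = admit, covered = which(sat),
         error = if (n_neg == 0) 0 else sum(sat & !y_pos) / n_neg)
  })
}

# positives coverable at zero error: some enumerated implicant covers them
# and no negative
oracle_coverable <- function(bins, y_pos) {
  imps <- oracle_enumerate_implicants(bins, y_pos)
  ok <- rep(FALSE, nrow(bins))
  for (im in imps) {
    if (im$error == 0) ok[im$covered] <- TRUE
  }
  which(ok & y_pos)
}

# random binary-feature dataset wrapped in package containers; bins are the
# raw 1/2 values, the disc_map places one cutoff at 0.5 per feature so that
# value 0 -> bin 1 and value 1 -> bin 2
make_binary_dataset <- function(n, nf, seed) {
  set.seed(seed)
  vals <- matrix(sample(0:1, n * nf, replace = TRUE), n, nf,
                 dimnames = list(NULL, paste0("f", seq_len(nf))))
  labels <- sample(c("pos", "neg"), n, replace = TRUE)
  # ensure both classes appear
  if (length(unique(labels)) == 1L) {
    labels[1] <- setdiff(c("pos", "neg"), labels[1])
  }
  map <- structure(list(cutoffs = stats::setNames(
    rep(list(0.5), nf), colnames(vals)), features = colnames(vals)),
    class = "disc_map")
  list(x = vals, labels = labels, map = map,
       patterns = binarize(vals, map))
}

# a trainer that memorizes training samples and predicts the label of the
# exactly-matching stored sample, falling back to the majority class
memorizer_trainer <- function() {
  trainer(
    fit = function(x, labels) list(x = x, labels = labels),
    predict = function(model, newdata) {
      apply(newdata, 1L, function(row) {
        hit <- which(colSums(abs(t(model$x) - row)) < 1e-12)
        if (length(hit) > 0L) model$labels[hit[1L]]
        else names(sort(table(model$labels), decreasing = TRUE))[1L]
      })
    },
    name = "memorizer")
}

# majority-class trainer (the classic LOOCV pathology on balanced data)
majority_trainer <- function() {
  trainer(
    fit = function(x, labels) {
      tab <- sort(table(labels), decreasing = TRUE)
      names(tab)[1L]
    },
    predict = function(model, newdata) rep(model, nrow(newdata)),
    name = "majority")
}
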