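sep_toy <- function() {
  # one informative feature cleanly separating two classes, one constant
  x <- cbind(g1 = c(1, 2, 3, 4, 11, 12, 13, 14),
             g2 = rep(5, 8))
  labels <- rep(c("neg", "pos"), each = 4)
  map <- fit_discretizer(x, labels, max_bins = 2)
  list(x = x, labels = labels, map = map,
       patterns = binarize(x, map))
}

test_that("a separable toy yields one zero-error implicant covering all positives", {
  toy <- sep_toy()
  imps <- generate_implicants(toy$patterns, toy$labels, "pos", max_error = 0)
  expect_length(imps, 1L)
  expect_equal(imps[[1]]$error, 0)
  expect_setequal(imps[[1]]$covered, 5:8)
  expect_length(attr(imps, "uncovered"), 0L)
  expect_error(generate_implicants(toy$patterns, toy$labels, "nope"),
               "absent")
  expect_error(generate_implicants(toy$patterns, toy$labels, "pos",
                                   max_error = 0.7), "max_error")
})

test_that("greedy implicants are validated by exhaustive enumeration", {
  # fixture battery of random binary datasets, n <= 8, 4 binary features
  for (seed in 1:30) {
    ds <- make_binary_dataset(n = sample(4:8, 1), nf = 4, seed = seed)
    y_pos <- ds$labels == "pos"
    if (!any(y_pos) || all(y_pos)) next
    imps <- generate_implicants(ds$patterns, ds$labels, "pos", max_error = 0)
    n_neg <- sum(!y_pos)
    for (im in imps) {
      # covered set must match an independent re-evaluation of the mask
      run_sat <- rep(TRUE, nrow(ds$x))
      for (f in 1:4) {
        adm <- which(im$admitted[ds$patterns$block_offsets[f] + 1:2])
        run_sat <- run_sat & ds$patterns$bins[, f] %in% adm
      }
      expect_setequal(im$covered, which(run_sat))
      expect_equal(im$error, sum(run_sat & !y_pos) / n_neg)
      expect_equal(im$error, 0)
    }
    # every positive the oracle proves coverable at zero error is covered
    coverable <- oracle_coverable(ds$patterns$bins, y_pos)
    covered <- sort(unique(unlist(lapply(imps, function(im) {
      intersect(im$covered, which(y_pos))
    }))))
    expect_true(all(coverable %in% covered))
    # and the uncovered report holds exactly the rest
    expect_setequal(attr(imps, "uncovered"),
                    setdiff(which(y_pos), covered))
  }
})

test_that("implicants_to_rules emits threshold, interval and no-op conditions", {
  toy <- sep_toy()
  map <- structure(list(cutoffs = list(g = c(2.5, 7)), features = "g"),
                   class = "disc_map")
  x <- matrix(c(1, 2, 4, 6, 9, 10), ncol = 1, dimnames = list(NULL, "g"))
  labels <- c("a", "a", "b", "b", "c", "c")
  mk_imp <- function(admitted) {
    structure(list(list(admitted = admitted, covered = integer(0),
                        error = 0, seed = 1L)),
              class = "implicant_set", bin_count = c(g = 3L),
              block_offsets = c(g = 0L))
  }
  r1 <- implicants_to_rules(mk_imp(c(TRUE, FALSE, FALSE)), map, "a", x, labels)
  expect_length(r1[[1]]$premise, 1L)
  expect_equal(r1[[1]]$premise[[1]]$op, "<=")
  expect_equal(r1[[1]]$premise[[1]]$high, 2.5)
  expect_equal(r1[[1]]$covering, 1)

  r2 <- implicants_to_rules(mk_imp(c(FALSE, TRUE, FALSE)), map, "b", x, labels)
  expect_equal(r2[[1]]$premise[[1]]$op, "in")
  expect_equal(r2[[1]]$premise[[1]]$low, 2.5)
  expect_equal(r2[[1]]$premise[[1]]$high, 7)

  r3 <- implicants_to_rules(mk_imp(c(TRUE, TRUE, TRUE)), map, "a", x, labels)
  expect_length(r3[[1]]$premise, 0L)

  # non-contiguous admitted bins are split, with a warning
  expect_warning(
    r4 <- implicants_to_rules(mk_imp(c(TRUE, FALSE, TRUE)), map, "a", x,
                              labels),
    "non-contiguous")
  expect_gte(length(r4), 1L)
  for (r in r4) expect_gt(r$covering, 0)
})

test_that("rule_quality counts covering and error directly", {
  rule <- new_rule_for_test <- condition("g1", ">", low = 5)
  r <- structure(list(premise = list(rule), class = "pos",
                      covering = NA, error = NA), class = "llm_rule")
  x <- cbind(g1 = c(1:10))
  labels <- rep(c("neg", "pos"), each = 5)
  q <- rule_quality(r, x, labels)
  expect_equal(unname(q["covering"]), 1.0)   # pos are 6..10
  expect_equal(unname(q["error"]), 0.0)

  # empty premise covers everything
  r0 <- structure(list(premise = list(), class = "pos",
                       covering = NA, error = NA), class = "llm_rule")
  q0 <- rule_quality(r0, x, labels)
  expect_equal(unname(q0["covering"]), 1)
  expect_equal(unname(q0["error"]), 1)

  # random rules against a direct counting oracle
  set.seed(5)
  for (i in 1:20) {
    xx <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
    yy <- sample(c("p", "q"), 30, replace = TRUE)
    if (length(unique(yy)) < 2) next
    t1 <- rnorm(1); t2 <- rnorm(1)
    rr <- structure(list(premise = list(condition("a", "<=", high = t1),
                                        condition("b", ">", low = t2)),
                         class = "p", covering = NA, error = NA),
                    class = "llm_rule")
    got <- rule_quality(rr, xx, yy)
    sat <- xx[, "a"] <= t1 & xx[, "b"] > t2
    expect_equal(unname(got["covering"]), sum(sat & yy == "p") / sum(yy == "p"))
    expect_equal(unname(got["error"]), sum(sat & yy == "q") / sum(yy == "q"))
  }
  expect_error(rule_quality(r, x, rep("pos", 10)), "outside")
})

test_that("condition_relevance is dE times covering, clipped at zero", {
  # engineered dataset: premise (g1 <= 0.5) & (g2 <= 0.5) on 0/1 features
  # 10 positives: 5 satisfy both; 10 negatives: 1 satisfies both and
  # 2 more satisfy g1 only, so dropping the g2 condition raises E by 0.2
  x <- cbind(
    g1 = c(rep(0, 5), rep(1, 5), rep(0, 3), rep(1, 7)),
    g2 = c(rep(0, 5), rep(1, 5), 0, 1, 1, rep(0, 7)))
  labels <- rep(c("pos", "neg"), each = 10)
  r <- structure(list(premise = list(condition("g1", "<=", high = 0.5),
                                     condition("g2", "<=", high = 0.5)),
                      class = "pos", covering = NA, error = NA),
                 class = "llm_rule")
  q <- rule_quality(r, x, labels)
  expect_equal(unname(q["covering"]), 0.5)
  expect_equal(unname(q["error"]), 0.1)
  # dropping condition 2: E goes 0.1 -> 0.3, so R = 0.2 * 0.5
  expect_equal(condition_relevance(r, 2, x, labels), 0.2 * 0.5)
  expect_error(condition_relevance(r, 9, x, labels), "index")

  # random data: matches recompute-from-scratch
  set.seed(8)
  xx <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("g1", "g2")))
  yy <- sample(c("pos", "neg"), 40, replace = TRUE)
  rr <- structure(list(premise = list(condition("g1", "<=", high = 0.6),
                                      condition("g2", ">", low = 0.3)),
                       class = "pos", covering = NA, error = NA),
                  class = "llm_rule")
  ce <- rule_quality(rr, xx, yy)
  rdrop <- rr; rdrop$premise <- rr$premise[-1]
  e_prime <- rule_quality(rdrop, xx, yy)[["error"]]
  expect_equal(condition_relevance(rr, 1, xx, yy),
               max(e_prime - ce[["error"]], 0) * ce[["covering"]])
})

test_that("variable_relevance aggregates 1 - prod(1 - R) and flags marginals", {
  set.seed(19)
  x <- matrix(rnorm(200, 7), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c("A", "B"), 25)
  x[y == "B", "g2"] <- x[y == "B", "g2"] + 3
  model <- llm_train(x, y, max_error = 0.05)
  rv <- variable_relevance(model, x, y)
  # independent recomputation from per-condition relevances
  manual <- stats::setNames(rep(0, 4), paste0("g", 1:4))
  for (rule in model$rules) {
    for (i in seq_along(rule$premise)) {
      f <- rule$premise[[i]]$feature
      manual[f] <- 1 - (1 - manual[f]) *
        (1 - condition_relevance(rule, i, x, y))
    }
  }
  expect_equal(rv, manual, ignore_attr = TRUE)
  # unused features have zero relevance and are flagged marginal
  unused <- setdiff(paste0("g", 1:4),
                    unlist(lapply(model$rules, function(r) {
                      vapply(r$premise, function(cond) cond$feature, "")
                    })))
  for (f in unused) expect_equal(unname(rv[f]), 0)
  expect_true(all(attr(rv, "marginal")[rv <= 0.10]))
  expect_error(variable_relevance(model, x, y, features = "nope"), "unknown")
})

test_that("prediction votes by covering with prior and name tie-breaks", {
  map <- structure(list(cutoffs = list(g1 = 5, g2 = 5),
                        features = c("g1", "g2")), class = "disc_map")
  mk_model <- function(rules, sizes) {
    structure(list(discretization = map, rules = rules,
                   default_class = names(sizes)[which.max(sizes)],
                   class_sizes = sizes, uncovered = list(),
                   params = list()), class = "llm_model")
  }
  rule <- function(feature, op, thr, cls, cov, id) {
    r <- structure(list(premise = list(
      if (op == "<=") condition(feature, "<=", high = thr)
      else condition(feature, ">", low = thr)),
      class = cls, covering = cov, error = 0), class = "llm_rule")
    r$id <- id
    r
  }
  m <- mk_model(list(rule("g1", "<=", 5, "A", 0.9, 1L),
                     rule("g2", "<=", 5, "B", 0.3, 2L)),
                c(A = 10L, B = 10L))
  # fires only rule 1 -> A
  expect_equal(unname(predict(m, c(g1 = 1, g2 = 9))), "A")
  # fires both -> A wins on covering 0.9 vs 0.3
  expect_equal(unname(predict(m, c(g1 = 1, g2 = 1))), "A")
  # fires nothing -> default class
  expect_equal(unname(predict(m, c(g1 = 9, g2 = 9))), "A")
  expect_equal(fired_rules(m, c(g1 = 1, g2 = 1)), c(1L, 2L))
  # exact score tie -> larger training class, then name
  m2 <- mk_model(list(rule("g1", "<=", 5, "A", 0.5, 1L),
                      rule("g2", "<=", 5, "B", 0.5, 2L)),
                 c(A = 8L, B = 12L))
  expect_equal(unname(predict(m2, c(g1 = 1, g2 = 1))), "B")
  m3 <- mk_model(list(rule("g1", "<=", 5, "A", 0.5, 1L),
                      rule("g2", "<=", 5, "B", 0.5, 2L)),
                 c(A = 10L, B = 10L))
  expect_equal(unname(predict(m3, c(g1 = 1, g2 = 1))), "A")
  expect_error(predict(m, c(g1 = 1)), "g2")
  sc <- predict(m, rbind(c(1, 1), c(9, 9)) |>
                  (\(z) {colnames(z) <- c("g1", "g2"); z})(), type = "score")
  expect_equal(dim(sc), c(2L, 2L))
})

test_that("outlier rules are flagged by C(1 - E) <= 10%", {
  mk_rule <- function(cov, err, id) {
    r <- structure(list(premise = list(condition("g", "<=", high = 1)),
                        class = "A", covering = cov, error = err),
                   class = "llm_rule")
    r$id <- id
    r
  }
  model <- structure(list(
    discretization = structure(list(cutoffs = list(g = 1), features = "g"),
                               class = "disc_map"),
    rules = list(mk_rule(1, 0, 1L), mk_rule(0.05, 0, 2L),
                 mk_rule(0.5, 0.9, 3L)),
    default_class = "A", class_sizes = c(A = 5L), uncovered = list(),
    params = list()), class = "llm_model")
  expect_equal(flag_outlier_rules(model), c(2L, 3L))
})

test_that("trained models honour the error bound and coverage contract", {
  set.seed(23)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 30, 7), 40, 30,
                dimnames = list(NULL, paste0("g", 1:30)))
    y <- rep(c("A", "B"), 20)
    x[y == "B", "g1"] <- x[y == "B", "g1"] + 3
    model <- llm_train(x, y, max_error = 0.05)
    for (rule in model$rules) {
      expect_lte(rule$error, 0.05 + 1e-12)
      expect_length(rule$premise, length(rule$premise)) # premise well formed
      expect_gt(rule$covering, 0)
    }
    # union of a class's rules covers its training samples except the
    # explicitly reported ones
    for (cls in c("A", "B")) {
      own <- which(y == cls)
      fired <- rep(FALSE, nrow(x))
      for (rule in model$rules) {
        if (rule$class == cls) fired <- fired | rule_fires(rule, x)
      }
      uncov <- model$uncovered[[cls]]
      expect_setequal(setdiff(own, which(fired)),
                      if (is.null(uncov)) integer(0) else uncov)
    }
  }
})

test_that("planted single-feature rules are recovered near the true threshold", {
  spec <- synth_spec(classes = c("A", "B"), sizes = 20, p = 50, effect = 3,
                     seed = 424)
  sim <- simulate_expression(spec)
  model <- llm_train(sim$x, sim$labels)
  rv <- variable_relevance(model, sim$x, sim$labels)
  expect_true(names(which.max(rv)) %in% sim$truth$feature)
  # the top rule's threshold sits within one bin of the planted threshold
  planted <- sim$truth$feature
  thr <- sim$truth$threshold[1]
  hits <- unlist(lapply(model$rules, function(r) {
    vapply(r$premise, function(cond) {
      if (cond$feature %in% planted) {
        min(abs(c(cond$low, cond$high) - thr), na.rm = TRUE)
      } else NA_real_
    }, numeric(1))
  }))
  expect_true(any(hits[!is.na(hits)] < 1.5))
})

test_that("multi-class training produces per-class rules and sane predictions", {
  spec <- synth_spec(classes = c("mm", "mgus", "smm"), sizes = c(14, 12, 10),
                     p = 60, effect = 3, seed = 555)
  sim <- simulate_expression(spec)
  model <- llm_train(sim$x, sim$labels)
  classes_with_rules <- unique(vapply(model$rules, function(r) r$class, ""))
  expect_setequal(classes_with_rules, c("mm", "mgus", "smm"))
  expect_equal(model$default_class, "mm")   # largest training class
  # rules sorted by decreasing covering within class
  for (cls in classes_with_rules) {
    cov <- vapply(Filter(function(r) r$class == cls, model$rules),
                  function(r) r$covering, numeric(1))
    expect_true(all(diff(cov) <= 1e-12))
  }
  preds <- predict(model, sim$x)
  expect_gt(mean(preds == sim$labels), 0.9)
  cm <- confusion_matrix(sim$labels, preds)
  acc <- study_accuracy(cm, reference = select_reference(
    rownames(cm), sizes = rowSums(cm)))
  expect_true(is.finite(acc$log_or))
  expect_equal(acc$youden, acc$se + acc$sp - 1, tolerance = 1e-12)
})
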