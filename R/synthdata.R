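#' Specification of a synthetic expression dataset
#'
#' Describes a gene-expression-like dataset with planted threshold rules.
#' Values live on a log2-intensity-like scale: every feature is Normal with
#' the baseline location and scale, and each class gets one (or more)
#' informative feature shifted upward by `effect` standard deviations in that
#' class only, so the true decision boundary for feature `f_k` of class `k`
#' is the threshold `mu + effect*sigma/2`.
#'
#' @param classes class names.
#' @param sizes samples per class (recycled if scalar).
#' @param p total number of features.
#' @param informative number of informative features per class.
#' @param effect location shift of informative features, in units of `sigma`.
#' @param mu,sigma baseline location and scale of the log-intensity values.
#' @param seed optional integer seed stored in the spec; `simulate_expression`
#'   uses it so the same spec always yields the same dataset.
#' @return a `synth_spec` object.
#' @export
synth_spec <- function(classes = c("A", "B"), sizes = 20L, p = 200L,
                       informative = 1L, effect = 3, mu = 7, sigma = 1,
                       seed = NULL) {
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("need at least 2 classes")
  sizes <- rep_len(as.integer(sizes), length(classes))
  if (any(sizes < 1L)) stop("class sizes must be >= 1")
  if (informative * length(classes) > p) {
    stop("more informative features than total features")
  }
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(classes = classes, sizes = sizes, p = as.integer(p),
                 informative = as.integer(informative), effect = effect,
                 mu = mu, sigma = sigma, seed = seed),
            class = "synth_spec")
}

#' Simulate an expression dataset with planted threshold rules
#'
#' Noise features are identically distributed across classes; informative
#' feature `gene<j>` of class `k` is shifted by `effect*sigma` in class `k`
#' only.  The returned ground truth lists one single-condition rule per
#' informative feature: `gene<j> > mu + effect*sigma/2  =>  class k`.
#'
#' @param spec a `synth_spec`.
#' @return list with `x` (n x p matrix, sample ids in rownames), `labels`,
#'   and `truth` (data.frame: feature, op, threshold, class).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- sum(spec$sizes)
  p <- spec$p
  labels <- rep(spec$classes, spec$sizes)
  x <- matrix(stats::rnorm(n * p, mean = spec$mu, sd = spec$sigma), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("gene%d", seq_len(p))))
  k <- length(spec$classes)
  truth <- NULL
  if (spec$informative > 0L) {
    feat_idx <- seq_len(spec$informative * k)
    truth <- data.frame(
      feature = colnames(x)[feat_idx],
      op = ">",
      threshold = spec$mu + spec$effect * spec$sigma / 2,
      class = rep(spec$classes, each = spec$informative),
      stringsAsFactors = FALSE)
    for (r in seq_len(nrow(truth))) {
      in_class <- labels == truth$class[r]
      x[in_class, truth$feature[r]] <-
        x[in_class, truth$feature[r]] + spec$effect * spec$sigma
    }
  }
  list(x = x, labels = labels, truth = truth)
}

#' Simulate a table of study-level odds ratios
#'
#' Draws `log(OR_i) ~ Normal(log(sor_true), sigma_i^2)` with per-study
#' variances uniform on `var_range`; feeds the summary-ROC pooling stage.
#'
#' @param n_studies number of studies (>= 1).
#' @param sor_true generating summary odds ratio.
#' @param var_range length-2 range for the per-study variance of log(OR); a
#'   degenerate range (equal endpoints) gives homogeneous variances.
#' @param seed optional integer seed.
#' @return data.frame with `study`, `log_or`, `var`.
#' @export
make_study_set <- function(n_studies, sor_true, var_range = c(0.05, 0.5),
                           seed = NULL) {
  if (n_studies < 1L) stop("n_studies must be >= 1")
  if (sor_true <= 0) stop("sor_true must be positive")
  if (length(var_range) != 2L || any(var_range <= 0)) {
    stop("var_range must be two positive values")
  }
  if (!is.null(seed)) set.seed(seed)
  v <- stats::runif(n_studies, min(var_range), max(var_range))
  data.frame(study = sprintf("study%03d", seq_len(n_studies)),
             log_or = stats::rnorm(n_studies, log(sor_true), sqrt(v)),
             var = v,
             stringsAsFactors = FALSE)
}
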