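#' Supervised entropy-based discretization of expression features
#'
#' Fits per-feature cutoffs by greedy top-down minimization of the weighted
#' class entropy.  Candidate cutoffs are midpoints between consecutive sorted
#' distinct values of a feature; cutoffs are added one at a time (each new cut
#' splits the segment where it most reduces the weighted entropy) until
#' `max_bins - 1` cutoffs are placed or no candidate reduces the entropy.
#' Constant features receive no cutoffs and a single bin; such features are
#' non-informative and never appear in rule conditions.
#'
#' @param x numeric matrix, samples in rows, features in columns (named).
#' @param labels class label per sample (character or factor), at least two
#'   distinct classes.
#' @param max_bins maximum number of bins per feature (>= 2); the default 4
#'   keeps rule conditions to at most two thresholds (one interval).
#' @param top_k optional univariate pre-filter: keep only the `top_k` features
#'   with the largest entropy gain of their first cut.  Off (`NULL`) by
#'   default; intended for very wide matrices.
#' @param stopping cut acceptance rule.  `"mdl"` (default) additionally
#'   requires every cut to pass the Fayyad-Irani minimum-description-length
#'   test, so features carrying no class signal receive no cutoffs and are
#'   excluded from rule conditions; `"none"` accepts any cut that reduces
#'   the weighted class entropy.
#' @return an object of class `disc_map`: a list with `cutoffs` (named list of
#'   strictly increasing numeric vectors, possibly empty) and `features`.
#' @export
fit_discretizer <- function(x, labels, max_bins = 4L, top_k = NULL,
                            stopping = c("mdl", "none")) {
  stopping <- match.arg(stopping)
  x <- as_expression_matrix(x)
  labels <- as.character(labels)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (length(labels) != nrow(x)) stop("labels length must match rows of x")
  if (length(unique(labels)) < 2L) stop("degenerate labels: need >= 2 classes")
  if (max_bins < 2L) stop("max_bins must be >= 2")

  y <- as.integer(factor(labels))
  m <- max(y)
  mdl <- stopping == "mdl"
  cuts <- lapply(seq_len(ncol(x)), function(j) {
    feature_cutoffs(x[, j], y, m, as.integer(max_bins), mdl)
  })
  names(cuts) <- colnames(x)

  if (!is.null(top_k) && top_k < length(cuts)) {
    gain <- vapply(seq_len(ncol(x)), function(j) {
      first_cut_gain(x[, j], y, m)
    }, numeric(1))
    keep <- order(gain, decreasing = TRUE)[seq_len(top_k)]
    keep <- sort(keep)
    cuts <- cuts[keep]
  }

  structure(list(cutoffs = cuts, features = names(cuts)), class = "disc_map")
}

# Shannon entropy (nats would do; base 2 kept for the usual convention)
class_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# x*log2(x) with 0*log(0) = 0, elementwise
xlog2 <- function(z) {
  r <- z * log(z)
  r[z == 0] <- 0
  r / log(2)
}

# Best single split of the sorted slice vs[lo:hi] / ys[lo:hi].  Returns the
# cutoff (midpoint), its position (last index of the left part), and the
# summed count-weighted entropy of the two parts (in count x bits units, so
# the entropy drop relative to the parent is parent_h - entropy).
best_split_sorted <- function(vs, ys, lo, hi, m) {
  if (hi - lo < 1L) return(list(cut = NA_real_, at = NA_integer_, entropy = Inf))
  v <- vs[lo:hi]
  y <- ys[lo:hi]
  edge <- which(diff(v) > 0)               # split after local position i
  if (length(edge) == 0L) {
    return(list(cut = NA_real_, at = NA_integer_, entropy = Inf))
  }
  nseg <- length(v)
  left <- matrix(0, length(edge), m)
  tot <- numeric(m)
  for (c in seq_len(m)) {
    cs <- cumsum(y == c)
    left[, c] <- cs[edge]
    tot[c] <- cs[nseg]
  }
  right <- -left + rep(tot, each = length(edge))
  nl <- rowSums(left)
  nr <- nseg - nl
  # count-weighted entropy: n*H = n*log2(n) - sum_c cnt*log2(cnt)
  w <- (xlog2(nl) - rowSums(xlog2(left))) + (xlog2(nr) - rowSums(xlog2(right)))
  best <- which.min(w)                     # ties: earliest candidate
  i <- edge[best]
  list(cut = (v[i] + v[i + 1L]) / 2, at = lo + i - 1L, entropy = w[best])
}

first_cut_gain <- function(v, y, m) {
  o <- order(v)
  n <- length(v)
  h0 <- class_entropy(tabulate(y, m)) * n
  s <- best_split_sorted(v[o], y[o], 1L, n, m)
  if (!is.finite(s$entropy)) 0 else max((h0 - s$entropy) / n, 0)
}

# Greedy top-down cutoffs for one feature (C hot path; feature_cutoffs_r is
# the reference implementation the tests compare against).
feature_cutoffs <- function(v, y, m, max_bins, mdl = TRUE) {
  o <- order(v)
  .Call(C_feature_cutoffs, as.numeric(v[o]), as.integer(y[o]),
        as.integer(m), as.integer(max_bins), as.integer(mdl))
}

# Pure-R reference: repeatedly split the segment whose best cut most reduces
# the total weighted entropy; each segment's best cut computed on creation.
feature_cutoffs_r <- function(v, y, m, max_bins, mdl = TRUE) {
  o <- order(v)
  vs <- v[o]
  ys <- y[o]
  n <- length(v)
  seg_h <- function(lo, hi) {
    cnt <- tabulate(ys[lo:hi], m)
    xlog2(hi - lo + 1L) - sum(xlog2(cnt))
  }
  # Fayyad-Irani MDL acceptance of a candidate split
  mdl_accept <- function(lo, hi, at) {
    nn <- hi - lo + 1L
    ent <- function(a, b) {
      cnt <- tabulate(ys[a:b], m)
      list(e = class_entropy(cnt), k = sum(cnt > 0L))
    }
    s0 <- ent(lo, hi); s1 <- ent(lo, at); s2 <- ent(at + 1L, hi)
    gain <- s0$e - ((at - lo + 1L) * s1$e + (hi - at) * s2$e) / nn
    delta <- log2(3^s0$k - 2) - (s0$k * s0$e - s1$k * s1$e - s2$k * s2$e)
    gain > (log2(nn - 1) + delta) / nn
  }
  new_seg <- function(lo, hi) {
    split <- best_split_sorted(vs, ys, lo, hi, m)
    if (mdl && !is.na(split$at) && !mdl_accept(lo, hi, split$at)) {
      split <- list(cut = NA_real_, at = NA_integer_, entropy = Inf)
    }
    list(lo = lo, hi = hi, h = seg_h(lo, hi), split = split)
  }
  segs <- list(new_seg(1L, n))
  cuts <- numeric(0)
  while (length(cuts) < max_bins - 1L) {
    delta <- vapply(segs, function(s) {
      if (!is.finite(s$split$entropy)) Inf else s$split$entropy - s$h
    }, numeric(1))
    k <- which.min(delta)
    if (!is.finite(delta[k]) || delta[k] >= -1e-9) break
    s <- segs[[k]]
    segs <- c(segs[-k], list(new_seg(s$lo, s$split$at),
                             new_seg(s$split$at + 1L, s$hi)))
    cuts <- sort(c(cuts, s$split$cut))
  }
  cuts
}

#' Number of bins per feature of a discretization map
#' @param map a `disc_map`.
#' @return named integer vector, `length(cutoffs) + 1` per feature.
#' @export
bin_counts <- function(map) {
  stopifnot(inherits(map, "disc_map"))
  vapply(map$cutoffs, function(cc) length(cc) + 1L, integer(1))
}

#' Bin index of values under a cutoff vector
#'
#' Bins are half-open on the right: `(-Inf, c1], (c1, c2], ..., (c_q, Inf)`.
#' A value exactly equal to a cutoff falls in the lower bin, matching the
#' `<=` convention used when rendering rule conditions.
#'
#' @param v numeric values.
#' @param cutoffs strictly increasing numeric vector (possibly empty).
#' @return integer bin indices in `1..length(cutoffs)+1`.
#' @export
bin_index <- function(v, cutoffs) {
  if (length(cutoffs) == 0L) return(rep(1L, length(v)))
  findInterval(v, cutoffs, left.open = TRUE) + 1L
}

#' Latticization: inverse only-one binarization of samples
#'
#' Encodes each sample as one concatenated binary string, one block per
#' feature.  A feature with `q` bins contributes `q` bits, all 1 except a
#' single 0 at the position of the bin containing the value (the complement
#' of one-hot coding).  All feature blocks are concatenated into a single
#' fixed-length pattern per sample.
#'
#' @param x numeric matrix (samples x features) or a single named numeric
#'   vector; must provide a value for every feature in `map`.
#' @param map a `disc_map` from [fit_discretizer()].
#' @return an object of class `binary_pattern`: list with `bits` (n x L 0/1
#'   integer matrix), `bins` (n x F integer matrix of bin indices),
#'   `block_offsets` (0-based start of each feature block) and `bin_count`.
#' @export
binarize <- function(x, map) {
  stopifnot(inherits(map, "disc_map"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  missing <- setdiff(map$features, colnames(x))
  if (length(missing) > 0L) {
    stop("missing feature value(s): ", paste(missing, collapse = ", "))
  }
  q <- bin_counts(map)
  off <- cumsum(c(0L, q[-length(q)]))
  names(off) <- map$features
  n <- nrow(x)
  bins <- matrix(0L, n, length(map$features),
                 dimnames = list(rownames(x), map$features))
  for (j in seq_along(map$features)) {
    bins[, j] <- bin_index(x[, map$features[j]], map$cutoffs[[j]])
  }
  L <- sum(q)
  bits <- matrix(1L, n, L)
  zero_col <- sweep(bins, 2L, off, "+")  # n x F, column of the single 0 bit
  bits[cbind(rep(seq_len(n), ncol(bins)), as.vector(zero_col))] <- 0L
  structure(list(bits = bits, bins = bins, block_offsets = off, bin_count = q),
            class = "binary_pattern")
}

#' @export
print.disc_map <- function(x, ...) {
  nb <- bin_counts(x)
  cat("Discretization map:", length(x$features), "features,",
      sum(nb > 1L), "informative (>1 bin)\n")
  invisible(x)
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat("Binary patterns:", nrow(x$bits), "samples x", ncol(x$bits),
      "bits (", length(x$block_offsets), "feature blocks )\n")
  invisible(x)
}

# coerce + validate an expression matrix (numeric, named columns)
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("feature", seq_len(ncol(x)))
  }
  x
}
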