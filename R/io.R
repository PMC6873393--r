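#' Read a delimited expression matrix
#'
#' Expects a header row of feature ids and a first column of sample ids
#' (`samples` orientation), or a header of sample ids and first column of
#' feature ids (`genes` orientation, transposed on read).  The delimiter is
#' taken from the file extension (`.csv` = comma, otherwise tab) unless
#' given.
#'
#' @param path file path.
#' @param orientation `"samples"` (samples in rows, default) or `"genes"`.
#' @param sep field delimiter override.
#' @return numeric matrix, samples in rows, with dimnames.
#' @export
read_expression <- function(path, orientation = c("samples", "genes"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feats <- colnames(df)[-1L]
  if (anyDuplicated(feats)) {
    stop("duplicated column id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  x <- matrix(NA_real_, length(ids), length(feats),
              dimnames = list(ids, feats))
  for (j in seq_along(feats)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
    if (length(bad) > 0L) {
      stop("non-numeric value '", raw[bad[1L]], "' at row '", ids[bad[1L]],
           "', column '", feats[j], "'")
    }
    x[, j] <- val
  }
  if (orientation == "genes") x <- t(x)
  x
}

#' Write an expression matrix
#' @param x numeric matrix, samples in rows.
#' @param path output path; delimiter from extension unless `sep` given.
#' @param sep field delimiter override.
#' @export
write_expression <- function(x, path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  x <- as_expression_matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  df <- data.frame(sample = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column (sample id, class) label file
#' @param path file path.
#' @return named character vector of classes, names = sample ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) != 2L) stop("label file must have exactly 2 columns")
  if (anyDuplicated(df[[1L]])) stop("duplicated sample id(s) in label file")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a two-column label file
#' @param labels classes, named by sample id (or `ids` given separately).
#' @param path output path.
#' @param ids sample ids (defaults to `names(labels)`).
#' @export
write_labels <- function(labels, path, ids = names(labels)) {
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(labels))
  utils::write.table(data.frame(sample = ids, class = as.character(labels)),
                     path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# percent with one decimal, rounded half-up (report convention)
format_pct <- function(x) {
  p <- x * 100
  sprintf("%.1f", sign(p) * floor(abs(p) * 10 + 0.5) / 10)
}

fmt_num <- function(x) as.character(signif(x, 10))

quote_feature <- function(f) {
  if (grepl("[\"[:space:]<>\u2264]", f)) paste0('"', gsub('"', '\\\\"', f), '"')
  else f
}

render_condition <- function(cond) {
  f <- quote_feature(cond$feature)
  switch(cond$op,
         "<=" = paste0(f, " \u2264 ", fmt_num(cond$high)),
         ">"  = paste0(f, " > ", fmt_num(cond$low)),
         "in" = paste0(fmt_num(cond$low), " < ", f, " \u2264 ",
                       fmt_num(cond$high)))
}

render_rule <- function(rule) {
  premise <- if (length(rule$premise) == 0L) "TRUE" else {
    paste(vapply(rule$premise, render_condition, character(1)),
          collapse = " AND ")
  }
  sprintf("if %s then %s  [covering %s%%]", premise, rule$class,
          format_pct(rule$covering))
}

#' Render a rule model as human-readable text
#'
#' One line per rule, in the style
#' `if AQP7 <= 8.46 AND X > 2 then HC  [covering 100.0%]`, with interval
#' conditions rendered as `a < x <= b` and the covering as a percentage with
#' one decimal.  The first line is a `#` header; [parse_rules()] inverts the
#' rendering.
#'
#' @param model an `llm_model`, or a list of `llm_rule`s.
#' @return character vector of lines (header first).
#' @export
render_rules <- function(model) {
  rules <- if (inherits(model, "llm_model")) model$rules else model
  c("# rules (one per line; covering on training data)",
    vapply(rules, render_rule, character(1)))
}

#' Parse rules rendered by [render_rules()]
#'
#' @param lines character vector; `#` comments and blank lines are skipped.
#' @return list of `llm_rule` objects (error is `NA`: the rendering does not
#'   carry it).
#' @export
parse_rules <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_rule_line)
}

parse_rule_line <- function(line) {
  m <- regmatches(line, regexec(
    "^if (.*) then (.*?)  \\[covering ([-0-9.]+)%\\]$", line))[[1L]]
  if (length(m) != 4L) stop("unparseable rule line: ", line)
  premise <- if (m[2] == "TRUE") list() else {
    lapply(strsplit(m[2], " AND ", fixed = TRUE)[[1L]], parse_condition)
  }
  new_rule(premise, m[3], covering = as.numeric(m[4]) / 100)
}

parse_condition <- function(txt) {
  txt <- gsub("\u2264", "<=", txt)
  feat_rx <- "(\"(?:[^\"\\\\]|\\\\\")+\"|[^\" ]+)"
  num_rx <- "([-+0-9.eE]+)"
  unq <- function(f) {
    if (startsWith(f, "\"")) gsub('\\\\"', '"', substr(f, 2, nchar(f) - 1L))
    else f
  }
  m <- regmatches(txt, regexec(
    paste0("^", num_rx, " < ", feat_rx, " <= ", num_rx, "$"), txt))[[1L]]
  if (length(m) == 4L) {
    return(condition(unq(m[3]), "in", low = as.numeric(m[2]),
                     high = as.numeric(m[4])))
  }
  m <- regmatches(txt, regexec(paste0("^", feat_rx, " <= ", num_rx, "$"),
                               txt))[[1L]]
  if (length(m) == 3L) return(condition(unq(m[2]), "<=", high = as.numeric(m[3])))
  m <- regmatches(txt, regexec(paste0("^", feat_rx, " > ", num_rx, "$"),
                               txt))[[1L]]
  if (length(m) == 3L) return(condition(unq(m[2]), ">", low = as.numeric(m[3])))
  stop("unparseable condition: ", txt)
}

#' Serialize a rule model to JSON
#'
#' Schema: `{discretization: {feature: [cutoffs]}, rules: [{premise:
#' [{feature, op, low, high}], class, covering, error}], default_class,
#' class_sizes, params}`.
#'
#' @param model an `llm_model`.
#' @param path output path.
#' @export
write_rule_model <- function(model, path) {
  stopifnot(inherits(model, "llm_model"))
  obj <- list(
    discretization = lapply(model$discretization$cutoffs, function(cc) {
      as.numeric(cc)
    }),
    rules = lapply(model$rules, function(r) {
      list(premise = lapply(r$premise, function(cond) {
             list(feature = cond$feature, op = cond$op,
                  low = cond$low, high = cond$high)
           }),
           class = r$class, covering = r$covering, error = r$error,
           id = r$id)
    }),
    default_class = model$default_class,
    class_sizes = as.list(model$class_sizes),
    params = model$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a rule model written by [write_rule_model()]
#' @param path JSON file path.
#' @return an `llm_model`.
#' @export
read_rule_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cutoffs <- lapply(obj$discretization, function(cc) {
    as.numeric(unlist(cc))
  })
  map <- structure(list(cutoffs = cutoffs, features = names(cutoffs)),
                   class = "disc_map")
  rules <- lapply(obj$rules, function(r) {
    premise <- lapply(r$premise, function(cond) {
      structure(list(feature = cond$feature, op = cond$op,
                     low = if (is.null(cond$low)) NA_real_ else cond$low,
                     high = if (is.null(cond$high)) NA_real_ else cond$high),
                class = "condition")
    })
    rule <- new_rule(premise, r$class, covering = r$covering, error = r$error)
    rule$id <- r$id
    rule
  })
  params <- obj$params
  if (!is.null(params$top_k)) params$top_k <- as.integer(params$top_k)
  structure(list(discretization = map, rules = rules,
                 default_class = obj$default_class,
                 class_sizes = stats::setNames(
                   vapply(obj$class_sizes, as.integer, integer(1)),
                   names(obj$class_sizes)),
                 uncovered = list(),
                 params = params),
            class = "llm_model")
}
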