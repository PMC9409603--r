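#' Column similarity components
#'
#' For one shared parameter `j`, the membership component compares the two
#' membership columns with a ratio similarity,
#' `1 - sum_i |a_i - b_i| / sum_i (a_i + b_i)`, and the reliability component
#' does the same for the reliability columns. When a denominator is zero both
#' columns are identically zero, and the component is defined as 1, the limit
#' for identical columns.
#'
#' @param x,y `"znss"` objects over the same universe, both containing
#'   parameter `parameter`.
#' @param parameter A parameter label present in both sets.
#' @return A number in `[0, 1]`.
#' @export
column_membership_similarity <- function(x, y, parameter) {
  cols <- .similarity_columns(x, y, parameter)
  .ratio_similarity(cols$x$mu[, parameter], cols$y$mu[, parameter])
}

#' @rdname column_membership_similarity
#' @export
column_reliability_similarity <- function(x, y, parameter) {
  cols <- .similarity_columns(x, y, parameter)
  .ratio_similarity(cols$x$r[, parameter], cols$y$r[, parameter])
}

#' Parameter similarity
#'
#' The similarity attached to one parameter is the product of its membership
#' and reliability column components.
#'
#' @inheritParams column_membership_similarity
#' @return A number in `[0, 1]`.
#' @export
parameter_similarity <- function(x, y, parameter) {
  column_membership_similarity(x, y, parameter) *
    column_reliability_similarity(x, y, parameter)
}

.similarity_columns <- function(x, y, parameter) {
  stopifnot(inherits(x, "znss"), inherits(y, "znss"))
  y <- align_universe(y, x)
  for (s in list(x, y)) {
    if (!parameter %in% present_parameters(s)) {
      stop(sprintf("parameter '%s' is not present in both sets", parameter),
           call. = FALSE)
    }
  }
  list(x = x, y = y)
}

.ratio_similarity <- function(a, b) {
  den <- sum(a + b)
  if (den == 0) return(1)
  1 - sum(abs(a - b)) / den
}

#' Similarity between two Z-number soft sets
#'
#' Computes, for every parameter, the product of the membership-column and
#' reliability-column ratio similarities, and aggregates them into an overall
#' score: the maximum over parameters by default (the parameter on which the
#' two sets agree best), or the arithmetic mean under `aggregate = "mean"` for
#' sensitivity studies.
#'
#' By default both sets must present the same parameters; `shared_only = TRUE`
#' relaxes this and scores over the ordered intersection of present
#' parameters.
#'
#' @param x,y `"znss"` objects over the same universe.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @param shared_only Score only the parameters present in both sets instead
#'   of requiring identical parameter sets.
#' @return An object of class `"znss_similarity"`: a list with
#'   `per_parameter` (data frame of parameter, membership and reliability
#'   components and their product), `score`, `best_parameter` (first argmax in
#'   column order), `aggregate` and `zero_denominator` (labels of components
#'   where the 0/0 convention fired).
#' @examples
#' a <- paper_fixture("sim_example_F")
#' b <- paper_fixture("sim_example_G")
#' znss_similarity(a, b)
#' @export
znss_similarity <- function(x, y, aggregate = c("max", "mean"),
                            shared_only = FALSE) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(x, "znss"), inherits(y, "znss"))
  y <- align_universe(y, x)
  px <- present_parameters(x)
  py <- present_parameters(y)
  if (shared_only) {
    params <- px[px %in% py]
    if (!length(params)) {
      stop("no shared present parameters to compare", call. = FALSE)
    }
  } else {
    if (!setequal(px, py)) {
      stop(sprintf(
        "parameter sets differ: only in first {%s}; only in second {%s}",
        paste(setdiff(px, py), collapse = ", "),
        paste(setdiff(py, px), collapse = ", ")), call. = FALSE)
    }
    params <- px
  }
  n <- length(params)
  m_mu <- m_r <- numeric(n)
  zero_den <- character()
  for (k in seq_len(n)) {
    p <- params[k]
    if (sum(x$mu[, p] + y$mu[, p]) == 0) {
      zero_den <- c(zero_den, paste0(p, ":membership"))
    }
    if (sum(x$r[, p] + y$r[, p]) == 0) {
      zero_den <- c(zero_den, paste0(p, ":reliability"))
    }
    m_mu[k] <- .ratio_similarity(x$mu[, p], y$mu[, p])
    m_r[k] <- .ratio_similarity(x$r[, p], y$r[, p])
  }
  product <- m_mu * m_r
  score <- if (n == 0) NA_real_
           else if (aggregate == "max") max(product) else mean(product)
  best <- if (n == 0) NA_character_ else params[which.max(product)]
  structure(list(
    per_parameter = data.frame(parameter = params,
                               membership = m_mu,
                               reliability = m_r,
                               product = product,
                               stringsAsFactors = FALSE),
    score = score,
    best_parameter = best,
    aggregate = aggregate,
    zero_denominator = zero_den
  ), class = "znss_similarity")
}

#' @export
print.znss_similarity <- function(x, digits = 3, ...) {
  cat("Z-number soft set similarity\n")
  df <- x$per_parameter
  df$membership <- round(df$membership, digits)
  df$reliability <- round(df$reliability, digits)
  df$product <- round(df$product, digits)
  print(df, row.names = FALSE)
  cat(sprintf("score (%s): %s", x$aggregate,
              formatC(x$score, digits = digits, format = "f")))
  if (x$aggregate == "max") cat(sprintf("  at parameter %s", x$best_parameter))
  cat("\n")
  if (length(x$zero_denominator)) {
    cat("zero-denominator convention used for:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  }
  invisible(x)
}
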