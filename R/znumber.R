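#' Construct a Z-number
#'
#' A Z-number records a single uncertain judgment as an ordered pair: a
#' membership degree `mu` (how strongly the alternative satisfies the
#' parameter) and a reliability degree `r` (how much confidence is attached to
#' that membership judgment). Both lie in `[0, 1]`.
#'
#' @param mu Membership degree in `[0, 1]`.
#' @param r Reliability degree in `[0, 1]`.
#' @return An object of class `"znumber"`: a named numeric vector
#'   `c(mu = mu, r = r)`.
#' @examples
#' znumber(0.2, 0.5)
#' @export
znumber <- function(mu, r) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) ||
      !is.numeric(r) || length(r) != 1L || is.na(r)) {
    stop("a Z-number needs two finite numeric components (mu, r)", call. = FALSE)
  }
  if (mu < 0 || mu > 1 || r < 0 || r > 1) {
    stop(sprintf("Z-number components must lie in [0, 1], got (%g, %g)", mu, r),
         call. = FALSE)
  }
  structure(c(mu = as.numeric(mu), r = as.numeric(r)), class = "znumber")
}

as_znumber <- function(z) {
  if (inherits(z, "znumber")) return(z)
  if (is.numeric(z) && length(z) == 2L) return(znumber(z[[1L]], z[[2L]]))
  stop("cannot interpret object as a Z-number", call. = FALSE)
}

#' @export
print.znumber <- function(x, ...) {
  cat(sprintf("(%g, %g)\n", x[["mu"]], x[["r"]]))
  invisible(x)
}

#' Complement of a Z-number
#'
#' Negates a judgment: both the membership and the reliability degrees are
#' reflected, `(mu, r) -> (1 - mu, 1 - r)`.
#'
#' The complement is re-rounded at the 15th decimal so that complementing
#' twice restores a judgment recorded with at most 15 decimals *exactly*
#' (plain `1 - (1 - x)` drifts by one ulp for decimals such as 0.1 or 0.2).
#'
#' @param z A [znumber()] (or a length-2 numeric `(mu, r)`).
#' @return A `"znumber"`.
#' @examples
#' z_complement(znumber(0.2, 0.5)) # (0.8, 0.5)
#' @export
z_complement <- function(z) {
  z <- as_znumber(z)
  znumber(complement_vals(z[["mu"]]), complement_vals(z[["r"]]))
}

complement_vals <- function(x) round(1 - x, 15)

.norm_choices <- c("product", "minmax")

# Componentwise t-conorm / t-norm on plain numeric vectors. The probabilistic
# sum is clamped into its mathematical envelope [max(a,b), 1] (and the product
# into [0, min(a,b)]) so boundary identities — combining with 0 or 1 — hold
# exactly despite rounding.
conorm_vals <- function(a, b, norm) {
  if (norm == "product") pmin(pmax(a + b - a * b, a, b), 1) else pmax(a, b)
}
norm_vals <- function(a, b, norm) {
  if (norm == "product") pmax(pmin(a * b, a, b), 0) else pmin(a, b)
}

#' Union (disjunction) of two Z-numbers
#'
#' Combines two judgments with a t-conorm applied to each component. The
#' `product` norm is the probabilistic sum `a + b - a*b`; the `minmax` norm is
#' the Zadeh maximum.
#'
#' @param z1,z2 [znumber()] values.
#' @param norm `"product"` (default) or `"minmax"`.
#' @return A `"znumber"`.
#' @examples
#' z_union(znumber(0.2, 0.5), znumber(0.1, 0.4)) # (0.28, 0.7)
#' @export
z_union <- function(z1, z2, norm = c("product", "minmax")) {
  norm <- match.arg(norm)
  z1 <- as_znumber(z1); z2 <- as_znumber(z2)
  znumber(conorm_vals(z1[["mu"]], z2[["mu"]], norm),
          conorm_vals(z1[["r"]], z2[["r"]], norm))
}

#' Intersection (conjunction) of two Z-numbers
#'
#' Combines two judgments with a t-norm applied to each component: the
#' componentwise product, or the Zadeh minimum under `"minmax"`.
#'
#' @inheritParams z_union
#' @return A `"znumber"`.
#' @examples
#' z_intersection(znumber(0.2, 0.5), znumber(0.1, 0.4)) # (0.02, 0.2)
#' @export
z_intersection <- function(z1, z2, norm = c("product", "minmax")) {
  norm <- match.arg(norm)
  z1 <- as_znumber(z1); z2 <- as_znumber(z2)
  znumber(norm_vals(z1[["mu"]], z2[["mu"]], norm),
          norm_vals(z1[["r"]], z2[["r"]], norm))
}

#' Componentwise order on Z-numbers
#'
#' `z1` is a Z-number subset of `z2` when both its membership and its
#' reliability degree are no larger than those of `z2`.
#'
#' @inheritParams z_union
#' @return `TRUE` or `FALSE`.
#' @export
z_subset <- function(z1, z2) {
  z1 <- as_znumber(z1); z2 <- as_znumber(z2)
  z1[["mu"]] <= z2[["mu"]] && z1[["r"]] <= z2[["r"]]
}
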