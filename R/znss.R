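#' Construct a Z-number soft set
#'
#' A Z-number soft set (ZnSS) records, for every alternative in a finite
#' universe and every *present* parameter, a Z-number judgment `(mu, r)`.
#' Parameters may be declared but absent (no judgments at all for that
#' column); a present column must carry a judgment for every alternative —
#' ragged columns are rejected.
#'
#' @param universe Character vector of distinct alternative labels, in order.
#' @param parameters Character vector of distinct parameter labels, in order.
#'   May include labels with no entry in `cells` (absent parameters).
#' @param cells Named list keyed by parameter label. Each element gives that
#'   column's judgments: either a named list of `(mu, r)` pairs keyed by
#'   alternative, or an `m x 2` numeric matrix with the universe as rownames.
#' @return An object of class `"znss"` with fields `universe`, `parameters`
#'   (all declared labels) and numeric matrices `mu` and `r` whose columns are
#'   the present parameters.
#' @examples
#' s <- znss(c("y", "n"), c("e1", "e2"),
#'           list(e1 = list(y = c(0.5, 0.8), n = c(0.5, 0.8)),
#'                e2 = list(y = c(0.9, 0.9), n = c(0.1, 0.9))))
#' print(s)
#' @seealso [znss_grid()] for construction from matrices, [znss_union()],
#'   [znss_similarity()], [read_znss()].
#' @export
znss <- function(universe, parameters, cells = list()) {
  universe <- as.character(universe)
  parameters <- as.character(parameters)
  if (anyDuplicated(universe)) {
    stop(sprintf("duplicate alternative label: '%s'",
                 universe[duplicated(universe)][1L]), call. = FALSE)
  }
  if (anyDuplicated(parameters)) {
    stop(sprintf("duplicate parameter label: '%s'",
                 parameters[duplicated(parameters)][1L]), call. = FALSE)
  }
  if (length(cells) && is.null(names(cells))) {
    stop("'cells' must be a named list keyed by parameter label", call. = FALSE)
  }
  unknown <- setdiff(names(cells), parameters)
  if (length(unknown)) {
    stop(sprintf("cells given for undeclared parameter: '%s'", unknown[1L]),
         call. = FALSE)
  }
  present <- parameters[parameters %in% names(cells)]
  m <- length(universe)
  mu <- matrix(NA_real_, m, length(present),
               dimnames = list(universe, present))
  r <- mu
  for (p in present) {
    col <- .cell_column(cells[[p]], universe, p)
    mu[, p] <- col[, 1L]
    r[, p] <- col[, 2L]
  }
  new_znss(mu, r, parameters)
}

# normalise one column specification to an m x 2 matrix in universe order
.cell_column <- function(col, universe, param) {
  m <- length(universe)
  if (is.matrix(col)) {
    if (ncol(col) != 2L) {
      stop(sprintf("column '%s' must have two components per cell", param),
           call. = FALSE)
    }
    if (!is.null(rownames(col))) {
      missing_alt <- setdiff(universe, rownames(col))
      if (length(missing_alt)) {
        stop(sprintf("ragged column: parameter '%s' has no judgment for alternative '%s'",
                     param, missing_alt[1L]), call. = FALSE)
      }
      col <- col[universe, , drop = FALSE]
    } else if (nrow(col) != m) {
      stop(sprintf("ragged column: parameter '%s' has %d rows for %d alternatives",
                   param, nrow(col), m), call. = FALSE)
    }
    return(col)
  }
  if (is.list(col)) {
    out <- matrix(NA_real_, m, 2L)
    for (i in seq_len(m)) {
      alt <- universe[i]
      z <- col[[alt]]
      if (is.null(z)) {
        stop(sprintf("ragged column: parameter '%s' has no judgment for alternative '%s'",
                     param, alt), call. = FALSE)
      }
      if (!is.numeric(z) || length(z) != 2L) {
        stop(sprintf("cell (%s, %s) is not a (mu, r) pair", alt, param),
             call. = FALSE)
      }
      out[i, ] <- as.numeric(z)
    }
    return(out)
  }
  stop(sprintf("column '%s' must be a named list of pairs or an m x 2 matrix",
               param), call. = FALSE)
}

#' Construct a Z-number soft set from membership and reliability matrices
#'
#' @param mu,r Numeric matrices of identical dimension, rows named by
#'   alternatives and columns by present parameters.
#' @param parameters Full ordered declared parameter list; must contain
#'   `colnames(mu)`. Defaults to the present parameters, i.e. no absent
#'   columns.
#' @return A `"znss"`.
#' @export
znss_grid <- function(mu, r, parameters = colnames(mu)) {
  if (!is.matrix(mu) || !is.matrix(r) || !all(dim(mu) == dim(r))) {
    stop("'mu' and 'r' must be matrices of identical dimension", call. = FALSE)
  }
  if (is.null(parameters)) parameters <- character()
  if (!is.null(colnames(mu)) && !is.null(colnames(r)) &&
      !identical(colnames(mu), colnames(r))) {
    stop("'mu' and 'r' must have identical column names", call. = FALSE)
  }
  new_znss(mu, r, as.character(parameters))
}

new_znss <- function(mu, r, parameters) {
  x <- structure(list(universe = rownames(mu) %||% character(),
                      parameters = parameters,
                      mu = mu, r = r),
                 class = "znss")
  validate_znss(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_znss <- function(x) {
  if (anyDuplicated(x$universe) || anyDuplicated(x$parameters)) {
    stop("alternative and parameter labels must be unique", call. = FALSE)
  }
  present <- colnames(x$mu) %||% character()
  if (!all(present %in% x$parameters)) {
    stop("present parameter columns must appear in the declared parameter list",
         call. = FALSE)
  }
  bad <- which(is.na(x$mu) | x$mu < 0 | x$mu > 1 |
               is.na(x$r) | x$r < 0 | x$r > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("cell (%s, %s) = (%g, %g) is outside [0, 1]^2",
                 x$universe[i], present[j], x$mu[i, j], x$r[i, j]),
         call. = FALSE)
  }
  x
}

#' @export
print.znss <- function(x, ...) {
  pres <- present_parameters(x)
  absent <- setdiff(x$parameters, pres)
  cat(sprintf("Z-number soft set: %d alternatives x %d parameters",
              length(x$universe), length(x$parameters)))
  if (length(absent)) cat(sprintf(" (%d absent)", length(absent)))
  cat("\n")
  if (length(x$universe) && length(pres)) {
    cells <- matrix(sprintf("(%g, %g)", x$mu, x$r),
                    nrow = nrow(x$mu),
                    dimnames = dimnames(x$mu))
    print(as.data.frame(cells, check.names = FALSE))
  }
  if (length(absent)) cat("absent:", paste(absent, collapse = ", "), "\n")
  invisible(x)
}

#' Present parameters of a Z-number soft set
#'
#' @param x A `"znss"`.
#' @return Character vector of the parameters that carry judgments, in
#'   declared order.
#' @export
present_parameters <- function(x) {
  stopifnot(inherits(x, "znss"))
  colnames(x$mu) %||% character()
}

# reorder y's rows to x's universe order; labels must match as sets
align_universe <- function(y, x) {
  if (!setequal(x$universe, y$universe)) {
    only_x <- setdiff(x$universe, y$universe)
    only_y <- setdiff(y$universe, x$universe)
    stop(sprintf("universes differ: only in first {%s}; only in second {%s}",
                 paste(only_x, collapse = ", "),
                 paste(only_y, collapse = ", ")), call. = FALSE)
  }
  if (identical(x$universe, y$universe)) return(y)
  idx <- match(x$universe, y$universe)
  new_znss(y$mu[idx, , drop = FALSE], y$r[idx, , drop = FALSE], y$parameters)
}

#' Complement of a Z-number soft set
#'
#' Every cell is complemented via [z_complement()] and every parameter label
#' is negated with a `"not "` prefix (a second complement strips the prefix,
#' so the operation is an involution on cell values and labels alike; see
#' [z_complement()] for the re-rounding that makes the value round trip
#' exact).
#'
#' @param x A `"znss"`.
#' @return A `"znss"` over the same universe.
#' @export
znss_complement <- function(x) {
  stopifnot(inherits(x, "znss"))
  negate <- function(p) ifelse(startsWith(p, "not "),
                               substring(p, 5L), paste("not", p))
  mu <- complement_vals(x$mu)
  r <- complement_vals(x$r)
  colnames(mu) <- colnames(r) <- negate(colnames(x$mu) %||% character())
  new_znss(mu, r, negate(x$parameters))
}

# shared parameter bookkeeping for the set-level binary operations
.binary_setup <- function(x, y) {
  stopifnot(inherits(x, "znss"), inherits(y, "znss"))
  y <- align_universe(y, x)
  list(y = y, px = present_parameters(x), py = present_parameters(y))
}

#' Union of two Z-number soft sets
#'
#' The parameter set of the result is the ordered union of the operands'
#' parameters. A parameter present in only one operand keeps that operand's
#' column unchanged; a parameter present in both is combined cellwise with the
#' t-conorm of [z_union()].
#'
#' @param x,y `"znss"` objects over the same universe (labels are matched by
#'   name; `y` is reordered to `x`'s universe order).
#' @param norm `"product"` (probabilistic sum, default) or `"minmax"`.
#' @return A `"znss"`.
#' @export
znss_union <- function(x, y, norm = c("product", "minmax")) {
  norm <- match.arg(norm)
  s <- .binary_setup(x, y)
  y <- s$y
  params <- c(x$parameters, setdiff(y$parameters, x$parameters))
  pres <- params[params %in% c(s$px, s$py)]
  m <- length(x$universe)
  mu <- matrix(NA_real_, m, length(pres), dimnames = list(x$universe, pres))
  r <- mu
  for (p in pres) {
    in_x <- p %in% s$px
    in_y <- p %in% s$py
    if (in_x && in_y) {
      mu[, p] <- conorm_vals(x$mu[, p], y$mu[, p], norm)
      r[, p] <- conorm_vals(x$r[, p], y$r[, p], norm)
    } else if (in_x) {
      mu[, p] <- x$mu[, p]; r[, p] <- x$r[, p]
    } else {
      mu[, p] <- y$mu[, p]; r[, p] <- y$r[, p]
    }
  }
  new_znss(mu, r, params)
}

#' Intersection of two Z-number soft sets
#'
#' The parameter set of the result is the ordered intersection of the present
#' parameters; shared columns are combined cellwise with the t-norm of
#' [z_intersection()].
#'
#' @inheritParams znss_union
#' @return A `"znss"`.
#' @export
znss_intersection <- function(x, y, norm = c("product", "minmax")) {
  norm <- match.arg(norm)
  s <- .binary_setup(x, y)
  y <- s$y
  pres <- s$px[s$px %in% s$py]
  mu <- norm_vals(x$mu[, pres, drop = FALSE], y$mu[, pres, drop = FALSE], norm)
  r <- norm_vals(x$r[, pres, drop = FALSE], y$r[, pres, drop = FALSE], norm)
  dimnames(mu) <- dimnames(r) <- list(x$universe, pres)
  new_znss(mu, r, pres)
}

#' Soft-subset predicate
#'
#' `x` is a Z-number soft subset of `y` when every present parameter of `x` is
#' present in `y` and every shared cell of `x` is componentwise no larger than
#' the corresponding cell of `y` ([z_subset()]).
#'
#' @inheritParams znss_union
#' @return `TRUE` or `FALSE`.
#' @export
znss_subset <- function(x, y) {
  s <- .binary_setup(x, y)
  y <- s$y
  if (!all(s$px %in% s$py)) return(FALSE)
  p <- s$px
  all(x$mu[, p, drop = FALSE] <= y$mu[, p, drop = FALSE]) &&
    all(x$r[, p, drop = FALSE] <= y$r[, p, drop = FALSE])
}

#' Soft-set equality
#'
#' Two Z-number soft sets are equal when each is a soft subset of the other:
#' identical present-parameter sets and identical cell values (exact
#' floating-point comparison; this is a definition-level identity, not a
#' numerical tolerance test).
#'
#' @inheritParams znss_union
#' @return `TRUE` or `FALSE`.
#' @export
znss_equal <- function(x, y) {
  znss_subset(x, y) && znss_subset(y, x)
}

#' Null and absolute Z-number soft sets
#'
#' The null set holds the judgment `(0, 1)` in every cell (certainly absent);
#' the absolute set holds `(1, 1)` (certainly present).
#'
#' @param universe,parameters Label vectors as in [znss()].
#' @return A `"znss"` with every parameter present.
#' @export
null_znss <- function(universe, parameters) {
  .constant_znss(universe, parameters, 0, 1)
}

#' @rdname null_znss
#' @export
absolute_znss <- function(universe, parameters) {
  .constant_znss(universe, parameters, 1, 1)
}

.constant_znss <- function(universe, parameters, mu, r) {
  universe <- as.character(universe)
  parameters <- as.character(parameters)
  m <- length(universe); n <- length(parameters)
  dn <- list(universe, parameters)
  new_znss(matrix(mu, m, n, dimnames = dn),
           matrix(r, m, n, dimnames = dn),
           parameters)
}

#' Matrix form of a Z-number soft set
#'
#' `as_znss_matrix()` exposes the grid view (rows = alternatives, columns =
#' present parameters); absent parameters are dropped from the grid but kept
#' in metadata, so `as_znss()` round-trips losslessly.
#'
#' @param x A `"znss"`.
#' @return An object of class `"znss_matrix"` with fields `mu`, `r` (numeric
#'   matrices), `rows`, `cols`, `absent` and the full declared `parameters`.
#' @export
as_znss_matrix <- function(x) {
  stopifnot(inherits(x, "znss"))
  pres <- present_parameters(x)
  structure(list(mu = x$mu, r = x$r,
                 rows = x$universe, cols = pres,
                 absent = setdiff(x$parameters, pres),
                 parameters = x$parameters),
            class = "znss_matrix")
}

#' @rdname as_znss_matrix
#' @param m A `"znss_matrix"`.
#' @export
as_znss <- function(m) {
  stopifnot(inherits(m, "znss_matrix"))
  if (!all(dim(m$mu) == c(length(m$rows), length(m$cols)))) {
    stop(sprintf("grid is %d x %d but labels give %d x %d",
                 nrow(m$mu), ncol(m$mu), length(m$rows), length(m$cols)),
         call. = FALSE)
  }
  mu <- m$mu; r <- m$r
  dimnames(mu) <- dimnames(r) <- list(m$rows, m$cols)
  params <- m$parameters %||% c(m$cols, setdiff(m$absent, m$cols))
  new_znss(mu, r, params)
}

#' @export
print.znss_matrix <- function(x, ...) {
  cat(sprintf("Z-number soft matrix %d x %d\n", length(x$rows), length(x$cols)))
  if (length(x$rows) && length(x$cols)) {
    cells <- matrix(sprintf("(%g, %g)", x$mu, x$r), nrow = nrow(x$mu),
                    dimnames = list(x$rows, x$cols))
    print(as.data.frame(cells, check.names = FALSE))
  }
  invisible(x)
}
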