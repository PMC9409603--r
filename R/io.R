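#' Read a Z-number soft set from a file
#'
#' Two interchange formats are supported. The delimited table format has a
#' header row `alternative,<param>,<param>,...` and one row per alternative;
#' each cell is `mu:r` (the parenthesised style `(mu, r)` used in printed
#' tables is also accepted on input). Absent parameters are simply omitted
#' from the header. The JSON format is an object with `universe`,
#' `parameters` and `cells` (parameter -> alternative -> `[mu, r]`); absent
#' parameters appear in `parameters` but not in `cells`, so JSON round-trips
#' the declared parameter list exactly.
#'
#' @param path File path.
#' @param format `"auto"` (by extension, default), `"csv"` or `"json"`.
#' @return A validated `"znss"`.
#' @export
read_znss <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "json") .read_znss_json(path) else .read_znss_csv(path)
}

.parse_cell <- function(text, alt, param) {
  s <- trimws(text)
  if (grepl("^\\(.*\\)$", s)) {
    parts <- strsplit(sub("^\\((.*)\\)$", "\\1", s), ",", fixed = TRUE)[[1L]]
  } else {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  }
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) != 2L || anyNA(vals)) {
    stop(sprintf("cell (%s, %s): cannot parse '%s' as 'mu:r'", alt, param, text),
         call. = FALSE)
  }
  if (any(vals < 0 | vals > 1)) {
    stop(sprintf("cell (%s, %s) = (%g, %g) is outside [0, 1]^2",
                 alt, param, vals[1L], vals[2L]), call. = FALSE)
  }
  vals
}

.read_znss_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 1L || tolower(names(df)[1L]) != "alternative") {
    stop(sprintf("%s: first column of a ZnSS table must be 'alternative'", path),
         call. = FALSE)
  }
  universe <- df[[1L]]
  params <- names(df)[-1L]
  m <- length(universe)
  mu <- matrix(NA_real_, m, length(params), dimnames = list(universe, params))
  r <- mu
  for (j in seq_along(params)) {
    for (i in seq_len(m)) {
      vals <- .parse_cell(df[i, j + 1L], universe[i], params[j])
      mu[i, j] <- vals[1L]
      r[i, j] <- vals[2L]
    }
  }
  tryCatch(znss_grid(mu, r),
           error = function(e) {
             stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
           })
}

.read_znss_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("universe", "parameters", "cells")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("%s: missing required field '%s'", path, field),
           call. = FALSE)
    }
  }
  universe <- vapply(obj$universe, as.character, character(1))
  parameters <- vapply(obj$parameters, as.character, character(1))
  cells <- lapply(obj$cells, function(col) {
    lapply(col, function(z) vapply(z, as.numeric, numeric(1)))
  })
  tryCatch(znss(universe, parameters, cells),
           error = function(e) {
             stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
           })
}

#' Write a Z-number soft set to a file
#'
#' Numbers are serialized with up to 6 significant digits; see [read_znss()]
#' for the formats. Note the delimited table format cannot represent declared
#' but absent parameters (they are omitted from the header); use JSON to
#' preserve the full declared parameter list.
#'
#' @param x A `"znss"`.
#' @inheritParams read_znss
#' @return The path, invisibly.
#' @export
write_znss <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "znss"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    pres <- present_parameters(x)
    cells <- lapply(pres, function(p) {
      col <- lapply(seq_along(x$universe),
                    function(i) c(x$mu[i, p], x$r[i, p]))
      names(col) <- x$universe
      col
    })
    names(cells) <- pres
    jsonlite::write_json(list(universe = x$universe,
                              parameters = x$parameters,
                              cells = cells),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    pres <- present_parameters(x)
    cells <- matrix(paste0(sprintf("%.6g", x$mu), ":", sprintf("%.6g", x$r)),
                    nrow = nrow(x$mu))
    df <- data.frame(alternative = x$universe, stringsAsFactors = FALSE)
    for (j in seq_along(pres)) df[[pres[j]]] <- cells[, j]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
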