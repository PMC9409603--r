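#' Fuse multi-observer reports into one Z-number soft set
#'
#' Folds the soft-set union over a list of observer reports, left to right.
#' With every parameter shared, the cellwise t-conorm makes the result
#' independent of both grouping and observer order; with partially observed
#' parameter sets the fold is still associative.
#'
#' @param reports Non-empty list of `"znss"` objects over a shared universe
#'   (optionally named by observer).
#' @param norm `"product"` (default) or `"minmax"`, passed to [znss_union()].
#' @return A `"znss"`: the fused judgment over all observed parameters.
#' @examples
#' fused <- fuse_observers(list(paper_fixture("observer1_t7"),
#'                              paper_fixture("observer2_t8"),
#'                              paper_fixture("observer3_t9")))
#' fused$mu["y", "e1"] # 0.96
#' @export
fuse_observers <- function(reports, norm = c("product", "minmax")) {
  norm <- match.arg(norm)
  if (!is.list(reports) || length(reports) == 0L) {
    stop("need at least one observer report", call. = FALSE)
  }
  for (k in seq_along(reports)) {
    if (!inherits(reports[[k]], "znss")) {
      stop(sprintf("report %d is not a Z-number soft set", k), call. = FALSE)
    }
  }
  Reduce(function(a, b) znss_union(a, b, norm = norm), reports)
}

#' Rank disease models against fused observer reports
#'
#' The multi-observer diagnostic workflow: fuse all observer reports by soft
#' union, score the fused set against each disease model with
#' [znss_similarity()], and rank the models by score, descending. Tied scores
#' keep their input order and are flagged.
#'
#' @inheritParams fuse_observers
#' @param models Non-empty named list of `"znss"` disease models; each model
#'   must present the same parameters as the fused report.
#' @param aggregate Similarity aggregation, `"max"` (default) or `"mean"`.
#' @param min_score Optional refusal threshold in `[0, 1]`: when the best
#'   score falls below it, no disease is recommended. Default `NULL` (always
#'   recommend the top-ranked model).
#' @param fused Optional `"znss"` overriding the fusion step, so a published
#'   fused table can be scored directly; `reports` may then be `NULL`.
#' @return An object of class `"znss_diagnosis"`: a list with `fused`,
#'   `ranking` (data frame of disease, score, tied flag), `breakdown` (the
#'   full `"znss_similarity"` report per disease), `ties` (labels involved in
#'   a score tie) and `recommended` (disease label, or `NA` under the
#'   threshold).
#' @export
diagnose <- function(reports, models, norm = c("product", "minmax"),
                     aggregate = c("max", "mean"),
                     min_score = NULL, fused = NULL) {
  norm <- match.arg(norm)
  aggregate <- match.arg(aggregate)
  if (!is.list(models) || length(models) == 0L) {
    stop("need at least one disease model", call. = FALSE)
  }
  labels <- names(models)
  if (is.null(labels) || any(labels == "")) {
    stop("'models' must be a named list (names are the disease labels)",
         call. = FALSE)
  }
  if (is.null(fused)) {
    fused <- fuse_observers(reports, norm = norm)
  } else {
    stopifnot(inherits(fused, "znss"))
  }
  breakdown <- vector("list", length(models))
  names(breakdown) <- labels
  for (d in labels) {
    breakdown[[d]] <- tryCatch(
      znss_similarity(fused, models[[d]], aggregate = aggregate),
      error = function(e) {
        stop(sprintf("model '%s': %s", d, conditionMessage(e)), call. = FALSE)
      })
  }
  scores <- vapply(breakdown, function(b) b$score, numeric(1))
  ord <- order(-scores) # stable: ties keep input order
  ranking <- data.frame(disease = labels[ord],
                        score = unname(scores[ord]),
                        stringsAsFactors = FALSE)
  ranking$tied <- ranking$score %in% ranking$score[duplicated(ranking$score)]
  ties <- ranking$disease[ranking$tied]
  recommended <- ranking$disease[1L]
  if (!is.null(min_score) && ranking$score[1L] < min_score) {
    recommended <- NA_character_
  }
  structure(list(fused = fused, ranking = ranking, breakdown = breakdown,
                 ties = ties, norm = norm, aggregate = aggregate,
                 min_score = min_score, recommended = recommended),
            class = "znss_diagnosis")
}

#' @export
print.znss_diagnosis <- function(x, digits = 3, ...) {
  cat(sprintf("Z-number soft set diagnosis (norm = %s, aggregate = %s)\n",
              x$norm, x$aggregate))
  df <- x$ranking
  df$score <- round(df$score, digits)
  print(df, row.names = FALSE)
  if (length(x$ties)) {
    cat("tied:", paste(x$ties, collapse = ", "), "\n")
  }
  if (is.na(x$recommended)) {
    cat(sprintf("no recommendation: best score below threshold %g\n",
                x$min_score))
  } else {
    cat("recommended:", x$recommended, "\n")
  }
  invisible(x)
}
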