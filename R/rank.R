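# Benefit/cost decision matrix and the weighted performance index used to
# rank algorithms.

#' Decision matrix for algorithm ranking
#'
#' @param values numeric matrix, algorithms in rows, measures in columns
#'   (dimnames required).
#' @param kind character vector per column, "benefit" (larger is better) or
#'   "cost" (smaller is better).
#' @param weight numeric weights per column, in [0, 1]; normalized to sum
#'   to 1.
#' @return object of class `decision_matrix`.
#' @export
decision_matrix <- function(values, kind, weight = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_data("decision matrix needs algorithm and measure names")
  if (length(kind) != ncol(values))
    stop_data("one kind per measure required")
  kind <- match.arg(kind, c("benefit", "cost"), several.ok = TRUE)
  if (is.null(weight)) weight <- rep(1, ncol(values))
  if (any(weight < 0)) stop_data("weights must be non-negative")
  weight <- weight / sum(weight)
  structure(list(values = values, kind = kind, weight = weight),
            class = "decision_matrix")
}

#' Weighted benefit/cost performance index
#'
#' Cost measures are inverted to benefits by min-max normalization across
#' algorithms (`(max - x) / (max - min)`; a constant column maps to 1).
#' Benefit measures enter as-is. The index per algorithm is the weighted
#' mean of the normalized values over non-missing measures (0 = worst,
#' 1 = best when benefits live in [0, 1]). Algorithms with no usable
#' measure are excluded with a warning. The ranking is by descending index,
#' ties broken alphabetically.
#'
#' @param m a [decision_matrix()].
#' @return list with `index` (named numeric) and `ranking` (character).
#' @export
performance_index <- function(m) {
  v <- m$values
  norm <- v
  for (j in seq_len(ncol(v))) {
    if (m$kind[j] == "cost") {
      col <- v[, j]
      rng <- range(col, na.rm = TRUE)
      norm[, j] <- if (diff(rng) == 0) ifelse(is.na(col), NA, 1)
                   else (rng[2] - col) / (rng[2] - rng[1])
    }
  }
  idx <- vapply(seq_len(nrow(norm)), function(i) {
    ok <- !is.na(norm[i, ])
    if (!any(ok)) return(NA_real_)
    sum(m$weight[ok] * norm[i, ok]) / sum(m$weight[ok])
  }, 1)
  names(idx) <- rownames(v)
  if (anyNA(idx)) {
    gd_warn("gaitdmo_algorithm_excluded",
            sprintf("algorithm(s) with no usable measure excluded: %s",
                    paste(names(idx)[is.na(idx)], collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  ranking <- names(idx)[order(-idx, names(idx))]
  list(index = idx, ranking = ranking)
}
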