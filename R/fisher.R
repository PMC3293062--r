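#' Fisher coefficient of a single feature
#'
#' The ratio of between-class to within-class variance of one descriptor.
#' With group proportions `p_k = n_k / N`, group means `mu_k`, population
#' group variances `sigma_k^2` and grand mean `mu`:
#' `F = sum_k p_k (mu_k - mu)^2 / sum_k p_k sigma_k^2`.
#' The group-size weighting matches the classical Fisher discriminant and
#' handles unequal group sizes. A zero denominator with a positive
#' numerator gives `Inf` (a perfectly separating feature); `0/0` gives 0.
#'
#' @param table a feature table with at least two groups of at least two
#'   samples each.
#' @param feature name of the descriptor column.
#' @return a single nonnegative number (possibly `Inf`).
#' @export
fisher_coefficient <- function(table, feature) {
  assert_feature_table(table)
  if (!feature %in% feature_names(table)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  x <- table[[feature]]
  g <- as.character(table$group)
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least two samples (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")", call. = FALSE)
  }
  n <- length(x)
  mu <- mean(x)
  between <- 0; within <- 0
  for (grp in names(sizes)) {
    xi <- x[g == grp]
    pk <- length(xi) / n
    between <- between + pk * (mean(xi) - mu)^2
    within <- within + pk * mean((xi - mean(xi))^2)
  }
  if (within > 0) between / within else if (between > 0) Inf else 0
}

#' Rank all features of a table by Fisher coefficient
#'
#' @param table a feature table.
#' @return `data.frame` with columns `feature`, `f_value`, `rank`
#'   (1 = highest F; ties broken by ascending feature name; `Inf` sorts
#'   above every finite value).
#' @export
fisher_rank <- function(table) {
  feats <- feature_names(table)
  fv <- vapply(feats, function(f) fisher_coefficient(table, f), numeric(1))
  ord <- order(-fv, feats)
  data.frame(feature = feats[ord], f_value = unname(fv[ord]),
             rank = seq_along(feats), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Retain the k features of highest Fisher coefficient
#'
#' @param table a feature table.
#' @param k number of features to keep (default 10).
#' @return list with elements `table` (the input restricted to the selected
#'   features, in rank order) and `ranking` (as [fisher_rank()], plus a
#'   logical `selected` column).
#' @export
select_top_k <- function(table, k = 10L) {
  assert_feature_table(table)
  feats <- feature_names(table)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  if (k > length(feats)) {
    stop("'k' (", k, ") exceeds the number of features (", length(feats), ")",
         call. = FALSE)
  }
  ranking <- fisher_rank(table)
  ranking$selected <- ranking$rank <= k
  keep <- ranking$feature[ranking$selected]
  list(table = table[, c(.meta_cols, keep), drop = FALSE],
       ranking = ranking)
}

#' Write a Fisher ranking to CSV
#'
#' @param ranking the `ranking` element of [select_top_k()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}
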