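.meta_cols <- c("sample_id", "group")

#' Names of the descriptor columns of a feature table
#'
#' A feature table is a plain `data.frame` whose first columns are
#' `sample_id` and `group`; every remaining column is a numeric descriptor.
#'
#' @param table a feature table.
#' @return character vector of descriptor column names.
#' @export
feature_names <- function(table) {
  stopifnot(is.data.frame(table))
  setdiff(names(table), .meta_cols)
}

feature_matrix <- function(table) {
  m <- as.matrix(table[, feature_names(table), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

assert_feature_table <- function(table) {
  if (!is.data.frame(table) || !all(.meta_cols %in% names(table))) {
    stop("expected a feature table with 'sample_id' and 'group' columns",
         call. = FALSE)
  }
  invisible(table)
}

#' Read and write feature tables as CSV
#'
#' The on-disk dialect is a plain CSV with a mandatory header; the first two
#' columns are `sample_id` and `group`, all further columns are numeric
#' descriptors.
#'
#' @param table a feature table.
#' @param path file path.
#' @return `read_feature_table` returns the feature table;
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  assert_feature_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_feature_table(tab)
  tab
}

# -x*log2(x) with the 0*log(0) = 0 convention
xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}
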