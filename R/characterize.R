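#' Group-by-cluster distribution table
#'
#' Tabulates, for every group, the percentage of its samples falling in
#' each cluster, and canonicalizes the cluster order against two reference
#' groups: cluster 1 becomes the majority cluster of `reference_groups[1]`
#' and cluster 2 the majority cluster of `reference_groups[2]`. Raw cluster
#' indices from competitive learning are arbitrary (label symmetry), so this
#' relabeling is what makes distribution tables comparable across runs and
#' seeds. If both reference groups share a majority cluster the raw order is
#' kept and `degenerate` is set.
#'
#' @param assignment an `nnc_assignment` (carries `group` per sample).
#' @param reference_groups character vector of two group labels expected to
#'   dominate opposite clusters.
#' @return an object of class `cluster_distribution` with fields
#'   `percentages` and `counts` (groups x clusters, reference groups first),
#'   `cluster_order` (canonical -> raw index map), `degenerate`,
#'   `reference_groups`, `n_clusters`.
#' @export
cluster_distribution <- function(assignment, reference_groups) {
  stopifnot(inherits(assignment, "nnc_assignment"))
  if (length(reference_groups) != 2L) {
    stop("'reference_groups' must name exactly two groups", call. = FALSE)
  }
  g <- assignment$group
  missing <- setdiff(reference_groups, g)
  if (length(missing) > 0L) {
    stop("reference group(s) absent from the assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  k <- max(assignment$cluster)
  group_order <- c(reference_groups, setdiff(unique(g), reference_groups))
  counts <- table(factor(g, levels = group_order),
                  factor(assignment$cluster, levels = seq_len(k)))
  counts <- unclass(counts)

  maj1 <- which.max(counts[reference_groups[1], ])
  maj2 <- which.max(counts[reference_groups[2], ])
  if (maj1 != maj2) {
    cluster_order <- c(maj1, maj2, setdiff(seq_len(k), c(maj1, maj2)))
    degenerate <- FALSE
  } else {
    cluster_order <- seq_len(k)
    degenerate <- TRUE
  }
  counts <- counts[, cluster_order, drop = FALSE]
  colnames(counts) <- sprintf("cluster_%d", seq_len(k))
  pct <- 100 * counts / rowSums(counts)

  structure(list(percentages = pct, counts = counts,
                 cluster_order = cluster_order, degenerate = degenerate,
                 reference_groups = as.character(reference_groups),
                 n_clusters = as.integer(k)),
            class = "cluster_distribution")
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat("Sample distribution among clusters (%):\n")
  print(round(x$percentages, 1))
  if (x$degenerate) {
    cat("note: reference groups share a majority cluster;",
        "raw cluster order kept\n")
  }
  invisible(x)
}

#' Weighted-average descriptor profile of the clusters
#'
#' For every cluster `c` and descriptor `d`, the relative deviation of the
#' cluster mean from the overall mean:
#' `wa = (mu_d - mu_a) / mu_a`, where `mu_d` is the descriptor's mean over
#' the samples of the cluster and `mu_a` its mean over all samples. Taking
#' `mu_a` over all samples (rather than the mean of cluster means) makes the
#' mass balance `sum_c n_c * wa_c = 0` exact for unequal cluster sizes.
#' Descriptors with `mu_a = 0` are flagged undefined (`NA`) and excluded
#' from plots.
#'
#' @param table the feature table the clustering was run on.
#' @param assignment the matching `nnc_assignment`.
#' @param cluster_order optional canonical -> raw cluster index map (the
#'   `cluster_order` of a [cluster_distribution()]); rows of the profile are
#'   reported in this order.
#' @return an object of class `weighted_average_profile` with fields `wa`
#'   (clusters x descriptors), `n_c` (cluster sizes), `mu_a`, `undefined`
#'   (descriptor names with `mu_a = 0`).
#' @export
weighted_average_profile <- function(table, assignment, cluster_order = NULL) {
  assert_feature_table(table)
  stopifnot(inherits(assignment, "nnc_assignment"),
            nrow(table) == nrow(assignment))
  x <- feature_matrix(table)
  k <- max(assignment$cluster)
  if (is.null(cluster_order)) cluster_order <- seq_len(k)
  sizes <- tabulate(assignment$cluster, nbins = k)
  if (any(sizes == 0L)) {
    stop("empty cluster(s): ", paste(which(sizes == 0L), collapse = ", "),
         call. = FALSE)
  }
  mu_a <- colMeans(x)
  wa <- matrix(NA_real_, nrow = k, ncol = ncol(x),
               dimnames = list(sprintf("cluster_%d", seq_len(k)),
                               colnames(x)))
  undefined <- colnames(x)[mu_a == 0]
  ok <- mu_a != 0
  for (c in seq_len(k)) {
    raw <- cluster_order[c]
    mu_d <- colMeans(x[assignment$cluster == raw, , drop = FALSE])
    wa[c, ok] <- (mu_d[ok] - mu_a[ok]) / mu_a[ok]
  }
  structure(list(wa = wa, n_c = sizes[cluster_order], mu_a = mu_a,
                 undefined = undefined, cluster_order = cluster_order),
            class = "weighted_average_profile")
}

#' @export
print.weighted_average_profile <- function(x, ...) {
  cat("Weighted-average profile (mu_d - mu_a) / mu_a:\n")
  print(round(x$wa, 3))
  if (length(x$undefined) > 0L) {
    cat("undefined (mu_a = 0):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a cluster report to disk
#'
#' Writes the group-by-cluster percentage table as CSV, the weighted-average
#' profile as CSV, the full report (including the degeneracy flag) as JSON,
#' and one bar-chart PNG of the weighted averages per cluster. File content
#' is deterministic given the inputs.
#'
#' @param dist a [cluster_distribution()].
#' @param profile a [weighted_average_profile()].
#' @param path output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
export_report <- function(dist, profile, path) {
  stopifnot(inherits(dist, "cluster_distribution"),
            inherits(profile, "weighted_average_profile"))
  ok <- tryCatch({
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    file.access(path, mode = 2L) == 0L
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write report to: ", path, call. = FALSE)

  dist_csv <- file.path(path, "cluster_distribution.csv")
  dtab <- data.frame(group = rownames(dist$percentages),
                     round(dist$percentages, 6), check.names = FALSE,
                     row.names = NULL)
  write.csv(dtab, dist_csv, row.names = FALSE)

  prof_csv <- file.path(path, "weighted_average_profile.csv")
  ptab <- data.frame(cluster = rownames(profile$wa), profile$wa,
                     check.names = FALSE, row.names = NULL)
  write.csv(ptab, prof_csv, row.names = FALSE)

  report_json <- file.path(path, "report.json")
  jsonlite::write_json(list(distribution_pct = dist$percentages,
                            counts = dist$counts,
                            reference_groups = dist$reference_groups,
                            degenerate = dist$degenerate,
                            weighted_average = profile$wa,
                            cluster_sizes = profile$n_c,
                            undefined_descriptors = profile$undefined),
                       report_json, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")

  pngs <- character(0)
  for (c in seq_len(nrow(profile$wa))) {
    f <- file.path(path, sprintf("weighted_average_cluster_%d.png", c))
    grDevices::png(f, width = 900, height = 480)
    wa <- profile$wa[c, ]
    wa_plot <- wa[!is.na(wa)]
    par(mar = c(9, 4, 3, 1))
    barplot(wa_plot, las = 2, cex.names = 0.7,
            main = sprintf("Weighted averages, cluster %d (n = %d)",
                           c, profile$n_c[c]),
            ylab = "(mu_d - mu_a) / mu_a")
    abline(h = 0)
    dev.off()
    pngs <- c(pngs, f)
  }
  invisible(c(distribution = dist_csv, profile = prof_csv,
              report = report_json, pngs))
}
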