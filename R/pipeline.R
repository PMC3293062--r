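#' Run one clustering attempt against two reference groups
#'
#' The full analysis for one test group: restrict the feature table to the
#' two reference groups plus the optional test group, optionally keep only
#' the `top_k` features of highest Fisher coefficient (the texture route;
#' the indicator route uses all descriptors), train the two-cluster
#' competitive network, canonicalize clusters by the reference-group
#' majorities, and compute the distribution table and weighted-average
#' profile.
#'
#' @param table a feature table.
#' @param reference_groups two group labels expected to dominate opposite
#'   clusters.
#' @param test_group optional further group clustered jointly with the
#'   references.
#' @param top_k if non-`NULL`, number of Fisher-selected features to keep.
#' @param n_clusters,seed,epochs,lr passed to [train_nnc()].
#' @return an object of class `nnc_report`: list with `model`,
#'   `assignment`, `distribution`, `profile`, `ranking` (or `NULL`),
#'   `config`.
#' @export
run_nnc_analysis <- function(table, reference_groups, test_group = NULL,
                             top_k = NULL, n_clusters = 2L, seed = 42L,
                             epochs = 100L, lr = 0.5) {
  assert_feature_table(table)
  wanted <- c(reference_groups, test_group)
  available <- unique(as.character(table$group))
  unknown <- setdiff(wanted, available)
  if (length(unknown) > 0L) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "), call. = FALSE)
  }
  sub <- table[table$group %in% wanted, , drop = FALSE]
  rownames(sub) <- NULL
  ranking <- NULL
  if (!is.null(top_k)) {
    sel <- select_top_k(sub, k = top_k)
    sub <- sel$table
    ranking <- sel$ranking
  }
  fit <- train_nnc(sub, n_clusters = n_clusters, seed = seed,
                   epochs = epochs, lr = lr)
  dist <- cluster_distribution(fit$assignment, reference_groups)
  profile <- weighted_average_profile(sub, fit$assignment,
                                      cluster_order = dist$cluster_order)
  structure(list(model = fit$model, assignment = fit$assignment,
                 distribution = dist, profile = profile, ranking = ranking,
                 config = list(reference_groups = reference_groups,
                               test_group = test_group, top_k = top_k,
                               n_clusters = n_clusters, seed = seed,
                               epochs = epochs, lr = lr)),
            class = "nnc_report")
}

#' @export
print.nnc_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<nnc_report: references %s vs %s%s%s>\n",
              cfg$reference_groups[1], cfg$reference_groups[2],
              if (is.null(cfg$test_group)) "" else
                paste0(", test group ", cfg$test_group),
              if (is.null(cfg$top_k)) "" else
                paste0(", top-", cfg$top_k, " features")))
  print(x$distribution)
  invisible(x)
}

#' Run the three-attempt comparison design
#'
#' Repeats [run_nnc_analysis()] once per test group, each attempt
#' clustering that group jointly with the two reference groups — the design
#' in which each treated group is placed between an intact and a damaged
#' reference.
#'
#' @inheritParams run_nnc_analysis
#' @param test_groups character vector of test groups (one attempt each).
#' @return named list of `nnc_report`, one per test group.
#' @export
run_group_comparisons <- function(table, reference_groups = c("N", "CIS"),
                                  test_groups = c("CIS+H", "CIS+M", "CIS+L"),
                                  top_k = NULL, n_clusters = 2L, seed = 42L,
                                  epochs = 100L, lr = 0.5) {
  reports <- lapply(test_groups, function(tg) {
    run_nnc_analysis(table, reference_groups, test_group = tg,
                     top_k = top_k, n_clusters = n_clusters, seed = seed,
                     epochs = epochs, lr = lr)
  })
  names(reports) <- test_groups
  reports
}

#' Write an `nnc_report` to a directory
#'
#' Exports the distribution CSV, profile CSV, per-cluster bar charts and a
#' deterministic `report.json`; the serialized model and, if present, the
#' Fisher ranking are written alongside.
#'
#' @param report an `nnc_report`.
#' @param path output directory.
#' @return named character vector of files written, invisibly.
#' @export
write_nnc_report <- function(report, path) {
  stopifnot(inherits(report, "nnc_report"))
  files <- export_report(report$distribution, report$profile, path)
  model_file <- file.path(path, "model.json")
  write_nnc_model(report$model, model_file)
  files <- c(files, model = model_file)
  if (!is.null(report$ranking)) {
    rank_file <- file.path(path, "fisher_ranking.csv")
    write_ranking(report$ranking, rank_file)
    files <- c(files, ranking = rank_file)
  }
  invisible(files)
}

#' Extract features from every image file in a directory
#'
#' Reads each PNG/BMP in `dir` (non-recursively, sorted by name), converts
#' to luminance and runs [extract_features()]. The group label is taken
#' from the leading part of the file name (up to the last underscore), as
#' written by [simulate_dataset()].
#'
#' @param dir directory of `.png` / `.bmp` images.
#' @param ... passed to [extract_features()].
#' @return a feature table, one row per image.
#' @export
extract_feature_dir <- function(dir, ...) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.(png|bmp)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no PNG or BMP images in: ", dir,
                                call. = FALSE)
  images <- lapply(files, function(f) to_gray(read_image(f)))
  ids <- sub("\\.[^.]+$", "", basename(files))
  meta <- data.frame(sample_id = ids,
                     group = sub("_[^_]*$", "", ids),
                     stringsAsFactors = FALSE)
  extract_features(images, metadata = meta, ...)
}

#' Simulate a dataset onto disk
#'
#' `kind = "images"` writes one PNG per synthetic micrograph
#' (`<group>_<i>.png`); `kind = "table"` writes a per-animal indicator CSV.
#' A `manifest.json` recording the parameters and seed is written
#' alongside, so any dataset can be regenerated exactly.
#'
#' @param kind `"images"` or `"table"`.
#' @param out_dir output directory (created if absent).
#' @param seed integer RNG seed.
#' @param ... passed on to [make_image_dataset()] or [make_animal_table()].
#' @return path of the manifest file, invisibly.
#' @export
simulate_dataset <- function(kind = c("images", "table"), out_dir,
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "images") {
    ds <- make_image_dataset(seed = seed, ...)
    for (i in seq_len(nrow(ds$metadata))) {
      write_image(ds$images[[i]],
                  file.path(out_dir,
                            paste0(ds$metadata$sample_id[i], ".png")))
    }
    manifest <- list(kind = "images", seed = seed,
                     n_images = nrow(ds$metadata),
                     groups = unique(ds$metadata$group),
                     deltas = ds$metadata$delta[!duplicated(ds$metadata$group)],
                     size = dim(ds$images[[1]]$pixels))
  } else {
    tab <- make_animal_table(seed = seed, ...)
    write_feature_table(tab, file.path(out_dir, "animal_table.csv"))
    manifest <- list(kind = "table", seed = seed, n_rows = nrow(tab),
                     groups = unique(tab$group))
  }
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest_file)
}
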