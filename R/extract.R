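com_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("'angles' must be drawn from 0, 45, 90, 135", call. = FALSE))
}

#' Extract a texture feature table from a batch of gray images
#'
#' Runs the full texture stage on each image: the image is quantized (by
#' default to 64 gray levels over its min-max range) for the co-occurrence
#' and run-length statistics, while gradient features are computed on the
#' unquantized input. Co-occurrence features are computed at each distance
#' in `distances` and averaged over the four angles (rotation-robust
#' aggregation); run-length features are averaged over the four directions.
#'
#' With the defaults this yields `11 * 5 + 5 + 5 = 65` named descriptors per
#' image: `com_d<d>_<stat>`, `rlm_<stat>` and `grm_<stat>`.
#'
#' @param images list of [gray_image()] (256-level, e.g. from [to_gray()]).
#' @param metadata optional `data.frame` with columns `sample_id` and
#'   `group`, one row per image; defaults to `img_<i>` / `"all"`.
#' @param levels,normalize quantization applied before the co-occurrence and
#'   run-length stages; see [quantize()].
#' @param distances integer co-occurrence displacement distances.
#' @param angles angles (degrees) averaged over for the co-occurrence and
#'   run-length stages.
#' @return a feature table: `data.frame` with `sample_id`, `group` and one
#'   numeric column per descriptor.
#' @export
extract_features <- function(images, metadata = NULL, levels = 64L,
                             normalize = "minmax", distances = 1:5,
                             angles = c(0, 45, 90, 135)) {
  if (!is.list(images) || length(images) == 0L) {
    stop("'images' must be a non-empty list of gray images", call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = sprintf("img_%d", seq_along(images)),
                           group = "all", stringsAsFactors = FALSE)
  }
  if (!all(.meta_cols %in% names(metadata)) ||
      nrow(metadata) != length(images)) {
    stop("'metadata' needs sample_id and group columns, one row per image",
         call. = FALSE)
  }
  rows <- lapply(images, function(img) {
    q <- quantize(img, levels = levels, mode = normalize)
    com <- unlist(lapply(distances, function(d) {
      f <- rowMeans(vapply(angles,
                           function(a) com_features(compute_com(q, com_offset(a, d))),
                           numeric(11L)))
      names(f) <- sprintf("com_d%d_%s", d, names(f))
      f
    }))
    rlm <- rowMeans(vapply(angles,
                           function(a) rlm_features(compute_rlm(q, a)),
                           numeric(5L)))
    names(rlm) <- sprintf("rlm_%s", names(rlm))
    grm <- grm_features(compute_grm(img))
    names(grm) <- sprintf("grm_%s", names(grm))
    c(com, rlm, grm)
  })
  feats <- do.call(rbind, rows)
  out <- data.frame(sample_id = as.character(metadata$sample_id),
                    group = as.character(metadata$group),
                    feats, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
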