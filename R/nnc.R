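# Reference threshold neuron --------------------------------------------------

#' Binary threshold neuron
#'
#' The elementary McCulloch-Pitts-style unit: output 1 if the net input
#' `w . x` strictly exceeds the threshold, else 0 (equality falls to 0).
#' Kept as a separately tested reference model of the "neuron" underlying
#' network clustering; binary threshold units cannot themselves implement
#' distance-based clustering.
#'
#' @param weights numeric weight vector `w`.
#' @param threshold scalar threshold.
#' @return an object of class `threshold_neuron`.
#' @export
threshold_neuron <- function(weights, threshold = 0) {
  stopifnot(is.numeric(weights), length(weights) >= 1L,
            is.numeric(threshold), length(threshold) == 1L)
  structure(list(weights = as.numeric(weights),
                 threshold = as.numeric(threshold)),
            class = "threshold_neuron")
}

#' @rdname threshold_neuron
#' @param neuron a `threshold_neuron`.
#' @param x input vector of the same dimension as `weights`.
#' @export
neuron_output <- function(neuron, x) {
  stopifnot(inherits(neuron, "threshold_neuron"))
  if (length(x) != length(neuron$weights)) {
    stop("input dimension (", length(x), ") does not match weight dimension (",
         length(neuron$weights), ")", call. = FALSE)
  }
  as.integer(sum(neuron$weights * x) > neuron$threshold)
}

# Competitive-learning clustering ---------------------------------------------

#' Train a winner-take-all neural-network clustering model
#'
#' Unsupervised clustering by seeded winner-take-all competitive learning (a
#' one-dimensional Kohonen network without a neighborhood function).
#' Features are standardized to zero mean / unit SD (descriptor panels span
#' orders of magnitude, so raw Euclidean distance would be dominated by the
#' largest-scaled descriptor). Units are initialized to `n_clusters`
#' distinct randomly chosen samples; in every epoch the samples are visited
#' in seeded random order and the nearest unit is moved toward each sample
#' by the decaying rate `eta(t) = lr * (1 - t / epochs)`. The final
#' assignment is nearest-unit, ties going to the lowest unit index.
#' Training is bit-reproducible given `(seed, epochs, lr)`; the caller's RNG
#' state is left untouched.
#'
#' @param table a feature table with finite feature values.
#' @param n_clusters number of competitive units (default 2).
#' @param seed integer RNG seed.
#' @param epochs training epochs (default 100).
#' @param lr initial learning rate `eta_0` (default 0.5).
#' @return list with elements `model` (class `nnc_model`: unit weights,
#'   standardization, config) and `assignment` (class `nnc_assignment`: a
#'   `data.frame` with `sample_id`, `group`, `cluster`, `distance`).
#' @export
train_nnc <- function(table, n_clusters = 2L, seed = 42L, epochs = 100L,
                      lr = 0.5) {
  assert_feature_table(table)
  x <- feature_matrix(table)
  n <- nrow(x)
  if (n_clusters < 1L || n_clusters > n) {
    stop("'n_clusters' must lie in [1, n_samples = ", n, "]", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("feature values must all be finite",
                               call. = FALSE)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  dropped <- colnames(x)[sdev == 0]
  if (length(dropped) > 0L) {
    warning("excluding zero-SD feature(s) from clustering distance: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- sdev > 0
  if (!any(keep)) stop("all features have zero SD; nothing to cluster on",
                       call. = FALSE)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdev[keep], "/")

  units <- withr::with_seed(as.integer(seed), {
    init <- sample.int(n, n_clusters)
    u <- z[init, , drop = FALSE]
    for (t in seq_len(epochs)) {
      eta <- lr * (1 - t / epochs)
      if (eta <= 0) next
      for (s in sample.int(n, n)) {
        d2 <- rowSums((u - matrix(z[s, ], n_clusters, ncol(z),
                                  byrow = TRUE))^2)
        win <- which.min(d2)
        u[win, ] <- u[win, ] + eta * (z[s, ] - u[win, ])
      }
    }
    u
  })
  rownames(units) <- NULL

  model <- structure(list(units = units,
                          center = mu[keep], scale = sdev[keep],
                          features = colnames(x)[keep],
                          dropped_features = dropped,
                          n_clusters = as.integer(n_clusters),
                          seed = as.integer(seed),
                          epochs = as.integer(epochs), lr = lr),
                     class = "nnc_model")
  list(model = model, assignment = predict(model, table))
}

#' Assign samples to the clusters of a trained model
#'
#' Nearest-unit assignment using the model's stored standardization; ties
#' (equal distances to several units) go to the lowest unit index. This is
#' how a held-out group is clustered jointly with the reference groups the
#' model was trained on.
#'
#' @param object an `nnc_model`.
#' @param table a feature table containing at least the model's features.
#' @param ... unused.
#' @return an `nnc_assignment`: `data.frame` with `sample_id`, `group`,
#'   `cluster` (1-based unit index) and `distance` to the winning unit.
#' @export
predict.nnc_model <- function(object, table, ...) {
  assert_feature_table(table)
  missing <- setdiff(object$features, names(table))
  if (length(missing) > 0L) {
    stop("feature mismatch: table lacks ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  k <- nrow(object$units)
  d2 <- matrix(0, nrow(z), k)
  for (c in seq_len(k)) {
    d2[, c] <- rowSums(sweep(z, 2L, object$units[c, ])^2)
  }
  cl <- apply(d2, 1L, which.min)          # which.min takes the lowest index
  out <- data.frame(sample_id = as.character(table$sample_id),
                    group = as.character(table$group),
                    cluster = as.integer(cl),
                    distance = sqrt(d2[cbind(seq_len(nrow(z)), cl)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("nnc_assignment", "data.frame")
  out
}

#' @export
print.nnc_model <- function(x, ...) {
  cat(sprintf("<nnc_model: %d clusters, %d features, seed %d, %d epochs, lr %g>\n",
              x$n_clusters, length(x$features), x$seed, x$epochs, x$lr))
  invisible(x)
}

# Serialization ---------------------------------------------------------------

#' Save or load an `nnc_model` as JSON
#'
#' @param model an `nnc_model`.
#' @param path JSON file path.
#' @return `write_nnc_model` returns `path` invisibly; `read_nnc_model`
#'   returns the model.
#' @export
write_nnc_model <- function(model, path) {
  stopifnot(inherits(model, "nnc_model"))
  payload <- list(units = model$units, center = model$center,
                  scale = model$scale, features = model$features,
                  dropped_features = model$dropped_features,
                  n_clusters = model$n_clusters, seed = model$seed,
                  epochs = model$epochs, lr = model$lr)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nnc_model
#' @export
read_nnc_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- as.matrix(p$units)
  dimnames(units) <- list(NULL, p$features)
  structure(list(units = units,
                 center = stats::setNames(as.numeric(p$center), p$features),
                 scale = stats::setNames(as.numeric(p$scale), p$features),
                 features = as.character(p$features),
                 dropped_features = as.character(p$dropped_features),
                 n_clusters = as.integer(p$n_clusters),
                 seed = as.integer(p$seed),
                 epochs = as.integer(p$epochs), lr = as.numeric(p$lr)),
            class = "nnc_model")
}
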