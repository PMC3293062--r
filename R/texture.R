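# Co-occurrence --------------------------------------------------------------

#' Gray-level co-occurrence matrix
#'
#' Tallies, for a fixed pixel displacement `offset = (dy, dx)`, how often
#' each ordered pair of gray levels co-occurs. Accumulation is symmetric:
#' each pixel pair increments both `counts[i, j]` and `counts[j, i]`, so the
#' matrix equals its transpose and features are invariant to reversing the
#' offset.
#'
#' @param img a quantized [gray_image()].
#' @param offset integer `(dy, dx)` displacement; not `(0, 0)` and smaller
#'   than the image in each dimension.
#' @return an object of class `cooccurrence_matrix` with fields `counts`
#'   (L x L integer), `normalized` (L x L probabilities), `offset`,
#'   `levels`.
#' @export
compute_com <- function(img, offset) {
  if (!inherits(img, "gray_image")) stop("'img' must be a gray_image",
                                         call. = FALSE)
  offset <- as.integer(offset)
  if (length(offset) != 2L) stop("'offset' must be (dy, dx)", call. = FALSE)
  dy <- offset[1]; dx <- offset[2]
  if (dy == 0L && dx == 0L) stop("offset (0, 0) is not a valid displacement",
                                 call. = FALSE)
  h <- img$height; w <- img$width; L <- img$levels
  if (abs(dy) >= h || abs(dx) >= w) {
    stop("offset (", dy, ", ", dx, ") larger than the image", call. = FALSE)
  }
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  a <- img$pixels[ys, xs, drop = FALSE]
  b <- img$pixels[ys + dy, xs + dx, drop = FALSE]
  counts <- matrix(tabulate(as.integer(a) * L + as.integer(b) + 1L,
                            nbins = L * L),
                   nrow = L, byrow = TRUE)
  counts <- counts + t(counts)
  total <- sum(counts)
  structure(list(counts = counts,
                 normalized = counts / total,
                 offset = c(dy = dy, dx = dx),
                 levels = L),
            class = "cooccurrence_matrix")
}

#' Scalar features of a co-occurrence matrix
#'
#' The eleven classical second-order statistics of the normalized matrix
#' `p(i, j)` with gray levels indexed `1..L`: angular second moment,
#' contrast, correlation, sum of squares (variance), inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance and difference entropy. Entropies use log base 2 with the
#' `0 log 0 = 0` convention; the sum variance is taken around the sum
#' average; a zero-variance marginal makes the correlation 0 by convention
#' so that feature vectors stay finite.
#'
#' @param M a `cooccurrence_matrix` with at least one counted pair.
#' @return named numeric vector of length 11.
#' @export
com_features <- function(M) {
  if (!inherits(M, "cooccurrence_matrix")) {
    stop("'M' must be a cooccurrence_matrix", call. = FALSE)
  }
  if (sum(M$counts) == 0) stop("co-occurrence matrix has no counted pairs",
                               call. = FALSE)
  p <- M$normalized
  L <- M$levels
  i <- seq_len(L)
  px <- rowSums(p)
  py <- colSums(p)
  ii <- row(p); jj <- col(p)
  dmat <- ii - jj

  mu_x <- sum(i * px); mu_y <- sum(i * py)
  var_x <- sum((i - mu_x)^2 * px); var_y <- sum((i - mu_y)^2 * py)

  asm <- sum(p^2)
  contrast <- sum(dmat^2 * p)
  correlation <- if (var_x > 0 && var_y > 0) {
    (sum(ii * jj * p) - mu_x * mu_y) / sqrt(var_x * var_y)
  } else 0
  sum_of_squares <- sum((ii - mu_x)^2 * p)
  idm <- sum(p / (1 + dmat^2))

  p_sum <- as.numeric(rowsum(as.numeric(p), group = as.numeric(ii + jj)))
  ks <- sort(unique(as.numeric(ii + jj)))
  sum_average <- sum(ks * p_sum)
  sum_variance <- sum((ks - sum_average)^2 * p_sum)
  sum_entropy <- -sum(xlog2(p_sum))

  p_diff <- as.numeric(rowsum(as.numeric(p), group = as.numeric(abs(dmat))))
  ds <- sort(unique(as.numeric(abs(dmat))))
  mu_diff <- sum(ds * p_diff)
  difference_variance <- sum((ds - mu_diff)^2 * p_diff)
  difference_entropy <- -sum(xlog2(p_diff))

  entropy <- -sum(xlog2(p))

  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_of_squares = sum_of_squares, idm = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy)
}

# Run length ------------------------------------------------------------------

#' Gray-level run-length matrix
#'
#' Counts maximal runs of identical gray level along every line of the image
#' in one of four directions (degrees): `0` (rows, left-right), `90`
#' (columns), `45` (anti-diagonals, up-right) and `135` (diagonals,
#' down-right). Single pixels count as runs of length 1, so every pixel
#' belongs to exactly one maximal run.
#'
#' @param img a quantized [gray_image()].
#' @param direction one of 0, 45, 90, 135.
#' @return an object of class `runlength_matrix` with fields `counts`
#'   (L x Rmax), `direction`, `levels`, `n_pixels`.
#' @export
compute_rlm <- function(img, direction = 0) {
  if (!inherits(img, "gray_image")) stop("'img' must be a gray_image",
                                         call. = FALSE)
  if (!direction %in% c(0, 45, 90, 135)) {
    stop("'direction' must be one of 0, 45, 90, 135", call. = FALSE)
  }
  p <- img$pixels
  lines <- switch(as.character(direction),
    "0"   = asplit(p, 1L),
    "90"  = asplit(p, 2L),
    "45"  = split(as.vector(p), as.vector(row(p) + col(p))),
    "135" = split(as.vector(p), as.vector(col(p) - row(p))))
  vals <- integer(0); lens <- integer(0)
  for (v in lines) {
    r <- rle(as.integer(v))
    vals <- c(vals, r$values)
    lens <- c(lens, r$lengths)
  }
  L <- img$levels
  rmax <- max(img$height, img$width)
  counts <- matrix(tabulate((lens - 1L) * L + vals + 1L, nbins = L * rmax),
                   nrow = L)
  structure(list(counts = counts, direction = direction, levels = L,
                 n_pixels = img$height * img$width),
            class = "runlength_matrix")
}

#' Scalar features of a run-length matrix
#'
#' Five classical run-length statistics: short-run emphasis, long-run
#' emphasis, gray-level nonuniformity, run-length nonuniformity and run
#' percentage (number of runs over number of pixels).
#'
#' @param R a `runlength_matrix` with at least one run.
#' @return named numeric vector of length 5.
#' @export
rlm_features <- function(R) {
  if (!inherits(R, "runlength_matrix")) {
    stop("'R' must be a runlength_matrix", call. = FALSE)
  }
  n_runs <- sum(R$counts)
  if (n_runs == 0) stop("run-length matrix is empty", call. = FALSE)
  r <- seq_len(ncol(R$counts))
  by_len <- colSums(R$counts)
  by_lvl <- rowSums(R$counts)
  c(sre = sum(by_len / r^2) / n_runs,
    lre = sum(by_len * r^2) / n_runs,
    gln = sum(by_lvl^2) / n_runs,
    rln = sum(by_len^2) / n_runs,
    rp  = n_runs / R$n_pixels)
}

# Gradient --------------------------------------------------------------------

#' Gradient-magnitude map
#'
#' Central-difference gradient magnitude
#' `sqrt((I[y+1,x] - I[y-1,x])^2 + (I[y,x+1] - I[y,x-1])^2)` at every
#' interior pixel (the absolute-gradient convention: the spacing of 2 is not
#' divided out). Border pixels are excluded rather than padded.
#'
#' @param img a [gray_image()] of at least 3 x 3 pixels; typically the
#'   unquantized 256-level image.
#' @return an object of class `gradient_map` with field `magnitudes`, an
#'   `(H-2) x (W-2)` matrix of nonnegative reals.
#' @export
compute_grm <- function(img) {
  if (!inherits(img, "gray_image")) stop("'img' must be a gray_image",
                                         call. = FALSE)
  h <- img$height; w <- img$width
  if (h < 3L || w < 3L) stop("gradient map needs an image of at least 3 x 3",
                             call. = FALSE)
  p <- img$pixels
  gy <- p[3:h, 2:(w - 1L), drop = FALSE] - p[1:(h - 2L), 2:(w - 1L), drop = FALSE]
  gx <- p[2:(h - 1L), 3:w, drop = FALSE] - p[2:(h - 1L), 1:(w - 2L), drop = FALSE]
  structure(list(magnitudes = sqrt(gy^2 + gx^2)), class = "gradient_map")
}

#' Scalar features of a gradient map
#'
#' Mean, population variance, skewness, excess kurtosis and the percentage
#' of interior pixels with nonzero gradient magnitude. Skewness and
#' kurtosis of a zero-variance map are 0 by convention, keeping feature
#' vectors finite.
#'
#' @param G a `gradient_map`.
#' @return named numeric vector of length 5.
#' @export
grm_features <- function(G) {
  if (!inherits(G, "gradient_map")) stop("'G' must be a gradient_map",
                                         call. = FALSE)
  m <- as.numeric(G$magnitudes)
  if (length(m) == 0L) stop("gradient map is empty", call. = FALSE)
  mu <- mean(m)
  v <- mean((m - mu)^2)
  skew <- if (v > 0) mean((m - mu)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((m - mu)^4) / v^2 - 3 else 0
  c(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
    nonzero_pct = 100 * mean(m > 0))
}
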