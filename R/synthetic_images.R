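# Synthetic tubular-tissue texture images -------------------------------------

#' Parameters of a synthetic tubular-tissue texture class
#'
#' Describes one morphological class of the image generator, which emulates
#' cross-sectioned seminiferous-tubule-like architecture: ring-shaped tubule
#' walls, a stippled epithelial interior, and a continuous degeneration
#' level `delta` in `[0, 1]`. `delta = 0` is intact morphology (dense,
#' well-filled tubules); `delta = 1` is severe atrophy (fewer, shrunken
#' tubules, depleted epithelium, luminal vacuolation). Intermediate values
#' model partial protection.
#'
#' @param density expected tubule cross-sections per 10^4 pixels^2.
#' @param radius_range length-2 positive numeric, tubule radius range (px).
#' @param wall wall thickness (px).
#' @param p_fill probability that an interior pixel carries an
#'   epithelial-cell dot, before degeneration scaling.
#' @param noise_sd SD of additive Gaussian pixel noise (gray levels).
#' @param delta degeneration level in `[0, 1]`; scales the tubule density
#'   and the fill probability down and adds luminal vacuoles.
#' @return an object of class `texture_class_params`.
#' @export
texture_class_params <- function(density = 1.2, radius_range = c(18, 32),
                                 wall = 3, p_fill = 0.35, noise_sd = 8,
                                 delta = 0) {
  stopifnot(length(radius_range) == 2L, all(radius_range > 0),
            radius_range[1] <= radius_range[2],
            wall > 0, density >= 0, noise_sd >= 0)
  if (p_fill < 0 || p_fill > 1) stop("'p_fill' must lie in [0, 1]",
                                     call. = FALSE)
  if (delta < 0 || delta > 1) stop("'delta' must lie in [0, 1]",
                                   call. = FALSE)
  structure(list(density = density, radius_range = radius_range,
                 wall = wall, p_fill = p_fill, noise_sd = noise_sd,
                 delta = delta),
            class = "texture_class_params")
}

# fixed stain-like intensities (8-bit luminance)
.bg_int <- 200; .wall_int <- 70; .cell_int <- 90; .lumen_int <- 180
.vac_int <- 235

#' Generate one synthetic tubular-tissue image
#'
#' Seeded placement of non-overlapping annuli (tubule walls) with interior
#' stippling at probability `(1 - delta) * p_fill`, delta-dependent luminal
#' vacuoles and additive Gaussian noise. Deterministic given `(params,
#' size, seed)`; the caller's RNG state is left untouched.
#'
#' @param params a [texture_class_params()].
#' @param size `(H, W)` in pixels, at least 64 x 64.
#' @param seed integer RNG seed.
#' @return a 256-level [gray_image()].
#' @export
make_texture_image <- function(params, size = c(256L, 256L), seed = 1L) {
  stopifnot(inherits(params, "texture_class_params"))
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h < 64L || w < 64L) stop("'size' must be at least 64 x 64",
                               call. = FALSE)
  withr::with_seed(as.integer(seed), {
    img <- matrix(.bg_int, h, w)
    delta <- params$delta
    n_tub <- round(params$density * h * w / 1e4 * (1 - 0.35 * delta))
    if (n_tub > 0) {
      radii <- runif(n_tub, params$radius_range[1], params$radius_range[2]) *
        (1 - 0.25 * delta)
      radii <- sort(radii, decreasing = TRUE)   # pack large tubules first
      cys <- numeric(0); cxs <- numeric(0); rs <- numeric(0)
      for (i in seq_len(n_tub)) {
        r <- radii[i]
        placed <- FALSE
        for (try in seq_len(500L)) {
          cy <- runif(1, r + params$wall + 2, h - r - params$wall - 2)
          cx <- runif(1, r + params$wall + 2, w - r - params$wall - 2)
          if (length(cys) == 0L ||
              all((cy - cys)^2 + (cx - cxs)^2 > (r + rs + 4)^2)) {
            placed <- TRUE; break
          }
        }
        if (!placed) {
          stop("could not place ", n_tub, " non-overlapping tubules in a ",
               h, " x ", w, " field; lower 'density' or the radius range",
               call. = FALSE)
        }
        cys <- c(cys, cy); cxs <- c(cxs, cx); rs <- c(rs, r)
        img <- paint_tubule(img, cy, cx, r, params, delta)
      }
    }
    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, params$noise_sd), h, w)
    }
    gray_image(pmin(pmax(round(img), 0), 255), levels = 256L)
  })
}

paint_tubule <- function(img, cy, cx, r, params, delta) {
  h <- nrow(img); w <- ncol(img)
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(h, ceiling(cy + r + 1))
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(w, ceiling(cx + r + 1))
  ys <- y0:y1; xs <- x0:x1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  block <- img[ys, xs]
  inner_r <- r - params$wall
  block[d <= r & d > inner_r] <- .wall_int
  interior <- d <= inner_r
  if (any(interior)) {
    p_eff <- params$p_fill * (1 - delta)
    fill <- matrix(runif(length(block)) < p_eff, nrow(block))
    block[interior] <- ifelse(fill[interior], .cell_int, .lumen_int)
    n_vac <- round(3 * delta)
    if (n_vac > 0 && inner_r > 4) {
      for (v in seq_len(n_vac)) {
        vr <- runif(1, inner_r / 6, inner_r / 3)
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, inner_r - vr)
        vy <- cy + rad * sin(ang); vx <- cx + rad * cos(ang)
        dv <- sqrt(outer((ys - vy)^2, (xs - vx)^2, "+"))
        block[dv <= vr] <- .vac_int
      }
    }
  }
  img[ys, xs] <- block
  img
}

#' Default per-group degeneration schedule
#'
#' A named schedule of degeneration levels emulating an untreated control
#' (`N`, intact), a toxicant group (`CIS`, severe), and three protected
#' groups at increasing protectant dose (`CIS+L`, `CIS+M`, `CIS+H`, i.e.
#' decreasing residual damage).
#'
#' @return named numeric vector of `delta` values.
#' @export
default_group_deltas <- function() {
  c("N" = 0, "CIS" = 1, "CIS+L" = 0.7, "CIS+M" = 0.35, "CIS+H" = 0.15)
}

#' Generate a labeled multi-group image dataset
#'
#' @param class_specs named list of [texture_class_params()], one per group
#'   (names must be unique). Default: [default_group_deltas()] applied to
#'   otherwise-default parameters.
#' @param n_images images per group (default 36).
#' @param size image size `(H, W)` (default 256 x 256).
#' @param seed integer RNG seed; per-image seeds are derived from it, so the
#'   whole dataset is deterministic.
#' @return list with `images` (list of [gray_image()]) and `metadata`
#'   (`data.frame` with `sample_id`, `group`, `delta`, `image_seed`).
#' @export
make_image_dataset <- function(class_specs = NULL, n_images = 36L,
                               size = c(256L, 256L), seed = 1L) {
  if (is.null(class_specs)) {
    class_specs <- lapply(default_group_deltas(),
                          function(d) texture_class_params(delta = d))
  }
  if (is.null(names(class_specs)) || anyDuplicated(names(class_specs))) {
    stop("'class_specs' must be a uniquely named list of group parameters",
         call. = FALSE)
  }
  if (n_images < 1L) stop("'n_images' must be at least 1", call. = FALSE)
  total <- length(class_specs) * n_images
  image_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max - 1L, total))
  images <- vector("list", total)
  meta <- data.frame(sample_id = character(total), group = character(total),
                     delta = numeric(total), image_seed = integer(total),
                     stringsAsFactors = FALSE)
  idx <- 0L
  for (g in names(class_specs)) {
    for (i in seq_len(n_images)) {
      idx <- idx + 1L
      images[[idx]] <- make_texture_image(class_specs[[g]], size = size,
                                          seed = image_seeds[idx])
      meta$sample_id[idx] <- sprintf("%s_%02d", g, i)
      meta$group[idx] <- g
      meta$delta[idx] <- class_specs[[g]]$delta
      meta$image_seed[idx] <- image_seeds[idx]
    }
  }
  list(images = images, metadata = meta)
}
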