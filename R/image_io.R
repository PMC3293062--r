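# Image containers -----------------------------------------------------------

#' RGB image container
#'
#' A thin container around an `H x W x 3` integer array of 8-bit channel
#' intensities. Texture statistics degenerate on very small rasters, so
#' images smaller than 16 x 16 are rejected.
#'
#' @param pixels `H x W x 3` array of integers in `[0, 255]`.
#' @return an object of class `rgb_image` with fields `pixels`, `height`,
#'   `width`.
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  }
  if (d[1] < 16L || d[2] < 16L) {
    stop("image must be at least 16 x 16 pixels, got ",
         d[1], " x ", d[2], call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, height = d[1], width = d[2]),
            class = "rgb_image")
}

#' Gray-level image container
#'
#' @param pixels `H x W` matrix of integers in `[0, levels - 1]`.
#' @param levels number of gray levels, between 2 and 256 (the container is
#'   permissive so small synthetic rasters can be built directly;
#'   [quantize()] itself only targets 16, 32, 64, 128 or 256 levels).
#' @param source_range length-2 numeric, the source intensity range mapped
#'   onto `[0, levels - 1]`.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, levels = 256L, source_range = range(pixels)) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix", call. = FALSE)
  if (length(levels) != 1L || levels < 2L || levels > 256L) {
    stop("'levels' must lie between 2 and 256", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > levels - 1) {
    stop("gray levels must lie in [0, levels - 1]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, levels = as.integer(levels),
                 source_range = as.numeric(source_range),
                 height = nrow(pixels), width = ncol(pixels)),
            class = "gray_image")
}

check_levels <- function(levels) {
  if (length(levels) != 1L || !levels %in% c(16L, 32L, 64L, 128L, 256L)) {
    stop("'levels' must be one of 16, 32, 64, 128, 256", call. = FALSE)
  }
  invisible(levels)
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, 8-bit>\n", x$height, x$width))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels, source range [%g, %g]>\n",
              x$height, x$width, x$levels,
              x$source_range[1], x$source_range[2]))
  invisible(x)
}

# Reading and writing ---------------------------------------------------------

#' Read a micrograph from disk
#'
#' Reads PNG (via the \pkg{png} package) or uncompressed 8-/24-bit BMP
#' (built-in reader). Grayscale files are promoted to three identical
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png` or `.bmp` file.
#' @return an [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path,
                               call. = FALSE)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 8L &&
      identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    arr <- tryCatch(png::readPNG(path), error = function(e) {
      stop("cannot read image (corrupt or truncated PNG): ", path,
           call. = FALSE)
    })
    px <- as.integer(round(arr * 255))
    d <- dim(arr)
    if (length(d) == 2L) {
      pixels <- array(px, dim = c(d[1], d[2], 3L))
    } else if (d[3] >= 3L) {
      pixels <- array(px, dim = d)[, , 1:3, drop = FALSE]
    } else {                       # gray + alpha
      pixels <- array(array(px, dim = d)[, , 1L], dim = c(d[1], d[2], 3L))
    }
    return(rgb_image(pixels))
  }
  if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0x42, 0x4d)))) {
    return(rgb_image(read_bmp(path)))
  }
  stop("cannot read image (not a PNG or BMP file): ", path, call. = FALSE)
}

# Minimal reader for uncompressed BMP (BITMAPINFOHEADER, 8- or 24-bit).
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  s32 <- function(i) { v <- u32(i); if (v >= 2^31) v - 2^32 else v }
  fail <- function(why) stop("cannot read image (", why, "): ", path,
                             call. = FALSE)
  if (length(raw) < 54L) fail("truncated BMP")
  data_off <- u32(11L)
  width    <- s32(19L)
  height   <- s32(23L)
  bitcount <- u16(29L)
  compress <- u32(31L)
  if (compress != 0) fail("compressed BMP not supported")
  if (!bitcount %in% c(8L, 24L)) fail(paste0(bitcount, "-bit BMP not supported"))
  flip <- height > 0              # positive height => rows stored bottom-up
  height <- abs(height)
  bytes_pp <- bitcount / 8L
  row_size <- 4L * ceiling(width * bytes_pp / 4)
  need <- data_off + row_size * height
  if (length(raw) < need) fail("truncated BMP")
  body <- matrix(as.integer(raw[(data_off + 1L):(data_off + row_size * height)]),
                 nrow = row_size)
  if (bitcount == 24L) {
    b <- t(body[seq(1L, 3L * width, by = 3L), , drop = FALSE])
    g <- t(body[seq(2L, 3L * width, by = 3L), , drop = FALSE])
    r <- t(body[seq(3L, 3L * width, by = 3L), , drop = FALSE])
  } else {
    hdr_size <- u32(15L)
    n_col <- u32(47L)
    if (n_col == 0) n_col <- 256L
    pal_off <- 14L + hdr_size
    pal <- matrix(as.integer(raw[(pal_off + 1L):(pal_off + 4L * n_col)]),
                  nrow = 4L)            # B, G, R, reserved
    idx <- t(body[seq_len(width), , drop = FALSE]) + 1L
    b <- matrix(pal[1L, idx], nrow = height)
    g <- matrix(pal[2L, idx], nrow = height)
    r <- matrix(pal[3L, idx], nrow = height)
  }
  if (flip) { r <- r[height:1, , drop = FALSE]
              g <- g[height:1, , drop = FALSE]
              b <- b[height:1, , drop = FALSE] }
  array(c(r, g, b), dim = c(height, width, 3L))
}

#' Write an image to disk
#'
#' PNG output goes through the \pkg{png} package; BMP output uses the
#' built-in uncompressed 24-bit writer. [gray_image()] inputs are written as
#' 8-bit grayscale (their levels rescaled to `[0, 255]`).
#'
#' @param img an [rgb_image()] or [gray_image()].
#' @param path output path ending in `.png` or `.bmp`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(img, "gray_image")) {
    scale <- if (img$levels > 1L) 255 / (img$levels - 1L) else 0
    px <- round(img$pixels * scale)
    arr <- array(as.integer(px), dim = c(nrow(px), ncol(px), 3L))
  } else if (inherits(img, "rgb_image")) {
    arr <- img$pixels
  } else stop("'img' must be an rgb_image or gray_image", call. = FALSE)
  if (ext == "png") {
    if (inherits(img, "gray_image")) {
      png::writePNG(arr[, , 1L] / 255, target = path)
    } else {
      png::writePNG(arr / 255, target = path)
    }
  } else if (ext == "bmp") {
    write_bmp24(arr, path)
  } else stop("unsupported image extension: .", ext, call. = FALSE)
  invisible(path)
}

write_bmp24 <- function(arr, path) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  row_size <- 4L * ceiling(3L * w / 4)
  body <- matrix(0L, nrow = row_size, ncol = h)
  rows <- h:1                      # bottom-up storage
  body[seq(1L, 3L * w, by = 3L), ] <- t(arr[rows, , 3L])  # B
  body[seq(2L, 3L * w, by = 3L), ] <- t(arr[rows, , 2L])  # G
  body[seq(3L, 3L * w, by = 3L), ] <- t(arr[rows, , 1L])  # R
  con <- file(path, "wb")
  on.exit(close(con))
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeBin(as.raw(c(0x42, 0x4d)), con)
  wr32(54L + row_size * h); wr32(0L); wr32(54L)      # file size, reserved, offset
  wr32(40L); wr32(w); wr32(h); wr16(1L); wr16(24L)   # DIB header
  wr32(0L); wr32(row_size * h); wr32(2835L); wr32(2835L); wr32(0L); wr32(0L)
  writeBin(as.raw(body), con)
  invisible(path)
}

# Gray conversion and quantization --------------------------------------------

#' Convert an RGB image to 256-level luminance
#'
#' Uses the fixed ITU-R 601 luminance weights
#' `0.299 R + 0.587 G + 0.114 B`, rounded half-up, so feature values are
#' bit-reproducible across platforms. Pixels with `R = G = B` map to that
#' common value unchanged.
#'
#' @param img an [rgb_image()].
#' @return a [gray_image()] with 256 levels.
#' @export
to_gray <- function(img) {
  if (!inherits(img, "rgb_image")) stop("'img' must be an rgb_image",
                                        call. = FALSE)
  p <- img$pixels
  y <- floor(0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L] + 0.5)
  gray_image(y, levels = 256L, source_range = range(y))
}

#' Quantize gray levels for texture computation
#'
#' Reduces a gray image to `levels` gray levels. `"minmax"` maps the
#' observed intensity range linearly onto `0..levels-1` (equal-width integer
#' bins; a constant image maps to all zeros). `"3sigma"` maps
#' `[mu - 3 sigma, mu + 3 sigma]` with clipping, which is robust to
#' intensity outliers. `"none"` rescales the nominal `[0, 255]` range and is
#' the identity at `levels = 256`.
#'
#' @param img a [gray_image()].
#' @param levels target gray-level count: 16, 32, 64, 128 or 256.
#' @param mode `"minmax"`, `"3sigma"` or `"none"`.
#' @return a [gray_image()] with `levels` gray levels.
#' @export
quantize <- function(img, levels = 64L,
                     mode = c("minmax", "3sigma", "none")) {
  if (!inherits(img, "gray_image")) stop("'img' must be a gray_image",
                                         call. = FALSE)
  check_levels(levels)
  mode <- match.arg(mode)
  x <- img$pixels
  if (mode == "minmax") {
    lo <- min(x); hi <- max(x)
    q <- if (hi == lo) {
      matrix(0L, nrow(x), ncol(x))
    } else {
      floor((x - lo) * levels / (hi - lo + 1))
    }
    src <- c(lo, hi)
  } else if (mode == "3sigma") {
    mu <- mean(x); sig <- sd(as.numeric(x))
    if (sig == 0) {
      q <- matrix(0L, nrow(x), ncol(x)); src <- c(mu, mu)
    } else {
      lo <- mu - 3 * sig; hi <- mu + 3 * sig
      q <- floor((x - lo) / (hi - lo) * levels)
      q <- pmin(pmax(q, 0), levels - 1L)
      src <- c(lo, hi)
    }
  } else {                         # "none": nominal 8-bit range
    if (img$levels != 256L) {
      stop("mode 'none' expects a 256-level input image", call. = FALSE)
    }
    q <- floor(x * levels / 256)
    src <- c(0, 255)
  }
  gray_image(q, levels = levels, source_range = src)
}
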