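# Fixture builders (all programmatic; no binary fixtures on disk).

rand_gray <- function(h, w, levels, seed) {
  withr::with_seed(seed, {
    gray_image(matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w),
               levels = levels)
  })
}

rand_rgb_array <- function(h, w, seed) {
  withr::with_seed(seed, array(sample(0:255, h * w * 3, replace = TRUE),
                               dim = c(h, w, 3)))
}

checkerboard <- function(n, levels) {
  m <- outer(1:n, 1:n, function(y, x) ((y + x) %% 2) * (levels - 1))
  gray_image(m, levels = levels)
}

# Reference BMP writer used to test the package reader against an
# independently constructed byte stream (uncompressed 24-bit, bottom-up).
write_bmp_reference <- function(arr, path) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  row_size <- 4 * ceiling(3 * w / 4)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(as.raw(c(0x42, 0x4d)), con)
  w32(54 + row_size * h); w32(0); w32(54)
  w32(40); w32(w); w32(h); w16(1); w16(24); w32(0); w32(row_size * h)
  w32(0); w32(0); w32(0); w32(0)
  for (y in h:1) {                      # bottom row first
    row <- integer(row_size)
    for (x in 1:w) {
      row[3 * (x - 1) + 1:3] <- c(arr[y, x, 3], arr[y, x, 2], arr[y, x, 1])
    }
    writeBin(as.raw(row), con)
  }
  invisible(path)
}

# Per-animal table with one informative feature and pure-noise companions.
toy_two_group_table <- function(n_per_group = 10, n_noise = 20, sep_sd = 6,
                                seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    tab <- data.frame(sample_id = sprintf("s%02d", 1:n),
                      group = rep(c("A", "B"), each = n_per_group),
                      stringsAsFactors = FALSE)
    tab$strong <- c(rnorm(n_per_group, 0, 1), rnorm(n_per_group, sep_sd, 1))
    for (k in seq_len(n_noise)) {
      tab[[sprintf("noise_%02d", k)]] <- rnorm(n)
    }
    tab
  })
}
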