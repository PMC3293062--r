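# Independent brute-force oracles, written as direct loop translations of
# the textbook formulas. Deliberately share no code with the package.

oracle_com_counts <- function(pix, L, dy, dx) {
  h <- nrow(pix); w <- ncol(pix)
  counts <- matrix(0L, L, L)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 >= 1 && y2 <= h && x2 >= 1 && x2 <= w) {
        a <- pix[y, x] + 1L; b <- pix[y2, x2] + 1L
        counts[a, b] <- counts[a, b] + 1L
        counts[b, a] <- counts[b, a] + 1L
      }
    }
  }
  counts
}

oracle_com_features <- function(counts) {
  p <- counts / sum(counts)
  L <- nrow(p)
  px <- rep(0, L); py <- rep(0, L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mu_x <- sum((1:L) * px); mu_y <- sum((1:L) * py)
  var_x <- sum(((1:L) - mu_x)^2 * px); var_y <- sum(((1:L) - mu_y)^2 * py)

  asm <- 0; contrast <- 0; ent <- 0; ssq <- 0; idm <- 0; cor_num <- 0
  p_sum <- rep(0, 2 * L)          # index k = i + j, 2..2L
  p_diff <- rep(0, L)             # index d = |i - j| + 1
  for (i in 1:L) for (j in 1:L) {
    v <- p[i, j]
    asm <- asm + v^2
    contrast <- contrast + (i - j)^2 * v
    if (v > 0) ent <- ent - v * log2(v)
    ssq <- ssq + (i - mu_x)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    cor_num <- cor_num + i * j * v
    p_sum[i + j] <- p_sum[i + j] + v
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + v
  }
  correlation <- if (var_x > 0 && var_y > 0) {
    (cor_num - mu_x * mu_y) / sqrt(var_x * var_y)
  } else 0
  sa <- 0; for (k in 2:(2 * L)) sa <- sa + k * p_sum[k]
  sv <- 0; se_ <- 0
  for (k in 2:(2 * L)) {
    sv <- sv + (k - sa)^2 * p_sum[k]
    if (p_sum[k] > 0) se_ <- se_ - p_sum[k] * log2(p_sum[k])
  }
  mu_d <- 0; for (d in 0:(L - 1)) mu_d <- mu_d + d * p_diff[d + 1]
  dv <- 0; de <- 0
  for (d in 0:(L - 1)) {
    dv <- dv + (d - mu_d)^2 * p_diff[d + 1]
    if (p_diff[d + 1] > 0) de <- de - p_diff[d + 1] * log2(p_diff[d + 1])
  }
  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_of_squares = ssq, idm = idm, sum_average = sa, sum_variance = sv,
    sum_entropy = se_, entropy = ent, difference_variance = dv,
    difference_entropy = de)
}

# Lines of the image in a given direction, each an integer vector.
oracle_lines <- function(pix, direction) {
  h <- nrow(pix); w <- ncol(pix)
  lines <- list()
  if (direction == 0) {
    for (y in 1:h) lines[[length(lines) + 1L]] <- pix[y, ]
  } else if (direction == 90) {
    for (x in 1:w) lines[[length(lines) + 1L]] <- pix[, x]
  } else if (direction == 45) {        # up-right: y decreases as x increases
    for (s in 2:(h + w)) {
      xs <- max(1, s - h):min(w, s - 1)
      lines[[length(lines) + 1L]] <- pix[cbind(s - xs, xs)]
    }
  } else {                             # 135, down-right
    for (cst in (1 - w):(h - 1)) {
      xs <- max(1, 1 - cst):min(w, h - cst)
      lines[[length(lines) + 1L]] <- pix[cbind(xs + cst, xs)]
    }
  }
  lines
}

oracle_rlm_counts <- function(pix, L, direction) {
  rmax <- max(nrow(pix), ncol(pix))
  counts <- matrix(0L, L, rmax)
  for (v in oracle_lines(pix, direction)) {
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
      len <- j - i + 1L
      counts[v[i] + 1L, len] <- counts[v[i] + 1L, len] + 1L
      i <- j + 1L
    }
  }
  counts
}

oracle_rlm_features <- function(counts, n_pixels) {
  n_runs <- sum(counts)
  sre <- 0; lre <- 0; rln <- 0
  for (r in seq_len(ncol(counts))) {
    cr <- sum(counts[, r])
    sre <- sre + cr / r^2
    lre <- lre + cr * r^2
    rln <- rln + cr^2
  }
  gln <- 0
  for (g in seq_len(nrow(counts))) gln <- gln + sum(counts[g, ])^2
  c(sre = sre / n_runs, lre = lre / n_runs, gln = gln / n_runs,
    rln = rln / n_runs, rp = n_runs / n_pixels)
}

oracle_grm_features <- function(pix) {
  h <- nrow(pix); w <- ncol(pix)
  mags <- c()
  for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
    gy <- pix[y + 1, x] - pix[y - 1, x]
    gx <- pix[y, x + 1] - pix[y, x - 1]
    mags <- c(mags, sqrt(gy^2 + gx^2))
  }
  mu <- mean(mags)
  v <- mean((mags - mu)^2)
  c(mean = mu, variance = v,
    skewness = if (v > 0) mean((mags - mu)^3) / v^1.5 else 0,
    kurtosis = if (v > 0) mean((mags - mu)^4) / v^2 - 3 else 0,
    nonzero_pct = 100 * sum(mags > 0) / length(mags))
}

oracle_fisher <- function(groups) {
  # groups: list of numeric vectors
  n <- sum(lengths(groups))
  mu <- mean(unlist(groups))
  between <- 0; within <- 0
  for (g in groups) {
    pk <- length(g) / n
    between <- between + pk * (mean(g) - mu)^2
    within <- within + pk * sum((g - mean(g))^2) / length(g)
  }
  if (within > 0) between / within else if (between > 0) Inf else 0
}

# Exhaustive two-cluster least-squares partition (n <= 12 feasible).
oracle_two_means <- function(z) {
  n <- nrow(z)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {     # sample 1 fixed in cluster A
    in_a <- c(TRUE, as.logical(bitwAnd(2^(0:(n - 2)), mask)))
    if (!any(!in_a)) next
    ss <- 0
    for (side in list(z[in_a, , drop = FALSE], z[!in_a, , drop = FALSE])) {
      ctr <- colMeans(side)
      ss <- ss + sum(sweep(side, 2, ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- in_a }
  }
  list(in_a = best, ss = best_ss)
}
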