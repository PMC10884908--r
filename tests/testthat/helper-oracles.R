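# Independent brute-force oracles. These deliberately re-derive each
# operation from its definition with a different code path than the package
# (dense 2-D kernels, per-pixel loops) so agreement is informative.

# dense 2-D Gaussian convolution, kernel truncated at 4*sigma, replicate
# border, computed pixel-by-pixel
oracle_gaussian_blur <- function(x, sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in (-r):r) {
        ii <- min(max(i + di, 1L), nr)
        for (dj in (-r):r) {
          jj <- min(max(j + dj, 1L), nc)
          acc <- acc + k2[di + r + 1L, dj + r + 1L] * x[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_ivm <- function(x, sigma_bg = 1.0, sigma_info = 1.5) {
  bg <- oracle_gaussian_blur(x, sigma_bg)
  oracle_gaussian_blur(pmax(x - bg, 0), sigma_info) +
    oracle_gaussian_blur(pmax(bg - x, 0), sigma_info)
}

# per-pixel disk max-min scan with replicate border
oracle_disk_maxmin <- function(x, radius) {
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(0, nr, nc)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- mapply(function(dr, dc) {
        x[min(max(i + dr, 1L), nr), min(max(j + dc, 1L), nc)]
      }, offs$dr, offs$dc)
      out[i, j] <- max(v) - min(v)
    }
  }
  out
}

# naive two-pass population variance
oracle_pop_var <- function(v) {
  v <- as.numeric(v)
  mu <- sum(v) / length(v)
  sum((v - mu)^2) / length(v)
}

# naive sample mean / sd
oracle_mean_sd <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  mu <- sum(v) / n
  list(mean = mu, sd = if (n < 2) 0 else sqrt(sum((v - mu)^2) / (n - 1)))
}

# exhaustive optimal one-to-one assignment (max matches, then min total
# distance) between small point sets, pairs beyond max_dist excluded
oracle_assignment <- function(truth, det, max_dist) {
  nt <- nrow(truth)
  nd <- nrow(det)
  d <- sqrt(outer(truth$row_px, det$row_px, `-`)^2 +
              outer(truth$col_px, det$col_px, `-`)^2)
  best <- list(n = -1L, cost = Inf, pairs = NULL)
  # enumerate injective maps truth -> det (0 = unmatched)
  recurse <- function(ti, used, pairs, cost) {
    if (ti > nt) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    recurse(ti + 1L, used, pairs, cost)  # leave ti unmatched
    for (di in seq_len(nd)) {
      if (!used[di] && d[ti, di] <= max_dist) {
        used2 <- used
        used2[di] <- TRUE
        recurse(ti + 1L, used2,
                rbind(pairs, c(ti, di)), cost + d[ti, di])
      }
    }
  }
  recurse(1L, rep(FALSE, nd), matrix(integer(0), 0, 2), 0)
  best
}

pair_key <- function(t_idx, d_idx) paste(t_idx, d_idx, sep = "-")
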