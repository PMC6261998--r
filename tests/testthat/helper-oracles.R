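## Independent brute-force oracles used across the suite.  These deliberately
## re-derive results by enumeration / closed form and must stay independent
## of the package's implementation paths.

## triple-loop maximum projection
oracle_max_projection <- function(v) {
  d <- dim(v)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3]))
        out[y, x] <- max(out[y, x], v[z, y, x])
  out
}

## per-pixel local entropy by explicit neighbourhood enumeration
oracle_local_entropy <- function(q, radius) {
  ny <- nrow(q); nx <- ncol(q)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      vals <- c()
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          if (dy^2 + dx^2 > radius^2) next
          ii <- i + dy; jj <- j + dx
          if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
          vals <- c(vals, q[ii, jj])
        }
      }
      p <- table(vals) / length(vals)
      out[i, j] <- -sum(p * log2(p))
    }
  }
  out
}

## exhaustive Otsu: maximise between-class variance over every candidate
## split of the same 256-bin histogram the implementation uses
oracle_otsu <- function(v, bins = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  bw <- (hi - lo) / bins
  q <- pmin(floor((v - lo) / bw), bins - 1)
  best_k <- NA; best_s <- -Inf
  for (k in seq_len(bins - 1L)) {
    g1 <- q < k; n1 <- sum(g1); n2 <- length(q) - n1
    if (n1 == 0 || n2 == 0) next
    s <- n1 / length(q) * n2 / length(q) * (mean(q[g1]) - mean(q[!g1]))^2
    if (s > best_s + 1e-12) { best_s <- s; best_k <- k }
  }
  lo + best_k * bw
}

## analytic ray-sphere chord: path length inside the sphere from point p
## along unit direction d (independent re-derivation via the quadratic)
oracle_chord <- function(p, d, center, radius) {
  oc <- p - center
  b <- sum(oc * d)
  disc <- b^2 - (sum(oc^2) - radius^2)
  if (disc <= 0) return(0)
  t_exit <- -b + sqrt(disc)
  max(t_exit, 0)
}

## field of 2D Gaussian blobs for entropy-regime tests
blob_field <- function(n = 60, sz = 200, sigma = 4, amp = 1000, bg = 100,
                       bg_sd = 2, seed = 1) {
  set.seed(seed)
  img <- matrix(rnorm(sz * sz, bg, bg_sd), sz, sz)
  cx <- runif(n, 10, sz - 10); cy <- runif(n, 10, sz - 10)
  xs <- seq_len(sz)
  for (i in seq_len(n)) {
    gx <- exp(-(xs - cx[i])^2 / (2 * sigma^2))
    gy <- exp(-(xs - cy[i])^2 / (2 * sigma^2))
    img <- img + amp * (gy %o% gx)
  }
  img
}

## small phantom + stack used by several io/quality tests
tiny_stack <- function(seed = 1, sd = 2) {
  ph <- make_phantom(sphere_radius = 24, n_nuclei = 20, cap_half_angle = 90,
                     seed = seed, shell_thickness = 12, nucleus_radius = 5,
                     nucleus_radius_sd = 0.5)
  render_view(ph, optics_model(background_sd = sd), c(16, 32, 32), 2, 4,
              seed = seed)
}
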