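# Independent oracles and fixture builders used across the test files.
# Each oracle is deliberately written as plain enumeration / search,
# separate from the implementation path it checks.

# exhaustive Otsu: try every threshold, compute between-class variance
# directly from the class definitions
otsu_bruteforce <- function(values) {
  values <- as.integer(values)
  best_t <- NA_integer_
  best_v <- -1  # between-class variance is non-negative
  n <- length(values)
  for (t in 0:254) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    # keep the earlier threshold under numerical ties (identical splits)
    if (v > best_v + 1e-9 * (1 + abs(best_v))) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# hole filling by explicit breadth-first flood fill from the border
# (4-connected background)
fill_holes_floodfill <- function(m) {
  h <- nrow(m); w <- ncol(m)
  reach <- matrix(FALSE, h, w)
  queue <- which(!m & (row(m) %in% c(1L, h) | col(m) %in% c(1L, w)))
  reach[queue] <- TRUE
  while (length(queue) > 0L) {
    i <- queue[[1]]
    queue <- queue[-1]
    r <- ((i - 1L) %% h) + 1L
    cc <- ((i - 1L) %/% h) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cn <- cc + d[2]
      if (rr >= 1L && rr <= h && cn >= 1L && cn <= w) {
        j <- (cn - 1L) * h + rr
        if (!m[j] && !reach[j]) {
          reach[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  m | !reach
}

# 8-connected component count by repeated breadth-first search
count_components_bfs <- function(m) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      i <- queue[[1]]
      queue <- queue[-1]
      r <- ((i - 1L) %% h) + 1L
      cc <- ((i - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cn <- cc + dc
        if ((dr != 0L || dc != 0L) && rr >= 1L && rr <= h &&
            cn >= 1L && cn <= w) {
          j <- (cn - 1L) * h + rr
          if (m[j] && !seen[j]) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  count
}

# closed-form OLS through the normal equations
ols_normal_equations <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- (sum(y) - slope * sum(x)) / n
  c(slope = slope, intercept = intercept)
}

# random blobby mask with a clear border margin (disks on a grid)
random_blob_mask <- function(seed, h = 40, w = 50, n_disks = 6,
                             r_range = c(2, 5)) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_disks)) {
    r <- runif(1, r_range[1], r_range[2])
    cy <- runif(1, r + 2, h - r - 2)
    cx <- runif(1, r + 2, w - r - 2)
    d2 <- outer(seq_len(h) - cy, seq_len(w) - cx, function(a, b) a^2 + b^2)
    m <- m | (d2 <= r^2)
  }
  m
}

# digitized solid ellipse, centred in its canvas: a pixel belongs to the
# region when its centre lies inside the ellipse (point sampling, whose
# moments plus the 1/12 pixel-variance correction track the continuum
# moments); half-integer semi-axes avoid pixels sitting exactly on the
# boundary
digitized_ellipse <- function(a, b, theta = 0) {
  half <- ceiling(a) + 3L
  cs <- seq(-half, half)
  ct <- cos(theta); st <- sin(theta)
  u <- outer(cs, cs, function(y, x) x * ct + y * st)
  v <- outer(cs, cs, function(y, x) -x * st + y * ct)
  (u / a)^2 + (v / b)^2 <= 1
}

# quick gray/rgb fixtures
as_rgb_fixture <- function(gray_matrix, dpi = 72) {
  rgb_image(array(rep(gray_matrix, 3L), c(dim(gray_matrix), 3L)), dpi = dpi)
}

as_plain_logical <- function(m) {
  m <- as.matrix(m)
  attributes(m) <- list(dim = dim(m))
  m > 0
}

reference_means <- function() {
  read.csv(system.file("extdata", "snps_reference_means.csv",
                       package = "paniclescan"),
           stringsAsFactors = FALSE)
}
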