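# Independent brute-force reference implementations. These deliberately use
# explicit loops over pixels/objects and textbook formulas so they share no
# code path with the package functions they check.

brute_pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  sa <- 0; sb <- 0
  for (i in seq_len(n)) { sa <- sa + a[i]; sb <- sb + b[i] }
  ma <- sa / n; mb <- sb / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

brute_manders <- function(a, b, t_a, t_b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- 0; d1 <- 0; n2 <- 0; d2 <- 0
  for (i in seq_along(a)) {
    if (a[i] > t_a) {
      d1 <- d1 + a[i]
      if (b[i] > t_b) n1 <- n1 + a[i]
    }
    if (b[i] > t_b) {
      d2 <- d2 + b[i]
      if (a[i] > t_a) n2 <- n2 + b[i]
    }
  }
  c(m1 = if (d1 > 0) n1 / d1 else NA_real_,
    m2 = if (d2 > 0) n2 / d2 else NA_real_)
}

brute_max_project <- function(arr) {
  d <- dim(arr)
  out <- matrix(-Inf, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (arr[y, x, z] > out[y, x]) out[y, x] <- arr[y, x, z]
  }
  out
}

brute_total_masked <- function(img, t) {
  s <- 0
  for (v in as.numeric(img)) if (v > t) s <- s + v
  s
}

# percentage of A centroids with some B centroid strictly closer than res
brute_object_percent <- function(ca, cb, res) {
  if (nrow(ca) == 0L) return(NA_real_)
  hits <- 0
  for (i in seq_len(nrow(ca))) {
    matched <- FALSE
    if (nrow(cb) > 0L) for (j in seq_len(nrow(cb))) {
      d <- sqrt((ca[i, 1] - cb[j, 1])^2 + (ca[i, 2] - cb[j, 2])^2)
      if (d < res) matched <- TRUE
    }
    if (matched) hits <- hits + 1
  }
  100 * hits / nrow(ca)
}

# Costes by exhaustive scan: TLS slope from the covariance-matrix eigenvector
# (a route independent of the closed form in the package), then recompute the
# below-threshold Pearson at every unit candidate.
brute_costes <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  ev <- eigen(stats::cov(cbind(av, bv)))$vectors[, 1]
  slope <- ev[2] / ev[1]
  intercept <- mean(bv) - slope * mean(av)
  for (t_a in seq(max(1, floor(max(av))), 1)) {
    t_b <- slope * t_a + intercept
    sel <- av < t_a & bv < t_b
    if (sum(sel) >= 2 && stats::sd(av[sel]) > 0 && stats::sd(bv[sel]) > 0) {
      if (stats::cor(av[sel], bv[sel]) <= 0) {
        return(list(t_a = t_a, t_b = t_b, converged = TRUE))
      }
    }
  }
  list(t_a = 1, t_b = slope + intercept, converged = FALSE)
}

# paired t statistic straight from the textbook definition
brute_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# build an object_set-shaped data frame from centroid vectors (handles empty)
mk_objset <- function(y, x) {
  data.frame(label = seq_along(y), centroid_y = as.numeric(y),
             centroid_x = as.numeric(x),
             total_intensity = rep(1, length(y)), area = rep(1L, length(y)))
}
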