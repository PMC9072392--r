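# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately use naive double loops and must stay
# independent of the package internals.

naive_fos <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  list(mean = mu, std = sqrt(m2),
       skewness = if (m2 == 0) NA_real_ else m3 / sqrt(m2)^3,
       kurtosis = if (m2 == 0) NA_real_ else m4 / m2^2)
}

# naive GLCM by explicit pair enumeration; directions in degrees
naive_glcm <- function(x, n_levels = 64, distance = 1,
                       directions = c(0, 45, 90, 135), symmetric = TRUE) {
  rng <- range(x)
  lev <- if (rng[2] > rng[1]) {
    pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_levels), n_levels - 1)
  } else x * 0
  dim(lev) <- dim(x)
  offs <- list("0" = c(0, distance), "45" = c(-distance, distance),
               "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, n_levels, n_levels)
  for (a in as.character(directions)) {
    dr <- offs[[a]][1]; dc <- offs[[a]][2]
    for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(x) && c2 >= 1 && c2 <= ncol(x)) {
        counts[lev[r, c] + 1, lev[r2, c2] + 1] <-
          counts[lev[r, c] + 1, lev[r2, c2] + 1] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# naive Haralick scalars from a probability matrix by double loops
naive_sos <- function(p) {
  n <- nrow(p)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum((0:(n - 1)) * pi_); mu_j <- sum((0:(n - 1)) * pj_)
  si <- sqrt(sum(((0:(n - 1)) - mu_i)^2 * pi_))
  sj <- sqrt(sum(((0:(n - 1)) - mu_j)^2 * pj_))
  energy <- inertia <- idm <- entropy <- corr_num <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    pij <- p[i + 1, j + 1]
    energy <- energy + pij^2
    inertia <- inertia + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    if (pij > 0) entropy <- entropy - pij * log(pij)
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * pij
  }
  list(energy = energy, inertia = inertia,
       correlation = if (si == 0 || sj == 0) 0 else corr_num / (si * sj),
       idm = idm, entropy = entropy)
}

# brute-force axis ratio of a binary mask via explicit moment loops
naive_axis_oi <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  mr <- mean(pts[, 1]); mc <- mean(pts[, 2])
  sxx <- sxy <- syy <- 0
  for (k in seq_len(nrow(pts))) {
    dr <- pts[k, 1] - mr; dc <- pts[k, 2] - mc
    sxx <- sxx + dr * dr; sxy <- sxy + dr * dc; syy <- syy + dc * dc
  }
  n <- nrow(pts)
  tr <- (sxx + syy) / n
  det <- (sxx / n) * (syy / n) - (sxy / n)^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  if (l1 <= 0) 0 else unname(1 - sqrt(max(l2, 0) / l1))
}

# two-sample permutation p-value for the difference in means
perm_pvalue <- function(a, b, n_perm = 2000, seed = 99) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# radially symmetric Gaussian spot centered between pixels, so the image is
# invariant under 90-degree rotation about the grid center
gaussian_spot <- function(n = 256, sigma = 15) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(r, c)
    exp(-((r - ctr)^2 + (c - ctr)^2) / (2 * sigma^2)))
}
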