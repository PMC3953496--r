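# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized/queue-based code paths: plain per-pixel
# loops and set-fixpoint iterations.

# Pixel count of the rasterized disk (x - x0)^2 + (y - y0)^2 <= r^2 by
# exhaustive scan of every pixel.
oracle_disk_area <- function(x0, y0, r, width, height) {
  n <- 0L
  for (x in 0:(width - 1)) for (y in 0:(height - 1))
    if ((x - x0)^2 + (y - y0)^2 <= r^2) n <- n + 1L
  n
}

# Connected component (8-connectivity) of `cond` containing the seed pixels,
# as a set fixpoint: repeatedly add any cond pixel adjacent to the current
# set until nothing changes.
oracle_flood <- function(cond, seed_idx) {
  nr <- nrow(cond); nc <- ncol(cond)
  member <- matrix(FALSE, nr, nc)
  member[seed_idx] <- TRUE
  repeat {
    grown <- member
    for (r in 1:nr) for (c in 1:nc) {
      if (grown[r, c] || !cond[r, c]) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && member[rr, cc])
          grown[r, c] <- TRUE
      }
    }
    if (identical(grown, member)) break
    member <- grown
  }
  member
}

# Median filter by per-pixel neighbourhood sort with clamped (edge
# replicated) indices.
oracle_median_filter <- function(img, window) {
  k <- (window - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (r in 1:nr) for (c in 1:nc) {
    vals <- c()
    for (dr in -k:k) for (dc in -k:k) {
      rr <- min(max(r + dr, 1), nr)
      cc <- min(max(c + dc, 1), nc)
      vals <- c(vals, img[rr, cc])
    }
    out[r, c] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# Boundary pixels of a member set: any member with an 8-neighbour outside
# the set or outside the image, counted by exhaustive scan.
oracle_boundary_count <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  n <- 0L
  for (r in 1:nr) for (c in 1:nc) {
    if (!member[r, c]) next
    on_border <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !member[rr, cc])
        on_border <- TRUE
    }
    if (on_border) n <- n + 1L
  }
  n
}

# One assignment/update/move pass of moving k-means on a raw pixel vector,
# written step by step (no histogram weighting).
oracle_mkm_pass <- function(px, centres, alpha) {
  nc_ <- length(centres)
  cl <- sapply(px, function(v) which.min(abs(v - centres)))
  upd <- sapply(seq_len(nc_), function(j)
    if (any(cl == j)) mean(px[cl == j]) else centres[j])
  repeat {
    cl <- sapply(px, function(v) which.min(abs(v - upd)))
    fit <- sapply(seq_len(nc_), function(j) sum((px[cl == j] - upd[j])^2))
    if (min(fit) >= alpha * max(fit)) break
    js <- which.min(fit); jl <- which.max(fit)
    take <- cl == jl & px < upd[jl]
    keep <- cl == jl & !take
    if (any(take) && any(keep)) {
      upd[js] <- mean(px[take])
      upd[jl] <- mean(px[keep])
    }
    alpha <- alpha - alpha / nc_
    if (alpha < 1e-6) break
  }
  upd
}

# Centroid by explicit raw-moment sums over true pixels.
oracle_moments <- function(mask) {
  m00 <- 0; m10 <- 0; m01 <- 0
  for (r in 1:nrow(mask)) for (c in 1:ncol(mask)) {
    if (mask[r, c]) {
      m00 <- m00 + 1
      m10 <- m10 + (c - 1)   # x
      m01 <- m01 + (r - 1)   # y
    }
  }
  c(x = m10 / m00, y = m01 / m00)
}

# Per-sample, per-layer ANFIS forward evaluation with scalar loops.
oracle_anfis_forward <- function(model, x) {
  R <- nrow(model$rules)
  w <- numeric(R)
  for (r in seq_len(R)) {
    wr <- 1
    for (i in seq_len(model$d)) {
      m <- model$rules[r, i]
      wr <- wr * (1 / (1 + (((x[i] - model$c[i, m]) / model$a[i, m])^2)^model$b[i, m]))
    }
    w[r] <- wr
  }
  wbar <- w / sum(w)
  f <- 0
  for (r in seq_len(R)) f <- f + wbar[r] * (sum(model$P[1:model$d, r] * x) + model$P[model$d + 1, r])
  f
}

# A tiny fully specified sub-model for forward/gradient tests.
toy_anfis <- function(d = 2, n_mf = 2, seed = 1) {
  set.seed(seed)
  m <- cellafe:::anfis_init(d, n_mf)
  m$a <- matrix(runif(d * n_mf, 0.2, 0.6), d, n_mf)
  m$b <- matrix(runif(d * n_mf, 1, 3), d, n_mf)
  m$c <- matrix(runif(d * n_mf, 0, 1), d, n_mf)
  m$P <- matrix(rnorm((d + 1) * nrow(m$rules)), d + 1, nrow(m$rules))
  m
}

# Column-major linear index of a 0-based (x, y) seed in an nr-row matrix.
rc_to_idx_helper <- function(seed, nr) seed[["x"]] * nr + seed[["y"]] + 1
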