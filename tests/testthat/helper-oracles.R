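# Independent brute-force oracles used to check the package implementations.
# These deliberately use naive loops / set arithmetic, not the vectorized
# code paths under test.

# Median filter with edge replication, per-pixel sort-based.
naive_median_filter <- function(img, w) {
  h <- w %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - h):(i + h), 1), nr)
      cj <- pmin(pmax((j - h):(j + h), 1), nc)
      out[i, j] <- stats::median(img[ri, cj])
    }
  }
  out
}

# Unit offset matching the package's direction convention.
oracle_offset <- function(theta) {
  rad <- theta * pi / 180
  c(-round(sin(rad)), round(cos(rad)))
}

# Block mean via explicit accumulation (rows outer, cols inner).
oracle_block_mean <- function(img, r, c, N) {
  nb <- N %/% 2
  s <- 0
  for (di in -nb:nb) for (dj in -nb:nb) s <- s + img[r + di, c + dj]
  s / (N * N)
}

# Scalar ratio parameter from first principles.
oracle_ratio <- function(img, seed, theta, w, N) {
  h <- w %/% 2
  d <- oracle_offset(theta)
  cand <- seed + d
  vc <- img[cand[1], cand[2]]
  c1 <- oracle_block_mean(img, cand[1] + h * d[1], cand[2] + h * d[2], N)
  c2 <- oracle_block_mean(img, cand[1] - h * d[1], cand[2] - h * d[2], N)
  (c1 + c2 - 2 * vc) / (2 * vc)
}

# Naive per-pixel / per-direction maximal ratio field.
oracle_max_ratio_field <- function(img, w = 9, N = 3,
                                   directions = seq(0, 315, by = 45)) {
  h <- w %/% 2; nb <- N %/% 2
  m <- h + nb + 1
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in (m + 1):(nr - m)) {
    for (j in (m + 1):(nc - m)) {
      best <- 0
      for (theta in directions) {
        best <- max(best, abs(oracle_ratio(img, c(i, j), theta, w, N)))
      }
      out[i, j] <- best
    }
  }
  out
}

# Disk offsets: di^2 + dj^2 <= (radius + 0.5)^2, the package's disk rule.
disk_offsets <- function(radius) {
  g <- expand.grid(di = -radius:radius, dj = -radius:radius)
  g[g$di^2 + g$dj^2 <= (radius + 0.5)^2, ]
}

# Binary erosion/dilation/opening with background padding.
naive_erode <- function(mask, radius) {
  off <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      keep <- TRUE
      for (k in seq_len(nrow(off))) {
        r <- i + off$di[k]; c <- j + off$dj[k]
        if (r < 1 || r > nr || c < 1 || c > nc || mask[r, c] == 0L) {
          keep <- FALSE; break
        }
      }
      if (keep) out[i, j] <- 1L
    }
  }
  out
}

naive_dilate <- function(mask, radius) {
  off <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask == 1L, arr.ind = TRUE)
  for (n in seq_len(nrow(idx))) {
    for (k in seq_len(nrow(off))) {
      r <- idx[n, 1] + off$di[k]; c <- idx[n, 2] + off$dj[k]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc) out[r, c] <- 1L
    }
  }
  out
}

naive_opening <- function(mask, radius) naive_dilate(naive_erode(mask, radius), radius)

# Queue-based flood fill labeling.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask == 1L)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nbrs))) {
        r <- pr + nbrs[k, 1]; c <- pc + nbrs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
          q <- (c - 1L) * nr + r
          if (mask[q] == 1L && labels[q] == 0L) {
            labels[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

# Per-pixel confusion counting.
naive_confusion <- function(pred, ref) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1L && ref[i, j] == 1L) tp <- tp + 1L
      else if (pred[i, j] == 0L && ref[i, j] == 0L) tn <- tn + 1L
      else if (pred[i, j] == 1L) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# All-pairs symmetric surface distances.
naive_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] == 1L) {
        bg <- (i == 1 || mask[i - 1, j] == 0L) ||
          (i == nr || mask[i + 1, j] == 0L) ||
          (j == 1 || mask[i, j - 1] == 0L) ||
          (j == nc || mask[i, j + 1] == 0L)
        if (bg) out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

naive_surface_metrics <- function(pred, ref, spacing = c(1, 1)) {
  bp <- naive_border(pred); br <- naive_border(ref)
  dist_set <- function(a, b) {
    apply(a, 1, function(p) {
      min(sqrt(((p[1] - b[, 1]) * spacing[1])^2 +
                 ((p[2] - b[, 2]) * spacing[2])^2))
    })
  }
  pooled <- c(dist_set(bp, br), dist_set(br, bp))
  list(asd = mean(pooled), rmsd = sqrt(mean(pooled^2)), msd = max(pooled))
}

# Small phantom used across tests where full-size runs are unnecessary.
small_phantom_spec <- function(...) {
  phantom_spec(...)
}

# A random blob mask for metric property tests.
random_blob <- function(n, seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * n), n, n)
  g <- EBImage::gblur(x, sigma = 3)
  m <- matrix(as.integer(g > stats::quantile(g, 0.7)), n, n)
  if (sum(m) == 0) m[n %/% 2, n %/% 2] <- 1L
  m
}
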