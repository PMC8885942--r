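# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops, BFS queues, exhaustive
# sorts.

# Digital disk mask: pixel centers within radius r of (cy, cx).
digital_disk <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# Clamped-border (edge-replicated) min/max filtering, one pixel at a time.
bf_filter <- function(img, offsets, maximum) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  f <- if (maximum) max else min
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- pmin(pmax(i + offsets[, 1], 1L), H)
    jj <- pmin(pmax(j + offsets[, 2], 1L), W)
    out[i, j] <- f(img[cbind(ii, jj)])
  }
  out
}

bf_close <- function(img, offsets) {
  bf_filter(bf_filter(img, offsets, TRUE), offsets, FALSE)
}

# BFS connected-component labeling, components numbered in raster scan order.
bfs_label <- function(mask, conn = 8) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (conn == 8) offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lab <- matrix(0L, H, W); nl <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nl <- nl + 1L
      queue <- list(c(i, j)); lab[i, j] <- nl
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
          if (r >= 1 && r <= H && cc >= 1 && cc <= W &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- nl
            queue <- c(queue, list(c(r, cc)))
          }
        }
      }
    }
  }
  lab
}

# Enclosed-background (hole) pixel count by 4-connected BFS from the border.
bf_hole_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  seen <- matrix(FALSE, H, W)
  queue <- list()
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if ((i == 1 || i == H || j == 1 || j == W) && bg[i, j] && !seen[i, j]) {
      seen[i, j] <- TRUE; queue <- c(queue, list(c(i, j)))
    }
  }
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in 1:4) {
      r <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
      if (r >= 1 && r <= H && cc >= 1 && cc <= W && bg[r, cc] && !seen[r, cc]) {
        seen[r, cc] <- TRUE
        queue <- c(queue, list(c(r, cc)))
      }
    }
  }
  sum(bg & !seen)
}

# Exhaustive-sort KNN prediction: all distances, stable ascending-index tie
# order, simple majority, 50/50 decided by the nearest neighbor.
bf_knn_predict <- function(train, labels, x, k) {
  d <- apply(train, 1, function(r) sqrt(sum((r - x)^2)))
  ord <- sort.int(d, index.return = TRUE)$ix  # sort.int radix sort is stable
  nb <- ord[seq_len(k)]
  v1 <- sum(labels[nb] == 1L)
  if (2L * v1 > k) 1L else if (2L * v1 < k) 0L else labels[nb[1L]]
}

# Independent leave-one-out grid search (scaler fitted once on all rows).
bf_loo_select <- function(X, labels, grid) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  n <- nrow(Xs)
  acc <- sapply(grid, function(k) {
    mean(sapply(seq_len(n), function(i) {
      bf_knn_predict(Xs[-i, , drop = FALSE], labels[-i], Xs[i, ], k) == labels[i]
    }))
  })
  list(k = grid[which.max(acc)], accuracy = acc)
}

# Random single-blob mask (union of overlapping digital disks) with optional
# small interior holes carved out; the blob stays 8-connected.
random_blob_mask <- function(seed, H = 30, W = 30, carve_holes = TRUE) {
  set.seed(seed)
  cy <- sample(10:(H - 10), 1); cx <- sample(10:(W - 10), 1)
  m <- digital_disk(H, W, cy, cx, sample(4:7, 1))
  for (b in seq_len(sample(2:4, 1))) {
    idx <- which(m, arr.ind = TRUE)
    p <- idx[sample(nrow(idx), 1), ]
    r <- sample(2:5, 1)
    m <- m | digital_disk(H, W, p[1], p[2], r)
  }
  m[c(1, H), ] <- FALSE; m[, c(1, W)] <- FALSE
  if (carve_holes) {
    # interior pixels whose full 8-neighborhood is foreground
    for (h in seq_len(sample(0:2, 1))) {
      interior <- m
      for (dy in -1:1) for (dx in -1:1) {
        shifted <- matrix(FALSE, H, W)
        ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
        ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
        shifted[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
        interior <- interior & shifted
      }
      idx <- which(interior, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        p <- idx[sample(nrow(idx), 1), ]
        m[p[1], p[2]] <- FALSE
      }
    }
  }
  m
}

mad_diff <- function(a, b) mean(abs(as.numeric(a) - as.numeric(b)))

# Rotate a matrix by 90 degrees (counter-clockwise).
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
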