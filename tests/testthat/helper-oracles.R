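# Independent oracles, written straight from definitions (loops, no shared
# code with the implementation paths they check).

# Is the foreground a single 6-connected component? Breadth-first flood fill.
flood_fill_connected <- function(mask) {
  lab <- mask$labels
  idx <- which(lab != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  d <- dim(lab)
  seen <- array(FALSE, d)
  queue <- matrix(idx[1, ], 1)
  seen[queue] <- TRUE
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0) {
    v <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (k in 1:6) {
      w <- v + nb[k, , drop = FALSE]
      if (any(w < 1) || any(w > d)) next
      if (lab[w] != 0 && !seen[w]) {
        seen[w] <- TRUE
        queue <- rbind(queue, w)
      }
    }
  }
  sum(seen) == nrow(idx)
}

# Brute-force nearest-feature distance with anisotropic spacing.
edt_oracle <- function(mask, spacing = mask$spacing) {
  idx <- which(mask$labels != 0, arr.ind = TRUE)
  d <- dim(mask$labels)
  out <- array(Inf, d)
  if (nrow(idx) == 0) return(out)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    dd <- sweep(idx, 2, all_idx[r, ], `-`)
    dd <- sweep(dd, 2, spacing, `*`)
    out[r] <- sqrt(min(rowSums(dd^2)))
  }
  out
}

# STAPLE EM straight from the update equations: per-voxel loops, explicit
# products, no log-space tricks. D is n x J of 0/1; returns one entry per
# iteration with the E-step weights and M-step (p, q).
staple_oracle <- function(D, gamma, n_iter, p0 = 0.9999, q0 = 0.9999) {
  n <- nrow(D); J <- ncol(D)
  clamp <- function(x) pmin(pmax(x, 1e-10), 1 - 1e-10)
  p <- rep(p0, J); q <- rep(q0, J)
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    pc <- clamp(p); qc <- clamp(q)
    W <- numeric(n)
    for (i in seq_len(n)) {
      a <- gamma
      b <- 1 - gamma
      for (j in seq_len(J)) {
        if (D[i, j] == 1) {
          a <- a * pc[j]
          b <- b * (1 - qc[j])
        } else {
          a <- a * (1 - pc[j])
          b <- b * qc[j]
        }
      }
      W[i] <- a / (a + b)
    }
    p_new <- numeric(J); q_new <- numeric(J)
    for (j in seq_len(J)) {
      p_new[j] <- sum(W * D[, j]) / sum(W)
      q_new[j] <- sum((1 - W) * (1 - D[, j])) / sum(1 - W)
    }
    out[[it]] <- list(W = W, p = p_new, q = q_new)
    p <- p_new; q <- q_new
  }
  out
}

# Exposed in-plane boundary edges of one 2D slice, by explicit neighbour
# loops: list of (y_mm, x_mm, len_mm) for edge midpoints.
slice_edges_oracle <- function(L, sy, sx) {
  d <- dim(L)
  out <- NULL
  for (j in seq_len(d[1]))
    for (i in seq_len(d[2])) {
      if (L[j, i] == 0) next
      at <- function(jj, ii) {
        if (jj < 1 || jj > d[1] || ii < 1 || ii > d[2]) 0 else L[jj, ii]
      }
      if (at(j, i + 1) == 0)
        out <- rbind(out, c((j - 1) * sy, (i - 0.5) * sx, sy))
      if (at(j, i - 1) == 0)
        out <- rbind(out, c((j - 1) * sy, (i - 1.5) * sx, sy))
      if (at(j + 1, i) == 0)
        out <- rbind(out, c((j - 0.5) * sy, (i - 1) * sx, sx))
      if (at(j - 1, i) == 0)
        out <- rbind(out, c((j - 1.5) * sy, (i - 1) * sx, sx))
    }
  colnames(out) <- c("y_mm", "x_mm", "len_mm")
  out
}

# Added path length by exhaustive pairwise distances between per-slice edge
# midpoints.
apl_oracle <- function(reference, test, tolerance_mm) {
  sy <- reference$spacing[2]; sx <- reference$spacing[3]
  apl <- 0
  for (k in seq_len(dim(reference$labels)[1])) {
    re <- slice_edges_oracle(reference$labels[k, , ], sy, sx)
    if (is.null(re)) next
    te <- slice_edges_oracle(test$labels[k, , ], sy, sx)
    for (r in seq_len(nrow(re))) {
      if (is.null(te)) {
        apl <- apl + unname(re[r, "len_mm"])
        next
      }
      dmin <- Inf
      for (t in seq_len(nrow(te)))
        dmin <- min(dmin, sqrt((re[r, 1] - te[t, 1])^2 +
                                 (re[r, 2] - te[t, 2])^2))
      if (dmin > tolerance_mm) apl <- apl + re[r, "len_mm"]
    }
  }
  unname(apl)
}

# Linear-interpolation percentile of a vector, written out by hand.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive sign-assignment enumeration for the one-sided/two-sided paired
# Wilcoxon signed-rank p-value (no ties assumed).
wilcoxon_enum_oracle <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% rk
  switch(alternative,
         greater = mean(w_all >= w_obs),
         less = mean(w_all <= w_obs),
         two_sided = min(1, 2 * min(mean(w_all >= w_obs),
                                    mean(w_all <= w_obs))))
}
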