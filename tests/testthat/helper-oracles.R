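# Independent brute-force reference implementations used to validate the
# package's operators. Deliberately naive: direct kernel enumeration, exhaustive
# threshold search, queue-based flood fill. Never call package internals.

oracle_disc_filter <- function(x, r, stat) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ii <- pmin(pmax(i + offs$dr, 1), H)
      jj <- pmin(pmax(j + offs$dc, 1), W)
      out[i, j] <- stat(x[cbind(ii, jj)])
    }
  }
  out
}

# exhaustive search over all 8-bit histogram bins; returns the foreground mask
oracle_ptile_mask <- function(x) {
  v <- as.vector(x)
  fs <- vapply(0:255, function(t) mean(v <= t), numeric(1))
  t <- (0:255)[which.min(abs(fs - 0.5))]
  x > t
}

# queue-based flood fill labelling
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] && lab[r2, c2] == 0) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# per-component moments computed independently with plain loops
oracle_roundness <- function(mask) {
  lab <- oracle_label(mask, 8)
  vapply(seq_len(max(lab)), function(l) {
    pts <- which(lab == l, arr.ind = TRUE)
    n <- nrow(pts)
    mr <- mean(pts[, 1]); mc <- mean(pts[, 2])
    mu20 <- mean((pts[, 1] - mr)^2)
    mu02 <- mean((pts[, 2] - mc)^2)
    mu11 <- mean((pts[, 1] - mr) * (pts[, 2] - mc))
    lam <- (mu20 + mu02 + sqrt((mu20 - mu02)^2 + 4 * mu11^2)) / 2
    major <- 4 * sqrt(lam)
    if (major > 0) min(1, 4 * n / (pi * major^2)) else 1
  }, numeric(1))
}

disc_mask <- function(H, W, cr, cc, radius) {
  rr <- matrix(seq_len(H), H, W)
  cc2 <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - cr)^2 + (cc2 - cc)^2 <= radius^2
}

ellipse_mask <- function(H, W, cr, cc, a, b) {
  rr <- matrix(seq_len(H), H, W)
  cc2 <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rr - cr) / a)^2 + ((cc2 - cc) / b)^2 <= 1
}
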