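# Shared fixtures and independent oracles, built in code at test time.

# blank logical canvas
blank <- function(rows, cols) matrix(FALSE, rows, cols)

# rasterize a 1-px-wide segment with Bresenham; returns mask with TRUE line
bresenham_line <- function(mask, r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  repeat {
    mask[r, c] <- TRUE
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  mask
}

# independent connected-component oracle: BFS flood fill, 8-connectivity
label8_oracle <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask)
  for (i in idx) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue) > 0L) {
      j <- queue[[1L]]; queue <- queue[-1L]
      r <- ((j - 1L) %% nrow(mask)) + 1L
      c <- ((j - 1L) %/% nrow(mask)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nrow(mask) || cc < 1L || cc > ncol(mask)) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, (cc - 1L) * nrow(mask) + rr)
        }
      }
    }
  }
  lab
}

# exhaustive pair-count oracle: enumerate all unordered 8-adjacent pairs
count_pairs_oracle <- function(px) {
  coords <- which(px, arr.ind = TRUE)
  N_o <- 0L; N_d <- 0L
  n <- nrow(coords)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      dr <- abs(coords[i, 1L] - coords[j, 1L])
      dc <- abs(coords[i, 2L] - coords[j, 2L])
      if (max(dr, dc) == 1L) {
        if (dr + dc == 1L) N_o <- N_o + 1L else N_d <- N_d + 1L
      }
    }
  }
  list(N_o = N_o, N_d = N_d)
}

# per-row run-count oracle via explicit rle
row_runs_oracle <- function(mask) {
  apply(mask, 1L, function(row) {
    r <- rle(row)
    sum(r$values)
  })
}

# tie-corrected Kruskal-Wallis H via explicit ranks (independent of
# stats::kruskal.test)
kw_H_oracle <- function(y, g) {
  r <- rank(y); n <- length(y)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(y)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / C
}

# R^2 of y ~ design factors, by direct projection (independent of lm)
r2_oracle <- function(y, X) {
  X <- cbind(1, X)
  qr_ <- qr(X)
  fitted <- qr.fitted(qr_, y)
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

# model matrix (dummy coding, drop first level) for marker factor columns
marker_design <- function(dat, cols) {
  if (length(cols) == 0L) return(matrix(nrow = nrow(dat), ncol = 0L))
  do.call(cbind, lapply(cols, function(cl) {
    f <- factor(dat[[cl]])
    stats::model.matrix(~f)[, -1L, drop = FALSE]
  }))
}
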