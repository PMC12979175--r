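# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals: flood-fill
# labeling by explicit BFS, all-pairs surface distances, direct formulas.

# BFS flood fill with 26-connectivity; labels in first-voxel scan order.
oracle_label_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] == 0 || lab[i, j, k] != 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j, k), 1)
    lab[i, j, k] <- nxt
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(nbrs))) {
        u <- v + nbrs[r, ]
        if (any(u < 1) || any(u > d)) next
        if (mask[u[1], u[2], u[3]] != 0 && lab[u[1], u[2], u[3]] == 0) {
          lab[u[1], u[2], u[3]] <- nxt
          queue <- rbind(queue, u)
        }
      }
    }
  }
  lab
}

oracle_dice <- function(r, p) {
  if (sum(r) + sum(p) == 0) return(1)
  2 * sum(r & p) / (sum(r) + sum(p))
}

oracle_ppv <- function(r, p) {
  if (sum(p) == 0) return(if (sum(r) == 0) 1 else NaN)
  sum(r & p) / sum(p)
}

oracle_object_dice <- function(r, p) {
  R <- oracle_label_26(r); P <- oracle_label_26(p)
  nR <- max(R); nP <- max(P)
  if (nR == 0 && nP == 0) return(1)
  if (nR == 0 || nP == 0) return(0)
  side <- function(A, B, nA, nB) {
    tot <- sum(A > 0)
    s <- 0
    for (i in seq_len(nA)) {
      ai <- A == i
      best_ov <- 0; best_j <- 0
      for (j in seq_len(nB)) {
        ov <- sum(ai & B == j)
        if (ov > best_ov) { best_ov <- ov; best_j <- j }
      }
      di <- if (best_j == 0) 0 else
        2 * best_ov / (sum(ai) + sum(B == best_j))
      s <- s + sum(ai) / tot * di
    }
    s
  }
  0.5 * (side(R, P, nR, nP) + side(P, R, nP, nR))
}

oracle_object_rates <- function(r, p) {
  R <- oracle_label_26(r); P <- oracle_label_26(p)
  nR <- max(R); nP <- max(P)
  otpr <- if (nR == 0) NaN else
    mean(vapply(seq_len(nR), function(i) any(p[R == i] > 0), logical(1)))
  ofpr <- if (nP == 0) NaN else
    mean(vapply(seq_len(nP), function(j) !any(r[P == j] > 0), logical(1)))
  list(otpr = otpr, ofpr = ofpr)
}

oracle_surface <- function(m) {
  d <- dim(m)
  s <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (m[i, j, k] == 0) next
    bg <- FALSE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      u <- c(i, j, k) + off
      if (any(u < 1) || any(u > d) || m[u[1], u[2], u[3]] == 0) bg <- TRUE
    }
    s[i, j, k] <- bg
  }
  s
}

oracle_assd <- function(r, p, spacing = c(1, 1, 1)) {
  sr <- which(oracle_surface(r), arr.ind = TRUE)
  sp <- which(oracle_surface(p), arr.ind = TRUE)
  scale_rows <- function(m) sweep(m, 2, spacing, `*`)
  a <- scale_rows(sr); b <- scale_rows(sp)
  mind <- function(x, ys) min(sqrt(rowSums(sweep(ys, 2, x, `-`)^2)))
  da <- vapply(seq_len(nrow(a)), function(i) mind(a[i, ], b), numeric(1))
  db <- vapply(seq_len(nrow(b)), function(i) mind(b[i, ], a), numeric(1))
  (sum(da) + sum(db)) / (nrow(a) + nrow(b))
}

oracle_soft_dice <- function(g, p, eps = 1e-6) {
  1 - (2 * sum(p * g) + 2 * eps) / (sum(p) + sum(g) + 2 * eps)
}

rand_mask <- function(dims, prob = 0.2) {
  array(as.integer(runif(prod(dims)) < prob), dims)
}
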