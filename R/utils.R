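# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic package code routes through this
# so results are reproducible per seed without disturbing the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a 3D array by integer offsets, zero-filling exposed voxels.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]
      src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o)
      src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

# Offsets (as an integer matrix, one row per voxel) of a sphere of the given
# radius in voxels, i.e. all integer displacements with ||d|| <= radius.
sphere_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# Binary dilation of a 3D 0/1 array by a set of offsets.
dilate_mask <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  m <- mask > 0
  for (i in seq_len(nrow(offsets))) {
    out <- out | (shift_array(m, offsets[i, ]) > 0)
  }
  storage.mode(out) <- "integer"
  out
}

# Separable Gaussian blur of a 3D array; sigma in voxels (scalar or length 3).
gaussian_blur3 <- function(a, sigma) {
  sigma <- rep(as.numeric(sigma), length.out = 3L)
  cpp_gaussian_blur(as.numeric(a), dim(a), sigma)
}

stop_wml <- function(...) stop(sprintf(...), call. = FALSE)

assert_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop_wml("%s are on different grids: %s vs %s", what,
             paste(dim(vol_data(a)), collapse = "x"),
             paste(dim(vol_data(b)), collapse = "x"))
  invisible(TRUE)
}
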