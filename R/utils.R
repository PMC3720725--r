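# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators do not
#' perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-item seed derivation, kept below 2^31
derive_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 7919) %% 2147483647L)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Sigma is given per axis in voxel units; the kernel is truncated at
#' 3 sigma and renormalized. Implemented as three passes of stats::filter
#' (C-level moving filter) on zero-padded data, so edges behave as if the
#' array were embedded in zeros.
#' @noRd
gauss_blur3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    a <- filter_axis(a, k, ax)
  }
  a
}

# apply a symmetric FIR kernel along one axis of a 3D array
filter_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  b <- aperm(a, perm)
  db <- dim(b)
  r <- (length(k) - 1L) / 2L
  m <- matrix(0, db[1] + 2L * r, db[2] * db[3])
  m[(r + 1L):(r + db[1]), ] <- b
  f <- stats::filter(m, k, method = "convolution", sides = 2L)
  f <- matrix(as.numeric(f), nrow(m), ncol(m))  # drop costly ts attributes
  f <- f[(r + 1L):(r + db[1]), , drop = FALSE]
  dim(f) <- db
  aperm(f, order(perm))
}

# linear index array <-> (z,y,x) helpers are avoided; slicing is used instead
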