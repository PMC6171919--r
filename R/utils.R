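# Internal helpers: hierarchical seed splitting, smooth random fields,
# signed distance transforms.

# Deterministic child seed from a master seed and a key path. Polynomial
# string hash modulo the Mersenne prime 2^31 - 1 keeps results inside R's
# 32-bit integer range and independent across keys.
childSeed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  key <- paste(c(...), collapse = "/")
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(max(1, h))
}

# Smooth standardized Gaussian random field on a voxel grid: white noise
# convolved with a Gaussian of physical correlation length corrMm, rescaled
# to unit SD. Deterministic given seed. The field is generated on a grid
# coarsened to ~corrMm/2 sampling and linearly upsampled: well above the
# Nyquist rate of a field this smooth, at a fraction of the convolution
# cost.
smoothNoiseField <- function(dim, spacing, corrMm, seed) {
  dim <- as.integer(dim)
  fac <- pmax(1L, as.integer(floor(corrMm / (2 * spacing))))
  cd <- as.integer(ceiling((dim - 1L) / fac) + 1L)
  noise <- withr::with_seed(seed, rnorm(prod(cd)))
  f <- array(cpp_gauss_smooth(noise, cd, corrMm / (spacing * fac)), cd)
  for (ax in 1:3) if (fac[ax] > 1L) f <- upsampleAxis(f, fac[ax], ax)
  f <- f[seq_len(dim[1]), seq_len(dim[2]), seq_len(dim[3]), drop = FALSE]
  s <- stats::sd(f)
  if (s == 0) s <- 1
  array((f - mean(f)) / s, dim = dim)
}

# Linear upsampling of a 3D array by an integer factor along one axis.
upsampleAxis <- function(f, fac, axis) {
  if (axis == 3L) return(upsampleAlongZ(f, fac))
  perm <- if (axis == 1L) c(2L, 3L, 1L) else c(1L, 3L, 2L)
  inv <- order(perm)
  aperm(upsampleAlongZ(aperm(f, perm), fac), inv)
}

# Signed Euclidean distance (mm) from every voxel center to the mask
# interface, negative inside, positive outside; (sdt <= 0) reproduces the
# mask exactly. The interface is represented by the midpoints of all
# face-adjacent inside/outside voxel pairs; those midpoints are exact grid
# points of a 2x upsampled lattice, where one distance transform gives
# sub-voxel surface distances (accurate to ~half a voxel, far better than
# center-to-center distances which carry a systematic half-voxel gap).
signedDistance <- function(mask, spacing) {
  dm <- dim(mask)
  sp <- as.numeric(spacing)
  fd <- 2L * dm - 1L
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  ox <- seq(1L, fd[1], 2L); oy <- seq(1L, fd[2], 2L); oz <- seq(1L, fd[3], 2L)
  F <- array(FALSE, fd)
  if (nx > 1L)
    F[seq(2L, fd[1] - 1L, 2L), oy, oz] <-
      mask[-1, , , drop = FALSE] != mask[-nx, , , drop = FALSE]
  if (ny > 1L)
    F[ox, seq(2L, fd[2] - 1L, 2L), oz] <-
      F[ox, seq(2L, fd[2] - 1L, 2L), oz] |
      (mask[, -1, , drop = FALSE] != mask[, -ny, , drop = FALSE])
  if (nz > 1L)
    F[ox, oy, seq(2L, fd[3] - 1L, 2L)] <-
      F[ox, oy, seq(2L, fd[3] - 1L, 2L)] |
      (mask[, , -1, drop = FALSE] != mask[, , -nz, drop = FALSE])
  d <- sqrt(cpp_edt_sq(as.logical(F), as.integer(fd), sp / 2))
  d <- array(d, fd)[ox, oy, oz]
  array(ifelse(mask, -d, d), dim = dm)
}

# Keep only the largest 6-connected component of a mask.
largestComponent <- function(mask) {
  array(cpp_largest_component(as.logical(mask), as.integer(dim(mask))),
        dim = dim(mask))
}

# Physical coordinates (mm) of TRUE voxels, voxel-center convention.
voxelCoords <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

stopIfNot3dMask <- function(mask, what = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
}

# Provenance columns every feature table carries, in order.
PROVENANCE_COLS <- c("patient_id", "arm", "tool_id", "observer_id", "run")

featureColumns <- function(table) {
  setdiff(colnames(table), PROVENANCE_COLS)
}
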