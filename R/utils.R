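# Internal helpers shared across modules.

# Evaluate expr under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.  Keeps builds and fixtures reproducible
# without clobbering the user's random stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Minimum-image displacement for a displacement matrix (n x 3) in an
# orthorhombic box.
minImage <- function(d, box) {
  d <- as.matrix(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

rowNorms <- function(m) sqrt(rowSums(m * m))

normalizeRows <- function(m) m / rowNorms(m)

# Near-uniform points on the unit sphere: golden-spiral (Fibonacci)
# lattice.  Deterministic for a given n; rotate with a random rotation
# for seed-controlled variation.
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- i * ga
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Uniform random rotation matrix from the current RNG state (random
# unit quaternion).
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Angles (degrees) between row vectors of two matrices.
rowAngles <- function(v1, v2) {
  n1 <- rowNorms(v1); n2 <- rowNorms(v2)
  if (any(n1 == 0) || any(n2 == 0))
    stop("singular geometry: zero-length bond vector")
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Resolve a bead selection against a bead table.  Accepts NULL (all
# beads), a character vector matched against group labels and species
# names, a logical mask, or integer bead indices.
resolveSelection <- function(beads, selection) {
  n <- nrow(beads)
  if (is.null(selection)) return(seq_len(n))
  if (is.character(selection)) {
    hit <- beads$group %in% selection | beads$species %in% selection
    idx <- which(hit)
  } else if (is.logical(selection)) {
    if (length(selection) != n) stop("logical selection must have one entry per bead")
    idx <- which(selection)
  } else if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > n)) stop("bead indices out of range")
  } else stop("unsupported selection type")
  if (!length(idx)) stop("selection matches no beads")
  idx
}

# Split selected bead indices into molecules (list of integer vectors,
# in molecule order).
moleculeBeadList <- function(beads, idx) {
  split(idx, factor(beads$molId[idx], levels = unique(beads$molId[idx])))
}

# Resolve a frame specification: "all", "last10" (final 10% of frames,
# at least one) or an integer vector.
resolveFrames <- function(nf, frames) {
  if (is.character(frames)) {
    frames <- match.arg(frames, c("all", "last10"))
    if (frames == "all") return(seq_len(nf))
    k <- max(1L, ceiling(0.1 * nf))
    return(seq.int(nf - k + 1L, nf))
  }
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > nf)) stop("frame indices out of range")
  frames
}

# Coerce a single structure to a one-frame trajectory so frame-wise
# analyses accept both.
asTrajectory <- function(x) {
  if (is(x, "TrajectorySlice")) return(x)
  if (is(x, "ParticleSystem")) {
    arr <- array(x@coords, dim = c(nrow(x@coords), 3L, 1L))
    return(new("ArrayTrajectory", coords = arr, times = 0,
               box = matrix(x@box, nrow = 1), beads = x@beads))
  }
  stop("expected a ParticleSystem or TrajectorySlice")
}
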