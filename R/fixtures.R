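# Ground-truth-known synthetic inputs: Brownian random walks with a
# known diffusion coefficient, Boltzmann-sampled lipid conformers with
# a known angle distribution, and punched-hole vesicles with known pore
# geometry.  All fixtures are bit-reproducible from their seed and can
# be emitted through the regular file writers.

#' Brownian random-walk trajectory
#'
#' Independent per-axis Gaussian increments of variance `sigma2` per
#' frame, so the true 3-D diffusion coefficient is
#' `D = sigma2 / (2 dt)` and the expected MSD at lag `k dt` is
#' `3 k sigma2`.
#'
#' @param n number of particles.
#' @param frames number of frames.
#' @param sigma2 per-axis step variance, nm^2 (0 gives a static
#'   trajectory).
#' @param dt frame spacing, ps.
#' @param seed integer seed.
#' @return an [ArrayTrajectory-class] of single-bead molecules.
#' @export
randomWalkTrajectory <- function(n, frames, sigma2, dt, seed) {
  if (n <= 0 || frames <= 0) stop("n and frames must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  steps <- withSeed(seed, array(rnorm(n * 3 * frames, sd = sqrt(sigma2)),
                                dim = c(n, 3, frames)))
  steps[, , 1] <- 0
  pos <- if (frames == 1L) steps
         else aperm(apply(steps, c(1, 2), cumsum), c(2, 3, 1))
  # shift into a box comfortably larger than the walk's extent, so
  # minimum-image distances never wrap
  span <- max(1, max(abs(pos)))
  box <- 4 * span
  pos <- pos + box / 2
  beads <- data.frame(index = seq_len(n), molId = seq_len(n),
                      species = "RW", beadName = "RW",
                      group = NA_character_, leaflet = NA_character_)
  traj <- new("ArrayTrajectory", coords = pos,
              times = (seq_len(frames) - 1) * dt,
              box = matrix(box, frames, 3), beads = beads)
  validObject(traj)
  traj
}

# Rejection sampler for the cosine-harmonic bending angle with the
# sin(theta) Jacobian; vectorised, exact.
sampleAngles <- function(nSamples, theta0, kAngle, temperature) {
  grid <- seq(1e-4, pi - 1e-4, length.out = 2048)
  M <- max(angleDensity(grid, theta0, kAngle, temperature)) * 1.05
  out <- numeric(0)
  tried <- 0
  while (length(out) < nSamples) {
    m <- max(1024L, 2L * (nSamples - length(out)))
    th <- runif(m, 0, pi)
    keep <- runif(m, 0, M) < angleDensity(th, theta0, kAngle, temperature)
    out <- c(out, th[keep])
    tried <- tried + m
    if (tried >= 2e4 && length(out) / tried < 1e-3)
      stop("sampler failure: rejection acceptance below 1e-3")
  }
  out[seq_len(nSamples)]
}

# Place bead positions one bond at a time from internal coordinates:
# new = parent + r * (-cos(theta) u + sin(theta) (cos(phi) p + sin(phi) q)),
# where u is the grand->parent unit vector and (p, q) span its normal
# plane.  Vectorised across conformers.
extendChain <- function(grand, parent, r, theta, phi) {
  u <- normalizeRows(parent - grand)
  ref <- matrix(rep(c(0, 0, 1), each = nrow(u)), ncol = 3)
  flip <- abs(u[, 3]) > 0.99
  ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
  p <- normalizeRows(cbind(
    u[, 2] * ref[, 3] - u[, 3] * ref[, 2],
    u[, 3] * ref[, 1] - u[, 1] * ref[, 3],
    u[, 1] * ref[, 2] - u[, 2] * ref[, 1]))
  q <- cbind(
    u[, 2] * p[, 3] - u[, 3] * p[, 2],
    u[, 3] * p[, 1] - u[, 1] * p[, 3],
    u[, 1] * p[, 2] - u[, 2] * p[, 1])
  parent + r * (-cos(theta) * u +
                sin(theta) * (cos(phi) * p + sin(phi) * q))
}

#' Boltzmann-sampled lipid conformers
#'
#' Independent conformers of one lipid template: bond lengths fixed at
#' `b0`, every bending angle drawn from its cosine-harmonic Boltzmann
#' density (with the sin-theta Jacobian) by rejection sampling, and
#' free uniform dihedrals.  Because the tails of unsaturated species
#' carry a 120-degree kink angle, their sampled tail angles have a low
#' mean while saturated tails stay near straight.
#'
#' @param template a [LipidTemplate-class].
#' @param temperature in K.
#' @param n number of conformers.
#' @param seed integer seed.
#' @return an [ArrayTrajectory-class]: one 12-bead molecule, one frame
#'   per conformer (frame times index the conformers).
#' @export
boltzmannChainSamples <- function(template, temperature, n, seed) {
  if (temperature <= 0) stop("temperature must be positive")
  if (n <= 0) stop("n must be positive")
  validObject(template)
  bonds <- template@bonds
  angles <- template@angles
  b0 <- function(i, j) {
    hit <- (bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i)
    if (!any(hit)) stop("template lacks bond ", i, "-", j)
    bonds$b0[which(hit)[1]]
  }
  angleFor <- function(i, j, k) {
    hit <- (angles$i == i & angles$j == j & angles$k == k) |
           (angles$i == k & angles$j == j & angles$k == i)
    if (!any(hit)) return(NULL)
    angles[which(hit)[1], ]
  }
  pos <- withSeed(seed, {
    pos <- array(0, dim = c(12, 3, n))
    pos[2, 3, ] <- b0(1, 2)
    # build order: (grandparent, parent, new bead)
    buildSteps <- list(c(1, 2, 3), c(2, 3, 5), c(3, 5, 6), c(5, 6, 7),
                       c(6, 7, 8), c(2, 3, 4), c(3, 4, 9), c(4, 9, 10),
                       c(9, 10, 11), c(10, 11, 12))
    for (st in buildSteps) {
      g <- st[1]; p <- st[2]; w <- st[3]
      a <- angleFor(g, p, w)
      th <- if (is.null(a)) acos(runif(n, -1, 1))
            else sampleAngles(n, a$theta0, a$kAngle, temperature)
      phi <- runif(n, 0, 2 * pi)
      pos[w, , ] <- t(extendChain(t(pos[g, , , drop = TRUE]),
                                  t(pos[p, , , drop = TRUE]),
                                  b0(p, w), th, phi))
    }
    pos
  })
  # centre each conformer in a box large enough that min-image is inert
  box <- 25
  for (f in seq_len(n))
    pos[, , f] <- sweep(pos[, , f], 2, colMeans(pos[, , f])) + box / 2
  beads <- data.frame(index = 1:12, molId = 1L,
                      species = template@name,
                      beadName = template@beads$name,
                      group = "BILAYER", leaflet = NA_character_)
  traj <- new("ArrayTrajectory", coords = pos, times = seq_len(n) - 1,
              box = matrix(box, n, 3), beads = beads)
  validObject(traj)
  traj
}

#' Punch a conical hole through a vesicle
#'
#' Removes every lipid molecule whose head-bead direction (from the
#' lipid centre of geometry of the selection) lies within the cone of
#' the given half-angle about `direction`; water is untouched.  The
#' expected removal fraction is the spherical-cap area fraction
#' `(1 - cos(halfAngle)) / 2` per leaflet.  Ground truth for
#' [detectPores()].
#'
#' @param system a built [ParticleSystem-class].
#' @param direction length-3 cone axis (need not be normalised).
#' @param halfAngle cone half-angle in radians, in `[0, pi)`.
#' @return the system without the removed lipids; the number of removed
#'   molecules is recorded in `provenance$removedLipids`.
#' @export
punchHole <- function(system, direction, halfAngle) {
  if (halfAngle < 0 || halfAngle >= pi)
    stop("halfAngle must lie in [0, pi)")
  if (halfAngle == 0) return(system)
  b <- system@beads
  lipIdx <- which(b$group == "BILAYER")
  if (!length(lipIdx)) stop("system has no lipid (BILAYER) beads")
  centre <- colMeans(system@coords[lipIdx, , drop = FALSE])
  d <- direction / sqrt(sum(direction^2))
  mols <- moleculeBeadList(b, lipIdx)
  headIdx <- vapply(mols, `[`, integer(1), 1L)
  hv <- sweep(system@coords[headIdx, , drop = FALSE], 2, centre)
  cosang <- (hv %*% d) / rowNorms(hv)
  remove <- as.integer(names(mols))[cosang >= cos(halfAngle)]
  keep <- !(b$molId %in% remove)
  beads <- b[keep, , drop = FALSE]
  beads$index <- seq_len(nrow(beads))
  rownames(beads) <- NULL
  out <- new("ParticleSystem", beads = beads,
             coords = system@coords[keep, , drop = FALSE],
             box = system@box,
             provenance = c(system@provenance,
                            list(removedLipids = length(remove),
                                 holeDirection = d, holeHalfAngle = halfAngle)))
  validObject(out)
  out
}
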