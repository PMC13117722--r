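# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately written with plain R loops and none of the package's
# kernels, so agreement is a genuine cross-check.

miniSpec <- function(seed = 42L, nWaterIn = 8L, nWaterOut = 200L, ...) {
  vesicleSpec(outerDiameter = 10, boxEdge = 16, seed = seed,
              nWaterIn = nWaterIn, nWaterOut = nWaterOut, ...)
}

# memoised heavy systems shared across test files
.cache <- new.env()
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}
miniVesicle <- function() cached("mini", buildVesicle(miniSpec()))
defaultBuild <- function() cached("default", buildVesicle(defaultVesicleSpec()))

minImg <- function(d, box) d - box * round(d / box)

# O(N^2) all-pairs shifted LJ + Coulomb between two bead index sets.
oracleEnergy <- function(coords, box, typeNames, charges, molIds,
                         idxA, idxB, params) {
  same <- setequal(idxA, idxB)
  lj <- 0; coul <- 0
  rc <- params@cutoff
  for (i in idxA) {
    for (j in idxB) {
      if (same && j <= i) next
      if (molIds[i] == molIds[j]) next
      d <- sqrt(sum(minImg(coords[i, ] - coords[j, ], box)^2))
      if (d > rc) next
      s <- params@sigma[typeNames[i], typeNames[j]]
      e <- params@epsilon[typeNames[i], typeNames[j]]
      v <- function(r) 4 * e * ((s / r)^12 - (s / r)^6)
      lj <- lj + v(d) - v(rc)
      qq <- charges[i] * charges[j]
      if (qq != 0)
        coul <- coul + 138.935 * qq / params@epsR * (1 / d - 1 / rc)
    }
  }
  list(lj = lj, coulomb = coul)
}

# Brute-force molecular RDF: loop over all molecule pairs and all bead
# pairs, histogram the minimum distances in 0.01 nm bins.
oracleMolRdf <- function(coords, box, beads, refSel, tarSel, rMax) {
  refMols <- split(refSel, beads$molId[refSel])
  tarMols <- split(tarSel, beads$molId[tarSel])
  nBins <- round(rMax / 0.01)
  counts <- numeric(nBins)
  for (rn in names(refMols)) {
    for (tn in names(tarMols)) {
      if (rn == tn) next
      best <- Inf
      for (i in refMols[[rn]]) for (j in tarMols[[tn]]) {
        d <- sqrt(sum(minImg(coords[i, ] - coords[j, ], box)^2))
        if (d < best) best <- d
      }
      k <- floor(best / 0.01 + 0.5)
      if (k >= 1 && k <= nBins) counts[k] <- counts[k] + 1
    }
  }
  counts / length(refMols)
}

# Leaflet assignment by radial rank of the phosphate beads: sort the
# radii and split at the largest gap.
oracleLeaflets <- function(system) {
  b <- beadData(system)
  lip <- which(b$group == "BILAYER")
  mols <- split(lip, b$molId[lip])
  centre <- colMeans(coords(system)[lip, , drop = FALSE])
  phosR <- vapply(mols, function(m)
    sqrt(sum((coords(system)[m[2], ] - centre)^2)), numeric(1))
  ord <- order(phosR)
  gap <- which.max(diff(phosR[ord]))
  lf <- rep("outer", length(mols))
  lf[ord[seq_len(gap)]] <- "inner"
  data.frame(molId = as.integer(names(mols)), leaflet = lf)
}

# Independent Boltzmann angle sampler: numerical inverse-CDF on a fine
# grid (no rejection), for cross-checking sampled angle means.
oracleSampleAngles <- function(n, theta0, kAngle, temperature) {
  th <- seq(1e-5, pi - 1e-5, length.out = 20000)
  dens <- exp(-0.5 * kAngle * (cos(th) - cos(theta0 * pi / 180))^2 /
                (0.0083144621 * temperature)) * sin(th)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  approx(cdf, th, runif(n), ties = "ordered")$y
}

# Independent straight-forward chain builder (sequential, Rodrigues
# rotations) for end-to-end cross-checks on one lipid template.
oracleChainEndToEnd <- function(template, temperature, n) {
  bonds <- template@bonds
  angles <- template@angles
  b0 <- function(i, j) {
    hit <- (bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i)
    bonds$b0[which(hit)[1]]
  }
  aFor <- function(i, j, k) {
    hit <- (angles$i == i & angles$j == j & angles$k == k) |
           (angles$i == k & angles$j == j & angles$k == i)
    if (!any(hit)) NULL else angles[which(hit)[1], ]
  }
  rotate <- function(v, axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    v * cos(ang) + pracma::cross(axis, v) * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang))
  }
  steps <- list(c(1, 2, 3), c(2, 3, 5), c(3, 5, 6), c(5, 6, 7), c(6, 7, 8),
                c(2, 3, 4), c(3, 4, 9), c(4, 9, 10), c(9, 10, 11),
                c(10, 11, 12))
  out <- numeric(n)
  for (s in seq_len(n)) {
    pos <- matrix(0, 12, 3)
    pos[2, ] <- c(0, 0, b0(1, 2))
    for (st in steps) {
      g <- st[1]; p <- st[2]; w <- st[3]
      a <- aFor(g, p, w)
      th <- if (is.null(a)) acos(runif(1, -1, 1))
            else oracleSampleAngles(1, a$theta0, a$kAngle, temperature)
      u <- pos[p, ] - pos[g, ]
      u <- u / sqrt(sum(u^2))
      perp <- if (abs(u[3]) < 0.9) pracma::cross(u, c(0, 0, 1))
              else pracma::cross(u, c(1, 0, 0))
      perp <- perp / sqrt(sum(perp^2))
      dir <- rotate(u, perp, pi - th)            # bend away from u
      dir <- rotate(dir, u, runif(1, 0, 2 * pi)) # free dihedral
      pos[w, ] <- pos[p, ] + b0(p, w) * dir
    }
    out[s] <- sqrt(sum((pos[8, ] - pos[12, ])^2))
  }
  out
}

# Small random systems for oracle comparisons --------------------------

# n uncharged single-bead (water) molecules at random positions
randomWaterSystem <- function(n, box, seed, group = "OUTER_WATER") {
  xyz <- withr::with_seed(seed, matrix(runif(3 * n, 0, box), ncol = 3))
  beads <- data.frame(index = seq_len(n), molId = seq_len(n), species = "W",
                      beadName = "W", group = group, leaflet = NA_character_)
  new("ParticleSystem", beads = beads, coords = xyz, box = rep(box, 3),
      provenance = list())
}

# nLip 12-bead lipids with compact random conformations
randomLipidSystem <- function(nLip, box, seed, species = "DPPC") {
  tpl <- lipidTemplate(species)
  xyz <- withr::with_seed(seed, {
    cent <- matrix(runif(3 * nLip, 1, box - 1), ncol = 3)
    do.call(rbind, lapply(seq_len(nLip), function(i)
      sweep(matrix(rnorm(36, sd = 0.3), ncol = 3), 2, cent[i, ], `+`)))
  })
  beads <- data.frame(
    index = seq_len(12 * nLip), molId = rep(seq_len(nLip), each = 12),
    species = species, beadName = rep(tpl@beads$name, nLip),
    group = "BILAYER", leaflet = NA_character_)
  new("ParticleSystem", beads = beads, coords = xyz %% box,
      box = rep(box, 3), provenance = list())
}

oneFrameTraj <- function(beads, xyz, box) {
  new("ArrayTrajectory", coords = array(xyz, c(nrow(xyz), 3, 1)),
      times = 0, box = matrix(box, 1, 3), beads = beads)
}
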