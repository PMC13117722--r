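# Measurements on coarse-grained structures and trajectories: molecular
# radial distribution, vesicle area-per-lipid, MSD/diffusion,
# group-group nonbonded energies, kink angles, end-to-end distances and
# spherical pore detection.
#
# Conventions shared by all operators: the vesicle centre is the centre
# of geometry of the selected lipid beads, per frame; all distances use
# the minimum-image convention in the orthorhombic box; trajectory
# averages default to the final 10% of frames (frames = "last10").

#' Tail-angle statistics
#' @slot mean mean angle over lipids, triples and frames (degrees).
#' @slot n number of angle samples.
#' @slot angles all sampled angles (degrees).
#' @slot triples the (i, j, k) bead triples measured.
#' @slot saturatedFallback `TRUE` when the species has no unsaturated
#'   beads and saturated-triple statistics were reported instead.
#' @exportClass AngleStats
setClass("AngleStats",
  representation(mean = "numeric", n = "integer", angles = "numeric",
                 triples = "matrix", saturatedFallback = "logical"))

#' End-to-end tail distance statistics
#' @slot mean mean distance between the tail end beads 8 and 12 (nm).
#' @slot n number of samples (lipids x frames).
#' @slot distances all sampled distances (nm).
#' @exportClass DistanceStats
setClass("DistanceStats",
  representation(mean = "numeric", n = "integer", distances = "numeric"))

#' Molecular radial distribution by minimum inter-bead distance
#'
#' For each reference lipid and frame, the distance to every other
#' molecule is the minimum over all inter-bead pairs; counts are
#' histogrammed in 0.01 nm bins (bin centred at r collects distances in
#' `[r - 0.005, r + 0.005)`) and averaged over references and frames.
#' Values are raw average neighbour counts, so the sum over bins is the
#' average number of neighbours within range; set `normalized = TRUE`
#' for a density-normalised g(r).
#'
#' @param x a [TrajectorySlice-class] or [ParticleSystem-class].
#' @param ref reference selection (e.g. a species name or `"BILAYER"`).
#' @param target target selection (lipid or water molecules).
#' @param rMax histogram range in nm.
#' @param frames `"last10"` (default), `"all"`, or frame indices.
#' @param normalized divide by the ideal-gas shell count.
#' @return an [RdfResult-class].
#' @export
molecularRdf <- function(x, ref, target, rMax = 1.5, frames = "last10",
                         normalized = FALSE) {
  if (rMax <= 0) stop("rMax must be positive")
  traj <- asTrajectory(x)
  beads <- beadData(traj)
  refMols <- moleculeBeadList(beads, resolveSelection(beads, ref))
  tarMols <- moleculeBeadList(beads, resolveSelection(beads, target))
  refIds <- as.integer(names(refMols))
  tarIds <- as.integer(names(tarMols))
  binWidth <- 0.01
  nBins <- round(rMax / binWidth)
  fr <- resolveFrames(nFrames(traj), frames)
  counts <- numeric(nBins)
  vol <- 0
  trajApply(traj, fr, function(i, time, xyz, box) {
    counts <<- counts + cppMolRdf(xyz, box, unname(refMols), unname(tarMols),
                                  refIds, tarIds, rMax, nBins, binWidth)
    vol <<- vol + prod(box)
  })
  value <- counts / (length(refMols) * length(fr))
  r <- seq_len(nBins) * binWidth
  if (normalized) {
    rho <- length(tarMols) / (vol / length(fr))
    value <- value / (4 * pi * r^2 * binWidth * rho)
  }
  new("RdfResult", r = r, value = value, nRef = length(refMols),
      nFrames = length(fr), normalized = normalized)
}

# Leaflet assignment and APL for one frame.
aplFrame <- function(xyz, beads, selIdx) {
  mols <- moleculeBeadList(beads, selIdx)
  if (any(lengths(mols) != 12L))
    stop("APL requires whole 12-bead lipid molecules in the selection")
  if (length(mols) < 20L)
    stop("need at least 10 lipids per leaflet (", length(mols),
         " lipids selected)")
  idxMat <- matrix(unlist(mols, use.names = FALSE), nrow = 12L)
  centre <- colMeans(xyz[selIdx, , drop = FALSE])
  pick <- function(k) xyz[idxMat[k, ], , drop = FALSE]
  headB <- pick(1L)
  phos <- pick(2L)
  tailMid <- Reduce(`+`, lapply(5:12, pick)) / 8
  cog <- Reduce(`+`, lapply(1:12, pick)) / 12
  radial <- sweep(cog, 2, centre)
  orient <- rowSums((tailMid - headB) * radial)
  outer <- orient < 0
  phosR <- rowNorms(sweep(phos, 2, centre))
  res <- lapply(c(outer = TRUE, inner = FALSE), function(isOuter) {
    sel <- if (isOuter) outer else !outer
    nm <- if (isOuter) "outer" else "inner"
    if (!any(sel)) stop("degenerate leaflet: no lipids assigned to the ",
                        nm, " leaflet")
    if (sum(sel) < 10L) stop("fewer than 10 lipids in the ", nm, " leaflet")
    R <- mean(phosR[sel])
    list(n = sum(sel), radius = R, apl = 4 * pi * R^2 / sum(sel))
  })
  leaflets <- data.frame(
    leaflet = c("outer", "inner"),
    nLipids = c(res$outer$n, res$inner$n),
    radius = c(res$outer$radius, res$inner$radius),
    apl = c(res$outer$apl, res$inner$apl))
  area <- 4 * pi * leaflets$radius^2
  list(leaflets = leaflets,
       combined = sum(area * leaflets$apl) / sum(area),
       outerMask = outer, mols = mols)
}

#' Vesicle area per lipid
#'
#' Assigns each lipid to a leaflet by the sign of the dot product
#' between its head-to-tail-midpoint vector and the radial direction at
#' its centre of geometry, takes each leaflet's radius as the mean
#' radial distance of the phosphate beads (bead 2) from the vesicle
#' centre, and reports APL = 4 pi R^2 / N per leaflet plus the
#' area-weighted combination.  For a trajectory the report is averaged
#' over the selected frames.
#'
#' @param x a [ParticleSystem-class] or [TrajectorySlice-class].
#' @param selection lipid selection (default all `BILAYER` beads).
#' @param frames for trajectories: `"last10"`, `"all"` or indices.
#' @return an [AplReport-class].
#' @export
vesicleApl <- function(x, selection = "BILAYER", frames = "last10") {
  traj <- asTrajectory(x)
  beads <- beadData(traj)
  selIdx <- resolveSelection(beads, selection)
  fr <- resolveFrames(nFrames(traj), frames)
  acc <- NULL
  trajApply(traj, fr, function(i, time, xyz, box) {
    res <- aplFrame(xyz, beads, selIdx)
    if (is.null(acc)) acc <<- res
    else {
      acc$leaflets$radius <<- acc$leaflets$radius + res$leaflets$radius
      acc$leaflets$apl <<- acc$leaflets$apl + res$leaflets$apl
      acc$combined <<- acc$combined + res$combined
    }
  })
  nf <- length(fr)
  acc$leaflets$radius <- acc$leaflets$radius / nf
  acc$leaflets$apl <- acc$leaflets$apl / nf
  new("AplReport", leaflets = acc$leaflets, combined = acc$combined / nf)
}

# Leaflet assignment used by punchHole and available to callers who
# want the per-lipid labels of a single structure.
leafletAssignment <- function(system, selection = "BILAYER") {
  beads <- beadData(system)
  selIdx <- resolveSelection(beads, selection)
  res <- aplFrame(coords(system), beads, selIdx)
  data.frame(molId = as.integer(names(res$mols)),
             leaflet = ifelse(res$outerMask, "outer", "inner"))
}

# Shared core of the energy operator.
energyCore <- function(xyz, box, beads, groupA, groupB, params) {
  idxA <- resolveSelection(beads, groupA)
  idxB <- resolveSelection(beads, groupB)
  same <- length(idxA) == length(idxB) && setequal(idxA, idxB)
  if (!same && length(intersect(idxA, idxB)))
    stop("overlapping distinct groups: make the groups disjoint or identical")
  tc <- beadTypesCharges(new("ParticleSystem", beads = beads,
                             coords = xyz, box = box, provenance = list()))
  typeIdx <- match(tc$type, params@types)
  if (anyNA(typeIdx))
    stop("missing nonbonded parameters for bead type(s): ",
         paste(unique(tc$type[is.na(typeIdx)]), collapse = ", "))
  out <- cppGroupEnergy(xyz, typeIdx, tc$charge, beads$molId,
                        idxA, idxB, box, params@cutoff, params@epsR,
                        params@sigma, params@epsilon, same)
  if (isTRUE(out$singular))
    stop("singular geometry: coincident beads (r = 0) within the cutoff")
  out
}

#' Group-group nonbonded interaction energy
#'
#' Sums the shifted Lennard-Jones and Coulomb energies over all
#' intermolecular bead pairs between two groups within the cutoff:
#' `V_LJ = sum 4 eps ((sigma/r)^12 - (sigma/r)^6) - V(rc)` and
#' `V_C = sum f q_i q_j / (eps_r r) - shift`, with
#' f = 138.935 kJ nm/(mol e^2).  Pairs within the same molecule are
#' excluded; identical groups trigger intra-group mode (each unordered
#' pair counted once); overlapping distinct groups are an error.  The
#' implementation is a cell list (with a brute-force fallback for small
#' boxes); it reproduces a direct all-pairs sum exactly.
#'
#' Because the coarse-grained water bead is uncharged, the Coulomb
#' component between any lipid group and any water group is exactly
#' zero.
#'
#' @param x a [ParticleSystem-class] or [TrajectorySlice-class].
#' @param groupA,groupB selections (group labels, species or indices).
#' @param params a [NonbondedParams-class].
#' @param frames for trajectories: `"all"`, `"last10"` or indices.
#' @return an [EnergyBreakdown-class] for a structure; for a
#'   trajectory, a `data.frame` with columns `time`, `lj`, `coulomb`.
#' @export
groupInteractionEnergy <- function(x, groupA, groupB,
                                   params = defaultNonbonded(),
                                   frames = "all") {
  labA <- if (is.character(groupA) && length(groupA) == 1) groupA else "groupA"
  labB <- if (is.character(groupB) && length(groupB) == 1) groupB else "groupB"
  if (is(x, "ParticleSystem")) {
    out <- energyCore(x@coords, x@box, x@beads, groupA, groupB, params)
    return(new("EnergyBreakdown", groups = c(labA, labB),
               lj = out$lj, coulomb = out$coulomb, time = NA_real_))
  }
  traj <- asTrajectory(x)
  beads <- beadData(traj)
  fr <- resolveFrames(nFrames(traj), frames)
  rows <- vector("list", length(fr))
  k <- 0L
  trajApply(traj, fr, function(i, time, xyz, box) {
    out <- energyCore(xyz, box, beads, groupA, groupB, params)
    k <<- k + 1L
    rows[[k]] <<- data.frame(time = time, lj = out$lj, coulomb = out$coulomb)
  })
  do.call(rbind, rows)
}

# Angle triples of a species template centred on unsaturated beads,
# falling back (with a notice) to all triples for saturated species.
kinkTriples <- function(template) {
  a <- template@angles
  if (length(template@unsaturatedBeads)) {
    sel <- a$j %in% template@unsaturatedBeads
    list(triples = as.matrix(a[sel, c("i", "j", "k")]), fallback = FALSE)
  } else {
    message("species ", template@name,
            " has no unsaturated beads; reporting saturated-triple statistics")
    list(triples = as.matrix(a[, c("i", "j", "k")]), fallback = TRUE)
  }
}

#' Tail kink angles
#'
#' For each angle triple centred on an unsaturated bead (the C3 kink
#' position), the angle between the two adjacent bond vectors, averaged
#' over lipids and frames.  For fully saturated species the operator
#' reports the saturated-triple statistics and says so.
#'
#' @param x a [TrajectorySlice-class] or [ParticleSystem-class].
#' @param selection lipid selection (single species).
#' @param frames `"last10"`, `"all"` or frame indices.
#' @return an [AngleStats-class].
#' @export
kinkAngles <- function(x, selection = NULL, frames = "last10") {
  traj <- asTrajectory(x)
  beads <- beadData(traj)
  selIdx <- resolveSelection(beads, selection)
  sp <- unique(beads$species[selIdx])
  sp <- setdiff(sp, "W")
  if (length(sp) != 1L)
    stop("kink-angle selection must contain exactly one lipid species, got: ",
         paste(sp, collapse = ", "))
  tpl <- lipidTemplate(sp)
  kt <- kinkTriples(tpl)
  mols <- moleculeBeadList(beads, selIdx[beads$species[selIdx] == sp])
  if (any(lengths(mols) != 12L))
    stop("kink angles require whole 12-bead lipids")
  idxMat <- matrix(unlist(mols, use.names = FALSE), nrow = 12L)
  fr <- resolveFrames(nFrames(traj), frames)
  out <- vector("list", length(fr))
  k <- 0L
  trajApply(traj, fr, function(f, time, xyz, box) {
    ang <- lapply(seq_len(nrow(kt$triples)), function(t) {
      i <- idxMat[kt$triples[t, 1], ]
      j <- idxMat[kt$triples[t, 2], ]
      l <- idxMat[kt$triples[t, 3], ]
      v1 <- minImage(xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE], box)
      v2 <- minImage(xyz[l, , drop = FALSE] - xyz[j, , drop = FALSE], box)
      rowAngles(v1, v2)
    })
    k <<- k + 1L
    out[[k]] <<- unlist(ang)
  })
  angles <- unlist(out)
  new("AngleStats", mean = mean(angles), n = length(angles), angles = angles,
      triples = kt$triples, saturatedFallback = kt$fallback)
}

#' End-to-end tail distance (beads 8 and 12)
#'
#' Euclidean distance between the two tail end beads of each lipid,
#' averaged over lipids and frames.
#'
#' @param x a [TrajectorySlice-class] or [ParticleSystem-class].
#' @param selection lipid selection.
#' @param frames `"last10"`, `"all"` or frame indices.
#' @return a [DistanceStats-class].
#' @export
endToEnd <- function(x, selection = NULL, frames = "last10") {
  traj <- asTrajectory(x)
  beads <- beadData(traj)
  selIdx <- resolveSelection(beads, selection)
  selIdx <- selIdx[beads$species[selIdx] != "W"]
  if (!length(selIdx)) stop("selection contains no lipid beads")
  mols <- moleculeBeadList(beads, selIdx)
  if (any(lengths(mols) < 12L))
    stop("template error: end-to-end distance needs 12-bead lipids ",
         "(beads 8 and 12 missing)")
  idxMat <- matrix(unlist(mols, use.names = FALSE), nrow = 12L)
  fr <- resolveFrames(nFrames(traj), frames)
  out <- vector("list", length(fr))
  k <- 0L
  trajApply(traj, fr, function(f, time, xyz, box) {
    d <- minImage(xyz[idxMat[8L, ], , drop = FALSE] -
                  xyz[idxMat[12L, ], , drop = FALSE], box)
    k <<- k + 1L
    out[[k]] <<- rowNorms(d)
  })
  d <- unlist(out)
  new("DistanceStats", mean = mean(d), n = length(d), distances = d)
}

# Mean-square displacement for a set of position series via the
# FFT-based autocorrelation identity (averaged over all time origins).
# X: F x M matrix of coordinates (one column per particle-axis).
msdAllOrigins <- function(X) {
  nf <- nrow(X)
  pad <- rbind(X, matrix(0, nf, ncol(X)))
  fx <- mvfft(pad)
  ac <- Re(mvfft(fx * Conj(fx), inverse = TRUE))[seq_len(nf), , drop = FALSE] /
    (2 * nf)
  sq <- X * X
  headcs <- apply(sq, 2, cumsum)
  tailcs <- apply(sq[nf:1, , drop = FALSE], 2, cumsum)
  SS <- matrix(rep(colSums(sq), each = nf), nrow = nf)
  k <- seq_len(nf) - 1L
  Q <- 2 * SS
  Q[-1, ] <- 2 * SS[-1, , drop = FALSE] - headcs[seq_len(nf - 1), , drop = FALSE] -
    tailcs[seq_len(nf - 1), , drop = FALSE]
  D <- Q - 2 * ac
  sweep(D, 1, nf - k, "/")
}

#' Mean-square displacement and diffusion coefficient
#'
#' Tracks one marker bead per selected molecule (the phosphate bead for
#' lipids; the bead itself for single-bead molecules), removes the
#' selection's per-frame centre-of-geometry drift, averages the squared
#' displacement over particles and all time origins, and fits a line
#' over the requested lag-time window.  The diffusion coefficient is
#' `D = slope / dFit`, with `dFit = 4` (the lateral, quasi-2-D
#' convention for lipids diffusing on the vesicle shell) or `dFit = 6`
#' (3-D), converted to 1e-5 cm^2/s.  Positions are assumed unwrapped.
#'
#' @param x a [TrajectorySlice-class].
#' @param selection molecule selection.
#' @param fitWindow lag-time window `c(tmin, tmax)` in ps; default the
#'   central 10-80% of the lag range.
#' @param dFit MSD-slope divisor: 4 (lateral, default) or 6 (3-D).
#' @param maxLag largest lag (in frames) to evaluate; default half the
#'   trajectory.
#' @return an [MsdResult-class].
#' @export
msdDiffusion <- function(x, selection = NULL, fitWindow = NULL, dFit = 4,
                         maxLag = NULL) {
  if (!dFit %in% c(4, 6)) stop("dFit must be 4 (lateral) or 6 (3-D)")
  traj <- asTrajectory(x)
  nf <- nFrames(traj)
  if (nf < 10L) stop("need at least 10 frames for an MSD")
  beads <- beadData(traj)
  selIdx <- resolveSelection(beads, selection)
  mols <- moleculeBeadList(beads, selIdx)
  marker <- vapply(mols, function(m) {
    po4 <- m[beads$beadName[m] == "PO4"]
    if (length(po4)) po4[1]
    else if (length(m) == 1L) m
    else stop("selection must contain phosphate beads or single-bead molecules")
  }, integer(1))
  n <- length(marker)
  pos <- array(NA_real_, dim = c(nf, n, 3))
  trajApply(traj, seq_len(nf), function(i, time, xyz, box) {
    p <- xyz[marker, , drop = FALSE]
    pos[i, , ] <<- sweep(p, 2, colMeans(p))  # remove COG drift
  })
  X <- matrix(pos, nrow = nf)  # F x (3n)
  msdFull <- rowMeans(msdAllOrigins(X)) * 3
  if (is.null(maxLag)) maxLag <- max(2L, nf %/% 2L)
  maxLag <- min(maxLag, nf - 1L)
  lagIdx <- 0:maxLag
  times <- frameTimes(traj)
  lag <- times[lagIdx + 1L] - times[1L]
  msd <- msdFull[lagIdx + 1L]
  if (is.null(fitWindow)) fitWindow <- c(0.1, 0.8) * max(lag)
  inWin <- lag >= fitWindow[1] & lag <= fitWindow[2] & lagIdx > 0L
  if (sum(inWin) < 3L) stop("fit window contains fewer than 3 MSD points")
  fit <- lm(msd[inWin] ~ lag[inWin])
  slope <- unname(coef(fit)[2])  # nm^2/ps
  D <- slope / dFit * 1e3        # 1e-5 cm^2/s
  new("MsdResult", lag = lag, msd = msd, fitWindow = fitWindow,
      slope = slope, dFit = dFit, D = D)
}

# Minimal union-find for pore patch merging.
ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect lipid-depleted pores on the vesicle shell
#'
#' Projects the selected lipid beads onto the mid-radius sphere, bins
#' them on a near-equal-area band grid with the requested linear
#' resolution, and reports maximal connected patches of empty cells.
#' Each patch's equivalent angular radius alpha comes from its solid
#' angle (a spherical cap of the same area), and the estimated pore
#' diameter is `2 * R_mid * alpha`.  The grid must be coarse relative
#' to the projected bead spacing, otherwise discreteness would read as
#' spurious vacancies; too fine a resolution is an error.
#'
#' Patch diameters carry a half-cell rim correction (a boundary cell
#' containing any bead counts as occupied, shrinking the empty patch by
#' about half a cell on each side), and patches smaller than
#' `minDiameter` — by default three grid cells, the scale of ordinary
#' packing vacancies between discrete lipids — are not reported, so a
#' pristine vesicle yields zero pores.
#'
#' @param x a [ParticleSystem-class] (or one-frame trajectory).
#' @param selection lipid selection.
#' @param resolution grid linear resolution on the mid-sphere, nm.
#' @param minDiameter drop patches with a smaller estimated diameter;
#'   default `3 * resolution`.
#' @return a [PoreReport-class].
#' @export
detectPores <- function(x, selection = "BILAYER", resolution = 0.5,
                        minDiameter = 3 * resolution) {
  if (is(x, "TrajectorySlice")) {
    fr <- getFrame(x, nFrames(x))
    x <- new("ParticleSystem", beads = beadData(x), coords = fr$coords,
             box = matrix(fr$box, ncol = 3)[1, ], provenance = list())
  }
  beads <- beadData(x)
  selIdx <- resolveSelection(beads, selection)
  rel <- sweep(coords(x)[selIdx, , drop = FALSE], 2,
               colMeans(coords(x)[selIdx, , drop = FALSE]))
  r <- rowNorms(rel)
  if (any(r == 0)) stop("bead at the vesicle centre; cannot project")
  rMid <- mean(r)
  meanSpacing <- sqrt(4 * pi * rMid^2 / length(selIdx))
  if (resolution < 2 * meanSpacing)
    stop("resolution error: grid resolution ", resolution,
         " nm is finer than twice the mean projected bead spacing (",
         sprintf("%.3f", meanSpacing), " nm); coarsen the grid")
  theta <- acos(pmin(1, pmax(-1, rel[, 3] / r)))
  phi <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  nBands <- max(3L, as.integer(round(pi * rMid / resolution)))
  mB <- vapply(seq_len(nBands), function(b) {
    thc <- (b - 0.5) * pi / nBands
    max(1L, as.integer(round(2 * pi * rMid * sin(thc) / resolution)))
  }, integer(1))
  cellsPerBandBefore <- c(0L, cumsum(mB))[seq_len(nBands)]
  band <- pmin(nBands, pmax(1L, ceiling(theta / pi * nBands)))
  cellInBand <- pmin(mB[band], pmax(1L, ceiling(phi / (2 * pi) * mB[band])))
  occupied <- unique(cellsPerBandBefore[band] + cellInBand)
  total <- sum(mB)
  empty <- setdiff(seq_len(total), occupied)
  emptyPores <- function() new("PoreReport",
    pores = data.frame(dirX = numeric(), dirY = numeric(), dirZ = numeric(),
                       angularRadius = numeric(), diameter = numeric(),
                       nCells = integer()),
    rMid = rMid, resolution = resolution)
  if (!length(empty)) return(emptyPores())
  # geometry of the empty cells
  cellBand <- findInterval(empty - 0.5, cellsPerBandBefore)
  cellIdx <- empty - cellsPerBandBefore[cellBand]
  thTop <- (cellBand - 1) * pi / nBands
  thBot <- cellBand * pi / nBands
  thC <- (cellBand - 0.5) * pi / nBands
  phW <- 2 * pi / mB[cellBand]
  phC <- (cellIdx - 0.5) * phW
  area <- (cos(thTop) - cos(thBot)) * phW * rMid^2
  # union-find over empty cells: neighbours within a band (wrapped) and
  # across adjacent bands when azimuth ranges overlap
  ne <- length(empty)
  parent <- seq_len(ne)
  link <- function(a, b) {
    ra <- ufFind(parent, a); rb <- ufFind(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  angDiff <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  byBand <- split(seq_len(ne), cellBand)
  for (bn in names(byBand)) {
    b <- as.integer(bn)
    ids <- byBand[[bn]]
    if (length(ids) > 1L) {
      ord <- ids[order(cellIdx[ids])]
      ci <- cellIdx[ord]
      for (t in seq_len(length(ord) - 1L))
        if (ci[t + 1L] - ci[t] == 1L) link(ord[t], ord[t + 1L])
      if (mB[b] > 2L && ci[length(ci)] == mB[b] && ci[1L] == 1L)
        link(ord[length(ord)], ord[1L])
      if (mB[b] <= 2L) for (t in seq_len(length(ord) - 1L))
        link(ord[t], ord[t + 1L])
    }
    below <- byBand[[as.character(b + 1L)]]
    if (!is.null(below)) {
      for (i in ids) {
        tol <- (phW[i] + phW[below]) / 2
        hit <- below[angDiff(phC[i], phC[below]) <= tol]
        for (j in hit) link(i, j)
      }
    }
  }
  comp <- vapply(seq_len(ne), function(i) ufFind(parent, i), integer(1))
  dirs <- cbind(sin(thC) * cos(phC), sin(thC) * sin(phC), cos(thC))
  pores <- do.call(rbind, lapply(unique(comp), function(cc) {
    sel <- comp == cc
    aTot <- sum(area[sel])
    f <- min(1, aTot / (4 * pi * rMid^2))
    alpha <- acos(1 - 2 * f) + resolution / (2 * rMid)  # half-cell rim
    d <- colSums(dirs[sel, , drop = FALSE] * area[sel])
    d <- d / sqrt(sum(d^2))
    data.frame(dirX = d[1], dirY = d[2], dirZ = d[3],
               angularRadius = alpha, diameter = 2 * rMid * alpha,
               nCells = sum(sel))
  }))
  pores <- pores[pores$diameter >= minDiameter, , drop = FALSE]
  pores <- pores[order(-pores$diameter), , drop = FALSE]
  rownames(pores) <- NULL
  new("PoreReport", pores = pores, rMid = rMid, resolution = resolution)
}

setMethod("show", "RdfResult", function(object) {
  cat("RdfResult:", length(object@r), "bins of 0.01 nm,",
      object@nRef, "reference molecules,", object@nFrames, "frames\n")
  cat(sprintf("  neighbours within range: %.3f per reference\n",
              sum(object@value)))
  if (object@normalized) cat("  (density-normalised g(r))\n")
})

setMethod("show", "AplReport", function(object) {
  cat("AplReport\n")
  with(object@leaflets, for (i in seq_along(leaflet))
    cat(sprintf("  %-6s leaflet: %5d lipids, R = %7.3f nm, APL = %.4f nm^2\n",
                leaflet[i], nLipids[i], radius[i], apl[i])))
  cat(sprintf("  combined (area-weighted): %.4f nm^2\n", object@combined))
})

setMethod("show", "MsdResult", function(object) {
  cat(sprintf("MsdResult: %d lags, fit window %.2f..%.2f ps\n",
              length(object@lag), object@fitWindow[1], object@fitWindow[2]))
  cat(sprintf("  slope %.4g nm^2/ps, divisor %d -> D = %.4g x 1e-5 cm^2/s\n",
              object@slope, as.integer(object@dFit), object@D))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown %s - %s\n", object@groups[1], object@groups[2]))
  cat(sprintf("  LJ      %12.3f kJ/mol\n  Coulomb %12.3f kJ/mol\n",
              object@lj, object@coulomb))
})

setMethod("show", "AngleStats", function(object) {
  cat(sprintf("AngleStats: mean %.2f deg over %d samples (%d triples)%s\n",
              object@mean, object@n, nrow(object@triples),
              if (object@saturatedFallback) " [saturated fallback]" else ""))
})

setMethod("show", "DistanceStats", function(object) {
  cat(sprintf("DistanceStats: mean %.3f nm over %d samples\n",
              object@mean, object@n))
})

setMethod("show", "PoreReport", function(object) {
  cat(sprintf("PoreReport: %d pore(s) on R_mid = %.3f nm (resolution %.2f nm)\n",
              nrow(object@pores), object@rMid, object@resolution))
  if (nrow(object@pores))
    print(round(object@pores[, c("angularRadius", "diameter", "nCells")], 3))
})
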