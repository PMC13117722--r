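#' Coarse-grained lipid template
#'
#' One lipid species as a 12-bead coarse-grained molecule: ordered bead
#' records (name, MARTINI-style bead type, charge in e), harmonic bonds
#' (`b0` in nm, `k` in kJ/mol/nm^2), cosine-harmonic angles (`theta0` in
#' degrees, `k` in kJ/mol) and the 1-based indices of tail beads carrying
#' a cis double bond.  Bead 1 is the choline head (+1 e), bead 2 the
#' phosphate (-1 e), beads 3-4 the glycerol linkers, beads 5-8 tail A and
#' beads 9-12 tail B, so that "the end beads" of the two tails are beads
#' 8 and 12.
#'
#' @slot name species identifier (e.g. `"DPPC"`).
#' @slot beads `data.frame` with columns `index`, `name`, `type`,
#'   `charge` (12 rows).
#' @slot bonds `data.frame` with columns `i`, `j`, `b0`, `k`.
#' @slot angles `data.frame` with columns `i`, `j`, `k`, `theta0`,
#'   `kAngle`.
#' @slot unsaturatedBeads integer vector of bead indices with a cis
#'   double bond (subset of 7 and 11, the third bead of each tail).
#' @exportClass LipidTemplate
setClass("LipidTemplate",
  representation(
    name = "character",
    beads = "data.frame",
    bonds = "data.frame",
    angles = "data.frame",
    unsaturatedBeads = "integer"
  )
)

setValidity("LipidTemplate", function(object) {
  msg <- character()
  b <- object@beads
  if (nrow(b) != 12L) msg <- c(msg, "a lipid template must have exactly 12 beads")
  if (!all(c("index", "name", "type", "charge") %in% names(b)))
    msg <- c(msg, "beads must have columns index, name, type, charge")
  if (nrow(b) == 12L) {
    if (!identical(as.integer(b$index), 1:12))
      msg <- c(msg, "bead indices must be 1..12 in order")
    if (b$charge[1] != 1) msg <- c(msg, "bead 1 (choline) must carry charge +1")
    if (b$charge[2] != -1) msg <- c(msg, "bead 2 (phosphate) must carry charge -1")
    if (any(b$charge[3:12] != 0)) msg <- c(msg, "beads 3-12 must be uncharged")
  }
  if (!all(object@unsaturatedBeads %in% c(7L, 11L)))
    msg <- c(msg, "unsaturated beads must be a subset of {7, 11}")
  a <- object@angles
  if (nrow(a) > 0) {
    bondKey <- paste(pmin(object@bonds$i, object@bonds$j),
                     pmax(object@bonds$i, object@bonds$j))
    ok <- paste(pmin(a$i, a$j), pmax(a$i, a$j)) %in% bondKey &
          paste(pmin(a$j, a$k), pmax(a$j, a$k)) %in% bondKey
    if (!all(ok)) msg <- c(msg, "every angle triple must be consecutive along bonds")
  }
  if (length(msg)) msg else TRUE
})

#' Nonbonded parameter table
#'
#' Symmetric Lennard-Jones pair table (sigma in nm, epsilon in kJ/mol)
#' over bead types, plus the uniform relative dielectric and the cutoff
#' used for both the LJ and Coulomb potentials.
#'
#' @slot types character vector of bead type names.
#' @slot sigma,epsilon symmetric numeric matrices indexed by type.
#' @slot epsR relative dielectric constant (default 15).
#' @slot cutoff cutoff radius in nm (default 1.2).
#' @exportClass NonbondedParams
setClass("NonbondedParams",
  representation(
    types = "character",
    sigma = "matrix",
    epsilon = "matrix",
    epsR = "numeric",
    cutoff = "numeric"
  )
)

setValidity("NonbondedParams", function(object) {
  msg <- character()
  n <- length(object@types)
  if (!all(dim(object@sigma) == c(n, n)) || !all(dim(object@epsilon) == c(n, n)))
    msg <- c(msg, "sigma and epsilon must be square matrices over the types")
  else {
    if (!isTRUE(all.equal(object@sigma, t(object@sigma))))
      msg <- c(msg, "sigma must be symmetric")
    if (!isTRUE(all.equal(object@epsilon, t(object@epsilon))))
      msg <- c(msg, "epsilon must be symmetric")
    if (any(object@sigma <= 0, na.rm = TRUE)) msg <- c(msg, "all sigma must be > 0")
    if (any(object@epsilon < 0, na.rm = TRUE)) msg <- c(msg, "all epsilon must be >= 0")
  }
  if (object@epsR <= 0) msg <- c(msg, "epsR must be positive")
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be positive")
  if (length(msg)) msg else TRUE
})

#' Coarse-grained water bead
#'
#' A single MARTINI-style water bead representing four water molecules,
#' uncharged, with a configurable nominal volume.
#'
#' @slot type bead type identifier (default `"P4"`).
#' @slot charge charge in e (always 0).
#' @slot representedMolecules number of waters per bead (always 4).
#' @slot volume nominal bead volume in nm^3.
#' @exportClass WaterBead
setClass("WaterBead",
  representation(
    type = "character",
    charge = "numeric",
    representedMolecules = "integer",
    volume = "numeric"
  ),
  prototype(type = "P4", charge = 0, representedMolecules = 4L, volume = 0.12)
)

setValidity("WaterBead", function(object) {
  msg <- character()
  if (object@charge != 0) msg <- c(msg, "a water bead must be uncharged")
  if (object@representedMolecules != 4L)
    msg <- c(msg, "a water bead represents exactly 4 water molecules")
  if (object@volume <= 0) msg <- c(msg, "volume must be positive")
  if (length(msg)) msg else TRUE
})

#' Vesicle build specification
#'
#' Geometry, composition and solvation parameters for one spherical
#' liposome build.  Leaflet reference radii are the phosphate-bead
#' spheres used for leaflet population counting (N = 4 pi r^2 / APL);
#' water counts of `NA` mean "fill the available lattice".
#'
#' @slot species lipid species name.
#' @slot outerDiameter outer diameter in nm.
#' @slot apl target area per lipid in nm^2.
#' @slot boxEdge cubic box edge in nm.
#' @slot rOutRef,rInRef leaflet reference (phosphate) radii in nm.
#' @slot nOut,nIn leaflet lipid-count overrides (`NA` = from APL).
#' @slot nWaterIn,nWaterOut water bead-count overrides (`NA` = fill).
#' @slot minSeparation minimum water-lipid separation in nm.
#' @slot latticeSpacing water lattice constant in nm.
#' @slot jitter per-axis uniform lattice jitter amplitude in nm.
#' @slot seed integer random seed controlling the build.
#' @exportClass VesicleSpec
setClass("VesicleSpec",
  representation(
    species = "character",
    outerDiameter = "numeric",
    apl = "numeric",
    boxEdge = "numeric",
    rOutRef = "numeric",
    rInRef = "numeric",
    nOut = "integer",
    nIn = "integer",
    nWaterIn = "integer",
    nWaterOut = "integer",
    minSeparation = "numeric",
    latticeSpacing = "numeric",
    jitter = "numeric",
    seed = "integer"
  )
)

setValidity("VesicleSpec", function(object) {
  msg <- character()
  if (object@apl <= 0) msg <- c(msg, "apl must be positive")
  if (object@outerDiameter <= 0) msg <- c(msg, "outerDiameter must be positive")
  if (!(object@rInRef > 0 && object@rInRef < object@rOutRef &&
        object@rOutRef < object@boxEdge / 2))
    msg <- c(msg, "need 0 < rInRef < rOutRef < boxEdge/2")
  if (object@outerDiameter > object@boxEdge - 4)
    msg <- c(msg, "outerDiameter must leave a >= 4 nm solvent margin in the box")
  for (nm in c("nOut", "nIn")) {
    v <- slot(object, nm)
    if (!is.na(v) && v <= 0L) msg <- c(msg, paste(nm, "must be a positive integer"))
  }
  for (nm in c("nWaterIn", "nWaterOut")) {
    v <- slot(object, nm)
    if (!is.na(v) && v < 0L) msg <- c(msg, paste(nm, "must be non-negative"))
  }
  if (object@minSeparation <= 0) msg <- c(msg, "minSeparation must be positive")
  if (object@latticeSpacing <= 0) msg <- c(msg, "latticeSpacing must be positive")
  if (object@jitter < 0) msg <- c(msg, "jitter must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Particle system: beads, coordinates, box, provenance
#'
#' The builder's product and the analysis input: one frame of bead
#' records (global index, molecule id, species, bead name,
#' temperature-coupling group label, optional leaflet label), their
#' coordinates in nm, the box vector, and build provenance.
#'
#' @slot beads `data.frame` with columns `index`, `molId`, `species`,
#'   `beadName`, `group`, and optionally `leaflet`.
#' @slot coords numeric matrix (nBeads x 3), nm.
#' @slot box numeric length-3 box vector, nm.
#' @slot provenance list (spec, seed, stage, ...).
#' @exportClass ParticleSystem
setClass("ParticleSystem",
  representation(
    beads = "data.frame",
    coords = "matrix",
    box = "numeric",
    provenance = "list"
  )
)

setValidity("ParticleSystem", function(object) {
  msg <- character()
  b <- object@beads
  n <- nrow(b)
  if (!all(c("index", "molId", "species", "beadName", "group") %in% names(b)))
    msg <- c(msg, "beads must have columns index, molId, species, beadName, group")
  if (nrow(object@coords) != n || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be an nBeads x 3 matrix")
  if (length(object@box) != 3 || any(object@box <= 0))
    msg <- c(msg, "box must be three positive lengths")
  if (n > 0) {
    if (!all(is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
    if (any(diff(match(b$molId, unique(b$molId))) < 0))
      msg <- c(msg, "beads of one molecule must be contiguous")
    grp <- b$group
    if (!all(is.na(grp) | grp %in% .canonicalGroups))
      msg <- c(msg, "group labels must be INNER_WATER, BILAYER or OUTER_WATER (or NA)")
  }
  if (length(msg)) msg else TRUE
})

#' Thermostat/barostat protocol for one run phase
#'
#' Everything the MDP writer needs for an equilibration or production
#' run: leap-frog integrator time step, step count, per-group reference
#' temperatures for the three coupling groups, v-rescale thermostat,
#' Parrinello-Rahman semi-isotropic barostat and the Verlet cutoff
#' scheme with a 1.2 nm cutoff.
#'
#' @slot phase `"equilibration"` or `"production"`.
#' @slot dt time step in ps.
#' @slot nSteps number of integrator steps.
#' @slot groupTemps named numeric: reference temperature (K) for
#'   `INNER_WATER`, `BILAYER`, `OUTER_WATER`, in that order.
#' @slot thermostat,barostat coupling algorithm names.
#' @slot tauT,tauP coupling time constants in ps.
#' @slot refPressure reference pressure in bar.
#' @slot pressureCoupling `"semiisotropic"` or `"isotropic"`.
#' @slot cutoffScheme neighbour-list scheme (`"Verlet"`).
#' @slot rc cutoff in nm for both LJ and Coulomb.
#' @exportClass ThermalProtocol
setClass("ThermalProtocol",
  representation(
    phase = "character",
    dt = "numeric",
    nSteps = "numeric",
    groupTemps = "numeric",
    thermostat = "character",
    barostat = "character",
    tauT = "numeric",
    tauP = "numeric",
    refPressure = "numeric",
    pressureCoupling = "character",
    cutoffScheme = "character",
    rc = "numeric"
  )
)

setValidity("ThermalProtocol", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@nSteps <= 0) msg <- c(msg, "nSteps must be positive")
  if (length(object@groupTemps) != 3 ||
      !identical(names(object@groupTemps), .canonicalGroups))
    msg <- c(msg, "groupTemps must be named INNER_WATER, BILAYER, OUTER_WATER")
  else if (any(object@groupTemps <= 0))
    msg <- c(msg, "all group temperatures must be positive")
  if (!object@phase %in% c("equilibration", "production"))
    msg <- c(msg, "phase must be equilibration or production")
  if (length(msg)) msg else TRUE
})

#' Trajectory contract
#'
#' A sequence of frames (time in ps, coordinates in nm, box in nm) over
#' a fixed bead table, streamed from a multi-frame GRO file
#' ([GroTrajectory]) or held in memory ([ArrayTrajectory]).
#'
#' @exportClass TrajectorySlice
setClass("TrajectorySlice", representation("VIRTUAL"))

#' @rdname TrajectorySlice-class
#' @slot coords numeric array nBeads x 3 x nFrames, nm.
#' @slot times frame times in ps (strictly increasing).
#' @slot box nFrames x 3 matrix of box vectors, nm.
#' @slot beads bead table as in [ParticleSystem-class].
#' @exportClass ArrayTrajectory
setClass("ArrayTrajectory",
  contains = "TrajectorySlice",
  representation(
    coords = "array",
    times = "numeric",
    box = "matrix",
    beads = "data.frame"
  )
)

setValidity("ArrayTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be an nBeads x 3 x nFrames array")
  else {
    if (length(object@times) != d[3]) msg <- c(msg, "times must match frame count")
    if (d[3] > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
    if (nrow(object@box) != d[3]) msg <- c(msg, "box must have one row per frame")
    if (nrow(object@beads) != d[1]) msg <- c(msg, "beads must match coords")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TrajectorySlice-class
#' @slot structurePath,trajectoryPath source file paths.
#' @slot nAtoms bead count per frame.
#' @slot nFramesTotal number of complete frames found.
#' @slot frameTimesPs frame times parsed from the titles, ps.
#' @slot beads bead table read from the structure file.
#' @exportClass GroTrajectory
setClass("GroTrajectory",
  contains = "TrajectorySlice",
  representation(
    structurePath = "character",
    trajectoryPath = "character",
    nAtoms = "integer",
    nFramesTotal = "integer",
    frameTimesPs = "numeric",
    beads = "data.frame"
  )
)

#' Molecular radial-distribution result
#'
#' Average number of target molecules per reference lipid whose
#' molecular (minimum inter-bead) distance falls in each 0.01 nm bin
#' centred at `r`.  Raw counts by default, so the sum over bins is the
#' average neighbour count within range.
#'
#' @slot r bin centres in nm (bin width 0.01 nm).
#' @slot value mean counts per reference per frame.
#' @slot nRef,nFrames averaging denominators.
#' @slot normalized whether values were density-normalised to g(r).
#' @exportClass RdfResult
setClass("RdfResult",
  representation(r = "numeric", value = "numeric", nRef = "integer",
                 nFrames = "integer", normalized = "logical"))

#' Mean-square-displacement result
#'
#' @slot lag lag times in ps.
#' @slot msd mean square displacement in nm^2 (msd at lag 0 is 0).
#' @slot fitWindow lag-time window (ps) used for the linear fit.
#' @slot slope fitted slope in nm^2/ps.
#' @slot dFit the MSD-slope divisor (4 = lateral convention, 6 = 3-D).
#' @slot D diffusion coefficient in 1e-5 cm^2/s.
#' @exportClass MsdResult
setClass("MsdResult",
  representation(lag = "numeric", msd = "numeric", fitWindow = "numeric",
                 slope = "numeric", dFit = "numeric", D = "numeric"))

#' Group-group nonbonded energy breakdown
#'
#' @slot groups the two group names.
#' @slot lj Lennard-Jones energy, kJ/mol (potential-shifted at the cutoff).
#' @slot coulomb Coulomb energy, kJ/mol (shifted at the cutoff).
#' @slot time frame time, ps (NA for a single structure).
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
  representation(groups = "character", lj = "numeric", coulomb = "numeric",
                 time = "numeric"))

#' Spherical pore report
#'
#' Lipid-depleted patches of the vesicle shell found on an occupancy
#' grid over the mid-radius sphere; each pore has a direction (unit
#' vector from the vesicle centre), an equivalent angular radius and an
#' estimated diameter 2 * R_mid * alpha.
#'
#' @slot pores `data.frame` with columns `dirX`, `dirY`, `dirZ`,
#'   `angularRadius` (rad), `diameter` (nm), `nCells`.
#' @slot rMid mid-sphere radius in nm.
#' @slot resolution grid linear resolution in nm.
#' @exportClass PoreReport
setClass("PoreReport",
  representation(pores = "data.frame", rMid = "numeric", resolution = "numeric"))

#' Vesicle area-per-lipid report
#'
#' @slot leaflets `data.frame` with columns `leaflet`, `nLipids`,
#'   `radius` (nm, mean phosphate radial distance), `apl` (nm^2).
#' @slot combined area-weighted combined APL, nm^2.
#' @exportClass AplReport
setClass("AplReport",
  representation(leaflets = "data.frame", combined = "numeric"))
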