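# Construction of whole spherical liposomes: two leaflet shells of
# radially oriented lipids plus inner-core and outer-box water.

# Lateral offset (nm) between the two tails of a straight-built lipid,
# so the chains do not coincide before energy minimisation.
.tailOffset <- 0.25

#' Create a vesicle build specification
#'
#' Leaflet reference radii are the phosphate-bead spheres on which
#' leaflet populations are counted via N = round(4 pi r^2 / APL).  When
#' not given they are derived from the outer diameter with fixed
#' offsets (rOut = D/2 - 1.299 nm, rIn = rOut - 2.161 nm) chosen so the
#' 30 nm / 0.46 nm^2 default reproduces leaflet populations of 5128
#' (outer) and 3638 (inner).  Water counts of `NA` fill the available
#' solvation lattice.
#'
#' @param species lipid species (`"DPPC"`, `"DOPC"` or `"POPC"`).
#' @param outerDiameter vesicle outer diameter, nm.
#' @param apl target area per lipid, nm^2.
#' @param boxEdge cubic box edge, nm.
#' @param rOutRef,rInRef leaflet reference radii, nm (`NA` = derive).
#' @param nOut,nIn leaflet lipid-count overrides (`NA` = from APL).
#' @param nWaterIn,nWaterOut water bead counts (`NA` = fill lattice).
#' @param minSeparation minimum water-lipid distance, nm.
#' @param latticeSpacing water lattice constant, nm.
#' @param jitter per-axis uniform jitter amplitude of lattice sites, nm.
#' @param seed integer seed controlling the (deterministic) build.
#' @return a validated [VesicleSpec-class].
#' @export
vesicleSpec <- function(species = "DPPC", outerDiameter = 30, apl = 0.46,
                        boxEdge = 40, rOutRef = NA, rInRef = NA,
                        nOut = NA, nIn = NA, nWaterIn = NA, nWaterOut = NA,
                        minSeparation = 0.40, latticeSpacing = 0.415,
                        jitter = 0.01, seed = 1L) {
  if (is.na(rOutRef)) rOutRef <- outerDiameter / 2 - 1.299
  if (is.na(rInRef)) rInRef <- rOutRef - 2.161
  spec <- new("VesicleSpec",
    species = toupper(species), outerDiameter = outerDiameter, apl = apl,
    boxEdge = boxEdge, rOutRef = rOutRef, rInRef = rInRef,
    nOut = as.integer(nOut), nIn = as.integer(nIn),
    nWaterIn = as.integer(nWaterIn), nWaterOut = as.integer(nWaterOut),
    minSeparation = minSeparation, latticeSpacing = latticeSpacing,
    jitter = jitter, seed = as.integer(seed))
  validObject(spec)
  spec
}

#' The packaged default build configuration
#'
#' Reads the configuration shipped with the package (30 nm DPPC vesicle,
#' APL 0.46 nm^2, 40 nm box, fixed water counts 67,522 inner and
#' 334,358 outer) or a user configuration in the same YAML layout.
#'
#' @param path a YAML configuration file; default: the packaged one.
#' @param seed optional seed overriding the configured one.
#' @return a [VesicleSpec-class].
#' @export
defaultVesicleSpec <- function(path = NULL, seed = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_vesicle.yaml",
                        package = "vesica", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  pick <- function(nm, dflt = NA) if (!is.null(cfg[[nm]])) cfg[[nm]] else dflt
  vesicleSpec(
    species = pick("species", "DPPC"),
    outerDiameter = pick("outer_diameter", 30),
    apl = pick("apl", 0.46),
    boxEdge = pick("box_edge", 40),
    rOutRef = pick("r_out_ref"), rInRef = pick("r_in_ref"),
    nOut = pick("n_out"), nIn = pick("n_in"),
    nWaterIn = pick("n_water_in"), nWaterOut = pick("n_water_out"),
    minSeparation = pick("min_separation", 0.40),
    latticeSpacing = pick("lattice_spacing", 0.415),
    jitter = pick("jitter", 0.01),
    seed = if (!is.null(seed)) seed else pick("seed", 1L))
}

#' Leaflet population from a reference sphere and an area per lipid
#'
#' @param radius leaflet reference radius in nm.
#' @param apl area per lipid in nm^2.
#' @return `round(4 pi radius^2 / apl)`, nearest integer (ties to even).
#' @examples
#' leafletCount(13.701, 0.46)  # 5128
#' leafletCount(11.540, 0.46)  # 3638
#' @export
leafletCount <- function(radius, apl) {
  if (any(radius <= 0) || any(apl <= 0))
    stop("radius and apl must be positive")
  as.integer(round(4 * pi * radius^2 / apl))
}

# Radial depth (nm, measured inward from the choline bead) and lateral
# offset of each template bead in the straight-built conformation.
# Chain A runs 1-2-3-5-6-7-8 along the radial axis; bead 4 and chain B
# (9-12) are displaced laterally by .tailOffset so the tails are
# parallel, 0.25 nm apart.
beadLayout <- function(template) {
  bonds <- template@bonds
  b0 <- function(i, j) {
    hit <- (bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i)
    if (!any(hit)) stop("template lacks bond ", i, "-", j)
    bonds$b0[which(hit)[1]]
  }
  depth <- numeric(12)
  lateral <- numeric(12)
  pathA <- c(1, 2, 3, 5, 6, 7, 8)
  for (k in 2:length(pathA))
    depth[pathA[k]] <- depth[pathA[k - 1]] + b0(pathA[k - 1], pathA[k])
  depth[4] <- depth[3]
  lateral[4] <- .tailOffset
  pathB <- c(4, 9, 10, 11, 12)
  for (k in 2:length(pathB)) {
    depth[pathB[k]] <- depth[pathB[k - 1]] + b0(pathB[k - 1], pathB[k])
    lateral[pathB[k]] <- .tailOffset
  }
  list(depth = depth, lateral = lateral, anchorDepth = depth[2])
}

#' Place one leaflet of radially oriented lipids
#'
#' Phosphate-bead anchors are distributed near-uniformly on the leaflet
#' reference sphere by a Fibonacci (golden-spiral) lattice with a
#' seed-controlled random global rotation; each lipid's bead chain is
#' laid straight along the local radial axis (head outermost for the
#' outer leaflet, innermost for the inner leaflet) with template bond
#' lengths.  Deterministic for a fixed seed.
#'
#' @param spec a [VesicleSpec-class].
#' @param which `"outer"` or `"inner"`.
#' @return a [ParticleSystem-class] holding one leaflet (group
#'   `BILAYER`, `leaflet` column set).
#' @export
placeLeaflet <- function(spec, which = c("outer", "inner")) {
  which <- match.arg(which)
  validObject(spec)
  template <- lipidTemplate(spec@species)
  lay <- beadLayout(template)
  rRef <- if (which == "outer") spec@rOutRef else spec@rInRef
  n <- if (which == "outer") spec@nOut else spec@nIn
  if (is.na(n)) n <- leafletCount(rRef, spec@apl)
  chainDepth <- max(lay$depth) - lay$anchorDepth
  if (which == "inner" && rRef - lay$anchorDepth <= 0.5)
    stop("build error: inner-leaflet lipids would reach the vesicle centre ",
         "(rInRef too small for the lipid length)")
  if (which == "outer" && rRef + lay$anchorDepth >= spec@boxEdge / 2)
    stop("build error: outer-leaflet head beads would leave the box")
  rot <- withSeed(spec@seed + (which == "inner"), randomRotation())
  u <- fibonacciSphere(n) %*% t(rot)
  # local tangent frame per anchor
  ref <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  flip <- abs(u[, 3]) > 0.9
  ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
  t1 <- normalizeRows(cbind(
    ref[, 2] * u[, 3] - ref[, 3] * u[, 2],
    ref[, 3] * u[, 1] - ref[, 1] * u[, 3],
    ref[, 1] * u[, 2] - ref[, 2] * u[, 1]))
  # radial coordinate of each bead: head bead outermost for the outer
  # leaflet, innermost for the inner leaflet; phosphate on the sphere.
  sgn <- if (which == "outer") -1 else 1
  rBead <- rRef + sgn * (lay$depth - lay$anchorDepth)
  centre <- rep(spec@boxEdge / 2, 3)
  nb <- 12L
  coords <- matrix(0, n * nb, 3)
  for (k in seq_len(nb)) {
    rows <- seq.int(k, by = nb, length.out = n)
    coords[rows, ] <- rep(centre, each = n) + rBead[k] * u + lay$lateral[k] * t1
  }
  beads <- data.frame(
    index = seq_len(n * nb),
    molId = rep(seq_len(n), each = nb),
    species = spec@species,
    beadName = rep(template@beads$name, n),
    group = "BILAYER",
    leaflet = which)
  sys <- new("ParticleSystem", beads = beads, coords = coords,
             box = rep(spec@boxEdge, 3),
             provenance = list(spec = spec, seed = spec@seed,
                               stage = "leaflet", leaflet = which))
  validObject(sys)
  sys
}

# Combine particle systems (same box), renumbering beads and molecules.
combineSystems <- function(..., provenance) {
  parts <- list(...)
  beads <- do.call(rbind, lapply(parts, function(p) p@beads))
  coords <- do.call(rbind, lapply(parts, function(p) p@coords))
  offs <- 0L
  molOff <- 0L
  for (p in parts) {
    n <- nrow(p@beads)
    if (n == 0) next
    rows <- seq.int(offs + 1L, offs + n)
    beads$index[rows] <- rows
    beads$molId[rows] <- p@beads$molId + molOff
    molOff <- molOff + length(unique(p@beads$molId))
    offs <- offs + n
  }
  new("ParticleSystem", beads = beads, coords = coords,
      box = parts[[1]]@box, provenance = provenance)
}

#' Solvate a bilayer system inside and out
#'
#' Adds water beads on a jittered simple-cubic lattice: the inner group
#' strictly inside an exclusion sphere below the inner-leaflet head
#' beads, the outer group filling the box outside an exclusion sphere
#' above the outermost lipid bead.  Exclusion radii include the jitter
#' envelope, so no water bead comes closer than `minSeparation` to any
#' lipid bead.  Requested counts are honoured exactly by trimming the
#' candidate beads closest to the exclusion shells (deterministic
#' tie-break by lattice generation order).
#'
#' @param system a [ParticleSystem-class] containing both leaflets.
#' @param spec the [VesicleSpec-class] used for the build.
#' @return the system with `INNER_WATER` and `OUTER_WATER` beads added.
#' @export
solvateVesicle <- function(system, spec) {
  b <- system@beads
  if (!all(c("outer", "inner") %in% b$leaflet))
    stop("system must contain both leaflets before solvation")
  centre <- rep(spec@boxEdge / 2, 3)
  rLip <- rowNorms(sweep(system@coords, 2, centre))
  margin <- spec@minSeparation + sqrt(3) * spec@jitter
  rInExcl <- min(rLip) - margin
  rOutExcl <- max(rLip) + margin
  if (rInExcl <= 0 && !is.na(spec@nWaterIn) && spec@nWaterIn > 0)
    stop("capacity error: no room for inner water (maximum 0 beads)")
  s <- spec@latticeSpacing
  n1 <- floor(spec@boxEdge / s)
  ax <- (seq_len(n1) - 1) * s + (spec@boxEdge - (n1 - 1) * s) / 2
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE))
  rGrid <- rowNorms(sweep(grid, 2, centre))
  pickWater <- function(cand, keepN, fromShell) {
    # cand: candidate indices into grid; fromShell: distance to the
    # exclusion shell (smaller = trimmed first); ties by lattice order.
    if (is.na(keepN)) return(cand)
    if (keepN > length(cand))
      stop("capacity error: requested ", keepN, " water beads but the ",
           "lattice holds at most ", length(cand))
    cand[order(-fromShell, cand)][seq_len(keepN)]
  }
  innerCand <- which(rGrid <= rInExcl)
  outerCand <- which(rGrid >= rOutExcl)
  innerSel <- sort(pickWater(innerCand, spec@nWaterIn, rInExcl - rGrid[innerCand]))
  outerSel <- sort(pickWater(outerCand, spec@nWaterOut, rGrid[outerCand] - rOutExcl))
  nIn <- length(innerSel); nOut <- length(outerSel)
  wcoords <- grid[c(innerSel, outerSel), , drop = FALSE]
  if (spec@jitter > 0 && nrow(wcoords) > 0) {
    jit <- withSeed(spec@seed + 2L,
                    matrix(runif(3 * nrow(wcoords), -spec@jitter, spec@jitter),
                           ncol = 3))
    wcoords <- wcoords + jit
    wcoords <- wcoords %% spec@boxEdge
  }
  if (nIn + nOut == 0) {
    out <- system
    out@provenance <- c(system@provenance[setdiff(names(system@provenance), "stage")],
                        list(stage = "solvated"))
    return(out)
  }
  molStart <- max(b$molId)
  wbeads <- data.frame(
    index = nrow(b) + seq_len(nIn + nOut),
    molId = molStart + seq_len(nIn + nOut),
    species = "W", beadName = "W",
    group = rep(c("INNER_WATER", "OUTER_WATER"), c(nIn, nOut)),
    leaflet = NA_character_)
  out <- new("ParticleSystem",
             beads = rbind(b, wbeads),
             coords = rbind(system@coords, wcoords),
             box = system@box,
             provenance = list(spec = spec, seed = spec@seed, stage = "solvated"))
  validObject(out)
  out
}

#' Build a whole spherical liposome
#'
#' Places the outer and inner leaflets, merges them, and solvates the
#' core and the outer box.  All lipid beads are labelled `BILAYER`; the
#' water beads form the `INNER_WATER` and `OUTER_WATER` groups, the
#' three-portion partition used for separate temperature coupling.
#'
#' @param spec a [VesicleSpec-class]; see [defaultVesicleSpec()] for the
#'   packaged 30 nm DPPC configuration.
#' @return a [ParticleSystem-class].
#' @examples
#' \donttest{
#' tiny <- vesicleSpec(outerDiameter = 10, boxEdge = 16, seed = 7)
#' sys <- buildVesicle(tiny)
#' table(groupLabels(sys))
#' }
#' @export
buildVesicle <- function(spec) {
  validObject(spec)
  outer <- placeLeaflet(spec, "outer")
  inner <- placeLeaflet(spec, "inner")
  lipids <- combineSystems(outer, inner,
                           provenance = list(spec = spec, seed = spec@seed,
                                             stage = "bilayer"))
  solvateVesicle(lipids, spec)
}

setMethod("nBeads", "ParticleSystem", function(x) nrow(x@beads))
setMethod("nMolecules", "ParticleSystem", function(x) length(unique(x@beads$molId)))
setMethod("beadData", "ParticleSystem", function(x) x@beads)
setMethod("coords", "ParticleSystem", function(x) x@coords)
setMethod("boxVector", "ParticleSystem", function(x) x@box)
setMethod("groupLabels", "ParticleSystem", function(x) x@beads$group)

setMethod("show", "ParticleSystem", function(object) {
  cat("ParticleSystem:", nBeads(object), "beads,",
      nMolecules(object), "molecules\n")
  cat("  box:", paste(sprintf("%.3f", object@box), collapse = " x "), "nm\n")
  grp <- table(object@beads$group, useNA = "ifany")
  for (g in names(grp)) cat(sprintf("  %-12s %d beads\n", g, grp[[g]]))
  if (!is.null(object@provenance$stage))
    cat("  stage:", object@provenance$stage, "\n")
})

setMethod("show", "VesicleSpec", function(object) {
  cat("VesicleSpec:", object@species, "vesicle, outer diameter",
      object@outerDiameter, "nm, APL", object@apl, "nm^2\n")
  cat(sprintf("  leaflet radii %.3f / %.3f nm, box %.1f nm, seed %d\n",
              object@rOutRef, object@rInRef, object@boxEdge, object@seed))
})
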