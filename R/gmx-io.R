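# Readers/writers for the GROMACS-dialect formats the toolkit touches:
# GRO structures, NDX index groups, TOP topologies and MDP run
# parameters, plus the multi-frame-GRO trajectory backend.
# All writers are deterministic byte-for-byte for identical inputs.

groAtomLines <- function(beads, coords) {
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
          beads$molId %% 100000L,
          substr(beads$species, 1, 5),
          substr(beads$beadName, 1, 5),
          beads$index %% 100000L,
          coords[, 1], coords[, 2], coords[, 3])
}

#' Write a structure file (GRO dialect)
#'
#' Fixed-width format: title, atom count, one line per bead (residue
#' number and name, bead name, atom number, x y z in nm to 3 decimals),
#' box line.  Residue and atom numbers wrap modulo 100,000 per the
#' format convention.
#'
#' @param system a [ParticleSystem-class].
#' @param path output path.
#' @param title title line (keep deterministic for reproducible bytes).
#' @return the path, invisibly.
#' @export
writeGro <- function(system, path, title = "vesica system") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, sprintf("%d", nBeads(system))), con)
  if (nBeads(system) > 0)
    writeLines(groAtomLines(system@beads, system@coords), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     system@box[1], system@box[2], system@box[3]), con)
  invisible(path)
}

parseGroBlock <- function(lines) {
  natoms <- as.integer(trimws(lines[2]))
  if (is.na(natoms)) stop("malformed GRO: bad atom count line")
  if (length(lines) < natoms + 3L) stop("malformed GRO: truncated frame")
  if (natoms == 0L) {
    boxf <- as.numeric(strsplit(trimws(lines[3L]), "[[:space:]]+")[[1]])
    return(list(
      beads = data.frame(index = integer(), molId = integer(),
                         species = character(), beadName = character(),
                         group = character(), leaflet = character()),
      coords = matrix(numeric(), 0, 3), box = boxf[1:3], title = lines[1]))
  }
  al <- lines[seq.int(3L, 2L + natoms)]
  resnr <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  beadName <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  boxf <- as.numeric(strsplit(trimws(lines[natoms + 3L]), "[[:space:]]+")[[1]])
  newMol <- c(TRUE, resnr[-1] != resnr[-natoms] | resname[-1] != resname[-natoms])
  list(
    beads = data.frame(index = seq_len(natoms), molId = cumsum(newMol),
                       species = resname, beadName = beadName,
                       group = NA_character_, leaflet = NA_character_),
    coords = cbind(x, y, z), box = boxf[1:3], title = lines[1])
}

#' Read a structure file (GRO dialect)
#'
#' Molecule ids are inferred from residue-number/name changes; group
#' labels are unknown to the format and left `NA` (apply an NDX file
#' with [applyGroups()]).
#'
#' @param path a GRO file.
#' @return a [ParticleSystem-class].
#' @export
readGro <- function(path) {
  blk <- parseGroBlock(readLines(path, warn = FALSE))
  sys <- new("ParticleSystem", beads = blk$beads, coords = blk$coords,
             box = blk$box, provenance = list(source = path))
  validObject(sys)
  sys
}

#' Write temperature-coupling index groups (NDX dialect)
#'
#' Writes the three canonical groups `[ INNER_WATER ]`, `[ BILAYER ]`
#' and `[ OUTER_WATER ]` as 1-based bead indices, 15 per line, after
#' checking that the labels partition the bead set.  When the system
#' carries leaflet labels, auxiliary `[ OUTER_LEAFLET ]` and
#' `[ INNER_LEAFLET ]` groups are appended for analysis convenience.
#'
#' @param system a [ParticleSystem-class] with group labels assigned.
#' @param path output path.
#' @param leafletGroups also write the per-leaflet auxiliary groups.
#' @return the path, invisibly.
#' @export
writeNdx <- function(system, path, leafletGroups = TRUE) {
  grp <- system@beads$group
  if (anyNA(grp))
    stop("consistency error: ", sum(is.na(grp)), " beads have no group label")
  bad <- setdiff(unique(grp), .canonicalGroups)
  if (length(bad))
    stop("consistency error: unknown group label(s): ", paste(bad, collapse = ", "))
  groups <- lapply(setNames(.canonicalGroups, .canonicalGroups),
                   function(g) which(grp == g))
  if (sum(lengths(groups)) != length(grp))
    stop("consistency error: group labels do not partition the beads")
  if (leafletGroups && "leaflet" %in% names(system@beads) &&
      any(!is.na(system@beads$leaflet))) {
    lf <- system@beads$leaflet
    groups$OUTER_LEAFLET <- which(!is.na(lf) & lf == "outer")
    groups$INNER_LEAFLET <- which(!is.na(lf) & lf == "inner")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(groups)) {
    writeLines(paste0("[ ", g, " ]"), con)
    idx <- groups[[g]]
    if (length(idx)) {
      rows <- split(idx, ceiling(seq_along(idx) / 15))
      writeLines(vapply(rows, function(r) paste(sprintf("%d", r), collapse = " "), ""),
                 con)
    }
  }
  invisible(path)
}

#' Read an index file (NDX dialect)
#'
#' @param path an NDX file.
#' @return named list of 1-based integer index vectors.
#' @export
readNdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub(";.*$", "", lines))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^\\[.*\\]$", lines)
  if (!any(hdr)) stop("not an ndx file: no [ group ] headers")
  grpAt <- cumsum(hdr)
  names <- trimws(gsub("\\[|\\]", "", lines[hdr]))
  out <- lapply(seq_along(names), function(g) {
    body <- lines[!hdr & grpAt == g]
    if (!length(body)) return(integer())
    as.integer(unlist(strsplit(body, "[[:space:]]+")))
  })
  setNames(out, names)
}

#' Apply NDX groups to a particle system
#'
#' Assigns the three canonical group labels from an index-file listing;
#' labels, not geometry, are authoritative.
#'
#' @param system a [ParticleSystem-class].
#' @param ndx a named list as returned by [readNdx()].
#' @return the relabelled system.
#' @export
applyGroups <- function(system, ndx) {
  grp <- rep(NA_character_, nBeads(system))
  for (g in intersect(.canonicalGroups, names(ndx))) grp[ndx[[g]]] <- g
  system@beads$group <- grp
  if (all(c("OUTER_LEAFLET", "INNER_LEAFLET") %in% names(ndx))) {
    lf <- rep(NA_character_, nBeads(system))
    lf[ndx$OUTER_LEAFLET] <- "outer"
    lf[ndx$INNER_LEAFLET] <- "inner"
    system@beads$leaflet <- lf
  }
  validObject(system)
  system
}

#' Write a topology file (TOP dialect)
#'
#' Includes the packaged parameter file and lists molecule counts in
#' build order (adjacent molecules of the same species are merged into
#' one count line).
#'
#' @param system a built [ParticleSystem-class]; systems without build
#'   provenance (e.g. read from a bare structure file) are rejected.
#' @param path output path.
#' @param include include line target (default: the packaged parameter
#'   file name).
#' @param name system title.
#' @return the path, invisibly.
#' @export
writeTop <- function(system, path, include = "martini_v2x_cg.itp",
                     name = "vesica system") {
  if (is.null(system@provenance$spec))
    stop("cannot write a topology for a system without build provenance")
  b <- system@beads
  reg <- lipidRegistry()
  molSpecies <- b$species[!duplicated(b$molId)]
  unknown <- setdiff(toupper(unique(molSpecies)), names(reg))
  if (length(unknown))
    stop("species without a packaged template: ", paste(unknown, collapse = ", "))
  runs <- rle(molSpecies)
  lines <- c(
    sprintf('#include "%s"', include),
    "",
    "[ system ]",
    name,
    "",
    "[ molecules ]",
    "; name  count",
    sprintf("%-6s %d", reg[toupper(runs$values)], runs$lengths))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run-parameter file (MDP dialect)
#'
#' Emits the leap-frog integrator, time step and step count, the Verlet
#' cutoff scheme with 1.2 nm LJ/Coulomb cutoffs, v-rescale temperature
#' coupling over the three portion groups (`tc-grps`), per-group
#' reference temperatures, and Parrinello-Rahman semi-isotropic
#' pressure coupling.
#'
#' @param protocol a [ThermalProtocol-class].
#' @param path output path.
#' @param system optional [ParticleSystem-class]; when given, the
#'   protocol's group names are checked against the system's labels.
#' @return the path, invisibly.
#' @export
writeMdp <- function(protocol, path, system = NULL) {
  validObject(protocol)
  if (!is.null(system)) {
    have <- unique(system@beads$group)
    missing <- setdiff(names(protocol@groupTemps), have)
    if (length(missing))
      stop("consistency error: protocol groups absent from system: ",
           paste(missing, collapse = ", "))
  }
  kv <- c(
    integrator = "md",
    dt = sprintf("%g", protocol@dt),
    nsteps = sprintf("%.0f", protocol@nSteps),
    `cutoff-scheme` = protocol@cutoffScheme,
    rvdw = sprintf("%g", protocol@rc),
    rcoulomb = sprintf("%g", protocol@rc),
    coulombtype = "cut-off",
    epsilon_r = "15",
    `vdw-modifier` = "Potential-shift-Verlet",
    tcoupl = protocol@thermostat,
    `tc-grps` = paste(names(protocol@groupTemps), collapse = " "),
    tau_t = paste(rep(sprintf("%g", protocol@tauT), 3), collapse = " "),
    ref_t = paste(sprintf("%g", protocol@groupTemps), collapse = " "),
    pcoupl = protocol@barostat,
    pcoupltype = protocol@pressureCoupling,
    tau_p = sprintf("%g", protocol@tauP),
    ref_p = if (protocol@pressureCoupling == "semiisotropic")
      sprintf("%g %g", protocol@refPressure, protocol@refPressure)
      else sprintf("%g", protocol@refPressure),
    compressibility = if (protocol@pressureCoupling == "semiisotropic")
      "3e-4 3e-4" else "3e-4")
  writeLines(sprintf("%-22s = %s", names(kv), kv), path)
  invisible(path)
}

#' Construct a thermostat/barostat protocol
#'
#' @param phase `"equilibration"` or `"production"`.
#' @param dt time step in ps (default 0.01 ps = 10 fs).
#' @param nSteps step count.
#' @param groupTemps named temperatures (K) for `INNER_WATER`,
#'   `BILAYER`, `OUTER_WATER`, in that canonical order.
#' @param tauT thermostat time constant, ps.
#' @param tauP barostat time constant, ps (default 13).
#' @param refPressure reference pressure, bar.
#' @param pressureCoupling `"semiisotropic"` (default, as emitted for
#'   the vesicle runs) or `"isotropic"`.
#' @param rc cutoff in nm for both potentials.
#' @return a [ThermalProtocol-class].
#' @export
thermalProtocol <- function(phase = c("production", "equilibration"),
                            dt = 0.01, nSteps = 30000,
                            groupTemps = c(INNER_WATER = 300, BILAYER = 300,
                                           OUTER_WATER = 300),
                            tauT = 1.0, tauP = 13, refPressure = 1,
                            pressureCoupling = c("semiisotropic", "isotropic"),
                            rc = 1.2) {
  phase <- match.arg(phase)
  pressureCoupling <- match.arg(pressureCoupling)
  p <- new("ThermalProtocol", phase = phase, dt = dt, nSteps = nSteps,
           groupTemps = groupTemps[.canonicalGroups],
           thermostat = "v-rescale", barostat = "parrinello-rahman",
           tauT = tauT, tauP = tauP, refPressure = refPressure,
           pressureCoupling = pressureCoupling, cutoffScheme = "Verlet",
           rc = rc)
  validObject(p)
  p
}

#' The 300 ps equilibration protocol
#'
#' 10 fs steps at 1 bar with all three portions coupled to 300 K.
#'
#' @return a [ThermalProtocol-class].
#' @export
equilibrationProtocol <- function() {
  thermalProtocol("equilibration", dt = 0.01, nSteps = 30000)
}

#' A portion-selective heating production protocol
#'
#' One portion (inner water core, lipid bilayer or outside water) is
#' coupled to the hot temperature while the other two stay at the base
#' temperature; defaults emit the 230 ns, 10 fs-step run heated from
#' 300 K to 390 K.
#'
#' @param portion which group to heat.
#' @param hotTemp heated-group temperature, K.
#' @param baseTemp temperature of the other two groups, K.
#' @param lengthNs production length in ns.
#' @param dt time step in ps.
#' @return a [ThermalProtocol-class].
#' @export
heatingProtocol <- function(portion = c("BILAYER", "INNER_WATER", "OUTER_WATER"),
                            hotTemp = 390, baseTemp = 300,
                            lengthNs = 230, dt = 0.01) {
  portion <- match.arg(portion)
  temps <- setNames(rep(baseTemp, 3), .canonicalGroups)
  temps[portion] <- hotTemp
  thermalProtocol("production", dt = dt,
                  nSteps = round(lengthNs * 1000 / dt), groupTemps = temps)
}

#' Emit the full simulation input set for one build
#'
#' Writes `<prefix>.gro`, `<prefix>.ndx`, `<prefix>.top`,
#' `<prefix>_eq.mdp` (300 ps all-300 K equilibration) and one
#' `<prefix>_heat_<group>.mdp` production file per portion.
#'
#' @param system a built [ParticleSystem-class].
#' @param prefix output path prefix.
#' @param hotTemp,lengthNs heating-protocol parameters.
#' @return named character vector of the written paths, invisibly.
#' @export
emitSimulationInputs <- function(system, prefix, hotTemp = 390, lengthNs = 230) {
  paths <- c(gro = paste0(prefix, ".gro"), ndx = paste0(prefix, ".ndx"),
             top = paste0(prefix, ".top"), eq = paste0(prefix, "_eq.mdp"))
  writeGro(system, paths["gro"])
  writeNdx(system, paths["ndx"])
  writeTop(system, paths["top"])
  writeMdp(equilibrationProtocol(), paths["eq"], system)
  for (g in .canonicalGroups) {
    p <- paste0(prefix, "_heat_", tolower(g), ".mdp")
    writeMdp(heatingProtocol(g, hotTemp = hotTemp, lengthNs = lengthNs), p, system)
    paths[paste0("heat_", tolower(g))] <- p
  }
  invisible(paths)
}

setMethod("show", "ThermalProtocol", function(object) {
  cat("ThermalProtocol (", object@phase, "): dt ", object@dt, " ps, ",
      sprintf("%.0f", object@nSteps), " steps\n", sep = "")
  cat("  ref_t:", paste(sprintf("%s=%gK", names(object@groupTemps),
                                object@groupTemps), collapse = ", "), "\n")
  cat("  ", object@thermostat, "+", object@barostat,
      paste0("(", object@pressureCoupling, ", tau_p ", object@tauP, " ps)"), "\n")
})
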