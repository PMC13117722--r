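# Lipid templates and force-field parameter access.
#
# The parameter set ships as a plain-text file in the GROMACS itp
# dialect (inst/extdata/martini_v2x_cg.itp) so users can substitute a
# force-field revision without touching code.

defaultParamFile <- function() {
  system.file("extdata", "martini_v2x_cg.itp", package = "vesica", mustWork = TRUE)
}

registryFile <- function() {
  system.file("extdata", "lipid_registry.txt", package = "vesica", mustWork = TRUE)
}

# Strip comments/blank lines and split an itp file into named sections.
# Repeated section names (e.g. several [ moleculetype ] blocks) are kept
# in order.
itpSections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  isHdr <- grepl("^\\[.*\\]$", lines)
  if (!any(isHdr)) stop("not an itp file: no [ section ] headers found")
  hdrIdx <- which(isHdr)
  name <- tolower(trimws(gsub("\\[|\\]", "", lines[hdrIdx])))
  end <- c(hdrIdx[-1] - 1L, length(lines))
  out <- vector("list", length(hdrIdx))
  for (s in seq_along(hdrIdx)) {
    body <- if (hdrIdx[s] + 1L > end[s]) character() else lines[(hdrIdx[s] + 1L):end[s]]
    out[[s]] <- list(name = name[s], body = body)
  }
  out
}

splitFields <- function(x) strsplit(trimws(x), "[[:space:]]+")

#' Parse a coarse-grained parameter file (itp dialect)
#'
#' Reads the sections this toolkit uses: `[ nonbond_params ]` (pairwise
#' sigma/epsilon over bead types) and each `[ moleculetype ]` with its
#' `[ atoms ]`, `[ bonds ]` and `[ angles ]` blocks.
#'
#' @param path path to an itp file.
#' @return a list with elements `nonbonded` (a [NonbondedParams-class],
#'   or `NULL` if the file has no pair table) and `molecules` (named
#'   list of [LipidTemplate-class]-shaped records; single-bead molecules
#'   such as water are returned as plain lists).
#' @export
readItp <- function(path) {
  secs <- itpSections(readLines(path, warn = FALSE))
  nb <- NULL
  for (s in secs) {
    if (s$name == "nonbond_params") {
      f <- splitFields(s$body)
      df <- data.frame(
        a = vapply(f, `[`, "", 1L), b = vapply(f, `[`, "", 2L),
        sigma = as.numeric(vapply(f, `[`, "", 4L)),
        epsilon = as.numeric(vapply(f, `[`, "", 5L))
      )
      types <- sort(unique(c(df$a, df$b)))
      S <- matrix(NA_real_, length(types), length(types), dimnames = list(types, types))
      E <- S
      for (r in seq_len(nrow(df))) {
        S[df$a[r], df$b[r]] <- S[df$b[r], df$a[r]] <- df$sigma[r]
        E[df$a[r], df$b[r]] <- E[df$b[r], df$a[r]] <- df$epsilon[r]
      }
      nb <- new("NonbondedParams", types = types, sigma = S, epsilon = E,
                epsR = 15, cutoff = 1.2)
    }
  }
  mols <- list()
  i <- 1L
  while (i <= length(secs)) {
    if (secs[[i]]$name == "moleculetype") {
      molName <- splitFields(secs[[i]]$body[1])[[1]][1]
      atoms <- bonds <- angles <- NULL
      j <- i + 1L
      while (j <= length(secs) && secs[[j]]$name != "moleculetype") {
        f <- splitFields(secs[[j]]$body)
        if (secs[[j]]$name == "atoms" && length(f)) {
          atoms <- data.frame(
            index = as.integer(vapply(f, `[`, "", 1L)),
            type = vapply(f, `[`, "", 2L),
            name = vapply(f, `[`, "", 5L),
            charge = as.numeric(vapply(f, `[`, "", 7L))
          )
        } else if (secs[[j]]$name == "bonds" && length(f)) {
          bonds <- data.frame(
            i = as.integer(vapply(f, `[`, "", 1L)),
            j = as.integer(vapply(f, `[`, "", 2L)),
            b0 = as.numeric(vapply(f, `[`, "", 4L)),
            k = as.numeric(vapply(f, `[`, "", 5L))
          )
        } else if (secs[[j]]$name == "angles" && length(f)) {
          angles <- data.frame(
            i = as.integer(vapply(f, `[`, "", 1L)),
            j = as.integer(vapply(f, `[`, "", 2L)),
            k = as.integer(vapply(f, `[`, "", 3L)),
            theta0 = as.numeric(vapply(f, `[`, "", 5L)),
            kAngle = as.numeric(vapply(f, `[`, "", 6L))
          )
        }
        j <- j + 1L
      }
      mols[[molName]] <- list(name = molName, atoms = atoms,
                              bonds = bonds, angles = angles)
      i <- j
    } else i <- i + 1L
  }
  list(nonbonded = nb, molecules = mols)
}

paramCache <- function() {
  if (is.null(.vesicaEnv$params))
    .vesicaEnv$params <- readItp(defaultParamFile())
  .vesicaEnv$params
}

lipidRegistry <- function() {
  if (is.null(.vesicaEnv$registry)) {
    lines <- readLines(registryFile(), warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    f <- splitFields(lines)
    .vesicaEnv$registry <- setNames(vapply(f, `[`, "", 2L),
                                    toupper(vapply(f, `[`, "", 1L)))
  }
  .vesicaEnv$registry
}

molToTemplate <- function(mol) {
  atoms <- mol$atoms
  tails <- 5:12
  unsat <- as.integer(intersect(atoms$index[atoms$type == "C3"], tails))
  new("LipidTemplate",
      name = mol$name,
      beads = data.frame(index = atoms$index, name = atoms$name,
                         type = atoms$type, charge = atoms$charge),
      bonds = mol$bonds, angles = mol$angles,
      unsaturatedBeads = sort(unsat))
}

#' Retrieve a packaged lipid template
#'
#' Looks a species up in the plain-text registry and materialises its
#' template from the packaged parameter file.  DPPC is fully saturated;
#' DOPC carries a cis double bond at the third bead of each tail (beads
#' 7 and 11); POPC carries one on tail B only (bead 11, modelling the
#' sn-2 oleoyl chain).
#'
#' @param name species name, case-insensitive: `"DPPC"`, `"DOPC"` or
#'   `"POPC"`.
#' @return a [LipidTemplate-class].
#' @examples
#' tpl <- lipidTemplate("DOPC")
#' tpl@unsaturatedBeads  # 7 and 11
#' @export
lipidTemplate <- function(name) {
  key <- toupper(name)
  reg <- lipidRegistry()
  lipids <- setdiff(names(reg), "W")
  if (!key %in% lipids)
    stop("unknown lipid '", name, "'; supported species: ",
         paste(lipids, collapse = ", "))
  cacheKey <- paste0("tpl_", key)
  if (is.null(.vesicaEnv[[cacheKey]])) {
    mol <- paramCache()$molecules[[reg[[key]]]]
    if (is.null(mol)) stop("species '", key, "' missing from parameter file")
    tpl <- molToTemplate(mol)
    validObject(tpl)
    expected <- switch(key, DPPC = integer(), DOPC = c(7L, 11L), POPC = 11L, NULL)
    if (!is.null(expected) && !identical(tpl@unsaturatedBeads, expected))
      stop("packaged template for ", key, " has inconsistent unsaturation flags")
    .vesicaEnv[[cacheKey]] <- tpl
  }
  .vesicaEnv[[cacheKey]]
}

#' Packaged nonbonded parameter table
#'
#' The pair table read from the packaged parameter file, with the
#' default relative dielectric (15) and cutoff (1.2 nm).
#'
#' @return a [NonbondedParams-class].
#' @export
defaultNonbonded <- function() paramCache()$nonbonded

#' The coarse-grained water bead
#'
#' @param volume nominal bead volume in nm^3 (default 0.12, i.e. four
#'   0.03 nm^3 waters).
#' @return a [WaterBead-class].
#' @export
waterBead <- function(volume = 0.12) {
  new("WaterBead", type = "P4", charge = 0, representedMolecules = 4L,
      volume = volume)
}

#' Look up a nonbonded pair
#'
#' @param a,b bead type names.
#' @param params a [NonbondedParams-class] (defaults to the packaged
#'   table).
#' @return named numeric: `sigma` (nm) and `epsilon` (kJ/mol).  The
#'   result is symmetric in `a` and `b`.
#' @export
lookupNonbonded <- function(a, b, params = defaultNonbonded()) {
  miss <- setdiff(c(a, b), params@types)
  if (length(miss))
    stop("missing nonbonded parameters for bead type(s): ",
         paste(miss, collapse = ", "))
  s <- params@sigma[a, b]
  e <- params@epsilon[a, b]
  if (is.na(s) || is.na(e))
    stop("missing nonbonded parameters for pair (", a, ", ", b, ")")
  c(sigma = s, epsilon = e)
}

#' Boltzmann-average angle under a cosine-harmonic potential
#'
#' Computes the canonical mean of the bending angle theta under
#' U(theta) = k/2 (cos theta - cos theta0)^2 including the sin(theta)
#' Jacobian of the polar angle, by deterministic midpoint quadrature
#' over theta in (0, 180) degrees.  This is the reference value that
#' sampled tail kink angles converge to; for the unsaturated-bead angle
#' (theta0 = 120 deg, k = 45 kJ/mol) it sits a few degrees above theta0
#' because the Jacobian weights open angles.
#'
#' @param theta0 equilibrium angle in degrees, 0 < theta0 < 180.
#' @param kAngle force constant in kJ/mol, > 0.
#' @param temperature in K, > 0.
#' @param nGrid number of quadrature nodes.
#' @return the mean angle in degrees.
#' @export
equilibriumAngleMean <- function(theta0, kAngle, temperature, nGrid = 20001L) {
  if (temperature <= 0) stop("temperature must be positive")
  if (kAngle <= 0) stop("kAngle must be positive")
  if (theta0 <= 0 || theta0 >= 180) stop("theta0 must lie in (0, 180) degrees")
  th <- (seq_len(nGrid) - 0.5) * pi / nGrid
  u <- 0.5 * kAngle * (cos(th) - cos(theta0 * pi / 180))^2
  logw <- -(u - min(u)) / (.kB * temperature) + log(sin(th))
  w <- exp(logw - max(logw))
  sum(th * w) / sum(w) * 180 / pi
}

# Boltzmann density of the cosine-harmonic angle (with Jacobian),
# unnormalised, theta in radians.  Shared with the rejection sampler.
angleDensity <- function(th, theta0, kAngle, temperature) {
  u <- 0.5 * kAngle * (cos(th) - cos(theta0 * pi / 180))^2
  exp(-u / (.kB * temperature)) * sin(th)
}

#' Write a lipid template in the itp dialect
#'
#' Serialises one template as a `[ moleculetype ]` block with
#' `[ atoms ]`, `[ bonds ]` and `[ angles ]`; [readItp()] on the result
#' reproduces the template exactly.
#'
#' @param template a [LipidTemplate-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeLipidItp <- function(template, path) {
  b <- template@beads
  lines <- c(
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s    1", template@name),
    "",
    "[ atoms ]",
    "; id type resnr residue atom cgnr charge",
    sprintf("%4d %4s %4d %6s %5s %4d %8.3f",
            b$index, b$type, 1L, template@name, b$name, b$index, b$charge),
    "",
    "[ bonds ]",
    "; i j func b0 kb",
    sprintf("%3d %3d 1 %7.3f %8.1f",
            template@bonds$i, template@bonds$j,
            template@bonds$b0, template@bonds$k),
    "",
    "[ angles ]",
    "; i j k func theta0 ka",
    sprintf("%3d %3d %3d 2 %7.1f %7.1f",
            template@angles$i, template@angles$j, template@angles$k,
            template@angles$theta0, template@angles$kAngle)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a single-molecule template file
#'
#' @param path an itp file containing one `[ moleculetype ]`.
#' @return a [LipidTemplate-class].
#' @export
readLipidItp <- function(path) {
  mols <- readItp(path)$molecules
  if (length(mols) != 1L) stop("expected exactly one moleculetype in ", path)
  tpl <- molToTemplate(mols[[1]])
  validObject(tpl)
  tpl
}

# Per-bead types and charges for a system, via the species templates.
beadTypesCharges <- function(system) {
  b <- system@beads
  type <- character(nrow(b))
  charge <- numeric(nrow(b))
  for (sp in unique(b$species)) {
    sel <- b$species == sp
    if (toupper(sp) == "W") {
      wb <- waterBead()
      type[sel] <- wb@type
      charge[sel] <- wb@charge
    } else {
      tpl <- lipidTemplate(sp)
      # match by bead name within each molecule
      m <- match(b$beadName[sel], tpl@beads$name)
      if (anyNA(m)) stop("bead names of species ", sp, " not in its template")
      type[sel] <- tpl@beads$type[m]
      charge[sel] <- tpl@beads$charge[m]
    }
  }
  list(type = type, charge = charge)
}

#' Net charge of a particle system
#'
#' @param system a [ParticleSystem-class].
#' @return total charge in e (0 for every system this toolkit builds).
#' @export
systemNetCharge <- function(system) sum(beadTypesCharges(system)$charge)

setMethod("show", "LipidTemplate", function(object) {
  cat("LipidTemplate", object@name, "\n")
  cat("  12 beads,", nrow(object@bonds), "bonds,", nrow(object@angles), "angles\n")
  if (length(object@unsaturatedBeads))
    cat("  unsaturated beads:", paste(object@unsaturatedBeads, collapse = ", "), "\n")
  else cat("  fully saturated\n")
})

setMethod("show", "NonbondedParams", function(object) {
  cat("NonbondedParams:", length(object@types), "bead types (",
      paste(object@types, collapse = ", "), ")\n")
  cat("  eps_r =", object@epsR, ", cutoff =", object@cutoff, "nm\n")
})
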