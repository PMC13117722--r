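# Trajectory contract: streaming frames from a multi-frame GRO file or
# an in-memory array.  Frame titles carry "t= <ps>" time stamps.

#' Write a trajectory as a multi-frame GRO file
#'
#' Concatenated GRO blocks, one per frame, with `t=` time stamps in the
#' title lines; this is the package's text trajectory carrier.
#'
#' @param traj a [TrajectorySlice-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrajectoryGro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  beads <- beadData(traj)
  for (i in seq_len(nFrames(traj))) {
    fr <- getFrame(traj, i)
    writeLines(c(sprintf("frame t= %.4f", fr$time),
                 sprintf("%d", nrow(beads))), con)
    writeLines(groAtomLines(beads, fr$coords), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

parseFrameTime <- function(title, fallback) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m) && nzchar(m)) as.numeric(sub("t=\\s*", "", m)) else fallback
}

#' Open a structure + trajectory pair
#'
#' Streams frames from a multi-frame GRO trajectory against a structure
#' file that defines the bead table.  The whole file is never held in
#' memory; frames are re-read on demand.  Bead counts must agree
#' between the two files; a truncated final frame is dropped with a
#' warning reporting the complete-frame count.
#'
#' @param structurePath single-frame GRO structure.
#' @param trajectoryPath multi-frame GRO trajectory.
#' @return a [GroTrajectory-class].
#' @export
openTrajectory <- function(structurePath, trajectoryPath) {
  if (!file.exists(structurePath)) stop("structure file not found: ", structurePath)
  if (!file.exists(trajectoryPath)) stop("trajectory file not found: ", trajectoryPath)
  structure <- readGro(structurePath)
  nat <- nBeads(structure)
  con <- file(trajectoryPath, "r")
  on.exit(close(con))
  times <- numeric()
  nf <- 0L
  repeat {
    hdr <- readLines(con, n = 2L)
    if (length(hdr) == 0L) break
    if (length(hdr) < 2L) { warning("partial frame dropped; read ", nf, " frames"); break }
    natFrame <- as.integer(trimws(hdr[2]))
    if (is.na(natFrame))
      stop("malformed trajectory frame ", nf + 1L, ": bad atom count")
    if (natFrame != nat)
      stop("mismatch error: structure has ", nat, " beads but trajectory frame ",
           nf + 1L, " has ", natFrame)
    body <- readLines(con, n = natFrame + 1L)
    if (length(body) < natFrame + 1L) {
      warning("partial frame dropped; read ", nf, " complete frames")
      break
    }
    nf <- nf + 1L
    times[nf] <- parseFrameTime(hdr[1], fallback = nf - 1)
    }
  if (nf == 0L) stop("trajectory contains no complete frames")
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  new("GroTrajectory", structurePath = structurePath,
      trajectoryPath = trajectoryPath, nAtoms = nat, nFramesTotal = nf,
      frameTimesPs = times, beads = structure@beads)
}

setMethod("nFrames", "ArrayTrajectory", function(x) dim(x@coords)[3])
setMethod("nFrames", "GroTrajectory", function(x) x@nFramesTotal)
setMethod("frameTimes", "ArrayTrajectory", function(x) x@times)
setMethod("frameTimes", "GroTrajectory", function(x) x@frameTimesPs)
setMethod("nBeads", "ArrayTrajectory", function(x) dim(x@coords)[1])
setMethod("nBeads", "GroTrajectory", function(x) x@nAtoms)
setMethod("beadData", "ArrayTrajectory", function(x) x@beads)
setMethod("beadData", "GroTrajectory", function(x) x@beads)
setMethod("nMolecules", "ArrayTrajectory", function(x) length(unique(x@beads$molId)))
setMethod("nMolecules", "GroTrajectory", function(x) length(unique(x@beads$molId)))

setMethod("getFrame", "ArrayTrajectory", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > nFrames(x)) stop("frame index out of range")
  list(time = x@times[i], coords = x@coords[, , i, drop = TRUE], box = x@box[i, ])
})

setMethod("getFrame", "GroTrajectory", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > x@nFramesTotal) stop("frame index out of range")
  con <- file(x@trajectoryPath, "r")
  on.exit(close(con))
  perFrame <- x@nAtoms + 3L
  if (i > 1L) readLines(con, n = (i - 1L) * perFrame)
  blk <- parseGroBlock(readLines(con, n = perFrame))
  list(time = parseFrameTime(blk$title, fallback = i - 1),
       coords = unname(blk$coords), box = blk$box)
})

# Stream frames sequentially, calling fun(frameIndex, time, coords,
# box) for each selected frame.  For file-backed trajectories this is a
# single sequential pass regardless of the subset.
trajApply <- function(traj, frames, fun) {
  frames <- sort(unique(as.integer(frames)))
  if (is(traj, "ArrayTrajectory")) {
    for (i in frames) {
      fr <- getFrame(traj, i)
      fun(i, fr$time, fr$coords, fr$box)
    }
    return(invisible(NULL))
  }
  con <- file(traj@trajectoryPath, "r")
  on.exit(close(con))
  perFrame <- traj@nAtoms + 3L
  at <- 0L
  for (i in frames) {
    if (i - at > 1L) readLines(con, n = (i - at - 1L) * perFrame)
    blk <- parseGroBlock(readLines(con, n = perFrame))
    fun(i, parseFrameTime(blk$title, fallback = i - 1), unname(blk$coords), blk$box)
    at <- i
  }
  invisible(NULL)
}

setMethod("show", "ArrayTrajectory", function(object) {
  cat("ArrayTrajectory:", nBeads(object), "beads x", nFrames(object), "frames\n")
  tr <- range(object@times)
  cat(sprintf("  time %.3f .. %.3f ps\n", tr[1], tr[2]))
})

setMethod("show", "GroTrajectory", function(object) {
  cat("GroTrajectory:", object@nAtoms, "beads x", object@nFramesTotal,
      "frames (", basename(object@trajectoryPath), ")\n")
})
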