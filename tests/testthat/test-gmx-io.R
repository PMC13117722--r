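# Structure, index, topology and run-parameter writers plus the
# multi-frame trajectory reader.

toySystem <- function() {
  beads <- data.frame(index = 1:3, molId = c(1L, 1L, 2L), species = c("W", "W", "W"),
                      beadName = "W", group = c("INNER_WATER", "INNER_WATER",
                                                "OUTER_WATER"),
                      leaflet = NA_character_)
  new("ParticleSystem", beads = beads,
      coords = rbind(c(0.1234, 0.9, 1.5), c(2, 2.0006, 2), c(3, 3, 3.4449)),
      box = c(5, 5, 5), provenance = list(spec = "toy"))
}

test_that("GRO round-trip preserves names and coordinates to 0.001 nm", {
  sys <- toySystem()
  f <- withr::local_tempfile(fileext = ".gro")
  writeGro(sys, f)
  expect_identical(readLines(f)[2], "3")
  back <- readGro(f)
  expect_identical(beadData(back)$beadName, beadData(sys)$beadName)
  expect_identical(beadData(back)$species, beadData(sys)$species)
  expect_identical(beadData(back)$molId, beadData(sys)$molId)
  expect_lte(max(abs(coords(back) - coords(sys))), 0.0005 + 1e-12)
  expect_equal(boxVector(back), boxVector(sys))
  # writing the reread system reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".gro")
  writeGro(back, f2)
  expect_identical(readLines(f)[-1], readLines(f2)[-1])
})

test_that("an empty system writes a valid zero-atom file", {
  empty <- new("ParticleSystem",
               beads = data.frame(index = integer(), molId = integer(),
                                  species = character(), beadName = character(),
                                  group = character(), leaflet = character()),
               coords = matrix(numeric(), 0, 3), box = c(1, 1, 1),
               provenance = list())
  f <- withr::local_tempfile(fileext = ".gro")
  writeGro(empty, f)
  expect_identical(readLines(f)[2], "0")
  expect_identical(nBeads(readGro(f)), 0L)
})

test_that("the default build writes the expected atom count line", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeGro(defaultBuild(), f)
  expect_identical(readLines(f, n = 2)[2], "507072")
})

test_that("NDX groups partition the bead set and are read back intact", {
  sys <- miniVesicle()
  f <- withr::local_tempfile(fileext = ".ndx")
  writeNdx(sys, f)
  ndx <- readNdx(f)
  core <- ndx[c("INNER_WATER", "BILAYER", "OUTER_WATER")]
  expect_identical(sort(unlist(core, use.names = FALSE)), seq_len(nBeads(sys)))
  expect_identical(sum(vapply(combn(3, 2, simplify = FALSE), function(p)
    length(intersect(core[[p[1]]], core[[p[2]]])), integer(1))), 0L)
  expect_identical(length(ndx$BILAYER), sum(groupLabels(sys) == "BILAYER"))
  # labels, not geometry, are authoritative: relabelling one water bead
  # moves it between groups but the write still succeeds
  sys2 <- sys
  iw <- which(groupLabels(sys2) == "OUTER_WATER")[1]
  sys2@beads$group[iw] <- "INNER_WATER"
  f2 <- withr::local_tempfile(fileext = ".ndx")
  expect_no_error(writeNdx(sys2, f2))
  expect_identical(length(readNdx(f2)$INNER_WATER),
                   length(ndx$INNER_WATER) + 1L)
  # unlabelled bead is a consistency error
  sys3 <- sys
  sys3@beads$group[1] <- NA_character_
  expect_error(writeNdx(sys3, withr::local_tempfile()), "consistency error")
})

test_that("NDX groups applied to a bare structure restore the labels", {
  sys <- miniVesicle()
  g <- withr::local_tempfile(fileext = ".gro")
  n <- withr::local_tempfile(fileext = ".ndx")
  writeGro(sys, g); writeNdx(sys, n)
  back <- applyGroups(readGro(g), readNdx(n))
  expect_identical(groupLabels(back), groupLabels(sys))
})

test_that("topology lists molecule counts in build order", {
  f <- withr::local_tempfile(fileext = ".top")
  writeTop(miniVesicle(), f)
  lines <- readLines(f)
  expect_true(any(grepl('#include "martini_v2x_cg.itp"', lines, fixed = TRUE)))
  mol <- grep("^(DPPC|W)\\s+\\d+$", lines, value = TRUE)
  counts <- setNames(as.integer(sub("^\\S+\\s+", "", mol)),
                     sub("\\s.*$", "", mol))
  expect_identical(counts, c(DPPC = nMolecules(miniVesicle()) - 208L, W = 208L))
  # analysis-only systems without build provenance are rejected
  g <- withr::local_tempfile(fileext = ".gro")
  writeGro(miniVesicle(), g)
  expect_error(writeTop(readGro(g), withr::local_tempfile()), "provenance")
})

test_that("run-parameter files carry the three-portion heating protocol", {
  sys <- miniVesicle()
  f <- withr::local_tempfile(fileext = ".mdp")
  writeMdp(heatingProtocol("BILAYER"), f, sys)
  kv <- readLines(f)
  getv <- function(key) trimws(sub(".*=", "", grep(paste0("^", key, "\\s"),
                                                   kv, value = TRUE)))
  expect_identical(getv("ref_t"), "300 390 300")
  expect_identical(getv("tc-grps"), "INNER_WATER BILAYER OUTER_WATER")
  expect_identical(getv("tau_p"), "13")
  expect_identical(getv("integrator"), "md")
  expect_identical(getv("cutoff-scheme"), "Verlet")
  expect_identical(getv("rvdw"), "1.2")
  expect_identical(getv("rcoulomb"), "1.2")
  expect_identical(getv("tcoupl"), "v-rescale")
  expect_identical(getv("pcoupl"), "parrinello-rahman")
  expect_identical(getv("pcoupltype"), "semiisotropic")
  expect_identical(getv("nsteps"), "23000000")  # 230 ns at 10 fs
  # equilibration: 300 ps at 10 fs, everything at 300 K
  f2 <- withr::local_tempfile(fileext = ".mdp")
  writeMdp(equilibrationProtocol(), f2)
  kv <- readLines(f2)
  expect_identical(getv("dt"), "0.01")
  expect_identical(getv("nsteps"), "30000")
  expect_identical(getv("ref_t"), "300 300 300")
  # group-name mismatch against a label-free system
  g <- withr::local_tempfile(fileext = ".gro")
  writeGro(sys, g)
  expect_error(writeMdp(heatingProtocol("BILAYER"), withr::local_tempfile(),
                        readGro(g)),
               "consistency error")
  # heating the inner core targets that group only
  f3 <- withr::local_tempfile(fileext = ".mdp")
  writeMdp(heatingProtocol("INNER_WATER"), f3)
  expect_match(grep("^ref_t", readLines(f3), value = TRUE), "390 300 300")
})

test_that("trajectories stream with matching counts and increasing times", {
  rw <- randomWalkTrajectory(20, 5, 0.01, 2, seed = 9)
  d <- withr::local_tempdir()
  sgro <- file.path(d, "s.gro"); tgro <- file.path(d, "t.gro")
  f1 <- getFrame(rw, 1)
  sys <- new("ParticleSystem", beads = beadData(rw), coords = f1$coords,
             box = f1$box, provenance = list())
  writeGro(sys, sgro)
  writeTrajectoryGro(rw, tgro)
  tr <- openTrajectory(sgro, tgro)
  expect_identical(nFrames(tr), 5L)
  expect_true(all(diff(frameTimes(tr)) > 0))
  expect_equal(frameTimes(tr), (0:4) * 2)
  for (i in c(1L, 3L, 5L))
    expect_lte(max(abs(getFrame(tr, i)$coords - getFrame(rw, i)$coords)), 0.0005)
  # a structure with its own single-frame trajectory: one frame, equal coords
  one <- file.path(d, "one.gro")
  writeLines(readLines(tgro)[seq_len(nBeads(rw) + 3L)], one)
  tr1 <- openTrajectory(sgro, one)
  expect_identical(nFrames(tr1), 1L)
  expect_equal(getFrame(tr1, 1)$coords, coords(sys), tolerance = 1e-9)
  # mismatched bead counts are an explicit error
  bad <- file.path(d, "bad.gro")
  writeGro(toySystem(), bad)
  expect_error(openTrajectory(bad, tgro), "mismatch error")
  # truncated trailing frame is dropped with a warning
  trunc <- file.path(d, "trunc.gro")
  writeLines(head(readLines(tgro), -5L), trunc)
  expect_warning(tr2 <- openTrajectory(sgro, trunc), "partial")
  expect_identical(nFrames(tr2), 4L)
})

test_that("writers are deterministic byte-for-byte", {
  sys <- miniVesicle()
  d <- withr::local_tempdir()
  a <- emitSimulationInputs(sys, file.path(d, "a"))
  b <- emitSimulationInputs(sys, file.path(d, "b"))
  for (k in names(a))
    expect_identical(readLines(a[[k]]), readLines(b[[k]]))
})
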