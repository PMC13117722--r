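# Analysis operators against constructed cases and brute-force oracles.

test_that("molecular RDF bins the minimum inter-bead distance", {
  # two 2-bead molecules whose closest beads are 0.50 nm apart
  beads <- data.frame(index = 1:4, molId = c(1L, 1L, 2L, 2L), species = "W",
                      beadName = "W", group = "OUTER_WATER",
                      leaflet = NA_character_)
  xyz <- rbind(c(1, 1, 1), c(1, 1, 1.47), c(1, 1, 1.97), c(1, 1, 2.44))
  sys <- new("ParticleSystem", beads = beads, coords = xyz, box = rep(10, 3),
             provenance = list())
  r <- molecularRdf(sys, ref = 1:4, target = 1:4, rMax = 1)
  expect_equal(r@value[r@r == 0.50], 1)
  expect_equal(sum(r@value), 1)  # one neighbour per reference on average
  # a single molecule alone: self-pair excluded, all-zero histogram
  solo <- new("ParticleSystem", beads = beads[1:2, ], coords = xyz[1:2, ],
              box = rep(10, 3), provenance = list())
  expect_equal(sum(molecularRdf(solo, 1:2, 1:2, rMax = 1)@value), 0)
})

test_that("molecular RDF equals the brute-force oracle on toy systems", {
  for (seed in c(1L, 2L)) {
    sys <- randomLipidSystem(10, box = 6, seed = seed)
    b <- beadData(sys)
    got <- molecularRdf(sys, "DPPC", "DPPC", rMax = 3)
    want <- oracleMolRdf(coords(sys), boxVector(sys), b,
                         seq_len(nBeads(sys)), seq_len(nBeads(sys)), rMax = 3)
    expect_equal(got@value, want, tolerance = 1e-12)
  }
})

test_that("leaflet assignment matches the radial-rank oracle", {
  sys <- miniVesicle()
  got <- leafletAssignment(sys)
  want <- oracleLeaflets(sys)
  expect_identical(got$leaflet[order(got$molId)],
                   want$leaflet[order(want$molId)])
})

test_that("APL scales quadratically under radial inflation", {
  sys <- miniVesicle()
  a0 <- vesicleApl(sys)
  s <- 1.3
  infl <- sys
  lip <- which(groupLabels(sys) == "BILAYER")
  centre <- rep(boxVector(sys)[1] / 2, 3)
  infl@coords[lip, ] <- sweep(sweep(coords(sys)[lip, ], 2, centre) * s,
                              2, centre, `+`)
  a1 <- vesicleApl(infl)
  expect_equal(a1@combined / a0@combined, s^2, tolerance = 1e-6)
  expect_gt(a1@combined, a0@combined)  # monotone under inflation
  # degenerate selections are refused
  few <- randomLipidSystem(5, box = 6, seed = 3)
  expect_error(vesicleApl(few, "DPPC"), "at least 10")
})

test_that("group energies equal the brute-force oracle to 1e-9 relative", {
  params <- defaultNonbonded()
  # 50-bead random water system, cell-list path (box >= 3 cells)
  sysW <- randomWaterSystem(50, box = 6, seed = 7)
  idxA <- 1:25; idxB <- 26:50
  sysW@beads$group[idxA] <- "INNER_WATER"
  got <- groupInteractionEnergy(sysW, idxA, idxB, params)
  b <- beadData(sysW)
  want <- oracleEnergy(coords(sysW), boxVector(sysW), rep("P4", 50),
                       rep(0, 50), b$molId, idxA, idxB, params)
  expect_equal(got@lj, want$lj, tolerance = 1e-9)
  expect_equal(got@coulomb, want$coulomb, tolerance = 1e-9)
  # brute-force path (small box, under three cells per edge)
  sysS <- randomWaterSystem(40, box = 2.5, seed = 8)
  gotS <- groupInteractionEnergy(sysS, 1:20, 21:40, params)
  wantS <- oracleEnergy(coords(sysS), boxVector(sysS), rep("P4", 40),
                        rep(0, 40), beadData(sysS)$molId, 1:20, 21:40, params)
  expect_equal(gotS@lj, wantS$lj, tolerance = 1e-9)
  # charged lipids, intramolecular exclusion and intra-group halving
  sysL <- randomLipidSystem(6, box = 6, seed = 9)
  tc <- rep(lipidTemplate("DPPC")@beads$type, 6)
  qc <- rep(lipidTemplate("DPPC")@beads$charge, 6)
  gotL <- groupInteractionEnergy(sysL, "BILAYER", "BILAYER", params)
  wantL <- oracleEnergy(coords(sysL), boxVector(sysL), tc, qc,
                        beadData(sysL)$molId,
                        seq_len(nBeads(sysL)), seq_len(nBeads(sysL)), params)
  expect_equal(gotL@lj, wantL$lj, tolerance = 1e-9)
  expect_equal(gotL@coulomb, wantL$coulomb, tolerance = 1e-9)
  expect_false(gotL@coulomb == 0)
})

test_that("group energies are symmetric and respect the cutoff", {
  params <- defaultNonbonded()
  sysL <- randomLipidSystem(4, box = 6, seed = 10)
  sysL@beads$group[1:24] <- "BILAYER"
  sysL@beads$group[25:48] <- "INNER_WATER"  # labels are authoritative
  ab <- groupInteractionEnergy(sysL, 1:24, 25:48, params)
  ba <- groupInteractionEnergy(sysL, 25:48, 1:24, params)
  expect_equal(ab@lj, ba@lj, tolerance = 1e-12)
  expect_equal(ab@coulomb, ba@coulomb, tolerance = 1e-12)
  # two uncharged beads just beyond the cutoff interact not at all
  pair <- randomWaterSystem(2, box = 6, seed = 1)
  pair@coords <- rbind(c(1, 1, 1), c(1, 1, 1 + params@cutoff + 0.01))
  e <- groupInteractionEnergy(pair, 1, 2, params)
  expect_identical(e@lj, 0)
  expect_identical(e@coulomb, 0)
  # overlapping distinct groups are refused; coincident beads are singular
  expect_error(groupInteractionEnergy(pair, 1:2, 2, params), "overlapping")
  pair@coords[2, ] <- pair@coords[1, ]
  expect_error(groupInteractionEnergy(pair, 1, 2, params), "singular")
})

test_that("lipid-water Coulomb energy is exactly zero on built systems", {
  sys <- miniVesicle()
  for (wg in c("INNER_WATER", "OUTER_WATER")) {
    e <- groupInteractionEnergy(sys, "BILAYER", wg)
    expect_identical(e@coulomb, 0)
  }
})

test_that("kink angles recover constructed and sampled geometry", {
  tpl <- lipidTemplate("DOPC")
  beads <- data.frame(index = 1:12, molId = 1L, species = "DOPC",
                      beadName = tpl@beads$name, group = "BILAYER",
                      leaflet = NA_character_)
  # collinear tails: every angle is 180 degrees
  straight <- cbind(0, 0, seq(1, by = 0.47, length.out = 12))
  sys <- new("ParticleSystem", beads = beads, coords = straight,
             box = rep(20, 3), provenance = list())
  expect_equal(kinkAngles(sys)@mean, 180)
  # equilateral triangle at the kink triples (6,7,8) and (10,11,12)
  equi <- straight
  equi[6, ] <- c(0, 0, 1); equi[7, ] <- c(0.5, 0, 1 + sqrt(3) / 2)
  equi[8, ] <- c(1, 0, 1)
  equi[10, ] <- c(3, 0, 1); equi[11, ] <- c(3.5, 0, 1 + sqrt(3) / 2)
  equi[12, ] <- c(4, 0, 1)
  sysE <- new("ParticleSystem", beads = beads, coords = equi,
              box = rep(20, 3), provenance = list())
  expect_equal(kinkAngles(sysE)@mean, 60, tolerance = 1e-9)
  # zero-length bond vector is singular
  degen <- straight; degen[7, ] <- degen[6, ]
  sysD <- new("ParticleSystem", beads = beads, coords = degen,
              box = rep(20, 3), provenance = list())
  expect_error(kinkAngles(sysD), "singular")
  # Boltzmann-sampled chains match the quadrature mean within 3 SE
  ch <- boltzmannChainSamples(tpl, 390, 4000, seed = 21)
  ka <- kinkAngles(ch, frames = "all")
  se <- sd(ka@angles) / sqrt(ka@n)
  expect_lt(abs(ka@mean - equilibriumAngleMean(120, 45, 390)), 3 * se)
})

test_that("end-to-end distance handles limits, construction and sampling", {
  tpl <- lipidTemplate("DPPC")
  beads <- data.frame(index = 1:12, molId = 1L, species = "DPPC",
                      beadName = tpl@beads$name, group = "BILAYER",
                      leaflet = NA_character_)
  xyz <- matrix(seq_len(36) / 10, 12, 3)
  xyz[12, ] <- xyz[8, ]  # coincident end beads
  sys <- new("ParticleSystem", beads = beads, coords = xyz, box = rep(20, 3),
             provenance = list())
  expect_equal(endToEnd(sys)@mean, 0)
  # straight-built lipids keep the builder's 0.25 nm tail offset
  lf <- placeLeaflet(miniSpec(), "outer")
  expect_equal(endToEnd(lf)@mean, 0.25, tolerance = 1e-9)
  # sampled chains agree with an independent Monte-Carlo builder
  set.seed(31)
  ours <- endToEnd(boltzmannChainSamples(tpl, 390, 1500, seed = 31),
                   frames = "all")
  ref <- oracleChainEndToEnd(tpl, 390, 600)
  se <- sqrt(sd(ours@distances)^2 / ours@n + var(ref) / length(ref))
  expect_lt(abs(ours@mean - mean(ref)), 3 * se)
  # template error when beads 8/12 are missing
  part <- sys
  part@beads <- part@beads[1:8, ]; part@coords <- part@coords[1:8, ]
  expect_error(endToEnd(part), "12-bead")
})

test_that("MSD is zero for static input and invariant to time shifts", {
  st <- randomWalkTrajectory(50, 40, 0, 1, seed = 3)
  m0 <- msdDiffusion(st, dFit = 6)
  expect_equal(max(abs(m0@msd)), 0)
  expect_equal(m0@D, 0)
  rw <- randomWalkTrajectory(200, 200, 0.02, 2, seed = 4)
  m1 <- msdDiffusion(rw, dFit = 6)
  shifted <- rw
  shifted@times <- rw@times + 1000
  m2 <- msdDiffusion(shifted, dFit = 6)
  expect_equal(m1@D, m2@D, tolerance = 1e-12)
  expect_error(msdDiffusion(rw, fitWindow = c(0, 0.001)), "fewer than 3")
})

test_that("pore detection recovers punched holes and stays silent otherwise", {
  spec <- vesicleSpec(outerDiameter = 20, boxEdge = 26, seed = 3,
                      nWaterIn = 5L, nWaterOut = 5L)
  sys <- cached("poreVesicle", buildVesicle(spec))
  expect_identical(nrow(detectPores(sys)@pores), 0L)
  alpha <- 0.3
  h <- punchHole(sys, c(1, 1, 0), alpha)
  p <- detectPores(h)
  expect_identical(nrow(p@pores), 1L)
  expect_equal(p@pores$diameter[1], 2 * p@rMid * alpha, tolerance = 0.2)
  dir <- unlist(p@pores[1, c("dirX", "dirY", "dirZ")])
  expect_gt(sum(dir * c(1, 1, 0) / sqrt(2)), 0.95)
  # two antipodal holes give two antipodal pores
  h2 <- punchHole(punchHole(sys, c(0, 0, 1), alpha), c(0, 0, -1), alpha)
  p2 <- detectPores(h2)
  expect_identical(nrow(p2@pores), 2L)
  expect_lt(sum(p2@pores$dirZ), 0.01)
  expect_gt(abs(p2@pores$dirZ[1]), 0.99)
  # too fine a grid is a resolution error
  expect_error(detectPores(sys, resolution = 0.05), "resolution error")
})
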