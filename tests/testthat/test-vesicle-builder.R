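# Spherical vesicle construction: leaflet counting, placement geometry,
# solvation and the composition arithmetic.

test_that("leaflet counting inverts the area-per-lipid formula", {
  expect_identical(leafletCount(13.701, 0.46), 5128L)
  expect_identical(leafletCount(11.540, 0.46), 3638L)
  expect_identical(leafletCount(1, 4 * pi), 1L)
  expect_error(leafletCount(-1, 0.46), "positive")
  expect_error(leafletCount(10, 0), "positive")
})

test_that("leaflets are radially oriented with phosphates on the reference sphere", {
  spec <- miniSpec()
  for (which in c("outer", "inner")) {
    lf <- placeLeaflet(spec, which)
    b <- beadData(lf)
    n <- nMolecules(lf)
    expect_identical(nBeads(lf), 12L * n)
    centre <- rep(spec@boxEdge / 2, 3)
    idx <- matrix(b$index, nrow = 12)
    headB <- coords(lf)[idx[1, ], , drop = FALSE]
    phos <- coords(lf)[idx[2, ], , drop = FALSE]
    tailMid <- Reduce(`+`, lapply(5:12, function(k)
      coords(lf)[idx[k, ], , drop = FALSE])) / 8
    rRef <- if (which == "outer") spec@rOutRef else spec@rInRef
    phosR <- sqrt(rowSums(sweep(phos, 2, centre)^2))
    expect_equal(phosR, rep(rRef, n), tolerance = 1e-10)
    cog <- sweep(headB + tailMid, 2, 2 * centre) / 2
    orient <- rowSums((tailMid - headB) * cog)
    if (which == "outer") expect_true(all(orient < 0))
    else expect_true(all(orient > 0))
  }
  # geometric impossibility: lipid longer than the inner radius
  tiny <- vesicleSpec(outerDiameter = 7, boxEdge = 12, rOutRef = 3.2,
                      rInRef = 0.9, seed = 1)
  expect_error(placeLeaflet(tiny, "inner"), "build error")
})

test_that("default leaflets reproduce the printed populations", {
  spec <- defaultVesicleSpec()
  outer <- placeLeaflet(spec, "outer")
  expect_identical(nMolecules(outer), 5128L)
  expect_identical(nBeads(outer), 61536L)
  inner <- placeLeaflet(spec, "inner")
  expect_identical(nMolecules(inner), 3638L)
})

test_that("builds are deterministic: same spec and seed, identical bytes", {
  s1 <- buildVesicle(miniSpec())
  s2 <- buildVesicle(miniSpec())
  expect_identical(coords(s1), coords(s2))
  f1 <- withr::local_tempfile(fileext = ".gro")
  f2 <- withr::local_tempfile(fileext = ".gro")
  writeGro(s1, f1); writeGro(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed moves the anchors
  s3 <- buildVesicle(miniSpec(seed = 43L))
  expect_false(identical(coords(s1), coords(s3)))
})

test_that("solvation honours counts, exclusions and the empty-core case", {
  sys <- miniVesicle()
  grp <- table(groupLabels(sys))
  expect_identical(unname(grp["INNER_WATER"]), 8L)
  expect_identical(unname(grp["OUTER_WATER"]), 200L)
  # water-lipid minimum separation, brute force over all pairs
  w <- which(groupLabels(sys) != "BILAYER")
  l <- which(groupLabels(sys) == "BILAYER")
  box <- boxVector(sys)
  dmin <- Inf
  for (i in w) {
    d <- sweep(coords(sys)[l, , drop = FALSE], 2, coords(sys)[i, ])
    d <- d - rep(box, each = length(l)) * round(d / rep(box, each = length(l)))
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  expect_gte(dmin, miniSpec()@minSeparation)
  # no core water at all is a valid system
  dry <- buildVesicle(miniSpec(nWaterIn = 0L))
  expect_false("INNER_WATER" %in% groupLabels(dry))
  expect_true(validObject(dry))
  # over-capacity request reports the maximum
  expect_error(buildVesicle(miniSpec(nWaterIn = 10000000L)),
               "capacity error.*at most")
})

test_that("full build satisfies composition, charge and radial ordering", {
  sys <- defaultBuild()
  expect_identical(nBeads(sys), 507072L)
  grp <- table(groupLabels(sys))
  expect_identical(unname(grp["BILAYER"]), 105192L)
  expect_identical(unname(grp["INNER_WATER"]), 67522L)
  expect_identical(unname(grp["OUTER_WATER"]), 334358L)
  expect_equal(systemNetCharge(sys), 0)
  # radial ordering: inner water < inner heads <= lipids < outer water
  centre <- rep(boxVector(sys)[1] / 2, 3)
  r <- sqrt(rowSums(sweep(coords(sys), 2, centre)^2))
  b <- beadData(sys)
  innerHead <- r[b$group == "BILAYER" & !is.na(b$leaflet) &
                   b$leaflet == "inner" & b$beadName == "NC3"]
  expect_lt(max(r[b$group == "INNER_WATER"]), min(innerHead))
  expect_lt(max(r[b$group == "BILAYER"]), min(r[b$group == "OUTER_WATER"]))
  # group labels partition the beads
  expect_false(anyNA(b$group))
})

test_that("anchor placement is areally uniform (nearest-neighbour CV < 15%)", {
  sys <- defaultBuild()
  b <- beadData(sys)
  for (lf in c("outer", "inner")) {
    phos <- which(b$beadName == "PO4" & !is.na(b$leaflet) & b$leaflet == lf)
    xyz <- coords(sys)[phos, , drop = FALSE]
    nn <- numeric(nrow(xyz))
    chunk <- 512L
    for (st in seq(1L, nrow(xyz), by = chunk)) {
      en <- min(st + chunk - 1L, nrow(xyz))
      d2 <- outer(rowSums(xyz[st:en, , drop = FALSE]^2), rowSums(xyz^2), `+`) -
        2 * xyz[st:en, , drop = FALSE] %*% t(xyz)
      d2[cbind(seq_len(en - st + 1L), st:en)] <- Inf
      nn[st:en] <- sqrt(pmax(0, apply(d2, 1, min)))
    }
    expect_lt(sd(nn) / mean(nn), 0.15)
  }
})

test_that("area per lipid of a fresh build recovers the input APL within 2%", {
  apl <- vesicleApl(miniVesicle())
  expect_equal(apl@combined, miniSpec()@apl, tolerance = 0.02)
  expect_equal(apl@leaflets$apl, rep(miniSpec()@apl, 2), tolerance = 0.02)
})
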