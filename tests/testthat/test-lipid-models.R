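# Lipid templates, nonbonded table and the Boltzmann angle average.

test_that("packaged templates satisfy the 12-bead PC invariants", {
  for (sp in c("DPPC", "DOPC", "POPC")) {
    tpl <- lipidTemplate(sp)
    expect_s4_class(tpl, "LipidTemplate")
    expect_identical(nrow(tpl@beads), 12L)
    expect_equal(tpl@beads$charge[1], 1)
    expect_equal(tpl@beads$charge[2], -1)
    expect_equal(sum(tpl@beads$charge), 0)  # lipid is net neutral
    expect_true(all(tpl@unsaturatedBeads %in% c(7L, 11L)))
  }
  expect_identical(lipidTemplate("DPPC")@unsaturatedBeads, integer(0))
  expect_identical(lipidTemplate("DOPC")@unsaturatedBeads, c(7L, 11L))
  expect_identical(lipidTemplate("POPC")@unsaturatedBeads, 11L)
  # case-insensitive, repeated calls identical
  expect_identical(lipidTemplate("dopc"), lipidTemplate("DOPC"))
  expect_error(lipidTemplate("DMPC"), "unknown lipid.*DPPC")
})

test_that("nonbonded lookup is symmetric, complete, and file-backed", {
  params <- defaultNonbonded()
  expect_equal(params@cutoff, 1.2)
  expect_equal(params@epsR, 15)
  for (t in params@types) {
    v <- lookupNonbonded(t, t, params)
    expect_true(is.finite(v["sigma"]) && v["sigma"] > 0)
    expect_true(is.finite(v["epsilon"]))
  }
  for (a in params@types) for (b in params@types)
    expect_identical(lookupNonbonded(a, b, params),
                     lookupNonbonded(b, a, params))
  expect_error(lookupNonbonded("C1", "XX", params), "missing.*XX")
  # cross-check one pair against an independent parse of the packaged file
  lines <- readLines(system.file("extdata", "martini_v2x_cg.itp",
                                 package = "vesica"))
  row <- grep("^\\s*C1\\s+P4\\s", lines, value = TRUE)
  f <- strsplit(trimws(row), "\\s+")[[1]]
  expect_equal(unname(lookupNonbonded("C1", "P4", params)),
               as.numeric(f[4:5]))
})

test_that("water bead is uncharged and represents four waters", {
  wb <- waterBead()
  expect_equal(wb@charge, 0)
  expect_identical(wb@representedMolecules, 4L)
  expect_error(new("WaterBead", type = "P4", charge = 0.1,
                   representedMolecules = 4L, volume = 0.12) |> validObject(),
               "uncharged")
})

test_that("equilibrium angle mean matches quadrature oracle and limits", {
  # stiff-spring limit pins the mean at theta0
  expect_equal(equilibriumAngleMean(120, 1e6, 300), 120, tolerance = 0.1 / 120)
  # at theta0 = 90 the density is symmetric about 90: never below it
  expect_gte(equilibriumAngleMean(90, 25, 300), 90)
  expect_gte(equilibriumAngleMean(90, 5, 500), 90)
  # independent trapezoid quadrature at 1e5 nodes
  bruteMean <- function(theta0, k, temp) {
    th <- seq(1e-7, pi - 1e-7, length.out = 1e5)
    w <- exp(-0.5 * k * (cos(th) - cos(theta0 * pi / 180))^2 /
               (0.0083144621 * temp)) * sin(th)
    sum(th * w) / sum(w) * 180 / pi
  }
  for (p in list(c(120, 45, 390), c(120, 45, 300), c(150, 25, 390),
                 c(100, 10, 310))) {
    expect_equal(equilibriumAngleMean(p[1], p[2], p[3]),
                 bruteMean(p[1], p[2], p[3]), tolerance = 1e-5)
  }
  # the kink-angle configuration brackets the in-membrane value
  v <- equilibriumAngleMean(120, 45, 390)
  expect_gt(v, 115); expect_lt(v, 130)
  expect_error(equilibriumAngleMean(120, 45, -1), "temperature")
  expect_error(equilibriumAngleMean(120, -2, 300), "kAngle")
  expect_error(equilibriumAngleMean(181, 45, 300), "theta0")
})

test_that("quadrature mean agrees with a Monte-Carlo sampler within 3 SE", {
  set.seed(101)
  s <- oracleSampleAngles(1e5, 120, 45, 390) * 180 / pi
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - equilibriumAngleMean(120, 45, 390)), 3 * se)
})

test_that("template round-trips through the itp dialect", {
  for (sp in c("DPPC", "DOPC", "POPC")) {
    tpl <- lipidTemplate(sp)
    path <- withr::local_tempfile(fileext = ".itp")
    writeLipidItp(tpl, path)
    back <- readLipidItp(path)
    expect_identical(back@name, tpl@name)
    expect_equal(back@beads, tpl@beads)
    expect_equal(back@bonds, tpl@bonds)
    expect_equal(back@angles, tpl@angles)
    expect_identical(back@unsaturatedBeads, tpl@unsaturatedBeads)
  }
})
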