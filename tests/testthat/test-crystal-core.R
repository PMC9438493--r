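# Unit cells, symmetry, grids, Fourier transforms and file I/O.

test_that("scattering magnitudes follow the reciprocal metric", {
  cub <- unitCell(10, 10, 10)
  expect_equal(scatteringMagnitude(1, 0, 0, cub), 0.1)
  expect_equal(scatteringMagnitude(0, 0, 0, cub), 0)

  # brute-force reciprocal-metric oracle on an orthorhombic cell
  ortho <- unitCell(10, 20, 40)
  sOracle <- sqrt((1 / 10)^2 + (2 / 20)^2 + (4 / 40)^2)
  expect_equal(scatteringMagnitude(1, 2, 4, ortho), sOracle, tolerance = 1e-12)

  # triclinic: compare against explicit G* = (O^T O)^-1 evaluation
  tric <- unitCell(11, 13, 17, 80, 95, 103)
  G <- t(orthoMatrix(tric)) %*% orthoMatrix(tric)
  h <- c(2, -1, 3)
  expect_equal(scatteringMagnitude(2, -1, 3, tric),
               sqrt(drop(t(h) %*% solve(G) %*% h)), tolerance = 1e-10)
})

test_that("degenerate cells are rejected at construction", {
  expect_error(unitCell(-5, 10, 10), "finite and > 0")
  expect_error(unitCell(10, 10, 10, alpha = 0), "angles")
  # angle combination with no positive-definite metric
  expect_error(unitCell(10, 10, 10, 30, 30, 120), "degenerate")
})

test_that("built-in space groups form closed operator groups", {
  for (nm in c("P1", "P21", "P212121", "I222", "P61", "P65")) {
    sg <- spaceGroup(nm)
    expect_true(validObject(sg))
    expect_equal(sg@chiral, nm %in% c("P61", "P65"))
    expect_equal(inversionAmbiguous(sg), !sg@chiral)
  }
  expect_equal(spaceGroup("P 21 21 21")@name, "P212121")
  expect_equal(spaceGroup("P65")@enantiomorphPartner, "P61")
})

test_that("user-supplied operators reproduce a built-in group", {
  tmp <- tempfile(fileext = ".symop")
  writeLines(c("# twofold screw along b", "x,y,z", "-x, y+1/2, -z"), tmp)
  sg <- readSymmetryOps(tmp, name = "usergroup")
  expect_equal(nSymops(sg), 2L)
  ref <- spaceGroup("P21")
  expect_equal(continuousOriginAxes(sg), continuousOriginAxes(ref))
  expect_setequal(apply(originShifts(sg), 1, paste, collapse = ","),
                  apply(originShifts(ref), 1, paste, collapse = ","))
})

test_that("symmetry reduction is idempotent and classifies correctly", {
  sg <- spaceGroup("P212121")
  set.seed(1)
  hkl <- matrix(sample(-6:6, 300, replace = TRUE), ncol = 3)
  can1 <- canonicalHKL(hkl, sg)
  can2 <- canonicalHKL(as.matrix(can1[, 1:3]), sg)
  expect_equal(can1[, 1:3], can2[, 1:3])
  expect_equal(can1$centric, can2$centric)

  # in P212121 the principal zones are centric, general reflections are not
  z <- canonicalHKL(rbind(c(0, 2, 3), c(1, 2, 3)), sg)
  expect_true(z$centric[1])
  expect_false(z$centric[2])
  # axial reflections carry the screw-axis enhancement
  ax <- canonicalHKL(rbind(c(2, 0, 0), c(1, 2, 3)), sg)
  expect_equal(ax$epsilon, c(2L, 1L))
})

test_that("symmetry-consistent maps are invariant under every operator", {
  for (nm in c("P21", "P212121", "I222", "P61")) {
    sg <- spaceGroup(nm)
    cell <- if (nm == "P61") unitCell(20, 20, 24, 90, 90, 120)
            else unitCell(18, 20, 24)
    dims <- suggestGrid(cell, 1.8, sg)
    m <- randomMap(dims, cell, nm, seed = 42)
    perms <- dmphase:::.opPermutations(sg, dims)
    for (p in perms) {
      expect_lt(max(abs(mapValues(m)[p] - mapValues(m))), 1e-10)
    }
  }
})

test_that("Fourier analysis obeys the expected identities", {
  cell <- unitCell(20, 20, 20)
  cst <- densityMap(array(3.5, c(8, 8, 8)), cell)
  sf <- structureFactors(cst)
  expect_equal(Mod(sf[1, 1, 1]), 3.5)
  expect_lt(max(Mod(sf[-1])), 1e-12)

  imp <- array(0, c(8, 8, 8)); imp[1, 1, 1] <- 1
  sfi <- structureFactors(densityMap(imp, cell))
  expect_lt(diff(range(Mod(sfi))), 1e-14)  # impulse: all amplitudes equal

  m <- randomMap(c(8, 8, 8), cell, seed = 5)
  sfr <- structureFactors(m)
  # Hermitian symmetry F(-h) = conj(F(h))
  d <- dim(sfr)
  neg <- lapply(d, function(n) c(1L, rev(seq_len(n)[-1])))
  expect_lt(max(Mod(sfr[neg[[1]], neg[[2]], neg[[3]]] - Conj(sfr))), 1e-12)
  # round trip
  back <- mapFromStructureFactors(sfr, cell)
  expect_lt(max(abs(mapValues(back) - mapValues(m))) / diff(range(mapValues(m))),
            1e-10)
})

test_that("round trip on random 16^3 fixtures stays below 1e-8", {
  cell <- unitCell(30, 30, 30)
  for (seed in 1:3) {
    m <- randomMap(c(16, 16, 16), cell, seed = seed)
    back <- mapFromStructureFactors(structureFactors(m), cell)
    relErr <- max(abs(mapValues(back) - mapValues(m))) /
      diff(range(mapValues(m)))
    expect_lt(relErr, 1e-8)
  }
})

test_that("reflection input handles symmetry mates, duplicates and cutoffs", {
  cell <- unitCell(30, 40, 50)
  tmp <- tempfile(fileext = ".hkl")
  writeLines(c("# toy file", "1 0 0 10.0", "2 1 1 5.5 0.3", "0 0 1 2.0"), tmp)
  r <- readHKL(tmp, cell, "P1")
  expect_equal(nReflections(r), 3L)
  expect_equal(sort(reflTable(r)$fobs), c(2.0, 5.5, 10.0))
  expect_equal(reflTable(r)$s[reflTable(r)$h == 1 & reflTable(r)$k == 0],
               1 / 30)

  # symmetry mates with one amplitude collapse to a single unique record
  r2 <- reflectionData(c(1, -1), c(0, 0), c(0, 0), c(10, 10), cell = cell,
                       spacegroup = "P212121",
                       lowResCutoff = 25)
  expect_equal(nReflections(r2), 1L)

  # conflicting duplicates are an error naming the offenders
  expect_error(reflectionData(c(1, -1), c(0, 0), c(0, 0), c(10, 99),
                              cell = cell, spacegroup = "P212121"),
               "duplicate reflection")
  expect_error(reflectionData(1, 0, 0, -3, cell = cell), "negative amplitude")

  # a 30 A record is below the 25 A cutoff and is flagged missing
  r3 <- reflectionData(1, 0, 0, 7, cell = unitCell(30, 30, 30),
                       lowResCutoff = 25)
  expect_true(reflTable(r3)$missing[1])
  r4 <- reflectionData(1, 0, 0, 7, cell = unitCell(30, 30, 30),
                       lowResCutoff = 40)
  expect_false(reflTable(r4)$missing[1])
})

test_that("expanded HKL files reduce back to the same unique set", {
  toy <- smallToy()
  tb <- reflTable(toy@refl)
  sg <- toy@spacegroup
  # expand a subset over the group and Friedel, then re-reduce
  sub <- tb[seq(1, nrow(tb), by = 7), ]
  exp <- do.call(rbind, lapply(sg@ops, function(g) {
    hkl <- as.matrix(sub[, c("h", "k", "l")]) %*% g$R
    rbind(hkl, -hkl)
  }))
  f <- rep(sub$fobs, 2 * length(sg@ops))
  rr <- reflectionData(exp[, 1], exp[, 2], exp[, 3], f, cell = toy@cell,
                       spacegroup = sg)
  expect_equal(nReflections(rr), nrow(sub))
})

test_that("CCP4 map output round-trips and matches an independent reader", {
  toy <- smallToy()
  tmp <- tempfile(fileext = ".ccp4")
  writeCCP4Map(toy@map, tmp)
  back <- readCCP4Map(tmp)
  expect_equal(dim(mapValues(back)), dim(mapValues(toy@map)))
  expect_lt(max(abs(mapValues(back) - mapValues(toy@map))) /
              diff(range(mapValues(toy@map))), 1e-6)
  expect_equal(cellParameters(back@cell), cellParameters(toy@cell),
               tolerance = 1e-5)

  # cross-check with gemmi as an independent implementation of the format
  py <- Sys.which("python")
  if (nzchar(py)) {
    script <- tempfile(fileext = ".py")
    out <- tempfile(fileext = ".txt")
    writeLines(sprintf(paste0(
      "import gemmi, json\n",
      "m = gemmi.read_ccp4_map('%s')\n",
      "import numpy as np\n",
      "a = np.array(m.grid, copy=False)\n",
      "print(json.dumps({'shape': list(a.shape), 'mean': float(a.mean()),",
      " 'max': float(a.max()), 'cell_a': m.grid.unit_cell.a}))"), tmp), script)
    res <- system2(py, script, stdout = TRUE)
    info <- jsonlite::fromJSON(res[length(res)])
    expect_equal(unlist(info$shape), dim(mapValues(toy@map)),
                 ignore_attr = TRUE)
    expect_equal(info$mean, mean(mapValues(toy@map)), tolerance = 1e-5)
    expect_equal(info$max, max(mapValues(toy@map)), tolerance = 1e-5)
    expect_equal(info$cell_a, 24, tolerance = 1e-4)
  }

  bad <- tempfile()
  writeLines("not a map", bad)
  expect_error(readCCP4Map(bad), "malformed header")
})

test_that("grid suggestion respects symmetry and the spacing rule", {
  cell <- unitCell(40, 40, 40)
  n <- suggestGrid(cell, 2 / 5 * 3.6)
  expect_true(all(40 / n <= 2 / 5 * 3.6))
  hexCell <- unitCell(30, 30, 36, 90, 90, 120)
  nh <- suggestGrid(hexCell, 1.5, "P61")
  expect_equal(nh[1], nh[2])        # a/b mixed by the sixfold
  expect_equal(nh[3] %% 6, 0)       # 6_1 translations on-grid
  expect_true(dmphase:::.gridCompatible(spaceGroup("P61"), nh))
})

test_that("phase sets round-trip through the text format", {
  toy <- smallToy()
  tmp <- tempfile(fileext = ".phs")
  writePhaseSet(toy@phases, tmp)
  back <- readPhaseSet(tmp, toy@cell, toy@spacegroup)
  common <- !is.na(phaseValues(back))
  expect_equal(phaseDistance(back, toy@phases), 0, tolerance = 1e-3)
})
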