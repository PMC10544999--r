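# Spectral theories: monomer anchor, stick structure, sum rules.

test_that("both theories reduce exactly to the monomer response", {
  lt <- shared_lt()
  mono <- build_system(list(pigment_site("m", 15000, c(0, 0, 2))))
  st <- diagonalize(mono)
  grid <- seq(13500, 16500, by = 2)
  orac <- pmax(oracle_monomer_od(15000, 4, lt, grid), 0)
  for (th in c("modified_redfield", "cumulant")) {
    od <- absorption_spectrum(st, mono, lt, theory = th, wavenumber_grid = grid)
    expect_rel_equal(od$intensity, orac, 1e-6)
  }
})

test_that("degenerate H-dimer: sticks split by 2V with a dark lower state", {
  lt <- shared_lt()
  d <- gen_dimer_fixture(gap = 0, V = 238)
  st <- diagonalize(d)
  expect_equal(diff(st$energies), 476)
  grid <- seq(13200, 17200, by = 2)
  od <- absorption_spectrum(st, d, lt, theory = "modified_redfield",
                            wavenumber_grid = grid)
  pk <- grid[which.max(od$intensity)]
  ## all intensity sits near the bright (upper) stick
  expect_lt(abs(pk - 15238), 60)
  lower <- od$intensity[abs(grid - 14762) < 50]
  expect_lt(max(lower), 0.05 * max(od$intensity))
})

test_that("zero coupling makes spectra additive over monomers", {
  lt <- shared_lt()
  s1 <- pigment_site("a", 15200, c(1, 0, 0), c(0, 0, 0))
  s2 <- pigment_site("b", 14800, c(0, 1, 0), c(0, 0, 10))
  duo <- build_system(list(s1, s2), matrix(0, 2, 2))
  std <- diagonalize(duo)
  grid <- seq(13000, 17000, by = 2)
  for (th in c("modified_redfield", "cumulant")) {
    od <- absorption_spectrum(std, duo, lt, theory = th, wavenumber_grid = grid)
    m1 <- build_system(list(s1)); m2 <- build_system(list(s2))
    ref <- absorption_spectrum(diagonalize(m1), m1, lt, wavenumber_grid = grid)$intensity +
      absorption_spectrum(diagonalize(m2), m2, lt, wavenumber_grid = grid)$intensity
    ## equality up to the clip-at-zero ripple of the half-Fourier transform
    expect_rel_equal(od$intensity, ref, 1e-6)
  }
})

test_that("spectra translate rigidly under a uniform site-energy shift", {
  lt <- shared_lt()
  sys <- rand_system(3, 11)
  shift <- 500
  sites2 <- lapply(sys$sites, function(s) { s$energy <- s$energy + shift; s })
  sys2 <- build_system(sites2, sys$couplings)
  grid <- seq(13000, 17000, by = 2)
  for (th in c("modified_redfield", "cumulant")) {
    a <- absorption_spectrum(diagonalize(sys), sys, lt, theory = th,
                             wavenumber_grid = grid)
    b <- absorption_spectrum(diagonalize(sys2), sys2, lt, theory = th,
                             wavenumber_grid = grid + shift)
    expect_rel_equal(b$intensity, a$intensity, 1e-8)
  }
})

test_that("integrated OD is conserved between coupled and uncoupled systems", {
  lt <- shared_lt()
  sys <- gen_antenna_fixture("closed")
  sys0 <- build_system(sys$sites, matrix(0, 8, 8))
  grid <- seq(12000, 19500, by = 2)
  for (th in c("modified_redfield", "cumulant")) {
    a <- absorption_spectrum(diagonalize(sys), sys, lt, theory = th,
                             wavenumber_grid = grid)
    b <- absorption_spectrum(diagonalize(sys0), sys0, lt, theory = th,
                             wavenumber_grid = grid)
    expect_equal(sum(a$intensity), sum(b$intensity),
                 tolerance = 0.01 * sum(b$intensity))
    expect_true(all(a$intensity >= 0))
  }
})

test_that("CD: achiral systems are silent, chiral dimers give a couplet", {
  lt <- shared_lt()
  mono <- build_system(list(pigment_site("m", 15000, c(0, 0, 2), c(0, 0, 0))))
  grid <- seq(13500, 16500, by = 2)
  cd0 <- cd_spectrum(diagonalize(mono), mono, lt, wavenumber_grid = grid)
  expect_equal(max(abs(cd0$intensity)), 0)

  par2 <- build_system(
    list(pigment_site("a", 15000, c(1, 0, 0), c(0, 0, 0)),
         pigment_site("b", 15100, c(2, 0, 0), c(5, 3, 8))),
    matrix(c(0, 80, 80, 0), 2))
  cdp <- cd_spectrum(diagonalize(par2), par2, lt, wavenumber_grid = grid)
  expect_lt(max(abs(cdp$intensity)), 1e-10)

  ## degenerate chiral dimer: bisignate couplet, equal lobes to 2%
  chir <- gen_dimer_fixture(gap = 0, V = 150, geometry = "chiral")
  stc <- diagonalize(chir)
  cdc <- cd_spectrum(stc, chir, lt, theory = "modified_redfield",
                     wavenumber_grid = grid)
  expect_gt(max(cdc$intensity), 0)
  expect_lt(min(cdc$intensity), 0)
  expect_equal(max(cdc$intensity), -min(cdc$intensity),
               tolerance = 0.02 * max(cdc$intensity))
  ## integrated CD vanishes (sum rule through symmetric broadening)
  expect_lt(abs(sum(cdc$intensity)) / sum(abs(cdc$intensity)), 0.02)
})

test_that("fluorescence: Boltzmann weighting and the monomer Stokes shift", {
  ## population ratio for a 500 cm^-1 gap at 300 K
  s <- list(pigment_site("a", 15000), pigment_site("b", 15500))
  st <- diagonalize(build_system(s, matrix(0, 2, 2)))
  p <- boltzmann_populations(st, 300)
  expect_equal(p[2] / p[1], exp(-500 / 208.5), tolerance = 1e-3)
  expect_equal(kT_cm1(300), 208.5, tolerance = 1e-3)

  ## T -> 0: emission only from the lowest state (well-separated pair)
  lt <- shared_lt()
  duo <- build_system(
    list(pigment_site("a", 15000, c(1, 0, 0)), pigment_site("b", 17000, c(1, 0, 0))),
    matrix(0, 2, 2))
  std <- diagonalize(duo)
  grid <- seq(13000, 18500, by = 2)
  flu_cold <- fluorescence_spectrum(std, duo, lt, temperature = 10,
                                    wavenumber_grid = grid)
  lone <- build_system(list(pigment_site("a", 15000, c(1, 0, 0))))
  ref <- fluorescence_spectrum(diagonalize(lone), lone, lt, temperature = 10,
                               wavenumber_grid = grid)
  expect_rel_equal(flu_cold$intensity, ref$intensity, 1e-8)
  expect_error(fluorescence_spectrum(std, duo, lt, temperature = -1), "temperature")

  ## slow-bath monomer: Stokes shift = 2 lambda to grid resolution
  lts <- shared_lt_slow()   # lambda = 200, gamma = 5 (slow modulation)
  mono <- build_system(list(pigment_site("m", 15000, c(0, 0, 1))))
  stm <- diagonalize(mono)
  g10 <- seq(13800, 16200, by = 10)
  od <- absorption_spectrum(stm, mono, lts, wavenumber_grid = g10)
  flu <- fluorescence_spectrum(stm, mono, lts, wavenumber_grid = g10)
  stokes <- g10[which.max(od$intensity)] - g10[which.max(flu$intensity)]
  expect_lt(abs(stokes - 2 * 200), 10 + 1e-9)
})

test_that("spectra CSV round-trips with metadata", {
  lt <- shared_lt()
  mono <- build_system(list(pigment_site("m", 15000, c(0, 0, 2), c(0, 0, 0))))
  st <- diagonalize(mono)
  grid <- seq(14000, 16000, by = 5)
  od <- absorption_spectrum(st, mono, lt, wavenumber_grid = grid)
  cd <- cd_spectrum(st, mono, lt, wavenumber_grid = grid)
  flu <- fluorescence_spectrum(st, mono, lt, wavenumber_grid = grid)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(f, od = od, cd = cd, flu = flu, meta = list(theory = "x", seed = 3))
  back <- read_spectra_csv(f)
  expect_equal(back$wavenumber_cm1, grid)
  expect_equal(back$od, od$intensity)
  expect_equal(attr(back, "meta")[["seed"]], "3")
})
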