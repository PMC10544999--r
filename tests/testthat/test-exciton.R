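test_that("build_system assembles and validates the Hamiltonian", {
  s <- list(pigment_site("a", 15000), pigment_site("b", 15000))
  sys <- build_system(s, matrix(c(0, 238, 238, 0), 2))
  expect_identical(unname(hamiltonian(sys)),
                   matrix(c(15000, 238, 238, 15000), 2))

  mono <- build_system(list(pigment_site("m", 16000)))
  expect_equal(n_sites(mono), 1L)
  expect_identical(unname(hamiltonian(mono)), matrix(16000, 1, 1))

  expect_error(build_system(s, matrix(c(0, 238, 100, 0), 2)), "symmetric")
  expect_error(build_system(s, matrix(0, 3, 3)), "3 x 3|matrix")
  expect_error(
    build_system(list(pigment_site("a", 1), pigment_site("a", 2)), matrix(0, 2, 2)),
    "duplicate")
  ## tiny asymmetry below 1e-6 is repaired
  v <- matrix(c(0, 238, 238 + 1e-8, 0), 2)
  expect_silent(sys2 <- build_system(s, v))
  expect_identical(sys2$couplings[1, 2], sys2$couplings[2, 1])
})

test_that("diagonalize matches the 2x2 closed form and conventions", {
  ## degenerate dimer: +/- V, coefficients 1/sqrt(2)
  d <- gen_dimer_fixture(gap = 0, V = 238, mean_energy = 15000)
  st <- diagonalize(d)
  expect_equal(st$energies, 15000 + c(-238, 238))
  expect_equal(abs(st$coefficients), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)

  ## diagonal Hamiltonian: localized, unchanged
  s <- list(pigment_site("a", 15000, c(1, 0, 0)), pigment_site("b", 15500, c(1, 0, 0)))
  st0 <- diagonalize(build_system(s, matrix(0, 2, 2)))
  expect_equal(st0$energies, c(15000, 15500))
  expect_equal(st0$coefficients, diag(2))

  ## general 2x2 closed form, and a printed example
  st1 <- diagonalize(build_system(s, matrix(c(0, 100, 100, 0), 2)))
  expect_equal(st1$energies, 15250 + c(-1, 1) * sqrt(250^2 + 100^2), tolerance = 1e-12)
  expect_equal(st1$energies, c(14980.7418, 15519.2582), tolerance = 1e-8)

  ## sign convention: largest-magnitude coefficient positive
  for (k in 1:2) {
    expect_gt(st1$coefficients[which.max(abs(st1$coefficients[, k])), k], 0)
  }
})

test_that("eigen-solutions agree with a characteristic-polynomial oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    e <- runif(2, 14000, 17000)
    v <- runif(1, -500, 500)
    st <- diagonalize(build_system(
      list(pigment_site("a", e[1]), pigment_site("b", e[2])),
      matrix(c(0, v, v, 0), 2)))
    eb <- mean(e)
    expect_equal(st$energies, eb + c(-1, 1) * sqrt((diff(e) / 2)^2 + v^2),
                 tolerance = 1e-9)
  }
  ## 3x3 via polyroot of det(H - xI)
  for (seed in 1:10) {
    sys <- rand_system(3, seed + 400)
    h <- hamiltonian(sys)
    cfs <- c(-det(h),
             h[1, 1] * h[2, 2] + h[1, 1] * h[3, 3] + h[2, 2] * h[3, 3] -
               h[1, 2]^2 - h[1, 3]^2 - h[2, 3]^2,
             -sum(diag(h)), 1)
    roots <- sort(Re(polyroot(cfs)))
    st <- diagonalize(sys)
    expect_equal(st$energies, roots, tolerance = 1e-6)
  }
})

test_that("sum rules hold on randomized systems up to N = 8", {
  for (seed in 1:40) {
    n <- sample(2:8, 1)
    sys <- rand_system(n, seed)
    st <- diagonalize(sys)
    ## orthonormality
    expect_lt(max(abs(crossprod(st$coefficients) - diag(n))), 1e-8)
    ## trace conservation
    expect_lt(abs(sum(st$energies) - sum(site_energies(sys))), 1e-6)
    ## dipole-strength sum rule
    expect_lt(abs(sum(st$dipole_strengths) - sum(site_dipoles(sys)^2)) /
                sum(site_dipoles(sys)^2), 1e-8)
    ## rotational-strength sum rule
    expect_lt(abs(sum(st$rotational_strengths)), 1e-8)
  }
})

test_that("dipole strengths follow the exciton contraction", {
  ## H-aggregate: parallel dipoles, V > 0 -> dark lower, bright upper
  d <- gen_dimer_fixture(gap = 0, V = 238)
  st <- diagonalize(d)
  expect_equal(st$dipole_strengths, c(0, 2), tolerance = 1e-12)

  mono <- build_system(list(pigment_site("m", 15000, c(0, 0, 2))))
  expect_equal(diagonalize(mono)$dipole_strengths, 4)

  ## brute-force contraction oracle on a 4-site system
  sys <- rand_system(4, 99)
  st4 <- diagonalize(sys)
  mu <- site_dipoles(sys)
  for (k in 1:4) {
    muk <- colSums(st4$coefficients[, k] * mu)
    expect_equal(st4$dipole_strengths[k], sum(muk^2), tolerance = 1e-12)
  }
})

test_that("rotational strengths: parallel dipoles vanish, chiral pairs split", {
  sys <- build_system(
    lapply(1:3, function(i) pigment_site(paste0("p", i), 15000 + 100 * i,
                                         c(2, 0, 0), c(3 * i, i, 0))),
    matrix(c(0, 50, 20, 50, 0, 50, 20, 50, 0), 3))
  st <- diagonalize(sys)
  expect_equal(st$rotational_strengths, rep(0, 3), tolerance = 1e-12)

  chir <- gen_dimer_fixture(gap = 100, V = 150, geometry = "chiral")
  stc <- diagonalize(chir)
  ## term-by-term brute force
  mu <- site_dipoles(chir); rr <- site_centers(chir)
  for (k in 1:2) {
    acc <- 0
    for (n in 1:1) for (m in 2:2) {
      acc <- acc + stc$coefficients[n, k] * stc$coefficients[m, k] *
        sum((rr[n, ] - rr[m, ]) * .cross_oracle(mu[n, ], mu[m, ]))
    }
    expect_equal(stc$rotational_strengths[k], acc, tolerance = 1e-12)
  }
  expect_equal(sum(stc$rotational_strengths), 0, tolerance = 1e-12)
  expect_gt(max(abs(stc$rotational_strengths)), 0.1)
  expect_error(rotational_strengths(stc, rand_system(2, 1, with_centers = FALSE)),
               "centers")
})

test_that("participation ratio measures delocalization", {
  s <- list(pigment_site("a", 15000), pigment_site("b", 15500))
  expect_equal(diagonalize(build_system(s, matrix(0, 2, 2)))$participation,
               c(1, 1), tolerance = 1e-12)
  expect_equal(diagonalize(gen_dimer_fixture(0, 238))$participation,
               c(2, 2), tolerance = 1e-12)
  ## stronger coupling on a 500 cm^-1 gap -> more delocalized
  ipr_weak <- diagonalize(build_system(s, matrix(c(0, 16, 16, 0), 2)))$participation
  ipr_strong <- diagonalize(build_system(s, matrix(c(0, 238, 238, 0), 2)))$participation
  expect_true(all(ipr_strong > ipr_weak))
})

test_that("diagonalize is invariant to site ordering", {
  sys <- rand_system(5, 123)
  perm <- c(3, 1, 5, 2, 4)
  sys_p <- build_system(sys$sites[perm], sys$couplings[perm, perm])
  st <- diagonalize(sys)
  st_p <- diagonalize(sys_p)
  expect_equal(st_p$energies, st$energies, tolerance = 1e-9)
  expect_equal(st_p$coefficients, st$coefficients[perm, ], tolerance = 1e-8)
  expect_equal(st_p$dipole_strengths, st$dipole_strengths, tolerance = 1e-9)
})

test_that("Hamiltonian files round-trip through JSON and CSV", {
  sys <- rand_system(4, 7)
  jf <- withr::local_tempfile(fileext = ".json")
  write_hamiltonian_json(sys, jf)
  back <- read_hamiltonian_json(jf)
  expect_equal(site_energies(back), site_energies(sys))
  expect_equal(back$couplings, sys$couplings)
  expect_equal(site_dipoles(back), site_dipoles(sys))
  expect_equal(site_centers(back), site_centers(sys))

  sf <- withr::local_tempfile(fileext = ".csv")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_hamiltonian_csv(sys, sf, cf)
  back2 <- read_hamiltonian_csv(sf, cf)
  expect_equal(site_energies(back2), site_energies(sys))
  expect_equal(unname(back2$couplings), unname(sys$couplings))
})
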