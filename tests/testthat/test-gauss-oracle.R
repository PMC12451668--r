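test_that("Boys function matches its limits and an independent quadrature", {
  expect_identical(boys0(0), 1)
  # large-x asymptote (1/2) sqrt(pi/x)
  x <- 1e6
  expect_equal(boys0(x), 0.5 * sqrt(pi / x), tolerance = 1e-10)
  # F0(x) = int_0^1 exp(-x t^2) dt, checked by quadrature at x = 1
  quad <- stats::integrate(function(t) exp(-t^2), 0, 1,
                           rel.tol = 1e-13)$value
  expect_equal(boys0(1), quad, tolerance = 1e-12)
  expect_error(boys0(-1), "non-negative")
})

test_that("s-Gaussian pair integrals agree with separable Simpson quadrature", {
  set.seed(11)
  for (trial in 1:3) {
    A <- stats::rnorm(3); B <- A + stats::rnorm(3)
    a <- sgauss(A, stats::runif(1, 0.3, 2))
    b <- sgauss(B, stats::runif(1, 0.3, 2))
    got <- pair_integrals_ss(a, b)
    # overlap factorizes into three 1-D Gaussian integrals
    ov <- prod(vapply(1:3, function(k) {
      simpson(function(x) {
        exp(-a$exponent * (x - A[k])^2 - b$exponent * (x - B[k])^2)
      }, -12, 12)
    }, numeric(1))) * a$coef * b$coef
    expect_equal(got[["overlap"]], ov, tolerance = 1e-9)
    # kinetic via -(1/2) Laplacian applied analytically to the ket
    kin <- 0
    for (k in 1:3) {
      lap1 <- simpson(function(x) {
        d <- x - B[k]
        exp(-a$exponent * (x - A[k])^2) *
          (4 * b$exponent^2 * d^2 - 2 * b$exponent) * exp(-b$exponent * d^2)
      }, -12, 12)
      rest <- prod(vapply(setdiff(1:3, k), function(j) {
        simpson(function(x) {
          exp(-a$exponent * (x - A[j])^2 - b$exponent * (x - B[j])^2)
        }, -12, 12)
      }, numeric(1)))
      kin <- kin - 0.5 * lap1 * rest
    }
    expect_equal(got[["kinetic"]], kin * a$coef * b$coef, tolerance = 1e-8)
  }
})

test_that("normalized primitives and distant pairs behave as required", {
  a <- sgauss(c(0, 0, 0), 1.3)
  expect_equal(pair_integrals_ss(a, a)[["overlap"]], 1, tolerance = 1e-14)
  b <- sgauss(c(0, 0, 50), 1)
  a1 <- sgauss(c(0, 0, 0), 1)
  expect_lt(pair_integrals_ss(a1, b)[["overlap"]], 1e-100)
})

test_that("two-electron integral matches radial quadrature and its limits", {
  # (aa|aa) for one normalized primitive: charge density rho = g^2 is a
  # unit-charge Gaussian with exponent 2*alpha and known potential
  # erf(sqrt(2 alpha) r)/r -- an independent closed form + quadrature
  for (alpha in c(0.4, 1.1)) {
    g <- sgauss(c(0, 0, 0), alpha)
    rho <- function(r) (2 * alpha / pi)^1.5 * exp(-2 * alpha * r^2)
    # erf(sqrt(2 alpha) r)/r written through pnorm
    pot <- function(r) (2 * stats::pnorm(sqrt(4 * alpha) * r) - 1) / r
    val <- stats::integrate(function(r) 4 * pi * r^2 * rho(r) * pot(r),
                            0, Inf, rel.tol = 1e-12)$value
    expect_equal(eri_ssss(g, g, g, g), val, tolerance = 1e-9)
  }
  # index symmetries
  set.seed(4)
  gs <- lapply(1:4, function(i) sgauss(stats::rnorm(3), stats::runif(1, .4, 2)))
  v <- eri_ssss(gs[[1]], gs[[2]], gs[[3]], gs[[4]])
  expect_identical(v, eri_ssss(gs[[3]], gs[[4]], gs[[1]], gs[[2]]))
  expect_equal(v, eri_ssss(gs[[2]], gs[[1]], gs[[3]], gs[[4]]),
               tolerance = 1e-14)
  # multipole limit: two far-separated unit-charge pairs -> 1/R
  R <- 30
  p1 <- sgauss(c(0, 0, 0), 1)
  p2 <- sgauss(c(0, 0, R), 1)
  expect_equal(eri_ssss(p1, p1, p2, p2), 1 / R, tolerance = 1e-6)
})

test_that("direct_two_center reduces to the closed-form s-s path", {
  a <- sgauss(c(0, 0, 0), 0.7)
  b <- sgauss(c(0.4, -0.3, 1.1), 1.2)
  pa <- gauss_orbital(a$center, 0, 0, 0.7)
  pb <- gauss_orbital(b$center, 0, 0, 1.2)
  expect_equal(direct_two_center("overlap", pa, pb),
               pair_integrals_ss(a, b)[["overlap"]], tolerance = 1e-12)
  expect_error(direct_two_center("overlap", pa, pa), "coincident")
})

test_that("even-tempered atom energies are variational and monotone", {
  # n = 1: bounded below by the exact value
  expect_gte(hydrogen_atom_energy(even_tempered_basis(1, 0.3, 2)), -0.5)
  # growing the basis never raises the energy
  es <- vapply(c(2, 4, 6, 8), function(n) {
    hydrogen_atom_energy(even_tempered_basis(n, 0.05, 2.5))
  }, numeric(1))
  expect_true(all(diff(es) <= 1e-12))
  expect_true(all(es >= -0.5))
})

test_that("default reference basis reproduces the frozen atom energy", {
  # regression value computed once from the one-atom diagonalization
  expect_equal(hydrogen_atom_energy(), -0.49996835, tolerance = 2e-7)
  expect_error(even_tempered_basis(0, 1, 2))
  expect_error(even_tempered_basis(3, 1, 0.5))
})

test_that("reference energies are invariant under rigid motions", {
  # compare FCI sector energies of a dimer in canonical pose vs a
  # rotated + translated copy, at reduced basis size
  basis <- even_tempered_basis(3, 0.1, 3)
  ints1 <- sqmkit:::oracle_ao_integrals(rbind(c(0, 0, 0), c(0, 0, 1.4)),
                                        basis)
  A <- sqmkit:::rotation_from_z(c(0.48, -0.6, 0.64))
  pos2 <- t(A %*% t(rbind(c(0, 0, 0), c(0, 0, 1.4))) + c(0.3, -1, 2))
  ints2 <- sqmkit:::oracle_ao_integrals(pos2, basis)
  for (ints in list(ints1, ints2)) {
    expect_equal(ints1$enuc, ints$enuc, tolerance = 1e-12)
  }
  o1 <- lowdin_orthogonalize(ints1$S, ints1$h, ints1$eri)
  o2 <- lowdin_orthogonalize(ints2$S, ints2$h, ints2$eri)
  for (N in 1:2) {
    e1 <- sector_fci(o1$h, o1$eri, N, (N %% 2) / 2)$energies
    e2 <- sector_fci(o2$h, o2$eri, N, (N %% 2) / 2)$energies
    expect_equal(e1, e2, tolerance = 1e-10)
  }
})

test_that("dimer reference orders the lowest singlet below the triplet", {
  ref <- reference_spectrum(hcluster("dimer", 1.4),
                            even_tempered_basis(4, 0.08, 3), system = "H2")
  blk <- ref[ref$N == 2 & ref$Sz == 0, ]
  expect_identical(nrow(blk), 2L)
  expect_identical(blk$s2_label, c(0, 1))
  expect_lt(blk$energy_hartree[1], blk$energy_hartree[2])
  # the Sz = 1 component matches the Sz = 0 triplet energy
  t1 <- ref[ref$N == 2 & ref$Sz == 1, ]
  expect_equal(t1$energy_hartree, blk$energy_hartree[2], tolerance = 1e-8)
})
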