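test_that("determinant enumeration matches exhaustive counting", {
  expect_length(enumerate_configs(2, 2, 0, TRUE)$ups, 2)
  expect_length(enumerate_configs(3, 2, 0, TRUE)$ups, 6)
  expect_length(enumerate_configs(3, 0, 0)$ups, 1)   # vacuum
  expect_length(enumerate_configs(3, 2, 0, FALSE)$ups, 9)
  # infeasible sector is empty, not an error
  expect_length(enumerate_configs(2, 1, 1, TRUE)$ups, 0)
  # single-occupancy dimension by brute force for a larger case
  n <- 4; N <- 3; Sz <- 0.5
  cnt <- 0
  for (up in 0:(2^n - 1)) for (dn in 0:(2^n - 1)) {
    nu <- sum(bitwAnd(up, 2^(0:(n - 1))) > 0)
    nd <- sum(bitwAnd(dn, 2^(0:(n - 1))) > 0)
    if (nu + nd == N && (nu - nd) / 2 == Sz && bitwAnd(up, dn) == 0) {
      cnt <- cnt + 1
    }
  }
  expect_length(enumerate_configs(n, N, Sz, TRUE)$ups, cnt)
})

test_that("Löwdin orthogonalization is exact and guards definiteness", {
  M <- 2
  eri <- array(0, rep(M, 4))
  h <- matrix(c(-1, 0.2, 0.2, -0.8), 2)
  out <- lowdin_orthogonalize(diag(2), h, eri)
  expect_equal(out$h, h, tolerance = 1e-14)
  S <- matrix(c(1, 1.2, 1.2, 1), 2) # eigenvalue 1 - 1.2 < 0
  expect_error(lowdin_orthogonalize(S, h, eri), "positive definite")
})

test_that("FCI spectra are invariant under the orthogonalization choice", {
  set.seed(3)
  M <- 2
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  h <- matrix(c(-1.1, -0.6, -0.6, -1.1), 2)
  eri <- random_sym_eri(M) * 0.2
  lo <- lowdin_orthogonalize(S, h, eri)
  # canonical orthogonalization: C = U diag(1/sqrt(e))
  es <- eigen(S, symmetric = TRUE)
  C <- es$vectors %*% diag(1 / sqrt(es$values))
  hc <- t(C) %*% h %*% C
  ec <- eri
  for (step in 1:4) {
    ec <- aperm(array(crossprod(C, matrix(ec, M, M^3)), rep(M, 4)),
                c(2, 3, 4, 1))
  }
  for (N in 0:3) for (twoSz in seq(N %% 2, N, by = 2)) {
    a <- sector_fci(lo$h, lo$eri, N, twoSz / 2)
    b <- sector_fci(hc, ec, N, twoSz / 2)
    if (a$dim == 0) next
    expect_equal(a$energies, b$energies, tolerance = 1e-10)
  }
})

test_that("sector FCI reproduces the Jordan-Wigner operator oracle", {
  set.seed(42)
  M <- 3
  h <- matrix(stats::rnorm(M^2), M); h <- (h + t(h)) / 2
  eri <- random_sym_eri(M)
  Hfull <- jw_hamiltonian(h, eri)
  sec <- jw_sector_index(M)
  for (N in 0:3) for (twoSz in seq(-N, N, by = 2)) {
    sel <- which(sec$nup + sec$ndn == N & sec$nup - sec$ndn == twoSz)
    if (length(sel) == 0) next
    want <- sort(eigen(Hfull[sel, sel], symmetric = TRUE)$values)
    got <- sector_fci(h, eri, N, twoSz / 2)
    expect_equal(got$energies, want, tolerance = 1e-12)
    # spin labels sit on exact S(S+1) ladders
    SS <- spin_label(got$s2)
    expect_true(all(abs(got$s2 - SS * (SS + 1)) < 1e-8))
  }
  # spin-flip symmetry of (N, +-Sz)
  up <- sector_fci(h, eri, 2, 1)
  dn <- sector_fci(h, eri, 2, -1)
  expect_equal(up$energies, dn$energies, tolerance = 1e-12)
})

test_that("two-site Hubbard sector has its closed-form ground state", {
  for (t in c(0.05, 0.3, 1)) for (U in c(0.2, 1, 4)) {
    h <- matrix(c(0, -t, -t, 0), 2)
    eri <- array(0, rep(2, 4))
    eri[1, 1, 1, 1] <- eri[2, 2, 2, 2] <- U
    sp <- sector_fci(h, eri, 2, 0)
    exact <- U / 2 - sqrt((U / 2)^2 + 4 * t^2)
    expect_equal(sp$energies[1], exact, tolerance = 1e-10)
    # any triplet state has <S^2> = 2
    trip <- which(abs(sp$s2 - 2) < 1e-8)
    expect_gte(length(trip), 1)
  }
  # N = 0 sector: one state at zero electronic energy
  sp0 <- sector_fci(matrix(0, 2, 2), array(0, rep(2, 4)), 0, 0)
  expect_identical(sp0$energies, 0)
})

test_that("canonical-orbital rotation leaves sector spectra unchanged", {
  set.seed(8)
  M <- 3
  h <- matrix(stats::rnorm(M^2), M); h <- (h + t(h)) / 2
  eri <- random_sym_eri(M) * 0.3
  can <- canonicalize_orbitals(h, eri)
  for (N in 1:3) {
    a <- sector_fci(h, eri, N, (N %% 2) / 2)
    b <- sector_fci(can$h, can$eri, N, (N %% 2) / 2)
    expect_equal(a$energies, b$energies, tolerance = 1e-10)
  }
})

test_that("Davidson agrees with dense diagonalization on a forced block", {
  set.seed(99)
  M <- 4
  h <- matrix(stats::rnorm(M^2), M); h <- (h + t(h)) / 2
  eri <- random_sym_eri(M) * 0.4
  dense <- sector_fci(h, eri, 4, 0, k = 3)
  iter <- sector_fci(h, eri, 4, 0, k = 3, dense_cutoff = 2)
  expect_equal(iter$energies, dense$energies, tolerance = 1e-7)
})

test_that("task combinatorics reproduce the printed sizes", {
  expect_identical(count_task_targets(1), 10L)
  expect_identical(count_task_targets(2), 23L)
  expect_identical(count_task_targets(1, cluster_sizes = 2), 4L)
  expect_identical(count_task_targets(2, cluster_sizes = 2), 6L)
  expect_identical(count_task_targets(2, cluster_sizes = 3), 17L)
  expect_identical(nrow(task_targets(1)), 10L)
  expect_identical(nrow(task_targets(2)), 23L)
})

test_that("distinct-level merging collapses quasi-degeneracies", {
  expect_equal(distinct_levels(c(1, 1 + 1e-12, 2), tol = 1e-9), c(1, 2))
  expect_identical(distinct_levels(numeric(0)), numeric(0))
  expect_error(distinct_levels(c(1, 2), tol = 0))
})

test_that("an equilateral trimer produces degenerate merges below 23", {
  p <- hmodel_parameters(U = 0.7, S = 0.3, H = -0.5, Vee = 0.4,
                         VeH = 0.45, VHH = 0.7, r = 1.4)
  sp <- cluster_spectrum(hcluster("equilateral_trimer", 1.4), p,
                         system = "H3eq")
  merged <- 0
  for (key in unique(paste(sp$N, sp$Sz))) {
    rows <- sp[paste(sp$N, sp$Sz) == key, ]
    merged <- merged + length(distinct_levels(rows$energy_hartree, 1e-9))
  }
  lin <- cluster_spectrum(hcluster("linear_trimer", 1.4), p, system = "H3")
  merged_lin <- 0
  for (key in unique(paste(lin$N, lin$Sz))) {
    rows <- lin[paste(lin$N, lin$Sz) == key, ]
    merged_lin <- merged_lin + length(distinct_levels(rows$energy_hartree, 1e-9))
  }
  expect_equal(merged_lin, 17)
  expect_lt(merged, 17L)
})
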