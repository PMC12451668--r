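test_that("pair metric blocks invert in closed form and reject singularity", {
  U <- 0.62; Vee <- 0.41
  aux <- aux_basis(atom = 1:2, Q = c(1, 1))
  m <- build_metric(aux, V = matrix(c(U, Vee, Vee, U), 2))
  lam <- m$Lambda[["1_2"]]$inv
  closed <- matrix(c(U, -Vee, -Vee, U), 2) / (U^2 - Vee^2)
  expect_equal(lam, closed, tolerance = 1e-14)
  # degenerate block U = Vee is rank one
  expect_error(build_metric(aux, V = matrix(0.5, 2, 2)), "singular")
})

test_that("every pair block inverse multiplies back to the identity", {
  set.seed(9)
  aux <- aux_basis(atom = 1:3, Q = c(1, 1, 1))
  V <- diag(c(0.7, 0.65, 0.6))
  V[1, 2] <- V[2, 1] <- 0.31
  V[1, 3] <- V[3, 1] <- 0.17
  V[2, 3] <- V[3, 2] <- 0.28
  m <- build_metric(aux, V = V)
  for (key in names(m$Lambda)) {
    idx <- m$Lambda[[key]]$idx
    expect_lt(max(abs(m$Lambda[[key]]$inv %*% V[idx, idx] - diag(2))), 1e-10)
  }
})

test_that("one-center fits impose the charge sum rule exactly", {
  # single s auxiliary with Q = 1 fully determined by the constraint
  X <- one_center_X(matrix(1), Q = 1, V_block = matrix(0.62))
  expect_equal(as.numeric(X), 1, tolerance = 1e-12)
  # Q = (1, 0): the charged function carries the whole constraint
  X2 <- one_center_X(matrix(1), Q = c(1, 0),
                     V_block = matrix(c(0.6, 0.1, 0.1, 0.4), 2))
  expect_equal(sum(X2[, 1, 1] * c(1, 0)), 1, tolerance = 1e-14)
  expect_error(one_center_X(matrix(1), Q = c(0, 0),
                            V_block = diag(2)), "infeasible")
})

test_that("KKT fit equals brute-force constrained quadratic programming", {
  set.seed(13)
  for (trial in 1:3) {
    n <- 4
    Arand <- matrix(stats::rnorm(n * n), n)
    V <- crossprod(Arand) + diag(n) * 0.5 # SPD metric
    Q <- stats::rnorm(n)
    b <- stats::rnorm(n)
    s <- stats::runif(1, -1, 1)
    x_kkt <- sqmkit:::kkt_constrained_fit(V, Q, s, b)
    # brute force: parameterize the feasible affine subspace and optimize
    x0 <- Q * s / sum(Q^2)
    Nmat <- svd(matrix(Q, 1), nv = n)$v[, -1, drop = FALSE] # null space of Q'
    obj <- function(z) {
      x <- x0 + Nmat %*% z
      as.numeric(t(x) %*% V %*% x - 2 * sum(b * x))
    }
    z <- stats::optim(rep(0, n - 1), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))$par
    x_qp <- x0 + Nmat %*% z
    expect_equal(as.numeric(x_kkt), as.numeric(x_qp), tolerance = 1e-6)
    expect_lt(abs(sum(x_kkt * Q) - s), 1e-12)
  }
})

test_that("two-center fit gives Mulliken halves for Z = 0 symmetric dimers", {
  U <- 0.62; Vee <- 0.41; S12 <- 0.37
  Lambda <- solve(matrix(c(U, Vee, Vee, U), 2))
  fit <- two_center_X(matrix(S12), Q = c(1, 1), Lambda = Lambda)
  expect_equal(as.numeric(fit$X), c(S12 / 2, S12 / 2), tolerance = 1e-14)
  # S = 0 with Z = 0 gives a vanishing fit
  fit0 <- two_center_X(matrix(0), Q = c(1, 1), Lambda = Lambda)
  expect_identical(max(abs(fit0$X)), 0)
  # annihilated charges -> zero denominator error
  expect_error(two_center_X(matrix(1), Q = c(1, -1),
                            Lambda = matrix(0.5, 2, 2)), "denominator")
})

test_that("the charge sum rule holds for every fitted pair on random systems", {
  set.seed(23)
  for (trial in 1:3) {
    n <- 3
    V <- diag(stats::runif(n, 0.5, 0.9))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      V[i, j] <- V[j, i] <- stats::runif(1, 0.05, 0.3)
    }
    aux <- aux_basis(atom = 1:n, Q = rep(1, n))
    m <- build_metric(aux, V = V)
    S <- diag(n)
    S[1, 2] <- S[2, 1] <- stats::runif(1, -0.5, 0.5)
    S[1, 3] <- S[3, 1] <- stats::runif(1, -0.5, 0.5)
    S[2, 3] <- S[3, 2] <- stats::runif(1, -0.5, 0.5)
    X <- density_fit_X(S, 1:n, m)
    for (p in 1:n) for (q in 1:n) {
      expect_lt(abs(sum(X[, p, q] * aux$Q) - S[p, q]), 1e-12)
    }
    # eight-fold symmetry of the factored tensor
    eri <- factored_eri(X, m)
    perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1))
    for (pm in perms) {
      expect_lt(max(abs(eri - aperm(eri, pm))), 1e-12)
    }
  }
})

test_that("identity fits recover the metric entries and bridge integrals", {
  p <- hmodel_parameters(U = 0.62, S = 0.4, H = -0.7, Vee = 0.45,
                         VeH = 0.5, VHH = 0.7, r = 1.4)
  mi <- model_integrals(hcluster("dimer", 1.4), p)
  expect_equal(mi$eri[1, 1, 1, 1], 0.62, tolerance = 1e-14)
  expect_equal(mi$eri[1, 1, 2, 2], 0.45, tolerance = 1e-14)
  # (ij|kk) = S_ij (V_ik + V_jk) / 2 with Z = 0
  expect_equal(mi$eri[1, 2, 2, 2], 0.4 / 2 * (0.62 + 0.45),
               tolerance = 1e-14)
})

test_that("projection Z fits reproduce the sampled ratio and symmetric dimers", {
  # single-auxiliary s-only fit against oracle three-center integrals:
  # V_mu phi_p phi_q integrals for a Gaussian-charge potential
  alpha <- 0.8; gamma <- 1.1
  ds <- seq(1, 5, by = 0.5)
  over <- integ <- numeric(length(ds))
  for (i in seq_along(ds)) {
    A <- c(0, 0, 0); B <- c(0, 0, ds[i])
    ga <- sgauss(A, alpha); gb <- sgauss(B, alpha)
    over[i] <- pair_integrals_ss(ga, gb)[["overlap"]]
    # represent the unit-charge auxiliary rho_mu (exponent gamma) as a
    # square of two identical s primitives for the eri engine
    ch <- sqrt(1 / (pi / gamma)^1.5)
    gm <- sgauss(A, gamma / 2, coef = ch)
    integ[i] <- eri_ssss(ga, gb, gm, gm)
  }
  Z <- projection_Z(over, integ)
  # residual of the fitted one-term model is small against the scale
  expect_lt(max(abs(integ - Z * over)), 0.05 * max(abs(integ)))
  expect_equal(Z, sum(integ * over) / sum(over^2), tolerance = 1e-14)
})

test_that("the NDDO limit is exact and the factored model is improvable", {
  p <- hmodel_parameters(U = 0.62, S = 0.4, H = -0.7, Vee = 0.45,
                         VeH = 0.5, VHH = 0.7, r = 1.4)
  mi <- model_integrals(hcluster("dimer", 1.4), p)
  chk <- nddo_limit_check(mi$S, 1:2, mi$metric)
  expect_true(chk$pass)
  expect_identical(chk$max_cross, 0)
  # one-center integrals unchanged by the orthogonality switch
  expect_identical(chk$eri_nddo[1, 1, 1, 1], chk$eri[1, 1, 1, 1])
  expect_identical(chk$eri_nddo[1, 1, 2, 2], chk$eri[1, 1, 2, 2])
  # a real Gaussian dimer has nonzero (ij|kk); the NDDO error shrinks as
  # the overlap decays with distance
  alpha <- 1
  bridge <- vapply(c(1.5, 3, 5), function(d) {
    ga <- sgauss(c(0, 0, 0), alpha); gb <- sgauss(c(0, 0, d), alpha)
    abs(eri_ssss(ga, gb, gb, gb))
  }, numeric(1))
  expect_true(all(bridge > 0))
  expect_true(all(diff(bridge) < 0))
})

test_that("growing the auxiliary set systematically improves the fit", {
  # fixed s-Gaussian dimer; primary = one function per atom; nested
  # auxiliary sets of unit-charge Gaussian distributions per atom.  The
  # Coulomb-metric residual of the constrained cross-pair fit must fall
  # monotonically over nested sets, and the richest set must beat the
  # poorest on the worst-case integral error.
  alpha <- 1.0
  d <- 2.0
  A <- c(0, 0, 0); B <- c(0, 0, d)
  ga <- gauss_orbital(A, 0, 0, alpha)
  gb <- gauss_orbital(B, 0, 0, alpha)
  prim <- list(sgauss(A, alpha, coef = ga$coefs),
               sgauss(B, alpha, coef = gb$coefs))
  Smat <- diag(2)
  Smat[1, 2] <- Smat[2, 1] <- pair_integrals_ss(prim[[1]], prim[[2]])[["overlap"]]
  make_charge <- function(center, gammab) {
    sgauss(center, gammab / 2, coef = sqrt(1 / (pi / gammab)^1.5))
  }
  exact <- array(0, c(2, 2, 2, 2))
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    exact[p, q, r, s] <- eri_ssss(prim[[p]], prim[[q]], prim[[r]], prim[[s]])
  }
  fit_for <- function(gammas) {
    centers <- list(A, B)
    chg <- list(); atom <- integer(0)
    for (at in 1:2) for (g in gammas) {
      chg[[length(chg) + 1L]] <- make_charge(centers[[at]], g)
      atom <- c(atom, at)
    }
    nA <- length(chg)
    V <- matrix(0, nA, nA)
    for (i in 1:nA) for (j in 1:nA) {
      V[i, j] <- sqmkit:::gauss_charge_coulomb(
        2 * chg[[i]]$exponent, if (atom[i] == 1) A else B,
        2 * chg[[j]]$exponent, if (atom[j] == 1) A else B)
    }
    aux <- aux_basis(atom = atom, Q = rep(1, nA))
    m <- build_metric(aux, V = V)
    b_one <- list()
    for (at in 1:2) {
      mus <- which(atom == at)
      barr <- array(0, c(length(mus), 1, 1))
      for (k in seq_along(mus)) {
        barr[k, 1, 1] <- eri_ssss(prim[[at]], prim[[at]],
                                  chg[[mus[k]]], chg[[mus[k]]])
      }
      b_one[[as.character(at)]] <- barr
    }
    # oracle Coulomb projections of the cross-pair density: this is the
    # explicit-function-approximation mode of the two-center fit (the W
    # intermediate carries the metric projections)
    W12 <- array(0, c(nA, 1, 1))
    for (k in 1:nA) {
      W12[k, 1, 1] <- eri_ssss(prim[[1]], prim[[2]], chg[[k]], chg[[k]])
    }
    X <- density_fit_X(Smat, 1:2, m, b_one = b_one,
                       W_two = list("1_2" = W12))
    X12 <- X[, 1, 2]
    resid2 <- exact[1, 2, 1, 2] - 2 * sum(W12[, 1, 1] * X12) +
      as.numeric(t(X12) %*% V %*% X12)
    list(metric_residual2 = resid2,
         max_err = max(abs(factored_eri(X, m) - exact)))
  }
  sets <- list(c(2), c(2, 1), c(2, 1, 4), c(2, 1, 4, 0.5))
  fits <- lapply(sets, fit_for)
  res2 <- vapply(fits, `[[`, numeric(1), "metric_residual2")
  expect_true(all(res2 > -1e-12))          # residual norm is non-negative
  expect_true(all(diff(res2) < 1e-10))     # nested sets never fit worse
  poorest <- fit_for(c(1))
  expect_lt(fits[[length(fits)]]$max_err, poorest$max_err)
})
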