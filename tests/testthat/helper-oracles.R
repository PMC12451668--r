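# Independent test oracles, kept deliberately separate from the package's
# own code paths.

# --- Jordan-Wigner operator-matrix many-body oracle ------------------------
# Spin orbitals ordered all-up (1..M) then all-down (M+1..2M); annihilation
# operators as explicit kron-product matrices on the 4^M Fock space.
jw_annihilators <- function(M) {
  nso <- 2L * M
  I2 <- diag(2)
  Z <- diag(c(1, -1))
  a <- matrix(c(0, 0, 1, 0), 2) # annihilates |1>
  ops <- vector("list", nso)
  for (p in seq_len(nso)) {
    mats <- rep(list(I2), nso)
    if (p > 1) for (q in 1:(p - 1)) mats[[q]] <- Z
    mats[[p]] <- a
    Mfull <- 1
    for (m in mats) Mfull <- kronecker(Mfull, m)
    ops[[p]] <- Mfull
  }
  ops
}

# full Fock-space Hamiltonian from (h, eri) via explicit operators
jw_hamiltonian <- function(h, eri) {
  M <- nrow(h)
  an <- jw_annihilators(M)
  cr <- lapply(an, t)
  so <- function(p, spin) if (spin == "u") p else M + p
  H <- matrix(0, 4^M, 4^M)
  for (p in 1:M) for (q in 1:M) for (sp in c("u", "d")) {
    if (h[p, q] != 0) H <- H + h[p, q] * cr[[so(p, sp)]] %*% an[[so(q, sp)]]
  }
  for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
    if (eri[p, q, r, s] == 0) next
    for (s1 in c("u", "d")) for (s2 in c("u", "d")) {
      H <- H + 0.5 * eri[p, q, r, s] *
        cr[[so(p, s1)]] %*% cr[[so(r, s2)]] %*% an[[so(s, s2)]] %*%
        an[[so(q, s1)]]
    }
  }
  H
}

# sector occupation bookkeeping for the JW basis
jw_sector_index <- function(M) {
  an <- jw_annihilators(M)
  occ <- sapply(seq_len(2 * M), function(p) diag(t(an[[p]]) %*% an[[p]]))
  nup <- rowSums(occ[, 1:M, drop = FALSE])
  ndn <- rowSums(occ[, M + (1:M), drop = FALSE])
  list(nup = nup, ndn = ndn)
}

# random 8-fold-symmetric eri tensor
random_sym_eri <- function(M) {
  eri <- array(stats::rnorm(M^4), rep(M, 4))
  sym <- array(0, rep(M, 4))
  for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
    sym[p, q, r, s] <- mean(c(
      eri[p, q, r, s], eri[q, p, r, s], eri[p, q, s, r], eri[q, p, s, r],
      eri[r, s, p, q], eri[s, r, p, q], eri[r, s, q, p], eri[s, r, q, p]))
  }
  sym
}

# --- real spherical harmonics for the sphere-sampling rotation oracle ------
# consistent unnormalized set, m = -l..l
real_harmonic <- function(l, m, v) {
  x <- v[1]; y <- v[2]; z <- v[3]
  if (l == 0) return(1)
  if (l == 1) return(c(y, z, x)[m + 2])
  if (l == 2) {
    vals <- c(sqrt(3) * x * y, sqrt(3) * y * z, 0.5 * (3 * z^2 - 1),
              sqrt(3) * x * z, sqrt(3) / 2 * (x^2 - y^2))
    return(vals[m + 3])
  }
  stop("real_harmonic: l > 2 not needed by the oracle")
}

# least-squares re-expansion of lab harmonics in rotated harmonics,
# sampled on the unit sphere
rotation_oracle <- function(l, u) {
  A <- sqmkit:::rotation_from_z(u)
  n <- 400
  pts <- matrix(stats::rnorm(3 * n), n)
  pts <- pts / sqrt(rowSums(pts^2))
  B <- sapply(-l:l, function(M) {
    apply(pts, 1, function(v) real_harmonic(l, M, as.vector(t(A) %*% v)))
  })
  Ymat <- sapply(-l:l, function(m) {
    apply(pts, 1, function(v) real_harmonic(l, m, v))
  })
  t(qr.solve(B, Ymat))
}

# --- Slater-Koster channels generated from explicit Gaussian orbitals ------
# standard pose: bra orbital at r*z, ket at the origin
sk_channels_from_gorbs <- function(kernel, lA, lB, exA, exB,
                                   tau = c("a", "b"), cutoff = 50) {
  chans <- list()
  for (M in 0:min(lA, lB)) {
    fn <- local({
      kernel0 <- kernel; lA0 <- lA; lB0 <- lB; M0 <- M
      exA0 <- exA; exB0 <- exB
      function(r) {
        direct_two_center(kernel0,
                          gauss_orbital(c(0, 0, r), lA0, M0, exA0),
                          gauss_orbital(c(0, 0, 0), lB0, M0, exB0))
      }
    })
    chans[[length(chans) + 1L]] <-
      radial_channel(tau, c(lA, lB), M, fn, cutoff = cutoff)
  }
  chans
}

# 1D Simpson quadrature helper (independent numerical oracle)
simpson <- function(f, a, b, n = 2001) {
  if (n %% 2 == 0) n <- n + 1
  x <- seq(a, b, length.out = n)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  sum(w * f(x)) * (x[2] - x[1]) / 3
}
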