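#' The Boys function of order zero
#'
#' \code{boys0(x)} evaluates \eqn{F_0(x) = \frac{1}{2}\sqrt{\pi/x}\,
#' \mathrm{erf}(\sqrt{x})}, the order-zero Boys function that underlies all
#' closed-form Coulomb integrals over s-type Gaussians.  A Taylor branch is
#' used near the origin where the closed form is indeterminate.
#'
#' @param x numeric vector, dimensionless, \code{x >= 0}.
#' @return numeric vector of \eqn{F_0(x)} values; \code{boys0(0) == 1}.
#' @examples
#' boys0(c(0, 1, 10))
#' @export
boys0 <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("boys0: x must be finite and non-negative")
  }
  out <- numeric(length(x))
  small <- x < 1e-6
  xs <- x[small]
  # series 1 - x/3 + x^2/10 - x^3/42; truncation error < x^4/216
  out[small] <- 1 - xs / 3 + xs^2 / 10 - xs^3 / 42
  xl <- x[!small]
  # erf(t) = 2*pnorm(t*sqrt(2)) - 1
  out[!small] <- 0.5 * sqrt(pi / xl) * (2 * stats::pnorm(sqrt(2 * xl)) - 1)
  out
}

#' Construct a primitive s-type Gaussian
#'
#' A primitive \eqn{g(r) = c\,e^{-\alpha |r - A|^2}}.  When \code{coef} is
#' omitted the primitive is normalized to unit self-overlap,
#' \eqn{c = (2\alpha/\pi)^{3/4}}.
#'
#' @param center numeric length-3 position (bohr).
#' @param exponent Gaussian exponent \eqn{\alpha} (bohr^-2), positive.
#' @param coef contraction coefficient; default normalizes the primitive.
#' @return an object of class \code{"sgauss"}.
#' @export
sgauss <- function(center, exponent, coef = NULL) {
  stopifnot(length(center) == 3, is.finite(exponent), exponent > 0)
  if (is.null(coef)) coef <- (2 * exponent / pi)^0.75
  structure(list(center = as.numeric(center), exponent = exponent,
                 coef = coef), class = "sgauss")
}

#' Overlap, kinetic and nuclear-attraction integrals for an s-Gaussian pair
#'
#' Closed-form two-center integrals between primitive s-Gaussians:
#' overlap, kinetic energy, and the attraction to a set of point nuclei
#' (returned with its physical negative sign).  All values in atomic units.
#'
#' @param a,b \code{sgauss} primitives.
#' @param nuclei optional matrix with columns \code{charge, x, y, z}; when
#'   \code{NULL} the nuclear-attraction entry is 0.
#' @return named numeric vector \code{c(overlap=, kinetic=, nuclear=)}.
#' @export
pair_integrals_ss <- function(a, b, nuclei = NULL) {
  p <- a$exponent + b$exponent
  mu <- a$exponent * b$exponent / p
  d2 <- sum((a$center - b$center)^2)
  pref <- a$coef * b$coef * exp(-mu * d2)
  s <- pref * (pi / p)^1.5
  t <- mu * (3 - 2 * mu * d2) * s
  v <- 0
  if (!is.null(nuclei) && nrow(nuclei) > 0) {
    P <- (a$exponent * a$center + b$exponent * b$center) / p
    for (k in seq_len(nrow(nuclei))) {
      C <- as.numeric(nuclei[k, 2:4])
      v <- v - nuclei[k, 1] * pref * (2 * pi / p) *
        boys0(p * sum((P - C)^2))
    }
  }
  c(overlap = s, kinetic = t, nuclear = v)
}

#' Four-center two-electron repulsion integral over s-Gaussians
#'
#' Closed-form \eqn{(ab|cd)} in chemists' notation for primitive s-type
#' Gaussians, in hartree.
#'
#' @param a,b,c,d \code{sgauss} primitives.
#' @return the integral value (hartree).
#' @export
eri_ssss <- function(a, b, c, d) {
  p <- a$exponent + b$exponent
  q <- c$exponent + d$exponent
  P <- (a$exponent * a$center + b$exponent * b$center) / p
  Q <- (c$exponent * c$center + d$exponent * d$center) / q
  Eab <- a$coef * b$coef *
    exp(-a$exponent * b$exponent / p * sum((a$center - b$center)^2))
  Ecd <- c$coef * d$coef *
    exp(-c$exponent * d$exponent / q * sum((c$center - d$center)^2))
  rho <- p * q / (p + q)
  2 * pi^2.5 / (p * q * sqrt(p + q)) * Eab * Ecd *
    boys0(rho * sum((P - Q)^2))
}

# Coulomb energy of two spherical Gaussian charge distributions
# exp(-p|r-P|^2), exp(-q|r-Q|^2) normalized to unit charge.
gauss_charge_coulomb <- function(p, P, q, Q) {
  t <- p * q / (p + q)
  2 * sqrt(t / pi) * boys0(t * sum((P - Q)^2))
}

# --- Cartesian Gaussian machinery (s and p shells) -------------------------
#
# 1D overlap integrals S_ij = int x_A^i x_B^j exp(-a x_A^2) exp(-b x_B^2) dx
# by the standard two-term recursion; enough angular momentum for p (and the
# j+2 shifts needed by the kinetic kernel).

ob_1d_overlap <- function(i, j, a, b, Ax, Bx) {
  p <- a + b
  Px <- (a * Ax + b * Bx) / p
  XPA <- Px - Ax
  XPB <- Px - Bx
  nmax <- max(i, j) + 3L
  S <- matrix(0, nmax + 1L, nmax + 1L) # S[i+1, j+1]
  S[1, 1] <- sqrt(pi / p) * exp(-a * b / p * (Ax - Bx)^2)
  for (ii in 0:nmax) {
    for (jj in 0:nmax) {
      if (ii == 0 && jj == 0) next
      if (ii > 0) {
        val <- XPA * S[ii, jj + 1L]
        if (ii > 1) val <- val + (ii - 1) * S[ii - 1L, jj + 1L] / (2 * p)
        if (jj > 0) val <- val + jj * S[ii, jj] / (2 * p)
        S[ii + 1L, jj + 1L] <- val
      } else {
        val <- XPB * S[1L, jj]
        if (jj > 1) val <- val + (jj - 1) * S[1L, jj - 1L] / (2 * p)
        S[ii + 1L, jj + 1L] <- val
      }
    }
  }
  S
}

# overlap and kinetic between Cartesian Gaussians with angular vectors
# la, lb (e.g. c(1,0,0) for p_x), unit-coefficient primitives
cart_gauss_pair <- function(la, lb, a, b, A, B) {
  Sx <- ob_1d_overlap(la[1], lb[1], a, b, A[1], B[1])
  Sy <- ob_1d_overlap(la[2], lb[2], a, b, A[2], B[2])
  Sz <- ob_1d_overlap(la[3], lb[3], a, b, A[3], B[3])
  s1 <- function(S, i, j) S[i + 1L, j + 1L]
  ov <- s1(Sx, la[1], lb[1]) * s1(Sy, la[2], lb[2]) * s1(Sz, la[3], lb[3])
  k1 <- function(S, i, j) {
    val <- b * (2 * j + 1) * s1(S, i, j) - 2 * b^2 * s1(S, i, j + 2L)
    if (j >= 2) val <- val - 0.5 * j * (j - 1) * s1(S, i, j - 2L)
    val
  }
  kin <- k1(Sx, la[1], lb[1]) * s1(Sy, la[2], lb[2]) * s1(Sz, la[3], lb[3]) +
    s1(Sx, la[1], lb[1]) * k1(Sy, la[2], lb[2]) * s1(Sz, la[3], lb[3]) +
    s1(Sx, la[1], lb[1]) * s1(Sy, la[2], lb[2]) * k1(Sz, la[3], lb[3])
  c(overlap = ov, kinetic = kin)
}

# map real-harmonic (l, m) to a Cartesian power vector for l <= 1;
# ordering m = -1, 0, 1  <->  y, z, x
lm_to_cart <- function(l, m) {
  if (l == 0) return(c(0L, 0L, 0L))
  if (l == 1) {
    if (m == -1) return(c(0L, 1L, 0L))
    if (m == 0) return(c(0L, 0L, 1L))
    if (m == 1) return(c(1L, 0L, 0L))
  }
  stop("lm_to_cart: only s and p orbitals are supported by the Gaussian engine")
}

#' Construct a contracted s/p Gaussian orbital for the integral oracle
#'
#' Builds a real atomic orbital \eqn{\phi(r)} as a contraction of Cartesian
#' Gaussians sharing one center, with real-spherical-harmonic angular
#' character \code{(l, m)} (ordering \code{m = -l..l}; for p this maps to
#' \code{y, z, x}).  The contraction is normalized to unit self-overlap.
#'
#' @param center numeric length-3 (bohr).
#' @param l,m angular quantum numbers; \code{l <= 1}.
#' @param exponents,coefs primitive exponents and (pre-normalization)
#'   contraction weights.
#' @return object of class \code{"gorb"}.
#' @export
gauss_orbital <- function(center, l = 0, m = 0, exponents, coefs = NULL) {
  stopifnot(l %in% c(0L, 1L), abs(m) <= l, length(center) == 3)
  if (is.null(coefs)) coefs <- rep(1, length(exponents))
  stopifnot(length(coefs) == length(exponents), all(exponents > 0))
  orb <- structure(list(center = as.numeric(center), l = as.integer(l),
                        m = as.integer(m), exponents = exponents,
                        coefs = coefs), class = "gorb")
  n2 <- direct_two_center("overlap", orb, orb, .allow_coincident = TRUE)
  orb$coefs <- coefs / sqrt(n2)
  orb
}

#' Direct two-center integral between explicit Gaussian orbitals
#'
#' Evaluates \eqn{\int \phi_p(r) K(r, r') \phi_q(r')\,dr\,dr'} (with
#' \eqn{K} collapsing to a one-center kernel for \code{overlap} and
#' \code{kinetic}) by brute-force closed forms.  This is the equivalence
#' oracle for the rotation-based Slater-Koster assembly.
#'
#' @param kernel one of \code{"overlap"}, \code{"kinetic"},
#'   \code{"coulomb"} (s orbitals only: the two-electron repulsion between
#'   the squared-orbital charge clouds is not meant here; \code{"coulomb"}
#'   is the \eqn{1/|r-r'|} kernel between the two orbital densities'
#'   generating pair, i.e. \eqn{(pp|qq)}-style channel values are built
#'   from \code{\link{eri_ssss}} directly by callers).
#' @param p,q \code{gorb} orbitals.
#' @param .allow_coincident internal flag used during normalization.
#' @return the integral value in atomic units.
#' @export
direct_two_center <- function(kernel, p, q, .allow_coincident = FALSE) {
  if (!.allow_coincident && sum((p$center - q$center)^2) < 1e-20) {
    stop("direct_two_center: coincident centers belong to one-center handling")
  }
  if (!kernel %in% c("overlap", "kinetic")) {
    stop("direct_two_center: unsupported kernel '", kernel, "'")
  }
  la <- lm_to_cart(p$l, p$m)
  lb <- lm_to_cart(q$l, q$m)
  idx <- if (kernel == "overlap") 1L else 2L
  acc <- 0
  for (i in seq_along(p$exponents)) {
    for (j in seq_along(q$exponents)) {
      val <- cart_gauss_pair(la, lb, p$exponents[i], q$exponents[j],
                             p$center, q$center)[idx]
      acc <- acc + p$coefs[i] * q$coefs[j] * val
    }
  }
  unname(acc)
}

#' Even-tempered s-Gaussian basis for one hydrogen atom
#'
#' Exponents form the geometric sequence \eqn{\alpha_0 \beta^k},
#' \eqn{k = 0..n-1}; each primitive is its own normalized basis function.
#' The defaults (10 functions, \eqn{\alpha_0 = 0.02}, \eqn{\beta = 2.5})
#' are the package's internal large-s reference basis for hydrogen.
#'
#' @param n number of primitives per atom.
#' @param alpha0 smallest exponent (bohr^-2).
#' @param beta geometric ratio, \code{> 1}.
#' @return object of class \code{"oracle_basis"}: list with the exponent
#'   vector and the per-atom function count.
#' @export
even_tempered_basis <- function(n = 10, alpha0 = 0.02, beta = 2.5) {
  stopifnot(n >= 1, alpha0 > 0, beta > 1)
  structure(list(exponents = alpha0 * beta^(0:(n - 1)), n_per_atom = n),
            class = "oracle_basis")
}

# Vectorized AO integral set for an s-Gaussian basis on a hydrogen cluster.
# positions: n_atom x 3 matrix (bohr); returns S, h (kinetic + attraction to
# all unit-charge nuclei), full 4-index ERI array, nuclear repulsion, and
# the atom index of every basis function.
oracle_ao_integrals <- function(positions, basis) {
  positions <- matrix(positions, ncol = 3)
  na <- nrow(positions)
  ex <- rep(basis$exponents, times = na)
  atom <- rep(seq_len(na), each = basis$n_per_atom)
  M <- length(ex)
  cen <- positions[atom, , drop = FALSE]
  nc <- (2 * ex / pi)^0.75

  # pair quantities (ordered pairs, M x M)
  p <- outer(ex, ex, "+")
  d2 <- outer(cen[, 1], cen[, 1], "-")^2 + outer(cen[, 2], cen[, 2], "-")^2 +
    outer(cen[, 3], cen[, 3], "-")^2
  mu <- outer(ex, ex) / p
  pref <- outer(nc, nc) * exp(-mu * d2)
  S <- pref * (pi / p)^1.5
  Tm <- mu * (3 - 2 * mu * d2) * S
  # product-Gaussian centers
  Px <- (outer(ex * cen[, 1], ex * cen[, 1], "+")) / p
  Py <- (outer(ex * cen[, 2], ex * cen[, 2], "+")) / p
  Pz <- (outer(ex * cen[, 3], ex * cen[, 3], "+")) / p
  V <- matrix(0, M, M)
  for (k in seq_len(na)) {
    r2 <- (Px - positions[k, 1])^2 + (Py - positions[k, 2])^2 +
      (Pz - positions[k, 3])^2
    V <- V - pref * (2 * pi / p) * boys0(p * r2)
  }
  h <- Tm + V

  # ERI over ordered pairs: (ab|cd)
  pv <- as.vector(p)
  Ev <- as.vector(pref)
  Pxv <- as.vector(Px); Pyv <- as.vector(Py); Pzv <- as.vector(Pz)
  np <- M * M
  psum <- outer(pv, pv, "+")
  rho <- outer(pv, pv) / psum
  R2 <- outer(Pxv, Pxv, "-")^2 + outer(Pyv, Pyv, "-")^2 +
    outer(Pzv, Pzv, "-")^2
  eri <- 2 * pi^2.5 / (outer(pv, pv) * sqrt(psum)) * outer(Ev, Ev) *
    boys0(rho * R2)
  dim(eri) <- c(M, M, M, M)

  enuc <- 0
  if (na > 1) {
    for (i in 1:(na - 1)) for (j in (i + 1):na) {
      enuc <- enuc + 1 / sqrt(sum((positions[i, ] - positions[j, ])^2))
    }
  }
  list(S = S, h = h, eri = eri, enuc = enuc, atom = atom, M = M)
}
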