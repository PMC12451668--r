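#' @useDynLib sqmkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cartesian rotation matrix taking the z axis onto the unit vector u.
# The anti-parallel case u ~ (0,0,-1) is resolved by a rotation of pi
# about the x axis (fixed tie-break).
rotation_from_z <- function(u) {
  nu <- sqrt(sum(u^2))
  if (abs(nu - 1) > 1e-10) stop("rotation_from_z: u must be a unit vector")
  u <- u / nu
  uz <- u[3]
  if (uz >= 1 - 1e-14) return(diag(3))
  if (uz <= -1 + 1e-14) return(diag(c(1, -1, -1)))
  k <- c(-u[2], u[1], 0)
  s <- sqrt(sum(k^2))
  k <- k / s
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * uz + s * K + (1 - uz) * tcrossprod(k)
}

#' Rotation block for real spherical harmonics
#'
#' Returns the \eqn{(2l+1)\times(2l+1)} orthogonal matrix
#' \eqn{R^l_{m,M}(u)} expressing the lab-frame (z-aligned) real spherical
#' harmonics in terms of harmonics aligned to the unit vector \code{u}:
#' \eqn{Y_{l,m}(\hat r) = \sum_M R^l_{m,M}(u)\, Y_{l,M}(A^{-1}\hat r)}
#' where \eqn{A} is the rotation taking z onto \code{u}.  Rows and columns
#' are indexed by \eqn{m, M = -l..l} in ascending order; for \eqn{l = 1}
#' this corresponds to the Cartesian ordering \code{(y, z, x)}.  Blocks for
#' \eqn{l \ge 2} are built by the stable recursion of Ivanic-Ruedenberg
#' type from the \eqn{l = 1} block.
#'
#' @param l angular momentum, non-negative integer.
#' @param u unit length-3 direction vector.
#' @return a list of class \code{"rotation_block"} with fields \code{l},
#'   \code{u} and \code{matrix}.
#' @examples
#' rotation_block(1, c(1, 0, 0))$matrix
#' @export
rotation_block <- function(l, u) {
  if (!is.numeric(l) || length(l) != 1 || l < 0 || l != round(l)) {
    stop("rotation_block: l must be a non-negative integer")
  }
  l <- as.integer(l)
  nu <- sqrt(sum(u^2))
  if (abs(nu - 1) > 1e-10) stop("rotation_block: u must be a unit vector")
  u <- u / nu
  A <- rotation_from_z(u)
  structure(list(l = l, u = u, matrix = real_sph_rotation(l, A)),
            class = "rotation_block")
}

# Real-spherical-harmonic rotation matrix of order l for a given 3x3
# Cartesian rotation A (recursion from the l=1 block).
real_sph_rotation <- function(l, A) {
  if (l == 0) return(matrix(1, 1, 1))
  cart <- c(2L, 3L, 1L) # m = -1, 0, 1  ->  y, z, x
  R1 <- A[cart, cart]
  if (l == 1) return(R1)
  Rprev <- R1
  for (ll in 2:l) {
    Rprev <- rsh_step(ll, R1, Rprev)
  }
  Rprev
}

# one recursion step: build the order-l block from the (l-1) block
rsh_step <- function(l, R1, Rprev) {
  r1 <- function(i, j) R1[i + 2L, j + 2L]           # i, j in -1..1
  rp <- function(mu, mp) {                          # indices -l+1..l-1
    Rprev[mu + l, mp + l]
  }
  Pfun <- function(i, mu, mp) {
    if (abs(mp) < l) {
      r1(i, 0) * rp(mu, mp)
    } else if (mp == l) {
      r1(i, 1) * rp(mu, l - 1) - r1(i, -1) * rp(mu, -l + 1)
    } else {
      r1(i, 1) * rp(mu, -l + 1) + r1(i, -1) * rp(mu, l - 1)
    }
  }
  out <- matrix(0, 2 * l + 1, 2 * l + 1)
  for (m in -l:l) {
    for (mp in -l:l) {
      denom <- if (abs(mp) < l) (l + mp) * (l - mp) else (2 * l) * (2 * l - 1)
      am <- abs(m)
      ucf <- sqrt((l + m) * (l - m) / denom)
      vcf <- 0.5 * sqrt((1 + (m == 0)) * (l + am - 1) * (l + am) / denom) *
        (1 - 2 * (m == 0))
      wcf <- -0.5 * sqrt((l - am - 1) * (l - am) / denom) * (1 - (m == 0))
      val <- 0
      if (ucf != 0) val <- val + ucf * Pfun(0, m, mp)
      if (vcf != 0) {
        V <- if (m == 0) {
          Pfun(1, 1, mp) + Pfun(-1, -1, mp)
        } else if (m > 0) {
          Pfun(1, m - 1, mp) * sqrt(1 + (m == 1)) -
            Pfun(-1, -m + 1, mp) * (1 - (m == 1))
        } else {
          Pfun(1, m + 1, mp) * (1 - (m == -1)) +
            Pfun(-1, -m - 1, mp) * sqrt(1 + (m == -1))
        }
        val <- val + vcf * V
      }
      if (wcf != 0) {
        W <- if (m > 0) {
          Pfun(1, m + 1, mp) + Pfun(-1, -m - 1, mp)
        } else {
          Pfun(1, m - 1, mp) - Pfun(-1, -m + 1, mp)
        }
        val <- val + wcf * W
      }
      out[m + l + 1L, mp + l + 1L] <- val
    }
  }
  out
}
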