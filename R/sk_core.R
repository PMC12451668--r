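#' Atomic-orbital label
#'
#' Labels a real atomic orbital by its center (bohr), atom/orbital type
#' tag, angular momentum \code{l} and magnetic number \code{m}.
#'
#' @param center numeric length-3 (bohr).
#' @param tau type tag (string).
#' @param l,m angular quantum numbers, \code{|m| <= l}.
#' @return object of class \code{"orbital_label"}.
#' @export
orbital_label <- function(center, tau, l, m) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            l >= 0, abs(m) <= l)
  structure(list(center = as.numeric(center), tau = as.character(tau),
                 l = as.integer(l), m = as.integer(m)),
            class = "orbital_label")
}

#' Radial Slater-Koster channel
#'
#' A distance-resolved channel \eqn{K_m^{\tau\tau'}(r)} given either as an
#' analytic callable or as values on a grid (interpolated by a cubic
#' spline).  Beyond the cutoff radius the channel follows its declared
#' tail: identically zero for local matrix elements, or the
#' monopole-monopole form \eqn{q q'/r} for Coulomb matrix elements.  For
#' grid channels the knot at the cutoff must equal the tail value there
#' (continuity; checked to 1e-8).
#'
#' @param tau_pair length-2 character, the \eqn{(\tau, \tau')} type pair.
#' @param l_pair length-2 integer \eqn{(l, l')}.
#' @param m channel index, \code{0 <= m <= min(l_pair)}.
#' @param values a function of distance (bohr), or a numeric vector of
#'   values on the grid \code{r}.
#' @param r grid of distances (bohr) when \code{values} is numeric.
#' @param cutoff cutoff radius (bohr).
#' @param tail \code{"zero"} or \code{"monopole"}.
#' @param charges length-2 numeric, the monopole charges \eqn{(q, q')}
#'   used by the monopole tail.
#' @return object of class \code{"radial_channel"}.
#' @export
radial_channel <- function(tau_pair, l_pair, m, values, r = NULL,
                           cutoff = 10, tail = c("zero", "monopole"),
                           charges = c(1, 1)) {
  tail <- match.arg(tail)
  l_pair <- as.integer(l_pair)
  stopifnot(length(tau_pair) == 2, length(l_pair) == 2,
            m >= 0, m <= min(l_pair), cutoff > 0)
  ch <- list(tau_pair = as.character(tau_pair), l_pair = l_pair,
             m = as.integer(m), cutoff = cutoff, tail = tail,
             charges = charges)
  if (is.function(values)) {
    ch$fun <- values
    ch$grid_start <- 0
  } else {
    stopifnot(is.numeric(values), !is.null(r), length(r) == length(values),
              !is.unsorted(r))
    ch$fun <- stats::splinefun(r, values, method = "natural")
    ch$grid_start <- r[1]
    ch$grid <- list(r = r, values = values)
    if (max(r) >= cutoff - 1e-12) {
      tv <- if (tail == "zero") 0 else prod(charges) / cutoff
      cv <- ch$fun(cutoff)
      if (abs(cv - tv) > 1e-8) {
        warning(sprintf(
          "radial_channel: value at cutoff (%.3e) does not match tail (%.3e)",
          cv, tv))
      }
    }
  }
  structure(ch, class = "radial_channel")
}

#' Evaluate a radial channel at a distance
#'
#' For \code{r <= cutoff} the interpolated (or analytic) value is
#' returned; beyond the cutoff the declared tail is used exactly.
#'
#' @param channel a \code{\link{radial_channel}}.
#' @param r distance in bohr, \code{r > 0}.
#' @return channel value (hartree for energy kernels, dimensionless for
#'   overlap).
#' @export
radial_value <- function(channel, r) {
  if (!is.finite(r) || r <= 0) stop("radial_value: r must be positive")
  if (r > channel$cutoff) {
    return(switch(channel$tail,
                  zero = 0,
                  monopole = prod(channel$charges) / r))
  }
  if (r < channel$grid_start - 1e-12) {
    stop("radial_value: r below the tabulated grid start (no extrapolation)")
  }
  channel$fun(r)
}

channel_key <- function(tau, taup, l, lp, m) {
  paste(tau, taup, l, lp, m, sep = "|")
}

#' Slater-Koster table
#'
#' A set of radial channels for one kernel kind, keyed by
#' \eqn{(\tau, \tau', l, l', m)}.  Channels are auto-completed from the
#' independent set \eqn{0 \le m \le l \le l'} using the symmetry
#' \eqn{K_m^{\tau\tau'}(r) = (-1)^{l+l'} K_m^{\tau'\tau}(r)}.
#'
#' @param kernel_kind one of \code{"overlap"}, \code{"one_body"},
#'   \code{"ee_coulomb"}, \code{"eH_coulomb"}, \code{"HH_coulomb"}.
#' @param channels list of \code{\link{radial_channel}} objects.
#' @return object of class \code{"sk_table"}.
#' @export
sk_table <- function(kernel_kind = c("overlap", "one_body", "ee_coulomb",
                                     "eH_coulomb", "HH_coulomb"),
                     channels = list()) {
  kernel_kind <- match.arg(kernel_kind)
  tab <- list()
  for (ch in channels) {
    key <- channel_key(ch$tau_pair[1], ch$tau_pair[2],
                       ch$l_pair[1], ch$l_pair[2], ch$m)
    tab[[key]] <- ch
  }
  # auto-complete transposed partners
  for (key in names(tab)) {
    ch <- tab[[key]]
    tkey <- channel_key(ch$tau_pair[2], ch$tau_pair[1],
                        ch$l_pair[2], ch$l_pair[1], ch$m)
    if (is.null(tab[[tkey]])) {
      sgn <- (-1)^(sum(ch$l_pair))
      tch <- ch
      tch$tau_pair <- rev(ch$tau_pair)
      tch$l_pair <- rev(ch$l_pair)
      f <- ch$fun
      tch$fun <- local({
        f0 <- f; s0 <- sgn
        function(r) s0 * f0(r)
      })
      if (!is.null(ch[["grid"]])) {
        tch[["grid"]]$values <- sgn * ch[["grid"]]$values
      }
      if (tch$tail == "monopole") {
        tch$charges <- sgn * ch$charges # keep tail consistent with sign
      }
      tab[[tkey]] <- tch
    }
  }
  structure(list(kernel_kind = kernel_kind, channels = tab),
            class = "sk_table")
}

get_channel <- function(table, tau, taup, l, lp, m) {
  ch <- table$channels[[channel_key(tau, taup, l, lp, m)]]
  if (is.null(ch)) {
    stop(sprintf("missing Slater-Koster channel (%s,%s,l=%d,l'=%d,m=%d)",
                 tau, taup, l, lp, m))
  }
  ch
}

#' Two-center matrix element from Slater-Koster channels
#'
#' Assembles
#' \eqn{K_{p,q} = \sum_{M=-L}^{L} R^{l}_{m,M}(u)\, K^{\tau\tau'}_{|M|}(r)\,
#' R^{l'}_{m',M}(u)} with \eqn{L = \min(l, l')}, \eqn{r = |r_p - r_q|}
#' and \eqn{u = (r_p - r_q)/r}, using \code{\link{rotation_block}} and
#' \code{\link{radial_value}}.
#'
#' @param p,q \code{\link{orbital_label}} objects on distinct centers.
#' @param table an \code{\link{sk_table}} covering the required channels.
#' @return the matrix element (atomic units).
#' @export
sk_element <- function(p, q, table) {
  d <- p$center - q$center
  r <- sqrt(sum(d^2))
  if (r < 1e-12) {
    stop("sk_element: coincident centers are one-center elements")
  }
  u <- d / r
  L <- min(p$l, q$l)
  Rp <- rotation_block(p$l, u)$matrix
  Rq <- rotation_block(q$l, u)$matrix
  acc <- 0
  for (M in -L:L) {
    ch <- get_channel(table, p$tau, q$tau, p$l, q$l, abs(M))
    acc <- acc + Rp[p$m + p$l + 1L, M + p$l + 1L] *
      radial_value(ch, r) *
      Rq[q$m + q$l + 1L, M + q$l + 1L]
  }
  acc
}

#' Assemble a full two-center matrix over a cluster
#'
#' Builds the matrix of a two-center kernel over all atomic orbitals of a
#' typed geometry.  Off-diagonal atom blocks come from
#' \code{\link{sk_element}}; diagonal (one-center) blocks are supplied by
#' the caller through \code{one_center}, defaulting to the identity for
#' the overlap kernel and to zero otherwise.
#'
#' @param geometry list with \code{positions} (n x 3 matrix, bohr) and
#'   \code{tau} (character vector of atom types).
#' @param basis_spec named list: for each type tag, the integer vector of
#'   shell angular momenta carried by that atom.
#' @param table an \code{\link{sk_table}}.
#' @param one_center optional function \code{function(tau)} returning that
#'   atom's one-center block (matrix over its orbitals in \code{l}, then
#'   \code{m = -l..l} order).
#' @return matrix with orbital labels in attribute \code{"labels"}.
#' @export
assemble_two_center <- function(geometry, basis_spec, table,
                                one_center = NULL) {
  pos <- matrix(geometry$positions, ncol = 3)
  tau <- geometry$tau
  stopifnot(nrow(pos) == length(tau))
  labels <- list()
  for (i in seq_along(tau)) {
    shells <- basis_spec[[tau[i]]]
    if (is.null(shells)) stop("assemble_two_center: untyped atom ", tau[i])
    for (l in shells) for (m in -l:l) {
      labels[[length(labels) + 1L]] <- orbital_label(pos[i, ], tau[i], l, m)
    }
  }
  n <- length(labels)
  atom_of <- unlist(lapply(seq_along(tau), function(i) {
    rep(i, sum(2 * basis_spec[[tau[i]]] + 1))
  }))
  K <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (atom_of[a] == atom_of[b]) next
      K[a, b] <- sk_element(labels[[a]], labels[[b]], table)
    }
  }
  # one-center blocks
  for (i in seq_along(tau)) {
    idx <- which(atom_of == i)
    blk <- if (!is.null(one_center)) {
      one_center(tau[i])
    } else if (table$kernel_kind == "overlap") {
      diag(length(idx))
    } else {
      matrix(0, length(idx), length(idx))
    }
    K[idx, idx] <- blk
  }
  attr(K, "labels") <- labels
  attr(K, "atom_of") <- atom_of
  K
}

#' Check the transposition symmetry of a Slater-Koster table
#'
#' Verifies \eqn{K_m^{\tau\tau'}(r) = (-1)^{l+l'} K_m^{\tau'\tau}(r)} on a
#' sample of distances for every stored channel pair.
#'
#' @param table an \code{\link{sk_table}}.
#' @param r_sample distances at which to test (bohr).
#' @param tol tolerance for reported violations.
#' @return data frame of violations (zero rows when the table is
#'   consistent).
#' @export
check_symmetry <- function(table, r_sample = seq(0.6, 9.5, by = 0.7),
                           tol = 1e-10) {
  out <- list()
  for (key in names(table$channels)) {
    ch <- table$channels[[key]]
    tkey <- channel_key(ch$tau_pair[2], ch$tau_pair[1],
                        ch$l_pair[2], ch$l_pair[1], ch$m)
    tch <- table$channels[[tkey]]
    if (is.null(tch)) {
      out[[length(out) + 1L]] <- data.frame(channel = key, r = NA,
                                            deviation = NA,
                                            problem = "missing transpose")
      next
    }
    sgn <- (-1)^(sum(ch$l_pair))
    for (r in r_sample) {
      dev <- abs(radial_value(ch, r) - sgn * radial_value(tch, r))
      if (dev > tol) {
        out[[length(out) + 1L]] <- data.frame(channel = key, r = r,
                                              deviation = dev,
                                              problem = "sign relation")
      }
    }
  }
  if (length(out) == 0) {
    data.frame(channel = character(), r = numeric(), deviation = numeric(),
               problem = character())
  } else {
    do.call(rbind, out)
  }
}
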