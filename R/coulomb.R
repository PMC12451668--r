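#' Auxiliary basis for atom-local density fitting
#'
#' Atom-centered auxiliary functions \eqn{\rho_\mu} carry a type tag,
#' angular indices and a total charge \eqn{Q_\mu}; their mutual Coulomb
#' interactions define the fitting metric.  At least one function per
#' atom must carry nonzero charge for the charge-conservation constraint
#' to be feasible.
#'
#' @param atom integer vector: owning atom of each auxiliary function.
#' @param Q numeric vector of total charges \eqn{Q_\mu}.
#' @param tau character vector of type tags (recycled).
#' @param l,m angular indices (recycled; default s functions).
#' @return object of class \code{"aux_basis"}.
#' @export
aux_basis <- function(atom, Q, tau = "s_aux", l = 0L, m = 0L) {
  n <- length(atom)
  stopifnot(length(Q) == n, all(is.finite(Q)))
  structure(list(atom = as.integer(atom), Q = as.numeric(Q),
                 tau = rep_len(tau, n), l = rep_len(as.integer(l), n),
                 m = rep_len(as.integer(m), n), n = n),
            class = "aux_basis")
}

#' Coulomb metric of an auxiliary basis
#'
#' Builds the two-center Coulomb matrix \eqn{V_{\mu\nu}} over the
#' auxiliary basis (one-center diagonal from declared self-energies,
#' off-diagonal entries supplied as a matrix or computed from a
#' Slater-Koster Coulomb table), together with the inverse
#' \eqn{\Lambda} of every two-atom pair block.
#'
#' @param aux an \code{\link{aux_basis}}.
#' @param V either the full \eqn{V_{\mu\nu}} matrix (hartree), or
#'   \code{NULL} to assemble it from \code{table} and \code{positions}.
#' @param table optional \code{\link{sk_table}} of kind
#'   \code{"ee_coulomb"} used when \code{V} is \code{NULL}.
#' @param positions atom positions (n_atoms x 3, bohr) for table
#'   assembly.
#' @param self_energy numeric vector of one-center diagonal entries
#'   \eqn{V_{\mu\mu}} used when assembling from a table.
#' @return object of class \code{"coulomb_metric"}: list with \code{V},
#'   \code{Lambda} (named list of pair-block inverses, keys
#'   \code{"a_b"}), and the basis.
#' @export
build_metric <- function(aux, V = NULL, table = NULL, positions = NULL,
                         self_energy = NULL) {
  stopifnot(inherits(aux, "aux_basis"), aux$n >= 1)
  if (is.null(V)) {
    stopifnot(!is.null(table), !is.null(positions), !is.null(self_energy))
    positions <- matrix(positions, ncol = 3)
    V <- matrix(0, aux$n, aux$n)
    diag(V) <- rep_len(self_energy, aux$n)
    for (i in seq_len(aux$n)) for (j in seq_len(aux$n)) {
      if (aux$atom[i] == aux$atom[j]) next
      p <- orbital_label(positions[aux$atom[i], ], aux$tau[i],
                         aux$l[i], aux$m[i])
      q <- orbital_label(positions[aux$atom[j], ], aux$tau[j],
                         aux$l[j], aux$m[j])
      V[i, j] <- sk_element(p, q, table)
    }
  }
  stopifnot(nrow(V) == aux$n, max(abs(V - t(V))) < 1e-10)
  atoms <- sort(unique(aux$atom))
  Lambda <- list()
  for (ai in seq_along(atoms)) {
    for (bi in seq_along(atoms)) {
      if (bi <= ai) next
      a <- atoms[ai]; b <- atoms[bi]
      idx <- which(aux$atom %in% c(a, b))
      blk <- V[idx, idx, drop = FALSE]
      ev <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-12 * max(abs(ev))) {
        stop(sprintf(
          "build_metric: singular pair block for atoms (%d, %d); condition number %.3e",
          a, b, max(abs(ev)) / max(min(abs(ev)), 1e-300)))
      }
      Lambda[[paste(a, b, sep = "_")]] <-
        list(idx = idx, inv = solve(blk))
    }
  }
  structure(list(V = V, Lambda = Lambda, aux = aux),
            class = "coulomb_metric")
}

# KKT solve: minimize x' V x - 2 b' x  subject to  Q' x = s.
# Exact equality constraint; smallest-norm solution via pseudoinverse on
# rank deficiency (reported).
kkt_constrained_fit <- function(V, Q, s, b = NULL) {
  n <- length(Q)
  if (all(Q == 0)) stop("charge constraint infeasible: all Q are zero")
  if (is.null(b)) b <- numeric(n)
  K <- rbind(cbind(V, Q), c(Q, 0))
  rhs <- c(b, s)
  sv <- svd(K)
  tolr <- max(dim(K)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tolr)
  if (r < nrow(K)) {
    message("kkt_constrained_fit: rank-deficient KKT system; ",
            "smallest-norm solution used")
  }
  dinv <- ifelse(sv$d > tolr, 1 / sv$d, 0)
  x <- sv$v %*% (dinv * crossprod(sv$u, rhs))
  x[seq_len(n)]
}

#' One-center density-fit tensor with exact charge conservation
#'
#' For primary orbital pairs \eqn{(p, q)} on one atom, fits the expansion
#' coefficients \eqn{X^\mu_{p,q}} over that atom's auxiliary functions by
#' constrained least squares in the Coulomb metric, imposing the charge
#' sum rule \eqn{\sum_\mu X^\mu_{p,q} Q_\mu = S_{p,q}} exactly through a
#' KKT system (never a penalty).
#'
#' @param S_one symmetric one-center overlap block (n_orb x n_orb).
#' @param Q auxiliary charges on this atom.
#' @param V_block one-center Coulomb metric block over these auxiliaries.
#' @param b optional array \code{[n_aux, n_orb, n_orb]} of Coulomb-metric
#'   projections \eqn{\int\!\!\int \rho_\mu(r) \phi_p\phi_q(r')/|r-r'|};
#'   zero when omitted (constraint-determined fit).
#' @return array \code{X[mu, p, q]} with the sum rule exact to 1e-12.
#' @export
one_center_X <- function(S_one, Q, V_block, b = NULL) {
  stopifnot(max(abs(S_one - t(S_one))) < 1e-12)
  n_orb <- nrow(S_one)
  n_aux <- length(Q)
  X <- array(0, c(n_aux, n_orb, n_orb))
  for (p in seq_len(n_orb)) for (q in p:n_orb) {
    bpq <- if (is.null(b)) NULL else b[, p, q]
    x <- kkt_constrained_fit(V_block, Q, S_one[p, q], bpq)
    X[, p, q] <- x
    X[, q, p] <- x
  }
  X
}

#' One-center projection tensor for two-center density fitting
#'
#' Fits the tensor \eqn{Z^\mu_{p,r}} that approximates the one-center
#' product of the auxiliary potential \eqn{V_\mu} with a primary orbital
#' on the primary basis of the same atom:
#' \eqn{\int V_\mu(r) \phi_p(r) \phi_q(r) dr \approx \sum_r Z^\mu_{p,r}
#' S_{r,q}} for partners \eqn{q} on the other atom.  The fit is least
#' squares over a sample of partner positions.  \code{Z = 0} (the
#' parameter-free mode) makes the downstream two-center fit reduce to
#' symmetric Mulliken-type charge splitting.
#'
#' @param overlaps numeric vector \eqn{S(d_k)} at the sampled partner
#'   distances (s-only case: one primary orbital per atom).
#' @param integrals numeric vector of oracle values
#'   \eqn{\int V_\mu \phi_p \phi_q} at the same distances.
#' @param ridge regularization added when the normal equations are
#'   rank-deficient (reported via a message).
#' @return the fitted scalar \eqn{Z} (s-only single-auxiliary case).
#' @export
projection_Z <- function(overlaps, integrals, ridge = 0) {
  stopifnot(length(overlaps) == length(integrals), length(overlaps) >= 1)
  g <- sum(overlaps^2)
  if (g < 1e-14) {
    message("projection_Z: rank-deficient fit; ridge regularization applied")
    g <- g + max(ridge, 1e-10)
  }
  sum(integrals * overlaps) / g
}

#' Two-center density-fit tensor with exact charge conservation
#'
#' Implements the charge-conserving two-center fit
#' \deqn{W^\mu_{p,q} = \sum_r (Z^\mu_{p,r} S_{r,q} + Z^\mu_{q,r} S_{r,p}),}
#' \deqn{w_{p,q} = (S_{p,q} - \sum_{\mu\nu} Q_\mu \Lambda_{\mu\nu}
#'   W^\nu_{p,q}) / \sum_{\mu\nu} Q_\mu \Lambda_{\mu\nu} Q_\nu,}
#' \deqn{X^\mu_{p,q} = \sum_\nu \Lambda_{\mu\nu} (Q_\nu w_{p,q} +
#'   W^\nu_{p,q}),}
#' for primary orbitals \eqn{p} on atom A and \eqn{q} on atom B, with the
#' auxiliary index restricted to those two atoms.
#'
#' @param S_pq two-center overlap block (orbitals of A x orbitals of B).
#' @param Q auxiliary charges of the pair's auxiliaries (A's then B's).
#' @param Lambda inverse of the pair's two-center metric block.
#' @param W optional pre-built array \code{[n_aux_pair, n_p, n_q]} of the
#'   \eqn{W} intermediates (defaults to zero, i.e. \eqn{Z = 0}).
#' @return list with \code{X} (\code{[n_aux_pair, n_p, n_q]}), \code{w}
#'   and \code{W}; the sum rule \eqn{\sum_\mu X^\mu Q_\mu = S_{p,q}} is
#'   exact to 1e-12.
#' @export
two_center_X <- function(S_pq, Q, Lambda, W = NULL) {
  S_pq <- as.matrix(S_pq)
  np <- nrow(S_pq); nq <- ncol(S_pq)
  na <- length(Q)
  if (is.null(W)) W <- array(0, c(na, np, nq))
  QLQ <- as.numeric(t(Q) %*% Lambda %*% Q)
  if (abs(QLQ) < 1e-14) {
    stop("two_center_X: auxiliary charges annihilated by the metric (zero denominator)")
  }
  QL <- as.numeric(t(Q) %*% Lambda)
  X <- array(0, c(na, np, nq))
  w <- matrix(0, np, nq)
  for (p in seq_len(np)) for (q in seq_len(nq)) {
    Wv <- W[, p, q]
    w[p, q] <- (S_pq[p, q] - sum(QL * Wv)) / QLQ
    X[, p, q] <- Lambda %*% (Q * w[p, q] + Wv)
  }
  list(X = X, w = w, W = W)
}

#' Assemble the full density-fit tensor for a cluster
#'
#' Combines the one-center fits (per atom) and the charge-conserving
#' two-center fits (per atom pair, Eq.-8-type algebra) into one array
#' \code{X[mu, p, q]} over all auxiliaries and primary orbitals.
#'
#' @param S full primary overlap matrix.
#' @param atom_of owning atom of each primary orbital.
#' @param metric a \code{\link{build_metric}} result.
#' @param b_one optional one-center oracle projections passed through to
#'   \code{\link{one_center_X}} (list per atom).
#' @param W_two optional list per atom-pair key \code{"a_b"} of
#'   \eqn{W} arrays for \code{\link{two_center_X}}.
#' @return array \code{X[n_aux, n_orb, n_orb]}.
#' @export
density_fit_X <- function(S, atom_of, metric, b_one = NULL, W_two = NULL) {
  aux <- metric$aux
  n <- nrow(S)
  X <- array(0, c(aux$n, n, n))
  atoms <- sort(unique(atom_of))
  for (a in atoms) {
    po <- which(atom_of == a)
    mu <- which(aux$atom == a)
    ba <- if (is.null(b_one)) NULL else b_one[[as.character(a)]]
    X[mu, po, po] <- one_center_X(S[po, po, drop = FALSE], aux$Q[mu],
                                  metric$V[mu, mu, drop = FALSE], ba)
  }
  for (key in names(metric$Lambda)) {
    ab <- as.integer(strsplit(key, "_")[[1]])
    pa <- which(atom_of == ab[1]); pb <- which(atom_of == ab[2])
    if (length(pa) == 0 || length(pb) == 0) next
    mu <- metric$Lambda[[key]]$idx
    Wab <- if (is.null(W_two)) NULL else W_two[[key]]
    fit <- two_center_X(S[pa, pb, drop = FALSE], aux$Q[mu],
                        metric$Lambda[[key]]$inv, Wab)
    for (ip in seq_along(pa)) for (iq in seq_along(pb)) {
      X[mu, pa[ip], pb[iq]] <- fit$X[, ip, iq]
      X[mu, pb[iq], pa[ip]] <- fit$X[, ip, iq]
    }
  }
  X
}

#' Factored four-center Coulomb integrals
#'
#' Contracts the density-fit tensor with the auxiliary Coulomb metric:
#' \eqn{V_{pq,rs} = \sum_{\mu\nu} X^\mu_{p,q} V_{\mu\nu} X^\nu_{r,s}}.
#' The result inherits the full eight-fold index symmetry from the
#' symmetry of \code{X} and \code{V}.
#'
#' @param X array \code{[n_aux, n_orb, n_orb]}.
#' @param V auxiliary Coulomb matrix (or a \code{coulomb_metric}).
#' @return four-index array \code{(pq|rs)} (hartree).
#' @export
factored_eri <- function(X, V) {
  if (inherits(V, "coulomb_metric")) V <- V$V
  na <- dim(X)[1]; n <- dim(X)[2]
  Xm <- matrix(X, na, n * n)
  out <- crossprod(Xm, V %*% Xm)
  array(out, c(n, n, n, n))
}

#' Verify the NDDO limit of the factored Coulomb model
#'
#' With the two-center overlap set to zero (orthogonal orbitals) and no
#' projection tensor (\eqn{Z = 0}), every two-center fit coefficient
#' vanishes, so all integrals carrying differential overlap across atoms
#' are exactly zero -- the neglect-of-diatomic-differential-overlap
#' limit.  One-center integrals are untouched by the switch.
#'
#' @param S primary overlap matrix of the system.
#' @param atom_of owning atom of each primary orbital.
#' @param metric a \code{\link{build_metric}} result.
#' @return list with the maximal absolute cross-atom differential-overlap
#'   integral under orthogonality (\code{max_cross}; exactly 0), the
#'   factored tensors with and without the orthogonality switch, and a
#'   \code{pass} flag.
#' @export
nddo_limit_check <- function(S, atom_of, metric) {
  S0 <- S
  n <- nrow(S)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (atom_of[p] != atom_of[q]) S0[p, q] <- 0
  }
  X0 <- density_fit_X(S0, atom_of, metric)
  eri0 <- factored_eri(X0, metric)
  Xfull <- density_fit_X(S, atom_of, metric)
  eri_full <- factored_eri(Xfull, metric)
  cross <- 0
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (atom_of[p] == atom_of[q]) next
    cross <- max(cross, max(abs(eri0[p, q, , ])))
  }
  list(max_cross = cross, eri_nddo = eri0, eri = eri_full,
       pass = cross == 0)
}
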