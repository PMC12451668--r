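#' Enumerate determinants of an (N, Sz) sector
#'
#' Lists all Slater determinants with \code{N} electrons and spin
#' projection \code{Sz} over \code{n_sites} spatial orbitals, optionally
#' restricted to the single-occupancy space (no orbital holding two
#' electrons).  Determinants are returned as up/down-spin occupation
#' bitmasks.
#'
#' @param n_sites number of spatial orbitals (at most 30).
#' @param N electron count, \code{0 <= N <= 2 * n_sites}.
#' @param Sz spin projection (half-integer).
#' @param single_occupancy logical; keep only determinants with at most
#'   one electron per orbital.
#' @return list with integer vectors \code{ups}, \code{downs} (bitmasks)
#'   and the sector metadata.  An infeasible sector gives zero
#'   determinants (not an error).
#' @export
enumerate_configs <- function(n_sites, N, Sz, single_occupancy = FALSE) {
  stopifnot(n_sites >= 1, n_sites <= 30, N >= 0, N <= 2 * n_sites)
  n_up <- N / 2 + Sz
  n_dn <- N / 2 - Sz
  empty <- list(ups = integer(0), downs = integer(0), n_sites = n_sites,
                N = N, Sz = Sz)
  if (n_up != round(n_up) || n_up < 0 || n_dn < 0 ||
      n_up > n_sites || n_dn > n_sites) {
    return(empty)
  }
  masks_of <- function(nel) {
    if (nel == 0) return(0L)
    cmb <- utils::combn(n_sites, nel)
    as.integer(colSums(matrix(bitwShiftL(1L, cmb - 1L), nrow = nel)))
  }
  um <- masks_of(n_up)
  dm <- masks_of(n_dn)
  ups <- rep(um, times = length(dm))
  downs <- rep(dm, each = length(um))
  if (single_occupancy) {
    keep <- bitwAnd(ups, downs) == 0L
    ups <- ups[keep]; downs <- downs[keep]
  }
  list(ups = ups, downs = downs, n_sites = n_sites, N = N, Sz = Sz)
}

#' Löwdin symmetric orthogonalization of an integral set
#'
#' Transforms one-body integrals by \eqn{S^{-1/2} h S^{-1/2}} and the
#' four-index Coulomb tensor by four factors of \eqn{S^{-1/2}}.  Any FCI
#' spectrum computed downstream is invariant under the choice of
#' orthogonalizer (symmetric vs canonical), since full CI is invariant
#' under nonsingular one-particle congruences of the same span.
#'
#' @param S overlap matrix (positive definite).
#' @param h one-body matrix (hartree).
#' @param eri four-index Coulomb array \code{(pq|rs)} in chemists'
#'   notation (hartree).
#' @return list with transformed \code{h}, \code{eri} and the
#'   transformation matrix \code{C = S^{-1/2}}.
#' @export
lowdin_orthogonalize <- function(S, h, eri) {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) <= 1e-12) stop("overlap not positive definite")
  C <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  ht <- t(C) %*% h %*% C
  M <- nrow(S)
  et <- eri
  for (step in 1:4) {
    et <- aperm(array(crossprod(C, matrix(et, M, M^3)), rep(M, 4)),
                c(2, 3, 4, 1))
  }
  list(h = ht, eri = et, C = C)
}

#' Rotate an orthogonal integral set to the one-electron eigenbasis
#'
#' Unitary rotation of an already-orthonormal integral set into the
#' eigenbasis of its one-body Hamiltonian.  FCI spectra are invariant
#' under this rotation; it is applied before iterative diagonalization
#' because it makes the determinant Hamiltonian diagonally dominant.
#'
#' @param h one-body matrix in an orthonormal basis.
#' @param eri four-index tensor in the same basis.
#' @return list with rotated \code{h} (diagonal), \code{eri} and the
#'   rotation \code{U}.
#' @export
canonicalize_orbitals <- function(h, eri) {
  es <- eigen((h + t(h)) / 2, symmetric = TRUE)
  U <- es$vectors[, order(es$values), drop = FALSE]
  M <- nrow(h)
  et <- eri
  for (step in 1:4) {
    et <- aperm(array(crossprod(U, matrix(et, M, M^3)), rep(M, 4)),
                c(2, 3, 4, 1))
  }
  list(h = diag(sort(es$values), M, M), eri = et, U = U)
}

# deterministic pseudo-random start vector (no global RNG use)
.lcg_vector <- function(n, seed = 987654321) {
  x <- as.double(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    out[i] <- x / 2147483648 - 0.5
  }
  out / sqrt(sum(out^2))
}

# Davidson solver with diagonal preconditioning for the k lowest
# eigenpairs of a symmetric sparse matrix; the standard iterative
# diagonalizer for configuration-interaction Hamiltonians.
davidson_lowest <- function(A, k, tol = 1e-8, maxiter = 200,
                            max_subspace = NULL) {
  n <- nrow(A)
  d <- Matrix::diag(A)
  nb <- min(n, k + min(k, 4))          # block size with a small buffer
  if (is.null(max_subspace)) max_subspace <- min(n, max(8 * nb, 60))
  # start: unit vectors on the lowest-diagonal determinants, slightly
  # perturbed (deterministically) to avoid symmetry-orthogonal starts
  ord <- order(d)[seq_len(nb)]
  B <- matrix(0, n, nb)
  B[cbind(ord, seq_len(nb))] <- 1
  B <- B + 1e-3 * matrix(.lcg_vector(n * nb), n, nb)
  B <- qr.Q(qr(B))
  W <- as.matrix(A %*% B)
  for (iter in seq_len(maxiter)) {
    Tm <- crossprod(B, W)
    Tm <- (Tm + t(Tm)) / 2
    eT <- eigen(Tm, symmetric = TRUE)
    m <- ncol(B)
    sel <- m:(m - k + 1)  # eigen() sorts decreasing; these are the k lowest, ascending
    theta <- eT$values[sel]
    y <- eT$vectors[, sel, drop = FALSE]
    X <- B %*% y
    WX <- W %*% y
    Rres <- WX - X %*% diag(theta, k, k)
    rn <- sqrt(colSums(Rres^2))
    if (all(rn < tol)) {
      return(list(values = theta, vectors = X, iterations = iter))
    }
    if (ncol(B) + sum(rn >= tol) > max_subspace) {
      # restart from current Ritz vectors
      B <- qr.Q(qr(X))
      W <- as.matrix(A %*% B)
      Tm <- crossprod(B, W)
    }
    added <- 0
    for (j in which(rn >= tol)) {
      denom <- theta[j] - d
      denom[abs(denom) < 1e-6] <- sign(denom[abs(denom) < 1e-6] + 1e-30) * 1e-6
      t <- Rres[, j] / denom
      # orthogonalize against current subspace (two passes)
      for (pass in 1:2) t <- t - B %*% crossprod(B, t)
      nt <- sqrt(sum(t^2))
      if (nt < 1e-10) next
      t <- t / nt
      B <- cbind(B, t)
      W <- cbind(W, as.numeric(A %*% t))
      added <- added + 1
    }
    if (added == 0) {
      if (all(rn < 1e-6)) {
        return(list(values = theta, vectors = X, iterations = iter))
      }
      stop("davidson_lowest: stagnated before convergence")
    }
  }
  stop("davidson_lowest: eigensolve did not converge")
}

#' Sector-resolved full configuration interaction
#'
#' Exact diagonalization of the many-electron Hamiltonian in the
#' \code{(N, Sz)} determinant block of an orthogonal integral set.  Small
#' blocks are diagonalized densely; large blocks use a Lanczos solver
#' with full reorthogonalization on a sparse Hamiltonian.  Each returned
#' state carries its \eqn{\langle S^2 \rangle} expectation.
#'
#' @param h one-body matrix in an orthonormal orbital basis (hartree).
#' @param eri four-index \code{(pq|rs)} array in the same basis.
#' @param N,Sz sector quantum numbers.
#' @param k number of lowest states wanted; \code{NULL} for all.
#' @param single_occupancy restrict the determinant space to at most one
#'   electron per orbital.
#' @param dense_cutoff largest block dimension diagonalized densely.
#' @param vectors logical, keep eigenvectors.
#' @return object of class \code{"sector_spectrum"}: list with
#'   \code{energies} (ascending, electronic only), \code{s2}, \code{N},
#'   \code{Sz}, \code{dim} and optionally \code{vectors}.
#' @export
sector_fci <- function(h, eri, N, Sz, k = NULL, single_occupancy = FALSE,
                       dense_cutoff = 1500, vectors = FALSE) {
  M <- nrow(h)
  cfg <- enumerate_configs(M, N, Sz, single_occupancy)
  dim <- length(cfg$ups)
  if (dim == 0) {
    return(structure(list(energies = numeric(0), s2 = numeric(0),
                          N = N, Sz = Sz, dim = 0), class = "sector_spectrum"))
  }
  if (dim > 1e5) stop("sector_fci: block dimension ", dim,
                      " too large; split the sector")
  if (is.null(k)) k <- dim
  k <- min(k, dim)
  if (dim <= dense_cutoff) {
    H <- fci_build_dense(cfg$ups, cfg$downs, h, as.numeric(eri), M)
    eH <- eigen(H, symmetric = TRUE)
    vals <- eH$values[dim:1][1:k]
    vecs <- eH$vectors[, dim:1, drop = FALSE][, 1:k, drop = FALSE]
  } else {
    tri <- fci_build_triplets(cfg$ups, cfg$downs, h, as.numeric(eri), M)
    A <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                              dims = c(dim, dim))
    A <- (A + Matrix::t(A)) / 2  # remove rounding asymmetry of the assembly
    sol <- davidson_lowest(A, k)
    vals <- sol$values
    vecs <- sol$vectors
  }
  # spin expectations; within degenerate energy groups the eigenvectors
  # are rotated to diagonalize S^2 so spin labels stay well defined
  s2mat <- s2_bilinear(cfg$ups, cfg$downs, M, vecs)
  s2 <- diag(s2mat)
  grp_start <- 1L
  for (i in seq_len(k)) {
    end_of_group <- i == k || (vals[min(i + 1L, k)] - vals[i]) > 1e-9
    if (end_of_group && i > grp_start) {
      idx <- grp_start:i
      es2 <- eigen((s2mat[idx, idx] + t(s2mat[idx, idx])) / 2,
                   symmetric = TRUE)
      ord <- order(es2$values)
      vecs[, idx] <- vecs[, idx, drop = FALSE] %*% es2$vectors[, ord]
      s2[idx] <- es2$values[ord]
    }
    if (end_of_group) grp_start <- i + 1L
  }
  out <- list(energies = vals, s2 = s2, N = N, Sz = Sz, dim = dim)
  if (vectors) out$vectors <- vecs
  structure(out, class = "sector_spectrum")
}

#' Spin quantum number from an S^2 expectation value
#'
#' Maps \eqn{\langle S^2 \rangle} to the nearest half-integer spin
#' \eqn{S} with \eqn{S(S+1)} closest to the input.
#'
#' @param s2 numeric vector of expectation values.
#' @param tol largest tolerated deviation from an exact \eqn{S(S+1)}.
#' @return numeric vector of half-integer spins.
#' @export
spin_label <- function(s2, tol = 1e-6) {
  S <- round((sqrt(1 + 4 * pmax(s2, 0)) - 1))/ 2 # nearest half-integer
  S <- round(2 * S) / 2
  bad <- abs(s2 - S * (S + 1)) > tol
  if (any(bad)) {
    warning(sprintf("spin_label: %d state(s) deviate from pure spin by up to %.2e",
                    sum(bad), max(abs(s2 - S * (S + 1))[bad])))
  }
  S
}

#' Merge quasi-degenerate energies into distinct levels
#'
#' Energies closer than \code{tol} (within one block) are merged to a
#' single level represented by the first member.
#'
#' @param energies numeric vector, ascending.
#' @param tol merging tolerance (hartree), positive.
#' @return numeric vector of distinct level energies.
#' @export
distinct_levels <- function(energies, tol = 1e-9) {
  stopifnot(tol > 0)
  if (length(energies) == 0) return(numeric(0))
  energies <- sort(energies)
  out <- energies[1]
  for (e in energies[-1]) {
    if (e - out[length(out)] > tol) out <- c(out, e)
  }
  out
}

# (N, Sz >= 0) blocks of a cluster with nonzero single-occupancy dimension,
# with that dimension attached
single_occupancy_blocks <- function(n_sites) {
  out <- list()
  for (N in 0:n_sites) {
    for (twoSz in seq(N %% 2, N, by = 2)) {
      Sz <- twoSz / 2
      d <- length(enumerate_configs(n_sites, N, Sz, TRUE)$ups)
      if (d > 0) {
        out[[length(out) + 1L]] <- list(N = N, Sz = Sz, k = d)
      }
    }
  }
  out
}

#' Target counts of the two hydrogen-cluster fitting tasks
#'
#' Task 1 counts one ground-state target per distinct \code{(N, S)}
#' sector reachable with at most one electron per atom; task 2 counts all
#' retained stationary states over the \code{(N, Sz >= 0)}
#' single-occupancy blocks.  Both totals run over the hydrogen dimer and
#' the symmetric trimer.
#'
#' @param task 1 or 2.
#' @param cluster_sizes atom counts of the clusters (default dimer and
#'   trimer).
#' @return integer target count.
#' @examples
#' count_task_targets(1) # 10
#' count_task_targets(2) # 23
#' @export
count_task_targets <- function(task, cluster_sizes = c(2, 3)) {
  stopifnot(task %in% c(1, 2))
  total <- 0L
  for (n in cluster_sizes) {
    if (task == 2) {
      total <- total + sum(vapply(single_occupancy_blocks(n),
                                  function(b) b$k, numeric(1)))
    } else {
      # multiplet count per N: number of S with dim(Sz=S) > dim(Sz=S+1)
      for (N in 0:n) {
        dims <- vapply(seq(N %% 2, N, by = 2), function(twoSz) {
          length(enumerate_configs(n, N, twoSz / 2, TRUE)$ups)
        }, numeric(1))
        dims <- c(dims, 0)
        total <- total + sum(diff(-dims) > 0)
      }
    }
  }
  as.integer(total)
}

#' Retain the lowest single-occupancy-sector states per block
#'
#' Given full sector spectra, keeps the \code{k} lowest states of every
#' \code{(N, Sz >= 0)} block, where \code{k} is the dimension of that
#' block's single-occupancy configuration space in the minimal atomic
#' basis (one orbital per atom).
#'
#' @param spectra list of \code{\link{sector_fci}} results keyed by
#'   block.
#' @param n_sites number of atoms of the cluster (defines \code{k}).
#' @param system label recorded in the output.
#' @param enuc nuclear repulsion energy added to electronic energies.
#' @return data frame with columns \code{system, N, Sz, index,
#'   energy_hartree, s2_label} (total energies).
#' @export
select_single_occupancy <- function(spectra, n_sites, system = "cluster",
                                    enuc = 0) {
  blocks <- single_occupancy_blocks(n_sites)
  rows <- list()
  for (b in blocks) {
    key <- sprintf("N%d_Sz%g", b$N, b$Sz)
    sp <- spectra[[key]]
    if (is.null(sp)) stop("select_single_occupancy: missing block ", key)
    if (length(sp$energies) < b$k) {
      stop(sprintf("select_single_occupancy: block %s has %d < %d states",
                   key, length(sp$energies), b$k))
    }
    idx <- seq_len(b$k)
    rows[[length(rows) + 1L]] <- data.frame(
      system = system, N = b$N, Sz = b$Sz, index = idx,
      energy_hartree = sp$energies[idx] + enuc,
      s2_label = spin_label(sp$s2[idx]))
  }
  do.call(rbind, rows)
}
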