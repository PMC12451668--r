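#' Hydrogen cluster geometry
#'
#' @param kind \code{"dimer"}, \code{"linear_trimer"} or
#'   \code{"equilateral_trimer"}.
#' @param spacing nearest-neighbor distance r (bohr), positive.
#' @return object of class \code{"hcluster"} with the atom positions.
#' @export
hcluster <- function(kind = c("dimer", "linear_trimer",
                              "equilateral_trimer"), spacing) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(spacing), spacing > 0)
  r <- spacing
  positions <- switch(kind,
    dimer = rbind(c(0, 0, 0), c(0, 0, r)),
    linear_trimer = rbind(c(0, 0, 0), c(0, 0, r), c(0, 0, 2 * r)),
    equilateral_trimer = rbind(c(0, 0, 0), c(0, 0, r),
                               c(0, r * sqrt(3) / 2, r / 2)))
  structure(list(kind = kind, spacing = r, positions = positions,
                 n_atoms = nrow(positions)), class = "hcluster")
}

#' Ground-state energy of one hydrogen atom in an oracle basis
#'
#' Diagonalizes the one-electron Hamiltonian of a single H atom in the
#' given even-tempered s basis; by the variational principle the result
#' is bounded below by the exact -0.5 hartree.
#'
#' @param basis an \code{\link{even_tempered_basis}}.
#' @return energy in hartree.
#' @export
hydrogen_atom_energy <- function(basis = even_tempered_basis()) {
  ints <- oracle_ao_integrals(matrix(c(0, 0, 0), 1), basis)
  es <- eigen(ints$S, symmetric = TRUE)
  if (min(es$values) < 1e-12) {
    warning(sprintf("oracle basis nearly dependent; smallest overlap eigenvalue %.3e",
                    min(es$values)))
  }
  C <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  min(eigen(t(C) %*% ints$h %*% C, symmetric = TRUE)$values)
}

#' Sector-resolved FCI reference spectra for a hydrogen cluster
#'
#' Generates the package's internal reference data: full configuration
#' interaction in a large even-tempered s-Gaussian basis, resolved by
#' electron count and spin projection.  For every \code{(N, Sz >= 0)}
#' block the k lowest total energies are retained, where k is the
#' dimension of the block's single-occupancy configuration space in the
#' minimal atomic basis, and spin labels are attached from
#' \eqn{\langle S^2\rangle}.  This is a reduced-scale, fully internal
#' stand-in for large-basis quantum-chemistry reference data; an
#' external engine can replace it through any function with the same
#' signature and return schema.
#'
#' @param geometry an \code{\link{hcluster}} (at most 3 atoms).
#' @param basis an \code{\link{even_tempered_basis}} per atom.
#' @param system label stored in the output (defaults to the cluster
#'   kind).
#' @return data frame with columns \code{system, N, Sz, index,
#'   energy_hartree, s2_label}; energies are total (electronic +
#'   nuclear repulsion), ascending within each block.
#' @export
reference_spectrum <- function(geometry, basis = even_tempered_basis(),
                               system = geometry$kind) {
  stopifnot(inherits(geometry, "hcluster"), geometry$n_atoms <= 3)
  ints <- oracle_ao_integrals(geometry$positions, basis)
  if (ints$M > 40) stop("reference_spectrum: more than 40 orbitals")
  orth <- lowdin_orthogonalize(ints$S, ints$h, ints$eri)
  # rotate to the eigenbasis of the one-electron Hamiltonian: the FCI
  # spectrum is invariant, and the CI matrix becomes diagonally dominant,
  # which the Davidson solver needs on the large trimer blocks
  can <- canonicalize_orbitals(orth$h, orth$eri)
  spectra <- list()
  for (b in single_occupancy_blocks(geometry$n_atoms)) {
    key <- sprintf("N%d_Sz%g", b$N, b$Sz)
    spectra[[key]] <- sector_fci(can$h, can$eri, b$N, b$Sz, k = b$k)
  }
  select_single_occupancy(spectra, geometry$n_atoms, system = system,
                          enuc = ints$enuc)
}

#' Combined dimer + trimer reference set at one spacing
#'
#' Convenience wrapper producing the reference data both fitting tasks
#' consume: the hydrogen dimer and the symmetric (linear) trimer at a
#' common nearest-neighbor distance.
#'
#' @param r nearest-neighbor spacing (bohr).
#' @param basis oracle basis per atom.
#' @param trimer_kind geometry of the trimer (linear by default).
#' @return data frame in the \code{\link{reference_spectrum}} schema with
#'   systems \code{"H2"} and \code{"H3"}.
#' @export
make_reference <- function(r, basis = even_tempered_basis(),
                           trimer_kind = "linear_trimer") {
  rbind(
    reference_spectrum(hcluster("dimer", r), basis, system = "H2"),
    reference_spectrum(hcluster(trimer_kind, r), basis, system = "H3"))
}
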