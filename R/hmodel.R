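#' Parameters of the minimal-basis hydrogen cluster model
#'
#' The model carries two one-center parameters -- the on-site orbital
#' energy \code{eps} (held at the exact isolated-atom value -0.5 hartree
#' and never fit) and the electronic Coulomb self-energy \code{U} -- and
#' five two-center parameters at the working distance: overlap \code{S}
#' (dimensionless), one-body Hamiltonian \code{H}, and the
#' electron-electron (\code{Vee}), electron-proton (\code{VeH}) and
#' proton-proton (\code{VHH}) Coulomb interactions (hartree).  Each
#' two-center entry may alternatively be a \code{\link{radial_channel}}
#' for distance scans.
#'
#' @param U one-center Coulomb self-energy (hartree).
#' @param S,H,Vee,VeH,VHH two-center values at the working distance, or
#'   radial channels.
#' @param eps on-site orbital energy (hartree); fixed at -0.5 unless
#'   explicitly overridden.
#' @param r working nearest-neighbor distance (bohr), required when the
#'   two-center entries are scalars.
#' @return object of class \code{"hmodel_parameters"}.
#' @export
hmodel_parameters <- function(U, S, H, Vee, VeH, VHH, eps = -0.5, r = NULL) {
  two_center <- list(S = S, H = H, Vee = Vee, VeH = VeH, VHH = VHH)
  scalars <- !vapply(two_center, inherits, logical(1), "radial_channel")
  if (any(scalars) && is.null(r)) {
    stop("hmodel_parameters: scalar two-center values need the distance r")
  }
  if (scalars[["S"]] && abs(S) >= 1) {
    stop("hmodel_parameters: |S| must be < 1 for a positive-definite dimer overlap")
  }
  if (scalars[["VHH"]] && VHH < 0) {
    stop("hmodel_parameters: VHH must be non-negative")
  }
  structure(list(eps = eps, U = U, two_center = two_center, r = r),
            class = "hmodel_parameters")
}

#' @export
print.hmodel_parameters <- function(x, ...) {
  cat("Minimal-basis hydrogen model parameters\n")
  cat(sprintf("  one-center: eps = %.6f (fixed), U = %.6f hartree\n",
              x$eps, x$U))
  tc <- vapply(x$two_center, function(v) {
    if (inherits(v, "radial_channel")) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (!is.null(x$r)) cat(sprintf("  two-center at r = %.3f bohr:\n", x$r))
  cat(sprintf("    S = %.6f, H = %.6f, Vee = %.6f, VeH = %.6f, VHH = %.6f\n",
              tc["S"], tc["H"], tc["Vee"], tc["VeH"], tc["VHH"]))
  invisible(x)
}

# evaluate one two-center parameter for an atom pair at distance d.
# Scalars apply at the nearest-neighbor spacing; beyond it, local
# channels (S, H) truncate to zero and Coulomb channels follow their
# parameter-free monopole tails q q'/d.
.tc_value <- function(par, name, d, r_nn) {
  if (inherits(par, "radial_channel")) return(radial_value(par, d))
  if (abs(d - r_nn) < 1e-9) return(as.numeric(par))
  if (name %in% c("S", "H")) return(0)
  1 / d
}

#' Integral set of the hydrogen cluster model
#'
#' Maps the seven model parameters onto the overlap matrix, one-body
#' Hamiltonian, factored four-center Coulomb tensor and nuclear
#' repulsion of a hydrogen cluster with a single s-type primary and
#' auxiliary function per atom.  The diagonal one-body entries collect
#' the on-site energy minus the electron-proton attraction to every
#' other nucleus (a positive \code{VeH} lowers the energy); off-diagonal
#' electron-proton terms are absorbed in the \code{H} channel.  The
#' Coulomb tensor is built through the charge-conserving density fit
#' with the primary function as its own auxiliary (\eqn{V_{\mu\mu} = U},
#' \eqn{V_{\mu\nu} = V_{ee}(r_{\mu\nu})}, \eqn{Z = 0}).
#'
#' @param geom an \code{\link{hcluster}}.
#' @param params an \code{\link{hmodel_parameters}}.
#' @return list with \code{S}, \code{h}, \code{eri}, \code{enuc},
#'   \code{metric} and \code{X}.
#' @export
model_integrals <- function(geom, params) {
  stopifnot(inherits(geom, "hcluster"), inherits(params, "hmodel_parameters"))
  n <- geom$n_atoms
  pos <- geom$positions
  r_nn <- geom$spacing
  D <- as.matrix(stats::dist(pos))
  S <- diag(n)
  h <- matrix(0, n, n)
  Vaux <- matrix(0, n, n)
  diag(Vaux) <- params$U
  enuc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- D[i, j]
    sij <- .tc_value(params$two_center$S, "S", d, r_nn)
    if (abs(sij) >= 1) stop("model_integrals: |S| >= 1 breaks overlap positivity")
    S[i, j] <- sij
    h[i, j] <- .tc_value(params$two_center$H, "H", d, r_nn)
    Vaux[i, j] <- .tc_value(params$two_center$Vee, "Vee", d, r_nn)
    if (i < j) enuc <- enuc + .tc_value(params$two_center$VHH, "VHH", d, r_nn)
  }
  for (i in seq_len(n)) {
    att <- 0
    for (j in seq_len(n)) {
      if (j != i) att <- att + .tc_value(params$two_center$VeH, "VeH",
                                         D[i, j], r_nn)
    }
    h[i, i] <- params$eps - att
  }
  aux <- aux_basis(atom = seq_len(n), Q = rep(1, n))
  metric <- build_metric(aux, V = Vaux)
  X <- density_fit_X(S, seq_len(n), metric)
  eri <- factored_eri(X, metric)
  list(S = S, h = h, eri = eri, enuc = enuc, metric = metric, X = X)
}

#' Sector-resolved spectrum of the hydrogen cluster model
#'
#' Löwdin-orthogonalizes the model integral set, runs FCI in every
#' \code{(N, Sz >= 0)} block, retains the lowest k states per block
#' (k = single-occupancy block dimension) and adds the nuclear energy.
#' With \code{single_occupancy = TRUE} the FCI itself is restricted to
#' the single-occupancy determinant space instead.
#'
#' @param geom an \code{\link{hcluster}}.
#' @param params an \code{\link{hmodel_parameters}}.
#' @param system label for the output rows.
#' @param single_occupancy restrict the model CI space (default selects
#'   lowest-k states of the full minimal-basis FCI).
#' @return data frame in the \code{\link{reference_spectrum}} schema.
#' @export
cluster_spectrum <- function(geom, params, system = geom$kind,
                             single_occupancy = FALSE) {
  ints <- model_integrals(geom, params)
  orth <- lowdin_orthogonalize(ints$S, ints$h, ints$eri)
  spectra <- list()
  for (b in single_occupancy_blocks(geom$n_atoms)) {
    key <- sprintf("N%d_Sz%g", b$N, b$Sz)
    spectra[[key]] <- sector_fci(orth$h, orth$eri, b$N, b$Sz, k = b$k,
                                 single_occupancy = single_occupancy)
  }
  select_single_occupancy(spectra, geom$n_atoms, system = system,
                          enuc = ints$enuc)
}
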