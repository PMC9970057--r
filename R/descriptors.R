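#' Wave Kernel Signature point descriptors
#'
#' The WKS evaluates, at every vertex `x` and each energy level `e`, the
#' expected probability of locating a quantum particle of that energy at
#' `x`:
#' `WKS(x, e) = sum_i phi_i(x)^2 exp(-(e - log lambda_i)^2 / (2 sigma^2)) / Z(e)`
#' with `Z(e)` the sum of the Gaussian energy weights. Energies are
#' log-spaced over the nonzero spectrum, with the grid shrunk by `2 sigma`
#' at each end; `sigma` is `sigma_scale` times the raw energy-grid step.
#' The WKS is intrinsic: invariant to rigid motion and to isometric
#' deformation, which is why it seeds functional-map estimation.
#'
#' @param basis a `spectral_basis` with at least 2 nonzero eigenvalues.
#' @param n_energies number of energy channels (columns), >= 2.
#' @param sigma_scale Gaussian width as a multiple of the energy-grid step.
#' @param mass_normalize scale each channel to unit L2(A) norm (balances the
#'   least-squares data term in map estimation; default `TRUE`).
#' @return object of class `descriptor_field`: list with `values` (n x d),
#'   `energies` (length d), `source_id`.
#' @export
wks <- function(basis, n_energies = 100, sigma_scale = 7, mass_normalize = TRUE) {
  if (n_energies < 2) stop("n_energies must be >= 2")
  ev <- basis$evals
  pos <- which(ev > max(ev) * 1e-10)
  if (length(pos) < 2) stop("basis needs at least 2 nonzero eigenvalues")
  le <- log(ev[pos])
  step <- (max(le) - min(le)) / n_energies
  sigma <- sigma_scale * step
  energies <- seq(min(le) + 2 * sigma, max(le) - 2 * sigma, length.out = n_energies)
  Phi2 <- basis$Phi[, pos, drop = FALSE]^2
  # Gaussian energy weights: d x |pos|
  Wgt <- exp(-(outer(energies, le, `-`))^2 / (2 * sigma^2))
  Wgt <- Wgt / rowSums(Wgt)
  vals <- Phi2 %*% t(Wgt)
  if (mass_normalize) {
    nrm <- sqrt(colSums(vals^2 * basis$a))
    nrm[nrm == 0] <- 1
    vals <- sweep(vals, 2, nrm, `/`)
  }
  structure(list(values = vals, energies = energies,
                 source_id = attr(basis, "mesh_id")),
            class = "descriptor_field")
}

#' Heat Kernel Signature point descriptors
#'
#' Provided behind the same contract as [wks()] but not used by default:
#' `HKS(x, t) = sum_i phi_i(x)^2 exp(-lambda_i t)` over log-spaced times.
#'
#' @inheritParams wks
#' @param n_times number of time channels.
#' @return a `descriptor_field`.
#' @export
hks <- function(basis, n_times = 100, mass_normalize = TRUE) {
  ev <- basis$evals
  pos <- which(ev > max(ev) * 1e-10)
  tmin <- 4 * log(10) / max(ev[pos]); tmax <- 4 * log(10) / min(ev[pos])
  times <- exp(seq(log(tmin), log(tmax), length.out = n_times))
  Phi2 <- basis$Phi[, pos, drop = FALSE]^2
  vals <- Phi2 %*% exp(-outer(ev[pos], times))
  if (mass_normalize) {
    nrm <- sqrt(colSums(vals^2 * basis$a)); nrm[nrm == 0] <- 1
    vals <- sweep(vals, 2, nrm, `/`)
  }
  structure(list(values = vals, energies = times, source_id = NULL),
            class = "descriptor_field")
}

#' @export
print.descriptor_field <- function(x, ...) {
  cat(sprintf("<descriptor_field: %d vertices x %d channels>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Validate a descriptor field against the descriptor contract
#'
#' Any descriptor fed to functional-map estimation — axiomatic or learned —
#' must be finite, have no identically-zero channel, and be invariant to
#' rigid motion of the mesh. The rigid-invariance check recomputes the
#' descriptors on a rotated copy (using `recompute`) and reports the maximum
#' relative channel change.
#'
#' @param field a `descriptor_field` (or n x d matrix).
#' @param mesh the `surface_mesh` the field was computed on.
#' @param recompute function `(mesh) -> descriptor matrix` used to
#'   re-evaluate the descriptors on a transformed copy; if `NULL` the
#'   rigid-invariance check is skipped.
#' @param rel_tol relative tolerance for the rigid-invariance flag.
#' @param seed seed for the random rotation.
#' @return list report: `finite`, `nonzero_channels`, `channel_variance`,
#'   `rigid_invariant` (logical or `NA`), `rigid_rel_change`, `pass`.
#' @export
descriptor_contract_check <- function(field, mesh, recompute = NULL,
                                      rel_tol = 0.05, seed = 0) {
  vals <- if (inherits(field, "descriptor_field")) field$values else as.matrix(field)
  finite <- all(is.finite(vals))
  cvar <- apply(vals, 2, stats::var)
  nonzero <- all(colSums(abs(vals)) > 0)
  rigid_ok <- NA; rel_change <- NA_real_
  if (!is.null(recompute)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    Rm <- random_rotation()
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    rot <- mesh
    rot$vertices <- mesh$vertices %*% t(Rm) + matrix(c(0.3, -0.2, 0.5), nrow(mesh$vertices), 3, byrow = TRUE)
    vals2 <- recompute(rot)
    if (inherits(vals2, "descriptor_field")) vals2 <- vals2$values
    denom <- max(abs(vals))
    rel_change <- max(abs(vals2 - vals)) / if (denom > 0) denom else 1
    rigid_ok <- rel_change <= rel_tol
  }
  list(finite = finite, nonzero_channels = nonzero, channel_variance = cvar,
       rigid_invariant = rigid_ok, rigid_rel_change = rel_change,
       pass = finite && nonzero && !isFALSE(rigid_ok))
}
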