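#' Specification of a constant in-degree E-I connectivity ensemble
#'
#' Every unit receives exactly `C_E` excitatory synapses of weight `+J` and
#' `C_I` inhibitory synapses of weight `-g J`, drawn uniformly at random from
#' the excitatory and inhibitory pools. Columns are single-signed (Dale's
#' principle). Two ensemble summaries govern the dynamics: the common row sum
#' `J_eff = J (C_E - g C_I)` (outlier eigenvalue, order parameter of the
#' population-averaged activity) and the bulk spectral radius
#' `J_cs = J sqrt(C_E + g^2 C_I)` (order parameter of heterogeneous activity).
#'
#' Exactly one of `J` or `radius` must be given; `radius` sets
#' `J = radius / sqrt(C_E + g^2 C_I)`.
#'
#' @param N number of units.
#' @param C_E,C_I excitatory and inhibitory in-degrees.
#' @param J excitatory synaptic weight.
#' @param g ratio of inhibitory to excitatory weight magnitude.
#' @param radius desired bulk spectral radius `J_cs` (alternative to `J`).
#' @param seed integer seed making the sampled matrix reproducible.
#' @param allow_self allow self-connections (default `FALSE`).
#' @return an object of class `connectivity_spec`.
#' @examples
#' connectivity_spec(N = 300, radius = 1.2)
#' @export
connectivity_spec <- function(N = 3000, C_E = 80, C_I = 20, J = NULL,
                              g = 4.1, radius = NULL, seed = 1L,
                              allow_self = FALSE) {
  stopifnot(N >= 2, C_E >= 1, C_I >= 1, g >= 0,
            C_E == round(C_E), C_I == round(C_I))
  if (is.null(J) == is.null(radius))
    abort("give exactly one of `J` or `radius`")
  if (!is.null(radius)) J <- radius / sqrt(C_E + g^2 * C_I)
  if (!allow_self && C_E + C_I > N - 1)
    abort("C_E + C_I must be at most N - 1 without self-connections")
  structure(list(N = as.integer(N), C_E = as.integer(C_E),
                 C_I = as.integer(C_I), J = J, g = g,
                 seed = as.integer(seed), allow_self = allow_self),
            class = "connectivity_spec")
}

#' Effective recurrent coupling J_eff = J (C_E - g C_I)
#'
#' @param x a `connectivity_spec` or `connectivity` object.
#' @return the common row sum of the connectivity matrix.
#' @export
effective_coupling <- function(x) {
  s <- if (inherits(x, "connectivity")) x$spec else x
  s$J * (s$C_E - s$g * s$C_I)
}

#' Bulk spectral radius J_cs = J sqrt(C_E + g^2 C_I)
#'
#' @inheritParams effective_coupling
#' @return the standard deviation-based radius of the eigenvalue disk.
#' @export
coupling_radius <- function(x) {
  s <- if (inherits(x, "connectivity")) x$spec else x
  s$J * sqrt(s$C_E + s$g^2 * s$C_I)
}

#' Sample a constant in-degree E-I connectivity matrix
#'
#' The excitatory pool has `round(N C_E / C)` units (uniform expected
#' out-degree), the rest are inhibitory. Presynaptic partners are drawn
#' uniformly without replacement per row, independently across rows.
#'
#' @param spec a [connectivity_spec()].
#' @return an object of class `connectivity`: `weights` (a sparse `dgCMatrix`),
#'   `e_mask` (logical, `TRUE` for excitatory units) and `spec`.
#' @examples
#' W <- build_connectivity(connectivity_spec(N = 100, C_E = 8, C_I = 2, J = 0.1))
#' range(Matrix::rowSums(W$weights))  # all rows sum to J (C_E - g C_I)
#' @export
build_connectivity <- function(spec) {
  stopifnot(inherits(spec, "connectivity_spec"))
  N <- spec$N
  C <- spec$C_E + spec$C_I
  N_E <- round(N * spec$C_E / C)
  N_I <- N - N_E
  # worst case: a unit draws from its own pool with itself excluded
  if (spec$C_E > N_E - (!spec$allow_self) || spec$C_I > N_I - (!spec$allow_self))
    abort(sprintf(
      "infeasible spec: pools (N_E=%d, N_I=%d) too small for in-degrees (%d, %d)",
      N_E, N_I, spec$C_E, spec$C_I))
  e_mask <- c(rep(TRUE, N_E), rep(FALSE, N_I))
  exc_pool <- seq_len(N_E)
  inh_pool <- N_E + seq_len(N_I)
  with_seed(spec$seed, {
    pre <- matrix(0L, nrow = N, ncol = C)
    for (i in seq_len(N)) {
      pe <- if (spec$allow_self) exc_pool else setdiff(exc_pool, i)
      pi_ <- if (spec$allow_self) inh_pool else setdiff(inh_pool, i)
      pre[i, ] <- c(sample(pe, spec$C_E), sample(pi_, spec$C_I))
    }
  })
  w <- rep(c(rep(spec$J, spec$C_E), rep(-spec$g * spec$J, spec$C_I)),
           times = N)
  W <- Matrix::sparseMatrix(i = rep(seq_len(N), each = C),
                            j = as.vector(t(pre)),
                            x = w, dims = c(N, N))
  structure(list(weights = W, e_mask = e_mask, spec = spec),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<connectivity> N = %d (%d E / %d I), in-degree %d + %d\n",
              s$N, sum(x$e_mask), sum(!x$e_mask), s$C_E, s$C_I))
  cat(sprintf("  J = %.5g, g = %.3g -> J_eff = %.5g, J_cs = %.5g\n",
              s$J, s$g, effective_coupling(x), coupling_radius(x)))
  invisible(x)
}

#' @export
dim.connectivity <- function(x) dim(x$weights)

#' Numerical spectrum of a connectivity matrix with ensemble theory values
#'
#' Computes the dense eigendecomposition of the sampled matrix and reports it
#' next to the large-`N` theory: the bulk is enclosed in a disk of radius
#' `J sqrt(C_E + g^2 C_I)` and the constant row sums force an outlier real
#' eigenvalue at exactly `J (C_E - g C_I)` (the all-ones vector is a right
#' eigenvector).
#'
#' @param W a `connectivity` object with `N <= 5000`.
#' @return an object of class `spectrum_summary` with elements `eigenvalues`
#'   (complex), `radius_theory` and `outlier_theory`.
#' @export
spectrum_summary <- function(W) {
  stopifnot(inherits(W, "connectivity"))
  N <- nrow(W$weights)
  if (N > 5000) abort("dense eigendecomposition guarded at N <= 5000")
  ev <- eigen(as.matrix(W$weights), only.values = TRUE)$values
  structure(list(eigenvalues = ev,
                 radius_theory = coupling_radius(W),
                 outlier_theory = effective_coupling(W),
                 N = N),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> N = %d eigenvalues\n", x$N))
  cat(sprintf("  bulk radius (theory) = %.5g, outlier (theory) = %.5g\n",
              x$radius_theory, x$outlier_theory))
  invisible(x)
}

#' Export a connectivity matrix as MatrixMarket plus a JSON sidecar
#'
#' @param W a `connectivity` object.
#' @param path output `.mtx` path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(W, path) {
  stopifnot(inherits(W, "connectivity"))
  Matrix::writeMM(W$weights, path)
  side <- c(unclass(W$spec), list(e_mask = as.integer(W$e_mask)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path the `.mtx` path.
#' @return a `connectivity` object.
#' @export
read_connectivity <- function(path) {
  W <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- connectivity_spec(N = side$N, C_E = side$C_E, C_I = side$C_I,
                            J = side$J, g = side$g, seed = side$seed,
                            allow_self = side$allow_self)
  structure(list(weights = W, e_mask = as.logical(side$e_mask), spec = spec),
            class = "connectivity")
}
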