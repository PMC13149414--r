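#' Precision-structure matrices for intrinsic Gaussian priors
#'
#' A `structure_matrix` holds a symmetric positive semi-definite precision
#' structure Q with a known null space (the directions an intrinsic prior
#' leaves unpenalized, which become sum-to-zero constraints), its eigen
#' decomposition restricted to the positive part, and — once scaled — the
#' variance-scaling factor that makes the geometric mean of the constrained
#' marginal variances equal to 1.
#'
#' @name structure_matrix
NULL

.new_structure_matrix <- function(Q, null_basis, kind, scaled = FALSE,
                                  scaling = NA_real_) {
  eg <- eigen(Q, symmetric = TRUE)
  r <- sum(eg$values > max(eg$values, 1) * 1e-10)
  idx <- seq_len(r)
  structure(list(
    Q = Q, kind = kind, n = nrow(Q),
    rank = r,
    values = eg$values[idx],          # positive eigenvalues, decreasing
    vectors = eg$vectors[, idx, drop = FALSE],
    null_basis = null_basis,          # columns span the null space
    scaled = scaled, scaling = scaling
  ), class = "structure_matrix")
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat(sprintf("structure_matrix [%s]: %d x %d, rank %d%s\n", x$kind, x$n, x$n,
              x$rank,
              if (x$scaled) sprintf(", scaled (s = %.4g)", x$scaling) else ""))
  invisible(x)
}

#' Intrinsic CAR (graph Laplacian) structure
#'
#' Builds Q = D - W from an areal adjacency graph: the precision structure of
#' the intrinsic conditional autoregression, with rank n - c (c = number of
#' connected components) and null space spanned by the per-component
#' indicator vectors. A fully disconnected graph yields the all-zero
#' structure, which is permitted but flagged with a warning (the spatial
#' prior degenerates to pure iid).
#'
#' @param graph a `country_graph`.
#' @return an unscaled `structure_matrix` of kind `"icar"`.
#' @export
build_icar_structure <- function(graph) {
  stopifnot(inherits(graph, "country_graph"))
  W <- graph$W
  Q <- diag(rowSums(W), nrow(W)) - W
  dimnames(Q) <- dimnames(W)
  comp <- graph$component
  null_basis <- vapply(seq_len(graph$n_components),
                       function(k) as.numeric(comp == k),
                       numeric(length(comp)))
  if (all(Q == 0)) {
    warning("graph has no edges: ICAR structure is all-zero (pure iid limit)")
  }
  .new_structure_matrix(Q, null_basis, "icar")
}

#' First-order random-walk structure
#'
#' Tridiagonal first-difference penalty on T ordered time points:
#' Q[t,t] = number of neighbors in time, Q[t,t+1] = -1. Rank T - 1 with the
#' constant vector as null space.
#'
#' @param T_len integer number of time points, >= 2.
#' @return an unscaled `structure_matrix` of kind `"rw1"`.
#' @export
build_rw1_structure <- function(T_len) {
  T_len <- as.integer(T_len)
  if (is.na(T_len) || T_len < 2L) stop("RW1 needs at least 2 time points")
  Dm <- diff(diag(T_len))            # (T-1) x T first-difference operator
  Q <- t(Dm) %*% Dm
  .new_structure_matrix(Q, matrix(1, T_len, 1L), "rw1")
}

#' Variance-scaling factor of an intrinsic structure
#'
#' The generalized inverse of Q under sum-to-zero within each connected
#' component has marginal variances diag(Q^+). The scaling factor s is their
#' geometric mean over all nodes; the scaled structure Q* = s Q has
#' generalized marginal variance 1, which makes penalized-complexity priors
#' on the precision comparable across components and graphs.
#'
#' @param structure an unscaled `structure_matrix` with rank >= 1.
#' @return positive scalar s.
#' @export
bym2_scaling_factor <- function(structure) {
  stopifnot(inherits(structure, "structure_matrix"))
  if (structure$rank < 1L) stop("all-zero structure: scaling undefined")
  if (any(colSums(abs(structure$null_basis) > 0) == 1L)) {
    stop("structure has an isolated (singleton) block: marginal variance 0, ",
         "scaling undefined")
  }
  # Moore-Penrose pseudoinverse diag via the positive eigen pairs; for a
  # block-diagonal Q this is the per-component constrained inverse.
  mv <- rowSums(sweep(structure$vectors^2, 2L, structure$values, `/`))
  exp(mean(log(mv)))
}

#' Scale an intrinsic structure to unit generalized variance
#'
#' @param structure an unscaled `structure_matrix`.
#' @return the scaled `structure_matrix` (Q multiplied by the scaling factor).
#' @export
scale_structure <- function(structure) {
  s <- bym2_scaling_factor(structure)
  out <- .new_structure_matrix(structure$Q * s, structure$null_basis,
                               structure$kind, scaled = TRUE, scaling = s)
  out
}

#' Constrained marginal variances of a structure matrix
#'
#' diag of the generalized inverse (sum-to-zero within components).
#' @param structure a `structure_matrix`.
#' @return numeric vector of marginal variances.
#' @export
structure_marginal_variances <- function(structure) {
  rowSums(sweep(structure$vectors^2, 2L, structure$values, `/`))
}
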