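# ---- parameters ----------------------------------------------------------

#' Mechanical parameters of the wall spring network
#'
#' The model is nondimensionalised with spring stiffness `k = 1`. Turgor
#' pressure `P` (force per unit boundary length) is calibrated once on the
#' packaged disk so that the equilibrium boundary strain is well under a
#' percent, giving quasi-static, few-fold tissue expansion over a typical
#' 100-iteration run.
#'
#' @param k spring stiffness (force per unit strain)
#' @param P turgor pressure (force per unit boundary length)
#' @param relax_tol residual force-norm tolerance for equilibration
#' @param relax_max_steps maximum implicit steps per equilibration
#' @param euler_dt backward-Euler step size
#' @param damping mobility coefficient of the overdamped dynamics
#' @return a `mechanics_params` list
#' @export
mechanics_params <- function(k = 1, P = 0.001, relax_tol = 1e-4 * k,
                             relax_max_steps = 200L, euler_dt = 500,
                             damping = 1) {
  stopifnot(k > 0, P > 0, relax_tol > 0, relax_max_steps > 0, euler_dt > 0,
            damping > 0)
  structure(list(k = k, P = P, relax_tol = relax_tol,
                 relax_max_steps = as.integer(relax_max_steps),
                 euler_dt = euler_dt, damping = damping),
            class = "mechanics_params")
}

#' Growth parameters
#'
#' Rest lengths grow at rate `g * strain` (micrometres per iteration): the
#' extensibility `g` converts relative spring over-stretch into rest-length
#' extension. One growth step of size `dt_growth` is applied per iteration.
#'
#' @param g extensibility factor (>= 0)
#' @param dt_growth step size in iterations
#' @return a `growth_params` list
#' @export
growth_params <- function(g = 0.8, dt_growth = 1) {
  stopifnot(g >= 0, dt_growth > 0)
  structure(list(g = g, dt_growth = dt_growth), class = "growth_params")
}

# ---- forces ---------------------------------------------------------------

#' Spring forces on the mesh vertices
#'
#' For each vertex v, `F_v = sum_n k (|p_n - p_v| / L_vn - 1) (p_n - p_v) /
#' |p_n - p_v|` over its spring neighbours, with `L_vn` the rest length.
#'
#' @param mesh a `tissue_mesh`
#' @param k spring stiffness
#' @return V x 2 matrix of forces
#' @export
spring_forces <- function(mesh, k = 1) {
  d <- mesh$pos[mesh$walls$v2, , drop = FALSE] - mesh$pos[mesh$walls$v1, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  if (any(len < 1e-14)) stop("zero-length spring")
  co <- k * (len / mesh$walls$rest - 1) / len
  f <- d * co
  F <- matrix(0, n_vertices(mesh), 2L)
  for (col in 1:2) {
    a1 <- rowsum(f[, col], mesh$walls$v1)
    F[as.integer(rownames(a1)), col] <- F[as.integer(rownames(a1)), col] + a1
    a2 <- rowsum(-f[, col], mesh$walls$v2)
    F[as.integer(rownames(a2)), col] <- F[as.integer(rownames(a2)), col] + a2
  }
  F
}

# outward-normal sign per boundary wall, relative to the stored (v1, v2)
# orientation: +1 if (dy, -dx) points away from the incident cell
boundary_signs <- function(mesh, bidx) {
  ctr <- cell_centroids(mesh)
  p1 <- mesh$pos[mesh$walls$v1[bidx], , drop = FALSE]
  p2 <- mesh$pos[mesh$walls$v2[bidx], , drop = FALSE]
  d <- p2 - p1
  mid <- (p1 + p2) / 2
  cc <- ctr[mesh$walls$c1[bidx], , drop = FALSE]
  s <- sign(d[, 2L] * (mid[, 1L] - cc[, 1L]) - d[, 1L] * (mid[, 2L] - cc[, 2L]))
  s[s == 0] <- 1
  s
}

#' Turgor forces on the mesh vertices
#'
#' Uniform pressure acts on boundary walls only (it cancels on interior
#' walls): each boundary wall contributes `P * length / 2` to each endpoint
#' along its outward normal. This equals `P` times the gradient of the
#' enclosed tissue area.
#'
#' @param mesh a `tissue_mesh`
#' @param P turgor pressure
#' @return V x 2 matrix of forces
#' @export
turgor_forces <- function(mesh, P) {
  bidx <- which(is.na(mesh$walls$c2))
  F <- matrix(0, n_vertices(mesh), 2L)
  if (length(bidx) == 0L) return(F)
  s <- boundary_signs(mesh, bidx)
  p1 <- mesh$pos[mesh$walls$v1[bidx], , drop = FALSE]
  p2 <- mesh$pos[mesh$walls$v2[bidx], , drop = FALSE]
  d <- p2 - p1
  f <- cbind(s * d[, 2L], -s * d[, 1L]) * (P / 2)   # P * len/2 * unit normal
  for (vcol in list(mesh$walls$v1[bidx], mesh$walls$v2[bidx])) {
    for (col in 1:2) {
      a <- rowsum(f[, col], vcol)
      F[as.integer(rownames(a)), col] <- F[as.integer(rownames(a)), col] + a
    }
  }
  F
}

# ---- relaxation -----------------------------------------------------------

#' Relax the mesh to mechanical equilibrium
#'
#' Repeated backward-Euler steps of the overdamped spring-turgor dynamics
#' until the maximum per-vertex force norm falls below `relax_tol` or
#' `relax_max_steps` is reached. Topology and rest lengths are unchanged.
#' Convergence diagnostics are attached as `attr(, "relax")`.
#'
#' @param mesh a `tissue_mesh`
#' @param params a [mechanics_params()] list
#' @return the mesh with updated vertex positions
#' @export
relax_to_equilibrium <- function(mesh, params = mechanics_params()) {
  bidx <- which(is.na(mesh$walls$c2))
  bsign <- if (length(bidx)) boundary_signs(mesh, bidx) else numeric(0)
  res <- .relax_kernel(mesh$pos, mesh$walls$v1, mesh$walls$v2, mesh$walls$rest,
                       bidx, bsign, params$k, params$P, params$euler_dt,
                       params$damping, params$relax_tol,
                       params$relax_max_steps, 1e-5, 30L)
  if (!res$converged && res$residual >= params$relax_tol)
    warning(sprintf("relaxation did not converge: residual %.3g after %d steps",
                    res$residual, res$steps))
  mesh$pos <- res$pos
  attr(mesh, "relax") <- list(steps = res$steps, residual = res$residual,
                              converged = res$converged)
  mesh
}

# ---- growth ---------------------------------------------------------------

#' Grow spring rest lengths from their current stretch
#'
#' Applies `L <- L + dt_growth * g * (|p_n - p_v| - L) / L` to every spring.
#' Positions are unchanged. Compressed springs shrink (the rate is negative),
#' following the growth law literally.
#'
#' @param mesh a `tissue_mesh`
#' @param params a [growth_params()] list
#' @return the mesh with updated rest lengths
#' @export
grow_rest_lengths <- function(mesh, params = growth_params()) {
  len <- wall_lengths(mesh)
  mesh$walls$rest <- mesh$walls$rest +
    params$dt_growth * params$g * (len - mesh$walls$rest) / mesh$walls$rest
  mesh
}
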