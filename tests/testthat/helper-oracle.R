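# independent energy oracle: total spring energy minus pressure-area work,
# minimised by BFGS over free vertex coordinates
mesh_energy <- function(xy, mesh, k, P) {
  pos <- matrix(xy, ncol = 2L)
  d <- pos[mesh$walls$v2, , drop = FALSE] - pos[mesh$walls$v1, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  es <- sum(0.5 * k * (len - mesh$walls$rest)^2 / mesh$walls$rest)
  area <- sum(vapply(mesh$loops,
                     function(l) meristemsim:::polygon_area(pos[l, , drop = FALSE]),
                     numeric(1L)))
  es - P * area
}

oracle_equilibrium <- function(mesh, k, P) {
  fit <- stats::optim(as.numeric(mesh$pos), mesh_energy, mesh = mesh, k = k,
                      P = P, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  matrix(fit$par, ncol = 2L)
}

# the energy is invariant to rigid motions, so compare shapes after optimal
# rigid (Kabsch) alignment of b onto a
align_rigid <- function(b, a) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  sv <- svd(crossprod(B, A))
  R <- sv$u %*% diag(c(1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  sweep(B %*% R, 2L, ca, `+`)
}
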