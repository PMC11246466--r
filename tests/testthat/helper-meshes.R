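# small meshes built in code for unit tests

# one rectangular cell, w x h, corner at the origin
rect_mesh <- function(w = 1, h = 1) {
  pos <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
  meristemsim:::mesh_from_loops(pos, list(1:4))
}

# regular n-gon cell with given side length
ngon_mesh <- function(n = 6, side = 1) {
  r <- side / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  meristemsim:::mesh_from_loops(cbind(r * cos(ang), r * sin(ang)),
                                list(seq_len(n)))
}

# two unit squares sharing a vertical wall
two_cell_mesh <- function() {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(1, 1), c(0, 1))
  meristemsim:::mesh_from_loops(pos, list(c(1L, 2L, 5L, 6L), c(2L, 3L, 4L, 5L)))
}

# chain of n unit squares in a row (cell i adjacent to i +/- 1)
chain_mesh <- function(n = 3) {
  pos <- NULL
  loops <- vector("list", n)
  bottom <- cbind(0:n, 0)
  top <- cbind(0:n, 1)
  pos <- rbind(bottom, top)
  for (i in seq_len(n))
    loops[[i]] <- c(i, i + 1L, n + 1L + i + 1L, n + 1L + i)
  meristemsim:::mesh_from_loops(pos, loops)
}

# rotate a mesh rigidly about the origin (degrees)
rotate_mesh <- function(mesh, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  mesh$pos <- mesh$pos %*% t(R)
  mesh
}

quick_config <- function(...) {
  args <- utils::modifyList(list(n_iterations = 5L, snapshot_every = 5L),
                            list(...))
  do.call(sim_config, args)
}
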