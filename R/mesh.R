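#' @useDynLib meristemsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- tissue mesh container ---------------------------------------------------
#
# A tissue mesh is a planar polygonal tessellation of a disk:
#   pos    V x 2 matrix of vertex coordinates (micrometres)
#   walls  data.frame(v1, v2, rest, c1, c2, pin1, pin2)
#          one row per wall segment (spring). (v1, v2) is the traversal order
#          of cell c1; interior walls have c2 = the cell traversing (v2, v1),
#          boundary walls have c2 = NA. pin1/pin2 are the PIN allocations of
#          c1/c2 on this segment (0 on the outward side of boundary walls).
#   loops  list of integer vectors: ordered (counterclockwise) vertex loop of
#          each cell. Consecutive loop pairs correspond 1:1 to wall rows.
#   aux, cuc, delta  per-cell auxin, CUC1 and auxin-production noise multiplier
#   iteration        simulation iteration counter

new_tissue_mesh <- function(pos, walls, loops, aux, cuc, delta, iteration = 0L) {
  structure(list(pos = pos, walls = walls, loops = loops,
                 aux = aux, cuc = cuc, delta = delta,
                 iteration = as.integer(iteration)),
            class = "tissue_mesh")
}

#' Number of cells, wall segments and vertices in a mesh
#'
#' @param mesh a `tissue_mesh`
#' @return integer count
#' @export
n_cells <- function(mesh) length(mesh$loops)

#' @rdname n_cells
#' @export
n_walls <- function(mesh) nrow(mesh$walls)

#' @rdname n_cells
#' @export
n_vertices <- function(mesh) nrow(mesh$pos)

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("<tissue_mesh> ", n_cells(x), " cells, ", n_walls(x), " walls, ",
      n_vertices(x), " vertices (iteration ", x$iteration, ")\n", sep = "")
  cat("  total area ", format(sum(cell_areas(x)), digits = 6), " um^2; aux in [",
      format(min(x$aux), digits = 3), ", ", format(max(x$aux), digits = 3),
      "]; cuc in [", format(min(x$cuc), digits = 3), ", ",
      format(max(x$cuc), digits = 3), "]\n", sep = "")
  invisible(x)
}

# ---- geometry helpers --------------------------------------------------------

polygon_area <- function(xy) {
  # signed shoelace area; positive for counterclockwise loops
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

point_in_polygon <- function(p, xy) {
  # even-odd ray casting along +x
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  crosses <- ((y > p[2L]) != (y2 > p[2L]))
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (p[2L] - y[crosses]) / (y2[crosses] - y[crosses]) *
    (x2[crosses] - x[crosses])
  sum(xi > p[1L]) %% 2L == 1L
}

#' Wall segment lengths
#' @param mesh a `tissue_mesh`
#' @return numeric vector, micrometres
#' @export
wall_lengths <- function(mesh) {
  d <- mesh$pos[mesh$walls$v2, , drop = FALSE] - mesh$pos[mesh$walls$v1, , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Area of one cell polygon
#'
#' Shoelace area of the cell's ordered vertex loop.
#'
#' @param cell cell index
#' @param mesh a `tissue_mesh`
#' @return area in square micrometres
#' @export
cell_area <- function(cell, mesh) {
  a <- polygon_area(mesh$pos[mesh$loops[[cell]], , drop = FALSE])
  if (a <= 0) stop("cell ", cell, " has non-positive area (degenerate or misoriented loop)")
  a
}

#' Areas of all cells
#' @param mesh a `tissue_mesh`
#' @return numeric vector of cell areas (um^2)
#' @export
cell_areas <- function(mesh) {
  vapply(mesh$loops, function(l) polygon_area(mesh$pos[l, , drop = FALSE]), numeric(1L))
}

#' Cell centroids
#' @param mesh a `tissue_mesh`
#' @return C x 2 matrix of polygon centroids
#' @export
cell_centroids <- function(mesh) {
  t(vapply(mesh$loops, function(l) polygon_centroid(mesh$pos[l, , drop = FALSE]),
           numeric(2L)))
}

# ---- construction from loops -------------------------------------------------

# Build the wall table from vertex loops. Each undirected vertex pair occurring
# in the loops becomes one wall; the cell whose loop traverses it first fixes
# the stored (v1, v2) orientation.
mesh_from_loops <- function(pos, loops, aux = NULL, cuc = NULL, delta = NULL,
                            iteration = 0L) {
  nc <- length(loops)
  # enforce counterclockwise loops
  for (i in seq_len(nc)) {
    if (polygon_area(pos[loops[[i]], , drop = FALSE]) < 0)
      loops[[i]] <- rev(loops[[i]])
  }
  ev1 <- unlist(loops, use.names = FALSE)
  ev2 <- unlist(lapply(loops, function(l) c(l[-1L], l[1L])), use.names = FALSE)
  ecell <- rep.int(seq_len(nc), lengths(loops))
  M <- nrow(pos) + 1
  uk <- pmin(ev1, ev2) * M + pmax(ev1, ev2)
  first <- !duplicated(uk)
  wid <- match(uk, uk[first])
  nw <- sum(first)
  c2 <- rep.int(NA_integer_, nw)
  dup <- duplicated(uk)
  if (anyDuplicated(uk[dup]))
    stop("non-manifold input: a wall is shared by more than two cells")
  c2[wid[dup]] <- ecell[dup]
  walls <- data.frame(v1 = ev1[first], v2 = ev2[first], rest = NA_real_,
                      c1 = ecell[first], c2 = c2,
                      pin1 = 0, pin2 = 0)
  zero <- function(x) if (is.null(x)) numeric(nc) else x
  m <- new_tissue_mesh(pos, walls, loops, zero(aux), zero(cuc),
                       if (is.null(delta)) rep(1, nc) else delta, iteration)
  m$walls$rest <- wall_lengths(m)
  m
}

# ---- disk construction -------------------------------------------------------

#' Build a polygonal tessellation of a disk
#'
#' Constructs a round tissue of roughly equal-area cells arranged as a central
#' cell surrounded by concentric rings of annular-sector cells, with seeded
#' angular jitter for an organic look. Ring boundaries are placed so cells have
#' equal target area and near-unit aspect ratio. Optionally refines the mesh by
#' repeatedly splitting the longest wall until an exact wall count is reached.
#'
#' @param target_cells desired number of cells (the ring construction hits it
#'   exactly for `target_cells >= 1`)
#' @param radius disk radius in micrometres
#' @param seed integer seed for the angular jitter
#' @param n_walls optional exact total number of wall segments; must be at
#'   least the base construction's count
#' @param jitter angular jitter as a fraction of the local sector spacing
#' @return a `tissue_mesh` with rest lengths equal to current lengths,
#'   `aux = cuc = 0`, `delta = 1`, and no PIN allocated
#' @export
build_disk <- function(target_cells, radius, seed = 1L, n_walls = NULL,
                       jitter = 0.15) {
  if (target_cells < 1 || radius <= 0)
    stop("target_cells must be >= 1 and radius > 0")
  set.seed(seed)
  if (target_cells == 1L) {
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    pos <- cbind(radius * cos(ang), radius * sin(ang))
    m <- mesh_from_loops(pos, list(seq_len(24L)))
  } else {
    N <- as.integer(target_cells)
    K <- max(1L, as.integer(round((sqrt(N) - 1) / sqrt(pi))))
    w <- seq_len(K) - 0.5
    m_k <- pmax(3L, as.integer(round((N - 1L) * w / sum(w))))
    # fix rounding so ring cells sum to N - 1
    excess <- sum(m_k) - (N - 1L)
    m_k[K] <- m_k[K] - excess
    if (m_k[K] < 3L) stop("target_cells too small for ", K, " rings")
    cum <- cumsum(c(1L, m_k))
    radii <- radius * sqrt(cum / N)        # circle j = boundary of cumulative cell count
    radii <- c(radius * sqrt(1 / N), radii[-1L])
    # sector angles per ring, jittered
    ring_ang <- vector("list", K)
    for (k in seq_len(K)) {
      base <- 2 * pi * (seq_len(m_k[k]) - 1L) / m_k[k] + stats::runif(1L, 0, 2 * pi)
      base <- base + stats::rnorm(m_k[k], 0, jitter * 2 * pi / m_k[k])
      ring_ang[[k]] <- sort(base %% (2 * pi))
    }
    # angles present on each circle j (0..K): radial wall endpoints of the
    # adjacent rings
    circ_ang <- vector("list", K + 1L)
    circ_ang[[1L]] <- ring_ang[[1L]]
    for (j in seq_len(K - 1L)) circ_ang[[j + 1L]] <- sort(c(ring_ang[[j]], ring_ang[[j + 1L]]))
    circ_ang[[K + 1L]] <- ring_ang[[K]]
    # vertices
    pos <- NULL
    vid <- vector("list", K + 1L)   # vertex ids per circle, in angle order
    nv <- 0L
    for (j in seq_len(K + 1L)) {
      a <- circ_ang[[j]]
      pos <- rbind(pos, cbind(radii[j] * cos(a), radii[j] * sin(a)))
      vid[[j]] <- nv + seq_along(a)
      nv <- nv + length(a)
    }
    # loops: central cell = circle 1 counterclockwise
    loops <- list(vid[[1L]])
    arc_ids <- function(j, a1, a2) {
      # vertex ids on circle j with angle in [a1, a2] (counterclockwise span)
      a <- circ_ang[[j]]
      eps <- 1e-12
      if (a2 > a1) sel <- which(a >= a1 - eps & a <= a2 + eps)
      else sel <- c(which(a >= a1 - eps), which(a <= a2 + eps))
      vid[[j]][sel]
    }
    for (k in seq_len(K)) {
      ak <- ring_ang[[k]]
      for (s in seq_along(ak)) {
        a1 <- ak[s]
        a2 <- if (s < length(ak)) ak[s + 1L] else ak[1L]
        outer_v <- arc_ids(k + 1L, a1, a2)
        inner_v <- arc_ids(k, a1, a2)
        loops[[length(loops) + 1L]] <- c(outer_v, rev(inner_v))
      }
    }
    m <- mesh_from_loops(pos, loops)
  }
  if (!is.null(n_walls)) {
    if (n_walls < n_walls(m))
      stop("n_walls (", n_walls, ") below base construction count (", n_walls(m), ")")
    while (n_walls(m) < n_walls) {
      len <- wall_lengths(m)
      m <- split_wall(m, which.max(len), 2L)
    }
  }
  m
}

# ---- wall splitting ----------------------------------------------------------

# Split wall `w` into `parts` equal sub-segments, inserting parts - 1 collinear
# vertices. Rest length and PIN are apportioned equally (i.e. proportional to
# the equal new lengths); incident cell loops are updated in place.
split_wall <- function(mesh, w, parts) {
  if (parts < 2L) return(mesh)
  wr <- mesh$walls[w, ]
  p1 <- mesh$pos[wr$v1, ]; p2 <- mesh$pos[wr$v2, ]
  fr <- seq_len(parts - 1L) / parts
  newp <- cbind(p1[1L] + fr * (p2[1L] - p1[1L]), p1[2L] + fr * (p2[2L] - p1[2L]))
  newv <- nrow(mesh$pos) + seq_len(parts - 1L)
  mesh$pos <- rbind(mesh$pos, newp)
  chain <- c(wr$v1, newv, wr$v2)
  seg <- data.frame(v1 = chain[-length(chain)], v2 = chain[-1L],
                    rest = wr$rest / parts, c1 = wr$c1, c2 = wr$c2,
                    pin1 = wr$pin1 / parts, pin2 = wr$pin2 / parts)
  mesh$walls <- rbind(mesh$walls[-w, ], seg)
  rownames(mesh$walls) <- NULL
  for (cc in c(wr$c1, wr$c2)) {
    if (is.na(cc)) next
    lp <- mesh$loops[[cc]]
    n <- length(lp)
    nxt <- c(lp[-1L], lp[1L])
    i <- which(lp == wr$v1 & nxt == wr$v2)
    if (length(i) == 1L) ins <- newv
    else {
      i <- which(lp == wr$v2 & nxt == wr$v1)
      ins <- rev(newv)
    }
    mesh$loops[[cc]] <- append(lp, ins, after = i)
  }
  mesh
}

#' Subdivide wall segments exceeding a maximum length
#'
#' Every wall segment longer than `max_len` is replaced by
#' `ceiling(length / max_len)` equal collinear sub-segments. Rest lengths and
#' PIN allocations are apportioned proportionally to the new lengths, so
#' per-cell PIN totals and total tissue area are conserved exactly.
#'
#' @param mesh a `tissue_mesh`
#' @param max_len maximum allowed segment length (micrometres)
#' @return the subdivided `tissue_mesh`
#' @export
split_long_walls <- function(mesh, max_len = 1) {
  len <- wall_lengths(mesh)
  parts <- pmax(1L, as.integer(ceiling(len / max_len - 1e-12)))
  idx <- which(parts > 1L)
  if (length(idx) == 0L) return(mesh)
  V0 <- nrow(mesh$pos)
  npart <- parts[idx]
  nper <- npart - 1L                       # new vertices per split wall
  wi <- rep.int(idx, nper)                 # owning wall of each new vertex
  frac <- unlist(lapply(seq_along(idx), function(i) seq_len(nper[i]) / npart[i]),
                 use.names = FALSE)
  P1 <- mesh$pos[mesh$walls$v1[wi], , drop = FALSE]
  P2 <- mesh$pos[mesh$walls$v2[wi], , drop = FALSE]
  newids <- V0 + seq_along(wi)
  mesh$pos <- rbind(mesh$pos, P1 + frac * (P2 - P1))
  chains <- split(newids, factor(wi, levels = idx))  # in (v1 -> v2) order
  sv1 <- mesh$walls$v1[idx]
  # replacement wall rows
  chain_full <- Map(function(w, ch) c(mesh$walls$v1[w], ch, mesh$walls$v2[w]),
                    idx, chains)
  newrows <- data.frame(
    v1 = unlist(lapply(chain_full, function(ch) ch[-length(ch)]), use.names = FALSE),
    v2 = unlist(lapply(chain_full, function(ch) ch[-1L]), use.names = FALSE),
    rest = rep.int(mesh$walls$rest[idx] / npart, npart),
    c1 = rep.int(mesh$walls$c1[idx], npart),
    c2 = rep.int(mesh$walls$c2[idx], npart),
    pin1 = rep.int(mesh$walls$pin1[idx] / npart, npart),
    pin2 = rep.int(mesh$walls$pin2[idx] / npart, npart))
  # rebuild the loops of affected cells, inserting the chains
  M <- nrow(mesh$pos) + 1
  key_split <- pmin(mesh$walls$v1[idx], mesh$walls$v2[idx]) * M +
    pmax(mesh$walls$v1[idx], mesh$walls$v2[idx])
  cells_aff <- unique(c(mesh$walls$c1[idx], mesh$walls$c2[idx]))
  cells_aff <- cells_aff[!is.na(cells_aff)]
  for (cc in cells_aff) {
    l <- mesh$loops[[cc]]
    nxt <- c(l[-1L], l[1L])
    k <- pmin(l, nxt) * M + pmax(l, nxt)
    hit <- match(k, key_split)
    pieces <- vector("list", length(l))
    for (e in seq_along(l)) {
      if (is.na(hit[e])) pieces[[e]] <- l[e]
      else {
        ch <- chains[[hit[e]]]
        if (l[e] != sv1[hit[e]]) ch <- rev(ch)
        pieces[[e]] <- c(l[e], ch)
      }
    }
    mesh$loops[[cc]] <- unlist(pieces, use.names = FALSE)
  }
  mesh$walls <- rbind(mesh$walls[-idx, , drop = FALSE], newrows)
  rownames(mesh$walls) <- NULL
  mesh
}

# ---- cell division -----------------------------------------------------------

#' Division-rule noise parameters
#'
#' Controls the stochastic perturbations of the minimal-wall-length division
#' rule: `center_sd` is the isotropic Gaussian displacement (micrometres) of
#' the cell centroid through which candidate division planes pass;
#' `division_sd` perturbs each candidate plane's chord-length score before the
#' minimum is taken; `junction_sd` displaces each junction point along its
#' intersected wall (clamped inside the wall).
#'
#' @param center_sd,division_sd,junction_sd standard deviations in micrometres
#' @return a `division_noise` parameter list
#' @export
division_noise <- function(center_sd = 2, division_sd = 2, junction_sd = 2) {
  stopifnot(center_sd >= 0, division_sd >= 0, junction_sd >= 0)
  structure(list(center_sd = center_sd, division_sd = division_sd,
                 junction_sd = junction_sd), class = "division_noise")
}

# signed area of the sub-polygon cut off by the chord (j1 on edge e1, j2 on
# edge e2): path j1 -> v[e1+1] -> ... -> v[e2] -> j2 -> j1
chord_side_area <- function(xy, ch) {
  n <- nrow(xy)
  idx <- if (ch$e1 < ch$e2) seq(ch$e1 + 1L, ch$e2)
         else c(if (ch$e1 < n) seq(ch$e1 + 1L, n), seq_len(ch$e2))
  poly <- rbind(ch$p1, xy[idx, , drop = FALSE], ch$p2)
  abs(polygon_area(poly))
}

# chords of the lines through `center` at all direction angles `thetas` across
# the polygon, vectorised over angles; returns per-angle edge indices, edge
# parameters, junction points, chord length and the cut-off area fraction
# (NA where no valid chord exists)
polygon_chords_all <- function(xy, center, thetas) {
  n <- nrow(xy)
  na <- length(thetas)
  a2 <- xy[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  ex <- a2[, 1L] - xy[, 1L]; ey <- a2[, 2L] - xy[, 2L]
  bx <- xy[, 1L] - center[1L]; by <- xy[, 2L] - center[2L]
  ux <- cos(thetas); uy <- sin(thetas)
  den <- outer(-ey, ux) + outer(ex, uy)               # n x na
  tt <- (outer(-ey * bx, rep(1, na)) + outer(ex * by, rep(1, na))) / den
  ss <- (outer(by, ux) - outer(bx, uy)) / den
  hit <- is.finite(tt) & ss >= 0 & ss < 1
  nhit <- colSums(hit)
  tneg <- ifelse(hit & tt < 0, tt, -Inf)
  tpos <- ifelse(hit & tt >= 0, tt, Inf)
  e1 <- max.col(t(tneg), ties.method = "first")       # per-angle argmax of t<0
  e2 <- max.col(t(-tpos), ties.method = "first")
  pick <- function(m, e) m[cbind(e, seq_len(na))]
  t1 <- pick(tneg, e1); t2 <- pick(tpos, e2)
  # lines crossing the boundary more than twice (possible when the plane runs
  # nearly parallel to a chain of collinear wall segments) give degenerate
  # local chords whose cut-off area is ill-defined; reject them
  ok <- is.finite(t1) & is.finite(t2) & e1 != e2 & nhit == 2L
  s1 <- pick(ss, e1); s2 <- pick(ss, e2)
  p1x <- center[1L] + t1 * ux; p1y <- center[2L] + t1 * uy
  p2x <- center[1L] + t2 * ux; p2y <- center[2L] + t2 * uy
  # cut-off area via prefix sums of the shoelace terms
  crv <- xy[, 1L] * a2[, 2L] - a2[, 1L] * xy[, 2L]    # cross(v_i, v_{i+1})
  S <- cumsum(crv)                                     # S[k] = sum over edges 1..k
  total <- S[n]
  e1n <- ifelse(e1 == n, 1L, e1 + 1L)
  mid <- ifelse(e1 < e2, S[pmax(e2 - 1L, 1L)] * (e2 > 1) - S[e1],
                (total - S[e1]) + ifelse(e2 > 1, S[e2 - 1L], 0))
  mid[e1 < e2 & e2 == 1L] <- 0   # unreachable (e2 > e1 >= 1), kept for safety
  crossv <- function(ax, ay, bx, by) ax * by - bx * ay
  areaA <- 0.5 * (crossv(p1x, p1y, xy[e1n, 1L], xy[e1n, 2L]) + mid +
                  crossv(xy[e2, 1L], xy[e2, 2L], p2x, p2y) +
                  crossv(p2x, p2y, p1x, p1y))
  frac <- abs(areaA) / abs(total / 2)
  list(ok = ok, e1 = e1, e2 = e2, s1 = s1, s2 = s2,
       len = t2 - t1, frac = pmin(frac, 1 - frac))
}

# chord of the line through `center` with direction angle `theta` across the
# polygon: returns the two intersections bracketing the center, or NULL
polygon_chord <- function(xy, center, theta) {
  u <- c(cos(theta), sin(theta))
  a1 <- xy
  a2 <- xy[c(seq_len(nrow(xy))[-1L], 1L), , drop = FALSE]
  ex <- a2[, 1L] - a1[, 1L]; ey <- a2[, 2L] - a1[, 2L]
  # center + t u = a1 + s e
  den <- u[1L] * (-ey) - u[2L] * (-ex)
  bx <- a1[, 1L] - center[1L]; by <- a1[, 2L] - center[2L]
  ok <- abs(den) > 1e-12
  s <- rep(NA_real_, length(den))
  t <- rep(NA_real_, length(den))
  t[ok] <- (bx[ok] * (-ey[ok]) - by[ok] * (-ex[ok])) / den[ok]
  s[ok] <- (u[1L] * by[ok] - u[2L] * bx[ok]) / den[ok]
  hit <- ok & s >= 0 & s < 1
  if (!any(hit)) return(NULL)
  tn <- t[hit]; en <- which(hit); sn <- s[hit]
  neg <- tn < 0; pospart <- tn >= 0
  if (!any(neg) || !any(pospart)) return(NULL)
  i1 <- which(neg)[which.max(tn[neg])]
  i2 <- which(pospart)[which.min(tn[pospart])]
  list(t1 = tn[i1], e1 = en[i1], s1 = sn[i1],
       t2 = tn[i2], e2 = en[i2], s2 = sn[i2],
       p1 = center + tn[i1] * u, p2 = center + tn[i2] * u,
       len = tn[i2] - tn[i1])
}

#' Divide a cell by the noisy minimal-wall-length rule
#'
#' Candidate division planes are 180 orientations at 1 degree spacing through
#' the (noise-displaced) cell centroid; each candidate's chord length across
#' the cell polygon receives a Gaussian score perturbation and the minimum is
#' taken. Junction points are displaced along their intersected walls and
#' clamped inside them. The parent is replaced by two daughters sharing the new
#' wall; daughters inherit the parent's `aux`, `cuc` and `delta` unchanged,
#' split walls apportion PIN by length, and the new wall receives an
#' infinitesimal PIN (1e-6) on both sides followed by per-cell renormalisation
#' to sum 1. Uses the R random number generator.
#'
#' @param mesh a `tissue_mesh`
#' @param cell index of the cell to divide (caller enforces the area threshold)
#' @param noise a [division_noise()] parameter list
#' @param min_daughter_frac minimum admissible daughter-to-parent area
#'   fraction; candidate planes cutting off a smaller sliver are rejected
#'   (sliver cells are biologically implausible and destabilise the transport
#'   dynamics)
#' @return the modified mesh; if the cell is too degenerate to bisect, the mesh
#'   is returned unchanged with a warning recorded in
#'   `attr(, "division_skipped")`
#' @export
divide_cell <- function(mesh, cell, noise = division_noise(),
                        min_daughter_frac = 0.2) {
  lp <- mesh$loops[[cell]]
  xy <- mesh$pos[lp, , drop = FALSE]
  ctr0 <- polygon_centroid(xy)
  ctr <- ctr0
  if (noise$center_sd > 0) {
    cand <- ctr0 + stats::rnorm(2L, 0, noise$center_sd)
    if (point_in_polygon(cand, xy)) ctr <- cand
  }
  area_tot <- abs(polygon_area(xy))
  thetas <- (0:179) * pi / 180
  pert <- if (noise$division_sd > 0) stats::rnorm(180L, 0, noise$division_sd) else numeric(180L)
  score_planes <- function(center) {
    ch <- polygon_chords_all(xy, center, thetas)
    # reject planes that would cut off a sliver daughter (they destabilise
    # the transport dynamics and do not occur in real tissue)
    ok <- ch$ok & ch$frac >= min_daughter_frac
    scores <- ifelse(ok, ch$len + pert, Inf)
    list(scores = scores, ch = ch, center = center)
  }
  sc <- score_planes(ctr)
  if (all(is.infinite(sc$scores)) && !identical(ctr, ctr0))
    sc <- score_planes(ctr0)   # noisy centre found no admissible plane
  if (all(is.infinite(sc$scores))) {
    attr(mesh, "division_skipped") <- c(attr(mesh, "division_skipped"), cell)
    warning("cell ", cell, " too degenerate to bisect; division skipped")
    return(mesh)
  }
  best <- which.min(sc$scores)
  ch <- list(e1 = sc$ch$e1[best], e2 = sc$ch$e2[best],
             s1 = sc$ch$s1[best], s2 = sc$ch$s2[best])
  nl <- length(lp)
  # polygon edge k runs from loop vertex k to k+1; junction parameter s along it
  junction <- function(edge, s) {
    va <- lp[edge]; vb <- lp[if (edge == nl) 1L else edge + 1L]
    elen <- sqrt(sum((mesh$pos[vb, ] - mesh$pos[va, ])^2))
    if (noise$junction_sd > 0) s <- s + stats::rnorm(1L, 0, noise$junction_sd) / elen
    s <- min(max(s, 0.05), 0.95)
    list(va = va, vb = vb, s = s)
  }
  j1 <- junction(ch$e1, ch$s1)
  j2 <- junction(ch$e2, ch$s2)

  insert_on_wall <- function(mesh, va, vb, s) {
    # create a vertex at fraction s from va to vb on the wall joining them;
    # returns list(mesh, vnew). s is relative to the (va, vb) direction.
    w <- which((mesh$walls$v1 == va & mesh$walls$v2 == vb) |
               (mesh$walls$v1 == vb & mesh$walls$v2 == va))
    wr <- mesh$walls[w, ]
    if (wr$v1 != va) s <- 1 - s          # express along stored orientation
    p <- mesh$pos[wr$v1, ] + s * (mesh$pos[wr$v2, ] - mesh$pos[wr$v1, ])
    vnew <- nrow(mesh$pos) + 1L
    mesh$pos <- rbind(mesh$pos, matrix(p, 1L))
    seg <- data.frame(v1 = c(wr$v1, vnew), v2 = c(vnew, wr$v2),
                      rest = wr$rest * c(s, 1 - s),
                      c1 = wr$c1, c2 = wr$c2,
                      pin1 = wr$pin1 * c(s, 1 - s), pin2 = wr$pin2 * c(s, 1 - s))
    mesh$walls <- rbind(mesh$walls[-w, ], seg)
    rownames(mesh$walls) <- NULL
    for (cc in c(wr$c1, wr$c2)) {
      if (is.na(cc)) next
      l <- mesh$loops[[cc]]
      nxt <- c(l[-1L], l[1L])
      i <- which((l == wr$v1 & nxt == wr$v2) | (l == wr$v2 & nxt == wr$v1))
      mesh$loops[[cc]] <- append(l, vnew, after = i)
    }
    list(mesh = mesh, vnew = vnew)
  }
  r1 <- insert_on_wall(mesh, j1$va, j1$vb, j1$s); mesh <- r1$mesh; w1 <- r1$vnew
  r2 <- insert_on_wall(mesh, j2$va, j2$vb, j2$s); mesh <- r2$mesh; w2 <- r2$vnew

  # split the parent loop at the two junction vertices
  l <- mesh$loops[[cell]]
  i1 <- which(l == w1); i2 <- which(l == w2)
  if (i1 < i2) { seqA <- l[i1:i2]; seqB <- l[c(i2:length(l), 1:i1)] }
  else { seqA <- l[i2:i1]; seqB <- l[c(i1:length(l), 1:i2)] }
  areaA <- polygon_area(mesh$pos[seqA, , drop = FALSE])
  areaB <- polygon_area(mesh$pos[seqB, , drop = FALSE])
  # junction jitter can still degrade the realised cut; refuse degenerate
  # daughters (the cell remains above threshold and redivides next iteration)
  if (min(abs(areaA), abs(areaB)) < 0.05 * area_tot) {
    attr(mesh, "division_skipped") <- c(attr(mesh, "division_skipped"), cell)
    warning("cell ", cell, " division would create a degenerate daughter; skipped")
    return(mesh)
  }
  newc <- n_cells(mesh) + 1L
  mesh$loops[[cell]] <- if (areaA > 0) seqA else rev(seqA)
  lB <- if (areaB > 0) seqB else rev(seqB)
  mesh$loops[[newc]] <- lB
  mesh$aux <- c(mesh$aux, mesh$aux[cell])
  mesh$cuc <- c(mesh$cuc, mesh$cuc[cell])
  mesh$delta <- c(mesh$delta, mesh$delta[cell])
  # reassign walls of daughter B from parent id to the new id
  M <- nrow(mesh$pos) + 1
  nxtA <- c(seqA[-1L], seqA[1L])
  keyA <- pmin(seqA, nxtA) * M + pmax(seqA, nxtA)
  wall_key <- pmin(mesh$walls$v1, mesh$walls$v2) * M +
    pmax(mesh$walls$v1, mesh$walls$v2)
  on_parent1 <- which(mesh$walls$c1 == cell)
  on_parent2 <- which(!is.na(mesh$walls$c2) & mesh$walls$c2 == cell)
  toB1 <- on_parent1[!(wall_key[on_parent1] %in% keyA)]
  toB2 <- on_parent2[!(wall_key[on_parent2] %in% keyA)]
  mesh$walls$c1[toB1] <- newc
  mesh$walls$c2[toB2] <- newc
  # the new wall between the daughters
  mesh$walls <- rbind(mesh$walls,
                      data.frame(v1 = w1, v2 = w2,
                                 rest = sqrt(sum((mesh$pos[w2, ] - mesh$pos[w1, ])^2)),
                                 c1 = cell, c2 = newc, pin1 = 1e-6, pin2 = 1e-6))
  rownames(mesh$walls) <- NULL
  # fix new-wall incidence: ensure c1 traverses (v1, v2)
  mesh <- renormalize_pins(mesh, c(cell, newc))
  mesh
}

# rescale the PIN allocations of the given cells so each sums to 1 (cells with
# no PIN at all are left untouched)
renormalize_pins <- function(mesh, cells) {
  for (cc in cells) {
    i1 <- which(mesh$walls$c1 == cc)
    i2 <- which(!is.na(mesh$walls$c2) & mesh$walls$c2 == cc)
    tot <- sum(mesh$walls$pin1[i1]) + sum(mesh$walls$pin2[i2])
    if (tot > 0) {
      mesh$walls$pin1[i1] <- mesh$walls$pin1[i1] / tot
      mesh$walls$pin2[i2] <- mesh$walls$pin2[i2] / tot
    }
  }
  mesh
}

# per-cell PIN totals (over each cell's own wall sides)
pin_sums <- function(mesh) {
  s <- numeric(n_cells(mesh))
  t1 <- rowsum(mesh$walls$pin1, mesh$walls$c1)
  s[as.integer(rownames(t1))] <- t1
  int <- !is.na(mesh$walls$c2)
  if (any(int)) {
    t2 <- rowsum(mesh$walls$pin2[int], mesh$walls$c2[int])
    s[as.integer(rownames(t2))] <- s[as.integer(rownames(t2))] + t2
  }
  s
}

# ---- validation --------------------------------------------------------------

#' Check structural invariants of a tissue mesh
#'
#' Verifies the Euler relation V - E + C = 1, positive cell areas, closed
#' consistent cell loops, wall-cell incidence, positive rest lengths, finite
#' coordinates, PIN non-negativity and (when PIN has been initialised) per-cell
#' PIN normalisation. Violations are reported, not raised.
#'
#' @param mesh a `tissue_mesh`
#' @return character vector of violation messages (empty if the mesh is valid)
#' @export
validate_mesh <- function(mesh) {
  bad <- character(0)
  V <- n_vertices(mesh); E <- n_walls(mesh); C <- n_cells(mesh)
  if (V - E + C != 1L)
    bad <- c(bad, sprintf("Euler relation violated: V - E + C = %d", V - E + C))
  if (!all(is.finite(mesh$pos))) bad <- c(bad, "non-finite vertex coordinates")
  if (any(mesh$walls$v1 > V | mesh$walls$v2 > V | mesh$walls$v1 < 1 | mesh$walls$v2 < 1))
    bad <- c(bad, "wall endpoint references a missing vertex")
  if (any(mesh$walls$rest <= 0)) bad <- c(bad, "non-positive rest length")
  if (any(mesh$walls$pin1 < 0) || any(mesh$walls$pin2 < 0))
    bad <- c(bad, "negative PIN allocation")
  ar <- vapply(mesh$loops, function(l) polygon_area(mesh$pos[l, , drop = FALSE]),
               numeric(1L))
  if (any(ar <= 0)) bad <- c(bad, sprintf("%d cell(s) with non-positive area", sum(ar <= 0)))
  bw <- is.na(mesh$walls$c2)
  if (any(mesh$walls$pin1[bw] != 0) || any(mesh$walls$pin2[bw] != 0))
    bad <- c(bad, "PIN allocated on the outward side of a boundary wall")
  # loop/wall incidence: every consecutive loop pair must be a wall whose
  # c1/c2 matches the traversing cell
  M <- V + 1
  wall_uk <- pmin(mesh$walls$v1, mesh$walls$v2) * M + pmax(mesh$walls$v1, mesh$walls$v2)
  for (cc in seq_len(C)) {
    l <- mesh$loops[[cc]]
    if (anyDuplicated(l)) { bad <- c(bad, sprintf("cell %d loop revisits a vertex", cc)); next }
    nxt <- c(l[-1L], l[1L])
    uk <- pmin(l, nxt) * M + pmax(l, nxt)
    w <- match(uk, wall_uk)
    if (anyNA(w)) { bad <- c(bad, sprintf("cell %d loop edge has no wall", cc)); next }
    inc <- mesh$walls$c1[w] == cc | (!is.na(mesh$walls$c2[w]) & mesh$walls$c2[w] == cc)
    if (!all(inc)) bad <- c(bad, sprintf("cell %d loop/wall incidence mismatch", cc))
  }
  ps <- pin_sums(mesh)
  if (any(ps > 0) && any(abs(ps[ps > 0] - 1) > 1e-6))
    bad <- c(bad, "per-cell PIN allocations do not sum to 1")
  bad
}

# ---- packaged initial disk ---------------------------------------------------

#' Load the packaged initial meristem disk
#'
#' Returns the shipped starting tissue: a round disk of 73 cells and 348 wall
#' segments with no auxin, no CUC1, apolar (length-proportional) PIN and rest
#' lengths equal to current lengths.
#'
#' @return a `tissue_mesh`
#' @export
load_default_disk <- function() {
  path <- system.file("extdata", "default_disk.json", package = "meristemsim")
  if (path == "" || !file.exists(path))
    stop("packaged default disk fixture is missing")
  mesh <- read_snapshot(path)
  if (n_cells(mesh) != 73L || n_walls(mesh) != 348L)
    stop("packaged default disk fixture is corrupt: expected 73 cells / 348 walls, got ",
         n_cells(mesh), " / ", n_walls(mesh))
  mesh
}
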