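# ---- parameters ------------------------------------------------------------

#' Chemical parameters of the auxin-CUC1-PIN1 network
#'
#' Rates are per unit chemical time; each simulation iteration runs
#' `n_substeps` explicit-Euler substeps of size `dt_chem`.
#'
#' @param alpha PIN repolarisation speed per substep (0 < alpha <= 1)
#' @param cuc_thres CUC1 concentration above which the PIN sensitivity
#'   exponent switches from 1 to 2
#' @param prod_aux,dec_aux auxin production and decay coefficients
#' @param tran_aux polar auxin transport coefficient
#' @param prod_cuc,dec_cuc CUC1 production and decay coefficients (`prod_cuc`
#'   is 0 in cuc1 genotypes)
#' @param k_aux auxin level at which CUC1 production is halved
#' @param hill Hill coefficient of the auxin repression of CUC1
#' @param sd_aux standard deviation of the per-cell auxin production noise
#'   multiplier (drawn from N(1, sd_aux), negatives set to 0)
#' @param dt_chem substep size
#' @param n_substeps substeps per iteration
#' @param frozen_noise if TRUE, noise multipliers are drawn only at
#'   initialisation and never redrawn
#' @return a `chem_params` list
#' @export
chem_params <- function(alpha = 0.01, cuc_thres = 2, prod_aux = 1,
                        dec_aux = 0.2, tran_aux = 400, prod_cuc = 1,
                        dec_cuc = 0.2, k_aux = 5, hill = 4, sd_aux = 0.1,
                        dt_chem = 0.01, n_substeps = 10L,
                        frozen_noise = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, cuc_thres >= 0, prod_aux >= 0, dec_aux >= 0,
            tran_aux >= 0, prod_cuc >= 0, dec_cuc >= 0, k_aux > 0, hill > 0,
            sd_aux >= 0, dt_chem > 0, n_substeps >= 1)
  structure(list(alpha = alpha, cuc_thres = cuc_thres, prod_aux = prod_aux,
                 dec_aux = dec_aux, tran_aux = tran_aux, prod_cuc = prod_cuc,
                 dec_cuc = dec_cuc, k_aux = k_aux, hill = hill,
                 sd_aux = sd_aux, dt_chem = dt_chem,
                 n_substeps = as.integer(n_substeps),
                 frozen_noise = isTRUE(frozen_noise)),
            class = "chem_params")
}

# ---- directed neighbour-pair table ------------------------------------------
#
# PIN dynamics and transport act between cell pairs; the wall segments between
# a pair are aggregated (total shared length, total PIN) and allocations are
# redistributed to segments proportionally to segment length afterwards.

cell_pairs <- function(mesh) {
  C <- n_cells(mesh)
  int <- which(!is.na(mesh$walls$c2))
  len <- wall_lengths(mesh)
  si <- c(mesh$walls$c1[int], mesh$walls$c2[int])   # owner cell of each side
  sj <- c(mesh$walls$c2[int], mesh$walls$c1[int])   # its neighbour
  spin <- c(mesh$walls$pin1[int], mesh$walls$pin2[int])
  slen <- c(len[int], len[int])
  key <- (si - 1) * C + sj
  ukey <- unique(key)
  g <- match(key, ukey)
  np <- length(ukey)
  L <- as.numeric(rowsum(slen, g, reorder = FALSE))
  pin <- as.numeric(rowsum(spin, g, reorder = FALSE))
  i <- (ukey - 1L) %/% C + 1L
  j <- ukey - (i - 1L) * C
  list(i = i, j = j, L = L, pin = pin, np = np,
       seg_wall = c(int, int), seg_side = rep(1:2, each = length(int)),
       seg_len = slen, seg_pair = g)
}

# accumulate x by integer group g into a dense length-C vector
acc_by_cell <- function(x, g, C) {
  out <- numeric(C)
  r <- rowsum(x, g)
  out[as.integer(rownames(r))] <- r
  out
}

# write aggregated pair PIN back to wall segments, proportionally to length
scatter_pins <- function(mesh, pr) {
  segpin <- pr$pin[pr$seg_pair] * pr$seg_len / pr$L[pr$seg_pair]
  n <- length(segpin) / 2L
  mesh$walls$pin1[pr$seg_wall[seq_len(n)]] <- segpin[seq_len(n)]
  mesh$walls$pin2[pr$seg_wall[n + seq_len(n)]] <- segpin[n + seq_len(n)]
  mesh
}

# ---- PIN ---------------------------------------------------------------------

#' Initialise apolar PIN allocations
#'
#' Each cell allocates PIN to its interior walls proportionally to wall
#' length: `pin(i -> j) = L_j / sum_k L_k` over interior walls only. Boundary
#' walls carry no PIN (zero-flux boundary), so each cell's allocations sum
#' to 1. Isolated cells (no interior walls) are left without PIN and flagged
#' in `attr(, "isolated_cells")`.
#'
#' @param mesh a `tissue_mesh`
#' @return the mesh with initialised PIN
#' @export
init_pin <- function(mesh) {
  C <- n_cells(mesh)
  len <- wall_lengths(mesh)
  int <- !is.na(mesh$walls$c2)
  tot <- acc_by_cell(len[int], mesh$walls$c1[int], C) +
    acc_by_cell(len[int], mesh$walls$c2[int], C)
  pin1 <- numeric(n_walls(mesh))
  pin2 <- numeric(n_walls(mesh))
  w <- which(int)
  pin1[w] <- len[w] / tot[mesh$walls$c1[w]]
  pin2[w] <- len[w] / tot[mesh$walls$c2[w]]
  mesh$walls$pin1 <- pin1
  mesh$walls$pin2 <- pin2
  iso <- which(tot == 0)
  if (length(iso)) attr(mesh, "isolated_cells") <- iso
  mesh
}

#' PIN sensitivity exponent
#'
#' Returns 1 below the CUC1 threshold and 2 at or above it (the measure-zero
#' tie is assigned to the high branch so the rule is deterministic).
#'
#' @param cuc CUC1 concentration(s)
#' @param cuc_thres threshold concentration
#' @return integer exponent(s), 1 or 2
#' @export
pin_sensitivity <- function(cuc, cuc_thres = 2) {
  ifelse(cuc >= cuc_thres, 2L, 1L)
}

#' One PIN repolarisation substep
#'
#' For every cell i and interior neighbour j,
#' `pin(i->j) <- (1 - alpha) pin(i->j) + alpha aux_j^n L_j / sum_k aux_k^n L_k`
#' with exponent n from [pin_sensitivity()] of cell i's CUC1. When all of a
#' cell's neighbours have zero auxin the target falls back to the
#' length-proportional (apolar) allocation, so per-cell sums remain exactly 1.
#'
#' @param mesh a `tissue_mesh` with initialised PIN
#' @param params a [chem_params()] list
#' @return the mesh with updated PIN
#' @export
update_pin <- function(mesh, params = chem_params()) {
  pr <- cell_pairs(mesh)
  pr$pin <- update_pin_pairs(pr, mesh$aux, mesh$cuc, params, n_cells(mesh))
  scatter_pins(mesh, pr)
}

update_pin_pairs <- function(pr, aux, cuc, params, C) {
  n_i <- pin_sensitivity(cuc, params$cuc_thres)
  w <- aux[pr$j]^n_i[pr$i] * pr$L
  den <- acc_by_cell(w, pr$i, C)
  Lden <- acc_by_cell(pr$L, pr$i, C)
  target <- ifelse(den[pr$i] > 0, w / den[pr$i], pr$L / Lden[pr$i])
  (1 - params$alpha) * pr$pin + params$alpha * target
}

# ---- noise -------------------------------------------------------------------

#' Draw per-cell auxin production noise
#'
#' Each cell's noise multiplier is drawn independently from N(1, sd_aux) in
#' ascending cell order (negative draws set to 0). Under frozen noise, values
#' are drawn at initialisation only and kept unchanged afterwards. Uses the R
#' random number generator.
#'
#' @param mesh a `tissue_mesh`
#' @param sd_aux noise standard deviation
#' @param frozen if TRUE, redraws are suppressed except at initialisation
#' @param at_init TRUE for the initialisation draw
#' @return the mesh with updated `delta`
#' @export
draw_noise <- function(mesh, sd_aux, frozen = FALSE, at_init = FALSE) {
  if (frozen && !at_init) return(mesh)
  if (sd_aux == 0) mesh$delta <- rep(1, n_cells(mesh))
  else mesh$delta <- pmax(0, stats::rnorm(n_cells(mesh), 1, sd_aux))
  mesh
}

# ---- concentration substeps --------------------------------------------------

#' One auxin substep (production, decay, polar transport)
#'
#' Explicit-Euler update
#' `aux_i <- aux_i + dt [prod_aux delta_i - dec_aux aux_i +
#'   tran_aux sum_j (aux_j pin(j->i) - aux_i pin(i->j)) / Area_i]`,
#' clamped at 0. No flux crosses the tissue boundary.
#'
#' @param mesh a `tissue_mesh` with current PIN and areas
#' @param params a [chem_params()] list
#' @return the mesh with updated auxin
#' @export
auxin_substep <- function(mesh, params = chem_params()) {
  C <- n_cells(mesh)
  pr <- cell_pairs(mesh)
  mesh$aux <- auxin_step_values(mesh$aux, mesh$delta, cell_areas(mesh), pr,
                                params)
  mesh
}

auxin_step_values <- function(aux, delta, areas, pr, params) {
  C <- length(aux)
  flow <- aux[pr$i] * pr$pin                      # flux i -> j per pair
  net <- acc_by_cell(flow, pr$j, C) - acc_by_cell(flow, pr$i, C)
  daux <- params$prod_aux * delta - params$dec_aux * aux +
    params$tran_aux * net / areas
  out <- aux + params$dt_chem * daux
  if (any(!is.finite(out)))
    stop("non-finite auxin in cell(s) ", paste(which(!is.finite(out)), collapse = ", "))
  pmax(out, 0)
}

#' One CUC1 substep (Hill-repressed production, decay)
#'
#' Explicit-Euler update
#' `cuc_i <- cuc_i + dt [prod_cuc / (1 + (aux_i / k_aux)^hill) - dec_cuc cuc_i]`,
#' clamped at 0.
#'
#' @param mesh a `tissue_mesh`
#' @param params a [chem_params()] list
#' @return the mesh with updated CUC1
#' @export
cuc_substep <- function(mesh, params = chem_params()) {
  mesh$cuc <- cuc_step_values(mesh$cuc, mesh$aux, params)
  mesh
}

cuc_step_values <- function(cuc, aux, params) {
  dcuc <- params$prod_cuc / (1 + (aux / params$k_aux)^params$hill) -
    params$dec_cuc * cuc
  out <- cuc + params$dt_chem * dcuc
  if (any(!is.finite(out)))
    stop("non-finite CUC1 in cell(s) ", paste(which(!is.finite(out)), collapse = ", "))
  pmax(out, 0)
}

# ---- full chemistry pass -----------------------------------------------------

#' Run the chemical interactions for one iteration
#'
#' Executes `n_substeps` rounds. Within each round the PIN repolarisation,
#' auxin and CUC1 updates are all computed from the same pre-round state
#' (concomitant semantics) and applied together.
#'
#' @param mesh a `tissue_mesh` with initialised PIN and current noise
#' @param params a [chem_params()] list
#' @param engine `"cpp"` (compiled inner loop, the default) or `"r"` (the
#'   reference composition of the substep operations); both compute the same
#'   update
#' @return the mesh after the chemistry pass
#' @export
run_chemistry <- function(mesh, params = chem_params(), engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  C <- n_cells(mesh)
  pr <- cell_pairs(mesh)
  areas <- cell_areas(mesh)
  aux <- mesh$aux
  cuc <- mesh$cuc
  if (pr$np == 0L) {
    for (s in seq_len(params$n_substeps)) {
      newaux <- auxin_step_values(aux, mesh$delta, areas, pr, params)
      cuc <- cuc_step_values(cuc, aux, params)
      aux <- newaux
    }
  } else if (engine == "cpp") {
    res <- .chem_kernel(pr$i, pr$j, pr$L, pr$pin, aux, cuc, mesh$delta, areas,
                        params$alpha, params$cuc_thres, params$prod_aux,
                        params$dec_aux, params$tran_aux, params$prod_cuc,
                        params$dec_cuc, params$k_aux, params$hill,
                        params$dt_chem, params$n_substeps)
    pr$pin <- res$pin
    aux <- res$aux
    cuc <- res$cuc
  } else {
    for (s in seq_len(params$n_substeps)) {
      newpin <- update_pin_pairs(pr, aux, cuc, params, C)
      newaux <- auxin_step_values(aux, mesh$delta, areas, pr, params)
      newcuc <- cuc_step_values(cuc, aux, params)
      pr$pin <- newpin
      aux <- newaux
      cuc <- newcuc
    }
  }
  mesh$aux <- aux
  mesh$cuc <- cuc
  if (pr$np > 0L) mesh <- scatter_pins(mesh, pr)
  mesh
}

# ---- dilution ---------------------------------------------------------------

#' Dilute concentrations after cell size changes
#'
#' Scales each cell's auxin and CUC1 by `areas_before / areas_after` so the
#' amounts `aux * Area` and `cuc * Area` are conserved. Noise multipliers are
#' unchanged.
#'
#' @param mesh a `tissue_mesh`
#' @param areas_before,areas_after per-cell areas before and after the size
#'   change (same cell order as the mesh)
#' @return the mesh with diluted concentrations
#' @export
dilute_concentrations <- function(mesh, areas_before, areas_after) {
  if (any(areas_after <= 0) || any(areas_before <= 0))
    stop("non-positive cell area in dilution")
  ratio <- areas_before / areas_after
  mesh$aux <- mesh$aux * ratio
  mesh$cuc <- mesh$cuc * ratio
  mesh
}
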