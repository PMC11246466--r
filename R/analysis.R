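# ---- auxin maxima ------------------------------------------------------------

#' Extract auxin maxima in the middle ring of the tissue
#'
#' Candidate cells are those whose auxin is at least `threshold_frac` of the
#' snapshot maximum; candidates are grouped into connected components of the
#' cell-adjacency graph, and a component becomes a maximum if its
#' auxin-weighted centroid lies in the annulus `ring[1] * R < r < ring[2] * R`,
#' where R is the maximum distance of any cell centroid from the tissue
#' centroid. Angles are measured counterclockwise from the +x axis about the
#' tissue centroid.
#'
#' @param mesh a `tissue_mesh` snapshot
#' @param threshold_frac relative auxin threshold (fraction of snapshot max)
#' @param ring inner and outer ring radii as fractions of the tissue radius
#' @return a data.frame with one row per maximum: `angle` (degrees in
#'   \[0, 360)), `r_frac` (radial position as a fraction of R), `x`, `y`,
#'   `mean_aux`, `peak_aux`, `n_cells`, plus a list-column `members` of cell
#'   indices
#' @export
extract_auxin_maxima <- function(mesh, threshold_frac = 0.5,
                                 ring = c(1 / 3, 2 / 3)) {
  empty <- data.frame(angle = numeric(0), r_frac = numeric(0), x = numeric(0),
                      y = numeric(0), mean_aux = numeric(0),
                      peak_aux = numeric(0), n_cells = integer(0))
  empty$members <- list()
  if (n_cells(mesh) < 1L || max(mesh$aux) <= 0) return(empty)
  ctr_cells <- cell_centroids(mesh)
  areas <- cell_areas(mesh)
  tissue_ctr <- colSums(ctr_cells * areas) / sum(areas)
  rel <- sweep(ctr_cells, 2L, tissue_ctr)
  rr <- sqrt(rowSums(rel^2))
  R <- max(rr)
  cand <- which(mesh$aux >= threshold_frac * max(mesh$aux))
  if (length(cand) == 0L) return(empty)
  # connected components of the candidate set under cell adjacency
  int <- !is.na(mesh$walls$c2)
  a <- mesh$walls$c1[int]; b <- mesh$walls$c2[int]
  keep <- a %in% cand & b %in% cand
  comp <- seq_len(n_cells(mesh))          # union-find with path halving
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in which(keep)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) comp[ra] <- rb
  }
  roots <- vapply(cand, find, integer(1L))
  groups <- split(cand, roots)
  rows <- lapply(groups, function(g) {
    w <- mesh$aux[g]
    cc <- colSums(ctr_cells[g, , drop = FALSE] * w) / sum(w)
    d <- cc - tissue_ctr
    r <- sqrt(sum(d^2))
    if (r <= ring[1L] * R || r >= ring[2L] * R) return(NULL)
    ang <- (atan2(d[2L], d[1L]) * 180 / pi) %% 360
    out <- data.frame(angle = ang, r_frac = r / R, x = cc[1L], y = cc[2L],
                      mean_aux = mean(mesh$aux[g]), peak_aux = max(mesh$aux[g]),
                      n_cells = length(g))
    out$members <- list(g)
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$angle), , drop = FALSE]
}

# ---- angular statistics --------------------------------------------------------

#' Coefficient of variation of circular gaps between angles
#'
#' Angles are sorted circularly; the gaps between circularly adjacent angles
#' (summing to 360 degrees) are computed, and the sample standard deviation of
#' the gaps divided by their mean is returned. 0 means perfectly even spacing.
#'
#' @param angles numeric vector of angles in degrees (>= 2 values)
#' @return the CV (dimensionless); `NA` with a warning for fewer than 2 angles
#' @export
angular_cv <- function(angles) {
  if (length(angles) < 2L) {
    warning("angular CV undefined for fewer than 2 angles")
    return(NA_real_)
  }
  a <- sort(angles %% 360)
  gaps <- c(diff(a), 360 - (a[length(a)] - a[1L]))
  stats::sd(gaps) / mean(gaps)
}

#' Summarise the final pattern of a simulation run
#'
#' Extracts auxin maxima from the final snapshot and reports their count, the
#' mean over maxima of the per-maximum mean auxin, and the angular CV of the
#' maxima positions (NA when fewer than 2 maxima).
#'
#' @param trajectory a `trajectory` from [run_simulation()]
#' @param threshold_frac,ring passed to [extract_auxin_maxima()]
#' @return a list with `maxima_count`, `mean_max_aux`, `angular_cv`,
#'   `iteration`
#' @export
summarize_run <- function(trajectory, threshold_frac = 0.5,
                          ring = c(1 / 3, 2 / 3)) {
  fin <- final_snapshot(trajectory)
  mx <- extract_auxin_maxima(fin, threshold_frac, ring)
  list(maxima_count = nrow(mx),
       mean_max_aux = if (nrow(mx)) mean(mx$mean_aux) else NA_real_,
       angular_cv = if (nrow(mx) >= 2L) angular_cv(mx$angle) else NA_real_,
       iteration = fin$iteration)
}

# ---- circular histogram --------------------------------------------------------

#' Circular intensity histogram around a centre
#'
#' Sums point intensities into 360 one-degree sectors around `center`
#' (counterclockwise from the +x axis, minus `alignment_offset`, wrapped to
#' \[0, 360)), then aggregates exact groups of four fine bins into 90
#' four-degree bins. The total equals the summed input intensity. For data
#' aligned so the incipient outer sepal sits at 45 degrees, pass the
#' appropriate offset; simulations use 0 (no sepal identity exists).
#'
#' @param points n x 2 matrix of positions
#' @param intensity numeric vector of intensities (length n)
#' @param center 2-vector; the rotation axis
#' @param alignment_offset degrees subtracted from every angle
#' @return a `circular_histogram`: list with `fine_bins` (360), `coarse_bins`
#'   (90), `alignment_offset`, `total`
#' @export
circular_histogram <- function(points, intensity, center = c(0, 0),
                               alignment_offset = 0) {
  points <- matrix(points, ncol = 2L)
  stopifnot(nrow(points) >= 1L, length(intensity) == nrow(points))
  d <- sweep(points, 2L, center)
  at_center <- rowSums(d^2) < 1e-24
  if (any(at_center))
    warning(sum(at_center), " point(s) exactly at the centre assigned to bin 0")
  ang <- (atan2(d[, 2L], d[, 1L]) * 180 / pi - alignment_offset) %% 360
  ang[at_center] <- 0
  bin <- pmin(floor(ang), 359)             # fine bin index 0..359
  fine <- numeric(360L)
  agg <- rowsum(intensity, bin)
  fine[as.integer(rownames(agg)) + 1L] <- agg
  coarse <- colSums(matrix(fine, nrow = 4L))
  structure(list(fine_bins = fine, coarse_bins = coarse,
                 alignment_offset = alignment_offset, total = sum(intensity)),
            class = "circular_histogram")
}

#' @export
print.circular_histogram <- function(x, ...) {
  cat("<circular_histogram> total signal ", format(x$total, digits = 6),
      "; peak 4-degree bin at ", (which.max(x$coarse_bins) - 1L) * 4,
      " degrees\n", sep = "")
  invisible(x)
}

# ---- ensemble comparison -------------------------------------------------------

#' Compare ensemble groups on a summary metric
#'
#' Per-group mean/SD/variance of the metric, pairwise mean comparisons with
#' Tukey's HSD family-wise correction, and pairwise robust dispersion
#' comparisons (median-centred Levene test on each pair of groups).
#'
#' @param summary_table a data.frame of per-run summaries (e.g. from
#'   [run_ensemble()], possibly row-bound across conditions)
#' @param metric column name of the metric to compare
#' @param grouping column name(s) defining the groups
#' @return an `ensemble_comparison`: list with `groups` (per-group stats),
#'   `means` (Tukey HSD table) and `variances` (pairwise Levene tests with
#'   direction)
#' @export
compare_ensembles <- function(summary_table, metric = "maxima_count",
                              grouping = "genotype") {
  g <- interaction(summary_table[grouping], drop = TRUE, sep = ":")
  x <- summary_table[[metric]]
  ok <- is.finite(x)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("need at least 2 runs per group")
  groups <- data.frame(group = levels(g),
                       n = as.integer(table(g)),
                       mean = as.numeric(tapply(x, g, mean)),
                       sd = as.numeric(tapply(x, g, stats::sd)),
                       variance = as.numeric(tapply(x, g, stats::var)))
  if (all(groups$variance == 0)) {
    warning("all groups are constant; comparisons skipped")
    return(structure(list(groups = groups, means = NULL, variances = NULL,
                          metric = metric), class = "ensemble_comparison"))
  }
  hsd <- stats::TukeyHSD(stats::aov(x ~ g))$g
  means <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                      p_adj = hsd[, "p adj"], row.names = NULL)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  variances <- do.call(rbind, lapply(pairs, function(p) {
    sel <- g %in% p
    gi <- droplevels(g[sel])
    lt <- car::leveneTest(x[sel] ~ gi, center = stats::median)
    data.frame(pair = paste(p[2L], p[1L], sep = "-"),
               var_1 = stats::var(x[g == p[1L]]),
               var_2 = stats::var(x[g == p[2L]]),
               higher_var = p[which.max(c(stats::var(x[g == p[1L]]),
                                          stats::var(x[g == p[2L]])))],
               p_value = lt[["Pr(>F)"]][1L])
  }))
  structure(list(groups = groups, means = means, variances = variances,
                 metric = metric), class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("<ensemble_comparison> metric:", x$metric, "\n\nGroups:\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$means)) {
    cat("\nPairwise mean comparisons (Tukey HSD):\n")
    print(x$means, row.names = FALSE)
    cat("\nPairwise dispersion comparisons (median-centred Levene):\n")
    print(x$variances, row.names = FALSE)
  }
  invisible(x)
}
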