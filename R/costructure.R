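# Clutch-seeded co-structure analysis: Voronoi partition of DNA around H2B
# clutch centroids, clipped-disk radial density profiles, clutch-associated
# DNA fractions, annulus similarity matrices with the clutch-DNA transition
# radius, NND-conditioned density curves, and shift/subsample controls.

#' Voronoi partition seeded at clutch centroids
#'
#' Tessellates the usable mask region with one polygon per clutch centroid;
#' every DNA localization inside the mask then belongs to exactly one clutch,
#' which prevents over-counting in the radial analysis. Polygons exceeding
#' the nuclear periphery or crossing nucleolar exclusions are clipped to the
#' mask.
#'
#' @param clutches A [segment_clutches()] result (or a data.frame with
#'   columns `id`, `x`, `y`).
#' @param mask A [nuclear_mask()].
#' @return A `clutch_polygons` object: `ids`, `centroids`, convex `cells`
#'   (pre-mask), masked `areas`, `dist_to_mask`, and the mask.
#' @export
clutch_voronoi <- function(clutches, mask) {
  df <- if (inherits(clutches, "clutch_set")) clutches$clutches else clutches
  inside <- cpp_points_in_polygon(df$x, df$y, mask$boundary, 1e-9)
  for (ex in mask$exclusions)
    inside <- inside & !cpp_points_in_polygon(df$x, df$y, ex, 1e-9)
  if (!all(inside)) {
    warning(sum(!inside), " clutch centroids outside usable mask excluded")
    df <- df[inside, , drop = FALSE]
  }
  if (nrow(df) < 4) stop("need >= 4 clutch centroids inside the mask")
  jj <- .jitter_duplicates(df$x, df$y)
  bb <- .mask_bbox(mask, pad = 1)
  cells <- cpp_voronoi2d(jj$x, jj$y, bb[1], bb[2], bb[3], bb[4])
  areas <- cpp_masked_areas(cells, .mask_polys(mask))
  dmask <- cpp_dist_to_polygon(df$x, df$y, mask$boundary)
  for (ex in mask$exclusions)
    dmask <- pmin(dmask, cpp_dist_to_polygon(df$x, df$y, ex))
  structure(list(ids = df$id, centroids = cbind(x = jj$x, y = jj$y),
                 cells = cells, areas = areas, dist_to_mask = dmask,
                 mask = mask),
            class = "clutch_polygons")
}

#' @export
print.clutch_polygons <- function(x, ...) {
  cat(sprintf("<clutch_polygons> %d polygons, total area %.6g nm^2\n",
              length(x$ids), sum(x$areas)))
  invisible(x)
}

#' Assign DNA localizations to clutch polygons
#'
#' Each DNA localization (already clipped to the mask) is assigned to the
#' clutch whose centroid is nearest, i.e. to the Voronoi polygon containing
#' it; boundary ties resolve to the lower clutch id. The assignment
#' conserves counts: every localization belongs to exactly one clutch.
#'
#' @param dna A [loc_table()] clipped to the mask.
#' @param polygons A [clutch_voronoi()] result.
#' @return Integer vector: for each DNA record, the index (into
#'   `polygons$ids`) of its clutch.
#' @export
assign_dna <- function(dna, polygons) {
  cpp_assign_nearest(dna$x, dna$y,
                     polygons$centroids[, 1], polygons$centroids[, 2])
}

#' Radial DNA density profiles around clutch centroids
#'
#' For each clutch, disks of increasing radius (steps of `dr`, default
#' 10 nm) are drawn at the centroid and clipped to the clutch's Voronoi
#' polygon and the nuclear mask; the cumulative density at radius r is the
#' number of assigned DNA localizations within the clipped disk divided by
#' its area. Annulus quantities follow by differencing. Disk-polygon
#' intersections use 128-vertex polygonized circles (area error < 0.1%).
#'
#' @param polygons A [clutch_voronoi()] result.
#' @param dna A [loc_table()] clipped to the mask.
#' @param dr Radial step (nm, > 0).
#' @param r_max Largest radius (nm, multiple of `dr`).
#' @param assignment Optional precomputed [assign_dna()] vector.
#' @param cell_id Replicate (nucleus) label attached to every clutch.
#' @return A `radial_profiles` object: `radii`, matrices `area` and `count`
#'   (clutch x radius, cumulative), `total_count` (per polygon),
#'   `cum_density`, plus the polygon metadata.
#' @export
radial_profile <- function(polygons, dna, dr = 10, r_max = 200,
                           assignment = NULL, cell_id = 1L) {
  stopifnot(dr > 0)
  if (abs(r_max / dr - round(r_max / dr)) > 1e-9)
    stop("r_max must be a multiple of dr")
  radii <- seq(dr, r_max, by = dr)
  n <- length(polygons$ids)
  if (is.null(assignment)) assignment <- assign_dna(dna, polygons)
  area <- cpp_clipped_disk_areas(polygons$cells, polygons$centroids[, 1],
                                 polygons$centroids[, 2], radii,
                                 .mask_polys(polygons$mask),
                                 polygons$dist_to_mask, 128L)
  # cumulative counts: distance of each DNA record to its assigned centroid
  d <- sqrt((dna$x - polygons$centroids[assignment, 1])^2 +
              (dna$y - polygons$centroids[assignment, 2])^2)
  bin <- ceiling(pmax(d, 1e-12) / dr)
  inr <- bin <= length(radii)   # beyond r_max: counted in totals only
  counts <- matrix(tabulate(assignment[inr] + n * (bin[inr] - 1L),
                            nbins = n * length(radii)),
                   nrow = n)
  cum <- t(apply(counts, 1, cumsum))
  total <- tabulate(assignment, nbins = n)
  dens <- cum / area
  dens[area <= 0] <- NA_real_   # flagged: zero clipped area at that radius
  structure(list(radii = radii, area = area, count = cum,
                 cum_density = dens, total_count = total,
                 ids = polygons$ids, cell_id = rep(cell_id, n),
                 dr = dr),
            class = "radial_profiles")
}

#' @export
print.radial_profiles <- function(x, ...) {
  cat(sprintf("<radial_profiles> %d clutches, radii %g..%g nm (dr = %g)\n",
              length(x$ids), min(x$radii), max(x$radii), x$dr))
  invisible(x)
}

.bind_profiles <- function(profiles) {
  if (inherits(profiles, "radial_profiles")) return(profiles)
  stopifnot(length(profiles) >= 1)
  r0 <- profiles[[1]]$radii
  for (p in profiles)
    if (!isTRUE(all.equal(p$radii, r0))) stop("profiles have mismatched radii")
  structure(list(radii = r0,
                 area = do.call(rbind, lapply(profiles, `[[`, "area")),
                 count = do.call(rbind, lapply(profiles, `[[`, "count")),
                 cum_density = do.call(rbind, lapply(profiles, `[[`, "cum_density")),
                 total_count = unlist(lapply(profiles, `[[`, "total_count")),
                 ids = unlist(lapply(profiles, `[[`, "ids")),
                 cell_id = unlist(lapply(profiles, `[[`, "cell_id")),
                 dr = profiles[[1]]$dr),
            class = "radial_profiles")
}

.radius_index <- function(profiles, r) {
  i <- match(TRUE, abs(profiles$radii - r) < 1e-9)
  if (is.na(i)) stop("profiles do not reach radius ", r)
  i
}

#' Clutch-associated DNA fraction
#'
#' The percentage of DNA localizations falling within the clipped search
#' disk of radius `r` (default 120 nm, about 2.5 clutch standard deviations)
#' over the total DNA localizations in the polygons. Reported pooled and per
#' replicate cell.
#'
#' @param profiles A [radial_profile()] result or list thereof.
#' @param r Search radius (nm).
#' @return List `percent` (pooled), `per_cell` (named vector).
#' @export
associated_fraction <- function(profiles, r = 120) {
  p <- .bind_profiles(profiles)
  i <- .radius_index(p, r)
  tot <- sum(p$total_count)
  if (tot == 0) stop("zero total DNA")
  per_cell <- vapply(split(seq_along(p$ids), p$cell_id), function(ix) {
    100 * sum(p$count[ix, i]) / sum(p$total_count[ix])
  }, numeric(1))
  list(percent = 100 * sum(p$count[, i]) / tot, per_cell = per_cell)
}

#' Fraction of clutches co-localized with DNA
#'
#' Percent of clutches with more than `min_locs` DNA localizations (strict
#' inequality) inside the clipped disk of radius `r`.
#'
#' @inheritParams associated_fraction
#' @param min_locs Count threshold (default 5).
#' @return Percent of clutches.
#' @export
colocalized_clutch_fraction <- function(profiles, r = 120, min_locs = 5) {
  p <- .bind_profiles(profiles)
  i <- .radius_index(p, r)
  100 * mean(p$count[, i] > min_locs)
}

#' Annulus similarity matrix (Kruskal-Wallis)
#'
#' For each pair of annuli (10 nm thick rings of increasing radius), a
#' two-group Kruskal-Wallis test compares the per-clutch annulus densities
#' pooled over all clutches of all cells; the p-value is the similarity
#' (high p = similar density distributions). The diagonal is not computed.
#'
#' @param profiles A [radial_profile()] result or list thereof.
#' @param use `"annulus"` (default; 10 nm rings) or `"disk"` (cumulative
#'   clipped disks).
#' @return A `similarity_matrix`: symmetric p-value matrix with NA diagonal,
#'   `radii` (outer radius of each annulus), and the sample matrix.
#' @export
similarity_matrix <- function(profiles, use = c("annulus", "disk")) {
  use <- match.arg(use)
  p <- .bind_profiles(profiles)
  nr <- length(p$radii)
  if (nr < 2) stop("need >= 2 annuli")
  if (use == "annulus") {
    darea <- cbind(p$area[, 1], p$area[, -1, drop = FALSE] -
                     p$area[, -nr, drop = FALSE])
    dcount <- cbind(p$count[, 1], p$count[, -1, drop = FALSE] -
                      p$count[, -nr, drop = FALSE])
    samples <- dcount / darea
    samples[darea <= 1e-9] <- NA_real_
  } else {
    samples <- p$cum_density
  }
  P <- matrix(NA_real_, nr, nr)
  for (j in seq_len(nr - 1)) {
    sj <- samples[, j]
    for (k in seq((j + 1), nr)) {
      sk <- samples[, k]
      a <- sj[!is.na(sj)]; b <- sk[!is.na(sk)]
      if (length(a) < 2 || length(b) < 2) next  # excluded pair, flagged NA
      P[j, k] <- P[k, j] <- suppressWarnings(
        kruskal.test(list(a, b))$p.value)
    }
  }
  structure(list(p = P, radii = p$radii, use = use),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d annuli (%s), %.1f%% of pairs p < 0.05\n",
              length(x$radii), x$use,
              100 * mean(x$p[upper.tri(x$p)] < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Clutch-DNA transition radius
#'
#' Formalizes the visually drawn switch from low to high similarity in the
#' annulus matrix: the smallest radius r* such that every annulus pair with
#' both radii above r* has p >= alpha while at least one pair involving a
#' radius at or below r* has p < alpha. `NA` when no switch exists (e.g.
#' uniform DNA).
#'
#' @param matrix A [similarity_matrix()].
#' @param alpha Significance threshold (default 0.05).
#' @return Radius in nm, or `NA_real_` (not determined).
#' @export
transition_radius <- function(matrix, alpha = 0.05) {
  P <- matrix$p
  radii <- matrix$radii
  for (rstar in c(0, radii)) {
    hi <- which(radii > rstar)
    lo <- which(radii <= rstar)
    sub <- P[hi, hi, drop = FALSE]
    all_similar <- all(sub[upper.tri(sub)] >= alpha, na.rm = TRUE)
    below <- if (length(lo)) any(P[lo, , drop = FALSE] < alpha, na.rm = TRUE)
    else FALSE
    if (all_similar && below) return(rstar)
  }
  NA_real_
}

#' Nearest-neighbour distances between clutch centroids
#'
#' Per-clutch distance to the closest other clutch centroid; optionally
#' restricted to neighbours within the same island (clutches in singleton
#' islands are then omitted and counted).
#'
#' @param clutches A [segment_clutches()] result (with islands assigned for
#'   the restricted variant).
#' @param same_island_only Restrict neighbours to the clutch's island.
#' @return data.frame `id, neighbor, nnd` (+ attribute `n_omitted`).
#' @export
nnd <- function(clutches, same_island_only = FALSE) {
  df <- clutches$clutches
  if (nrow(df) < 2) stop("need >= 2 clutches")
  if (!same_island_only) {
    nn <- cpp_nearest_neighbor(df$x, df$y)
    out <- data.frame(id = df$id, neighbor = df$id[nn$index], nnd = nn$dist)
    attr(out, "n_omitted") <- 0L
    return(out)
  }
  if (all(is.na(df$island))) stop("islands not assigned; run group_islands()")
  res <- list(); omitted <- 0L
  for (isl in unique(df$island)) {
    sub <- df[df$island == isl, , drop = FALSE]
    if (nrow(sub) < 2) { omitted <- omitted + nrow(sub); next }
    nn <- cpp_nearest_neighbor(sub$x, sub$y)
    res[[length(res) + 1]] <- data.frame(id = sub$id,
                                         neighbor = sub$id[nn$index],
                                         nnd = nn$dist)
  }
  out <- if (length(res)) do.call(rbind, res)
  else data.frame(id = integer(), neighbor = integer(), nnd = numeric())
  attr(out, "n_omitted") <- omitted
  out
}

#' DNA density versus clutch nearest-neighbour distance
#'
#' Groups same-island NNDs into bins (default 20 nm); per replicate cell,
#' the mean cumulative DNA density within `r` (default 70 nm) of the clutch
#' centroid is computed over the clutches in each bin; the curve is the
#' across-cell mean with standard deviation per bin.
#'
#' @param profiles A [radial_profile()] result or a per-cell list.
#' @param nnd_tables An [nnd()] result (same-island restricted) or a per-cell
#'   list parallel to `profiles` (clutch ids are only unique within a cell).
#' @param r Search radius (nm, default 70).
#' @param bin NND bin width (nm, default 20).
#' @param max_nnd Largest NND bin edge; larger NNDs fall in the last bin.
#' @return data.frame `nnd_mid, mean, sd, n_cells`.
#' @export
density_vs_nnd <- function(profiles, nnd_tables, r = 70, bin = 20,
                           max_nnd = 300) {
  if (inherits(profiles, "radial_profiles")) profiles <- list(profiles)
  if (is.data.frame(nnd_tables)) nnd_tables <- list(nnd_tables)
  stopifnot(length(profiles) == length(nnd_tables))
  edges <- seq(0, max_nnd, by = bin)
  nb <- length(edges) - 1
  mat <- vapply(seq_along(profiles), function(ci) {
    p <- profiles[[ci]]
    nt <- nnd_tables[[ci]]
    i <- .radius_index(p, r)
    key <- match(nt$id, p$ids)
    dens <- p$cum_density[key, i]
    bidx <- findInterval(pmin(nt$nnd, max_nnd - 1e-9), edges)
    as.numeric(tapply(dens, factor(bidx, levels = seq_len(nb)), mean,
                      na.rm = TRUE))
  }, numeric(nb))
  mat <- matrix(mat, nrow = nb)
  data.frame(nnd_mid = edges[-length(edges)] + bin / 2,
             mean = rowMeans(mat, na.rm = TRUE),
             sd = apply(mat, 1, stats::sd, na.rm = TRUE),
             n_cells = rowSums(!is.na(mat)))
}

#' DNA density versus clutch size
#'
#' Clutches are binned by hull area; for each search radius (default 30 to
#' 100 nm) the mean and sd of the cumulative density per area bin is
#' reported, together with a Spearman rank correlation of density versus
#' area.
#'
#' @param profiles A [radial_profile()] result or list thereof.
#' @param clutches A `clutch_set` (or data.frame with `id`, `area`) for the
#'   hull areas.
#' @param radii Search radii (nm).
#' @param n_bins Number of (quantile) area bins.
#' @return List `curve` (data.frame radius, bin, area_mid, mean, sd) and
#'   `correlation` (data.frame radius, rho, p.value).
#' @export
density_vs_size <- function(profiles, clutches, radii = seq(30, 100, by = 10),
                            n_bins = 8) {
  p <- .bind_profiles(profiles)
  df <- if (inherits(clutches, "clutch_set")) clutches$clutches else clutches
  area <- df$area[match(p$ids, df$id)]
  qs <- unique(quantile(area, seq(0, 1, length.out = n_bins + 1), na.rm = TRUE))
  bidx <- cut(area, qs, include.lowest = TRUE, labels = FALSE)
  curve <- list(); corr <- list()
  for (r in radii) {
    i <- .radius_index(p, r)
    dens <- p$cum_density[, i]
    m <- tapply(dens, bidx, mean, na.rm = TRUE)
    s <- tapply(dens, bidx, stats::sd, na.rm = TRUE)
    am <- tapply(area, bidx, mean, na.rm = TRUE)
    curve[[length(curve) + 1]] <- data.frame(radius = r,
                                             bin = as.integer(names(m)),
                                             area_mid = as.numeric(am),
                                             mean = as.numeric(m),
                                             sd = as.numeric(s))
    ok <- is.finite(dens) & is.finite(area)
    ct <- suppressWarnings(cor.test(area[ok], dens[ok], method = "spearman"))
    corr[[length(corr) + 1]] <- data.frame(radius = r,
                                           rho = unname(ct$estimate),
                                           p.value = ct$p.value)
  }
  list(curve = do.call(rbind, curve), correlation = do.call(rbind, corr))
}

#' Rigid-shift randomization control
#'
#' Translates all DNA coordinates by `(+shift, +shift)` nm; rerunning the
#' radial analysis on the shifted table probes how registration errors of
#' that size would degrade the clutch-DNA signal.
#'
#' @param dna A [loc_table()].
#' @param shift Shift in nm applied to both x and y.
#' @return The shifted [loc_table()].
#' @export
shift_control <- function(dna, shift) {
  out <- dna
  out$x <- dna$x + shift
  out$y <- dna$y + shift
  out
}

#' Clutch subsampling control
#'
#' Seeded uniform random subset of the clutches; downstream similarity
#' analysis on the subset probes how many clutches the transition-radius
#' estimate needs.
#'
#' @param clutches A [segment_clutches()] result.
#' @param fraction Fraction of clutches to keep (0 < fraction <= 1).
#' @param seed Integer seed.
#' @return A `clutch_set` restricted to the sampled clutches.
#' @export
subsample_control <- function(clutches, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  df <- clutches$clutches
  n <- nrow(df)
  if (fraction == 1) return(clutches)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sort(sample.int(n, max(1L, round(fraction * n))))
  out <- clutches
  out$clutches <- df[keep, , drop = FALSE]
  out$members <- clutches$members[keep]
  out
}

#' Plot an annulus similarity matrix
#'
#' Heatmap of the pairwise p-values with the conventional color coding:
#' p = 0.0001 in blue through p = 0.05 and above in yellow; the diagonal
#' (not computed) is drawn white.
#'
#' @param sm A [similarity_matrix()] result.
#' @param lo,hi P-value color-scale endpoints.
#' @param ... Passed to [graphics::image()].
#' @export
plot_similarity <- function(sm, lo = 1e-4, hi = 0.05, ...) {
  P <- pmin(pmax(sm$p, lo), hi)
  pal <- grDevices::colorRampPalette(c("#08306b", "#2171b5", "#41ab5d",
                                       "#fee391", "#ffff00"))(64)
  graphics::image(sm$radii, sm$radii, log10(P), col = pal,
                  zlim = log10(c(lo, hi)),
                  xlab = "annulus outer radius (nm)",
                  ylab = "annulus outer radius (nm)", ...)
  invisible(sm)
}
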