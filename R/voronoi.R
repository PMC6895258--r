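# Voronoi tessellation density analysis: per-localization cell areas (2D) or
# volumes (3D) clipped to the nuclear mask, local density = 1 / measure,
# compaction statistics and between-condition distribution comparison.

.jitter_duplicates <- function(x, y, mag = 1e-6) {
  key <- paste(x, y)
  dup <- duplicated(key)
  if (any(dup)) {
    # deterministic jitter keyed by record index; magnitude <= 1e-6 nm
    i <- which(dup)
    ang <- (i %% 360) * pi / 180
    x[i] <- x[i] + mag * cos(ang) * (1 + (i %% 7)) / 7
    y[i] <- y[i] + mag * sin(ang) * (1 + (i %% 7)) / 7
  }
  list(x = x, y = y)
}

#' Voronoi tessellation of a localization point cloud
#'
#' Partitions the usable mask region (boundary minus exclusions) into one
#' cell per localization; the local density at each point is the inverse of
#' its cell measure (area in 2D, volume in 3D). Cells extending beyond the
#' nuclear periphery or into nucleolar exclusions are clipped; in 3D the
#' clipping region is the prism of the mask polygon over the z-slab.
#' Duplicate coordinates are jittered deterministically by <= 1e-6 nm.
#'
#' @param table A [loc_table()] (with `z` for `dimension = 3`), already
#'   restricted to the mask (points outside are dropped with a warning).
#' @param mask A [nuclear_mask()].
#' @param dimension 2 or 3.
#' @param z_slab For 3D: `c(zlo, zhi)` of the slab (default range of z).
#' @return A `voronoi_map`: data.frame `cells` (id, measure, density,
#'   clipped), the mask, dimension, and (2D only) the cell polygons.
#' @export
tessellate <- function(table, mask, dimension = 2, z_slab = NULL) {
  stopifnot(dimension %in% c(2, 3))
  inside <- cpp_points_in_polygon(table$x, table$y, mask$boundary, 1e-9)
  for (ex in mask$exclusions)
    inside <- inside & !cpp_points_in_polygon(table$x, table$y, ex, 1e-9)
  if (!all(inside)) {
    warning(sum(!inside), " localizations outside usable mask dropped")
    table <- table[inside, , drop = FALSE]
  }
  n <- nrow(table)
  if (dimension == 2 && n < 4) stop("need >= 4 points for 2D tessellation")
  if (dimension == 3 && n < 5) stop("need >= 5 points for 3D tessellation")
  jj <- .jitter_duplicates(table$x, table$y)
  if (dimension == 2) {
    if (length(unique(jj$x)) == 1 || length(unique(jj$y)) == 1)
      stop("tessellation error: points are collinear")
    bb <- .mask_bbox(mask, pad = 1)
    cells <- cpp_voronoi2d(jj$x, jj$y, bb[1], bb[2], bb[3], bb[4])
    raw_area <- vapply(cells, function(m) abs(cpp_polygon_area(m)), numeric(1))
    area <- cpp_masked_areas(cells, .mask_polys(mask))
    clipped <- abs(area - raw_area) > 1e-9 * pmax(raw_area, 1)
    if (any(area <= 0)) warning(sum(area <= 0), " degenerate cells (zero area)")
    df <- data.frame(id = seq_len(n), measure = area, density = 1 / area,
                     clipped = clipped)
    structure(list(cells = df, polygons = cells, mask = mask, dimension = 2L,
                   n = n),
              class = "voronoi_map")
  } else {
    if (is.null(table$z)) stop("3D tessellation requires z")
    if (is.null(z_slab)) z_slab <- range(table$z)
    vol <- cpp_voronoi3d_volumes(jj$x, jj$y, table$z, .mask_polys(mask),
                                 z_slab[1], z_slab[2])
    df <- data.frame(id = seq_len(n), measure = vol, density = 1 / vol,
                     clipped = NA)
    structure(list(cells = df, polygons = NULL, mask = mask, dimension = 3L,
                   n = n, z_slab = z_slab),
              class = "voronoi_map")
  }
}

#' @export
print.voronoi_map <- function(x, ...) {
  cat(sprintf("<voronoi_map> %dD, %d cells, total measure %.6g %s\n",
              x$dimension, nrow(x$cells), sum(x$cells$measure),
              if (x$dimension == 2) "nm^2" else "nm^3"))
  invisible(x)
}

#' Heterochromatin / euchromatin compaction fold
#'
#' Ratio of the mean Voronoi density of 'heterochromatic' cells (area at or
#' below the `hetero_pct` area percentile, default the smallest 15%) to the
#' mean density of 'euchromatic' cells (area at or above the `eu_pct`
#' percentile, default the largest 15%).
#'
#' @param map A [tessellate()] result with >= 100 cells.
#' @param hetero_pct,eu_pct Area percentiles (0-100).
#' @param weight `"count"` (default): plain mean density over cells in the
#'   class; `"area"`: area-weighted mean density, i.e. class localization
#'   count / class area.
#' @return The fold ratio (dimensionless).
#' @export
compaction_fold <- function(map, hetero_pct = 15, eu_pct = 85,
                            weight = c("count", "area")) {
  weight <- match.arg(weight)
  cells <- map$cells[map$cells$measure > 0, ]
  if (nrow(cells) < 100) stop("need >= 100 cells")
  qh <- quantile(cells$measure, hetero_pct / 100)
  qe <- quantile(cells$measure, eu_pct / 100)
  het <- cells[cells$measure <= qh, ]
  eu <- cells[cells$measure >= qe, ]
  if (!nrow(het) || !nrow(eu)) stop("empty percentile class")
  if (weight == "count") mean(het$density) / mean(eu$density)
  else (nrow(het) / sum(het$measure)) / (nrow(eu) / sum(eu$measure))
}

#' Log-binned cumulative Voronoi density distributions
#'
#' Per replicate (cell/nucleus), the normalized cumulative histogram of cell
#' densities over `n_bins` logarithmically spaced bins; the median and 25-75
#' interquartile band are computed across replicates per bin. Default bin
#' ranges: 0.1e-9 to 0.94 nm^-2 in 2D and 5e-7 to 0.0025 nm^-3 in 3D.
#'
#' @param maps A list of [tessellate()] results (one per replicate).
#' @param bin_lo,bin_hi Density bin range; defaults chosen by dimension.
#' @param n_bins Number of log-spaced bin edges (300).
#' @return A `density_distribution`: `edges`, per-replicate cumulative matrix
#'   (bins x replicates), `median`, `q25`, `q75`.
#' @export
density_distribution <- function(maps, bin_lo = NULL, bin_hi = NULL,
                                 n_bins = 300) {
  if (inherits(maps, "voronoi_map")) maps <- list(maps)
  if (!length(maps)) stop("need >= 1 replicate map")
  dim1 <- maps[[1]]$dimension
  if (is.null(bin_lo)) bin_lo <- if (dim1 == 2) 0.1e-9 else 5e-7
  if (is.null(bin_hi)) bin_hi <- if (dim1 == 2) 0.94 else 0.0025
  stopifnot(bin_lo < bin_hi)
  edges <- exp(seq(log(bin_lo), log(bin_hi), length.out = n_bins))
  cum <- vapply(maps, function(m) {
    d <- m$cells$density[is.finite(m$cells$density)]
    out_of_range <- sum(d < bin_lo | d > bin_hi)
    if (out_of_range)
      warning(out_of_range, " densities outside bin range counted in end bins")
    counts <- findInterval(d, edges, all.inside = TRUE)
    h <- tabulate(counts, nbins = n_bins)
    cumsum(h) / sum(h)
  }, numeric(n_bins))
  structure(list(edges = edges,
                 cumulative = cum,
                 median = apply(cum, 1, median),
                 q25 = apply(cum, 1, quantile, 0.25),
                 q75 = apply(cum, 1, quantile, 0.75),
                 dimension = dim1),
            class = "density_distribution")
}

#' Compare two density distributions
#'
#' Two-sample Kolmogorov-Smirnov test applied to the per-bin median
#' cumulative curves of the two conditions (the literal reading of the
#' reference analysis); a KS test on the pooled per-cell densities of each
#' condition is reported alongside as a statistically conventional secondary.
#'
#' @param a,b [density_distribution()] objects with identical binning.
#' @param maps_a,maps_b Optional lists of [tessellate()] maps for the pooled
#'   secondary test.
#' @return List with `statistic` (KS D), `p.value`, and optionally
#'   `pooled_statistic`, `pooled_p.value`.
#' @export
compare_distributions <- function(a, b, maps_a = NULL, maps_b = NULL) {
  if (length(a$edges) != length(b$edges) ||
      any(abs(a$edges - b$edges) > 1e-12 * a$edges))
    stop("mismatched bins")
  if (isTRUE(all.equal(a$median, b$median))) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    kt <- suppressWarnings(ks.test(a$median, b$median))
    res <- list(statistic = unname(kt$statistic), p.value = kt$p.value)
  }
  if (!is.null(maps_a) && !is.null(maps_b)) {
    da <- unlist(lapply(maps_a, function(m) m$cells$density))
    db <- unlist(lapply(maps_b, function(m) m$cells$density))
    kp <- suppressWarnings(ks.test(da, db))
    res$pooled_statistic <- unname(kp$statistic)
    res$pooled_p.value <- kp$p.value
  }
  res
}

#' Color assignment for Voronoi density maps
#'
#' Maps densities onto a `[lo, hi]` display scale covering 99% of polygons
#' (default 0.001 nm^-2 blue to 0.02 nm^-2 yellow); the largest
#' `black_tail` fraction of polygons by area (default 0.5%) is assigned a
#' sentinel black class. Ties at the area cutoff are broken by cell id.
#'
#' @param map A [tessellate()] result.
#' @param lo,hi Density scale endpoints (nm^-2).
#' @param black_tail Fraction of largest-area polygons set to black.
#' @return data.frame `id, value` (0-1 scale position, NA for black),
#'   `black` flag.
#' @export
colorize <- function(map, lo = 0.001, hi = 0.02, black_tail = 0.005) {
  cells <- map$cells
  n <- nrow(cells)
  if (!n) stop("empty map")
  n_black <- floor(black_tail * n)
  ord <- order(-cells$measure, cells$id)  # largest area first; ties by id
  black <- logical(n)
  if (n_black > 0) black[ord[seq_len(n_black)]] <- TRUE
  val <- (log10(pmin(pmax(cells$density, lo), hi)) - log10(lo)) /
    (log10(hi) - log10(lo))
  val[black] <- NA_real_
  data.frame(id = cells$id, value = val, black = black)
}
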