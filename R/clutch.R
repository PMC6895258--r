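# Nucleosome-clutch segmentation of H2B localizations, island grouping, and
# per-dataset quality metrics (occupancy, Nyquist sampling, clustered area,
# clusters per island, localization precision, FRC resolution) with QC gating.

.hull_area <- function(x, y, pooled_sd) {
  if (length(x) >= 3) {
    h <- grDevices::chull(x, y)
    if (length(h) >= 3) {
      a <- abs(cpp_polygon_area(cbind(x[h], y[h])))
      if (a > 0) return(a)
    }
  }
  # <3 members or collinear: disk of radius equal to the pooled sd
  pi * pooled_sd^2
}

#' Segment H2B localizations into nucleosome clutches
#'
#' Distance-based clustering: single-linkage connected components of the
#' graph joining localizations within `eps` of one another; components with
#' fewer than `min_size` members are discarded. Defaults `eps = 40` nm
#' (about twice the median lateral localization precision) and
#' `min_size = 5`.
#'
#' @param table A [loc_table()].
#' @param eps Linkage distance (nm, > 0).
#' @param min_size Minimum localizations per retained clutch.
#' @return A `clutch_set`: data.frame `clutches` (id, x, y, sd, area,
#'   n_locs, island = NA) and `members` (list of row indices into `table`).
#' @export
segment_clutches <- function(table, eps = 40, min_size = 5) {
  stopifnot(eps > 0)
  if (nrow(table) == 0) {
    return(structure(list(clutches = data.frame(id = integer(), x = numeric(),
                                                y = numeric(), sd = numeric(),
                                                area = numeric(),
                                                n_locs = integer(),
                                                island = integer()),
                          members = list(), eps = eps),
                     class = "clutch_set"))
  }
  lab <- cpp_single_linkage(table$x, table$y, eps)
  tab <- tabulate(lab)
  keep_lab <- which(tab >= min_size)
  members <- lapply(keep_lab, function(l) which(lab == l))
  stats <- lapply(members, function(ix) {
    xs <- table$x[ix]; ys <- table$y[ix]
    sdx <- stats::sd(xs); sdy <- stats::sd(ys)
    psd <- mean(c(sdx, sdy))
    c(x = mean(xs), y = mean(ys), sd = psd,
      area = .hull_area(xs, ys, psd), n = length(ix))
  })
  df <- if (length(stats)) {
    m <- do.call(rbind, stats)
    data.frame(id = seq_along(members), x = m[, "x"], y = m[, "y"],
               sd = m[, "sd"], area = m[, "area"],
               n_locs = as.integer(m[, "n"]), island = NA_integer_)
  } else {
    data.frame(id = integer(), x = numeric(), y = numeric(), sd = numeric(),
               area = numeric(), n_locs = integer(), island = integer())
  }
  structure(list(clutches = df, members = members, eps = eps,
                 locs = table[, c("x", "y"), drop = FALSE]),
            class = "clutch_set")
}

#' @export
print.clutch_set <- function(x, ...) {
  cat(sprintf("<clutch_set> %d clutches (eps = %g nm), mean %0.1f locs/clutch\n",
              nrow(x$clutches), x$eps,
              if (nrow(x$clutches)) mean(x$clutches$n_locs) else 0))
  invisible(x)
}

#' Group clutches into islands
#'
#' Clutches are joined into one island when the minimum distance between any
#' member localization of one and any member of the other is at most `link`
#' (transitive closure). Default link distance is 1.5 x the segmentation
#' `eps`. An isolated clutch is an island of size one.
#'
#' @param clutches A [segment_clutches()] result.
#' @param link Linking distance (nm, > 0).
#' @return The `clutch_set` with the `island` column filled in, plus an
#'   `islands` summary attribute (`clutch_count` per island,
#'   `clusters_per_island` mean, `percent_isolated`).
#' @export
group_islands <- function(clutches, link = 1.5 * clutches$eps) {
  stopifnot(link > 0)
  df <- clutches$clutches
  if (!nrow(df)) return(clutches)
  # single linkage over all member localizations at the island link distance;
  # two clutches share an island iff a chain of <= link steps connects them
  ix <- unlist(clutches$members)
  cl_of <- rep(seq_along(clutches$members),
               vapply(clutches$members, length, integer(1)))
  lab <- cpp_single_linkage(clutches$locs$x[ix], clutches$locs$y[ix], link)
  island_of <- vapply(split(lab, cl_of), function(v) v[1], integer(1))
  island_ids <- as.integer(factor(island_of, levels = unique(island_of)))
  df$island <- island_ids
  out <- clutches
  out$clutches <- df
  sizes <- tabulate(island_ids)
  attr(out, "islands") <- list(
    clutch_count = sizes,
    clusters_per_island = mean(sizes),
    percent_isolated = 100 * sum(sizes == 1) / nrow(df))
  out
}

#' Localization occupancy of the nuclear area
#'
#' Localizations are binned onto two grids anchored at the mask bounding-box
#' origin: a super-resolved `fine` grid (20 nm) and a diffraction-scale
#' `coarse` grid (160 nm). Occupancy is the summed occupied fine-bin area
#' over the summed occupied coarse-bin area, in percent.
#'
#' @param table A [loc_table()].
#' @param mask A [nuclear_mask()] (grid anchor and extent).
#' @param fine,coarse Pixel sizes (nm, fine < coarse).
#' @return Percent occupancy.
#' @export
occupancy <- function(table, mask, fine = 20, coarse = 160) {
  stopifnot(fine < coarse)
  bb <- .mask_bbox(mask)
  nxf <- ceiling((bb[2] - bb[1]) / fine); nyf <- ceiling((bb[4] - bb[3]) / fine)
  nxc <- ceiling((bb[2] - bb[1]) / coarse); nyc <- ceiling((bb[4] - bb[3]) / coarse)
  occ_f <- cpp_occupied_bins(table$x, table$y, bb[1], bb[3], fine, nxf, nyf)
  occ_c <- cpp_occupied_bins(table$x, table$y, bb[1], bb[3], coarse, nxc, nyc)
  if (occ_c == 0) stop("zero occupied coarse bins: occupancy undefined")
  100 * (occ_f * fine^2) / (occ_c * coarse^2)
}

#' Nyquist sampling metric
#'
#' Estimated sampling frequency in nm per localization:
#' `(area_per_localization x slab)^(1/3)`, where the area per localization
#' uses (i) the mask (diffraction-limited) area and (ii) the summed occupied
#' 20 nm bin area as the reference. Datasets are conventionally kept when
#' both variants are at or below 32 nm/localization.
#'
#' @param table A [loc_table()].
#' @param mask A [nuclear_mask()].
#' @param slab Slice thickness (nm, default 120).
#' @param fine Fine bin size for the occupied-area variant (nm).
#' @return Named vector `c(mask = ..., occupied = ...)` in nm/localization.
#' @export
nyquist_metric <- function(table, mask, slab = 120, fine = 20) {
  n <- nrow(table)
  if (n == 0) stop("no localizations")
  bb <- .mask_bbox(mask)
  nxf <- ceiling((bb[2] - bb[1]) / fine); nyf <- ceiling((bb[4] - bb[3]) / fine)
  occ_area <- cpp_occupied_bins(table$x, table$y, bb[1], bb[3], fine,
                                nxf, nyf) * fine^2
  c(mask = (mask_usable_area(mask) / n * slab)^(1 / 3),
    occupied = (occ_area / n * slab)^(1 / 3))
}

#' Lateral localization precision from repeated localizations
#'
#' Localizations of the same emitter appearing in `min_consecutive` or more
#' strictly sequential frames are grouped into point clouds
#' (proximity-linked at `radius`); the per-cloud precision is the pooled
#' per-axis standard deviation `sqrt((sd_x^2 + sd_y^2) / 2)`. Returns the
#' median and 25-75 interquartile range over clouds.
#'
#' @param table A [loc_table()] with frames.
#' @param min_consecutive Minimum run of sequential frames (default 5).
#' @param radius Proximity-linking radius (nm).
#' @return List `median`, `q25`, `q75`, `n_clouds`, `precisions`.
#' @export
localization_precision <- function(table, min_consecutive = 5, radius = 100) {
  if (is.null(table$frame)) stop("frame indices required")
  lab <- cpp_single_linkage(table$x, table$y, radius)
  prec <- c()
  for (l in unique(lab)) {
    ix <- which(lab == l)
    if (length(ix) < min_consecutive) next
    fr <- sort(unique(table$frame[ix]))
    # maximal runs of strictly consecutive frames
    brk <- c(0, which(diff(fr) > 1), length(fr))
    for (b in seq_len(length(brk) - 1)) {
      run <- fr[(brk[b] + 1):brk[b + 1]]
      if (length(run) < min_consecutive) next
      jx <- ix[table$frame[ix] %in% run]
      sdx <- stats::sd(table$x[jx]); sdy <- stats::sd(table$y[jx])
      prec <- c(prec, sqrt((sdx^2 + sdy^2) / 2))
    }
  }
  if (!length(prec)) {
    warning("no qualifying clouds")
    return(list(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                n_clouds = 0L, precisions = numeric()))
  }
  list(median = median(prec), q25 = unname(quantile(prec, 0.25)),
       q75 = unname(quantile(prec, 0.75)), n_clouds = length(prec),
       precisions = prec)
}

#' Fourier ring correlation image resolution
#'
#' Localizations are split into random halves (seeded), each half rendered
#' as a 2D histogram image, and the ring-wise correlation of the two Fourier
#' transforms computed. The resolution is the inverse of the first spatial
#' frequency at which the smoothed FRC curve drops below `threshold`
#' (canonically 1/7).
#'
#' @param table A [loc_table()] with >= 1000 localizations.
#' @param pixel Rendering pixel size (nm, default 20).
#' @param threshold FRC crossing threshold.
#' @param seed Seed for the half-split.
#' @param smooth_span Moving-average span (rings) applied to the raw curve.
#' @return List `resolution` (nm; NA when the curve never crosses),
#'   `freq` (nm^-1), `frc` (smoothed curve).
#' @export
frc_resolution <- function(table, pixel = 20, threshold = 1 / 7, seed = 1,
                           smooth_span = 5) {
  n <- nrow(table)
  if (n < 1000) stop("need >= 1000 localizations for FRC")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- sample.int(n, n %/% 2)
  ext <- c(min(table$x), max(table$x), min(table$y), max(table$y))
  npx <- 2^ceiling(log2(max((ext[2] - ext[1]) / pixel,
                            (ext[4] - ext[3]) / pixel, 32)))
  hist2 <- function(sub) {
    ix <- pmin(npx - 1, pmax(0, floor((sub$x - ext[1]) / pixel)))
    iy <- pmin(npx - 1, pmax(0, floor((sub$y - ext[3]) / pixel)))
    m <- matrix(0, npx, npx)
    tb <- table(iy * npx + ix + 1)
    m[as.integer(names(tb))] <- as.integer(tb)
    m
  }
  i1 <- hist2(table[half, , drop = FALSE])
  i2 <- hist2(table[-half, , drop = FALSE])
  f1 <- fft(i1); f2 <- fft(i2)
  num <- Re(f1 * Conj(f2))
  d1 <- Mod(f1)^2; d2 <- Mod(f2)^2
  # ring index from FFT frequency coordinates
  k <- c(0:(npx / 2), -((npx / 2 - 1):1)) / npx
  kr <- sqrt(outer(k^2, k^2, "+"))
  ring <- pmin(round(kr * npx), npx %/% 2)
  nr <- npx %/% 2
  s_num <- tapply(num, ring, sum)
  s_d1 <- tapply(d1, ring, sum)
  s_d2 <- tapply(d2, ring, sum)
  frc <- as.numeric(s_num / sqrt(s_d1 * s_d2))[2:(nr + 1)]  # skip DC
  freq <- (1:nr) / (npx * pixel)
  w <- max(1L, as.integer(smooth_span))
  frc_s <- as.numeric(stats::filter(c(rep(frc[1], w), frc, rep(frc[length(frc)], w)),
                                    rep(1 / w, w), sides = 2))[(w + 1):(w + nr)]
  # resolution = first crossing from above the threshold; a curve that never
  # rises above it (pure noise) has no determinable resolution
  below <- which(frc_s < threshold)
  resolution <- if (length(below) && frc_s[1] >= threshold)
    1 / freq[below[1]] else NA_real_
  list(resolution = resolution, freq = freq, frc = frc_s)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a QC report for one dataset
#'
#' @param table H2B [loc_table()] for the dataset.
#' @param mask A [nuclear_mask()].
#' @param clutches A [group_islands()] result for the same table (computed
#'   if missing).
#' @param eps,min_size Segmentation parameters when `clutches` is missing.
#' @param slab Slice thickness for the Nyquist metric (nm).
#' @return A `qc_report` list: `occupancy`, `clustered_area`,
#'   `clusters_per_island`, `nyquist` (both variants), `n_locs`.
#' @export
qc_report <- function(table, mask, clutches = NULL, eps = 40, min_size = 5,
                      slab = 120) {
  if (is.null(clutches))
    clutches <- group_islands(segment_clutches(table, eps, min_size))
  isl <- attr(clutches, "islands")
  if (is.null(isl)) {
    clutches <- group_islands(clutches)
    isl <- attr(clutches, "islands")
  }
  occ <- occupancy(table, mask)
  # clustered area: hull area of in-clutch localizations over the 20 nm
  # occupied-bin area of all localizations
  bb <- .mask_bbox(mask)
  nxf <- ceiling((bb[2] - bb[1]) / 20); nyf <- ceiling((bb[4] - bb[3]) / 20)
  loc_area <- cpp_occupied_bins(table$x, table$y, bb[1], bb[3], 20,
                                nxf, nyf) * 400
  cl_area <- sum(clutches$clutches$area)
  structure(list(occupancy = occ,
                 clustered_area = 100 * cl_area / loc_area,
                 clusters_per_island = isl$clusters_per_island,
                 percent_isolated = isl$percent_isolated,
                 nyquist = nyquist_metric(table, mask, slab = slab),
                 n_locs = nrow(table),
                 n_clutches = nrow(clutches$clutches)),
            class = "qc_report")
}

#' QC gate for dataset selection
#'
#' Control datasets require occupancy > 35%, clustered area > 15% and
#' clusters per island > 3; TSA-treated datasets require occupancy > 25%,
#' clustered area > 10% and clusters per island > 1.5. All inequalities are
#' strict: a report exactly at a threshold
#' fails. An optional Nyquist gate (<= `nyquist_max` for both variants)
#' applies when the report carries the metric.
#'
#' @param report A [qc_report()] (or any list with the needed fields).
#' @param condition `"control"` or `"treated"`.
#' @param nyquist_max Maximum Nyquist metric (nm/localization); `NULL`
#'   disables that gate. Default 32.
#' @return List `pass` (flag) and `failed` (character vector of criteria).
#' @export
qc_gate <- function(report, condition = c("control", "treated"),
                    nyquist_max = 32) {
  condition <- match.arg(condition)
  th <- if (condition == "control")
    c(occupancy = 35, clustered_area = 15, clusters_per_island = 3)
  else c(occupancy = 25, clustered_area = 10, clusters_per_island = 1.5)
  failed <- character()
  for (k in names(th))
    if (!(report[[k]] > th[[k]]))
      failed <- c(failed, sprintf("%s (%.3g <= %.3g)", k, report[[k]], th[[k]]))
  if (!is.null(nyquist_max) && !is.null(report$nyquist)) {
    if (!all(report$nyquist <= nyquist_max))
      failed <- c(failed, sprintf("nyquist (%.3g > %g)",
                                  max(report$nyquist), nyquist_max))
  }
  list(pass = length(failed) == 0, failed = failed)
}
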