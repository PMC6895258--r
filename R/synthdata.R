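# Synthetic two-channel nucleus generator with known ground truth: H2B
# nucleosome clutches grouped into islands, DNA partitioned into a
# clutch-associated pool (step or Gaussian radial profile around clutch
# centers) and a uniform clutch-free pool, fiducial beads, frame-indexed
# drift, a smooth chromatic warp between channels and astigmatic
# width-vs-z encoding. Every pipeline stage is testable against the
# recorded truth without external data.

.ellipse_poly <- function(cx, cy, a, b, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

#' Nucleus geometry model
#'
#' Describes the analyzed nuclear sub-region: an elliptical boundary with
#' optional nucleolar exclusions, islands of nucleosome clutches (parent
#' Poisson process), intra-island clutch spacing, clutch localization
#' spread and localization counts.
#'
#' @param semi_axes Ellipse semi-axes (nm); default 3500 x 2500 (a manually
#'   selected, uniformly illuminated sub-region rather than a whole nucleus).
#' @param n_nucleoli Number of elliptical nucleolar exclusions.
#' @param island_density Islands per nm^2 (default 1 per um^2).
#' @param clutches_per_island_mean Mean extra clutches per island; per-island
#'   count is `1 + Poisson(mean - 1)`.
#' @param spacing_mean,spacing_min Intra-island centre spacing (nm): gamma
#'   distributed with the given mean (shape 6), floored at `spacing_min`.
#' @param clutch_sd_median,clutch_sd_sdlog Per-clutch localization spread
#'   (nm): log-normal.
#' @param locs_per_clutch_mean Mean H2B localizations per clutch (Poisson).
#' @param margin Keep island centres this far inside the boundary (nm).
#' @return A `nucleus_model` list.
#' @export
nucleus_model <- function(semi_axes = c(3500, 2500), n_nucleoli = 0,
                          island_density = 0.3e-6,
                          clutches_per_island_mean = 4,
                          spacing_mean = 220, spacing_min = 160,
                          clutch_sd_median = 20, clutch_sd_sdlog = 0.3,
                          locs_per_clutch_mean = 150,
                          margin = 400) {
  structure(as.list(environment()), class = "nucleus_model")
}

#' DNA localization model
#'
#' @param association_fraction Probability that a DNA localization is
#'   clutch-associated (drawn around a parent clutch centre) rather than
#'   background (uniform over the usable mask).
#' @param clutch_dna_radius Radial scale (nm) of the associated pool.
#' @param profile `"step"` (uniform over the disk of radius
#'   `clutch_dna_radius`; sharp transition) or `"gaussian"` (Rayleigh radius
#'   with sigma = radius / 2; smoother falloff).
#' @param density DNA localizations per nm^2 of usable mask (default 0.004,
#'   about 5e5 per full nucleus, placing the Nyquist metric near the
#'   reference 30 nm/localization). Ignored when `n_total` given.
#' @param n_total Absolute number of DNA localizations, optional.
#' @param bg_field_sdlog Log-sd of the smooth background intensity field.
#'   Clutch-free DNA is not uniform in real nuclei: its local density varies
#'   over micron scales (eu-/heterochromatin, nuclear edge). The background
#'   pool is drawn from a log-normal-weighted mixture of broad Gaussian
#'   domains over a uniform floor; 0 gives a homogeneous Poisson background.
#' @param bg_field_scale Correlation length of the background field (nm).
#' @param bg_floor Fraction of background drawn from the uniform floor.
#' @return A `dna_model` list.
#' @export
dna_model <- function(association_fraction = 0.717, clutch_dna_radius = 70,
                      profile = c("step", "gaussian"), density = 0.004,
                      n_total = NULL, bg_field_sdlog = 1.2,
                      bg_field_scale = 1000, bg_floor = 0.2) {
  profile <- match.arg(profile)
  stopifnot(association_fraction >= 0, association_fraction <= 1,
            clutch_dna_radius > 0, density >= 0)
  structure(list(association_fraction = association_fraction,
                 clutch_dna_radius = clutch_dna_radius,
                 profile = profile, density = density, n_total = n_total,
                 bg_field_sdlog = bg_field_sdlog,
                 bg_field_scale = bg_field_scale, bg_floor = bg_floor),
            class = "dna_model")
}

#' Ground-truth astigmatic calibration used by the generator
#'
#' Cubic width curves with Wx(z) - Wy(z) strictly monotone (identifiable z)
#' and positive widths over the +/- 800 nm range scanned in 10 nm steps by
#' the reference protocol.
#' @return A `z_calibration`.
#' @export
true_z_calibration <- function() {
  structure(list(cx = c(450, 0.55, 2e-4, 0), cy = c(450, -0.55, 2e-4, 0),
                 z_range = c(-800, 800), rms = c(x = 0, y = 0)),
            class = "z_calibration")
}

#' Ground-truth chromatic warp used by the generator
#'
#' A gentle second-order field: tens of nm of offset, per-mil scale error
#' and a few nm of quadratic distortion across a ~7 um field.
#' @return A `poly_warp`.
#' @export
true_poly_warp <- function() {
  structure(list(coeff_x = c(25, 1.0008, 2e-4, 3e-7, -1e-7, 1e-7),
                 coeff_y = c(-18, -3e-4, 0.9994, -1e-7, 2e-7, 3e-7),
                 rms = 0),
            class = "poly_warp")
}

#' Acquisition / distortion model
#'
#' @param noise_sd Lateral localization noise sd (nm).
#' @param frames Number of (regrouped) acquisition frames.
#' @param blink_frames Mean consecutive frames per emitter; 1 gives
#'   independent localizations, larger values produce sequential-frame point
#'   clouds for precision analysis.
#' @param z_slab Axial slab `c(zlo, zhi)` localizations are drawn from (nm).
#' @param drift_rate Per-frame linear drift `c(dx, dy, dz)` (nm/frame);
#'   `NULL` disables drift.
#' @param drift_rw_sd Per-frame random-walk drift step sd (nm).
#' @param warp True chromatic warp applied to channel b (`NULL` = none).
#' @param z_offset True rigid z offset added to channel b (nm).
#' @param astig A `z_calibration` encoding z as widths (`NULL` = no widths).
#' @param width_noise_sd Noise on encoded widths (nm).
#' @param n_beads Number of fiducial beads.
#' @param bead_noise_sd Per-frame bead localization noise (nm).
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(noise_sd = 10, frames = 10000, blink_frames = 1,
                              z_slab = c(-60, 60), drift_rate = NULL,
                              drift_rw_sd = 0, warp = NULL, z_offset = 0,
                              astig = NULL, width_noise_sd = 0,
                              n_beads = 8, bead_noise_sd = 5) {
  structure(as.list(environment()), class = "acquisition_model")
}

#' Condition presets
#'
#' The two experimental conditions the generator emulates. The presets
#' differ only in the declared fields: the clutch-associated DNA fraction
#' (control 0.717, TSA 0.627), the clutch-DNA radius (70 vs 40 nm), the
#' mean H2B localizations per clutch (TSA clutches are smaller) and the
#' intra-island spacing (mean clutch NND reduced by 5 nm under TSA).
#'
#' @param name `"control"` or `"tsa"`.
#' @return List with `nucleus` ([nucleus_model()]) and `dna` ([dna_model()]).
#' @export
condition_presets <- function(name = c("control", "tsa")) {
  name <- match.arg(name)
  if (name == "control") {
    list(nucleus = nucleus_model(locs_per_clutch_mean = 150,
                                 spacing_mean = 220),
         dna = dna_model(association_fraction = 0.717,
                         clutch_dna_radius = 70))
  } else {
    list(nucleus = nucleus_model(locs_per_clutch_mean = 90,
                                 spacing_mean = 215),
         dna = dna_model(association_fraction = 0.627,
                         clutch_dna_radius = 40))
  }
}

.sample_in_mask <- function(n, mask, margin = 0) {
  bb <- .mask_bbox(mask)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 100)
    x <- runif(m, bb[1], bb[2]); y <- runif(m, bb[3], bb[4])
    ok <- cpp_points_in_polygon(x, y, mask$boundary, 0)
    for (ex in mask$exclusions)
      ok <- ok & !cpp_points_in_polygon(x, y, ex, 0)
    if (margin > 0) {
      d <- cpp_dist_to_polygon(x, y, mask$boundary)
      for (ex in mask$exclusions)
        d <- pmin(d, cpp_dist_to_polygon(x, y, ex))
      ok <- ok & d >= margin
    }
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a two-channel synthetic nucleus
#'
#' Draws H2B localizations as isotropic Gaussians at clutch centres laid out
#' in islands, DNA localizations as a mixture of a clutch-associated pool
#' (per-clutch counts proportional to the clutch's localization count;
#' radial step or Gaussian profile) and a uniform background pool, plus
#' fiducial beads in both channels. Acquisition distortions (drift, warp,
#' z-offset, astigmatic widths) are applied separately by
#' [apply_distortions()] so the undistorted truth stays available.
#'
#' @param nucleus A [nucleus_model()].
#' @param dna A [dna_model()].
#' @param acq An [acquisition_model()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `h2b`, `dna`, `beads_a`, `beads_b` ([loc_table()]s),
#'   `mask` ([nuclear_mask()]), `truth` (clutch centres/sds/memberships,
#'   per-DNA association labels and parent clutch, bead positions, models).
#' @export
simulate_nucleus <- function(nucleus = nucleus_model(), dna = dna_model(),
                             acq = acquisition_model(), seed = 1) {
  set.seed(seed)
  a <- nucleus$semi_axes[1]; b <- nucleus$semi_axes[2]
  exclusions <- list()
  if (nucleus$n_nucleoli > 0) {
    for (k in seq_len(nucleus$n_nucleoli)) {
      cx <- runif(1, -0.4 * a, 0.4 * a); cy <- runif(1, -0.4 * b, 0.4 * b)
      exclusions[[k]] <- .ellipse_poly(cx, cy, 0.15 * a, 0.15 * b, 36)
    }
  }
  mask <- nuclear_mask(.ellipse_poly(0, 0, a, b), exclusions)
  usable <- mask_usable_area(mask)

  # --- islands and clutch centres ------------------------------------------
  n_islands <- max(1L, rpois(1, nucleus$island_density * usable))
  island_xy <- .sample_in_mask(n_islands, mask, margin = nucleus$margin)
  centers <- list(); island_of <- integer()
  for (i in seq_len(n_islands)) {
    k <- 1L + rpois(1, max(nucleus$clutches_per_island_mean - 1, 0))
    pts <- matrix(island_xy[i, ], 1, 2)
    tries <- 0L
    while (nrow(pts) < k && tries < 200L) {
      tries <- tries + 1L
      anchor <- pts[sample.int(nrow(pts), 1), ]
      d <- max(nucleus$spacing_min,
               stats::rgamma(1, shape = 6, scale = nucleus$spacing_mean / 6))
      th <- runif(1, 0, 2 * pi)
      cand <- anchor + d * c(cos(th), sin(th))
      # keep every pair of clutch centres at least spacing_min apart so
      # neighbouring clutches stay resolvable by distance-based segmentation
      if (min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          nucleus$spacing_min)
        pts <- rbind(pts, cand)
    }
    centers[[i]] <- pts
    k <- nrow(pts)
    island_of <- c(island_of, rep(i, k))
  }
  centers <- do.call(rbind, centers)
  # Matern-II style thinning across islands: overlapping islands may place
  # clutches from different parents too close for segmentation
  if (nrow(centers) > 1) {
    # keep one clutch per sub-spacing linkage component: distinct components
    # are guaranteed to be > spacing_min apart
    lab <- cpp_single_linkage(centers[, 1], centers[, 2],
                              nucleus$spacing_min * 0.999)
    keep_idx <- !duplicated(lab)
    centers <- centers[keep_idx, , drop = FALSE]
    island_of <- island_of[keep_idx]
  }
  # drop clutches that left the usable region
  ok <- cpp_points_in_polygon(centers[, 1], centers[, 2], mask$boundary, 0)
  for (ex in mask$exclusions)
    ok <- ok & !cpp_points_in_polygon(centers[, 1], centers[, 2], ex, 0)
  centers <- centers[ok, , drop = FALSE]
  island_of <- island_of[ok]
  n_clutch <- nrow(centers)

  clutch_sd <- stats::rlnorm(n_clutch, log(nucleus$clutch_sd_median),
                             nucleus$clutch_sd_sdlog)
  n_locs <- pmax(1L, rpois(n_clutch, nucleus$locs_per_clutch_mean))

  # --- H2B localizations ----------------------------------------------------
  parent <- rep(seq_len(n_clutch), n_locs)
  hx <- centers[parent, 1] + rnorm(length(parent), 0, clutch_sd[parent])
  hy <- centers[parent, 2] + rnorm(length(parent), 0, clutch_sd[parent])
  hx <- hx + rnorm(length(hx), 0, acq$noise_sd)
  hy <- hy + rnorm(length(hy), 0, acq$noise_sd)
  hz <- runif(length(hx), acq$z_slab[1], acq$z_slab[2])
  if (acq$blink_frames > 1) {
    # emitters blink in runs of consecutive frames; localizations within a
    # run share the true position, each with fresh localization noise
    nloc <- length(hx)
    run_len <- pmax(1L, rpois(nloc, acq$blink_frames))
    # treat each original draw as one emitter; expand to run_len localizations
    start <- sample.int(max(acq$frames - max(run_len), 1), nloc, replace = TRUE)
    idx <- rep(seq_len(nloc), run_len)
    off <- sequence(run_len) - 1L
    hx <- (centers[parent, 1] + rnorm(nloc, 0, clutch_sd[parent]))[idx] +
      rnorm(length(idx), 0, acq$noise_sd)
    hy <- (centers[parent, 2] + rnorm(nloc, 0, clutch_sd[parent]))[idx] +
      rnorm(length(idx), 0, acq$noise_sd)
    hz <- runif(nloc, acq$z_slab[1], acq$z_slab[2])[idx]
    hframe <- start[idx] + off
    parent <- parent[idx]
  } else {
    hframe <- sample.int(acq$frames, length(hx), replace = TRUE) - 1L
  }
  h2b <- loc_table(hx, hy, z = hz, frame = hframe, channel = "h2b",
                   provenance = "synthetic")

  # --- DNA localizations ----------------------------------------------------
  n_dna <- if (!is.null(dna$n_total)) dna$n_total
  else round(dna$density * usable)
  n_assoc <- round(dna$association_fraction * n_dna)
  n_bg <- n_dna - n_assoc
  if (n_assoc > 0 && n_clutch > 0) {
    pa <- sample.int(n_clutch, n_assoc, replace = TRUE, prob = n_locs)
    R <- dna$clutch_dna_radius
    r <- if (dna$profile == "step") R * sqrt(runif(n_assoc))
    else abs(rnorm(n_assoc, 0, R / 2))
    th <- runif(n_assoc, 0, 2 * pi)
    dx <- centers[pa, 1] + r * cos(th)
    dy <- centers[pa, 2] + r * sin(th)
    # redraw the rare associated draws that leave the usable region so that
    # the realized association fraction matches the model parameter
    in_usable <- function(x, y) {
      ok <- cpp_points_in_polygon(x, y, mask$boundary, 0)
      for (ex in mask$exclusions)
        ok <- ok & !cpp_points_in_polygon(x, y, ex, 0)
      ok
    }
    bad <- which(!in_usable(dx, dy))
    for (it in 1:50) {
      if (!length(bad)) break
      r2 <- if (dna$profile == "step") R * sqrt(runif(length(bad)))
      else abs(rnorm(length(bad), 0, R / 2))
      th2 <- runif(length(bad), 0, 2 * pi)
      dx[bad] <- centers[pa[bad], 1] + r2 * cos(th2)
      dy[bad] <- centers[pa[bad], 2] + r2 * sin(th2)
      bad <- bad[!in_usable(dx[bad], dy[bad])]
    }
  } else {
    pa <- integer(); dx <- numeric(); dy <- numeric()
  }
  bg <- if (is.null(dna$bg_field_sdlog) || dna$bg_field_sdlog <= 0 ||
            n_bg == 0) {
    .sample_in_mask(n_bg, mask)
  } else {
    # smooth heterogeneous background: log-normal-weighted Gaussian domains
    # over a uniform floor (micron-scale chromatin density variation)
    n_dom <- max(3L, round(usable / 8e6))
    dom_xy <- .sample_in_mask(n_dom, mask)
    w <- stats::rlnorm(n_dom, 0, dna$bg_field_sdlog)
    n_floor <- rbinom(1, n_bg, dna$bg_floor)
    comp <- sample.int(n_dom, n_bg - n_floor, replace = TRUE, prob = w)
    pts <- matrix(NA_real_, n_bg - n_floor, 2)
    left <- seq_len(nrow(pts))
    for (it in 1:200) {
      if (!length(left)) break
      cand <- dom_xy[comp[left], , drop = FALSE] +
        matrix(rnorm(2 * length(left), 0, dna$bg_field_scale), ncol = 2)
      ok <- cpp_points_in_polygon(cand[, 1], cand[, 2], mask$boundary, 0)
      for (ex in mask$exclusions)
        ok <- ok & !cpp_points_in_polygon(cand[, 1], cand[, 2], ex, 0)
      pts[left[ok], ] <- cand[ok, , drop = FALSE]
      left <- left[!ok]
    }
    if (length(left)) pts[left, ] <- .sample_in_mask(length(left), mask)
    rbind(pts, .sample_in_mask(n_floor, mask))
  }
  # DNA is modeled directly at the localization level: the association
  # fraction and clutch-DNA radius are properties of the localization map
  # (what the radial analysis measures), so no extra lateral noise is added
  dxall <- c(dx, bg[, 1])
  dyall <- c(dy, bg[, 2])
  dz <- runif(n_dna, acq$z_slab[1], acq$z_slab[2])
  dframe <- sample.int(acq$frames, n_dna, replace = TRUE) - 1L
  dna_tab <- loc_table(dxall, dyall, z = dz, frame = dframe, channel = "dna",
                       provenance = "synthetic")
  assoc_label <- c(rep(TRUE, n_assoc), rep(FALSE, n_bg))
  parent_clutch <- c(pa, rep(NA_integer_, n_bg))

  # --- fiducial beads -------------------------------------------------------
  bead_xy <- .sample_in_mask(acq$n_beads, mask, margin = 200)
  bead_z <- runif(acq$n_beads, -100, 100)
  mk_beads <- function() {
    idx <- rep(seq_len(acq$n_beads), each = acq$frames)
    loc_table(bead_xy[idx, 1] + rnorm(length(idx), 0, acq$bead_noise_sd),
              bead_xy[idx, 2] + rnorm(length(idx), 0, acq$bead_noise_sd),
              z = bead_z[idx] + rnorm(length(idx), 0, acq$bead_noise_sd),
              frame = rep(seq_len(acq$frames) - 1L, acq$n_beads),
              channel = "bead", provenance = "synthetic")
  }
  beads_a <- mk_beads()
  beads_b <- mk_beads()

  truth <- list(centers = centers, island_of = island_of,
                clutch_sd = clutch_sd, n_locs = n_locs,
                h2b_parent = parent,
                dna_associated = assoc_label, dna_parent = parent_clutch,
                bead_positions = cbind(bead_xy, z = bead_z),
                nucleus = nucleus, dna = dna, acq = acq, seed = seed)
  list(h2b = h2b, dna = dna_tab, beads_a = beads_a, beads_b = beads_b,
       mask = mask, truth = truth)
}

#' Build a linear (+ optional random-walk) drift trajectory
#'
#' @param frames Number of frames (trajectory covers 0..frames-1).
#' @param rate Per-frame displacement `c(dx, dy, dz)` (nm/frame).
#' @param rw_sd Random-walk step sd (nm); uses the current RNG stream.
#' @return A `drift_trajectory` zeroed at frame 0.
#' @export
make_drift <- function(frames, rate = c(0.02, 0.015, 0.01), rw_sd = 0) {
  fr <- seq_len(frames) - 1L
  tr <- data.frame(frame = fr,
                   dx = rate[1] * fr, dy = rate[2] * fr, dz = rate[3] * fr)
  if (rw_sd > 0) {
    tr$dx <- tr$dx + cumsum(rnorm(frames, 0, rw_sd))
    tr$dy <- tr$dy + cumsum(rnorm(frames, 0, rw_sd))
    tr$dz <- tr$dz + cumsum(rnorm(frames, 0, rw_sd))
  }
  tr$dx <- tr$dx - tr$dx[1]; tr$dy <- tr$dy - tr$dy[1]
  tr$dz <- tr$dz - tr$dz[1]
  structure(tr, class = c("drift_trajectory", "data.frame"),
            reference_frame = 0L)
}

#' Apply acquisition distortions to a simulated nucleus
#'
#' Channel b (H2B/PAINT plus its beads) is warped by the true polynomial and
#' shifted axially by the true z offset; both channels receive the
#' frame-indexed drift; astigmatic widths are encoded from true z via the
#' true calibration. The inverse of the full registration workflow.
#'
#' @param sim A [simulate_nucleus()] result.
#' @param acq The [acquisition_model()] holding the true distortions.
#' @return The sim list with distorted tables and a `truth$transforms` entry
#'   (`warp`, `drift`, `z_offset`, `astig`).
#' @export
apply_distortions <- function(sim, acq = sim$truth$acq) {
  drift <- NULL
  if (!is.null(acq$drift_rate) || acq$drift_rw_sd > 0) {
    rate <- if (is.null(acq$drift_rate)) c(0, 0, 0) else acq$drift_rate
    drift <- make_drift(acq$frames, rate, acq$drift_rw_sd)
  }
  warp_b <- function(tab) {
    if (!is.null(acq$warp)) tab <- apply_warp(acq$warp, tab)
    if (acq$z_offset != 0 && !is.null(tab$z)) tab$z <- tab$z - acq$z_offset
    tab
  }
  encode_widths <- function(tab) {
    if (is.null(acq$astig) || is.null(tab$z)) return(tab)
    tab$wx <- pmax(.calib_wx(acq$astig, tab$z) +
                     rnorm(nrow(tab), 0, acq$width_noise_sd), 1)
    tab$wy <- pmax(.calib_wy(acq$astig, tab$z) +
                     rnorm(nrow(tab), 0, acq$width_noise_sd), 1)
    tab
  }
  out <- sim
  out$h2b <- warp_b(sim$h2b)
  out$beads_b <- warp_b(sim$beads_b)
  if (!is.null(drift)) {
    out$h2b <- apply_drift(out$h2b, drift)
    out$beads_b <- apply_drift(out$beads_b, drift)
    out$dna <- apply_drift(out$dna, drift)
    out$beads_a <- apply_drift(out$beads_a, drift)
  }
  out$h2b <- encode_widths(out$h2b)
  out$dna <- encode_widths(out$dna)
  out$beads_a <- encode_widths(out$beads_a)
  out$beads_b <- encode_widths(out$beads_b)
  out$truth$transforms <- list(warp = acq$warp, drift = drift,
                               z_offset = acq$z_offset, astig = acq$astig)
  out
}

#' Write a simulated nucleus to a directory
#'
#' Localization CSVs, mask JSON and truth JSON, mirroring the CLI
#' `clutchscope simulate` interface.
#' @param sim A [simulate_nucleus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_localizations(sim$h2b, file.path(dir, "h2b.csv"))
  write_localizations(sim$dna, file.path(dir, "dna.csv"))
  write_localizations(sim$beads_a, file.path(dir, "beads_a.csv"))
  write_localizations(sim$beads_b, file.path(dir, "beads_b.csv"))
  write_mask(sim$mask, file.path(dir, "mask.json"))
  tr <- sim$truth
  jsonlite::write_json(list(centers = tr$centers, island_of = tr$island_of,
                            clutch_sd = tr$clutch_sd, n_locs = tr$n_locs,
                            dna_associated = tr$dna_associated,
                            dna_parent = tr$dna_parent, seed = tr$seed),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
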