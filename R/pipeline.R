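# End-to-end orchestration: configuration validation with reference
# defaults, per-cell staging (QC -> Voronoi -> clutches -> co-structure)
# and a condition-comparison report.

#' Default pipeline configuration
#'
#' Every stage parameter with its reference default: 120 nm axial slice,
#' eps = 40 nm / min_size = 5 clutch segmentation, island link 1.5 x eps,
#' 10 nm radial step to 200 nm, 120 nm association radius, 70 nm NND-curve
#' radius with 20 nm bins, 300 log-spaced density bins, condition-dependent
#' QC thresholds, Nyquist gate 32 nm/localization.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    slice = list(z_center = 0, thickness = 120),
    segmentation = list(eps = 40, min_size = 5, island_link_factor = 1.5),
    radial = list(dr = 10, r_max = 200, association_radius = 120,
                  coloc_min_locs = 5),
    nnd_curve = list(radius = 70, bin = 20),
    voronoi = list(n_bins = 300, bin_lo_2d = 0.1e-9, bin_hi_2d = 0.94,
                   bin_lo_3d = 5e-7, bin_hi_3d = 0.0025),
    occupancy = list(fine = 20, coarse = 160),
    qc = list(nyquist_max = 32, enabled = TRUE),
    transition = list(alpha = 0.05),
    seed = 1,
    conditions = list()
  )
}

.check_unknown <- function(config, template, path = "") {
  for (k in names(config)) {
    if (!(k %in% names(template)))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        k != "conditions") {
      if (!is.list(config[[k]])) stop("config key ", paste0(path, k),
                                      " must be a list")
      .check_unknown(config[[k]], template[[k]], paste0(path, k, "$"))
    }
  }
}

#' Validate and normalize a pipeline configuration
#'
#' Unknown keys are rejected before any computation; missing keys filled
#' with [default_config()] values; cross-field constraints enforced
#' (`dr` divides `r_max`, radii reachable, `fine < coarse`, slice thickness
#' positive).
#'
#' @param config Partial configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  template <- default_config()
  .check_unknown(config, template)
  conds <- config$conditions
  config$conditions <- NULL
  cfg <- utils::modifyList(template, config)
  cfg$conditions <- if (is.null(conds)) list() else conds
  with(cfg, {
    if (slice$thickness <= 0) stop("slice thickness must be > 0")
    if (radial$dr <= 0) stop("dr must be > 0")
    if (abs(radial$r_max / radial$dr - round(radial$r_max / radial$dr)) > 1e-9)
      stop("r_max (", radial$r_max, ") must be a multiple of dr (", radial$dr, ")")
    for (r in c(radial$association_radius, nnd_curve$radius))
      if (r > radial$r_max) stop("radius ", r, " exceeds r_max")
    if (occupancy$fine >= occupancy$coarse) stop("fine must be < coarse")
    if (segmentation$eps <= 0) stop("eps must be > 0")
  })
  for (i in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[i]]
    if (is.null(cond$condition) ||
        !cond$condition %in% c("control", "treated"))
      stop("condition ", i, " must declare condition = control|treated")
  }
  cfg
}

.pipeline_cell <- function(h2b, dna, mask, cfg, cell_id) {
  if (!is.null(h2b$z)) h2b <- select_slice(h2b, cfg$slice$z_center,
                                           cfg$slice$thickness)
  if (!is.null(dna$z)) dna <- select_slice(dna, cfg$slice$z_center,
                                           cfg$slice$thickness)
  h2b <- clip_to_mask(h2b, mask)
  dna <- clip_to_mask(dna, mask)
  clutches <- group_islands(
    segment_clutches(h2b, cfg$segmentation$eps, cfg$segmentation$min_size),
    link = cfg$segmentation$island_link_factor * cfg$segmentation$eps)
  qc <- qc_report(h2b, mask, clutches = clutches)
  vor <- tessellate(dna, mask, dimension = 2)
  polys <- clutch_voronoi(clutches, mask)
  prof <- radial_profile(polys, dna, dr = cfg$radial$dr,
                         r_max = cfg$radial$r_max, cell_id = cell_id)
  list(qc = qc, clutches = clutches, voronoi = vor, profiles = prof,
       n_h2b = nrow(h2b), n_dna = nrow(dna))
}

#' Run the full comparison pipeline
#'
#' For every cell of every condition: axial slicing, mask clipping, clutch
#' segmentation and island grouping, QC gating (cells failing the
#' condition's thresholds are excluded from condition statistics and
#' listed), DNA Voronoi tessellation, clutch-seeded radial profiling. Per
#' condition: association fractions (mean +/- sd over passing cells),
#' log-binned Voronoi density distributions, pooled similarity matrix and
#' transition radius, NND-conditioned density curve. Conditions are
#' compared pairwise on their Voronoi median curves (KS).
#'
#' Cells are supplied either as file paths (`h2b`, `dna`, `mask`) or as
#' simulation specs (`preset`, `seed`), e.g.
#' `list(label = "control", condition = "control",
#'       cells = list(list(preset = "control", seed = 11)))`.
#'
#' @param config Configuration (see [default_config()]); must contain
#'   `conditions`.
#' @return A `comparison_report` list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (!length(cfg$conditions)) stop("config$conditions is empty")
  conds <- list()
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[ci]]
    label <- if (!is.null(cond$label)) cond$label else cond$condition
    cells <- list(); qc_rows <- list(); excluded <- character()
    for (k in seq_along(cond$cells)) {
      spec <- cond$cells[[k]]
      cell_id <- sprintf("%s_%d", label, k)
      res <- tryCatch({
        if (!is.null(spec$preset)) {
          sim <- simulate_nucleus(
            nucleus = condition_presets(spec$preset)$nucleus,
            dna = condition_presets(spec$preset)$dna,
            acq = acquisition_model(),
            seed = if (!is.null(spec$seed)) spec$seed else cfg$seed + k)
          .pipeline_cell(sim$h2b, sim$dna, sim$mask, cfg, cell_id)
        } else {
          .pipeline_cell(read_localizations(spec$h2b),
                         read_localizations(spec$dna),
                         read_mask(spec$mask), cfg, cell_id)
        }
      }, error = function(e) {
        stop("stage failure in cell ", cell_id, ": ", conditionMessage(e))
      })
      message(sprintf("[%s] %d H2B / %d DNA localizations", cell_id,
                      res$n_h2b, res$n_dna))
      gate <- qc_gate(res$qc, cond$condition,
                      nyquist_max = cfg$qc$nyquist_max)
      qc_rows[[k]] <- data.frame(cell = cell_id,
                                 occupancy = res$qc$occupancy,
                                 clustered_area = res$qc$clustered_area,
                                 clusters_per_island = res$qc$clusters_per_island,
                                 nyquist_mask = res$qc$nyquist[["mask"]],
                                 nyquist_occupied = res$qc$nyquist[["occupied"]],
                                 pass = gate$pass,
                                 failed = paste(gate$failed, collapse = "; "))
      if (gate$pass || !cfg$qc$enabled) cells[[length(cells) + 1]] <- res
      else excluded <- c(excluded, cell_id)
    }
    if (!length(cells))
      stop("no cells passed QC for condition ", label)
    profiles <- lapply(cells, `[[`, "profiles")
    assoc <- vapply(cells, function(cl)
      associated_fraction(cl$profiles, cfg$radial$association_radius)$percent,
      numeric(1))
    coloc <- vapply(cells, function(cl)
      colocalized_clutch_fraction(cl$profiles, cfg$radial$association_radius,
                                  cfg$radial$coloc_min_locs), numeric(1))
    sim_mat <- similarity_matrix(profiles)
    dist <- density_distribution(lapply(cells, `[[`, "voronoi"),
                                 bin_lo = cfg$voronoi$bin_lo_2d,
                                 bin_hi = cfg$voronoi$bin_hi_2d,
                                 n_bins = cfg$voronoi$n_bins)
    nnd_curves <- tryCatch({
      nnds <- lapply(cells, function(cl) nnd(cl$clutches,
                                             same_island_only = TRUE))
      density_vs_nnd(profiles, nnds,
                     r = cfg$nnd_curve$radius, bin = cfg$nnd_curve$bin)
    }, error = function(e) NULL)
    conds[[label]] <- list(
      label = label, condition = cond$condition,
      qc_table = do.call(rbind, qc_rows), excluded = excluded,
      n_cells_in = length(cond$cells), n_cells_pass = length(cells),
      association_mean = mean(assoc), association_sd = stats::sd(assoc),
      association_per_cell = assoc,
      colocalized_mean = mean(coloc),
      transition_radius = transition_radius(sim_mat, cfg$transition$alpha),
      similarity = sim_mat, density_distribution = dist,
      nnd_curve = nnd_curves,
      mean_locs_per_clutch = mean(unlist(lapply(cells, function(cl)
        cl$clutches$clutches$n_locs))))
  }
  comparisons <- list()
  labs <- names(conds)
  if (length(labs) >= 2) {
    for (i in seq_len(length(labs) - 1)) for (j in seq(i + 1, length(labs))) {
      ks <- compare_distributions(conds[[labs[i]]]$density_distribution,
                                  conds[[labs[j]]]$density_distribution)
      comparisons[[paste(labs[i], "vs", labs[j])]] <- ks
    }
  }
  structure(list(conditions = conds, comparisons = comparisons,
                 config = cfg,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("clutchscope")),
                   seed = cfg$seed)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (cond in x$conditions) {
    cat(sprintf(
      " %s: %d/%d cells pass QC; association %.1f +/- %.1f %%; transition %s nm\n",
      cond$label, cond$n_cells_pass, cond$n_cells_in,
      cond$association_mean,
      ifelse(is.na(cond$association_sd), 0, cond$association_sd),
      format(cond$transition_radius)))
  }
  for (nm in names(x$comparisons))
    cat(sprintf(" %s: KS D = %.3f, p = %.3g\n", nm,
                x$comparisons[[nm]]$statistic, x$comparisons[[nm]]$p.value))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Numeric summaries only (matrices flattened); timestamps excluded so a
#' rerun with identical config and seeds is byte-identical.
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  ser <- list(conditions = lapply(report$conditions, function(cond) {
    list(label = cond$label, condition = cond$condition,
         qc = cond$qc_table, excluded = cond$excluded,
         association_mean = cond$association_mean,
         association_sd = cond$association_sd,
         colocalized_mean = cond$colocalized_mean,
         transition_radius = cond$transition_radius,
         mean_locs_per_clutch = cond$mean_locs_per_clutch)
  }),
  comparisons = report$comparisons,
  config = report$config)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}
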