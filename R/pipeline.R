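#' Default study configuration
#'
#' The configuration is a plain named list mirroring the JSON config file:
#' blocks \code{geometry}, \code{rheology}, \code{waveform}, \code{coil},
#' \code{hct}, \code{solver}, plus top-level \code{resolution} (mesh size
#' h, m), \code{grid_ladder} (resolutions for the grid-independence
#' study), \code{osi_threshold}, \code{iso_velocity_level} and
#' \code{wall_csv_stride}.  Every default is echoed into the study report
#' so that no silent defaults exist.  The default sweep is the 2 x 2
#' porosity (0.79, 0.89) by haematocrit (0.35, 0.45) design.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    geometry = list(parent_width = 4e-3, parent_length = 40e-3,
                    curvature = 50, sac_neck_width = 4e-3,
                    dome_radius = 3e-3, sac_shape = "circular_segment",
                    sac_center_arc = NULL, coil_fill_fraction = 0.85),
    rheology = list(model = "casson", density = 1060,
                    plasma_viscosity = 0.00145,
                    yield_coef = 0.185, yield_hct_crit = 0.10,
                    gamma_min = 1e-3),
    waveform = list(period = 0.8, mean_velocity = 0.3,
                    amplitudes = c(0.55, 0.30, 0.12),
                    phases = 2 * pi * c(1, 2, 3) * 0.15),
    coil = list(porosity = c(0.79, 0.89), wire_diameter = 2.5e-4,
                include_uncoiled = FALSE),
    hct = c(0.35, 0.45),
    solver = list(dt = "auto", cycles_to_run = 3, cycles_to_discard = 2,
                  cfl_target = 0.35, wall_stride = 1,
                  divergence_tolerance = 1e-6,
                  periodicity_tolerance = 0.02),
    resolution = 4e-4,
    grid_ladder = c(5e-4, 3.5e-4, 2.5e-4),
    osi_threshold = 0.2,
    iso_velocity_level = 0.4,
    wall_csv_stride = 10
  )
}

#' Read a study configuration file
#'
#' Reads a JSON config and merges it over \code{\link{default_config}}
#' (recursively: unspecified keys keep their defaults).
#'
#' @param path path to a JSON file.
#' @return Config list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), user)
}

cfg_geometry <- function(cfg) {
  g <- cfg$geometry
  build_idealized_aneurysm(
    parent_width = g$parent_width, parent_length = g$parent_length,
    curvature = g$curvature, sac_neck_width = g$sac_neck_width,
    sac_depth = g$sac_depth, dome_radius = g$dome_radius,
    sac_shape = g$sac_shape, sac_center_arc = g$sac_center_arc,
    coil_fill_fraction = g$coil_fill_fraction)
}

cfg_waveform <- function(cfg) {
  w <- cfg$waveform
  pulsatile_waveform(period = w$period, mean_velocity = w$mean_velocity,
                     amplitudes = w$amplitudes, phases = w$phases)
}

cfg_blood <- function(cfg, hct) {
  r <- cfg$rheology
  blood_properties(hct = hct, density = r$density,
                   plasma_viscosity = r$plasma_viscosity,
                   yield_coef = r$yield_coef,
                   yield_hct_crit = r$yield_hct_crit,
                   gamma_min = r$gamma_min, model = r$model,
                   mu_inf = r$mu_inf, tau_y = r$tau_y)
}

cfg_coil <- function(cfg, porosity) {
  if (is.na(porosity)) return(NULL)
  coil_properties(porosity = porosity, wire_diameter = cfg$coil$wire_diameter,
                  permeability = cfg$coil$permeability,
                  inertial_coef = cfg$coil$inertial_coef)
}

cfg_solver <- function(cfg) {
  s <- cfg$solver
  solver_config(dt = s$dt, cycles_to_run = s$cycles_to_run,
                cycles_to_discard = s$cycles_to_discard,
                divergence_tolerance = s$divergence_tolerance,
                cfl_target = s$cfl_target, wall_stride = s$wall_stride,
                periodicity_tolerance = s$periodicity_tolerance)
}

condition_label <- function(porosity, hct) {
  if (is.na(porosity)) sprintf("uncoiled_hct%.2f", hct)
  else sprintf("eps%.2f_hct%.2f", porosity, hct)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "string")
  invisible(path)
}

#' Run a single simulation condition and write its artifacts
#'
#' One pulsatile run at the given coil porosity (or \code{NA} for the
#' uncoiled baseline) and haematocrit, writing under
#' \code{out_dir/<label>/}: VTK snapshots at the four landmarks, the wall
#' series CSV, per-sample and per-landmark index CSVs, and a JSON run
#' report echoing the full configuration.
#'
#' @param cfg config list (see \code{\link{default_config}}).
#' @param porosity coil porosity, or \code{NA} for no coil.
#' @param hct haematocrit.
#' @param out_dir output directory (created if needed).
#' @param mesh optional pre-built mesh (shared across conditions).
#' @param quiet suppress progress messages?
#' @return List with the \code{\link{hemodynamic_indices}}, the
#'   \code{sacflow_result}, the condition label and the artifact paths.
#' @export
run_condition <- function(cfg, porosity, hct, out_dir, mesh = NULL,
                          quiet = FALSE) {
  label <- condition_label(porosity, hct)
  dir <- file.path(out_dir, label)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- cfg_geometry(cfg)
  if (is.null(mesh)) mesh <- generate_mesh(geom, cfg$resolution)
  props <- cfg_blood(cfg, hct)
  coil <- cfg_coil(cfg, porosity)
  w <- cfg_waveform(cfg)
  scfg <- cfg_solver(cfg)
  if (!quiet) message(sprintf("[sacflow] running %s ...", label))
  res <- run_pulsatile(mesh, props, coil, w, scfg)
  ind <- hemodynamic_indices(res, osi_threshold = cfg$osi_threshold)

  files <- character(0)
  for (nm in names(res$snapshots)) {
    f <- file.path(dir, sprintf("snapshot_%s.vtk", nm))
    write_vtk(mesh, f, res$snapshots[[nm]],
              title = sprintf("sacflow %s landmark %s", label, nm))
    files <- c(files, f)
  }
  f <- file.path(dir, "wall_series.csv")
  write_wall_series_csv(res$wall_series, f, stride = cfg$wall_csv_stride)
  files <- c(files, f)
  f <- file.path(dir, "indices_samples.csv")
  utils::write.csv(ind$samples, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "indices_per_landmark.csv")
  utils::write.csv(ind$per_landmark, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "iso_velocity_area.csv")
  iso <- iso_velocity_area(res, level = cfg$iso_velocity_level)
  utils::write.csv(data.frame(landmark = names(iso), area_m2 = as.numeric(iso),
                              level = cfg$iso_velocity_level),
                   f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "report.json")
  rep <- res$report
  rep$condition <- list(label = label, porosity = porosity, hct = hct)
  rep$config_full <- cfg
  rep$high_risk_regions <- high_risk_regions(ind)
  write_json_report(rep, f); files <- c(files, f)

  list(indices = ind, result = res, label = label, files = files)
}

#' Run the porosity x haematocrit study
#'
#' One pulsatile run per (porosity, HCT) pair of the configured sweep
#' (plus an uncoiled baseline per HCT when
#' \code{cfg$coil$include_uncoiled}), per-run artifacts, per-HCT
#' comparisons of the landmark indices against the highest-porosity
#' condition (the paper's reading direction: how much does tighter coil
#' packing reduce each index), and a manifest of every output file with
#' its MD5 checksum.  A failed run aborts the study with the failing
#' condition named; artifacts of completed runs are retained.
#'
#' @param cfg config list.
#' @param out_dir output directory.
#' @param quiet suppress progress messages?
#' @return An object of class \code{sacflow_study}: list with
#'   \code{indices} (per condition), \code{comparisons} (per HCT),
#'   \code{manifest} (data.frame file/md5), \code{report_path}.
#' @export
run_study <- function(cfg = default_config(), out_dir = "sacflow_out",
                      quiet = FALSE) {
  eps_list <- cfg$coil$porosity
  if (length(eps_list) == 0 || length(cfg$hct) == 0)
    stopf("empty sweep: config must list at least one porosity and one hct")
  if (isTRUE(cfg$coil$include_uncoiled)) eps_list <- c(eps_list, NA_real_)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- cfg_geometry(cfg)
  mesh <- generate_mesh(geom, cfg$resolution)

  runs <- list(); files <- character(0)
  for (hct in cfg$hct) for (eps in eps_list) {
    label <- condition_label(eps, hct)
    r <- tryCatch(
      run_condition(cfg, eps, hct, out_dir, mesh = mesh, quiet = quiet),
      error = function(e) stopf("study aborted: condition %s failed: %s",
                                label, conditionMessage(e)))
    runs[[label]] <- r
    files <- c(files, r$files)
  }

  comparisons <- list()
  coiled <- Filter(function(r) !grepl("^uncoiled", r$label), runs)
  for (hct in cfg$hct) {
    sub <- Filter(function(r) isTRUE(all.equal(r$indices$condition$hct, hct)), coiled)
    if (length(sub) >= 2) {
      eps_vals <- vapply(sub, function(r) r$indices$condition$porosity, numeric(1))
      ref <- names(sub)[which.max(eps_vals)]
      cmp <- compare_conditions(lapply(sub, `[[`, "indices"), reference = ref)
      key <- sprintf("hct%.2f", hct)
      comparisons[[key]] <- cmp
      f <- file.path(out_dir, sprintf("comparison_%s.csv", key))
      utils::write.csv(cmp, f, row.names = FALSE)
      files <- c(files, f)
    }
  }

  report <- list(
    conditions = lapply(runs, function(r) r$indices$condition),
    landmarks = runs[[1]]$result$report$landmarks,
    dt = runs[[1]]$result$report$dt,
    periodicity = lapply(runs, function(r) r$result$report$periodicity),
    config = cfg)
  report_path <- file.path(out_dir, "study_report.json")
  write_json_report(report, report_path)
  files <- c(files, report_path)

  prefix <- paste0(out_dir, .Platform$file.sep)
  rel <- ifelse(startsWith(files, prefix),
                substring(files, nchar(prefix) + 1L), files)
  manifest <- data.frame(file = rel, md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)

  structure(list(indices = lapply(runs, `[[`, "indices"),
                 comparisons = comparisons, manifest = manifest,
                 manifest_path = mpath, report_path = report_path,
                 out_dir = out_dir),
            class = "sacflow_study")
}

#' @export
print.sacflow_study <- function(x, ...) {
  cat(sprintf("<sacflow_study> %d condition(s) in %s\n",
              length(x$indices), x$out_dir))
  for (nm in names(x$comparisons)) {
    cat(sprintf("-- comparison %s --\n", nm))
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

#' Grid-independence study
#'
#' Runs the pulsatile problem (uncoiled, first configured HCT) on a ladder
#' of successively finer meshes and tabulates the monitored quantity —
#' the neck-average velocity magnitude at maximum acceleration (A) and
#' peak systole (B); for a geometry without a sac, the peak cell speed at
#' those instants — with the successive relative changes.  The
#' recommended mesh is the coarsest whose change from the next coarser
#' mesh is below \code{tol} in both monitored columns.
#'
#' @param cfg config list; \code{cfg$grid_ladder} must hold >= 3 strictly
#'   decreasing resolutions (m).
#' @param tol relative-change acceptance threshold. Default 0.01.
#' @param quiet suppress progress messages?
#' @return An object of class \code{grid_study}: data.frame \code{table}
#'   (label, h, cells, v_A, v_B, rel_change_A, rel_change_B) and
#'   \code{recommended} (row index or NA).
#' @export
grid_independence <- function(cfg = default_config(), tol = 0.01,
                              quiet = FALSE) {
  ladder <- cfg$grid_ladder
  if (length(ladder) < 3)
    stopf("grid ladder must contain at least 3 resolutions (got %d)", length(ladder))
  if (any(diff(ladder) >= 0))
    stopf("grid ladder must be strictly decreasing (finer meshes): got %s",
          paste(signif(ladder, 3), collapse = ", "))
  geom <- cfg_geometry(cfg)
  props <- cfg_blood(cfg, cfg$hct[1])
  w <- cfg_waveform(cfg)
  labels <- c("coarse", "medium", "fine", "very fine",
              paste0("level", seq_len(max(0, length(ladder) - 4)) + 4L))
  vals <- data.frame(label = labels[seq_along(ladder)], h = ladder,
                     cells = NA_integer_, v_A = NA_real_, v_B = NA_real_)
  for (k in seq_along(ladder)) {
    if (!quiet) message(sprintf("[sacflow] grid study: h = %g m", ladder[k]))
    mesh <- generate_mesh(geom, ladder[k])
    scfg <- cfg_solver(cfg)
    res <- run_pulsatile(mesh, props, NULL, w, scfg)
    vals$cells[k] <- sum(mesh$fluid)
    if (length(mesh$neck_cols) > 0) {
      vals$v_A[k] <- neck_mean_speed(res$snapshots$A, mesh)
      vals$v_B[k] <- neck_mean_speed(res$snapshots$B, mesh)
    } else {
      vals$v_A[k] <- max(cell_velocity(res$snapshots$A, mesh)$speed)
      vals$v_B[k] <- max(cell_velocity(res$snapshots$B, mesh)$speed)
    }
  }
  vals$rel_change_A <- c(NA, abs(diff(vals$v_A)) / abs(vals$v_A[-1]))
  vals$rel_change_B <- c(NA, abs(diff(vals$v_B)) / abs(vals$v_B[-1]))
  ok <- which(pmax(vals$rel_change_A, vals$rel_change_B) < tol)
  recommended <- if (length(ok)) min(ok) - 1L else NA_integer_
  structure(list(table = vals, recommended = recommended, tol = tol),
            class = "grid_study")
}

#' @export
print.grid_study <- function(x, ...) {
  cat("<grid_study> neck-average velocity vs mesh\n")
  print(x$table, row.names = FALSE)
  if (!is.na(x$recommended))
    cat(sprintf("recommended: %s (change < %g%% from next coarser)\n",
                x$table$label[x$recommended], 100 * x$tol))
  invisible(x)
}

#' Rebuild the comparison tables from stored study artifacts
#'
#' Reads the per-condition \code{indices_per_landmark.csv} files under a
#' study output directory and regenerates the per-HCT comparison tables
#' without re-running any simulation.
#'
#' @param out_dir a directory previously written by \code{\link{run_study}}.
#' @return Named list of comparison data.frames, keyed by HCT.
#' @export
rebuild_report <- function(out_dir) {
  dirs <- list.dirs(out_dir, recursive = FALSE)
  dirs <- dirs[grepl("eps[0-9.]+_hct[0-9.]+$", basename(dirs))]
  if (length(dirs) < 2) stopf("no stored study conditions found under '%s'", out_dir)
  tabs <- lapply(dirs, function(d)
    utils::read.csv(file.path(d, "indices_per_landmark.csv")))
  names(tabs) <- basename(dirs)
  eps <- as.numeric(sub("^eps([0-9.]+)_.*$", "\\1", names(tabs)))
  hct <- as.numeric(sub("^.*_hct([0-9.]+)$", "\\1", names(tabs)))
  out <- list()
  idx_cols <- c(max_wss = "max_wss_sac", max_osi = "max_osi_sac",
                sac_mean_velocity = "sac_mean_velocity")
  for (h in unique(hct)) {
    sel <- which(hct == h)
    if (length(sel) < 2) next
    ref_i <- sel[which.max(eps[sel])]
    ref <- tabs[[ref_i]]
    rows <- list()
    for (ci in setdiff(sel, ref_i)) {
      cur <- tabs[[ci]]
      for (li in seq_len(nrow(ref))) for (k in seq_along(idx_cols)) {
        xr <- ref[[idx_cols[k]]][li]; xc <- cur[[idx_cols[k]]][li]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = names(tabs)[ci], reference = names(tabs)[ref_i],
          landmark = ref$landmark[li], index = names(idx_cols)[k],
          value = xc, reference_value = xr,
          percent_change = if (is.finite(xr) && xr != 0) 100 * (xr - xc) / xr else NA_real_)
      }
    }
    out[[sprintf("hct%.2f", h)]] <- do.call(rbind, rows)
  }
  out
}
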