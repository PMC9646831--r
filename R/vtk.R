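# Legacy-ASCII VTK unstructured-grid writer (quad cells of the fluid
# region).  Deliberately minimal: deterministic text output, no external
# dependency; readable by ParaView/VisIt/meshio.

fmt_num <- function(x) sprintf("%.9g", x)

vtk_grid_skeleton <- function(mesh, bend = TRUE) {
  nx <- mesh$nx; ny <- mesh$ny; hx <- mesh$hx; hy <- mesh$hy
  cells <- which(mesh$fluid, arr.ind = TRUE)
  # nodes of used cells, deduplicated
  node_id <- matrix(NA_integer_, nx + 1, ny + 1)
  corn <- rbind(cbind(cells[, 1], cells[, 2]),
                cbind(cells[, 1] + 1L, cells[, 2]),
                cbind(cells[, 1] + 1L, cells[, 2] + 1L),
                cbind(cells[, 1], cells[, 2] + 1L))
  uniq <- unique(corn)
  node_id[uniq] <- seq_len(nrow(uniq)) - 1L   # VTK is 0-based
  xy <- cbind((uniq[, 1] - 1L) * hx, (uniq[, 2] - 1L) * hy)
  if (bend) xy <- bend_coordinates(mesh$geom, xy)
  conn <- cbind(node_id[corn[seq_len(nrow(cells)), , drop = FALSE]],
                node_id[corn[nrow(cells) + seq_len(nrow(cells)), , drop = FALSE]],
                node_id[corn[2L * nrow(cells) + seq_len(nrow(cells)), , drop = FALSE]],
                node_id[corn[3L * nrow(cells) + seq_len(nrow(cells)), , drop = FALSE]])
  list(points = xy, conn = conn, cells = cells)
}

#' Write a mesh or flow snapshot as a legacy VTK file
#'
#' Writes the fluid region as VTK quads (legacy ASCII unstructured grid),
#' bent onto the curved vessel.  With a \code{state}, cell data are
#' attached: pressure, velocity (cell-centred vector), speed, apparent
#' viscosity and the coil mask.
#'
#' @param mesh a \code{sacflow_mesh}.
#' @param path output file path (conventionally \code{.vtk}).
#' @param state optional \code{flow_state} to attach as cell data.
#' @param title dataset title line.
#' @return Invisibly, the path.
#' @export
write_vtk <- function(mesh, path, state = NULL, title = "sacflow") {
  sk <- vtk_grid_skeleton(mesh)
  npts <- nrow(sk$points); ncl <- nrow(sk$conn)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", title, "ASCII", "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", npts))
  wl(paste(fmt_num(sk$points[, 1]), fmt_num(sk$points[, 2]), "0"))
  wl(sprintf("CELLS %d %d", ncl, 5L * ncl))
  wl(paste(4L, sk$conn[, 1], sk$conn[, 2], sk$conn[, 3], sk$conn[, 4]))
  wl(sprintf("CELL_TYPES %d", ncl))
  wl(as.character(rep(9L, ncl)))   # VTK_QUAD
  wl(sprintf("CELL_DATA %d", ncl))
  ci <- sk$cells
  wl("SCALARS coil_mask int 1", "LOOKUP_TABLE default")
  wl(as.character(as.integer(mesh$coil[ci])))
  if (!is.null(state)) {
    cv <- cell_velocity(state, mesh)
    wl("SCALARS pressure double 1", "LOOKUP_TABLE default")
    wl(fmt_num(state$p[ci]))
    wl("SCALARS speed double 1", "LOOKUP_TABLE default")
    wl(fmt_num(cv$speed[ci]))
    wl("SCALARS viscosity double 1", "LOOKUP_TABLE default")
    wl(fmt_num(state$mu[ci]))
    wl("VECTORS velocity double")
    wl(paste(fmt_num(cv$uc[ci]), fmt_num(cv$vc[ci]), "0"))
  }
  invisible(path)
}

#' Export a wall series as CSV
#'
#' Long-format CSV with columns \code{time}, \code{face}, \code{arclength},
#' \code{tag}, \code{tx}, \code{ty}, \code{wss}, \code{pressure}.
#'
#' @param series a \code{wall_series}.
#' @param path output path.
#' @param stride keep every \code{stride}-th time sample.
#' @return Invisibly, the path.
#' @export
write_wall_series_csv <- function(series, path, stride = 1L) {
  keep <- seq(1L, length(series$times), by = stride)
  nf <- nrow(series$faces)
  df <- data.frame(
    time = rep(series$times[keep], each = nf),
    face = rep(seq_len(nf), times = length(keep)),
    arclength = rep(series$faces$arclength, times = length(keep)),
    tag = rep(series$faces$tag, times = length(keep)),
    tx = as.vector(series$tx[, keep]),
    ty = as.vector(series$ty[, keep]),
    wss = as.vector(sqrt(series$tx[, keep]^2 + series$ty[, keep]^2)),
    pressure = as.vector(series$pressure[, keep]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
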