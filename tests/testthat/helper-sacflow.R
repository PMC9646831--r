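# shared fixtures: cheap geometries, meshes and synthetic wall series

chan_geom <- function(L = 16e-3, D = 4e-3)
  build_idealized_aneurysm(parent_width = D, parent_length = L,
                           curvature = 0, sac_neck_width = 0)

sac_geom <- function(L = 24e-3, ...)
  build_idealized_aneurysm(parent_length = L, sac_center_arc = L / 2, ...)

newt_blood <- function(mu = 0.0035)
  blood_properties(model = "newtonian", mu_inf = mu)

# synthetic wall series: one cycle of given traction histories
# tx, ty: n_faces x n_times matrices (ty defaults to zero)
make_series <- function(tx, ty = NULL, period = 1) {
  nf <- nrow(tx); nt <- ncol(tx)
  if (is.null(ty)) ty <- matrix(0, nf, nt)
  faces <- data.frame(i = seq_len(nf), j = 1L, side = "N",
                      tag = "sac_wall", x = seq_len(nf) * 1e-3, y = 4e-3,
                      length = 1e-3,
                      arclength = seq_len(nf) * 1e-3, loop = 1L,
                      group = 1L)
  structure(list(faces = faces, times = period * seq_len(nt) / nt,
                 period = period, tx = tx, ty = ty,
                 pressure = matrix(0, nf, nt)),
            class = "wall_series")
}

quiet_steady <- function(...) suppressWarnings(run_steady(...))
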