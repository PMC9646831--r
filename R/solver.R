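#' Solver configuration
#'
#' Settings for the transient incompressible flow solver.  The scheme is a
#' pressure-correction (projection) method on the staggered Cartesian grid:
#' explicit first-order upwind advection, semi-implicit viscous terms
#' (implicit constant reference viscosity plus the explicit remainder of
#' the full variable-viscosity stress divergence), a pointwise-implicit
#' Darcy-Forchheimer coil sink, and an exact discrete pressure projection
#' via a once-factorized Poisson operator.
#'
#' With explicit advection the time step must satisfy an advective CFL
#' condition; \code{dt = "auto"} (the default) picks
#' \code{min(T/1000, cfl_target * h / u_peak)} with \code{u_peak} the
#' estimated peak centerline speed, then rounds so that one cycle is an
#' integer number of steps.  The chosen value is echoed in the run report.
#'
#' @param dt time step in s, or \code{"auto"}.
#' @param cycles_to_run total cardiac cycles to integrate.
#' @param cycles_to_discard startup cycles excluded from reporting; must be
#'   \code{< cycles_to_run}.
#' @param pressure_velocity_scheme only \code{"projection"} is implemented;
#'   requesting \code{"simple"} is rejected with a clear message.
#' @param divergence_tolerance admissible post-projection divergence, 1/s.
#' @param nonlinear_tolerance relative tolerance of the optional Picard
#'   loop on viscosity/advection (used when \code{max_inner_iterations > 1}).
#' @param max_inner_iterations Picard iterations per step; 1 (default)
#'   means a single linearized pass with lagged coefficients.
#' @param cfl_target advective CFL number used by \code{dt = "auto"}.
#' @param wall_stride record wall tractions every this many steps of the
#'   final cycle (1 = every step).
#' @param inlet_bc \code{"velocity"} (pulsatile parabolic inlet profile) or
#'   \code{"pressure"} (prescribed inlet pressure, zero-gradient velocity;
#'   used e.g. for pressure-driven channel benchmarks).
#' @param pressure_inlet for \code{inlet_bc = "pressure"}: function of time
#'   returning the inlet pressure in Pa.
#' @param periodicity_tolerance relative L2 velocity difference between the
#'   last two cycles above which a non-periodicity warning is issued.
#' @param seed optional integer seed; the solver itself is deterministic
#'   (no randomized initial perturbation is applied by default), the seed
#'   is stored and echoed so runs are reproducible by construction.
#' @return An object of class \code{solver_config}.
#' @export
solver_config <- function(dt = "auto", cycles_to_run = 3L, cycles_to_discard = 2L,
                          pressure_velocity_scheme = c("projection", "simple"),
                          divergence_tolerance = 1e-6,
                          nonlinear_tolerance = 1e-3,
                          max_inner_iterations = 1L,
                          cfl_target = 0.35,
                          wall_stride = 1L,
                          inlet_bc = c("velocity", "pressure"),
                          pressure_inlet = NULL,
                          periodicity_tolerance = 0.02,
                          seed = NULL) {
  pressure_velocity_scheme <- match.arg(pressure_velocity_scheme)
  if (pressure_velocity_scheme == "simple")
    stopf("pressure_velocity_scheme = 'simple' is not implemented; use 'projection'")
  inlet_bc <- match.arg(inlet_bc)
  if (inlet_bc == "pressure" && !is.function(pressure_inlet))
    stopf("inlet_bc = 'pressure' requires 'pressure_inlet' to be a function of time")
  if (!identical(dt, "auto")) check_scalar(dt, "dt", 0, strict_lower = TRUE)
  cycles_to_run <- as.integer(cycles_to_run)
  cycles_to_discard <- as.integer(cycles_to_discard)
  if (cycles_to_run < cycles_to_discard + 1L)
    stopf("cycles_to_run (%d) must be >= cycles_to_discard + 1 (%d)",
          cycles_to_run, cycles_to_discard + 1L)
  check_scalar(divergence_tolerance, "divergence_tolerance", 0, strict_lower = TRUE)
  check_scalar(nonlinear_tolerance, "nonlinear_tolerance", 0, strict_lower = TRUE)
  check_scalar(cfl_target, "cfl_target", 0, 1, strict_lower = TRUE)
  structure(list(dt = dt, cycles_to_run = cycles_to_run,
                 cycles_to_discard = cycles_to_discard,
                 pressure_velocity_scheme = pressure_velocity_scheme,
                 divergence_tolerance = divergence_tolerance,
                 nonlinear_tolerance = nonlinear_tolerance,
                 max_inner_iterations = as.integer(max_inner_iterations),
                 cfl_target = cfl_target,
                 wall_stride = as.integer(wall_stride),
                 inlet_bc = inlet_bc, pressure_inlet = pressure_inlet,
                 periodicity_tolerance = periodicity_tolerance,
                 seed = seed),
            class = "solver_config")
}

# resolve dt: CFL bound from estimated peak centerline speed
resolve_dt <- function(cfg, mesh, w) {
  if (!identical(cfg$dt, "auto")) return(cfg$dt)
  h <- min(mesh$hx, mesh$hy)
  if (cfg$inlet_bc == "velocity" && inherits(w, "waveform")) {
    u_peak <- 1.5 * w$mean_velocity * (1 + sum(abs(w$amplitudes)))
    T <- w$period
  } else {
    u_peak <- 1.0   # conservative default for pressure-driven runs, m/s
    T <- if (inherits(w, "waveform")) w$period else 0.8
  }
  dt <- min(T / 1000, cfg$cfl_target * h / max(u_peak, 1e-12))
  T / ceiling(T / dt)
}

# ---- workspace: masks, operators, factorizations ------------------------

solver_workspace <- function(mesh, props, coil, cfg, w) {
  nx <- mesh$nx; ny <- mesh$ny; hx <- mesh$hx; hy <- mesh$hy
  Fl <- mesh$fluid
  FlW <- shiftm(Fl, 1, 0, FALSE)   # FlW[i,j] = Fl[i-1,j]
  FlS <- shiftm(Fl, 0, 1, FALSE)

  # u faces: (nx+1) x ny ; face i between cells (i-1) and i
  Flu_w <- rbind(matrix(FALSE, 1, ny), Fl)        # cell west of u-face
  Flu_e <- rbind(Fl, matrix(FALSE, 1, ny))        # cell east of u-face
  u_def <- Flu_w | Flu_e
  u_int <- Flu_w & Flu_e
  u_inlet <- matrix(FALSE, nx + 1, ny); u_inlet[1, ] <- Fl[1, ]
  u_outlet <- matrix(FALSE, nx + 1, ny); u_outlet[nx + 1, ] <- Fl[nx, ]
  u_zero <- u_def & !u_int & !u_inlet & !u_outlet
  uN_def <- shiftm(u_def, 0, -1, FALSE)           # u_def[i, j+1]
  uS_def <- shiftm(u_def, 0, 1, FALSE)

  # v faces: nx x (ny+1) ; face j between cells (j-1) and j
  Flv_s <- cbind(matrix(FALSE, nx, 1), Fl)
  Flv_n <- cbind(Fl, matrix(FALSE, nx, 1))
  v_def <- Flv_s | Flv_n
  v_int <- Flv_s & Flv_n
  vE_def <- shiftm(v_def, -1, 0, FALSE)
  vW_def <- shiftm(v_def, 1, 0, FALSE)

  rho <- props$density
  mu0 <- if (props$tau_y > 0)
    0.5 * (sqrt(props$mu_inf) + sqrt(props$tau_y / props$gamma_min))^2
  else props$mu_inf

  dt <- resolve_dt(cfg, mesh, w)
  a_u <- dt * mu0 / rho

  pressure_mode <- cfg$inlet_bc == "pressure"

  # --- A_u ---------------------------------------------------------------
  idu <- matrix(seq_len((nx + 1) * ny), nx + 1, ny)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  push <- function(ii, jj, xx) {
    trip_i <<- c(trip_i, ii); trip_j <<- c(trip_j, jj); trip_x <<- c(trip_x, xx)
  }
  ii <- which(u_int, arr.ind = TRUE)
  fi <- ii[, 1]; fj <- ii[, 2]
  me <- idu[cbind(fi, fj)]
  # tangential wall treatment in y: one-sided quadratic (second order)
  # when the opposite neighbour exists, linear reflection otherwise
  hasN <- uN_def[cbind(fi, fj)]; hasS <- uS_def[cbind(fi, fj)]
  both <- hasN & hasS
  wallN <- !hasN & hasS   # wall above, fluid below
  wallS <- hasN & !hasS   # wall below, fluid above
  none <- !hasN & !hasS
  diag_y <- numeric(length(me))
  diag_y[both] <- 2; diag_y[wallN | wallS] <- 4; diag_y[none] <- 4
  diag_u <- 1 + a_u * (2 / hx^2 + diag_y / hy^2)
  push(me, me, diag_u)
  push(me, idu[cbind(fi - 1L, fj)], rep(-a_u / hx^2, length(me)))
  push(me, idu[cbind(fi + 1L, fj)], rep(-a_u / hx^2, length(me)))
  cN_off <- ifelse(both, 1, ifelse(wallS, 4 / 3, 0))
  cS_off <- ifelse(both, 1, ifelse(wallN, 4 / 3, 0))
  selN <- cN_off > 0
  push(me[selN], idu[cbind(fi[selN], fj[selN] + 1L)], -a_u * cN_off[selN] / hy^2)
  selS <- cS_off > 0
  push(me[selS], idu[cbind(fi[selS], fj[selS] - 1L)], -a_u * cS_off[selS] / hy^2)
  # identity / copy rows
  others <- setdiff(seq_len((nx + 1) * ny), me)
  push(others, others, rep(1, length(others)))
  io <- which(u_outlet, arr.ind = TRUE)
  push(idu[cbind(io[, 1], io[, 2])] * 0 + idu[cbind(io[, 1], io[, 2])],
       idu[cbind(io[, 1] - 1L, io[, 2])], rep(-1, nrow(io)))
  if (pressure_mode) {
    iin <- which(u_inlet, arr.ind = TRUE)
    push(idu[cbind(iin[, 1], iin[, 2])], idu[cbind(iin[, 1] + 1L, iin[, 2])],
         rep(-1, nrow(iin)))
  }
  A_u <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = rep((nx + 1) * ny, 2))
  lu_u <- Matrix::lu(A_u)

  # --- A_v ---------------------------------------------------------------
  idv <- matrix(seq_len(nx * (ny + 1)), nx, ny + 1)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  ii <- which(v_int, arr.ind = TRUE)
  fi <- ii[, 1]; fj <- ii[, 2]
  me <- idv[cbind(fi, fj)]
  # x-direction neighbour classes: open (coupled), wall (no-slip plane at
  # half spacing) or free (zero-gradient: outlet, or inlet in pressure mode)
  hasW <- ifelse(fi == 1L, FALSE, vW_def[cbind(fi, fj)])
  hasE <- ifelse(fi == nx, FALSE, vE_def[cbind(fi, fj)])
  freeW <- (fi == 1L) & pressure_mode
  freeE <- fi == nx
  wallW <- !hasW & !freeW
  wallE <- !hasE & !freeE
  # quadratic wall flux needs the opposite neighbour open
  quadW <- wallW & hasE
  quadE <- wallE & hasW
  diag_x <- ifelse(hasW, 1, ifelse(quadW, 4 - 1, ifelse(freeW, 0, 2))) +
    ifelse(hasE, 1, ifelse(quadE, 4 - 1, ifelse(freeE, 0, 2)))
  # note: quad side contributes 4 to the diagonal but adjusts the opposite
  # off-diagonal from 1 to 4/3, hence the net extra 3 on the diagonal and
  # the correction below
  cE_off <- ifelse(hasE, ifelse(quadW, 4 / 3, 1), 0)
  cW_off <- ifelse(hasW, ifelse(quadE, 4 / 3, 1), 0)
  diag_v <- 1 + a_u * (2 / hy^2 + diag_x / hx^2)
  push(me, me, diag_v)
  push(me, idv[cbind(fi, fj - 1L)], rep(-a_u / hy^2, length(me)))
  push(me, idv[cbind(fi, fj + 1L)], rep(-a_u / hy^2, length(me)))
  selW <- cW_off > 0
  push(me[selW], idv[cbind(fi[selW] - 1L, fj[selW])], -a_u * cW_off[selW] / hx^2)
  selE <- cE_off > 0
  push(me[selE], idv[cbind(fi[selE] + 1L, fj[selE])], -a_u * cE_off[selE] / hx^2)
  others <- setdiff(seq_len(nx * (ny + 1)), me)
  push(others, others, rep(1, length(others)))
  A_v <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = rep(nx * (ny + 1), 2))
  lu_v <- Matrix::lu(A_v)

  # x-direction neighbour-class masks for v (used by the explicit operator)
  iM <- matrix(seq_len(nx), nx, ny + 1)
  hasW_m <- (iM > 1L) & vW_def
  hasE_m <- (iM < nx) & vE_def
  freeW_m <- (iM == 1L) & pressure_mode
  freeE_m <- iM == nx
  wallW_m <- !hasW_m & !freeW_m
  wallE_m <- !hasE_m & !freeE_m
  v_xpart <- lapply(list(
    both = hasW_m & hasE_m,
    quadW = wallW_m & hasE_m,
    quadE = wallE_m & hasW_m,
    freeW_openE = freeW_m & hasE_m,
    freeE_openW = freeE_m & hasW_m,
    wall_both = wallW_m & wallE_m,
    free_wallE = freeW_m & wallE_m,
    free_wallW = wallW_m & freeE_m,
    free_wall = (freeW_m & wallE_m) | (wallW_m & freeE_m)), function(m) m * 1)

  # --- Poisson -----------------------------------------------------------
  idp <- matrix(seq_len(nx * ny), nx, ny)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  ii <- which(Fl, arr.ind = TRUE)
  fi <- ii[, 1]; fj <- ii[, 2]
  me <- idp[cbind(fi, fj)]
  nb <- function(di, dj) {
    gi <- fi + di; gj <- fj + dj
    ok <- gi >= 1L & gi <= nx & gj >= 1L & gj <= ny
    res <- rep(FALSE, length(fi))
    res[ok] <- Fl[cbind(gi[ok], gj[ok])]
    res
  }
  fW <- nb(-1L, 0L); fE <- nb(1L, 0L); fS <- nb(0L, -1L); fN <- nb(0L, 1L)
  outlet_cell <- fi == nx
  inlet_cell <- fi == 1L
  cW <- ifelse(fW, 1, ifelse(inlet_cell & pressure_mode, 2, 0)) / hx^2
  cE <- ifelse(fE, 1, ifelse(outlet_cell, 2, 0)) / hx^2
  cS <- ifelse(fS, 1, 0) / hy^2
  cN <- ifelse(fN, 1, 0) / hy^2
  push(me, me, cW + cE + cS + cN)
  push(me[fW], idp[cbind(fi[fW] - 1L, fj[fW])], rep(-1 / hx^2, sum(fW)))
  push(me[fE], idp[cbind(fi[fE] + 1L, fj[fE])], rep(-1 / hx^2, sum(fE)))
  push(me[fS], idp[cbind(fi[fS], fj[fS] - 1L)], rep(-1 / hy^2, sum(fS)))
  push(me[fN], idp[cbind(fi[fN], fj[fN] + 1L)], rep(-1 / hy^2, sum(fN)))
  others <- setdiff(seq_len(nx * ny), me)
  push(others, others, rep(1, length(others)))
  A_p <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = rep(nx * ny, 2))
  chol_p <- Matrix::Cholesky(Matrix::forceSymmetric(A_p), LDL = FALSE, perm = TRUE)
  p_dirichlet_in <- inlet_cell & !fW & pressure_mode
  inlet_dir_rows <- me[p_dirichlet_in]

  # inlet parabolic profile, normalized so the discrete mean is exactly 1
  jj <- which(Fl[1, ])
  xi <- (2 * (mesh$yc[jj] - mesh$geom$parent_width / 2) / mesh$geom$parent_width)
  shape <- 1.5 * (1 - xi^2)
  shape <- shape / mean(shape)

  # coil sink factors at faces (0, 0.5 or 1 weighting)
  Co <- mesh$coil * 1
  cfac_u <- (rbind(0, Co) + rbind(Co, 0)) / 2 * u_int  # only solved faces
  cfac_v <- (cbind(0, Co) + cbind(Co, 0)) / 2 * v_int

  ws <- new.env(parent = emptyenv())
  ws$mesh <- mesh; ws$dt <- dt; ws$mu0 <- mu0; ws$rho <- rho
  ws$nx <- nx; ws$ny <- ny; ws$hx <- hx; ws$hy <- hy
  ws$Fl <- Fl
  ws$u_int <- u_int; ws$u_def <- u_def; ws$u_inlet <- u_inlet
  ws$u_outlet <- u_outlet; ws$u_zero <- u_zero
  ws$uN_def_n <- uN_def * 1; ws$uS_def_n <- uS_def * 1
  ws$v_int <- v_int; ws$v_def <- v_def
  ws$vE_def_n <- vE_def * 1; ws$vW_def_n <- vW_def * 1
  ws$v_xpart <- v_xpart
  ws$lu_u <- lu_u; ws$lu_v <- lu_v; ws$chol_p <- chol_p
  ws$inlet_rows_j <- jj; ws$inlet_shape <- shape
  ws$cfac_u <- cfac_u; ws$cfac_v <- cfac_v
  ws$coil_face_u <- cfac_u > 0; ws$coil_face_v <- cfac_v > 0
  ws$pressure_mode <- pressure_mode
  ws$inlet_dir_rows <- inlet_dir_rows
  ws$wall_geom <- wall_probe_geometry(mesh)
  ws
}

# Precompute index arrays for wall traction probes (one row per wall face,
# in boundary-walk order): linear indices of the near and far tangential
# velocity samples and the adjacent pressure cell.
wall_probe_geometry <- function(mesh) {
  bf <- wall_faces(mesh)
  nx <- mesh$nx; ny <- mesh$ny
  nu <- (nx + 1) * ny
  idu <- function(i, j) i + (nx + 1) * (j - 1)
  idv <- function(i, j) i + nx * (j - 1)
  n <- nrow(bf)
  near1 <- near2 <- far1 <- far2 <- integer(n)
  has_far <- logical(n); horiz <- logical(n)
  dn <- numeric(n); tsign <- numeric(n)
  for (k in seq_len(n)) {
    i <- bf$i[k]; j <- bf$j[k]; side <- bf$side[k]
    if (side == "S" || side == "N") {
      horiz[k] <- TRUE; dn[k] <- mesh$hy
      near1[k] <- idu(i, j); near2[k] <- idu(i + 1, j)
      j2 <- if (side == "S") j + 1L else j - 1L
      ok <- j2 >= 1L && j2 <= ny && mesh$fluid[i, j2]
      has_far[k] <- ok
      if (ok) { far1[k] <- idu(i, j2); far2[k] <- idu(i + 1, j2) }
      tsign[k] <- 1
    } else {
      horiz[k] <- FALSE; dn[k] <- mesh$hx
      near1[k] <- idv(i, j); near2[k] <- idv(i, j + 1L)
      i2 <- if (side == "W") i + 1L else i - 1L
      ok <- i2 >= 1L && i2 <= nx && mesh$fluid[i2, j]
      has_far[k] <- ok
      if (ok) { far1[k] <- idv(i2, j); far2[k] <- idv(i2, j + 1L) }
      tsign[k] <- 1
    }
  }
  pidx <- bf$i + nx * (bf$j - 1)
  list(faces = bf, near1 = near1, near2 = near2, far1 = far1, far2 = far2,
       has_far = has_far, horiz = horiz, dn = dn, pcell = pidx, nu = nu)
}

#' Initial flow state
#'
#' Quiescent (zero-velocity, zero-pressure) state bound to a mesh, with
#' the solver workspace (sparse factorizations) attached.
#'
#' @param mesh a \code{sacflow_mesh}.
#' @param props \code{\link{blood_properties}}.
#' @param coil \code{\link{coil_properties}} or \code{NULL} for no coil.
#' @param w \code{\link{pulsatile_waveform}} (may be \code{NULL} in
#'   pressure-inlet mode).
#' @param cfg \code{\link{solver_config}}.
#' @return An object of class \code{flow_state}: velocity fields \code{u}
#'   (x-faces), \code{v} (y-faces), pressure \code{p} (cells), apparent
#'   viscosity \code{mu} (cells), \code{time}, \code{step}.
#' @export
initial_state <- function(mesh, props, coil, w, cfg) {
  ws <- solver_workspace(mesh, props, coil, cfg, w)
  state <- list(u = matrix(0, mesh$nx + 1, mesh$ny),
                v = matrix(0, mesh$nx, mesh$ny + 1),
                p = matrix(0, mesh$nx, mesh$ny),
                mu = matrix(props$mu_inf, mesh$nx, mesh$ny),
                time = 0, step = 0L,
                max_divergence = 0,
                .ws = ws)
  class(state) <- "flow_state"
  state
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> t = %.5f s, step %d, max|u| = %.4g m/s, max|div| = %.3g 1/s\n",
              x$time, x$step, max(abs(x$u)), x$max_divergence))
  invisible(x)
}

# shear-rate magnitude at cell centres: sqrt(2 ux^2 + 2 vy^2 + (uy+vx)^2)
cell_shear_rate <- function(U, V, ws) {
  nx <- ws$nx; ny <- ws$ny; hx <- ws$hx; hy <- ws$hy
  ux <- (U[2:(nx + 1), , drop = FALSE] - U[1:nx, , drop = FALSE]) / hx
  vy <- (V[, 2:(ny + 1), drop = FALSE] - V[, 1:ny, drop = FALSE]) / hy
  # cross shear at nodes with no-slip ghosting, averaged to centres
  dudy <- node_dudy(U, ws)
  dvdx <- node_dvdx(V, ws)
  S <- dudy + dvdx                              # (nx+1) x (ny+1) nodes
  Sc <- 0.25 * (S[1:nx, 1:ny] + S[2:(nx + 1), 1:ny] +
                S[1:nx, 2:(ny + 1)] + S[2:(nx + 1), 2:(ny + 1)])
  sqrt(pmax(2 * ux^2 + 2 * vy^2 + Sc^2, 0))
}

# du/dy at grid nodes ((nx+1) x (ny+1)), reflecting across walls
node_dudy <- function(U, ws) {
  hy <- ws$hy
  Ud <- ws$u_def
  top <- rbind2pad(U, Ud)     # list(top value, bottom value) with ghosts
  (top$up - top$dn) / hy
}

rbind2pad <- function(U, Ud) {
  # values above and below each node line j = 1..ny+1 (node y = (j-1)*hy):
  # above: U[, j] (face in row j), below: U[, j-1]; ghost by reflection
  nxp <- nrow(U); ny <- ncol(U)
  up <- cbind(U, 0); dn <- cbind(0, U)               # (nx+1) x (ny+1)
  ud_up <- cbind(Ud, FALSE); ud_dn <- cbind(FALSE, Ud)
  up2 <- ifelse(ud_up, up, -dn)
  dn2 <- ifelse(ud_dn, dn, -up)
  list(up = up2, dn = dn2)
}

# dv/dx at grid nodes, reflecting across walls
node_dvdx <- function(V, ws) {
  hx <- ws$hx
  Vd <- ws$v_def
  rt <- rbind(V, 0); lt <- rbind(0, V)               # (nx+1) x (ny+1)
  vd_rt <- rbind(Vd, FALSE); vd_lt <- rbind(FALSE, Vd)
  rt2 <- ifelse(vd_rt, rt, -lt)
  lt2 <- ifelse(vd_lt, lt, -rt)
  (rt2 - lt2) / hx
}

# node viscosity: fluid-weighted average of adjacent cell viscosities
node_viscosity <- function(MU, ws) {
  Fn <- ws$Fl * 1
  pad <- function(M) cbind(rbind(0, M), 0)  # place cell (i,j) at node (i+1, j+1)? see below
  # node (i,j) touches cells (i-1,j-1), (i,j-1), (i-1,j), (i,j)
  Mz <- MU * Fn
  num <- padTL(Mz) + padTR(Mz) + padBL(Mz) + padBR(Mz)
  den <- padTL(Fn) + padTR(Fn) + padBL(Fn) + padBR(Fn)
  out <- num / pmax(den, 1)
  out[den == 0] <- ws$mu0
  out
}
padTL <- function(M) { nx <- nrow(M); ny <- ncol(M); out <- matrix(0, nx + 1, ny + 1); out[2:(nx + 1), 2:(ny + 1)] <- M; out }
padTR <- function(M) { nx <- nrow(M); ny <- ncol(M); out <- matrix(0, nx + 1, ny + 1); out[1:nx, 2:(ny + 1)] <- M; out }
padBL <- function(M) { nx <- nrow(M); ny <- ncol(M); out <- matrix(0, nx + 1, ny + 1); out[2:(nx + 1), 1:ny] <- M; out }
padBR <- function(M) { nx <- nrow(M); ny <- ncol(M); out <- matrix(0, nx + 1, ny + 1); out[1:nx, 1:ny] <- M; out }

# reference-viscosity Laplacian of U matching the implicit operator
# (one-sided quadratic wall flux in the tangential-wall direction)
applyLu <- function(U, ws) {
  hx <- ws$hx; hy <- ws$hy
  UE <- shiftm(U, -1, 0); UW <- shiftm(U, 1, 0)
  UN <- shiftm(U, 0, -1); US <- shiftm(U, 0, 1)
  nNd <- ws$uN_def_n; nSd <- ws$uS_def_n
  both <- nNd * nSd
  wallN <- (1 - nNd) * nSd
  wallS <- nNd * (1 - nSd)
  none <- (1 - nNd) * (1 - nSd)
  ypart <- both * (UN - 2 * U + US) +
    wallN * ((4 / 3) * US - 4 * U) +
    wallS * ((4 / 3) * UN - 4 * U) +
    none * (-4 * U)
  (UE - 2 * U + UW) / hx^2 + ypart / hy^2
}

applyLv <- function(V, ws) {
  nx <- ws$nx; hx <- ws$hx; hy <- ws$hy
  VN <- shiftm(V, 0, -1); VS <- shiftm(V, 0, 1)
  VE <- shiftm(V, -1, 0); VW <- shiftm(V, 1, 0)
  xp <- ws$v_xpart
  xpart <- xp$both * (VE - 2 * V + VW) +
    xp$quadW * ((4 / 3) * VE - 4 * V) +
    xp$quadE * ((4 / 3) * VW - 4 * V) +
    xp$freeW_openE * (VE - V) +        # zero-gradient W, open E
    xp$freeE_openW * (VW - V) +        # zero-gradient E, open W
    xp$wall_both * (-4 * V) +
    xp$free_wall * (-2 * V)            # one free side, one (linear) wall side
  (VN - 2 * V + VS) / hy^2 + xpart / hx^2
}

# one time step: explicit advection + semi-implicit viscosity + implicit
# sink + Chorin projection.  Internal core; see advance() for the
# user-facing contract.
step_once <- function(state, props, coil, w, cfg, mu_override = NULL) {
  ws <- state$.ws
  nx <- ws$nx; ny <- ws$ny; hx <- ws$hx; hy <- ws$hy
  dt <- ws$dt; rho <- ws$rho; mu0 <- ws$mu0
  U <- state$u; V <- state$v
  t_new <- state$time + dt

  # viscosity from current shear rate (or the Picard iterate's viscosity)
  if (!is.null(mu_override)) {
    MU <- mu_override
  } else if (props$tau_y > 0) {
    gam <- cell_shear_rate(U, V, ws)
    MU <- casson_viscosity(gam, props)
  } else MU <- state$mu
  MUn <- node_viscosity(MU, ws)

  # --- explicit terms on u ----------------------------------------------
  UE <- shiftm(U, -1, 0); UW <- shiftm(U, 1, 0)
  UN <- shiftm(U, 0, -1); US <- shiftm(U, 0, 1)
  nNd <- ws$uN_def_n; nSd <- ws$uS_def_n
  UNg <- nNd * UN - (1 - nNd) * U
  USg <- nSd * US - (1 - nSd) * U
  Vc <- V[, 1:ny, drop = FALSE] + V[, 2:(ny + 1), drop = FALSE]
  Vbar <- matrix(0, nx + 1, ny)
  Vbar[2:nx, ] <- 0.25 * (Vc[1:(nx - 1), , drop = FALSE] + Vc[2:nx, , drop = FALSE])
  dudx <- ifelse(U >= 0, (U - UW) / hx, (UE - U) / hx)
  dudy <- ifelse(Vbar >= 0, (U - USg) / hy, (UNg - U) / hy)
  adv_u <- U * dudx + Vbar * dudy

  # full variable-viscosity stress divergence, x-component
  MC <- MU; MC[!ws$Fl] <- mu0
  MCe <- rbind(MC, mu0); MCw <- rbind(mu0, MC)        # at u-faces
  T1 <- 2 * (MCe * (UE - U) - MCw * (U - UW)) / hx^2
  Vr <- rbind(V, 0); Vl <- rbind(0, V)                # (nx+1) x (ny+1)
  dvdx_n <- (Vr - Vl) / hx
  # du/dy at the face's top/bottom node: quadratic one-sided at walls
  Stop_sh <- nNd * (UN - U) / hy +
    (1 - nNd) * (nSd * (-(9 * U - US) / (3 * hy)) + (1 - nSd) * (-2 * U / hy))
  Sbot_sh <- nSd * (U - US) / hy +
    (1 - nSd) * (nNd * ((9 * U - UN) / (3 * hy)) + (1 - nNd) * (2 * U / hy))
  Stop <- Stop_sh + dvdx_n[, 2:(ny + 1), drop = FALSE]
  Sbot <- Sbot_sh + dvdx_n[, 1:ny, drop = FALSE]
  T2 <- (MUn[, 2:(ny + 1), drop = FALSE] * Stop -
           MUn[, 1:ny, drop = FALSE] * Sbot) / hy
  visc_u <- T1 + T2

  # velocity-inlet mode runs incremental projection (predictor carries the
  # old pressure gradient; the Poisson solve returns the increment), which
  # keeps the steady Darcy balance exact even for stiff coil sinks.
  # Pressure-inlet mode uses the non-incremental form with the prescribed
  # inlet pressure as a Dirichlet value.
  incremental <- !ws$pressure_mode
  P <- state$p
  rhs_u_int <- U + dt * (-adv_u + visc_u / rho - (mu0 / rho) * applyLu(U, ws))

  # --- explicit terms on v ----------------------------------------------
  VN <- shiftm(V, 0, -1); VS <- shiftm(V, 0, 1)
  VE <- shiftm(V, -1, 0); VW <- shiftm(V, 1, 0)
  nEd <- ws$vE_def_n; nWd <- ws$vW_def_n
  VEg <- nEd * VE - (1 - nEd) * V
  VWg <- nWd * VW - (1 - nWd) * V
  VEg[nx, ] <- V[nx, ]                                 # outlet: zero-gradient
  if (ws$pressure_mode) VWg[1, ] <- V[1, ] else VWg[1, ] <- -V[1, ]
  Uc <- U[1:nx, , drop = FALSE] + U[2:(nx + 1), , drop = FALSE]
  Ubar <- matrix(0, nx, ny + 1)
  Ubar[, 2:ny] <- 0.25 * (Uc[, 1:(ny - 1), drop = FALSE] + Uc[, 2:ny, drop = FALSE])
  dvdy <- ifelse(V >= 0, (V - VS) / hy, (VN - V) / hy)
  dvdx <- ifelse(Ubar >= 0, (V - VWg) / hx, (VEg - V) / hx)
  adv_v <- Ubar * dvdx + V * dvdy

  MCn <- cbind(MC, mu0); MCs <- cbind(mu0, MC)         # at v-faces
  T2v <- 2 * (MCn * (VN - V) - MCs * (V - VS)) / hy^2
  Ua <- cbind(U, 0); Ub <- cbind(0, U)                 # (nx+1) x (ny+1)
  dudy_n <- (Ua - Ub) / hy
  xp <- ws$v_xpart
  # dv/dx at the face's east/west node, matching applyLv case by case
  Se_sh <- (xp$both + xp$freeW_openE + xp$quadW) * (VE - V) / hx +
    xp$quadE * (-(9 * V - VW) / (3 * hx)) +
    (xp$wall_both + xp$free_wallE) * (-2 * V / hx)
  Sw_sh <- (xp$both + xp$freeE_openW + xp$quadE) * (V - VW) / hx +
    xp$quadW * ((9 * V - VE) / (3 * hx)) +
    (xp$wall_both + xp$free_wallW) * (2 * V / hx)
  Se <- Se_sh + dudy_n[2:(nx + 1), , drop = FALSE]
  Sw <- Sw_sh + dudy_n[1:nx, , drop = FALSE]
  T1v <- (MUn[2:(nx + 1), , drop = FALSE] * Se -
            MUn[1:nx, , drop = FALSE] * Sw) / hx
  visc_v <- T2v + T1v

  rhs_v_int <- V + dt * (-adv_v + visc_v / rho - (mu0 / rho) * applyLv(V, ws))

  # --- implicit reference-viscosity solve -------------------------------
  b_u <- matrix(0, nx + 1, ny)
  b_u[ws$u_int] <- rhs_u_int[ws$u_int]
  if (!ws$pressure_mode) {
    u_in <- inlet_velocity(t_new, w) * ws$inlet_shape
    b_u[1, ws$inlet_rows_j] <- u_in
  }
  Ustar <- matrix(as.numeric(Matrix::solve(ws$lu_u, as.vector(b_u))), nx + 1, ny)

  b_v <- matrix(0, nx, ny + 1)
  b_v[ws$v_int] <- rhs_v_int[ws$v_int]
  Vstar <- matrix(as.numeric(Matrix::solve(ws$lu_v, as.vector(b_v))), nx, ny + 1)

  # old-pressure gradient (incremental projection), applied after the
  # viscous solve so the implicit sink division below also damps it —
  # required for stable stiff Darcy/pressure balance in coil cells
  if (incremental) {
    Gpx <- matrix(0, nx + 1, ny)
    Gpx[2:nx, ] <- (P[2:nx, , drop = FALSE] - P[1:(nx - 1), , drop = FALSE]) / hx
    Ustar[ws$u_int] <- Ustar[ws$u_int] - (dt / rho) * Gpx[ws$u_int]
    Gpy <- matrix(0, nx, ny + 1)
    Gpy[, 2:ny] <- (P[, 2:ny, drop = FALSE] - P[, 1:(ny - 1), drop = FALSE]) / hy
    Vstar[ws$v_int] <- Vstar[ws$v_int] - (dt / rho) * Gpy[ws$v_int]
  }

  # --- implicit Darcy-Forchheimer sink in coil faces --------------------
  if (!is.null(coil)) {
    k <- coil$permeability; C2 <- coil$inertial_coef
    if (any(ws$coil_face_u)) {
      mu_fu <- 0.5 * (MCe + MCw)
      spd_u <- sqrt(U^2 + Vbar^2)
      den_u <- 1 + ws$cfac_u * dt * (mu_fu / (rho * k) + 0.5 * C2 * spd_u)
      Ustar <- Ustar / den_u
    }
    if (any(ws$coil_face_v)) {
      mu_fv <- 0.5 * (MCn + MCs)
      spd_v <- sqrt(V^2 + Ubar^2)
      den_v <- 1 + ws$cfac_v * dt * (mu_fv / (rho * k) + 0.5 * C2 * spd_v)
      Vstar <- Vstar / den_v
    }
  }
  Ustar[!ws$u_def] <- 0; Ustar[ws$u_zero] <- 0
  Vstar[!ws$v_def] <- 0; Vstar[!ws$v_int] <- 0

  # --- projection --------------------------------------------------------
  div <- (Ustar[2:(nx + 1), , drop = FALSE] - Ustar[1:nx, , drop = FALSE]) / hx +
    (Vstar[, 2:(ny + 1), drop = FALSE] - Vstar[, 1:ny, drop = FALSE]) / hy
  rhs_p <- -(rho / dt) * div
  rhs_p[!ws$Fl] <- 0
  b_p <- as.vector(rhs_p)
  if (ws$pressure_mode && length(ws$inlet_dir_rows)) {
    P_in <- cfg$pressure_inlet(t_new)
    b_p[ws$inlet_dir_rows] <- b_p[ws$inlet_dir_rows] + 2 * P_in / hx^2
  }
  phi <- matrix(as.numeric(Matrix::solve(ws$chol_p, b_p)), nx, ny)

  Unew <- Ustar
  gpx <- (phi[2:nx, , drop = FALSE] - phi[1:(nx - 1), , drop = FALSE]) / hx
  idx_int <- ws$u_int
  Gx <- matrix(0, nx + 1, ny); Gx[2:nx, ] <- gpx
  Unew[idx_int] <- Ustar[idx_int] - (dt / rho) * Gx[idx_int]
  # outlet faces: Dirichlet phi = 0 at the face, one-sided gradient
  jout <- which(ws$Fl[nx, ])
  Unew[nx + 1, jout] <- Ustar[nx + 1, jout] - (dt / rho) * (0 - phi[nx, jout]) / (hx / 2)
  if (ws$pressure_mode) {
    P_in <- cfg$pressure_inlet(t_new)
    jin <- which(ws$Fl[1, ])
    Unew[1, jin] <- Ustar[1, jin] - (dt / rho) * (phi[1, jin] - P_in) / (hx / 2)
  }
  Vnew <- Vstar
  gpy <- (phi[, 2:ny, drop = FALSE] - phi[, 1:(ny - 1), drop = FALSE]) / hy
  Gy <- matrix(0, nx, ny + 1); Gy[, 2:ny] <- gpy
  Vnew[ws$v_int] <- Vstar[ws$v_int] - (dt / rho) * Gy[ws$v_int]

  div2 <- (Unew[2:(nx + 1), , drop = FALSE] - Unew[1:nx, , drop = FALSE]) / hx +
    (Vnew[, 2:(ny + 1), drop = FALSE] - Vnew[, 1:ny, drop = FALSE]) / hy
  maxdiv <- max(abs(div2[ws$Fl]))

  if (!all(is.finite(Unew)) || !all(is.finite(Vnew)))
    stopf("solver produced non-finite fields at t = %g s (step %d): unstable or invalid setup",
          t_new, state$step + 1L)

  Pnew <- if (incremental) P + phi else phi
  Pnew[!ws$Fl] <- 0
  state$u <- Unew; state$v <- Vnew; state$p <- Pnew; state$mu <- MU
  state$time <- t_new; state$step <- state$step + 1L
  state$max_divergence <- maxdiv
  state
}

#' Advance the flow state by one time step
#'
#' One step of the projection scheme: refresh the apparent-viscosity field
#' from the local shear rate (Casson), apply explicit upwind advection and
#' the explicit part of the variable-viscosity stress, solve the implicit
#' reference-viscosity Helmholtz systems, apply the coil momentum sink
#' pointwise-implicitly, and project onto divergence-free fields.  When
#' \code{cfg$max_inner_iterations > 1} the step is Picard-iterated with
#' refreshed coefficients until the relative change is below
#' \code{cfg$nonlinear_tolerance}; exceeding the iteration budget aborts
#' with the residual history in the error.
#'
#' @param state a \code{flow_state} from \code{\link{initial_state}}.
#' @param mesh the mesh the state was created on.
#' @param props \code{\link{blood_properties}}.
#' @param coil \code{\link{coil_properties}} or \code{NULL}.
#' @param w \code{\link{pulsatile_waveform}} (ignored in pressure-inlet mode).
#' @param cfg \code{\link{solver_config}}.
#' @return The advanced \code{flow_state}; its \code{max_divergence} field
#'   holds the post-projection divergence, checked against
#'   \code{cfg$divergence_tolerance}.
#' @export
advance <- function(state, mesh, props, coil, w, cfg) {
  if (!inherits(state, "flow_state")) stopf("'state' must be a flow_state")
  if (is.null(state$.ws)) {
    state$.ws <- solver_workspace(mesh, props, coil, cfg, w)
  }
  if (cfg$max_inner_iterations <= 1L) {
    new <- step_once(state, props, coil, w, cfg)
  } else {
    # Picard on the nonlinear (shear-dependent) viscosity: re-advance the
    # base state with the viscosity of the latest end-of-step iterate
    prev <- step_once(state, props, coil, w, cfg)
    hist <- numeric(0)
    converged <- FALSE
    for (it in 2:cfg$max_inner_iterations) {
      mu_k <- if (props$tau_y > 0)
        casson_viscosity(cell_shear_rate(prev$u, prev$v, state$.ws), props)
      else prev$mu
      cand <- step_once(state, props, coil, w, cfg, mu_override = mu_k)
      res <- max(abs(cand$u - prev$u)) / max(max(abs(cand$u)), 1e-12)
      hist <- c(hist, res)
      prev <- cand
      if (res < cfg$nonlinear_tolerance) { converged <- TRUE; break }
    }
    if (!converged)
      stopf("inner iterations exceeded max_inner_iterations = %d without reaching nonlinear_tolerance = %g; residual history: %s",
            cfg$max_inner_iterations, cfg$nonlinear_tolerance,
            paste(signif(hist, 3), collapse = ", "))
    new <- prev
  }
  if (new$max_divergence > cfg$divergence_tolerance)
    warnf("post-projection divergence %.3g 1/s exceeds tolerance %.3g 1/s",
          new$max_divergence, cfg$divergence_tolerance)
  new
}

# wall traction (tangential viscous stress vector) + wall pressure at the
# ordered wall faces; one-sided second order where two interior samples
# exist, first order otherwise.  Local apparent viscosity from the wall
# shear rate itself (Casson) or the constant viscosity (Newtonian).
wall_traction <- function(state, ws, props) {
  wg <- ws$wall_geom
  U <- as.vector(state$u); V <- as.vector(state$v)
  val <- function(idx, horiz) ifelse(horiz, U[pmax(idx, 1)], V[pmax(idx, 1)])
  t1 <- 0.5 * (val(wg$near1, wg$horiz) + val(wg$near2, wg$horiz))
  t2 <- 0.5 * (val(wg$far1, wg$horiz) + val(wg$far2, wg$horiz))
  slope <- ifelse(wg$has_far,
                  (9 * t1 - t2) / (3 * wg$dn),
                  2 * t1 / wg$dn)
  mu_w <- if (props$tau_y > 0) casson_viscosity(abs(slope), props) else props$mu_inf
  tau <- mu_w * slope
  tx <- ifelse(wg$horiz, tau, 0)
  ty <- ifelse(wg$horiz, 0, tau)
  pr <- as.vector(state$p)[wg$pcell]
  list(tx = tx, ty = ty, p = pr)
}

#' Run a full pulsatile simulation
#'
#' Integrates \code{cfg$cycles_to_run} cardiac cycles from rest, discards
#' \code{cfg$cycles_to_discard} startup cycles, records wall tractions
#' (every \code{cfg$wall_stride} steps) over the final cycle into a
#' \code{wall_series}, snapshots the full fields at the four phase
#' landmarks of the final cycle, and reports a cycle-periodicity metric
#' (relative L2 velocity difference between the ends of the last two
#' cycles; a warning is issued above \code{cfg$periodicity_tolerance}).
#'
#' @inheritParams advance
#' @param mesh a \code{sacflow_mesh}.
#' @return An object of class \code{sacflow_result}: list with
#'   \code{snapshots} (named A/B/C/D \code{flow_state}s), \code{wall_series}
#'   (see \code{\link{osi}}), \code{landmarks}, \code{report} (dt, steps per
#'   cycle, periodicity metric, max divergence, config echo), and the
#'   inputs.
#' @export
run_pulsatile <- function(mesh, props, coil, w, cfg) {
  if (!inherits(w, "waveform")) stopf("'w' must be a waveform")
  state <- initial_state(mesh, props, coil, w, cfg)
  ws <- state$.ws
  dt <- ws$dt
  T <- w$period
  n_per <- as.integer(round(T / dt))
  if (abs(n_per * dt - T) > 1e-9 * T)
    warnf("T/dt = %.6f is not an integer; cycle bookkeeping uses %d steps per cycle",
          T / dt, n_per)
  lm <- phase_landmarks(w)
  lmt <- landmark_times(lm)
  total <- cfg$cycles_to_run * n_per
  rec_from <- (cfg$cycles_to_run - 1L) * n_per   # final cycle
  rec_steps <- seq.int(rec_from + 1L, total, by = cfg$wall_stride)
  snap_steps <- (cfg$cycles_to_run - 1L) * n_per +
    pmin(pmax(as.integer(round(lmt / dt)), 1L), n_per)

  wf <- wall_faces(mesh)
  nrec <- length(rec_steps)
  TX <- matrix(0, nrow(wf), nrec); TY <- TX; PW <- TX
  times <- numeric(nrec)
  snapshots <- vector("list", 4L); names(snapshots) <- names(lmt)
  cyc_end <- vector("list", cfg$cycles_to_run)
  maxdiv <- 0
  irec <- 0L
  for (s in seq_len(total)) {
    state <- advance(state, mesh, props, coil, w, cfg)
    maxdiv <- max(maxdiv, state$max_divergence)
    if (s %in% rec_steps) {
      irec <- irec + 1L
      tr <- wall_traction(state, ws, props)
      TX[, irec] <- tr$tx; TY[, irec] <- tr$ty; PW[, irec] <- tr$p
      times[irec] <- state$time - (cfg$cycles_to_run - 1L) * T
    }
    ksnap <- which(snap_steps == s)
    for (k in ksnap) {
      sn <- state; sn$.ws <- NULL
      snapshots[[k]] <- sn
    }
    if (s %% n_per == 0L) {
      cyc_end[[s %/% n_per]] <- list(u = state$u, v = state$v)
    }
  }
  per <- NA_real_
  if (cfg$cycles_to_run >= 2L) {
    a <- cyc_end[[cfg$cycles_to_run - 1L]]; b <- cyc_end[[cfg$cycles_to_run]]
    num <- sqrt(sum((b$u - a$u)^2) + sum((b$v - a$v)^2))
    den <- sqrt(sum(b$u^2) + sum(b$v^2))
    per <- if (den > 0) num / den else 0
    if (per > cfg$periodicity_tolerance)
      warnf("solution not cycle-periodic: relative L2 change %.3g between last two cycles (tolerance %g); consider more startup cycles",
            per, cfg$periodicity_tolerance)
  }
  series <- structure(list(faces = wf, times = times, period = T,
                           tx = TX, ty = TY, pressure = PW),
                      class = "wall_series")
  report <- list(scheme = "projection (non-incremental pressure correction)",
                 dt = dt, steps_per_cycle = n_per,
                 cycles_to_run = cfg$cycles_to_run,
                 cycles_to_discard = cfg$cycles_to_discard,
                 periodicity = per,
                 max_divergence = maxdiv,
                 landmarks = as.list(lmt),
                 landmark_convention = "D = min inlet speed in the half-cycle after max deceleration",
                 reference_viscosity_mu0 = ws$mu0,
                 config = cfg[setdiff(names(cfg), "pressure_inlet")])
  structure(list(mesh = mesh, props = props, coil = coil, waveform = w,
                 cfg = cfg, landmarks = lm, snapshots = snapshots,
                 wall_series = series, report = report),
            class = "sacflow_result")
}

#' @export
print.sacflow_result <- function(x, ...) {
  cat(sprintf("<sacflow_result> %d wall samples x %d times; dt = %.3g s; periodicity = %.3g\n",
              nrow(x$wall_series$faces), length(x$wall_series$times),
              x$report$dt, x$report$periodicity))
  invisible(x)
}

#' Run to steady state with a constant inlet
#'
#' Marches the unsteady solver with a constant mean inlet speed (velocity
#' mode) or constant inlet pressure (pressure mode) until the velocity
#' field stops changing: \eqn{\max|\Delta u| / (dt\, U_{ref})} below
#' \code{steady_tol} (an estimate of the normalized rate of change).
#'
#' @inheritParams run_pulsatile
#' @param inlet_speed constant mean inlet speed, m/s (velocity mode).
#' @param t_max physical time budget, s.
#' @param steady_tol convergence tolerance on the normalized rate, 1/s.
#' @return The converged \code{flow_state} (with workspace attached).
#' @export
run_steady <- function(mesh, props, coil, inlet_speed, cfg,
                       t_max = 5, steady_tol = 1e-3) {
  w0 <- if (cfg$inlet_bc == "velocity")
    pulsatile_waveform(period = 0.8, mean_velocity = inlet_speed,
                       amplitudes = numeric(0), phases = numeric(0))
  else NULL
  state <- initial_state(mesh, props, coil, w0, cfg)
  dt <- state$.ws$dt
  U_ref <- if (cfg$inlet_bc == "velocity") inlet_speed else 1
  n_max <- ceiling(t_max / dt)
  check_every <- 20L
  u_prev <- state$u
  for (s in seq_len(n_max)) {
    state <- advance(state, mesh, props, coil, w0, cfg)
    if (s %% check_every == 0L) {
      rate <- max(abs(state$u - u_prev)) / (check_every * dt * U_ref)
      if (rate < steady_tol) return(state)
      u_prev <- state$u
    }
  }
  warnf("steady state not reached within t_max = %g s (last normalized rate above %g)",
        t_max, steady_tol)
  state
}

#' Cell-centred velocity of a flow state
#'
#' @param state a \code{flow_state}.
#' @param mesh the mesh.
#' @return List with matrices \code{uc}, \code{vc}, \code{speed} (nx x ny);
#'   entries outside the fluid are zero.
#' @export
cell_velocity <- function(state, mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  uc <- 0.5 * (state$u[1:nx, , drop = FALSE] + state$u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (state$v[, 1:ny, drop = FALSE] + state$v[, 2:(ny + 1), drop = FALSE])
  uc[!mesh$fluid] <- 0; vc[!mesh$fluid] <- 0
  list(uc = uc, vc = vc, speed = sqrt(uc^2 + vc^2))
}
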