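# Steady laminar incompressible flow on the voxel grid of a segmented airway.
#
# Discretisation: staggered (MAC) grid — velocity components on cell faces,
# pressure at cell centres. Pseudo-transient projection iterations drive the
# flow to steady state: implicit viscous step (pre-factored sparse Cholesky),
# explicit first-order upwind advection, and a pressure-Poisson projection
# that enforces a divergence-free field each step. Boundary conditions follow
# the inspiratory set-up: pressure fixed at 0 Pa on the open inlet (nostril)
# faces, uniform Dirichlet velocity on the outlet face delivering the
# prescribed volumetric flow, and no-slip walls (tangential wall velocity
# imposed at the half-cell via ghost antisymmetry, so the effective wall sits
# on the voxel face).

axis_side <- function(spec) {
  stopifnot(grepl("^[xyz][+-]$", spec))
  list(axis = match(substr(spec, 1, 1), c("x", "y", "z")),
       side = substr(spec, 2, 2))
}

# shift array: result[idx] = A[idx + o], `fill` outside
ashift <- function(A, o, fill = 0) {
  d <- dim(A)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (o[ax] >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o[ax])
      src[[ax]] <- seq_len(d[ax] - o[ax]) + o[ax]
    } else {
      dst[[ax]] <- seq_len(d[ax] + o[ax]) - o[ax]
      src[[ax]] <- seq_len(d[ax] + o[ax])
    }
    if (length(dst[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

unit3 <- function(axis) { e <- c(0, 0, 0); e[axis] <- 1; e }

# face types: 0 solid/closed, 1 unknown interior, 2 Dirichlet velocity
# (outlet), 3 open pressure inlet (velocity updated by projection only)
classify_faces <- function(F, axis, inlet, outlet) {
  d <- dim(F)
  e <- unit3(axis)
  df <- d + e
  Lf <- array(FALSE, df) # cell on the low side of the face is fluid
  Rf <- array(FALSE, df)
  idxL <- lapply(1:3, function(ax) seq_len(d[ax]))
  idxH <- lapply(1:3, function(ax) if (ax == axis) seq_len(d[ax]) + 1 else seq_len(d[ax]))
  Lf[idxH[[1]], idxH[[2]], idxH[[3]]] <- F
  Rf[idxL[[1]], idxL[[2]], idxL[[3]]] <- F
  type <- array(0L, df)
  type[Lf & Rf] <- 1L
  mark_open <- function(type, spec, code) {
    as <- axis_side(spec)
    if (as$axis != axis) return(type)
    if (as$side == "-") {
      sl <- slice_index(df, axis, 1)
      open <- Rf[sl[[1]], sl[[2]], sl[[3]]] & !Lf[sl[[1]], sl[[2]], sl[[3]]]
      type[sl[[1]], sl[[2]], sl[[3]]][open] <- code
    } else {
      sl <- slice_index(df, axis, df[axis])
      open <- Lf[sl[[1]], sl[[2]], sl[[3]]] & !Rf[sl[[1]], sl[[2]], sl[[3]]]
      type[sl[[1]], sl[[2]], sl[[3]]][open] <- code
    }
    type
  }
  for (spec in inlet) type <- mark_open(type, spec, 3L)
  type <- mark_open(type, outlet, 2L)
  type
}

slice_index <- function(d, axis, at) {
  idx <- lapply(1:3, function(ax) seq_len(d[ax]))
  idx[[axis]] <- at
  idx
}

# implicit viscous operator for one velocity component
assemble_momentum <- function(type, axis, h, nu, dt) {
  df <- dim(type)
  unknown <- type == 1L
  n <- sum(unknown)
  ids <- array(0L, df)
  ids[unknown] <- seq_len(n)
  diag_c <- rep(1 / dt, n)
  tri_i <- vector("list", 6)
  tri_j <- vector("list", 6)
  rhs_dirs <- list()
  k <- 0
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      k <- k + 1
      o <- unit3(ax) * sgn
      nb_type <- ashift(type, o, fill = 0L)
      nb_id <- ashift(ids, o, fill = 0L)
      tangential <- ax != axis
      # diagonal weights: tangential wall/closed neighbour => ghost
      # antisymmetry (coefficient 2); everything else coefficient 1
      w <- ifelse(tangential & nb_type == 0L, 2, 1)
      diag_c <- diag_c + nu / h^2 * w[unknown]
      link <- unknown & nb_type == 1L
      tri_i[[k]] <- ids[link]
      tri_j[[k]] <- nb_id[link]
    }
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), unlist(tri_i)),
    j = c(seq_len(n), unlist(tri_j)),
    x = c(diag_c, rep(-nu / h^2, length(unlist(tri_i)))),
    dims = c(n, n), symmetric = FALSE
  )
  list(chol = Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
       ids = ids, unknown = unknown, n = n)
}

# pressure-Poisson operator over fluid cells (Neumann walls, ghost Dirichlet
# at open inlet faces)
assemble_poisson <- function(F, types, h) {
  d <- dim(F)
  n <- sum(F)
  ids <- array(0L, d)
  ids[F] <- seq_len(n)
  diag_c <- rep(0, n)
  tri_i <- list(); tri_j <- list()
  k <- 0
  for (ax in 1:3) {
    tf <- types[[ax]]
    for (sgn in c(-1L, 1L)) {
      k <- k + 1
      # type of each cell's face on side sgn along ax
      ftype <- slice_pad(tf, ax, drop_first = sgn > 0)
      nbF <- ashift(F, unit3(ax) * sgn, fill = FALSE)
      nb_id <- ashift(ids, unit3(ax) * sgn, fill = 0L)
      through <- F & ftype == 1L & nbF
      diag_c <- diag_c + (ftype == 1L)[F] * 1
      diag_c <- diag_c + (ftype == 3L)[F] * 2
      link <- through
      tri_i[[k]] <- ids[link]
      tri_j[[k]] <- nb_id[link]
    }
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), unlist(tri_i)),
    j = c(seq_len(n), unlist(tri_j)),
    x = c(diag_c / h^2, rep(-1 / h^2, length(unlist(tri_i)))),
    dims = c(n, n)
  )
  list(chol = Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE), ids = ids, n = n)
}

# face-type array restricted to the faces touching each cell on one side:
# returns an array with cell dims holding the type of the cell's face
slice_pad <- function(face_arr, axis, drop_first) {
  df <- dim(face_arr)
  d <- df - unit3(axis)
  idx <- lapply(1:3, function(ax) {
    if (ax != axis) return(seq_len(d[ax]))
    if (drop_first) seq_len(d[ax]) + 1 else seq_len(d[ax])
  })
  array(face_arr[idx[[1]], idx[[2]], idx[[3]]], dim = d)
}

#' Steady incompressible 3D airflow through a voxel mask
#'
#' Solves steady, Newtonian, homogeneous, incompressible laminar flow on the
#' lumen voxel grid with inspiratory boundary conditions: pressure 0 Pa on
#' the open inlet faces (nostrils), a uniform Dirichlet velocity on the open
#' outlet face scaled to deliver the prescribed flow, and no-slip walls. The
#' scheme is a pseudo-transient MAC projection with implicit diffusion; see
#' the package vignette for numerical details. The Reynolds number is
#' estimated and a warning issued above 2000 (no turbulence closure).
#'
#' @param mask a [binary_mask] of the lumen, connected from inlet to outlet;
#'   voxel spacing must be isotropic.
#' @param inlet character vector of open boundary sides (`"x-"`, `"x+"`,
#'   `"y-"`, `"y+"`, `"z-"`, `"z+"`): volume faces where lumen voxels touch
#'   the boundary become pressure inlets.
#' @param outlet single boundary side string: the Dirichlet-velocity outlet.
#' @param bc a [flow_bc()]; `flow_ml_s` is drawn through the outlet.
#' @param fluid a [fluid_properties()].
#' @param grid_tolerance convergence threshold on the maximum relative
#'   velocity change per pseudo-time step.
#' @param max_iterations iteration cap; exceeding it without convergence is
#'   an error (with a residual report).
#' @param dt_s pseudo-time step, s; default `0.4 h / u_ref` with
#'   `u_ref = peak_factor` times the outlet speed.
#' @param peak_factor expected ratio of peak to outlet speed (CFL safety;
#'   raise for strongly constricted geometries).
#' @param outlet_profile `"extrapolated"` (default) imposes a zero-gradient
#'   outlet shape rescaled every iteration to deliver exactly the prescribed
#'   flow — the constant-Q condition without forcing an artificial flat
#'   profile; `"uniform"` imposes a flat Dirichlet profile.
#' @param verbose print residuals every few iterations.
#' @return a `flow_3d` object: face velocities `u`, `v`, `w` (m/s), cell
#'   `speed` (m/s), cell `pressure_pa`, iteration diagnostics and the
#'   applied boundary conditions.
#' @export
solve_flow_3d <- function(mask, inlet = "z-", outlet = "z+",
                          bc = flow_bc(), fluid = fluid_properties(),
                          grid_tolerance = 1e-5, max_iterations = 2000,
                          dt_s = NULL, peak_factor = 4,
                          outlet_profile = c("extrapolated", "uniform"),
                          verbose = FALSE) {
  outlet_profile <- match.arg(outlet_profile)
  stopifnot(inherits(mask, "binary_mask"))
  sp <- mask$spacing_mm
  if (max(sp) - min(sp) > 1e-9 * max(sp)) {
    stop("3D solver requires isotropic voxel spacing", call. = FALSE)
  }
  h <- sp[1] * 1e-3
  F <- mask$voxels
  d <- dim(F)
  rho <- fluid$density_kg_m3
  nu <- fluid$viscosity_pa_s / rho
  Q <- bc$flow_ml_s * 1e-6

  types <- lapply(1:3, function(ax) classify_faces(F, ax, inlet, outlet))
  n_in <- sum(vapply(types, function(t) sum(t == 3L), numeric(1)))
  n_out <- sum(vapply(types, function(t) sum(t == 2L), numeric(1)))
  if (n_in == 0) stop("topology error: no lumen voxels on the inlet boundary", call. = FALSE)
  if (n_out == 0) stop("topology error: no lumen voxels on the outlet boundary", call. = FALSE)

  # Reynolds estimate on the outlet section
  a_out <- n_out * h^2
  u_out <- Q / a_out
  d_h <- 2 * sqrt(a_out / pi)
  re <- rho * u_out * d_h / fluid$viscosity_pa_s
  if (re > 2000) {
    warning(sprintf("Reynolds number ~ %.0f exceeds 2000; laminar solution may not be physical", re),
            call. = FALSE)
  }

  out_as <- axis_side(outlet)
  out_sign <- if (out_as$side == "+") 1 else -1

  vals <- lapply(1:3, function(ax) array(0, d + unit3(ax)))
  for (ax in 1:3) {
    vals[[ax]][types[[ax]] == 2L] <- out_sign * u_out * (ax == out_as$axis)
  }
  # plug-flow initialisation along the outlet axis shortens the transient
  oax <- out_as$axis
  init <- vals[[oax]]
  init[types[[oax]] == 1L] <- out_sign * u_out
  vals[[oax]] <- init

  # linear indices for the extrapolated-outlet update: each outlet face and
  # the same-axis face one cell inward
  out_faces <- which(types[[oax]] == 2L)
  if (length(out_faces)) {
    fo <- arrayInd(out_faces, dim(types[[oax]]))
    fo_in <- fo
    fo_in[, oax] <- fo[, oax] - out_sign
    dfo <- dim(types[[oax]])
    out_inner <- (fo_in[, 3] - 1) * dfo[1] * dfo[2] + (fo_in[, 2] - 1) * dfo[1] + fo_in[, 1]
  }

  if (is.null(dt_s)) dt_s <- 0.4 * h / (peak_factor * abs(u_out))
  mom <- lapply(1:3, function(ax) assemble_momentum(types[[ax]], ax, h, nu, dt_s))
  poi <- assemble_poisson(F, types, h)
  p <- array(0, d) # kinematic pressure P/rho, zero at the inlet

  cell_center_vel <- function(vals) {
    lapply(1:3, function(ax) {
      lo <- slice_pad(vals[[ax]], ax, drop_first = FALSE)
      hi <- slice_pad(vals[[ax]], ax, drop_first = TRUE)
      (lo + hi) / 2
    })
  }

  advection_term <- function(vals, ax) {
    Fa <- vals[[ax]]
    cc <- cell_center_vel(vals)
    # advecting velocity components interpolated to ax-faces
    at_face <- function(comp) {
      df <- dim(Fa)
      out <- array(0, df)
      dlo <- dim(cc[[comp]])
      idxR <- slice_index(df, ax, seq_len(dlo[ax]))
      idxL <- slice_index(df, ax, seq_len(dlo[ax]) + 1)
      A <- array(0, df); B <- array(0, df)
      A[idxR[[1]], idxR[[2]], idxR[[3]]] <- cc[[comp]]    # right cell value at face
      B[idxL[[1]], idxL[[2]], idxL[[3]]] <- cc[[comp]]    # left cell value at face
      (A + B) / 2
    }
    adv <- array(0, dim(Fa))
    for (cax in 1:3) {
      ua <- if (cax == ax) Fa else at_face(cax)
      fwd <- (ashift(Fa, unit3(cax)) - Fa) / h
      bwd <- (Fa - ashift(Fa, -unit3(cax))) / h
      adv <- adv + ifelse(ua > 0, ua * bwd, ua * fwd)
    }
    adv
  }

  grad_p <- function(p, ax) {
    df <- d + unit3(ax)
    g <- array(0, df)
    hi <- array(0, df); lo <- array(0, df)
    idxR <- slice_index(df, ax, seq_len(d[ax]))
    idxL <- slice_index(df, ax, seq_len(d[ax]) + 1)
    hi[idxR[[1]], idxR[[2]], idxR[[3]]] <- p
    lo[idxL[[1]], idxL[[2]], idxL[[3]]] <- p
    (hi - lo) / h
  }

  divergence <- function(vals) {
    div <- array(0, d)
    for (ax in 1:3) {
      lo <- slice_pad(vals[[ax]], ax, drop_first = FALSE)
      hi <- slice_pad(vals[[ax]], ax, drop_first = TRUE)
      div <- div + (hi - lo) / h
    }
    div
  }

  iterations <- 0
  residual <- Inf
  repeat {
    iterations <- iterations + 1
    old <- vals
    star <- vals
    for (ax in 1:3) {
      ty <- types[[ax]]
      unk <- mom[[ax]]$unknown
      if (mom[[ax]]$n == 0) next
      adv <- advection_term(vals, ax)
      gp <- grad_p(p, ax)
      nb_sum <- array(0, dim(ty))
      for (cax in 1:3) {
        for (sgn in c(-1L, 1L)) {
          o <- unit3(cax) * sgn
          nb_t <- ashift(ty, o, fill = 0L)
          nb_v <- ashift(vals[[ax]], o, fill = 0)
          nb_sum <- nb_sum + nb_v * (nb_t != 1L)
        }
      }
      rhs <- (vals[[ax]] / dt_s - adv - gp + nu / h^2 * nb_sum)[unk]
      sol <- as.numeric(Matrix::solve(mom[[ax]]$chol, rhs, system = "A"))
      star[[ax]][unk] <- sol
    }
    # refresh the extrapolated outlet profile before projecting, so the
    # projection enforces zero divergence against the final outlet values
    if (outlet_profile == "extrapolated" && length(out_faces)) {
      shape <- star[[oax]][out_inner]
      tot <- sum(shape) * h^2
      if (abs(tot) > 1e-12 * abs(Q) && sign(tot) == sign(out_sign * Q)) {
        star[[oax]][out_faces] <- shape * (out_sign * Q / tot)
      }
    }
    # projection: A_p is the negative Laplacian, so solve  -lap(phi) = -div/dt
    div <- divergence(star)
    rhs_p <- -div[F] / dt_s
    phi_v <- as.numeric(Matrix::solve(poi$chol, rhs_p, system = "A"))
    phi <- array(0, d)
    phi[F] <- phi_v
    newv <- star
    for (ax in 1:3) {
      ty <- types[[ax]]
      gphi <- grad_p(phi, ax)
      corr <- which(ty == 1L)
      newv[[ax]][corr] <- star[[ax]][corr] - dt_s * gphi[corr]
      open <- which(ty == 3L)
      if (length(open)) {
        # ghost Dirichlet phi = 0 at the open face, half-cell away
        df <- dim(ty)
        fi <- arrayInd(open, df)
        # cell adjacent to each open face
        cell_idx <- fi
        at_low <- fi[, ax] == 1
        cell_idx[, ax] <- ifelse(at_low, 1, fi[, ax] - 1)
        lin <- (cell_idx[, 3] - 1) * d[1] * d[2] + (cell_idx[, 2] - 1) * d[1] + cell_idx[, 1]
        sgn_face <- ifelse(at_low, 1, -1) # +: gradient (phi_c - 0)/(h/2) along +ax at low face
        newv[[ax]][open] <- star[[ax]][open] - dt_s * sgn_face * 2 * phi[lin] / h
      }
    }
    p <- p + phi
    vals <- newv

    umax <- max(abs(unlist(lapply(vals, range))))
    dmax <- max(vapply(1:3, function(ax) max(abs(vals[[ax]] - old[[ax]])), numeric(1)))
    residual <- dmax / max(umax, 1e-300)
    if (verbose && (iterations %% 10 == 1 || !is.finite(residual))) {
      message(sprintf("iter %d: umax %.4g, residual %.4g", iterations, umax, residual))
    }
    if (!is.finite(residual)) {
      stop("solver error: numerical divergence (non-finite velocity field)",
           call. = FALSE)
    }
    if (residual < grid_tolerance) break
    if (iterations >= max_iterations) {
      stop(sprintf(
        "solver error: no convergence in %d iterations (relative residual %.3g, tolerance %.3g)",
        iterations, residual, grid_tolerance), call. = FALSE)
    }
  }

  cc <- cell_center_vel(vals)
  speed <- sqrt(cc[[1]]^2 + cc[[2]]^2 + cc[[3]]^2)
  speed[!F] <- 0
  pressure <- rho * p
  pressure[!F] <- NA_real_
  div_final <- divergence(vals)

  structure(
    list(
      mask = mask, u = vals[[1]], v = vals[[2]], w = vals[[3]],
      speed_m_s = speed, pressure_pa = pressure,
      iterations = iterations, convergence_residual = residual,
      converged = TRUE, div_max = max(abs(div_final[F])),
      reynolds = re, inlet = inlet, outlet = outlet,
      inlet_face_pressure_pa = bc$inlet_pressure_pa,
      bc = bc, fluid = fluid, dt_s = dt_s, h_m = h,
      n_inlet_faces = n_in, n_outlet_faces = n_out
    ),
    class = "flow_3d"
  )
}

#' @export
print.flow_3d <- function(x, ...) {
  cat(sprintf(
    "<flow_3d> %d iterations, residual %.2e, Re ~ %.0f\n  peak speed %.4g m/s, pressure range [%.4g, %.4g] Pa\n",
    x$iterations, x$convergence_residual, x$reynolds,
    max(x$speed_m_s), min(x$pressure_pa, na.rm = TRUE), max(x$pressure_pa, na.rm = TRUE)))
  invisible(x)
}

#' Volumetric flux through each perpendicular grid section
#'
#' Sums the face velocities crossing every plane of constant index along the
#' given axis — for an incompressible solution every section must carry the
#' full prescribed flow.
#'
#' @param solution a `flow_3d`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return tibble with `plane_index` and `flux_ml_s`.
#' @export
slice_flux <- function(solution, axis = 3) {
  vals <- list(solution$u, solution$v, solution$w)[[axis]]
  h <- solution$h_m
  df <- dim(vals)
  flux <- vapply(seq_len(df[axis]), function(k) {
    sl <- slice_index(df, axis, k)
    sum(vals[sl[[1]], sl[[2]], sl[[3]]]) * h^2
  }, numeric(1))
  tibble::tibble(plane_index = seq_len(df[axis]), flux_ml_s = flux * 1e6)
}
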