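#' @importFrom Matrix sparseMatrix Cholesky solve t crossprod Diagonal
NULL

# ---- P1 finite-element Navier-Stokes machinery ---------------------------
#
# Equal-order P1/P1 velocity-pressure discretization with PSPG pressure
# stabilization and streamline-upwind (SU) stabilization of the implicit
# convective term. Each nonlinear (Picard) iteration solves the Oseen
# system
#     [ A + rho (C(w) + S(w))   -W ] [u]   [ b_m ]
#     [ W^T + P(w)               Cp] [p] = [ b_c ]
# where A = mu K (+ rho/dt M in transient mode) is the component-decoupled
# symmetric viscous/mass operator, C(w) the Galerkin convection at the
# previous iterate w, S(w) the streamline diffusion, W_i the pressure
# gradient coupling, P(w) the PSPG convective coupling and Cp the PSPG
# pressure Laplacian. The nonsymmetric system is solved by right-
# preconditioned GMRES; the preconditioner is block upper-triangular with
# sparse Cholesky (CHOLMOD) factorizations of A and of the pressure Schur
# approximation Cp + M_p/mu, both factored once per solve.

# basis gradients and volumes for all tets; returns list(vol, g[,a,i])
.p1_gradients <- function(nodes, tets) {
  M <- nrow(tets)
  x1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - x1
  e2 <- nodes[tets[, 3], , drop = FALSE] - x1
  e3 <- nodes[tets[, 4], , drop = FALSE] - x1
  cx <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
              e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
              e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])      # e2 x e3
  det <- rowSums(e1 * cx)                                  # 6V signed
  cy <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])      # e3 x e1
  cz <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])      # e1 x e2
  g <- array(0, c(M, 4L, 3L))
  g[, 2L, ] <- cx / det
  g[, 3L, ] <- cy / det
  g[, 4L, ] <- cz / det
  g[, 1L, ] <- -(g[, 2L, ] + g[, 3L, ] + g[, 4L, ])
  list(vol = det / 6, g = g)
}

# scalar stiffness  K[a,b] = sum_T weight V g_a . g_b
.assemble_stiffness <- function(tets, vol, g, N, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(vol))
  ii <- jj <- xx <- vector("list", 16L)
  k <- 1L
  for (a in 1:4) for (b in 1:4) {
    ii[[k]] <- tets[, a]
    jj[[k]] <- tets[, b]
    xx[[k]] <- weight * vol * rowSums(g[, a, ] * g[, b, ])
    k <- k + 1L
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(N, N))
}

# pressure-gradient coupling  W_i[a,j] = int N_j dN_a/dx_i = V/4 g_{a,i}
.assemble_w <- function(tets, vol, g, N, dir) {
  ii <- jj <- xx <- vector("list", 16L)
  k <- 1L
  for (a in 1:4) for (b in 1:4) {
    ii[[k]] <- tets[, a]
    jj[[k]] <- tets[, b]
    xx[[k]] <- vol / 4 * g[, a, dir]
    k <- k + 1L
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(N, N))
}

# Galerkin convection  C[a,b] = int N_a (w . grad N_b)
# with w linear: int N_a w_i = V/20 (sum_c w_{c,i} + w_{a,i})
.assemble_convection <- function(tets, vol, g, N, w) {
  wt <- array(0, c(nrow(tets), 4L, 3L))
  for (a in 1:4) wt[, a, ] <- w[tets[, a], , drop = FALSE]
  wsum <- wt[, 1, ] + wt[, 2, ] + wt[, 3, ] + wt[, 4, ]
  ii <- jj <- xx <- vector("list", 16L)
  k <- 1L
  for (a in 1:4) {
    inta <- (vol / 20) * (wsum + wt[, a, ])    # int N_a w, per direction
    for (b in 1:4) {
      ii[[k]] <- tets[, a]
      jj[[k]] <- tets[, b]
      xx[[k]] <- rowSums(inta * g[, b, ])
      k <- k + 1L
    }
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(N, N))
}

# streamline (upwind) diffusion  S[a,b] = sum_T tau V (wbar.grad N_a)(wbar.grad N_b)
.assemble_su <- function(tets, vol, g, N, w, tau) {
  wbar <- (w[tets[, 1], , drop = FALSE] + w[tets[, 2], , drop = FALSE] +
           w[tets[, 3], , drop = FALSE] + w[tets[, 4], , drop = FALSE]) / 4
  d <- matrix(0, nrow(tets), 4L)
  for (a in 1:4) d[, a] <- rowSums(wbar * g[, a, ])
  ii <- jj <- xx <- vector("list", 16L)
  k <- 1L
  for (a in 1:4) for (b in 1:4) {
    ii[[k]] <- tets[, a]
    jj[[k]] <- tets[, b]
    xx[[k]] <- tau * vol * d[, a] * d[, b]
    k <- k + 1L
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(N, N))
}

# PSPG convective coupling  P_d[j,b] = sum_T tau V g_{j,d} (wbar . g_b)
.assemble_pspg_conv <- function(tets, vol, g, N, w, tau, dir) {
  wbar <- (w[tets[, 1], , drop = FALSE] + w[tets[, 2], , drop = FALSE] +
           w[tets[, 3], , drop = FALSE] + w[tets[, 4], , drop = FALSE]) / 4
  db <- matrix(0, nrow(tets), 4L)
  for (b in 1:4) db[, b] <- rowSums(wbar * g[, b, ])
  ii <- jj <- xx <- vector("list", 16L)
  k <- 1L
  for (a in 1:4) for (b in 1:4) {
    ii[[k]] <- tets[, a]
    jj[[k]] <- tets[, b]
    xx[[k]] <- tau * vol * g[, a, dir] * db[, b]
    k <- k + 1L
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(N, N))
}

# lumped mass vector (V/4 to each vertex)
.lumped_mass <- function(tets, vol, N) {
  m <- numeric(N)
  for (a in 1:4) {
    acc <- tapply(vol / 4, tets[, a], sum)
    m[as.integer(names(acc))] <- m[as.integer(names(acc))] + as.numeric(acc)
  }
  m
}

# PSPG stabilization parameter per element (units: s); the continuity
# equation receives sum_K (tau/rho) grad q . R_m
.tau_pspg <- function(vol, props, v_ref, dt = NULL) {
  h <- (6 * sqrt(2) * vol)^(1 / 3)
  nu <- props$mu / props$rho
  inv2 <- (2 * v_ref / h)^2 + (4 * nu / h^2)^2
  if (!is.null(dt)) inv2 <- inv2 + (2 / dt)^2
  1 / sqrt(inv2)
}

# boundary flux of a P1 velocity field through the faces in `sel`
# (positive along the outward normal); exact for linear fields
.face_flux <- function(mesh, u, sel) {
  f <- mesh$boundary_faces[sel, , drop = FALSE]
  nrm <- mesh$face_normal[sel, , drop = FALSE]
  un <- (rowSums(u[f[, 1], , drop = FALSE] * nrm) +
         rowSums(u[f[, 2], , drop = FALSE] * nrm) +
         rowSums(u[f[, 3], , drop = FALSE] * nrm)) / 3
  sum(un * mesh$face_area[sel])
}

# right-preconditioned GMRES (no restart; maxit bounds the Krylov size)
.gmres <- function(apply_A, b, precond, x0 = NULL, tol = 1e-6,
                   maxit = 200L) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - apply_A(x)
  beta <- sqrt(sum(r * r))
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(list(x = numeric(n), iters = 0L, relres = 0))
  if (beta / nb < tol) return(list(x = x, iters = 0L, relres = beta / nb))
  V <- matrix(0, n, maxit + 1L)
  H <- matrix(0, maxit + 1L, maxit)
  cs <- sn <- numeric(maxit)
  gvec <- numeric(maxit + 1L)
  V[, 1L] <- r / beta
  gvec[1L] <- beta
  k_used <- 0L
  for (k in seq_len(maxit)) {
    z <- precond(V[, k])
    wv <- apply_A(z)
    # modified Gram-Schmidt
    for (j in seq_len(k)) {
      H[j, k] <- sum(wv * V[, j])
      wv <- wv - H[j, k] * V[, j]
    }
    H[k + 1L, k] <- sqrt(sum(wv * wv))
    if (H[k + 1L, k] > 0) V[, k + 1L] <- wv / H[k + 1L, k]
    # apply stored Givens rotations
    for (j in seq_len(k - 1L)) {
      tmp <- cs[j] * H[j, k] + sn[j] * H[j + 1L, k]
      H[j + 1L, k] <- -sn[j] * H[j, k] + cs[j] * H[j + 1L, k]
      H[j, k] <- tmp
    }
    denom <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
    cs[k] <- H[k, k] / denom
    sn[k] <- H[k + 1L, k] / denom
    H[k, k] <- denom
    H[k + 1L, k] <- 0
    gvec[k + 1L] <- -sn[k] * gvec[k]
    gvec[k] <- cs[k] * gvec[k]
    k_used <- k
    if (abs(gvec[k + 1L]) / nb < tol) break
  }
  y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                 gvec[seq_len(k_used)])
  dx <- numeric(n)
  for (j in seq_len(k_used)) dx <- dx + y[j] * V[, j]
  list(x = x + precond(dx), iters = k_used,
       relres = abs(gvec[k_used + 1L]) / nb)
}

#' Solve the incompressible Navier-Stokes equations on a labeled mesh
#'
#' Unsteady incompressible Newtonian flow
#' \eqn{\partial_t v + (v\cdot\nabla)v = -\nabla p/\rho + (\mu/\rho)\nabla^2 v + f},
#' \eqn{\nabla\cdot v = 0}, with a no-slip wall, a prescribed parabolic
#' inlet profile scaled to the requested flow rate, and resistance outlets
#' whose traction is set from \eqn{P_{out} = R_{out} Q_{out}} with
#' \eqn{Q_{out}} lagged one nonlinear iterate. The discretization is
#' equal-order P1/P1 with PSPG pressure stabilization and streamline-upwind
#' stabilization of the convective term; each Picard step solves the
#' resulting Oseen system with preconditioned GMRES. In steady mode (the
#' default, matching the cycle-mean boundary data) the steady state is
#' computed directly by Picard iteration from the Stokes solution; in
#' transient mode the solution is advanced from zero initial conditions by
#' implicit backward Euler with time step `cfg$dt` until `t_end`, or until
#' the steady criterion
#' \eqn{\|v^{n+1}-v^n\| / (\|v^n\|\,\Delta t) <} `tol_nonlinear` is met.
#'
#' @param mesh a labeled `volume_mesh`.
#' @param bc a [boundary_conditions()] object.
#' @param props a [blood_properties()] object.
#' @param cfg a [solver_config()] object.
#' @return object of class `flow_solution`: `velocity` (nodes x 3, m/s),
#'   `pressure` (Pa), `times`, `converged`, `residual_history`, measured
#'   `q_in`, per-outlet `q_out` and `p_out`.
#' @export
solve_flow <- function(mesh, bc, props = blood_properties(),
                       cfg = solver_config()) {
  stopifnot(inherits(mesh, "volume_mesh"))
  N <- nrow(mesh$nodes)
  gr <- .p1_gradients(mesh$nodes, mesh$tets)
  vol <- gr$vol; g <- gr$g
  tets <- mesh$tets

  # node sets -------------------------------------------------------------
  wall_nodes <- sort(unique(as.integer(
    mesh$boundary_faces[mesh$face_label == "wall", ])))
  inlet_sel <- mesh$face_label == "inlet"
  outlet_labels <- sort(unique(mesh$face_label[startsWith(mesh$face_label,
                                                          "outlet")]))
  inlet_nodes <- sort(unique(as.integer(
    mesh$boundary_faces[inlet_sel, , drop = FALSE])))
  fixed <- sort(unique(c(wall_nodes, inlet_nodes)))
  free <- setdiff(seq_len(N), fixed)
  n_f <- length(free)

  # inlet parabolic profile scaled to the requested discrete flux ----------
  cl <- mesh$meta$centerline
  t_in <- cl$tangents[1, ]                 # inward flow direction at inlet
  u_fix <- matrix(0, N, 3L)
  if (bc$q_in > 0) {
    rim <- intersect(inlet_nodes, wall_nodes)
    p0 <- cl$points[1, ]
    rad <- .row_norm(mesh$nodes[inlet_nodes, , drop = FALSE] -
                     matrix(p0, length(inlet_nodes), 3, byrow = TRUE))
    rmax <- max(rad)
    prof <- 1 - (rad / rmax)^2
    prof[match(rim, inlet_nodes)] <- 0
    u_fix[inlet_nodes, ] <- outer(prof, t_in)
    flux0 <- -.face_flux(mesh, u_fix, inlet_sel)   # inward positive
    u_fix <- u_fix * (bc$q_in / flux0)
  }

  # frozen operators -------------------------------------------------------
  Ks <- .assemble_stiffness(tets, vol, g, N)
  W <- lapply(1:3, function(d) .assemble_w(tets, vol, g, N, d))
  mlump <- .lumped_mass(tets, vol, N)
  v_ref <- max(if (is.null(bc$v_in)) 0 else bc$v_in,
               bc$q_in / max(sum(mesh$face_area[inlet_sel]), 1e-30), 1e-9)
  transient <- !cfg$steady
  # no dt term in tau: the discrete steady state is then independent of the
  # time step; in Stokes mode the diffusive limit applies (no velocity
  # scale), which also keeps Stokes solutions exactly linear in the flow
  tau <- .tau_pspg(vol, props, if (cfg$convective) v_ref else 0)
  Cp <- .assemble_stiffness(tets, vol, g, N, weight = tau / props$rho)

  A <- props$mu * Ks
  if (transient) A <- A + Diagonal(N, props$rho * mlump / cfg$dt)
  A_ff <- A[free, free, drop = FALSE]
  A_fe <- A[free, fixed, drop = FALSE]
  FA <- Cholesky(Matrix::forceSymmetric(A_ff), LDL = FALSE, super = TRUE)
  Wf <- lapply(W, function(w) w[free, , drop = FALSE])
  # Scale the pressure unknown and the continuity rows by alpha = mu/h so
  # momentum and continuity residuals carry comparable weight in the GMRES
  # residual norm (entries of A scale like mu*h, of W like h^2).
  h_ref <- mean((6 * sqrt(2) * vol)^(1 / 3))
  alpha <- props$mu / h_ref
  # SIMPLE-type Schur approximation Cp + W^T diag(A)^-1 W: robust on the
  # anisotropic near-wall grading where mass scaling of the Schur complement
  # degrades
  dAinv <- Diagonal(n_f, 1 / Matrix::diag(A_ff))
  Shat <- alpha^2 * (Cp + crossprod(Wf[[1]], dAinv %*% Wf[[1]]) +
                     crossprod(Wf[[2]], dAinv %*% Wf[[2]]) +
                     crossprod(Wf[[3]], dAinv %*% Wf[[3]]))
  FS <- Cholesky(Matrix::forceSymmetric(Shat), LDL = FALSE, super = TRUE)

  iu <- function(d) (d - 1L) * n_f + seq_len(n_f)
  ip <- 3L * n_f + seq_len(N)

  # block upper-triangular right preconditioner (scaled system)
  precond <- function(r) {
    z <- numeric(3L * n_f + N)
    zp <- as.numeric(solve(FS, r[ip]))
    ru <- cbind(r[iu(1)], r[iu(2)], r[iu(3)]) +
      alpha * cbind(as.numeric(Wf[[1]] %*% zp), as.numeric(Wf[[2]] %*% zp),
                    as.numeric(Wf[[3]] %*% zp))
    zu <- as.matrix(solve(FA, ru))
    z[seq_len(3L * n_f)] <- as.numeric(zu)
    z[ip] <- zp
    z
  }

  # outlet bookkeeping ------------------------------------------------------
  out_faces <- lapply(outlet_labels, function(l) mesh$face_label == l)
  r_out <- rep(bc$r_out, length.out = length(outlet_labels))
  cond <- (1 / r_out) / sum(1 / r_out)
  q_out <- bc$q_in * cond
  p_out <- r_out * q_out

  out_area <- vapply(out_faces, function(sel) sum(mesh$face_area[sel]),
                     numeric(1))

  # Outlet tractions are applied relative to their area-weighted mean
  # (the pressure datum p_ref, re-added to the reported pressure): adding a
  # constant to every outlet traction only shifts the pressure level, and
  # removing the large uniform mode keeps the GMRES residual norm focused
  # on the velocity-scale physics.
  traction_rhs <- function(p_out, p_ref) {
    b <- matrix(0, N, 3L)
    for (k in seq_along(out_faces)) {
      if (p_out[k] == p_ref) next
      sel <- out_faces[[k]]
      f <- mesh$boundary_faces[sel, , drop = FALSE]
      w3 <- -(p_out[k] - p_ref) * mesh$face_normal[sel, , drop = FALSE] *
        mesh$face_area[sel] / 3
      for (a in 1:3) for (d in 1:3) {
        acc <- tapply(w3[, d], f[, a], sum)
        j <- as.integer(names(acc))
        b[j, d] <- b[j, d] + as.numeric(acc)
      }
    }
    b
  }

  body_rhs <- if (any(bc$body_force != 0)) {
    props$rho * outer(mlump, bc$body_force)
  } else matrix(0, N, 3L)

  hist <- numeric(0)
  log_msg <- function(...) if (cfg$verbose) message(sprintf(...))

  # one Oseen solve: velocity w in the convective operator, u_old for the
  # transient term, q_scale scales the inlet Dirichlet data
  solve_oseen <- function(w, u_old, q_scale, p_out, tol_lin, x0 = NULL) {
    if (cfg$convective) {
      tau_loc <- .tau_pspg(vol, props,
                           pmax(.row_norm((w[tets[, 1], , drop = FALSE] +
                                           w[tets[, 2], , drop = FALSE] +
                                           w[tets[, 3], , drop = FALSE] +
                                           w[tets[, 4], , drop = FALSE]) / 4),
                                1e-9))
      Cc <- .assemble_convection(tets, vol, g, N, w)
      Su <- .assemble_su(tets, vol, g, N, w, tau_loc)
      B <- props$rho * (Cc + Su)
      Pd <- lapply(1:3, function(d)
        .assemble_pspg_conv(tets, vol, g, N, w, tau, d))
      B_ff <- B[free, free, drop = FALSE]
      B_fe <- B[free, fixed, drop = FALSE]
      Pd_f <- lapply(Pd, function(p) p[, free, drop = FALSE])
      Pd_e <- lapply(Pd, function(p) p[, fixed, drop = FALSE])
    } else {
      B_ff <- NULL
    }
    u_d <- u_fix * q_scale
    ue <- u_d[fixed, , drop = FALSE]
    p_ref <- sum(p_out * out_area) / sum(out_area)
    bm <- body_rhs + traction_rhs(p_out, p_ref)
    if (transient) bm <- bm + (props$rho / cfg$dt) * (mlump * u_old)
    bm_f <- bm[free, , drop = FALSE] - as.matrix(A_fe %*% ue)
    bc_p <- -as.numeric(crossprod(W[[1]][fixed, , drop = FALSE], ue[, 1]) +
                        crossprod(W[[2]][fixed, , drop = FALSE], ue[, 2]) +
                        crossprod(W[[3]][fixed, , drop = FALSE], ue[, 3]))
    if (cfg$convective) {
      bm_f <- bm_f - as.matrix(B_fe %*% ue)
      bc_p <- bc_p - as.numeric(Pd_e[[1]] %*% ue[, 1] +
                                Pd_e[[2]] %*% ue[, 2] +
                                Pd_e[[3]] %*% ue[, 3])
    }
    b <- c(as.numeric(bm_f), alpha * bc_p)

    apply_A <- function(x) {
      U <- cbind(x[iu(1)], x[iu(2)], x[iu(3)])
      p <- x[ip]
      yu <- as.matrix(A_ff %*% U) -
        alpha * cbind(as.numeric(Wf[[1]] %*% p), as.numeric(Wf[[2]] %*% p),
                      as.numeric(Wf[[3]] %*% p))
      yp <- alpha * as.numeric(crossprod(Wf[[1]], U[, 1]) +
                               crossprod(Wf[[2]], U[, 2]) +
                               crossprod(Wf[[3]], U[, 3])) +
        alpha^2 * as.numeric(Cp %*% p)
      if (cfg$convective) {
        yu <- yu + as.matrix(B_ff %*% U)
        yp <- yp + alpha * as.numeric(Pd_f[[1]] %*% U[, 1] +
                                      Pd_f[[2]] %*% U[, 2] +
                                      Pd_f[[3]] %*% U[, 3])
      }
      c(as.numeric(yu), yp)
    }

    gm <- .gmres(apply_A, b, precond, x0 = x0, tol = tol_lin,
                 maxit = 250L)
    U <- u_d
    U[free, ] <- cbind(gm$x[iu(1)], gm$x[iu(2)], gm$x[iu(3)])
    list(u = U, p = alpha * gm$x[ip] + p_ref, x = gm$x, gmres = gm)
  }

  check_finite <- function(sol) {
    if (any(!is.finite(sol$u)) || any(!is.finite(sol$p)))
      stop("non-finite field encountered; aborting (residual history: ",
           paste(signif(utils::tail(hist, 10), 3), collapse = ", "), ")",
           call. = FALSE)
  }

  # Picard loop at fixed boundary data with Aitken adaptive relaxation
  # (plain damped Picard oscillates on curved geometries; Aitken's secant
  # update of the relaxation factor breaks the limit cycle)
  run_picard <- function(w, u_old, q_scale, p_out, q_out, max_iter,
                         x_warm = NULL) {
    rel <- Inf
    p <- numeric(N)
    res <- NULL
    omega <- cfg$relax
    r_prev <- NULL
    for (it in seq_len(max_iter)) {
      # inexact-Newton forcing: the linear residual must shrink with the
      # nonlinear one, or solver noise puts a floor under the Picard loop
      tol_lin <- max(min(cfg$tol_linear, 1e-3 * rel), 1e-10)
      res <- solve_oseen(w, u_old, q_scale, p_out, tol_lin, x0 = x_warm)
      check_finite(res)
      r <- res$u - w
      nrm <- sqrt(sum(res$u^2))
      rel <- if (nrm > 0) sqrt(sum(r^2)) / nrm else 0
      hist <<- c(hist, rel)
      log_msg("  picard %d: rel change %.3e, omega %.2f (gmres %d its, relres %.1e)",
              it, rel, omega, res$gmres$iters, res$gmres$relres)
      p <- res$p
      x_warm <- res$x
      if (rel < cfg$tol_nonlinear || (!cfg$convective && it >= 2L)) {
        w <- res$u
        for (k in seq_along(out_faces))
          q_out[k] <- .face_flux(mesh, w, out_faces[[k]])
        p_out <- r_out * q_out
        return(list(u = w, p = p, q_out = q_out, p_out = p_out,
                    converged = rel < cfg$tol_nonlinear || !cfg$convective,
                    rel = rel, x = x_warm))
      }
      if (cfg$convective) {
        if (!is.null(r_prev)) {
          dr <- r - r_prev
          dr2 <- sum(dr^2)
          if (dr2 > 0)
            omega <- max(0.1, min(1, -omega * sum(r_prev * dr) / dr2))
        }
        r_prev <- r
      } else omega <- 1
      w <- w + omega * r
      for (k in seq_along(out_faces))
        q_out[k] <- .face_flux(mesh, w, out_faces[[k]])
      p_out <- r_out * q_out
      if (it > 15L && rel > 1e3 * min(hist))
        stop("nonlinear iteration diverged (residual history: ",
             paste(signif(utils::tail(hist, 10), 3), collapse = ", "), ")",
             call. = FALSE)
    }
    list(u = w, p = p, q_out = q_out, p_out = p_out, converged = FALSE,
         rel = rel, x = x_warm)
  }

  if (cfg$steady) {
    res <- run_picard(matrix(0, N, 3L), NULL, 1, p_out, q_out,
                      cfg$max_picard)
    times <- NA_real_
    u <- res$u; p <- res$p
    converged <- res$converged
  } else {
    u <- matrix(0, N, 3L); p <- numeric(N)
    nsteps <- max(1L, ceiling(cfg$t_end / cfg$dt))
    times <- seq_len(nsteps) * cfg$dt
    converged <- FALSE
    x_warm <- NULL
    res <- NULL
    for (n in seq_len(nsteps)) {
      q_scale <- if (bc$waveform == "pulsatile")
        1 + bc$pulse_amplitude * sin(2 * pi * times[n] / bc$period) else 1
      res <- run_picard(u, u, q_scale, p_out, q_out,
                        max(3L, cfg$max_picard %/% 10L), x_warm = x_warm)
      rate <- sqrt(sum((res$u - u)^2)) /
        max(sqrt(sum(u^2)), 1e-30) / cfg$dt
      u <- res$u; p <- res$p; q_out <- res$q_out; p_out <- res$p_out
      x_warm <- res$x
      log_msg("t = %.3f s: steady rate %.3e", times[n], rate)
      if (bc$waveform == "steady" && rate < cfg$tol_nonlinear) {
        converged <- TRUE
        times <- times[seq_len(n)]
        break
      }
    }
    if (bc$waveform == "pulsatile") converged <- TRUE
  }

  q_in_meas <- -.face_flux(mesh, u, inlet_sel)
  structure(list(velocity = u, pressure = p, times = times,
                 converged = converged, residual_history = hist,
                 q_in = q_in_meas, q_out = res$q_out, p_out = res$p_out,
                 outlet_labels = outlet_labels,
                 props = props, config = cfg),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution: %d nodes, %s, Q_in %.3g m^3/s, max |v| %.3g m/s>\n",
              nrow(x$velocity),
              if (x$converged) "converged" else "NOT converged",
              x$q_in, max(.row_norm(x$velocity))))
  invisible(x)
}

#' Global mass-conservation residual
#'
#' \eqn{|\sum Q_{out} - \sum Q_{in}| / \sum Q_{in}} from exact boundary-face
#' integration of the P1 velocity field. Zero-flow solutions return 0 by
#' convention.
#'
#' @param sol a `flow_solution`.
#' @param mesh the mesh it was computed on.
#' @return the residual ratio.
#' @export
check_mass_conservation <- function(sol, mesh) {
  q_in <- -.face_flux(mesh, sol$velocity, mesh$face_label == "inlet")
  outs <- unique(mesh$face_label[startsWith(mesh$face_label, "outlet")])
  q_out <- sum(vapply(outs, function(l)
    .face_flux(mesh, sol$velocity, mesh$face_label == l), numeric(1)))
  if (abs(q_in) == 0) return(0)
  abs(q_out - q_in) / abs(q_in)
}

#' Write a flow solution as VTU point data
#'
#' @param sol a `flow_solution`.
#' @param mesh the mesh.
#' @param path output `.vtu` path.
#' @return the path, invisibly.
#' @export
write_solution_vtu <- function(sol, mesh, path) {
  write_mesh_vtu(mesh, path,
                 point_data = list(velocity = sol$velocity,
                                   pressure = sol$pressure))
}
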