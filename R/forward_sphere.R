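## Analytic EEG forward model for a three-shell concentric spherical head.
##
## The potential of a current dipole inside a layered conducting sphere is
## expanded in spherical harmonics. Within each shell the potential is
## a_i r^n + b_i r^-(n+1) per harmonic degree n (plus the primary dipole term
## in the innermost region); coefficients follow from continuity of potential
## and radial current at the interfaces and a no-flux condition at the scalp.
## Lengths are mm (converted to m only in the physical prefactor), moments are
## A.m, conductivities S/m, potentials V.

# Surface transfer factors T_n: scalp-surface potential per unit primary
# expansion coefficient (1/sigma_brain included), for n = 1..n_max.
# Depends on geometry only, so it is computed once per head and cached.
sphere_transfer_factors <- function(shell_radii, conductivities, n_max = 200) {
  u1 <- shell_radii[1] / shell_radii[3]
  u2 <- shell_radii[2] / shell_radii[3]
  s1 <- conductivities[1]; s2 <- conductivities[2]; s3 <- conductivities[3]
  tn <- numeric(n_max)
  for (n in seq_len(n_max)) {
    q <- 1 / s1  # primary coefficient scale
    # unknowns: a1, a2, b2, a3, b3
    M <- rbind(
      c(u1^n, -u1^n, -u1^(-(n + 1)), 0, 0),
      c(s1 * n * u1^(n - 1), -s2 * n * u1^(n - 1),
        s2 * (n + 1) * u1^(-(n + 2)), 0, 0),
      c(0, u2^n, u2^(-(n + 1)), -u2^n, -u2^(-(n + 1))),
      c(0, s2 * n * u2^(n - 1), -s2 * (n + 1) * u2^(-(n + 2)),
        -s3 * n * u2^(n - 1), s3 * (n + 1) * u2^(-(n + 2))),
      c(0, 0, 0, n, -(n + 1)))
    rhs <- c(-q * u1^(-(n + 1)),
             s1 * (n + 1) * q * u1^(-(n + 2)),
             0, 0, 0)
    # column equilibration: the r^n / r^-(n+1) scales differ by many orders
    cs <- apply(abs(M), 2, max)
    sol <- tryCatch(solve(M * rep(1 / cs, each = 5), rhs) / cs,
                    error = function(e) NULL)
    if (is.null(sol)) {  # beyond usable precision; higher terms are negligible
      tn <- tn[seq_len(n - 1)]
      break
    }
    # potential at the outer surface (u = 1): a3 + b3, plus nothing primary
    tn[n] <- sol[4] + sol[5]
  }
  tn
}

# Decompose a dipole at `position` into radial / tangential parts and return
# the per-electrode geometry needed by the series and the closed form.
dipole_geometry <- function(electrode_positions, position, moment) {
  b <- sqrt(sum(position^2))
  if (b < 1e-9) {
    # central dipole: any axis through the moment works, purely "radial"
    mn <- sqrt(sum(moment^2))
    bhat <- if (mn > 0) moment / mn else c(0, 0, 1)
  } else bhat <- position / b
  m_r <- sum(moment * bhat)
  mt_vec <- moment - m_r * bhat
  m_t <- sqrt(sum(mt_vec^2))
  that <- if (m_t > 1e-300) mt_vec / m_t else c(0, 0, 0)
  re <- sqrt(rowSums(electrode_positions^2))
  rhat <- electrode_positions / re
  list(b = b, m_r = m_r, m_t = m_t,
       cosg = as.vector(rhat %*% bhat),   # cos(angle dipole axis, electrode)
       x_t = as.vector(rhat %*% that))    # sin(gamma) cos(phi)
}

#' Electrode potentials of a dipole in the multilayer spherical head
#'
#' Series solution of Poisson's equation for a current dipole inside the
#' innermost shell of a three-shell concentric spherical conductor. The series
#' is truncated when the relative increment of the last term falls below
#' `tol` (hard cap `n_max` terms), and the result is average-referenced.
#'
#' @param head an `esi_head` (only shell radii, conductivities and electrode
#'   positions are used).
#' @param position dipole location, mm 3-vector, strictly inside the brain
#'   shell.
#' @param moment dipole moment, A.m 3-vector.
#' @param tol relative truncation tolerance.
#' @param n_max series cap.
#' @return average-referenced potentials (V), one per electrode.
#' @export
leadfield_dipole <- function(head, position, moment, tol = 1e-10, n_max = 200) {
  radii <- head$shell_radii
  if (radii[1] <= 0) stopf("zero-radius head")
  b <- sqrt(sum(position^2))
  if (b >= radii[1])
    stopf("dipole at radius %.2f mm lies outside the brain shell (%.2f mm)",
          b, radii[1])
  if (all(moment == 0)) return(numeric(nrow(head$electrode_positions)))
  tn <- head$.transfer
  if (is.null(tn))
    tn <- sphere_transfer_factors(radii, head$conductivities, n_max)
  geo <- dipole_geometry(head$electrode_positions, position, moment)
  tt <- geo$b / radii[3]
  r3_m <- radii[3] / 1000
  pref <- 1 / (4 * pi * r3_m^2)  # 1/sigma is inside the transfer factors
  ne <- length(geo$cosg)
  # radial and tangential unit-moment series are accumulated separately and
  # truncated on geometry alone, so the result is exactly linear in the
  # moment and truncation never depends on its orientation
  v_rad <- numeric(ne)
  v_tan <- numeric(ne)
  # Legendre recursions in cos(gamma)
  p_prev <- rep(1, ne); p_cur <- geo$cosg       # P_0, P_1
  dp_prev <- rep(0, ne); dp_cur <- rep(1, ne)   # P'_0, P'_1
  tpow <- 1  # t^(n-1)
  for (n in seq_len(min(n_max, length(tn)))) {
    term_rad <- pref * tn[n] * tpow * n * p_cur
    term_tan <- pref * tn[n] * tpow * dp_cur
    v_rad <- v_rad + term_rad
    v_tan <- v_tan + term_tan
    scale_now <- max(max(abs(v_rad)), max(abs(v_tan)))
    if (n >= 2 && scale_now > 0 &&
        max(max(abs(term_rad)), max(abs(term_tan))) / scale_now < tol) break
    # advance recursions to degree n+1
    p_next <- ((2 * n + 1) * geo$cosg * p_cur - n * p_prev) / (n + 1)
    dp_next <- dp_prev + (2 * n + 1) * p_cur
    p_prev <- p_cur; p_cur <- p_next
    dp_prev <- dp_cur; dp_cur <- dp_next
    tpow <- tpow * tt
  }
  v <- geo$m_r * v_rad + geo$m_t * geo$x_t * v_tan
  v - mean(v)
}

#' Closed-form dipole potential on a homogeneous conducting sphere
#'
#' Independent closed-form solution (no series, no linear solves) for the
#' surface potential of a dipole inside a homogeneous sphere with insulating
#' exterior; used as the analytic oracle for the multilayer series when all
#' three conductivities are equal. Average-referenced like
#' [leadfield_dipole()].
#'
#' @param electrode_positions Ne x 3 matrix (mm) on the sphere surface.
#' @param position,moment dipole location (mm) and moment (A.m).
#' @param radius sphere radius (mm).
#' @param sigma conductivity (S/m).
#' @return average-referenced potentials (V).
#' @export
homogeneous_sphere_dipole <- function(electrode_positions, position, moment,
                                      radius, sigma) {
  geo <- dipole_geometry(electrode_positions, position, moment)
  tt <- geo$b / radius
  c_ <- geo$cosg
  rq <- sqrt(pmax(1 - 2 * tt * c_ + tt^2, 1e-300))
  if (tt > 1e-12) {
    s_rad <- 2 * (c_ - tt) / rq^3 + (1 / rq - 1) / tt
  } else {
    s_rad <- 3 * c_  # t -> 0 limit: only the n = 1 term survives
  }
  f_tan <- 2 / rq^3 + (1 + rq) / (rq * (1 - tt * c_ + rq))
  r_m <- radius / 1000
  v <- (geo$m_r * s_rad + geo$m_t * geo$x_t * f_tan) / (4 * pi * sigma * r_m^2)
  v - mean(v)
}
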