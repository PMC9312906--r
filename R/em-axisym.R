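# Axisymmetric frequency-domain EM solve for the slot antenna.
#
# The antenna is rotationally symmetric, so the radiated field is the
# azimuthal-magnetic (TM0) mode: H = H_phi(r, z) e_phi. Writing v = r H_phi
# and s = 1/eps_c with eps_c = eps_r - j sigma/(omega eps0), the vector
# Helmholtz equation reduces to
#
#   d/dr( (s/r) dv/dr ) + d/dz( (s/r) dv/dz ) + (k0^2/r) v = 0,
#
# a self-adjoint scalar problem discretized here with a conservative
# cell-centred finite-volume scheme on an (r, z) grid (radially graded so the
# thin coax feed is resolved). Conductors enter as zero-flux (PEC) faces,
# the outer boundary carries a first-order absorbing condition, and the coax
# port is driven with the analytic TEM profile H_phi = C/r.

EPS0 <- 8.8541878128e-12
MU0 <- 4e-7 * pi
C0 <- 299792458

# radially graded cell widths: uniform dr_fine out to r_fine, then geometric
axisym_r_grid <- function(r_fine, r_max, dr_fine, growth = 1.08) {
  dr <- rep(dr_fine, ceiling(r_fine / dr_fine))
  r_edge <- sum(dr)
  w <- dr_fine
  while (r_edge < r_max) {
    w <- w * growth
    dr <- c(dr, w)
    r_edge <- r_edge + w
  }
  edges <- c(0, cumsum(dr))
  list(centers = (edges[-1] + edges[-length(edges)]) / 2,
       widths = dr, edges = edges)
}

# cell material codes on the EM grid
EM_METAL <- 0L
EM_FEED <- 1L
EM_CATH <- 2L
EM_TISSUE <- 3L

axisym_materials <- function(antenna, r, z) {
  nr <- length(r); nz <- length(z)
  mat <- matrix(EM_TISSUE, nr, nz)
  arr_len <- slot_array_length(antenna)
  z_tip <- -arr_len / 2 - antenna$tip_length
  slots <- slot_offsets(antenna)
  for (j in seq_len(nz)) {
    zj <- z[j]
    if (zj < z_tip) next # below the tip: all tissue
    in_tip <- zj < -arr_len / 2 # solid metallic tip below the first slot
    in_slot <- any(abs(zj - slots) <= antenna$slot_width / 2)
    for (i in seq_len(nr)) {
      ri <- r[i]
      if (ri >= antenna$catheter_radius) break
      mat[i, j] <-
        if (ri >= antenna$outer_radius) EM_CATH
        else if (in_tip) EM_METAL
        else if (ri < antenna$inner_radius) EM_METAL
        else if (ri < antenna$dielectric_radius) EM_FEED
        else if (in_slot) EM_FEED # slot aperture through the outer conductor
        else EM_METAL
    }
  }
  mat
}

#' Solve the axisymmetric antenna field and tissue heating density
#'
#' Finite-volume frequency-domain solution of the azimuthally symmetric
#' transverse-magnetic mode radiated by the slot antenna, with PEC conductor
#' faces, a first-order absorbing outer boundary, and TEM excitation at the
#' coaxial port. Returns the complex azimuthal magnetic field and the local
#' dissipation density Q = sigma |E|^2 / 2 on the (r, z) grid, in antenna-
#' local coordinates (z = 0 at the slot-array midpoint, antenna along +z).
#'
#' @param antenna an [antenna_spec()].
#' @param tissue_profile function(r, z) returning `list(eps_r, sigma)` for
#'   tissue points (vectorized); e.g. from [profile_from_grid()].
#' @param r_max radial domain size (m).
#' @param z_range length-2 axial domain (m, antenna-local).
#' @param dz axial cell size (m); must resolve the slot width with at least
#'   3 cells.
#' @param dr_fine radial cell size inside the antenna bore (m).
#' @return object of class `mwa_em` with the field `u` (H_phi, A/m), the
#'   dissipation density `Q2d` (W/m^3), grid vectors and the raw dissipated
#'   power `power` (W) before any efficiency normalization.
#' @export
solve_axisym_field <- function(antenna, tissue_profile,
                               r_max = 0.025, z_range = c(-0.03, 0.03),
                               dz = 0.2e-3, dr_fine = 0.03e-3) {
  stopifnot(inherits(antenna, "mwa_antenna"))
  if (dz > antenna$slot_width / 3 * (1 + 1e-9)) {
    stop(sprintf("axial cell size %.3g mm does not resolve the %.3g mm slot width with >= 3 cells; use dz <= %.3g mm",
                 dz * 1e3, antenna$slot_width * 1e3, antenna$slot_width / 3 * 1e3))
  }
  rg <- axisym_r_grid(r_fine = 1.3 * antenna$catheter_radius,
                      r_max = r_max, dr_fine = dr_fine)
  r <- rg$centers; dr <- rg$widths; redge <- rg$edges
  z <- seq(z_range[1] + dz / 2, z_range[2] - dz / 2, by = dz)
  nr <- length(r); nz <- length(z)
  omega <- 2 * pi * antenna$frequency
  k0 <- omega / C0
  mat <- axisym_materials(antenna, r, z)
  # complex permittivity per cell
  eps <- matrix(complex(real = 1), nr, nz)
  eps[mat == EM_FEED] <- antenna$feed_permittivity
  eps[mat == EM_CATH] <- antenna$catheter_permittivity
  tis <- which(mat == EM_TISSUE, arr.ind = TRUE)
  tp <- tissue_profile(r[tis[, 1]], z[tis[, 2]])
  eps[tis] <- complex(real = tp$eps_r, imaginary = -tp$sigma / (omega * EPS0))
  if (any(!is.finite(Mod(eps))) || any(Mod(eps) == 0)) {
    stop("degenerate material profile: singular permittivity")
  }
  s <- 1 / eps
  s[mat == EM_METAL] <- 0 # PEC: zero-flux faces
  live <- mat != EM_METAL
  idx <- matrix(0L, nr, nz)
  idx[live] <- seq_len(sum(live))
  n <- sum(live)

  # port: matched TEM excitation on the top face of the feed dielectric --
  # Robin condition du/dz + j k_d u = 2 j k_d u_inc with u_inc = C/r, which
  # injects the incident coax mode and absorbs the reflected one
  z0_imp <- sqrt(MU0 / (EPS0 * antenna$feed_permittivity)) / (2 * pi) *
    log(antenna$dielectric_radius / antenna$inner_radius)
  i_amp <- sqrt(2 * antenna$power / z0_imp)
  c_amp <- i_amp / (2 * pi)
  k_feed <- k0 * sqrt(antenna$feed_permittivity)
  is_port <- matrix(FALSE, nr, nz)
  is_port[, nz] <- mat[, nz] == EM_FEED

  ti_l <- list(); tj_l <- list(); tv_l <- list()
  bi_l <- list(); bv_l <- list()
  add <- function(ii, jj, vv) {
    k <- length(ti_l) + 1
    ti_l[[k]] <<- ii; tj_l[[k]] <<- jj; tv_l[[k]] <<- vv
  }
  add_b <- function(ii, vv) {
    k <- length(bi_l) + 1
    bi_l[[k]] <<- ii; bv_l[[k]] <<- vv
  }
  # assemble vectorized over j-columns
  for (j in seq_len(nz)) {
    liv <- which(live[, j])
    if (!length(liv)) next
    rows <- idx[liv, j]
    dcol <- rep(complex(real = 0), length(liv))
    # k0^2/r term (cell volume factor 1/ (dr dz) cancels in flux form below)
    dcol <- dcol + k0^2 / r[liv]
    # radial neighbours
    for (dir in c(-1L, 1L)) {
      ni <- liv + dir
      face_r <- if (dir == 1L) redge[liv + 1] else redge[liv]
      inb <- ni >= 1 & ni <= nr
      # harmonic face coefficient (0 against metal)
      s_here <- s[cbind(liv, j)]
      s_nb <- ifelse(inb, s[cbind(pmax(pmin(ni, nr), 1), j)], 0)
      s_face <- ifelse(s_here == 0 | s_nb == 0, 0,
                       2 * s_here * s_nb / (s_here + s_nb))
      dist <- ifelse(inb, abs(r[pmax(pmin(ni, nr), 1)] - r[liv]), dr[liv])
      coef <- s_face / face_r * 1 / dist / dr[liv]
      # interior face
      sel <- inb & s_face != 0
      if (any(sel)) {
        add(rows[sel], idx[cbind(ni[sel], rep(j, sum(sel)))], coef[sel])
        dcol[sel] <- dcol[sel] - coef[sel]
      }
      # axis face for the innermost cell: flux -> 2 s v / r1^2
      if (dir == -1L) {
        ax <- which(liv == 1L)
        if (length(ax)) {
          sa <- s[1, j]
          dcol[ax] <- dcol[ax] - 2 * sa / (r[1]^2) / dr[1]
        }
      }
      # outer absorbing face at r_max
      if (dir == 1L) {
        ob <- which(liv == nr)
        if (length(ob)) {
          sc <- s[nr, j]
          kc <- k0 * sqrt(eps[nr, j])
          if (Im(kc) > 0) kc <- -kc
          # flux = s (du/dr + u/r), du/dr = -j k u  (outgoing)
          dcol[ob] <- dcol[ob] +
            sc * (-1i * kc + 1 / r[nr]) / r[nr] / dr[nr]
        }
      }
    }
    # axial neighbours
    for (dj in c(-1L, 1L)) {
      nj <- j + dj
      s_here <- s[liv, j]
      if (nj >= 1 && nj <= nz) {
        s_nb <- s[liv, nj]
        s_face <- ifelse(s_here == 0 | s_nb == 0, 0,
                         2 * s_here * s_nb / (s_here + s_nb))
        coef <- s_face / r[liv] / dz^2
        sel <- s_face != 0
        if (any(sel)) {
          add(rows[sel], idx[cbind(liv[sel], rep(nj, sum(sel)))], coef[sel])
          dcol[sel] <- dcol[sel] - coef[sel]
        }
      } else if (j == nz && any(is_port[liv, j])) {
        prt <- is_port[liv, j]
        # matched port on feed cells, absorbing elsewhere on the top face
        kc <- k0 * sqrt(eps[liv, j])
        kc <- ifelse(Im(kc) > 0, -kc, kc)
        kc[prt] <- k_feed
        dcol <- dcol + s_here * (-1i * kc) / r[liv] / dz
        if (any(prt)) {
          # residual constant of the matched port is 2 j k s u_inc / dz
          add_b(rows[prt],
                -2i * s_here[prt] * k_feed * c_amp / (r[liv[prt]] * dz))
        }
      } else {
        # absorbing z boundary (top boundary outside the coax, bottom)
        kc <- k0 * sqrt(eps[liv, j])
        kc <- ifelse(Im(kc) > 0, -kc, kc)
        dcol <- dcol + s_here * (-1i * kc) / r[liv] / dz
      }
    }

    add(rows, rows, dcol)
  }
  # port rows: identity
  ti <- unlist(ti_l); tj <- unlist(tj_l); tv <- unlist(tv_l)
  bi <- unlist(bi_l); bv <- unlist(bv_l)
  b <- rep(complex(real = 0), n)
  bagg <- tapply(bv, bi, sum)
  b[as.integer(names(bagg))] <- bagg
  # real block system [[Re, -Im], [Im, Re]]
  A <- Matrix::sparseMatrix(
    i = c(ti, ti, ti + n, ti + n),
    j = c(tj, tj + n, tj, tj + n),
    x = c(Re(tv), -Im(tv), Im(tv), Re(tv)),
    dims = c(2 * n, 2 * n))
  sol <- Matrix::solve(A, c(Re(b), Im(b)))
  v <- complex(real = sol[seq_len(n)], imaginary = sol[n + seq_len(n)])
  vfield <- matrix(complex(real = NA_real_), nr, nz)
  vfield[live] <- v
  u <- sweep(vfield, 1, r, "/") # H_phi
  u[!live] <- NA

  # E-field recovery and dissipation density
  q2d <- matrix(0, nr, nz)
  sig <- matrix(0, nr, nz)
  sig[tis] <- tp$sigma
  efac <- s / (1i * omega * EPS0) # E = s/(j w eps0) * curl(H)
  # d(v)/dr / r  -> E_z ; d(u)/dz -> -E_r
  vv <- vfield; vv[!live] <- 0
  dvdr <- matrix(0, nr, nz)
  dvdr[2:(nr - 1), ] <- (vv[3:nr, ] - vv[1:(nr - 2), ]) /
    (r[3:nr] - r[1:(nr - 2)])
  dvdr[1, ] <- vv[1, ] * 2 / r[1] # v ~ c r^2 near the axis
  dvdr[nr, ] <- (vv[nr, ] - vv[nr - 1, ]) / (r[nr] - r[nr - 1])
  uu <- u; uu[!live] <- 0
  dudz <- matrix(0, nr, nz)
  dudz[, 2:(nz - 1)] <- (uu[, 3:nz] - uu[, 1:(nz - 2)]) / (2 * dz)
  e_z <- efac * sweep(dvdr, 1, r, "/")
  e_r <- -efac * dudz
  q2d <- 0.5 * sig * (Mod(e_r)^2 + Mod(e_z)^2)
  q2d[!live] <- 0
  ring_vol <- outer(2 * pi * r * dr, rep(dz, nz))
  p_diss <- sum(q2d * ring_vol)
  structure(list(backend = "axisym", r = r, dr = dr, z = z, dz = dz,
                 u = u, Q2d = q2d, materials = mat, power = p_diss,
                 omega = omega, k0 = k0, antenna = antenna),
            class = "mwa_em")
}

#' @export
print.mwa_em <- function(x, ...) {
  cat(sprintf("<mwa_em> %s backend, %d x %d (r, z) cells, dissipated %.3g W (raw)\n",
              x$backend, length(x$r), length(x$z), x$power))
  invisible(x)
}

#' Angle-averaged tissue dielectric profile from a labeled grid
#'
#' The EM solve is axisymmetric while the tissue map is fully 3D, so the
#' voxel dielectric properties (baseline per label, declining with
#' temperature through the water-content factor) are averaged over azimuth
#' into (r, z) bins around the antenna axis. Full 3D heterogeneity is kept
#' in the thermal solve; this angle average only shapes the EM source.
#'
#' @param grid an `mwa_grid`.
#' @param props an [mwa_properties()] object.
#' @param temperature optional temperature field on the grid (degC) for the
#'   evaporation decline of (eps_r, sigma); baseline 37 degC when omitted.
#' @param bin bin size (m) of the (r, z) average.
#' @return function(r, z) -> list(eps_r, sigma), vectorized, in antenna-local
#'   coordinates (z = 0 at the slot-array midpoint).
#' @export
profile_from_grid <- function(grid, props, temperature = NULL, bin = 1e-3) {
  lab <- grid$labels
  tissue <- lab == LBL_HEALTHY | lab == LBL_TUMOR
  xc <- grid_centers(grid, 1); yc <- grid_centers(grid, 2)
  zc <- grid_centers(grid, 3)
  coords <- which(tissue, arr.ind = TRUE)
  rv <- sqrt((xc[coords[, 1]] - grid$axis$x)^2 +
               (yc[coords[, 2]] - grid$axis$y)^2)
  zv <- zc[coords[, 3]] - grid$axis$slot_center_z
  base_eps <- ifelse(lab[tissue] == LBL_TUMOR,
                     props$tumor$rel_permittivity,
                     props$healthy$rel_permittivity)
  base_sig <- ifelse(lab[tissue] == LBL_TUMOR,
                     props$tumor$conductivity, props$healthy$conductivity)
  scale <- if (is.null(temperature)) 1 else
    dielectric_scale(temperature[tissue], props)
  ir <- pmin(floor(rv / bin), 199) + 1
  z0 <- min(zv)
  iz <- pmin(floor((zv - z0) / bin), 399) + 1
  key <- ir + 200L * (iz - 1L)
  eps_bin <- tapply(base_eps * scale, key, mean)
  sig_bin <- tapply(base_sig * scale, key, mean)
  lookup_e <- rep(NA_real_, 200 * 400)
  lookup_s <- rep(NA_real_, 200 * 400)
  kk <- as.integer(names(eps_bin))
  lookup_e[kk] <- eps_bin
  lookup_s[kk] <- sig_bin
  h_eps <- props$healthy$rel_permittivity
  h_sig <- props$healthy$conductivity
  function(r, z) {
    ir <- pmin(pmax(floor(r / bin), 0), 199) + 1
    iz <- pmin(pmax(floor((z - z0) / bin), 0), 399) + 1
    k <- ir + 200L * (iz - 1L)
    e <- lookup_e[k]; s <- lookup_s[k]
    e[is.na(e)] <- h_eps
    s[is.na(s)] <- h_sig
    list(eps_r = e, sigma = s)
  }
}

#' Uniform-tissue dielectric profile
#'
#' Convenience profile for tests and free-space-like scenarios: constant
#' (eps_r, sigma) everywhere outside the antenna.
#'
#' @param eps_r relative permittivity.
#' @param sigma electric conductivity (S/m).
#' @return function(r, z) -> list(eps_r, sigma).
#' @export
uniform_profile <- function(eps_r, sigma) {
  force(eps_r); force(sigma)
  function(r, z) list(eps_r = rep(eps_r, length(r)),
                      sigma = rep(sigma, length(r)))
}
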