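# Trajectory-derived structural estimators: per-lipid cone geometry and
# CPP_V, alignment-based CPP_Rg, shape classification, density profiles,
# bilayer thickness, monolayer torque density, area compressibility, and
# the escape-based stability screen.

#' Per-lipid truncated-cone geometry
#'
#' For each selected lipid and frame: \code{r_head} is half the maximum
#' pairwise distance between head atoms in the membrane (xy) plane;
#' \code{r_tail} the same over terminal tail atoms; \code{l_c} the mean 3D
#' distance from the head-group centroid to each terminal tail atom;
#' \code{a_0 = pi r_head^2}; and the truncated-cone volume
#' \code{V = (pi l_c / 3)(r_head^2 + r_head r_tail + r_tail^2)}. Lipids
#' whose head collapses to a point (\code{r_head = 0}) are flagged
#' degenerate. Lipids are made whole across periodic boundaries before
#' measuring.
#'
#' @param traj an \code{lnp_trajectory}.
#' @param topo an \code{lnp_topology}.
#' @param frames frame indices (default: all frames).
#' @param lipids lipid ids to analyze (default: all ionizable lipids, or
#'   all lipids when none are labelled ionizable).
#' @return data frame of class \code{lipid_geometry}: lipid_id, frame,
#'   r_head, r_tail, l_c, a_0, V, degenerate_flag.
#' @export
compute_lipid_geometry <- function(traj, topo, frames = NULL, lipids = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) == 0L) stop("range error: empty frame selection")
  if (is.null(lipids)) {
    lipids <- unique(topo$lipid_id[topo$lipid_type == "ionizable"])
    if (length(lipids) == 0L) lipids <- unique(topo$lipid_id)
  }
  res <- vector("list", length(lipids) * length(frames))
  k <- 0L
  for (lip in lipids) {
    sel <- which(topo$lipid_id == lip)
    head_i <- sel[topo$role[sel] == "head"]
    term_i <- sel[topo$is_terminal_tail[sel]]
    if (length(head_i) == 0L || length(term_i) == 0L)
      stop("lipid ", lip, " lacks head or terminal-tail atoms")
    for (f in frames) {
      xyz <- traj$coords[sel, , f, drop = FALSE][, , 1L]
      box <- if (is.null(traj$box)) NULL else traj$box[f, ]
      xyz <- .make_whole(xyz, box)
      hidx <- match(head_i, sel)
      tidx <- match(term_i, sel)
      hxy <- xyz[hidx, 1:2, drop = FALSE]
      txy <- xyz[tidx, 1:2, drop = FALSE]
      r_head <- if (nrow(hxy) < 2L) 0 else max(stats::dist(hxy)) / 2
      r_tail <- if (nrow(txy) < 2L) 0 else max(stats::dist(txy)) / 2
      hc <- colMeans(xyz[hidx, , drop = FALSE])
      l_c <- mean(sqrt(colSums((t(xyz[tidx, , drop = FALSE]) - hc)^2)))
      a_0 <- pi * r_head^2
      V <- pi * l_c / 3 * (r_head^2 + r_head * r_tail + r_tail^2)
      k <- k + 1L
      res[[k]] <- data.frame(lipid_id = lip, frame = f, r_head = r_head,
                             r_tail = r_tail, l_c = l_c, a_0 = a_0, V = V,
                             degenerate_flag = r_head == 0)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  class(out) <- c("lipid_geometry", class(out))
  out
}

.new_cpp_result <- function(method, per_lipid, excluded) {
  pooled <- mean(per_lipid)
  sd_l <- stats::sd(per_lipid)
  structure(list(
    method = method,
    per_lipid_means = per_lipid,
    pooled_mean = pooled,
    dispersion = if (method == "cpp_v") sd_l / sqrt(length(per_lipid)) else sd_l,
    dispersion_type = if (method == "cpp_v") "SEM" else "SD",
    variance_across_lipids = stats::var(per_lipid),
    n_lipids = length(per_lipid),
    excluded_lipids = excluded
  ), class = "cpp_result")
}

#' @export
print.cpp_result <- function(x, ...) {
  cat(sprintf("CPP (%s): %.4f +/- %.4f (%s over %d lipids; %d excluded)\n",
              x$method, x$pooled_mean, x$dispersion, x$dispersion_type,
              x$n_lipids, x$excluded_lipids))
  invisible(x)
}

#' Volume-based critical packing parameter (CPP_V)
#'
#' Per lipid-frame, CPP_V = V / (a_0 l_c) with the truncated-cone volume
#' of \code{\link{compute_lipid_geometry}}; algebraically this reduces to
#' (r_head^2 + r_head r_tail + r_tail^2) / (3 r_head^2), independent of
#' the lipid length. Values are averaged over frames per lipid first, then
#' pooled across lipids; dispersion is the standard error of the mean over
#' lipid means (CPP_V fluctuates strongly across lipids and time steps, so
#' the uncertainty of its central tendency is reported). The variance of
#' the per-lipid means is also returned. Degenerate lipid-frames are
#' excluded and counted.
#'
#' @param geometries a \code{lipid_geometry} data frame.
#' @return object of class \code{cpp_result}.
#' @export
compute_cpp_v <- function(geometries) {
  g <- geometries[!geometries$degenerate_flag, , drop = FALSE]
  excluded <- length(unique(geometries$lipid_id)) -
    length(unique(g$lipid_id))
  if (nrow(g) == 0L) stop("empty-result error: all lipids degenerate")
  cpp <- g$V / (g$a_0 * g$l_c)
  per_lipid <- tapply(cpp, g$lipid_id, mean)
  .new_cpp_result("cpp_v", as.numeric(per_lipid), excluded)
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
.rotation_onto <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Radius-of-gyration-based critical packing parameter (CPP_Rg)
#'
#' Per lipid-frame: the head and tail centers of mass are computed, the
#' lipid is translated so their midpoint sits at the origin, and the
#' orientation vector v = R_head - R_tail is rotated onto the membrane
#' normal z. The mass-weighted planar radius of gyration
#' Rg = sqrt(sum_i m_i (x_i^2 + y_i^2) / M) is then computed for the head
#' and tail atom subsets. Per lipid, Rg values are averaged over frames
#' and CPP_Rg = mean(Rg_tail) / mean(Rg_head); the pooled value is the
#' mean over lipids with SD dispersion. Lipid-frames whose head and tail
#' centers coincide (|v| below \code{tol}) are skipped with a warning.
#'
#' @inheritParams compute_lipid_geometry
#' @param tol minimum |v| (angstrom) for a defined orientation.
#' @return object of class \code{cpp_result}.
#' @export
compute_cpp_rg <- function(traj, topo, frames = NULL, lipids = NULL,
                           tol = 1e-6) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) == 0L) stop("range error: empty frame selection")
  if (is.null(lipids)) {
    lipids <- unique(topo$lipid_id[topo$lipid_type == "ionizable"])
    if (length(lipids) == 0L) lipids <- unique(topo$lipid_id)
  }
  per_lipid <- numeric(0)
  excluded <- 0L
  n_skipped <- 0L
  for (lip in lipids) {
    sel <- which(topo$lipid_id == lip)
    hidx <- topo$role[sel] == "head"
    tidx <- topo$role[sel] == "tail"
    if (!any(hidx) || !any(tidx))
      stop("lipid ", lip, " lacks head or tail atoms")
    m <- topo$mass[sel]
    rg_h <- rg_t <- numeric(0)
    for (f in frames) {
      xyz <- traj$coords[sel, , f, drop = FALSE][, , 1L]
      box <- if (is.null(traj$box)) NULL else traj$box[f, ]
      xyz <- .make_whole(xyz, box)
      com <- function(ii) colSums(xyz[ii, , drop = FALSE] * m[ii]) / sum(m[ii])
      ch <- com(hidx); ct <- com(tidx)
      v <- ch - ct
      if (sqrt(sum(v^2)) < tol) { n_skipped <- n_skipped + 1L; next }
      mid <- (ch + ct) / 2
      xyz <- sweep(xyz, 2, mid)
      R <- .rotation_onto(v, c(0, 0, 1))
      xyz <- xyz %*% t(R)
      prg <- function(ii) {
        sqrt(sum(m[ii] * (xyz[ii, 1]^2 + xyz[ii, 2]^2)) / sum(m[ii]))
      }
      rg_h <- c(rg_h, prg(hidx))
      rg_t <- c(rg_t, prg(tidx))
    }
    if (length(rg_h) == 0L || mean(rg_h) == 0) {
      excluded <- excluded + 1L
      next
    }
    per_lipid <- c(per_lipid, mean(rg_t) / mean(rg_h))
  }
  if (n_skipped > 0L)
    warning(n_skipped, " lipid-frame(s) skipped: undefined orientation")
  if (length(per_lipid) == 0L) stop("empty-result error: no usable lipids")
  .new_cpp_result("cpp_rg", per_lipid, excluded)
}

#' Classify lipid shape from a CPP value
#'
#' CPP below 1 indicates a cone (positive-curvature preference), close to
#' 1 a cylinder, and above 1 an inverted cone (negative-curvature
#' preference, associated with inverse-hexagonal phases and membrane
#' fusion). "Close to 1" is operationalized as |CPP - 1| <= band.
#'
#' @param cpp CPP value(s), non-negative.
#' @param cylinder_band half-width of the cylinder band (default 0.05).
#' @return character vector: "cone", "cylinder" or "inverted_cone".
#' @export
classify_shape <- function(cpp, cylinder_band = 0.05) {
  if (any(cpp < 0)) stop("domain error: negative CPP")
  ifelse(abs(cpp - 1) <= cylinder_band, "cylinder",
         ifelse(cpp < 1, "cone", "inverted_cone"))
}

#' Component density profiles along the membrane normal
#'
#' Tracks one representative atom per lipid (the flagged reference atom:
#' hydroxyl oxygen for cholesterol, phosphorus for helper lipids, head
#' nitrogen for ionizable lipids), recenters each frame so the membrane
#' center of mass is at z = 0, bins the z-positions, averages counts over
#' frames and divides by the bin width. The integral of each profile times
#' the bin width equals the mean representative-atom count of that
#' component.
#'
#' @inheritParams compute_lipid_geometry
#' @param bin_width bin width in angstrom.
#' @return data frame (component, z, density) of class
#'   \code{density_profile}, with attribute \code{bin_width}.
#' @export
compute_density_profile <- function(traj, topo, frames = NULL,
                                    bin_width = 1) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  comps <- unique(topo$lipid_type)
  for (comp in comps) {
    sel <- topo$lipid_type == comp
    if (!any(topo$reference_kind[sel] != "none"))
      stop("topology error: component '", comp,
           "' has no representative (reference) atoms")
  }
  ref <- topo$reference_kind != "none"
  zmat <- sapply(frames, function(f) {
    traj$coords[ref, 3, f] - .midplane_z(traj, topo, f)
  })
  zmat <- matrix(zmat, nrow = sum(ref))
  zr <- range(zmat)
  lo <- floor(zr[1] / bin_width) * bin_width
  hi <- ceiling(zr[2] / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  comp_of <- topo$lipid_type[ref]
  out <- do.call(rbind, lapply(comps, function(comp) {
    rows <- comp_of == comp
    counts <- rowMeans(sapply(seq_along(frames), function(j) {
      graphics::hist(zmat[rows, j], breaks = breaks, plot = FALSE)$counts
    }))
    data.frame(component = comp, z = centers,
               density = counts / bin_width)
  }))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("density_profile", class(out))
  out
}

#' Bilayer thickness from leaflet reference planes
#'
#' Instantaneous thickness d_B(t) is the difference between the average
#' z-coordinates of the reference atoms (phosphate or fallback) in the
#' upper and lower leaflets, evaluated per analysis frame and averaged
#' over the window. Invariant under global translation.
#'
#' @inheritParams compute_lipid_geometry
#' @return list with \code{series} (per-frame d_B, angstrom), \code{mean}.
#' @export
compute_thickness <- function(traj, topo, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  ref <- which(topo$reference_kind != "none")
  pref <- which(topo$reference_kind == "phosphate_P")
  if (length(pref) > 0L) ref <- pref
  if (length(ref) == 0L) stop("reference error: no reference atoms flagged")
  series <- vapply(frames, function(f) {
    leaf <- assign_leaflets(traj, topo, f)
    up_lip <- as.integer(names(leaf)[leaf == "upper"])
    lo_lip <- as.integer(names(leaf)[leaf == "lower"])
    up <- ref[topo$lipid_id[ref] %in% up_lip]
    lo <- ref[topo$lipid_id[ref] %in% lo_lip]
    if (length(up) == 0L || length(lo) == 0L)
      stop("reference error: a leaflet has no reference atoms in frame ", f)
    mean(traj$coords[up, 3, f]) - mean(traj$coords[lo, 3, f])
  }, numeric(1))
  list(series = series, mean = mean(series))
}

#' Monolayer torque density from a lateral pressure profile
#'
#' The lateral-minus-normal pressure p(z) = p_T(z) - p_N(z) with
#' p_T = (p_xx + p_yy)/2 and, by default, p_N = p_zz (the normal component
#' of the pressure tensor; \code{normal = "pxx"} reproduces the
#' lateral-component convention instead, under which p(z) reduces to
#' (p_yy - p_xx)/2). Leaflet torques are the first moments
#' tau_upper = int_0^{Lz/2} z p(z) dz and tau_lower over [-Lz/2, 0],
#' computed by composite trapezoidal quadrature on bin centers with the
#' z = 0 endpoint added (its integrand is exactly zero). Two means are
#' returned: the literal average (tau_upper + tau_lower)/2, which vanishes
#' for any symmetric profile, and the leaflet-oriented
#' (tau_upper - tau_lower)/2, which equals tau_upper for symmetric
#' profiles and is the convention under which a nonzero per-monolayer
#' torque is reported.
#'
#' @param profile a \code{pressure_profile} data frame (columns z, p_xx,
#'   p_yy, p_zz; uniform contiguous bins spanning [-Lz/2, Lz/2]).
#' @param normal \code{"pzz"} (default) or \code{"pxx"}.
#' @return list of class \code{torque_result}: per-bin p_T, p_N, p, and
#'   tau_upper, tau_lower, tau_mean_literal, tau_mean_leaflet (bar
#'   angstrom).
#' @export
compute_torque_density <- function(profile, normal = c("pzz", "pxx")) {
  normal <- match.arg(normal)
  z <- profile$z
  dz <- diff(z)
  if (length(dz) > 0L && (max(dz) - min(dz)) > 1e-6 * stats::median(dz))
    stop("format error: non-uniform pressure-profile bins")
  p_T <- (profile$p_xx + profile$p_yy) / 2
  p_N <- if (normal == "pzz") profile$p_zz else profile$p_xx
  p <- p_T - p_N
  upper <- z > 0
  lower <- z < 0
  zp <- z * p
  tau_upper <- pracma::trapz(c(0, z[upper]), c(0, zp[upper]))
  tau_lower <- pracma::trapz(c(z[lower], 0), c(zp[lower], 0))
  structure(list(
    z = z, p_T = p_T, p_N = p_N, p = p,
    tau_upper = tau_upper, tau_lower = tau_lower,
    tau_mean_literal = (tau_upper + tau_lower) / 2,
    tau_mean_leaflet = (tau_upper - tau_lower) / 2
  ), class = "torque_result")
}

#' Area compressibility modulus from area fluctuations
#'
#' K_A = k_B T <A> / <(A(t) - <A>)^2> with the population variance of the
#' instantaneous projected bilayer area. Inputs in square angstrom;
#' output in mN/m.
#'
#' @param area_series projected areas A(t) (square angstrom), length >= 2.
#' @param temperature simulation temperature (K), default 310.
#' @return list of class \code{compressibility_result}: K_A (mN/m),
#'   mean_area, area_variance, temperature.
#' @export
compute_area_compressibility <- function(area_series, temperature = 310) {
  if (length(area_series) < 2L) stop("area series too short")
  m <- mean(area_series)
  v <- mean((area_series - m)^2)
  if (v == 0) stop("degenerate-fluctuation error: zero area variance")
  # kB[J/K] * T[K] * <A>[A^2 -> m^2: 1e-20] / var[A^4 -> m^4: 1e-40]
  # = N/m * 1e20 ; * 1e3 -> mN/m
  k_a <- .kB * temperature * m / v * 1e23
  structure(list(K_A = k_a, mean_area = m, area_variance = v,
                 temperature = temperature),
            class = "compressibility_result")
}

#' Bilayer stability screen from lipid escape events
#'
#' An ionizable lipid has escaped when its center of mass sits farther
#' than d_B/2 + escape_margin from the bilayer midplane for at least
#' \code{persistence} consecutive analysis frames, where d_B is the mean
#' bilayer thickness over the window. Any single escaped ionizable lipid
#' renders the bilayer unstable.
#'
#' @inheritParams compute_lipid_geometry
#' @param escape_margin extra clearance beyond the membrane slab
#'   half-thickness (angstrom), default 10.
#' @param persistence minimum consecutive frames beyond the slab, default 5.
#' @return list of class \code{stability_report}: \code{escaped_lipids}
#'   (data frame lipid_id, first_escape_frame), \code{stable},
#'   \code{criterion}.
#' @export
classify_stability <- function(traj, topo, frames = NULL,
                               escape_margin = 10, persistence = 5) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  d_b <- compute_thickness(traj, topo, frames)$mean
  slab <- d_b / 2 + escape_margin
  lips <- unique(topo$lipid_id[topo$lipid_type == "ionizable"])
  if (length(lips) == 0L) lips <- unique(topo$lipid_id)
  escaped <- data.frame(lipid_id = integer(0),
                        first_escape_frame = integer(0))
  for (lip in lips) {
    sel <- topo$lipid_id == lip
    m <- topo$mass[sel]
    out_flags <- vapply(frames, function(f) {
      mid <- .midplane_z(traj, topo, f)
      zc <- sum(m * traj$coords[sel, 3, f]) / sum(m)
      abs(zc - mid) > slab
    }, logical(1))
    r <- rle(out_flags)
    hit <- which(r$values & r$lengths >= persistence)
    if (length(hit) > 0L) {
      first <- sum(r$lengths[seq_len(hit[1L] - 1L)]) + 1L
      escaped <- rbind(escaped, data.frame(
        lipid_id = lip, first_escape_frame = frames[first]))
    }
  }
  structure(list(escaped_lipids = escaped, stable = nrow(escaped) == 0L,
                 criterion = list(escape_margin = escape_margin,
                                  persistence = persistence,
                                  thickness = d_b)),
            class = "stability_report")
}
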