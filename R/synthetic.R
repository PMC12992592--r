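# Synthetic-data generators: bilayer trajectories with analytically known
# cone geometry, area time series, piecewise-analytic pressure profiles,
# delivery datasets with prescribed correlation, and annotated SMILES
# fixtures. Every generator is a pure function of its spec (incl. seed).

#' Specification for a synthetic bilayer trajectory
#'
#' Each lipid is a rigid pseudo-atom construction: \code{atoms_per_head}
#' atoms equally spaced on a circle of radius \code{r_head} at the
#' head-group interface and \code{atoms_per_tail} terminal-tail atoms on a
#' circle of radius \code{r_tail} at depth \code{lipid_length} below it,
#' leaflets mirrored about z = 0. Per-atom, per-frame isotropic Gaussian
#' noise of sd \code{positional_noise_sd} emulates thermal disorder. Even
#' atom counts place antipodal pairs on each circle, so the half-max-
#' pairwise-distance radius estimator is exact in the noiseless limit.
#'
#' Defaults emulate the conditions of an all-atom bilayer production run
#' analyzed every 1 ns: about 100 lipids per leaflet, sub-angstrom
#' positional noise, cylindrical lipids (r_head = r_tail).
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param r_head,r_tail head/terminal-tail circle radii (angstrom).
#' @param lipid_length head-to-tail-plane depth (angstrom).
#' @param atoms_per_head,atoms_per_tail pseudo-atoms per circle (even).
#' @param positional_noise_sd per-atom Gaussian noise sd (angstrom).
#' @param n_frames number of frames; \code{frame_spacing} in ns.
#' @param box c(Lx, Ly, Lz) in angstrom; \code{NULL} sizes the box to the
#'   lipid grid automatically.
#' @param protonated_fraction fraction of lipids labelled protonated.
#' @param escape_events data frame (lipid_id, start_frame, z_offset) of
#'   lipids displaced out of the membrane slab from start_frame onward.
#' @param masses per-atom mass (amu); scalar recycled over all atoms.
#' @param seed RNG seed; identical spec implies identical trajectory.
#' @return list of class \code{bilayer_spec}.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet = 100,
                         r_head = 4, r_tail = 4, lipid_length = 20,
                         atoms_per_head = 6, atoms_per_tail = 6,
                         positional_noise_sd = 0.1,
                         n_frames = 100, frame_spacing = 1,
                         box = NULL,
                         protonated_fraction = 0,
                         escape_events = NULL,
                         masses = 1,
                         seed = 1) {
  stopifnot(r_head > 0, r_tail >= 0, lipid_length > 0,
            n_lipids_per_leaflet >= 1, n_frames >= 1,
            atoms_per_head >= 1, atoms_per_tail >= 1,
            positional_noise_sd >= 0,
            protonated_fraction >= 0, protonated_fraction <= 1)
  if (atoms_per_head %% 2L == 1L && atoms_per_head > 1L)
    warning("odd atoms_per_head: half-max-pairwise radius underestimates r_head")
  structure(as.list(environment()), class = "bilayer_spec")
}

.circle_points <- function(n, r, z) {
  if (n == 1L) return(cbind(0, 0, z))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(th), r * sin(th), rep(z, n))
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' Builds the trajectory, its topology table, and a ground-truth record
#' holding the exact geometry and the expected values of every downstream
#' estimator (CPP by both definitions, bilayer thickness, escape labels).
#' Lipid centers are laid out on a square grid per leaflet; the grid pitch
#' must exceed the lipid diameter or a geometry error is raised.
#'
#' Expected values: CPP_V = (r_h^2 + r_h r_t + r_t^2) / (3 r_h^2)
#' (truncated cone; the length cancels), CPP_Rg = r_tail / r_head (planar
#' radius of gyration of equal-mass circle points equals the circle
#' radius), thickness = 2 * lipid_length (head planes at +/- lipid_length).
#'
#' @param spec a \code{\link{bilayer_spec}}.
#' @return list with \code{trajectory} (\code{lnp_trajectory}),
#'   \code{topology} (\code{lnp_topology} data frame) and \code{truth}
#'   (list: r_head, r_tail, lipid_length, cpp_v, cpp_rg, thickness,
#'   escaped_lipids).
#' @export
make_bilayer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  n_side <- ceiling(sqrt(spec$n_lipids_per_leaflet))
  pitch <- 2 * max(spec$r_head, spec$r_tail) + 4
  if (is.null(spec$box)) {
    L <- n_side * pitch
    box <- c(L, L, 4 * spec$lipid_length + 40)
  } else {
    box <- spec$box
    if (box[1] / n_side < 2 * max(spec$r_head, spec$r_tail))
      stop("geometry error: box too small for lipid placement (",
           n_side, " x ", n_side, " grid of diameter ",
           2 * max(spec$r_head, spec$r_tail), " lipids in Lx = ", box[1], ")")
    pitch <- box[1] / n_side
  }

  apl <- spec$atoms_per_head + spec$atoms_per_tail   # atoms per lipid
  n_lip <- 2L * spec$n_lipids_per_leaflet
  n_atoms <- n_lip * apl

  # template lipid (upper leaflet): head circle at z = +l, tails at z = 0+
  head_u <- .circle_points(spec$atoms_per_head, spec$r_head, spec$lipid_length)
  tail_u <- .circle_points(spec$atoms_per_tail, spec$r_tail, 0)
  template_u <- rbind(head_u, tail_u)
  template_l <- template_u %*% diag(c(1, 1, -1))  # mirror about z = 0

  centers <- expand.grid(ix = seq_len(n_side) - 1L, iy = seq_len(n_side) - 1L)
  centers <- centers[seq_len(spec$n_lipids_per_leaflet), , drop = FALSE]
  cx <- (centers$ix + 0.5) * pitch - box[1] / 2
  cy <- (centers$iy + 0.5) * pitch - box[2] / 2

  base <- matrix(NA_real_, n_atoms, 3)
  lipid_id <- rep(seq_len(n_lip), each = apl)
  leaflet0 <- rep(c("upper", "lower"), each = spec$n_lipids_per_leaflet * apl)
  for (k in seq_len(spec$n_lipids_per_leaflet)) {
    iu <- ((k - 1L) * apl + 1L):(k * apl)
    il <- iu + spec$n_lipids_per_leaflet * apl
    base[iu, ] <- sweep(template_u, 2, c(cx[k], cy[k], 0), "+")
    base[il, ] <- sweep(template_l, 2, c(cx[k], cy[k], 0), "+")
  }

  esc <- spec$escape_events
  if (!is.null(esc)) {
    stopifnot(all(c("lipid_id", "start_frame", "z_offset") %in% names(esc)))
  }

  set.seed(spec$seed)
  coords <- array(NA_real_, dim = c(n_atoms, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    fr <- base
    if (spec$positional_noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(n_atoms * 3, 0, spec$positional_noise_sd),
                        n_atoms, 3)
    }
    if (!is.null(esc)) {
      for (r in seq_len(nrow(esc))) {
        if (f >= esc$start_frame[r]) {
          sel <- lipid_id == esc$lipid_id[r]
          sgn <- if (leaflet0[which(sel)[1L]] == "upper") 1 else -1
          fr[sel, 3] <- fr[sel, 3] + sgn * esc$z_offset[r]
        }
      }
    }
    coords[, , f] <- fr
  }

  role <- rep(rep(c("head", "tail"),
                  c(spec$atoms_per_head, spec$atoms_per_tail)), n_lip)
  is_terminal <- role == "tail"
  reference_kind <- ifelse(
    rep(seq_len(apl), n_lip) == 1L, "head_N", "none")
  n_prot <- round(spec$protonated_fraction * n_lip)
  charge_state <- ifelse(lipid_id <= n_prot, "protonated", "neutral")
  topo <- data.frame(
    atom_id = seq_len(n_atoms),
    lipid_id = lipid_id,
    lipid_type = "ionizable",
    charge_state = charge_state,
    role = role,
    is_terminal_tail = is_terminal,
    reference_kind = reference_kind,
    mass = rep_len(spec$masses, n_atoms)
  )
  class(topo) <- c("lnp_topology", class(topo))

  traj <- new_trajectory(
    coords = coords,
    time = (seq_len(spec$n_frames) - 1L) * spec$frame_spacing,
    box = matrix(box, spec$n_frames, 3, byrow = TRUE))

  rh <- spec$r_head; rt <- spec$r_tail
  truth <- list(
    r_head = rh, r_tail = rt, lipid_length = spec$lipid_length,
    cpp_v = (rh^2 + rh * rt + rt^2) / (3 * rh^2),
    cpp_rg = rt / rh,
    thickness = 2 * spec$lipid_length,
    escaped_lipids = if (is.null(esc)) integer(0) else unique(esc$lipid_id))
  list(trajectory = traj, topology = topo, truth = truth)
}

#' Generate a Gaussian projected-area time series
#'
#' I.i.d. Gaussian draws emulating equilibrium fluctuations of the
#' instantaneous projected bilayer area, with the analytic area
#' compressibility target K_A = k_B T <A> / var(A) recorded for a given
#' temperature.
#'
#' @param mean_area mean area (square angstrom).
#' @param sd_area fluctuation sd (square angstrom); 0 gives a constant
#'   series (downstream estimation must then error).
#' @param n series length.
#' @param seed RNG seed.
#' @param temperature kelvin (for the analytic target only).
#' @return list with \code{area} (numeric vector) and \code{k_a_target}
#'   (mN/m, analytic value at the prescribed moments).
#' @export
make_area_series <- function(mean_area, sd_area, n, seed = 1,
                             temperature = 310) {
  stopifnot(mean_area > 0, sd_area >= 0, n >= 2)
  set.seed(seed)
  area <- stats::rnorm(n, mean_area, sd_area)
  k_a <- if (sd_area > 0) {
    .kB * temperature * mean_area / sd_area^2 * 1e23  # mN/m, A^2 inputs
  } else {
    Inf
  }
  list(area = area, k_a_target = k_a, temperature = temperature)
}

.kB <- 1.380649e-23  # J/K

#' Generate an analytic lateral pressure profile table
#'
#' Produces a binned (z, p_xx, p_yy, p_zz) table over [-Lz/2, Lz/2] whose
#' lateral-minus-normal pressure p(z) follows a chosen analytic shape, with
#' the closed-form leaflet torques recorded as ground truth. The normal
#' component p_zz is zero, so p(z) = (p_xx + p_yy)/2.
#'
#' Shapes: \code{piecewise_constant} (params: p, zmin, zmax, and
#' \code{symmetric}; constant p on [zmin, zmax], mirrored with equal sign
#' onto the lower leaflet when \code{symmetric = TRUE}, the default, or
#' confined to the upper leaflet when \code{FALSE}),
#' \code{symmetric_gaussian} (params: a, z0, s; Gaussian bumps at +/- z0),
#' \code{antisymmetric} (params: c; linear ramp c*z, p(-z) = -p(z)).
#'
#' @param shape profile family.
#' @param params named list of shape parameters (see above).
#' @param bin_width slab width (angstrom), default 0.2.
#' @param Lz box height (angstrom).
#' @return data frame of class \code{pressure_profile} with columns z,
#'   p_xx, p_yy, p_zz; attributes \code{bin_width}, \code{Lz}, and
#'   \code{truth} (closed-form tau_upper, tau_lower in bar angstrom).
#' @export
make_pressure_profile <- function(shape = c("piecewise_constant",
                                            "symmetric_gaussian",
                                            "antisymmetric"),
                                  params = list(),
                                  bin_width = 0.2, Lz = 100) {
  shape <- match.arg(shape)
  stopifnot(bin_width > 0)
  n_bins <- round(Lz / bin_width)
  z <- (seq_len(n_bins) - 0.5) * bin_width - Lz / 2
  p <- switch(shape,
    piecewise_constant = {
      pr <- params$p; zmin <- params$zmin; zmax <- params$zmax
      zz <- if (isFALSE(params$symmetric)) z else abs(z)
      ifelse(zz >= zmin & zz <= zmax, pr, 0)
    },
    symmetric_gaussian = {
      a <- params$a; z0 <- params$z0; s <- params$s
      a * (exp(-(z - z0)^2 / (2 * s^2)) + exp(-(z + z0)^2 / (2 * s^2)))
    },
    antisymmetric = params$c * z
  )
  truth <- switch(shape,
    piecewise_constant = {
      tu <- params$p * (params$zmax^2 - params$zmin^2) / 2
      tl <- if (isFALSE(params$symmetric)) 0 else -tu
      list(tau_upper = tu, tau_lower = tl)
    },
    symmetric_gaussian = {
      a <- params$a; z0 <- params$z0; s <- params$s
      erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
      half <- function(mu) {  # int_0^Inf z a exp(-(z-mu)^2/(2 s^2)) dz
        a * (s^2 * exp(-mu^2 / (2 * s^2)) +
               mu * s * sqrt(pi / 2) * (1 + erf(mu / (s * sqrt(2)))))
      }
      tu <- half(z0) + half(-z0)
      list(tau_upper = tu, tau_lower = -tu)
    },
    antisymmetric = {
      tu <- params$c * (Lz / 2)^3 / 3
      list(tau_upper = tu, tau_lower = tu)
    })
  out <- data.frame(z = z, p_xx = p, p_yy = p, p_zz = 0)
  attr(out, "bin_width") <- bin_width
  attr(out, "Lz") <- Lz
  attr(out, "truth") <- truth
  class(out) <- c("pressure_profile", class(out))
  out
}

#' Generate a delivery dataset with prescribed feature-delivery correlation
#'
#' Bivariate-normal (feature, delivery) pairs with population correlation
#' \code{rho}; optional stratum labels (e.g. amine identities) assigned
#' round-robin. Emulates per-formulation mean-CPP versus standardized
#' delivery tables.
#'
#' @param n number of formulations.
#' @param rho population Pearson correlation, in [-1, 1].
#' @param strata optional character vector of stratum labels.
#' @param seed RNG seed.
#' @return data frame (feature, delivery, stratum).
#' @export
make_delivery_dataset <- function(n, rho, strata = NULL, seed = 1) {
  stopifnot(abs(rho) <= 1, n >= 1)
  set.seed(seed)
  feature <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  delivery <- rho * feature + sqrt(1 - rho^2) * noise
  stratum <- if (is.null(strata)) "overall"
             else rep_len(strata, n)
  data.frame(feature = feature, delivery = delivery, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Hand-annotated SMILES fixtures for the protonation decision tree
#'
#' Curated molecules covering every branch of the selection rules:
#' single-nitrogen shortcut, class hierarchy, amide/sulfonamide/quaternary
#' exclusions, aromatic ring versus aromatic amine classes, the
#' eccentricity tie-break, and the centrality (tail-amine) rule. The
#' expected answer is encoded as the expected class of the selected site
#' plus a discriminator identifying it among same-class candidates:
#' \code{"only"} (unique candidate), \code{"max_ecc"}, \code{"min_msd"},
#' or \code{"none"} (no protonatable nitrogen).
#'
#' @return data frame (smiles, label, expected_class, discriminator,
#'   dataset_rule).
#' @export
fixture_smiles <- function() {
  df <- rbind(
    c("CCN(CC)CC",            "triethylamine",        "tertiary_amine", "only",    "default"),
    c("CNC(C)=O",             "N-methylacetamide",    "none",           "none",    "default"),
    c("C[N+](C)(C)C",         "tetramethylammonium",  "none",           "none",    "default"),
    c("CS(=O)(=O)NC",         "N-methyl methanesulfonamide", "none",    "none",    "default"),
    c("CC#N",                 "acetonitrile",         "none",           "none",    "default"),
    c("c1ccncc1",             "pyridine",             "pyridine",       "only",    "default"),
    c("c1c[nH]cn1",           "imidazole",            "imidazole",      "only",    "default"),
    c("Nc1ccccc1",            "aniline",              "primary_aromatic_amine", "only", "default"),
    c("CN(C)c1ccccc1",        "N,N-dimethylaniline",  "tertiary_aromatic_amine", "only", "default"),
    c("CNCCN(C)C",            "secondary+tertiary diamine", "tertiary_amine", "only", "default"),
    c("CNCCc1ccncc1",         "secondary amine beats pyridine", "secondary_amine", "only", "default"),
    c("O=C(N)c1ccc(CN(C)C)cc1", "amide excluded, tertiary wins", "tertiary_amine", "only", "default"),
    c("CN(C)CCN(C)CC",        "two tertiary, periphery rule", "tertiary_amine", "max_ecc", "default"),
    c("CN(C)CCN(C)CC",        "two tertiary, centrality rule", "tertiary_amine", "min_msd", "tail_amine_central")
  )
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  names(out) <- c("smiles", "label", "expected_class", "discriminator",
                  "dataset_rule")
  out
}
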