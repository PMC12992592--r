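# Trajectory/topology data model, readers and writers, leaflet assignment,
# and analysis-window selection. Coordinates are in angstrom, times in ns,
# z is the membrane normal.

#' Construct a trajectory object
#'
#' @param coords numeric array [n_atoms, 3, n_frames] in angstrom.
#' @param time numeric vector of frame times (ns), strictly increasing.
#' @param box matrix [n_frames, 3] of box dimensions (Lx, Ly, Lz), or NULL.
#' @return object of class \code{lnp_trajectory}.
#' @export
new_trajectory <- function(coords, time, box = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[3] == length(time))
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    stopifnot(nrow(box) == length(time))
  }
  structure(list(coords = coords, time = time, box = box),
            class = "lnp_trajectory")
}

#' @export
print.lnp_trajectory <- function(x, ...) {
  cat("lnp_trajectory:", dim(x$coords)[1], "atoms,", dim(x$coords)[3],
      "frames, t =", min(x$time), "-", max(x$time), "ns\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_atoms <- function(traj) dim(traj$coords)[1]

#' Write a trajectory
#'
#' \code{pdb_multimodel}: standard multi-model PDB with one CRYST1 record
#' per MODEL block. \code{plain_frames}: a documented plain-text format —
#' a header line \code{natoms <n>}, then per frame one line
#' \code{FRAME <time_ns> <Lx> <Ly> <Lz>} followed by n lines \code{x y z}.
#'
#' @param traj an \code{lnp_trajectory}.
#' @param path output file.
#' @param format \code{"pdb_multimodel"} or \code{"plain_frames"}.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_multimodel", "plain_frames")) {
  format <- match.arg(format)
  na <- n_atoms(traj); nf <- n_frames(traj)
  box <- traj$box
  if (is.null(box)) box <- matrix(0, nf, 3)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb_multimodel") {
    for (f in seq_len(nf)) {
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
        box[f, 1], box[f, 2], box[f, 3]), con)
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- traj$coords[, , f]
      writeLines(sprintf(
        "ATOM  %5d  C   LIP A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        ((seq_len(na) - 1L) %% 99999L) + 1L,
        ((seq_len(na) - 1L) %/% 100L %% 9999L) + 1L,
        xyz[, 1], xyz[, 2], xyz[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    writeLines(paste("natoms", na), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("FRAME %.6f %.4f %.4f %.4f",
                         traj$time[f], box[f, 1], box[f, 2], box[f, 3]), con)
      xyz <- traj$coords[, , f]
      writeLines(sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

#' Load a trajectory
#'
#' Multi-model PDB files are read through bio3d; per-model CRYST1 box
#' records are collected by a supplementary scan (bio3d keeps a single box
#' record). Frame times for PDB input are taken as 0, 1, 2, ... ns unless
#' \code{frame_spacing} says otherwise. An atom-count mismatch between
#' MODEL blocks is a format error naming the frame.
#'
#' @param path input file.
#' @param format \code{"pdb_multimodel"} or \code{"plain_frames"}.
#' @param frame_spacing time between PDB frames (ns), default 1.
#' @return an \code{lnp_trajectory}.
#' @export
load_trajectory <- function(path,
                            format = c("pdb_multimodel", "plain_frames"),
                            frame_spacing = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  if (format == "pdb_multimodel") {
    model_starts <- grep("^MODEL", lines)
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_starts) != length(model_ends) ||
        length(model_starts) == 0L)
      stop("format error: unbalanced MODEL/ENDMDL records")
    counts <- vapply(seq_along(model_starts), function(f) {
      blk <- lines[model_starts[f]:model_ends[f]]
      sum(grepl("^(ATOM|HETATM)", blk))
    }, integer(1))
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("format error: atom count mismatch at frame ", bad,
           " (", counts[bad], " vs ", counts[1L], ")")
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nf <- nrow(pdb$xyz)
    na <- ncol(pdb$xyz) / 3L
    coords <- array(NA_real_, c(na, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    }
    cryst <- grep("^CRYST1", lines, value = TRUE)
    box <- NULL
    if (length(cryst) > 0L) {
      bx <- t(vapply(cryst, function(l) {
        c(as.numeric(substr(l, 7, 15)), as.numeric(substr(l, 16, 24)),
          as.numeric(substr(l, 25, 33)))
      }, numeric(3)))
      box <- if (nrow(bx) == nf) bx
             else matrix(bx[1L, ], nf, 3, byrow = TRUE)
    }
    new_trajectory(coords, time = (seq_len(nf) - 1L) * frame_spacing,
                   box = box)
  } else {
    hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    if (hdr[1L] != "natoms") stop("format error: missing natoms header")
    na <- as.integer(hdr[2L])
    body <- lines[-1L]
    frame_at <- grep("^FRAME", body)
    nf <- length(frame_at)
    if (nf == 0L) stop("format error: no FRAME records")
    coords <- array(NA_real_, c(na, 3, nf))
    time <- numeric(nf)
    box <- matrix(NA_real_, nf, 3)
    bounds <- c(frame_at, length(body) + 1L)
    for (f in seq_len(nf)) {
      navail <- bounds[f + 1L] - frame_at[f] - 1L
      if (navail != na)
        stop("format error: frame ", f, " has ", navail,
             " coordinate lines, expected ", na)
      hl <- strsplit(trimws(body[frame_at[f]]), "\\s+")[[1L]]
      time[f] <- as.numeric(hl[2L])
      box[f, ] <- as.numeric(hl[3:5])
      blk <- body[(frame_at[f] + 1L):(frame_at[f] + na)]
      m <- matrix(as.numeric(unlist(strsplit(trimws(blk), "\\s+"))),
                  ncol = 3, byrow = TRUE)
      coords[, , f] <- m
    }
    new_trajectory(coords, time = time, box = box)
  }
}

.topology_required <- c("atom_id", "lipid_id", "lipid_type", "charge_state",
                        "role", "is_terminal_tail", "reference_kind", "mass")
.role_levels <- c("head", "tail", "linker", "other")
.reference_levels <- c("phosphate_P", "hydroxyl_O", "head_N", "none")
.charge_levels <- c("neutral", "protonated")

#' Write a topology table to CSV
#' @param topo an \code{lnp_topology} data frame.
#' @param path output CSV path.
#' @export
write_topology <- function(topo, path) {
  utils::write.csv(as.data.frame(topo)[, .topology_required],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a topology table
#'
#' Reads the atom-to-lipid mapping CSV and validates enums and invariants:
#' every lipid has at least one atom, masses are positive, ionizable lipids
#' have head atoms. When a lipid has tail atoms but no terminal-tail flag,
#' the last tail atom (highest atom_id) is auto-flagged with a warning
#' (topology CSVs carry no bond table, so chain termini cannot be detected
#' by connectivity).
#'
#' @param path CSV with the columns atom_id, lipid_id, lipid_type,
#'   charge_state, role, is_terminal_tail, reference_kind, mass.
#' @return an \code{lnp_topology} data frame.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  topo <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.topology_required, names(topo))
  if (length(missing_cols) > 0L)
    stop("topology error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  topo$is_terminal_tail <- as.logical(topo$is_terminal_tail)
  bad_role <- setdiff(unique(topo$role), .role_levels)
  if (length(bad_role) > 0L)
    stop("topology error: unknown role value(s) ",
         paste(bad_role, collapse = ", "))
  bad_ref <- setdiff(unique(topo$reference_kind), .reference_levels)
  if (length(bad_ref) > 0L)
    stop("topology error: unknown reference_kind value(s) ",
         paste(bad_ref, collapse = ", "))
  bad_cs <- setdiff(unique(topo$charge_state), .charge_levels)
  if (length(bad_cs) > 0L)
    stop("topology error: unknown charge_state value(s) ",
         paste(bad_cs, collapse = ", "))
  if (any(!is.finite(topo$mass)) || any(topo$mass <= 0))
    stop("topology error: masses must be positive")
  for (lip in unique(topo$lipid_id)) {
    sel <- topo$lipid_id == lip
    if (topo$lipid_type[sel][1L] == "ionizable" &&
        !any(topo$role[sel] == "head"))
      stop("topology error: ionizable lipid ", lip, " has no head atoms")
    tails <- sel & topo$role == "tail"
    if (any(tails) && !any(topo$is_terminal_tail[tails])) {
      last <- which(tails)[which.max(topo$atom_id[tails])]
      topo$is_terminal_tail[last] <- TRUE
      warning("lipid ", lip,
              ": no terminal-tail flag; auto-flagged last tail atom ",
              topo$atom_id[last])
    }
  }
  class(topo) <- c("lnp_topology", class(topo))
  topo
}

# mass-weighted membrane center-of-mass z in one frame
.midplane_z <- function(traj, topo, frame) {
  z <- traj$coords[, 3, frame]
  sum(topo$mass * z) / sum(topo$mass)
}

# make a lipid whole across periodic boundaries (minimum image about the
# lipid's first atom); identity when no box is available
.make_whole <- function(xyz, box) {
  if (is.null(box)) return(xyz)
  ref <- xyz[1L, ]
  for (d in 1:2) {  # xy only; z is the membrane normal, never wrapped here
    L <- box[d]
    if (L <= 0) next
    dx <- xyz[, d] - ref[d]
    xyz[, d] <- ref[d] + dx - L * round(dx / L)
  }
  xyz
}

#' Assign lipids to leaflets
#'
#' A lipid belongs to the upper leaflet iff its reference z-coordinate
#' (reference atom if flagged, else the lipid's mass-weighted center)
#' exceeds the bilayer midplane, taken as the mass-weighted center of mass
#' of all membrane atoms in that frame. Translation invariant.
#'
#' @param traj an \code{lnp_trajectory}.
#' @param topo an \code{lnp_topology}.
#' @param frame frame index (1-based).
#' @return named character vector lipid_id -> "upper"/"lower".
#' @export
assign_leaflets <- function(traj, topo, frame = 1L) {
  mid <- .midplane_z(traj, topo, frame)
  z <- traj$coords[, 3, frame]
  lips <- unique(topo$lipid_id)
  out <- vapply(lips, function(lip) {
    sel <- topo$lipid_id == lip
    ref <- sel & topo$reference_kind != "none"
    zl <- if (any(ref)) mean(z[ref])
          else sum(topo$mass[sel] * z[sel]) / sum(topo$mass[sel])
    if (zl > mid) "upper" else "lower"
  }, character(1))
  names(out) <- as.character(lips)
  out
}

#' Select analysis frames: final window at a given stride
#'
#' Returns the indices of frames in the final \code{window_ns} of the
#' trajectory, sampled every \code{stride_ns} counting back from (and
#' including) the last frame. With 1500 frames at 1 ns spacing, window
#' 500 and stride 1 give the final 500 frames.
#'
#' @param traj an \code{lnp_trajectory}.
#' @param window_ns analysis window length (ns).
#' @param stride_ns sampling interval (ns).
#' @return integer vector of frame indices (ascending).
#' @export
select_analysis_frames <- function(traj, window_ns, stride_ns = 1) {
  t <- traj$time
  span <- max(t) - min(t) + (if (length(t) > 1L) t[2] - t[1] else window_ns)
  if (window_ns > span + 1e-9)
    stop("range error: window ", window_ns, " ns exceeds trajectory span ",
         span, " ns")
  cutoff <- max(t) - window_ns
  eligible <- which(t > cutoff + 1e-9)
  keep_t <- rev(seq(from = max(t), by = -stride_ns,
                    length.out = ceiling(window_ns / stride_ns)))
  idx <- eligible[vapply(t[eligible], function(tt) {
    any(abs(tt - keep_t) < 1e-9)
  }, logical(1))]
  sort(idx)
}
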