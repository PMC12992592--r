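# Molecular-graph analysis of ionizable lipids: nitrogen classification,
# rule-based protonation-site selection, and summary statistics.
# SMILES I/O and canonicalisation are delegated to OpenBabel (ChemmineOB);
# the classification and selection logic lives here.

# standard atomic weights (IUPAC 2021, conventional values)
.atomic_mass <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

.ob_convert <- function(from, to, source, add_h = FALSE) {
  out <- if (add_h) {
    ChemmineOB::convertFormat(from, to, source = source,
                              options = data.frame(names = c("h", "gen2D"),
                                                   args = c("", "")))
  } else {
    ChemmineOB::convertFormat(from, to, source = source)
  }
  out
}

#' Parse a lipid SMILES into an annotated molecular graph
#'
#' Canonicalizes the SMILES via OpenBabel, then extracts the heavy-atom
#' graph with per-atom element, formal charge, aromaticity, ring membership,
#' heavy-atom degree and implicit hydrogen count. Atom indices refer to the
#' canonical atom order, so identical molecules written with different atom
#' orderings yield identical graphs.
#'
#' @param smiles a single SMILES string.
#' @return object of class \code{mol_graph}: list with \code{atoms} (data
#'   frame), \code{bonds} (data frame with \code{i}, \code{j}, \code{order},
#'   \code{aromatic}), \code{graph} (igraph over heavy atoms),
#'   \code{canonical_smiles}, and the kekulized \code{sdf} text lines.
#' @export
parse_lipid <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- trimws(.ob_convert("SMI", "CAN", smiles))
  can <- sub("\\s.*$", "", can)  # strip molecule title
  if (!nzchar(can)) stop("SMILES parse error: '", smiles, "'")
  sdf <- strsplit(ChemmineOB::convertFormat("SMI", "SDF", source = can),
                  "\n", fixed = TRUE)[[1L]]
  counts <- sdf[4L]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_atoms) || n_atoms < 1L) stop("SMILES parse error: '", smiles, "'")
  atom_lines <- sdf[5L:(4L + n_atoms)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", sdf, value = TRUE)) {
    k <- as.integer(substr(ln, 7L, 9L))
    for (f in seq_len(k)) {
      off <- 10L + (f - 1L) * 8L
      a <- as.integer(substr(ln, off, off + 3L))
      v <- as.integer(substr(ln, off + 4L, off + 7L))
      charge[a] <- v
    }
  }
  if (n_bonds > 0L) {
    bond_lines <- sdf[(5L + n_atoms):(4L + n_atoms + n_bonds)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1L, 3L)),
      j = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }

  # aromaticity from the TRIPOS mol2 atom/bond types (same atom order)
  mol2 <- strsplit(ChemmineOB::convertFormat("SMI", "MOL2", source = can),
                   "\n", fixed = TRUE)[[1L]]
  a0 <- grep("^@<TRIPOS>ATOM", mol2)
  b0 <- grep("^@<TRIPOS>BOND", mol2)
  atom_rows <- mol2[(a0 + 1L):(a0 + n_atoms)]
  types <- vapply(strsplit(trimws(atom_rows), "\\s+"),
                  function(x) x[6L], character(1))
  aromatic_atom <- grepl("\\.ar$", types)
  aromatic_bond <- logical(nrow(bonds))
  if (n_bonds > 0L) {
    bond_rows <- mol2[(b0 + 1L):(b0 + n_bonds)]
    parts <- strsplit(trimws(bond_rows), "\\s+")
    bi <- vapply(parts, function(x) as.integer(x[2L]), integer(1))
    bj <- vapply(parts, function(x) as.integer(x[3L]), integer(1))
    bt <- vapply(parts, function(x) x[4L], character(1))
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    key2 <- paste(pmin(bi, bj), pmax(bi, bj))
    aromatic_bond <- bt[match(key, key2)] == "ar"
    aromatic_bond[is.na(aromatic_bond)] <- FALSE
  }
  bonds$aromatic <- aromatic_bond

  # implicit hydrogen counts from an explicit-H conversion (heavy atoms
  # keep their order; hydrogens are appended)
  hsdf <- strsplit(.ob_convert("SMI", "SDF", can, add_h = TRUE),
                   "\n", fixed = TRUE)[[1L]]
  hn_atoms <- as.integer(substr(hsdf[4L], 1L, 3L))
  hn_bonds <- as.integer(substr(hsdf[4L], 4L, 6L))
  h_count <- integer(n_atoms)
  if (hn_bonds > 0L) {
    hb <- hsdf[(5L + hn_atoms):(4L + hn_atoms + hn_bonds)]
    hi <- as.integer(substr(hb, 1L, 3L))
    hj <- as.integer(substr(hb, 4L, 6L))
    helem <- trimws(substr(hsdf[5L:(4L + hn_atoms)], 32L, 34L))
    for (b in seq_along(hi)) {
      if (hi[b] <= n_atoms && helem[hj[b]] == "H") {
        h_count[hi[b]] <- h_count[hi[b]] + 1L
      } else if (hj[b] <= n_atoms && helem[hi[b]] == "H") {
        h_count[hj[b]] <- h_count[hj[b]] + 1L
      }
    }
  }

  g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  }
  degree <- igraph::degree(g)
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds) > 0L) {
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
    if (length(ring_edges) > 0L) {
      ends <- igraph::ends(g, ring_edges)
      in_ring[unique(as.vector(ends))] <- TRUE
    }
  }

  structure(list(
    atoms = data.frame(element = element, charge = charge,
                       aromatic = aromatic_atom, in_ring = in_ring,
                       degree = degree, h_count = h_count),
    bonds = bonds,
    graph = g,
    canonical_smiles = can,
    sdf = sdf
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph:", x$canonical_smiles, "-", nrow(x$atoms), "heavy atoms,",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

# smallest ring through atom v: for each incident ring edge, length of the
# shortest alternative path + 1; returns the vertex set of that cycle
.smallest_ring <- function(mol, v) {
  g <- mol$graph
  inc <- igraph::incident(g, v)
  best <- NULL
  for (e in inc) {
    ends <- igraph::ends(g, e)
    u <- ends[ends != v][1L]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = v, to = u))
    verts <- sp$vpath[[1L]]
    if (length(verts) == 0L) next
    if (is.null(best) || length(verts) < length(best)) best <- as.integer(verts)
  }
  best
}

.amine_classes <- c("tertiary_amine", "secondary_amine", "primary_amine",
                    "imidazole", "pyridine", "tertiary_aromatic_amine",
                    "secondary_aromatic_amine", "primary_aromatic_amine")

#' Classify the nitrogen atoms of an ionizable lipid
#'
#' Assigns each nitrogen one of the protonation-hierarchy classes
#' (tertiary/secondary/primary amine, imidazole, pyridine,
#' tertiary/secondary/primary aromatic amine) or \code{excluded}. Excluded
#' nitrogens are amide and sulfonamide nitrogens, quaternary or already
#' charged nitrogens, nitrogens carrying non-aromatic multiple bonds
#' (imines, nitriles, nitro groups), and pyrrole-type aromatic nitrogens
#' whose lone pair is part of the aromatic system. Aromatic ring nitrogens
#' of pyridine type are classed \code{imidazole} in five-membered rings and
#' \code{pyridine} otherwise; an exocyclic nitrogen bonded to an aromatic
#' atom is an aromatic amine.
#'
#' Eccentricity is the longest shortest-path graph distance from the
#' nitrogen to any heavy atom (unit bond lengths);
#' \code{mean_sq_graph_distance} is the average squared distance to all
#' other heavy atoms. Both feed the tie-break rules of
#' \code{\link{select_protonation_site}}.
#'
#' @param mol a \code{mol_graph} from \code{\link{parse_lipid}}.
#' @return data frame with one row per nitrogen: \code{atom_index},
#'   \code{site_class}, \code{eccentricity}, \code{mean_sq_graph_distance}.
#' @export
classify_nitrogen_sites <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  at <- mol$atoms
  n_idx <- which(at$element == "N")
  D <- igraph::distances(mol$graph)
  out <- data.frame(atom_index = integer(0), site_class = character(0),
                    eccentricity = integer(0),
                    mean_sq_graph_distance = numeric(0))
  neighbors_of <- function(v) {
    b <- mol$bonds
    c(b$j[b$i == v], b$i[b$j == v])
  }
  bond_between <- function(v, u) {
    b <- mol$bonds
    b[(b$i == v & b$j == u) | (b$i == u & b$j == v), , drop = FALSE]
  }
  for (v in n_idx) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    ecc <- if (length(d) > 0L) max(d) else 0
    msd <- if (length(d) > 0L) mean(d^2) else 0
    heavy_deg <- at$degree[v]
    total_bonds <- heavy_deg + at$h_count[v]
    nb <- neighbors_of(v)
    cls <- NULL
    if (at$charge[v] != 0 || total_bonds >= 4L) {
      cls <- "excluded"  # quaternary / already charged / nitro-type
    }
    if (is.null(cls)) {
      for (u in nb) {
        bb <- bond_between(v, u)
        if (any(bb$order >= 2L & !bb$aromatic)) { cls <- "excluded"; break }
      }
    }
    if (is.null(cls)) {
      # amide: N-C(=O); sulfonamide: N-S(=O)
      for (u in nb) {
        if (!(at$element[u] %in% c("C", "S"))) next
        for (w in neighbors_of(u)) {
          if (w == v) next
          bw <- bond_between(u, w)
          if (at$element[w] == "O" && any(bw$order == 2L & !bw$aromatic)) {
            cls <- "excluded"
            break
          }
        }
        if (!is.null(cls)) break
      }
    }
    if (is.null(cls) && at$aromatic[v]) {
      if (total_bonds >= 3L) {
        cls <- "excluded"  # pyrrole-type: lone pair in the ring, non-basic
      } else {
        ring <- .smallest_ring(mol, v)
        cls <- if (!is.null(ring) && length(ring) == 5L) "imidazole" else "pyridine"
      }
    }
    if (is.null(cls)) {
      arom_neighbor <- any(at$aromatic[nb])
      base <- switch(as.character(min(heavy_deg, 3L)),
                     "3" = "tertiary", "2" = "secondary", "primary")
      cls <- if (arom_neighbor) paste0(base, "_aromatic_amine")
             else paste0(base, "_amine")
    }
    out <- rbind(out, data.frame(atom_index = v, site_class = cls,
                                 eccentricity = as.integer(ecc),
                                 mean_sq_graph_distance = msd))
  }
  out
}

#' Select the nitrogen to protonate
#'
#' Applies the rule-based decision tree for assigning one representative
#' +1e protonation site per ionizable lipid. A molecule with a single
#' (non-excluded) nitrogen selects that nitrogen. Otherwise the
#' highest-priority class wins, in the order tertiary amine, secondary
#' amine, primary amine, imidazole, pyridine, tertiary aromatic amine,
#' secondary aromatic amine, primary aromatic amine. Ties within a class
#' are broken by greatest graph eccentricity (the candidate closest to the
#' molecular periphery; \code{dataset_rule = "default"}) or by lowest mean
#' squared graph distance to all other atoms (the most central candidate;
#' \code{dataset_rule = "tail_amine_central"}, used for tail-amine lipids in
#' KZ-style combinatorial libraries). Any remaining tie falls to the lowest
#' canonical atom index.
#'
#' @param sites data frame from \code{\link{classify_nitrogen_sites}}.
#' @param dataset_rule \code{"default"} or \code{"tail_amine_central"}.
#' @return list with \code{selected_index} (canonical atom index or
#'   \code{NA}) and \code{rule_trace} (character vector of applied rules).
#' @export
select_protonation_site <- function(sites,
                                    dataset_rule = c("default",
                                                     "tail_amine_central")) {
  dataset_rule <- match.arg(dataset_rule)
  trace <- character(0)
  if (nrow(sites) == 0L) {
    return(list(selected_index = NA_integer_,
                rule_trace = "no nitrogen atoms present"))
  }
  cand <- sites[sites$site_class != "excluded", , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(selected_index = NA_integer_,
                rule_trace = "all nitrogens excluded (amide/sulfonamide/quaternary/non-basic)"))
  }
  if (nrow(sites) == 1L) {
    return(list(selected_index = sites$atom_index[1L],
                rule_trace = "single nitrogen"))
  }
  rank <- match(cand$site_class, .amine_classes)
  best <- cand[rank == min(rank), , drop = FALSE]
  trace <- c(trace, paste0("hierarchy: ", best$site_class[1L],
                           " (", nrow(best), " candidate(s))"))
  if (nrow(best) > 1L) {
    if (dataset_rule == "default") {
      best <- best[best$eccentricity == max(best$eccentricity), , drop = FALSE]
      trace <- c(trace, "tie-break: greatest graph eccentricity")
    } else {
      best <- best[best$mean_sq_graph_distance ==
                     min(best$mean_sq_graph_distance), , drop = FALSE]
      trace <- c(trace, "tie-break: lowest mean squared graph distance")
    }
  }
  if (nrow(best) > 1L) {
    best <- best[which.min(best$atom_index), , drop = FALSE]
    trace <- c(trace, "tie-break: lowest canonical atom index")
  }
  list(selected_index = best$atom_index[1L], rule_trace = trace)
}

#' Protonate a nitrogen site
#'
#' Assigns a +1 formal charge (and one hydrogen equivalent) to the selected
#' nitrogen and emits the protonated canonical SMILES. The molecule is
#' otherwise unchanged; the net molecular charge increases by exactly 1.
#'
#' @param mol a \code{mol_graph}.
#' @param site canonical atom index of a neutral, non-excluded nitrogen.
#' @return list of class \code{protonation_result} with
#'   \code{selected_index}, \code{protonated_smiles}, \code{rule_trace}.
#' @export
protonate <- function(mol, site) {
  stopifnot(inherits(mol, "mol_graph"))
  at <- mol$atoms
  if (is.na(site) || site < 1L || site > nrow(at) || at$element[site] != "N")
    stop("invalid protonation site: atom ", site, " is not a nitrogen")
  sites <- classify_nitrogen_sites(mol)
  cls <- sites$site_class[sites$atom_index == site]
  if (length(cls) == 0L || cls == "excluded")
    stop("invalid protonation site: atom ", site,
         " is an excluded nitrogen (amide/sulfonamide/quaternary or charged)")
  charges <- at$charge
  charges[site] <- 1L
  sdf <- mol$sdf[!grepl("^M  CHG", mol$sdf)]
  iend <- grep("^M  END", sdf)[1L]
  chg_idx <- which(charges != 0L)
  chg_lines <- character(0)
  for (s in seq(1L, length(chg_idx), by = 8L)) {
    chunk <- chg_idx[s:min(s + 7L, length(chg_idx))]
    chg_lines <- c(chg_lines, paste0(
      sprintf("M  CHG%3d", length(chunk)),
      paste0(sprintf("%4d%4d", chunk, charges[chunk]), collapse = "")))
  }
  sdf <- append(sdf, chg_lines, after = iend - 1L)
  out <- trimws(.ob_convert("SDF", "CAN", paste(sdf, collapse = "\n")))
  out <- sub("\\s.*$", "", out)
  if (!nzchar(out)) stop("protonated SMILES emission failed")
  structure(list(selected_index = site, protonated_smiles = out,
                 rule_trace = paste0("protonated atom ", site, " (+1)")),
            class = "protonation_result")
}

#' End-to-end protonation of an ionizable lipid SMILES
#'
#' Convenience wrapper: parse, classify, select, protonate. When no
#' protonatable nitrogen exists, the result carries \code{NA} indices and
#' the rule trace explains why.
#'
#' @inheritParams parse_lipid
#' @inheritParams select_protonation_site
#' @return a \code{protonation_result} list; \code{protonated_smiles} is
#'   \code{NA} when no site was selected.
#' @export
protonate_smiles <- function(smiles, dataset_rule = "default") {
  mol <- parse_lipid(smiles)
  sites <- classify_nitrogen_sites(mol)
  sel <- select_protonation_site(sites, dataset_rule)
  if (is.na(sel$selected_index)) {
    return(structure(list(selected_index = NA_integer_,
                          protonated_smiles = NA_character_,
                          rule_trace = sel$rule_trace),
                     class = "protonation_result"))
  }
  res <- protonate(mol, sel$selected_index)
  res$rule_trace <- c(sel$rule_trace, res$rule_trace)
  res
}

#' @export
print.protonation_result <- function(x, ...) {
  if (is.na(x$selected_index)) {
    cat("protonation: no site selected\n ", x$rule_trace[1L], "\n")
  } else {
    cat("protonation: atom", x$selected_index, "->", x$protonated_smiles, "\n")
    cat(paste(" ", x$rule_trace, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Protonated fraction of a basic site (Henderson-Hasselbalch)
#'
#' Fraction of a monobasic site carrying the proton at a given pH:
#' \eqn{f = 1 / (1 + 10^{pH - pKa})}. At endosomal pH below the pKa of a
#' typical ionizable lipid (about 6.5) most lipids are protonated; at
#' physiological pH most are neutral.
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant of the conjugate acid.
#' @return protonated fraction in [0, 1]; vectorized.
#' @export
protonation_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pH - pKa))
}

#' Summary statistics over a set of lipid SMILES
#'
#' Per lipid: molecular weight (standard atomic masses, implicit hydrogens
#' included), nitrogen count, and a substitution-class label reflecting the
#' set of amine substitution levels present (e.g. "tertiary only",
#' "secondary+tertiary", "no amine"). Unparseable entries are reported and
#' excluded from the aggregate.
#'
#' @param smiles_list character vector of SMILES.
#' @return list with \code{per_lipid} (data frame) and \code{aggregate}
#'   (mean/sd/range of molecular weight, mean nitrogen count, n parsed,
#'   n failed).
#' @export
lipid_summary_stats <- function(smiles_list) {
  rows <- lapply(smiles_list, function(s) {
    mol <- tryCatch(parse_lipid(s), error = function(e) NULL)
    if (is.null(mol)) {
      return(data.frame(smiles = s, mw = NA_real_, n_nitrogens = NA_integer_,
                        amine_class = NA_character_, parsed = FALSE))
    }
    at <- mol$atoms
    known <- at$element %in% names(.atomic_mass)
    if (!all(known)) {
      return(data.frame(smiles = s, mw = NA_real_, n_nitrogens = NA_integer_,
                        amine_class = NA_character_, parsed = FALSE))
    }
    mw <- sum(.atomic_mass[at$element]) + sum(at$h_count) * .atomic_mass[["H"]]
    sites <- classify_nitrogen_sites(mol)
    lev <- unique(sub("_(aromatic_)?amine$", "",
                      grep("amine$", sites$site_class, value = TRUE)))
    lev <- intersect(c("primary", "secondary", "tertiary"), lev)
    label <- if (length(lev) == 0L) "no amine"
             else if (length(lev) == 1L) paste(lev, "only")
             else paste(lev, collapse = "+")
    data.frame(smiles = s, mw = mw, n_nitrogens = sum(at$element == "N"),
               amine_class = label, parsed = TRUE)
  })
  per <- do.call(rbind, rows)
  ok <- per[per$parsed, , drop = FALSE]
  agg <- list(
    n_parsed = nrow(ok), n_failed = sum(!per$parsed),
    mw_mean = mean(ok$mw), mw_sd = stats::sd(ok$mw),
    mw_range = if (nrow(ok) > 0L) range(ok$mw) else c(NA_real_, NA_real_),
    n_nitrogens_mean = mean(ok$n_nitrogens)
  )
  list(per_lipid = per, aggregate = agg)
}
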