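# Shared fixtures, built in code at test time.

# write a toy formulation CSV; returns its path
write_toy_formulations <- function(path = tempfile(fileext = ".csv"),
                                   drop_column = NULL) {
  df <- data.frame(
    lnp_id = c("L1", "L2", "L3"),
    ionizable_lipid_smiles = c("CCN(CC)CC", "CN(C)CCO", "CCCN"),
    ionizable_lipid_amine_id = c("A2", "A3", "A2"),
    ratio_ionizable = c(50, 50, 50),
    ratio_helper = c(10, 10, 10),
    ratio_chol = c(38.5, 38.5, 38.5),
    ratio_peg = c(1.5, 1.5, 1.5),
    il_to_na_mass_ratio = c(10, 10, 10),
    publication_id = c("P1", "P1", "P1"),
    delivery_context = c("in vitro", "in vitro", "in vitro"),
    cargo = "mRNA",
    readout_method = "luminescence",
    readout_value = c(1, 2, 3),
    stringsAsFactors = FALSE
  )
  if (!is.null(drop_column)) df[[drop_column]] <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# single-frame trajectory of disc lipids with exact radii; lipids spaced
# far apart so geometry is unambiguous. radii/lengths are per-lipid vectors.
make_disc_lipids <- function(r_head, r_tail, length_, n_head = 4L,
                             n_tail = 4L) {
  n <- length(r_head)
  apl <- n_head + n_tail
  circle <- function(k, r, z) {
    th <- 2 * pi * (seq_len(k) - 1L) / k
    cbind(r * cos(th), r * sin(th), rep(z, k))
  }
  coords <- array(NA_real_, c(n * apl, 3, 1))
  for (i in seq_len(n)) {
    off <- c((i - 1) * 1000, 0, 0)
    lip <- rbind(circle(n_head, r_head[i], length_[i]),
                 circle(n_tail, r_tail[i], 0))
    coords[((i - 1) * apl + 1):(i * apl), , 1] <- sweep(lip, 2, off, "+")
  }
  topo <- data.frame(
    atom_id = seq_len(n * apl),
    lipid_id = rep(seq_len(n), each = apl),
    lipid_type = "ionizable",
    charge_state = "neutral",
    role = rep(rep(c("head", "tail"), c(n_head, n_tail)), n),
    is_terminal_tail = rep(rep(c(FALSE, TRUE), c(n_head, n_tail)), n),
    reference_kind = ifelse(rep(seq_len(apl), n) == 1L, "head_N", "none"),
    mass = 1
  )
  list(trajectory = new_trajectory(coords, time = 0),
       topology = topo)
}

cpp_v_reduced <- function(r_h, r_t) (r_h^2 + r_h * r_t + r_t^2) / (3 * r_h^2)
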