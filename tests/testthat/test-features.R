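test_that("disc lipids recover exact radii, areas and cone volumes", {
  fx <- make_disc_lipids(r_head = 4, r_tail = 6, length_ = 20)
  g <- compute_lipid_geometry(fx$trajectory, fx$topology)
  expect_equal(g$r_head, 4)
  expect_equal(g$r_tail, 6)
  expect_equal(g$a_0, pi * 16)
  expect_equal(g$V, pi * g$l_c / 3 * (16 + 24 + 36))
  expect_false(g$degenerate_flag)
  # rigid z-translation leaves the geometry unchanged
  shifted <- fx$trajectory
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 123
  expect_equal(compute_lipid_geometry(shifted, fx$topology)[, -2],
               g[, -2])
})

test_that("a single head atom is degenerate, not an answer", {
  fx <- make_disc_lipids(4, 4, 20, n_head = 1L)
  g <- compute_lipid_geometry(fx$trajectory, fx$topology)
  expect_equal(g$r_head, 0)
  expect_true(g$degenerate_flag)
  expect_error(compute_cpp_v(g), "all lipids degenerate")
})

test_that("CPP_V hits the cylinder and cone limits", {
  cyl <- make_disc_lipids(4, 4, 15)
  expect_equal(compute_cpp_v(
    compute_lipid_geometry(cyl$trajectory, cyl$topology))$pooled_mean, 1)
  cone <- make_disc_lipids(4, 0, 15, n_tail = 1L)
  expect_equal(compute_cpp_v(
    compute_lipid_geometry(cone$trajectory, cone$topology))$pooled_mean,
    1 / 3)
  frustum <- make_disc_lipids(4, 6, 33)
  expect_equal(compute_cpp_v(
    compute_lipid_geometry(frustum$trajectory, frustum$topology))$pooled_mean,
    76 / 48)
})

test_that("CPP aggregation: per-lipid means first, SEM over lipids", {
  fx <- make_disc_lipids(c(4, 4), c(4, 6), c(20, 20))
  g <- compute_lipid_geometry(fx$trajectory, fx$topology)
  res <- compute_cpp_v(g)
  expect_equal(res$n_lipids, 2L)
  expect_equal(res$pooled_mean, mean(res$per_lipid_means))
  expect_equal(res$dispersion,
               sd(res$per_lipid_means) / sqrt(res$n_lipids))
  expect_equal(res$dispersion_type, "SEM")
  expect_equal(res$variance_across_lipids, var(res$per_lipid_means))
})

test_that("CPP_Rg equals the circle-radius ratio and uses SD dispersion", {
  fx <- make_disc_lipids(2, 3, 20)
  res <- compute_cpp_rg(fx$trajectory, fx$topology)
  expect_equal(res$pooled_mean, 1.5, tolerance = 1e-12)
  expect_equal(res$dispersion_type, "SD")
  eq <- make_disc_lipids(3, 3, 20)
  expect_equal(compute_cpp_rg(eq$trajectory, eq$topology)$pooled_mean, 1)
})

test_that("CPP_Rg is invariant under uniform mass rescaling", {
  fx <- make_disc_lipids(2, 3, 20)
  base <- compute_cpp_rg(fx$trajectory, fx$topology)$pooled_mean
  heavy <- fx$topology
  heavy$mass <- heavy$mass * 12
  expect_equal(compute_cpp_rg(fx$trajectory, heavy)$pooled_mean, base,
               tolerance = 1e-12)
})

test_that("coincident head and tail centers exclude the lipid with warning", {
  fx <- make_disc_lipids(3, 3, 0)  # zero length: COMs coincide
  expect_warning(expect_error(
    compute_cpp_rg(fx$trajectory, fx$topology), "no usable lipids"),
    "undefined orientation")
})

test_that("shape classification maps CPP to cone / cylinder / inverted cone", {
  expect_equal(classify_shape(0.8), "cone")
  expect_equal(classify_shape(1.0), "cylinder")
  expect_equal(classify_shape(1.4), "inverted_cone")
  expect_equal(classify_shape(c(0.97, 1.04), cylinder_band = 0.05),
               c("cylinder", "cylinder"))
  expect_error(classify_shape(-0.1), "domain error")
})

test_that("density profiles conserve representative-atom counts", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 5,
                                              n_frames = 4, seed = 8))
  prof <- compute_density_profile(sim$trajectory, sim$topology,
                                  bin_width = 1)
  integral <- sum(prof$density) * attr(prof, "bin_width")
  expect_equal(integral, 10)  # one reference atom per lipid
  # two symmetric peaks at +/- lipid_length
  peaks <- prof$z[prof$density > max(prof$density) / 2]
  expect_true(any(peaks > 0) && any(peaks < 0))
  bad <- sim$topology
  bad$reference_kind <- "none"
  expect_error(compute_density_profile(sim$trajectory, bad),
               "no representative")
})

test_that("thickness equals the constructed separation and is translation invariant", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 4,
                                              lipid_length = 20,
                                              positional_noise_sd = 0,
                                              n_frames = 2))
  th <- compute_thickness(sim$trajectory, sim$topology)
  expect_equal(th$mean, 40, tolerance = 1e-12)
  shifted <- sim$trajectory
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 17.3
  expect_equal(compute_thickness(shifted, sim$topology)$mean, th$mean,
               tolerance = 1e-12)
})

test_that("noisy thickness stays within sampling error of the truth", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 16,
                                              lipid_length = 20,
                                              positional_noise_sd = 1,
                                              n_frames = 30, seed = 5))
  th <- compute_thickness(sim$trajectory, sim$topology)
  sem <- sd(th$series) / sqrt(length(th$series))
  expect_lt(abs(th$mean - 40), 3 * sem + 0.05)
})

test_that("torque density matches closed forms and both conventions", {
  pp <- make_pressure_profile("piecewise_constant",
                              list(p = 2, zmin = 5, zmax = 10,
                                   symmetric = FALSE), 0.2, 100)
  tq <- compute_torque_density(pp)
  expect_equal(tq$tau_upper, 75, tolerance = 0.005 * 75)
  expect_equal(tq$tau_lower, 0)
  expect_equal(tq$tau_mean_literal, tq$tau_upper / 2, tolerance = 1e-9)
  sym <- make_pressure_profile("piecewise_constant",
                               list(p = 2, zmin = 5, zmax = 10), 0.2, 100)
  tqs <- compute_torque_density(sym)
  expect_lt(abs(tqs$tau_mean_literal), 1e-9)
  expect_equal(tqs$tau_mean_leaflet, tqs$tau_upper)
  zero <- make_pressure_profile("piecewise_constant",
                                list(p = 0, zmin = 1, zmax = 2), 0.2, 50)
  expect_equal(compute_torque_density(zero)$tau_upper, 0)
  # the printed-normal convention makes p vanish for isotropic stress
  iso <- compute_torque_density(sym, normal = "pxx")
  expect_equal(iso$tau_upper, 0)
})

test_that("area compressibility has the right value and scaling law", {
  # series with exact moments: mean 4900, population variance 100
  ka <- compute_area_compressibility(c(4890, 4910), temperature = 310)
  expect_equal(ka$K_A, 20972.06, tolerance = 1e-6)
  half_var <- compute_area_compressibility(4900 + c(-1, 1) * sqrt(50))
  expect_equal(half_var$K_A / ka$K_A, 2, tolerance = 1e-9)
  expect_error(compute_area_compressibility(rep(100, 5)),
               "degenerate-fluctuation")
})

test_that("stability screen flags injected escapes and nothing else", {
  esc <- data.frame(lipid_id = 3L, start_frame = 20L, z_offset = 30)
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 6,
                                              n_frames = 40, seed = 6,
                                              escape_events = esc))
  rep_ <- classify_stability(sim$trajectory, sim$topology)
  expect_false(rep_$stable)
  expect_equal(rep_$escaped_lipids$lipid_id, 3L)
  expect_gte(rep_$escaped_lipids$first_escape_frame, 20L)
  clean <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 6,
                                                n_frames = 40, seed = 6))
  expect_true(classify_stability(clean$trajectory, clean$topology)$stable)
})

test_that("transient excursions below the persistence threshold are stable", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 4,
                                              n_frames = 30, seed = 2))
  traj <- sim$trajectory
  sel <- sim$topology$lipid_id == 2
  traj$coords[sel, 3, 10] <- traj$coords[sel, 3, 10] + 60  # one frame only
  rep_ <- classify_stability(traj, sim$topology, persistence = 5)
  expect_true(rep_$stable)
})

test_that("disjoint charge-state subsets aggregate to the weighted mean", {
  sim <- make_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 6,
                                              r_head = 4, r_tail = 6,
                                              n_frames = 5, seed = 4,
                                              protonated_fraction = 0.5))
  topo <- sim$topology
  prot <- unique(topo$lipid_id[topo$charge_state == "protonated"])
  neut <- unique(topo$lipid_id[topo$charge_state == "neutral"])
  g_all <- compute_lipid_geometry(sim$trajectory, topo)
  res_all <- compute_cpp_v(g_all)
  res_p <- compute_cpp_v(g_all[g_all$lipid_id %in% prot, ])
  res_n <- compute_cpp_v(g_all[g_all$lipid_id %in% neut, ])
  pooled <- (res_p$pooled_mean * res_p$n_lipids +
               res_n$pooled_mean * res_n$n_lipids) /
    (res_p$n_lipids + res_n$n_lipids)
  expect_equal(pooled, res_all$pooled_mean, tolerance = 1e-12)
})
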