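test_that("nitrogen classes match manual valence inspection", {
  cls <- function(s) classify_nitrogen_sites(parse_lipid(s))$site_class
  expect_equal(cls("CCN(CC)CC"), "tertiary_amine")
  expect_equal(cls("CNC(C)=O"), "excluded")          # amide
  expect_equal(cls("CS(=O)(=O)NC"), "excluded")      # sulfonamide
  expect_equal(cls("C[N+](C)(C)C"), "excluded")      # quaternary
  expect_equal(cls("c1ccncc1"), "pyridine")
  expect_setequal(cls("c1c[nH]cn1"), c("imidazole", "excluded"))
  expect_equal(cls("Nc1ccccc1"), "primary_aromatic_amine")
  expect_equal(cls("CN(C)c1ccccc1"), "tertiary_aromatic_amine")
})

test_that("hierarchy prefers higher amine substitution and graph tie-breaks", {
  pick <- function(s, rule = "default") {
    sites <- classify_nitrogen_sites(parse_lipid(s))
    sel <- select_protonation_site(sites, rule)
    sites[sites$atom_index == sel$selected_index, , drop = FALSE]
  }
  expect_equal(pick("CNCCN(C)C")$site_class, "tertiary_amine")
  # two tertiary amines: peripheral rule takes the eccentricity-5 nitrogen
  chosen <- pick("CN(C)CCN(C)CC")
  all_sites <- classify_nitrogen_sites(parse_lipid("CN(C)CCN(C)CC"))
  expect_equal(chosen$eccentricity, max(all_sites$eccentricity))
  expect_equal(chosen$eccentricity, 5L)  # hand-counted shortest paths
  # centrality rule flips to the lowest mean squared distance
  central <- pick("CN(C)CCN(C)CC", "tail_amine_central")
  expect_equal(central$mean_sq_graph_distance,
               min(all_sites$mean_sq_graph_distance))
  expect_false(chosen$atom_index == central$atom_index)
})

test_that("selection is invariant to SMILES atom-order permutation", {
  variants <- c("CN(C)CCN(C)CC", "CCN(C)CCN(C)C", "N(C)(C)CCN(CC)C")
  picks <- vapply(variants, function(s) {
    mol <- parse_lipid(s)
    sel <- select_protonation_site(classify_nitrogen_sites(mol))
    protonate(mol, sel$selected_index)$protonated_smiles
  }, character(1))
  expect_length(unique(picks), 1L)
})

test_that("protonation adds exactly one positive charge and round-trips", {
  res <- protonate_smiles("CCN(CC)CC")
  expect_equal(res$protonated_smiles, "CC[NH+](CC)CC")
  reparsed <- parse_lipid(res$protonated_smiles)
  expect_equal(sum(reparsed$atoms$charge), 1L)
  # protonating the already-charged nitrogen is an invalid site
  expect_error(protonate(reparsed, which(reparsed$atoms$element == "N")),
               "invalid protonation site")
})

test_that("all-excluded and nitrogen-free molecules select nothing", {
  for (s in c("CNC(C)=O", "CS(=O)(=O)NC", "C[N+](C)(C)C", "CCO")) {
    res <- protonate_smiles(s)
    expect_true(is.na(res$selected_index), info = s)
    expect_true(is.na(res$protonated_smiles), info = s)
  }
})

test_that("exclusion safety holds across the randomized fixture sweep", {
  excluded_patterns <- c("CNC(C)=O", "CS(=O)(=O)NC", "C[N+](C)(C)C",
                         "CC(=O)N(C)C", "O=S(=O)(c1ccccc1)N(C)C")
  set.seed(11)
  for (rep in 1:3) {
    for (s in sample(excluded_patterns)) {
      res <- protonate_smiles(s)
      expect_true(is.na(res$selected_index), info = s)
    }
  }
})

test_that("adding a higher-priority nitrogen wins over a lower one", {
  # pyridine alone selects the ring nitrogen; grafting a secondary amine
  # moves the site off the ring
  base <- protonate_smiles("c1ccncc1")
  expect_equal(classify_nitrogen_sites(
    parse_lipid("c1ccncc1"))$site_class, "pyridine")
  grafted <- parse_lipid("CNCCc1ccncc1")
  sites <- classify_nitrogen_sites(grafted)
  sel <- select_protonation_site(sites)
  expect_equal(sites$site_class[sites$atom_index == sel$selected_index],
               "secondary_amine")
  expect_false(is.na(base$selected_index))
})

test_that("protonation fraction follows Henderson-Hasselbalch", {
  expect_equal(protonation_fraction(6.5, 6.5), 0.5)
  expect_equal(protonation_fraction(7.5, 6.5), 1 / 11, tolerance = 1e-12)
  expect_equal(protonation_fraction(-100, 6.5), 1)
  pH <- seq(3, 10, by = 0.5)
  expect_true(all(diff(protonation_fraction(pH, 6.5)) < 0))
})

test_that("summary statistics compute mass-correct molecular weights", {
  out <- lipid_summary_stats(c("CN(C)C", "CCO", "CN(C)C"))
  per <- out$per_lipid
  expect_equal(per$mw[1], 59.112, tolerance = 1e-3)  # 3C + 9H + N
  expect_equal(per$n_nitrogens, c(1L, 0L, 1L))
  expect_equal(per$amine_class, c("tertiary only", "no amine",
                                  "tertiary only"))
  same <- lipid_summary_stats(rep("CN(C)C", 4))
  expect_equal(same$aggregate$mw_sd, 0)
  mixed <- lipid_summary_stats("CNCCN(C)C")
  expect_equal(mixed$per_lipid$amine_class, "secondary+tertiary")
})
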