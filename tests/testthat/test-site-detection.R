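test_that("candidate search honours class radii and picks one N per His", {
  s <- build_site(site_spec("Cys4"))
  zn <- find_zinc_ions(s)
  cand <- find_candidates(s, zn[1, ])
  expect_equal(nrow(cand), 4)
  expect_true(all(cand$ligand_class == "SG"))
  expect_equal(cand$dist, rep(2.330, 4), tolerance = 1e-6)

  # S-gamma beyond 4.8 A is not a candidate
  s2 <- distort(s, "stretch_one_bond", magnitude = 4.9)
  expect_equal(nrow(find_candidates(s2, find_zinc_ions(s2)[1, ])), 3)

  # His contributes its nearer ring nitrogen only
  sh <- build_site(site_spec("Cys2His2"))
  cand_h <- find_candidates(sh, find_zinc_ions(sh)[1, ])
  expect_equal(nrow(cand_h), 4)
  his <- cand_h[cand_h$resname == "HIS", ]
  expect_true(all(his$atom == "ND1"))
  sh2 <- build_site(site_spec("Cys2His2", nd_vs_ne = "NE2"))
  cand_h2 <- find_candidates(sh2, find_zinc_ions(sh2)[1, ])
  expect_true(all(cand_h2$atom[cand_h2$resname == "HIS"] == "NE2"))
})

test_that("Dixon Q-test matches the gap/range formula on worked examples", {
  # clear outlier: Q = (4.50-2.32)/(4.50-2.29)
  res <- q_test_filter(fake_candidates(c(2.29, 2.30, 2.31, 2.32, 4.50)))
  expect_equal(res$results$q_statistic[1], (4.50 - 2.32) / (4.50 - 2.29),
               tolerance = 1e-12)
  expect_equal(round(res$results$q_statistic[1], 3), 0.986)
  expect_true(res$results$rejected[1])
  expect_equal(nrow(res$kept), 4)

  # four candidates: "five or more" precondition -> identity, no test
  res4 <- q_test_filter(fake_candidates(c(2.30, 2.31, 2.32, 2.33)))
  expect_equal(nrow(res4$results), 0)
  expect_equal(nrow(res4$kept), 4)

  # degenerate gap-equals-range sample: Q = 1 exceeds any critical value
  res5 <- q_test_filter(fake_candidates(c(2.30, 2.30, 2.30, 2.30, 2.31)))
  expect_equal(res5$results$q_statistic[1], 1)
  expect_true(res5$results$q_statistic[1] > res5$results$critical_value[1])
  expect_true(res5$results$rejected[1])
  expect_equal(nrow(res5$kept), 4)

  # zero range: no rejection possible
  res0 <- q_test_filter(fake_candidates(rep(2.1, 6)))
  expect_false(any(res0$results$rejected))
  expect_equal(nrow(res0$kept), 6)
})

test_that("iterative Q-test filter equals the brute-force oracle on seeded multisets", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(5:8, 1)
    d <- sort(round(runif(n, 2.0, 5.0), 3))
    kept <- q_test_filter(fake_candidates(d))$kept$dist
    expect_identical(kept, oracle_q_filter(d))
  }
})

test_that("discard rules (i)/(ii), His4 and His-heavy conditions apply as published", {
  cfg <- detection_config()
  # accepted ZnCys4, no foreign atom
  s <- build_site(site_spec("Cys4"))
  ss <- detect_sites(s)
  expect_length(ss$sites, 1)
  expect_equal(unname(ss$sites[[1]]$composition), c(4L, 0L))

  # (i) + (ii) together discard under the default "and" rule
  s_ii <- distort(s, "stretch_one_bond", magnitude = 3.30)
  expect_length(detect_sites(s_ii)$sites, 1)  # (ii) alone: still accepted
  s_both <- distort(s_ii, "add_decoy_ligand", magnitude = 2.7)
  ss_both <- detect_sites(s_both)
  expect_length(ss_both$sites, 0)
  expect_equal(ss_both$rejected[[1]]$reason, "foreign_ligand_and_long_ligand")
  # under "or", condition (ii) alone already discards
  ss_or <- detect_sites(s_ii, detection_config(discard_combination = "or"))
  expect_length(ss_or$sites, 0)

  # ZnHis4 is discarded on (i) alone (octahedral-site guard)
  h4 <- build_site(site_spec("His4"))
  h4_w <- distort(h4, "add_decoy_ligand", magnitude = 2.6)
  ss_h4 <- detect_sites(h4_w)
  expect_length(ss_h4$sites, 0)
  expect_equal(ss_h4$rejected[[1]]$reason, "his4_foreign_ligand")
  # a Cys-containing site with the same decoy is kept ("and" needs (ii) too)
  c4_w <- distort(s, "add_decoy_ligand", magnitude = 2.6)
  expect_length(detect_sites(c4_w)$sites, 1)

  # >= 3 His requires all ligands within 3.0 A
  h3 <- build_site(site_spec("Cys1His3",
                             distances = c(2.298, 2.002, 2.002, 3.1)))
  ss_h3 <- detect_sites(h3)
  expect_length(ss_h3$sites, 0)
  expect_equal(ss_h3$rejected[[1]]$reason, "his_heavy_distance")
  # the same distance on a Cys-rich site is fine
  c3 <- build_site(site_spec("Cys3His1", distances = c(2.318, 2.318, 3.1, 2.074)))
  expect_length(detect_sites(c3)$sites, 1)
})

test_that("detection recovers each composition from its ideal fixture", {
  for (comp in ALL_COMPOSITIONS) {
    for (pa in list(NULL, "table")) {
      s <- build_site(site_spec(comp, pair_angles = pa))
      ss <- detect_sites(s)
      expect_length(ss$sites, 1)
      expect_equal(composition_key_of(ss$sites[[1]]), comp)
    }
  }
})

test_that("decoy outcomes hold across seeds", {
  for (seed in 1:10) {
    dec <- decoy_suite(seed)
    ss <- detect_sites(dec$octahedral_his6$structure)
    expect_length(ss$sites, 0)

    ss <- detect_sites(dec$cys3_water$structure)
    expect_length(ss$sites, 0)
    expect_equal(ss$rejected[[1]]$reason, "undercoordinated")

    ss <- detect_sites(dec$fifth_sg$structure)
    expect_length(ss$sites, 1)
    tr <- ss$q_traces[[1]]
    expect_equal(sum(tr$rejected), 1)

    ss <- detect_sites(dec$bridged_cluster$structure)
    expect_length(ss$sites, 2)
    expect_length(ss$cluster_groups, 1)
    expect_true(all(vapply(ss$sites, function(x) length(x$bridging_sg) > 0,
                           logical(1))))
  }
})

test_that("detection is invariant under rigid motion and record reordering", {
  s <- build_composition_suite()
  ss <- detect_sites(s)
  set.seed(7)
  for (i in 1:3) {
    rm_ <- random_rigid_motion()
    st <- transform_structure(s, rm_$rotation, rm_$translation)
    sst <- detect_sites(st)
    expect_equal(length(sst$sites), length(ss$sites))
    expect_equal(lapply(sst$sites, function(x) x$composition),
                 lapply(ss$sites, function(x) x$composition))
    expect_equal(lapply(sst$sites, function(x) x$ligands$dist),
                 lapply(ss$sites, function(x) x$ligands$dist),
                 tolerance = 1e-9)
  }
  # shuffle atom records
  set.seed(8)
  s_sh <- s
  s_sh$atoms <- s_sh$atoms[sample(nrow(s_sh$atoms)), ]
  ss_sh <- detect_sites(s_sh)
  expect_equal(length(ss_sh$sites), length(ss$sites))
  expect_equal(lapply(ss_sh$sites, function(x) sort(x$ligands$resseq)),
               lapply(ss$sites, function(x) sort(x$ligands$resseq)))
})

test_that("chain-break adjacency flags missing neighbours and broken peptides", {
  s <- build_site(site_spec("Cys4"))
  ss <- detect_sites(s)
  expect_false(ss$sites[[1]]$chain_break_adjacent)

  # neighbour residue deleted (interior of the chain span)
  s_gap <- s
  s_gap$atoms <- s_gap$atoms[s_gap$atoms$resseq != 11, ]
  expect_true(detect_sites(s_gap)$sites[[1]]$chain_break_adjacent)

  # neighbour present but peptide C--N stretched to ~4 A
  s_far <- s
  i <- which(s_far$atoms$resseq == 11 & s_far$atoms$atom == "N")
  s_far$atoms$x[i] <- s_far$atoms$x[i] + 4
  expect_true(detect_sites(s_far)$sites[[1]]$chain_break_adjacent)
})

test_that("accepted sites satisfy their structural invariants", {
  s <- build_composition_suite()
  ss <- detect_sites(s)
  cfg <- detection_config()
  for (site in ss$sites) {
    expect_equal(sum(site$composition), 4L)
    expect_equal(nrow(site$ligands), 4)
    expect_true(all(site$ligands$dist < cfg$ligand_reject_min))
    if (site$composition[["his"]] >= 3) {
      expect_true(all(site$ligands$dist < cfg$his_heavy_max))
    }
  }
})
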