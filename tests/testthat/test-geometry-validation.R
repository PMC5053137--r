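test_that("built-in res16 targets hold the published values verbatim", {
  tg <- builtin_targets("res16")
  chk <- function(comp, kind, mean, sd, n) {
    row <- target_for(tg, comp, kind)
    expect_false(is.null(row), label = paste(comp, kind))
    expect_equal(row$mean, mean)
    expect_equal(row$sd, sd)
    if (!is.na(n)) expect_equal(row$n, n)
  }
  chk("Cys4", "zn_sg_distance", 2.330, 0.029, 1033L)
  chk("Cys3His1", "zn_sg_distance", 2.318, 0.027, 912L)
  chk("Cys2His2", "zn_sg_distance", 2.306, 0.029, 76L)
  chk("Cys1His3", "zn_sg_distance", 2.298, 0.017, 12L)
  chk("Cys4", "sg_zn_sg_angle", 109.45, 5.46, 1553L)
  chk("Cys3His1", "sg_zn_sg_angle", 112.15, 3.96, 912L)
  chk("Cys2His2", "sg_zn_sg_angle", 116.23, 4.58, 38L)
  chk("Cys3His1", "zn_n_distance", 2.074, 0.056, 303L)
  chk("Cys2His2", "zn_n_distance", 2.040, 0.050, 65L)
  chk("Cys1His3", "zn_n_distance", 2.002, 0.045, 36L)
  chk("Cys2His2", "n_zn_n_angle", 102.38, 5.44, 38L)
  chk("Cys1His3", "n_zn_n_angle", 107.23, 4.78, 36L)
  # entries published as n/a or insufficient data are absent
  expect_null(target_for(tg, "His4", "zn_n_distance"))
  expect_null(target_for(tg, "His4", "n_zn_n_angle"))
  expect_null(target_for(tg, "Cys4", "zn_n_distance"))
  expect_null(target_for(tg, "Cys1His3", "sg_zn_sg_angle"))
  # the 2.5 A table is not distributed
  expect_error(builtin_targets("res25"), "not distributed")
})

test_that("derived targets follow the stated propagation formulas", {
  tg <- builtin_targets()
  # SG-SG: 2 d sin(theta/2)
  ss <- target_for(tg, "Cys4", "sg_sg_distance")
  expect_equal(ss$mean, 2 * 2.330 * sin(109.45 / 2 * pi / 180), tolerance = 1e-12)
  sd_expect <- sqrt((2 * sin(109.45 / 2 * pi / 180) * 0.029)^2 +
                      (2.330 * cos(109.45 / 2 * pi / 180) * 5.46 * pi / 180)^2)
  expect_equal(ss$sd, sd_expect, tolerance = 1e-12)
  # Zn-CB: law of cosines with the 1.81 A bond and 109 deg angle
  cb <- target_for(tg, "Cys4", "zn_cb_distance")
  expect_equal(cb$mean,
               sqrt(2.330^2 + 1.81^2 - 2 * 2.330 * 1.81 * cos(109 * pi / 180)),
               tolerance = 1e-12)
  # centroid deviation target: zero for single-class compositions
  expect_equal(target_for(tg, "Cys4", "zn_centroid_deviation")$mean, 0)
  expect_equal(target_for(tg, "His4", "zn_centroid_deviation")$mean, 0)
  # mixed compositions: the offset implied by the published means
  expect_gt(target_for(tg, "Cys2His2", "zn_centroid_deviation")$mean, 0)
  expect_lt(target_for(tg, "Cys2His2", "zn_centroid_deviation")$mean, 0.05)
})

test_that("zscore matches direct arithmetic", {
  expect_equal(zscore(2.330, 2.330, 0.029), 0)
  expect_equal(zscore(2.359, 2.330, 0.029), 1.0, tolerance = 1e-12)
  expect_equal(zscore(2.272, 2.330, 0.029), -2.0, tolerance = 1e-12)
  expect_error(zscore(1, 1, 0), "positive")
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(1); m <- rnorm(1); s <- runif(1, 0.01, 2)
    expect_equal(zscore(v, m, s), (v - m) / s, tolerance = 1e-12)
  }
})

test_that("measure_site reports exact geometry on ideal fixtures", {
  s <- build_site(site_spec("Cys4"))
  site <- detect_sites(s)$sites[[1]]
  f <- measure_site(site, s)
  expect_equal(unname(f$zn_ligand_distances), rep(2.330, 4), tolerance = 1e-6)
  expect_equal(f$ligand_pair_angles$angle, rep(acos(-1 / 3) * 180 / pi, 6),
               tolerance = 0.01)
  expect_equal(f$zn_centroid_deviation, 0, tolerance = 1e-6)
  expect_equal(f$cys_bridge_multiplicity, 0L)
  expect_equal(nrow(f$sg_sg_distances), 6)
  expect_length(f$zn_cb_distances, 4)
  expect_equal(f$occupancy_summary[["mean"]], 1)

  # two S-gamma atoms pushed within 2.5 A read as one apparent bridge
  s2 <- s
  i <- which(s2$atoms$atom == "SG")[1:2]
  mid <- colMeans(s2$atoms[i, c("x", "y", "z")])
  s2$atoms[i[1], c("x", "y", "z")] <- mid + c(0.9, 0, 0)
  s2$atoms[i[2], c("x", "y", "z")] <- mid - c(0.9, 0, 0)
  site2 <- detect_sites(s2)$sites[[1]]
  f2 <- measure_site(site2, s2)
  expect_equal(f2$cys_bridge_multiplicity, 1L)
})

test_that("His flips are detected when a ring carbon faces the Zn", {
  s <- build_site(site_spec("Cys2His2"))
  site <- detect_sites(s)$sites[[1]]
  expect_false(any(detect_his_flip(site, s)))

  flipped <- distort(s, "flip_his")
  site_f <- detect_sites(flipped)$sites[[1]]
  flags <- detect_his_flip(site_f, flipped)
  expect_equal(sum(flags), 1)
  r <- attr(flipped, "manifest")$residue
  expect_true(flags[[r]])
  rep <- validate_site(site_f, flipped)
  expect_true(rep$flags$his_flip)

  # incomplete ring: FALSE with a warning
  s3 <- s
  s3$atoms <- s3$atoms[!(s3$atoms$atom == "CE1" &
                           s3$atoms$resseq == site$ligands$resseq[
                             site$ligands$resname == "HIS"][1]), ]
  site3 <- detect_sites(s3)$sites[[1]]
  expect_warning(f3 <- detect_his_flip(site3, s3), "incomplete")
  expect_false(any(f3))
})

test_that("r.m.s.Z is near zero at target geometry and grows with distortion", {
  for (comp in ALL_COMPOSITIONS) {
    s <- build_site(site_spec(comp, pair_angles = "table"))
    rep <- validate_site(detect_sites(s)$sites[[1]], s)
    expect_lt(rep$rmsz, 0.05)
    expect_gte(rep$rmsz, 0)
  }
  # one bond stretched to mean + 3 sd scores Z = 3 on that component
  d <- c(2.330 + 3 * 0.029, 2.330, 2.330, 2.330)
  s3 <- build_site(site_spec("Cys4", distances = d))
  rep3 <- validate_site(detect_sites(s3)$sites[[1]], s3)
  zt <- rep3$zscores
  z_sg <- zt$z[zt$kind == "zn_sg_distance"]
  expect_equal(max(z_sg), 3, tolerance = 1e-3)
  base <- validate_site(detect_sites(build_site(site_spec("Cys4")))$sites[[1]],
                        build_site(site_spec("Cys4")))
  expect_gt(rep3$rmsz, base$rmsz)

  # ZnHis4: no published targets; rmsz over the remaining components
  h4 <- build_site(site_spec("His4"))
  rep_h4 <- validate_site(detect_sites(h4)$sites[[1]], h4)
  expect_true("zn_n_distance" %in% rep_h4$flags$insufficient_targets)
  expect_true("n_zn_n_angle" %in% rep_h4$flags$insufficient_targets)
  expect_false(is.na(rep_h4$rmsz))
})

test_that("validation is invariant under rigid motion", {
  s <- build_composition_suite()
  base <- validate_structure(s)
  set.seed(11)
  rm_ <- random_rigid_motion()
  st <- transform_structure(s, rm_$rotation, rm_$translation)
  moved <- validate_structure(st)
  expect_equal(moved$summary$rmsz, base$summary$rmsz, tolerance = 1e-9)
})

test_that("whole-structure validation excludes chain-break sites from aggregates", {
  s <- build_composition_suite()
  vs <- validate_structure(s)
  expect_equal(nrow(vs$summary), 5)
  expect_false(any(vs$summary$chain_break))

  # empty structure: empty report
  empty <- build_site(site_spec("Cys4"))
  empty$atoms <- empty$atoms[empty$atoms$element != "ZN", ]
  empty$links <- empty$links[0, ]
  vs0 <- validate_structure(empty)
  expect_length(vs0$reports, 0)

  # break the chain next to the Cys4 site: flagged and excluded
  s_b <- s
  s_b$atoms <- s_b$atoms[!(s_b$atoms$chain == "A" & s_b$atoms$resseq == 11), ]
  vs_b <- validate_structure(s_b)
  expect_true(vs_b$summary$chain_break[vs_b$summary$composition == "Cys4"])
  kept <- vs_b$summary$rmsz[!vs_b$summary$chain_break]
  expect_equal(vs_b$mean_rmsz, mean(kept))
})

test_that("noise strictly increases every site's rmsz over the ideal fixture", {
  s <- build_composition_suite()
  base <- validate_structure(s)$summary
  noisy <- distort(s, "gaussian_noise", 0.3, seed = 99)
  vn <- validate_structure(noisy)$summary
  shared <- intersect(base$zn, vn$zn)
  expect_gt(length(shared), 0)
  for (id in shared) {
    expect_gt(vn$rmsz[vn$zn == id], base$rmsz[base$zn == id])
  }
})
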