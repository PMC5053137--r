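test_that("site construction is deterministic and round-trips through PDB", {
  for (comp in c("Cys4", "Cys1His3")) {
    t1 <- withr::local_tempfile(fileext = ".pdb")
    t2 <- withr::local_tempfile(fileext = ".pdb")
    write_structure(build_site(site_spec(comp, seed = 5)), t1)
    write_structure(build_site(site_spec(comp, seed = 5)), t2)
    expect_identical(readLines(t1), readLines(t2))
    s <- read_structure(t1)
    expect_length(detect_sites(s)$sites, 1)
  }
})

test_that("built geometry hits the requested distances and angles", {
  s <- build_site(site_spec("Cys4", distances = rep(2.330, 4)))
  site <- detect_sites(s)$sites[[1]]
  expect_equal(site$ligands$dist, rep(2.330, 4), tolerance = 1e-6)
  f <- measure_site(site, s)
  expect_equal(f$ligand_pair_angles$angle, rep(acos(-1 / 3) * 180 / pi, 6),
               tolerance = 1e-6)
  # "table" construction reproduces the composition-specific angle means
  s2 <- build_site(site_spec("Cys2His2", pair_angles = "table"))
  f2 <- measure_site(detect_sites(s2)$sites[[1]], s2)
  pa <- f2$ligand_pair_angles
  sg_sg <- pa$angle[pa$class_i == "SG" & pa$class_j == "SG"]
  nn <- pa$angle[pa$class_i != "SG" & pa$class_j != "SG"]
  expect_equal(sg_sg, 116.23, tolerance = 1e-6)
  expect_equal(nn, 102.38, tolerance = 1e-6)
  expect_error(build_site(site_spec("Cys4", distances = c(-1, 2, 2, 2))))
})

test_that("gaussian noise with sigma zero is the identity", {
  s <- build_site(site_spec("Cys3His1"))
  s0 <- distort(s, "gaussian_noise", 0, seed = 4)
  expect_identical(s0$atoms[, c("x", "y", "z")], s$atoms[, c("x", "y", "z")])
})

test_that("distortion modes change what their manifests claim", {
  s <- build_site(site_spec("Cys2His2"))

  d1 <- distort(s, "stretch_one_bond", 3.30)
  zn <- find_zinc_ions(d1)[1, ]
  i <- which(d1$atoms$atom == "SG")[1]
  expect_equal(coord_distance(c(zn$x, zn$y, zn$z),
                              unlist(d1$atoms[i, c("x", "y", "z")])),
               3.30, tolerance = 1e-9)

  d2 <- distort(s, "rotate_cys_away", 1.5)
  expect_equal(attr(d2, "manifest")$displacement, 1.5, tolerance = 1e-9)
  # SG-CB bond length preserved by the rotation
  sg <- unlist(d2$atoms[d2$atoms$atom == "SG", c("x", "y", "z")][1, ])
  cb <- unlist(d2$atoms[d2$atoms$atom == "CB" &
                          d2$atoms$resname == "CYS", c("x", "y", "z")][1, ])
  expect_equal(coord_distance(sg, cb), 1.81, tolerance = 1e-9)

  d3 <- distort(s, "displace_zn", 1.0, seed = 2)
  zn0 <- find_zinc_ions(s)[1, ]
  zn3 <- find_zinc_ions(d3)[1, ]
  expect_equal(coord_distance(c(zn0$x, zn0$y, zn0$z),
                              c(zn3$x, zn3$y, zn3$z)), 1.0, tolerance = 1e-9)
  # seeded: same seed, same displacement
  d3b <- distort(s, "displace_zn", 1.0, seed = 2)
  expect_identical(d3$atoms, d3b$atoms)

  d4 <- distort(s, "add_decoy_ligand", 2.2)
  expect_equal(sum(d4$atoms$resname == "HOH"), 1)

  d5 <- distort(s, "drop_links")
  expect_equal(nrow(d5$links), 0)

  expect_error(distort(s, "no_such_mode"))
})

test_that("the disulfide-annotation distortion is undone by cleaning", {
  s <- build_site(site_spec("Cys4"))
  bad <- distort(s, "swap_to_disulfide_annotation")
  expect_equal(nrow(bad$ssbonds), 1)
  plan <- plan_changes(bad, detect_sites(bad))
  expect_equal(nrow(plan$ssbond_removals), 1)
  cleaned <- apply_changes(bad, plan)
  expect_equal(nrow(cleaned$ssbonds), 0)
})

test_that("every decoy parses, round-trips and keeps its stated outcome", {
  for (seed in c(1, 7)) {
    for (nm in names(decoy_suite(seed))) {
      entry <- decoy_suite(seed)[[nm]]
      tf <- withr::local_tempfile(fileext = ".pdb")
      write_structure(entry$structure, tf)
      s <- read_structure(tf)
      expect_equal(nrow(s$atoms), nrow(entry$structure$atoms), label = nm)
      ss <- detect_sites(s)
      n_expect <- switch(entry$expected,
                         no_site = 0L, rejected = 0L,
                         accepted_with_q_rejection = 1L,
                         two_sites_one_cluster = 2L)
      expect_length(ss$sites, n_expect)
    }
  }
})
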