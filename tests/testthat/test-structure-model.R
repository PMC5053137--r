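test_that("single-record PDB parsing recovers atoms and annotation", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 ZN    ZN A 101       0.000   0.000   0.000  1.00 20.00          ZN",
    "END"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$element, "ZN")
  expect_equal(s$atoms$resseq, 101L)

  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "SSBOND   1 CYS A   10    CYS A   20                          1555   1555  2.04",
    "LINK        ZN    ZN A 101                 SG  CYS A  10     1555   1555  2.33",
    "ATOM      1  SG  CYS A  10       1.000   2.000   3.000  1.00 10.00           S",
    "END"), tf2)
  s2 <- read_structure(tf2)
  expect_equal(nrow(s2$ssbonds), 1)
  expect_equal(s2$ssbonds$seq2, 20L)
  expect_equal(nrow(s2$links), 1)
  expect_equal(s2$links$name1, "ZN")
  expect_equal(s2$links$name2, "SG")
  expect_equal(s2$links$dist, 2.33)
})

test_that("write/read round-trip preserves atoms and records", {
  s <- distort(build_site(site_spec("Cys2His2")), "swap_to_disulfide_annotation")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- read_structure(tf)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$x, round(s$atoms$x, 3))
  expect_equal(s2$atoms$atom, s$atoms$atom)
  expect_equal(nrow(s2$links), nrow(s$links))
  expect_equal(nrow(s2$ssbonds), nrow(s$ssbonds))
  # second round-trip is exact
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, tf2)
  expect_identical(readLines(tf), readLines(tf2))
  # coordinate rounding rule
  s3 <- s
  s3$atoms$x[1] <- 1.23456
  tf3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s3, tf3)
  expect_equal(read_structure(tf3)$atoms$x[1], 1.235)
})

test_that("structures without LINK records render no LINK lines", {
  s <- build_site(site_spec("Cys4"), annotate = FALSE)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  expect_false(any(grepl("^LINK", readLines(tf))))
  s4 <- build_site(site_spec("Cys4"))
  write_structure(s4, tf)
  expect_equal(sum(grepl("^LINK", readLines(tf))), 4)
})

test_that("distance and angle primitives match analytic values and are rigid-motion invariant", {
  expect_equal(coord_distance(c(0, 0, 0), c(0, 0, 2.34)), 2.34)
  expect_equal(coord_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(coord_angle(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)), 180)
  expect_equal(coord_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # tetrahedral vertex angle: arccos(-1/3)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1)) / sqrt(3)
  expect_equal(coord_angle(tet[1, ], c(0, 0, 0), tet[2, ]),
               acos(-1 / 3) * 180 / pi, tolerance = 1e-4)
  expect_error(coord_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")

  set.seed(42)
  a <- c(0.3, -1.2, 2.5); b <- c(-2, 0.1, 4); v <- c(1, 1, 0)
  for (i in 1:100) {
    rm_ <- random_rigid_motion()
    tr <- function(p) as.vector(rm_$rotation %*% p) + rm_$translation
    expect_equal(coord_distance(tr(a), tr(b)), coord_distance(a, b),
                 tolerance = 1e-9)
    expect_equal(coord_angle(tr(a), tr(v), tr(b)), coord_angle(a, v, b),
                 tolerance = 1e-9)
  }
  # symmetry of the primitives
  expect_equal(coord_distance(a, b), coord_distance(b, a))
  expect_equal(coord_angle(a, v, b), coord_angle(b, v, a))
})

test_that("symmetry expansion handles P1 translations and degrades gracefully", {
  s <- build_site(site_spec("Cys4"))
  # no CRYST1: identical to a plain radius query
  plain <- symmetry_expand(s, c(0, 0, 0), 3)
  expect_true(all(plain$symop == "1_555"))
  expect_equal(sort(plain$atom), sort(c("SG", "SG", "SG", "SG", "ZN")))

  s$cryst <- list(a = 25, b = 25, c = 25, alpha = 90, beta = 90, gamma = 90,
                  sgroup = "P 1")
  # one lattice translation along +a brings the site to x = 25
  hit <- symmetry_expand(s, c(25, 0, 0), 3)
  expect_true(all(hit$symop == "1_655"))
  expect_equal(sum(hit$atom == "ZN"), 1)
  # determinism
  expect_identical(hit, symmetry_expand(s, c(25, 0, 0), 3))
  # unknown space group: warning + identity only
  s$cryst$sgroup <- "P 21 21 21"
  expect_warning(far <- symmetry_expand(s, c(25, 0, 0), 3), "not supported")
  expect_equal(nrow(far), 0)
})

test_that("mmCIF atom_site loops are read", {
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a 25.0", "_cell.length_b 25.0", "_cell.length_c 25.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0", "_cell.angle_gamma 90.0",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 S SG CYS A 10 1.000 2.000 3.000 1.00 10.00",
    "HETATM 2 ZN ZN ZN A 101 0.000 0.000 0.000 1.00 20.00"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$element, c("S", "ZN"))
  expect_equal(s$cryst$a, 25)
  expect_equal(s$cryst$sgroup, "P 1")
})

test_that("highest-occupancy alternate conformers are kept for geometry", {
  s <- build_site(site_spec("Cys4"))
  # duplicate the Zn with a low-occupancy alternate elsewhere
  zn_row <- s$atoms[s$atoms$element == "ZN", ]
  zn_row$alt <- "B"; zn_row$occ <- 0.3; zn_row$x <- zn_row$x + 5
  s$atoms[s$atoms$element == "ZN", "alt"] <- "A"
  s$atoms[s$atoms$element == "ZN", "occ"] <- 0.7
  s$atoms <- rbind(s$atoms, zn_row)
  zns <- find_zinc_ions(s)
  expect_equal(nrow(zns), 1)
  expect_equal(zns$occ, 0.7)
})
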