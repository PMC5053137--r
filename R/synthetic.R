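# Synthetic coordinate fixtures: ideal and distorted ZnCys(x)His(y)
# sites, octahedral decoys, bridged clusters and corrupted annotation.
# Everything detection, cleaning, restraint generation and validation
# need is generated here in code; no external data.

TETRA_DIRS <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

# Imidazole modelled as a regular pentagon with side 1.35 A.
IMID_SIDE <- 1.35
IMID_R <- IMID_SIDE / (2 * sin(pi / 5))

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of one synthetic Zn site
#'
#' @param composition `"Cys4"`, `"Cys3His1"`, `"Cys2His2"`, `"Cys1His3"`
#'   or `"His4"`; alternatively an integer vector `c(x, y)`.
#' @param distances Optional 4 Zn--ligand distances (A).  Defaults to
#'   the composition's published mean Zn--SG / Zn--N values; His4 (no
#'   published validation target) falls back to the 2.057/2.058 A
#'   refinement targets.
#' @param nd_vs_ne Per-His coordinating nitrogen, recycled:
#'   `"ND1"` (default) or `"NE2"`.
#' @param pair_angles `NULL` (default): ligands on exact tetrahedral
#'   vertices, pair angle arccos(-1/3).  `"table"`: the Cys and His
#'   ligand groups are placed on opposing symmetric cones so that the
#'   within-class pair angles equal the composition's published
#'   SG--Zn--SG / N--Zn--N means (the construction underlying the
#'   derived Zn-centroid target).  Alternatively a named numeric vector
#'   `c(sg = ..., nn = ...)` of within-class pair angles in degrees.
#' @param seed Integer seed recorded in the spec (construction itself
#'   is deterministic).
#' @return List of class `zn_site_spec`.
#' @export
site_spec <- function(composition, distances = NULL, nd_vs_ne = "ND1",
                      pair_angles = NULL, seed = 1L) {
  if (is.numeric(composition)) {
    stopifnot(length(composition) == 2, sum(composition) == 4)
    composition <- composition_key(composition[1], composition[2])
  }
  stopifnot(composition %in% COMPOSITIONS)
  x <- if (grepl("Cys", composition)) {
    as.integer(sub(".*Cys([0-9]).*", "\\1", composition))
  } else 0L
  y <- 4L - x
  if (is.null(distances)) {
    tab <- RES16_TARGETS
    d_sg <- tab$mean[tab$composition == composition & tab$kind == "zn_sg_distance"]
    d_n <- tab$mean[tab$composition == composition & tab$kind == "zn_n_distance"]
    nd_choice <- rep_len(nd_vs_ne, y)
    if (!length(d_n)) d_n <- ifelse(nd_choice == "ND1", 2.057, 2.058)
    distances <- c(rep(d_sg, length.out = x), rep(d_n, length.out = y))
  }
  stopifnot(length(distances) == 4, all(distances > 0))
  structure(list(composition = composition, x = x, y = y,
                 distances = distances,
                 nd_vs_ne = rep_len(nd_vs_ne, y),
                 pair_angles = pair_angles, seed = as.integer(seed)),
            class = "zn_site_spec")
}

# Unit cone of n directions around `axis` with the given pairwise angle
# (degrees); azimuth offset rotates the cone about its axis.
cone_directions <- function(n, theta, axis, azimuth0 = 0) {
  axis <- unit_vec(axis)
  if (n == 1) return(matrix(axis, nrow = 1))
  if (n == 4 || is.na(theta)) {
    # tetrahedral group aligned so its first vertex is along axis
    v1 <- TETRA_DIRS[1, ]
    ax <- cross3(v1, axis)
    nax <- sqrt(sum(ax^2))
    rot <- if (nax < 1e-10) diag(3) else {
      rotation_matrix(ax, acos(min(1, max(-1, sum(v1 * axis)))))
    }
    return(TETRA_DIRS %*% t(rot))
  }
  th <- theta * pi / 180
  alpha <- if (n == 2) th / 2 else acos(sqrt((2 * cos(th) + 1) / 3))
  e1 <- perp_vec(axis)
  e2 <- cross3(axis, e1)
  t(vapply(seq_len(n), function(k) {
    phi <- azimuth0 + (k - 1) * 2 * pi / n
    cos(alpha) * axis + sin(alpha) * (cos(phi) * e1 + sin(phi) * e2)
  }, numeric(3)))
}

# Ligand direction matrix (4 rows) for a spec: tetrahedral by default,
# opposing-cone construction at the published pair-angle means (or
# user-supplied angles) otherwise.
ligand_directions <- function(spec) {
  if (is.null(spec$pair_angles)) return(TETRA_DIRS)
  x <- spec$x; y <- spec$y
  if (x == 0L || y == 0L) return(TETRA_DIRS)
  comp <- spec$composition
  if (identical(spec$pair_angles, "table")) {
    tab <- RES16_TARGETS
    th_s <- tab$mean[tab$composition == comp & tab$kind == "sg_zn_sg_angle"]
    th_n <- tab$mean[tab$composition == comp & tab$kind == "n_zn_n_angle"]
    if (!length(th_s)) th_s <- NA_real_
    if (!length(th_n)) th_n <- NA_real_
  } else {
    th_s <- unname(spec$pair_angles["sg"])
    th_n <- unname(spec$pair_angles["nn"])
  }
  if (x >= 2 && is.na(th_s)) th_s <- 2 * asin(sqrt(2 / 3)) * 180 / pi
  if (y >= 2 && is.na(th_n)) th_n <- 2 * asin(sqrt(2 / 3)) * 180 / pi
  up <- c(0, 0, 1)
  # offset the His cone's azimuth so ligands interleave
  rbind(cone_directions(x, th_s, up),
        cone_directions(y, th_n, -up, azimuth0 = pi / y))
}

atom_row <- function(record, serial, atom, resname, chain, resseq, pos,
                     element, occ = 1, b = 20) {
  data.frame(record = record, serial = as.integer(serial), atom = atom,
             alt = "", resname = resname, chain = chain,
             resseq = as.integer(resseq), icode = "",
             x = pos[1], y = pos[2], z = pos[3], occ = occ, b = b,
             element = element, charge = "", symop = SYMOP_IDENTITY,
             stringsAsFactors = FALSE)
}

# Pick, between pos0 +/- len*dir variants, the candidate farther from `away`.
place_away <- function(base, len, v_par, v_perp, angle_deg, away) {
  th <- angle_deg * pi / 180
  w1 <- cos(th) * v_par + sin(th) * v_perp
  w2 <- cos(th) * v_par - sin(th) * v_perp
  p1 <- base + len * w1
  p2 <- base + len * w2
  if (sum((p1 - away)^2) >= sum((p2 - away)^2)) p1 else p2
}

# Gram-Schmidt: unit component of v orthogonal to u.
ortho_unit <- function(v, u) {
  w <- v - sum(v * u) * u
  n <- sqrt(sum(w^2))
  if (n < 1e-8) w <- perp_vec(u) else w <- w / n
  w
}

# Backbone (N, CA, C, O) grown from an anchor CB towards `away`-free
# space; returns named list of positions.
grow_backbone <- function(cb, toward_cb, zn) {
  # CA at ~109.5 deg from the CB->side-chain direction
  v <- unit_vec(toward_cb)              # CB -> side-chain anchor
  e1 <- perp_vec(v)
  ca <- place_away(cb, 1.53, v, e1, 111, zn)
  vca <- unit_vec(cb - ca)
  f1 <- ortho_unit(perp_vec(vca), vca)
  f2 <- cross3(vca, f1)
  n <- place_away(ca, 1.46, vca, f1, 109.5, zn)
  # C on the other side of the CA tetrahedron
  g <- ortho_unit(unit_vec(n - ca), vca)
  c_ <- place_away(ca, 1.53, vca, -g, 109.5, zn)
  o <- c_ + 1.23 * ortho_unit(f2, unit_vec(c_ - ca))
  list(N = n, CA = ca, C = c_, O = o)
}

build_cys_residue <- function(zn, u, d, chain, resseq, serial0) {
  p <- perp_vec(u)
  sg <- zn + d * u
  # Zn-SG-CB angle 109 deg
  cb <- place_away(sg, SG_CB_BOND, -u, p, ZN_SG_CB_ANGLE, zn)
  bb <- grow_backbone(cb, unit_vec(sg - cb), zn)
  rows <- rbind(
    atom_row("ATOM", serial0 + 0, "N", "CYS", chain, resseq, bb$N, "N"),
    atom_row("ATOM", serial0 + 1, "CA", "CYS", chain, resseq, bb$CA, "C"),
    atom_row("ATOM", serial0 + 2, "C", "CYS", chain, resseq, bb$C, "C"),
    atom_row("ATOM", serial0 + 3, "O", "CYS", chain, resseq, bb$O, "O"),
    atom_row("ATOM", serial0 + 4, "CB", "CYS", chain, resseq, cb, "C"),
    atom_row("ATOM", serial0 + 5, "SG", "CYS", chain, resseq, sg, "S"))
  list(rows = rows, ligand_atom = "SG", n = bb$N, c = bb$C, ca = bb$CA)
}

build_his_residue <- function(zn, u, d, coord_n, chain, resseq, serial0) {
  p <- perp_vec(u)
  ctr <- zn + (d + IMID_R) * u
  e1 <- -u
  e2 <- p
  vert <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    ctr + IMID_R * (cos(phi) * e1 + sin(phi) * e2)
  }
  if (coord_n == "ND1") {
    ring <- list(ND1 = vert(0), CE1 = vert(72), NE2 = vert(144),
                 CD2 = vert(216), CG = vert(288))
  } else {
    ring <- list(NE2 = vert(0), CE1 = vert(72), ND1 = vert(144),
                 CG = vert(216), CD2 = vert(288))
  }
  cb <- ring$CG + 1.50 * unit_vec(ring$CG - ctr)
  bb <- grow_backbone(cb, unit_vec(ring$CG - cb), zn)
  rows <- rbind(
    atom_row("ATOM", serial0 + 0, "N", "HIS", chain, resseq, bb$N, "N"),
    atom_row("ATOM", serial0 + 1, "CA", "HIS", chain, resseq, bb$CA, "C"),
    atom_row("ATOM", serial0 + 2, "C", "HIS", chain, resseq, bb$C, "C"),
    atom_row("ATOM", serial0 + 3, "O", "HIS", chain, resseq, bb$O, "O"),
    atom_row("ATOM", serial0 + 4, "CB", "HIS", chain, resseq, cb, "C"),
    atom_row("ATOM", serial0 + 5, "CG", "HIS", chain, resseq, ring$CG, "C"),
    atom_row("ATOM", serial0 + 6, "ND1", "HIS", chain, resseq, ring$ND1, "N"),
    atom_row("ATOM", serial0 + 7, "CD2", "HIS", chain, resseq, ring$CD2, "C"),
    atom_row("ATOM", serial0 + 8, "CE1", "HIS", chain, resseq, ring$CE1, "C"),
    atom_row("ATOM", serial0 + 9, "NE2", "HIS", chain, resseq, ring$NE2, "N"))
  list(rows = rows, ligand_atom = coord_n, n = bb$N, c = bb$C, ca = bb$CA)
}

# Glycine stub residues flanking a ligand residue so that chain-break
# flags are false by construction.
build_stubs <- function(res, chain, resseq, serial0) {
  t_next <- unit_vec(res$c - res$ca)
  t_prev <- unit_vec(res$n - res$ca)
  mk <- function(rs, n, ca, c_, o, s0) {
    rbind(atom_row("ATOM", s0 + 0, "N", "GLY", chain, rs, n, "N"),
          atom_row("ATOM", s0 + 1, "CA", "GLY", chain, rs, ca, "C"),
          atom_row("ATOM", s0 + 2, "C", "GLY", chain, rs, c_, "C"),
          atom_row("ATOM", s0 + 3, "O", "GLY", chain, rs, o, "O"))
  }
  # residue r+1 grows from the ligand C
  n1 <- res$c + 1.33 * t_next
  ca1 <- n1 + 1.46 * t_next
  c1 <- ca1 + 1.53 * t_next
  o1 <- c1 + 1.23 * perp_vec(t_next)
  # residue r-1 ends at the ligand N
  c0 <- res$n + 1.33 * t_prev
  ca0 <- c0 + 1.53 * t_prev
  n0 <- ca0 + 1.46 * t_prev
  o0 <- c0 + 1.23 * perp_vec(t_prev)
  rbind(mk(resseq - 1L, n0, ca0, c0, o0, serial0),
        mk(resseq + 1L, n1, ca1, c1, o1, serial0 + 4L))
}

#' Build an ideal synthetic Zn site
#'
#' Places the Zn ion at `origin` and the four ligand atoms on exact
#' tetrahedral vertices at the specified distances (pair angle
#' arccos(-1/3) ~ 109.47 deg), completes each Cys with CB/backbone
#' (SG--CB 1.81 A, Zn--SG--CB 109 deg) and each His with a planar
#' imidazole whose chosen ring nitrogen coordinates the Zn, adds
#' flanking backbone stub residues so chain-break flags stay false, and
#' (by default) writes the four canonical Zn--ligand LINK records.
#' Construction is deterministic.
#'
#' @param spec A [site_spec()].
#' @param chain Chain identifier.
#' @param ligand_resseq Residue numbers of the four ligand residues.
#' @param zn_resseq Residue number of the Zn ion.
#' @param origin Zn position (A).
#' @param annotate Write the canonical LINK records.
#' @param neighbors Include the flanking stub residues.
#' @return A `zn_structure`.
#' @export
build_site <- function(spec, chain = "A", ligand_resseq = c(10L, 20L, 30L, 40L),
                       zn_resseq = 101L, origin = c(0, 0, 0),
                       annotate = TRUE, neighbors = TRUE) {
  stopifnot(inherits(spec, "zn_site_spec"), length(ligand_resseq) == 4)
  if (any(spec$distances <= 0)) stop("ligand distances must be positive")
  rows <- list()
  links <- list()
  serial <- 1L
  his_i <- 0L
  dirs <- ligand_directions(spec)
  for (k in 1:4) {
    u <- dirs[k, ]
    is_cys <- k <= spec$x
    res <- if (is_cys) {
      build_cys_residue(origin, u, spec$distances[k], chain,
                        ligand_resseq[k], serial)
    } else {
      his_i <- his_i + 1L
      build_his_residue(origin, u, spec$distances[k], spec$nd_vs_ne[his_i],
                        chain, ligand_resseq[k], serial)
    }
    serial <- serial + nrow(res$rows)
    rows[[length(rows) + 1L]] <- res$rows
    if (neighbors) {
      st <- build_stubs(res, chain, ligand_resseq[k], serial)
      serial <- serial + nrow(st)
      rows[[length(rows) + 1L]] <- st
    }
    links[[length(links) + 1L]] <- data.frame(
      name1 = "ZN", alt1 = "", resname1 = "ZN", chain1 = chain,
      seq1 = as.integer(zn_resseq), icode1 = "",
      name2 = res$ligand_atom, alt2 = "",
      resname2 = if (is_cys) "CYS" else "HIS", chain2 = chain,
      seq2 = as.integer(ligand_resseq[k]), icode2 = "",
      sym1 = SYMOP_IDENTITY, sym2 = SYMOP_IDENTITY,
      dist = round(spec$distances[k], 2), resolved = TRUE,
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- atom_row("HETATM", serial, "ZN", "ZN", chain,
                                        zn_resseq, origin, "ZN")
  atoms <- do.call(rbind, rows)
  ord <- order(atoms$resseq, atoms$serial)
  atoms <- atoms[ord, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  lnk <- if (annotate) do.call(rbind, links) else empty_links()
  resolve_records(new_structure(atoms, links = lnk))
}

#' Merge several structures into one
#'
#' Atoms, LINK and SSBOND records are concatenated; serial numbers are
#' reassigned.  Chains are expected to be distinct.
#'
#' @param ... `zn_structure` objects.
#' @param cryst Optional unit cell for the merged structure.
#' @return A `zn_structure`.
#' @export
merge_structures <- function(..., cryst = NULL) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(s) s$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  links <- do.call(rbind, lapply(parts, function(s) s$links))
  ssbonds <- do.call(rbind, lapply(parts, function(s) s$ssbonds))
  resolve_records(new_structure(atoms, links, ssbonds, cryst = cryst))
}

#' Fixture with one ideal site of each composition
#'
#' Five well-separated sites (chains A..E, 40 A apart), each built at
#' the composition's target geometry (`pair_angles = "table"`: the
#' published within-class angle means, so validation scores each site
#' near zero).
#'
#' @param seed Seed recorded in the specs.
#' @param pair_angles Passed to [site_spec()].
#' @return A `zn_structure` with five Zn sites.
#' @export
build_composition_suite <- function(seed = 1L, pair_angles = "table") {
  parts <- lapply(seq_along(COMPOSITIONS), function(i) {
    build_site(site_spec(COMPOSITIONS[i], pair_angles = pair_angles,
                         seed = seed),
               chain = LETTERS[i],
               origin = c((i - 1) * 40, 0, 0))
  })
  do.call(merge_structures, parts)
}

#' Distort a synthetic structure
#'
#' Applies one of the error modes observed in deposited structures:
#' \describe{
#'   \item{gaussian_noise}{adds N(0, magnitude) noise to every
#'     coordinate (magnitude in A; 0 is the identity).}
#'   \item{stretch_one_bond}{moves the first ligand Cys S-gamma radially
#'     to `magnitude` A from its Zn.}
#'   \item{rotate_cys_away}{rotates the first ligand Cys S-gamma about
#'     its CB so it is displaced by `magnitude` A (default 2.7).}
#'   \item{displace_zn}{moves the first Zn by `magnitude` A in a seeded
#'     random direction.}
#'   \item{add_decoy_ligand}{adds a water oxygen `magnitude` A (default
#'     2.2) from the first Zn.}
#'   \item{swap_to_disulfide_annotation}{adds a spurious SSBOND between
#'     the first two Cys residues.}
#'   \item{drop_links}{removes all LINK records.}
#'   \item{flip_his}{rotates the first His imidazole 180 degrees
#'     (swaps ND1/CD2 and CE1/NE2 coordinates).}
#' }
#'
#' @param structure A `zn_structure` containing at least one site.
#' @param mode Distortion mode (see above).
#' @param magnitude Mode-specific magnitude (>= 0).
#' @param seed Seed for the stochastic modes.
#' @return The distorted `zn_structure`; a manifest of what changed is
#'   attached as attribute `"manifest"`.
#' @export
distort <- function(structure,
                    mode = c("gaussian_noise", "stretch_one_bond",
                             "rotate_cys_away", "displace_zn",
                             "add_decoy_ligand", "swap_to_disulfide_annotation",
                             "drop_links", "flip_his"),
                    magnitude = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "zn_structure"))
  a <- structure$atoms
  manifest <- list(mode = mode, seed = seed)
  first_zn <- which(a$element == "ZN")[1]
  if (mode == "gaussian_noise") {
    if (is.null(magnitude)) magnitude <- 0.3
    stopifnot(magnitude >= 0)
    if (magnitude > 0) {
      noise <- with_seed(seed, matrix(stats::rnorm(3 * nrow(a), 0, magnitude),
                                      ncol = 3))
      a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
    }
    manifest$sigma <- magnitude
  } else if (mode == "stretch_one_bond") {
    if (is.null(magnitude)) magnitude <- 3.30
    i <- which(a$resname == "CYS" & a$atom == "SG")[1]
    if (is.na(i) || is.na(first_zn)) stop("structure has no Cys SG / Zn")
    zn <- c(a$x[first_zn], a$y[first_zn], a$z[first_zn])
    sg <- c(a$x[i], a$y[i], a$z[i])
    newp <- zn + magnitude * unit_vec(sg - zn)
    a$x[i] <- newp[1]; a$y[i] <- newp[2]; a$z[i] <- newp[3]
    manifest$atom <- sprintf("%s/CYS%d/SG", a$chain[i], a$resseq[i])
    manifest$new_distance <- magnitude
  } else if (mode == "rotate_cys_away") {
    if (is.null(magnitude)) magnitude <- 2.7
    i <- which(a$resname == "CYS" & a$atom == "SG")[1]
    j <- which(a$resname == "CYS" & a$atom == "CB" &
                 a$resseq == a$resseq[i] & a$chain == a$chain[i])[1]
    sg <- c(a$x[i], a$y[i], a$z[i])
    cb <- c(a$x[j], a$y[j], a$z[j])
    arm <- sg - cb
    theta <- 2 * asin(min(1, magnitude / (2 * sqrt(sum(arm^2)))))
    axis <- perp_vec(arm)
    newp <- cb + as.vector(rotation_matrix(axis, theta) %*% arm)
    a$x[i] <- newp[1]; a$y[i] <- newp[2]; a$z[i] <- newp[3]
    manifest$atom <- sprintf("%s/CYS%d/SG", a$chain[i], a$resseq[i])
    manifest$displacement <- coord_distance(sg, newp)
  } else if (mode == "displace_zn") {
    if (is.null(magnitude)) magnitude <- 1.0
    dir <- with_seed(seed, unit_vec(stats::rnorm(3)))
    a$x[first_zn] <- a$x[first_zn] + magnitude * dir[1]
    a$y[first_zn] <- a$y[first_zn] + magnitude * dir[2]
    a$z[first_zn] <- a$z[first_zn] + magnitude * dir[3]
    manifest$displacement <- magnitude
  } else if (mode == "add_decoy_ligand") {
    if (is.null(magnitude)) magnitude <- 2.2
    zn <- c(a$x[first_zn], a$y[first_zn], a$z[first_zn])
    pos <- zn - magnitude * TETRA_DIRS[1, ]
    a <- rbind(a, atom_row("HETATM", max(a$serial) + 1L, "O", "HOH",
                           a$chain[first_zn], 900L, pos, "O"))
    manifest$added <- "HOH O"
    manifest$distance <- magnitude
  } else if (mode == "swap_to_disulfide_annotation") {
    cys <- unique(a[a$resname == "CYS" & a$atom == "SG",
                    c("chain", "resseq", "icode")])
    if (nrow(cys) < 2) stop("need two Cys residues for an SSBOND")
    sb <- data.frame(chain1 = cys$chain[1], seq1 = cys$resseq[1],
                     icode1 = cys$icode[1], chain2 = cys$chain[2],
                     seq2 = cys$resseq[2], icode2 = cys$icode[2],
                     sym1 = SYMOP_IDENTITY, sym2 = SYMOP_IDENTITY,
                     dist = NA_real_, resolved = TRUE,
                     stringsAsFactors = FALSE)
    structure$ssbonds <- rbind(structure$ssbonds, sb)
    manifest$ssbond <- sprintf("%s%d-%s%d", cys$chain[1], cys$resseq[1],
                               cys$chain[2], cys$resseq[2])
  } else if (mode == "drop_links") {
    manifest$removed_links <- nrow(structure$links)
    structure$links <- empty_links()
  } else if (mode == "flip_his") {
    his <- a[a$resname == "HIS", , drop = FALSE]
    if (!nrow(his)) stop("structure has no His residue")
    r <- his$resseq[1]; ch <- his$chain[1]
    swap <- function(n1, n2) {
      i <- which(a$resname == "HIS" & a$resseq == r & a$chain == ch & a$atom == n1)
      j <- which(a$resname == "HIS" & a$resseq == r & a$chain == ch & a$atom == n2)
      tmp <- a[i, c("x", "y", "z")]
      a[i, c("x", "y", "z")] <<- a[j, c("x", "y", "z")]
      a[j, c("x", "y", "z")] <<- tmp
    }
    swap("ND1", "CD2")
    swap("CE1", "NE2")
    manifest$residue <- sprintf("%s/HIS%d", ch, r)
  }
  structure$atoms <- a
  out <- resolve_records(structure)
  attr(out, "manifest") <- manifest
  out
}

# Octahedral ZnHis6 decoy: six His nitrogens at 2.1 A along +/- axes.
build_his6_octahedron <- function() {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  rows <- list()
  serial <- 1L
  for (k in 1:6) {
    res <- build_his_residue(c(0, 0, 0), dirs[k, ], 2.10, "ND1", "A",
                             10L * k, serial)
    serial <- serial + nrow(res$rows)
    rows[[length(rows) + 1L]] <- res$rows
  }
  rows[[length(rows) + 1L]] <- atom_row("HETATM", serial, "ZN", "ZN", "A",
                                        101L, c(0, 0, 0), "ZN")
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  resolve_records(new_structure(atoms))
}

# Three Cys ligands plus a water oxygen close to the Zn.
build_cys3_water <- function() {
  rows <- list()
  serial <- 1L
  for (k in 1:3) {
    res <- build_cys_residue(c(0, 0, 0), TETRA_DIRS[k, ], 2.330, "A",
                             10L * k, serial)
    serial <- serial + nrow(res$rows)
    rows[[length(rows) + 1L]] <- res$rows
  }
  rows[[length(rows) + 1L]] <- atom_row("HETATM", serial, "O", "HOH", "A",
                                        900L, 2.2 * TETRA_DIRS[4, ], "O")
  rows[[length(rows) + 1L]] <- atom_row("HETATM", serial + 1L, "ZN", "ZN", "A",
                                        101L, c(0, 0, 0), "ZN")
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  resolve_records(new_structure(atoms))
}

# Ideal ZnCys4 plus a fifth Cys S-gamma at 4.5 A.
build_fifth_sg <- function() {
  base <- build_site(site_spec("Cys4"), annotate = FALSE)
  extra <- build_cys_residue(c(0, 0, 0), unit_vec(c(-1, -1, -1)), 4.5, "A",
                             60L, max(base$atoms$serial) + 1L)
  atoms <- rbind(base$atoms, extra$rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  resolve_records(new_structure(atoms))
}

#' Two Zn sites bridged by a shared cysteine S-gamma
#'
#' A Cys3--Zn--Cys(bridge)--Zn--Cys2His1 cluster: the bridging S-gamma
#' coordinates both Zn ions, so detection should report two accepted
#' sites joined in one cluster group.
#'
#' @return A `zn_structure`.
#' @export
build_bridged_cluster <- function() {
  zn1 <- c(0, 0, 0)
  u1 <- TETRA_DIRS[1, ]
  d <- 2.330
  # bridge S-gamma and second Zn: Zn1-SG-Zn2 angle 120 deg keeps the
  # two coordination shells well separated
  bridge_sg <- zn1 + d * u1
  pe <- perp_vec(u1)
  w <- cos(120 * pi / 180) * (-u1) + sin(120 * pi / 180) * pe
  zn2 <- bridge_sg + d * w
  # frame for Zn2's tetrahedron: first vertex points back at the bridge
  v1 <- unit_vec(bridge_sg - zn2)
  # rotation taking TETRA_DIRS[1,] onto v1
  axis <- cross3(TETRA_DIRS[1, ], v1)
  nax <- sqrt(sum(axis^2))
  rot <- if (nax < 1e-10) diag(3) else {
    rotation_matrix(axis, acos(min(1, max(-1, sum(TETRA_DIRS[1, ] * v1)))))
  }
  dirs2 <- TETRA_DIRS %*% t(rot)
  rows <- list()
  serial <- 1L
  add_res <- function(res) {
    serial <<- serial + nrow(res$rows)
    rows[[length(rows) + 1L]] <<- res$rows
  }
  # bridge Cys: backbone built away from both Zn ions (use midpoint)
  mid <- (zn1 + zn2) / 2
  pbr <- unit_vec(cross3(u1, w))
  cb <- place_away(bridge_sg, SG_CB_BOND,
                   unit_vec(bridge_sg - mid), pbr, 60, mid)
  bb <- grow_backbone(cb, unit_vec(bridge_sg - cb), mid)
  bridge_rows <- rbind(
    atom_row("ATOM", serial + 0, "N", "CYS", "A", 50L, bb$N, "N"),
    atom_row("ATOM", serial + 1, "CA", "CYS", "A", 50L, bb$CA, "C"),
    atom_row("ATOM", serial + 2, "C", "CYS", "A", 50L, bb$C, "C"),
    atom_row("ATOM", serial + 3, "O", "CYS", "A", 50L, bb$O, "O"),
    atom_row("ATOM", serial + 4, "CB", "CYS", "A", 50L, cb, "C"),
    atom_row("ATOM", serial + 5, "SG", "CYS", "A", 50L, bridge_sg, "S"))
  serial <- serial + 6L
  rows[[length(rows) + 1L]] <- bridge_rows
  # Zn1: three more Cys
  for (k in 2:4) {
    add_res(build_cys_residue(zn1, TETRA_DIRS[k, ], d, "A", 10L * (k - 1L),
                              serial))
  }
  # Zn2: two Cys + one His on its remaining vertices
  add_res(build_cys_residue(zn2, dirs2[2, ], 2.306, "B", 10L, serial))
  add_res(build_cys_residue(zn2, dirs2[3, ], 2.306, "B", 20L, serial))
  add_res(build_his_residue(zn2, dirs2[4, ], 2.040, "ND1", "B", 30L, serial))
  rows[[length(rows) + 1L]] <- atom_row("HETATM", serial, "ZN", "ZN", "A",
                                        101L, zn1, "ZN")
  rows[[length(rows) + 1L]] <- atom_row("HETATM", serial + 1L, "ZN", "ZN", "B",
                                        102L, zn2, "ZN")
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  resolve_records(new_structure(atoms))
}

#' Decoy suite
#'
#' Structures with known expected detection outcomes: an octahedral
#' ZnHis6 site (no accepted site), a ZnCys3 + water site (rejected,
#' undercoordinated), an ideal ZnCys4 with a fifth S-gamma at 4.5 A
#' (accepted after one Q-test rejection) and a bridged two-Zn cluster
#' (two sites, one cluster group).
#'
#' @param seed Seed recorded in the entries (construction is
#'   deterministic).
#' @return Named list of entries `list(structure, expected)`.
#' @export
decoy_suite <- function(seed = 1L) {
  list(
    octahedral_his6 = list(structure = build_his6_octahedron(),
                           expected = "no_site"),
    cys3_water = list(structure = build_cys3_water(),
                      expected = "rejected"),
    fifth_sg = list(structure = build_fifth_sg(),
                    expected = "accepted_with_q_rejection"),
    bridged_cluster = list(structure = build_bridged_cluster(),
                           expected = "two_sites_one_cluster"))
}
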