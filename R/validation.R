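# Geometric measurement of detected sites, composition-specific
# Z-scores and the combined r.m.s.Z quality metric.

resolve_atom <- function(structure, chain, resseq, icode, atom, symop = SYMOP_IDENTITY) {
  a <- geometry_atoms(structure)
  i <- which(a$chain == chain & a$resseq == resseq & a$icode == icode &
               a$atom == atom)
  if (!length(i)) return(NULL)
  pos <- c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  apply_symop(pos, symop, structure$cryst)
}

ligand_positions <- function(site) {
  lapply(seq_len(nrow(site$ligands)), function(i) {
    c(site$ligands$x[i], site$ligands$y[i], site$ligands$z[i])
  })
}

#' Measure the geometric features of a detected site
#'
#' Computes Zn--ligand distances, all six ligand-pair angles at the Zn
#' vertex, SG--SG distances for every S-gamma pair, Zn--CB distances for
#' every Cys, the deviation of Zn from the centroid of the four ligand
#' atoms, occupancy/B-factor summaries, the apparent multiplicity of
#' cysteine bridges (ligand SG pairs closer than 2.5 A) and a per-His
#' side-chain flip suspicion flag.
#'
#' @param site A `zn_site` from [detect_sites()].
#' @param structure The `zn_structure` the site was detected in.
#' @return A list of class `zn_geometry_features`.
#' @export
measure_site <- function(site, structure) {
  zn <- atom_pos(site$zn)
  lg <- site$ligands
  pos <- ligand_positions(site)
  dists <- vapply(pos, function(p) coord_distance(zn, p), numeric(1))
  names(dists) <- sprintf("%s/%s%d/%s", lg$chain, lg$resname, lg$resseq, lg$atom)

  pairs <- utils::combn(4, 2)
  pair_angles <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    class_i = lg$ligand_class[pairs[1, ]],
    class_j = lg$ligand_class[pairs[2, ]],
    angle = apply(pairs, 2, function(ij) {
      coord_angle(pos[[ij[1]]], zn, pos[[ij[2]]])
    }))

  sg_idx <- which(lg$ligand_class == "SG")
  sg_sg <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (length(sg_idx) >= 2) {
    sp <- utils::combn(sg_idx, 2)
    sg_sg <- data.frame(i = sp[1, ], j = sp[2, ],
                        dist = apply(sp, 2, function(ij) {
                          coord_distance(pos[[ij[1]]], pos[[ij[2]]])
                        }))
  }

  zn_cb <- numeric(0)
  for (i in sg_idx) {
    cb <- resolve_atom(structure, lg$chain[i], lg$resseq[i], lg$icode[i],
                       "CB", lg$symop[i])
    if (is.null(cb)) {
      warning(sprintf("CB atom missing for %s %s%d; Zn-CB feature skipped",
                      lg$chain[i], lg$resname[i], lg$resseq[i]))
      next
    }
    v <- coord_distance(zn, cb)
    names(v) <- sprintf("%s/%s%d", lg$chain[i], lg$resname[i], lg$resseq[i])
    zn_cb <- c(zn_cb, v)
  }

  centroid <- Reduce(`+`, pos) / 4
  centroid_dev <- coord_distance(zn, centroid)

  bridge_mult <- if (nrow(sg_sg)) sum(sg_sg$dist < 2.5) else 0L

  his_idx <- which(lg$ligand_class %in% c("ND", "NE"))
  his_flip <- detect_his_flip(site, structure)

  occ_b <- site_occ_b(site, structure)

  structure(list(zn_ligand_distances = dists,
                 ligand_pair_angles = pair_angles,
                 sg_sg_distances = sg_sg,
                 zn_cb_distances = zn_cb,
                 zn_centroid_deviation = centroid_dev,
                 occupancy_summary = occ_b$occ,
                 b_factor_summary = occ_b$b,
                 cys_bridge_multiplicity = as.integer(bridge_mult),
                 his_flip_suspect = his_flip),
            class = "zn_geometry_features")
}

site_occ_b <- function(site, structure) {
  a <- geometry_atoms(structure)
  lg <- site$ligands
  keys <- atom_keys(a)
  want <- c(paste(site$zn$chain, site$zn$resseq, site$zn$icode, site$zn$atom, sep = "|"),
            paste(lg$chain, lg$resseq, lg$icode, lg$atom, sep = "|"))
  sel <- a[keys %in% want, , drop = FALSE]
  summ <- function(v) c(min = min(v), mean = mean(v), max = max(v))
  list(occ = summ(sel$occ), b = summ(sel$b))
}

#' Histidine side-chain flip detection
#'
#' A flip is suspected when a ring carbon (CD2 or CE1) of a coordinating
#' His lies nearer to the Zn ion than both ring nitrogens, i.e. the
#' imidazole appears rotated by 180 degrees so that a carbon occupies
#' the coordinating position.  Incomplete rings yield `FALSE` with a
#' warning.
#'
#' @param site A `zn_site`.
#' @param structure A `zn_structure`.
#' @return Named logical vector, one entry per His ligand (empty when
#'   the site has none).
#' @export
detect_his_flip <- function(site, structure) {
  lg <- site$ligands
  his_idx <- which(lg$resname == "HIS")
  out <- logical(0)
  for (i in his_idx) {
    zn <- atom_pos(site$zn)
    get <- function(nm) resolve_atom(structure, lg$chain[i], lg$resseq[i],
                                     lg$icode[i], nm, lg$symop[i])
    nd1 <- get("ND1"); ne2 <- get("NE2"); cd2 <- get("CD2"); ce1 <- get("CE1")
    lab <- sprintf("%s/HIS%d", lg$chain[i], lg$resseq[i])
    if (is.null(nd1) || is.null(ne2) || is.null(cd2) || is.null(ce1)) {
      warning("incomplete imidazole ring for ", lab, "; flip not assessed")
      v <- FALSE
    } else {
      dn <- c(coord_distance(zn, nd1), coord_distance(zn, ne2))
      dc <- c(coord_distance(zn, cd2), coord_distance(zn, ce1))
      v <- any(dc < min(dn))
    }
    names(v) <- lab
    out <- c(out, v)
  }
  out
}

#' Validate one site against a target table
#'
#' Z-scores every feature with an available composition-specific target
#' (Zn--ligand distances, SG--Zn--SG and N--Zn--N angles, SG--SG
#' distances, Zn--CB distances and the Zn-centroid deviation) and
#' combines them into the root-mean-square Z-score.  Mixed S--Zn--N
#' angles have no published target and are reported raw only.  Features
#' whose composition has no target are excluded from r.m.s.Z and listed
#' under `insufficient_targets`.
#'
#' @param site A `zn_site`.
#' @param structure The `zn_structure` the site was detected in.
#' @param targets A [builtin_targets()] table.
#' @return A list of class `zn_site_validation` with `site`, `features`,
#'   `zscores` (data.frame kind/label/value/mean/sd/z), `rmsz`, `flags`.
#' @export
validate_site <- function(site, structure, targets = builtin_targets()) {
  comp <- composition_name(site)
  feats <- measure_site(site, structure)
  lg <- site$ligands
  rows <- list()
  missing_kinds <- character()
  add <- function(kind, label, value) {
    tg <- target_for(targets, comp, kind)
    if (is.null(tg)) {
      missing_kinds <<- union(missing_kinds, kind)
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, label = label, value = value,
        mean = NA_real_, sd = NA_real_, z = NA_real_)
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, label = label, value = value,
        mean = tg$mean, sd = tg$sd, z = zscore(value, tg$mean, tg$sd))
    }
  }
  for (i in seq_len(nrow(lg))) {
    kind <- if (lg$ligand_class[i] == "SG") "zn_sg_distance" else "zn_n_distance"
    add(kind, names(feats$zn_ligand_distances)[i], feats$zn_ligand_distances[[i]])
  }
  pa <- feats$ligand_pair_angles
  for (k in seq_len(nrow(pa))) {
    ci <- pa$class_i[k]; cj <- pa$class_j[k]
    lab <- sprintf("angle %d-Zn-%d", pa$i[k], pa$j[k])
    if (ci == "SG" && cj == "SG") {
      add("sg_zn_sg_angle", lab, pa$angle[k])
    } else if (ci != "SG" && cj != "SG") {
      add("n_zn_n_angle", lab, pa$angle[k])
    }
    # mixed S-Zn-N: reported raw in features, never Z-scored
  }
  ss <- feats$sg_sg_distances
  for (k in seq_len(nrow(ss))) {
    add("sg_sg_distance", sprintf("SG%d-SG%d", ss$i[k], ss$j[k]), ss$dist[k])
  }
  for (k in seq_along(feats$zn_cb_distances)) {
    add("zn_cb_distance", names(feats$zn_cb_distances)[k],
        feats$zn_cb_distances[[k]])
  }
  add("zn_centroid_deviation", "Zn-centroid", feats$zn_centroid_deviation)

  ztab <- do.call(rbind, rows)
  zincl <- ztab$z[!is.na(ztab$z)]
  rmsz <- if (length(zincl)) sqrt(mean(zincl^2)) else NA_real_
  flags <- list(chain_break = isTRUE(site$chain_break_adjacent),
                his_flip = any(feats$his_flip_suspect),
                bridging_sg = length(site$bridging_sg) > 0,
                insufficient_targets = missing_kinds)
  structure(list(site = site, features = feats, zscores = ztab,
                 rmsz = rmsz, flags = flags),
            class = "zn_site_validation")
}

#' @export
print.zn_site_validation <- function(x, ...) {
  cat(sprintf("<validation %s %s: rmsz = %.3f over %d component(s)%s>\n",
              site_label(x$site), composition_name(x$site), x$rmsz,
              sum(!is.na(x$zscores$z)),
              if (length(x$flags$insufficient_targets))
                paste0("; no targets for ",
                       paste(x$flags$insufficient_targets, collapse = ", "))
              else ""))
  invisible(x)
}

#' Detect and validate every site in a structure
#'
#' Runs [detect_sites()] and then [validate_site()] on every accepted
#' site.  Sites adjacent to a chain break are reported but flagged, and
#' excluded from the aggregate r.m.s.Z summary.
#'
#' @param structure A `zn_structure`.
#' @param config A [detection_config()].
#' @param targets A [builtin_targets()] table.
#' @return A list of class `zn_validation_set`: `reports` (list of
#'   `zn_site_validation`), `summary` (data.frame), `mean_rmsz`
#'   (aggregate over non-chain-break sites), `site_set`.
#' @export
validate_structure <- function(structure, config = detection_config(),
                               targets = builtin_targets()) {
  ss <- detect_sites(structure, config)
  reports <- lapply(ss$sites, validate_site, structure = structure,
                    targets = targets)
  summ <- validation_summary(reports)
  ok <- !vapply(reports, function(r) r$flags$chain_break, logical(1))
  mean_rmsz <- if (any(ok)) {
    mean(vapply(reports[ok], function(r) r$rmsz, numeric(1)), na.rm = TRUE)
  } else NA_real_
  structure(list(reports = reports, summary = summ,
                 mean_rmsz = mean_rmsz, site_set = ss),
            class = "zn_validation_set")
}

validation_summary <- function(reports) {
  if (!length(reports)) {
    return(data.frame(zn = character(), composition = character(),
                      rmsz = numeric(), worst_component = character(),
                      worst_z = numeric(), chain_break = logical(),
                      his_flip = logical(), bridging = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(reports, function(r) {
    zt <- r$zscores[!is.na(r$zscores$z), , drop = FALSE]
    worst <- if (nrow(zt)) zt[which.max(abs(zt$z)), ] else NULL
    data.frame(zn = site_label(r$site),
               composition = composition_name(r$site),
               rmsz = r$rmsz,
               worst_component = if (is.null(worst)) "" else
                 paste(worst$kind, worst$label),
               worst_z = if (is.null(worst)) NA_real_ else worst$z,
               chain_break = r$flags$chain_break,
               his_flip = r$flags$his_flip,
               bridging = r$flags$bridging_sg,
               stringsAsFactors = FALSE)
  }))
}
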