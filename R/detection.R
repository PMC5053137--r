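# Detection of putative tetrahedral ZnCys(x)His(y) complexes: candidate
# search radii, Dixon's Q-test outlier rejection, discard rules, His-heavy
# rule, bridging-Sgamma cluster detection and chain-break flagging.

# Standard one-sided Dixon r10 (gap/range) critical values, n = 3..10
# (Dean & Dixon 1951; Rorabacher 1991).
DIXON_Q_TABLE <- list(
  "0.9"  = c(`3` = 0.941, `4` = 0.765, `5` = 0.642, `6` = 0.560,
             `7` = 0.507, `8` = 0.468, `9` = 0.437, `10` = 0.412),
  "0.95" = c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
             `7` = 0.568, `8` = 0.526, `9` = 0.493, `10` = 0.466),
  "0.99" = c(`3` = 0.994, `4` = 0.926, `5` = 0.821, `6` = 0.740,
             `7` = 0.680, `8` = 0.634, `9` = 0.598, `10` = 0.568))

#' Critical value for Dixon's Q-test (r10 variant)
#'
#' @param n Sample size (3..10; larger n clamp to the n = 10 value).
#' @param level Confidence level: 0.90, 0.95 or 0.99.
#' @return The critical Q value.
#' @export
dixon_q_critical <- function(n, level = 0.95) {
  key <- as.character(level)
  if (!key %in% names(DIXON_Q_TABLE)) {
    stop("q_confidence must be one of 0.90, 0.95, 0.99")
  }
  tab <- DIXON_Q_TABLE[[key]]
  unname(tab[as.character(max(3L, min(as.integer(n), 10L)))])
}

#' Detection configuration
#'
#' Search radii and rule settings for tetrahedral Zn-site detection.
#' Defaults are the published cutoffs: Cys S-gamma searched within 4.8 A,
#' His ring N within 3.8 A, foreign coordinating atoms flagged at 2.9 A
#' or closer, ligands flagged at 3.25 A or further, and His-heavy sites
#' (>= 3 His) requiring all four ligands within 3.0 A.
#'
#' @param s_gamma_radius Search radius for Cys SG atoms (A).
#' @param his_n_radius Search radius for His ND1/NE2 atoms (A).
#' @param foreign_ligand_max Distance at or below which a non-Cys/His
#'   donor atom triggers discard condition (i) (A).
#' @param ligand_reject_min Distance at or above which a ligand triggers
#'   discard condition (ii) (A).
#' @param his_heavy_max All-ligand distance bound for sites with at
#'   least three His ligands (A).
#' @param q_confidence Dixon Q-test confidence level (0.90/0.95/0.99).
#' @param discard_combination `"and"`: discard when (i) and (ii) both
#'   hold (ZnHis4 additionally on (i) alone); `"or"`: either alone.
#' @param use_symmetry Consider P1 lattice translations when a CRYST1
#'   cell is present.
#' @param chain_break_max Peptide C--N distance above which sequential
#'   neighbours count as a chain break (A).
#' @return A list of class `zn_detection_config`.
#' @export
detection_config <- function(s_gamma_radius = 4.8,
                             his_n_radius = 3.8,
                             foreign_ligand_max = 2.9,
                             ligand_reject_min = 3.25,
                             his_heavy_max = 3.0,
                             q_confidence = 0.95,
                             discard_combination = c("and", "or"),
                             use_symmetry = TRUE,
                             chain_break_max = 2.5) {
  discard_combination <- match.arg(discard_combination)
  stopifnot(s_gamma_radius > 0, his_n_radius > 0, foreign_ligand_max > 0,
            ligand_reject_min > 0, his_heavy_max > 0,
            ligand_reject_min < s_gamma_radius)
  if (!as.character(q_confidence) %in% names(DIXON_Q_TABLE)) {
    stop("q_confidence must be one of 0.90, 0.95, 0.99")
  }
  structure(list(s_gamma_radius = s_gamma_radius,
                 his_n_radius = his_n_radius,
                 foreign_ligand_max = foreign_ligand_max,
                 ligand_reject_min = ligand_reject_min,
                 his_heavy_max = his_heavy_max,
                 q_confidence = q_confidence,
                 discard_combination = discard_combination,
                 use_symmetry = use_symmetry,
                 chain_break_max = chain_break_max),
            class = "zn_detection_config")
}

#' Zinc ions in a structure
#'
#' All Zn atoms (HETATM residue name ZN), one per site after alternate
#' locations are collapsed to the highest-occupancy conformer.
#'
#' @param structure A `zn_structure`.
#' @return Data.frame of Zn atoms (possibly 0 rows).
#' @export
find_zinc_ions <- function(structure) {
  a <- geometry_atoms(structure)
  zn <- a[a$element == "ZN", , drop = FALSE]
  zn[order(zn$chain, zn$resseq, zn$icode), , drop = FALSE]
}

atom_pos <- function(row) c(row$x, row$y, row$z)

#' Candidate coordinating atoms around one Zn ion
#'
#' Cys SG atoms within `s_gamma_radius` and His ND1/NE2 atoms within
#' `his_n_radius`, sorted by distance.  At most one ring N per His
#' residue is kept (the nearer of ND1/NE2; ties towards ND1).
#'
#' @param structure A `zn_structure`.
#' @param zn One-row data.frame for the Zn atom (from [find_zinc_ions()]).
#' @param config A [detection_config()].
#' @return Data.frame of candidate ligands with columns `chain`,
#'   `resseq`, `icode`, `resname`, `atom`, `ligand_class` (SG/ND/NE),
#'   `dist`, `x`, `y`, `z`, `symop`.
#' @export
find_candidates <- function(structure, zn, config = detection_config()) {
  centre <- atom_pos(zn)
  near <- if (config$use_symmetry && !is.null(structure$cryst)) {
    symmetry_expand(structure, centre, config$s_gamma_radius)
  } else {
    a <- geometry_atoms(structure)
    d <- sqrt((a$x - centre[1])^2 + (a$y - centre[2])^2 + (a$z - centre[3])^2)
    a[d <= config$s_gamma_radius, , drop = FALSE]
  }
  if (!nrow(near)) return(candidate_frame())
  d <- sqrt((near$x - centre[1])^2 + (near$y - centre[2])^2 + (near$z - centre[3])^2)
  near$dist <- d
  is_sg <- near$resname == "CYS" & near$atom == "SG" & d < config$s_gamma_radius & d > 0
  is_n <- near$resname == "HIS" & near$atom %in% c("ND1", "NE2") &
    d < config$his_n_radius & d > 0
  cand <- near[is_sg | is_n, , drop = FALSE]
  if (!nrow(cand)) return(candidate_frame())
  cand$ligand_class <- ifelse(cand$atom == "SG", "SG",
                              ifelse(cand$atom == "ND1", "ND", "NE"))
  # one N per His residue: nearer of ND1/NE2, ties toward ND1
  reskey <- paste(cand$chain, cand$resseq, cand$icode, cand$symop, sep = "|")
  keep <- rep(TRUE, nrow(cand))
  for (k in unique(reskey[cand$resname == "HIS"])) {
    i <- which(reskey == k & cand$resname == "HIS")
    if (length(i) > 1) {
      best <- i[order(cand$dist[i], cand$atom[i] != "ND1")][1]
      keep[setdiff(i, best)] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$dist), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("chain", "resseq", "icode", "resname", "atom", "ligand_class",
           "dist", "x", "y", "z", "symop")]
}

candidate_frame <- function() {
  data.frame(chain = character(), resseq = integer(), icode = character(),
             resname = character(), atom = character(),
             ligand_class = character(), dist = numeric(),
             x = numeric(), y = numeric(), z = numeric(),
             symop = character(), stringsAsFactors = FALSE)
}

#' Dixon Q-test outlier filter on candidate ligand distances
#'
#' Applied only when five or more candidates are found.  The largest
#' distance is tested with Q = (d_n - d_(n-1)) / (d_n - d_1) against the
#' critical value for the current sample size and removed while the test
#' rejects and more than four candidates remain.
#'
#' @param candidates Candidate data.frame from [find_candidates()],
#'   sorted by distance.
#' @param config A [detection_config()].
#' @return List with `kept` (surviving candidates) and `results`
#'   (data.frame trace: one row per test with `n`, `tested_value`,
#'   `q_statistic`, `critical_value`, `rejected`).
#' @export
q_test_filter <- function(candidates, config = detection_config()) {
  results <- data.frame(n = integer(), tested_value = numeric(),
                        q_statistic = numeric(), critical_value = numeric(),
                        rejected = logical())
  cand <- candidates[order(candidates$dist), , drop = FALSE]
  if (nrow(cand) < 5) {
    return(list(kept = candidates, results = results))
  }
  repeat {
    n <- nrow(cand)
    if (n <= 4 || n < 3) break
    d <- cand$dist
    rng <- d[n] - d[1]
    q <- if (rng == 0) 0 else (d[n] - d[n - 1]) / rng
    crit <- dixon_q_critical(n, config$q_confidence)
    rej <- q > crit
    results <- rbind(results, data.frame(n = n, tested_value = d[n],
                                         q_statistic = q,
                                         critical_value = crit,
                                         rejected = rej))
    if (!rej) break
    cand <- cand[-n, , drop = FALSE]
  }
  rownames(cand) <- NULL
  list(kept = cand, results = results)
}

# Donor elements that can coordinate Zn; carbon and hydrogen excluded.
FOREIGN_DONORS <- c("N", "O", "S", "P", "F", "CL", "BR", "I")

# Foreign coordinating atoms within `foreign_ligand_max` of the Zn:
# donor-element atoms that are neither the candidates themselves nor
# side-chain atoms of the candidate residues.
foreign_ligands <- function(structure, zn, survivors, config) {
  centre <- atom_pos(zn)
  near <- if (config$use_symmetry && !is.null(structure$cryst)) {
    symmetry_expand(structure, centre, config$foreign_ligand_max)
  } else {
    a <- geometry_atoms(structure)
    d <- sqrt((a$x - centre[1])^2 + (a$y - centre[2])^2 + (a$z - centre[3])^2)
    a[d <= config$foreign_ligand_max, , drop = FALSE]
  }
  if (!nrow(near)) return(near)
  d <- sqrt((near$x - centre[1])^2 + (near$y - centre[2])^2 + (near$z - centre[3])^2)
  near$dist <- d
  near <- near[d > 0 & near$element %in% FOREIGN_DONORS, , drop = FALSE]
  if (!nrow(near)) return(near)
  survkey <- paste(survivors$chain, survivors$resseq, survivors$icode,
                   survivors$atom, survivors$symop, sep = "|")
  nearkey <- paste(near$chain, near$resseq, near$icode, near$atom,
                   near$symop, sep = "|")
  near <- near[!nearkey %in% survkey, , drop = FALSE]
  if (!nrow(near)) return(near)
  # side-chain atoms of candidate residues do not count as foreign
  backbone <- c("N", "CA", "C", "O", "OXT")
  sresk <- unique(paste(survivors$chain, survivors$resseq, survivors$icode,
                        sep = "|"))
  nresk <- paste(near$chain, near$resseq, near$icode, sep = "|")
  near[!(nresk %in% sresk & !(near$atom %in% backbone)), , drop = FALSE]
}

#' Classify one Zn environment as an accepted site or a rejection
#'
#' Acceptance requires exactly four surviving candidates.  Discard
#' condition (i): a foreign donor atom at 2.9 A or closer; condition
#' (ii): any ligand at 3.25 A or further.  Under the default "and"
#' combination a site is discarded when both hold, ZnHis4 already when
#' (i) alone holds, and any site with three or more His ligands unless
#' all four distances are below 3.0 A.
#'
#' @param zn One-row Zn data.frame.
#' @param survivors Candidates surviving [q_test_filter()].
#' @param structure A `zn_structure`.
#' @param config A [detection_config()].
#' @return A `zn_site` (accepted) or a list of class `zn_rejection`
#'   with a `reason` string.
#' @export
classify_site <- function(zn, survivors, structure, config = detection_config()) {
  reject <- function(reason) {
    structure(list(zn = zn, reason = reason, n_candidates = nrow(survivors)),
              class = "zn_rejection")
  }
  if (nrow(survivors) < 4) return(reject("undercoordinated"))
  if (nrow(survivors) > 4) return(reject("overcoordinated"))
  x <- sum(survivors$ligand_class == "SG")
  y <- 4L - x
  foreign <- foreign_ligands(structure, zn, survivors, config)
  cond_i <- nrow(foreign) > 0
  cond_ii <- any(survivors$dist >= config$ligand_reject_min)
  if (config$discard_combination == "or") {
    if (cond_i) return(reject("foreign_ligand"))
    if (cond_ii) return(reject("long_ligand"))
  } else {
    if (cond_i && cond_ii) return(reject("foreign_ligand_and_long_ligand"))
    if (y == 4L && cond_i) return(reject("his4_foreign_ligand"))
  }
  if (y >= 3L && any(survivors$dist >= config$his_heavy_max)) {
    return(reject("his_heavy_distance"))
  }
  new_site(zn, survivors, x, y)
}

new_site <- function(zn, ligands, x, y) {
  structure(list(zn = zn,
                 ligands = ligands[order(ligands$dist), , drop = FALSE],
                 composition = c(cys = as.integer(x), his = as.integer(y)),
                 bridging_sg = character(),
                 chain_break_adjacent = FALSE),
            class = "zn_site")
}

#' @export
print.zn_site <- function(x, ...) {
  cat(sprintf("<zn_site %s %s%d: ZnCys%dHis%d; d = %s A%s>\n",
              x$zn$chain, x$zn$resname, x$zn$resseq,
              x$composition["cys"], x$composition["his"],
              paste(sprintf("%.2f", x$ligands$dist), collapse = ", "),
              if (length(x$bridging_sg)) " [bridged]" else ""))
  invisible(x)
}

site_label <- function(site) {
  sprintf("%s/%s%d%s", site$zn$chain, site$zn$resname, site$zn$resseq,
          site$zn$icode)
}

composition_name <- function(site) {
  x <- site$composition[["cys"]]
  y <- site$composition[["his"]]
  paste0(if (x > 0) paste0("Cys", x) else "", if (y > 0) paste0("His", y) else "")
}

ligand_sg_keys <- function(site) {
  lg <- site$ligands
  sg <- lg[lg$ligand_class == "SG", , drop = FALSE]
  paste(sg$chain, sg$resseq, sg$icode, sg$atom, sep = "|")
}

#' Chain-break adjacency of a site's ligand residues
#'
#' TRUE when any ligand residue has a sequence-adjacent neighbour (r-1
#' or r+1, strictly inside the chain's polymer numbering span) missing
#' from its chain, or present but with a peptide C--N distance above
#' `chain_break_max` (default 2.5 A).
#'
#' @param site A `zn_site`.
#' @param structure A `zn_structure`.
#' @param config A [detection_config()].
#' @return Logical flag.
#' @export
flag_chain_break <- function(site, structure, config = detection_config()) {
  a <- geometry_atoms(structure)
  poly <- a[a$record == "ATOM" & a$atom == "CA", , drop = FALSE]
  for (i in seq_len(nrow(site$ligands))) {
    lg <- site$ligands[i, ]
    chain_res <- sort(unique(poly$resseq[poly$chain == lg$chain]))
    if (!length(chain_res)) next
    span <- range(chain_res)
    for (s in c(lg$resseq - 1L, lg$resseq + 1L)) {
      if (s < span[1] || s > span[2]) next   # chain terminus
      if (!s %in% chain_res) return(TRUE)
      lo <- min(s, lg$resseq); hi <- max(s, lg$resseq)
      cpos <- a[a$chain == lg$chain & a$resseq == lo & a$atom == "C", , drop = FALSE]
      npos <- a[a$chain == lg$chain & a$resseq == hi & a$atom == "N", , drop = FALSE]
      if (!nrow(cpos) || !nrow(npos)) next
      if (coord_distance(atom_pos(cpos[1, ]), atom_pos(npos[1, ])) >
          config$chain_break_max) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect all tetrahedral ZnCys(x)His(y) sites in a structure
#'
#' Runs the full per-Zn pipeline (candidate search, Dixon Q-test,
#' discard rules), flags chain-break adjacency, and groups accepted
#' sites sharing an S-gamma atom into clusters of bridged sites.
#'
#' @param structure A `zn_structure`.
#' @param config A [detection_config()].
#' @return A list of class `zn_site_set` with elements `sites` (list of
#'   `zn_site`), `rejected` (list of `zn_rejection`), `cluster_groups`
#'   (list of integer vectors indexing `sites`) and `q_traces`.
#' @export
detect_sites <- function(structure, config = detection_config()) {
  zns <- find_zinc_ions(structure)
  sites <- list()
  rejected <- list()
  q_traces <- list()
  for (i in seq_len(nrow(zns))) {
    zn <- zns[i, ]
    cand <- find_candidates(structure, zn, config)
    qt <- q_test_filter(cand, config)
    q_traces[[sprintf("%s|%d|%s", zn$chain, zn$resseq, zn$icode)]] <- qt$results
    res <- classify_site(zn, qt$kept, structure, config)
    if (inherits(res, "zn_site")) {
      res$chain_break_adjacent <- flag_chain_break(res, structure, config)
      sites[[length(sites) + 1L]] <- res
    } else {
      rejected[[length(rejected) + 1L]] <- res
    }
  }
  # bridging S-gamma / cluster groups via connected components
  nsite <- length(sites)
  groups <- list()
  if (nsite) {
    sgk <- lapply(sites, ligand_sg_keys)
    parent <- seq_len(nsite)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nsite)) for (j in seq_len(nsite)) {
      if (j <= i) next
      shared <- intersect(sgk[[i]], sgk[[j]])
      if (length(shared)) parent[find(j)] <- find(i)
    }
    for (i in seq_len(nsite)) {
      shared <- character()
      for (j in setdiff(seq_len(nsite), i)) {
        shared <- union(shared, intersect(sgk[[i]], sgk[[j]]))
      }
      sites[[i]]$bridging_sg <- shared
    }
    roots <- vapply(seq_len(nsite), find, integer(1))
    for (r in unique(roots)) {
      members <- which(roots == r)
      if (length(members) > 1) groups[[length(groups) + 1L]] <- members
    }
  }
  structure(list(sites = sites, rejected = rejected,
                 cluster_groups = groups, q_traces = q_traces),
            class = "zn_site_set")
}

#' @export
print.zn_site_set <- function(x, ...) {
  cat(sprintf("<zn_site_set: %d accepted, %d rejected, %d cluster group(s)>\n",
              length(x$sites), length(x$rejected), length(x$cluster_groups)))
  for (s in x$sites) print(s)
  for (r in x$rejected) {
    cat(sprintf("  rejected %s/%s%d: %s\n", r$zn$chain, r$zn$resname,
                r$zn$resseq, r$reason))
  }
  invisible(x)
}

#' Tabular detection report
#'
#' One row per Zn ion with status, composition, ligand list, distances
#' and flags.
#'
#' @param site_set A `zn_site_set` from [detect_sites()].
#' @return A data.frame.
#' @export
detection_report <- function(site_set) {
  rows <- list()
  for (s in site_set$sites) {
    rows[[length(rows) + 1L]] <- data.frame(
      zn = site_label(s), status = "accepted",
      composition = composition_name(s),
      ligands = paste(sprintf("%s/%s%d/%s", s$ligands$chain, s$ligands$resname,
                              s$ligands$resseq, s$ligands$atom), collapse = ","),
      distances = paste(sprintf("%.3f", s$ligands$dist), collapse = ","),
      chain_break = s$chain_break_adjacent,
      bridging = length(s$bridging_sg) > 0,
      reason = "", stringsAsFactors = FALSE)
  }
  for (r in site_set$rejected) {
    rows[[length(rows) + 1L]] <- data.frame(
      zn = sprintf("%s/%s%d%s", r$zn$chain, r$zn$resname, r$zn$resseq, r$zn$icode),
      status = "rejected", composition = "", ligands = "", distances = "",
      chain_break = NA, bridging = NA, reason = r$reason,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(zn = character(), status = character(),
                      composition = character(), ligands = character(),
                      distances = character(), chain_break = logical(),
                      bridging = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$zn), , drop = FALSE]
}
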