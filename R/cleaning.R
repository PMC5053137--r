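# "Cys-cleaning": removal of spurious SSBOND/LINK records at detected
# Zn sites and addition of canonical Zn--ligand LINK records.  Atom
# coordinates are never touched.

link_key <- function(df) {
  paste(df$chain1, df$seq1, df$icode1, df$name1,
        df$chain2, df$seq2, df$icode2, df$name2, sep = "|")
}

ssbond_key <- function(df) {
  paste(df$chain1, df$seq1, df$icode1, df$chain2, df$seq2, df$icode2, sep = "|")
}

#' Plan annotation corrections for detected sites
#'
#' Removes every SSBOND in which either cysteine's S-gamma coordinates a
#' detected Zn ion, removes every LINK from a site's Zn to an atom that
#' is not one of its four ligands (including spurious LINKs joining two
#' detected sites), and adds a Zn--ligand LINK for each of the four
#' ligands that lacks one.  Records referencing atoms absent from the
#' model are left untouched and logged.
#'
#' @param structure A `zn_structure`.
#' @param sites A `zn_site_set` from [detect_sites()] on `structure`.
#' @return A list of class `zn_changeset`: `ssbond_removals`,
#'   `link_removals`, `link_additions` (data.frames in the structure's
#'   record layout) and `log` (character).
#' @export
plan_changes <- function(structure, sites) {
  stopifnot(inherits(structure, "zn_structure"), inherits(sites, "zn_site_set"))
  log <- character()
  # residue-level keys of ligand cysteines; atom-level keys of site atoms
  lig_cys_res <- character()
  site_atoms <- character()      # all Zn + ligand atom keys across sites
  zn_keys <- character()
  lig_by_zn <- list()
  for (s in sites$sites) {
    zk <- paste(s$zn$chain, s$zn$resseq, s$zn$icode, s$zn$atom, sep = "|")
    zn_keys <- c(zn_keys, zk)
    lk <- paste(s$ligands$chain, s$ligands$resseq, s$ligands$icode,
                s$ligands$atom, sep = "|")
    lig_by_zn[[zk]] <- lk
    site_atoms <- union(site_atoms, c(zk, lk))
    cys <- s$ligands[s$ligands$resname == "CYS", , drop = FALSE]
    lig_cys_res <- union(lig_cys_res,
                         paste(cys$chain, cys$resseq, cys$icode, sep = "|"))
  }

  # SSBOND removals
  sb <- structure$ssbonds
  sb_rm <- sb[0, , drop = FALSE]
  if (nrow(sb)) {
    k1 <- paste(sb$chain1, sb$seq1, sb$icode1, sep = "|")
    k2 <- paste(sb$chain2, sb$seq2, sb$icode2, sep = "|")
    hit <- (k1 %in% lig_cys_res) | (k2 %in% lig_cys_res)
    unresolved <- hit & !sb$resolved
    for (i in which(unresolved)) {
      log <- c(log, sprintf("SSBOND %s-%s references atoms absent from the model; left untouched",
                            k1[i], k2[i]))
    }
    hit <- hit & sb$resolved
    sb_rm <- sb[hit, , drop = FALSE]
    for (i in which(hit)) {
      log <- c(log, sprintf("remove SSBOND CYS %s%d%s -- CYS %s%d%s (ligand cysteine of a Zn site)",
                            sb$chain1[i], sb$seq1[i], sb$icode1[i],
                            sb$chain2[i], sb$seq2[i], sb$icode2[i]))
    }
  }

  # LINK removals
  ln <- structure$links
  ln_rm <- ln[0, , drop = FALSE]
  existing_pairs <- character()
  if (nrow(ln)) {
    a1 <- paste(ln$chain1, ln$seq1, ln$icode1, ln$name1, sep = "|")
    a2 <- paste(ln$chain2, ln$seq2, ln$icode2, ln$name2, sep = "|")
    rm_idx <- logical(nrow(ln))
    for (i in seq_len(nrow(ln))) {
      if (!ln$resolved[i]) {
        if (a1[i] %in% zn_keys || a2[i] %in% zn_keys) {
          log <- c(log, sprintf("LINK %s -- %s references atoms absent from the model; left untouched",
                                a1[i], a2[i]))
        }
        next
      }
      zn_side <- c(a1[i] %in% zn_keys, a2[i] %in% zn_keys)
      if (any(zn_side)) {
        zk <- if (zn_side[1]) a1[i] else a2[i]
        other <- if (zn_side[1]) a2[i] else a1[i]
        if (!other %in% lig_by_zn[[zk]]) {
          rm_idx[i] <- TRUE
          log <- c(log, sprintf("remove LINK %s -- %s (not a ligand of this Zn site)",
                                a1[i], a2[i]))
        } else {
          existing_pairs <- c(existing_pairs, paste(zk, other, sep = "::"))
        }
      } else if (a1[i] %in% site_atoms && a2[i] %in% site_atoms) {
        # spurious LINK joining atoms of detected sites (e.g. SG--SG)
        rm_idx[i] <- TRUE
        log <- c(log, sprintf("remove LINK %s -- %s (spurious link between Zn-site atoms)",
                              a1[i], a2[i]))
      }
    }
    ln_rm <- ln[rm_idx, , drop = FALSE]
  }

  # LINK additions: one per missing Zn--ligand bond
  adds <- list()
  for (s in sites$sites) {
    zk <- paste(s$zn$chain, s$zn$resseq, s$zn$icode, s$zn$atom, sep = "|")
    for (j in seq_len(nrow(s$ligands))) {
      lg <- s$ligands[j, ]
      lk <- paste(lg$chain, lg$resseq, lg$icode, lg$atom, sep = "|")
      if (paste(zk, lk, sep = "::") %in% existing_pairs) next
      adds[[length(adds) + 1L]] <- data.frame(
        name1 = s$zn$atom, alt1 = "", resname1 = s$zn$resname,
        chain1 = s$zn$chain, seq1 = s$zn$resseq, icode1 = s$zn$icode,
        name2 = lg$atom, alt2 = "", resname2 = lg$resname,
        chain2 = lg$chain, seq2 = lg$resseq, icode2 = lg$icode,
        sym1 = SYMOP_IDENTITY, sym2 = lg$symop,
        dist = round(lg$dist, 2), resolved = TRUE,
        stringsAsFactors = FALSE)
      log <- c(log, sprintf("add LINK %s -- %s (value %.2f A)", zk, lk, lg$dist))
    }
  }
  ln_add <- if (length(adds)) do.call(rbind, adds) else empty_links()
  if (nrow(ln_add)) {
    ord <- order(ln_add$chain1, ln_add$seq1, ln_add$chain2, ln_add$seq2,
                 ln_add$name2)
    ln_add <- ln_add[ord, , drop = FALSE]
  }
  structure(list(ssbond_removals = sb_rm, link_removals = ln_rm,
                 link_additions = ln_add, log = log),
            class = "zn_changeset")
}

#' @export
print.zn_changeset <- function(x, ...) {
  cat(sprintf("<zn_changeset: -%d SSBOND, -%d LINK, +%d LINK>\n",
              nrow(x$ssbond_removals), nrow(x$link_removals),
              nrow(x$link_additions)))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Apply a planned changeset
#'
#' Returns a new structure with the records removed/added; atomic
#' coordinates are untouched.  Additions are appended sorted by Zn and
#' ligand so output is deterministic.  Applying the plan twice is a
#' no-op.
#'
#' @param structure The `zn_structure` the plan was made against.
#' @param changes A `zn_changeset` from [plan_changes()].
#' @return The corrected `zn_structure`.
#' @export
apply_changes <- function(structure, changes) {
  stopifnot(inherits(structure, "zn_structure"), inherits(changes, "zn_changeset"))
  sb <- structure$ssbonds
  if (nrow(sb) && nrow(changes$ssbond_removals)) {
    sb <- sb[!ssbond_key(sb) %in% ssbond_key(changes$ssbond_removals), ,
             drop = FALSE]
  }
  ln <- structure$links
  if (nrow(ln) && nrow(changes$link_removals)) {
    ln <- ln[!link_key(ln) %in% link_key(changes$link_removals), , drop = FALSE]
  }
  if (nrow(changes$link_additions)) {
    new <- changes$link_additions[!link_key(changes$link_additions) %in%
                                    link_key(ln), , drop = FALSE]
    ln <- rbind(ln, new)
  }
  rownames(sb) <- NULL
  rownames(ln) <- NULL
  structure$ssbonds <- sb
  structure$links <- ln
  structure
}
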