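# Distance and angle restraints for detected sites and their rendering
# in the REFMAC external-restraint keyword dialect.

# Published refinement dictionary targets.
ZN_SG_TARGET <- c(value = 2.340, sigma = 0.020)
ZN_ND_TARGET <- c(value = 2.057, sigma = 0.064)
ZN_NE_TARGET <- c(value = 2.058, sigma = 0.073)
SG_ZN_SG_ANGLE <- c(value = 109.5, sigma = 3.0)
ZN_SG_CB_DICT <- c(value = 109.000, sigma = 3.000)
ZN_N_C_DICT <- c(value = 125.350, sigma = 3.000)

restraint_atom <- function(chain, resseq, icode, resname, atom,
                           symop = SYMOP_IDENTITY) {
  data.frame(chain = chain, resseq = resseq, icode = icode,
             resname = resname, atom = atom, symop = symop,
             stringsAsFactors = FALSE)
}

site_zn_atomref <- function(site) {
  restraint_atom(site$zn$chain, site$zn$resseq, site$zn$icode,
                 site$zn$resname, site$zn$atom)
}

site_ligand_atomref <- function(site, i) {
  lg <- site$ligands[i, ]
  restraint_atom(lg$chain, lg$resseq, lg$icode, lg$resname, lg$atom, lg$symop)
}

#' Distance restraints for one site
#'
#' One Zn--ligand restraint per ligand with the published dictionary
#' targets: Zn--SG 2.340 +/- 0.020 A, Zn--ND 2.057 +/- 0.064 A,
#' Zn--NE 2.058 +/- 0.073 A.
#'
#' @param site A `zn_site`.
#' @return Data.frame with one row per restraint (atom1/atom2 fields,
#'   `target`, `sigma`).
#' @export
make_distance_restraints <- function(site) {
  zn <- site_zn_atomref(site)
  rows <- lapply(seq_len(nrow(site$ligands)), function(i) {
    lg <- site_ligand_atomref(site, i)
    tg <- switch(site$ligands$ligand_class[i],
                 SG = ZN_SG_TARGET, ND = ZN_ND_TARGET, NE = ZN_NE_TARGET)
    data.frame(chain1 = zn$chain, resseq1 = zn$resseq, icode1 = zn$icode,
               atom1 = zn$atom, symop1 = zn$symop,
               chain2 = lg$chain, resseq2 = lg$resseq, icode2 = lg$icode,
               atom2 = lg$atom, symop2 = lg$symop,
               target = unname(tg["value"]), sigma = unname(tg["sigma"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Angle restraints for one site
#'
#' One SG--Zn--SG external restraint per S-gamma pair at the ideal
#' tetrahedral 109.5 +/- 3.0 degrees.  Angles involving histidine
#' ligands at the Zn vertex are never restrained.  When
#' `include_dictionary_angles` is TRUE, dictionary-style angles are
#' added: Zn--SG--CB at 109.000 +/- 3.000 per Cys and the two Zn--N--C
#' ring angles at 125.350 +/- 3.000 per coordinated His nitrogen.
#'
#' @param site A `zn_site`.
#' @param include_dictionary_angles Emit the dictionary-style angles
#'   too (default FALSE: external-restraint content only).
#' @return Data.frame with one row per restraint (atom1/vertex/atom3
#'   fields, `target`, `sigma`); zero rows when the site has fewer than
#'   two Cys and dictionary angles are off.
#' @export
make_angle_restraints <- function(site, include_dictionary_angles = FALSE) {
  zn <- site_zn_atomref(site)
  rows <- list()
  ang_row <- function(a1, v, a3, tg) {
    data.frame(chain1 = a1$chain, resseq1 = a1$resseq, icode1 = a1$icode,
               atom1 = a1$atom, symop1 = a1$symop,
               chainv = v$chain, resseqv = v$resseq, icodev = v$icode,
               atomv = v$atom, symopv = v$symop,
               chain3 = a3$chain, resseq3 = a3$resseq, icode3 = a3$icode,
               atom3 = a3$atom, symop3 = a3$symop,
               target = unname(tg["value"]), sigma = unname(tg["sigma"]),
               stringsAsFactors = FALSE)
  }
  sg_idx <- which(site$ligands$ligand_class == "SG")
  if (length(sg_idx) >= 2) {
    pr <- utils::combn(sg_idx, 2)
    for (k in seq_len(ncol(pr))) {
      rows[[length(rows) + 1L]] <- ang_row(
        site_ligand_atomref(site, pr[1, k]), zn,
        site_ligand_atomref(site, pr[2, k]), SG_ZN_SG_ANGLE)
    }
  }
  if (include_dictionary_angles) {
    for (i in sg_idx) {
      sg <- site_ligand_atomref(site, i)
      cb <- sg; cb$atom <- "CB"
      rows[[length(rows) + 1L]] <- ang_row(zn, sg, cb, ZN_SG_CB_DICT)
    }
    for (i in which(site$ligands$ligand_class %in% c("ND", "NE"))) {
      n <- site_ligand_atomref(site, i)
      flank <- if (site$ligands$ligand_class[i] == "ND") c("CG", "CE1")
               else c("CD2", "CE1")
      for (cn in flank) {
        cc <- n; cc$atom <- cn
        rows[[length(rows) + 1L]] <- ang_row(zn, n, cc, ZN_N_C_DICT)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chain1 = character(), resseq1 = integer(),
                      icode1 = character(), atom1 = character(),
                      symop1 = character(),
                      chainv = character(), resseqv = integer(),
                      icodev = character(), atomv = character(),
                      symopv = character(),
                      chain3 = character(), resseq3 = integer(),
                      icode3 = character(), atom3 = character(),
                      symop3 = character(),
                      target = numeric(), sigma = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Restraint set for one site
#'
#' @param site A `zn_site`.
#' @param include_dictionary_angles Passed to [make_angle_restraints()].
#' @return List of class `zn_restraint_set` with `distances`, `angles`
#'   and `site`.
#' @export
restraint_set <- function(site, include_dictionary_angles = FALSE) {
  structure(list(distances = make_distance_restraints(site),
                 angles = make_angle_restraints(site, include_dictionary_angles),
                 site = site),
            class = "zn_restraint_set")
}

chain_or_placeholder <- function(ch) {
  if (is.na(ch) || !nzchar(trimws(ch))) {
    warning("blank chain id rendered as '.' in external restraint")
    return(".")
  }
  ch
}

sel_txt <- function(chain, resseq, icode, atom, symop) {
  s <- sprintf("chain %s resi %d", chain_or_placeholder(chain), resseq)
  if (nzchar(icode)) s <- paste0(s, sprintf(" ins %s", icode))
  s <- paste0(s, sprintf(" atom %s", atom))
  if (!identical(symop, SYMOP_IDENTITY)) s <- paste0(s, " symm y")
  s
}

#' Render a restraint set as REFMAC external-restraint keywords
#'
#' One `exte dist` line per distance restraint and one `exte angle`
#' line per angle restraint, selectors by chain/residue/atom, values and
#' sigmas printed with three decimals.  Output is deterministic; an
#' empty restraint set renders as empty text.  Atoms reached through a
#' non-identity symmetry operation carry a `symm y` selector.
#'
#' @param rset A `zn_restraint_set` (or a list of them).
#' @return A single character string of keyword lines.
#' @export
render_refmac_external <- function(rset) {
  if (inherits(rset, "zn_restraint_set")) rset <- list(rset)
  out <- character()
  for (rs in rset) {
    d <- rs$distances
    a <- rs$angles
    if ((is.null(d) || !nrow(d)) && (is.null(a) || !nrow(a))) next
    out <- c(out, sprintf("# Zn site %s (%s)", site_label(rs$site),
                          composition_name(rs$site)))
    for (i in seq_len(NROW(d))) {
      out <- c(out, sprintf("exte dist first %s second %s value %.3f sigma %.3f",
                            sel_txt(d$chain1[i], d$resseq1[i], d$icode1[i],
                                    d$atom1[i], d$symop1[i]),
                            sel_txt(d$chain2[i], d$resseq2[i], d$icode2[i],
                                    d$atom2[i], d$symop2[i]),
                            d$target[i], d$sigma[i]))
    }
    for (i in seq_len(NROW(a))) {
      out <- c(out, sprintf("exte angle first %s next %s next %s value %.3f sigma %.3f",
                            sel_txt(a$chain1[i], a$resseq1[i], a$icode1[i],
                                    a$atom1[i], a$symop1[i]),
                            sel_txt(a$chainv[i], a$resseqv[i], a$icodev[i],
                                    a$atomv[i], a$symopv[i]),
                            sel_txt(a$chain3[i], a$resseq3[i], a$icode3[i],
                                    a$atom3[i], a$symop3[i]),
                            a$target[i], a$sigma[i]))
    }
  }
  if (!length(out)) return("")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Parse REFMAC external-restraint text back into a table
#'
#' Round-trip companion to [render_refmac_external()], used to verify
#' that rendered targets and sigmas survive serialization.
#'
#' @param text Keyword text.
#' @return List with `distances` and `angles` data.frames (selector
#'   fields, `target`, `sigma`).
#' @export
parse_refmac_external <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parse_sel <- function(s) {
    m <- regexec(paste0("chain (\\S+) resi (\\d+)(?: ins (\\S+))? atom (\\S+)",
                        "( symm y)?"), s)
    g <- regmatches(s, m)[[1]]
    list(chain = g[2], resseq = as.integer(g[3]),
         icode = ifelse(is.na(g[4]) | g[4] == "", "", g[4]),
         atom = g[5], symm = nzchar(g[6]))
  }
  dists <- list(); angs <- list()
  for (ln in lines) {
    vs <- as.numeric(sub(".*value ([0-9.]+) sigma.*", "\\1", ln))
    sg <- as.numeric(sub(".*sigma ([0-9.]+).*", "\\1", ln))
    if (grepl("^exte dist", ln)) {
      parts <- regmatches(ln, regexec(
        "first (.*) second (.*) value", ln))[[1]]
      s1 <- parse_sel(parts[2]); s2 <- parse_sel(parts[3])
      dists[[length(dists) + 1L]] <- data.frame(
        chain1 = s1$chain, resseq1 = s1$resseq, icode1 = s1$icode,
        atom1 = s1$atom, chain2 = s2$chain, resseq2 = s2$resseq,
        icode2 = s2$icode, atom2 = s2$atom,
        target = vs, sigma = sg, stringsAsFactors = FALSE)
    } else if (grepl("^exte angle", ln)) {
      parts <- regmatches(ln, regexec(
        "first (.*) next (.*) next (.*) value", ln))[[1]]
      s1 <- parse_sel(parts[2]); sv <- parse_sel(parts[3]); s3 <- parse_sel(parts[4])
      angs[[length(angs) + 1L]] <- data.frame(
        chain1 = s1$chain, resseq1 = s1$resseq, atom1 = s1$atom,
        chainv = sv$chain, resseqv = sv$resseq, atomv = sv$atom,
        chain3 = s3$chain, resseq3 = s3$resseq, atom3 = s3$atom,
        target = vs, sigma = sg, stringsAsFactors = FALSE)
    }
  }
  list(distances = if (length(dists)) do.call(rbind, dists) else NULL,
       angles = if (length(angs)) do.call(rbind, angs) else NULL)
}
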