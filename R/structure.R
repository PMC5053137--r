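# Coordinate-file I/O (wwPDB v3.3 fixed columns, minimal mmCIF) and the
# zn_structure container used by every other module.
#
# A zn_structure is a list:
#   atoms   data.frame: record serial atom alt resname chain resseq icode
#                       x y z occ b element charge symop
#   links   data.frame: name1 alt1 resname1 chain1 seq1 icode1
#                       name2 alt2 resname2 chain2 seq2 icode2
#                       sym1 sym2 dist resolved
#   ssbonds data.frame: chain1 seq1 icode1 chain2 seq2 icode2
#                       sym1 sym2 dist resolved
#   cryst   list(a, b, c, alpha, beta, gamma, sgroup) or NULL
#   other   character: unknown header lines preserved for round-trip
#
# symop is "1_555" for the identity copy; pure lattice translations are
# encoded "1_<5+na><5+nb><5+nc>" as in PDB LINK symmetry fields.

SYMOP_IDENTITY <- "1_555"

empty_links <- function() {
  data.frame(name1 = character(), alt1 = character(), resname1 = character(),
             chain1 = character(), seq1 = integer(), icode1 = character(),
             name2 = character(), alt2 = character(), resname2 = character(),
             chain2 = character(), seq2 = integer(), icode2 = character(),
             sym1 = character(), sym2 = character(), dist = numeric(),
             resolved = logical(), stringsAsFactors = FALSE)
}

empty_ssbonds <- function() {
  data.frame(chain1 = character(), seq1 = integer(), icode1 = character(),
             chain2 = character(), seq2 = integer(), icode2 = character(),
             sym1 = character(), sym2 = character(), dist = numeric(),
             resolved = logical(), stringsAsFactors = FALSE)
}

empty_atoms <- function() {
  data.frame(record = character(), serial = integer(), atom = character(),
             alt = character(), resname = character(), chain = character(),
             resseq = integer(), icode = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), element = character(),
             charge = character(), symop = character(),
             stringsAsFactors = FALSE)
}

new_structure <- function(atoms = empty_atoms(), links = empty_links(),
                          ssbonds = empty_ssbonds(), cryst = NULL,
                          other = character()) {
  structure(list(atoms = atoms, links = links, ssbonds = ssbonds,
                 cryst = cryst, other = other),
            class = "zn_structure")
}

#' @export
print.zn_structure <- function(x, ...) {
  cat(sprintf("<zn_structure: %d atoms, %d LINK, %d SSBOND%s>\n",
              nrow(x$atoms), nrow(x$links), nrow(x$ssbonds),
              if (is.null(x$cryst)) "" else paste0(", cell ", x$cryst$sgroup)))
  invisible(x)
}

substr_trim <- function(line, from, to) {
  n <- nchar(line)
  if (from > n) return("")
  trimws(substr(line, from, min(to, n)))
}

num_or_na <- function(s) {
  if (length(s) != 1 || is.na(s)) return(NA_real_)
  s <- trimws(s)
  if (s == "" || s %in% c(".", "?")) return(NA_real_)
  suppressWarnings(as.numeric(s))
}

int_or_na <- function(s) {
  v <- num_or_na(s)
  if (is.na(v)) NA_integer_ else as.integer(v)
}

guess_element <- function(atom_name, resname) {
  nm <- toupper(trimws(atom_name))
  if (nm == "" ) return("")
  if (toupper(trimws(resname)) == "ZN" || nm == "ZN") return("ZN")
  # common two-letter elements found as hetero atoms
  two <- c("FE", "MG", "MN", "CU", "NA", "CL", "BR", "CA2", "SE")
  if (nm %in% c("FE", "MG", "MN", "CU", "CL", "BR", "SE")) return(nm)
  substr(gsub("[^A-Z]", "", nm), 1, 1)
}

parse_atom_line <- function(line) {
  el <- substr_trim(line, 77, 78)
  nm <- substr_trim(line, 13, 16)
  rn <- substr_trim(line, 18, 20)
  if (el == "") el <- guess_element(nm, rn)
  list(record = substr_trim(line, 1, 6),
       serial = int_or_na(substr(line, 7, 11)),
       atom = nm,
       alt = substr_trim(line, 17, 17),
       resname = rn,
       chain = substr_trim(line, 22, 22),
       resseq = int_or_na(substr(line, 23, 26)),
       icode = substr_trim(line, 27, 27),
       x = num_or_na(substr(line, 31, 38)),
       y = num_or_na(substr(line, 39, 46)),
       z = num_or_na(substr(line, 47, 54)),
       occ = num_or_na(substr(line, 55, 60)),
       b = num_or_na(substr(line, 61, 66)),
       element = toupper(el),
       charge = substr_trim(line, 79, 80))
}

parse_link_line <- function(line) {
  list(name1 = substr_trim(line, 13, 16), alt1 = substr_trim(line, 17, 17),
       resname1 = substr_trim(line, 18, 20), chain1 = substr_trim(line, 22, 22),
       seq1 = int_or_na(substr(line, 23, 26)), icode1 = substr_trim(line, 27, 27),
       name2 = substr_trim(line, 43, 46), alt2 = substr_trim(line, 47, 47),
       resname2 = substr_trim(line, 48, 50), chain2 = substr_trim(line, 52, 52),
       seq2 = int_or_na(substr(line, 53, 56)), icode2 = substr_trim(line, 57, 57),
       sym1 = sym_or_identity(substr_trim(line, 60, 65)),
       sym2 = sym_or_identity(substr_trim(line, 67, 72)),
       dist = num_or_na(substr(line, 74, 78)))
}

parse_ssbond_line <- function(line) {
  list(chain1 = substr_trim(line, 16, 16), seq1 = int_or_na(substr(line, 18, 21)),
       icode1 = substr_trim(line, 22, 22),
       chain2 = substr_trim(line, 30, 30), seq2 = int_or_na(substr(line, 32, 35)),
       icode2 = substr_trim(line, 36, 36),
       sym1 = sym_or_identity(substr_trim(line, 60, 65)),
       sym2 = sym_or_identity(substr_trim(line, 67, 72)),
       dist = num_or_na(substr(line, 74, 78)))
}

sym_or_identity <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "1555") return(SYMOP_IDENTITY)
  # normalise "1555" style to "1_555"
  if (grepl("^[0-9]{4,6}$", s)) {
    k <- nchar(s)
    return(paste0(substr(s, 1, k - 3), "_", substr(s, k - 2, k)))
  }
  s
}

parse_cryst1 <- function(line) {
  list(a = num_or_na(substr(line, 7, 15)),
       b = num_or_na(substr(line, 16, 24)),
       c = num_or_na(substr(line, 25, 33)),
       alpha = num_or_na(substr(line, 34, 40)),
       beta = num_or_na(substr(line, 41, 47)),
       gamma = num_or_na(substr(line, 48, 54)),
       sgroup = substr_trim(line, 56, 66))
}

#' Read a macromolecular coordinate file
#'
#' Parses ATOM/HETATM, LINK, SSBOND and CRYST1 records from a PDB file
#' (fixed columns, wwPDB v3.3) or the `atom_site` loop of an mmCIF file.
#' Unknown PDB header records are preserved verbatim so that
#' [write_structure()] round-trips.  Atoms with missing coordinates are
#' dropped with a message.
#'
#' @param path Path to the coordinate file.
#' @param dialect `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `zn_structure` object.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (dialect == "mmcif") return(read_mmcif(path))
  lines <- readLines(path, warn = FALSE)
  rec6 <- toupper(substr(lines, 1, 6))
  is_atom <- rec6 %in% c("ATOM  ", "HETATM")
  is_link <- substr(rec6, 1, 4) == "LINK"
  is_ss <- rec6 == "SSBOND"
  is_cryst <- rec6 == "CRYST1"
  skip <- rec6 %in% c("TER   ", "END   ", "ENDMDL", "MODEL ", "ANISOU",
                      "CONECT", "MASTER") | lines == "END" | lines == ""
  other <- lines[!(is_atom | is_link | is_ss | is_cryst | skip)]

  atoms <- empty_atoms()
  if (any(is_atom)) {
    parsed <- lapply(lines[is_atom], function(l) {
      p <- tryCatch(parse_atom_line(l), error = function(e) {
        stop("unparseable ATOM/HETATM line: ", l, call. = FALSE)
      })
      p
    })
    bad <- vapply(parsed, function(p) anyNA(c(p$x, p$y, p$z)), logical(1))
    if (any(bad)) {
      message(sum(bad), " atom record(s) without coordinates dropped")
      parsed <- parsed[!bad]
    }
    if (length(parsed)) {
      atoms <- do.call(rbind, lapply(parsed, function(p) {
        as.data.frame(p, stringsAsFactors = FALSE)
      }))
      atoms$occ[is.na(atoms$occ)] <- 1
      atoms$b[is.na(atoms$b)] <- 0
      atoms$symop <- SYMOP_IDENTITY
    }
  }
  links <- empty_links()
  if (any(is_link)) {
    links <- do.call(rbind, lapply(lines[is_link], function(l) {
      as.data.frame(parse_link_line(l), stringsAsFactors = FALSE)
    }))
  }
  ssbonds <- empty_ssbonds()
  if (any(is_ss)) {
    ssbonds <- do.call(rbind, lapply(lines[is_ss], function(l) {
      as.data.frame(parse_ssbond_line(l), stringsAsFactors = FALSE)
    }))
  }
  cryst <- if (any(is_cryst)) parse_cryst1(lines[which(is_cryst)[1]]) else NULL
  s <- new_structure(atoms, links, ssbonds, cryst, other)
  resolve_records(s)
}

# Mark link/ssbond rows whose atoms are present in the model.
resolve_records <- function(s) {
  akey <- atom_keys(s$atoms)
  rkey <- paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode, sep = "|")
  if (nrow(s$links)) {
    k1 <- paste(s$links$chain1, s$links$seq1, s$links$icode1, s$links$name1, sep = "|")
    k2 <- paste(s$links$chain2, s$links$seq2, s$links$icode2, s$links$name2, sep = "|")
    s$links$resolved <- k1 %in% akey & k2 %in% akey
  }
  if (nrow(s$ssbonds)) {
    k1 <- paste(s$ssbonds$chain1, s$ssbonds$seq1, s$ssbonds$icode1, sep = "|")
    k2 <- paste(s$ssbonds$chain2, s$ssbonds$seq2, s$ssbonds$icode2, sep = "|")
    s$ssbonds$resolved <- k1 %in% rkey & k2 %in% rkey
  }
  s
}

atom_keys <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, sep = "|")
}

# --- writing ----------------------------------------------------------------

format_atom_name <- function(name, element) {
  name <- trimws(name)
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 2) return(formatC(name, width = -4))
  paste0(" ", formatC(name, width = -3))
}

format_atom_line <- function(a) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%-2s",
          a$record, a$serial %% 100000L,
          format_atom_name(a$atom, a$element), a$alt, a$resname, a$chain,
          a$resseq, a$icode, a$x, a$y, a$z, a$occ, a$b,
          format_element(a$element), a$charge)
}

format_element <- function(el) {
  el <- trimws(el)
  if (nchar(el) == 2) paste0(substr(el, 1, 1), toupper(substr(el, 2, 2))) else el
}

format_sym <- function(s) {
  if (identical(s, SYMOP_IDENTITY)) "1555" else gsub("_", "", s)
}

format_link_line <- function(l, el1 = "", el2 = "") {
  sprintf("LINK        %s%1s%-3s %1s%4d%1s               %s%1s%-3s %1s%4d%1s  %6s %6s %5s",
          format_atom_name(l$name1, el1), l$alt1, l$resname1, l$chain1, l$seq1, l$icode1,
          format_atom_name(l$name2, el2), l$alt2, l$resname2, l$chain2, l$seq2, l$icode2,
          formatC(format_sym(l$sym1), width = 6),
          formatC(format_sym(l$sym2), width = 6),
          if (is.na(l$dist)) "     " else sprintf("%5.2f", l$dist))
}

format_ssbond_line <- function(b, serial) {
  sprintf("SSBOND %3d CYS %1s %4d%1s   CYS %1s %4d%1s  %21s%6s %6s %5s",
          serial, b$chain1, b$seq1, b$icode1, b$chain2, b$seq2, b$icode2, "",
          formatC(format_sym(b$sym1), width = 6),
          formatC(format_sym(b$sym2), width = 6),
          if (is.na(b$dist)) "     " else sprintf("%5.2f", b$dist))
}

format_cryst1 <- function(cr) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
          cr$a, cr$b, cr$c, cr$alpha, cr$beta, cr$gamma, cr$sgroup, 1L)
}

#' Write a structure as a PDB file
#'
#' Fixed-column PDB output: preserved header lines first, then SSBOND,
#' LINK and CRYST1 records, then ATOM/HETATM records (coordinates to
#' three decimals), then END.  Record order is deterministic.
#'
#' @param structure A `zn_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "zn_structure"))
  a <- structure$atoms
  # element lookup for LINK atom-name justification
  elem_of <- function(chain, seq, icode, name) {
    i <- which(a$chain == chain & a$resseq == seq & a$icode == icode & a$atom == name)
    if (length(i)) a$element[i[1]] else ""
  }
  out <- structure$other
  if (nrow(structure$ssbonds)) {
    out <- c(out, vapply(seq_len(nrow(structure$ssbonds)), function(i) {
      format_ssbond_line(structure$ssbonds[i, ], i)
    }, character(1)))
  }
  if (nrow(structure$links)) {
    out <- c(out, vapply(seq_len(nrow(structure$links)), function(i) {
      l <- structure$links[i, ]
      format_link_line(l, elem_of(l$chain1, l$seq1, l$icode1, l$name1),
                       elem_of(l$chain2, l$seq2, l$icode2, l$name2))
    }, character(1)))
  }
  if (!is.null(structure$cryst)) out <- c(out, format_cryst1(structure$cryst))
  if (nrow(a)) {
    out <- c(out, vapply(seq_len(nrow(a)), function(i) format_atom_line(a[i, ]),
                         character(1)))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

# --- minimal mmCIF reader ---------------------------------------------------

read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # cell + space group
  grab <- function(tag) {
    i <- grep(paste0("^", tag, "\\s"), lines)
    if (!length(i)) return(NA)
    trimws(sub(paste0("^", tag, "\\s+"), "", lines[i[1]]))
  }
  cryst <- NULL
  a_len <- num_or_na(as.character(grab("_cell.length_a")))
  if (!is.na(a_len)) {
    sg <- grab("_symmetry.space_group_name_H-M")
    if (is.na(sg)) sg <- "P 1"
    cryst <- list(a = a_len,
                  b = num_or_na(as.character(grab("_cell.length_b"))),
                  c = num_or_na(as.character(grab("_cell.length_c"))),
                  alpha = num_or_na(as.character(grab("_cell.angle_alpha"))),
                  beta = num_or_na(as.character(grab("_cell.angle_beta"))),
                  gamma = num_or_na(as.character(grab("_cell.angle_gamma"))),
                  sgroup = gsub("['\"]", "", sg))
  }
  # atom_site loop
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  atoms <- empty_atoms()
  for (ls in loop_starts) {
    j <- ls + 1
    fields <- character()
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      fields <- c(fields, trimws(lines[j]))
      j <- j + 1
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || grepl("^(#|loop_|_)", ln)) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                        quiet = TRUE)
      j <- j + 1
    }
    fidx <- function(nm) match(paste0("_atom_site.", nm), fields)
    pick <- function(r, nm, alt = NA) {
      i <- fidx(nm)
      if (is.na(i) && !is.na(alt)) i <- fidx(alt)
      if (is.na(i) || i > length(r)) return("")
      v <- r[[i]]
      if (v %in% c(".", "?")) "" else v
    }
    parsed <- lapply(rows, function(r) {
      el <- toupper(pick(r, "type_symbol"))
      rn <- pick(r, "auth_comp_id", "label_comp_id")
      nm <- pick(r, "auth_atom_id", "label_atom_id")
      if (el == "") el <- guess_element(nm, rn)
      data.frame(record = if (identical(pick(r, "group_PDB"), "HETATM")) "HETATM" else "ATOM",
                 serial = int_or_na(pick(r, "id")),
                 atom = gsub('"', "", nm), alt = pick(r, "label_alt_id"),
                 resname = rn,
                 chain = pick(r, "auth_asym_id", "label_asym_id"),
                 resseq = int_or_na(pick(r, "auth_seq_id", "label_seq_id")),
                 icode = pick(r, "pdbx_PDB_ins_code"),
                 x = num_or_na(pick(r, "Cartn_x")),
                 y = num_or_na(pick(r, "Cartn_y")),
                 z = num_or_na(pick(r, "Cartn_z")),
                 occ = num_or_na(pick(r, "occupancy")),
                 b = num_or_na(pick(r, "B_iso_or_equiv")),
                 element = el, charge = "",
                 symop = SYMOP_IDENTITY,
                 stringsAsFactors = FALSE)
    })
    atoms <- do.call(rbind, parsed)
    bad <- is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)
    if (any(bad)) {
      message(sum(bad), " atom record(s) without coordinates dropped")
      atoms <- atoms[!bad, , drop = FALSE]
    }
    atoms$occ[is.na(atoms$occ)] <- 1
    atoms$b[is.na(atoms$b)] <- 0
    break
  }
  resolve_records(new_structure(atoms, cryst = cryst))
}

# --- views used for geometry ------------------------------------------------

# Highest-occupancy alternate per atom (ties -> first in file), no H/D.
geometry_atoms <- function(structure) {
  a <- structure$atoms
  if (!nrow(a)) return(a)
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(a)) return(a)
  key <- atom_keys(a)
  ord <- order(key, -a$occ, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(atom_keys(a)), , drop = FALSE]
  a[order(as.integer(rownames(a))), , drop = FALSE]
}

# --- symmetry ---------------------------------------------------------------

cell_vectors <- function(cr) {
  d2r <- pi / 180
  al <- cr$alpha * d2r; be <- cr$beta * d2r; ga <- cr$gamma * d2r
  va <- c(cr$a, 0, 0)
  vb <- c(cr$b * cos(ga), cr$b * sin(ga), 0)
  cx <- cr$c * cos(be)
  cy <- cr$c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cr$c^2 - cx^2 - cy^2, 0))
  vc <- c(cx, cy, cz)
  rbind(va, vb, vc)
}

#' Atoms within a radius of a point, optionally with symmetry mates
#'
#' For structures with a P1 unit cell the 26 neighbouring lattice
#' translations are considered; the applied translation is recorded in
#' the `symop` column ("1_555" is the identity).  Other space groups are
#' not supported: a warning is emitted and only the identity copy is
#' searched.
#'
#' @param structure A `zn_structure`.
#' @param centre Numeric length-3 point (angstrom).
#' @param radius Search radius (angstrom).
#' @return A data.frame of atoms (geometry view: no hydrogens, single
#'   conformer) within `radius` of `centre`.
#' @export
symmetry_expand <- function(structure, centre, radius) {
  a <- geometry_atoms(structure)
  within <- function(df) {
    if (!nrow(df)) return(df)
    d <- sqrt((df$x - centre[1])^2 + (df$y - centre[2])^2 + (df$z - centre[3])^2)
    df[d <= radius, , drop = FALSE]
  }
  base <- within(a)
  cr <- structure$cryst
  if (is.null(cr) || is.na(cr$a)) return(base)
  sg <- toupper(gsub(" ", "", cr$sgroup))
  if (!sg %in% c("P1", "")) {
    warning("space group '", cr$sgroup,
            "' not supported for symmetry expansion; identity copy only")
    return(base)
  }
  vecs <- cell_vectors(cr)
  out <- list(base)
  for (na_ in -1:1) for (nb in -1:1) for (nc in -1:1) {
    if (na_ == 0 && nb == 0 && nc == 0) next
    shift <- na_ * vecs[1, ] + nb * vecs[2, ] + nc * vecs[3, ]
    mate <- a
    mate$x <- mate$x + shift[1]
    mate$y <- mate$y + shift[2]
    mate$z <- mate$z + shift[3]
    mate$symop <- sprintf("1_%d%d%d", 5 + na_, 5 + nb, 5 + nc)
    out[[length(out) + 1L]] <- within(mate)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Apply the lattice translation encoded in a symop string to a position.
apply_symop <- function(pos, symop, cryst) {
  if (identical(symop, SYMOP_IDENTITY) || is.null(cryst)) return(pos)
  m <- regmatches(symop, regexec("^1_([0-9])([0-9])([0-9])$", symop))[[1]]
  if (length(m) != 4) return(pos)
  vecs <- cell_vectors(cryst)
  sh <- (as.integer(m[2]) - 5) * vecs[1, ] +
    (as.integer(m[3]) - 5) * vecs[2, ] +
    (as.integer(m[4]) - 5) * vecs[3, ]
  pos + sh
}
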