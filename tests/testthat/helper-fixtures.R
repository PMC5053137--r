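# Shared helpers for the znsite test suite.  All fixtures are built in
# code; nothing is read from disk except files the tests write.

ALL_COMPOSITIONS <- c("Cys4", "Cys3His1", "Cys2His2", "Cys1His3", "His4")

ideal_site <- function(composition, ...) {
  build_site(site_spec(composition, ...))
}

# Independent brute-force Dixon filter: sort, apply gap/range against
# the critical table, drop the largest while rejected and n > 4.
oracle_q_filter <- function(d, level = 0.95) {
  d <- sort(d)
  if (length(d) < 5) return(d)
  repeat {
    n <- length(d)
    if (n <= 4) break
    rng <- d[n] - d[1]
    q <- if (rng == 0) 0 else (d[n] - d[n - 1]) / rng
    if (q > dixon_q_critical(n, level)) d <- d[-n] else break
  }
  d
}

# Candidate data.frame from a bare distance vector (for Q-test tests).
fake_candidates <- function(d) {
  n <- length(d)
  data.frame(chain = rep("A", n), resseq = seq_len(n) * 10L,
             icode = "", resname = "CYS", atom = "SG",
             ligand_class = "SG", dist = d,
             x = d, y = 0, z = 0, symop = "1_555",
             stringsAsFactors = FALSE)
}

# Mean per-site rmsz of a structure (all accepted sites, NA-safe).
mean_site_rmsz <- function(structure) {
  vs <- validate_structure(structure)
  if (!length(vs$reports)) return(NA_real_)
  mean(vapply(vs$reports, function(r) r$rmsz, numeric(1)), na.rm = TRUE)
}

composition_key_of <- function(site) {
  x <- site$composition[["cys"]]
  y <- site$composition[["his"]]
  paste0(if (x > 0) paste0("Cys", x) else "",
         if (y > 0) paste0("His", y) else "")
}

random_rigid_motion <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, sd = 10))
}
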