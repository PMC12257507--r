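# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no stored data files.

# Write a fixed-column PDB file from a record table (coordinates in
# Angstrom). Used to build tiny hand-written structures with known
# content, independently of the package's writer.
write_fixture_pdb <- function(path, records) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$type, r$serial, r$name, r$alt, r$resid, r$chain, r$resno,
            r$x, r$y, r$z, r$occ, 0, r$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

pdb_record <- function(serial, name, resid, chain, resno, x, y, z,
                       type = "ATOM", alt = " ", occ = 1,
                       element = substr(trimws(name), 1, 1)) {
  data.frame(type = type, serial = serial, name = name, alt = alt,
             resid = resid, chain = chain, resno = resno,
             x = x, y = y, z = z, occ = occ, element = element,
             stringsAsFactors = FALSE)
}

# three ATOM records at (0,0,0), (10,0,0), (0,10,0) Angstrom plus one
# HETATM water
three_atom_fixture <- function(path, with_water = TRUE) {
  rec <- rbind(
    pdb_record(1, " N  ", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_record(2, " CA ", "ALA", "A", 1, 10, 0, 0, element = "C"),
    pdb_record(3, " C  ", "ALA", "A", 1, 0, 10, 0, element = "C")
  )
  if (with_water) {
    rec <- rbind(rec, pdb_record(4, " O  ", "HOH", "A", 9, 5, 5, 5,
                                 type = "HETATM", element = "O"))
  }
  write_fixture_pdb(path, rec)
}

# independent exhaustive minimum cross-pair distance (plain distance
# matrix; no shared code with the package's grid index)
oracle_min_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

# independent one-site equilibrium: bound-titrant concentration solved
# numerically with uniroot from the mass-action law, never the closed
# form used by the package
oracle_bound_conc <- function(NM, X, K) {
  if (X <= 0 || NM <= 0) return(0)
  f <- function(Xb) K * (NM - Xb) * (X - Xb) - Xb
  stats::uniroot(f, c(0, min(NM, X)), tol = 1e-14)$root
}

# cumulative heat after each injection from the numerical equilibrium
# oracle, using the same displacement convention as the schedule
oracle_cumulative_heats <- function(params, schedule) {
  v <- cumsum(schedule$injection_volumes)
  V0 <- schedule$cell_volume
  M <- schedule$cell_conc0 * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  X <- schedule$syringe_conc * (v / V0) / (1 + v / (2 * V0))
  vapply(seq_along(v), function(i) {
    params$dH * V0 * oracle_bound_conc(params$N * M[i], X[i], params$K)
  }, numeric(1))
}

# uniform random point on the 2-simplex (for CD recovery sweeps)
random_simplex_point <- function() {
  e <- -log(runif(3))
  e / sum(e)
}
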