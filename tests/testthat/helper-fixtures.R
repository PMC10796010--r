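# Shared fixtures and independent oracles (brute-force reference
# implementations kept deliberately separate from the package's own
# algorithms).

# ---- PDB text fixtures -------------------------------------------------

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", record = "ATOM  ",
                          atom = " CA ") {
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, atom, alt, resname, chain, resno, x, y, z,
          occ, 0)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

two_residue_pdb <- function() {
  write_fixture_pdb(c(
    pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0)))
}

# three chains x three residues, author numbering offset by 27 on chain B
offset_pdb <- function() {
  lines <- c(
    pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "LYS", "A", 3, 7.6, 0, 0),
    "TER",
    pdb_atom_line(4, "MET", "B", 28, 0, 5, 0),
    pdb_atom_line(5, "SER", "B", 29, 3.8, 5, 0),
    pdb_atom_line(6, "THR", "B", 30, 7.6, 5, 0),
    pdb_atom_line(7, "VAL", "B", 31, 11.4, 5, 0))
  write_fixture_pdb(lines)
}

multimodel_pdb <- function(n_models = 3) {
  lines <- unlist(lapply(seq_len(n_models), function(m) {
    c(sprintf("MODEL     %4d", m),
      pdb_atom_line(1, "ALA", "A", 1, m, 0, 0),
      pdb_atom_line(2, "GLY", "A", 2, m + 3.8, 0, 0),
      pdb_atom_line(3, "LEU", "A", 3, m + 7.6, 0, 0),
      "ENDMDL")
  }))
  write_fixture_pdb(lines)
}

altloc_pdb <- function() {
  write_fixture_pdb(c(
    pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "GLY", "A", 2, 1.0, 0, 0, occ = 0.3, alt = "A"),
    pdb_atom_line(3, "GLY", "A", 2, 2.0, 0, 0, occ = 0.7, alt = "B"),
    pdb_atom_line(4, "LYS", "A", 3, 7.6, 0, 0)))
}

# ---- random rigid transforms ------------------------------------------

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_transform <- function(x, R = random_rotation(),
                            t = rnorm(3, sd = 10)) {
  sweep(x %*% R, 2, -t)
}

# ---- brute-force minimum-RMSD oracle ----------------------------------
# Nested grid search over Euler angles (zyz); translation handled by
# centring.  Independent of the SVD route.

euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

oracle_min_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  rmsd_at <- function(a, b, c) sqrt(mean(rowSums((P %*% t(euler_rot(a, b, c)) - Q)^2)))
  best <- c(0, 0, 0); best_val <- Inf
  step <- pi / 12
  grid <- list(a = seq(0, 2 * pi, by = step), b = seq(0, pi, by = step),
               c = seq(0, 2 * pi, by = step))
  for (a in grid$a) for (b in grid$b) for (c in grid$c) {
    v <- rmsd_at(a, b, c)
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  for (lvl in 1:4) {
    rng <- step; step <- step / 5
    for (a in seq(best[1] - rng, best[1] + rng, by = step))
      for (b in seq(best[2] - rng, best[2] + rng, by = step))
        for (c in seq(best[3] - rng, best[3] + rng, by = step)) {
          v <- rmsd_at(a, b, c)
          if (v < best_val) { best_val <- v; best <- c(a, b, c) }
        }
  }
  best_val
}

# ---- exhaustive global-alignment oracle -------------------------------
# Enumerates every global alignment path and scores it from scratch with
# the package's gap convention (gap of length L costs
# gap_open + (L - 1) * gap_extend).  Exponential; lengths <= 6 only.

oracle_nw_score <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pair_score <- function(x, y) if (x == y) scheme$match else scheme$mismatch
  best <- -Inf
  recurse <- function(i, j, score, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1, j + 1, score + pair_score(ca[i], cb[j]), "d")
    if (i <= length(ca))
      recurse(i + 1, j, score + if (last == "u") scheme$gap_extend
              else scheme$gap_open, "u")
    if (j <= length(cb))
      recurse(i, j + 1, score + if (last == "l") scheme$gap_extend
              else scheme$gap_open, "l")
  }
  recurse(1, 1, 0, "none")
  best
}

random_aa <- function(n) {
  paste(sample(setdiff(aa_alphabet(), "X"), n, replace = TRUE),
        collapse = "")
}
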