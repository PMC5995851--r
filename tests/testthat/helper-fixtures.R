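# fixture builders and independent oracles shared across the test files.
# Everything here is deliberately naive (loops, enumeration, closed forms)
# so it stays independent of the package's own code paths.

# --- phosphoform cycle ------------------------------------------------------

# explicit Euler integration of the cycle; checkpoints must be multiples of h
euler_cycle <- function(rates, initial, checkpoints, h = 1e-4) {
  k <- unlist(unclass(rates))
  M <- diag(-k)
  for (i in 1:4) M[if (i == 4) 1 else i + 1, i] <- k[i]
  A <- matrix(NA_real_, length(checkpoints), 4)
  a <- initial
  t <- 0
  for (j in seq_along(checkpoints)) {
    nstep <- round((checkpoints[j] - t) / h)
    for (s in seq_len(nstep)) a <- a + h * as.numeric(M %*% a)
    t <- checkpoints[j]
    A[j, ] <- a
  }
  A
}

# --- structures -------------------------------------------------------------

# small synthetic protein-like fragment: `n` glycine residues along a helix-ish
# curve, backbone only
make_toy_model <- function(n = 10, chain = "A", seed = 42) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- c(3.8 * i, 2 * sin(i), 2 * cos(i))
    data.frame(chain = chain, resno = i, ins = "", resid = "GLY",
               elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = base[1] + c(0, 1.4, 2.4, 3.0),
               y = base[2] + c(0, 0.5, 0.1, 1.2),
               z = base[3] + c(0, 0.3, 1.0, 1.1))
  }))
  structure_model(atoms, source = "toy")
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

transform_model <- function(model, R, shift) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]; a$y <- xyz[, 2] + shift[2]; a$z <- xyz[, 3] + shift[3]
  structure_model(a, source = paste0(model$source, "-moved"))
}

# exhaustive Euler-angle grid search for the optimal superposition RMSD,
# iteratively refined; independent of the SVD route
grid_search_rmsd <- function(P, Q, rounds = 7, halfwidth = pi, n = 9) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  centre <- c(0, 0, 0)
  best <- Inf
  for (r in seq_len(rounds)) {
    gx <- centre[1] + seq(-halfwidth, halfwidth, length.out = n)
    gy <- centre[2] + seq(-halfwidth, halfwidth, length.out = n)
    gz <- centre[3] + seq(-halfwidth / 2, halfwidth / 2, length.out = n)
    for (ax in gx) for (ay in gy) for (az in gz) {
      d <- Qc - Pc %*% t(rotation_matrix(ax, ay, az))
      v <- sqrt(mean(rowSums(d^2)))
      if (v < best) { best <- v; centre <- c(ax, ay, az) }
    }
    halfwidth <- halfwidth / (n - 1) * 2.5
  }
  best
}

# hand-written minimal PDB / mmCIF renderings of the same atom list
write_tiny_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$elety, a$resid, a$chain, a$resno, a$x, a$y, a$z, 1.0, 0.0,
            a$elesy)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_tiny_cif <- function(atoms, path) {
  header <- c(
    "data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
            i, a$elesy, a$elety, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
  }, character(1))
  writeLines(c(header, rows, "#"), path)
  path
}

tiny_atom_df <- function() {
  data.frame(chain = "A", resno = c(1, 1, 2), ins = "",
             resid = c("GLY", "GLY", "ALA"),
             elety = c("N", "CA", "CA"), elesy = c("N", "C", "C"),
             x = c(1.25, 2.5, -3.75), y = c(0.5, 1.5, 2.25),
             z = c(-1.5, 0.25, 3.5))
}

# accessible area of two overlapping equal spheres of radius R at distance d:
# each loses a spherical cap of height h = R - d/2 (area 2*pi*R*h)
two_sphere_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# --- binding ----------------------------------------------------------------

# synthetic relaxation curve from a closed-form trace
fake_curve <- function(times, fi) list(times = times, fi_app = fi)

# analytic CS profile with multiplicative noise, as a kobs_profile
noisy_cs_profile <- function(k_cf, k_cr, kd, b_grid, sigma, seed) {
  set.seed(seed)
  y <- analytic_kobs_cs(k_cf, k_cr, kd, b_grid) * (1 + rnorm(length(b_grid), 0, sigma))
  as_kobs_profile(b_grid, y)
}
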