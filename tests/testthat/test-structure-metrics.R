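test_that("a handcrafted PDB fixture parses to known coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(tiny_atom_df(), path)
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x, c(1.25, 2.5, -3.75), tolerance = 1e-9)
  expect_equal(m$atoms$resno, c(1, 1, 2))
  expect_equal(m$atoms$elety, c("N", "CA", "CA"))
  expect_false(any(m$atoms$het))
})

test_that("PDB and mmCIF renderings of the same model parse identically", {
  df <- tiny_atom_df()
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".cif")
  write_tiny_pdb(df, p1)
  write_tiny_cif(df, p2)
  a <- load_structure(p1)$atoms
  b <- load_structure(p2)$atoms
  cols <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  expect_equal(a[, cols], b[, cols], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("structures survive a write/read round trip to 1e-3 Angstrom", {
  m <- make_toy_model(6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- load_structure(path)
  expect_lt(max(abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                      as.matrix(m2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("malformed structure files raise a parse error", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("this is", "not a structure"), path)
  expect_error(load_structure(path, format = "cif"),
               class = "kaicdyn_parse_error")
})

test_that("RMSD is zero for identical structures and rigid-motion copies", {
  m <- make_toy_model(10)
  expect_equal(kabsch_rmsd(m, m)$rmsd, 0, tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:8) {
    R <- rotation_matrix(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    moved <- transform_model(m, R, runif(3, -20, 20))
    expect_equal(kabsch_rmsd(m, moved)$rmsd, 0, tolerance = 1e-9)
    # and invariance: transforming one input never changes the optimum
    noisy <- make_toy_model(10, seed = 31 + rep)
    expect_equal(kabsch_rmsd(noisy, m)$rmsd,
                 kabsch_rmsd(transform_model(noisy, R, c(1, -2, 3)), m)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("Kabsch optimum matches an exhaustive rotation-grid search", {
  set.seed(12)
  for (rep in 1:3) {
    P <- matrix(rnorm(12, sd = 3), 4, 3)
    Q <- matrix(rnorm(12, sd = 3), 4, 3)
    df <- function(X) data.frame(chain = "A", resno = 1:4, ins = "",
                                 resid = "GLY", elety = c("N", "CA", "C", "O"),
                                 elesy = c("N", "C", "C", "O"),
                                 x = X[, 1], y = X[, 2], z = X[, 3])
    res <- kabsch_rmsd(structure_model(df(P)), structure_model(df(Q)))
    expect_equal(res$rmsd, grid_search_rmsd(P, Q), tolerance = 1e-4)
    # cross-check against an established superposition routine
    bf <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
    rmsd_bio3d <- sqrt(mean(colSums(matrix(bf - as.vector(t(Q)), 3)^2)))
    expect_equal(res$rmsd, rmsd_bio3d, tolerance = 1e-6)
  }
})

test_that("no common atoms raises a pairing error", {
  a <- make_toy_model(4, chain = "A")
  b <- make_toy_model(4, chain = "B")
  bb <- b$atoms; bb$resno <- bb$resno + 100
  expect_error(kabsch_rmsd(a, structure_model(bb)),
               class = "kaicdyn_pairing_error")
})

one_atom <- function(x = 0, y = 0, z = 0, elety = "CA", elesy = "C",
                     resno = 1, chain = "A") {
  data.frame(chain = chain, resno = resno, ins = "", resid = "GLY",
             elety = elety, elesy = elesy, x = x, y = y, z = z)
}

test_that("SASA of isolated and separated atoms equals the sphere area", {
  m1 <- structure_model(one_atom())
  expect_equal(residue_sasa(m1)$sasa, 4 * pi * (1.70 + 1.4)^2,
               tolerance = 1e-6)
  # two far-apart atoms: independent full spheres (O radius 1.52)
  m2 <- structure_model(rbind(one_atom(), one_atom(x = 50, elety = "O",
                                                   elesy = "O", resno = 2)))
  s <- residue_sasa(m2)
  expect_equal(s$sasa, 4 * pi * (c(1.70, 1.52) + 1.4)^2, tolerance = 1e-6)
})

test_that("overlapping equal spheres match the spherical-cap closed form", {
  R <- 1.70 + 1.4
  for (d in c(1.5, 2.5, 4.0)) {
    m <- structure_model(rbind(one_atom(), one_atom(x = d, resno = 2)))
    total <- sum(residue_sasa(m)$sasa)
    expect_lt(abs(total - two_sphere_area(R, d)) / two_sphere_area(R, d), 0.01)
  }
})

test_that("adding atoms never increases any residue's SASA and burial is non-negative", {
  set.seed(9)
  base <- make_toy_model(5, chain = "A")
  s0 <- residue_sasa(base)
  extra <- do.call(rbind, lapply(1:10, function(i)
    one_atom(runif(1, 0, 20), runif(1, -3, 3), runif(1, -3, 3),
             resno = i, chain = "B")))
  grown <- structure_model(rbind(base$atoms[, names(extra)], extra))
  s1 <- residue_sasa(grown)
  a_rows <- s1$chain == "A"
  expect_true(all(s1$sasa[a_rows] <= s0$sasa + 1e-6))
  for (res in c(2, 4)) {
    bur <- assembly_burial(grown, "A", res)
    expect_gte(bur$delta, -1e-9)
    expect_equal(bur$sasa_assembly, s1$sasa[s1$chain == "A" & s1$resno == res],
                 tolerance = 1e-9)
  }
})

test_that("a residue engulfed by the partner chain loses all accessibility", {
  # cage: partner atoms on a dense sphere around a single CA
  pts <- kaicdyn:::sphere_points(80) * 3.4
  cage <- data.frame(chain = "B", resno = seq_len(80), ins = "", resid = "GLY",
                     elety = "CA", elesy = "C",
                     x = pts[, 1], y = pts[, 2], z = pts[, 3])
  dimer <- structure_model(rbind(one_atom(), cage))
  bur <- assembly_burial(dimer, "A", 1)
  expect_equal(bur$sasa_isolated, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  expect_lt(bur$sasa_assembly, 1e-6)
  expect_equal(bur$delta, bur$sasa_isolated, tolerance = 1e-6)
  # a residue far from any interface is untouched
  far <- structure_model(rbind(one_atom(x = 100), cage))
  bur_far <- assembly_burial(far, "A", 1)
  expect_lt(abs(bur_far$delta), 1e-9)
})

test_that("quadrature at 960 points agrees with 4000 points within 2%", {
  m <- make_toy_model(8)
  s960 <- residue_sasa(m, n_points = 960)$sasa
  s4000 <- residue_sasa(m, n_points = 4000)$sasa
  expect_lt(max(abs(s960 - s4000) / pmax(s4000, 1)), 0.02)
})

test_that("unknown elements error unless an override radius is supplied", {
  m <- structure_model(one_atom(elety = "FE", elesy = "FE"))
  expect_error(residue_sasa(m), class = "kaicdyn_radius_error")
  s <- residue_sasa(m, radii = c(FE = 1.6))
  expect_equal(s$sasa, 4 * pi * (1.6 + 1.4)^2, tolerance = 1e-6)
})

test_that("minimum distances match brute force", {
  m2 <- structure_model(rbind(one_atom(), one_atom(x = 3, y = 4, resno = 2,
                                                   chain = "B")))
  expect_equal(min_distance(m2, "A", 1, "CA",
                            atom_selection(chains = "A")), 0)
  expect_equal(min_distance(m2, "A", 1, "CA", "B"), 5)
  set.seed(14)
  cloud <- data.frame(chain = "B", resno = seq_len(100), ins = "",
                      resid = "GLY", elety = "CA", elesy = "C",
                      x = rnorm(100, 10, 5), y = rnorm(100, 0, 5),
                      z = rnorm(100, 0, 5))
  m <- structure_model(rbind(one_atom(), cloud))
  brute <- min(sqrt(cloud$x^2 + cloud$y^2 + cloud$z^2))
  expect_equal(min_distance(m, "A", 1, "CA", "B"), brute, tolerance = 1e-12)
  expect_error(min_distance(m, "A", 99, "CA", "B"),
               class = "kaicdyn_selection_error")
})
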