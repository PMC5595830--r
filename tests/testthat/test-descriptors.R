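test_that("pair-distance descriptor count is n(n-1)/2 and families assemble", {
  topo <- kinflow:::toy_topology(120)
  for (n in c(5L, 10L, 25L)) {
    ds <- build_descriptor_set(topo, selection = seq_len(n))
    expect_equal(nrow(ds), n * (n - 1) / 2)
  }
  ds <- build_descriptor_set(topo, selection = 1:5, ligand_range = c(10, 29))
  expect_equal(sum(ds$kind == "ligand_contact"), 20L)
  expect_error(build_descriptor_set(topo, selection = integer(0)), "empty")
})

test_that("sidechain contact pairs are discovered from reference structures", {
  atoms <- data.frame(serial = 1:3, name = "CB", element = "C", resno = 1:3,
                      resname = "ALA", chain = "A", is_ligand = FALSE,
                      stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0))
  colnames(xyz) <- c("x", "y", "z")
  ref <- structure(list(atoms = atoms, xyz = xyz, source = "f"),
                   class = "mol_structure")
  ds <- build_descriptor_set(ref, selection = 1:3, references = list(ref))
  sc <- ds[ds$kind == "sidechain_contact", ]
  expect_equal(nrow(sc), 1L)
  expect_equal(c(sc$res_a, sc$res_b), c(1L, 2L))
  # a second reference with a different contact adds the union
  xyz2 <- xyz; xyz2[3, 1] <- 6.5
  ref2 <- structure(list(atoms = atoms, xyz = xyz2, source = "f"),
                    class = "mol_structure")
  ds2 <- build_descriptor_set(ref, 1:3, references = list(ref, ref2))
  expect_equal(sum(ds2$kind == "sidechain_contact"), 3L)
})

test_that("contact columns switch strictly at the 7 A cutoff", {
  st <- two_residue_structure(gap = 6.9)
  ds <- build_descriptor_set(st, selection = 1:2, references = list(st))
  expect_equal(sum(ds$kind == "sidechain_contact"), 1L)
  f <- compute_features(single_frame_ensemble(st), ds)
  sc_col <- which(ds$kind == "sidechain_contact")
  expect_equal(unname(f$values[[1]][1, sc_col]), 1)
  st2 <- two_residue_structure(gap = 7.1)
  f2 <- compute_features(single_frame_ensemble(st2), ds)
  expect_equal(unname(f2$values[[1]][1, sc_col]), 0)
})

test_that("distances are exact and contacts invariant to rigid motion", {
  st <- two_residue_structure(gap = 5.0)
  # move residue 2 C-alpha so the CA-CA distance is exactly 5
  st$xyz[4, ] <- c(1, 0, 0)
  ds <- build_descriptor_set(st, selection = 1:2, references = list(st))
  f0 <- compute_features(single_frame_ensemble(st), ds)
  expect_equal(unname(f0$values[[1]][1, "ca_1_2"]), 5.0, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:5) {
    th <- runif(3, 0, 2 * pi); tr <- rnorm(3, sd = 20)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, byrow = TRUE)
    st_r <- st
    st_r$xyz <- sweep(st$xyz %*% t(Rz %*% Rx), 2, tr, "+")
    f1 <- compute_features(single_frame_ensemble(st_r), ds)
    expect_equal(unname(f1$values[[1]]), unname(f0$values[[1]]),
                 tolerance = 1e-9)
  }
})

test_that("pair_distance modes agree with hand-computed geometry", {
  st <- two_residue_structure(gap = 3.30)
  expect_equal(pair_distance(st, 1, 2, mode = "min_sidechain"), 3.30,
               tolerance = 1e-12)
  expect_equal(pair_distance(st, 1, 2, mode = "ca"),
               abs(unname(st$xyz[1, 1] - st$xyz[4, 1])), tolerance = 1e-12)
  st$xyz[4, ] <- st$xyz[1, ]
  expect_equal(pair_distance(st, 1, 2, mode = "ca"), 0)
  expect_error(pair_distance(st, 1, 9, mode = "ca"), "residue")
})

test_that("segment RMSD is superposition-invariant and matches the formula", {
  topo <- kinflow:::toy_topology(12)
  ref <- topo
  # displaced segment atom: RMSD = 0.6 / sqrt(6)
  arr <- array(0, dim = c(1, 12, 3)); arr[1, , ] <- ref$xyz
  arr[1, 7, 2] <- arr[1, 7, 2] + 0.6
  tr <- trajectory_ensemble(topo, list(arr), 1)
  r <- segment_rmsd(tr, ref, segment = c(7, 12), fit_selection = 1:6)
  expect_equal(r$values[[1]][1], 0.6 / sqrt(6), tolerance = 1e-9)
  # identity and rigid transforms give zero
  arr0 <- array(0, dim = c(1, 12, 3)); arr0[1, , ] <- ref$xyz
  expect_lt(segment_rmsd(trajectory_ensemble(topo, list(arr0), 1), ref,
                         c(7, 12))$values[[1]][1], 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  arr1 <- array(0, dim = c(1, 12, 3))
  arr1[1, , ] <- sweep(ref$xyz %*% t(R), 2, c(5, -3, 2), "+")
  expect_lt(segment_rmsd(trajectory_ensemble(topo, list(arr1), 1), ref,
                         c(7, 12))$values[[1]][1], 1e-9)
  expect_error(segment_rmsd(tr, ref, c(40, 45)), "missing")
})

test_that("hydrogen bond detection applies distance and angle criteria", {
  atoms <- data.frame(serial = 1:5, name = c("OG", "HG", "CB", "OD1", "CG"),
                      element = c("O", "H", "C", "O", "C"),
                      resno = c(1, 1, 1, 2, 2),
                      resname = c("SER", "SER", "SER", "ASN", "ASN"),
                      chain = "A", is_ligand = FALSE, stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1.4, 0, 0),
               c(2.9, 0, 0), c(4.1, 0, 0))
  colnames(xyz) <- c("x", "y", "z")
  st <- structure(list(atoms = atoms, xyz = xyz, source = "f"),
                  class = "mol_structure")
  expect_equal(detect_hbond(st, 1, 2), 1L)        # 2.9 A, linear
  st_far <- st; st_far$xyz[4, ] <- c(5, 0, 0)
  expect_equal(detect_hbond(st_far, 1, 2), 0L)    # 5.0 A
  st_bent <- st; st_bent$xyz[4, ] <- c(0, 3.4, 0) # 3.4 A but D-H...A ~74 deg
  expect_equal(detect_hbond(st_bent, 1, 2), 0L)
  # apolar residue cannot act as donor
  st_ala <- st
  st_ala$atoms$resname[1:3] <- "ALA"
  st_ala$atoms$name[1:3] <- c("CB", "HB1", "CG1")
  st_ala$atoms$element[1] <- "C"
  expect_error(detect_hbond(st_ala, 1, 2), "donor")
})
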