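test_that("PDB round-trip preserves atoms, order and coordinates to 3 dp", {
  spec <- toy_complex_spec(seed = 11)
  cx <- build_toy_complex(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, path)
  back <- read_pdb(path)
  expect_s3_class(back, "molecular_system")
  expect_equal(n_atoms(back), n_atoms(cx))
  expect_equal(back$atoms$name, cx$atoms$name)
  expect_equal(back$atoms$resname, cx$atoms$resname)
  expect_equal(back$atoms$resid, cx$atoms$resid)
  expect_equal(coords(back), round(coords(cx), 3), ignore_attr = TRUE)
  # parameters are placeholders until assigned
  expect_true(all(is.na(back$atoms$charge)))

  traj <- generate_trajectory(cx, spec, 3)
  tpath <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, tpath)
  tback <- read_pdb(tpath)
  expect_s3_class(tback, "trajectory")
  expect_equal(n_frames(tback), 3)
  expect_equal(n_atoms(tback), n_atoms(cx))
  for (f in 1:3) {
    expect_equal(tback$frames[[f]], round(traj$frames[[f]], 3),
                 ignore_attr = TRUE)
  }
})

test_that("single-atom and multi-model toy files parse with correct shapes", {
  one <- point_system(rbind(c(1.234, -2.5, 3.75)), charge = 0)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(one, p1)
  r1 <- read_pdb(p1)
  expect_equal(n_atoms(r1), 1)
  expect_equal(as.numeric(coords(r1)), c(1.234, -2.5, 3.75))

  five <- point_system(matrix(seq(0, 28, by = 2), 5, 3), charge = numeric(5))
  traj <- trajectory(five, lapply(1:3, function(i) coords(five) + i))
  p3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, p3)
  r3 <- read_pdb(p3)
  expect_equal(n_frames(r3), 3)
  expect_equal(n_atoms(r3), 5)
})

test_that("malformed and structurally inconsistent PDB input is rejected", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       garbage", "END"), bad)
  expect_error(read_pdb(bad), "line 1")

  uneq <- withr::local_tempfile(fileext = ".pdb")
  a <- "ATOM      1  CA  ALA A   1       1.000   1.000   1.000  1.00  0.00           C"
  writeLines(c("MODEL     1", a, a, "ENDMDL",
               "MODEL     2", a, "ENDMDL", "END"), uneq)
  expect_error(read_pdb(uneq), "differing atom counts")

  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("nm input coordinates are converted to Angstrom on request", {
  sys <- point_system(rbind(c(1.0, 2.0, 3.0)), charge = 0)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, p)
  expect_equal(as.numeric(coords(read_pdb(p, units = "nm"))), c(10, 20, 30))
})

test_that("coordinates outside the PDB fixed-column range refuse to format", {
  sys <- point_system(rbind(c(123456, 0, 0)), charge = 0)
  expect_error(write_pdb(sys, withr::local_tempfile()), "range")
})

test_that("assign_parameters uses pair-then-element precedence and is idempotent", {
  tab <- data.frame(
    resname = c("LIG", NA, NA), atom = c("N1", NA, NA),
    element = c("N", "N", "C"),
    charge = c(-0.5, -0.4, 0.1),
    lj_epsilon = c(0.17, 0.17, 0.1),
    lj_rmin_half = c(1.8, 1.8, 1.9),
    boundary_radius = c(1.8, 1.8, 1.9),
    stringsAsFactors = FALSE
  )
  sys <- molecular_system(data.frame(
    name = c("N1", "N2", "CA"), element = c("N", "N", "C"),
    resname = "LIG", resid = 1L, chain = "A",
    x = c(0, 3, 6), y = 0, z = 0, stringsAsFactors = FALSE
  ))
  out <- assign_parameters(sys, tab)
  expect_equal(out$atoms$charge, c(-0.5, -0.4, 0.1))  # pair beats element
  expect_identical(assign_parameters(out, tab), out)  # idempotent

  empty <- tab[0, ]
  expect_error(assign_parameters(sys, empty), "no parameters for atom")
  no_c <- tab[1:2, ]
  expect_error(assign_parameters(sys, no_c), "CA")
})

test_that("element-fallback parameterization accounts for every atom's charge", {
  sys <- random_system(10, seed = 4)
  sys$atoms$charge <- NA_real_
  sys$atoms$element <- rep(c("C", "N"), 5)
  tab <- data.frame(
    resname = NA, atom = NA, element = c("C", "N"),
    charge = c(0.1, -0.3), lj_epsilon = 0.1, lj_rmin_half = 1.9,
    boundary_radius = 1.9, stringsAsFactors = FALSE
  )
  out <- assign_parameters(sys, tab)
  expect_false(anyNA(out$atoms$charge))
  expect_equal(sum(out$atoms$charge), 5 * 0.1 + 5 * (-0.3))
})

test_that("selections resolve identically on topology and frames, and validate", {
  spec <- toy_complex_spec(seed = 2)
  cx <- build_toy_complex(spec)
  traj <- generate_trajectory(cx, spec, 2)
  s1 <- select_atoms(cx, "resname NAG and name N2")
  s2 <- select_atoms(traj, "resname NAG and name N2")
  expect_identical(as.integer(s1), as.integer(s2))
  expect_equal(length(s1), spec$n_sugar_units)

  rng <- select_atoms(cx, "resid 1-2 and resname NAG")
  expect_true(all(cx$atoms$resid[rng] %in% 1:2))
  expect_error(select_atoms(cx, "weird clause"), "unknown selection keyword")
  expect_error(subset_system(cx, integer(0)), "empty")
  expect_error(subset_system(cx, c(1, 1)), "unique")
  expect_error(subset_system(cx, n_atoms(cx) + 1), "range")
})
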