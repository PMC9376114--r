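# Structure parsing, atom selections and geometric primitives.

test_that("PDB reading handles single and multi-model files", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  s <- make_structure(rbind(c(0, 0, 0), c(1, 0, 0)), elements = c("N", "C"),
                      names = c("N", "CA"))
  write_pdb(s, tmp)
  got <- read_pdb(tmp)
  expect_length(got, 1L)
  expect_equal(nrow(got[[1L]]$atoms), 2L)
  expect_equal(sqrt(sum((got[[1L]]$xyz[1, ] - got[[1L]]$xyz[2, ])^2)), 1)

  models <- lapply(0:2, function(z) {
    make_structure(rbind(c(0, 0, z), c(1, 0, z)), elements = c("N", "C"),
                   names = c("N", "CA"))
  })
  write_pdb(models, tmp)
  got <- read_pdb(tmp)
  expect_length(got, 3L)
  expect_equal(vapply(got, function(m) m$model_id, 1L), 1:3)
})

test_that("PDB round trip preserves random coordinates to PDB precision", {
  set.seed(31)
  xyz <- matrix(runif(150, -40, 40), ncol = 3)
  s <- make_structure(xyz, elements = sample(c("C", "N", "O"), 50, TRUE))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tmp)
  back <- read_pdb(tmp)[[1L]]
  expect_true(max(abs(back$xyz - s$xyz)) < 5e-4)  # 3-decimal fixed columns
})

test_that("malformed and empty PDB input raise informative errors", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   1       x.xxx   0.000   0.000  1.00  0.00           C"),
    tmp)
  expect_error(read_pdb(tmp), "line 2")
  writeLines("REMARK nothing here", tmp)
  expect_error(read_pdb(tmp), "empty")
})

test_that("centroid matches a per-axis summation oracle and simple cases", {
  s1 <- make_structure(c(3, 4, 5))
  g1 <- atom_group("one", serials = 1L)
  expect_equal(unname(centroid(s1, g1)), c(3, 4, 5))

  s2 <- make_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(centroid(s2, atom_group("two", serials = 1:2))),
               c(1, 0, 0))

  set.seed(7)
  xyz <- matrix(rnorm(15), ncol = 3)
  s <- make_structure(xyz)
  expect_equal(unname(centroid(s, atom_group("g", serials = 1:5))),
               oracle_centroid(xyz))
})

test_that("centroid is equivariant under rigid motions", {
  set.seed(11)
  xyz <- matrix(rnorm(30), ncol = 3)
  s <- make_structure(xyz)
  g <- atom_group("g", serials = 1:10)
  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3)
    st <- transform_structure(s, R, t)
    expect_equal(unname(centroid(st, g)),
                 unname(as.vector(R %*% centroid(s, g)) + t), tolerance = 1e-10)
  }
})

test_that("min_heavy_distance excludes hydrogens and takes the minimum pair", {
  s <- make_structure(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(min_heavy_distance(s, atom_group("a", serials = 1L),
                                  atom_group("b", serials = 2L)), 0)

  # candidate pairs at 3, 4, 5 Angstrom -> 3; a hydrogen at 1 A is ignored
  s <- make_structure(rbind(c(0, 0, 0),
                            c(3, 0, 0), c(0, 4, 0), c(0, 0, 5), c(1, 0, 0)),
                      elements = c("C", "C", "C", "C", "H"))
  a <- atom_group("a", serials = 1L)
  b <- atom_group("b", serials = 2:5)
  expect_equal(min_heavy_distance(s, a, b), 3)
  expect_equal(min_heavy_distance(s, b, a), 3)  # symmetric

  s_h <- make_structure(c(0, 0, 0), elements = "H")
  expect_error(
    min_heavy_distance(s, a, atom_group("h", serials = 5L)), "hydrogens")
})

test_that("min_heavy_distance is symmetric and non-negative on random groups", {
  set.seed(5)
  for (i in 1:10) {
    s <- make_structure(matrix(rnorm(36, sd = 4), ncol = 3))
    a <- atom_group("a", serials = 1:5)
    b <- atom_group("b", serials = 6:12)
    d <- min_heavy_distance(s, a, b)
    expect_gte(d, 0)
    expect_equal(d, min_heavy_distance(s, b, a))
    expect_equal(d, oracle_min_dist(s$xyz[1:5, ], s$xyz[6:12, ]))
  }
})

test_that("superpose_rmsd recovers rigid motions and matches the oracle", {
  set.seed(13)
  xyz <- matrix(rnorm(24, sd = 3), ncol = 3)
  ref <- make_structure(xyz)
  g <- atom_group("all", serials = 1:8)
  expect_equal(superpose_rmsd(ref, ref, g)$rmsd, 0, tolerance = 1e-12)

  R <- random_rotation()
  mob <- transform_structure(ref, R, c(3, -2, 9))
  fit <- superpose_rmsd(mob, ref, g)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)

  # 4-atom toy: fit group held fixed, one rmsd_group atom displaced by 1 A
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(1, 1, 2))
  refs <- make_structure(base)
  moved <- base
  moved[4, ] <- moved[4, ] + c(0, 0, 1)
  mobs <- make_structure(moved)
  fitg <- atom_group("fit", serials = 1:3)
  rmsg <- atom_group("rmsd", serials = 4L)
  got <- superpose_rmsd(mobs, refs, fitg, rmsg)
  expect_equal(got$rmsd, oracle_rmsd(matrix(moved[4, ], 1), matrix(base[4, ], 1)),
               tolerance = 1e-9)
})

test_that("superposed RMSD never exceeds the unfitted RMSD", {
  set.seed(17)
  for (i in 1:8) {
    A <- matrix(rnorm(30, sd = 2), ncol = 3)
    B <- A + matrix(rnorm(30, sd = 0.7), ncol = 3)
    sa <- make_structure(A)
    sb <- make_structure(B)
    g <- atom_group("g", serials = 1:10)
    expect_lte(superpose_rmsd(sb, sa, g)$rmsd, oracle_rmsd(B, A) + 1e-12)
  }
})

test_that("Kabsch fit agrees with the bio3d reference implementation", {
  set.seed(19)
  A <- matrix(rnorm(30, sd = 3), ncol = 3)
  B <- A %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.4), ncol = 3)
  got <- superpose_rmsd(make_structure(B), make_structure(A),
                        atom_group("g", serials = 1:10))$rmsd
  xyz_fit <- bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B)),
                            fixed.inds = 1:30, mobile.inds = 1:30)
  ref <- sqrt(mean(rowSums((matrix(xyz_fit, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("degenerate fit sets are rejected", {
  line <- make_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))
  g <- atom_group("g", serials = 1:4)
  expect_error(superpose_rmsd(transform_structure(line, t = c(1, 1, 0)),
                              line, g), "collinear")
  expect_error(superpose_rmsd(line, line, atom_group("g2", serials = 1:2)),
               "at least 3")
})

test_that("orientation vectors are unit length and rotate as vectors", {
  tpl <- toy_complex_template()
  ov <- orientation_vectors(tpl$reference, tpl$groups$core, tpl$anchors)
  expect_equal(sqrt(sum(ov$v_left^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(ov$v_down^2)), 1, tolerance = 1e-9)
  # self-comparison: both scalar products are exactly 1
  expect_equal(sum(ov$v_left * ov$v_left), 1, tolerance = 1e-12)

  # rotate 90 degrees about the v_left axis: SP_left unchanged, SP_down -> 0
  ax <- ov$v_left
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R90 <- diag(3) + sin(pi / 2) * K + (1 - cos(pi / 2)) * (K %*% K)
  rot <- transform_structure(tpl$reference, R90)
  ov2 <- orientation_vectors(rot, tpl$groups$core, tpl$anchors)
  expect_equal(sum(ov2$v_left * ov$v_left), 1, tolerance = 1e-9)
  expect_equal(sum(ov2$v_down * ov$v_down), 0, tolerance = 1e-9)

  # general rigid rotation: vectors transform as vectors
  set.seed(23)
  R <- random_rotation()
  ov3 <- orientation_vectors(transform_structure(tpl$reference, R, rnorm(3)),
                             tpl$groups$core, tpl$anchors)
  expect_equal(unname(ov3$v_left), unname(as.vector(R %*% ov$v_left)),
               tolerance = 1e-9)
})

test_that("coincident anchors and unresolvable serials raise errors", {
  tpl <- toy_complex_template()
  expect_error(orientation_vectors(tpl$reference, tpl$groups$core,
                                   list(v_left = c("C1", "C1"),
                                        v_down = c("C2", "C6"))),
               "coincident")
  expect_error(resolve_group(tpl$reference, atom_group("x", serials = 9999L)),
               "not in structure")
})
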