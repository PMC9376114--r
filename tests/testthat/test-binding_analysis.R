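# Weighted-ensemble binding statistics.

# minimal two-snapshot ensemble built directly on the template
tiny_ensemble <- function(offsets, weights = NULL) {
  tpl <- toy_complex_template()
  ref <- tpl$reference
  n <- length(offsets)
  lidx <- resolve_group(ref, tpl$groups$ligand)
  coords <- array(rep(ref$xyz, n), dim = c(nrow(ref$atoms), 3L, n))
  for (i in seq_len(n)) {
    coords[lidx, , i] <- sweep(coords[lidx, , i], 2, offsets[[i]], "+")
  }
  snap <- data.frame(id = seq_len(n),
                     weight = if (is.null(weights)) rep(1 / n, n) else weights)
  weighted_ensemble(ref$atoms, coords, snap, ref, tpl$groups$align,
                    groups = tpl$groups, anchors = tpl$anchors,
                    contacts = tpl$contacts, tail_residues = tpl$tail_residues,
                    membrane_z = tpl$membrane_z)
}

test_that("density fields put single snapshots in single cubes", {
  ens <- tiny_ensemble(list(c(0, 0, 0)))
  f <- density_field(ens, ens$groups$ligand)
  expect_equal(sum(f$values == 1), 1L)
  expect_equal(sum(f$values), 1)

  # weights (0.75, 0.25) in different cubes -> (1, 1/3) after max-scaling
  ens2 <- tiny_ensemble(list(c(0, 0, 0), c(10, 0, 0)), weights = c(0.75, 0.25))
  f2 <- density_field(ens2, ens2$groups$ligand)
  expect_equal(sort(f2$values[f2$values > 0]), c(1 / 3, 1))
  f2p <- density_field(ens2, ens2$groups$ligand, normalize = "prob")
  expect_equal(sort(f2p$values[f2p$values > 0]), c(0.25, 0.75))
})

test_that("contact-ratio fields average the contact indicator per cube", {
  # two equal-weight snapshots in one cube: tail in contact in exactly one
  tpl <- toy_complex_template()
  ref <- tpl$reference
  coords <- array(rep(ref$xyz, 2), dim = c(nrow(ref$atoms), 3L, 2))
  tidx <- resolve_group(ref, tpl$groups$tail)
  lidx <- resolve_group(ref, tpl$groups$ligand)
  ctr <- colMeans(ref$xyz[lidx, ])
  # snapshot 1: first tail bead adjacent to the ligand; snapshot 2: far away
  coords[tidx, , 1] <- matrix(ref$xyz[lidx[1L], ] + c(2, 0, 0), 11, 3,
                              byrow = TRUE) + matrix(rnorm(33, sd = .1), 11, 3)
  coords[tidx, , 2] <- matrix(ctr + c(40, 40, 40), 11, 3, byrow = TRUE)
  ens <- weighted_ensemble(ref$atoms, coords, data.frame(id = 1:2,
                                                         weight = c(.5, .5)),
                           ref, tpl$groups$align, groups = tpl$groups,
                           tail_residues = tpl$tail_residues)
  f <- contact_ratio_field(ens, partner = tpl$groups$tail, cutoff = 5)
  expect_equal(f$values[f$counts == 2], 0.5)

  # slab partner: ligand well above the membrane -> no contact
  fm <- contact_ratio_field(ens, partner = list(z = -40), cutoff = 5)
  expect_equal(fm$values[f$counts == 2], 0)
  expect_error(contact_ratio_field(ens, partner = tpl$groups$tail,
                                   cutoff = -1), "positive")
})

test_that("slice assignment follows the half-open 5 A convention", {
  s <- slice_set()
  expect_equal(slice_assign(0, s), 1L)
  expect_equal(slice_assign(12, s), 3L)
  expect_equal(slice_assign(20, s), 5L)    # gate boundary -> upper slice
  expect_equal(slice_assign(64.999, s), 13L)
  expect_error(slice_assign(65, s), class = "zs_out_of_range")
  expect_error(slice_assign(-1, s), "non-negative")
})

test_that("residue-contact free energies obey the PMF definition", {
  gen <- cached_ensemble(400)
  rc <- residue_contact_pmf(gen$ensemble, temperature = 300)
  # RT at 300 K: rho = exp(-1) maps to F = RT = 0.5962 kcal/mol
  expect_equal(rc$RT, 0.5961613, tolerance = 1e-4)
  ok <- !is.na(rc$rho) & rc$rho > 0
  expect_equal(rc$F[ok], -rc$RT * log(rc$rho[ok]))
  # duality: exp(-F/RT) recovers rho wherever defined
  expect_equal(exp(-rc$F[ok] / rc$RT), rc$rho[ok], tolerance = 1e-12)
  # rho = 0 and empty slices are flagged, never zero-filled
  expect_true(all(is.na(rc$F[!is.na(rc$rho) & rc$rho == 0])))
})

test_that("atom-residue maps are per-slice max-normalized", {
  gen <- cached_ensemble(400)
  arc <- atom_residue_contact(gen$ensemble)
  for (s in seq_along(arc$theta)) {
    m <- arc$theta[[s]]
    if (all(is.na(m)) || max(arc$raw[[s]], na.rm = TRUE) == 0) next
    expect_equal(max(m, na.rm = TRUE), 1)
    expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  }
})

test_that("planted specific contacts concentrate the inner-slice maps", {
  # inner slices: only the Arg-like bead contacts, and only a 3-atom block;
  # an outer slice contacts every residue non-specifically
  pc <- matrix(0, 13, 11)
  pc[1:2, 5L] <- 0.5
  pc[6L, ] <- 0.5
  spec <- synthetic_ensemble_spec(
    n_snapshots = 3000, seed = 91, p_contact = pc,
    specific_contact = list(residue = 5L, atoms = 1:3, slices = 1:2),
    contact_distance_range = c(1.3, 2.0))
  gen <- generate_binding_ensemble(spec)
  # a tight cutoff resolves which atom the bead actually sits on
  arc <- atom_residue_contact(align_ensemble(gen$ensemble), cutoff = 2.5)
  ent <- function(m) {
    p <- m[is.finite(m) & m > 0]
    p <- p / sum(p)
    -sum(p * log(p))
  }
  inner <- arc$raw[[2L]]
  outer <- arc$raw[[6L]]
  # the contacted residue column is the planted one
  expect_equal(unname(which.max(colSums(inner, na.rm = TRUE))), 5L)
  # and within it, the most-contacted atom belongs to the planted block
  # (ring neighbours of the block may pick up incidental contacts)
  expect_true(which.max(inner[, 5L]) %in% 1:4)
  # non-specific outer contacts spread over all atoms and residues:
  # entropy of the normalized map at least twice the planted slice's
  expect_gt(ent(outer), 2 * ent(inner))
})

test_that("minimum-distance PMFs separate contact and diffuse modes", {
  # custom slice: 90% in contact near 3.5 A, 10% diffuse
  spec <- synthetic_ensemble_spec(n_snapshots = 2500, seed = 55,
                                  p_contact = {
                                    p <- matrix(0, 13, 11)
                                    p[6, ] <- 0.9
                                    p
                                  })
  gen <- generate_binding_ensemble(spec)
  mp <- min_distance_pmf(gen$ensemble, bin_width = 1, r_max = 40)
  prof <- mp$pmf[6L, ]
  expect_equal(min(prof, na.rm = TRUE), 0)   # min-shifted
  basin <- which.min(prof)
  expect_lt(mp$centers[basin], 5)            # basin is the contact mode
  # all snapshots of one slice at one distance -> single occupied bin
  one <- which(mp$slice == 6L & mp$r_bN < 5)
  expect_gt(length(one), 0)
})

test_that("orientation fields average unit vectors per cube", {
  # all snapshots share one orientation -> |vbar| = 1
  ens <- tiny_ensemble(list(c(0, 0, 0), c(0.5, 0, 0)))
  of <- orientation_field(ens)
  occ <- of$v_left$counts > 0
  expect_equal(unname(of$v_left$norm[occ]), rep(1, sum(occ)), tolerance = 1e-9)

  # two equal-weight antiparallel orientations -> |vbar| = 0
  tpl <- toy_complex_template()
  ref <- tpl$reference
  lidx <- resolve_group(ref, tpl$groups$ligand)
  ctr <- colMeans(ref$xyz[lidx, ])
  coords <- array(rep(ref$xyz, 2), dim = c(nrow(ref$atoms), 3L, 2))
  Rpi <- diag(c(-1, -1, 1))   # 180 degrees about z: flips both ring axes
  coords[lidx, , 2] <- sweep(sweep(ref$xyz[lidx, ], 2, ctr) %*% t(Rpi), 2,
                             ctr, "+")
  ens2 <- weighted_ensemble(ref$atoms, coords,
                            data.frame(id = 1:2, weight = c(.5, .5)), ref,
                            tpl$groups$align, groups = tpl$groups,
                            anchors = tpl$anchors)
  of2 <- orientation_field(ens2)
  expect_lt(max(of2$v_left$norm, na.rm = TRUE), 1e-9)

  # 1e4 isotropic (Haar) orientations in one cube: norm below 0.03
  set.seed(71)
  n <- 10000
  coords3 <- array(rep(ref$xyz, n), dim = c(nrow(ref$atoms), 3L, n))
  local <- sweep(ref$xyz[lidx, ], 2, ctr)
  for (i in seq_len(n)) {
    coords3[lidx, , i] <- sweep(local %*% t(random_rotation()), 2, ctr, "+")
  }
  ens3 <- weighted_ensemble(ref$atoms, coords3,
                            data.frame(id = seq_len(n), weight = rep(1 / n, n)),
                            ref, tpl$groups$align, groups = tpl$groups,
                            anchors = tpl$anchors)
  of3 <- orientation_field(ens3)
  expect_lt(max(of3$v_left$norm, na.rm = TRUE), 0.03)
})

test_that("scalar-product fields hit the parallel/antiparallel/perpendicular anchors", {
  grid <- cube_grid(c(0, 0, 0), 3, c(1, 1, 3))
  vf <- list(grid = grid,
             v = rbind(c(0, 0, 2), c(0, 0, -0.6), c(1, 0, 0)),
             norm = array(c(2, 0.6, 1), c(1, 1, 3)),
             counts = array(1L, c(1, 1, 3)))
  sp <- sp_field(vf, c(0, 0, 1))
  expect_equal(as.vector(sp$values), c(1, -1, 0))
  # below the norm floor -> flagged undefined
  vf$v[2, ] <- c(0, 0, -0.1)
  sp2 <- sp_field(vf, c(0, 0, 1), floor = 0.3)
  expect_true(is.na(sp2$values[1, 1, 2]))
})

test_that("native-contact profiles average counts per r_bb window", {
  gen <- cached_ensemble(400)
  prof <- native_contact_profile(gen$ensemble)
  expect_true(all(prof$n_cnt >= 0 & prof$n_cnt <= 4, na.rm = TRUE))
  expect_true(all(prof$sd_cnt >= 0, na.rm = TRUE))

  # closed form: two equal-weight snapshots with counts 0 and 4
  # realized with a custom two-snapshot ensemble at identical r_bb
  tpl <- toy_complex_template()
  ref <- tpl$reference
  coords <- array(rep(ref$xyz, 2), dim = c(nrow(ref$atoms), 3L, 2))
  far <- which(ref$atoms$resno %in% c(182L, 273L, 343L))
  coords[far, , 2] <- coords[far, , 2] + 50     # break all four contacts
  ens <- weighted_ensemble(ref$atoms, coords,
                           data.frame(id = 1:2, weight = c(.5, .5)), ref,
                           tpl$groups$align, groups = tpl$groups,
                           contacts = tpl$contacts)
  p <- native_contact_profile(ens, centers = 0.25, half_width = 0.25)
  expect_equal(p$n_cnt, 2)
  expect_equal(p$sd_cnt, 2)
  expect_equal(p$n_snapshots, 2L)
  # all contacts formed in every snapshot -> 4 with zero spread
  ens4 <- tiny_ensemble(list(c(0, 0, 0), c(0.2, 0, 0)))
  p4 <- native_contact_profile(ens4, centers = 0.25, half_width = 0.25)
  expect_equal(p4$n_cnt, 4)
  expect_equal(p4$sd_cnt, 0)
})

test_that("RMSD distributions: DDF, shell-corrected RDF and their relation", {
  # copies of the reference: all mass in the first bin
  ens0 <- tiny_ensemble(list(c(0, 0, 0), c(0, 0, 0)))
  rd0 <- rmsd_distributions(ens0, "whole", bin_width = 0.5)
  expect_equal(rd0$p_ddf[1L], 1)
  expect_equal(which.max(rd0$p_rdf), which.max(rd0$p_ddf))

  # rigid translations make RMSD exact; a flat DDF over [2,6] gives an RDF
  # proportional to 1/R^2 (monotone decreasing), peaked at the lowest bin
  set.seed(81)
  n <- 4000
  d <- runif(n, 2, 6)
  offs <- lapply(d, function(r) runit_test() * r)
  ens <- tiny_ensemble(offs)
  rd <- rmsd_distributions(ens, "whole", bin_width = 0.5, r_max = 7)
  expect_equal(rd$rmsd, d, tolerance = 1e-9)
  sel <- rd$centers > 2.01 & rd$centers < 5.99
  expect_equal(which.max(rd$p_rdf[sel]), 1L)
  expect_true(all(diff(rd$p_rdf[sel]) < 0))
  # defining relation between the two distributions
  expect_equal(rd$p_rdf,
               (rd$p_ddf / (4 * pi * rd$centers^2)) /
                 sum(rd$p_ddf / (4 * pi * rd$centers^2)), tolerance = 1e-12)
  # core-region selection is available and distinct
  rdc <- rmsd_distributions(ens0, "core", bin_width = 0.5)
  expect_equal(rdc$p_ddf[1L], 1)
})

test_that("protonation helper follows Henderson-Hasselbalch", {
  expect_equal(neutral_fraction(5.1, 7.4), 1 / (1 + 10^2.3), tolerance = 1e-12)
  expect_equal(sprintf("%.1f", 100 * neutral_fraction(5.1, 7.4)), "0.5")
  expect_equal(neutral_fraction(7.4, 7.4), 0.5)
  expect_equal(100 * neutral_fraction(5.79, 7.4), 2.40, tolerance = 0.005)
})

test_that("duplicating snapshots at half weight leaves statistics unchanged", {
  gen <- cached_ensemble(400)
  ens <- gen$ensemble
  n <- dim(ens$coords)[3L]
  dup <- ens
  dup$coords <- array(c(ens$coords, ens$coords),
                      dim = c(dim(ens$coords)[1:2], 2L * n))
  dup$snapshots <- rbind(ens$snapshots, ens$snapshots)
  dup$snapshots$weight <- dup$snapshots$weight / 2
  dup <- weighted_ensemble(dup$atoms, dup$coords, dup$snapshots,
                           dup$reference, dup$align_group, dup$groups,
                           dup$anchors, dup$contacts, dup$tail_residues,
                           dup$membrane_z)
  dup$aligned <- TRUE
  g <- cube_grid(c(-70, -70, -70), 3, c(50, 50, 50))
  f1 <- density_field(ens, ens$groups$ligand, grid = g)
  f2 <- density_field(dup, ens$groups$ligand, grid = g)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
  rc1 <- residue_contact_pmf(ens)
  rc2 <- residue_contact_pmf(dup)
  expect_equal(rc1$rho, rc2$rho, tolerance = 1e-12)
})

test_that("one rigid transform of snapshots and reference changes nothing", {
  gen <- cached_ensemble(400)
  ens <- gen$ensemble
  set.seed(61)
  R <- random_rotation()
  moved <- transform_ensemble(ens, R, c(12, -7, 3), move_reference = TRUE)
  # grid-free statistics are exactly invariant under any rigid motion
  p1 <- native_contact_profile(ens)
  p2 <- native_contact_profile(moved)
  expect_equal(p1$n_cnt, p2$n_cnt, tolerance = 1e-9)
  r1 <- rmsd_distributions(ens, "whole", bin_width = 0.5, r_max = 70)
  r2 <- rmsd_distributions(moved, "whole", bin_width = 0.5, r_max = 70)
  expect_equal(r1$p_ddf, r2$p_ddf, tolerance = 1e-9)
  rc1 <- residue_contact_pmf(ens)
  rc2 <- residue_contact_pmf(moved)
  expect_equal(rc1$rho, rc2$rho, tolerance = 1e-9)
  # cube fields live on an axis-aligned grid fitted to the data: exact
  # invariance holds for translations (the fitted origin co-moves)
  shifted <- transform_ensemble(ens, diag(3), c(17.3, -4.2, 9.9),
                                move_reference = TRUE)
  f1 <- density_field(ens, ens$groups$ligand)
  f2 <- density_field(shifted, shifted$groups$ligand)
  expect_equal(sort(f1$values[f1$values > 0]), sort(f2$values[f2$values > 0]),
               tolerance = 1e-9)
})

test_that("OpenDX output round-trips grid metadata and values", {
  ens2 <- tiny_ensemble(list(c(0, 0, 0), c(10, 0, 0)), weights = c(0.75, 0.25))
  f <- density_field(ens2, ens2$groups$ligand)
  tmp <- withr::local_tempfile(fileext = ".dx")
  write_dx(f, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1L], sprintf("counts %d %d %d", f$grid$extents[1],
                                  f$grid$extents[2], f$grid$extents[3]))
  vals <- as.numeric(unlist(strsplit(paste(
    lines[8:(length(lines) - 1L)], collapse = " "), " +")))
  expect_equal(sort(vals[vals > 0]), c(1 / 3, 1), tolerance = 1e-6)
})
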