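# Synthetic weighted ligand-receptor ensembles with known ground truth.
# The generator emulates the statistical structure the analysis module
# measures: a centroid density with a pocket mode and a diffuse shell,
# per-slice tail-contact probabilities, distance-dependent orientation
# concentration, and native-contact formation curves.

#' Toy ligand-receptor complex template
#'
#' A pseudo-atomic complex used by the synthetic generator and the examples:
#' a transmembrane (TM) pseudo-helix bundle (chain R, residues 100-113, CA
#' only) defining the alignment frame around a binding pocket; four
#' receptor side-chain nitrogens carrying the native contacts (Lys182 NZ,
#' Lys273 NZ, Arg343 NH1/NH2); an 11-bead intrinsically disordered
#' N-terminal tail (Ace cap numbered 79, then Ser80...Pro89, one bead per
#' residue) rooted at the pocket gate; and a 14-heavy-atom ligand (resname
#' LIG, chain L): a six-membered carbon ring C1-C6 (the rigid core), side
#' carbons C7-C10, a sulfonyl-like group S11/O12/O13 on one end and a
#' sulfonamide-like nitrogen N14 on the opposite end. The ligand reference
#' pose sits at the pocket center; the default orientation anchors are
#' `v_left = C1 -> C4` and `v_down = C2 -> C6` (perpendicular in-plane ring
#' axes).
#'
#' @return list with `reference` (`zs_structure` of the native-complex
#'   pose), `groups` (named `zs_atom_group`s: `align`, `ligand`, `core`,
#'   `soo`, `n14`, `tail`), `tail_residues` (data.frame resno/label),
#'   `anchors`, `pocket` (3-vector), `membrane_z`, and `contacts`
#'   (the four `zs_native_contact` definitions).
#' @export
toy_complex_template <- function() {
  pocket <- c(0, 0, -6)
  # TM bundle: two rings of 7 CA pseudo-atoms around the pocket axis
  th <- seq(0, 2 * pi, length.out = 8L)[-8L]
  tm <- rbind(cbind(7 * cos(th), 7 * sin(th), -2),
              cbind(7 * cos(th + pi / 7), 7 * sin(th + pi / 7), -11))
  # ligand: ring C1-C6 in the xy plane, side carbons, SOO end (+x), N14 end (-x)
  phi <- (0:5) * pi / 3
  ring <- cbind(1.4 * cos(phi), 1.4 * sin(phi), 0)
  side <- rbind(c(2.1, 1.8, 0.4), c(2.1, -1.8, 0.4),
                c(-2.1, 1.8, -0.4), c(-2.1, -1.8, -0.4))
  soo_s <- c(3.0, 0, 0.3)
  o12 <- c(3.8, 0.9, 0.7)
  o13 <- c(3.8, -0.9, 0.7)
  n14 <- c(-3.2, 0, 0.5)
  lig_xyz <- rbind(ring, side, soo_s, o12, o13, n14)
  lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))          # center, then ...
  lig_xyz <- sweep(lig_xyz, 2, pocket, "+")                # ... park in pocket
  lig_names <- c(paste0("C", 1:10), "S11", "O12", "O13", "N14")
  lig_elem <- c(rep("C", 10), "S", "O", "O", "N")
  # receptor contact side-chain nitrogens near their native partners; the
  # Lys182 NZ sits between the sulfonamide nitrogen and the sulfonyl
  # oxygens so that all four native contacts are formed in the reference
  nz182 <- (lig_xyz[14L, ] + (lig_xyz[12L, ] + lig_xyz[13L, ]) / 2) / 2 +
    c(0, 0.5, 1.0)
  nz273 <- lig_xyz[12L, ] + c(1.6, 1.2, 1.6)               # near O12
  nh1 <- lig_xyz[13L, ] + c(1.4, -1.6, 1.2)                # near O13
  nh2 <- nh1 + c(0.9, 0.3, 0.3)
  # tail beads: root at the gate (z = +14 over the pocket), tip pointing out
  tail_res <- data.frame(resno = 79:89,
                         label = c("Ace", "Ser80", "Pro81", "Pro82", "Arg83",
                                   "Thr84", "Ile85", "Ser86", "Pro87", "Pro88",
                                   "Pro89"))
  tail_xyz <- cbind(2 + 0.4 * (11:1), 0.3 * (11:1), pocket[3] + 14 + 3.8 * (11:1))
  atoms <- data.frame(
    serial = seq_len(14L + 4L + 11L + 14L),
    name = c(rep("CA", 14L), "NZ", "NZ", "NH1", "NH2", rep("CB", 11L), lig_names),
    element = c(rep("C", 14L), rep("N", 4L), rep("C", 11L), lig_elem),
    resno = c(100:113, 182L, 273L, 343L, 343L, tail_res$resno, rep(500L, 14L)),
    resname = c(rep("ALA", 14L), "LYS", "LYS", "ARG", "ARG",
                c("ACE", "SER", "PRO", "PRO", "ARG", "THR", "ILE", "SER",
                  "PRO", "PRO", "PRO"), rep("LIG", 14L)),
    chain = c(rep("R", 29L), rep("L", 14L)),
    insert = "", hetatm = c(rep(FALSE, 29L), rep(TRUE, 14L)),
    stringsAsFactors = FALSE)
  xyz <- rbind(tm, nz182, nz273, nh1, nh2, tail_xyz, lig_xyz)
  ref <- structure_model(atoms, xyz, 1L)
  grp <- function(label, mask, heavy = FALSE) {
    atom_group(label, serials = atoms$serial[mask], heavy_only = heavy)
  }
  groups <- list(
    align = grp("TM", atoms$chain == "R" & atoms$resno %in% 100:113),
    ligand = grp("ligand", atoms$chain == "L", heavy = TRUE),
    core = grp("core", atoms$chain == "L" & atoms$name %in% paste0("C", 1:6)),
    soo = grp("SOO", atoms$name %in% c("O12", "O13"), heavy = TRUE),
    n14 = grp("N14", atoms$name == "N14", heavy = TRUE),
    tail = grp("tail", atoms$chain == "R" & atoms$resno %in% 79:89))
  anchors <- list(v_left = c("C1", "C4"), v_down = c("C2", "C6"))
  contacts <- list(
    native_contact_def(groups$n14, grp("Lys182Nz", atoms$resno == 182), 5.0,
                       "N14;Lys182Nz"),
    native_contact_def(groups$soo, grp("Lys182Nz", atoms$resno == 182), 5.0,
                       "SOO;Lys182Nz"),
    native_contact_def(groups$soo, grp("Lys273Nz", atoms$resno == 273), 5.0,
                       "SOO;Lys273Nz"),
    native_contact_def(groups$soo, grp("Arg343Nh", atoms$resno == 343), 5.0,
                       "SOO;Arg343Nh"))
  list(reference = ref, groups = groups, tail_residues = tail_res,
       anchors = anchors, pocket = pocket, membrane_z = -24, contacts = contacts)
}

#' Specification of a synthetic weighted binding ensemble
#'
#' Defaults describe a ligand that is pocket-bound in about a third of the
#' ensemble and diffusing in a 5-62 Angstrom shell otherwise, with
#' tail-contact probabilities that move from the tail tip (slices 5-7) to
#' the tail root (slices 3-4) as the ligand approaches, a strongly ordered
#' orientation inside the pocket gate (r_bb < 20 Angstrom) and a nearly
#' isotropic one outside (kappa 50 vs 0.05), and four native-contact
#' formation curves rising as
#' r_bb -> 0.
#'
#' @param n_snapshots number of snapshots.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param pocket_weight mixture weight of the pocket Gaussian.
#' @param pocket_sigma sd (Angstrom) of the pocket Gaussian.
#' @param shell_range radial range (Angstrom) of the diffuse shell.
#' @param p_contact 13 x 11 matrix of per-slice, per-residue tail-contact
#'   probabilities (rows = slices, cols = Ace79...Pro89).
#' @param kappa_inside,kappa_outside orientation concentration inside /
#'   outside the gate.
#' @param gate_r_bb gate position on the r_bb axis (Angstrom).
#' @param contact_curves list of four `list(A, r0, s)` logistic formation
#'   curves `p(r_bb) = A / (1 + exp((r_bb - r0)/s))`.
#' @param specific_contact `list(residue, atoms, slices)`: in those slices
#'   the named tail residue contacts one of the given ligand atom indices
#'   specifically (elsewhere the contacted atom is drawn uniformly).
#' @param weights `"uniform"` or a numeric vector of length `n_snapshots`.
#' @param contact_cutoff contact cutoff used to realize indicator geometry.
#' @param contact_distance_range range the bead-to-contacted-atom distance
#'   is drawn from for tail contacts; default `c(1.3, contact_cutoff - 0.3)`.
#' @return object of class `zs_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(n_snapshots = 20000L, seed = 1L,
                                    pocket_weight = 0.35, pocket_sigma = 3,
                                    shell_range = c(5, 62),
                                    p_contact = NULL,
                                    kappa_inside = 50, kappa_outside = 0.05,
                                    gate_r_bb = 20,
                                    contact_curves = NULL,
                                    specific_contact = list(residue = 5L,
                                                            atoms = 1:13,
                                                            slices = 1:2),
                                    weights = "uniform",
                                    contact_cutoff = 5.0,
                                    contact_distance_range = NULL) {
  if (is.null(p_contact)) p_contact <- default_p_contact()
  p_contact <- as.matrix(p_contact)
  if (!all(dim(p_contact) == c(13L, 11L))) stop("p_contact must be 13 x 11")
  if (any(p_contact < 0 | p_contact > 1)) stop("probabilities must lie in [0,1]")
  if (kappa_inside < 0 || kappa_outside < 0) stop("kappa must be >= 0")
  if (is.null(contact_curves)) {
    contact_curves <- list(list(A = 0.90, r0 = 2.6, s = 0.8),
                           list(A = 0.65, r0 = 2.2, s = 0.8),
                           list(A = 0.75, r0 = 2.4, s = 0.8),
                           list(A = 0.55, r0 = 2.0, s = 0.8))
  }
  if (is.null(contact_distance_range)) {
    contact_distance_range <- c(1.3, contact_cutoff - 0.3)
  }
  if (contact_distance_range[2L] >= contact_cutoff) {
    stop("contact_distance_range must stay below the contact cutoff")
  }
  structure(list(n_snapshots = as.integer(n_snapshots), seed = as.integer(seed),
                 pocket_weight = pocket_weight, pocket_sigma = pocket_sigma,
                 shell_range = shell_range, p_contact = p_contact,
                 kappa_inside = kappa_inside, kappa_outside = kappa_outside,
                 gate_r_bb = gate_r_bb, contact_curves = contact_curves,
                 specific_contact = specific_contact, weights = weights,
                 contact_cutoff = contact_cutoff,
                 contact_distance_range = contact_distance_range),
            class = "zs_ensemble_spec")
}

# default per-slice tail-contact probability table (rows = slices 1..13,
# cols = Ace79, Ser80..Pro89): contact site slides from tip to root
default_p_contact <- function() {
  p <- matrix(0.05, 13L, 11L)
  p[13L, ] <- 0                     # no tail contact beyond 60 A
  p[12L, ] <- c(0.15, rep(0, 10))   # first touch: the Ace cap
  p[9:11, 1:4] <- 0.5               # tip region engaged
  p[9:11, 5:11] <- 0.1
  p[8L, 1:5] <- 0.4
  p[5:7, 2:5] <- 0.7                # tip basin (Ser80-Arg83)
  p[5:7, 7:11] <- 0.15
  p[3:4, 7:11] <- 0.85              # root basin (Ile85-Pro89)
  p[3:4, 1:4] <- 0.15
  p[1:2, ] <- 0.02                  # contact released at the pocket bottom
  p[1:2, 5] <- 0.30                 # weak residual Arg83 contact
  p
}

logistic_p <- function(curve, r) curve$A / (1 + exp((r - curve$r0) / curve$s))

# rotation matrix about unit axis by angle (Rodrigues)
rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# orientation noise: composition of three small random-axis rotations with
# wrapped-Gaussian angles of width 1/sqrt(3 kappa); kappa -> Inf gives the
# identity, kappa -> 0 gives a nearly isotropic rotation
random_rotation_kappa <- function(kappa) {
  R <- diag(3)
  sdv <- if (kappa > 0) 1 / sqrt(3 * kappa) else 1e6
  for (i in 1:3) {
    ax <- stats::rnorm(3)
    ang <- stats::rnorm(1, sd = sdv)
    ang <- atan2(sin(ang), cos(ang))  # wrap to (-pi, pi]
    R <- rot_about(ax, ang) %*% R
  }
  R
}

runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic weighted binding ensemble
#'
#' Draws `n_snapshots` pseudo-structures on the [toy_complex_template()]:
#' the ligand centroid comes from the declared pocket/shell mixture, the
#' rigid ligand is rotated about its centroid with concentration
#' `kappa(r_bb)`, each tail bead is placed in or out of ligand contact
#' according to `p_contact(slice, residue)`, and the four receptor contact
#' atoms are placed so that the realized native-contact indicators equal
#' independent Bernoulli draws from the formation curves. Weights default to
#' uniform. Deterministic given the spec seed.
#'
#' @param spec a `zs_ensemble_spec`.
#' @return list with `ensemble` (a `zs_ensemble`, see [weighted_ensemble()])
#'   and `truth` (per-snapshot latent variables: r_bb, slice, tail-contact
#'   indicator matrix, native-contact indicator matrix, contacted atom index
#'   per residue) for parameter-recovery tests.
#' @export
generate_binding_ensemble <- function(spec) {
  stopifnot(inherits(spec, "zs_ensemble_spec"))
  tpl <- toy_complex_template()
  ref <- tpl$reference
  n <- spec$n_snapshots
  set.seed(spec$seed)
  na <- nrow(ref$atoms)
  lig_idx <- resolve_group(ref, tpl$groups$ligand)
  tail_idx <- resolve_group(ref, tpl$groups$tail)
  if (length(tail_idx) != 11L) stop("tail template must have 11 beads")
  lig_ref <- ref$xyz[lig_idx, , drop = FALSE]
  lig_ctr_ref <- colMeans(lig_ref)
  lig_local <- sweep(lig_ref, 2, lig_ctr_ref)
  lig_rmax <- sqrt(max(rowSums(lig_local^2)))
  i_n14 <- which(ref$atoms$name[lig_idx] == "N14")
  i_o <- which(ref$atoms$name[lig_idx] %in% c("O12", "O13"))
  j_nz182 <- which(ref$atoms$resno == 182L)
  j_nz273 <- which(ref$atoms$resno == 273L)
  j_nh <- which(ref$atoms$resno == 343L)
  slices <- slice_set()
  cut <- spec$contact_cutoff

  coords <- array(rep(ref$xyz, n), dim = c(na, 3L, n))
  r_bb <- numeric(n)
  slice_k <- integer(n)
  tail_flags <- matrix(NA, n, 11L)
  atom_hit <- matrix(NA_integer_, n, 11L)
  native_flags <- matrix(NA, n, 4L)

  for (i in seq_len(n)) {
    # centroid: pocket Gaussian or diffuse shell
    if (stats::runif(1) < spec$pocket_weight) {
      ctr <- lig_ctr_ref + stats::rnorm(3, sd = spec$pocket_sigma)
    } else {
      ctr <- lig_ctr_ref + runit() *
        stats::runif(1, spec$shell_range[1], spec$shell_range[2])
    }
    rb <- sqrt(sum((ctr - lig_ctr_ref)^2))
    k <- slice_assign(min(rb, slices$upper - 1e-9), slices)
    kap <- if (rb < spec$gate_r_bb) spec$kappa_inside else spec$kappa_outside
    R <- random_rotation_kappa(kap)
    lig <- sweep(lig_local %*% t(R), 2, ctr, "+")
    coords[lig_idx, , i] <- lig
    # tail beads in/out of ligand contact per the slice table
    for (j in 1:11) {
      hit <- stats::runif(1) < spec$p_contact[k, j]
      tail_flags[i, j] <- hit
      if (hit) {
        sc <- spec$specific_contact
        ai <- if (!is.null(sc) && j == sc$residue && k %in% sc$slices) {
          sc$atoms[sample.int(length(sc$atoms), 1L)]
        } else sample.int(nrow(lig), 1L)
        atom_hit[i, j] <- ai
        coords[tail_idx[j], , i] <- lig[ai, ] + runit() *
          stats::runif(1, spec$contact_distance_range[1L],
                       spec$contact_distance_range[2L])
      } else {
        coords[tail_idx[j], , i] <- ctr + runit() *
          (lig_rmax + cut + stats::runif(1, 0.5, 20))
      }
    }
    # native contacts: Bernoulli draws realized geometrically
    p <- vapply(spec$contact_curves, logistic_p, 0, r = rb)
    f <- stats::runif(4) < p
    native_flags[i, ] <- f
    n14p <- lig[i_n14, ]
    sooc <- colMeans(lig[i_o, , drop = FALSE])
    sep <- (n14p - sooc) / sqrt(sum((n14p - sooc)^2))
    far <- function(extra = 0) ctr + runit() * (lig_rmax + cut + extra + stats::runif(1, 1, 10))
    coords[j_nz182, , i] <- if (f[1] && f[2]) {
      (n14p + sooc) / 2 + stats::rnorm(3, sd = 0.2)
    } else if (f[1]) {
      n14p + sep * stats::runif(1, 2.7, 4.0)
    } else if (f[2]) {
      lig[i_o[1], ] - sep * stats::runif(1, 2.0, 3.2)
    } else far()
    coords[j_nz273, , i] <- if (f[3]) {
      lig[i_o[1], ] + runit() * stats::runif(1, 2.7, 4.5)
    } else far()
    nh1 <- if (f[4]) lig[i_o[2], ] + runit() * stats::runif(1, 2.7, 4.3) else far(1.2)
    coords[j_nh[1], , i] <- nh1
    coords[j_nh[2], , i] <- nh1 + runit()
    r_bb[i] <- rb
    slice_k[i] <- k
  }
  w <- if (identical(spec$weights, "uniform")) rep(1 / n, n) else {
    stopifnot(length(spec$weights) == n, all(spec$weights >= 0))
    spec$weights / sum(spec$weights)
  }
  snap <- data.frame(id = seq_len(n), weight = w)
  ens <- weighted_ensemble(atoms = ref$atoms, coords = coords, snapshots = snap,
                           reference = ref, align_group = tpl$groups$align,
                           groups = tpl$groups, anchors = tpl$anchors,
                           contacts = tpl$contacts,
                           tail_residues = tpl$tail_residues,
                           membrane_z = tpl$membrane_z)
  truth <- list(spec = spec, r_bb = r_bb, slice = slice_k,
                tail_contacts = tail_flags, atom_hit = atom_hit,
                native_contacts = native_flags)
  list(ensemble = ens, truth = truth)
}

#' Weighted snapshot ensemble
#'
#' The universal input of the analysis operations: snapshots sharing one
#' atom table with the reference (native-complex) structure, per-snapshot
#' coordinates, and canonical weights that are normalized to sum 1.
#'
#' @param atoms shared atom table (see [structure_model()]).
#' @param coords numeric array `n_atoms x 3 x n_snapshots`.
#' @param snapshots data.frame with at least `id` and `weight`.
#' @param reference `zs_structure` of the native pose.
#' @param align_group `zs_atom_group` used to superpose snapshots onto the
#'   reference (the transmembrane selection for the real system).
#' @param groups,anchors,contacts,tail_residues,membrane_z optional named
#'   extras carried for convenience (used by the bundled template).
#' @return object of class `zs_ensemble`.
#' @export
weighted_ensemble <- function(atoms, coords, snapshots, reference, align_group,
                              groups = list(), anchors = NULL, contacts = NULL,
                              tail_residues = NULL, membrane_z = NULL) {
  coords <- array(as.numeric(coords), dim = dim(coords))
  n <- dim(coords)[3L]
  stopifnot(nrow(snapshots) == n, dim(coords)[1L] == nrow(atoms),
            nrow(reference$atoms) == nrow(atoms))
  if (is.null(snapshots$weight)) snapshots$weight <- rep(1 / n, n)
  if (any(snapshots$weight < 0)) stop("weights must be non-negative")
  s <- sum(snapshots$weight)
  if (s <= 0) stop("weights must not all be zero")
  snapshots$weight <- snapshots$weight / s
  structure(list(atoms = atoms, coords = coords, snapshots = snapshots,
                 reference = reference, align_group = align_group,
                 groups = groups, anchors = anchors, contacts = contacts,
                 tail_residues = tail_residues, membrane_z = membrane_z,
                 aligned = FALSE),
            class = "zs_ensemble")
}

#' @export
print.zs_ensemble <- function(x, ...) {
  cat(sprintf("<zs_ensemble> %d snapshots x %d atoms (%saligned)\n",
              dim(x$coords)[3L], dim(x$coords)[1L],
              if (isTRUE(x$aligned)) "" else "not "))
  invisible(x)
}

#' Superpose every snapshot onto the reference frame
#'
#' Kabsch fit of the alignment group of each snapshot onto the reference;
#' all coordinates are transformed. Statistics computed in the receptor
#' frame (densities, r_bb, RMSDs, orientation fields) require this.
#'
#' @param ensemble a `zs_ensemble`.
#' @return the ensemble with transformed coordinates and `aligned = TRUE`.
#' @export
align_ensemble <- function(ensemble) {
  if (isTRUE(ensemble$aligned)) return(ensemble)
  idx <- resolve_group(ensemble$reference, ensemble$align_group)
  Q <- ensemble$reference$xyz[idx, , drop = FALSE]
  n <- dim(ensemble$coords)[3L]
  for (i in seq_len(n)) {
    fit <- kabsch(ensemble$coords[idx, , i], Q)
    ensemble$coords[, , i] <-
      sweep(ensemble$coords[, , i] %*% t(fit$R), 2, fit$t, "+")
  }
  ensemble$aligned <- TRUE
  ensemble
}

#' Apply one rigid transform to all snapshots (and optionally the reference)
#'
#' Mainly used to verify rigid-motion invariance of the analysis statistics.
#'
#' @param ensemble a `zs_ensemble`.
#' @param R rotation matrix; `t` translation.
#' @param t translation vector.
#' @param move_reference also transform the reference structure.
#' @return transformed ensemble (marked unaligned).
#' @export
transform_ensemble <- function(ensemble, R = diag(3), t = c(0, 0, 0),
                               move_reference = FALSE) {
  n <- dim(ensemble$coords)[3L]
  for (i in seq_len(n)) {
    ensemble$coords[, , i] <- sweep(ensemble$coords[, , i] %*% t(R), 2, t, "+")
  }
  if (move_reference) {
    ensemble$reference <- transform_structure(ensemble$reference, R, t)
  }
  ensemble$aligned <- FALSE
  ensemble
}

# per-snapshot centroid of a group: n x 3 matrix
group_centroids <- function(ensemble, group) {
  idx <- resolve_group(ensemble$reference, group)
  sub <- ensemble$coords[idx, , , drop = FALSE]
  t(apply(sub, c(2L, 3L), mean))
}

# per-snapshot structure view (no copy of the atom table)
snapshot_structure <- function(ensemble, i) {
  structure(list(atoms = ensemble$atoms,
                 xyz = ensemble$coords[, , i],
                 model_id = i),
            class = "zs_structure")
}

#' Distance of each snapshot's ligand centroid from its native position
#'
#' `r_bb = |r_CM(snapshot) - r_CM(reference)|`, evaluated after receptor
#' superposition so the reference centroid is meaningful across snapshots.
#'
#' @param ensemble an aligned `zs_ensemble`.
#' @param ligand `zs_atom_group` of the ligand (default: the ensemble's).
#' @return numeric vector of distances in Angstrom.
#' @export
ensemble_r_bb <- function(ensemble, ligand = ensemble$groups$ligand) {
  if (!isTRUE(ensemble$aligned)) {
    stop("align_ensemble() the ensemble before computing r_bb")
  }
  ref_ctr <- centroid(ensemble$reference, ligand)
  ctr <- group_centroids(ensemble, ligand)
  sqrt(rowSums(sweep(ctr, 2, ref_ctr)^2))
}
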