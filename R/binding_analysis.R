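# Weighted-ensemble binding statistics: cube fields, slice-based contact
# free energies, orientation fields, native-contact profiles, RMSD
# distributions, and the protonation helper.

#' Cube grid in the receptor frame
#'
#' @param origin lower corner of cube (1,1,1), in Angstrom.
#' @param edge cube edge length (default 3).
#' @param extents integer triple of cube counts per axis.
#' @return object of class `zs_cube_grid`.
#' @export
cube_grid <- function(origin, edge = 3, extents) {
  stopifnot(edge > 0, length(origin) == 3L, length(extents) == 3L,
            all(extents >= 1))
  structure(list(origin = as.numeric(origin), edge = edge,
                 extents = as.integer(extents)),
            class = "zs_cube_grid")
}

#' Fit a cube grid around a point cloud
#'
#' @param points n x 3 matrix.
#' @param edge cube edge (default 3).
#' @param pad extra margin in Angstrom.
#' @return `zs_cube_grid` covering all points.
#' @export
cube_grid_fit <- function(points, edge = 3, pad = 0) {
  lo <- apply(points, 2L, min) - pad - 1e-9
  hi <- apply(points, 2L, max) + pad + 1e-9
  cube_grid(lo, edge, pmax(ceiling((hi - lo) / edge), 1L))
}

# per-point cube indices; returns list(ijk matrix, linear index, valid mask)
cube_index <- function(grid, points) {
  points <- matrix(points, ncol = 3L)
  ijk <- floor(sweep(points, 2, grid$origin) / grid$edge) + 1L
  valid <- rowSums(ijk >= 1L) == 3L & rowSums(sweep(ijk, 2, grid$extents, "<=")) == 3L
  lin <- as.integer((ijk[, 1L] - 1L) +
                      (ijk[, 2L] - 1L) * grid$extents[1L] +
                      (ijk[, 3L] - 1L) * grid$extents[1L] * grid$extents[2L] + 1L)
  lin[!valid] <- NA_integer_
  list(ijk = ijk, linear = lin, valid = valid)
}

#' Cube centers of a grid
#'
#' @param grid a `zs_cube_grid`.
#' @return matrix (prod(extents) x 3) of cube centers, x fastest.
#' @export
cube_centers <- function(grid) {
  g <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$extents[a]) - 0.5) * grid$edge
  })
  as.matrix(expand.grid(x = g[[1L]], y = g[[2L]], z = g[[3L]]))
}

new_scalar_field <- function(grid, values, counts, what) {
  structure(list(grid = grid, values = values, counts = counts, what = what),
            class = "zs_scalar_field")
}

#' @export
print.zs_scalar_field <- function(x, ...) {
  cat(sprintf("<zs_scalar_field> %s on %s cubes (%d occupied)\n", x$what,
              paste(x$grid$extents, collapse = "x"), sum(x$counts > 0)))
  invisible(x)
}

#' Spatial density field of a group centroid
#'
#' Weighted occupancy, per 3 Angstrom cube, of the centroid of `target`
#' (ligand centroid, tail tip, hairpin tip, a ring, ...), in the
#' receptor-superposed frame. With `normalize = "max"` (default) the maximum
#' cube value is scaled to 1 so contour levels such as 0.5 / 0.1 / 0.01 read
#' directly off the field; `"prob"` keeps raw probability mass per cube.
#'
#' @param ensemble a `zs_ensemble` (aligned automatically if needed).
#' @param target `zs_atom_group` whose centroid is binned.
#' @param grid optional `zs_cube_grid`; fitted to the data when `NULL`.
#' @param edge cube edge used when fitting a grid.
#' @param normalize `"max"` or `"prob"`.
#' @return a `zs_scalar_field` (undefined cubes have count 0 and value 0).
#' @export
density_field <- function(ensemble, target, grid = NULL, edge = 3,
                          normalize = c("max", "prob")) {
  normalize <- match.arg(normalize)
  ensemble <- align_ensemble(ensemble)
  ctr <- group_centroids(ensemble, target)
  if (is.null(grid)) grid <- cube_grid_fit(ctr, edge)
  ci <- cube_index(grid, ctr)
  if (!all(ci$valid)) {
    stop(sum(!ci$valid), " centroid(s) fall outside the cube grid; ",
         "enlarge it or pass grid = NULL to fit one")
  }
  ncube <- prod(grid$extents)
  w <- ensemble$snapshots$weight
  vals <- numeric(ncube)
  tal <- tapply(w, ci$linear, sum)
  vals[as.integer(names(tal))] <- tal
  counts <- tabulate(ci$linear, nbins = ncube)
  if (normalize == "max") vals <- vals / max(vals)
  new_scalar_field(grid, array(vals, grid$extents),
                   array(counts, grid$extents),
                   sprintf("density(%s)", target$label))
}

#' Cube-based contact-ratio field
#'
#' For each cube, the weighted fraction of the snapshots whose ligand
#' centroid falls in that cube in which the ligand contacts the partner
#' (minimum heavy-atom distance below `cutoff`). The partner is either an
#' atom group (e.g. the N-terminal tail) or a planar membrane slab given as
#' `list(z = z0)` occupying `z <= z0` (contact when the lowest ligand heavy
#' atom comes within `cutoff` of the slab). Cubes with zero occupancy are
#' undefined (`NA`).
#'
#' @param ensemble a `zs_ensemble`.
#' @param ligand ligand atom group (centroid defines the cube; heavy atoms
#'   define contact).
#' @param partner partner atom group, or `list(z = z0)` for the slab.
#' @param cutoff contact cutoff in Angstrom (> 0).
#' @param grid,edge as in [density_field()].
#' @return a `zs_scalar_field` with values in [0, 1] (NA where undefined).
#' @export
contact_ratio_field <- function(ensemble, ligand = ensemble$groups$ligand,
                                partner, cutoff = 5, grid = NULL, edge = 3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ensemble <- align_ensemble(ensemble)
  n <- dim(ensemble$coords)[3L]
  lidx <- resolve_group(ensemble$reference, ligand, heavy_only = TRUE)
  contact <- logical(n)
  if (is.list(partner) && !inherits(partner, "zs_atom_group")) {
    z0 <- partner$z
    for (i in seq_len(n)) {
      contact[i] <- (min(ensemble$coords[lidx, 3L, i]) - z0) < cutoff
    }
  } else {
    pidx <- resolve_group(ensemble$reference, partner, heavy_only = TRUE)
    for (i in seq_len(n)) {
      contact[i] <- min_sq_dist(ensemble$coords[lidx, , i, drop = TRUE],
                                ensemble$coords[pidx, , i, drop = TRUE]) < cutoff^2
    }
  }
  ctr <- group_centroids(ensemble, ligand)
  if (is.null(grid)) grid <- cube_grid_fit(ctr, edge)
  ci <- cube_index(grid, ctr)
  if (!all(ci$valid)) stop("centroid(s) outside the cube grid")
  ncube <- prod(grid$extents)
  w <- ensemble$snapshots$weight
  wsum <- rep(0, ncube)
  wc <- rep(0, ncube)
  t1 <- tapply(w, ci$linear, sum)
  wsum[as.integer(names(t1))] <- t1
  t2 <- tapply(w * contact, ci$linear, sum)
  wc[as.integer(names(t2))] <- t2
  vals <- ifelse(wsum > 0, wc / wsum, NA_real_)
  new_scalar_field(grid, array(vals, grid$extents),
                   array(tabulate(ci$linear, nbins = ncube), grid$extents),
                   "contact ratio")
}

#' Slice set along the r_bb axis
#'
#' Contiguous, non-overlapping slices of thickness 5 Angstrom (13 by
#' default): slice k covers `[5(k-1), 5k)`. With the default arrangement the
#' slice 4/5 boundary sits at the gate of the binding pocket, so slices 1-4
#' are inside the pocket.
#'
#' @param thickness slice thickness in Angstrom.
#' @param n number of slices.
#' @return object of class `zs_slice_set`.
#' @export
slice_set <- function(thickness = 5, n = 13L) {
  stopifnot(thickness > 0, n >= 1)
  structure(list(thickness = thickness, n = as.integer(n),
                 upper = thickness * n,
                 lower_bounds = thickness * (seq_len(n) - 1L)),
            class = "zs_slice_set")
}

#' Assign an r_bb value to its slice
#'
#' Half-open convention `[lower, upper)`: an exact multiple of the thickness
#' belongs to the upper slice (so r_bb = 20 lies in slice 5, just outside
#' the pocket gate).
#'
#' @param r_bb distance in Angstrom (>= 0).
#' @param slices a `zs_slice_set`.
#' @return integer slice index k.
#' @export
slice_assign <- function(r_bb, slices = slice_set()) {
  if (any(r_bb < 0)) stop("r_bb must be non-negative")
  if (any(r_bb >= slices$upper)) {
    stop(structure(class = c("zs_out_of_range", "error", "condition"),
                   list(message = sprintf(
                     "r_bb = %.3f beyond the last slice (upper bound %g)",
                     max(r_bb), slices$upper), call = sys.call(-1))))
  }
  as.integer(floor(r_bb / slices$thickness) + 1L)
}

# vectorized, NA for out-of-range
slice_of <- function(r_bb, slices) {
  k <- floor(r_bb / slices$thickness) + 1
  k[r_bb < 0 | r_bb >= slices$upper] <- NA
  as.integer(k)
}

# tail residue atom groups from the ensemble's tail_residues table
tail_groups <- function(ensemble) {
  tr <- ensemble$tail_residues
  if (is.null(tr)) stop("ensemble carries no tail residue table")
  at <- ensemble$reference$atoms
  lapply(seq_len(nrow(tr)), function(j) {
    atom_group(tr$label[j],
               serials = at$serial[at$chain != "L" & at$resno == tr$resno[j]],
               heavy_only = TRUE)
  })
}

# distances between ligand heavy atoms and tail residues for one snapshot:
# returns matrix n_lig_atoms x n_residues of pair distances (min over the
# residue's atoms)
lig_tail_dist <- function(xyz, lidx, tidx_list) {
  L <- xyz[lidx, , drop = FALSE]
  vapply(tidx_list, function(tid) {
    Tm <- xyz[tid, , drop = FALSE]
    cross <- tcrossprod(L, Tm)
    d2 <- outer(rowSums(L^2), rowSums(Tm^2), "+") - 2 * cross
    sqrt(pmax(apply(d2, 1L, min), 0))
  }, numeric(length(lidx)))
}

#' Residue-based ligand-tail contact free energy
#'
#' For each slice k of the r_bb axis and each tail residue j,
#' `rho(k, j)` is the weighted fraction of the slice's snapshots in which
#' residue j's heavy atoms contact the ligand within `cutoff`, converted to
#' a potential of mean force `F = -RT ln(rho)`. Cells with `rho = 0` and
#' empty slices are flagged `NA` (unsampled), never zero-filled.
#'
#' @param ensemble a `zs_ensemble` with a tail residue table.
#' @param slices a `zs_slice_set`.
#' @param cutoff contact cutoff in Angstrom.
#' @param temperature temperature in K (sets RT).
#' @return list with matrices `rho` and `F` (slices x residues), `RT`,
#'   `residues`, `slice_weight`.
#' @export
residue_contact_pmf <- function(ensemble, slices = slice_set(), cutoff = 5,
                                temperature = 300) {
  ensemble <- align_ensemble(ensemble)
  tg <- tail_groups(ensemble)
  lidx <- resolve_group(ensemble$reference, ensemble$groups$ligand,
                        heavy_only = TRUE)
  tidx <- lapply(tg, function(g) resolve_group(ensemble$reference, g,
                                               heavy_only = TRUE))
  r_bb <- ensemble_r_bb(ensemble)
  k <- slice_of(r_bb, slices)
  n <- dim(ensemble$coords)[3L]
  w <- ensemble$snapshots$weight
  J <- length(tg)
  num <- matrix(0, slices$n, J)
  den <- numeric(slices$n)
  for (i in seq_len(n)) {
    if (is.na(k[i])) next
    dmin <- apply(lig_tail_dist(ensemble$coords[, , i], lidx, tidx), 2L, min)
    num[k[i], ] <- num[k[i], ] + w[i] * (dmin < cutoff)
    den[k[i]] <- den[k[i]] + w[i]
  }
  rho <- sweep(num, 1L, den, "/")
  rho[den == 0, ] <- NA_real_
  rt <- rt_kcal(temperature)
  Fm <- -rt * log(rho)
  Fm[!is.na(rho) & rho == 0] <- NA_real_
  dimnames(rho) <- dimnames(Fm) <-
    list(paste0("slice", seq_len(slices$n)),
         vapply(tg, function(g) g$label, ""))
  list(rho = rho, F = Fm, RT = rt, residues = vapply(tg, function(g) g$label, ""),
       slice_weight = den)
}

#' Atom-residue contact-ratio maps per slice
#'
#' For each slice, the weighted contact fraction between each ligand heavy
#' atom i and each tail residue j, with each slice's matrix divided by its
#' own maximum (per-panel normalization, highlighting atom specificity
#' within the slice). Empty slices are flagged `NA`.
#'
#' @inheritParams residue_contact_pmf
#' @return list of `slices$n` matrices (ligand atoms x residues), plus
#'   `atom_names` and `raw` (un-normalized fractions).
#' @export
atom_residue_contact <- function(ensemble, slices = slice_set(), cutoff = 5,
                                 temperature = 300) {
  ensemble <- align_ensemble(ensemble)
  tg <- tail_groups(ensemble)
  lidx <- resolve_group(ensemble$reference, ensemble$groups$ligand,
                        heavy_only = TRUE)
  tidx <- lapply(tg, function(g) resolve_group(ensemble$reference, g,
                                               heavy_only = TRUE))
  r_bb <- ensemble_r_bb(ensemble)
  k <- slice_of(r_bb, slices)
  w <- ensemble$snapshots$weight
  nl <- length(lidx)
  J <- length(tg)
  num <- array(0, c(slices$n, nl, J))
  den <- numeric(slices$n)
  for (i in seq_len(dim(ensemble$coords)[3L])) {
    if (is.na(k[i])) next
    d <- lig_tail_dist(ensemble$coords[, , i], lidx, tidx)
    num[k[i], , ] <- num[k[i], , ] + w[i] * (d < cutoff)
    den[k[i]] <- den[k[i]] + w[i]
  }
  atom_names <- ensemble$reference$atoms$name[lidx]
  res_names <- vapply(tg, function(g) g$label, "")
  raw <- lapply(seq_len(slices$n), function(s) {
    m <- if (den[s] > 0) num[s, , ] / den[s] else matrix(NA_real_, nl, J)
    dimnames(m) <- list(atom_names, res_names)
    m
  })
  theta <- lapply(raw, function(m) {
    mx <- suppressWarnings(max(m, na.rm = TRUE))
    if (is.finite(mx) && mx > 0) m / mx else m
  })
  list(theta = theta, raw = raw, atom_names = atom_names,
       residues = res_names, slice_weight = den)
}

#' Minimum-distance potential of mean force per slice
#'
#' `P_k(r_bN)`: the weighted, normalized histogram of the minimum
#' ligand-tail heavy-atom distance within slice k, converted to
#' `PMF = -RT ln P` and (by default) shifted so each profile's minimum is 0.
#' Empty slices and empty bins are flagged `NA`.
#'
#' @inheritParams residue_contact_pmf
#' @param bin_width histogram bin width in Angstrom.
#' @param r_max histogram upper bound.
#' @param shift_min shift each slice profile so its minimum is 0.
#' @return list with `edges`, `P` (slices x bins), `pmf`, `RT`.
#' @export
min_distance_pmf <- function(ensemble, slices = slice_set(), bin_width = 0.5,
                             r_max = 30, temperature = 300, shift_min = TRUE) {
  if (bin_width <= 0) stop("bin width must be positive")
  ensemble <- align_ensemble(ensemble)
  tg <- tail_groups(ensemble)
  lidx <- resolve_group(ensemble$reference, ensemble$groups$ligand,
                        heavy_only = TRUE)
  tidx <- lapply(tg, function(g) resolve_group(ensemble$reference, g,
                                               heavy_only = TRUE))
  r_bb <- ensemble_r_bb(ensemble)
  k <- slice_of(r_bb, slices)
  n <- dim(ensemble$coords)[3L]
  rbn <- numeric(n)
  for (i in seq_len(n)) {
    rbn[i] <- min(lig_tail_dist(ensemble$coords[, , i], lidx, tidx))
  }
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  w <- ensemble$snapshots$weight
  P <- matrix(NA_real_, slices$n, nb)
  for (s in seq_len(slices$n)) {
    sel <- which(k == s)
    if (!length(sel)) next
    bi <- findInterval(rbn[sel], edges, rightmost.closed = TRUE)
    ok <- bi >= 1L & bi <= nb
    if (!any(ok)) next
    p <- vapply(seq_len(nb), function(b) sum(w[sel][ok][bi[ok] == b]), 0)
    P[s, ] <- p / sum(p)
  }
  rt <- rt_kcal(temperature)
  pmf <- -rt * log(P)
  pmf[is.infinite(pmf)] <- NA_real_
  if (shift_min) {
    for (s in seq_len(slices$n)) {
      if (any(is.finite(pmf[s, ]))) pmf[s, ] <- pmf[s, ] - min(pmf[s, ], na.rm = TRUE)
    }
  }
  list(edges = edges, centers = edges[-1L] - bin_width / 2, P = P, pmf = pmf,
       RT = rt, r_bN = rbn, slice = k)
}

#' Averaged orientation-vector fields
#'
#' Per cube, the weighted vector mean of the per-snapshot unit orientation
#' vectors of the ligand core; the norm of the averaged vector is 1 when all
#' vectors in the cube are perfectly ordered and approaches 0 when they are
#' completely randomized.
#'
#' @param ensemble a `zs_ensemble` with `core` group and anchors.
#' @param grid,edge as in [density_field()].
#' @return list of two vector fields (`v_left`, `v_down`), each a list with
#'   `grid`, `v` (ncube x 3), `norm` array, `counts` array.
#' @export
orientation_field <- function(ensemble, grid = NULL, edge = 3) {
  ensemble <- align_ensemble(ensemble)
  n <- dim(ensemble$coords)[3L]
  vl <- matrix(0, n, 3L)
  vd <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    ov <- orientation_vectors(snapshot_structure(ensemble, i),
                              ensemble$groups$core, ensemble$anchors)
    vl[i, ] <- ov$v_left
    vd[i, ] <- ov$v_down
  }
  ctr <- group_centroids(ensemble, ensemble$groups$ligand)
  if (is.null(grid)) grid <- cube_grid_fit(ctr, edge)
  ci <- cube_index(grid, ctr)
  if (!all(ci$valid)) stop("centroid(s) outside the cube grid")
  ncube <- prod(grid$extents)
  w <- ensemble$snapshots$weight
  one <- function(vm) {
    acc <- matrix(0, ncube, 3L)
    wsum <- rep(0, ncube)
    for (a in 1:3) {
      t1 <- tapply(w * vm[, a], ci$linear, sum)
      acc[as.integer(names(t1)), a] <- t1
    }
    t2 <- tapply(w, ci$linear, sum)
    wsum[as.integer(names(t2))] <- t2
    v <- acc / ifelse(wsum > 0, wsum, NA)
    structure(list(grid = grid, v = v,
                   norm = array(sqrt(rowSums(v^2)), grid$extents),
                   counts = array(tabulate(ci$linear, nbins = ncube),
                                  grid$extents)),
              class = "zs_vector_field")
  }
  list(v_left = one(vl), v_down = one(vd))
}

#' Scalar-product field against a reference orientation
#'
#' `SP = e_vbar . v_ref`, the unit vector of the averaged orientation vector
#' dotted with the (normalized) reference-pose orientation vector; in
#' [-1, 1]. Cubes whose averaged-vector norm falls below `floor` (default
#' 0.3, the conventional display threshold) are flagged `NA`.
#'
#' @param field one vector field from [orientation_field()].
#' @param reference reference orientation vector (normalized internally).
#' @param floor minimum averaged-vector norm for a defined SP.
#' @return a `zs_scalar_field` with values in [-1, 1].
#' @export
sp_field <- function(field, reference, floor = 0.3) {
  vref <- reference / sqrt(sum(reference^2))
  nrm <- sqrt(rowSums(field$v^2))
  sp <- as.vector(field$v %*% vref) / nrm
  sp[!is.finite(sp) | nrm < floor] <- NA_real_
  new_scalar_field(field$grid, array(sp, field$grid$extents), field$counts,
                   "scalar product")
}

#' Native-contact formation profile
#'
#' For windows `R(r_bb) = [r_bb - dr, r_bb + dr]` along the r_bb axis
#' (centers from 0.25 Angstrom in 0.5 Angstrom steps, half-width
#' `dr = 0.25` Angstrom by default), the weighted mean `N_cnt` and standard
#' deviation `SD_cnt` of the per-snapshot count of formed native contacts
#' (0..4 for the four standard contact definitions; a contact is formed when
#' its minimum heavy-atom distance is below the definition's cutoff).
#' Windows containing no snapshots are flagged `NA`.
#'
#' @param ensemble a `zs_ensemble`.
#' @param contacts list of `zs_native_contact` (default: the ensemble's).
#' @param centers window centers in Angstrom.
#' @param half_width window half-width in Angstrom.
#' @return data.frame with `r_bb`, `n_cnt`, `sd_cnt`, `n_snapshots`.
#' @export
native_contact_profile <- function(ensemble, contacts = ensemble$contacts,
                                   centers = seq(0.25, 15.25, by = 0.5),
                                   half_width = 0.25) {
  if (is.null(contacts)) stop("no native-contact definitions supplied")
  ensemble <- align_ensemble(ensemble)
  n <- dim(ensemble$coords)[3L]
  ref <- ensemble$reference
  idx <- lapply(contacts, function(cn) {
    list(l = resolve_group(ref, cn$ligand_atoms, heavy_only = TRUE),
         r = resolve_group(ref, cn$receptor_atoms, heavy_only = TRUE),
         cut2 = cn$cutoff^2)
  })
  counts <- integer(n)
  for (i in seq_len(n)) {
    xyz <- ensemble$coords[, , i]
    counts[i] <- sum(vapply(idx, function(cd) {
      min_sq_dist(xyz[cd$l, , drop = FALSE], xyz[cd$r, , drop = FALSE]) < cd$cut2
    }, logical(1)))
  }
  if (n == 0L) stop("the ensemble contains no snapshots")
  r_bb <- ensemble_r_bb(ensemble)
  w <- ensemble$snapshots$weight
  out <- lapply(centers, function(cc) {
    sel <- which(abs(r_bb - cc) <= half_width)
    if (!length(sel)) {
      return(data.frame(r_bb = cc, n_cnt = NA_real_, sd_cnt = NA_real_,
                        n_snapshots = 0L))
    }
    ws <- w[sel] / sum(w[sel])
    m <- sum(ws * counts[sel])
    m2 <- sum(ws * counts[sel]^2)
    data.frame(r_bb = cc, n_cnt = m, sd_cnt = sqrt(max(m2 - m^2, 0)),
               n_snapshots = length(sel))
  })
  do.call(rbind, out)
}

#' RMSD distance and radial distribution functions
#'
#' Per-snapshot RMSD of the ligand selection (whole heavy atoms or the core
#' region) against the reference pose, evaluated in the receptor-superposed
#' frame (superposition is on the receptor alignment group, never on the
#' ligand). `P_DDF` is the weighted, normalized RMSD histogram; `P_RDF` is
#' `P_DDF / (4 pi R^2)` renormalized, with R at bin centers (the shell-volume
#' corrected counterpart).
#'
#' @param ensemble a `zs_ensemble`.
#' @param selection `"whole"` (ligand heavy atoms) or `"core"`.
#' @param bin_width histogram bin width in Angstrom.
#' @param r_max histogram upper bound in Angstrom.
#' @return list with `centers`, `p_ddf`, `p_rdf`, `rmsd` (per snapshot).
#' @export
rmsd_distributions <- function(ensemble, selection = c("whole", "core"),
                               bin_width = 0.5, r_max = NULL) {
  selection <- match.arg(selection)
  if (bin_width <= 0) stop("bin width must be positive")
  ensemble <- align_ensemble(ensemble)
  grp <- if (selection == "whole") ensemble$groups$ligand else ensemble$groups$core
  idx <- resolve_group(ensemble$reference, grp, heavy_only = TRUE)
  refxyz <- ensemble$reference$xyz[idx, , drop = FALSE]
  n <- dim(ensemble$coords)[3L]
  rmsd <- vapply(seq_len(n), function(i) {
    sqrt(mean(rowSums((ensemble$coords[idx, , i] - refxyz)^2)))
  }, 0)
  if (is.null(r_max)) r_max <- max(rmsd) + bin_width
  edges <- seq(0, r_max + bin_width, by = bin_width)
  centers <- edges[-1L] - bin_width / 2
  p_ddf <- weighted_histogram(rmsd, ensemble$snapshots$weight, edges)
  p_rdf <- p_ddf / (4 * pi * centers^2)
  p_rdf <- p_rdf / sum(p_rdf)
  list(centers = centers, p_ddf = p_ddf, p_rdf = p_rdf, rmsd = rmsd,
       selection = selection)
}

#' Neutral fraction of a weak acid (Henderson-Hasselbalch)
#'
#' Fraction of molecules in the neutral (protonated) form of an acid with
#' the given pKa at the given pH: `1 / (1 + 10^(pH - pKa))`. For a pKa of
#' 5.1 at blood pH 7.4 this gives 0.005 (0.5% neutral, 99.5% ionic).
#'
#' @param pKa acid dissociation constant.
#' @param pH solution pH.
#' @return neutral fraction in [0, 1].
#' @export
neutral_fraction <- function(pKa, pH) 1 / (1 + 10^(pH - pKa))

#' Write a scalar field as an OpenDX volumetric file
#'
#' Plain-text OpenDX regular-grid format readable by common molecular
#' viewers; undefined cubes are written as 0.
#'
#' @param field a `zs_scalar_field`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dx <- function(field, file) {
  g <- field$grid
  nx <- g$extents[1L]; ny <- g$extents[2L]; nz <- g$extents[3L]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %.4f %.4f %.4f",
            g$origin[1L] + g$edge / 2, g$origin[2L] + g$edge / 2,
            g$origin[3L] + g$edge / 2),
    sprintf("delta %.4f 0 0", g$edge),
    sprintf("delta 0 %.4f 0", g$edge),
    sprintf("delta 0 0 %.4f", g$edge),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            nx * ny * nz)), con)
  v <- field$values
  v[!is.finite(v)] <- 0
  # OpenDX order: z fastest, x slowest
  ord <- as.vector(aperm(v, c(3L, 2L, 1L)))
  lines <- vapply(split(ord, ceiling(seq_along(ord) / 3)),
                  function(tr) paste(sprintf("%.6e", tr), collapse = " "), "")
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
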