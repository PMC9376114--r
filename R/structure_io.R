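# Molecular structures, atom selections and geometric primitives.
# All coordinates are handled in Angstrom; no internal unit conversion.

#' Molecular structure object
#'
#' A `zs_structure` holds one model of a molecular structure: a fixed-column
#' atom table plus an `n x 3` coordinate matrix in Angstrom. Multi-model PDB
#' files map to a list of `zs_structure` objects sharing one atom table.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, `chain`, `insert` (character, `""` if absent),
#'   `hetatm` (logical).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param model_id integer model identifier (1-based).
#' @return object of class `zs_structure`.
#' @export
structure_model <- function(atoms, xyz, model_id = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  stopifnot(is.numeric(xyz), ncol(xyz) == 3L, nrow(xyz) == nrow(atoms))
  if (nrow(atoms) < 1L) stop("a structure must contain at least one atom")
  if (!all(is.finite(xyz))) stop("all atom positions must be finite")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique within a model")
  need <- c("serial", "name", "element", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$hetatm)) atoms$hetatm <- FALSE
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, model_id = as.integer(model_id)),
            class = "zs_structure")
}

#' @export
print.zs_structure <- function(x, ...) {
  cat(sprintf("<zs_structure> model %d: %d atoms, %d residues, chains: %s\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a (possibly multi-model) PDB file
#'
#' Fixed-column ATOM/HETATM/MODEL/ENDMDL records are parsed with
#' [bio3d::read.pdb()]. HETATM ligand atoms are retained; for alternate
#' locations only the first is kept; insertion codes are preserved as part of
#' residue identity.
#'
#' @param file path to a PDB file.
#' @return list of `zs_structure`, one per model, in file order.
#' @export
read_pdb <- function(file) {
  if (!file.exists(file)) stop("no such PDB file: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty PDB input (no ATOM/HETATM records): ", file)
  # validate coordinate fields up front so errors can name the offending line
  bad <- which(rec)[is.na(suppressWarnings(
    as.numeric(substr(lines[rec], 31, 38)) +
      as.numeric(substr(lines[rec], 39, 46)) +
      as.numeric(substr(lines[rec], 47, 54))))]
  if (length(bad)) {
    stop(sprintf("malformed coordinate field at line %d of %s: '%s'",
                 bad[1L], file, lines[bad[1L]]))
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
    resno = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE)
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    structure_model(atoms, matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE), m)
  })
}

#' Write structures to a (multi-model) PDB file
#'
#' @param structures a `zs_structure` or list of them (shared atom table).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structures, file) {
  if (inherits(structures, "zs_structure")) structures <- list(structures)
  s1 <- structures[[1L]]
  xyz <- do.call(rbind, lapply(structures, function(s) as.vector(t(s$xyz))))
  bio3d::write.pdb(
    file = file, xyz = xyz,
    type = ifelse(s1$atoms$hetatm, "HETATM", "ATOM"),
    eleno = s1$atoms$serial, elety = s1$atoms$name,
    resid = s1$atoms$resname, resno = s1$atoms$resno,
    chain = s1$atoms$chain, insert = ifelse(s1$atoms$insert == "", NA, s1$atoms$insert),
    elesy = s1$atoms$element)
  invisible(file)
}

#' Named atom selection
#'
#' Defines a named group of atoms by explicit serials or by
#' chain/residue-range/atom-name filters evaluated against a structure.
#'
#' @param label group label.
#' @param serials explicit atom serial numbers (overrides filters).
#' @param structure structure used to resolve filters (required unless
#'   `serials` given).
#' @param chain,resno,names optional filters: chain id(s), residue numbers,
#'   atom names.
#' @param heavy_only if `TRUE` the group is restricted to heavy atoms when
#'   resolved.
#' @return object of class `zs_atom_group`.
#' @export
atom_group <- function(label, serials = NULL, structure = NULL,
                       chain = NULL, resno = NULL, names = NULL,
                       heavy_only = FALSE) {
  if (is.null(serials)) {
    if (is.null(structure)) stop("either serials or a structure to filter must be given")
    at <- structure$atoms
    keep <- rep(TRUE, nrow(at))
    if (!is.null(chain)) keep <- keep & at$chain %in% chain
    if (!is.null(resno)) keep <- keep & at$resno %in% resno
    if (!is.null(names)) keep <- keep & at$name %in% names
    serials <- at$serial[keep]
  }
  serials <- as.integer(serials)
  if (length(serials) < 1L) stop("atom group '", label, "' is empty")
  structure(list(label = label, serials = serials, heavy_only = isTRUE(heavy_only)),
            class = "zs_atom_group")
}

is_hydrogen <- function(element, name) {
  el <- toupper(trimws(element))
  known <- el %in% c("H", "D")
  # fall back to name-prefix heuristic when the element column is absent
  noel <- el == "" | is.na(el)
  nm <- sub("^[0-9']+", "", toupper(trimws(name)))
  known | (noel & substr(nm, 1L, 1L) %in% c("H", "D"))
}

#' Resolve an atom group to row indices of a structure
#'
#' @param structure a `zs_structure`.
#' @param group a `zs_atom_group`.
#' @param heavy_only force heavy-atom filtering regardless of the group flag.
#' @return integer row indices into `structure$atoms`.
#' @export
resolve_group <- function(structure, group, heavy_only = group$heavy_only) {
  idx <- match(group$serials, structure$atoms$serial)
  if (anyNA(idx)) {
    stop("atom group '", group$label, "': serial(s) ",
         paste(group$serials[is.na(idx)], collapse = ","), " not in structure")
  }
  if (heavy_only) {
    at <- structure$atoms[idx, ]
    idx <- idx[!is_hydrogen(at$element, at$name)]
    if (length(idx) < 1L) {
      stop("atom group '", group$label, "' is empty after removing hydrogens")
    }
  }
  idx
}

#' Geometric centroid of an atom group
#'
#' Unweighted arithmetic mean of the member positions (mass weighting
#' available via `mass_weighted = TRUE`, off by default).
#'
#' @inheritParams resolve_group
#' @param mass_weighted weight atoms by element mass.
#' @return length-3 numeric vector (Angstrom).
#' @export
centroid <- function(structure, group, mass_weighted = FALSE) {
  idx <- resolve_group(structure, group)
  xyz <- structure$xyz[idx, , drop = FALSE]
  if (!mass_weighted) return(colMeans(xyz))
  m <- element_mass(structure$atoms$element[idx], structure$atoms$name[idx])
  colSums(xyz * m) / sum(m)
}

element_mass <- function(element, name) {
  tab <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
           S = 32.06, P = 30.974, F = 18.998, CL = 35.45, BR = 79.904)
  el <- toupper(trimws(element))
  el[el == ""] <- substr(sub("^[0-9']+", "", toupper(trimws(name[el == ""]))), 1L, 1L)
  m <- tab[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Minimum heavy-atom distance between two groups
#'
#' Hydrogens (and deuterium) are excluded from both groups; the minimum over
#' all remaining atom pairs is returned.
#'
#' @param structure a `zs_structure` (or for `structure_b`, a second one).
#' @param a,b `zs_atom_group` selections.
#' @param structure_b structure on which `b` resolves (default: same).
#' @return minimum pairwise Euclidean distance in Angstrom.
#' @export
min_heavy_distance <- function(structure, a, b, structure_b = structure) {
  pa <- structure$xyz[resolve_group(structure, a, heavy_only = TRUE), , drop = FALSE]
  pb <- structure_b$xyz[resolve_group(structure_b, b, heavy_only = TRUE), , drop = FALSE]
  sqrt(max(0, min_sq_dist(pa, pb)))
}

# squared minimum cross distance between two coordinate sets
min_sq_dist <- function(pa, pb) {
  cross <- tcrossprod(pa, pb)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * cross
  min(d2)
}

#' Native-contact definition
#'
#' A ligand heavy-atom group, a receptor heavy-atom group, and a formation
#' cutoff: the contact is formed in a snapshot when the minimum heavy-atom
#' distance between the two groups is below the cutoff (default 5.0 Angstrom,
#' chosen ~0.5 Angstrom above the largest crystallographic contact distance to
#' absorb thermal fluctuation).
#'
#' @param ligand_atoms,receptor_atoms `zs_atom_group` (heavy-atom only).
#' @param cutoff formation cutoff in Angstrom.
#' @param label contact label.
#' @return object of class `zs_native_contact`.
#' @export
native_contact_def <- function(ligand_atoms, receptor_atoms, cutoff = 5.0,
                               label = paste(ligand_atoms$label,
                                             receptor_atoms$label, sep = ";")) {
  stopifnot(cutoff > 0)
  ligand_atoms$heavy_only <- TRUE
  receptor_atoms$heavy_only <- TRUE
  structure(list(ligand_atoms = ligand_atoms, receptor_atoms = receptor_atoms,
                 cutoff = cutoff, label = label),
            class = "zs_native_contact")
}

#' The four sulfonamide native contacts of the reference complex
#'
#' Builds the four ligand-receptor contact definitions used for the
#' native-contact profile: sulfonyl oxygens (and the sulfonamide nitrogen) of
#' the ligand against the side-chain nitrogens of Lys182 (N-zeta), Lys273
#' (N-zeta) and Arg343 (N-eta). Atom selection is by residue number and atom
#' name, so the definitions apply to any structure using that numbering
#' (crystal structure or the bundled synthetic receptor).
#'
#' @param structure structure holding both ligand and receptor.
#' @param ligand_resname residue name of the ligand (default tries common ids).
#' @param cutoff formation cutoff in Angstrom.
#' @return list of four `zs_native_contact` objects, in the order
#'   N14;Lys182Nz, SOO;Lys182Nz, SOO;Lys273Nz, SOO;Arg343Nh.
#' @export
native_contact_defs <- function(structure, ligand_resname = NULL, cutoff = 5.0) {
  at <- structure$atoms
  if (is.null(ligand_resname)) {
    het <- unique(at$resname[at$hetatm & !(at$resname %in% c("HOH", "WAT"))])
    if (length(het) < 1L) stop("cannot identify a ligand residue; give ligand_resname")
    ligand_resname <- het[1L]
  }
  lig <- at$resname == ligand_resname
  pick <- function(label, mask) {
    s <- at$serial[mask]
    if (length(s) < 1L) stop("no atoms for selection ", label)
    atom_group(label, serials = s, heavy_only = TRUE)
  }
  # sulfonyl oxygens and sulfonamide nitrogen of the ligand: selected by name
  soo <- pick("SOO", lig & grepl("^O", at$name))
  n14 <- pick("N14", lig & grepl("^N", at$name))
  rec <- function(resno, names, label) {
    pick(label, !lig & at$resno %in% resno & at$name %in% names)
  }
  k182 <- rec(182, "NZ", "Lys182Nz")
  k273 <- rec(273, "NZ", "Lys273Nz")
  r343 <- rec(343, c("NH1", "NH2"), "Arg343Nh")
  list(
    native_contact_def(n14, k182, cutoff, "N14;Lys182Nz"),
    native_contact_def(soo, k182, cutoff, "SOO;Lys182Nz"),
    native_contact_def(soo, k273, cutoff, "SOO;Lys273Nz"),
    native_contact_def(soo, r343, cutoff, "SOO;Arg343Nh"))
}

# --- Kabsch superposition -------------------------------------------------

# Proper-rotation least-squares fit of P (mobile) onto Q (reference).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.vector(R %*% cp), d = sv$d)
}

#' Superpose a mobile structure and evaluate RMSD
#'
#' Least-squares proper rigid-body fit (Kabsch, determinant +1) of
#' `fit_group` atoms of `mobile` onto the same atoms of `reference`; RMSD is
#' then evaluated on `rmsd_group` after applying the transform. The fitting
#' selection and the RMSD selection are independent, so the deviation of one
#' part (e.g. a ligand) can be measured in the frame defined by another
#' (e.g. the transmembrane helices).
#'
#' @param mobile,reference `zs_structure` objects with 1:1 matching groups.
#' @param fit_group group used for the fit (>= 3 non-collinear atoms).
#' @param rmsd_group group on which RMSD is evaluated (default: `fit_group`).
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd` (Angstrom).
#' @export
superpose_rmsd <- function(mobile, reference, fit_group, rmsd_group = fit_group) {
  im <- resolve_group(mobile, fit_group)
  ir <- resolve_group(reference, fit_group)
  if (length(im) != length(ir)) stop("fit_group atom counts differ between structures")
  if (length(im) < 3L) stop("fit_group needs at least 3 atoms")
  P <- mobile$xyz[im, , drop = FALSE]
  Q <- reference$xyz[ir, , drop = FALSE]
  fit <- kabsch(P, Q)
  if (fit$d[2L] < 1e-8 * max(fit$d[1L], 1)) {
    stop("fit_group is collinear/degenerate; rotation is not determined")
  }
  jm <- resolve_group(mobile, rmsd_group)
  jr <- resolve_group(reference, rmsd_group)
  if (length(jm) != length(jr)) stop("rmsd_group atom counts differ between structures")
  Pm <- sweep(mobile$xyz[jm, , drop = FALSE] %*% t(fit$R), 2, fit$t, "+")
  dif <- Pm - reference$xyz[jr, , drop = FALSE]
  list(R = fit$R, t = fit$t, rmsd = sqrt(mean(rowSums(dif^2))))
}

#' Apply a rigid transform to a structure
#'
#' @param structure a `zs_structure`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return transformed `zs_structure`.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  structure$xyz <- sweep(structure$xyz %*% t(R), 2, t, "+")
  structure
}

#' Ligand orientation vectors
#'
#' Two unit vectors fixed in the (approximately rigid) core region of the
#' ligand, defined by configured anchor atom pairs. The anchor configuration
#' is `list(v_left = c(from, to), v_down = c(from, to))` with atom names (or
#' serials) that are members of `core`. Both vectors are normalized to unit
#' length.
#'
#' @param structure a `zs_structure`.
#' @param core `zs_atom_group` of the core region.
#' @param anchors anchor configuration (see Details).
#' @return list with unit vectors `v_left` and `v_down`.
#' @export
orientation_vectors <- function(structure, core, anchors) {
  idx <- resolve_group(structure, core)
  at <- structure$atoms[idx, ]
  locate <- function(key) {
    if (is.numeric(key)) j <- match(as.integer(key), at$serial)
    else j <- match(key, at$name)
    if (is.na(j)) stop("orientation anchor '", key, "' is not a member of the core group")
    structure$xyz[idx[j], ]
  }
  one <- function(pair, lab) {
    v <- locate(pair[[2L]]) - locate(pair[[1L]])
    n <- sqrt(sum(v^2))
    if (n < 1e-9) stop("anchor atoms for ", lab, " are coincident")
    v / n
  }
  list(v_left = one(anchors$v_left, "v_left"),
       v_down = one(anchors$v_down, "v_down"))
}
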