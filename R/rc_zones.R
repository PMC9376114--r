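# Reaction coordinates as centroid-centroid distances and the overlapping
# zone decomposition of RC space.

#' Reaction-coordinate definition
#'
#' An RC is the distance between the centroids of two named atom groups.
#'
#' @param label RC label (e.g. `"alpha"`).
#' @param group_a,group_b `zs_atom_group` selections; must differ.
#' @return object of class `zs_rc_def`.
#' @export
rc_def <- function(label, group_a, group_b) {
  if (identical(group_a$serials, group_b$serials)) {
    stop("the two atom groups of an RC must differ")
  }
  structure(list(label = label, group_a = group_a, group_b = group_b),
            class = "zs_rc_def")
}

#' Evaluate a reaction coordinate on a structure
#'
#' @param structure a `zs_structure`.
#' @param rc a `zs_rc_def`.
#' @return centroid-centroid distance in Angstrom (>= 0).
#' @export
compute_rc <- function(structure, rc) {
  d <- centroid(structure, rc$group_a) - centroid(structure, rc$group_b)
  sqrt(sum(d^2))
}

#' Zone axis: overlapping intervals along one RC
#'
#' By default the coverage `[lower, upper]` is divided into `n_zones` uniform
#' intervals with `overlap_fraction` (default 0.5) shared between consecutive
#' intervals; the transition rule requires non-empty overlap regions.
#' Explicit `edges` (2-column matrix of lower/upper bounds) override the
#' uniform construction so a published zone table can be reproduced exactly.
#' Coverage bounds are mandatory: there are no silent defaults.
#'
#' @param label axis label (usually the RC label).
#' @param lower,upper coverage bounds in Angstrom.
#' @param n_zones number of intervals.
#' @param overlap_fraction fraction of each interval shared with the next,
#'   in (0, 1).
#' @param edges optional explicit interval bounds (overrides the uniform
#'   construction).
#' @return object of class `zs_zone_axis`.
#' @export
zone_axis <- function(label, lower = NA, upper = NA, n_zones = NA,
                      overlap_fraction = 0.5, edges = NULL) {
  if (is.null(edges)) {
    stopifnot(is.finite(lower), is.finite(upper), upper > lower, n_zones >= 1)
    if (n_zones == 1L) {
      edges <- cbind(lower, upper)
    } else {
      stopifnot(overlap_fraction > 0, overlap_fraction < 1)
      w <- (upper - lower) / (1 + (n_zones - 1) * (1 - overlap_fraction))
      lo <- lower + (seq_len(n_zones) - 1) * w * (1 - overlap_fraction)
      edges <- cbind(lo, lo + w)
    }
  }
  edges <- as.matrix(edges)
  colnames(edges) <- c("lower", "upper")
  n <- nrow(edges)
  if (any(edges[, 1] >= edges[, 2])) stop("each interval needs lower < upper")
  if (n > 1L) {
    if (any(diff(edges[, 1]) <= 0)) stop("intervals must be ordered by lower bound")
    if (any(edges[-1L, 1] >= edges[-n, 2])) {
      stop("consecutive intervals must overlap (lower[i+1] < upper[i])")
    }
  }
  structure(list(label = label, edges = edges, n_zones = n,
                 lower = edges[1L, 1L], upper = edges[n, 2L]),
            class = "zs_zone_axis")
}

#' Multi-dimensional zone grid
#'
#' @param axes list of `zs_zone_axis` (one per RC dimension).
#' @return object of class `zs_zone_grid`; zone indices are D-tuples of
#'   per-axis interval indices.
#' @export
zone_grid <- function(axes) {
  if (inherits(axes, "zs_zone_axis")) axes <- list(axes)
  stopifnot(length(axes) >= 1L, all(vapply(axes, inherits, TRUE, "zs_zone_axis")))
  nz <- vapply(axes, function(a) a$n_zones, 1L)
  structure(list(axes = axes, dim = length(axes), n_per_axis = nz,
                 n_zones = prod(nz)),
            class = "zs_zone_grid")
}

#' @export
print.zs_zone_grid <- function(x, ...) {
  cat(sprintf("<zs_zone_grid> %dD, %s zones (%s)\n", x$dim, x$n_zones,
              paste(x$n_per_axis, collapse = " x ")))
  invisible(x)
}

# tuple (matrix row or vector) <-> linear zone index
zone_linear <- function(grid, tuple) {
  tuple <- matrix(as.integer(tuple), ncol = grid$dim)
  if (any(tuple < 1L) || any(sweep(tuple, 2, grid$n_per_axis, ">")))
    stop("invalid zone index")
  mult <- cumprod(c(1L, grid$n_per_axis[-grid$dim]))
  as.integer((tuple - 1L) %*% mult + 1L)
}

zone_tuple <- function(grid, linear) {
  linear <- as.integer(linear)
  if (any(linear < 1L | linear > grid$n_zones)) stop("invalid zone index")
  out <- matrix(0L, length(linear), grid$dim)
  rem <- linear - 1L
  for (a in seq_len(grid$dim)) {
    out[, a] <- rem %% grid$n_per_axis[a] + 1L
    rem <- rem %/% grid$n_per_axis[a]
  }
  out
}

# per-axis box (lower/upper) of a zone tuple
zone_box <- function(grid, tuple) {
  tuple <- as.integer(tuple)
  lo <- vapply(seq_len(grid$dim), function(a) grid$axes[[a]]$edges[tuple[a], 1L], 0)
  hi <- vapply(seq_len(grid$dim), function(a) grid$axes[[a]]$edges[tuple[a], 2L], 0)
  rbind(lower = lo, upper = hi)
}

# per-axis interval membership with the half-open convention
# [lower, upper), last interval closed; overlap regions give multiplicity
axis_membership <- function(axis, x) {
  e <- axis$edges
  inside <- x >= e[, 1L] & (x < e[, 2L] | (x == e[, 2L] & seq_len(nrow(e)) == nrow(e)))
  which(inside)
}

#' Zones containing an RC-space point
#'
#' Returns every zone whose interval contains the point on all axes.
#' Intervals are closed at the lower bound and open at the upper, except the
#' last interval of an axis which is closed at both ends; points in overlap
#' regions therefore belong to up to `2^D` zones.
#'
#' @param grid a `zs_zone_grid`.
#' @param lambda numeric D-vector of RC values.
#' @return integer matrix, one row per containing zone (D-tuples). A point
#'   outside the coverage raises an error of class `zs_out_of_range`.
#' @export
zone_membership <- function(grid, lambda) {
  stopifnot(length(lambda) == grid$dim)
  per_axis <- lapply(seq_len(grid$dim), function(a) {
    m <- axis_membership(grid$axes[[a]], lambda[a])
    if (length(m) == 0L) {
      stop(structure(class = c("zs_out_of_range", "error", "condition"),
                     list(message = sprintf(
                       "RC value %.4f outside coverage [%.4f, %.4f] of axis '%s'",
                       lambda[a], grid$axes[[a]]$lower, grid$axes[[a]]$upper,
                       grid$axes[[a]]$label),
                       call = sys.call(-1))))
    }
    m
  })
  as.matrix(do.call(expand.grid, per_axis))
}

# unique zone assignment for histogramming: on each axis, the interval with
# the largest lower bound containing x (deterministic, no multiplicity)
zone_primary <- function(grid, lambda_mat) {
  lambda_mat <- matrix(lambda_mat, ncol = grid$dim)
  idx <- matrix(0L, nrow(lambda_mat), grid$dim)
  for (a in seq_len(grid$dim)) {
    e <- grid$axes[[a]]$edges
    i <- findInterval(lambda_mat[, a], e[, 1L])
    i[i > 0L & lambda_mat[, a] > e[pmax(i, 1L), 2L]] <- 0L  # beyond upper edge
    i[lambda_mat[, a] > grid$axes[[a]]$upper] <- 0L
    idx[, a] <- i
  }
  bad <- rowSums(idx < 1L) > 0
  idx[bad, ] <- NA_integer_
  idx
}

#' Neighboring zones
#'
#' Zones whose index tuple differs by +/-1 on exactly one axis; boundary
#' zones have fewer neighbors.
#'
#' @param grid a `zs_zone_grid`.
#' @param zone zone index tuple (or linear index).
#' @return integer matrix of neighbor tuples.
#' @export
zone_neighbors <- function(grid, zone) {
  if (length(zone) == 1L && grid$dim > 1L) zone <- zone_tuple(grid, zone)[1L, ]
  zone <- as.integer(zone)
  if (length(zone) != grid$dim || any(zone < 1L) || any(zone > grid$n_per_axis))
    stop("invalid zone index")
  out <- NULL
  for (a in seq_len(grid$dim)) {
    for (s in c(-1L, 1L)) {
      nb <- zone
      nb[a] <- nb[a] + s
      if (nb[a] >= 1L && nb[a] <= grid$n_per_axis[a]) out <- rbind(out, nb)
    }
  }
  rownames(out) <- NULL
  out
}

#' Serialize / read a zone table
#'
#' TSV with columns `axis`, `zone`, `lower`, `upper`, so a published zone
#' table can be stored and reproduced exactly.
#'
#' @param grid a `zs_zone_grid`.
#' @param file path.
#' @return `write_zone_table`: `file` invisibly; `read_zone_table`: a
#'   `zs_zone_grid`.
#' @export
write_zone_table <- function(grid, file) {
  rows <- do.call(rbind, lapply(grid$axes, function(a) {
    data.frame(axis = a$label, zone = seq_len(a$n_zones),
               lower = a$edges[, 1L], upper = a$edges[, 2L])
  }))
  utils::write.table(format(rows, digits = 12, trim = TRUE), file = file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_zone_table
#' @export
read_zone_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  axes <- lapply(split(tab, factor(tab$axis, levels = unique(tab$axis))),
                 function(d) {
                   d <- d[order(d$zone), ]
                   zone_axis(d$axis[1L], edges = cbind(d$lower, d$upper),
                             lower = NA, upper = NA, n_zones = nrow(d))
                 })
  zone_grid(unname(axes))
}
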