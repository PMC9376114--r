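# Canonical-density estimation over the zone grid: histogram update with
# inter-zone stitching, genetic-algorithm smoothing, per-zone convergence
# diagnostic, and snapshot reweighting.

#' Canonical density surface over a zone grid
#'
#' The density is stored per (zone, intra-zone bin) cell: each zone's RC box
#' is divided into `bins_per_axis` uniform bins per axis. Values are
#' non-negative and (by default) normalized to sum 1 over all cells.
#'
#' @param grid a `zs_zone_grid`.
#' @param bins_per_axis intra-zone bins per axis (default 10).
#' @param values optional Z x B matrix (Z zones, B = bins_per_axis^D cells);
#'   default uniform.
#' @param normalize renormalize to sum 1 (default TRUE).
#' @return object of class `zs_q_surface`.
#' @export
q_surface <- function(grid, bins_per_axis = 10L, values = NULL,
                      normalize = TRUE) {
  b <- as.integer(bins_per_axis)
  stopifnot(b >= 1L)
  B <- b^grid$dim
  if (is.null(values)) values <- matrix(1, grid$n_zones, B)
  values <- matrix(as.numeric(values), grid$n_zones, B)
  if (any(values < 0) || !all(is.finite(values))) {
    stop("Q values must be finite and non-negative")
  }
  if (normalize) {
    s <- sum(values)
    if (s <= 0) stop("Q surface has zero total mass")
    values <- values / s
  }
  structure(list(grid = grid, bins_per_axis = b, n_bins = B, values = values),
            class = "zs_q_surface")
}

# per-axis bin index within a zone (clamped to [1, b])
bin_axis_index <- function(q, axis, zone_ax_idx, x) {
  e <- q$grid$axes[[axis]]$edges[zone_ax_idx, ]
  pmin(pmax(floor((x - e[1L]) / (e[2L] - e[1L]) * q$bins_per_axis) + 1L, 1L),
       q$bins_per_axis)
}

# linear intra-zone bin index of lambda within zone (linear index)
bin_of <- function(q, zone_lin, lambda) {
  tup <- zone_tuple(q$grid, zone_lin)[1L, ]
  idx <- vapply(seq_len(q$grid$dim), function(a) {
    bin_axis_index(q, a, tup[a], lambda[a])
  }, 0)
  as.integer(sum((idx - 1L) * q$bins_per_axis^(seq_len(q$grid$dim) - 1L)) + 1L)
}

#' Density value of a Q surface at an RC point within a zone
#'
#' @param q a `zs_q_surface`.
#' @param zone_lin linear zone index.
#' @param lambda RC vector.
#' @return the (zone, bin) cell value.
#' @export
q_value <- function(q, zone_lin, lambda) {
  q$values[zone_lin, bin_of(q, zone_lin, lambda)]
}

# bin centers of a zone: B x D matrix
zone_bin_centers <- function(q, zone_lin) {
  tup <- zone_tuple(q$grid, zone_lin)[1L, ]
  per_axis <- lapply(seq_len(q$grid$dim), function(a) {
    e <- q$grid$axes[[a]]$edges[tup[a], ]
    e[1L] + (seq_len(q$bins_per_axis) - 0.5) * (e[2L] - e[1L]) / q$bins_per_axis
  })
  as.matrix(do.call(expand.grid, per_axis))
}

# volume of one intra-zone bin of a zone
zone_bin_volume <- function(q, zone_lin) {
  tup <- zone_tuple(q$grid, zone_lin)[1L, ]
  prod(vapply(seq_len(q$grid$dim), function(a) {
    e <- q$grid$axes[[a]]$edges[tup[a], ]
    (e[2L] - e[1L]) / q$bins_per_axis
  }, 0))
}

# indices of zone z's bins whose centers lie inside zone z2's box
overlap_bins <- function(q, z, z2) {
  ctr <- zone_bin_centers(q, z)
  box <- zone_box(q$grid, zone_tuple(q$grid, z2)[1L, ])
  inside <- rep(TRUE, nrow(ctr))
  for (a in seq_len(q$grid$dim)) {
    inside <- inside & ctr[, a] >= box["lower", a] & ctr[, a] <= box["upper", a]
  }
  which(inside)
}

# adjacency list of linear zone indices
zone_adjacency <- function(grid) {
  lapply(seq_len(grid$n_zones), function(z) {
    zone_linear(grid, zone_neighbors(grid, zone_tuple(grid, z)[1L, ]))
  })
}

#' Per-cell snapshot counts on a Q surface's binning
#'
#' Snapshots whose RC vector lies outside their recorded zone's box (the
#' flat-bottom restraint is soft, so walkers spill slightly past the walls)
#' are excluded: clamping them into edge cells would bias the within-zone
#' shape.
#'
#' @param snapshots snapshot data.frame with `zone` and `lambda*` columns.
#' @param q a `zs_q_surface` (defines the binning).
#' @return Z x B count matrix.
#' @export
zone_bin_counts <- function(snapshots, q) {
  D <- q$grid$dim
  lam <- as.matrix(snapshots[paste0("lambda", seq_len(D))])
  counts <- matrix(0, q$grid$n_zones, q$n_bins)
  inz <- in_zone_box(q$grid, snapshots$zone, lam)
  bins <- cell_bins(q, snapshots$zone[inz], lam[inz, , drop = FALSE])
  tab <- table(factor(snapshots$zone[inz], levels = seq_len(q$grid$n_zones)),
               factor(bins, levels = seq_len(q$n_bins)))
  counts[] <- as.numeric(tab)
  counts
}

# vectorized intra-zone bin index for (zone, lambda) pairs
cell_bins <- function(q, zone_lin, lam) {
  if (length(zone_lin) == 0L) return(integer(0))
  tup <- zone_tuple(q$grid, zone_lin)
  b <- q$bins_per_axis
  bin <- rep(1L, nrow(lam))
  mult <- 1L
  for (a in seq_len(q$grid$dim)) {
    e <- q$grid$axes[[a]]$edges
    lo <- e[tup[, a], 1L]
    hi <- e[tup[, a], 2L]
    ib <- pmin(pmax(floor((lam[, a] - lo) / (hi - lo) * b) + 1L, 1L), b)
    bin <- bin + (ib - 1L) * mult
    mult <- mult * b
  }
  as.integer(bin)
}

# TRUE where lambda (rows) lies inside the box of its recorded zone
in_zone_box <- function(grid, zone_lin, lam) {
  tup <- zone_tuple(grid, zone_lin)
  ok <- rep(TRUE, nrow(lam))
  for (a in seq_len(grid$dim)) {
    e <- grid$axes[[a]]$edges
    ok <- ok & lam[, a] >= e[tup[, a], 1L] & lam[, a] <= e[tup[, a], 2L]
  }
  ok
}

#' Update the canonical density from iteration histograms
#'
#' Within each zone the new unnormalized density is proportional to
#' `q_prev * observed / expected` per cell, with `expected` the previous
#' within-zone distribution scaled to the zone's total count and add-one
#' smoothing applied to empty observed cells; the within-zone shape therefore
#' follows the observation while the zone's mass is carried over. Zone masses
#' are then stitched by matching the average density over the shared overlap
#' cells of neighboring zones (breadth-first from the best-sampled zone), and
#' the surface is renormalized to sum 1. Zones with zero total counts carry
#' their previous values through (logged).
#'
#' @param q_prev a `zs_q_surface`.
#' @param counts Z x B count matrix on the same binning
#'   (see [zone_bin_counts()]).
#' @return updated `zs_q_surface`.
#' @export
update_q <- function(q_prev, counts) {
  counts <- matrix(as.numeric(counts), q_prev$grid$n_zones, q_prev$n_bins)
  Z <- q_prev$grid$n_zones
  vals <- q_prev$values
  new <- vals
  tot <- rowSums(counts)
  empty_zones <- which(tot == 0)
  if (length(empty_zones)) {
    message("zone(s) with zero counts carried through unchanged: ",
            paste(empty_zones, collapse = ","))
  }
  for (z in which(tot > 0)) {
    obs <- counts[z, ]
    obs[obs == 0] <- 1  # add-one smoothing on empty observed cells
    zmass <- sum(vals[z, ])
    if (zmass <= 0) zmass <- 1 / Z
    expected <- if (sum(vals[z, ]) > 0) vals[z, ] / sum(vals[z, ]) * sum(obs)
                else rep(sum(obs) / length(obs), length(obs))
    upd <- vals[z, ] * obs / expected
    upd[!is.finite(upd)] <- obs[!is.finite(upd)] * zmass / sum(obs)
    new[z, ] <- upd / sum(upd) * zmass
  }
  new <- stitch_zones(q_prev, new, start = which.max(tot))
  q_surface(q_prev$grid, q_prev$bins_per_axis, new, normalize = TRUE)
}

# rescale zone masses so neighboring zones agree on their overlap regions
stitch_zones <- function(q, vals, start = 1L) {
  adj <- zone_adjacency(q$grid)
  Z <- q$grid$n_zones
  visited <- rep(FALSE, Z)
  queue <- as.integer(start)
  visited[start] <- TRUE
  while (length(queue)) {
    z <- queue[1L]
    queue <- queue[-1L]
    for (z2 in adj[[z]]) {
      if (visited[z2]) next
      ob_z <- overlap_bins(q, z, z2)
      ob_z2 <- overlap_bins(q, z2, z)
      if (length(ob_z) && length(ob_z2)) {
        dz <- mean(vals[z, ob_z]) / zone_bin_volume(q, z)
        dz2 <- mean(vals[z2, ob_z2]) / zone_bin_volume(q, z2)
        if (dz > 0 && dz2 > 0) vals[z2, ] <- vals[z2, ] * dz / dz2
      }
      visited[z2] <- TRUE
      queue <- c(queue, z2)
    }
  }
  vals
}

#' Genetic-algorithm smoothing of a Q surface
#'
#' Candidates are log-density surfaces. The fitness is minus the sum over
#' all neighboring zone pairs of the squared mismatch of mean log-density on
#' their shared overlap cells, minus a (small) roughness penalty on squared
#' second differences along each axis within each zone, minus a within-zone
#' shape-fidelity anchor that keeps the measured intra-zone structure while
#' the zone offsets are free to move (see `shape_weight`). Selection is
#' tournament, crossover exchanges whole zones between parents, mutation
#' adds Gaussian noise to log values, and the best candidate is carried over
#' unchanged (elitism), so fitness never decreases across generations. The
#' fittest candidate is returned, renormalized.
#'
#' @param q a `zs_q_surface`.
#' @param population population size.
#' @param generations number of generations.
#' @param tournament tournament size.
#' @param crossover per-zone exchange probability between paired parents.
#' @param mutation_sigma sd of the additive Gaussian mutation on log values.
#' @param roughness_weight weight of the roughness penalty.
#' @param shape_weight weight of the within-zone shape-fidelity anchor: the
#'   deviation of each zone's mean-removed log-density from the input's is
#'   penalized, so the GA adjusts zone offsets (the seam-stitching degrees
#'   of freedom) while the measured within-zone shape is preserved; set to 0
#'   for a pure consistency/smoothness fitness.
#' @param seed RNG seed (deterministic output).
#' @return refined `zs_q_surface`.
#' @export
ga_refine <- function(q, population = 32L, generations = 100L,
                      tournament = 3L, crossover = 0.7,
                      mutation_sigma = 0.05, roughness_weight = 0.01,
                      shape_weight = 1, seed = 1L) {
  set.seed(as.integer(seed))
  Z <- q$grid$n_zones
  B <- q$n_bins
  vals <- q$values
  floorv <- if (any(vals > 0)) min(vals[vals > 0]) * 1e-3 else 1e-12
  L0 <- log(pmax(vals, floorv))
  adj <- zone_adjacency(q$grid)
  pairs <- do.call(rbind, lapply(seq_len(Z), function(z) {
    nb <- adj[[z]][adj[[z]] > z]
    if (length(nb)) cbind(z, nb) else NULL
  }))
  if (is.null(pairs)) pairs <- matrix(0L, 0L, 2L)
  ov <- lapply(seq_len(nrow(pairs)), function(i) {
    list(a = overlap_bins(q, pairs[i, 1], pairs[i, 2]),
         b = overlap_bins(q, pairs[i, 2], pairs[i, 1]),
         lva = log(zone_bin_volume(q, pairs[i, 1])),
         lvb = log(zone_bin_volume(q, pairs[i, 2])))
  })
  b1 <- q$bins_per_axis
  D <- q$grid$dim
  # within-zone shapes of the input (zone means removed): the data anchor
  shape0 <- L0 - rowMeans(L0)
  fitness <- function(L) {
    mism <- 0
    for (i in seq_along(ov)) {
      o <- ov[[i]]
      if (!length(o$a) || !length(o$b)) next
      mism <- mism + (mean(L[pairs[i, 1], o$a]) - o$lva -
                        (mean(L[pairs[i, 2], o$b]) - o$lvb))^2
    }
    fid <- sum(((L - rowMeans(L)) - shape0)^2)
    rough <- 0
    for (z in seq_len(Z)) {
      if (D == 1L) {
        if (b1 >= 3L) rough <- rough + sum(diff(L[z, ], differences = 2L)^2)
      } else {
        arr <- array(L[z, ], dim = rep(b1, D))
        for (a in seq_len(D)) {
          d2 <- apply(arr, setdiff(seq_len(D), a), function(v) {
            if (length(v) >= 3L) sum(diff(v, differences = 2L)^2) else 0
          })
          rough <- rough + sum(d2)
        }
      }
    }
    f <- -(mism + roughness_weight * rough + shape_weight * fid)
    if (!is.finite(f)) -Inf else f
  }
  pop <- c(list(L0), lapply(seq_len(population - 1L), function(i) {
    L0 + matrix(stats::rnorm(Z * B, sd = mutation_sigma), Z, B)
  }))
  fit <- vapply(pop, fitness, 0)
  for (g in seq_len(generations)) {
    elite <- pop[[which.max(fit)]]
    elite_fit <- max(fit)
    newpop <- vector("list", population)
    newpop[[1L]] <- elite
    i <- 2L
    while (i <= population) {
      sel <- function() {
        cand <- sample.int(population, tournament, replace = TRUE)
        pop[[cand[which.max(fit[cand])]]]
      }
      p1 <- sel(); p2 <- sel()
      swap <- stats::runif(Z) < crossover
      c1 <- p1; c1[swap, ] <- p2[swap, ]
      c1 <- c1 + matrix(stats::rnorm(Z * B, sd = mutation_sigma), Z, B)
      newpop[[i]] <- c1
      i <- i + 1L
    }
    pop <- newpop
    fit <- vapply(pop, fitness, 0)
    keep <- is.finite(fit)
    if (!all(keep)) {  # discard non-finite candidates in favour of the elite
      pop[!keep] <- list(elite)
      fit[!keep] <- elite_fit
    }
    if (max(fit) < elite_fit) {  # elitist carry-over
      pop[[1L]] <- elite
      fit[1L] <- elite_fit
    }
  }
  best <- pop[[which.max(fit)]]
  q_surface(q$grid, q$bins_per_axis, exp(best), normalize = TRUE)
}

#' Per-zone convergence diagnostic
#'
#' In the default `"iteration"` mode the diagnostic compares consecutive
#' density estimates: per zone, the mean over the zone's cells of
#' `|log(q_curr / q_prev)|` (cells where both are zero are skipped; one-sided
#' zeros are floored at half the smallest positive value so log ratios stay
#' finite). A zone with a value below `threshold` (default 0.25) is judged
#' accurately determined. The `"overlap"` mode instead measures, for a single
#' surface, the mean absolute mismatch of mean log-density against each
#' neighbor on their shared overlap cells.
#'
#' @param q_curr current `zs_q_surface`.
#' @param q_prev previous surface (required for `"iteration"` mode).
#' @param threshold convergence threshold (default 0.25).
#' @param mode `"iteration"` (default) or `"overlap"`.
#' @param iteration optional iteration number carried into the report.
#' @return object of class `zs_convergence_report`: list with `e_local`
#'   (per-zone), `converged_zones`, `converged` (logical vector),
#'   `threshold`, `iteration`.
#' @export
e_local <- function(q_curr, q_prev = NULL, threshold = 0.25,
                    mode = c("iteration", "overlap"), iteration = NA_integer_) {
  mode <- match.arg(mode)
  Z <- q_curr$grid$n_zones
  if (mode == "iteration") {
    if (is.null(q_prev)) stop("iteration mode needs q_prev")
    if (q_curr$n_bins != q_prev$n_bins ||
        q_curr$grid$n_zones != q_prev$grid$n_zones) {
      stop("binning mismatch between the two surfaces")
    }
    a <- q_curr$values
    b <- q_prev$values
    pos <- c(a[a > 0], b[b > 0])
    fl <- if (length(pos)) min(pos) / 2 else 1
    e <- vapply(seq_len(Z), function(z) {
      va <- a[z, ]; vb <- b[z, ]
      both0 <- va == 0 & vb == 0
      va <- pmax(va[!both0], fl)
      vb <- pmax(vb[!both0], fl)
      if (!length(va)) 0 else mean(abs(log(va / vb)))
    }, 0)
  } else {
    adj <- zone_adjacency(q_curr$grid)
    fl <- {
      pos <- q_curr$values[q_curr$values > 0]
      if (length(pos)) min(pos) / 2 else 1
    }
    e <- vapply(seq_len(Z), function(z) {
      nb <- adj[[z]]
      if (!length(nb)) return(0)
      mean(vapply(nb, function(z2) {
        oa <- overlap_bins(q_curr, z, z2)
        ob <- overlap_bins(q_curr, z2, z)
        if (!length(oa) || !length(ob)) return(0)
        da <- mean(pmax(q_curr$values[z, oa], fl)) / zone_bin_volume(q_curr, z)
        db <- mean(pmax(q_curr$values[z2, ob], fl)) / zone_bin_volume(q_curr, z2)
        abs(log(da / db))
      }, 0))
    }, 0)
  }
  structure(list(iteration = iteration, e_local = e,
                 converged = e < threshold,
                 converged_zones = sum(e < threshold),
                 threshold = threshold),
            class = "zs_convergence_report")
}

#' @export
print.zs_convergence_report <- function(x, ...) {
  cat(sprintf("<zs_convergence_report> %d/%d zones converged (E_local < %.2f)\n",
              x$converged_zones, length(x$e_local), x$threshold))
  invisible(x)
}

#' Assign canonical weights to snapshots
#'
#' The thermodynamic weight of a snapshot is proportional to the canonical
#' density of its (zone, bin) cell divided by the number of snapshots
#' recorded in that cell (the sampled marginal); weights are normalized to
#' sum 1 over the ensemble.
#'
#' @param snapshots snapshot data.frame with `zone` and `lambda*` columns.
#' @param q a `zs_q_surface`.
#' @param sampled_marginal optional Z x B count matrix; defaults to
#'   `zone_bin_counts(snapshots, q)`.
#' @return `snapshots` with a normalized `weight` column.
#' @export
snapshot_weights <- function(snapshots, q, sampled_marginal = NULL) {
  if (is.null(sampled_marginal)) sampled_marginal <- zone_bin_counts(snapshots, q)
  D <- q$grid$dim
  lam <- as.matrix(snapshots[paste0("lambda", seq_len(D))])
  n <- nrow(snapshots)
  w <- numeric(n)
  inz <- in_zone_box(q$grid, snapshots$zone, lam)
  idx <- which(inz)
  bins <- cell_bins(q, snapshots$zone[idx], lam[idx, , drop = FALSE])
  cells <- cbind(snapshots$zone[idx], bins)
  cnt <- sampled_marginal[cells]
  qv <- q$values[cells]
  w[idx] <- ifelse(cnt > 0, qv / cnt, 0)
  qzero <- sum(w[inz] == 0)
  if (qzero > 0) {
    warning(qzero, " snapshot(s) fall in cells with zero canonical ",
            "density; their weight is 0")
  }
  if (sum(w) <= 0) stop("all snapshot weights are zero")
  snapshots$weight <- w / sum(w)
  snapshots
}

#' Weighted histogram over plain bins
#'
#' @param x numeric values.
#' @param w weights (normalized internally).
#' @param edges bin edges (length nbins + 1); values outside are dropped.
#' @return vector of bin probabilities summing to 1.
#' @export
weighted_histogram <- function(x, w, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= length(edges) - 1L
  p <- vapply(seq_len(length(edges) - 1L), function(i) {
    sum(w[keep][idx[keep] == i])
  }, 0)
  p / sum(p)
}
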