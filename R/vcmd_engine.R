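# Virtual-system coupled sampling engine: flat-bottom zone confinement,
# inter-zone transitions on a fixed cadence driven by the current canonical
# density estimate, multi-run iteration scheduling, snapshot recording.

#' Sampler configuration
#'
#' Defaults are the production schedule of the method (2 fs step, transition
#' attempt every 10^4 steps = 20 ps, 2000 runs of 10^6 steps per iteration,
#' snapshot every 10^5 steps, 300 K); desk-scale work passes smaller values
#' explicitly.
#'
#' @param time_step integration time step in fs.
#' @param transition_interval_steps steps between inter-zone transition
#'   attempts.
#' @param temperature simulation temperature in K.
#' @param restraint_spring flat-bottom restraint spring in kcal/mol/A^2.
#' @param runs_per_iteration parallel runs per iteration (N_run).
#' @param steps_per_run steps per run.
#' @param snapshot_interval_steps steps between stored snapshots.
#' @param rng_seed master seed; per-run streams are derived from
#'   (seed, iteration, run) so run order never changes results.
#' @return object of class `zs_engine_config`.
#' @export
engine_config <- function(time_step = 2,
                          transition_interval_steps = 10000L,
                          temperature = 300,
                          restraint_spring = 10,
                          runs_per_iteration = 2000L,
                          steps_per_run = 1000000L,
                          snapshot_interval_steps = 100000L,
                          rng_seed = 1L) {
  cfg <- list(time_step = time_step,
              transition_interval_steps = as.integer(transition_interval_steps),
              temperature = temperature,
              restraint_spring = restraint_spring,
              runs_per_iteration = as.integer(runs_per_iteration),
              steps_per_run = as.integer(steps_per_run),
              snapshot_interval_steps = as.integer(snapshot_interval_steps),
              rng_seed = as.integer(rng_seed))
  num <- vapply(cfg, function(v) v[1L], 0)
  if (any(num <= 0)) stop("all engine parameters must be positive")
  if (cfg$transition_interval_steps > cfg$steps_per_run) {
    stop("transition_interval_steps must not exceed steps_per_run")
  }
  structure(cfg, class = "zs_engine_config")
}

#' Flat-bottom zone restraint
#'
#' Zero energy and gradient inside the zone's RC box; outside, a half-
#' harmonic penalty `0.5 * k * delta^2` per axis, with `delta` the overshoot
#' beyond the nearer edge. Continuous and once-differentiable everywhere.
#'
#' @param lambda numeric D-vector of RC values.
#' @param zone zone index tuple (or linear index).
#' @param grid a `zs_zone_grid`.
#' @param spring spring constant k in kcal/mol/A^2.
#' @return list with `energy` (kcal/mol) and `gradient` (dE/d lambda).
#' @export
restraint <- function(lambda, zone, grid, spring) {
  if (length(zone) == 1L && grid$dim > 1L) zone <- zone_tuple(grid, zone)[1L, ]
  box <- zone_box(grid, zone)
  below <- unname(pmax(box["lower", ] - lambda, 0))
  above <- unname(pmax(lambda - box["upper", ], 0))
  list(energy = 0.5 * spring * sum(below^2 + above^2),
       gradient = spring * (above - below))
}

# restraint force (-dE/dlambda), vectorized over runs (rows)
restraint_force_mat <- function(X, box_lo, box_hi, spring) {
  spring * (pmax(box_lo - X, 0) - pmax(X - box_hi, 0))
}

#' Overdamped Langevin backend on a toy potential
#'
#' The bundled dynamics backend: the sampler state *is* the RC vector
#' (identity mapping), evolved by overdamped Langevin dynamics on an
#' analytic potential. The default discretization averages consecutive
#' noise increments (Leimkuhler-Matthews), whose stationary distribution is
#' accurate to O(dt^2); the plain Euler-Maruyama update (O(dt) stationary
#' bias, visible as a flattening of sharp wells) is available for
#' comparison. Coupling a real MD engine is out of scope; any object
#' providing `dim`, `dt`, `friction`, `force(states)`, `rc(states)` and
#' `method` can stand in.
#'
#' @param potential a `zs_potential`.
#' @param dt time step in reduced units.
#' @param friction friction coefficient gamma.
#' @param method `"leimkuhler-matthews"` (default) or `"euler-maruyama"`.
#' @return backend list.
#' @export
make_langevin_backend <- function(potential, dt = 0.01, friction = 1,
                                  method = c("leimkuhler-matthews",
                                             "euler-maruyama")) {
  list(dim = potential$dim, dt = dt, friction = friction,
       force = potential$force,
       rc = function(X) X,
       method = match.arg(method))
}

# derived per-run RNG seed; kept well below 2^31 and exact in doubles
derive_seed <- function(rng_seed, iteration, run) {
  as.integer(((rng_seed %% 1000003) * 1009 + iteration * 131071 + run * 257) %%
               2147483629 + 1)
}

# per-zone mass of a Q surface (sum of bin values per zone)
q_zone_mass <- function(q) rowSums(q$values)

#' Attempt an inter-zone transition
#'
#' The candidate set consists of every zone containing the instantaneous RC
#' vector (the current zone plus overlapping neighbors). If the restraint
#' has let the walker drift outside its own zone the attempt is skipped (the
#' walker stays and the restraint pulls it back; relabelling a spilled
#' walker would be a one-way move that violates detailed balance). The
#' destination is drawn with probability proportional to each
#' candidate's *zone-normalized* canonical density at lambda,
#' `Q(lambda) / mass(zone)`; this satisfies detailed balance for the
#' zone-flattened target the sampler aims at. If every candidate has zero
#' density the walker stays put.
#'
#' @param current current zone (tuple or linear index).
#' @param lambda RC vector.
#' @param q a `zs_q_surface`.
#' @param grid a `zs_zone_grid`.
#' @param u optional pre-drawn uniform variate in (0,1); default `runif(1)`.
#' @return linear index of the destination zone.
#' @export
attempt_transition <- function(current, lambda, q, grid, u = NULL) {
  cur <- if (length(current) > 1L) zone_linear(grid, current) else as.integer(current)
  cand <- tryCatch(zone_linear(grid, zone_membership(grid, lambda)),
                   zs_out_of_range = function(e) integer(0))
  # a walker that has spilled outside its own zone stays put (the restraint
  # pulls it back): one-way relabelling would break detailed balance and
  # drain edge zones toward the centre
  if (!(cur %in% cand)) return(cur)
  if (length(cand) == 1L) return(cand)
  mass <- q_zone_mass(q)[cand]
  w <- vapply(seq_along(cand), function(i) {
    if (mass[i] <= 0) return(0)
    q_value(q, cand[i], lambda) / mass[i]
  }, 0)
  if (sum(w) <= 0) return(cur)  # all candidates empty: stay (logged upstream)
  if (is.null(u)) u <- stats::runif(1)
  cand[findInterval(u, cumsum(w) / sum(w)) + 1L]
}

#' Run one sampler iteration
#'
#' Evolves `runs_per_iteration` independent walkers under the backend
#' dynamics plus the flat-bottom zone restraint, attempting an inter-zone
#' transition every `transition_interval_steps` and recording a snapshot
#' every `snapshot_interval_steps`. Per-run RNG streams are derived from
#' `(rng_seed, iteration, run)`, so results are reproducible and independent
#' of execution order. Runs whose state turns non-finite are aborted and
#' reported; the others continue.
#'
#' @param config a `zs_engine_config`; `runs_per_iteration` must equal the
#'   number of seed states.
#' @param backend dynamics backend (see [make_langevin_backend()]).
#' @param q a `zs_q_surface` driving the transition probabilities.
#' @param grid a `zs_zone_grid`.
#' @param seeds numeric matrix of initial states, one row per run.
#' @param seed_zones optional vector of linear zone labels for the seeds
#'   (carried over from the snapshots they were selected from); by default
#'   each seed starts in the zone that contains its RC vector. A state that
#'   has spilled slightly outside its labelled zone is admissible: the
#'   restraint pulls it back.
#' @param iteration iteration number (enters the RNG stream derivation).
#' @return list with `snapshots` (data.frame: iteration, run, step, lambda.*,
#'   zone.*, zone, state.*), `histogram` (recorded visits per linear zone),
#'   and `aborted` (run indices).
#' @export
run_iteration <- function(config, backend, q, grid, seeds, seed_zones = NULL,
                          iteration = 1L) {
  seeds <- matrix(as.numeric(as.matrix(seeds)), ncol = backend$dim)
  n_run <- nrow(seeds)
  if (n_run != config$runs_per_iteration) {
    stop("number of seed states (", n_run, ") must equal runs_per_iteration (",
         config$runs_per_iteration, ")")
  }
  D <- backend$dim
  steps <- config$steps_per_run
  X <- seeds
  lam <- backend$rc(X)
  if (is.null(seed_zones)) {
    zone_t <- zone_primary(grid, lam)
    if (anyNA(zone_t)) stop("seed state(s) outside the zone-grid coverage")
    zone_l <- zone_linear(grid, zone_t)
  } else {
    zone_l <- as.integer(seed_zones)
    if (length(zone_l) != n_run) stop("one seed zone per run is required")
    zone_t <- zone_tuple(grid, zone_l)
  }
  box <- lapply(seq_len(n_run), function(r) zone_box(grid, zone_t[r, ]))
  box_lo <- matrix(vapply(box, function(b) b["lower", ], numeric(D)),
                   ncol = D, byrow = TRUE)
  box_hi <- matrix(vapply(box, function(b) b["upper", ], numeric(D)),
                   ncol = D, byrow = TRUE)

  # pre-generate per-run noise and transition uniforms from derived streams
  # (one extra noise row feeds the averaged-increment integrator)
  n_trans <- steps %/% config$transition_interval_steps
  noise <- matrix(NA_real_, (steps + 1L) * D, n_run)
  utrans <- matrix(NA_real_, max(n_trans, 1L), n_run)
  for (r in seq_len(n_run)) {
    set.seed(derive_seed(config$rng_seed, iteration, r))
    noise[, r] <- stats::rnorm((steps + 1L) * D)
    if (n_trans > 0L) utrans[, r] <- stats::runif(n_trans)
  }

  rt <- rt_kcal(config$temperature)
  sig <- sqrt(2 * rt * backend$dt / backend$friction)
  mob <- backend$dt / backend$friction
  alive <- rep(TRUE, n_run)
  n_snap <- steps %/% config$snapshot_interval_steps
  snap_rows <- vector("list", n_snap)
  ti <- 0L
  lm <- !identical(backend$method, "euler-maruyama")
  eta_prev <- matrix(noise[seq_len(D), ], ncol = D, byrow = TRUE)
  all_alive <- TRUE
  for (s in seq_len(steps)) {
    F <- backend$force(X) + restraint_force_mat(X, box_lo, box_hi,
                                                config$restraint_spring)
    eta <- matrix(noise[(s * D + 1L):((s + 1L) * D), ], ncol = D, byrow = TRUE)
    if (lm) {
      tmp <- eta
      eta <- (eta + eta_prev) / 2
      eta_prev <- tmp
    }
    if (all_alive) {
      X <- X + mob * F + sig * eta
    } else {
      X[alive, ] <- X[alive, , drop = FALSE] + mob * F[alive, , drop = FALSE] +
        sig * eta[alive, , drop = FALSE]
    }
    bad <- alive & !is.finite(rowSums(X))
    if (any(bad)) {
      warning("run(s) ", paste(which(bad), collapse = ","),
              " diverged at step ", s, " and were aborted")
      alive[bad] <- FALSE
      all_alive <- FALSE
      X[bad, ] <- seeds[bad, , drop = FALSE]  # freeze aborted runs at a finite state
    }
    # snapshots are recorded *before* a coinciding transition attempt, so a
    # stored state always has a full confinement interval behind it
    if (s %% config$snapshot_interval_steps == 0L) {
      lam <- backend$rc(X)
      k <- s %/% config$snapshot_interval_steps
      snap_rows[[k]] <- cbind(
        data.frame(iteration = iteration, run = which(alive), step = s),
        as_cols(lam[alive, , drop = FALSE], "lambda"),
        as_cols(zone_t[alive, , drop = FALSE], "zone"),
        data.frame(zone = zone_l[alive]),
        as_cols(X[alive, , drop = FALSE], "state"))
    }
    if (s %% config$transition_interval_steps == 0L) {
      ti <- ti + 1L
      lam <- backend$rc(X)
      for (r in which(alive)) {
        nz <- attempt_transition(zone_l[r], lam[r, ], q, grid, u = utrans[ti, r])
        if (nz != zone_l[r]) {
          zone_l[r] <- nz
          zt <- zone_tuple(grid, nz)[1L, ]
          zone_t[r, ] <- zt
          b <- zone_box(grid, zt)
          box_lo[r, ] <- b["lower", ]
          box_hi[r, ] <- b["upper", ]
        }
      }
    }
  }
  snapshots <- do.call(rbind, snap_rows)
  hist <- tabulate(snapshots$zone, nbins = grid$n_zones)
  list(snapshots = snapshots, histogram = hist, aborted = which(!alive))
}

as_cols <- function(m, prefix) {
  d <- as.data.frame(m)
  names(d) <- paste0(prefix, seq_len(ncol(m)))
  d
}

#' Schedule bookkeeping
#'
#' Exact integer/rational arithmetic for the iteration schedule: total steps,
#' aggregate simulated time, and stored snapshot count.
#'
#' @param config a `zs_engine_config`.
#' @param iterations number of iterations.
#' @return list with `total_iterations`, `total_runs`, `total_steps`,
#'   `iteration_time_us`, `total_simulated_time_us`, `total_snapshots`.
#' @export
plan_schedule <- function(config, iterations) {
  stopifnot(iterations >= 1)
  if (config$snapshot_interval_steps > config$steps_per_run) {
    stop("snapshot_interval_steps must not exceed steps_per_run")
  }
  runs <- as.numeric(iterations) * config$runs_per_iteration
  steps <- runs * as.numeric(config$steps_per_run)
  per_run_snaps <- config$steps_per_run %/% config$snapshot_interval_steps
  list(total_iterations = as.numeric(iterations),
       total_runs = runs,
       total_steps = steps,
       iteration_time_us = config$runs_per_iteration *
         as.numeric(config$steps_per_run) * config$time_step * 1e-9,
       total_simulated_time_us = steps * config$time_step * 1e-9,
       total_snapshots = runs * per_run_snaps)
}

#' Select seed snapshots for the next iteration
#'
#' Seeds are spread as evenly as possible over RC space, favouring poorly
#' sampled regions: zones are ranked by ascending recorded-visit count
#' (zones with zero snapshots skipped) and seeds are drawn round-robin
#' starting from the least-visited non-empty zone; within a zone the order is
#' a random permutation, cycling with replacement once a zone is exhausted.
#' Deterministic given `seed`.
#'
#' @param snapshots snapshot data.frame (needs a `zone` column).
#' @param histogram per-zone visit counts (linear indexing); defaults to the
#'   tabulation of `snapshots$zone`.
#' @param n number of seeds.
#' @param seed RNG seed.
#' @return the selected snapshot rows (possibly repeated).
#' @export
select_seeds <- function(snapshots, histogram = NULL, n, seed = 1L) {
  if (nrow(snapshots) < 1L) stop("no snapshots to select seeds from")
  stopifnot(n >= 1)
  if (is.null(histogram)) histogram <- tabulate(snapshots$zone)
  if (n > nrow(snapshots)) {
    message("more seeds requested than snapshots available; sampling with replacement")
  }
  present <- sort(unique(snapshots$zone))
  ord <- present[order(histogram[present], present)]
  set.seed(as.integer(seed))
  pools <- lapply(ord, function(z) {
    rows <- which(snapshots$zone == z)
    rows[sample.int(length(rows))]
  })
  taken <- integer(length(ord))
  picks <- integer(n)
  zi <- 0L
  for (i in seq_len(n)) {
    zi <- zi %% length(ord) + 1L
    taken[zi] <- taken[zi] + 1L
    pool <- pools[[zi]]
    picks[i] <- pool[(taken[zi] - 1L) %% length(pool) + 1L]
  }
  snapshots[picks, , drop = FALSE]
}
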