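# Reproducible command-line workflows: structured YAML config, pipeline
# driver, TSV/PDB artifact serialization, and a run manifest.

#' Validate a run configuration
#'
#' Reads a YAML configuration (path or literal text), fills documented
#' defaults, cross-checks consistency (RC/zone dimensionality against the
#' potential, mandatory seed, positive sizes) and echoes the effective
#' values. Unknown top-level keys, a missing seed, or inconsistent
#' dimensionality produce itemized errors.
#'
#' @param config path to a YAML file, or a YAML string.
#' @param quiet suppress the effective-config echo.
#' @return object of class `zs_run_config` (a validated, defaulted list).
#' @export
validate_config <- function(config, quiet = FALSE) {
  raw <- if (file.exists(config)) yaml::read_yaml(config) else yaml::yaml.load(config)
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  known <- c("seed", "output_dir", "log_level", "rc_space", "potential",
             "engine", "iterations", "ga", "convergence_threshold",
             "stop_when_converged", "min_iterations", "synthetic", "analysis")
  errs <- character()
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$seed)) errs <- c(errs, "a global rng seed is mandatory")
  dflt <- function(x, d) if (is.null(x)) d else x
  cfg <- list(
    seed = raw$seed,
    output_dir = dflt(raw$output_dir, "zonesampler-out"),
    log_level = dflt(raw$log_level, "info"),
    iterations = dflt(raw$iterations, 5L),
    convergence_threshold = dflt(raw$convergence_threshold, 0.25),
    stop_when_converged = dflt(raw$stop_when_converged, FALSE),
    min_iterations = dflt(raw$min_iterations, 2L))
  pot <- dflt(raw$potential, list())
  cfg$potential <- list(kind = dflt(pot$kind, "double_well"),
                        temperature = dflt(pot$temperature, 300),
                        params = pot[setdiff(names(pot), c("kind", "temperature"))])
  rc <- dflt(raw$rc_space, list())
  if (is.null(rc$axes)) {
    errs <- c(errs, "rc_space.axes must list the zone axes (coverage bounds are mandatory)")
    axes <- list()
  } else {
    axes <- lapply(rc$axes, function(a) {
      if (is.null(a$lower) || is.null(a$upper)) {
        stop("zone axis '", dflt(a$label, "?"),
             "': lower and upper coverage bounds are mandatory")
      }
      zone_axis(dflt(a$label, "rc"), a$lower, a$upper, dflt(a$n_zones, 6L),
                dflt(a$overlap_fraction, 0.5))
    })
  }
  cfg$rc_space <- list(axes = axes, bins_per_axis = dflt(rc$bins_per_axis, 10L))
  eng <- dflt(raw$engine, list())
  cfg$engine <- list(
    time_step = dflt(eng$time_step, 0.01),
    friction = dflt(eng$friction, 1),
    temperature = dflt(eng$temperature, cfg$potential$temperature),
    restraint_spring = dflt(eng$restraint_spring, 20),
    transition_interval_steps = dflt(eng$transition_interval_steps, 50L),
    runs_per_iteration = dflt(eng$runs_per_iteration, 100L),
    steps_per_run = dflt(eng$steps_per_run, 2000L),
    snapshot_interval_steps = dflt(eng$snapshot_interval_steps, 100L))
  ga <- dflt(raw$ga, list())
  cfg$ga <- list(population = dflt(ga$population, 32L),
                 generations = dflt(ga$generations, 100L),
                 tournament = dflt(ga$tournament, 3L),
                 crossover = dflt(ga$crossover, 0.7),
                 mutation_sigma = dflt(ga$mutation_sigma, 0.05),
                 roughness_weight = dflt(ga$roughness_weight, 0.01))
  syn <- dflt(raw$synthetic, list())
  cfg$synthetic <- list(n_snapshots = dflt(syn$n_snapshots, 2000L))
  ana <- dflt(raw$analysis, list())
  cfg$analysis <- list(cutoff = dflt(ana$cutoff, 5),
                       cube_edge = dflt(ana$cube_edge, 3),
                       rmsd_bin_width = dflt(ana$rmsd_bin_width, 0.5))
  # dimensionality cross-check
  pdim <- switch(cfg$potential$kind, binding_funnel = 3L, 1L)
  if (length(axes) && length(axes) != pdim) {
    errs <- c(errs, sprintf(
      "dimensionality mismatch: %d zone axes but the '%s' potential has %d RC(s)",
      length(axes), cfg$potential$kind, pdim))
  }
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  if (!quiet) {
    message(sprintf(
      "config: seed=%s, potential=%s, %d axis/axes, %d iterations, %d runs x %d steps",
      cfg$seed, cfg$potential$kind, length(axes), cfg$iterations,
      cfg$engine$runs_per_iteration, cfg$engine$steps_per_run))
  }
  structure(cfg, class = "zs_run_config")
}

#' Emit the effective configuration as YAML
#'
#' Re-validating the emitted text reproduces the same configuration
#' (fixed-point round trip).
#'
#' @param cfg a `zs_run_config`.
#' @return YAML string.
#' @export
emit_config <- function(cfg) {
  out <- list(
    seed = cfg$seed, output_dir = cfg$output_dir, log_level = cfg$log_level,
    iterations = cfg$iterations,
    convergence_threshold = cfg$convergence_threshold,
    potential = c(list(kind = cfg$potential$kind,
                       temperature = cfg$potential$temperature),
                  cfg$potential$params),
    rc_space = list(
      axes = lapply(cfg$rc_space$axes, function(a) {
        list(label = a$label, lower = a$lower, upper = a$upper,
             n_zones = a$n_zones)
      }),
      bins_per_axis = cfg$rc_space$bins_per_axis),
    engine = cfg$engine, ga = cfg$ga, synthetic = cfg$synthetic,
    analysis = cfg$analysis)
  yaml::as.yaml(out)
}

fmt_tsv <- function(df, file) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write / read sampler snapshots as TSV
#'
#' Columns: iteration, run, step, per-axis RC values (`lambda*`), per-axis
#' zone indices (`zone*`), linear `zone`, toy state columns (`state*`) and,
#' when assigned, `weight`. Floating-point formatting is pinned so identical
#' configurations give byte-identical files.
#'
#' @param snapshots snapshot data.frame.
#' @param file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_snapshots_tsv <- function(snapshots, file) fmt_tsv(snapshots, file)

#' @rdname write_snapshots_tsv
#' @export
read_snapshots_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a Q surface as TSV
#'
#' One row per (zone, intra-zone bin) cell: the linear zone index, the zone
#' tuple, the bin tuple, the bin-center RC values and the cell value.
#'
#' @param q a `zs_q_surface`.
#' @param file path.
#' @param grid zone grid (needed to rebuild the surface when reading).
#' @return the path (write) or a `zs_q_surface` (read).
#' @export
write_q_tsv <- function(q, file) {
  D <- q$grid$dim
  rows <- do.call(rbind, lapply(seq_len(q$grid$n_zones), function(z) {
    ctr <- zone_bin_centers(q, z)
    tup <- zone_tuple(q$grid, z)[1L, ]
    d <- data.frame(zone = z)
    for (a in seq_len(D)) d[[paste0("zone", a)]] <- tup[a]
    d <- d[rep(1L, q$n_bins), , drop = FALSE]
    d$bin <- seq_len(q$n_bins)
    for (a in seq_len(D)) d[[paste0("center", a)]] <- ctr[, a]
    d$value <- q$values[z, ]
    d
  }))
  fmt_tsv(rows, file)
}

#' @rdname write_q_tsv
#' @export
read_q_tsv <- function(file, grid) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  b <- round(max(tab$bin)^(1 / grid$dim))
  vals <- matrix(0, grid$n_zones, max(tab$bin))
  vals[cbind(tab$zone, tab$bin)] <- tab$value
  q_surface(grid, b, vals, normalize = FALSE)
}

#' Write a weighted ensemble to disk
#'
#' Snapshot table as TSV (id, weight, model reference) plus the snapshot
#' coordinates as a multi-model PDB and the reference structure as PDB.
#'
#' @param ensemble a `zs_ensemble`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_ensemble_files <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ensemble$coords)[3L]
  tab <- ensemble$snapshots
  tab$model <- seq_len(n)
  tab$structure_file <- "models.pdb"
  fmt_tsv(tab, file.path(dir, "ensemble.tsv"))
  models <- lapply(seq_len(n), function(i) snapshot_structure(ensemble, i))
  write_pdb(models, file.path(dir, "models.pdb"))
  write_pdb(ensemble$reference, file.path(dir, "reference.pdb"))
  invisible(dir)
}

#' Read a weighted ensemble written by [write_ensemble_files()]
#'
#' The bundled toy-template groups are re-attached when the atom table
#' matches the template.
#'
#' @param dir directory holding ensemble.tsv / models.pdb / reference.pdb.
#' @return a `zs_ensemble`.
#' @export
read_ensemble_files <- function(dir) {
  tab <- utils::read.table(file.path(dir, "ensemble.tsv"), header = TRUE,
                           sep = "\t")
  models <- read_pdb(file.path(dir, "models.pdb"))
  ref <- read_pdb(file.path(dir, "reference.pdb"))[[1L]]
  coords <- array(NA_real_, c(nrow(ref$atoms), 3L, length(models)))
  for (i in seq_along(models)) coords[, , i] <- models[[i]]$xyz
  tpl <- toy_complex_template()
  same <- nrow(tpl$reference$atoms) == nrow(ref$atoms) &&
    all(tpl$reference$atoms$name == ref$atoms$name)
  weighted_ensemble(
    atoms = ref$atoms, coords = coords,
    snapshots = tab[, c("id", "weight")], reference = ref,
    align_group = if (same) tpl$groups$align else
      atom_group("align", serials = ref$atoms$serial[!ref$atoms$hetatm]),
    groups = if (same) tpl$groups else list(),
    anchors = if (same) tpl$anchors else NULL,
    contacts = if (same) tpl$contacts else NULL,
    tail_residues = if (same) tpl$tail_residues else NULL,
    membrane_z = if (same) tpl$membrane_z else NULL)
}

#' Run one pipeline command
#'
#' Drives the sampler loop and the analyses with artifacts on disk:
#' \describe{
#'   \item{generate-toy}{synthetic weighted ensemble -> ensemble.tsv,
#'     models.pdb, reference.pdb, truth.json.}
#'   \item{sample}{iterative zone sampling on the configured toy potential:
#'     snapshots.tsv, zones.tsv, q.tsv, convergence.tsv.}
#'   \item{estimate-q}{histogram update + GA smoothing from snapshots.tsv
#'     -> q.tsv.}
#'   \item{convergence}{per-zone diagnostic between q.tsv and q_prev.tsv ->
#'     convergence.tsv.}
#'   \item{reweight}{canonical weights for snapshots.tsv under q.tsv ->
#'     weights.tsv.}
#'   \item{analyze}{binding statistics of the generate-toy ensemble ->
#'     density.dx, residue_contact_pmf.tsv, native_contacts.tsv, rmsd.tsv,
#'     orientation.tsv.}
#' }
#' A manifest (JSON) records the command, inputs, seed and package version.
#'
#' @param cfg a `zs_run_config`.
#' @param command one of the commands above.
#' @return invisible list of written artifact paths.
#' @export
run_pipeline <- function(cfg, command = c("generate-toy", "sample",
                                          "estimate-q", "convergence",
                                          "reweight", "analyze")) {
  command <- match.arg(command)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(cfg$output_dir, command)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- switch(command,
    "generate-toy" = pipe_generate_toy(cfg, out),
    "sample" = pipe_sample(cfg, out),
    "estimate-q" = pipe_estimate_q(cfg, out),
    "convergence" = pipe_convergence(cfg, out),
    "reweight" = pipe_reweight(cfg, out),
    "analyze" = pipe_analyze(cfg, out))
  manifest <- list(command = command, seed = cfg$seed,
                   artifacts = unname(unlist(art)),
                   package = as.character(utils::packageVersion("zonesampler")),
                   config = yaml::yaml.load(emit_config(cfg)))
  mf <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(art, manifest = mf))
}

pipe_generate_toy <- function(cfg, out) {
  spec <- synthetic_ensemble_spec(n_snapshots = cfg$synthetic$n_snapshots,
                                  seed = cfg$seed)
  gen <- generate_binding_ensemble(spec)
  write_ensemble_files(gen$ensemble, out)
  tf <- file.path(out, "truth.json")
  jsonlite::write_json(list(r_bb = gen$truth$r_bb, slice = gen$truth$slice,
                            tail_contacts = gen$truth$tail_contacts,
                            native_contacts = gen$truth$native_contacts),
                       tf, digits = NA)
  list(dir = out, truth = tf)
}

# build grid/potential/backend/config from a run configuration
toy_setup <- function(cfg) {
  grid <- zone_grid(cfg$rc_space$axes)
  pot <- do.call(toy_potential, c(list(kind = cfg$potential$kind,
                                       temperature = cfg$potential$temperature),
                                  cfg$potential$params))
  backend <- make_langevin_backend(pot, dt = cfg$engine$time_step,
                                   friction = cfg$engine$friction)
  ec <- engine_config(
    time_step = cfg$engine$time_step,
    transition_interval_steps = cfg$engine$transition_interval_steps,
    temperature = cfg$engine$temperature,
    restraint_spring = cfg$engine$restraint_spring,
    runs_per_iteration = cfg$engine$runs_per_iteration,
    steps_per_run = cfg$engine$steps_per_run,
    snapshot_interval_steps = cfg$engine$snapshot_interval_steps,
    rng_seed = cfg$seed)
  list(grid = grid, potential = pot, backend = backend, engine = ec)
}

# one full sampling loop: sample -> update -> refine -> diagnose, per
# iteration; returns pooled snapshots, the final surface, per-iteration
# reports
sampling_loop <- function(cfg, progress = interactive()) {
  st <- toy_setup(cfg)
  grid <- st$grid
  q <- q_surface(grid, cfg$rc_space$bins_per_axis)
  # initial walkers spread uniformly over the zone-grid coverage
  lo <- vapply(grid$axes, function(a) a$lower, 0)
  hi <- vapply(grid$axes, function(a) a$upper, 0)
  set.seed(cfg$seed)
  seeds <- matrix(stats::runif(st$engine$runs_per_iteration * st$potential$dim,
                               lo, hi),
                  ncol = st$potential$dim, byrow = TRUE)
  seed_zones <- NULL
  pooled <- NULL
  reports <- list()
  for (it in seq_len(cfg$iterations)) {
    res <- run_iteration(st$engine, st$backend, q, grid, seeds,
                         seed_zones = seed_zones, iteration = it)
    pooled <- rbind(pooled, res$snapshots)
    counts <- zone_bin_counts(res$snapshots, q)
    q_new <- update_q(q, counts)
    q_new <- ga_refine(q_new, population = cfg$ga$population,
                       generations = cfg$ga$generations,
                       tournament = cfg$ga$tournament,
                       crossover = cfg$ga$crossover,
                       mutation_sigma = cfg$ga$mutation_sigma,
                       roughness_weight = cfg$ga$roughness_weight,
                       seed = derive_seed(cfg$seed, it, 999L))
    rep <- e_local(q_new, q, threshold = cfg$convergence_threshold,
                   iteration = it)
    reports[[it]] <- rep
    q <- q_new
    message(sprintf("iteration %d: %d/%d zones converged (max E_local %.3f)",
                    it, rep$converged_zones, grid$n_zones, max(rep$e_local)))
    # convergence is recorded per iteration; sampling continues through the
    # configured schedule to accumulate snapshots unless asked to stop early
    if (isTRUE(cfg$stop_when_converged) && all(rep$converged) &&
        it >= cfg$min_iterations) break
    sel <- select_seeds(pooled, tabulate(pooled$zone, grid$n_zones),
                        n = st$engine$runs_per_iteration,
                        seed = derive_seed(cfg$seed, it, 1000L))
    seeds <- as.matrix(sel[paste0("state", seq_len(st$potential$dim))])
    seed_zones <- sel$zone
  }
  # final surface from the pooled histograms of all iterations: the
  # within-zone conditional is iteration-independent, so pooling only
  # lowers the variance of the final estimate
  q_final <- finalize_q(cfg, q, pooled)
  list(snapshots = pooled, q = q_final, q_prior = q, reports = reports,
       setup = st, cfg = cfg)
}

# pooled-count final estimate: update from the loop's last surface, then GA
finalize_q <- function(cfg, q_prior, snapshots) {
  qf <- update_q(q_prior, zone_bin_counts(snapshots, q_prior))
  ga_refine(qf, population = cfg$ga$population,
            generations = cfg$ga$generations,
            tournament = cfg$ga$tournament,
            crossover = cfg$ga$crossover,
            mutation_sigma = cfg$ga$mutation_sigma,
            roughness_weight = cfg$ga$roughness_weight,
            seed = derive_seed(cfg$seed, 999L, 999L))
}

#' Run the full iterative sampling loop on the configured toy system
#'
#' Convenience wrapper over the sample -> update -> smooth -> diagnose loop
#' used by the `sample` pipeline command: runs the configured number of
#' iterations (optionally stopping early once every zone passes the
#' convergence gate), then estimates the final canonical surface from the
#' pooled histograms of all iterations.
#'
#' @param cfg a `zs_run_config` (see [validate_config()]).
#' @return list with `snapshots` (pooled, with iteration/run columns), `q`
#'   (the final pooled-count surface), `q_prior` (the last per-iteration
#'   surface), `reports` (per-iteration convergence reports), `setup`
#'   (grid/potential/backend/engine) and `cfg`.
#' @export
run_sampling_loop <- function(cfg) sampling_loop(cfg)

#' Reweighted observables with jackknife standard errors
#'
#' Computes weighted-ensemble averages of per-snapshot statistics under the
#' final canonical surface, with standard errors from a delete-one-iteration
#' jackknife in which the surface itself is re-estimated for every
#' replicate. The jackknife therefore propagates both the snapshot sampling
#' noise and the uncertainty of the density estimate, which a weight-based
#' standard error conditional on the surface would miss.
#'
#' @param loop result of [run_sampling_loop()].
#' @param statistics named list of functions, each mapping the weighted
#'   snapshot data.frame (with a `weight` column) to one number.
#' @return data.frame with `statistic`, `estimate`, `se`, `n_iterations`.
#' @export
reweighted_observables <- function(loop, statistics) {
  eval_stats <- function(snaps) {
    qf <- finalize_q(loop$cfg, loop$q_prior, snaps)
    sw <- suppressWarnings(snapshot_weights(snaps, qf))
    vapply(statistics, function(f) f(sw), 0)
  }
  full <- eval_stats(loop$snapshots)
  its <- sort(unique(loop$snapshots$iteration))
  M <- length(its)
  reps <- vapply(its, function(m) {
    eval_stats(loop$snapshots[loop$snapshots$iteration != m, , drop = FALSE])
  }, numeric(length(statistics)))
  reps <- matrix(reps, nrow = length(statistics))
  se <- sqrt((M - 1) / M * rowSums((reps - rowMeans(reps))^2))
  data.frame(statistic = names(statistics), estimate = unname(full),
             se = se, n_iterations = M, row.names = NULL)
}

pipe_sample <- function(cfg, out) {
  loop <- sampling_loop(cfg)
  write_zone_table(loop$setup$grid, file.path(out, "zones.tsv"))
  write_snapshots_tsv(loop$snapshots, file.path(out, "snapshots.tsv"))
  write_q_tsv(loop$q, file.path(out, "q.tsv"))
  conv <- do.call(rbind, lapply(loop$reports, function(r) {
    data.frame(iteration = r$iteration, zone = seq_along(r$e_local),
               e_local = r$e_local, converged = r$converged)
  }))
  fmt_tsv(conv, file.path(out, "convergence.tsv"))
  list(zones = file.path(out, "zones.tsv"),
       snapshots = file.path(out, "snapshots.tsv"),
       q = file.path(out, "q.tsv"),
       convergence = file.path(out, "convergence.tsv"))
}

sample_dir <- function(cfg) file.path(cfg$output_dir, "sample")

need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path, "; run the '", producer,
         "' command first")
  }
  path
}

pipe_estimate_q <- function(cfg, out) {
  st <- toy_setup(cfg)
  snaps <- read_snapshots_tsv(need_artifact(
    file.path(sample_dir(cfg), "snapshots.tsv"), "sample"))
  q0 <- q_surface(st$grid, cfg$rc_space$bins_per_axis)
  q1 <- update_q(q0, zone_bin_counts(snaps, q0))
  q1 <- ga_refine(q1, population = cfg$ga$population,
                  generations = cfg$ga$generations,
                  seed = derive_seed(cfg$seed, 1L, 999L))
  write_q_tsv(q1, file.path(out, "q.tsv"))
  list(q = file.path(out, "q.tsv"))
}

pipe_convergence <- function(cfg, out) {
  st <- toy_setup(cfg)
  qc <- read_q_tsv(need_artifact(file.path(sample_dir(cfg), "q.tsv"), "sample"),
                   st$grid)
  qp <- q_surface(st$grid, cfg$rc_space$bins_per_axis)
  rep <- e_local(qc, qp, threshold = cfg$convergence_threshold)
  fmt_tsv(data.frame(zone = seq_along(rep$e_local), e_local = rep$e_local,
                     converged = rep$converged),
          file.path(out, "convergence.tsv"))
  list(convergence = file.path(out, "convergence.tsv"))
}

pipe_reweight <- function(cfg, out) {
  st <- toy_setup(cfg)
  snaps <- read_snapshots_tsv(need_artifact(
    file.path(sample_dir(cfg), "snapshots.tsv"), "sample"))
  q <- read_q_tsv(need_artifact(file.path(sample_dir(cfg), "q.tsv"), "sample"),
                  st$grid)
  sw <- snapshot_weights(snaps, q)
  write_snapshots_tsv(sw, file.path(out, "weights.tsv"))
  list(weights = file.path(out, "weights.tsv"))
}

pipe_analyze <- function(cfg, out) {
  gen_dir <- dirname(need_artifact(
    file.path(cfg$output_dir, "generate-toy", "ensemble.tsv"), "generate-toy"))
  ens <- read_ensemble_files(gen_dir)
  ens <- align_ensemble(ens)
  dens <- density_field(ens, ens$groups$ligand, edge = cfg$analysis$cube_edge)
  write_dx(dens, file.path(out, "density.dx"))
  pmf <- residue_contact_pmf(ens, cutoff = cfg$analysis$cutoff)
  fmt_tsv(as.data.frame(cbind(slice = seq_len(nrow(pmf$F)), pmf$F)),
          file.path(out, "residue_contact_pmf.tsv"))
  ncp <- native_contact_profile(ens)
  fmt_tsv(ncp, file.path(out, "native_contacts.tsv"))
  rd <- rmsd_distributions(ens, "whole",
                           bin_width = cfg$analysis$rmsd_bin_width)
  fmt_tsv(data.frame(rmsd = rd$centers, p_ddf = rd$p_ddf, p_rdf = rd$p_rdf),
          file.path(out, "rmsd.tsv"))
  of <- orientation_field(ens, edge = cfg$analysis$cube_edge)
  fmt_tsv(data.frame(cube = seq_along(of$v_left$norm),
                     norm_left = as.vector(of$v_left$norm),
                     norm_down = as.vector(of$v_down$norm)),
          file.path(out, "orientation.tsv"))
  list(density = file.path(out, "density.dx"),
       pmf = file.path(out, "residue_contact_pmf.tsv"),
       native = file.path(out, "native_contacts.tsv"),
       rmsd = file.path(out, "rmsd.tsv"),
       orientation = file.path(out, "orientation.tsv"))
}
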