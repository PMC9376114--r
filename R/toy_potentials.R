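# Analytic toy potentials with quadrature ground truth, and the bundled
# overdamped-Langevin dynamics backend.

# gas constant in kcal/(mol K), CODATA
.kB <- 1.987204259e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature temperature in K.
#' @return RT in kcal/mol (0.5962 at 300 K).
#' @export
rt_kcal <- function(temperature = 300) .kB * temperature

#' Analytic toy potential
#'
#' Three families are bundled, all with energies in kcal/mol and coordinates
#' in Angstrom:
#' \describe{
#'   \item{harmonic}{`U = sum(0.5 * k * x^2)`; parameter `k`.}
#'   \item{double_well}{`U = barrier * ((x/a)^2 - 1)^2` on the first axis
#'     (quartic double well with minima at +/-a and barrier height `barrier`
#'     at 0); parameters `barrier`, `a`.}
#'   \item{binding_funnel}{3D Gaussian funnel
#'     `U = plateau * (1 - exp(-|r - pocket|^2 / (2 w^2)))`: a pocket minimum
#'     at `pocket`, funnel width `w`, outer plateau level `plateau`.}
#' }
#'
#' @param kind one of `"harmonic"`, `"double_well"`, `"binding_funnel"`.
#' @param temperature temperature in K.
#' @param domain 2 x D matrix (rows lower/upper) of the declared domain.
#' @param k harmonic spring constant (kcal/mol/A^2).
#' @param dim harmonic dimensionality.
#' @param barrier double-well barrier height (kcal/mol).
#' @param a double-well minimum position (+/- a, Angstrom).
#' @param pocket binding-funnel minimum position (3-vector).
#' @param w binding-funnel width (Angstrom).
#' @param plateau binding-funnel outer plateau level (kcal/mol).
#' @return object of class `zs_potential` with elements `energy(x)` and
#'   `force(x)` operating on state matrices (rows = walkers).
#' @export
toy_potential <- function(kind = c("harmonic", "double_well", "binding_funnel"),
                          temperature = 300, domain = NULL,
                          k = 1, dim = 1L, barrier = 2, a = 1,
                          pocket = c(0, 0, 0), w = 2, plateau = 3) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    dim <- as.integer(dim)
    energy <- function(x) 0.5 * k * rowSums(mat(x, dim)^2)
    force <- function(x) -k * mat(x, dim)
    if (is.null(domain)) domain <- rbind(rep(-6 / sqrt(k), dim), rep(6 / sqrt(k), dim))
    p <- list(k = k, dim = dim)
  } else if (kind == "double_well") {
    dim <- 1L
    energy <- function(x) {
      x <- mat(x, 1L)
      barrier * ((x[, 1] / a)^2 - 1)^2
    }
    force <- function(x) {
      x <- mat(x, 1L)
      cbind(-4 * barrier * x[, 1] * ((x[, 1] / a)^2 - 1) / a^2)
    }
    if (is.null(domain)) domain <- rbind(-2.5 * a, 2.5 * a)
    p <- list(barrier = barrier, a = a)
  } else {
    dim <- 3L
    energy <- function(x) {
      x <- mat(x, 3L)
      d2 <- rowSums(sweep(x, 2, pocket)^2)
      plateau * (1 - exp(-d2 / (2 * w^2)))
    }
    force <- function(x) {
      x <- mat(x, 3L)
      dx <- sweep(x, 2, pocket)
      d2 <- rowSums(dx^2)
      -dx * (plateau * exp(-d2 / (2 * w^2)) / w^2)
    }
    if (is.null(domain)) domain <- rbind(pocket - 4 * w, pocket + 4 * w)
    p <- list(pocket = pocket, w = w, plateau = plateau)
  }
  domain <- matrix(as.numeric(domain), nrow = 2L)
  structure(list(kind = kind, params = p, temperature = temperature,
                 dim = dim, domain = domain, energy = energy, force = force),
            class = "zs_potential")
}

mat <- function(x, dim) {
  if (is.matrix(x)) x else matrix(x, ncol = dim)
}

#' Boltzmann marginal of a toy potential by quadrature
#'
#' Numerically integrates `exp(-U/RT)` over each requested bin of the first
#' coordinate (remaining coordinates, if any, integrated over the declared
#' domain on a quadrature grid) and normalizes to sum 1.
#'
#' @param potential a `zs_potential`.
#' @param edges bin edges along the first coordinate (length nbins + 1),
#'   covering the domain.
#' @param subdiv quadrature points per bin and per transverse axis.
#' @return numeric vector of bin probabilities summing to 1.
#' @export
boltzmann_marginal <- function(potential, edges, subdiv = 40L) {
  rt <- rt_kcal(potential$temperature)
  nb <- length(edges) - 1L
  D <- potential$dim
  # transverse quadrature grid (midpoint rule)
  if (D > 1L) {
    tgrid <- lapply(2:D, function(a) {
      lo <- potential$domain[1L, a]; hi <- potential$domain[2L, a]
      lo + (seq_len(subdiv) - 0.5) * (hi - lo) / subdiv
    })
    tpts <- as.matrix(do.call(expand.grid, tgrid))
  }
  mass <- vapply(seq_len(nb), function(i) {
    xs <- edges[i] + (seq_len(subdiv) - 0.5) * (edges[i + 1L] - edges[i]) / subdiv
    if (D == 1L) {
      sum(exp(-potential$energy(cbind(xs)) / rt)) * (edges[i + 1L] - edges[i]) / subdiv
    } else {
      tot <- 0
      for (x in xs) {
        tot <- tot + sum(exp(-potential$energy(cbind(x, tpts)) / rt))
      }
      tot * (edges[i + 1L] - edges[i]) / subdiv
    }
  }, 0)
  if (!all(is.finite(mass)) || sum(mass) <= 0) stop("divergent Boltzmann integral")
  mass / sum(mass)
}

#' Overdamped Langevin trajectory on a toy potential
#'
#' Integrates `dx = (F/gamma) dt + sqrt(2 RT dt / gamma) xi` at the
#' potential's temperature. The default discretization averages consecutive
#' noise increments (Leimkuhler-Matthews; stationary error O(dt^2)); plain
#' Euler-Maruyama is available via `method`. Deterministic given `seed`.
#'
#' @param potential a `zs_potential`.
#' @param x0 initial state (D-vector).
#' @param steps number of steps.
#' @param dt time step (reduced units).
#' @param friction friction coefficient gamma.
#' @param seed RNG seed.
#' @param record_every record every that many steps (default 1).
#' @param method `"leimkuhler-matthews"` (default) or `"euler-maruyama"`.
#' @return matrix of recorded states (rows = time points, incl. x0).
#' @export
simulate_langevin <- function(potential, x0, steps, dt = 0.01, friction = 1,
                              seed = 1L, record_every = 1L,
                              method = c("leimkuhler-matthews",
                                         "euler-maruyama")) {
  method <- match.arg(method)
  D <- potential$dim
  x <- matrix(as.numeric(x0), ncol = D)
  rt <- rt_kcal(potential$temperature)
  sig <- sqrt(2 * rt * dt / friction)
  out <- matrix(NA_real_, floor(steps / record_every) + 1L, D)
  out[1L, ] <- x
  set.seed(as.integer(seed))
  r <- 1L
  eta_prev <- matrix(stats::rnorm(D), ncol = D)
  for (s in seq_len(steps)) {
    eta <- matrix(stats::rnorm(D), ncol = D)
    use <- if (method == "euler-maruyama") eta else {
      tmp <- (eta + eta_prev) / 2
      eta_prev <- eta
      tmp
    }
    x <- x + potential$force(x) * dt / friction + if (sig > 0) sig * use else 0
    if (!all(is.finite(x))) stop("non-finite state at step ", s)
    if (s %% record_every == 0L) {
      r <- r + 1L
      out[r, ] <- x
    }
  }
  out
}
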