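# Particle swarm optimization of the least-squares cost, ensemble sampling,
# and best-fraction selection.

#' Particle swarm configuration
#'
#' Defaults follow the inertia-weight swarm: 80 particles, inertia 0.7,
#' individual and social weights drawn uniformly on (0, 1.5), velocities
#' clamped to half the box width per dimension, 400 iterations with early
#' stopping after 50 iterations without improvement of the global best.
#'
#' @param n_particles Swarm size (>= 2).
#' @param n_iterations Maximum iterations.
#' @param inertia Inertia weight psi in (0, 1).
#' @param phi_ind_max,phi_soc_max Upper limits of the per-particle,
#'   per-iteration uniform weights on the individual and social pull.
#' @param v_clamp Velocity clamp as a fraction of the box width.
#' @param stall_iterations Early-stop patience.
#' @return List of class `swarm_control`.
#' @export
swarm_control <- function(n_particles = 80, n_iterations = 400, inertia = 0.7,
                          phi_ind_max = 1.5, phi_soc_max = 1.5,
                          v_clamp = 0.5, stall_iterations = 50) {
  stopifnot(n_particles >= 2, inertia > 0, inertia < 1,
            phi_ind_max > 0, phi_soc_max > 0)
  structure(list(n_particles = n_particles, n_iterations = n_iterations,
                 inertia = inertia, phi_ind_max = phi_ind_max,
                 phi_soc_max = phi_soc_max, v_clamp = v_clamp,
                 stall_iterations = stall_iterations),
            class = "swarm_control")
}

#' Minimize an objective with a particle swarm
#'
#' Velocity update per particle:
#' `V <- psi*V + phi_ind*(L - X) + phi_soc*(G - X)` with `phi_*` drawn
#' uniformly on (0, phi_max) per particle and iteration.  Positions may leave
#' the box; the objective is expected to assign a large penalty there (as
#' [ls_cost()] does), so such positions never become personal or global
#' bests.  Fully reproducible given `seed`.
#'
#' @param objective Function of a position vector returning a finite cost.
#' @param lower,upper Box bounds (vectors).
#' @param control A [swarm_control()].
#' @param seed Integer RNG seed.
#' @return List: `par`, `cost`, `iterations`, `trace` (global best per
#'   iteration), `seed`.
#' @export
pso_minimize <- function(objective, lower, upper, control = swarm_control(),
                         seed = 1L) {
  set.seed(seed)
  d <- length(lower)
  P <- control$n_particles
  width <- upper - lower
  X <- matrix(runif(d * P, lower, upper), nrow = d)
  V <- matrix(0, d, P)
  vmax <- control$v_clamp * width
  cost <- apply(X, 2, objective)
  Lbest <- X; Lcost <- cost
  g <- which.min(cost)
  G <- X[, g]; Gcost <- cost[g]
  trace <- numeric(0)
  stall <- 0L
  it <- 0L
  while (it < control$n_iterations && stall < control$stall_iterations) {
    it <- it + 1L
    phi_i <- runif(P, 0, control$phi_ind_max)
    phi_s <- runif(P, 0, control$phi_soc_max)
    V <- control$inertia * V +
      rep(phi_i, each = d) * (Lbest - X) +
      rep(phi_s, each = d) * (G - X)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    cost <- apply(X, 2, objective)
    imp <- cost < Lcost
    Lbest[, imp] <- X[, imp]
    Lcost[imp] <- cost[imp]
    g <- which.min(Lcost)
    if (Lcost[g] < Gcost) {
      G <- Lbest[, g]; Gcost <- Lcost[g]; stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, Gcost)
  }
  list(par = G, cost = Gcost, iterations = it, trace = trace, seed = seed)
}

#' PSO ensemble fit of a spectrum
#'
#' Independently seeded swarm runs, each minimizing the least-squares cost
#' [ls_cost()] over the normalized parameter box, with starting positions
#' uniform over the box.  The collection of run winners is the PSO-based
#' random sample of the solution distribution.
#'
#' @param spec Band-selected `spectral_estimate`.
#' @param n_runs Number of independent runs (1000 at full scale).
#' @param box `param_box`.
#' @param control [swarm_control()].
#' @param seed Master seed; per-run seeds are derived from it and recorded.
#' @return Data frame of class `pso_ensemble`: one row per run with `run`,
#'   `seed`, `cost`, `alpha`, then the 22 normalized coordinates (`t_*`) and
#'   the 22 physical values.
#' @export
pso_ensemble <- function(spec, n_runs = 1000, box = default_box(),
                         control = swarm_control(), seed = 1L) {
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  obj <- .objective_ls(spec, box)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    fit <- pso_minimize(obj, rep(-1, 22), rep(1, 22), control, run_seeds[i])
    r <- spectrum_status(.theta_phys(denormalize_params(fit$par, box)),
                         spec$freqs)
    a <- if (r$status == 0) alpha_ls(spec$power, r$S) else NA_real_
    phys <- denormalize_params(fit$par, box)
    rows[[i]] <- data.frame(run = i, seed = run_seeds[i], cost = fit$cost,
                            alpha = a,
                            as.list(stats::setNames(fit$par,
                                                    paste0("t_", param_names()))),
                            as.list(unclass(phys)))
  }
  out <- do.call(rbind, rows)
  attr(out, "master_seed") <- seed
  class(out) <- c("pso_ensemble", class(out))
  out
}

#' Select the best fraction of ensemble fits
#'
#' Retains the `ceiling(fraction * n)` lowest-cost samples (default the best
#' 10 percent), breaking ties by run id.
#'
#' @param samples `pso_ensemble` (or any data frame with `cost` and `run`).
#' @param fraction Fraction in (0, 1].
#' @return The retained rows.
#' @export
select_best <- function(samples, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  k <- ceiling(fraction * nrow(samples))
  ord <- order(samples$cost, samples$run)
  samples[ord[seq_len(k)], , drop = FALSE]
}

#' Decile table of ensemble costs
#'
#' Costs relative to the ensemble minimum, summarized by decile.
#'
#' @param samples `pso_ensemble`.
#' @return Data frame with `decile` and `relative_cost`.
#' @export
cost_deciles <- function(samples) {
  rel <- samples$cost / min(samples$cost)
  q <- quantile(rel, probs = seq(0, 1, 0.1), names = FALSE)
  data.frame(decile = seq(0, 100, 10), relative_cost = q)
}

#' Normalized coordinates of ensemble samples as a matrix
#'
#' @param samples A `pso_ensemble` (or [select_best()] subset).
#' @return Numeric matrix, one row per retained run, columns over
#'   [param_names()].
#' @export
theta_matrix <- function(samples) {
  cols <- paste0("t_", param_names())
  m <- as.matrix(samples[, cols])
  colnames(m) <- param_names()
  m
}
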