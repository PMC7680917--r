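#' Kinetic constants of the two-variable Oregonator model
#'
#' The two-variable Oregonator is the canonical reduction of
#' Belousov-Zhabotinsky (BZ) reaction kinetics to an activator `u` (the
#' autocatalytic HBrO2 analogue) and an inhibitor `v` (the oxidised-catalyst
#' analogue). `epsilon` sets the ratio of the two time scales, `q` is a
#' scaling constant and `f` the stoichiometric coefficient. The defaults are
#' the values used throughout the package's benchmark problems.
#'
#' @param epsilon Time-scale ratio of activator to inhibitor; dimensionless,
#'   strictly positive.
#' @param q Scaling constant of the Oregonator nonlinearity; dimensionless,
#'   strictly positive.
#' @param f Stoichiometric coefficient; dimensionless, strictly positive.
#' @return An object of class `oregonator_params`.
#' @examples
#' oregonator_params()
#' @export
oregonator_params <- function(epsilon = 0.2, q = 2e-4, f = 1.1) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(q), length(q) == 1L, q > 0,
            is.numeric(f), length(f) == 1L, f > 0)
  structure(list(epsilon = epsilon, q = q, f = f),
            class = "oregonator_params")
}

#' Per-oscillator illumination schedule
#'
#' Each oscillator of the photosensitive BZ network is suppressed by light
#' until its switch-off time `t_ilum`, after which the illumination term
#' `phi(t) = amp * (offset + tanh(-steepness * (t - t_ilum)))` drops smoothly
#' from about `2 * amp` to `amp * (offset - 1)`. With the defaults that is
#' from 0.2001 (stable steady state) to 0.0001 (free-running oscillation).
#'
#' @param t_ilum Numeric vector of switch-off times, one per oscillator;
#'   non-negative, time units.
#' @param amp Illumination amplitude (dimensionless rate), positive.
#' @param offset Baseline term; must exceed 1 so that `phi` stays strictly
#'   positive for all times.
#' @param steepness Slope of the tanh switch, positive (1/time).
#' @return An object of class `illumination_schedule`.
#' @export
illumination_schedule <- function(t_ilum, amp = 0.1, offset = 1.001,
                                  steepness = 10) {
  stopifnot(is.numeric(t_ilum), length(t_ilum) >= 1L, all(t_ilum >= 0),
            amp > 0, steepness > 0, offset > 1)
  structure(list(t_ilum = as.numeric(t_ilum), amp = amp, offset = offset,
                 steepness = steepness),
            class = "illumination_schedule")
}

#' Network topology and reaction rates
#'
#' Oscillators are coupled through exchange of their activators with a common
#' rate `beta`; each oscillator additionally loses activator at rate `alpha`.
#' The `alpha` decay moderates the activator amplitude so that the `beta`
#' coupling is controllable.
#'
#' @param n_osc Number of oscillators (>= 1).
#' @param alpha Activator decay rate (1/time), non-negative.
#' @param beta Activator exchange rate between coupled pairs (1/time),
#'   non-negative.
#' @param coupling Symmetric logical/0-1 adjacency matrix with an empty
#'   diagonal; defaults to all-to-all.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_osc, alpha = 0, beta = 0, coupling = NULL) {
  stopifnot(n_osc >= 1, alpha >= 0, beta >= 0)
  if (is.null(coupling)) {
    coupling <- matrix(1L, n_osc, n_osc) - diag(1L, n_osc)
  }
  coupling <- matrix(as.integer(coupling != 0), n_osc, n_osc)
  diag(coupling) <- 0L
  if (!isTRUE(all.equal(coupling, t(coupling))))
    stop("coupling matrix must be symmetric")
  structure(list(n_osc = as.integer(n_osc), alpha = alpha, beta = beta,
                 coupling = coupling),
            class = "network_spec")
}

#' Fixed-step integrator settings
#'
#' @param t_max End of the integration window (time units), positive.
#' @param h RK4 time step, positive; default 1e-4.
#' @param store_stride Number of steps between stored samples; the default
#'   100 gives a sampling interval of 0.01 with the default `h`.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(t_max, h = 1e-4, store_stride = 100L) {
  stopifnot(h > 0, store_stride >= 1, t_max > 0)
  nsteps <- round(t_max / h)
  structure(list(h = h, store_stride = as.integer(store_stride),
                 t_max = t_max, nsteps = as.integer(nsteps)),
            class = "integrator_config")
}

#' Activator peak-detector settings
#'
#' A counted maximum is an interior strict local maximum of the stored
#' activator series whose height exceeds `height_threshold`. Spike amplitudes
#' are of order 0.1-1 while the illuminated baseline is about 2e-4, so the
#' default threshold of 0.05 sits more than two decades above baseline.
#'
#' @param height_threshold Minimum activator value for a counted maximum,
#'   in (0, 1).
#' @return An object of class `peak_config`.
#' @export
peak_config <- function(height_threshold = 0.05) {
  stopifnot(height_threshold > 0, height_threshold < 1)
  structure(list(height_threshold = height_threshold), class = "peak_config")
}

#' Illumination term at a given time
#'
#' Evaluates `phi(t) = amp * (offset + tanh(-steepness * (t - t_ilum)))`,
#' the light-intensity contribution to the Oregonator kinetics. Vectorised
#' over `t`.
#'
#' @param t Time(s), non-negative.
#' @param t_ilum Switch-off time of the oscillator.
#' @param sched An [illumination_schedule()] providing `amp`, `offset` and
#'   `steepness` (its `t_ilum` field is ignored here).
#' @return Illumination value(s), strictly positive, non-increasing in `t`.
#' @export
illumination <- function(t, t_ilum,
                         sched = illumination_schedule(t_ilum)) {
  stopifnot(all(t >= 0))
  sched$amp * (sched$offset + tanh(-sched$steepness * (t - t_ilum)))
}

#' Right-hand side of the network equations
#'
#' For each oscillator j:
#' `du_j/dt = (1/eps) * (u_j - u_j^2 - (f*v_j + phi_j(t)) * (u_j - q)/(u_j + q))
#'            - alpha*u_j + beta * sum_i A_ij (u_i - u_j)`
#' and `dv_j/dt = u_j - v_j`. For the all-to-all three-oscillator network the
#' coupling term equals `-(alpha + 3*beta)*u_j + beta*(u_1 + u_2 + u_3)` since
#' the self-exchange contributions cancel.
#'
#' @param u,v Activator and inhibitor vectors, one entry per oscillator.
#' @param t Time.
#' @param params An [oregonator_params()].
#' @param net A [network_spec()].
#' @param sched An [illumination_schedule()] with one `t_ilum` per oscillator.
#' @return A list with components `du` and `dv`.
#' @export
oregonator_rhs <- function(u, v, t, params, net, sched) {
  stopifnot(length(u) == net$n_osc, length(v) == net$n_osc,
            length(sched$t_ilum) == net$n_osc)
  if (any(u <= -params$q))
    stop("activator at or below -q: division domain violated (instability)")
  phi <- illumination(t, sched$t_ilum, sched)
  kin <- (1 / params$epsilon) *
    (u - u^2 - (params$f * v + phi) * (u - params$q) / (u + params$q))
  deg <- rowSums(net$coupling)
  du <- kin - net$alpha * u +
    net$beta * (as.vector(net$coupling %*% u) - deg * u)
  list(du = du, dv = u - v)
}

#' Steady state of a single illuminated oscillator
#'
#' Under constant illumination `phi` the single-oscillator system has a fixed
#' point with `v = u`; this solves the scalar equation
#' `(1/eps)*(u - u^2 - (f*u + phi)*(u - q)/(u + q)) = alpha * u` by bracketed
#' root-finding on (0, 1). At the initial illumination level 0.2001 the
#' steady state is approximately `u = v = 0.0002`.
#'
#' @param phi Constant illumination level, positive.
#' @param params An [oregonator_params()].
#' @param alpha Activator decay rate; default 0.
#' @return Named numeric vector `c(u = u_star, v = u_star)`.
#' @export
steady_state <- function(phi, params = oregonator_params(), alpha = 0) {
  stopifnot(phi > 0, alpha >= 0)
  g <- function(u) {
    (1 / params$epsilon) *
      (u - u^2 - (params$f * u + phi) * (u - params$q) / (u + params$q)) -
      alpha * u
  }
  lo <- 1e-12
  if (sign(g(lo)) == sign(g(1)))
    stop("no steady-state root bracketed in (0, 1)")
  root <- stats::uniroot(g, c(lo, 1), tol = 1e-14)$root
  c(u = root, v = root)
}

#' Integrate a network of illuminated Oregonator oscillators
#'
#' Classic fourth-order Runge-Kutta with fixed step `cfg$h` from `t = 0` to
#' `cfg$t_max`. Unless `init` is given, each oscillator starts in the steady
#' state of its own initial illumination `phi_j(0)` — the physically prepared
#' state of a strongly illuminated photosensitive BZ oscillator.
#'
#' @param params An [oregonator_params()].
#' @param net A [network_spec()].
#' @param sched An [illumination_schedule()], one `t_ilum` per oscillator.
#' @param cfg An [integrator_config()].
#' @param init Optional list with numeric vectors `u` and `v` of length
#'   `net$n_osc` overriding the steady-state initial condition.
#' @param phi_const Optional scalar: hold the illumination of every
#'   oscillator constant at this value instead of following the schedule
#'   (the initial condition still uses `phi_j(0)` from the schedule).
#' @return An object of class `oscnet_trajectory`: list with `times` (stored
#'   sample times), `u` and `v` (matrices, one column per oscillator), and the
#'   configuration used.
#' @export
integrate_network <- function(params, net, sched, cfg, init = NULL,
                              phi_const = NULL) {
  stopifnot(inherits(params, "oregonator_params"),
            inherits(net, "network_spec"),
            inherits(sched, "illumination_schedule"),
            inherits(cfg, "integrator_config"),
            length(sched$t_ilum) == net$n_osc)
  if (is.null(init)) {
    phi0 <- illumination(0, sched$t_ilum, sched)
    ss <- vapply(phi0, function(p) steady_state(p, params, net$alpha)[["u"]],
                 numeric(1))
    init <- list(u = ss, v = ss)
  }
  stopifnot(length(init$u) == net$n_osc, length(init$v) == net$n_osc)
  out <- rk4_trajectory_cpp(
    as.numeric(init$u), as.numeric(init$v), sched$t_ilum,
    sched$amp, sched$offset, sched$steepness,
    if (is.null(phi_const)) -1.0 else phi_const,
    params$epsilon, params$q, params$f, net$alpha, net$beta,
    net$coupling, cfg$h, cfg$nsteps, cfg$store_stride)
  structure(list(times = out$times, u = out$u, v = out$v,
                 params = params, net = net, sched = sched, cfg = cfg),
            class = "oscnet_trajectory")
}

#' @export
print.oscnet_trajectory <- function(x, ...) {
  cat("<oscnet_trajectory> ", ncol(x$u), " oscillator(s), ",
      length(x$times), " samples on [0, ", max(x$times), "]\n", sep = "")
  invisible(x)
}

#' Count activator maxima of one oscillator
#'
#' Counts interior strict local maxima (`u[i-1] < u[i] >= u[i+1]`) of the
#' stored activator series that exceed the height threshold. Samples at
#' `t = 0` and `t = t_max` are never counted.
#'
#' @param traj An `oscnet_trajectory` from [integrate_network()].
#' @param osc_index Which oscillator's activator to inspect.
#' @param pk A [peak_config()].
#' @return Integer count of maxima.
#' @export
count_maxima <- function(traj, osc_index = 1L, pk = peak_config()) {
  stopifnot(inherits(traj, "oscnet_trajectory"),
            osc_index >= 1L, osc_index <= ncol(traj$u))
  count_series_maxima(traj$u[, osc_index], pk$height_threshold)
}

# Shared detector: interior strict local maxima above threshold.
count_series_maxima <- function(x, threshold) {
  n <- length(x)
  if (n < 3L) return(0L)
  i <- 2:(n - 1L)
  sum(x[i - 1L] < x[i] & x[i] >= x[i + 1L] & x[i] > threshold)
}

#' Times of counted activator maxima
#'
#' @inheritParams count_maxima
#' @return Numeric vector of sample times of the counted maxima.
#' @export
maxima_times <- function(traj, osc_index = 1L, pk = peak_config()) {
  x <- traj$u[, osc_index]
  n <- length(x)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1L)
  keep <- x[i - 1L] < x[i] & x[i] >= x[i + 1L] & x[i] > pk$height_threshold
  traj$times[i][keep]
}

#' Oscillation period of a single free-running oscillator
#'
#' Integrates one oscillator with the illumination held at a constant level
#' (starting from the strongly illuminated steady state) and reports the mean
#' spacing of successive activator maxima after discarding the first two as
#' transient. At the long-time illumination level 0.0001 with activator decay
#' `alpha = 0.849` the period is approximately 10.8 time units.
#'
#' @param params An [oregonator_params()].
#' @param alpha Activator decay rate.
#' @param phi Constant illumination level during the run.
#' @param cfg An [integrator_config()]; the window must contain at least four
#'   maxima.
#' @param phi_init Illumination level defining the initial steady state;
#'   default 0.2001 (the fully illuminated state).
#' @param pk A [peak_config()].
#' @return Mean inter-maximum interval (time units), at the stored-sample
#'   resolution.
#' @export
measure_period <- function(params = oregonator_params(), alpha = 0.849,
                           phi = 1e-4, cfg = integrator_config(t_max = 200),
                           phi_init = 0.2001, pk = peak_config()) {
  net <- network_spec(1L, alpha = alpha, beta = 0)
  u0 <- steady_state(phi_init, params, alpha)[["u"]]
  sched <- illumination_schedule(t_ilum = 0)
  traj <- integrate_network(params, net, sched, cfg,
                            init = list(u = u0, v = u0), phi_const = phi)
  tmax <- maxima_times(traj, 1L, pk)
  if (length(tmax) < 4L)
    stop("no sustained oscillation: fewer than 4 activator maxima in window")
  mean(diff(tmax[-(1:2)]))
}
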