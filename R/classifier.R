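#' The seven adjustable traits of a three-oscillator classifier
#'
#' Oscillators #1 and #2 are input oscillators whose illumination switch-off
#' times encode the coordinates `x` and `y` through the affine map
#' `t_ilum = t_start + (t_end - t_start) * coordinate`. Oscillator #3 is
#' either a "normal" oscillator inhibited for the fixed time `t_ilum3`, or a
#' third input oscillator for `x` or `y`. The network is observed on
#' `[0, t_max]`; `alpha` and `beta` are the activator decay and coupling
#' rates.
#'
#' @param role3 One of `"normal"`, `"input_x"`, `"input_y"`.
#' @param t_ilum3 Fixed switch-off time of oscillator #3; used only when
#'   `role3 = "normal"`, retained (dormant) otherwise.
#' @param t_start,t_end Affine input-encoding times, `0 <= t_start < t_end`.
#' @param t_max Observation window length, positive.
#' @param alpha,beta Reaction rates (1/time), non-negative.
#' @return An object of class `network_genome`.
#' @seealso [published_genome()] for the optimised Japanese-flag network.
#' @export
network_genome <- function(role3 = c("normal", "input_x", "input_y"),
                           t_ilum3, t_start, t_end, t_max, alpha, beta) {
  role3 <- match.arg(role3)
  stopifnot(t_start >= 0, t_end > t_start, t_max > 0, t_ilum3 >= 0,
            alpha >= 0, beta >= 0)
  structure(list(role3 = role3, t_ilum3 = t_ilum3, t_start = t_start,
                 t_end = t_end, t_max = t_max, alpha = alpha, beta = beta),
            class = "network_genome")
}

#' The optimised Japanese-flag network
#'
#' The three-oscillator genome found by evolutionary optimisation for the
#' equal-area-disk problem: oscillator #3 is a normal oscillator with
#' `t_ilum3 = 6.37`, `t_start = 3.78`, `t_end = 12.10`, `t_max = 20.23`,
#' `alpha = 0.849`, `beta = 0.251`. With the majority rule (one activator
#' maximum on oscillator #3 means "sun") it classifies uniform points with
#' about 95% accuracy.
#'
#' @return A [network_genome()].
#' @export
published_genome <- function() {
  network_genome(role3 = "normal", t_ilum3 = 6.37, t_start = 3.78,
                 t_end = 12.10, t_max = 20.23, alpha = 0.849, beta = 0.251)
}

#' @export
print.network_genome <- function(x, ...) {
  cat("<network_genome> role3=", x$role3,
      sprintf(" t_ilum3=%.4g t_start=%.4g t_end=%.4g t_max=%.4g alpha=%.4g beta=%.4g\n",
              x$t_ilum3, x$t_start, x$t_end, x$t_max, x$alpha, x$beta),
      sep = "")
  invisible(x)
}

#' Encode a point as an illumination schedule
#'
#' Input encoding: `t_ilum(1) = t_start + (t_end - t_start) * x`,
#' `t_ilum(2) = t_start + (t_end - t_start) * y`; oscillator #3 gets the
#' fixed `t_ilum3` (normal role) or the affine encoding of `x` or `y`.
#'
#' @param genome A [network_genome()].
#' @param x,y Coordinates in the closed unit interval.
#' @return An [illumination_schedule()] of length 3.
#' @export
encode_inputs <- function(genome, x, y) {
  stopifnot(inherits(genome, "network_genome"),
            x >= 0, x <= 1, y >= 0, y <= 1)
  illumination_schedule(encode_t_ilum(genome, x, y))
}

# t_ilum matrix/vector shared by scalar and batch paths.
encode_t_ilum <- function(genome, x, y) {
  aff <- function(z) genome$t_start + (genome$t_end - genome$t_start) * z
  t3 <- switch(genome$role3,
               normal = rep(genome$t_ilum3, length(x)),
               input_x = aff(x),
               input_y = aff(y))
  cbind(aff(x), aff(y), t3)[, , drop = TRUE]
}

genome_network_spec <- function(genome) {
  network_spec(3L, alpha = genome$alpha, beta = genome$beta)
}

#' Maxima counts of the network for one record
#'
#' Encodes the record's coordinates, integrates the three-oscillator network
#' from the illuminated steady state and counts the activator maxima of each
#' oscillator within `[0, t_max]`.
#'
#' @param genome A [network_genome()].
#' @param rec List or one-row data frame with elements `x` and `y`.
#' @param params An [oregonator_params()].
#' @param cfg An [integrator_config()]; if `NULL`, built from
#'   `genome$t_max` with step `h`.
#' @param pk A [peak_config()].
#' @param h RK4 step used when `cfg` is `NULL`.
#' @return Named integer vector `c(o1, o2, o3)`.
#' @export
respond <- function(genome, rec, params = oregonator_params(), cfg = NULL,
                    pk = peak_config(), h = 1e-4) {
  if (is.null(cfg)) cfg <- default_cfg(genome$t_max, h)
  stopifnot(isTRUE(all.equal(cfg$t_max, genome$t_max)))
  sched <- encode_inputs(genome, rec$x, rec$y)
  traj <- integrate_network(params, genome_network_spec(genome), sched, cfg)
  counts <- vapply(1:3, function(j) count_maxima(traj, j, pk), integer(1))
  names(counts) <- c("o1", "o2", "o3")
  counts
}

# Integrator settings matched to a genome: sampling interval 0.01 regardless
# of the step size.
default_cfg <- function(t_max, h = 1e-4) {
  integrator_config(t_max = t_max, h = h,
                    store_stride = max(1L, as.integer(round(0.01 / h))))
}

#' Maxima counts for a whole dataset
#'
#' Vectorised driver over the records of a labeled dataset: one simulation
#' per record, all in compiled code. Produces the response table on which
#' the mutual-information fitness and the majority rule operate.
#'
#' @param genome A [network_genome()].
#' @param dataset Data frame with columns `x`, `y` and (optionally) `g`.
#' @param params An [oregonator_params()].
#' @param cfg An [integrator_config()] or `NULL` (built from `genome$t_max`).
#' @param pk A [peak_config()].
#' @param h RK4 step used when `cfg` is `NULL`.
#' @param on_failure `"error"` stops at the first record whose simulation
#'   blows up (reporting its index); `"na"` records `NA` counts for it.
#' @return A `data.frame` with the dataset's columns plus `o1`, `o2`, `o3`.
#' @export
respond_batch <- function(genome, dataset, params = oregonator_params(),
                          cfg = NULL, pk = peak_config(), h = 1e-4,
                          on_failure = c("error", "na")) {
  on_failure <- match.arg(on_failure)
  stopifnot(nrow(dataset) >= 1L, all(c("x", "y") %in% names(dataset)))
  if (is.null(cfg)) cfg <- default_cfg(genome$t_max, h)
  stopifnot(isTRUE(all.equal(cfg$t_max, genome$t_max)))
  ti <- encode_t_ilum(genome, dataset$x, dataset$y)
  if (is.null(dim(ti))) ti <- matrix(ti, nrow = 1L)
  sched0 <- illumination_schedule(t_ilum = c(0, 0, 0))
  net <- genome_network_spec(genome)
  # initial condition: steady state under phi_j(0); phi(0) varies only
  # through t_ilum, and for t_ilum >~ 2 it saturates at 0.2001, so cache
  # roots by the rounded phi value
  phi0 <- illumination(0, ti, sched0)
  phi_key <- signif(phi0, 12)
  uniq <- unique(as.vector(phi_key))
  roots <- vapply(uniq, function(p) steady_state(p, params, net$alpha)[["u"]],
                  numeric(1))
  u0 <- matrix(roots[match(as.vector(phi_key), uniq)], nrow = nrow(ti))
  out <- rk4_count_batch_cpp(ti, u0, u0, sched0$amp, sched0$offset,
                             sched0$steepness, params$epsilon, params$q,
                             params$f, net$alpha, net$beta, net$coupling,
                             cfg$h, cfg$nsteps, cfg$store_stride,
                             pk$height_threshold)
  if (on_failure == "error" && any(out$status != 0L))
    stop("simulation blew up for record(s): ",
         paste(which(out$status != 0L), collapse = ", "))
  res <- dataset
  res$o1 <- out$counts[, 1]
  res$o2 <- out$counts[, 2]
  res$o3 <- out$counts[, 3]
  res
}

#' Fit the per-count majority rule
#'
#' For each observed maxima count `c` of the chosen oscillator, the rule
#' predicts the majority label among training rows with that count. Ties and
#' counts unseen in training map to the fallback class 0 (the white
#' background).
#'
#' @param table A response table from [respond_batch()] with a label column
#'   `g`.
#' @param osc_index Output oscillator (column `o<osc_index>`).
#' @return An object of class `decision_rule`: named mapping count -> class
#'   plus a fallback.
#' @export
fit_decision_rule <- function(table, osc_index = 3L) {
  stopifnot(nrow(table) >= 1L, "g" %in% names(table))
  o <- table[[paste0("o", osc_index)]]
  stopifnot(!is.null(o))
  tab <- base::table(factor(table$g, levels = c(0, 1)), o)
  counts <- as.integer(colnames(tab))
  map <- ifelse(tab["1", ] > tab["0", ], 1L, 0L)  # tie -> 0
  structure(list(map = stats::setNames(as.integer(map), counts),
                 fallback = 0L, osc_index = as.integer(osc_index)),
            class = "decision_rule")
}

#' Apply a decision rule to maxima counts
#'
#' @param rule A `decision_rule` from [fit_decision_rule()].
#' @param counts Integer vector of maxima counts.
#' @return Integer vector of predicted classes in {0, 1}.
#' @export
predict_counts <- function(rule, counts) {
  stopifnot(inherits(rule, "decision_rule"))
  out <- rule$map[as.character(counts)]
  out[is.na(out)] <- rule$fallback
  unname(out)
}

#' Classification accuracy of a rule on a response table
#'
#' @param table Response table with label column `g`.
#' @param rule A `decision_rule`.
#' @param osc_index Output oscillator; defaults to the one the rule was
#'   fitted on.
#' @return Fraction of rows whose predicted class equals `g`, in [0, 1].
#' @export
classification_accuracy <- function(table, rule,
                                    osc_index = rule$osc_index) {
  o <- table[[paste0("o", osc_index)]]
  pred <- predict_counts(rule, o)
  mean(pred == table$g)
}
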