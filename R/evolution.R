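#' Settings of the evolutionary optimizer
#'
#' A generational genetic algorithm over [network_genome()]s: each
#' generation keeps the top `elite_fraction` unchanged and fills the rest
#' with mutated recombinations of two distinct parents drawn from the top
#' `parent_pool_fraction`. Mutation hits each of the 7 genes with
#' probability `expected_mutations_per_genome / 7` and perturbs a continuous
#' gene uniformly within `max_relative_mutation` of its current value.
#'
#' @param population_size Number of genomes K (>= 4); default 200.
#' @param elite_fraction Fraction carried unchanged; default 0.20.
#' @param parent_pool_fraction Fraction eligible as parents; default 0.50.
#' @param generations Number of generations; default 1000.
#' @param expected_mutations_per_genome Mean mutated genes per offspring;
#'   default 1.
#' @param max_relative_mutation Cap on a single relative change; default
#'   0.10.
#' @param rng_seed Integer seed driving initialization, parent choice,
#'   crossover and mutation.
#' @param gene_ranges Named list of `c(min, max)` sampling intervals for the
#'   continuous genes (`t_ilum3`, `t_start`, `t_end`, `t_max`, `alpha`,
#'   `beta`); `t_end` is sampled above `t_start + min_gap`.
#' @param min_gap Enforced minimum of `t_end - t_start` at initialization.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, elite_fraction = 0.20,
                      parent_pool_fraction = 0.50, generations = 1000L,
                      expected_mutations_per_genome = 1,
                      max_relative_mutation = 0.10, rng_seed = 1L,
                      gene_ranges = default_gene_ranges(), min_gap = 0.5) {
  stopifnot(population_size >= 4, generations >= 1,
            elite_fraction > 0, elite_fraction < parent_pool_fraction,
            parent_pool_fraction <= 1,
            max_relative_mutation > 0, max_relative_mutation < 1,
            expected_mutations_per_genome > 0)
  needed <- c("t_ilum3", "t_start", "t_end", "t_max", "alpha", "beta")
  stopifnot(all(needed %in% names(gene_ranges)))
  for (nm in needed) {
    r <- gene_ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("invalid range for gene '", nm, "'")
  }
  structure(list(population_size = as.integer(population_size),
                 elite_fraction = elite_fraction,
                 parent_pool_fraction = parent_pool_fraction,
                 generations = as.integer(generations),
                 expected_mutations_per_genome = expected_mutations_per_genome,
                 max_relative_mutation = max_relative_mutation,
                 rng_seed = as.integer(rng_seed),
                 gene_ranges = gene_ranges, min_gap = min_gap),
            class = "ga_config")
}

#' Default initialization ranges for the genome genes
#'
#' Chosen to bracket the ~10.8 time-unit free-running oscillation period
#' with margin; they contain the optimised Japanese-flag genome.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_gene_ranges <- function() {
  list(t_ilum3 = c(0, 30), t_start = c(0, 10), t_end = c(0.5, 40),
       t_max = c(5, 50), alpha = c(0, 1.5), beta = c(0, 1))
}

continuous_genes <- c("t_ilum3", "t_start", "t_end", "t_max", "alpha",
                      "beta")
role_levels <- c("normal", "input_x", "input_y")

#' Random initial population
#'
#' Samples `population_size` genomes independently and uniformly from the
#' configured gene ranges; `role3` is uniform over its three categories and
#' `t_end` is drawn above `t_start + min_gap` so every genome is valid by
#' construction. Uses the current RNG state (seed it, or use [evolve()]
#' which seeds from the config).
#'
#' @param cfg A [ga_config()].
#' @return List of [network_genome()]s.
#' @export
init_population <- function(cfg) {
  lapply(seq_len(cfg$population_size), function(i) random_genome(cfg))
}

random_genome <- function(cfg) {
  r <- cfg$gene_ranges
  runif1 <- function(rg) stats::runif(1, rg[1], rg[2])
  t_start <- runif1(r$t_start)
  te_lo <- max(r$t_end[1], t_start + cfg$min_gap)
  t_end <- stats::runif(1, te_lo, max(r$t_end[2], te_lo))
  network_genome(role3 = sample(role_levels, 1L),
                 t_ilum3 = runif1(r$t_ilum3), t_start = t_start,
                 t_end = t_end, t_max = runif1(r$t_max),
                 alpha = runif1(r$alpha), beta = runif1(r$beta))
}

#' Uniform crossover of two genomes
#'
#' Each of the 7 genes is copied from either parent with probability 1/2;
#' if the offspring ends with `t_end <= t_start` the two values are swapped
#' (never replaced by new ones).
#'
#' @param parent_a,parent_b Valid [network_genome()]s.
#' @return A [network_genome()] offspring.
#' @export
recombine <- function(parent_a, parent_b) {
  genes <- c("role3", continuous_genes)
  take_a <- stats::runif(length(genes)) < 0.5
  child <- parent_a
  for (k in seq_along(genes)) {
    child[[genes[k]]] <- if (take_a[k]) parent_a[[genes[k]]] else
      parent_b[[genes[k]]]
  }
  repair_genome(child)
}

repair_genome <- function(g) {
  if (g$t_end <= g$t_start) {
    tmp <- g$t_start
    g$t_start <- g$t_end
    g$t_end <- tmp
  }
  if (g$t_end <= g$t_start)  # equal after swap: nudge apart
    g$t_end <- g$t_start + .Machine$double.eps * max(1, g$t_start)
  g
}

#' Mutate a genome
#'
#' Each gene is mutated independently with probability
#' `expected_mutations_per_genome / 7`. A continuous gene is perturbed by a
#' uniform draw within `+/- max_relative_mutation` of its current value (a
#' gene at exactly 0 is therefore immobile); `role3`, if selected, is
#' resampled uniformly from the other two categories. The
#' `t_start < t_end` constraint is repaired by swapping.
#'
#' @param genome A valid [network_genome()].
#' @param cfg A [ga_config()].
#' @return A mutated [network_genome()].
#' @export
mutate_genome <- function(genome, cfg) {
  genes <- c("role3", continuous_genes)
  p <- cfg$expected_mutations_per_genome / length(genes)
  hit <- stats::runif(length(genes)) < p
  g <- genome
  for (k in seq_along(genes)) {
    if (!hit[k]) next
    nm <- genes[k]
    if (nm == "role3") {
      g$role3 <- sample(setdiff(role_levels, g$role3), 1L)
    } else {
      cur <- g[[nm]]
      g[[nm]] <- cur + stats::runif(1, -1, 1) * cfg$max_relative_mutation *
        abs(cur)
      if (g[[nm]] < 0) g[[nm]] <- 0  # rates and times stay non-negative
    }
  }
  repair_genome(g)
}

genome_fitness <- function(genome, dataset, params, pk, h) {
  tab <- tryCatch(
    respond_batch(genome, dataset, params = params, pk = pk, h = h,
                  on_failure = "na"),
    error = function(e) NULL)
  if (is.null(tab) || anyNA(tab$o3) || anyNA(tab$o1) || anyNA(tab$o2))
    return(list(fitness = 0, output = 1L))
  fr <- network_fitness(tab)
  list(fitness = fr$fitness, output = fr$output)
}

#' Evolve a network genome against the mutual-information fitness
#'
#' Generational GA with elitism: every genome is scored by
#' [network_fitness()] on its [respond_batch()] response table; the top
#' `elite_fraction` passes unchanged (fitness cached, never re-simulated);
#' the rest of the next generation are mutated recombinations of two
#' distinct parents drawn uniformly from the top `parent_pool_fraction`.
#' A genome whose simulation blows up scores fitness 0 and the run
#' continues. The RNG is seeded from `cfg$rng_seed`, so runs are exactly
#' reproducible.
#'
#' @param cfg A [ga_config()].
#' @param dataset Labeled training dataset (columns `x`, `y`, `g`).
#' @param params An [oregonator_params()].
#' @param pk A [peak_config()].
#' @param h RK4 step for fitness evaluation.
#' @param verbose Print a line per generation.
#' @return List with `best` (the best genome over all generations), `log`
#'   (data frame: generation, best_fitness_bits, mean_fitness_bits,
#'   best_output) and `best_fitness`.
#' @export
evolve <- function(cfg, dataset, params = oregonator_params(),
                   pk = peak_config(), h = 1e-4, verbose = FALSE) {
  stopifnot(inherits(cfg, "ga_config"), nrow(dataset) >= 1L)
  with_local_seed(cfg$rng_seed, {
    K <- cfg$population_size
    n_elite <- max(1L, as.integer(floor(cfg$elite_fraction * K)))
    n_pool <- max(2L, as.integer(floor(cfg$parent_pool_fraction * K)))
    pop <- init_population(cfg)
    fit <- rep(NA_real_, K)
    outp <- rep(NA_integer_, K)
    log <- data.frame(generation = integer(), best_fitness_bits = numeric(),
                      mean_fitness_bits = numeric(), best_output = integer())
    best_genome <- NULL
    best_fit <- -Inf
    for (gen in seq_len(cfg$generations)) {
      for (i in which(is.na(fit))) {
        sc <- genome_fitness(pop[[i]], dataset, params, pk, h)
        fit[i] <- sc$fitness
        outp[i] <- sc$output
      }
      ord <- order(fit, decreasing = TRUE)
      if (fit[ord[1]] > best_fit) {
        best_fit <- fit[ord[1]]
        best_genome <- pop[[ord[1]]]
      }
      log <- rbind(log, data.frame(generation = gen,
                                   best_fitness_bits = best_fit,
                                   mean_fitness_bits = mean(fit),
                                   best_output = outp[ord[1]]))
      if (verbose)
        message(sprintf("gen %d: best %.4f mean %.4f bits", gen, best_fit,
                        mean(fit)))
      if (gen == cfg$generations) break
      elite_idx <- ord[seq_len(n_elite)]
      pool_idx <- ord[seq_len(n_pool)]
      new_pop <- pop[elite_idx]
      new_fit <- fit[elite_idx]
      new_out <- outp[elite_idx]
      for (k in seq_len(K - n_elite)) {
        pr <- sample(pool_idx, 2L, replace = FALSE)
        child <- mutate_genome(recombine(pop[[pr[1]]], pop[[pr[2]]]), cfg)
        new_pop <- c(new_pop, list(child))
        new_fit <- c(new_fit, NA_real_)
        new_out <- c(new_out, NA_integer_)
      }
      pop <- new_pop
      fit <- new_fit
      outp <- new_out
    }
    list(best = best_genome, best_fitness = best_fit, log = log)
  })
}
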