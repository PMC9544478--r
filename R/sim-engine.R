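#' Simulation parameters for the TE-insertion fate model
#'
#' Bundles the parameters of the forward-in-time model: a population of `K`
#' diploids reproducing with partial selfing under hard selection, carrying a
#' single recessive transposon-insertion allele. The insertion only affects
#' fitness in the homozygous state (dominance `h = 0`): te-homozygotes have
#' fitness `1 + s_plus` during drought generations and `1 + s_minus`
#' otherwise; wild-type homozygotes and heterozygotes have fitness 1.
#'
#' @param carrying_capacity Carrying capacity `K` (diploid individuals).
#' @param selfing_rate Probability that an offspring is produced by selfing.
#' @param generations Number of generations `G` to simulate.
#' @param s_plus Selection coefficient of the te-homozygote during drought
#'   (study grid: 0.5, 1, 2, 5).
#' @param s_minus Selection coefficient of the te-homozygote under normal
#'   conditions (study grid: -0.1, -0.2, -0.5, -0.9). Must be >= -1 so that
#'   fitness stays non-negative.
#' @param dominance Dominance coefficient `h`; only `0` (fully recessive) is
#'   supported, matching the model.
#'
#' @return A list of class `sim_params`.
#' @examples
#' sim_params(s_plus = 1, s_minus = -0.5)
#' @export
sim_params <- function(carrying_capacity = 100, selfing_rate = 0.99,
                       generations = 50, s_plus = 0, s_minus = 0,
                       dominance = 0) {
  K <- as.integer(carrying_capacity)
  if (is.na(K) || K < 1) abort("`carrying_capacity` must be >= 1.")
  if (selfing_rate < 0 || selfing_rate > 1) abort("`selfing_rate` must be in [0, 1].")
  G <- as.integer(generations)
  if (is.na(G) || G < 1) abort("`generations` must be >= 1.")
  if (s_plus < -1 || s_minus < -1) {
    abort("Selection coefficients below -1 give negative fitness; s >= -1 required.")
  }
  if (dominance != 0) abort("Only the fully recessive model (dominance = 0) is supported.")
  structure(list(carrying_capacity = K, selfing_rate = selfing_rate,
                 generations = G, s_plus = s_plus, s_minus = s_minus,
                 dominance = 0), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> K = %d, selfing = %.3g, G = %d, s+ = %.3g, s- = %.3g, h = 0\n",
    x$carrying_capacity, x$selfing_rate, x$generations, x$s_plus, x$s_minus))
  invisible(x)
}

#' Fitness of a genotype under a given condition
#'
#' @param genotype One of `"wt_hom"`, `"het"`, `"te_hom"` (vectorised).
#' @param condition `"drought"` or `"normal"` (vectorised or length 1).
#' @param params A [sim_params()] object.
#' @return Numeric fitness values (wild-type reference = 1).
#' @examples
#' p <- sim_params(s_plus = 5, s_minus = -0.9)
#' genotype_fitness("te_hom", "drought", p) # 6
#' genotype_fitness("het", "normal", p)     # 1
#' @export
genotype_fitness <- function(genotype, condition, params) {
  genotype <- match.arg(genotype, c("wt_hom", "het", "te_hom"), several.ok = TRUE)
  condition <- match.arg(condition, c("drought", "normal"), several.ok = TRUE)
  s <- ifelse(condition == "drought", params$s_plus, params$s_minus)
  w <- ifelse(genotype == "te_hom", 1 + s, 1)
  if (any(w < 0)) abort("Negative fitness: selection coefficient below -1.")
  w
}

#' Founder population state
#'
#' The insertion enters the population as a single heterozygous carrier among
#' `K` individuals, i.e. one allele copy out of `2K` (frequency `1/(2K)`;
#' 0.005 at the default `K = 100`).
#'
#' @param params A [sim_params()] object.
#' @return A one-row tibble with columns `generation`, `n_wt_hom`, `n_het`,
#'   `n_te_hom`, `pop_size`, `tip_frequency`.
#' @examples
#' initialize_population(sim_params())
#' @export
initialize_population <- function(params) {
  K <- params$carrying_capacity
  population_state(0L, K - 1L, 1L, 0L)
}

population_state <- function(generation, n0, n1, n2) {
  size <- n0 + n1 + n2
  tibble::tibble(
    generation = as.integer(generation),
    n_wt_hom = as.integer(n0), n_het = as.integer(n1), n_te_hom = as.integer(n2),
    pop_size = as.integer(size),
    tip_frequency = ifelse(size > 0, (n1 + 2 * n2) / (2 * size), NA_real_))
}

#' Advance the population by one generation
#'
#' One reproduction step of the hard-selection model: mean fitness `wbar` is
#' computed over the current individuals, the next population size is
#' `N' = min(K, round(K * wbar))`, and each of the `N'` offspring draws
#' parent 1 proportional to fitness, selfs with probability `selfing_rate`
#' (otherwise parent 2 is an independent fitness-proportional draw), and
#' receives one Mendelian allele per parent. `N' = 0` extinguishes the
#' population.
#'
#' @param state A one-row population-state tibble (see
#'   [initialize_population()]).
#' @param condition `"drought"` or `"normal"`.
#' @param params A [sim_params()] object.
#' @return The next population-state tibble (generation incremented).
#' @examples
#' p <- sim_params(s_plus = 2, s_minus = -0.5)
#' set.seed(1)
#' next_generation(initialize_population(p), "normal", p)
#' @export
next_generation <- function(state, condition, params) {
  condition <- match.arg(condition, c("drought", "normal"))
  if (state$pop_size < 1) abort("Population is extinct; cannot reproduce.")
  s <- if (condition == "drought") params$s_plus else params$s_minus
  K <- params$carrying_capacity
  res <- sim_step_r(c(state$n_wt_hom, state$n_het, state$n_te_hom), s,
                    params$selfing_rate, K)
  population_state(state$generation + 1L, res[1], res[2], res[3])
}

# One reproduction step in R (used by next_generation; the replicate loop
# lives in C++). Returns integer counts c(n0, n1, n2).
sim_step_r <- function(n, s, selfing, K) {
  w2 <- 1 + s
  N <- sum(n)
  wbar <- (n[1] + n[2] + n[3] * w2) / N
  Np <- min(K, round(K * wbar))
  if (Np <= 0) return(c(0L, 0L, 0L))
  p <- offspring_probs_r(n, s, selfing)
  as.integer(stats::rmultinom(1, Np, p))
}

# Closed-form offspring genotype distribution (identical to the C++ engine):
# selfing mixture plus random outcrossing from the marginal gamete frequency.
offspring_probs_r <- function(n, s, selfing) {
  w2 <- 1 + s
  tot <- n[1] + n[2] + n[3] * w2
  q <- c(n[1], n[2], n[3] * w2) / tot
  a <- 0.5 * q[2] + q[3]
  p_self <- c(q[1] + 0.25 * q[2], 0.5 * q[2], q[3] + 0.25 * q[2])
  p_out <- c((1 - a)^2, 2 * a * (1 - a), a^2)
  selfing * p_self + (1 - selfing) * p_out
}

#' Run a single replicate of the fate simulation
#'
#' Simulates `G` generations from the founder state, applying drought fitness
#' in the scheduled generations, and summarises the outcome.
#'
#' @param params A [sim_params()] object.
#' @param schedule A [build_drought_schedule()] result or an integer vector of
#'   drought generation indices (possibly empty).
#' @param trajectory If `TRUE`, attach the per-generation state as a tibble in
#'   the `trajectory` list-column.
#' @return A one-row tibble with `final_frequency`, `persisted`, `fixed`,
#'   `extinct_population`, `pop_size` (and optionally `trajectory`).
#' @examples
#' set.seed(1)
#' run_replicate(sim_params(s_plus = 5, s_minus = -0.1),
#'               build_drought_schedule(50, 4, 4))
#' @export
run_replicate <- function(params, schedule = integer(), trajectory = FALSE) {
  G <- params$generations
  mask <- drought_mask(schedule, G)
  if (trajectory) {
    tr <- sim_trajectory_cpp(params$carrying_capacity, params$selfing_rate, G,
                             params$s_plus, params$s_minus, mask)
    final <- tr[nrow(tr), ]
    size <- final[2] + final[3] + final[4]
    freq <- if (size > 0) final[5] else 0
    out <- tibble::tibble(
      final_frequency = freq,
      persisted = size > 0 && freq > 0,
      fixed = size > 0 && freq == 1,
      extinct_population = size == 0,
      pop_size = as.integer(size),
      trajectory = list(tibble::tibble(
        generation = as.integer(tr[, 1]),
        n_wt_hom = as.integer(tr[, 2]), n_het = as.integer(tr[, 3]),
        n_te_hom = as.integer(tr[, 4]),
        pop_size = as.integer(tr[, 2] + tr[, 3] + tr[, 4]),
        tip_frequency = tr[, 5],
        drought = c(FALSE, mask))))
    return(out)
  }
  res <- sim_replicate_cpp(params$carrying_capacity, params$selfing_rate, G,
                           params$s_plus, params$s_minus, mask)
  replicate_row(res)
}

replicate_row <- function(res) {
  size <- res[1] + res[2] + res[3]
  tibble::tibble(
    final_frequency = res[4],
    persisted = res[5] == 0 & res[4] > 0,
    fixed = size > 0 & res[4] == 1,
    extinct_population = res[5] == 1,
    pop_size = as.integer(size))
}

#' Run many replicates under one parameter combination
#'
#' Each replicate runs in its own child RNG stream: `seed` seeds a root stream
#' from which one child seed per replicate is drawn, so results are
#' reproducible and independent of chunking.
#'
#' @inheritParams run_replicate
#' @param replicates Number of replicates.
#' @param seed Integer seed for the root stream (required for
#'   reproducibility; `NULL` continues the session RNG).
#' @return A tibble with one row per replicate (columns as [run_replicate()]
#'   plus `replicate`, `n_wt_hom`, `n_het`, `n_te_hom`).
#' @examples
#' run_replicates(sim_params(), replicates = 10, seed = 1)
#' @export
run_replicates <- function(params, schedule = integer(), replicates = 1000,
                           seed = NULL) {
  if (replicates < 1) abort("`replicates` must be >= 1.")
  G <- params$generations
  mask <- drought_mask(schedule, G)
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, replicates, replace = TRUE)
  out <- matrix(0, replicates, 5)
  for (r in seq_len(replicates)) {
    set.seed(child[r])
    out[r, ] <- sim_replicate_cpp(params$carrying_capacity, params$selfing_rate,
                                  G, params$s_plus, params$s_minus, mask)
  }
  size <- out[, 1] + out[, 2] + out[, 3]
  tibble::tibble(
    replicate = seq_len(replicates),
    n_wt_hom = as.integer(out[, 1]), n_het = as.integer(out[, 2]),
    n_te_hom = as.integer(out[, 3]),
    pop_size = as.integer(size),
    final_frequency = out[, 4],
    persisted = out[, 5] == 0 & out[, 4] > 0,
    fixed = size > 0 & out[, 4] == 1,
    extinct_population = out[, 5] == 1)
}

#' Run the full parameter grid of the fate simulation
#'
#' Crosses selection coefficients with drought-schedule shapes and summarises
#' each combination over replicate runs. The default grid is the study
#' design: `s_plus` in \{0.5, 1, 2, 5\}, `s_minus` in
#' \{-0.1, -0.2, -0.5, -0.9\}, 1-4 events of 2-4 generations, 1000
#' replicates per combination.
#'
#' @param s_plus,s_minus Selection-coefficient grids.
#' @param n_events,event_length Drought-schedule grids.
#' @param carrying_capacity,selfing_rate,generations Shared model parameters.
#' @param replicates Replicates per combination.
#' @param seed Root seed; every combination and replicate derives its own
#'   child stream, so the full grid is bit-reproducible.
#' @return A tibble (class `onsen_grid`) with one row per combination:
#'   `s_plus`, `s_minus`, `n_events`, `event_length`, `replicates`,
#'   `persistence_prob`, `mean_final_freq`, `fixation_prob`, `extinction_prob`.
#' @examples
#' run_grid(s_plus = c(0.5, 5), s_minus = -0.9, n_events = 1,
#'          event_length = 2, replicates = 50, seed = 1)
#' @export
run_grid <- function(s_plus = c(0.5, 1, 2, 5),
                     s_minus = c(-0.1, -0.2, -0.5, -0.9),
                     n_events = 1:4, event_length = 2:4,
                     carrying_capacity = 100, selfing_rate = 0.99,
                     generations = 50, replicates = 1000, seed = 1) {
  if (!length(s_plus) || !length(s_minus) || !length(n_events) ||
      !length(event_length)) abort("Empty parameter grid.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  grid <- tidyr::expand_grid(s_plus = s_plus, s_minus = s_minus,
                             n_events = as.integer(n_events),
                             event_length = as.integer(event_length))
  set.seed(seed)
  cell_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid), replace = TRUE)
  summaries <- purrr::pmap(
    list(grid$s_plus, grid$s_minus, grid$n_events, grid$event_length, cell_seed),
    function(sp, sm, ne, el, cs) {
      params <- sim_params(carrying_capacity, selfing_rate, generations, sp, sm)
      sched <- build_drought_schedule(generations, ne, el)
      reps <- run_replicates(params, sched, replicates, seed = cs)
      tibble::tibble(
        replicates = nrow(reps),
        persistence_prob = mean(reps$persisted),
        mean_final_freq = mean(reps$final_frequency),
        fixation_prob = mean(reps$fixed),
        extinction_prob = mean(reps$extinct_population))
    })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(summaries))
  class(out) <- c("onsen_grid", class(out))
  out
}

#' Plot a simulated persistence-probability grid
#'
#' @param object An [run_grid()] result.
#' @param ... Unused.
#' @return A ggplot: persistence probability against `s_plus`, coloured by
#'   `s_minus`, faceted by schedule shape.
#' @export
autoplot.onsen_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$s_plus), y = .data$persistence_prob,
    colour = factor(.data$s_minus), group = factor(.data$s_minus))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$event_length),
                        cols = ggplot2::vars(.data$n_events),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "s+ (drought advantage)", y = "Persistence probability",
                  colour = "s- (cost)") +
    ggplot2::theme_minimal()
}
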