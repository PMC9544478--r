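#' Exact state distribution of the fate model by transition-matrix iteration
#'
#' For small carrying capacities the fate model is a finite Markov chain over
#' genotype-count states `(n_wt_hom, n_het, n_te_hom)` with total size 0..K
#' (hard selection can shrink the population; `(0, 0, 0)` is absorbing
#' extinction). This enumerates the state space and propagates the founder
#' distribution through `G` condition-dependent multinomial transitions built
#' from the same reproduction rules as the stochastic engine, providing an
#' independent oracle for validation.
#'
#' @param params A [sim_params()] object; `carrying_capacity` must be small
#'   (at most `max_K`).
#' @param schedule Drought schedule (indices) as in [run_replicate()].
#' @param max_K Safety cap on the enumerable carrying capacity.
#' @return A tibble of states with columns `n_wt_hom`, `n_het`, `n_te_hom`,
#'   `pop_size`, `tip_frequency`, `probability` (summing to 1).
#' @examples
#' p <- sim_params(carrying_capacity = 2, selfing_rate = 1, generations = 1)
#' exact_chain_distribution(p)
#' @export
exact_chain_distribution <- function(params, schedule = integer(), max_K = 6) {
  K <- params$carrying_capacity
  if (K > max_K) {
    abort(sprintf("K = %d too large to enumerate (max_K = %d).", K, max_K))
  }
  G <- params$generations
  mask <- drought_mask(schedule, G)

  states <- enumerate_states(K)
  n_states <- nrow(states)
  key <- state_key(states$n0, states$n1, states$n2, K)
  index <- setNames(seq_len(n_states), key)

  trans <- list(
    normal = transition_matrix(states, index, params$s_minus,
                               params$selfing_rate, K),
    drought = transition_matrix(states, index, params$s_plus,
                                params$selfing_rate, K))

  v <- numeric(n_states)
  v[index[[state_key(K - 1L, 1L, 0L, K)]]] <- 1
  for (t in seq_len(G)) {
    M <- if (mask[t]) trans$drought else trans$normal
    v <- as.numeric(v %*% M)
  }

  size <- states$n0 + states$n1 + states$n2
  tibble::tibble(
    n_wt_hom = states$n0, n_het = states$n1, n_te_hom = states$n2,
    pop_size = size,
    tip_frequency = ifelse(size > 0, (states$n1 + 2 * states$n2) / (2 * size),
                           NA_real_),
    probability = v)
}

# All compositions of sizes 0..K into three genotype counts.
enumerate_states <- function(K) {
  out <- list()
  for (N in 0:K) {
    for (n0 in 0:N) {
      for (n1 in 0:(N - n0)) {
        out[[length(out) + 1L]] <- c(n0, n1, N - n0 - n1)
      }
    }
  }
  m <- do.call(rbind, out)
  tibble::tibble(n0 = as.integer(m[, 1]), n1 = as.integer(m[, 2]),
                 n2 = as.integer(m[, 3]))
}

state_key <- function(n0, n1, n2, K) {
  sprintf("%d.%d.%d", n0, n1, n2)
}

# Row-stochastic transition matrix for one condition, using the identical
# reproduction rules as the engine: N' = min(K, round(K * wbar)) with base-R
# round (half-to-even, matching nearbyint in C++), offspring counts
# Multinomial(N', p) with the closed-form offspring distribution.
transition_matrix <- function(states, index, s, selfing, K) {
  n_states <- nrow(states)
  M <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    n <- c(states$n0[i], states$n1[i], states$n2[i])
    N <- sum(n)
    if (N == 0) { # extinct: absorbing
      M[i, index[[state_key(0L, 0L, 0L, K)]]] <- 1
      next
    }
    w2 <- 1 + s
    wbar <- (n[1] + n[2] + n[3] * w2) / N
    Np <- min(K, round(K * wbar))
    if (Np <= 0) {
      M[i, index[[state_key(0L, 0L, 0L, K)]]] <- 1
      next
    }
    p <- offspring_probs_r(n, s, selfing)
    for (m0 in 0:Np) {
      for (m1 in 0:(Np - m0)) {
        m2 <- Np - m0 - m1
        j <- index[[state_key(m0, m1, m2, K)]]
        M[i, j] <- M[i, j] + dmultinom(c(m0, m1, m2), prob = p)
      }
    }
  }
  M
}

#' Total-variation distance between simulated and exact state distributions
#'
#' Convenience check used in validation: runs the stochastic engine and
#' compares the empirical distribution over final states with
#' [exact_chain_distribution()].
#'
#' @inheritParams exact_chain_distribution
#' @param replicates Number of stochastic replicates.
#' @param seed Root seed for the replicates.
#' @return A list with `tv` (total-variation distance), `exact` and
#'   `empirical` tibbles.
#' @export
sim_vs_exact_tv <- function(params, schedule = integer(), replicates = 1e5,
                            seed = 1, max_K = 6) {
  exact <- exact_chain_distribution(params, schedule, max_K = max_K)
  reps <- run_replicates(params, schedule, replicates, seed = seed)
  K <- params$carrying_capacity
  key_sim <- state_key(reps$n_wt_hom, reps$n_het, reps$n_te_hom, K)
  key_ex <- state_key(exact$n_wt_hom, exact$n_het, exact$n_te_hom, K)
  counts <- table(factor(key_sim, levels = key_ex))
  emp <- as.numeric(counts) / replicates
  list(tv = 0.5 * sum(abs(emp - exact$probability)),
       exact = exact,
       empirical = dplyr::mutate(exact, probability = emp))
}
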