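# Finite-population agent-based realization of the identical lifecycle,
# used as an independent validation oracle for the deterministic recursion.

# Sample an agent population of exact size N whose composition matches the
# genotype frequencies as closely as integers allow (largest remainder), so
# one-generation comparisons against the deterministic update carry no
# initial sampling noise.
.compose_agents <- function(freqs, N) {
  exact <- freqs * N
  counts <- floor(exact)
  short <- N - sum(counts)
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep.int(seq_along(freqs), counts)
}

#' Agent-based finite-population simulation of the lifecycle
#'
#' Explicit stochastic implementation of the same generational lifecycle as
#' the deterministic recursion: each agent searches for a partner (clone
#' with probability `theta`, implemented as an exact genotype copy of
#' itself, otherwise a uniformly drawn other agent), reassociating on tag
#' mismatch with probability `alpha` (retry loop capped at 1e4); helpers
#' that find a match pay `c` and deliver `b` to the realized partner
#' (credited to themselves when the partner was a clone); infection is a
#' Bernoulli draw with the lagged empirical Resist frequency; `N` offspring
#' are formed from fecundity-weighted parent pairs with free recombination
#' and Trait/Choice mutation.
#'
#' @param params A `kintags_params`.
#' @param N Population size (>= 2; constant across generations).
#' @param generations Number of generations to simulate.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param init Either a genotype frequency vector (agents composed by
#'   largest-remainder rounding) or arguments for [initialize_population()].
#' @param space Optional `kintags_space`.
#' @return List with `observables` (data.frame, one row per generation
#'   recorded after reproduction), `genotype_freqs` (empirical frequencies
#'   after the last generation), `N`, `params`.
#' @examples
#' p <- model_params(L_resist = 2, L_neutral = 2)
#' sim <- simulate_finite(p, N = 500, generations = 3, seed = 1)
#' sim$observables$p_bar
#' @export
simulate_finite <- function(params, N, generations, seed, init = list(),
                            space = NULL) {
  stopifnot(inherits(params, "kintags_params"))
  if (length(N) != 1L || !is.finite(N) || N < 2)
    stop("'N' must be at least 2", call. = FALSE)
  if (length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  N <- as.integer(N)
  if (is.null(space)) space <- build_space(params$L_resist, params$L_neutral)
  f0 <- if (is.numeric(init)) {
    simplex_check(init, what = "initial genotype frequencies")
    init
  } else {
    if (is.null(init$seed)) init$seed <- seed
    do.call(initialize_population, c(list(space = space), init))$freqs
  }

  with_preserved_rng(seed, function() {
    agents <- .compose_agents(f0, N)
    emp_resist <- function(a) tabulate(space$resist[a], space$L_resist) / N
    history <- resist_history(emp_resist(agents), params$lag)
    obs <- matrix(NA_real_, nrow = generations, ncol = length(OBS_COLS),
                  dimnames = list(NULL, OBS_COLS))
    theta <- params$theta; alpha <- params$alpha
    h_of <- space$trait == TRAIT_HELP
    for (t in seq_len(generations)) {
      res_t <- space$resist[agents]
      neu_t <- space$neutral[agents]
      own_tag <- ifelse(space$choice[agents] == CHOICE_USE_RESIST, res_t,
                        space$L_resist + neu_t)

      # Encounter loop: each focal independently searches until matched or
      # it gives up (prob 1 - alpha per mismatch).
      partner <- integer(N)      # 0 = none, -1 = clone, else agent index
      active <- seq_len(N)
      rounds <- 0L
      while (length(active)) {
        rounds <- rounds + 1L
        if (rounds > 10000L)
          stop("encounter loop exceeded 10000 reassociation rounds",
               call. = FALSE)
        is_clone <- stats::runif(length(active)) < theta
        cand <- sample.int(N, length(active), replace = TRUE)
        # a uniformly drawn *other* agent: redraw collisions with the focal
        coll <- which(!is_clone & cand == active)
        while (length(coll)) {
          cand[coll] <- sample.int(N, length(coll), replace = TRUE)
          coll <- coll[cand[coll] == active[coll]]
        }
        cand_tag <- ifelse(space$choice[agents[active]] == CHOICE_USE_RESIST,
                           space$resist[agents[cand]],
                           space$L_resist + space$neutral[agents[cand]])
        match <- is_clone | cand_tag == own_tag[active]
        partner[active[match]] <- ifelse(is_clone[match], -1L, cand[match])
        retry <- !match & stats::runif(length(active)) < alpha
        active <- active[retry]
      }

      helper <- h_of[agents]
      interacted <- partner != 0L
      gives <- helper & interacted
      received <- numeric(N)
      self_help <- which(gives & partner == -1L)
      received[self_help] <- received[self_help] + 1
      other_help <- which(gives & partner > 0L)
      if (length(other_help)) {
        tb <- tabulate(partner[other_help], N)
        received <- received + tb
      }

      Z <- lagged_frequencies(history, params$lag)
      infected <- stats::runif(N) < Z[res_t]
      fec <- (1 - params$c_cost * gives + params$b * received) *
        (1 - params$d * infected)
      if (all(fec <= 0)) stop("all fecundities are zero", call. = FALSE)

      # Reproduction: fecundity-weighted parent pairs, free recombination,
      # then Trait/Choice mutation.
      pa <- sample.int(N, N, replace = TRUE, prob = fec)
      pb <- sample.int(N, N, replace = TRUE, prob = fec)
      fromA <- matrix(stats::runif(4L * N) < 0.5, nrow = N)
      r_new <- ifelse(fromA[, 1L], space$resist[agents[pa]], space$resist[agents[pb]])
      n_new <- ifelse(fromA[, 2L], space$neutral[agents[pa]], space$neutral[agents[pb]])
      c_new <- ifelse(fromA[, 3L], space$choice[agents[pa]], space$choice[agents[pb]])
      t_new <- ifelse(fromA[, 4L], space$trait[agents[pa]], space$trait[agents[pb]])
      flip_t <- stats::runif(N) < params$mu_trait
      t_new[flip_t] <- 3L - t_new[flip_t]
      flip_c <- stats::runif(N) < params$mu_choice
      c_new[flip_c] <- 3L - c_new[flip_c]
      agents <- encode_genotype(space, r_new, n_new, c_new, t_new)

      xR <- emp_resist(agents)
      xN <- tabulate(space$neutral[agents], space$L_neutral) / N
      history <- history_append(history, xR)
      smax <- 1 - 1 / params$L_max
      rawR <- 1 - sum(xR^2); rawN <- 1 - sum(xN^2)
      obs[t, ] <- c(t, rawR, min(1, max(0, rawR / smax)),
                    rawN, min(1, max(0, rawN / smax)),
                    mean(h_of[agents]),
                    mean(space$choice[agents] == CHOICE_USE_RESIST),
                    sum(xR * lagged_frequencies(history, params$lag)),
                    NA_real_, NA_real_, mean(fec))
    }
    list(observables = as.data.frame(obs),
         genotype_freqs = tabulate(agents, space$G) / N,
         N = N, params = params)
  })
}
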