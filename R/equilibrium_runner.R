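# Lifecycle composition, iteration to fixed point / limit cycle, parameter
# sweeps, and figure-style presets.

# One lifecycle step on raw vectors; returns the new frequency vector plus
# the observables row assembled from quantities already computed.  Kept lean:
# it runs 1e4-1e5 times per equilibrium run.
.step_core <- function(freqs, history, params, space) {
  soc <- social_payoff_vector(freqs, params, space, per_tag = FALSE)
  Z <- lagged_frequencies(history, params$lag)
  w <- soc$payoff * (1 - params$d * Z[space$resist])
  wbar <- sum(freqs * w)
  if (!is.finite(wbar) || wbar <= 0)
    stop("mean fitness is not positive; selection step undefined", call. = FALSE)
  f <- freqs * w / wbar
  f <- recombine_free(f, space)
  f <- mutate(f, params$mu_trait, params$mu_choice, space)
  f <- simplex_clip(f)

  xR <- grouped_sum(f, space$gs_resist)
  history <- history_append(history, xR)

  obs <- c(NA_real_,  # generation, filled by caller
           1 - sum(soc$x_resist^2),
           NA_real_,  # scaled resist, filled below
           1 - sum(soc$x_neutral^2),
           NA_real_,
           soc$p_bar,
           grouped_sum(freqs, space$gs_choice)[CHOICE_USE_RESIST],
           sum(soc$x_resist * Z),
           NA_real_, NA_real_,  # LD assocs, filled below
           wbar)
  smax <- 1 - 1 / params$L_max
  obs[3L] <- min(1, max(0, obs[2L] / smax))
  obs[5L] <- min(1, max(0, obs[4L] / smax))
  h <- space$trait == TRAIT_HELP
  XoR <- soc$x_resist[space$resist]
  XoN <- soc$x_neutral[space$neutral]
  obs[9L] <- sum(freqs * XoR * h) - sum(freqs * XoR) * soc$p_bar
  obs[10L] <- sum(freqs * XoN * h) - sum(freqs * XoN) * soc$p_bar
  list(freqs = f, history = history, obs = obs)
}

#' Advance the population by one generation
#'
#' Applies, in lifecycle order: selection by the product of social and
#' parasite payoffs, free recombination, mutation at Trait and Choice, then
#' the Resist census is appended to the history and the generation counter
#' incremented.
#'
#' @param state A `kintags_state`.
#' @param history A `kintags_history`.
#' @param params A `kintags_params`.
#' @param space A `kintags_space`.
#' @return List with updated `state` and `history`.
#' @export
step_generation <- function(state, history, params, space) {
  stopifnot(inherits(state, "kintags_state"))
  st <- .step_core(state$freqs, history, params, space)
  list(state = population_state(st$freqs, space,
                                generation = state$generation + 1L),
       history = st$history)
}

#' Iterate the recursion to a fixed point or limit cycle
#'
#' Runs [step_generation()] until (a) the L-infinity genotype-frequency
#' change in one step drops below `params$fixed_point_tol` (status
#' `"fixed_point"`), (b) the observable means of two consecutive windows of
#' `params$cycle_window` generations agree within 1e-6 (status
#' `"limit_cycle"`, the expected outcome under Red Queen oscillations), or
#' (c) `params$max_generations` is reached (status `"max_generations"`).
#' Equilibrium observables are means over the final window, so cycling runs
#' are summarized stably.
#'
#' @param params A `kintags_params`.
#' @param init Either a `kintags_state` or a list of arguments passed to
#'   [initialize_population()] (`p0`, `q0`, `resist_freqs`, `neutral_freqs`,
#'   `eps`, `seed`; seed defaults to `params$seed`).
#' @param space Optional `kintags_space`; built from `params` if missing.
#' @param keep_trajectory If `FALSE` (default) only the final window of
#'   per-generation observables is returned in `$observables`; if `TRUE`,
#'   the full trajectory (one row per generation).
#' @return An object of class `kintags_trajectory`: list with
#'   `observables` (data.frame), `equilibrium` (named numeric: window-mean
#'   observables), `final_state`, `final_history`, `status`, `generations`,
#'   `params`.
#' @examples
#' p <- model_params(L_resist = 2, L_neutral = 2, max_generations = 200)
#' tr <- run_to_equilibrium(p)
#' tr$status
#' @export
run_to_equilibrium <- function(params, init = list(), space = NULL,
                               keep_trajectory = FALSE) {
  stopifnot(inherits(params, "kintags_params"))
  if (is.null(space)) space <- build_space(params$L_resist, params$L_neutral)
  state <- if (inherits(init, "kintags_state")) init else {
    if (is.null(init$seed)) init$seed <- params$seed
    do.call(initialize_population, c(list(space = space), init))
  }
  freqs <- state$freqs
  history <- resist_history(rowsum_vec(freqs, space$resist, space$L_resist),
                            params$lag)
  W <- params$cycle_window
  maxg <- params$max_generations
  obs <- matrix(NA_real_, nrow = maxg, ncol = length(OBS_COLS),
                dimnames = list(NULL, OBS_COLS))
  status <- "max_generations"
  gen <- state$generation
  t_done <- 0L
  for (t in seq_len(maxg)) {
    st <- .step_core(freqs, history, params, space)
    delta <- max(abs(st$freqs - freqs))
    st$obs[1L] <- gen  # row describes the pre-step adult census
    freqs <- st$freqs
    history <- st$history
    gen <- gen + 1L
    obs[t, ] <- st$obs
    t_done <- t
    if (!all(is.finite(freqs)))
      stop(sprintf("non-finite frequencies at generation %d", gen), call. = FALSE)
    if (delta < params$fixed_point_tol) { status <- "fixed_point"; break }
    if (t >= 2L * W && t %% W == 0L) {
      m1 <- colMeans(obs[(t - W + 1L):t, -1L, drop = FALSE])
      m2 <- colMeans(obs[(t - 2L * W + 1L):(t - W), -1L, drop = FALSE])
      if (max(abs(m1 - m2)) < 1e-6) { status <- "limit_cycle"; break }
    }
  }
  obs <- obs[seq_len(t_done), , drop = FALSE]
  wlen <- min(W, t_done)
  eq <- colMeans(obs[(t_done - wlen + 1L):t_done, , drop = FALSE])
  out_obs <- if (keep_trajectory) obs else
    obs[(t_done - wlen + 1L):t_done, , drop = FALSE]
  structure(list(
    observables = as.data.frame(out_obs),
    equilibrium = eq,
    final_state = population_state(freqs, space, generation = gen),
    final_history = history,
    status = status,
    generations = t_done,
    params = params
  ), class = "kintags_trajectory")
}

#' @export
print.kintags_trajectory <- function(x, ...) {
  cat(sprintf("Equilibrium run: %d generations, status '%s'\n",
              x$generations, x$status))
  eq <- x$equilibrium
  cat(sprintf("  scaled diversity: Resist %.3f, Neutral %.3f\n",
              eq[["div_resist_scaled"]], eq[["div_neutral_scaled"]]))
  cat(sprintf("  p_bar %.3f, use-Resist %.3f, susceptibility %.3f\n",
              eq[["p_bar"]], eq[["choice_freq"]], eq[["susceptibility"]]))
  invisible(x)
}

# Scenario handling: fixed scenarios force mu_choice = 0 and a monomorphic
# Choice locus; the evolving scenario keeps both Choice alleles segregating.
scenario_setup <- function(scenario, params, init) {
  scenario <- match.arg(scenario, c("choice_evolving", "choice_fixed_resist",
                                    "choice_fixed_neutral"))
  if (scenario == "choice_fixed_resist") {
    params$mu_choice <- 0; init$q0 <- 1
  } else if (scenario == "choice_fixed_neutral") {
    params$mu_choice <- 0; init$q0 <- 0
  } else if (is.null(init$q0)) init$q0 <- 0.5
  list(params = params, init = init, scenario = scenario)
}

#' Parameter sweep over a grid
#'
#' Runs [run_to_equilibrium()] once per grid row.  Grid columns matching
#' `kintags_params` fields override the base parameters; an optional
#' `scenario` column selects Choice handling per cell.  Errors in a cell are
#' recorded in its `status` field and the sweep continues.
#'
#' @param params_base A `kintags_params` supplying non-swept values.
#' @param grid A data.frame, one row per cell (e.g. from [expand.grid()]
#'   over `lag` and `d`).
#' @param init Initial-state specification list (see [run_to_equilibrium()]).
#' @param scenario Default scenario when the grid has no `scenario` column.
#' @param baseline If `TRUE`, each cell is paired with a matched run with
#'   `b = c = 0` (no social selection) and its equilibrium susceptibility is
#'   reported as `susceptibility_baseline`, isolating the
#'   recognition-induced change in parasite susceptibility.
#' @return A `kintags_sweep` data.frame: the grid columns plus
#'   `div_resist_scaled`, `div_neutral_scaled`, `p_bar`, `choice_freq`,
#'   `susceptibility`, `susceptibility_baseline`, `ld_assoc_resist`,
#'   `ld_assoc_neutral`, `status`, `generations`.
#' @export
sweep_grid <- function(params_base, grid, init = list(),
                       scenario = "choice_evolving", baseline = FALSE) {
  stopifnot(inherits(params_base, "kintags_params"), is.data.frame(grid))
  n <- nrow(grid)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- if ("scenario" %in% names(grid)) grid$scenario[i] else scenario
    row <- tryCatch({
      p_args <- unclass(params_base)
      for (nm in intersect(names(grid), names(p_args)))
        p_args[[nm]] <- grid[[nm]][i]
      p <- do.call(model_params, p_args)  # revalidates the overridden cell
      setup <- scenario_setup(sc, p, init)
      tr <- run_to_equilibrium(setup$params, setup$init)
      eq <- tr$equilibrium
      base_susc <- NA_real_
      if (baseline) {
        pb <- setup$params; pb$b <- 0; pb$c_cost <- 0
        trb <- run_to_equilibrium(pb, setup$init)
        base_susc <- trb$equilibrium[["susceptibility"]]
      }
      data.frame(
        div_resist_scaled = eq[["div_resist_scaled"]],
        div_neutral_scaled = eq[["div_neutral_scaled"]],
        p_bar = eq[["p_bar"]], choice_freq = eq[["choice_freq"]],
        susceptibility = eq[["susceptibility"]],
        susceptibility_baseline = base_susc,
        ld_assoc_resist = eq[["ld_assoc_resist"]],
        ld_assoc_neutral = eq[["ld_assoc_neutral"]],
        status = tr$status, generations = tr$generations,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(div_resist_scaled = NA_real_, div_neutral_scaled = NA_real_,
                 p_bar = NA_real_, choice_freq = NA_real_,
                 susceptibility = NA_real_, susceptibility_baseline = NA_real_,
                 ld_assoc_resist = NA_real_, ld_assoc_neutral = NA_real_,
                 status = paste0("error: ", conditionMessage(e)),
                 generations = NA_integer_, stringsAsFactors = FALSE)
    })
    res[[i]] <- cbind(grid[i, , drop = FALSE], row, scenario_used = sc)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("kintags_sweep", class(out))
  out
}

#' Figure-style experiment presets
#'
#' Canned parameter settings reproducing the model's headline analyses:
#' \describe{
#'   \item{`fig1b`}{Analytic curve: probability of being recognized and
#'     helped vs own-tag frequency at `alpha = 0` (Crozier's positive
#'     frequency dependence), with the pedigree-only baseline `theta`.}
#'   \item{`fig3`}{Lag x virulence sweep at `alpha = 0`, Choice fixed on
#'     Resist: scaled Resist diversity plus susceptibility and its matched
#'     no-social-selection baseline.}
#'   \item{`fig4b`}{Analytic curve: relatedness of tag-matched partners vs
#'     tag frequency (no tag-trait LD), with the random-partner baseline.}
#'   \item{`fig5a`}{Lag x virulence sweep at `alpha = 1`, evolving Choice:
#'     Neutral-minus-Resist scaled diversity (`div_diff` column).}
#'   \item{`fig5b`}{Lag x virulence sweep at `alpha = 0.99` comparing the
#'     evolving-Choice maximum diversity against both fixed-locus cases
#'     (`div_gain` = evolving max - best fixed max).}
#'   \item{`fig6`}{One low-lag, intermediate-virulence cell at
#'     `alpha = 0.99`: equilibrium Resist and Neutral diversity under fixed
#'     vs evolving recognition locus (hitchhiking demonstration).}
#' }
#'
#' @param name Preset name.
#' @param overrides Named list overriding `kintags_params` fields (e.g.
#'   `max_generations`) for the iterative presets.
#' @param lag_grid,d_grid Grid axes for the sweep presets.
#' @param X Tag-frequency grid for the analytic presets.
#' @return A data.frame (curve table or sweep table, see above).
#' @export
preset <- function(name, overrides = list(),
                   lag_grid = c(0L, 2L, 10L), d_grid = c(0.1, 0.5, 0.9),
                   X = seq(0.01, 1, by = 0.01)) {
  valid <- c("fig1b", "fig3", "fig4b", "fig5a", "fig5b", "fig6")
  if (!name %in% valid)
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(valid, collapse = ", ")), call. = FALSE)
  base <- list(theta = 0.25, b = 0.3, c_cost = 0.1, L_max = 10,
               L_resist = 10, L_neutral = 10, mu_trait = 0.001,
               mu_choice = 0.001, max_generations = 50000L)
  prm <- function(...) {
    args <- utils::modifyList(base, utils::modifyList(list(...), overrides))
    do.call(model_params, args[names(args) %in% names(formals(model_params))])
  }
  if (name == "fig1b") {
    p <- prm(alpha = 0)
    return(data.frame(X = X,
                      p_match = p_interact(X, p$theta, 0),
                      p_pedigree = p$theta))
  }
  if (name == "fig4b") {
    p <- prm()
    return(data.frame(X = X,
                      rtag = relatedness_rtag(X, 0.5, 0.5, p$theta),
                      rtag_random = p$theta))
  }
  grid <- expand.grid(lag = lag_grid, d = d_grid)
  if (name == "fig3") {
    p <- prm(alpha = 0)
    return(sweep_grid(p, grid, scenario = "choice_fixed_resist",
                      baseline = TRUE))
  }
  if (name == "fig5a") {
    p <- prm(alpha = 1)
    out <- sweep_grid(p, grid, scenario = "choice_evolving")
    out$div_diff <- out$div_neutral_scaled - out$div_resist_scaled
    return(out)
  }
  if (name == "fig5b") {
    p <- prm(alpha = 0.99)
    ev <- sweep_grid(p, grid, scenario = "choice_evolving")
    fr <- sweep_grid(p, grid, scenario = "choice_fixed_resist")
    fn <- sweep_grid(p, grid, scenario = "choice_fixed_neutral")
    mx <- function(s) pmax(s$div_resist_scaled, s$div_neutral_scaled)
    out <- grid
    out$div_max_evolving <- mx(ev)
    out$div_max_fixed_resist <- mx(fr)
    out$div_max_fixed_neutral <- mx(fn)
    out$div_gain <- out$div_max_evolving -
      pmax(out$div_max_fixed_resist, out$div_max_fixed_neutral)
    out$status_evolving <- ev$status
    class(out) <- c("kintags_sweep", class(out))
    return(out)
  }
  # fig6: single low-lag, intermediate-d cell, alpha = 0.99.  This is a
  # build-up experiment: Neutral starts nearly monomorphic (one tag at 0.91)
  # so that any equilibrium Neutral diversity had to be actively generated,
  # while Resist starts with standing uniform variation for parasites to
  # maintain.
  p <- prm(alpha = 0.99, lag = 1L, d = 0.5)
  init <- list(neutral_freqs = c(1 - 0.01 * (p$L_neutral - 1),
                                 rep(0.01, p$L_neutral - 1)),
               eps = 1e-4)
  cell <- data.frame(lag = p$lag, d = p$d)
  rows <- lapply(c("choice_fixed_resist", "choice_fixed_neutral",
                   "choice_evolving"), function(sc) {
    s <- sweep_grid(p, cell, init = init, scenario = sc)
    s$condition <- sc
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
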