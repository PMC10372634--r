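# Lagged frequency-dependent parasite selection at the Resist locus and the
# susceptibility statistic.

#' Ring buffer of past Resist allele frequencies
#'
#' Parasites adapt to the Resist allele composition of the host population
#' with a delay of `lag` generations, so the engine keeps the last
#' `lag + 1` censuses of Resist allele frequencies (newest last).  One
#' census is taken per generation, after the full lifecycle step
#' (post-mutation adults).
#'
#' @param initial_freqs Resist allele frequency vector at generation 0.
#' @param lag Nonnegative integer parasite adaptation delay.
#' @return An object of class `kintags_history`.
#' @export
resist_history <- function(initial_freqs, lag) {
  if (length(lag) != 1L || !is.finite(lag) || lag < 0 || lag != round(lag))
    stop("'lag' must be a nonnegative integer", call. = FALSE)
  simplex_check(initial_freqs, tol = 1e-12, what = "Resist frequency vector")
  structure(list(buffer = list(as.numeric(initial_freqs)),
                 lag = as.integer(lag)),
            class = "kintags_history")
}

#' Append a Resist census to the history, dropping entries older than needed
#'
#' @param history A `kintags_history`.
#' @param freqs Current Resist allele frequency vector.
#' @return The updated history.
#' @export
history_append <- function(history, freqs) {
  stopifnot(inherits(history, "kintags_history"))
  simplex_check(freqs, tol = 1e-9, what = "Resist frequency vector")
  buf <- c(history$buffer, list(as.numeric(freqs)))
  keep <- history$lag + 1L
  if (length(buf) > keep) buf <- buf[(length(buf) - keep + 1L):length(buf)]
  history$buffer <- buf
  history
}

#' Lagged Resist allele frequencies (the parasite target, Z)
#'
#' Returns the census recorded `lag` generations before the newest one.
#' During warm-up, when fewer than `lag + 1` censuses exist, the oldest
#' stored vector (the initial frequencies) is used; equilibrium statistics
#' are insensitive to this policy.
#'
#' @param history A `kintags_history`.
#' @param lag Nonnegative integer; defaults to the history's own lag and may
#'   not exceed it.
#' @return The Resist allele frequency vector Z.
#' @export
lagged_frequencies <- function(history, lag = history$lag) {
  stopifnot(inherits(history, "kintags_history"))
  if (length(lag) != 1L || !is.finite(lag) || lag < 0 || lag != round(lag))
    stop("'lag' must be a nonnegative integer", call. = FALSE)
  if (lag > history$lag)
    stop("'lag' exceeds the history's retention window", call. = FALSE)
  n <- length(history$buffer)
  history$buffer[[max(1L, n - lag)]]
}

#' Per-genotype parasite fecundity multipliers
#'
#' A host carrying Resist allele `i` is infected with probability `Z_i`, the
#' lagged population frequency of that allele, and infection reduces
#' fecundity by `d`; the expected multiplier is `1 - d Z_i`.
#'
#' @param freqs Genotype frequency vector (used only for validation).
#' @param history A `kintags_history`.
#' @param params A `kintags_params`.
#' @param space A `kintags_space`.
#' @return Numeric vector of per-genotype multipliers in `[1 - d, 1]`.
#' @export
parasite_payoff_vector <- function(freqs, history, params, space) {
  stopifnot(inherits(params, "kintags_params"), inherits(space, "kintags_space"))
  Z <- lagged_frequencies(history, params$lag)
  if (length(Z) != space$L_resist)
    stop("history Resist dimension does not match the genotype space",
         call. = FALSE)
  1 - params$d * Z[space$resist]
}

#' Population mean parasite susceptibility
#'
#' The generational probability that a random host is infected:
#' `sum_i x_i(t) Z_i`, with `x` the current Resist allele frequencies and
#' `Z` their lagged values.  With `lag = 0` this is the Simpson
#' concentration `sum_i x_i^2`, minimized at `1 / L_resist` by the uniform
#' tag distribution.
#'
#' @param resist_freqs Current Resist allele frequency vector.
#' @param history A `kintags_history`.
#' @param lag Lag to use (default: the history's lag).
#' @return Susceptibility in `[0, 1]`.
#' @export
susceptibility <- function(resist_freqs, history, lag = history$lag) {
  Z <- lagged_frequencies(history, lag)
  if (length(Z) != length(resist_freqs))
    stop("frequency vectors have mismatched lengths", call. = FALSE)
  sum(resist_freqs * Z)
}
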