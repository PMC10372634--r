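# Summary statistics tracked per generation: tag diversity, tag-trait
# linkage disequilibrium, per-tag relatedness, susceptibility, mean fitness.

#' Tag diversity at a recognition locus
#'
#' Raw diversity is the gene (Simpson) diversity `1 - sum_i x_i^2`: the
#' probability that two random individuals differ at the locus.  Scaled
#' diversity divides by the maximum attainable under the genetic constraint,
#' `1 - 1/L_max` (all `L_max` tags equifrequent), and is clipped to
#' `[0, 1]`.
#'
#' @param allele_freqs Allele frequency vector on the simplex.
#' @param L_max Genetic constraint used for scaling (>= 2).
#' @return List with elements `raw` and `scaled`.
#' @examples
#' tag_diversity(rep(0.1, 10), 10)  # raw 0.9, scaled 1
#' @export
tag_diversity <- function(allele_freqs, L_max) {
  simplex_check(allele_freqs, tol = 1e-9, what = "allele frequencies")
  if (L_max < 2) stop("'L_max' must be >= 2 for scaled diversity", call. = FALSE)
  raw <- 1 - sum(allele_freqs^2)
  scaled <- min(1, max(0, raw / (1 - 1 / L_max)))
  list(raw = raw, scaled = scaled)
}

#' Tag-trait linkage disequilibrium at a recognition locus
#'
#' `D_j = freq(tag j & HELP) - x_j p_bar` measures the association of each
#' tag with the helping allele; the deviations sum to zero over tags.  The
#' scalar `A` is the population covariance between an individual's own-tag
#' frequency at the locus and its helping indicator,
#' `A = sum_g x_g X_g h_g - (sum_g x_g X_g) p_bar`; negative `A` means
#' helpers disproportionately carry rare tags, the hitchhiking signature.
#'
#' @param freqs Genotype frequency vector.
#' @param locus `"resist"` or `"neutral"`.
#' @param space A `kintags_space`.
#' @return List with the per-tag vector `D` and the scalar association `A`.
#' @export
tag_trait_ld <- function(freqs, locus = c("resist", "neutral"), space) {
  locus <- match.arg(locus)
  stopifnot(inherits(space, "kintags_space"))
  simplex_check(freqs, tol = 1e-9, what = "genotype frequencies")
  tag_of <- space[[locus]]
  L <- if (locus == "resist") space$L_resist else space$L_neutral
  h <- as.numeric(space$trait == TRAIT_HELP)
  x_tag <- rowsum_vec(freqs, tag_of, L)
  p_bar <- sum(freqs * h)
  joint <- rowsum_vec(freqs * h, tag_of, L)
  D <- joint - x_tag * p_bar
  X_own <- x_tag[tag_of]
  A <- sum(freqs * X_own * h) - sum(freqs * X_own) * p_bar
  list(D = D, A = A)
}

#' Snapshot of all tracked observables
#'
#' Pure function assembling the per-generation record: raw and scaled tag
#' diversity at both loci, helper and use-Resist frequencies, parasite
#' susceptibility, per-tag relatedness where defined, tag-trait LD, and
#' mean fitness.
#'
#' @param state A `kintags_state`.
#' @param history A `kintags_history`.
#' @param params A `kintags_params`.
#' @param space A `kintags_space`.
#' @return An object of class `kintags_record`: a list with scalar fields
#'   (`generation`, `div_resist_raw`, `div_resist_scaled`, `div_neutral_raw`,
#'   `div_neutral_scaled`, `p_bar`, `choice_freq`, `susceptibility`,
#'   `ld_assoc_resist`, `ld_assoc_neutral`, `mean_fitness`) and vector fields
#'   (`rtag_resist`, `rtag_neutral`, `D_resist`, `D_neutral`).
#' @export
snapshot <- function(state, history, params, space) {
  stopifnot(inherits(state, "kintags_state"))
  freqs <- state$freqs
  soc <- social_payoff_vector(freqs, params, space)
  pmult <- parasite_payoff_vector(freqs, history, params, space)
  w <- soc$payoff * pmult
  divR <- tag_diversity(soc$x_resist, params$L_max)
  divN <- tag_diversity(soc$x_neutral, params$L_max)
  ldR <- tag_trait_ld(freqs, "resist", space)
  ldN <- tag_trait_ld(freqs, "neutral", space)
  marg <- locus_marginals(freqs, space)
  p_bar <- soc$p_bar

  rt <- function(x_tag, p_tag) {
    ifelse(x_tag > 0 & p_bar < 1,
           relatedness_rtag(pmax(x_tag, .Machine$double.xmin),
                            ifelse(is.na(p_tag), 0, p_tag), p_bar,
                            params$theta),
           NA_real_)
  }

  structure(list(
    generation = state$generation,
    div_resist_raw = divR$raw, div_resist_scaled = divR$scaled,
    div_neutral_raw = divN$raw, div_neutral_scaled = divN$scaled,
    p_bar = p_bar,
    choice_freq = marg$choice[CHOICE_USE_RESIST],
    susceptibility = susceptibility(soc$x_resist, history, params$lag),
    ld_assoc_resist = ldR$A, ld_assoc_neutral = ldN$A,
    mean_fitness = sum(freqs * w),
    rtag_resist = rt(soc$x_resist, soc$p_resist),
    rtag_neutral = rt(soc$x_neutral, soc$p_neutral),
    D_resist = ldR$D, D_neutral = ldN$D
  ), class = "kintags_record")
}

# Names of the scalar columns recorded each generation by the runner, in the
# order they appear in trajectory tables.
OBS_COLS <- c("generation", "div_resist_raw", "div_resist_scaled",
              "div_neutral_raw", "div_neutral_scaled", "p_bar", "choice_freq",
              "susceptibility", "ld_assoc_resist", "ld_assoc_neutral",
              "mean_fitness")

#' @export
print.kintags_record <- function(x, ...) {
  cat(sprintf(paste0("Generation %d: scaled diversity R %.3f / N %.3f, ",
                     "p_bar %.3f, use-Resist %.3f, susceptibility %.3f\n"),
              x$generation, x$div_resist_scaled, x$div_neutral_scaled,
              x$p_bar, x$choice_freq, x$susceptibility))
  invisible(x)
}
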