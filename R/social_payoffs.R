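# Social encounters, interaction probabilities, per-genotype expected social
# payoffs, and the relatedness of tag-matched partners.

#' Generational probability of finding a tag-matched partner
#'
#' An individual whose tag (at its chosen recognition locus) has population
#' frequency `X` encounters a clone with probability `theta`, otherwise a
#' random nonrelative.  On a tag mismatch the pair dissolves with probability
#' `alpha` and the search restarts.  The generational probability of ending
#' up in a tag-matched interaction is
#' \deqn{P = \frac{\theta + (1-\theta)X}{1 - \alpha (1-X)(1-\theta)}.}
#' At `alpha = 0` this is `theta + (1 - theta) X`; at `alpha = 1` it is 1
#' whenever a match is possible at all (`X > 0` or `theta > 0`).
#'
#' @param X Tag population frequency (vectorized, in `[0, 1]`).
#' @param theta Population viscosity.
#' @param alpha Encounter (reassociation) parameter.
#' @return Match probability, same length as `X`.
#' @examples
#' p_interact(0.5, theta = 0.25, alpha = 0)   # 0.625
#' p_interact(0.05, theta = 0.25, alpha = 1)  # 1
#' @export
p_interact <- function(X, theta, alpha) {
  if (any(X < 0 | X > 1) || theta < 0 || theta > 1 || alpha < 0 || alpha > 1)
    stop("'X', 'theta' and 'alpha' must lie in [0, 1]", call. = FALSE)
  num <- theta + (1 - theta) * X
  if (alpha == 0) return(num)
  # den = 1 - alpha (1-X)(1-theta), written so that den == num exactly when
  # alpha = 1 (the match probability is then exactly 1 whenever num > 0)
  den <- num + (1 - alpha) * (1 - X) * (1 - theta)
  ifelse(den > 0, num / den, 0)  # den = 0 only when no match is ever possible
}

#' Relatedness between an actor and its tag-matched social partner
#'
#' Relatedness here is genetic similarity at the Trait locus, standardized
#' against the population mean:
#' \deqn{R_{tag} = \frac{\frac{\theta + (1-\theta) X p}{\theta + (1-\theta) X} - \bar p}{1 - \bar p}}
#' where `X` is the actor's tag frequency, `p` the helper fraction among
#' carriers of that tag and `p_bar` the population helper fraction.  With
#' `p = p_bar` it decreases from 1 (as `X -> 0`: a matched partner is
#' certainly a clone) to `theta` at `X = 1` (tag at fixation: matching is
#' uninformative, leaving only viscosity).
#'
#' @param X Tag frequency in `(0, 1]` (vectorized).
#' @param p Helper fraction among carriers of the tag.
#' @param p_bar Population helper fraction (must be < 1).
#' @param theta Population viscosity.
#' @return Relatedness value(s).
#' @examples
#' relatedness_rtag(1, 0.5, 0.5, 0.25)    # 0.25 = theta
#' relatedness_rtag(0.5, 0.5, 0.5, 0.25)  # 0.4
#' @export
relatedness_rtag <- function(X, p, p_bar, theta) {
  if (any(X <= 0 | X > 1))
    stop("'X' must lie in (0, 1]", call. = FALSE)
  if (any(p < 0 | p > 1) || any(p_bar < 0 | p_bar > 1) || theta < 0 || theta > 1)
    stop("'p', 'p_bar' and 'theta' must lie in [0, 1]", call. = FALSE)
  if (any(p_bar >= 1))
    stop("'p_bar' must be < 1: relatedness is undefined when everyone helps",
         call. = FALSE)
  cond <- (theta + (1 - theta) * X * p) / (theta + (1 - theta) * X)
  (cond - p_bar) / (1 - p_bar)
}

#' Hamilton's rule for tag-based helping
#'
#' @param R Relatedness between actor and tag-matched partner.
#' @param b Benefit of helping.
#' @param c_cost Cost of helping.
#' @return `TRUE` iff `R * b > c_cost` (strict).
#' @examples
#' hamilton_check(0.4, 0.3, 0.1)   # TRUE
#' hamilton_check(0.25, 0.3, 0.1)  # FALSE
#' @export
hamilton_check <- function(R, b, c_cost) {
  if (b < 0 || c_cost < 0) stop("'b' and 'c_cost' must be >= 0", call. = FALSE)
  R * b > c_cost
}

#' Per-genotype expected social payoffs
#'
#' For each genotype `g`, the focal inspects its own tag at its chosen
#' recognition locus (frequency `X_g`) and interacts with probability
#' `P_g = p_interact(X_g, theta, alpha)`.  A helper that interacts pays cost
#' `c`; help is allocated donor-centrically: each donor's benefit `b` lands
#' on its realized matched partner, which is a clone (the donor's own
#' genotype) with conditional probability `theta / (theta + (1-theta) X)` and
#' otherwise a uniform draw among carriers of the donor's chosen tag.  This
#' bookkeeping conserves the help budget exactly: the population-mean benefit
#' received equals `b/c` times the population-mean cost paid.
#'
#' @param freqs Genotype frequency vector on the simplex.
#' @param params A `kintags_params`.
#' @param space A `kintags_space`.
#' @param per_tag If `FALSE`, skip the per-tag helper fractions (an
#'   optimization for the inner iteration loop, which does not need them).
#' @return A list of class `kintags_social` with per-genotype vectors
#'   `payoff` (`1 - c h P + b B`), `P` (interaction probability), `B`
#'   (expected benefit received, units of `b`), `C` (expected cost paid,
#'   units of `c_cost`), plus `p_bar` and the per-locus helper fractions
#'   `p_resist`, `p_neutral` and tag frequencies `x_resist`, `x_neutral`.
#' @export
social_payoff_vector <- function(freqs, params, space, per_tag = TRUE) {
  stopifnot(inherits(params, "kintags_params"), inherits(space, "kintags_space"))
  simplex_check(freqs, tol = 1e-9, what = "social payoff input")
  theta <- params$theta; alpha <- params$alpha
  xR <- grouped_sum(freqs, space$gs_resist)
  xN <- grouped_sum(freqs, space$gs_neutral)
  h <- space$trait == TRAIT_HELP
  p_bar <- sum(freqs[h])

  X <- c(xR, xN)[space$own_tag]
  num <- theta + (1 - theta) * X
  if (alpha == 0) P <- num else {
    den <- num + (1 - alpha) * (1 - X) * (1 - theta)
    P <- num / den
    if (any(den <= 0)) P[den <= 0] <- 0  # only at alpha=1, theta=0, X=0
  }

  # Conditional clone share among matched partners.
  inv_denom <- 1 / num
  if (any(num <= 0)) inv_denom[num <= 0] <- 0  # theta=0 and absent tag
  s <- theta * inv_denom

  # Clone-directed help returns to the donor's own genotype; the rest is
  # sprayed on nonrelative tag-sharers: donors grouped by chosen tag, every
  # carrier of that tag receiving density (1-theta)/num per unit donor help.
  hP <- P * h
  B <- hP * s
  w_donor <- freqs * hP * ((1 - theta) * inv_denom)
  Tgrp <- grouped_sum(w_donor, space$gs_own_tag)
  B <- B + Tgrp[space$resist] + Tgrp[space$L_resist + space$neutral]

  payoff <- 1 - params$c_cost * hP + params$b * B
  if (any(payoff < 0))
    stop("negative social payoff: parameters outside the model's fecundity assumptions",
         call. = FALSE)

  # Per-tag helper fractions (helpers among carriers of each tag).
  p_resist <- p_neutral <- NULL
  if (per_tag) {
    fh <- freqs * h
    hR <- grouped_sum(fh, space$gs_resist)
    hN <- grouped_sum(fh, space$gs_neutral)
    p_resist <- ifelse(xR > 0, hR / xR, NA_real_)
    p_neutral <- ifelse(xN > 0, hN / xN, NA_real_)
  }

  structure(list(payoff = payoff, P = P, B = B, C = hP, X = X,
                 p_bar = p_bar, p_resist = p_resist, p_neutral = p_neutral,
                 x_resist = xR, x_neutral = xN),
            class = "kintags_social")
}
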