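# Genotype space, model parameters, population state, and the mechanical
# lifecycle steps (free recombination, mutation) that are independent of
# social and parasite payoffs.

# Allele codes at the two biallelic loci.  Choice selects the locus an
# individual inspects before helping; Trait encodes conditional helping.
CHOICE_USE_RESIST <- 1L
CHOICE_USE_NEUTRAL <- 2L
TRAIT_HELP <- 1L
TRAIT_DEFECT <- 2L

#' Model parameters for the four-locus kin-recognition model
#'
#' Bundles and validates every lifecycle parameter plus run controls.
#' Defaults are the heatmap-figure settings used throughout: viscosity
#' `theta = 0.25`, helping benefit `b = 0.3`, helping cost `c = 0.1`,
#' genetic constraint `L_max = 10` tags per candidate recognition locus,
#' Trait and Choice mutation rates `1e-3`.
#'
#' @param theta Population viscosity: per-encounter probability that the
#'   social partner is a full clone (identical by descent at all loci).
#' @param b Fecundity benefit received by the target of helping.
#' @param c_cost Fecundity cost paid by a helper (named `c_cost` to avoid
#'   masking [base::c()]).
#' @param d Parasite virulence: fecundity loss when infected.
#' @param lag Parasite adaptation delay in host generations; `lag = 0`
#'   means parasites track current Resist frequencies perfectly.
#' @param alpha Encounter parameter: probability that a tag-mismatched pair
#'   dissolves and the focal individual searches again.
#' @param L_resist,L_neutral Number of tags segregating at the Resist and
#'   Neutral loci (each between 1 and `L_max`).
#' @param L_max Genetic constraint: maximum number of tags that may
#'   simultaneously segregate at one candidate recognition locus; also the
#'   normalizer of scaled tag diversity.
#' @param mu_trait,mu_choice Symmetric per-generation mutation rates at the
#'   Trait and Choice loci.  Tag loci do not mutate.
#' @param max_generations Iteration cap for [run_to_equilibrium()].
#' @param fixed_point_tol L-infinity genotype-frequency change below which a
#'   state is declared a fixed point.
#' @param cycle_window Window length (generations) used both for limit-cycle
#'   detection and for the window-averaged equilibrium summaries.
#' @param seed Integer seed used only for seeded initial-state perturbations.
#' @return An object of class `kintags_params` (a validated list).
#' @examples
#' p <- model_params(lag = 2, d = 0.5)
#' p$theta
#' @export
model_params <- function(theta = 0.25, b = 0.3, c_cost = 0.1, d = 0.5,
                         lag = 0L, alpha = 0, L_resist = 10L, L_neutral = 10L,
                         L_max = 10L, mu_trait = 0.001, mu_choice = 0.001,
                         max_generations = 200000L, fixed_point_tol = 1e-10,
                         cycle_window = 1000L, seed = 1L) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm),
           call. = FALSE)
  }
  chk_prob(theta, "theta"); chk_prob(alpha, "alpha"); chk_prob(d, "d")
  chk_prob(mu_trait, "mu_trait"); chk_prob(mu_choice, "mu_choice")
  if (!is.numeric(b) || b < 0 || !is.numeric(c_cost) || c_cost < 0)
    stop("'b' and 'c_cost' must be nonnegative", call. = FALSE)
  if (length(lag) != 1L || !is.finite(lag) || lag < 0 || lag != round(lag))
    stop("'lag' must be a nonnegative integer", call. = FALSE)
  chk_locus <- function(L, nm) {
    if (length(L) != 1L || !is.finite(L) || L < 1 || L != round(L))
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
  }
  chk_locus(L_resist, "L_resist"); chk_locus(L_neutral, "L_neutral")
  chk_locus(L_max, "L_max")
  if (L_resist > L_max || L_neutral > L_max)
    stop("locus sizes may not exceed the genetic constraint 'L_max'",
         call. = FALSE)
  if (fixed_point_tol <= 0) stop("'fixed_point_tol' must be > 0", call. = FALSE)
  structure(list(
    theta = theta, b = b, c_cost = c_cost, d = d, lag = as.integer(lag),
    alpha = alpha, L_resist = as.integer(L_resist),
    L_neutral = as.integer(L_neutral), L_max = as.integer(L_max),
    mu_trait = mu_trait, mu_choice = mu_choice,
    max_generations = as.integer(max_generations),
    fixed_point_tol = fixed_point_tol,
    cycle_window = as.integer(cycle_window), seed = as.integer(seed)
  ), class = "kintags_params")
}

#' @export
print.kintags_params <- function(x, ...) {
  cat("Four-locus kin-recognition model parameters\n")
  cat(sprintf("  viscosity theta = %g, encounter alpha = %g\n", x$theta, x$alpha))
  cat(sprintf("  helping b = %g, c = %g; parasite d = %g, lag = %d\n",
              x$b, x$c_cost, x$d, x$lag))
  cat(sprintf("  tags: Resist %d, Neutral %d (L_max %d); mu_trait = %g, mu_choice = %g\n",
              x$L_resist, x$L_neutral, x$L_max, x$mu_trait, x$mu_choice))
  invisible(x)
}

#' Build the four-locus genotype space
#'
#' Enumerates all haploid genotypes Resist x Neutral x Choice x Trait and
#' precomputes the index maps used by the recursion: per-genotype allele
#' indices, the Trait/Choice flip permutations for mutation, and the sixteen
#' inheritance-mask groupings that make free recombination O(16 G).
#'
#' Genotypes are ordered with Resist varying fastest, i.e. linear index
#' `k = resist + L_resist ((neutral - 1) + L_neutral ((choice - 1) + 2 (trait - 1)))`.
#'
#' @param L_resist Number of Resist tags (>= 1).
#' @param L_neutral Number of Neutral tags (>= 1).
#' @return An object of class `kintags_space` with fields `G`, `L_resist`,
#'   `L_neutral`, integer vectors `resist`, `neutral`, `choice`, `trait`
#'   (allele index of each genotype), flip permutations and mask tables.
#' @examples
#' sp <- build_space(10, 10)
#' sp$G  # 400
#' @export
build_space <- function(L_resist, L_neutral) {
  if (length(L_resist) != 1L || length(L_neutral) != 1L ||
      !is.finite(L_resist) || !is.finite(L_neutral) ||
      L_resist < 1 || L_neutral < 1 ||
      L_resist != round(L_resist) || L_neutral != round(L_neutral))
    stop("locus sizes must be positive integers", call. = FALSE)
  L_resist <- as.integer(L_resist); L_neutral <- as.integer(L_neutral)
  G <- L_resist * L_neutral * 4L
  k <- seq_len(G) - 1L
  resist <- k %% L_resist + 1L
  k <- k %/% L_resist
  neutral <- k %% L_neutral + 1L
  k <- k %/% L_neutral
  choice <- k %% 2L + 1L
  trait <- k %/% 2L + 1L

  alleles <- list(resist = resist, neutral = neutral,
                  choice = choice, trait = trait)
  sizes <- c(resist = L_resist, neutral = L_neutral, choice = 2L, trait = 2L)

  enc <- function(r, n, ch, tr) {
    (r - 1L) + L_resist * ((n - 1L) + L_neutral * ((ch - 1L) + 2L * (tr - 1L))) + 1L
  }

  # Flip permutations for symmetric biallelic mutation.
  perm_trait <- enc(resist, neutral, choice, 3L - trait)
  perm_choice <- enc(resist, neutral, 3L - choice, trait)

  # Precomputed grouped-sum plans (order + cumulative-sum boundaries): the
  # recursion aggregates over these groupings tens of thousands of times.
  make_gs <- function(group, n) {
    counts <- tabulate(group, n)
    stopifnot(all(counts > 0L))
    list(ord = order(group), ends = cumsum(counts), n = n)
  }

  # Inheritance masks: offspring takes loci with mask bit 1 from parent A and
  # the rest from parent B, each of the 16 masks with probability 1/16.  For
  # each mask we store the joint-marginal group index of every genotype over
  # the two complementary locus subsets.
  loci <- names(sizes)
  masks <- vector("list", 16L)
  for (m in 0:15) {
    inA <- as.logical(bitwAnd(m, c(1L, 2L, 4L, 8L)))
    grp <- function(sel) {
      id <- rep.int(1L, G); stride <- 1L
      for (l in loci[sel]) {
        id <- id + (alleles[[l]] - 1L) * stride
        stride <- stride * sizes[[l]]
      }
      list(id = id, n = as.integer(stride))
    }
    a <- grp(inA); b <- grp(!inA)
    masks[[m + 1L]] <- list(idA = a$id, nA = a$n, idB = b$id, nB = b$n,
                            gsA = make_gs(a$id, a$n), gsB = make_gs(b$id, b$n))
  }

  # An individual's own tag, indexed into the concatenated (Resist, Neutral)
  # tag list according to its Choice allele.
  own_tag <- ifelse(choice == CHOICE_USE_RESIST, resist, L_resist + neutral)

  structure(list(G = G, L_resist = L_resist, L_neutral = L_neutral,
                 resist = resist, neutral = neutral, choice = choice,
                 trait = trait, perm_trait = perm_trait,
                 perm_choice = perm_choice, masks = masks,
                 own_tag = own_tag,
                 gs_resist = make_gs(resist, L_resist),
                 gs_neutral = make_gs(neutral, L_neutral),
                 gs_choice = make_gs(choice, 2L),
                 gs_trait = make_gs(trait, 2L),
                 gs_own_tag = make_gs(own_tag, L_resist + L_neutral),
                 encode_fun = enc),
            class = "kintags_space")
}

#' @export
print.kintags_space <- function(x, ...) {
  cat(sprintf("Genotype space: %d x %d x 2 x 2 = %d genotypes\n",
              x$L_resist, x$L_neutral, x$G))
  invisible(x)
}

#' Encode a genotype 4-tuple as a linear index
#'
#' @param space A `kintags_space`.
#' @param resist,neutral,choice,trait 1-based allele indices (vectorized).
#' @return Integer linear indices in `1..G`.
#' @seealso [decode_genotype()]
#' @export
encode_genotype <- function(space, resist, neutral, choice, trait) {
  stopifnot(inherits(space, "kintags_space"))
  if (any(resist < 1L | resist > space$L_resist) ||
      any(neutral < 1L | neutral > space$L_neutral) ||
      any(!choice %in% c(1L, 2L)) || any(!trait %in% c(1L, 2L)))
    stop("allele index out of range", call. = FALSE)
  space$encode_fun(as.integer(resist), as.integer(neutral),
                   as.integer(choice), as.integer(trait))
}

#' Decode linear genotype indices into allele 4-tuples
#'
#' @param space A `kintags_space`.
#' @param k Integer indices in `1..G` (vectorized).
#' @return A data.frame with columns `resist`, `neutral`, `choice`, `trait`.
#' @export
decode_genotype <- function(space, k) {
  stopifnot(inherits(space, "kintags_space"))
  k <- as.integer(k)
  if (any(k < 1L | k > space$G)) stop("genotype index out of range", call. = FALSE)
  data.frame(resist = space$resist[k], neutral = space$neutral[k],
             choice = space$choice[k], trait = space$trait[k])
}

# Evaluate a function with a temporary RNG state so seeded helpers do not
# disturb the caller's random stream.
with_preserved_rng <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

simplex_check <- function(freqs, tol = 1e-9, what = "frequency vector") {
  if (any(!is.finite(freqs)))
    stop(sprintf("%s contains non-finite entries", what), call. = FALSE)
  if (any(freqs < -1e-15))
    stop(sprintf("%s has negative entries beyond round-off", what),
         call. = FALSE)
  if (abs(sum(freqs) - 1) > tol)
    stop(sprintf("%s does not sum to 1 (off by %.3g)", what,
                 sum(freqs) - 1), call. = FALSE)
  invisible(TRUE)
}

# Clip (-1e-15, 0) round-off to zero and renormalize; larger negatives are a
# logic error upstream and must not be silently absorbed.
simplex_clip <- function(freqs) {
  if (any(freqs < -1e-15))
    stop("negative frequency beyond round-off tolerance", call. = FALSE)
  freqs[freqs < 0] <- 0
  freqs / sum(freqs)
}

#' Population state on the genotype simplex
#'
#' @param freqs Numeric vector of `space$G` nonnegative frequencies summing
#'   to 1 (within 1e-12).
#' @param space A `kintags_space`.
#' @param generation Generation counter.
#' @return An object of class `kintags_state`.
#' @export
population_state <- function(freqs, space, generation = 0L) {
  stopifnot(inherits(space, "kintags_space"))
  if (length(freqs) != space$G)
    stop("'freqs' length does not match the genotype space", call. = FALSE)
  simplex_check(freqs, tol = 1e-12, what = "genotype frequency vector")
  structure(list(freqs = as.numeric(freqs), generation = as.integer(generation)),
            class = "kintags_state")
}

#' @export
print.kintags_state <- function(x, ...) {
  cat(sprintf("Population state, generation %d, %d genotypes (sum %.12f)\n",
              x$generation, length(x$freqs), sum(x$freqs)))
  invisible(x)
}

#' Single-locus allele frequencies of a genotype-frequency vector
#'
#' @param freqs Genotype frequency vector.
#' @param space A `kintags_space`.
#' @return List with numeric vectors `resist`, `neutral`, `choice`, `trait`.
#' @export
locus_marginals <- function(freqs, space) {
  list(resist = grouped_sum(freqs, space$gs_resist),
       neutral = grouped_sum(freqs, space$gs_neutral),
       choice = grouped_sum(freqs, space$gs_choice),
       trait = grouped_sum(freqs, space$gs_trait))
}

# Grouped sum over a precomputed plan (see make_gs in build_space): sort into
# group-contiguous order once at build time, then each aggregation is a
# cumulative sum plus boundary differences.  All groups are nonempty by
# construction.
grouped_sum <- function(x, gs) {
  s <- cumsum(x[gs$ord])
  res <- s[gs$ends]
  if (gs$n > 1L) res - c(0, res[-gs$n]) else res
}

# Fallback grouped sum for callers without a precomputed plan.
rowsum_vec <- function(x, group, n) {
  out <- rowsum(x, group, reorder = FALSE)
  v <- numeric(n)
  v[as.integer(rownames(out))] <- out[, 1L]
  v
}

#' Initialize a population state
#'
#' Builds the product measure over the four loci from the given marginal
#' specifications, then applies a seeded multiplicative perturbation of
#' relative magnitude at most `eps` and renormalizes.  The perfectly
#' symmetric product state is an (unstable) fixed point of the deterministic
#' recursion, so a small perturbation is needed for frequency-dependent
#' selection to express itself.
#'
#' @param space A `kintags_space`.
#' @param p0 Initial frequency of the conditional-helping Trait allele.
#' @param q0 Initial frequency of the use-Resist Choice allele.
#' @param resist_freqs,neutral_freqs Optional tag frequency vectors (default
#'   uniform over the locus's tags).
#' @param eps Perturbation magnitude (relative); must be below the smallest
#'   positive product frequency so no entry can be driven negative.
#' @param seed Integer seed; the same seed always yields the same state.
#' @return A `kintags_state` at generation 0.
#' @examples
#' sp <- build_space(10, 10)
#' st <- initialize_population(sp, seed = 1)
#' sum(st$freqs)
#' @export
initialize_population <- function(space, p0 = 0.5, q0 = 0.5,
                                  resist_freqs = NULL, neutral_freqs = NULL,
                                  eps = 1e-3, seed = 1L) {
  stopifnot(inherits(space, "kintags_space"))
  if (is.null(resist_freqs)) resist_freqs <- rep(1 / space$L_resist, space$L_resist)
  if (is.null(neutral_freqs)) neutral_freqs <- rep(1 / space$L_neutral, space$L_neutral)
  if (length(resist_freqs) != space$L_resist ||
      length(neutral_freqs) != space$L_neutral)
    stop("tag frequency vectors must match locus sizes", call. = FALSE)
  simplex_check(resist_freqs, what = "Resist tag frequencies")
  simplex_check(neutral_freqs, what = "Neutral tag frequencies")
  if (p0 < 0 || p0 > 1 || q0 < 0 || q0 > 1)
    stop("'p0' and 'q0' must be probabilities", call. = FALSE)
  choice_freqs <- c(q0, 1 - q0)
  trait_freqs <- c(p0, 1 - p0)
  freqs <- resist_freqs[space$resist] * neutral_freqs[space$neutral] *
    choice_freqs[space$choice] * trait_freqs[space$trait]
  pos <- freqs > 0
  if (eps < 0) stop("'eps' must be nonnegative", call. = FALSE)
  if (eps > 0) {
    if (eps >= min(freqs[pos]))
      stop("'eps' must be smaller than the smallest positive product frequency",
           call. = FALSE)
    u <- with_preserved_rng(seed, function() stats::runif(space$G, -1, 1))
    freqs[pos] <- freqs[pos] * (1 + eps * u[pos])
    freqs <- freqs / sum(freqs)
  }
  population_state(freqs, space, generation = 0L)
}

#' Free recombination between all four loci
#'
#' One round of random gamete fusion followed by meiosis with free
#' recombination (no physical linkage).  The offspring distribution is the
#' equal mixture over the sixteen inheritance masks of the product of the
#' two complementary joint marginals, which preserves every single-locus
#' allele frequency exactly and halves every pairwise linkage
#' disequilibrium coefficient.
#'
#' @param freqs Genotype frequency vector on the simplex.
#' @param space A `kintags_space`.
#' @return The post-recombination genotype frequency vector.
#' @examples
#' sp <- build_space(2, 2)
#' f <- rep(1 / 16, 16)           # linkage equilibrium: a fixed point
#' all.equal(recombine_free(f, sp), f)
#' @export
recombine_free <- function(freqs, space) {
  stopifnot(inherits(space, "kintags_space"))
  simplex_check(freqs, tol = 1e-9, what = "recombination input")
  # Mask m and its complement contribute identical product terms, so only
  # masks 1..7 need computing; the {empty, full} pair contributes the input
  # itself.
  out <- freqs * 2
  masks <- space$masks
  for (m in 2:8) {
    mk <- masks[[m]]
    mA <- grouped_sum(freqs, mk$gsA)
    mB <- grouped_sum(freqs, mk$gsB)
    out <- out + 2 * (mA[mk$idA] * mB[mk$idB])
  }
  out / 16
}

#' Symmetric mutation at the Trait and Choice loci
#'
#' Each allele at Trait flips with probability `mu_trait`, then each allele
#' at Choice flips with probability `mu_choice`.  Tag loci do not mutate, so
#' tag marginals are untouched; the helper marginal maps
#' `p -> p (1 - mu) + (1 - p) mu`.
#'
#' @param freqs Genotype frequency vector on the simplex.
#' @param mu_trait,mu_choice Flip probabilities in `[0, 1]`.
#' @param space A `kintags_space`.
#' @return The post-mutation genotype frequency vector.
#' @export
mutate <- function(freqs, mu_trait, mu_choice, space) {
  stopifnot(inherits(space, "kintags_space"))
  if (mu_trait < 0 || mu_trait > 1 || mu_choice < 0 || mu_choice > 1)
    stop("mutation rates must be probabilities in [0, 1]", call. = FALSE)
  simplex_check(freqs, tol = 1e-9, what = "mutation input")
  f <- freqs * (1 - mu_trait) + freqs[space$perm_trait] * mu_trait
  f * (1 - mu_choice) + f[space$perm_choice] * mu_choice
}
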