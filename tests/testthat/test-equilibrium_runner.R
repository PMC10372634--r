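test_that("one generation equals the composition of its tested stages", {
  sp <- build_space(3, 2)
  p <- model_params(L_resist = 3, L_neutral = 2, lag = 1, d = 0.4,
                    alpha = 0.3)
  f <- random_simplex(sp, 61)
  st <- population_state(f, sp)
  h <- resist_history(locus_marginals(f, sp)$resist, p$lag)
  out <- step_generation(st, h, p, sp)
  # manual composition: selection -> recombination -> mutation
  w <- social_payoff_vector(f, p, sp)$payoff *
    parasite_payoff_vector(f, h, p, sp)
  fsel <- f * w / sum(f * w)
  fman <- mutate(recombine_free(fsel, sp), p$mu_trait, p$mu_choice, sp)
  fman <- fman / sum(fman)
  expect_equal(out$state$freqs, fman, tolerance = 1e-14)
  expect_equal(out$state$generation, 1L)
  # history gained the post-step Resist census
  expect_equal(lagged_frequencies(out$history, 0),
               locus_marginals(fman, sp)$resist, tolerance = 1e-14)
})

test_that("neutral parameter settings leave states unchanged", {
  sp <- build_space(3, 2)
  p0 <- model_params(L_resist = 3, L_neutral = 2, b = 0, c_cost = 0, d = 0,
                     mu_trait = 0, mu_choice = 0)
  f <- random_product_state(sp, 62)
  st <- population_state(f, sp)
  h <- resist_history(locus_marginals(f, sp)$resist, p0$lag)
  out <- step_generation(st, h, p0, sp)
  expect_equal(out$state$freqs, f, tolerance = 1e-13)

  # monomorphic at every locus: unchanged for any parameters
  p1 <- model_params(L_resist = 3, L_neutral = 2, d = 0.7, lag = 2,
                     alpha = 0.5, mu_trait = 0, mu_choice = 0)
  fm <- numeric(sp$G); fm[encode_genotype(sp, 2, 1, 1, 1)] <- 1
  stm <- population_state(fm, sp)
  hm <- resist_history(locus_marginals(fm, sp)$resist, p1$lag)
  outm <- step_generation(stm, hm, p1, sp)
  expect_equal(outm$state$freqs, fm)
})

test_that("the Choice allele targeting the more diverse locus gains in one step", {
  # Resist uniform (scaled diversity 1), Neutral concentrated; helpers and
  # both Choice alleles segregating with no LD; Hamilton met at rare tags.
  sp <- build_space(10, 10)
  for (alpha in c(0, 0.5, 0.99)) {
    p <- model_params(alpha = alpha, d = 0, mu_choice = 0, mu_trait = 0)
    st <- initialize_population(sp, p0 = 0.5, q0 = 0.5,
                                neutral_freqs = c(0.82, rep(0.02, 9)),
                                eps = 0, seed = 1)
    h <- resist_history(rep(0.1, 10), p$lag)
    out <- step_generation(st, h, p, sp)
    q1 <- locus_marginals(out$state$freqs, sp)$choice[1]
    expect_gt(q1, 0.5)
  }
  # mirrored construction: Neutral diverse, Resist concentrated
  p <- model_params(alpha = 0.5, d = 0, mu_choice = 0, mu_trait = 0)
  st <- initialize_population(sp, p0 = 0.5, q0 = 0.5,
                              resist_freqs = c(0.82, rep(0.02, 9)),
                              eps = 0, seed = 1)
  h <- resist_history(c(0.82, rep(0.02, 9)), p$lag)
  out <- step_generation(st, h, p, sp)
  expect_lt(locus_marginals(out$state$freqs, sp)$choice[1], 0.5)
})

test_that("run_to_equilibrium converges, records and summarizes", {
  p <- model_params(L_resist = 2, L_neutral = 2, d = 0.5, lag = 0,
                    max_generations = 5000)
  tr <- run_to_equilibrium(p, list(seed = 1), keep_trajectory = TRUE)
  expect_s3_class(tr, "kintags_trajectory")
  expect_true(tr$status %in% c("fixed_point", "limit_cycle", "max_generations"))
  expect_equal(nrow(tr$observables), tr$generations)
  expect_true(all(tr$observables$div_resist_scaled >= 0 &
                  tr$observables$div_resist_scaled <= 1))
  # first trajectory row equals an independent snapshot of the initial state
  sp <- build_space(2, 2)
  st0 <- initialize_population(sp, seed = 1)
  h0 <- resist_history(locus_marginals(st0$freqs, sp)$resist, p$lag)
  rec <- snapshot(st0, h0, p, sp)
  row1 <- tr$observables[1, ]
  for (fld in c("div_resist_raw", "div_neutral_raw", "p_bar", "choice_freq",
                "susceptibility", "ld_assoc_resist", "ld_assoc_neutral"))
    expect_equal(row1[[fld]], rec[[fld]], tolerance = 1e-12,
                 label = fld)
  # fixed point status implies a genuinely stationary state
  if (tr$status == "fixed_point") {
    nxt <- step_generation(tr$final_state, tr$final_history, p, sp)
    expect_lt(max(abs(nxt$state$freqs - tr$final_state$freqs)), 1e-9)
  }
})

test_that("Red Queen cells sustain Resist cycling while summaries converge", {
  p <- model_params(lag = 20, d = 0.9, alpha = 0, max_generations = 15000)
  tr <- run_to_equilibrium(p, list(q0 = 1, seed = 1), keep_trajectory = TRUE)
  o <- tr$observables
  n <- nrow(o)
  expect_false(tr$status == "fixed_point")
  # sustained oscillation: window variance bounded away from zero
  expect_gt(var(o$div_resist_raw[(n - 999):n]), 1e-4)
})

test_that("sweep_grid has the contracted shape and is deterministic", {
  p <- model_params(L_resist = 2, L_neutral = 2, max_generations = 2000)
  g1 <- data.frame(lag = 1L, d = 0.4)
  sw1 <- sweep_grid(p, g1, scenario = "choice_fixed_resist")
  p1 <- p; p1$lag <- 1L; p1$d <- 0.4; p1$mu_choice <- 0
  tr1 <- run_to_equilibrium(do.call(model_params, unclass(p1)),
                            list(q0 = 1, seed = 1))
  expect_equal(sw1$div_resist_scaled, tr1$equilibrium[["div_resist_scaled"]])
  expect_equal(sw1$susceptibility, tr1$equilibrium[["susceptibility"]])

  grid <- expand.grid(lag = c(0L, 1L, 2L), d = c(0.2, 0.5, 0.8))
  swa <- sweep_grid(p, grid, scenario = "choice_fixed_resist")
  expect_equal(nrow(swa), 9L)
  expect_true(all(c("div_resist_scaled", "div_neutral_scaled", "p_bar",
                    "choice_freq", "susceptibility",
                    "susceptibility_baseline", "ld_assoc_resist",
                    "ld_assoc_neutral", "status", "generations")
                  %in% names(swa)))
  swb <- sweep_grid(p, grid, scenario = "choice_fixed_resist")
  expect_identical(swa, swb)
  # per-cell errors are recorded, not fatal
  gbad <- data.frame(lag = c(1L, 1L), d = c(0.4, 2)) # d = 2 invalid
  swbad <- sweep_grid(p, gbad, scenario = "choice_fixed_resist")
  expect_match(swbad$status[2], "error")
  expect_false(is.na(swbad$div_resist_scaled[1]))
})

test_that("analytic presets emit their closed-form curves", {
  f4 <- preset("fig4b")
  expect_equal(f4$rtag[f4$X == 1], 0.25)
  expect_equal(f4$rtag_random[1], 0.25)
  expect_true(all(diff(f4$rtag) < 0))
  f1 <- preset("fig1b")
  expect_equal(f1$p_match[f1$X == 1], 1)
  expect_equal(f1$p_match, 0.25 + 0.75 * f1$X)
  expect_error(preset("fig9"), "fig1b")
})
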