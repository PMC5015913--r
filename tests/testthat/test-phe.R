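test_that("ladder brackets map to the benefit-equivalence intervals", {
  phe <- data.frame(state_id = c("S001", "S002", "S003"),
                    bracket_lo = c(2000, -Inf, 10000),
                    bracket_hi = c(3000, 1500, Inf))
  iv <- phe_record_to_interval(phe)
  expect_equal(iv$lo, c(1000 / 3000, 2 / 3, 0.001))
  expect_equal(iv$hi, c(1000 / 2000, 1, 0.1))
  expect_true(all(iv$lo > 0 & iv$lo <= iv$hi & iv$hi <= 1))
})

test_that("interval conversion inverts the noiseless ladder walk", {
  # whenever 1000/w is inside the ladder's reach, the emitted interval
  # contains w; outside, the documented open-ended intervals apply
  for (w in seq(0.01, 1, by = 0.004)) {
    rec <- phe_ladder(w, 3000)
    iv <- phe_record_to_interval(data.frame(state_id = "s",
                                            bracket_lo = rec$final_bracket[1],
                                            bracket_hi = rec$final_bracket[2]))
    if (w > 0.1 && w <= 2 / 3) {
      expect_true(iv$lo <= w && w <= iv$hi + 1e-12)
    } else if (w <= 0.1) {
      expect_equal(c(iv$lo, iv$hi), c(0.001, 0.1))
    } else {
      expect_equal(c(iv$lo, iv$hi), c(2 / 3, 1))
    }
  }
})

test_that("malformed ladder traces are rejected", {
  bad <- data.frame(state_id = "S001",
                    trace = "2000:A;5000:B",    # skips a rung
                    bracket_lo = 2000, bracket_hi = 5000)
  expect_error(phe_record_to_interval(bad), "malformed")
  bad2 <- data.frame(state_id = "S001",
                     trace = "2000:A;3000:B",
                     bracket_lo = 3000, bracket_hi = 5000)  # wrong bracket
  expect_error(phe_record_to_interval(bad2), "malformed")
  ok <- data.frame(state_id = "S001", trace = "2000:A;3000:B",
                   bracket_lo = 2000, bracket_hi = 3000)
  expect_silent(phe_record_to_interval(ok))
})

test_that("interval regression matches a 2-parameter likelihood grid", {
  set.seed(41)
  reg <- manual_registry(0.4)
  cfg <- sim_config(300, sigma_phe = 0.15, k_phe = 1, seed = 41)
  phe <- simulate_phe_responses(reg, config = cfg)
  phe <- phe[phe$state_id == "S001", ]
  iv <- phe_record_to_interval(phe)
  est <- fit_phe_intervals(iv)
  oracle <- interval_grid_oracle(iv$lo, iv$hi,
                                 mu_range = c(-3, 0), sigma_range = c(0.05, 2))
  expect_equal(est$phe_dw, exp(oracle$mu), tolerance = 0.02)
  # the fitted estimate is within the bracket-consistent optimum's vicinity
  expect_lt(abs(est$phe_dw - 0.4), 0.05 + 0.1)
})

test_that("degenerate interval sets give flat-likelihood estimates inside", {
  obs <- data.frame(state_id = "S001", lo = rep(0.2, 15), hi = rep(0.4, 15))
  est <- fit_phe_intervals(obs)
  expect_true(est$phe_dw >= 0.2 && est$phe_dw <= 0.4)
  expect_equal(est$flag, "flat_likelihood")
  # the flat-likelihood plateau: our estimate attains the grid maximum
  oracle <- interval_grid_oracle(obs$lo, obs$hi,
                                 mu_range = c(log(0.1), log(0.6)),
                                 sigma_range = c(0.01, 1))
  ll_ours <- sum(log(pnorm((log(0.4) - log(est$phe_dw)) / 0.01) -
                     pnorm((log(0.2) - log(est$phe_dw)) / 0.01)))
  expect_gte(ll_ours, oracle$loglik - 1e-6)
  # all-point intervals: zero-width flag
  pt <- data.frame(state_id = "S002", lo = rep(0.3, 5), hi = rep(0.3, 5))
  ept <- fit_phe_intervals(pt)
  expect_equal(ept$phe_dw, 0.3)
  expect_equal(ept$flag, "zero_width")
})

test_that("interval regression preserves order and ignores duplication", {
  set.seed(43)
  obs <- data.frame(
    state_id = rep(c("low", "high"), each = 40),
    lo = c(runif(40, 0.08, 0.15), runif(40, 0.45, 0.55)),
    hi = c(runif(40, 0.2, 0.3), runif(40, 0.65, 0.8)))
  est <- fit_phe_intervals(obs)
  expect_lt(est$phe_dw[est$state_id == "low"],
            est$phe_dw[est$state_id == "high"])
  dup <- fit_phe_intervals(rbind(obs, obs))
  expect_equal(dup$phe_dw, est$phe_dw, tolerance = 1e-5)
})

test_that("linkage regression reproduces an exact linear relation", {
  p <- data.frame(state_id = paste0("S", 1:6),
                  p = c(0.2, 0.35, 0.5, 0.6, 0.75, 0.9),
                  ci_lo = NA, ci_hi = NA)
  phe_dws <- data.frame(state_id = paste0("S", 1:6),
                        phe_dw = 0.2 + 0.3 * p$p)
  # an exactly linear relation: lm warns about the perfect fit, expectedly
  lk <- suppressWarnings(link_hybrid(p, phe_dws))
  expect_equal(lk$linkage$r_squared, 1)
  expect_equal(lk$linkage$intercept, 0.2, tolerance = 1e-10)
  expect_equal(lk$linkage$slope, 0.3, tolerance = 1e-10)
  expect_equal(lk$estimates$dw, phe_dws$phe_dw, tolerance = 1e-10)
  expect_true(all(lk$estimates$model_tag == "model2"))
  # slope sign matches the correlation sign of the inputs
  phe_neg <- data.frame(state_id = p$state_id, phe_dw = 1 - 0.6 * p$p)
  expect_lt(suppressWarnings(link_hybrid(p, phe_neg))$linkage$slope, 0)
  # degenerate regressor
  p_flat <- p; p_flat$p <- 0.5
  expect_error(link_hybrid(p_flat, phe_dws), "rank deficient")
  expect_error(link_hybrid(p[1, ], phe_dws[1, ]), "at least 2")
})

test_that("hybrid model predicts every state, including those without ladders", {
  reg <- make_state_registry(12, seed = 51)
  cfg <- sim_config(150, k_phe = 1, seed = 51)
  sv <- simulate_survey(reg, config = cfg)
  fit <- fit_pc_probit(sv$pc, reg)
  # drop ladder data for two states entirely
  phe <- sv$phe[!(sv$phe$state_id %in% c("S001", "S002")), ]
  m2 <- dw_model2(phe, fit)
  expect_setequal(m2$estimates$state_id, names(fit$beta))
  expect_true(all(is.finite(m2$estimates$dw)))
  expect_true(all(m2$estimates$ci_lo <= m2$estimates$dw &
                    m2$estimates$dw <= m2$estimates$ci_hi))
})
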