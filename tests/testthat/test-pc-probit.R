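test_that("design rows carry the signed coding with the reference dropped", {
  reg <- tiny_registry(2)
  pc <- data.frame(respondent_id = 1:3,
                   state_a = c("S001", "DEAD", "S002"),
                   state_b = c("DEAD", "S001", "S001"),
                   chose_a_healthier = c(TRUE, FALSE, TRUE))
  des <- build_pc_design(pc, reg)
  expect_setequal(colnames(des$X), c("S001", "S002"))
  # A vs dead: +1 at A only, reference column absent
  expect_equal(unname(des$X[1, "S001"]), 1)
  expect_equal(unname(des$X[1, "S002"]), 0)
  expect_equal(unname(des$X[2, "S001"]), -1)
  expect_equal(des$X[3, c("S001", "S002")], c(S001 = -1, S002 = 1))
  expect_equal(des$y, c(1L, 0L, 1L))
  # FH never appears: unidentifiable, reported, no weight emitted
  expect_equal(des$unidentified, "FH")
})

test_that("swapping a pair and negating the outcome leaves the likelihood unchanged", {
  reg <- tiny_registry(4)
  cfg <- sim_config(60, seed = 21)
  pc <- simulate_pc_responses(reg, config = cfg)
  swapped <- data.frame(respondent_id = pc$respondent_id,
                        state_a = pc$state_b, state_b = pc$state_a,
                        chose_a_healthier = !pc$chose_a_healthier)
  f1 <- fit_pc_probit(pc, reg)
  f2 <- fit_pc_probit(swapped, reg)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$beta, f2$beta[names(f1$beta)], tolerance = 1e-6)
})

test_that("single-pair probit MLE equals the probit of the empirical frequency", {
  reg <- tiny_registry(1)
  pc <- data.frame(respondent_id = seq_len(100),
                   state_a = "S001", state_b = "DEAD",
                   chose_a_healthier = rep(c(TRUE, FALSE), c(84, 16)))
  fit <- fit_pc_probit(pc, reg)
  expect_equal(unname(fit$beta["S001"]), qnorm(0.84), tolerance = 1e-6)
  # predicted probability transforms straight back
  p <- predicted_probabilities(fit)
  expect_equal(p$p[p$state_id == "S001"], 0.84, tolerance = 1e-6)
  expect_equal(p$p[p$state_id == "DEAD"], 0.5)
})

test_that("MLE agrees with an exhaustive likelihood grid search", {
  reg <- manual_registry(c(0.25, 0.55, 0.8))
  reg$states <- reg$states[reg$states$state_id != "FH", ]
  reg$states$anchor[1] <- "full_health"   # keep a valid registry shape
  cfg <- sim_config(20, k_pairs = 10, sigma_pc = 0.4, seed = 31)
  pc <- simulate_pc_responses(reg,
    truth = reg$truth[reg$states$state_id], config = cfg)
  fit <- fit_pc_probit(pc, reg)
  des <- build_pc_design(pc, reg)
  beta_grid <- probit_grid_oracle(des$X[, fit$estimated_ids], des$y)
  expect_equal(unname(fit$beta[fit$estimated_ids]), beta_grid,
               tolerance = 2e-3)
})

test_that("null data recover coefficients near zero", {
  reg <- manual_registry(rep(0.5, 4))
  reg$truth[] <- 0.5    # anchors too: every pair is a coin flip
  cfg <- sim_config(150, k_pairs = 10, sigma_pc = 0.5, seed = 8)
  pc <- simulate_pc_responses(reg, config = cfg)
  fit <- fit_pc_probit(pc, reg)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta[fit$estimated_ids]) < 3 * se))
})

test_that("perfect separation is a named hard error; ridge and drop recover", {
  reg <- tiny_registry(2)
  pc <- data.frame(
    respondent_id = 1:23,
    state_a = c(rep("S001", 13), rep("S002", 10)),
    state_b = c(rep("DEAD", 13), rep("S001", 10)),
    chose_a_healthier = c(rep(TRUE, 10), rep(FALSE, 3), rep(FALSE, 10)))
  # S002 loses every comparison it appears in; S001 has mixed outcomes
  expect_error(fit_pc_probit(pc, reg), "S002")
  fdrop <- fit_pc_probit(pc, reg, separation = "drop")
  expect_true("S002" %in% fdrop$dropped)
  fridge <- fit_pc_probit(pc, reg, ridge = 0.5)
  expect_true(all(is.finite(fridge$beta)))
})

test_that("probabilities and anchoring behave as exact transforms", {
  reg <- tiny_registry(3)
  cfg <- sim_config(200, seed = 13)
  pc <- simulate_pc_responses(reg, config = cfg)
  fit <- fit_pc_probit(pc, reg)
  p <- predicted_probabilities(fit)
  expect_equal(p$p, pnorm(unname(fit$beta[p$state_id])))
  expect_true(all(p$ci_lo <= p$p & p$p <= p$ci_hi))
  expect_equal(p$p[p$state_id == "DEAD"], 0.5)

  dw <- anchor_to_dw(p, reg)
  expect_identical(dw$dw[dw$state_id == "FH"], 0)
  expect_identical(dw$dw[dw$state_id == "DEAD"], 1)
  expect_true(all(dw$ci_lo <= dw$dw & dw$dw <= dw$ci_hi))
  # anchoring reverses the coefficient ordering
  ord_beta <- order(fit$beta[dw$state_id])
  expect_equal(order(dw$dw), rev(ord_beta))
})

test_that("probability-scale anchoring reproduces the affine arithmetic", {
  reg <- tiny_registry(1)
  p <- data.frame(state_id = c("FH", "S001", "DEAD"),
                  p = c(0.9, 0.7, 0.5),
                  ci_lo = c(0.9, 0.6, 0.5), ci_hi = c(0.9, 0.8, 0.5))
  dw <- anchor_to_dw(p, reg, scale = "probability")
  expect_equal(dw$dw[dw$state_id == "S001"], 0.5)
  expect_equal(dw$ci_lo[dw$state_id == "S001"], (0.9 - 0.8) / 0.4)
  expect_equal(dw$ci_hi[dw$state_id == "S001"], (0.9 - 0.6) / 0.4)
  # p at an anchor's value maps to that anchor's weight
  p2 <- p; p2$p[2] <- 0.5; p2$ci_lo[2] <- 0.5; p2$ci_hi[2] <- 0.5
  expect_equal(anchor_to_dw(p2, reg, scale = "probability")$dw[2], 1)
  # the scale cannot be oriented when p(FH) <= p(dead)
  p3 <- p; p3$p[1] <- 0.4
  expect_error(anchor_to_dw(p3, reg, scale = "probability"), "degenerate")
})

test_that("relabelling states permutes the estimates identically", {
  reg <- tiny_registry(5, seed = 3)
  cfg <- sim_config(120, seed = 17)
  pc <- simulate_pc_responses(reg, config = cfg)
  perm <- c(S001 = "S004", S002 = "S005", S003 = "S001",
            S004 = "S002", S005 = "S003", FH = "FH", DEAD = "DEAD")
  pc2 <- pc
  pc2$state_a <- unname(perm[pc$state_a])
  pc2$state_b <- unname(perm[pc$state_b])
  f1 <- fit_pc_probit(pc, reg)
  f2 <- fit_pc_probit(pc2, reg)
  expect_equal(unname(f1$beta[names(perm)]), unname(f2$beta[perm]),
               tolerance = 1e-8)
})

test_that("holdout validation is exact when predictions match frequencies", {
  # sigma = 0 choices are deterministic for well-separated states, so every
  # holdout frequency is 0 or 1 and, after a consistent fit, mad is ~0
  reg <- manual_registry(c(0.2, 0.5, 0.8))
  cfg <- sim_config(200, k_pairs = 10, sigma_pc = 0.15, seed = 19)
  pc <- simulate_pc_responses(reg, config = cfg)
  rep_ho <- pc_holdout(pc, reg, frac = 0.8, seed = 19)
  expect_equal(rep_ho$n_fit + rep_ho$n_holdout + rep_ho$n_excluded_pairs,
               nrow(pc))
  expect_true(rep_ho$mad >= 0 && rep_ho$mad <= 1)
  expect_error(pc_holdout(pc, reg, frac = 1.0), "between 0 and 1")
})

test_that("model coefficients are invariant to the 'drop' option when clean", {
  reg <- tiny_registry(3)
  cfg <- sim_config(150, seed = 23)
  pc <- simulate_pc_responses(reg, config = cfg)
  f1 <- fit_pc_probit(pc, reg, separation = "error")
  f2 <- fit_pc_probit(pc, reg, separation = "drop")
  expect_equal(f1$beta, f2$beta)
})
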