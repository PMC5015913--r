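#' Simulation settings for the synthetic survey
#'
#' Bundles the design constants and noise scales used by the four instrument
#' simulators.  The defaults mirror the survey design the package emulates:
#' 15 paired comparisons per respondent, 3 VAS ratings (the third always
#' 'being dead'), 3 standard-gamble staircases on a 5% grid starting at 50%,
#' and person-trade-off ladders over 1,500 / 2,000 / 3,000 / 5,000 / 10,000
#' patients against a program averting 1,000 deaths.
#'
#' @param n_respondents Number of simulated respondents.
#' @param k_pairs Paired comparisons per respondent (default 15).
#' @param sigma_pc Latent noise scale of the Thurstone choice model: state a
#'   is judged healthier with probability `pnorm((d_b - d_a)/sigma_pc)`.
#' @param sigma_vas Standard deviation of VAS rating noise, in VAS points.
#' @param sigma_sg Standard deviation of the respondent's internal utility
#'   in the standard gamble, on the utility scale.
#' @param sigma_phe Standard deviation of the respondent's internal
#'   disability weight in the trade-off ladder.
#' @param k_phe Trade-off ladder tasks per respondent.
#' @param seed Optional integer seed controlling all simulator randomness.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_respondents, k_pairs = 15, sigma_pc = 0.25,
                       sigma_vas = 15, sigma_sg = 0.15, sigma_phe = 0.2,
                       k_phe = 1, seed = NULL) {
  stopifnot(n_respondents >= 1, k_pairs >= 1, k_phe >= 1,
            sigma_pc >= 0, sigma_vas >= 0, sigma_sg >= 0, sigma_phe >= 0)
  out <- list(n_respondents = as.integer(n_respondents),
              k_pairs = as.integer(k_pairs),
              sigma_pc = sigma_pc, sigma_vas = sigma_vas,
              sigma_sg = sigma_sg, sigma_phe = sigma_phe,
              k_phe = as.integer(k_phe), seed = seed)
  class(out) <- "sim_config"
  out
}

# Offsets keep the four instrument streams distinct but all derived from the
# single configured seed.
.instrument_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
  invisible(NULL)
}

#' Choice probability of the Thurstone paired-comparison responder
#'
#' Probability that the first state is judged healthier than the second,
#' given latent disability weights `d_a`, `d_b` and noise scale `sigma`.
#' With `sigma = 0` the choice is deterministic; an exact tie is resolved by
#' a fair coin (probability 0.5).
#'
#' @param d_a,d_b Latent disability weights of the two states.
#' @param sigma Latent noise scale (>= 0).
#' @return Vector of probabilities.
#' @examples
#' pc_choice_prob(0, 1, 0.2)   # full health vs dead: essentially certain
#' @export
pc_choice_prob <- function(d_a, d_b, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) {
    (d_b > d_a) + 0.5 * (d_b == d_a)
  } else {
    stats::pnorm((d_b - d_a) / sigma)
  }
}

#' Simulate paired-comparison responses
#'
#' Each respondent answers `k_pairs` forced choices.  The two states of every
#' comparison are drawn uniformly without replacement from the full registry
#' (anchors included, as in the survey design the simulator emulates), and
#' the healthier-state judgement follows [pc_choice_prob()].
#'
#' @param registry A `"dw_registry"` or a registry states data frame.
#' @param truth Named vector of latent disability weights covering every
#'   registry state (defaults to the registry's own truth).
#' @param config A [sim_config()] object.
#' @return Data frame with columns `respondent_id`, `state_a`, `state_b`,
#'   `chose_a_healthier` (logical); `n_respondents * k_pairs` rows.
#' @export
simulate_pc_responses <- function(registry, truth = NULL, config) {
  states <- validate_registry(as_states(registry))
  if (is.null(truth) && inherits(registry, "dw_registry")) truth <- registry$truth
  stopifnot(all(states$state_id %in% names(truth)))
  .instrument_seed(config, 0L)

  n <- config$n_respondents * config$k_pairs
  S <- nrow(states)
  # two distinct states per comparison, uniform over ordered pairs
  a <- sample.int(S, n, replace = TRUE)
  b <- sample.int(S - 1L, n, replace = TRUE)
  b <- b + (b >= a)
  ida <- states$state_id[a]
  idb <- states$state_id[b]
  p <- pc_choice_prob(truth[ida], truth[idb], config$sigma_pc)
  data.frame(respondent_id = rep(seq_len(config$n_respondents),
                                 each = config$k_pairs),
             state_a = ida, state_b = idb,
             chose_a_healthier = stats::runif(n) < p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate visual analogue scale ratings
#'
#' Each respondent rates two substantive states (sampled uniformly without
#' replacement, anchors excluded) and, in the third slot, 'being dead'.  The
#' recorded value is `100 * (1 - d)` plus Gaussian noise, clamped to the
#' instrument's 0--100 range.
#'
#' @inheritParams simulate_pc_responses
#' @return Data frame with columns `respondent_id`, `state_id`, `value`.
#' @export
simulate_vas_responses <- function(registry, truth = NULL, config) {
  states <- validate_registry(as_states(registry))
  if (is.null(truth) && inherits(registry, "dw_registry")) truth <- registry$truth
  stopifnot(all(states$state_id %in% names(truth)))
  .instrument_seed(config, 1L)

  sub <- substantive_ids(states)
  dead <- anchor_ids(states)[["dead"]]
  nr <- config$n_respondents
  picks <- replicate(nr, sample(sub, 2L))
  ids <- as.vector(rbind(picks, dead))
  d <- truth[ids]
  value <- 100 * (1 - d) + stats::rnorm(length(ids), 0, config$sigma_vas)
  value <- pmin(pmax(value, 0), 100)
  data.frame(respondent_id = rep(seq_len(nr), each = 3L),
             state_id = ids, value = value,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deterministic standard-gamble staircase responder
#'
#' Mechanics of the titration: the certain state is compared with a gamble
#' offering restoration to full health with probability p (else immediate
#' death).  If the respondent's internal utility `u` for the state is
#' negative the state is judged worse than dead at the opening question and
#' the staircase stops.  Otherwise p starts at `start` and moves in steps of
#' `grid_step` toward `u`; indifference is declared at the grid value nearest
#' `u`, ties broken toward the lower p, and the endpoint is capped to the
#' reachable grid `[grid_step, 1 - grid_step]`.
#'
#' @param u Internal utility of the certain state, in `(-Inf, 1]`.
#' @param grid_step Probability grid resolution (default 0.05).
#' @param start Opening gamble probability (default 0.50); must be a
#'   multiple of `grid_step`.
#' @return List with `worse_than_dead` (logical) and `endpoint_p` (the
#'   indifference probability, `NA` when worse than dead).
#' @examples
#' sg_staircase(0.62)   # endpoint 0.60: nearest grid value
#' sg_staircase(-0.1)   # worse than dead
#' @export
sg_staircase <- function(u, grid_step = 0.05, start = 0.50) {
  stopifnot(length(u) == 1L, grid_step > 0, start > 0, start < 1)
  if (abs(start / grid_step - round(start / grid_step)) > 1e-9)
    stop("`start` must be a multiple of `grid_step`", call. = FALSE)
  if (u < 0) return(list(worse_than_dead = TRUE, endpoint_p = NA_real_))
  # rounded so grid values are exact decimals (0.6, not 0.6 + 1e-16)
  grid <- round(seq(grid_step, 1 - grid_step, by = grid_step), 10)
  # nearest grid value; which.min takes the first (= lower p) on a tie
  endpoint <- grid[which.min(abs(grid - u))]
  list(worse_than_dead = FALSE, endpoint_p = endpoint)
}

#' Simulate standard-gamble staircases
#'
#' Each respondent evaluates three substantive states.  The internal utility
#' is `(1 - d)` plus Gaussian noise and the response follows
#' [sg_staircase()]: worse-than-dead judgements stop the staircase, all
#' others end at a 5%-grid indifference probability.
#'
#' @inheritParams simulate_pc_responses
#' @return Data frame with columns `respondent_id`, `state_id`,
#'   `worse_than_dead`, `endpoint_p` (`NA` when worse than dead).
#' @export
simulate_sg_responses <- function(registry, truth = NULL, config) {
  states <- validate_registry(as_states(registry))
  if (is.null(truth) && inherits(registry, "dw_registry")) truth <- registry$truth
  stopifnot(all(states$state_id %in% names(truth)))
  .instrument_seed(config, 2L)

  sub <- substantive_ids(states)
  nr <- config$n_respondents
  ids <- as.vector(replicate(nr, sample(sub, min(3L, length(sub)))))
  u <- (1 - truth[ids]) + stats::rnorm(length(ids), 0, config$sigma_sg)
  res <- lapply(u, sg_staircase)
  data.frame(respondent_id = rep(seq_len(nr), each = min(3L, length(sub))),
             state_id = ids,
             worse_than_dead = vapply(res, `[[`, logical(1), "worse_than_dead"),
             endpoint_p = vapply(res, `[[`, numeric(1), "endpoint_p"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ladder rungs of the population-health-equivalence task
#' @export
phe_ladder_values <- c(1500, 2000, 3000, 5000, 10000)

#' Deterministic population-health-equivalence ladder responder
#'
#' The respondent compares program A, averting 1,000 deaths, with program B,
#' preventing X cases of the proposed state.  Taking one averted death as one
#' unit of full health, the responder prefers B at rung X iff `X * w >= 1000`
#' (exact equality counts as preferring B).  The ladder is walked
#' monotonically from `start_X` until the preference flips or a ladder
#' extreme is reached.
#'
#' @param w Internal disability weight of the state, in `(0, 1]`.
#' @param start_X Starting rung; must be one of [phe_ladder_values].
#' @return List with `trace` (data frame of `X`, `chose_b` in question
#'   order) and `final_bracket` (length-2 numeric: the rungs straddling the
#'   flip; `c(-Inf, 1500)` when B is preferred even at the bottom rung,
#'   `c(10000, Inf)` when A is preferred even at the top).
#' @examples
#' phe_ladder(0.4, 2000)$final_bracket    # c(2000, 3000): 1000/0.4 = 2500
#' @export
phe_ladder <- function(w, start_X) {
  stopifnot(length(w) == 1L, w > 0, w <= 1, start_X %in% phe_ladder_values)
  prefers_b <- function(X) X * w >= 1000
  ladder <- phe_ladder_values
  i <- match(start_X, ladder)
  xs <- integer(0); cb <- logical(0)
  first <- prefers_b(ladder[i])
  repeat {
    xs <- c(xs, ladder[i]); choice <- prefers_b(ladder[i]); cb <- c(cb, choice)
    if (choice != first) break                       # preference flipped
    if (first && i == 1L) {                          # B even at bottom rung
      return(list(trace = data.frame(X = xs, chose_b = cb),
                  final_bracket = c(-Inf, ladder[1L])))
    }
    if (!first && i == length(ladder)) {             # A even at top rung
      return(list(trace = data.frame(X = xs, chose_b = cb),
                  final_bracket = c(ladder[length(ladder)], Inf)))
    }
    i <- i + if (first) -1L else 1L
  }
  # flip between the last two rungs visited: lower rung prefers A, upper B
  lo <- min(xs[length(xs) - 1L], xs[length(xs)])
  hi <- max(xs[length(xs) - 1L], xs[length(xs)])
  list(trace = data.frame(X = xs, chose_b = cb), final_bracket = c(lo, hi))
}

#' Simulate population-health-equivalence ladder tasks
#'
#' Each respondent performs `k_phe` ladder tasks on substantive states.  The
#' internal weight is the latent weight plus Gaussian noise, clamped to
#' `(0, 1]`, the starting rung is drawn uniformly from the ladder, and the
#' walk follows [phe_ladder()].
#'
#' @inheritParams simulate_pc_responses
#' @return Data frame with columns `respondent_id`, `state_id`, `trace`
#'   (the walk serialised as `"X:A"` / `"X:B"` tokens joined by `;`),
#'   `bracket_lo`, `bracket_hi` (`-Inf` / `Inf` for open-ended brackets).
#' @export
simulate_phe_responses <- function(registry, truth = NULL, config) {
  states <- validate_registry(as_states(registry))
  if (is.null(truth) && inherits(registry, "dw_registry")) truth <- registry$truth
  stopifnot(all(states$state_id %in% names(truth)))
  .instrument_seed(config, 3L)

  sub <- substantive_ids(states)
  nr <- config$n_respondents
  k <- min(config$k_phe, length(sub))
  ids <- as.vector(replicate(nr, sample(sub, k)))
  w <- pmin(pmax(truth[ids] + stats::rnorm(length(ids), 0, config$sigma_phe),
                 1e-6), 1)
  start <- sample(phe_ladder_values, length(ids), replace = TRUE)
  recs <- mapply(phe_ladder, w, start, SIMPLIFY = FALSE)
  data.frame(respondent_id = rep(seq_len(nr), each = k),
             state_id = ids,
             trace = vapply(recs, function(r)
               paste(sprintf("%d:%s", r$trace$X,
                             ifelse(r$trace$chose_b, "B", "A")),
                     collapse = ";"), character(1)),
             bracket_lo = vapply(recs, function(r) r$final_bracket[1], numeric(1)),
             bracket_hi = vapply(recs, function(r) r$final_bracket[2], numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a full four-instrument survey
#'
#' Runs all four instrument simulators under the single configured seed and
#' optionally writes the long-format response CSVs plus a JSON manifest
#' recording the configuration.
#'
#' @inheritParams simulate_pc_responses
#' @param dir Optional directory; when given, the four response CSVs and
#'   `manifest.json` are written there.
#' @return List with elements `pc`, `vas`, `sg`, `phe` (response data
#'   frames) and `config`.
#' @export
simulate_survey <- function(registry, truth = NULL, config, dir = NULL) {
  out <- list(pc  = simulate_pc_responses(registry, truth, config),
              vas = simulate_vas_responses(registry, truth, config),
              sg  = simulate_sg_responses(registry, truth, config),
              phe = simulate_phe_responses(registry, truth, config),
              config = config)
  if (!is.null(dir)) write_survey(out, dir)
  out
}
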