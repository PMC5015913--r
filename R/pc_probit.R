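# Paired-comparison probit model: signed-difference design, maximum
# likelihood fit with observed-information covariance, predicted
# probabilities against the 'being dead' reference, and anchoring onto the
# disability-weight scale.

#' Build the signed-difference probit design from paired comparisons
#'
#' Each forced choice becomes one row of a signed indicator matrix: +1 in the
#' column of the first state, -1 in the column of the second, with the
#' 'being dead' column dropped as the reference category.  Under the model
#' the probability that the first state is judged healthier is
#' `pnorm(beta_a - beta_b)`.
#'
#' States that appear in no response are unidentifiable; they are reported
#' in the `unidentified` element and no weight is ever emitted for them.
#'
#' @param pc Data frame of paired-comparison responses with columns
#'   `respondent_id`, `state_a`, `state_b`, `chose_a_healthier`.
#' @param registry A `"dw_registry"` or registry states data frame.
#' @return List with `X` (model matrix over identified non-reference
#'   states), `y` (0/1 outcome), `estimated_ids`, `unidentified`,
#'   `dead_id`, `n_obs`.
#' @export
build_pc_design <- function(pc, registry) {
  states <- validate_registry(as_states(registry))
  if (nrow(pc) < 1L) stop("no paired-comparison responses", call. = FALSE)
  bad <- !(pc$state_a %in% states$state_id) | !(pc$state_b %in% states$state_id)
  if (any(bad))
    stop("responses reference states absent from the registry (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")", call. = FALSE)
  if (any(pc$state_a == pc$state_b))
    stop("self-comparisons (state_a == state_b) are invalid", call. = FALSE)

  dead <- anchor_ids(states)[["dead"]]
  seen <- unique(c(pc$state_a, pc$state_b))
  unidentified <- setdiff(states$state_id, c(seen, dead))
  est_ids <- setdiff(intersect(states$state_id, seen), dead)

  n <- nrow(pc)
  X <- matrix(0, n, length(est_ids), dimnames = list(NULL, est_ids))
  ia <- match(pc$state_a, est_ids)
  ib <- match(pc$state_b, est_ids)
  ok <- !is.na(ia); X[cbind(which(ok), ia[ok])] <- 1
  ok <- !is.na(ib); X[cbind(which(ok), ib[ok])] <- X[cbind(which(ok), ib[ok])] - 1
  list(X = X, y = as.integer(pc$chose_a_healthier), estimated_ids = est_ids,
       unidentified = unidentified, dead_id = dead, n_obs = n)
}

# log-likelihood, gradient and observed information of the probit model
.probit_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * stats::pnorm(eta, log.p = TRUE) +
        (1 - y) * stats::pnorm(-eta, log.p = TRUE))
}

.probit_score_info <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  # inverse Mills ratios, computed on the log scale for stability
  m1 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE))
  m0 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(-eta, log.p = TRUE))
  g <- ifelse(y == 1, m1, -m0)                    # d loglik / d eta
  w <- ifelse(y == 1, m1 * (eta + m1), m0 * (m0 - eta))  # -d2 loglik / d eta2
  list(score = drop(crossprod(X, g)), info = crossprod(X, w * X))
}

# states whose every recorded comparison they won, or every one they lost:
# their coefficient diverges (perfect separation)
.separated_states <- function(design) {
  wins_of <- function(s) {
    ra <- design$X[, s] == 1
    rb <- design$X[, s] == -1
    c(design$y[ra], 1L - design$y[rb])
  }
  sep <- vapply(design$estimated_ids, function(s) {
    w <- wins_of(s); all(w == 1L) || all(w == 0L)
  }, logical(1))
  design$estimated_ids[sep]
}

#' Fit the paired-comparison probit model
#'
#' Maximum-likelihood probit regression on the signed-difference design of
#' [build_pc_design()], with 'being dead' as the reference category
#' (`beta = 0`).  The fit is started from [stats::glm()] (probit link) and
#' polished by Newton steps on the exact likelihood until the gradient norm
#' is below `tol`; the covariance is the inverse observed information at the
#' maximum.
#'
#' Perfect separation (a state that wins or loses every one of its
#' comparisons) is detected before fitting.  With `separation = "error"`
#' (default) it is a hard error naming the states; with `"drop"` the
#' offending states are removed from the design and reported alongside the
#' unidentified states.  A small ridge penalty (`ridge > 0`, penalised
#' log-likelihood `l - ridge/2 * ||beta||^2`) is available as an alternative
#' remedy.
#'
#' @inheritParams build_pc_design
#' @param ridge Ridge penalty on the coefficients (default 0: plain MLE).
#' @param separation `"error"` or `"drop"`; what to do with perfectly
#'   separated states.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param maxit Maximum Newton iterations.
#' @return Object of class `"pc_probit"`: list with `beta` (named, the
#'   reference included at exactly 0), `vcov` (estimated states only),
#'   `loglik`, `n_obs`, `estimated_ids`, `unidentified`, `dropped`,
#'   `registry`, `ridge`, `iterations`.
#' @examples
#' reg <- make_state_registry(4, seed = 1)
#' pc <- simulate_pc_responses(reg, config = sim_config(150, seed = 1))
#' fit <- fit_pc_probit(pc, reg)
#' coef(fit)
#' @export
fit_pc_probit <- function(pc, registry, ridge = 0,
                          separation = c("error", "drop"),
                          tol = 1e-8, maxit = 50L) {
  separation <- match.arg(separation)
  states <- validate_registry(as_states(registry))
  design <- build_pc_design(pc, registry)

  dropped <- character(0)
  if (ridge == 0) {
    sep <- .separated_states(design)
    if (length(sep)) {
      if (separation == "error")
        stop("perfect separation for state(s): ", paste(sep, collapse = ", "),
             "; drop them, collect more comparisons, or set ridge > 0",
             call. = FALSE)
      dropped <- sep
      keep <- setdiff(design$estimated_ids, sep)
      inrow <- rowSums(abs(design$X[, sep, drop = FALSE])) == 0
      design$X <- design$X[inrow, keep, drop = FALSE]
      design$y <- design$y[inrow]
      design$estimated_ids <- keep
      if (!length(keep)) stop("no identifiable states left after dropping ",
                              "separated states", call. = FALSE)
    }
  }

  X <- design$X; y <- design$y
  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y,
      family = stats::binomial(link = "probit"),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100)))$coefficients,
    error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0

  trace_norm <- numeric(0)
  for (it in seq_len(maxit)) {
    si <- .probit_score_info(beta, X, y)
    g <- si$score - ridge * beta
    H <- si$info + ridge * diag(ncol(X))
    trace_norm[it] <- max(abs(g))
    if (trace_norm[it] < tol) break
    step <- solve(H, g)
    ll0 <- .probit_loglik(beta, X, y) - ridge / 2 * sum(beta^2)
    alpha <- 1
    repeat {                                   # halving line search
      cand <- beta + alpha * step
      ll <- .probit_loglik(cand, X, y) - ridge / 2 * sum(cand^2)
      if (is.finite(ll) && ll >= ll0 - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { cand <- beta; break }
    }
    beta <- cand
  }
  if (trace_norm[length(trace_norm)] >= tol && length(trace_norm) == maxit)
    stop("probit fit did not converge in ", maxit, " iterations; ",
         "gradient norm trace: ",
         paste(signif(trace_norm, 3), collapse = " "), call. = FALSE)

  si <- .probit_score_info(beta, X, y)
  vc <- solve(si$info + ridge * diag(ncol(X)))
  dimnames(vc) <- list(design$estimated_ids, design$estimated_ids)
  full_beta <- c(stats::setNames(beta, design$estimated_ids),
                 stats::setNames(0, design$dead_id))

  out <- list(beta = full_beta, vcov = vc,
              loglik = .probit_loglik(beta, X, y),
              n_obs = design$n_obs,
              estimated_ids = design$estimated_ids,
              unidentified = design$unidentified, dropped = dropped,
              registry = states, ridge = ridge,
              iterations = length(trace_norm))
  class(out) <- "pc_probit"
  out
}

#' @export
print.pc_probit <- function(x, ...) {
  cat("Paired-comparison probit fit\n")
  cat("  ", length(x$estimated_ids), " states estimated against reference '",
      setdiff(names(x$beta), x$estimated_ids), "'\n", sep = "")
  cat("  n =", x$n_obs, " log-likelihood =", format(x$loglik, digits = 6), "\n")
  if (length(x$unidentified))
    cat("  unidentified states:", paste(x$unidentified, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped (separated) states:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pc_probit <- function(object, ...) object$beta

#' @export
vcov.pc_probit <- function(object, ...) object$vcov

#' @export
logLik.pc_probit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimated_ids),
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.pc_probit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- data.frame(state_id = object$estimated_ids,
                    beta = object$beta[object$estimated_ids],
                    se = se,
                    z = object$beta[object$estimated_ids] / se,
                    row.names = NULL)
  out <- list(coefficients = tab, loglik = object$loglik, n_obs = object$n_obs,
              unidentified = object$unidentified)
  class(out) <- "summary.pc_probit"
  out
}

#' @export
print.summary.pc_probit <- function(x, ...) {
  cat("Paired-comparison probit fit (n =", x$n_obs, ")\n\n")
  print(x$coefficients, digits = 4)
  cat("\nlog-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Predicted probabilities of being judged healthier than 'being dead'
#'
#' Transforms the probit coefficients to the probability scale.  With
#' `method = "vs_reference"` (the standard definition) the predicted
#' probability of state h is `pnorm(beta_h)`, the probability that h is
#' judged healthier than the reference 'being dead'; the reference itself
#' gets exactly 0.5.  With `method = "mean_win"` it is the average win
#' probability of h against every other estimated state.  Confidence
#' intervals transform the Wald interval of `beta_h` through the same
#' monotone map.
#'
#' @param fit A `"pc_probit"` object.
#' @param method Probability definition, see Details.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `state_id`, `p`, `ci_lo`, `ci_hi`.
#' @export
predicted_probabilities <- function(fit, method = c("vs_reference", "mean_win"),
                                    level = 0.95) {
  stopifnot(inherits(fit, "pc_probit"))
  method <- match.arg(method)
  ids <- names(fit$beta)
  se <- stats::setNames(rep(0, length(ids)), ids)
  se[fit$estimated_ids] <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- fit$beta - z * se
  hi <- fit$beta + z * se
  trans <- switch(method,
    vs_reference = stats::pnorm,
    mean_win = function(b) vapply(seq_along(b), function(i)
      mean(stats::pnorm(b[i] - fit$beta[-i])), numeric(1)))
  data.frame(state_id = ids, p = unname(trans(fit$beta)),
             ci_lo = unname(trans(lo)), ci_hi = unname(trans(hi)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Anchor predicted probabilities onto the disability-weight scale
#'
#' Rescales the predicted probabilities so that 'full health' maps to
#' exactly 0 and 'being dead' to exactly 1.  With `scale = "probit"` (the
#' default) the affine anchoring is applied on the probit index,
#' `dw_h = (q_FH - q_h) / (q_FH - q_dead)` with `q = qnorm(p)`, which is the
#' transform consistent with the Thurstone choice model and recovers latent
#' weights without mid-scale compression.  With `scale = "probability"` the
#' same affine map is applied to the probabilities themselves.  Anchors are
#' treated as fixed when mapping the confidence limits, which propagate the
#' probability intervals through the same (decreasing) transform.
#'
#' @param p Data frame from [predicted_probabilities()].
#' @param registry A `"dw_registry"` or registry states data frame
#'   identifying the anchor states.
#' @param scale Anchoring scale, see Details.
#' @return A `"dw_estimates"` data frame: `state_id`, `dw`, `ci_lo`,
#'   `ci_hi`, `model_tag = "model1"`.  Weights outside `[0, 1]` are kept
#'   (with a warning), never clipped.
#' @export
anchor_to_dw <- function(p, registry, scale = c("probit", "probability")) {
  scale <- match.arg(scale)
  states <- validate_registry(as_states(registry))
  anc <- anchor_ids(states)
  if (!all(anc %in% p$state_id))
    stop("both anchor states must be present in the probability map",
         call. = FALSE)
  p_fh <- p$p[p$state_id == anc[["full_health"]]]
  p_dead <- p$p[p$state_id == anc[["dead"]]]
  if (!(p_fh > p_dead))
    stop("anchoring degenerate: p(full health) must exceed p(dead); ",
         "the data cannot orient the scale", call. = FALSE)

  tr <- if (scale == "probit") function(v) stats::qnorm(pmin(pmax(v, 1e-12), 1 - 1e-12)) else identity
  q_fh <- tr(p_fh); q_dead <- tr(p_dead)
  map <- function(v) (q_fh - tr(v)) / (q_fh - q_dead)   # decreasing in p

  out <- data.frame(state_id = p$state_id,
                    dw = map(p$p),
                    ci_lo = map(p$ci_hi),   # decreasing map swaps endpoints
                    ci_hi = map(p$ci_lo),
                    model_tag = "model1",
                    row.names = NULL, stringsAsFactors = FALSE)
  fh_row <- out$state_id == anc[["full_health"]]
  dead_row <- out$state_id == anc[["dead"]]
  out[fh_row, c("dw", "ci_lo", "ci_hi")] <- 0
  out[dead_row, c("dw", "ci_lo", "ci_hi")] <- 1
  oob <- !fh_row & !dead_row & (out$dw < 0 | out$dw > 1)
  if (any(oob))
    warning(sum(oob), " disability weight(s) fall outside [0, 1]; ",
            "values are reported unclipped", call. = FALSE)
  class(out) <- c("dw_estimates", "data.frame")
  out
}

#' @export
predict.pc_probit <- function(object, type = c("prob", "dw"),
                              method = c("vs_reference", "mean_win"),
                              scale = c("probit", "probability"), ...) {
  type <- match.arg(type)
  p <- predicted_probabilities(object, method = match.arg(method))
  if (type == "prob") return(p)
  anchor_to_dw(p, object$registry, scale = match.arg(scale))
}

#' Disability weights from the paired-comparison-only model
#'
#' Convenience wrapper: fit probabilities from a `"pc_probit"` object and
#' anchor them to the 0--1 disability-weight scale (Model 1).
#'
#' @inheritParams predicted_probabilities
#' @inheritParams anchor_to_dw
#' @return A `"dw_estimates"` data frame with `model_tag = "model1"`.
#' @export
dw_model1 <- function(fit, method = c("vs_reference", "mean_win"),
                      scale = c("probit", "probability")) {
  anchor_to_dw(predicted_probabilities(fit, method = match.arg(method)),
               fit$registry, scale = match.arg(scale))
}

#' Holdout validation of the paired-comparison model
#'
#' Randomly splits the individual comparisons into a fit fraction and a
#' holdout fraction, fits the probit model on the fit fraction, and compares
#' the observed choice frequency of every unordered pair present in the
#' holdout with the model's predicted probability
#' `pnorm(beta_a - beta_b)`.  Holdout pairs involving a state that is
#' unidentified (or perfectly separated) in the fit fraction are excluded
#' and counted.
#'
#' @inheritParams build_pc_design
#' @param frac Fraction of comparisons used for fitting, in (0, 1).
#' @param seed Optional seed for the split.
#' @return Object of class `"pc_holdout"`: list with `n_fit`, `n_holdout`,
#'   `mad` (mean absolute difference between observed and predicted pair
#'   probabilities), `n_pairs`, `n_excluded_pairs`, and the underlying
#'   `fit`.
#' @export
pc_holdout <- function(pc, registry, frac = 0.8, seed = NULL) {
  if (!(frac > 0 && frac < 1))
    stop("`frac` must be strictly between 0 and 1 (the holdout may not be ",
         "empty)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pc)
  idx_fit <- sort(sample.int(n, round(frac * n)))
  if (length(idx_fit) == 0L || length(idx_fit) == n)
    stop("split leaves an empty fit or holdout fraction", call. = FALSE)
  fit <- fit_pc_probit(pc[idx_fit, ], registry, separation = "drop")
  ho <- pc[-idx_fit, ]

  known <- c(fit$estimated_ids, setdiff(names(fit$beta), fit$estimated_ids))
  ok <- ho$state_a %in% known & ho$state_b %in% known
  n_excl_rows <- sum(!ok)
  ho <- ho[ok, ]
  if (!nrow(ho)) stop("no usable holdout pairs", call. = FALSE)

  lo <- pmin(ho$state_a, ho$state_b)
  hi <- pmax(ho$state_a, ho$state_b)
  chose_lo <- ifelse(ho$state_a == lo, ho$chose_a_healthier,
                     !ho$chose_a_healthier)
  key <- paste(lo, hi, sep = "\r")
  obs <- tapply(as.numeric(chose_lo), key, mean)
  pair <- do.call(rbind, strsplit(names(obs), "\r", fixed = TRUE))
  pred <- stats::pnorm(fit$beta[pair[, 1]] - fit$beta[pair[, 2]])
  out <- list(n_fit = length(idx_fit), n_holdout = nrow(ho),
              mad = mean(abs(obs - pred)), n_pairs = length(obs),
              n_excluded_pairs = n_excl_rows, fit = fit)
  class(out) <- "pc_holdout"
  out
}

#' @export
print.pc_holdout <- function(x, ...) {
  cat("Paired-comparison holdout validation\n")
  cat("  fit on", x$n_fit, "comparisons; holdout", x$n_holdout,
      "comparisons over", x$n_pairs, "pairs\n")
  if (x$n_excluded_pairs)
    cat("  ", x$n_excluded_pairs,
        "holdout comparisons excluded (state not identified in fit)\n")
  cat("  mean absolute difference (observed vs predicted):",
      format(x$mad, digits = 4), "\n")
  invisible(x)
}
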