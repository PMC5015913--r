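# Hybrid model: population-health-equivalence ladder brackets are converted
# to disability-weight intervals, per-state weights are estimated by
# interval-censored regression, and a linear linkage to the
# paired-comparison probabilities produces Model 2 weights for all states.

#' Convert ladder brackets to disability-weight intervals
#'
#' Under benefit equivalence (averting 1,000 deaths = 1,000 units of full
#' health) the indifference rung X implies a weight of about 1000/X, so a
#' bracket (X_lo, X_hi) maps to the weight interval
#' `[1000/X_hi, 1000/X_lo]`.  Open-ended responses map to
#' `[2/3, 1]` (program B preferred even at 1,500 patients) and
#' `[0.001, 0.1]` (program A preferred even at 10,000; the 0.001 floor keeps
#' the log-scale likelihood finite, below the ladder's resolution the data
#' carry no information).
#'
#' When a `trace` column is present each walk is checked for consistency
#' (rungs adjacent on the ladder, a single preference flip, bracket matching
#' the walk); inconsistent records are a hard error with their row numbers.
#'
#' @param phe Data frame with columns `state_id`, `bracket_lo`,
#'   `bracket_hi` (and optionally `trace`), as produced by
#'   [simulate_phe_responses()] or [read_phe_responses()].
#' @return Data frame with columns `state_id`, `lo`, `hi` — one
#'   disability-weight interval per record, `0 < lo <= hi <= 1`.
#' @examples
#' phe_record_to_interval(data.frame(state_id = "S001",
#'                                   bracket_lo = 2000, bracket_hi = 3000))
#' @export
phe_record_to_interval <- function(phe) {
  stopifnot(all(c("state_id", "bracket_lo", "bracket_hi") %in% names(phe)))
  if (!is.null(phe$trace)) {
    bad <- which(!mapply(.phe_trace_consistent, phe$trace,
                         phe$bracket_lo, phe$bracket_hi))
    if (length(bad))
      stop("malformed ladder trace in record(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  lo <- ifelse(is.infinite(phe$bracket_hi), 0.001,
               ifelse(is.infinite(phe$bracket_lo), 2 / 3,
                      1000 / phe$bracket_hi))
  hi <- ifelse(is.infinite(phe$bracket_hi), 0.1,
               ifelse(is.infinite(phe$bracket_lo), 1,
                      1000 / phe$bracket_lo))
  data.frame(state_id = phe$state_id, lo = lo, hi = hi,
             row.names = NULL, stringsAsFactors = FALSE)
}

# a serialized trace is consistent when its rungs are ladder values walked
# monotonically one step at a time, all choices before the last agree, and
# the final bracket matches the walk's end
.phe_trace_consistent <- function(trace, bracket_lo, bracket_hi) {
  tok <- strsplit(trace, ";", fixed = TRUE)[[1]]
  m <- regmatches(tok, regexec("^([0-9]+):([AB])$", tok))
  if (any(lengths(m) != 3L)) return(FALSE)
  X <- as.numeric(vapply(m, `[`, character(1), 2L))
  cb <- vapply(m, `[`, character(1), 3L) == "B"
  if (!all(X %in% phe_ladder_values)) return(FALSE)
  i <- match(X, phe_ladder_values)
  if (length(i) > 1L) {
    d <- diff(i)
    if (any(abs(d) != 1L) || length(unique(sign(d))) > 1L) return(FALSE)
    if (length(unique(cb[-length(cb)])) > 1L) return(FALSE)
    # the walk continues only while the preference is unchanged
    same_dir <- if (cb[1]) -1L else 1L
    if (any(sign(d) != same_dir)) return(FALSE)
  }
  flipped <- cb[length(cb)] != cb[1]
  last <- X[length(X)]
  if (flipped) {
    prev <- X[length(X) - 1L]
    bracket_lo == min(prev, last) && bracket_hi == max(prev, last)
  } else if (cb[1]) {
    last == phe_ladder_values[1] && is.infinite(bracket_lo) &&
      bracket_hi == phe_ladder_values[1]
  } else {
    last == phe_ladder_values[length(phe_ladder_values)] &&
      bracket_lo == last && is.infinite(bracket_hi)
  }
}

#' Interval regression of disability weights on health states
#'
#' Fits an interval-censored normal likelihood on the log weight scale:
#' `log(DW) ~ N(mu_state, sigma^2)` with a dummy mean per state and a common
#' scale, each observation contributing
#' `Phi((log hi - mu)/sigma) - Phi((log lo - mu)/sigma)`.  Estimation uses
#' [survival::survreg()] with interval2 censoring; per-state estimates are
#' `exp(mu_hat)` with delta-method (log-normal Wald) confidence intervals.
#' The natural-scale variant (`scale_model = "natural"`) is available for
#' sensitivity analysis.
#'
#' When every state's intervals share a common interior the joint
#' likelihood is flat (the scale collapses to zero) and no proper MLE
#' exists; the function then reports, per state, the geometric midpoint of
#' the common interior with the interior as CI, flagged `flat_likelihood`
#' in the `flag` column (all-point interval sets get the point and a
#' `zero_width` flag).  A single non-degenerate state is enough to identify
#' the shared scale, in which case all states are estimated by the
#' regression.
#'
#' @param obs Data frame of interval observations (`state_id`, `lo`, `hi`).
#' @param scale_model `"log"` (default) or `"natural"`.
#' @return Data frame with columns `state_id`, `phe_dw`, `ci_lo`, `ci_hi`,
#'   `n`, `flag`.
#' @export
fit_phe_intervals <- function(obs, scale_model = c("log", "natural")) {
  scale_model <- match.arg(scale_model)
  stopifnot(all(c("state_id", "lo", "hi") %in% names(obs)), nrow(obs) >= 1)
  if (any(obs$lo <= 0 | obs$hi > 1 | obs$lo > obs$hi))
    stop("intervals must satisfy 0 < lo <= hi <= 1", call. = FALSE)

  # A state whose intervals share a common interior (max lo < min hi) has a
  # flat per-state likelihood: sigma -> 0 with the mean anywhere inside
  # attains the supremum.  When every state is flat no proper joint MLE
  # exists, so analytic suprema (geometric midpoint of the common interior,
  # the interior as CI, a flag) are reported instead of the regression;
  # with at least one non-flat state the shared scale is identified and all
  # states go to the regression.
  by_state <- split(obs, obs$state_id)
  inter_lo <- vapply(by_state, function(d) max(d$lo), numeric(1))
  inter_hi <- vapply(by_state, function(d) min(d$hi), numeric(1))
  point <- vapply(by_state, function(d)
    all(d$lo == d$lo[1] & d$hi == d$lo[1]), logical(1))
  degen <- point | (inter_lo < inter_hi)
  res <- list()
  if (all(degen)) {
    # every state flat: report analytic suprema instead of the regression
    for (s in names(by_state)) {
      d <- by_state[[s]]
      est <- if (point[s]) d$lo[1] else sqrt(inter_lo[[s]] * inter_hi[[s]])
      res[[s]] <- data.frame(state_id = s, phe_dw = est,
                             ci_lo = if (point[s]) est else inter_lo[[s]],
                             ci_hi = if (point[s]) est else inter_hi[[s]],
                             n = nrow(d),
                             flag = if (point[s]) "zero_width" else "flat_likelihood",
                             stringsAsFactors = FALSE)
    }
    fit_states <- character(0)
  } else {
    fit_states <- names(by_state)
  }
  if (length(fit_states)) {
    d <- obs[obs$state_id %in% fit_states, ]
    st <- factor(d$state_id)
    dist <- if (scale_model == "log") "lognormal" else "gaussian"
    form <- if (nlevels(st) > 1L)
      survival::Surv(lo, hi, type = "interval2") ~ st - 1
    else survival::Surv(lo, hi, type = "interval2") ~ 1
    sv <- survival::survreg(form, data = d, dist = dist,
                            control = survival::survreg.control(
                              rel.tolerance = 1e-10, maxiter = 100))
    if (!is.null(sv$fail) || any(!is.finite(stats::coef(sv))))
      stop("interval regression failed to converge", call. = FALSE)
    mu <- stats::coef(sv)
    se <- sqrt(diag(stats::vcov(sv)))[seq_along(mu)]
    z <- stats::qnorm(0.975)
    back <- if (scale_model == "log") exp else identity
    res[["__fit__"]] <- data.frame(
      state_id = levels(st),
      phe_dw = unname(back(mu)),
      ci_lo = unname(back(mu - z * se)),
      ci_hi = unname(back(mu + z * se)),
      n = as.integer(table(st)),
      flag = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$state_id), ]
  rownames(out) <- NULL
  out
}

#' Link paired-comparison probabilities to ladder weights (Model 2)
#'
#' Ordinary least squares of the interval-regression weight estimates on the
#' paired-comparison predicted probabilities over the states common to both,
#' then prediction at every state's probability — including states without
#' ladder data.  Confidence intervals are the regression's confidence
#' interval for the mean response.
#'
#' @param pc_probs Data frame from [predicted_probabilities()].
#' @param phe_dws Data frame from [fit_phe_intervals()].
#' @return List with
#'   \describe{
#'     \item{estimates}{`"dw_estimates"` data frame, `model_tag = "model2"`,
#'       one row per state in `pc_probs`.}
#'     \item{linkage}{list with `intercept`, `slope`, `r_squared`,
#'       `n_states`.}
#'   }
#' @export
link_hybrid <- function(pc_probs, phe_dws) {
  common <- intersect(pc_probs$state_id, phe_dws$state_id)
  if (length(common) < 2L)
    stop("need at least 2 states common to both maps", call. = FALSE)
  x <- pc_probs$p[match(common, pc_probs$state_id)]
  y <- phe_dws$phe_dw[match(common, phe_dws$state_id)]
  if (stats::var(x) == 0)
    stop("all paired-comparison probabilities equal: linkage regression is ",
         "rank deficient", call. = FALSE)
  df <- data.frame(p = x, dw = y)
  lf <- stats::lm(dw ~ p, data = df)

  pr <- stats::predict(lf, newdata = data.frame(p = pc_probs$p),
                       interval = "confidence", level = 0.95)
  est <- data.frame(state_id = pc_probs$state_id,
                    dw = unname(pr[, "fit"]),
                    ci_lo = unname(pr[, "lwr"]),
                    ci_hi = unname(pr[, "upr"]),
                    model_tag = "model2",
                    row.names = NULL, stringsAsFactors = FALSE)
  class(est) <- c("dw_estimates", "data.frame")
  list(estimates = est,
       linkage = list(intercept = unname(stats::coef(lf)[1]),
                      slope = unname(stats::coef(lf)[2]),
                      r_squared = summary(lf)$r.squared,
                      n_states = length(common)))
}

#' Disability weights from the hybrid model (Model 2)
#'
#' Convenience pipeline: ladder records to intervals, interval regression,
#' linkage to the paired-comparison probabilities.
#'
#' @param phe Ladder response data frame.
#' @param fit A `"pc_probit"` object.
#' @param scale_model Passed to [fit_phe_intervals()].
#' @return As [link_hybrid()].
#' @export
dw_model2 <- function(phe, fit, scale_model = "log") {
  intervals <- phe_record_to_interval(phe)
  phe_dws <- fit_phe_intervals(intervals, scale_model = scale_model)
  link_hybrid(predicted_probabilities(fit), phe_dws)
}
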