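# Direct valuation models: VAS ratings and SG staircase outcomes are turned
# into per-respondent disutilities (1 - utility) and per-state disability
# weights are the dummy-regression (group-mean) estimates.

#' Utility of a health state from a VAS rating
#'
#' Rescales a 0--100 VAS rating against the respondent's own rating of
#' 'being dead': utility is `v / 100` when the respondent rated dead at 0,
#' and `(v - v_dead) / (100 - v_dead)` otherwise.  A respondent who rated
#' dead at 100 leaves the denominator zero; such blocks must be excluded
#' upstream (see [vas_disutilities()]).
#'
#' @param v VAS value of the health state, in `[0, 100]`.
#' @param v_dead VAS value the same respondent gave 'being dead', in
#'   `[0, 100)`.
#' @return Utility (can be negative when the state is rated below dead).
#' @examples
#' vas_utility(80, 0)    # 0.80
#' vas_utility(80, 20)   # 0.75
#' @export
vas_utility <- function(v, v_dead) {
  stopifnot(all(v >= 0 & v <= 100), all(v_dead >= 0 & v_dead <= 100))
  if (any(v_dead == 100))
    stop("v_dead = 100 leaves the rescaling undefined; exclude the block",
         call. = FALSE)
  ifelse(v_dead == 0, v / 100, (v - v_dead) / (100 - v_dead))
}

#' Utility of a health state from a standard-gamble record
#'
#' The utility is the indifference probability of restoration to full
#' health; states judged worse than 'being dead' are censored at utility 0.
#'
#' @param worse_than_dead Logical vector.
#' @param endpoint_p Indifference probabilities (NA where worse than dead).
#' @return Utility vector in `[0, 0.95]`.
#' @examples
#' sg_utility(FALSE, 0.60)   # 0.60
#' sg_utility(TRUE, NA)      # 0 (censored)
#' @export
sg_utility <- function(worse_than_dead, endpoint_p) {
  if (any(!worse_than_dead & is.na(endpoint_p)))
    stop("malformed record: endpoint_p missing for a state not judged ",
         "worse than dead", call. = FALSE)
  ifelse(worse_than_dead, 0, endpoint_p)
}

#' Disutility records from VAS responses
#'
#' Rescales every respondent's substantive ratings against their own rating
#' of 'being dead' (the third VAS) and returns disutilities
#' (`1 - utility`).  Respondents who rated 'being dead' at 100 are excluded
#' with a logged exclusion record.  Disutilities above 1 (states rated below
#' dead) are retained unclipped and flagged.
#'
#' @param vas Data frame with columns `respondent_id`, `state_id`, `value`.
#' @param registry A `"dw_registry"` or registry states data frame
#'   (identifies the 'being dead' rows).
#' @return Data frame with columns `respondent_id`, `state_id`,
#'   `disutility`, `source = "vas"`, `below_dead` (logical flag); excluded
#'   respondents are recorded in the `"exclusions"` attribute.
#' @export
vas_disutilities <- function(vas, registry) {
  states <- validate_registry(as_states(registry))
  dead <- anchor_ids(states)[["dead"]]
  stopifnot(all(vas$value >= 0 & vas$value <= 100))
  dead_rows <- vas$state_id == dead
  v_dead <- tapply(vas$value[dead_rows], vas$respondent_id[dead_rows], `[`, 1L)
  sub <- vas[!dead_rows, ]
  vd <- v_dead[as.character(sub$respondent_id)]
  if (any(is.na(vd)))
    stop("respondents without a 'being dead' rating: ",
         paste(utils::head(unique(sub$respondent_id[is.na(vd)]), 5L),
               collapse = ", "), call. = FALSE)
  excl <- vd == 100
  excl_ids <- unique(sub$respondent_id[excl])
  exclusions <- data.frame(respondent_id = excl_ids,
                           reason = rep("rated 'being dead' at 100",
                                        length(excl_ids)),
                           stringsAsFactors = FALSE)
  sub <- sub[!excl, ]; vd <- vd[!excl]
  u <- vas_utility(sub$value, vd)
  out <- data.frame(respondent_id = sub$respondent_id,
                    state_id = sub$state_id,
                    disutility = 1 - u, source = "vas",
                    below_dead = (1 - u) > 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "exclusions") <- exclusions
  out
}

#' Disutility records from SG responses
#'
#' @param sg Data frame with columns `respondent_id`, `state_id`,
#'   `worse_than_dead`, `endpoint_p`.
#' @return Data frame with columns `respondent_id`, `state_id`,
#'   `disutility`, `source = "sg"`.  Censored (worse-than-dead) records get
#'   disutility exactly 1; all others lie in `[0.05, 0.95]`.
#' @export
sg_disutilities <- function(sg) {
  u <- sg_utility(sg$worse_than_dead, sg$endpoint_p)
  data.frame(respondent_id = sg$respondent_id, state_id = sg$state_id,
             disutility = 1 - u, source = "sg",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-state disability weights from disutility records
#'
#' Linear regression of disutility on state dummies without intercept —
#' algebraically the per-state arithmetic mean — with 95% confidence
#' intervals from the pooled residual variance of the single fit.  States
#' with exactly one record are estimated but flagged (`single_record`);
#' when the pooled residual degrees of freedom are zero the CI is
#' undefined (NA) and flagged.
#'
#' @param records Disutility data frame from [vas_disutilities()] or
#'   [sg_disutilities()].
#' @param model_tag `"model3"` (VAS) or `"model4"` (SG).
#' @return A `"dw_estimates"` data frame: `state_id`, `dw`, `ci_lo`,
#'   `ci_hi`, `model_tag`, `n`, `flag`.
#' @export
estimate_state_dws <- function(records, model_tag = c("model3", "model4")) {
  model_tag <- match.arg(model_tag)
  stopifnot(nrow(records) >= 1)
  st <- factor(records$state_id)
  fit <- if (nlevels(st) > 1L) stats::lm(records$disutility ~ st - 1)
         else stats::lm(records$disutility ~ 1)
  dw <- stats::coef(fit)
  n_s <- as.integer(table(st))
  rdf <- fit$df.residual
  if (rdf > 0) {
    s2 <- sum(stats::residuals(fit)^2) / rdf
    se <- sqrt(s2 / n_s)
    tq <- stats::qt(0.975, rdf)
    lo <- dw - tq * se; hi <- dw + tq * se
  } else {
    lo <- hi <- rep(NA_real_, length(dw))
  }
  flag <- ifelse(n_s == 1L, "single_record", "")
  if (rdf == 0) flag <- paste0(flag, ifelse(flag == "", "", ";"), "ci_undefined")
  out <- data.frame(state_id = levels(st), dw = unname(dw),
                    ci_lo = unname(lo), ci_hi = unname(hi),
                    model_tag = model_tag, n = n_s, flag = flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dw_estimates", "data.frame")
  out
}

#' Disability weights from the VAS model (Model 3)
#' @param vas VAS response data frame.
#' @inheritParams vas_disutilities
#' @return A `"dw_estimates"` data frame with `model_tag = "model3"`.
#' @export
dw_model3 <- function(vas, registry) {
  estimate_state_dws(vas_disutilities(vas, registry), "model3")
}

#' Disability weights from the SG model (Model 4)
#' @param sg SG response data frame.
#' @return A `"dw_estimates"` data frame with `model_tag = "model4"`.
#' @export
dw_model4 <- function(sg) {
  estimate_state_dws(sg_disutilities(sg), "model4")
}

#' @export
print.dw_estimates <- function(x, n = 10L, ...) {
  tag <- unique(x$model_tag)
  cat("Disability-weight estimates (", paste(tag, collapse = ", "), "): ",
      nrow(x), " states\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 3)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}
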