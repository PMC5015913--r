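#' Build a health-state registry with latent true weights
#'
#' Creates the universe of health states used by the survey simulator and the
#' estimators: `n_substantive` substantive states plus the two anchor
#' pseudo-states, 'full health' and 'being dead'.  Each substantive state is
#' assigned a latent disability weight drawn uniformly from `d_range`; the
#' anchors are fixed at 0 (full health) and 1 (dead).  The latent weights are
#' the simulator's ground truth and play no role when fitting real data.
#'
#' @param n_substantive Number of substantive (non-anchor) health states;
#'   must be at least 1.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   registry and weights exactly.
#' @param d_range Length-2 numeric range the substantive latent weights are
#'   drawn from.  The default `c(0.02, 0.95)` keeps substantive states away
#'   from exact coincidence with the anchors.
#'
#' @return An object of class `"dw_registry"`: a list with
#'   \describe{
#'     \item{states}{data frame with columns `state_id`, `label`, `anchor`
#'       (one of `"none"`, `"full_health"`, `"dead"`).}
#'     \item{truth}{named numeric vector of latent disability weights, one
#'       per state, anchors exactly 0 and 1.}
#'   }
#' @examples
#' reg <- make_state_registry(5, seed = 1)
#' reg$states
#' reg$truth
#' @export
make_state_registry <- function(n_substantive, seed = NULL,
                                d_range = c(0.02, 0.95)) {
  if (!is.numeric(n_substantive) || length(n_substantive) != 1L ||
      is.na(n_substantive) || n_substantive < 1) {
    stop("`n_substantive` must be a single integer >= 1", call. = FALSE)
  }
  n_substantive <- as.integer(n_substantive)
  stopifnot(length(d_range) == 2L, d_range[1] >= 0, d_range[2] <= 1,
            d_range[1] <= d_range[2])
  if (!is.null(seed)) set.seed(seed)

  ids <- c("FH", sprintf("S%03d", seq_len(n_substantive)), "DEAD")
  labels <- c("Full health",
              sprintf("Health state %d", seq_len(n_substantive)),
              "Being dead")
  anchor <- c("full_health", rep("none", n_substantive), "dead")
  states <- data.frame(state_id = ids, label = labels, anchor = anchor,
                       stringsAsFactors = FALSE)

  d <- c(0, stats::runif(n_substantive, d_range[1], d_range[2]), 1)
  names(d) <- ids

  out <- list(states = states, truth = d)
  class(out) <- "dw_registry"
  validate_registry(out$states)
  out
}

#' Validate a state registry table
#'
#' Checks the invariants every registry must satisfy: unique state ids,
#' exactly one 'full health' anchor, exactly one 'being dead' anchor, and at
#' least one substantive state.
#'
#' @param states Data frame with columns `state_id` and `anchor`.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(states) {
  if (!is.data.frame(states) || !all(c("state_id", "anchor") %in% names(states)))
    stop("registry must be a data frame with columns 'state_id' and 'anchor'",
         call. = FALSE)
  if (anyDuplicated(states$state_id))
    stop("registry state_id values must be unique", call. = FALSE)
  if (sum(states$anchor == "full_health") != 1L)
    stop("registry must contain exactly one full-health anchor state",
         call. = FALSE)
  if (sum(states$anchor == "dead") != 1L)
    stop("registry must contain exactly one dead anchor state", call. = FALSE)
  if (nrow(states) < 3L)
    stop("registry must contain at least one substantive state", call. = FALSE)
  invisible(states)
}

# state ids of the two anchors, named full_health / dead
anchor_ids <- function(states) {
  c(full_health = states$state_id[states$anchor == "full_health"],
    dead        = states$state_id[states$anchor == "dead"])
}

substantive_ids <- function(states) {
  states$state_id[states$anchor == "none"]
}

# accept either a dw_registry or a bare states data frame
as_states <- function(registry) {
  if (inherits(registry, "dw_registry")) registry$states else registry
}

#' @export
print.dw_registry <- function(x, ...) {
  ns <- sum(x$states$anchor == "none")
  cat("Health-state registry:", nrow(x$states), "states (",
      ns, "substantive + 2 anchors )\n")
  cat("Latent weight range over substantive states: [",
      format(min(x$truth[x$states$anchor == "none"]), digits = 3), ", ",
      format(max(x$truth[x$states$anchor == "none"]), digits = 3), "]\n",
      sep = "")
  invisible(x)
}
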