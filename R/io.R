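# Long-format CSV input/output for response and estimate tables, with
# schema validation that reports offending line numbers.

.check_cols <- function(x, need, path) {
  if (!all(need %in% names(x)))
    stop("'", path, "' must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
}

# data line numbers (header is line 1)
.rows_msg <- function(rows) paste(utils::head(rows + 1L, 5L), collapse = ", ")

#' Read paired-comparison responses from CSV
#'
#' Validates the schema (`respondent_id`, `state_a`, `state_b`,
#' `chose_a_healthier`), rejects self-comparisons and, when a registry is
#' given, unknown state ids — reporting file line numbers.
#'
#' @param path CSV path.
#' @param registry Optional registry for state-id validation.
#' @return Paired-comparison response data frame.
#' @export
read_pc_responses <- function(path, registry = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(x, c("respondent_id", "state_a", "state_b", "chose_a_healthier"),
              path)
  x$chose_a_healthier <- as.logical(x$chose_a_healthier)
  bad <- which(x$state_a == x$state_b)
  if (length(bad))
    stop("state_a equals state_b at line(s) ", .rows_msg(bad), call. = FALSE)
  if (!is.null(registry)) {
    states <- as_states(registry)$state_id
    bad <- which(!(x$state_a %in% states) | !(x$state_b %in% states))
    if (length(bad))
      stop("unknown state id at line(s) ", .rows_msg(bad), call. = FALSE)
  }
  x
}

#' Read VAS responses from CSV
#'
#' Validates the schema (`respondent_id`, `state_id`, `value`), the 0--100
#' range, and uniqueness of (respondent, state) keys.
#'
#' @inheritParams read_pc_responses
#' @return VAS response data frame.
#' @export
read_vas_responses <- function(path, registry = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(x, c("respondent_id", "state_id", "value"), path)
  bad <- which(is.na(x$value) | x$value < 0 | x$value > 100)
  if (length(bad))
    stop("VAS value outside [0, 100] at line(s) ", .rows_msg(bad),
         call. = FALSE)
  bad <- which(duplicated(x[c("respondent_id", "state_id")]))
  if (length(bad))
    stop("duplicate (respondent, state) key at line(s) ", .rows_msg(bad),
         call. = FALSE)
  if (!is.null(registry)) {
    states <- as_states(registry)$state_id
    bad <- which(!(x$state_id %in% states))
    if (length(bad))
      stop("unknown state id at line(s) ", .rows_msg(bad), call. = FALSE)
  }
  x
}

#' Read standard-gamble records from CSV
#'
#' Validates the schema (`respondent_id`, `state_id`, `worse_than_dead`,
#' `endpoint_p`) and that endpoints lie on the 5% grid and are absent
#' exactly when the state was judged worse than dead.
#'
#' @inheritParams read_pc_responses
#' @return SG record data frame.
#' @export
read_sg_responses <- function(path, registry = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(x, c("respondent_id", "state_id", "worse_than_dead",
                   "endpoint_p"), path)
  x$worse_than_dead <- as.logical(x$worse_than_dead)
  grid <- seq(0.05, 0.95, by = 0.05)
  on_grid <- !is.na(x$endpoint_p) &
    vapply(x$endpoint_p, function(p) any(abs(grid - p) < 1e-9), logical(1))
  bad <- which((!x$worse_than_dead & !on_grid) |
                 (x$worse_than_dead & !is.na(x$endpoint_p)))
  if (length(bad))
    stop("inconsistent SG record at line(s) ", .rows_msg(bad), call. = FALSE)
  if (!is.null(registry)) {
    states <- as_states(registry)$state_id
    bad <- which(!(x$state_id %in% states))
    if (length(bad))
      stop("unknown state id at line(s) ", .rows_msg(bad), call. = FALSE)
  }
  x
}

#' Read ladder (PHE) records from CSV
#'
#' Validates the schema (`respondent_id`, `state_id`, `trace`,
#' `bracket_lo`, `bracket_hi`) and the consistency of every serialized
#' ladder walk with its final bracket.
#'
#' @inheritParams read_pc_responses
#' @return PHE record data frame (`bracket_lo` / `bracket_hi` numeric with
#'   `-Inf` / `Inf` for open-ended brackets).
#' @export
read_phe_responses <- function(path, registry = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(x, c("respondent_id", "state_id", "trace", "bracket_lo",
                   "bracket_hi"), path)
  x$bracket_lo <- as.numeric(x$bracket_lo)
  x$bracket_hi <- as.numeric(x$bracket_hi)
  ok <- mapply(.phe_trace_consistent, x$trace, x$bracket_lo, x$bracket_hi)
  if (any(!ok))
    stop("malformed ladder trace at line(s) ", .rows_msg(which(!ok)),
         call. = FALSE)
  if (!is.null(registry)) {
    states <- as_states(registry)$state_id
    bad <- which(!(x$state_id %in% states))
    if (length(bad))
      stop("unknown state id at line(s) ", .rows_msg(bad), call. = FALSE)
  }
  x
}

#' Write disability-weight estimates to CSV
#'
#' Layout: one row per state with the weight, the 95% interval and the
#' model tag.
#'
#' @param est A `"dw_estimates"` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dw_estimates <- function(est, path) {
  stopifnot(all(c("state_id", "dw", "ci_lo", "ci_hi", "model_tag") %in%
                  names(est)))
  utils::write.csv(est[c("state_id", "dw", "ci_lo", "ci_hi", "model_tag")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read disability-weight estimates from CSV
#' @param path CSV path.
#' @return A `"dw_estimates"` data frame.
#' @export
read_dw_estimates <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(x, c("state_id", "dw", "ci_lo", "ci_hi", "model_tag"), path)
  bad <- which(!is.na(x$ci_lo) & !is.na(x$ci_hi) &
                 !(x$ci_lo <= x$dw & x$dw <= x$ci_hi))
  if (length(bad))
    stop("confidence bounds do not bracket the estimate at line(s) ",
         .rows_msg(bad), call. = FALSE)
  class(x) <- c("dw_estimates", "data.frame")
  x
}

#' Write a simulated survey to CSV files plus a manifest
#'
#' Writes `pc.csv`, `vas.csv`, `sg.csv`, `phe.csv` and `manifest.json`
#' (the simulation configuration, including the seed, and the row counts)
#' into `dir`.
#'
#' @param survey List from [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("pc", "vas", "sg", "phe"))
    utils::write.csv(survey[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  manifest <- c(unclass(survey$config),
                list(rows = lapply(survey[c("pc", "vas", "sg", "phe")], nrow)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a simulated survey back from a directory
#' @param dir Directory written by [write_survey()].
#' @param registry Optional registry for validation.
#' @return List with `pc`, `vas`, `sg`, `phe`.
#' @export
read_survey <- function(dir, registry = NULL) {
  list(pc  = read_pc_responses(file.path(dir, "pc.csv"), registry),
       vas = read_vas_responses(file.path(dir, "vas.csv"), registry),
       sg  = read_sg_responses(file.path(dir, "sg.csv"), registry),
       phe = read_phe_responses(file.path(dir, "phe.csv"), registry))
}
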