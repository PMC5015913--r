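# Model-comparison layer: correlations against a reference set, severity
# bin distributions, extremes, and the utility comparison.

#' Pearson correlation between two disability-weight vectors
#'
#' Pairs the two vectors on `state_id` (or on position when unnamed),
#' drops pairs with a missing value, and returns the product-moment
#' correlation together with the number of pairs used.
#'
#' @param x,y Numeric vectors, optionally named by state id.
#' @return List with `r` and `n`.
#' @export
dw_pearson <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (length(x) != length(y))
    stop("vectors must be paired (equal length or matching names)",
         call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  list(r = stats::cor(x, y), n = length(x))
}

#' Decile distribution of disability weights
#'
#' Counts weights into half-open bins `[lo, hi)` on the given edge grid,
#' the final bin closed on the right.  Values outside the grid are counted
#' in an overflow bucket with a warning, never silently dropped.
#'
#' @param dws Numeric vector of disability weights.
#' @param edges Increasing bin edges (default the 0.1 decile grid).
#' @return Data frame of class `"dw_bins"` with columns `bin`, `lo`, `hi`,
#'   `n`, `pct` (percentages rounded to 1 decimal); the overflow count is
#'   in the `"overflow"` attribute.
#' @export
dw_bin_distribution <- function(dws, edges = seq(0, 1, by = 0.1)) {
  stopifnot(length(dws) >= 1, length(edges) >= 2, !is.unsorted(edges))
  dws <- dws[!is.na(dws)]
  k <- length(edges) - 1L
  lo <- edges[-length(edges)]; hi <- edges[-1]
  idx <- findInterval(dws, edges, rightmost.closed = TRUE)
  over <- sum(idx < 1L | idx > k)
  if (over > 0)
    warning(over, " value(s) outside [", edges[1], ", ", edges[length(edges)],
            "] counted in the overflow bucket", call. = FALSE)
  n <- tabulate(idx[idx >= 1L & idx <= k], nbins = k)
  out <- data.frame(bin = sprintf("%.1f-%.1f", lo, hi), lo = lo, hi = hi,
                    n = n, pct = round(100 * n / length(dws), 1),
                    stringsAsFactors = FALSE)
  attr(out, "overflow") <- over
  class(out) <- c("dw_bins", "data.frame")
  out
}

#' Compare disability weights with external utility weights
#'
#' Computes the Pearson correlation between `1 - dw` and externally supplied
#' utilities over their common states and returns the paired scatter table.
#' The utilities are user input (for instance a national EQ-5D-5L tariff);
#' the package ships none.
#'
#' @param dws Named disability-weight vector or a `"dw_estimates"` frame.
#' @param utilities Named numeric vector of utility weights.
#' @return List with `r`, `n` and `table` (columns `state_id`,
#'   `one_minus_dw`, `utility`).
#' @export
compare_vs_utilities <- function(dws, utilities) {
  if (inherits(dws, "dw_estimates") || is.data.frame(dws))
    dws <- stats::setNames(dws$dw, dws$state_id)
  common <- intersect(names(dws), names(utilities))
  if (length(common) < 3L)
    stop("need at least 3 common states", call. = FALSE)
  tab <- data.frame(state_id = common,
                    one_minus_dw = 1 - unname(dws[common]),
                    utility = unname(utilities[common]),
                    stringsAsFactors = FALSE)
  r <- dw_pearson(stats::setNames(tab$one_minus_dw, tab$state_id),
                  stats::setNames(tab$utility, tab$state_id))
  list(r = r$r, n = r$n, table = tab)
}

#' Extremes and ranking of disability weights
#'
#' @param dws Named disability-weight vector or a `"dw_estimates"` frame.
#' @return List with `max` / `min` (values), `max_states` / `min_states`
#'   (tied argmax/argmin as character sets) and `ranked` (data frame sorted
#'   by decreasing weight).
#' @export
extremes_report <- function(dws) {
  if (inherits(dws, "dw_estimates") || is.data.frame(dws))
    dws <- stats::setNames(dws$dw, dws$state_id)
  dws <- dws[!is.na(dws)]
  stopifnot(length(dws) >= 1)
  ranked <- data.frame(state_id = names(dws), dw = unname(dws),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$dw), ]
  rownames(ranked) <- NULL
  list(max = max(dws), max_states = names(dws)[dws == max(dws)],
       min = min(dws), min_states = names(dws)[dws == min(dws)],
       ranked = ranked)
}

# md5 of the packaged reference table, frozen at transcription time
.reference_table_md5 <- "574b0077c2e763ed29f6236d0228c9ea"

#' Load the packaged reference disability-weight table
#'
#' The packaged table transcribes published per-state disability weights:
#' 256 substantive health states with the four model columns, 220 of them
#' carrying a reference (GBD 2010) weight.  The file checksum is verified
#' on load.
#'
#' @param path Path to a reference table TSV; defaults to the packaged one.
#' @param check Verify row counts and (for the packaged file) the checksum.
#' @return Data frame with columns `label`, `gbd2010`, `model1` ..
#'   `model4`.
#' @export
read_reference_table <- function(path = NULL, check = TRUE) {
  packaged <- is.null(path)
  if (packaged)
    path <- system.file("extdata", "reference_disability_weights.tsv",
                        package = "dwpaired", mustWork = TRUE)
  if (check && packaged &&
      unname(tools::md5sum(path)) != .reference_table_md5)
    stop("packaged reference table failed its checksum", call. = FALSE)
  x <- utils::read.delim(path, header = TRUE, na.strings = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", "gbd2010", paste0("model", 1:4))
  if (!all(need %in% names(x)))
    stop("reference table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (check && packaged && !(nrow(x) == 256L && sum(!is.na(x$gbd2010)) == 220L))
    stop("packaged reference table must have 256 rows, 220 with a gbd2010 ",
         "value", call. = FALSE)
  x
}

#' Model-comparison report over a reference table
#'
#' Recomputes the evaluation layer from a reference table: Pearson
#' correlation of each model column with the reference column over the
#' states carrying a reference value, the decile distribution of each
#' column over those states, the share of states below 0.4, and the
#' extremes of the paired-comparison-only model over all states.
#'
#' @param ref Reference table from [read_reference_table()].
#' @return List of class `"dw_evaluation"` with `correlations`,
#'   `bins`, `below_04`, `extremes_model1`, `n_reference`.
#' @export
evaluate_dw_table <- function(ref = read_reference_table()) {
  models <- paste0("model", 1:4)
  g <- ref[!is.na(ref$gbd2010), ]
  correlations <- vapply(models, function(m)
    dw_pearson(g$gbd2010, g[[m]])$r, numeric(1))
  cols <- c("gbd2010", models)
  bins <- lapply(stats::setNames(cols, cols), function(m)
    dw_bin_distribution(g[[m]]))
  below_04 <- vapply(stats::setNames(cols, cols), function(m) {
    b <- bins[[m]]
    sum(b$n[b$hi <= 0.4 + 1e-9]) / sum(b$n) * 100
  }, numeric(1))
  ext <- extremes_report(stats::setNames(ref$model1, ref$label))
  out <- list(correlations = correlations, bins = bins,
              below_04 = below_04, extremes_model1 = ext,
              n_reference = nrow(g))
  class(out) <- "dw_evaluation"
  out
}

#' @export
print.dw_evaluation <- function(x, ...) {
  cat("Model comparison over", x$n_reference, "reference states\n\n")
  cat("Pearson correlation with the reference weights:\n")
  print(round(x$correlations, 3))
  cat("\nShare of states below DW 0.4 (%):\n")
  print(round(x$below_04, 1))
  cat("\nModel 1 extremes: max", format(x$extremes_model1$max, digits = 3),
      "(", paste(x$extremes_model1$max_states, collapse = "; "), ")\n")
  cat("                  min", format(x$extremes_model1$min, digits = 3),
      "(", paste(x$extremes_model1$min_states, collapse = "; "), ")\n")
  invisible(x)
}
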