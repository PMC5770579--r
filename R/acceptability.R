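#' Round half away from zero
#'
#' Display rounding used for Likert summaries: 4.45 rounds to 4.5 (base R's
#' `round` rounds half to even). Full precision is retained internally;
#' rounding is applied only at the reporting boundary.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

validate_likert <- function(responses) {
  req <- c("respondent", "item", "rating")
  if (!is.data.frame(responses) || !all(req %in% names(responses))) {
    stop("Likert responses need columns: ", paste(req, collapse = ", "))
  }
  if (any(is.na(responses$rating)) ||
      any(responses$rating < 1 | responses$rating > 5) ||
      any(responses$rating != as.integer(responses$rating))) {
    stop("ratings must be integers in 1..5")
  }
  key <- paste(responses$respondent, responses$item)
  if (anyDuplicated(key)) {
    stop("duplicate rating for (respondent, item): ", key[duplicated(key)][1])
  }
  invisible(responses)
}

#' Per-item Likert summaries
#'
#' Computes each item's n, mean, and sample standard deviation (n-1
#' denominator). Items are reported in declared order (`item_order`) when
#' given, otherwise in order of first appearance. A single-response item has
#' undefined SD; it is reported as 0 with `sd_undefined = TRUE`.
#'
#' @param responses Long-format data.frame with columns `respondent`,
#'   `item`, `rating` (integers 1..5).
#' @param item_order Optional character vector fixing item order (also the
#'   tie-break order for [extreme_items()]).
#' @return Data.frame: `item`, `n`, `mean`, `sd`, `sd_undefined`, plus
#'   display columns `mean_display`, `sd_display` rounded half-up to one
#'   decimal.
#' @export
item_summaries <- function(responses, item_order = NULL) {
  validate_likert(responses)
  if (nrow(responses) == 0) stop("no responses")
  items <- if (is.null(item_order)) unique(responses$item) else item_order
  missing <- setdiff(items, responses$item)
  if (length(missing) > 0) stop("no responses for item(s): ", paste(missing, collapse = ", "))
  out <- lapply(items, function(it) {
    r <- responses$rating[responses$item == it]
    n <- length(r)
    m <- mean(r)
    s <- if (n > 1) stats::sd(r) else 0
    data.frame(item = it, n = n, mean = m, sd = s, sd_undefined = n == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$mean_display <- round_half_up(out$mean, 1)
  out$sd_display <- round_half_up(out$sd, 1)
  out
}

#' Overall acceptability across items
#'
#' The study convention: the overall rating is the unweighted mean of the
#' item means, its spread the sample SD of the item means, both reported to
#' one decimal. The verdict passes when the reported overall mean meets the
#' benchmark.
#'
#' @param items Either a data.frame from [item_summaries()] (or any frame
#'   with a `mean` column) or a bare numeric vector of item means.
#' @param benchmark Acceptability benchmark; default 4.0.
#' @return An object of class `acceptability_summary` with full-precision
#'   `overall_mean` / `overall_sd`, one-decimal `mean_display` /
#'   `sd_display`, the `benchmark`, and the logical `verdict`.
#' @export
overall_acceptability <- function(items, benchmark = 4.0) {
  means <- if (is.data.frame(items)) items$mean else as.numeric(items)
  if (length(means) == 0) stop("empty item list")
  if (any(is.na(means)) || any(means < 1 | means > 5)) {
    stop("item means must lie in 1..5")
  }
  m <- mean(means)
  s <- if (length(means) > 1) stats::sd(means) else 0
  md <- round_half_up(m, 1)
  sd_ <- round_half_up(s, 1)
  structure(list(n_items = length(means),
                 overall_mean = m, overall_sd = s,
                 mean_display = md, sd_display = sd_,
                 benchmark = benchmark,
                 verdict = md >= benchmark),
            class = "acceptability_summary")
}

#' @export
print.acceptability_summary <- function(x, ...) {
  cat(sprintf("<acceptability_summary> overall %.1f (SD %.1f) across %d items: %s benchmark %.1f\n",
              x$mean_display, x$sd_display, x$n_items,
              if (x$verdict) "meets" else "below", x$benchmark))
  invisible(x)
}

#' Lowest- and highest-rated items
#'
#' @param items Data.frame from [item_summaries()]; row order is the
#'   declared item order and breaks ties.
#' @return List with `min` and `max`, each a one-row data.frame.
#' @export
extreme_items <- function(items) {
  if (!is.data.frame(items) || nrow(items) == 0) stop("empty item list")
  list(min = items[which.min(items$mean), , drop = FALSE],
       max = items[which.max(items$mean), , drop = FALSE])
}

#' Read Likert responses from CSV
#'
#' Long format: `respondent, instrument, item, rating`.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_likert_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_likert(df)
  df
}
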