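# Deterministic lexicographic search for a response pattern achieving an
# exact target score. The pattern must be skip-consistent: a "never in the
# past 3 months" answer on item 2 removes items 3-5 from the branch.
find_response_pattern <- function(target, substance, config = assist_config()) {
  target <- as.integer(target)
  if (target < 0 || target > config$score_max) {
    stop("unachievable target score ", target, " (range 0..", config$score_max, ")")
  }
  items_all <- setdiff(branch_items(substance, config), 1L)

  item_codes <- function(i, drop_zero = FALSE) {
    it <- config$items[[as.character(i)]]
    keep <- if (drop_zero) it$codes != 0 else rep(TRUE, length(it$codes))
    list(codes = it$codes[keep], weights = it$weights[keep])
  }

  search <- function(items, item2_nonzero = FALSE) {
    cw <- lapply(items, function(i) item_codes(i, drop_zero = item2_nonzero && i == 2L))
    weights <- lapply(cw, `[[`, "weights")
    codes <- lapply(cw, `[[`, "codes")
    max_tail <- rev(cumsum(rev(vapply(weights, max, numeric(1)))))
    pick <- integer(0)
    dfs <- function(k, remaining) {
      if (k > length(items)) return(if (remaining == 0L) pick else NULL)
      tail_max <- if (k < length(items)) max_tail[k + 1] else 0
      for (ci in seq_along(codes[[k]])) {
        w <- weights[[k]][ci]
        if (w > remaining || remaining - w > tail_max) next
        pick[k] <<- codes[[k]][ci]
        hit <- dfs(k + 1L, remaining - as.integer(w))
        if (!is.null(hit)) return(hit)
      }
      NULL
    }
    res <- dfs(1L, target)
    if (is.null(res)) NULL else stats::setNames(res, items)
  }

  # Two skip-consistent branches: item 2 = "never" (items 3-5 skipped) or
  # item 2 > 0 (full item set). Try the reduced branch first -- it is the
  # lexicographically smaller item-2 answer -- then the full branch.
  reduced <- setdiff(items_all, config$skip$recent_never_skips)
  res <- search(reduced)  # item 2 = 0 sits in this branch naturally
  if (!is.null(res) && res[["2"]] == 0L) return(res)
  res <- search(items_all, item2_nonzero = TRUE)
  if (is.null(res)) stop("unachievable target score ", target, " for ", substance)
  res
}

stage_to_answers <- function(stage, reference_date) {
  reference_date <- as.Date(reference_date)
  switch(stage,
    precontemplation = staging_answers(FALSE, intention_window = "none_6mo",
                                       reference_date = reference_date),
    contemplation = staging_answers(FALSE, intention_window = "within_6mo",
                                    reference_date = reference_date),
    preparation = staging_answers(FALSE, intention_window = "within_30d",
                                  reference_date = reference_date),
    action = staging_answers(TRUE, change_date = reference_date - 61,
                             reference_date = reference_date),
    maintenance = staging_answers(TRUE, change_date = reference_date - 244,
                                  reference_date = reference_date),
    stop("unknown stage: ", stage))
}

#' Simulate a patient
#'
#' Generates a screening interview whose substance scores hit the profile's
#' targets exactly (found by deterministic lexicographic search over the
#' weight table, so the result is reproducible by construction), plus staging
#' answers realizing the profile's stages. Substances absent from the profile
#' are "never used".
#'
#' @param profile List with `scores` (named integer vector of target scores),
#'   `quit_stage`, optional `treatment_stage`, and optional `reference_date`
#'   (default 2017-06-01, fixed for reproducibility).
#' @param config An `assist_config`.
#' @param seed Integer; kept in the signature for interface stability --
#'   pattern search is deterministic and ignores it.
#' @return List with `interview` (an `assist_interview`), `quit_answers`,
#'   and `treatment_answers` (`NULL` unless the profile stages treatment).
#' @export
simulate_patient <- function(profile, config = assist_config(), seed = 1L) {
  ref <- if (is.null(profile$reference_date)) as.Date("2017-06-01")
         else as.Date(profile$reference_date)
  rows <- list()
  for (sub in config$substances) {
    tgt <- if (sub %in% names(profile$scores)) profile$scores[[sub]] else NA
    if (is.na(tgt)) {
      rows[[sub]] <- data.frame(substance = sub, item = 1L, code = 0L)
      next
    }
    pat <- find_response_pattern(tgt, sub, config)
    rows[[sub]] <- data.frame(
      substance = sub,
      item = c(1L, as.integer(names(pat))),
      code = c(1L, unname(pat)))
  }
  interview <- assist_interview(do.call(rbind, rows), config)
  list(
    interview = interview,
    quit_answers = stage_to_answers(profile$quit_stage, ref),
    treatment_answers = if (!is.null(profile$treatment_stage)) {
      stage_to_answers(profile$treatment_stage, ref)
    } else NULL
  )
}

#' The four-patient pilot fixture
#'
#' Four synthetic patients matching the pilot cohort's printed profile:
#' target-drug scores 21 and 30 on opioids and 27 and 29 on cocaine; quit
#' stages contemplation (x2), action, and maintenance; three of the four are
#' polysubstance users. Non-target substance scores are synthetic (never
#' printed) and chosen below the target-drug score so the target assignment
#' is stable. High scorers carry treatment staging answers (contemplation),
#' also synthetic.
#'
#' @param config An `assist_config`.
#' @return List of 4 patients, each with `name`, `dob` (synthetic),
#'   `profile`, `interview`, `quit_answers`, `treatment_answers`, and
#'   `polysubstance`.
#' @export
pilot_fixture <- function(config = assist_config()) {
  profiles <- list(
    list(name = "Alex Stone", dob = "1975-03-02",
         scores = c(opioids = 21L, cannabis = 10L),
         quit_stage = "contemplation", treatment_stage = NULL,
         polysubstance = TRUE),
    list(name = "Blake Reyes", dob = "1980-11-17",
         scores = c(opioids = 30L, cocaine = 14L),
         quit_stage = "maintenance", treatment_stage = "contemplation",
         polysubstance = TRUE),
    list(name = "Casey Moor", dob = "1969-07-23",
         scores = c(cocaine = 27L, cannabis = 13L),
         quit_stage = "action", treatment_stage = "contemplation",
         polysubstance = TRUE),
    list(name = "Drew Hale", dob = "1988-01-30",
         scores = c(cocaine = 29L),
         quit_stage = "contemplation", treatment_stage = "contemplation",
         polysubstance = FALSE)
  )
  lapply(profiles, function(p) {
    sim <- simulate_patient(p, config)
    c(list(name = p$name, dob = p$dob, profile = p,
           polysubstance = p$polysubstance), sim)
  })
}

#' Simulate Likert survey responses
#'
#' Produces integer ratings (1..5) whose per-item means land within `1/(2n)`
#' of the targets: each item's rating total is the target mean times `n`
#' rounded to the nearest integer, split as evenly as possible across
#' respondents. The assignment of ratings to respondents is shuffled with the
#' seed; the summaries are seed-invariant.
#'
#' @param item_ids Character vector of item identifiers.
#' @param target_means Numeric vector of target means in 1..5 (recycled
#'   against `item_ids` must match in length).
#' @param n Number of respondents (>= 1).
#' @param seed Integer seed.
#' @param instrument Instrument identifier stored with each row.
#' @return Long-format data.frame `respondent`, `instrument`, `item`,
#'   `rating`.
#' @export
simulate_likert <- function(item_ids, target_means, n, seed = 1L,
                            instrument = "survey") {
  stopifnot(length(item_ids) == length(target_means), n >= 1)
  if (any(target_means < 1 | target_means > 5)) {
    stop("unachievable mean: targets must lie in 1..5")
  }
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  out <- list()
  for (i in seq_along(item_ids)) {
    total <- round(target_means[i] * n)
    total <- min(max(total, n), 5L * n)
    base <- total %/% n
    rem <- total %% n
    ratings <- c(rep(base + 1L, rem), rep(base, n - rem))
    ratings <- ratings[sample.int(length(ratings))]  # avoids sample(<scalar>)
    out[[i]] <- data.frame(respondent = paste0("r", seq_len(n)),
                           instrument = instrument,
                           item = item_ids[i], rating = as.integer(ratings),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
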