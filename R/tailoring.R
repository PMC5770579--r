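#' Tailoring configuration
#'
#' Decision rules for the computer-tailored session: the expert harm ranking
#' used as a tie-breaker when two substances score equally, the set of
#' substances eligible for targeting (tobacco and alcohol are excluded by
#' default because the intervention addresses risky drug use), the treatment
#' cutpoint, the stage-to-change-process mapping (exactly 3 modules per
#' stage and purpose), and the stage-matched goal menus.
#'
#' @param path Path to a configuration JSON document; defaults to the
#'   bundled rules.
#' @return An object of class `tailoring_config`.
#' @export
tailoring_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tailoring_config.json", package = "sbirtcti")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranking <- cfg$drug_ranking
  if (anyDuplicated(ranking)) stop("drug ranking must be a total order")
  if (match("opioids", ranking) > match("cannabis", ranking)) {
    stop("drug ranking must place opioids above cannabis")
  }
  for (purpose in c("quit", "seek_treatment")) {
    for (stage in ttm_stages()) {
      mods <- cfg$stage_modules[[purpose]][[stage]]
      if (length(mods) != 3) {
        stop(sprintf("stage_modules[%s][%s] must name exactly 3 modules", purpose, stage))
      }
      if (length(cfg$goal_menus[[purpose]][[stage]]) < 1) {
        stop(sprintf("goal_menus[%s][%s] must offer at least one goal", purpose, stage))
      }
    }
  }
  structure(cfg, class = "tailoring_config")
}

#' The five stages of change
#'
#' @return Character vector of the transtheoretical-model stages in order of
#'   increasing readiness.
#' @export
ttm_stages <- function() {
  c("precontemplation", "contemplation", "preparation", "action", "maintenance")
}

#' Staging answers
#'
#' The raw inputs to stage classification: whether the behavior change has
#' already been made (and when), and otherwise the intention window.
#'
#' @param behavior_changed Logical; has the patient already made the change?
#' @param change_date Date of the change; required iff `behavior_changed`.
#' @param intention_window One of `"none_6mo"` (no intention in the next 6
#'   months), `"within_6mo"`, `"within_30d"`. Ignored when the change has
#'   been made.
#' @param reference_date Date the questions were answered.
#' @return An object of class `staging_answers`.
#' @export
staging_answers <- function(behavior_changed = FALSE, change_date = NULL,
                            intention_window = "none_6mo",
                            reference_date = Sys.Date()) {
  reference_date <- as.Date(reference_date)
  if (behavior_changed) {
    if (is.null(change_date)) stop("change_date required when behavior_changed")
    change_date <- as.Date(change_date)
  } else {
    change_date <- as.Date(NA)
    intention_window <- match.arg(intention_window,
                                  c("none_6mo", "within_6mo", "within_30d"))
  }
  structure(list(behavior_changed = isTRUE(behavior_changed),
                 change_date = change_date,
                 intention_window = intention_window,
                 reference_date = reference_date),
            class = "staging_answers")
}

#' Classify stage of change
#'
#' Maps staging answers to one of the five stages: a change made less than 6
#' months before the reference date is action and one made 6 or more months
#' ago is maintenance (6 months is taken as 183 days, with "less than"
#' strict); otherwise intention within 30 days is preparation, within 6
#' months contemplation, and none is precontemplation.
#'
#' @param answers A `staging_answers` object.
#' @param config A `tailoring_config` (carries the 183-day convention).
#' @return One stage name (see [ttm_stages()]).
#' @export
stage_from_answers <- function(answers, config = tailoring_config()) {
  stopifnot(inherits(answers, "staging_answers"))
  if (answers$behavior_changed) {
    days <- as.integer(answers$reference_date - answers$change_date)
    if (days < 0) stop("change_date is after reference_date")
    if (days < config$six_month_days) return("action")
    return("maintenance")
  }
  switch(answers$intention_window,
         within_30d = "preparation",
         within_6mo = "contemplation",
         none_6mo = "precontemplation")
}

#' Select the most problematic drug
#'
#' Returns the eligible substance with the highest involvement score,
#' breaking ties by the configured expert harm ranking (opioids at the top,
#' cannabis at the bottom). Low-risk patients are screened out: if no
#' eligible substance reaches the moderate range the result is
#' `NA_character_`.
#'
#' @param scores Named integer vector of substance scores, or a data.frame
#'   with columns `substance` and `score`.
#' @param ranking Character vector, highest harm first. Defaults to the
#'   configured ranking.
#' @param eligible Substances considered for targeting.
#' @param moderate_min Minimum score for moderate risk (default 4).
#' @param config A `tailoring_config` supplying defaults.
#' @return A substance identifier or `NA_character_`.
#' @export
select_target_drug <- function(scores, ranking = NULL, eligible = NULL,
                               moderate_min = 4L, config = tailoring_config()) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$substance)
  }
  if (is.null(ranking)) ranking <- config$drug_ranking
  if (is.null(eligible)) eligible <- config$eligible_substances
  if (length(eligible) == 0) stop("eligible substance set is empty")
  missing <- setdiff(eligible, names(scores))
  if (length(missing) > 0) {
    stop("scores missing for eligible substance(s): ", paste(missing, collapse = ", "))
  }
  s <- scores[eligible]
  if (max(s) < moderate_min) return(NA_character_)
  top <- names(s)[s == max(s)]
  top[which.min(match(top, ranking))]
}

#' Assign the intervention track
#'
#' @param target_category Risk category of the target drug (`"none"`,
#'   `"low"`, `"moderate"`, or `"high"`).
#' @return `"screened_out"`, `"moderate"`, or `"high"`.
#' @export
assign_track <- function(target_category) {
  switch(match.arg(target_category, c("none", "low", "moderate", "high")),
         none = "screened_out", low = "screened_out",
         moderate = "moderate", high = "high")
}

#' Stage-matched change-process modules
#'
#' Each stage maps to exactly 3 key processes and principles of change for
#' the given purpose (quitting the target drug, or seeking treatment).
#'
#' @param stage A stage name.
#' @param purpose `"quit"` or `"seek_treatment"`.
#' @param config A `tailoring_config`.
#' @return Character vector of exactly 3 module identifiers.
#' @export
select_stage_modules <- function(stage, purpose = c("quit", "seek_treatment"),
                                 config = tailoring_config()) {
  purpose <- match.arg(purpose)
  stage <- match.arg(stage, ttm_stages())
  mods <- config$stage_modules[[purpose]][[stage]]
  if (is.null(mods)) stop("no module mapping for (", stage, ", ", purpose, ")")
  mods
}

goal_menu <- function(stage, purpose, config) {
  config$goal_menus[[purpose]][[stage]]
}

#' Build a tailored session
#'
#' Executes the five-step session flow: (1) score the full screening
#' interview and build the per-substance risk chart; (2) select the most
#' problematic drug and assign the intervention track, screening out
#' low-risk patients; (3) assemble the drug-specific risk-education payload;
#' (4) stage the patient for quitting the target drug and attach the
#' stage-matched modules and goal menu; (5) if the target-drug score is at
#' or above the treatment cutpoint (27), stage the patient for seeking
#' treatment and attach that branch. Screened-out sessions carry only the
#' risk chart.
#'
#' @param interview A complete `assist_interview`.
#' @param quit_answers `staging_answers` for quitting the target drug.
#' @param treatment_answers `staging_answers` for seeking treatment;
#'   required iff the target-drug score reaches the cutpoint.
#' @param patient Optional list with `name` and `dob` used for dashboard
#'   lookup.
#' @param config A `tailoring_config`.
#' @param assist_cfg An `assist_config`.
#' @return An object of class `tailored_session`.
#' @export
build_session <- function(interview, quit_answers = NULL,
                          treatment_answers = NULL, patient = NULL,
                          config = tailoring_config(),
                          assist_cfg = assist_config()) {
  chart <- risk_chart(interview, assist_cfg)
  scores <- stats::setNames(chart$score, chart$substance)
  target <- select_target_drug(scores, config = config)

  session <- structure(list(
    patient = patient,
    chart = chart,
    target_drug = target,
    track = "screened_out",
    target_score = NA_integer_,
    target_category = NA_character_,
    education = NULL,
    quit_stage = NULL, quit_modules = NULL, goal_menu = NULL, goal_plan = NULL,
    treatment_stage = NULL, treatment_modules = NULL,
    treatment_goal_menu = NULL,
    audit = list()
  ), class = "tailored_session")

  if (is.na(target)) return(session)

  tailor_to_target(session, target, quit_answers, treatment_answers, config)
}

# Shared by build_session and provider overrides: (re)computes everything
# downstream of the target-drug decision.
tailor_to_target <- function(session, target, quit_answers, treatment_answers,
                             config) {
  chart <- session$chart
  row <- chart[chart$substance == target, ]
  session$target_drug <- target
  session$target_score <- row$score
  session$target_category <- row$category
  session$track <- assign_track(row$category)

  session$education <- list(
    drug = target,
    risk_level = row$category,
    body = sprintf(
      "Your score for %s is %d. That puts you at %s risk for health and other problems linked to this drug.",
      gsub("_", " ", target), row$score, row$category)
  )

  if (is.null(quit_answers)) stop("staging answers for quitting are required")
  session$quit_stage <- stage_from_answers(quit_answers, config)
  session$quit_modules <- select_stage_modules(session$quit_stage, "quit", config)
  session$goal_menu <- goal_menu(session$quit_stage, "quit", config)

  if (row$score >= config$treatment_cutpoint) {
    if (is.null(treatment_answers)) {
      stop("treatment staging answers required: target-drug score ",
           row$score, " is at or above the cutpoint ", config$treatment_cutpoint)
    }
    session$treatment_stage <- stage_from_answers(treatment_answers, config)
    session$treatment_modules <- select_stage_modules(session$treatment_stage,
                                                      "seek_treatment", config)
    session$treatment_goal_menu <- goal_menu(session$treatment_stage,
                                             "seek_treatment", config)
  } else {
    session$treatment_stage <- NULL
    session$treatment_modules <- NULL
    session$treatment_goal_menu <- NULL
  }
  session
}

#' @export
print.tailored_session <- function(x, ...) {
  cat("<tailored_session>\n")
  cat("  track:", x$track, "\n")
  if (!is.na(x$target_drug)) {
    cat("  target drug:", x$target_drug, sprintf("(score %d, %s risk)\n",
        x$target_score, x$target_category))
    cat("  stage (quit):", x$quit_stage, "\n")
    if (!is.null(x$treatment_stage)) {
      cat("  stage (seek treatment):", x$treatment_stage, "\n")
    }
  }
  invisible(x)
}

#' Record a stage-matched goal and plan
#'
#' The goal must come from the menu offered for the session's quit stage.
#' Re-recording the same goal and plan leaves the session unchanged.
#'
#' @param session A `tailored_session` that is not screened out.
#' @param goal A goal identifier from the session's goal menu.
#' @param plan Named list with free-text `when`, `where`, `how` fields.
#' @return The updated session.
#' @export
record_goal_plan <- function(session, goal, plan = list(when = "", where = "", how = "")) {
  stopifnot(inherits(session, "tailored_session"))
  if (is.null(session$goal_menu)) stop("session is screened out; no goal menu")
  if (!goal %in% session$goal_menu) {
    stop("goal '", goal, "' is not in the stage-matched menu: ",
         paste(session$goal_menu, collapse = ", "))
  }
  session$goal_plan <- list(goal = goal, plan = plan)
  session
}

# --- session (de)serialization -------------------------------------------

#' Read / write a tailored session as JSON
#'
#' @param session A `tailored_session`.
#' @param path File path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   a `tailored_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "tailored_session"))
  jsonlite::write_json(unclass(session), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$chart <- as.data.frame(doc$chart)
  if (!is.null(doc$target_drug) && is.null(doc$target_drug[[1]])) {
    doc$target_drug <- NA_character_
  }
  if (is.null(doc$target_drug)) doc$target_drug <- NA_character_
  structure(doc, class = "tailored_session")
}
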