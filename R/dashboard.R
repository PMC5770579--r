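# --- session store ---------------------------------------------------------

normalize_id <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Session store on disk
#'
#' A store is a directory of session JSON documents plus an `index.json`
#' mapping normalized (name, date of birth) pairs to files.
#'
#' @param dir Directory path; created if missing.
#' @return An object of class `session_store`.
#' @export
session_store <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx_path <- file.path(dir, "index.json")
  index <- if (file.exists(idx_path)) {
    as.data.frame(jsonlite::read_json(idx_path, simplifyVector = TRUE))
  } else {
    data.frame(name = character(), dob = character(), file = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(dir = dir, index = index), class = "session_store")
}

#' Save a session into a store
#'
#' @param store A `session_store`.
#' @param session A `tailored_session` carrying `patient$name` and
#'   `patient$dob`.
#' @return The updated store.
#' @export
save_session <- function(store, session) {
  stopifnot(inherits(store, "session_store"), inherits(session, "tailored_session"))
  if (is.null(session$patient$name) || is.null(session$patient$dob)) {
    stop("session lacks patient name/dob; cannot index it")
  }
  file <- paste0("session-", nrow(store$index) + 1L, ".json")
  write_session(session, file.path(store$dir, file))
  store$index <- rbind(store$index, data.frame(
    name = normalize_id(session$patient$name),
    dob = as.character(session$patient$dob),
    file = file, stringsAsFactors = FALSE))
  jsonlite::write_json(store$index, file.path(store$dir, "index.json"),
                       auto_unbox = FALSE, digits = NA)
  store
}

#' Retrieve a patient's session
#'
#' Providers retrieve a dashboard by entering the patient's name and date of
#' birth. Matching is case- and whitespace-normalized but otherwise exact; a
#' duplicate pair is an ambiguous-match error rather than a guess.
#'
#' @param store A `session_store`.
#' @param name Patient name.
#' @param date_of_birth Date of birth (`YYYY-MM-DD`).
#' @return A `tailored_session`, or `NULL` when not found.
#' @export
lookup_session <- function(store, name, date_of_birth) {
  stopifnot(inherits(store, "session_store"))
  hit <- store$index[store$index$name == normalize_id(name) &
                       store$index$dob == as.character(as.Date(date_of_birth)), ]
  if (nrow(hit) == 0) return(NULL)
  if (nrow(hit) > 1) {
    stop("ambiguous match: ", nrow(hit), " records share this name and date of birth")
  }
  read_session(file.path(store$dir, hit$file))
}

# --- dashboard views -------------------------------------------------------

select_script <- function(library, stage, purpose, risk = "any") {
  hit <- match_templates(library, "provider_script", stage = stage,
                         purpose = purpose, risk = risk)
  if (nrow(hit) == 0) stop("missing provider script for (", stage, ", ", purpose, ")")
  hit$body[1]
}

#' Render the provider dashboard
#'
#' An overview of the session: the full 9-substance risk chart, the target
#' drug and track, stages of change, the stage-matched counseling script(s),
#' and the goal/plan if one was recorded. Screened-out sessions render as a
#' chart-only view with no script.
#'
#' @param session A `tailored_session`.
#' @param library A `content_library` providing provider scripts.
#' @return An object of class `dashboard_view`.
#' @export
render_dashboard <- function(session, library = load_library()) {
  stopifnot(inherits(session, "tailored_session"))
  view <- list(chart = session$chart,
               target_drug = session$target_drug,
               track = session$track,
               quit_stage = session$quit_stage,
               treatment_stage = session$treatment_stage,
               script = NULL, treatment_script = NULL,
               goal_plan = session$goal_plan)
  if (session$track != "screened_out") {
    view$script <- resolve_placeholders(
      select_script(library, session$quit_stage, "quit"),
      session_placeholders(session))
    if (!is.null(session$treatment_stage)) {
      view$treatment_script <- resolve_placeholders(
        select_script(library, session$treatment_stage, "seek_treatment", risk = "high"),
        session_placeholders(session))
    }
  }
  structure(view, class = "dashboard_view")
}

#' @export
print.dashboard_view <- function(x, ...) {
  cat("<dashboard_view> track:", x$track, "\n")
  print(x$chart)
  invisible(x)
}

#' Load the referral resource list
#'
#' @param path JSON document with a `resources` array; defaults to the
#'   bundled synthetic list.
#' @return Data.frame of resources (possibly empty).
#' @export
referral_resources <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "referral_resources.json", package = "sbirtcti")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$resources) || length(doc$resources) == 0) {
    return(data.frame(name = character(), phone = character(),
                      services = character(), stringsAsFactors = FALSE))
  }
  as.data.frame(doc$resources)
}

# Feedback blocks a patient received during the session, resolved.
session_feedback_blocks <- function(session, library) {
  blocks <- list()
  if (!is.null(session$education)) {
    blocks[["risk_education"]] <- session$education$body
  }
  if (!is.null(session$quit_stage)) {
    fb <- match_templates(library, "cti_feedback", drug = session$target_drug,
                          risk = session$target_category,
                          stage = session$quit_stage, purpose = "quit")
    if (nrow(fb) > 0) {
      blocks[["quit_feedback"]] <- resolve_placeholders(
        fb$body[1], session_placeholders(session))
    }
  }
  if (!is.null(session$treatment_stage)) {
    fb <- match_templates(library, "cti_feedback", drug = session$target_drug,
                          risk = "high", stage = session$treatment_stage,
                          purpose = "seek_treatment")
    if (nrow(fb) > 0) {
      blocks[["treatment_feedback"]] <- resolve_placeholders(
        fb$body[1], session_placeholders(session))
    }
  }
  blocks
}

#' Render printable documents for a session
#'
#' Emits a renderer-agnostic sectioned text document (a character vector of
#' lines, one section per dashboard field) suitable for conversion to PDF by
#' any downstream adapter. `provider_summary` contains every dashboard field
#' plus the local referral resource list; `patient_report` contains every
#' feedback block the patient received plus resources and next steps.
#'
#' @param session A `tailored_session`.
#' @param mode `"provider_summary"` or `"patient_report"`.
#' @param library A `content_library`.
#' @param resources Data.frame of referral resources (see
#'   [referral_resources()]).
#' @return Character vector of document lines, with class `sbirt_document`.
#' @export
render_documents <- function(session, mode = c("provider_summary", "patient_report"),
                             library = load_library(),
                             resources = referral_resources()) {
  mode <- match.arg(mode)
  stopifnot(inherits(session, "tailored_session"))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  rule <- function(title) {
    add(""); add("== ", title, " =="); invisible(NULL)
  }

  if (mode == "provider_summary") {
    view <- render_dashboard(session, library)
    add("PROVIDER SUMMARY")
    rule("Risk chart")
    for (i in seq_len(nrow(view$chart))) {
      add(sprintf("%-28s score %2d  risk: %s", view$chart$substance[i],
                  view$chart$score[i], view$chart$category[i]))
    }
    rule("Decision")
    add("track: ", view$track)
    add("target drug: ", ifelse(is.na(view$target_drug), "none", view$target_drug))
    if (!is.null(view$quit_stage)) add("stage (quit): ", view$quit_stage)
    if (!is.null(view$treatment_stage)) add("stage (seek treatment): ", view$treatment_stage)
    if (!is.null(view$script)) { rule("Session script"); add(view$script) }
    if (!is.null(view$treatment_script)) { rule("Treatment script"); add(view$treatment_script) }
    rule("Goal and plan")
    if (is.null(view$goal_plan)) add("no goal recorded")
    else {
      add("goal: ", view$goal_plan$goal)
      for (k in names(view$goal_plan$plan)) add(k, ": ", view$goal_plan$plan[[k]])
    }
    rule("Local referral resources")
    if (nrow(resources) == 0) add("no referral resources configured")
    else for (i in seq_len(nrow(resources))) {
      add(resources$name[i], " | ", resources$phone[i], " | ", resources$services[i])
    }
  } else {
    add("YOUR SESSION REPORT")
    rule("Your risk chart")
    for (i in seq_len(nrow(session$chart))) {
      add(sprintf("%-28s risk: %s", session$chart$substance[i],
                  session$chart$category[i]))
    }
    blocks <- session_feedback_blocks(session, library)
    for (nm in names(blocks)) { rule(gsub("_", " ", nm)); add(blocks[[nm]]) }
    if (!is.null(session$goal_plan)) {
      rule("Your goal")
      add("goal: ", session$goal_plan$goal)
    }
    rule("Where to find help")
    if (nrow(resources) == 0) add("no referral resources configured")
    else for (i in seq_len(nrow(resources))) {
      add(resources$name[i], " | ", resources$phone[i])
    }
  }
  structure(lines, class = "sbirt_document")
}

#' @export
print.sbirt_document <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

# --- provider overrides ----------------------------------------------------

#' Construct a provider override
#'
#' @param kind `"target_drug"` (retailor to another substance the patient has
#'   used), `"treatment_needed"` (activate the treatment branch below the
#'   cutpoint), or `"restage_request"` (queue a stage-reassessment message).
#' @param ... Payload fields: `substance` plus `quit_answers` (and optional
#'   `treatment_answers`) for `target_drug`; `treatment_answers` for
#'   `treatment_needed`.
#' @return An object of class `provider_override`.
#' @export
provider_override <- function(kind = c("target_drug", "treatment_needed",
                                       "restage_request"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, payload = list(...)), class = "provider_override")
}

#' Apply a provider override to a session
#'
#' Overrides recompute everything downstream of the overridden decision and
#' record the prior decision in the session's audit trail. A target-drug
#' override must name a substance the patient has actually used (risk chart
#' category other than "none"). A restage request queues one
#' stage-assessment message that [append_queued_messages()] can push into a
#' schedule.
#'
#' @param session A `tailored_session`.
#' @param override A `provider_override`.
#' @param library A `content_library` (used by restage requests).
#' @param config A `tailoring_config`.
#' @return The updated session.
#' @export
apply_override <- function(session, override, library = load_library(),
                           config = tailoring_config()) {
  stopifnot(inherits(session, "tailored_session"),
            inherits(override, "provider_override"))
  audit_entry <- list(kind = override$kind,
                      prior = list(target_drug = session$target_drug,
                                   track = session$track,
                                   treatment_stage = session$treatment_stage))
  p <- override$payload
  if (override$kind == "target_drug") {
    sub <- p$substance
    if (is.null(sub) || !sub %in% session$chart$substance) {
      stop("invalid override target: ", sub)
    }
    if (session$chart$category[session$chart$substance == sub] == "none") {
      stop("override target '", sub, "' has no lifetime use")
    }
    if (is.null(p$quit_answers)) {
      stop("target-drug override requires quit staging answers for the new drug")
    }
    session <- tailor_to_target(session, sub, p$quit_answers,
                                p$treatment_answers, config)
  } else if (override$kind == "treatment_needed") {
    if (session$track == "screened_out") stop("cannot add a treatment branch to a screened-out session")
    if (is.null(p$treatment_answers)) {
      stop("treatment override requires treatment staging answers")
    }
    session$treatment_stage <- stage_from_answers(p$treatment_answers, config)
    session$treatment_modules <- select_stage_modules(session$treatment_stage,
                                                      "seek_treatment", config)
    session$treatment_goal_menu <- goal_menu(session$treatment_stage,
                                             "seek_treatment", config)
  } else { # restage_request
    tpl <- match_templates(library, "sms", purpose = "stage_assessment")
    if (nrow(tpl) == 0) stop("no stage-assessment template in library")
    body <- resolve_placeholders(tpl$body[1], session_placeholders(
      session, list(pac_link = "pac://restage")))
    session$queued_messages <- c(session$queued_messages,
                                 list(list(type = "stage_assessment",
                                           template_id = tpl$id[1], body = body)))
  }
  session$audit <- c(session$audit, list(audit_entry))
  session
}

#' Append a session's queued messages to a schedule
#'
#' @param schedule A `message_schedule`.
#' @param session A `tailored_session` with queued messages (e.g. after a
#'   restage request).
#' @param day_offset Day the queued message should go out (default: the day
#'   after the last scheduled message, capped at the horizon).
#' @param config A `tailoring_config`.
#' @return The updated schedule.
#' @export
append_queued_messages <- function(schedule, session, day_offset = NULL,
                                   config = tailoring_config()) {
  if (is.null(session$queued_messages) || length(session$queued_messages) == 0) {
    return(schedule)
  }
  if (is.null(day_offset)) {
    day_offset <- min(max(schedule$messages$day_offset) + 1L, config$schedule_days)
  }
  for (q in session$queued_messages) {
    schedule$messages <- rbind(schedule$messages, data.frame(
      day_offset = day_offset,
      date = schedule$start_date + day_offset - 1L,
      send_time = config$send_time,
      template_id = q$template_id, body = q$body,
      pac_link = FALSE, reminder = TRUE, stringsAsFactors = FALSE))
  }
  m <- schedule$messages
  schedule$messages <- m[order(m$day_offset, !m$reminder), ]
  rownames(schedule$messages) <- NULL
  schedule
}
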