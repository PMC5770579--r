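# Placeholder values available when resolving a template against a session.
session_placeholders <- function(session, extra = list()) {
  vals <- c(
    drug = gsub("_", " ", session$target_drug),
    score = as.character(session$target_score),
    risk = session$target_category,
    stage = session$quit_stage
  )
  c(vals, unlist(extra))
}

# Deterministic rotation order for a template pool: shuffle once with the
# seed, then cycle; no id repeats until every matching template was used.
rotation_order <- function(ids, n, seed) {
  if (length(ids) == 0) stop("no matching template for a required slot")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  shuffled <- sample(ids)
  rep(shuffled, length.out = n)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build the 30-day message schedule
#'
#' Generates the stage-matched text-message schedule for a tailored session:
#' messages every 1 to 3 days depending on the stage of change (configured
#' gap map), with exactly one message per 7-day window of days 1-28 carrying
#' a link to one of the 4 Personal Activity Center (PAC) activities. Template
#' choice among equally tagged candidates rotates through a seeded shuffle
#' (no template repeats until all matching templates have been used once);
#' the cadence itself is deterministic.
#'
#' @param session A `tailored_session` that is not screened out.
#' @param library A `content_library` whose validation verdict passes.
#' @param start_date Date of day 1.
#' @param seed Integer seed for template rotation.
#' @param config A `tailoring_config` (carries the stage-to-gap map).
#' @return An object of class `message_schedule` whose `messages` data.frame
#'   has columns `day_offset`, `date`, `send_time`, `template_id`, `body`,
#'   `pac_link`, `reminder`.
#' @export
build_schedule <- function(session, library = load_library(),
                           start_date = Sys.Date(), seed = 1L,
                           config = tailoring_config()) {
  stopifnot(inherits(session, "tailored_session"))
  if (session$track == "screened_out") {
    stop("screened-out sessions receive no message schedule")
  }
  report <- validate_library(library)
  if (!report$verdict) stop("content library does not validate; fix gaps/readability first")
  start_date <- as.Date(start_date)

  stage <- session$quit_stage
  gap <- config$stage_gap_days[[stage]]
  if (is.null(gap)) stop("no cadence configured for stage ", stage)
  offsets <- seq(1L, config$schedule_days, by = gap)

  # first scheduled day in each 7-day window of days 1..28 carries the PAC link
  win <- config$pac_window_days
  pac_days <- vapply(seq_len(config$pac_windows), function(w) {
    lo <- (w - 1L) * win + 1L
    cand <- offsets[offsets >= lo & offsets <= w * win]
    cand[1]
  }, integer(1))

  pool_plain <- match_templates(library, "sms", drug = session$target_drug,
                                risk = session$target_category, stage = stage,
                                purpose = "quit", link_slot = FALSE)
  pool_pac <- match_templates(library, "sms", drug = session$target_drug,
                              risk = session$target_category, stage = stage,
                              purpose = "quit", link_slot = TRUE)
  pac_activities <- match_templates(library, "pac_activity",
                                    drug = session$target_drug,
                                    risk = session$target_category,
                                    stage = stage, purpose = "quit")
  if (nrow(pac_activities) == 0) stop("no matching template for a required slot: pac_activity")

  is_pac <- offsets %in% pac_days
  ids_plain <- rotation_order(pool_plain$id, sum(!is_pac), seed)
  ids_pac <- rotation_order(pool_pac$id, sum(is_pac), seed + 1L)
  activity_ids <- rep(pac_activities$id, length.out = sum(is_pac))

  template_id <- character(length(offsets))
  template_id[!is_pac] <- ids_plain
  template_id[is_pac] <- ids_pac

  body <- character(length(offsets))
  pac_i <- 0L
  for (i in seq_along(offsets)) {
    tpl <- library$templates[library$templates$id == template_id[i], ]
    extra <- list()
    if (is_pac[i]) {
      pac_i <- pac_i + 1L
      extra$pac_link <- paste0("pac://activity/", activity_ids[pac_i])
    }
    resolved <- resolve_placeholders(tpl$body, session_placeholders(session, extra))
    left <- unresolved_placeholders(resolved)
    if (length(left) > 0) {
      stop("unresolved placeholder(s) in template ", tpl$id, ": ",
           paste(left, collapse = ", "))
    }
    body[i] <- resolved
  }

  messages <- data.frame(
    day_offset = offsets,
    date = start_date + offsets - 1L,
    send_time = config$send_time,
    template_id = template_id,
    body = body,
    pac_link = is_pac,
    reminder = FALSE,
    stringsAsFactors = FALSE
  )
  sched <- structure(list(start_date = start_date, seed = seed,
                          stage = stage, target_drug = session$target_drug,
                          appointments = as.Date(character(0)),
                          messages = messages),
                     class = "message_schedule")
  validate_schedule(sched, config)
  sched
}

# Invariants: strictly increasing offsets; gaps between consecutive
# non-reminder messages in {1,2,3}; exactly one PAC link per 7-day window of
# days 1..28. Reminder insertions may tighten gaps but never remove messages.
validate_schedule <- function(schedule, config = tailoring_config()) {
  m <- schedule$messages
  if (is.unsorted(m$day_offset, strictly = FALSE)) stop("offsets must be nondecreasing")
  base <- m[!m$reminder, ]
  gaps <- diff(base$day_offset)
  if (any(!gaps %in% 1:3)) stop("cadence gap outside 1..3 days")
  win <- config$pac_window_days
  for (w in seq_len(config$pac_windows)) {
    n_pac <- sum(m$pac_link & m$day_offset >= (w - 1) * win + 1 & m$day_offset <= w * win)
    if (n_pac != 1L) stop("window ", w, " has ", n_pac, " PAC links (needs exactly 1)")
  }
  if (any(m$day_offset < 1 | m$day_offset > config$schedule_days)) {
    stop("message outside the ", config$schedule_days, "-day horizon")
  }
  invisible(schedule)
}

#' @export
print.message_schedule <- function(x, ...) {
  cat("<message_schedule>", nrow(x$messages), "messages from",
      format(x$start_date), "|", sum(x$messages$pac_link), "PAC links |",
      sum(x$messages$reminder), "reminders\n")
  invisible(x)
}

#' Add appointment reminders to a schedule
#'
#' Inserts reminder-flagged messages on the configured lead days before the
#' appointment (default 3 and 1 days before). Lead days falling before day 1
#' are dropped; if no lead day remains (appointment on day 1) this is an
#' error. Re-adding the same appointment is a no-op.
#'
#' @param schedule A `message_schedule`.
#' @param appointment_date Date within the schedule horizon.
#' @param library A `content_library` providing the reminder template.
#' @param config A `tailoring_config`.
#' @return The updated schedule.
#' @export
add_appointment_reminders <- function(schedule, appointment_date,
                                      library = load_library(),
                                      config = tailoring_config()) {
  stopifnot(inherits(schedule, "message_schedule"))
  appointment_date <- as.Date(appointment_date)
  offset <- as.integer(appointment_date - schedule$start_date) + 1L
  if (offset < 1L || offset > config$schedule_days) {
    stop("appointment outside the ", config$schedule_days, "-day horizon")
  }
  if (appointment_date %in% schedule$appointments) return(schedule)

  lead_offsets <- offset - as.integer(config$reminder_lead_days)
  lead_offsets <- lead_offsets[lead_offsets >= 1L]
  if (length(lead_offsets) == 0) {
    stop("appointment on day ", offset, " leaves no lead time for reminders")
  }
  tpl <- match_templates(library, "sms", purpose = "appointment_reminder")
  if (nrow(tpl) == 0) stop("no matching template for a required slot: appointment_reminder")
  tpl <- tpl[1, ]
  body <- resolve_placeholders(tpl$body, c(date = format(appointment_date, "%b %d")))

  add <- data.frame(
    day_offset = lead_offsets,
    date = schedule$start_date + lead_offsets - 1L,
    send_time = config$send_time,
    template_id = tpl$id,
    body = body,
    pac_link = FALSE,
    reminder = TRUE,
    stringsAsFactors = FALSE
  )
  m <- rbind(schedule$messages, add)
  m <- m[order(m$day_offset, !m$reminder), ]
  rownames(m) <- NULL
  schedule$messages <- m
  schedule$appointments <- c(schedule$appointments, appointment_date)
  validate_schedule(schedule, config)
  schedule
}

#' Export a schedule
#'
#' @param schedule A `message_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$messages, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(start_date = format(schedule$start_date),
                            seed = schedule$seed, stage = schedule$stage,
                            target_drug = schedule$target_drug,
                            appointments = format(schedule$appointments),
                            messages = schedule$messages),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
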