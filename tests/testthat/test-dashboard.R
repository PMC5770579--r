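fixture_session <- function(i, with_patient = TRUE) {
  fx <- pilot_fixture(cfg_assist)[[i]]
  build_session(fx$interview, fx$quit_answers, fx$treatment_answers,
                patient = if (with_patient) list(name = fx$name, dob = fx$dob),
                config = cfg_tailor, assist_cfg = cfg_assist)
}

test_that("session store lookup is normalized exact-match", {
  dir <- tempfile("store")
  store <- session_store(dir)
  store <- save_session(store, fixture_session(1))
  store <- save_session(store, fixture_session(2))

  hit <- lookup_session(store, "  alex   STONE ", "1975-03-02")
  expect_s3_class(hit, "tailored_session")
  expect_identical(hit$target_drug, "opioids")
  expect_identical(hit$target_score, 21L)

  expect_null(lookup_session(store, "Nobody Here", "1975-03-02"))
  expect_null(lookup_session(store, "Alex Stone", "1999-01-01"))

  # duplicate (name, dob) is ambiguous, not a guess
  store <- save_session(store, fixture_session(1))
  expect_error(lookup_session(store, "Alex Stone", "1975-03-02"), "ambiguous")

  # a fresh handle on the same directory sees the index
  store2 <- session_store(dir)
  expect_identical(lookup_session(store2, "Blake Reyes", "1980-11-17")$target_score, 30L)

  expect_error(save_session(store, fixture_session(1, with_patient = FALSE)),
               "lacks patient name")
})

test_that("dashboard view covers all substances and matches stages", {
  s <- fixture_session(2)  # opioids 30, high, treatment branch
  view <- render_dashboard(s, lib_default)
  expect_identical(nrow(view$chart), 10L)
  expect_identical(view$target_drug, "opioids")
  expect_false(is.null(view$script))
  expect_false(is.null(view$treatment_script))
  # script text is the stage-matched one
  want <- match_templates(lib_default, "provider_script",
                          stage = s$quit_stage, purpose = "quit")$body[1]
  expect_identical(view$script,
                   sbirtcti:::resolve_placeholders(
                     want, sbirtcti:::session_placeholders(s)))
  # deterministic
  expect_identical(render_dashboard(s, lib_default), view)

  # screened-out: chart only
  s0 <- build_session(never_interview(), config = cfg_tailor,
                      assist_cfg = cfg_assist)
  v0 <- render_dashboard(s0, lib_default)
  expect_null(v0$script)
  expect_identical(nrow(v0$chart), 10L)
})

test_that("provider summary contains every dashboard field (round trip)", {
  s <- fixture_session(2)
  s <- record_goal_plan(s, s$goal_menu[1],
                        list(when = "tonight", where = "home", how = "call"))
  doc <- render_documents(s, "provider_summary", lib_default)
  txt <- paste(doc, collapse = "\n")
  view <- render_dashboard(s, lib_default)
  for (sub in view$chart$substance) expect_match(txt, sub, fixed = TRUE)
  expect_match(txt, view$track, fixed = TRUE)
  expect_match(txt, view$target_drug, fixed = TRUE)
  expect_match(txt, view$quit_stage, fixed = TRUE)
  expect_match(txt, view$treatment_stage, fixed = TRUE)
  expect_match(txt, view$script, fixed = TRUE)
  expect_match(txt, view$treatment_script, fixed = TRUE)
  expect_match(txt, s$goal_plan$goal, fixed = TRUE)
  expect_match(txt, "referral resources", ignore.case = TRUE)
  expect_match(txt, referral_resources()$name[1], fixed = TRUE)
})

test_that("patient report carries every feedback block; empty resources noticed", {
  s <- fixture_session(4)  # cocaine 29, contemplation + treatment branch
  doc <- render_documents(s, "patient_report", lib_default)
  txt <- paste(doc, collapse = "\n")
  blocks <- sbirtcti:::session_feedback_blocks(s, lib_default)
  expect_gte(length(blocks), 3)  # education + quit + treatment feedback
  for (b in blocks) expect_match(txt, b, fixed = TRUE)

  empty <- referral_resources(tempfile_with_json(list(resources = list())))
  doc2 <- render_documents(s, "patient_report", lib_default, resources = empty)
  expect_match(paste(doc2, collapse = "\n"), "no referral resources configured")
})

test_that("overrides retailor, audit, and queue restage messages", {
  s <- fixture_session(1)  # opioids 21, cannabis 10 in chart

  # target-drug override: retailor to cannabis
  ov <- provider_override("target_drug", substance = "cannabis",
                          quit_answers = answers_intend("within_6mo"))
  s2 <- apply_override(s, ov, lib_default, cfg_tailor)
  expect_identical(s2$target_drug, "cannabis")
  expect_identical(s2$target_score, 10L)
  expect_identical(s2$track, "moderate")
  # audit trail reproduces the pre-override decision
  expect_identical(s2$audit[[1]]$prior$target_drug, "opioids")
  expect_identical(s2$audit[[1]]$prior$track, "moderate")

  # overriding to a never-used substance is invalid
  bad <- provider_override("target_drug", substance = "inhalants",
                           quit_answers = answers_intend("within_6mo"))
  expect_error(apply_override(s, bad, lib_default, cfg_tailor), "no lifetime use")

  # treatment-needed below the cutpoint activates the branch
  ov2 <- provider_override("treatment_needed",
                           treatment_answers = answers_intend("within_30d"))
  s3 <- apply_override(s, ov2, lib_default, cfg_tailor)
  expect_identical(s3$treatment_stage, "preparation")
  expect_length(s3$treatment_modules, 3)
  expect_identical(s3$target_score, 21L)

  # restage request queues exactly one stage-assessment message
  ov3 <- provider_override("restage_request")
  s4 <- apply_override(s, ov3, lib_default, cfg_tailor)
  expect_length(s4$queued_messages, 1)
  expect_identical(s4$queued_messages[[1]]$type, "stage_assessment")
  sch <- build_schedule(s, lib_default, start_date = as.Date("2017-06-05"),
                        seed = 1, config = cfg_tailor)
  sch2 <- append_queued_messages(sch, s4, config = cfg_tailor)
  expect_identical(nrow(sch2$messages), nrow(sch$messages) + 1L)
  expect_identical(sum(sch2$messages$template_id == "sms_restage"), 1L)
})
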