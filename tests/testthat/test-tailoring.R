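test_that("target-drug selection maximizes score with ranking tie-breaks", {
  scores <- setNames(rep(0L, 10), assist_substances(cfg_assist))

  s <- scores; s["opioids"] <- 30L; s["cocaine"] <- 12L
  expect_identical(select_target_drug(s, config = cfg_tailor), "opioids")

  # tie: opioids outrank cannabis
  s <- scores; s["opioids"] <- 21L; s["cannabis"] <- 21L
  expect_identical(select_target_drug(s, config = cfg_tailor), "opioids")

  # tie among middle-ranked drugs follows the configured order
  s <- scores; s["cocaine"] <- 15L; s["sedatives"] <- 15L
  expect_identical(select_target_drug(s, config = cfg_tailor), "cocaine")

  # all low: screened out
  s <- scores; s["cannabis"] <- 3L
  expect_true(is.na(select_target_drug(s, config = cfg_tailor)))

  # tobacco and alcohol are ineligible by default
  s <- scores; s["tobacco"] <- 30L; s["alcohol"] <- 25L; s["cannabis"] <- 5L
  expect_identical(select_target_drug(s, config = cfg_tailor), "cannabis")

  expect_error(select_target_drug(s, eligible = character(0), config = cfg_tailor),
               "empty")
  expect_error(select_target_drug(s[1:3], config = cfg_tailor), "missing")
})

test_that("track assignment follows the risk category", {
  expect_identical(assign_track("none"), "screened_out")
  expect_identical(assign_track("low"), "screened_out")
  expect_identical(assign_track("moderate"), "moderate")
  expect_identical(assign_track("high"), "high")
})

test_that("staging is total, exclusive, and exact at boundaries", {
  expect_identical(stage_from_answers(answers_changed(61), cfg_tailor), "action")
  expect_identical(stage_from_answers(answers_changed(244), cfg_tailor), "maintenance")
  # boundary: 183 days is "6 months or more"
  expect_identical(stage_from_answers(answers_changed(182), cfg_tailor), "action")
  expect_identical(stage_from_answers(answers_changed(183), cfg_tailor), "maintenance")
  expect_identical(stage_from_answers(answers_changed(0), cfg_tailor), "action")

  expect_identical(stage_from_answers(answers_intend("within_30d"), cfg_tailor),
                   "preparation")
  expect_identical(stage_from_answers(answers_intend("within_6mo"), cfg_tailor),
                   "contemplation")
  expect_identical(stage_from_answers(answers_intend("none_6mo"), cfg_tailor),
                   "precontemplation")

  expect_error(stage_from_answers(answers_changed(-1), cfg_tailor),
               "after reference_date")
  expect_error(staging_answers(TRUE, change_date = NULL), "change_date required")

  # totality/exclusivity: every valid answer combination maps to one stage
  stages <- c(
    vapply(c("none_6mo", "within_6mo", "within_30d"),
           function(w) stage_from_answers(answers_intend(w), cfg_tailor), ""),
    vapply(c(0, 1, 90, 182, 183, 400),
           function(d) stage_from_answers(answers_changed(d), cfg_tailor), ""))
  expect_true(all(stages %in% ttm_stages()))
})

test_that("stage-module selection returns exactly 3 deterministic modules", {
  for (stage in ttm_stages()) {
    for (purpose in c("quit", "seek_treatment")) {
      mods <- select_stage_modules(stage, purpose, cfg_tailor)
      expect_length(mods, 3)
      expect_identical(mods, select_stage_modules(stage, purpose, cfg_tailor))
    }
  }
  # the pros-of-change module anchors the precontemplation intervention
  expect_true("pros_of_change" %in%
                select_stage_modules("precontemplation", "quit", cfg_tailor))
})

test_that("build_session executes the session flow end to end", {
  # moderate opioid user, contemplation: no treatment branch
  fx <- pilot_fixture(cfg_assist)
  s1 <- build_session(fx[[1]]$interview, fx[[1]]$quit_answers,
                      config = cfg_tailor, assist_cfg = cfg_assist)
  expect_identical(s1$target_drug, "opioids")
  expect_identical(s1$track, "moderate")
  expect_null(s1$treatment_stage)
  expect_identical(nrow(s1$chart), 10L)
  expect_identical(s1$quit_modules,
                   select_stage_modules("contemplation", "quit", cfg_tailor))

  # high-risk cocaine user in contemplation: treatment branch present
  s4 <- build_session(fx[[4]]$interview, fx[[4]]$quit_answers,
                      fx[[4]]$treatment_answers,
                      config = cfg_tailor, assist_cfg = cfg_assist)
  expect_identical(s4$target_drug, "cocaine")
  expect_identical(s4$track, "high")
  expect_identical(s4$quit_stage, "contemplation")
  expect_false(is.null(s4$treatment_stage))
  expect_length(s4$treatment_modules, 3)

  # missing treatment answers when the branch is required
  expect_error(build_session(fx[[4]]$interview, fx[[4]]$quit_answers,
                             config = cfg_tailor, assist_cfg = cfg_assist),
               "treatment staging answers required")

  # all-never interview screens out and carries only the chart
  s0 <- build_session(never_interview(), config = cfg_tailor,
                      assist_cfg = cfg_assist)
  expect_identical(s0$track, "screened_out")
  expect_true(is.na(s0$target_drug))
  expect_null(s0$quit_stage)
  expect_null(s0$education)
})

test_that("treatment branch appears iff the target score reaches 27 (sweep)", {
  for (target in c(0, 3, 4, 20, 26, 27, 30, 39)) {
    profile <- list(scores = c(opioids = target), quit_stage = "contemplation",
                    treatment_stage = "contemplation")
    if (target < 4) {
      sim <- simulate_patient(profile, cfg_assist)
      s <- build_session(sim$interview, sim$quit_answers, sim$treatment_answers,
                         config = cfg_tailor, assist_cfg = cfg_assist)
      expect_identical(s$track, "screened_out")
      next
    }
    sim <- simulate_patient(profile, cfg_assist)
    s <- build_session(sim$interview, sim$quit_answers, sim$treatment_answers,
                       config = cfg_tailor, assist_cfg = cfg_assist)
    expect_identical(!is.null(s$treatment_stage), target >= 27,
                     info = paste("target", target))
  }
})

test_that("goal recording validates the menu and is idempotent", {
  fx <- pilot_fixture(cfg_assist)
  s <- build_session(fx[[1]]$interview, fx[[1]]$quit_answers,
                     config = cfg_tailor, assist_cfg = cfg_assist)
  goal <- s$goal_menu[1]
  s2 <- record_goal_plan(s, goal, list(when = "tonight", where = "home", how = "call"))
  expect_identical(s2$goal_plan$goal, goal)
  expect_identical(record_goal_plan(s2, goal,
                                    list(when = "tonight", where = "home", how = "call")),
                   s2)
  # a goal from another stage's menu is rejected
  other <- setdiff(cfg_tailor$goal_menus$quit$action, s$goal_menu)[1]
  expect_error(record_goal_plan(s, other), "not in the stage-matched menu")
})

test_that("sessions round-trip through JSON", {
  fx <- pilot_fixture(cfg_assist)
  s <- build_session(fx[[2]]$interview, fx[[2]]$quit_answers,
                     fx[[2]]$treatment_answers,
                     patient = list(name = fx[[2]]$name, dob = fx[[2]]$dob),
                     config = cfg_tailor, assist_cfg = cfg_assist)
  path <- tempfile(fileext = ".json")
  write_session(s, path)
  back <- read_session(path)
  expect_identical(back$target_drug, s$target_drug)
  expect_identical(back$track, s$track)
  expect_identical(back$quit_stage, s$quit_stage)
  expect_identical(back$treatment_stage, s$treatment_stage)
  expect_equal(as.data.frame(back$chart), s$chart)
})
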