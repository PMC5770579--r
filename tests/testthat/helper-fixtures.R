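# Shared fixtures: configs are loaded once; small interview builders.

cfg_assist <- assist_config()
cfg_tailor <- tailoring_config()
lib_default <- load_library()

# interview rows for one substance from a named code vector c(`1`=1, `2`=3, ...)
sub_rows <- function(substance, codes) {
  data.frame(substance = substance, item = as.integer(names(codes)),
             code = as.integer(codes), stringsAsFactors = FALSE)
}

# complete all-never interview
never_interview <- function() {
  assist_interview(do.call(rbind, lapply(assist_substances(cfg_assist),
                                         function(s) sub_rows(s, c(`1` = 0)))),
                   cfg_assist)
}

# complete interview with given per-substance code maps; everything else never
interview_with <- function(...) {
  given <- list(...)
  rows <- lapply(assist_substances(cfg_assist), function(s) {
    if (s %in% names(given)) sub_rows(s, given[[s]]) else sub_rows(s, c(`1` = 0))
  })
  assist_interview(do.call(rbind, rows), cfg_assist)
}

# Independent brute-force scorer: reads the weight table straight from the
# bundled JSON and sums row by row; shares no code with score_substance().
oracle_score <- function(interview, substance) {
  raw <- jsonlite::read_json(system.file("extdata", "assist_config.json",
                                         package = "sbirtcti"),
                             simplifyVector = TRUE)
  r <- interview$responses
  r <- r[r$substance == substance, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(r))) {
    it <- raw$items[[as.character(r$item[i])]]
    if (!isTRUE(it$contributes)) next
    total <- total + it$weights[which(it$codes == r$code[i])]
  }
  as.integer(total)
}

ref_date <- as.Date("2017-06-01")

tempfile_with_json <- function(x) {
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(x, p, auto_unbox = TRUE)
  p
}

answers_intend <- function(window) {
  staging_answers(FALSE, intention_window = window, reference_date = ref_date)
}
answers_changed <- function(days_ago) {
  staging_answers(TRUE, change_date = ref_date - days_ago,
                  reference_date = ref_date)
}
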