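#' Count syllables in a word
#'
#' Documented heuristic used by the readability grade: lower-case the word,
#' strip non-letters, count maximal vowel groups (a, e, i, o, u, y), then
#' subtract one for a trailing silent "e" (unless the word ends in a
#' consonant + "le", as in "people"). Every word counts at least one
#' syllable. A small exception list covers common words the heuristic gets
#' wrong.
#'
#' @param word Character vector of words.
#' @return Integer vector of syllable counts.
#' @export
count_syllables <- function(word) {
  exceptions <- c(something = 2L, anyone = 3L, everyone = 3L, idea = 3L,
                  area = 3L, being = 2L, doing = 2L, going = 2L,
                  really = 3L, quiet = 2L)
  vapply(word, function(w) {
    w <- tolower(gsub("[^a-zA-Z]", "", w))
    if (!nzchar(w)) return(0L)
    if (w %in% names(exceptions)) return(exceptions[[w]])
    groups <- gregexpr("[aeiouy]+", w)[[1]]
    n <- if (groups[1] == -1L) 0L else length(groups)
    silent_e <- grepl("e$", w) && !grepl("[^aeiouy]le$", w)
    if (silent_e && n > 1L) n <- n - 1L
    max(n, 1L)
  }, integer(1), USE.NAMES = FALSE)
}

tokenize_text <- function(text) {
  text <- gsub("\\s+", " ", trimws(text))
  sentences <- unlist(strsplit(text, "[.!?]+"))
  sentences <- sentences[nzchar(trimws(sentences))]
  words <- unlist(strsplit(text, "[^A-Za-z']+"))
  words <- words[nzchar(words)]
  list(sentences = sentences, words = words)
}

#' Flesch-Kincaid grade level
#'
#' `grade = 0.39 * (words / sentences) + 11.8 * (syllables / words) - 15.59`,
#' with sentences split on `. ! ?`, words on non-letter runs, and syllables
#' counted by [count_syllables()]. The grade is invariant under whitespace
#' normalization and under concatenating a text with itself.
#'
#' @param text A single character string with at least one sentence.
#' @return The grade as a real number (can be negative for very easy text).
#' @export
fk_grade <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    stop("fk_grade requires non-empty text")
  }
  tk <- tokenize_text(text)
  if (length(tk$sentences) == 0 || length(tk$words) == 0) {
    stop("fk_grade requires at least one sentence of words")
  }
  w <- length(tk$words)
  s <- length(tk$sentences)
  syl <- sum(count_syllables(tk$words))
  0.39 * (w / s) + 11.8 * (syl / w) - 15.59
}

# Vocabularies templates may be tagged with. "any" matches every value.
library_vocab <- function() {
  list(
    channels = c("cti_feedback", "sms", "pac_activity", "provider_script"),
    risks = c("moderate", "high"),
    stages = ttm_stages(),
    purposes = c("quit", "seek_treatment", "appointment_reminder",
                 "stage_assessment")
  )
}

patient_facing_channels <- function() c("cti_feedback", "sms", "pac_activity")

#' Load a tagged content library
#'
#' A library is a JSON document with a `templates` array (each template has
#' an `id`, a `channel`, tags `drug` / `risk` / `stage` / `purpose` -- each
#' either a vocabulary value or `"any"` -- a `body` with named
#' `{placeholders}`, and a `link_slot` flag for templates carrying a
#' Personal Activity Center link) plus `coverage_requirements` describing
#' the (drug, risk, stage, channel) cells the library must cover.
#'
#' @param path Path to the library JSON; defaults to the bundled library.
#' @return An object of class `content_library`.
#' @export
load_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "content_library.json", package = "sbirtcti")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl <- as.data.frame(doc$templates)
  req <- c("id", "channel", "drug", "risk", "stage", "purpose", "link_slot", "body")
  if (!all(req %in% names(tpl))) {
    stop("library templates need fields: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tpl$id)) {
    stop("duplicate template id: ", tpl$id[duplicated(tpl$id)][1])
  }
  voc <- library_vocab()
  subs <- c(assist_substances(), "any")
  for (i in seq_len(nrow(tpl))) {
    where <- function(field, allowed) {
      val <- tpl[[field]][i]
      if (!val %in% allowed) {
        stop(sprintf("template '%s': unknown %s tag '%s'", tpl$id[i], field, val))
      }
    }
    where("channel", voc$channels)
    where("drug", subs)
    where("risk", c(voc$risks, "any"))
    where("stage", c(voc$stages, "any"))
    where("purpose", voc$purposes)
    if (!nzchar(trimws(tpl$body[i]))) stop("template '", tpl$id[i], "': empty body")
  }
  structure(list(templates = tpl,
                 coverage_requirements = doc$coverage_requirements,
                 version = doc$version),
            class = "content_library")
}

#' @export
print.content_library <- function(x, ...) {
  cat("<content_library>", nrow(x$templates), "templates (",
      x$version, ")\n")
  invisible(x)
}

tag_matches <- function(tag_value, wanted) tag_value == "any" | tag_value == wanted

#' Find templates matching a tag cell
#'
#' @param library A `content_library`.
#' @param channel,drug,risk,stage,purpose Tag values to match; a template
#'   tagged `"any"` matches every value of that tag.
#' @param link_slot If not `NULL`, additionally require the flag value.
#' @return Data.frame of matching templates (possibly empty).
#' @export
match_templates <- function(library, channel, drug = "any", risk = "any",
                            stage = "any", purpose = "quit", link_slot = NULL) {
  t <- library$templates
  keep <- t$channel == channel &
    tag_matches(t$drug, drug) &
    tag_matches(t$risk, risk) &
    tag_matches(t$stage, stage) &
    (t$purpose == purpose | purpose == "any")
  if (!is.null(link_slot)) keep <- keep & t$link_slot == link_slot
  t[keep, , drop = FALSE]
}

# Representative values used to resolve placeholders before grading
# readability, so "{drug}" is scored as a real word.
placeholder_stand_ins <- function() {
  c(drug = "drugs", score = "20", risk = "high", stage = "thinking",
    pac_link = "the link", goal = "your goal", date = "May 2",
    provider = "your provider", name = "you")
}

resolve_placeholders <- function(body, values) {
  for (k in names(values)) {
    body <- gsub(paste0("{", k, "}"), values[[k]], body, fixed = TRUE)
  }
  body
}

unresolved_placeholders <- function(body) {
  m <- gregexpr("\\{[a-z_]+\\}", body)[[1]]
  if (m[1] == -1L) character(0) else unique(regmatches(body, gregexpr("\\{[a-z_]+\\}", body))[[1]])
}

#' Validate a content library
#'
#' Report-only check of (1) coverage: every (drug, risk, stage, channel,
#' purpose) cell named by the library's coverage requirements must be
#' matched by at least one template; and (2) readability: every
#' patient-facing template (feedback, text message, activity) must score at
#' or below the Flesch-Kincaid grade threshold after placeholders are
#' resolved with representative words.
#'
#' @param library A `content_library`.
#' @param threshold Maximum patient-facing grade; default 5.0.
#' @return A list of class `library_report` with `gaps` (data.frame of
#'   uncovered cells), `readability` (per-template grades), and a logical
#'   `verdict` that is `TRUE` iff there are no gaps and no template exceeds
#'   the threshold.
#' @export
validate_library <- function(library, threshold = 5.0) {
  stopifnot(inherits(library, "content_library"))
  gaps <- list()
  for (i in seq_len(nrow(library$coverage_requirements))) {
    reqt <- library$coverage_requirements[i, ]
    cells <- expand.grid(drug = unlist(reqt$drugs), risk = unlist(reqt$risks),
                         stage = unlist(reqt$stages),
                         purpose = unlist(reqt$purposes),
                         stringsAsFactors = FALSE)
    for (j in seq_len(nrow(cells))) {
      hit <- match_templates(library, channel = reqt$channel,
                             drug = cells$drug[j], risk = cells$risk[j],
                             stage = cells$stage[j], purpose = cells$purpose[j])
      if (nrow(hit) == 0) {
        gaps[[length(gaps) + 1]] <- cbind(channel = reqt$channel, cells[j, ])
      }
    }
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(channel = character(), drug = character(), risk = character(),
               stage = character(), purpose = character())

  pf <- library$templates[library$templates$channel %in% patient_facing_channels(), ]
  grades <- vapply(pf$body, function(b) {
    fk_grade(resolve_placeholders(b, placeholder_stand_ins()))
  }, numeric(1), USE.NAMES = FALSE)
  readability <- data.frame(id = pf$id, channel = pf$channel, grade = grades,
                            pass = grades <= threshold,
                            stringsAsFactors = FALSE)
  structure(list(gaps = gaps, readability = readability,
                 threshold = threshold,
                 verdict = nrow(gaps) == 0 && all(readability$pass)),
            class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat("<library_report>", if (x$verdict) "PASS" else "FAIL", "\n")
  cat("  coverage gaps:", nrow(x$gaps), "\n")
  cat("  readability: ", sum(x$readability$pass), "/", nrow(x$readability),
      " templates at or below grade ", x$threshold, "\n", sep = "")
  invisible(x)
}
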