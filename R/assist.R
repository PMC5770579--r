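#' ASSIST screening configuration
#'
#' Loads the scoring configuration for the ASSIST screening instrument: the
#' nine substance classes (plus "other"), per-item allowed response codes and
#' integer weights, the set of items contributing to the substance involvement
#' score, the skip table, and the risk-category cutoffs. All scoring reads
#' from this configuration; nothing is hard-coded, so a site can ship a
#' variant weight table without touching code.
#'
#' @param path Path to a configuration JSON document. Defaults to the
#'   bundled V3.0-convention table.
#' @return An object of class `assist_config`.
#' @export
assist_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "assist_config.json", package = "sbirtcti")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("ASSIST configuration file not found: ", path)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_assist_config(cfg)
  structure(cfg, class = "assist_config")
}

validate_assist_config <- function(cfg) {
  needed <- c("substances", "items", "skip", "risk_cutoffs", "score_max")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    stop("ASSIST configuration missing fields: ", paste(missing, collapse = ", "))
  }
  if (length(cfg$substances) != 10L || !"other" %in% cfg$substances) {
    stop("ASSIST configuration must declare 9 substance classes plus 'other'")
  }
  for (k in names(cfg$items)) {
    it <- cfg$items[[k]]
    if (length(it$codes) != length(it$weights)) {
      stop("item ", k, ": every allowed response code needs a weight")
    }
    if (any(it$weights < 0)) stop("item ", k, ": weights must be >= 0")
  }
  if (!identical(sort(as.integer(names(cfg$items))), 1:7)) {
    stop("ASSIST configuration must declare items 1..7")
  }
  invisible(cfg)
}

#' The ASSIST substance classes
#'
#' @param config An `assist_config` object; defaults to the bundled one.
#' @return Character vector of substance identifiers in stable display order
#'   (the 9 named classes followed by `"other"`).
#' @export
assist_substances <- function(config = assist_config()) {
  config$substances
}

#' Construct an ASSIST interview
#'
#' An interview is the raw screening record: one row per answered item. The
#' constructor enforces the instrument's invariants: no duplicate
#' (substance, item) pairs, response codes drawn from each item's declared
#' code set, and skip-pattern consistency (no follow-up items for a substance
#' never used; no past-3-month items when recent use is "never").
#'
#' @param responses A data.frame with columns `substance` (character),
#'   `item` (integer 1..7), and `code` (integer response code).
#' @param config An `assist_config` object.
#' @return An object of class `assist_interview`.
#' @export
assist_interview <- function(responses = NULL, config = assist_config()) {
  if (is.null(responses)) {
    responses <- data.frame(substance = character(), item = integer(),
                            code = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(responses))
  req <- c("substance", "item", "code")
  if (!all(req %in% names(responses))) {
    stop("interview responses need columns: ", paste(req, collapse = ", "))
  }
  responses <- responses[, req, drop = FALSE]
  responses$substance <- as.character(responses$substance)
  responses$item <- as.integer(responses$item)
  responses$code <- as.integer(responses$code)
  iv <- structure(list(responses = responses), class = "assist_interview")
  validate_interview(iv, config)
  iv
}

#' @export
print.assist_interview <- function(x, ...) {
  cat("<assist_interview>", nrow(x$responses), "responses across",
      length(unique(x$responses$substance)), "substances\n")
  invisible(x)
}

# Items a substance's branch can ever present, in administration order.
branch_items <- function(substance, config) {
  excluded <- integer(0)
  if (!is.null(config$items_excluded[[substance]])) {
    excluded <- as.integer(config$items_excluded[[substance]])
  }
  setdiff(1:7, excluded)
}

substance_answers <- function(interview, substance) {
  r <- interview$responses
  r <- r[r$substance == substance, , drop = FALSE]
  stats::setNames(r$code, as.character(r$item))
}

# Full invariant check; stops with an addressed message on the first violation.
validate_interview <- function(interview, config) {
  r <- interview$responses
  if (nrow(r) == 0) return(invisible(interview))
  bad_sub <- setdiff(unique(r$substance), config$substances)
  if (length(bad_sub) > 0) {
    stop("unknown substance(s): ", paste(bad_sub, collapse = ", "))
  }
  key <- paste(r$substance, r$item)
  if (anyDuplicated(key)) {
    stop("duplicate (substance, item) response: ", key[duplicated(key)][1])
  }
  if (any(r$item < 1 | r$item > 7)) stop("item index must be in 1..7")
  for (i in seq_len(nrow(r))) {
    allowed <- config$items[[as.character(r$item[i])]]$codes
    if (!r$code[i] %in% allowed) {
      stop(sprintf("substance %s item %d: response code %d not in declared set {%s}",
                   r$substance[i], r$item[i], r$code[i],
                   paste(allowed, collapse = ",")))
    }
  }
  for (sub in unique(r$substance)) {
    ans <- substance_answers(interview, sub)
    items_here <- as.integer(names(ans))
    excluded <- setdiff(1:7, branch_items(sub, config))
    if (any(items_here %in% excluded)) {
      stop(sprintf("substance %s: item(s) %s are not administered for this substance",
                   sub, paste(intersect(items_here, excluded), collapse = ",")))
    }
    if (any(items_here > 1) && !("1" %in% names(ans))) {
      stop(sprintf("substance %s: follow-up items answered without item 1", sub))
    }
    if (!is.na(ans["1"]) && ans["1"] == 0 && any(items_here %in% config$skip$lifetime_never_skips)) {
      stop(sprintf("substance %s: lifetime use is 'never' but follow-up items are present", sub))
    }
    if (!is.na(ans["2"]) && ans["2"] == 0 && any(items_here %in% config$skip$recent_never_skips)) {
      stop(sprintf("substance %s: no past-3-month use but skipped items %s are present",
                   sub, paste(intersect(items_here, config$skip$recent_never_skips),
                              collapse = ",")))
    }
  }
  invisible(interview)
}

# Items the skip table still requires for a substance, given answers so far.
required_items <- function(interview, substance, config) {
  ans <- substance_answers(interview, substance)
  items <- branch_items(substance, config)
  if (!is.na(ans["1"]) && ans["1"] == 0) {
    return(setdiff(items, config$skip$lifetime_never_skips))
  }
  if (!is.na(ans["2"]) && ans["2"] == 0) {
    return(setdiff(items, config$skip$recent_never_skips))
  }
  items
}

#' Next question for a substance branch
#'
#' Walks the substance's item sequence honoring the configured skip table:
#' lifetime use "never" ends the branch; no use in the past 3 months skips
#' the past-3-month items but still asks the lifetime-concern and
#' tried-to-cut-down items.
#'
#' @param interview An `assist_interview`.
#' @param substance Substance identifier.
#' @param config An `assist_config` object.
#' @return The integer item index of the next unanswered question, or
#'   `NA_integer_` (the done marker) when the branch is exhausted.
#' @export
next_question <- function(interview, substance, config = assist_config()) {
  stopifnot(inherits(interview, "assist_interview"))
  if (!substance %in% config$substances) stop("unknown substance: ", substance)
  validate_interview(interview, config)
  req <- required_items(interview, substance, config)
  ans <- substance_answers(interview, substance)
  unanswered <- setdiff(req, as.integer(names(ans)))
  if (length(unanswered) == 0) return(NA_integer_)
  min(unanswered)
}

substance_complete <- function(interview, substance, config) {
  is.na(next_question(interview, substance, config))
}

#' Score one substance
#'
#' The substance involvement score is the sum of the configured weights of
#' the given responses over the contributing items (items 2-7; item 1 never
#' contributes). A substance whose branch was fully skipped at lifetime use
#' scores 0.
#'
#' @param interview An `assist_interview` whose branch for `substance` is
#'   complete.
#' @param substance Substance identifier.
#' @param config An `assist_config` object.
#' @return Integer score in 0..39.
#' @export
score_substance <- function(interview, substance, config = assist_config()) {
  stopifnot(inherits(interview, "assist_interview"))
  if (!substance_complete(interview, substance, config)) {
    stop("incomplete branch: substance ", substance,
         " still requires item ", next_question(interview, substance, config))
  }
  ans <- substance_answers(interview, substance)
  total <- 0L
  for (item in names(ans)) {
    it <- config$items[[item]]
    if (!isTRUE(it$contributes)) next
    idx <- match(ans[[item]], it$codes)
    if (is.na(idx)) stop("unknown response code for item ", item)
    total <- total + as.integer(it$weights[idx])
  }
  total
}

#' Score every substance in an interview
#'
#' @param interview A complete `assist_interview`.
#' @param config An `assist_config` object.
#' @return A data.frame with one row per substance in display order:
#'   `substance`, `score`, `lifetime_use`.
#' @export
score_interview <- function(interview, config = assist_config()) {
  subs <- config$substances
  lifetime <- vapply(subs, function(s) {
    ans <- substance_answers(interview, s)
    !is.na(ans["1"]) && ans["1"] == 1
  }, logical(1))
  scores <- vapply(subs, function(s) score_substance(interview, s, config),
                   integer(1))
  data.frame(substance = subs, score = unname(scores),
             lifetime_use = unname(lifetime), stringsAsFactors = FALSE)
}

#' Map a substance score to a risk category
#'
#' Uniform validated cutoffs: low 0-3, moderate 4-26, high 27+. The display
#' category "none" applies when the patient reports no lifetime use of the
#' substance; "low" means a 0-3 score with some use history.
#'
#' @param score Integer score in 0..39.
#' @param lifetime_use Logical; any lifetime use of the substance.
#' @param config An `assist_config` object (carries the cutoffs).
#' @return One of `"none"`, `"low"`, `"moderate"`, `"high"`.
#' @export
categorize_risk <- function(score, lifetime_use = TRUE, config = assist_config()) {
  if (length(score) != 1 || is.na(score) || score < 0 || score > config$score_max) {
    stop("score out of range 0..", config$score_max)
  }
  if (!lifetime_use) {
    if (score != 0) stop("a substance never used cannot carry a nonzero score")
    return("none")
  }
  cut <- config$risk_cutoffs
  if (score > cut$moderate_max) "high"
  else if (score > cut$low_max) "moderate"
  else "low"
}

#' Per-substance risk chart
#'
#' The chart shown to the patient and on the provider dashboard: one row per
#' substance with score and display category (none / low / moderate / high).
#'
#' @inheritParams score_interview
#' @return A data.frame `substance`, `score`, `category`.
#' @export
risk_chart <- function(interview, config = assist_config()) {
  sc <- score_interview(interview, config)
  sc$category <- mapply(categorize_risk, sc$score, sc$lifetime_use,
                        MoreArgs = list(config = config))
  sc[, c("substance", "score", "category")]
}

#' Read / write interviews as JSON
#'
#' Interviews round-trip through a plain JSON document:
#' `{"responses": [{"substance": ..., "item": ..., "code": ...}, ...]}`.
#'
#' @param path File path.
#' @param interview An `assist_interview`.
#' @param config An `assist_config` used for validation on read.
#' @return `read_interview` returns an `assist_interview`;
#'   `write_interview` returns `path` invisibly.
#' @export
read_interview <- function(path, config = assist_config()) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$responses)) stop("interview document lacks a 'responses' field: ", path)
  assist_interview(as.data.frame(doc$responses), config)
}

#' @rdname read_interview
#' @export
write_interview <- function(interview, path) {
  stopifnot(inherits(interview, "assist_interview"))
  jsonlite::write_json(list(responses = interview$responses), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Batch-import interviews from CSV
#'
#' Long-format CSV with columns `patient_id, substance, item, code`; one
#' interview per patient id. Validation failures report the offending CSV
#' line.
#'
#' @param path CSV file path.
#' @param config An `assist_config`.
#' @return Named list of `assist_interview` objects keyed by patient id.
#' @export
read_interviews_csv <- function(path, config = assist_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "substance", "item", "code")
  if (!all(req %in% names(df))) {
    stop("interview CSV needs columns: ", paste(req, collapse = ", "))
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  out <- list()
  for (pid in unique(df$patient_id)) {
    rows <- df[df$patient_id == pid, , drop = FALSE]
    iv <- tryCatch(
      assist_interview(rows[, c("substance", "item", "code")], config),
      error = function(e) {
        stop(sprintf("patient %s (lines %d-%d): %s", pid,
                     min(rows$.line), max(rows$.line), conditionMessage(e)),
             call. = FALSE)
      })
    out[[as.character(pid)]] <- iv
  }
  out
}
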