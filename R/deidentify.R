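# k-anonymity rendering of an observation table: free-text identifier
# scrubbing plus global recoding of the quasi-identifiers (postal code and
# birth date) along fixed generalization hierarchies until every
# equivalence class reaches the group-size threshold k.

POSTAL_LEVELS <- c("full", "5-char", "4-char", "fsa", "suppressed")
DOB_LEVELS <- c("full", "year-month", "year", "5-year-band", "suppressed")

#' Anonymization policy
#'
#' Bundles the group-size threshold `k`, the quasi-identifier fields, the
#' order in which their generalization hierarchies are walked, and the
#' free-text scrub patterns.  The postal hierarchy is 6-character code ->
#' 5 -> 4 -> 3-character FSA -> suppressed; the birth-date hierarchy is full
#' date -> year-month -> year -> 5-year band -> suppressed.  Each level
#' strictly coarsens the previous and both end in full suppression.
#'
#' @param k minimum equivalence-class size (>= 2; default 5).
#' @param quasi_identifiers fields forming the equivalence classes.
#' @param generalize_order order in which fields are coarsened; the first
#'   field is exhausted before the second is touched.  Reverse it to
#'   generalize birth date before postal code.
#' @param scrub_patterns named character vector of Perl regexes for direct
#'   identifiers in free text (defaults: person-name tokens after an
#'   honorific, and 10-digit health-card-number shapes).
#' @param redaction_token replacement for scrubbed matches.
#' @return An `anonymization_policy` object.
#' @export
#' @examples
#' anonymization_policy(k = 5)
anonymization_policy <- function(k = 5,
                                 quasi_identifiers =
                                   c("postal_code", "birth_date", "sex"),
                                 generalize_order =
                                   c("postal_code", "birth_date"),
                                 scrub_patterns = c(
                                   person_name =
                                     "(?:Dr|Doctor|Mr|Mrs|Ms|Prof)\\.?\\s+[A-Z][A-Za-z'-]+",
                                   health_card =
                                     "\\b\\d{4}[- ]?\\d{3}[- ]?\\d{3}\\b"),
                                 redaction_token = "[REDACTED]") {
  if (!is.numeric(k) || length(k) != 1 || k < 2) {
    stop("k must be a single number >= 2", call. = FALSE)
  }
  if (!all(generalize_order %in% c("postal_code", "birth_date"))) {
    stop("generalize_order may contain only postal_code and birth_date",
         call. = FALSE)
  }
  structure(list(k = as.integer(k),
                 quasi_identifiers = quasi_identifiers,
                 generalize_order = generalize_order,
                 scrub_patterns = scrub_patterns,
                 redaction_token = redaction_token),
            class = "anonymization_policy")
}

#' Strip direct identifiers from free text
#'
#' Replaces every substring matching a scrub pattern with the redaction
#' token.  The replacement is irreversible: nothing about the match (length,
#' content) survives in the output.
#'
#' @param text character vector of free-text notes.
#' @param policy an [anonymization_policy()].
#' @return character vector with all matches redacted.
#' @export
#' @examples
#' scrub_free_text("seen by Dr. Smith, HC 1234-567-890",
#'                 anonymization_policy())
scrub_free_text <- function(text, policy = anonymization_policy()) {
  stopifnot(inherits(policy, "anonymization_policy"))
  out <- text
  for (pat in policy$scrub_patterns) {
    out <- gsub(pat, policy$redaction_token, out, perl = TRUE)
  }
  out
}

generalize_postal <- function(x, level) {
  switch(as.character(level),
         "0" = x,
         "1" = substr(x, 1, 5),
         "2" = substr(x, 1, 4),
         "3" = substr(x, 1, 3),
         "4" = rep(NA_character_, length(x)),
         stop("bad postal level"))
}

generalize_dob <- function(x, level) {
  d <- as.Date(x)
  switch(as.character(level),
         "0" = format(d, "%Y-%m-%d"),
         "1" = format(d, "%Y-%m"),
         "2" = format(d, "%Y"),
         "3" = {
           y <- as.integer(format(d, "%Y")) %/% 5L * 5L
           sprintf("%d-%d", y, y + 4L)
         },
         "4" = rep(NA_character_, length(x)),
         stop("bad birth-date level"))
}

# Equivalence-class sizes over the quasi-identifiers.  If a patient_id
# column is present, classes count distinct patients (a patient's repeat
# visits must not let them hide behind themselves); otherwise rows.
class_size_table <- function(records, qis) {
  cols <- lapply(records[qis], function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "*"
    v
  })
  key <- do.call(paste, c(cols, sep = "\r"))
  if ("patient_id" %in% names(records)) {
    sizes <- tapply(records$patient_id, key,
                    function(p) length(unique(p)))
  } else {
    sizes <- table(key)
  }
  list(key = key, sizes = as.integer(sizes), class_of = names(sizes))
}

apply_levels <- function(records, policy, postal_level, dob_level) {
  out <- records
  if ("postal_code" %in% policy$quasi_identifiers &&
      "postal_code" %in% names(out)) {
    out$postal_code <- generalize_postal(as.character(records$postal_code),
                                         postal_level)
  }
  if ("birth_date" %in% policy$quasi_identifiers &&
      "birth_date" %in% names(out)) {
    out$birth_date <- generalize_dob(records$birth_date, dob_level)
  }
  out
}

# The generalization walk: coarsen the first field of generalize_order one
# level at a time to full suppression, then the second.
level_walk <- function(policy) {
  first <- policy$generalize_order[1]
  steps <- data.frame(postal = 0L, dob = 0L)
  for (l in 1:4) {
    steps <- rbind(steps,
                   if (first == "postal_code") c(l, 0L) else c(0L, l))
  }
  for (l in 1:4) {
    steps <- rbind(steps,
                   if (first == "postal_code") c(4L, l) else c(l, 4L))
  }
  names(steps) <- c("postal", "dob")
  steps
}

min_class_size_at <- function(records, policy, postal, dob) {
  g <- apply_levels(records, policy, postal, dob)
  qis <- intersect(policy$quasi_identifiers, names(g))
  min(class_size_table(g, qis)$sizes)
}

make_class_report <- function(records, policy, postal_level, dob_level,
                              n_suppressed) {
  qis <- intersect(policy$quasi_identifiers, names(records))
  if (nrow(records) == 0) {
    sizes <- integer(0)
  } else {
    sizes <- class_size_table(records, qis)$sizes
  }
  structure(list(
    k = policy$k,
    postal_level = POSTAL_LEVELS[postal_level + 1L],
    dob_level = DOB_LEVELS[dob_level + 1L],
    class_sizes = sort(sizes),
    n_classes = length(sizes),
    min_class_size = if (length(sizes)) min(sizes) else NA_integer_,
    n_suppressed = n_suppressed),
    class = "equiv_class_report")
}

#' @export
print.equiv_class_report <- function(x, ...) {
  cat("<equiv_class_report> k = ", x$k,
      "; postal level: ", x$postal_level,
      "; birth-date level: ", x$dob_level, "\n",
      "  classes: ", x$n_classes,
      "; minimum class size: ", x$min_class_size,
      "; records suppressed: ", x$n_suppressed, "\n", sep = "")
  invisible(x)
}

#' Generalize quasi-identifiers until every class reaches size k
#'
#' Global recoding: one generalization level per field for the whole table.
#' The hierarchies are walked level-by-level in `policy$generalize_order`
#' (postal code first by default), stopping at the least-coarse combination
#' at which the smallest equivalence class over the quasi-identifiers
#' reaches `k`.  Records still in classes below `k` at maximal
#' generalization are suppressed (dropped) and counted.
#'
#' @param records observation table containing the quasi-identifier columns.
#' @param policy an [anonymization_policy()].
#' @param suppress drop residual small-class records (default `TRUE`); with
#'   `FALSE` they are kept and the report's minimum class size may fall
#'   below `k`.
#' @return list with `records` (generalized table; `postal_code` and
#'   `birth_date` become character) and `report`, an `equiv_class_report`.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   patient_id = sprintf("P%d", 1:6),
#'   postal_code = paste0("K7M1A", 1:6),
#'   birth_date = as.Date("1980-01-01"),
#'   sex = "female")
#' generalize_until_k(tab, anonymization_policy(k = 5))$report
generalize_until_k <- function(records, policy = anonymization_policy(),
                               suppress = TRUE) {
  stopifnot(inherits(policy, "anonymization_policy"))
  if (nrow(records) == 0) {
    return(list(records = records,
                report = make_class_report(records, policy, 0L, 0L, 0L)))
  }
  qis <- intersect(policy$quasi_identifiers, names(records))
  if (length(qis) == 0) {
    stop("no quasi-identifier columns present", call. = FALSE)
  }
  walk <- level_walk(policy)
  chosen <- walk[nrow(walk), ]
  for (i in seq_len(nrow(walk))) {
    if (min_class_size_at(records, policy, walk$postal[i], walk$dob[i]) >=
        policy$k) {
      chosen <- walk[i, ]
      break
    }
  }
  out <- apply_levels(records, policy, chosen$postal, chosen$dob)
  n_suppressed <- 0L
  cs <- class_size_table(out, qis)
  small <- cs$sizes[match(cs$key, cs$class_of)] < policy$k
  if (any(small) && suppress) {
    n_suppressed <- sum(small)
    out <- out[!small, , drop = FALSE]
  }
  list(records = out,
       report = make_class_report(out, policy, chosen$postal, chosen$dob,
                                  n_suppressed))
}

#' Audit re-identification risk of a table
#'
#' Reports the equivalence-class size distribution over the policy's
#' quasi-identifiers as the table stands, without mutating it.  The minimum
#' class size is the headline re-identification statistic: a minimum of 1
#' means some record is unique on its quasi-identifiers.
#'
#' @inheritParams generalize_until_k
#' @return An `equiv_class_report` (generalization levels reported as
#'   "full" since nothing is recoded).
#' @export
reidentification_audit <- function(records,
                                   policy = anonymization_policy()) {
  stopifnot(inherits(policy, "anonymization_policy"))
  make_class_report(records, policy, 0L, 0L, 0L)
}
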