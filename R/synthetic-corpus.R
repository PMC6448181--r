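# Seeded generator of clinical-note-like corpora with a ground-truth ledger.
#
# The generator emulates the corpus structure the cohort analysis assumes --
# patients with several notes, a concept mentioned with an Arabic, Roman, or
# spelled-out numeric variant at configurable rates, and rare injected error
# forms -- without attempting realistic clinical language. Filler text is
# drawn from a fixed clinical-flavored vocabulary from which every token of
# every injected phrase is removed, so injected phrases cannot occur by
# accident; a post-generation scan asserts this. Every injection is recorded
# in a ledger that downstream search must recover exactly.

.filler_vocab <- c(
  "patient", "presents", "with", "stable", "vital", "signs", "exam",
  "unremarkable", "followup", "clinic", "today", "denies", "fever",
  "chills", "nausea", "vomiting", "pain", "medication", "continued",
  "plan", "reviewed", "labs", "within", "normal", "limits", "chest",
  "clear", "heart", "regular", "rhythm", "abdomen", "soft", "nontender",
  "extremities", "warm", "neuro", "intact", "alert", "oriented",
  "respiratory", "effort", "good", "skin", "dry", "mucosa", "moist",
  "continue", "monitor", "discharge", "home", "instructions", "given",
  "tolerating", "diet", "ambulating", "without", "difficulty", "wound",
  "healing", "well", "acute", "distress", "assessment", "impression",
  "discussed", "encounter", "note", "signed", "medications", "reconciled",
  "allergies", "none", "reported", "sleep", "appetite", "improved",
  "symptoms", "resolving", "recommend", "hydration", "rest", "recheck",
  "weeks", "appointment", "scheduled", "counseling", "provided", "family",
  "present", "agreeable", "questions", "answered", "return",
  "precautions", "explained", "gait", "steady", "pupils", "reactive",
  "breath", "sounds", "bilaterally", "murmur", "appreciated", "bowel",
  "active", "edema", "noted", "cooperative", "pleasant", "histories",
  "obtained", "records", "requested", "imaging", "pending", "results",
  "stable", "overall", "progress", "satisfactory")

.error_surfaces <- c(malformed_roman = "iiii",
                     bad_ordinal = "1rd",
                     invalid_date = "june 31",
                     implausible_age = "135 year old")

#' Specify a concept phrase to inject into a synthetic corpus
#'
#' A spec pairs a phrase template with a numeric slot (`"<N>"`) and a value,
#' the per-variant usage probabilities (Arabic digits, strict Roman
#' numeral, cardinal words -- summing to 1), the per-patient prevalence of
#' the concept, and per-note rates at which standalone error forms
#' (malformed Roman, bad ordinal suffix, invalid date, implausible age) are
#' injected.
#'
#' @param template Phrase with exactly one `"<N>"` slot, e.g.
#'   `"stage <N> chronic kidney disease"`.
#' @param value Integer filled into the slot (1..999 so that all three
#'   variant spellings exist).
#' @param p_arabic,p_roman,p_word Variant probabilities, summing to 1.
#' @param prevalence Probability that a patient carries the concept.
#' @param error_rates Named numeric vector with per-note injection rates
#'   for `malformed_roman`, `bad_ordinal`, `invalid_date`,
#'   `implausible_age`.
#' @return An object of class `injection_spec`.
#' @export
injection_spec <- function(template, value, p_arabic = 1, p_roman = 0,
                           p_word = 0, prevalence = 0.1,
                           error_rates = c(malformed_roman = 0,
                                           bad_ordinal = 0,
                                           invalid_date = 0,
                                           implausible_age = 0)) {
  if (!grepl("<N>", template, fixed = TRUE)) {
    stop("config error: template must contain the numeric slot '<N>'")
  }
  probs <- c(p_arabic, p_roman, p_word)
  if (any(probs < 0) || any(probs > 1) || abs(sum(probs) - 1) > 1e-9) {
    stop("config error: variant probabilities must lie in [0,1] and sum to 1")
  }
  if (prevalence < 0 || prevalence > 1) {
    stop("config error: prevalence must lie in [0,1]")
  }
  stopifnot(length(value) == 1L, value == trunc(value), value >= 1,
            value <= 999)
  er <- c(malformed_roman = 0, bad_ordinal = 0, invalid_date = 0,
          implausible_age = 0)
  if (length(error_rates)) {
    bad <- setdiff(names(error_rates), names(er))
    if (length(bad) || is.null(names(error_rates))) {
      stop("config error: unknown error_rates entries: ",
           paste(bad, collapse = ", "))
    }
    er[names(error_rates)] <- error_rates
  }
  if (any(er < 0) || any(er > 1)) {
    stop("config error: error rates must lie in [0,1]")
  }
  structure(list(template = template, value = as.integer(value),
                 p_arabic = p_arabic, p_roman = p_roman, p_word = p_word,
                 prevalence = prevalence, error_rates = er),
            class = "injection_spec")
}

# The three variant spellings of a spec's phrase, named by variant.
.spec_variants <- function(sp) {
  reprs <- c(arabic = as.character(sp$value),
             roman = tolower(int_to_roman(sp$value)),
             word = int_to_cardinal_words(sp$value))
  vapply(reprs, function(r) {
    tolower(sub("<N>", r, sp$template, fixed = TRUE))
  }, character(1))
}

# The concept key under which a spec's injections are ledgered.
.spec_concept <- function(sp) {
  tolower(sub("<N>", sp$value, sp$template, fixed = TRUE))
}

#' Default injection specs
#'
#' Two concepts with an Arabic-dominant and a mixed Arabic/Roman/word
#' variant usage, plus low rates of the four error forms. These are the
#' conditions the package's own synthetic experiments run under; the
#' prevalences and mixtures are synthetic choices, not estimates of any
#' real corpus.
#'
#' @return List of `injection_spec` objects.
#' @export
default_specs <- function() {
  list(
    injection_spec("stage <N> chronic kidney disease", 3,
                   p_arabic = 0.6, p_roman = 0.35, p_word = 0.05,
                   prevalence = 0.10,
                   error_rates = c(malformed_roman = 0.002,
                                   bad_ordinal = 0.002,
                                   invalid_date = 0.002,
                                   implausible_age = 0.001)),
    injection_spec("type <N> diabetes mellitus", 2,
                   p_arabic = 0.8, p_roman = 0.15, p_word = 0.05,
                   prevalence = 0.20))
}

#' Generate a synthetic note corpus with a ground-truth ledger
#'
#' Draws, for each patient, a note count from a truncated geometric
#' distribution; marks each patient as carrying each concept with the
#' spec's prevalence; injects one variant of the concept phrase (drawn from
#' the spec's variant probabilities) into every note of a carrying patient;
#' and appends standalone error-form sentences at the spec's per-note
#' rates. All randomness flows through R's RNG seeded once from `seed`, so
#' a fixed seed reproduces the corpus byte for byte. Filler text cannot
#' contain any injected phrase (the filler vocabulary excludes their
#' tokens) and a post-generation scan verifies this.
#'
#' @param specs An `injection_spec` or list of them.
#' @param n_patients Number of patients, `>= 1`.
#' @param seed Integer seed.
#' @param notes_mean Mean of the (untruncated) geometric note count.
#' @param notes_max Maximum notes per patient.
#' @param filler_words Filler words per note.
#' @return List with `corpus` (a data frame with `doc_id`, `patient_id`,
#'   `text`) and `ledger` (class `ground_truth_ledger`, with `injections`
#'   and `errors` data frames).
#' @export
#' @examples
#' gen <- generate_corpus(default_specs(), n_patients = 50, seed = 1)
#' head(gen$ledger$injections)
generate_corpus <- function(specs, n_patients, seed,
                            notes_mean = 3, notes_max = 20,
                            filler_words = 30) {
  if (inherits(specs, "injection_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1),
                                    "injection_spec"))) {
    stop("config error: specs must be injection_spec objects")
  }
  stopifnot(n_patients >= 1, notes_mean >= 1, notes_max >= 1,
            filler_words >= 1)
  set.seed(as.integer(seed))

  pid <- sprintf("p%05d", seq_len(n_patients))
  n_notes <- pmin(stats::rgeom(n_patients, prob = 1 / notes_mean) + 1L,
                  as.integer(notes_max))
  doc_pid <- rep(pid, n_notes)
  doc_id <- sprintf("%s-n%02d", doc_pid, sequence(n_notes))
  nd <- length(doc_id)

  variant_tab <- lapply(specs, .spec_variants)
  forbidden <- unique(unlist(c(lapply(variant_tab, function(v) {
    unlist(tokenize(v))
  }), tokenize(.error_surfaces))))
  pool <- setdiff(.filler_vocab, forbidden)
  if (length(pool) < 25) {
    stop("config error: filler vocabulary too small after excluding phrase tokens")
  }
  w <- sample(pool, nd * filler_words, replace = TRUE)
  filler <- apply(matrix(w, nrow = filler_words), 2L, paste, collapse = " ")

  extra <- vector("list", nd)
  inj_rows <- list()
  err_rows <- list()
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    variants <- variant_tab[[si]]
    concept <- .spec_concept(sp)
    carrier <- stats::runif(n_patients) < sp$prevalence
    affdocs <- which(doc_pid %in% pid[carrier])
    if (length(affdocs)) {
      v <- sample(names(variants), length(affdocs), replace = TRUE,
                  prob = c(sp$p_arabic, sp$p_roman, sp$p_word))
      surf <- unname(variants[v])
      for (j in seq_along(affdocs)) {
        k <- affdocs[j]
        extra[[k]] <- c(extra[[k]], surf[j])
      }
      inj_rows[[si]] <- data.frame(concept = concept,
                                   patient_id = doc_pid[affdocs],
                                   doc_id = doc_id[affdocs],
                                   variant = v, surface = surf,
                                   stringsAsFactors = FALSE)
    }
    for (etype in names(sp$error_rates)) {
      rate <- sp$error_rates[[etype]]
      if (rate <= 0) next
      sel <- which(stats::runif(nd) < rate)
      if (!length(sel)) next
      es <- .error_surfaces[[etype]]
      for (k in sel) extra[[k]] <- c(extra[[k]], es)
      err_rows[[length(err_rows) + 1L]] <-
        data.frame(type = etype, doc_id = doc_id[sel], surface = es,
                   stringsAsFactors = FALSE)
    }
  }

  # filler hygiene: no injected phrase may occur outside its ledger entry
  for (s in unlist(variant_tab)) {
    if (any(grepl(s, filler, fixed = TRUE))) {
      stop("filler hygiene violation: '", s, "' occurs in filler text")
    }
  }

  text <- filler
  has_extra <- lengths(extra) > 0L
  text[has_extra] <- vapply(which(has_extra), function(k) {
    paste(c(filler[k], extra[[k]]), collapse = " . ")
  }, character(1))

  corpus <- data.frame(doc_id = doc_id, patient_id = doc_pid, text = text,
                       stringsAsFactors = FALSE)
  empty_inj <- data.frame(concept = character(0), patient_id = character(0),
                          doc_id = character(0), variant = character(0),
                          surface = character(0), stringsAsFactors = FALSE)
  empty_err <- data.frame(type = character(0), doc_id = character(0),
                          surface = character(0), stringsAsFactors = FALSE)
  injections <- if (length(inj_rows)) {
    do.call(rbind, c(inj_rows, list(empty_inj)))
  } else {
    empty_inj
  }
  errors <- if (length(err_rows)) do.call(rbind, err_rows) else empty_err
  rownames(injections) <- rownames(errors) <- NULL
  ledger <- structure(list(injections = injections, errors = errors,
                           seed = as.integer(seed)),
                      class = "ground_truth_ledger")
  list(corpus = corpus, ledger = ledger)
}

#' @export
print.ground_truth_ledger <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_ledger> %d injections over %d concepts, %d error forms (seed %d)\n",
    nrow(x$injections), length(unique(x$injections$concept)),
    nrow(x$errors), x$seed))
  invisible(x)
}

#' Ground-truth overlap counts for a concept
#'
#' Collapses the ledger's per-note injections to patient level and returns
#' the Arabic-only / both / Roman-only patient counts -- the oracle that
#' [compute_overlap()] on the generated corpus must reproduce exactly.
#' Patients who only ever received the spelled-out word variant are found
#' by neither numeral search and appear in none of the three counts.
#'
#' @param ledger A `ground_truth_ledger`.
#' @param concept Concept key: the template with its Arabic value filled
#'   in, lowercase (e.g. `"stage 3 chronic kidney disease"`).
#' @return Named integer vector `c(n1_only, n_both, n2_only)`.
#' @export
ledger_counts <- function(ledger, concept) {
  stopifnot(inherits(ledger, "ground_truth_ledger"))
  inj <- ledger$injections
  if (!concept %in% inj$concept) stop("unknown concept: ", concept)
  sub <- inj[inj$concept == concept, ]
  has_a <- tapply(sub$variant == "arabic", sub$patient_id, any)
  has_r <- tapply(sub$variant == "roman", sub$patient_id, any)
  c(n1_only = sum(has_a & !has_r),
    n_both = sum(has_a & has_r),
    n2_only = sum(!has_a & has_r))
}

#' Write a ground-truth ledger as delimited text
#'
#' Two tab-separated files: `<stem>_injections.tsv` and
#' `<stem>_errors.tsv`.
#'
#' @param ledger A `ground_truth_ledger`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_ledger <- function(ledger, stem) {
  stopifnot(inherits(ledger, "ground_truth_ledger"))
  paths <- paste0(stem, c("_injections.tsv", "_errors.tsv"))
  utils::write.table(ledger$injections, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ledger$errors, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
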