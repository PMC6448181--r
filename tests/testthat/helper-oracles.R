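# Independent oracles, coded without reference to the package internals.

# Ordinal suffix oracle: explicit last-two-digit lookup table.
oracle_ordinal_suffix <- local({
  tab <- rep("th", 100)
  names(tab) <- sprintf("%02d", 0:99)
  tab[sprintf("%02d", c(1, 21, 31, 41, 51, 61, 71, 81, 91))] <- "st"
  tab[sprintf("%02d", c(2, 22, 32, 42, 52, 62, 72, 82, 92))] <- "nd"
  tab[sprintf("%02d", c(3, 23, 33, 43, 53, 63, 73, 83, 93))] <- "rd"
  function(n) unname(tab[sprintf("%02d", n %% 100)])
})

# Calendar oracle: delegate month-length knowledge to base R's Date
# parser, using a leap year (2000) or a common year (2001) to encode the
# February-29 policy.
oracle_valid_date <- function(month, day, lenient_feb29 = TRUE) {
  year <- if (lenient_feb29) 2000 else 2001
  !is.na(as.Date(sprintf("%d-%02d-%02d", year, month, day),
                 format = "%Y-%m-%d", optional = TRUE))
}

# A small fixed corpus with known patient-level phrase membership.
tiny_corpus <- function() {
  data.frame(
    doc_id = c("d1", "d2", "d3", "d4", "d5", "d6"),
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p4"),
    text = c("stage 3 chronic kidney disease noted",
             "stage iii chronic kidney disease stable",
             "stage 3 chronic kidney disease followup",
             "stage iii chronic kidney disease again stage iii chronic kidney disease",
             "unrelated note about followup",
             "type 2 diabetes mellitus"),
    stringsAsFactors = FALSE)
}
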