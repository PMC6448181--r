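test_that("strict Roman numeral conversion matches published spellings", {
  expect_identical(int_to_roman(28), "XXVIII")
  expect_identical(int_to_roman(39), "XXXIX")
  expect_identical(int_to_roman(1), "I")
  expect_identical(int_to_roman(1994), "MCMXCIV")
  expect_error(int_to_roman(0), "between 1 and 3999")
  expect_error(int_to_roman(4000), "between 1 and 3999")
})

test_that("malformed Roman generation yields the additive i-run series", {
  for (n in 4:9) {
    out <- generate_malformed_romans(n)
    expect_true(strrep("i", n) %in% out$text)
    expect_false(tolower(int_to_roman(n)) %in% out$text)
    expect_true(all(out$validity == "malformed"))
    expect_true(all(out$canonical_value == as.character(n)))
  }
  # i-run suppressed when it exceeds max_run
  expect_false("iiiiiiii" %in% generate_malformed_romans(8, max_run = 7)$text)
  # general additive spelling behind the flag
  expect_true("viiii" %in%
                generate_malformed_romans(9, include_other = TRUE)$text)
})

test_that("cardinal words use hyphenated tens-units compounds", {
  expect_identical(int_to_cardinal_words(33), "thirty-three")
  expect_identical(int_to_cardinal_words(73), "seventy-three")
  expect_identical(int_to_cardinal_words(0), "zero")
  expect_identical(int_to_cardinal_words(100), "one hundred")
  expect_identical(int_to_cardinal_words(215), "two hundred fifteen")
  expect_identical(int_to_cardinal_words(999), "nine hundred ninety-nine")
  expect_error(int_to_cardinal_words(1000), "between 0 and 999")
  expect_error(int_to_cardinal_words(-1), "between 0 and 999")
})

test_that("ordinal suffix follows the last-two-digit rule", {
  expect_identical(ordinal_suffix(1), "st")
  expect_identical(ordinal_suffix(3), "rd")
  expect_identical(ordinal_suffix(11), "th")
  expect_identical(ordinal_suffix(21), "st")
  expect_identical(ordinal_suffix(111), "th")
})

test_that("ordinal variants cover suffix grid, words, and hybrids", {
  v1 <- generate_ordinal_variants(1)
  expect_identical(v1$validity[v1$text == "1st"], "well_formed")
  for (bad in c("1rd", "1nd", "1th")) {
    expect_identical(v1$validity[v1$text == bad], "malformed")
  }
  expect_true(all(c("first", "firstly", "1stly", "primary", "1ary")
                  %in% v1$text))
  v2 <- generate_ordinal_variants(2)
  expect_identical(v2$validity[v2$text == "2ndary"], "malformed")
  expect_true("2ary" %in% v2$text)
  v3 <- generate_ordinal_variants(3)
  expect_identical(v3$validity[v3$text == "3rdly"], "malformed")
  # no -ary series beyond quaternary
  expect_false(any(grepl("ary$", generate_ordinal_variants(5)$text)))
})

test_that("fraction phrases agree in number, with optional error forms", {
  expect_identical(fraction_phrase(1, 3)$text, "one third")
  expect_identical(fraction_phrase(1, 2)$text, "one half")
  expect_identical(fraction_phrase(2, 2)$text, "two halves")
  expect_identical(fraction_phrase(2, 3)$text, "two thirds")
  err <- fraction_phrase(1, 3, include_errors = TRUE)
  expect_identical(err$text[err$validity == "malformed"], "one thirds")
  expect_true(all(err$canonical_value == "1/3"))
})

test_that("dimension and range phrases spell both operands", {
  expect_identical(dimension_phrase(2, 4), "two by four")
  expect_identical(dimension_phrase(1, 3), "one by three")
  expect_identical(dimension_phrase(1, 1), "one by one")
  expect_identical(range_phrase(1, 3), "one to three")
  expect_identical(range_phrase(5, 5), "five to five")
})

test_that("negative forms cover the four spelled/mixed variants", {
  f5 <- negative_forms(5)
  expect_setequal(f5$text,
                  c("minus five", "minus 5", "negative five", "negative 5"))
  expect_true(all(f5$canonical_value == "-5"))
  expect_true("negative one" %in% negative_forms(1)$text)
  expect_true("negative 10" %in% negative_forms(10)$text)
})

test_that("date strings carry calendar validity", {
  expect_identical(unique(date_strings(1, 35)$validity), "invalid_value")
  june31 <- date_strings(6, 31, with_suffix = TRUE)
  expect_true("june 31st" %in% june31$text)
  expect_identical(unique(june31$validity), "invalid_value")
  expect_identical(unique(date_strings(1, 31)$validity), "well_formed")
  expect_identical(date_strings(2, 29)$validity, "well_formed")
  expect_identical(date_strings(2, 29, leap_policy = "strict_feb29")$validity,
                   "invalid_value")
})

test_that("age phrases flag implausible ages", {
  expect_identical(unique(age_phrases(135)$validity), "invalid_value")
  expect_identical(unique(age_phrases(122)$validity), "well_formed")
  expect_identical(unique(age_phrases(0)$validity), "well_formed")
  expect_true("135-year-old" %in% age_phrases(135)$text)
})

test_that("decade terms resolve to the most specific bracket", {
  expect_identical(decade_age_term(75), "septuagenarian")
  expect_identical(decade_age_term(85), "octogenarian")
  expect_identical(decade_age_term(105), "centenarian")
  expect_identical(decade_age_term(112), "supercentenarian")
  expect_identical(decade_age_term(45), NA_character_)
})

test_that("tuple terms include morphology and offspring words", {
  t3 <- tuple_terms(3)$text
  expect_setequal(t3, c("triple", "tripling", "tripled", "triples",
                        "triplets"))
  expect_true("singleton" %in% tuple_terms(1)$text)
  t2 <- tuple_terms(2)$text
  expect_true("twins" %in% t2)
  expect_false("doublets" %in% t2)
})

test_that("classification variants emit Arabic, Roman, and compound forms", {
  expect_setequal(classification_variants("type", 2)$text,
                  c("type 2", "type ii"))
  expect_setequal(classification_variants("score", 4)$text,
                  c("score 4", "score iv"))
  s3b <- classification_variants("stage", 3, "b")
  expect_true(all(c("3b", "iiib") %in% s3b$text))
  # roman+letter compounds that read as Roman numerals are withheld
  c5i <- classification_variants("class", 5, "i")
  expect_false("vi" %in% c5i$text)
  expect_true("5i" %in% c5i$text)
  expect_error(classification_variants("level", 2), "prefix")
})

test_that("phrase expansion substitutes all numeric spellings", {
  ckd <- expand_phrase("stage 3 chronic kidney disease")
  expect_true("stage iii chronic kidney disease" %in% ckd)
  expect_true("stage three chronic kidney disease" %in% ckd)
  dm <- expand_phrase("type 2 diabetes mellitus")
  expect_true("type ii diabetes mellitus" %in% dm)
  expect_identical(expand_phrase("no numbers here"), "no numbers here")
  expect_error(expand_phrase("2 by 4"), "more than one numeric token")
})

test_that("phrase expansion is reflexive and deterministic", {
  phrases <- c("stage 3 chronic kidney disease", "phase i clinical trial",
               "mallampati score: iv", "grade three anaplastic astrocytoma",
               "no numbers here")
  for (p in phrases) {
    out <- expand_phrase(p)
    expect_true(any(out == tolower(p)) ||
                  any(out == paste(tokenize(p)[[1]], collapse = " ")))
    expect_identical(out, expand_phrase(p))
  }
})
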