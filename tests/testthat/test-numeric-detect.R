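test_that("strict parsing inverts strict generation; lenient extends it", {
  for (n in c(1, 4, 9, 14, 39, 40, 90, 444, 1994, 3999)) {
    r <- parse_roman(int_to_roman(n), "strict")
    expect_identical(r$value, as.integer(n))
    expect_true(r$well_formed)
    # lenient agrees wherever strict accepts
    expect_identical(parse_roman(int_to_roman(n), "lenient")$value,
                     as.integer(n))
  }
  expect_identical(parse_roman("XV", "strict")$value, 15L)
  l <- parse_roman("IIII", "lenient")
  expect_identical(l$value, 4L)
  expect_false(l$well_formed)
  expect_error(parse_roman("IIII", "strict"), "canonical")
  expect_error(parse_roman("ABC", "lenient"), "not a Roman numeral")
  expect_error(parse_roman("IIX", "lenient"), "parseable")
  expect_error(parse_roman("", "lenient"), "not a Roman numeral")
})

test_that("date validity matches an independent calendar oracle", {
  expect_false(is_valid_date(6, 31))
  expect_false(is_valid_date(2, 30))
  expect_true(is_valid_date(1, 31))
  expect_true(is_valid_date(2, 29))
  expect_false(is_valid_date(2, 29, "strict_feb29"))
  for (m in c(2, 4, 6, 9, 12)) {
    for (d in c(1, 28, 29, 30, 31, 35)) {
      expect_identical(is_valid_date(m, d), oracle_valid_date(m, d, TRUE),
                       info = sprintf("month %d day %d", m, d))
    }
  }
  expect_error(is_valid_date(13, 1), "month")
  expect_error(is_valid_date(0, 1), "month")
})

test_that("age plausibility flips at the documented lifespan record", {
  expect_true(is_plausible_age(122))
  expect_false(is_plausible_age(123))
  expect_true(is_plausible_age(0))
  expect_false(is_plausible_age(90, bound = 89))
  expect_error(is_plausible_age(-1), "age")
})

test_that("ordinal checking follows the suffix rule", {
  expect_true(check_ordinal("1", "st"))
  expect_false(check_ordinal("1", "rd"))
  expect_true(check_ordinal("11", "th"))
  expect_true(check_ordinal("21", "st"))
})

test_that("classification priority beats Roman reading for compounds", {
  expect_identical(classify_surface("iiib")$category,
                   "medical_classification")
  expect_identical(classify_surface("iiib")$canonical_value, "3b")
  expect_identical(classify_surface("3b")$canonical_value, "3b")
  expect_identical(classify_surface("iiii")$category, "roman_numeral")
  tid <- classify_surface("type iiii")
  expect_identical(tid$category, "medical_classification")
  expect_identical(tid$validity, "malformed")
})

test_that("classify_surface handles the category inventory", {
  expect_identical(classify_surface("january 35")$validity, "invalid_value")
  expect_identical(classify_surface("xv")$canonical_value, "15")
  expect_identical(classify_surface("type ii")$canonical_value, "type:2")
  expect_identical(classify_surface("135 year old")$validity,
                   "invalid_value")
  expect_identical(classify_surface("one to three")$category, "range_odds")
  expect_identical(classify_surface("two by four")$category, "dimension")
  expect_identical(classify_surface("minus five")$canonical_value, "-5")
  expect_identical(classify_surface("thirty three")$canonical_value, "33")
  expect_identical(classify_surface("billion")$canonical_value, "9")
  expect_identical(classify_surface("googol")$canonical_value, "100")
  expect_identical(classify_surface("twins")$canonical_value, "2")
  expect_identical(classify_surface("hello")$category, "unclassified")
})

test_that("classify_surface is total and idempotent in category", {
  set.seed(7)
  alphabet <- c(letters, 0:9, " ", "-")
  for (k in 1:200) {
    s <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE),
               collapse = "")
    if (!nzchar(trimws(s))) s <- "x"
    sf <- classify_surface(s)
    expect_s3_class(sf, "surface_form")
    expect_identical(classify_surface(sf$text)$category, sf$category)
  }
})

test_that("every generator output classifies back to itself", {
  check_duality <- function(forms) {
    for (i in seq_len(nrow(forms))) {
      sf <- classify_surface(forms$text[i])
      expect_identical(sf$category, forms$category[i], info = forms$text[i])
      expect_identical(sf$canonical_value, forms$canonical_value[i],
                       info = forms$text[i])
      expect_identical(sf$validity, forms$validity[i], info = forms$text[i])
    }
  }
  check_duality(generate_ordinal_variants(3))
  check_duality(fraction_phrase(2, 5, include_errors = TRUE))
  check_duality(negative_forms(7))
  check_duality(date_strings(11, 31, with_suffix = TRUE))
  check_duality(age_phrases(140))
  check_duality(tuple_terms(4))
  check_duality(classification_variants("grade", 4, "a"))
  check_duality(generate_malformed_romans(6))
})

test_that("annotation marks numerals and flags ambiguous tokens", {
  ann <- annotate_document(c("type", "ii", "diabetes"))
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$surface, "ii")
  expect_identical(ann$category, "roman_numeral")
  expect_identical(ann$canonical_value, "2")
  expect_false(ann$ambiguous)

  ann <- annotate_document(c("given", "iv", "fluids"))
  expect_identical(ann$surface, "iv")
  expect_true(ann$ambiguous)
  expect_true(is.na(ann$canonical_value))  # left un-normalized

  expect_identical(nrow(annotate_document(character(0))), 0L)
})

test_that("annotation spans are non-overlapping and longest-match", {
  toks <- tokenize("pt is a 135 year old with stage iii ckd seen june 31st")[[1]]
  ann <- annotate_document(toks)
  expect_true("135 year old" %in% ann$surface)
  expect_true("june 31st" %in% ann$surface)
  expect_true("iii" %in% ann$surface)
  ord <- order(ann$start)
  expect_true(all(ann$end[ord][-nrow(ann)] <= ann$start[ord][-1]))
  tmp <- tempfile(fileext = ".tsv")
  write_annotations(ann, "doc1", tmp)
  back <- read.delim(tmp)
  expect_identical(nrow(back), nrow(ann))
})
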