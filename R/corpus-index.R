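# Tokenization, positional inverted indexing, and phrase search.
#
# The tokenizer contract is deliberately simple: lowercase maximal runs of
# letters and digits. Mixed alphanumeric runs ("t2dm", "3b") stay single
# tokens; every other character -- including hyphens and colons -- is a
# separator and is discarded. Stop words are indexed like any other token:
# in clinical text, common function words double as medical acronyms
# (IS, AND, OR), so dropping them would lose real content.
#
# The index stores, per token, a vector of occurrence codes doc * M + pos
# (M a fixed positional radix). Phrase search intersects shifted occurrence
# codes, which yields exact consecutive-position (no slop) matching.

.POS_RADIX <- 2^20  # max tokens per document

#' Tokenize text
#'
#' Lowercases and extracts maximal runs of ASCII letters and digits.
#' Punctuation (including hyphens and colons) separates tokens and is
#' discarded, so `"thirty-three"` becomes `c("thirty", "three")` while
#' `"T2DM"` stays one token.
#'
#' @param text Character vector of documents.
#' @return A list of character vectors, one per input element (like
#'   [strsplit()]).
#' @export
#' @examples
#' tokenize("Mallampati score: IV")[[1]]  # "mallampati" "score" "iv"
tokenize <- function(text) {
  stopifnot(is.character(text))
  regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))
}

#' Build a positional inverted index over a note corpus
#'
#' @param docs Data frame with columns `doc_id` (unique), `patient_id`, and
#'   `text`. Many documents may share a `patient_id`.
#' @return An object of class `note_index`.
#' @export
#' @examples
#' idx <- build_index(data.frame(doc_id = "d1", patient_id = "p1",
#'                               text = "type II diabetes"))
#' phrase_search(idx, "type ii")
build_index <- function(docs) {
  stopifnot(is.data.frame(docs),
            all(c("doc_id", "patient_id", "text") %in% names(docs)))
  if (anyDuplicated(docs$doc_id)) stop("duplicate doc_id in corpus")
  toks <- tokenize(as.character(docs$text))
  nt <- lengths(toks)
  if (any(nt >= .POS_RADIX)) stop("document too long to index")
  doc_i <- rep.int(seq_len(nrow(docs)), nt)
  pos <- sequence(nt)
  enc <- doc_i * .POS_RADIX + pos
  postings <- split(enc, unlist(toks, use.names = FALSE))
  structure(list(postings = postings,
                 doc_id = as.character(docs$doc_id),
                 patient_id = as.character(docs$patient_id),
                 n_docs = nrow(docs),
                 radix = .POS_RADIX,
                 version = 1L),
            class = "note_index")
}

#' @export
print.note_index <- function(x, ...) {
  cat(sprintf("<note_index> %d documents, %d patients, %d distinct tokens\n",
              x$n_docs, length(unique(x$patient_id)), length(x$postings)))
  invisible(x)
}

#' Exact phrase search
#'
#' Returns the identifiers of documents containing the phrase's tokens at
#' consecutive positions. Matching is case-insensitive (both the index and
#' the query pass through [tokenize()]) and a document is returned once
#' regardless of how often the phrase occurs in it.
#'
#' @param index A `note_index`.
#' @param phrase Query phrase; must yield at least one token.
#' @return Character vector of matching `doc_id`s (corpus order).
#' @export
phrase_search <- function(index, phrase) {
  stopifnot(inherits(index, "note_index"), is.character(phrase),
            length(phrase) == 1L)
  toks <- tokenize(phrase)[[1]]
  if (!length(toks)) stop("phrase contains no tokens")
  cand <- index$postings[[toks[1]]]
  if (is.null(cand)) return(character(0))
  for (k in seq_along(toks)[-1]) {
    nxt <- index$postings[[toks[k]]]
    if (is.null(nxt)) return(character(0))
    cand <- cand[(cand + (k - 1)) %in% nxt]
    if (!length(cand)) return(character(0))
  }
  index$doc_id[sort(unique(cand %/% index$radix))]
}

#' Distinct patients owning a set of documents
#'
#' @param index A `note_index`.
#' @param doc_ids Document identifiers, all present in the index.
#' @return Sorted character vector of distinct `patient_id`s.
#' @export
patient_set <- function(index, doc_ids) {
  stopifnot(inherits(index, "note_index"))
  if (!length(doc_ids)) return(character(0))
  i <- match(doc_ids, index$doc_id)
  if (anyNA(i)) {
    stop("unknown doc_id: ", paste(doc_ids[is.na(i)], collapse = ", "))
  }
  sort(unique(index$patient_id[i]))
}

#' Read and write the corpus exchange format
#'
#' One record per line, tab-separated, with header and columns `doc_id`,
#' `patient_id`, `text`. Tabs and newlines inside `text` are flattened to
#' spaces on write (the tokenizer treats them as separators anyway).
#'
#' @param docs Corpus data frame.
#' @param path File path.
#' @return `write_corpus` returns the path invisibly; `read_corpus` returns
#'   the corpus data frame.
#' @export
write_corpus <- function(docs, path) {
  stopifnot(all(c("doc_id", "patient_id", "text") %in% names(docs)))
  out <- docs[, c("doc_id", "patient_id", "text")]
  out$text <- gsub("[\t\r\n]+", " ", out$text)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  utils::read.delim(path, colClasses = "character", quote = "",
                    comment.char = "")
}

#' Read and write an index snapshot
#'
#' Single-file plain-text snapshot with a versioned header, the document
#' table, and one line per token carrying its encoded occurrence list.
#'
#' @param index A `note_index`.
#' @param path File path.
#' @return `write_index` returns the path invisibly; `read_index` returns
#'   the reconstructed `note_index`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "note_index"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#clinnum_index\t%d\t%d\t%.0f", index$version,
                     index$n_docs, index$radix), con)
  writeLines(paste(index$doc_id, index$patient_id, sep = "\t"), con)
  writeLines(sprintf("#postings\t%d", length(index$postings)), con)
  writeLines(paste(names(index$postings),
                   vapply(index$postings,
                          function(v) paste(format(v, scientific = FALSE,
                                                   trim = TRUE),
                                            collapse = ","),
                          character(1)),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop("index snapshot does not exist: ", path)
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#clinnum_index") stop("not an index snapshot: ", path)
  n_docs <- as.integer(hdr[3])
  radix <- as.numeric(hdr[4])
  doc_rows <- strsplit(lines[seq_len(n_docs) + 1L], "\t", fixed = TRUE)
  plines <- lines[-seq_len(n_docs + 2L)]
  fields <- strsplit(plines, "\t", fixed = TRUE)
  postings <- lapply(fields, function(f) {
    as.numeric(strsplit(f[2], ",", fixed = TRUE)[[1]])
  })
  names(postings) <- vapply(fields, `[`, character(1), 1L)
  structure(list(postings = postings,
                 doc_id = vapply(doc_rows, `[`, character(1), 1L),
                 patient_id = vapply(doc_rows, `[`, character(1), 2L),
                 n_docs = n_docs,
                 radix = radix,
                 version = as.integer(hdr[2])),
            class = "note_index")
}
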