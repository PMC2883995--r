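#' Construct an onym lexicon
#'
#' An onym lexicon is a set of word records, each carrying the synonyms and
#' antonyms listed for that word in a source dictionary ("onym" is the
#' umbrella term for either relation). Duplicate records for the same word
#' are merged by set union, tokens are trimmed of surrounding whitespace
#' (no case folding: dictionaries distinguish entries), and a word is never
#' kept in its own synonym or antonym set.
#'
#' @param words character vector of head words.
#' @param synonyms list of character vectors, one per head word.
#' @param antonyms list of character vectors, one per head word.
#' @return An object of class `onym_lexicon`: a list with elements `word`,
#'   `synonyms` and `antonyms` (parallel lists), in first-seen word order.
#' @examples
#' lex <- onym_lexicon("good", list(c("fine", "nice")), list("bad"))
#' lex
#' @export
onym_lexicon <- function(words, synonyms = NULL, antonyms = NULL) {
  words <- trimws(as.character(words))
  n <- length(words)
  if (is.null(synonyms)) synonyms <- rep(list(character()), n)
  if (is.null(antonyms)) antonyms <- rep(list(character()), n)
  if (length(synonyms) != n || length(antonyms) != n)
    stop("`synonyms` and `antonyms` must have one entry per word")
  if (any(!nzchar(words))) stop("empty word token in lexicon")
  clean <- function(x) {
    x <- trimws(as.character(x))
    unique(x[nzchar(x)])
  }
  synonyms <- lapply(synonyms, clean)
  antonyms <- lapply(antonyms, clean)

  # merge duplicate head words by set union, preserving first-seen order
  ord <- !duplicated(words)
  uw <- words[ord]
  idx <- match(words, uw)
  syn <- rep(list(character()), length(uw))
  ant <- rep(list(character()), length(uw))
  for (k in seq_len(n)) {
    i <- idx[k]
    syn[[i]] <- union(syn[[i]], synonyms[[k]])
    ant[[i]] <- union(ant[[i]], antonyms[[k]])
  }
  for (i in seq_along(uw)) {
    syn[[i]] <- setdiff(syn[[i]], uw[i])
    ant[[i]] <- setdiff(ant[[i]], uw[i])
  }
  structure(list(word = uw, synonyms = syn, antonyms = ant),
            class = "onym_lexicon")
}

#' Read an onym lexicon from disk
#'
#' Two plain-text dialects are supported. `jsonl`: one JSON object per line
#' with keys `word`, `synonyms`, `antonyms` (arrays of strings). `tsv`:
#' three tab-separated columns (word, comma-separated synonyms,
#' comma-separated antonyms) with a header row; an empty cell is an empty
#' set. Records sharing a head word are merged by set union.
#'
#' @param path path to the dictionary file.
#' @param dialect `"jsonl"` or `"tsv"`.
#' @return An [onym_lexicon] object.
#' @export
read_onym_lexicon <- function(path, dialect = c("jsonl", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
      return(onym_lexicon(character()))
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$word))
        stop("malformed JSONL record at line ", i, " of ", path)
      recs[[i]] <- rec
    }
    onym_lexicon(vapply(recs, function(r) as.character(r$word)[1],
                        character(1)),
                 lapply(recs, function(r) as.character(r$synonyms)),
                 lapply(recs, function(r) as.character(r$antonyms)))
  } else {
    tab <- tryCatch(
      utils::read.delim(path, header = TRUE, colClasses = "character",
                        quote = "", na.strings = NULL),
      error = function(e) stop("malformed TSV in ", path, ": ",
                               conditionMessage(e)))
    if (ncol(tab) < 3L)
      stop("TSV dialect needs 3 columns (word, synonyms, antonyms), got ",
           ncol(tab), " in ", path)
    if (nrow(tab) == 0L)
      return(onym_lexicon(character()))
    split_cell <- function(x) {
      if (!nzchar(trimws(x))) character() else strsplit(x, ",", fixed = TRUE)[[1]]
    }
    onym_lexicon(tab[[1]],
                 lapply(tab[[2]], split_cell),
                 lapply(tab[[3]], split_cell))
  }
}

#' @export
print.onym_lexicon <- function(x, ...) {
  ns <- sum(lengths(x$synonyms))
  na <- sum(lengths(x$antonyms))
  cat(sprintf(
    "Onym lexicon: %d words, %d synonym listings, %d antonym listings\n",
    length(x$word), ns, na))
  invisible(x)
}

#' @export
length.onym_lexicon <- function(x) length(x$word)
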