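# Low-level text utilities shared by the taxonomy, sentiment and topic stages.

#' Split text into sentences
#'
#' Sentences end at ".", "!" or "?" followed by whitespace (or end of text);
#' a newline is also a sentence boundary. This is deliberately simple:
#' keyword disambiguation only needs sentence-level co-occurrence, not a
#' linguistically exact segmenter.
#'
#' @param text Character scalar.
#' @return Character vector of non-empty sentences.
#' @export
#' @examples
#' split_sentences("Tobacco kills. This tobacco flavor is smooth!")
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  parts <- strsplit(text, "(?:[.!?]+(?=\\s|$))|\\n+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Tokenize text into lowercase word tokens
#'
#' Tokens are maximal runs of letters, digits, apostrophes and internal
#' hyphens, lowercased. Hyphenated forms such as "e-juice" stay single
#' tokens, so hyphenated and fused spelling variants are distinct entries in
#' a keyword list.
#'
#' @param text Character vector.
#' @param lower Lowercase the tokens (default `TRUE`).
#' @return A list with one character vector of tokens per input element.
#' @export
#' @examples
#' tokenize("I love my e-juice!")
tokenize <- function(text, lower = TRUE) {
  if (lower) text <- tolower(text)
  out <- regmatches(text, gregexpr("[[:alnum:]']+(?:-[[:alnum:]']+)*", text,
                                   perl = TRUE))
  lapply(out, function(x) x[nzchar(x)])
}

#' Strip URLs and email addresses from text
#'
#' @param text Character vector.
#' @return Character vector with URLs / emails removed.
#' @export
strip_urls_emails <- function(text) {
  text <- gsub("(https?://|www\\.)[^[:space:]]+", " ", text, perl = TRUE)
  gsub("[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}", " ", text,
       perl = TRUE)
}

#' Heuristic English-language filter
#'
#' A post passes when at least `min_ascii_frac` of its word tokens consist
#' solely of ASCII letters (apostrophes and hyphens allowed). The check is a
#' pluggable default: any predicate `function(text) -> logical` can replace
#' it in [filter_corpus()].
#'
#' @param text Character vector.
#' @param min_ascii_frac Minimum fraction of ASCII-alphabetic tokens.
#' @return Logical vector, `TRUE` for texts that look English.
#' @export
is_english <- function(text, min_ascii_frac = 0.5) {
  toks <- tokenize(text, lower = FALSE)
  vapply(toks, function(tk) {
    if (length(tk) == 0L) return(FALSE)
    ok <- grepl("^[A-Za-z'-]+$", tk)
    mean(ok) >= min_ascii_frac
  }, logical(1))
}

# Default English stopword list (standard high-frequency function words).
#' English stopwords used by the mining and topic stages
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "could", "did",
    "do", "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "herself", "him", "himself", "his", "how", "i", "if", "in", "into", "is",
    "it", "its", "itself", "just", "me", "more", "most", "my", "myself",
    "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
    "other", "our", "ours", "ourselves", "out", "over", "own", "same", "she",
    "should", "so", "some", "such", "than", "that", "the", "their", "theirs",
    "them", "themselves", "then", "there", "these", "they", "this", "those",
    "through", "to", "too", "under", "until", "up", "very", "was", "we",
    "were", "what", "when", "where", "which", "while", "who", "whom", "why",
    "will", "with", "you", "your", "yours", "yourself", "yourselves",
    "it's", "i'm", "don't", "doesn't", "isn't", "aren't", "won't", "can't")
}

#' Minimal suffix-stripping lemmatizer
#'
#' A dependency-free fallback token normalizer: strips plural "-ies"/"-es"/
#' "-s" and verbal "-ing"/"-ed" suffixes with small stems left intact. It is
#' intentionally crude; any token -> lemma function can be plugged into
#' [preprocess_docs()] instead.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas.
#' @export
#' @examples
#' simple_lemmatize(c("coughing", "flavors", "batteries"))
simple_lemmatize <- function(tokens) {
  out <- tokens
  n <- nchar(out)
  i <- n > 4 & endsWith(out, "ies")
  out[i] <- paste0(substr(out[i], 1L, n[i] - 3L), "y")
  n <- nchar(out)
  i <- n > 5 & endsWith(out, "ing") & !endsWith(out, "thing")
  out[i] <- substr(out[i], 1L, n[i] - 3L)
  n <- nchar(out)
  i <- n > 4 & endsWith(out, "ed") & !endsWith(out, "eed")
  out[i] <- substr(out[i], 1L, n[i] - 2L)
  n <- nchar(out)
  i <- n > 3 & endsWith(out, "es") & endsWith(out, "sses")
  out[i] <- substr(out[i], 1L, n[i] - 2L)
  n <- nchar(out)
  i <- n > 3 & endsWith(out, "s") & !endsWith(out, "ss") & !endsWith(out, "us")
  out[i] <- substr(out[i], 1L, n[i] - 1L)
  out
}

# Escape a keyword for use in a token-boundary regex; internal whitespace
# matches any whitespace run so multi-word keywords behave as token sequences.
keyword_regex <- function(keyword) {
  esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", keyword, perl = TRUE)
  esc <- gsub("\\s+", "\\\\s+", esc)
  paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
}
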