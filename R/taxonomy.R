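# Keyword taxonomies: loading, validation, matching and disambiguation.
#
# A taxonomy groups lowercase keywords into named categories (e.g. the nine
# health-symptom categories) and optionally attaches sentence-scope
# disambiguation rules to individual keywords: an ambiguous keyword such as
# "tobacco" (a flavor name, but also the plant) only counts when the same
# sentence contains one of its context keywords ("flavor", "e-liquid", ...).

HEALTH_CATEGORIES <- c("Respiratory", "Cardiovascular", "Neurological",
                       "Psychological", "Digestive", "Mouth", "Throat",
                       "Cancer", "Other")
FLAVOR_CATEGORIES <- c("Fruit", "Menthol or Mint", "Tobacco", "Sweet",
                       "Beverage", "Mixed", "Other")

#' Construct a keyword taxonomy
#'
#' @param name Taxonomy label, one of `"ecig"`, `"health"`, `"flavor"` or any
#'   other label for ad hoc taxonomies.
#' @param categories Named list: category label -> character vector of
#'   lowercase keywords. No keyword may appear in two categories.
#' @param rules Optional list of disambiguation rules, each created by
#'   [disambiguation_rule()].
#' @param strict For `name = "health"` / `"flavor"`, require the canonical
#'   category sets (nine health categories, seven flavor categories).
#' @return An object of class `keyword_taxonomy`.
#' @export
#' @examples
#' tx <- keyword_taxonomy("ecig", list(ecig = c("vape", "e-juice")))
keyword_taxonomy <- function(name, categories, rules = list(), strict = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.list(categories),
            !is.null(names(categories)), all(nzchar(names(categories))))
  categories <- lapply(categories, function(k) unique(tolower(trimws(k))))
  kws <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(kws))
    stop("keyword(s) appear in more than one category: ",
         paste(unique(kws[duplicated(kws)]), collapse = ", "))
  if (strict && name == "health" &&
      !setequal(names(categories), HEALTH_CATEGORIES))
    stop("health taxonomy must have exactly the nine canonical categories")
  if (strict && name == "flavor" &&
      !setequal(names(categories), FLAVOR_CATEGORIES))
    stop("flavor taxonomy must have exactly the seven canonical categories")
  for (r in rules) {
    if (!inherits(r, "disambiguation_rule"))
      stop("rules must be created by disambiguation_rule()")
    if (!(r$keyword %in% kws))
      stop("rule keyword not in taxonomy: ", r$keyword)
  }
  structure(list(name = name, categories = categories,
                 rules = setNames(rules,
                                  vapply(rules, `[[`, "", "keyword"))),
            class = "keyword_taxonomy")
}

#' Sentence-scope disambiguation rule for an ambiguous keyword
#'
#' The keyword only produces a match when the sentence containing it also
#' contains at least one context keyword.
#'
#' @param keyword The ambiguous keyword (lowercase).
#' @param context Non-empty character vector of context keywords.
#' @return An object of class `disambiguation_rule`.
#' @export
disambiguation_rule <- function(keyword, context) {
  stopifnot(is.character(keyword), length(keyword) == 1L,
            is.character(context), length(context) >= 1L)
  structure(list(keyword = tolower(keyword), context = tolower(context),
                 scope = "sentence"),
            class = "disambiguation_rule")
}

#' @export
print.keyword_taxonomy <- function(x, ...) {
  cat(sprintf("<keyword_taxonomy '%s': %d categories, %d keywords, %d rules>\n",
              x$name, length(x$categories),
              length(unlist(x$categories)), length(x$rules)))
  invisible(x)
}

#' Read a taxonomy from CSV or YAML
#'
#' CSV columns: `taxonomy`, `category`, `keyword`, optional `ambiguous_flag`
#' (0/1) and `context_list` (context keywords separated by `;`). YAML layout:
#' top-level `name`, `categories` (category -> keyword list) and optional
#' `rules` (list of `{keyword, context}`).
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @param strict Passed to [keyword_taxonomy()].
#' @return A `keyword_taxonomy`.
#' @export
read_taxonomy <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rules <- lapply(y$rules, function(r)
      disambiguation_rule(r$keyword, unlist(r$context)))
    return(keyword_taxonomy(y$name,
                            lapply(y$categories, unlist),
                            rules, strict = strict))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxonomy", "category", "keyword")
  if (!all(need %in% names(df)))
    stop("taxonomy CSV needs columns: ", paste(need, collapse = ", "))
  name <- unique(df$taxonomy)
  if (length(name) != 1L) stop("taxonomy CSV mixes taxonomy labels")
  categories <- split(tolower(df$keyword), df$category)
  rules <- list()
  if ("ambiguous_flag" %in% names(df)) {
    amb <- df[!is.na(df$ambiguous_flag) & df$ambiguous_flag == 1, ,
              drop = FALSE]
    rules <- lapply(seq_len(nrow(amb)), function(i)
      disambiguation_rule(amb$keyword[i],
                          strsplit(amb$context_list[i], ";", fixed = TRUE)[[1]]))
  }
  keyword_taxonomy(name, categories, rules, strict = strict)
}

# Flat keyword table for a taxonomy: keyword, category, nchar (desc order so
# the longest keyword wins at a position, e.g. "sore throat" over "throat").
taxonomy_table <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "keyword_taxonomy"))
  df <- data.frame(
    keyword = unlist(taxonomy$categories, use.names = FALSE),
    category = rep(names(taxonomy$categories),
                   lengths(taxonomy$categories)),
    stringsAsFactors = FALSE)
  df[order(-nchar(df$keyword), df$keyword), , drop = FALSE]
}

#' Match taxonomy keywords in one post
#'
#' Case-insensitive matching on token boundaries; a keyword containing
#' spaces or hyphens matches as a contiguous token sequence. When two
#' keywords overlap at a position the longest wins (so "sore throat"
#' suppresses a separate "throat" hit). Matches of an ambiguous keyword are
#' kept only when its disambiguation rule passes in the same sentence.
#'
#' @param text Post text (title and body concatenated), character scalar.
#' @param taxonomy A `keyword_taxonomy`.
#' @param post_id Optional id copied into the result.
#' @return Data frame with columns `post_id`, `taxonomy`, `category`,
#'   `keyword`, `sentence_index` (0-based), one row per surviving
#'   (keyword, sentence) occurrence.
#' @export
#' @examples
#' tx <- keyword_taxonomy("ecig", list(ecig = "vape"))
#' match_keywords("I love my vape.", tx)
match_keywords <- function(text, taxonomy, post_id = NA_character_) {
  stopifnot(inherits(taxonomy, "keyword_taxonomy"))
  empty <- data.frame(post_id = character(0), taxonomy = character(0),
                      category = character(0), keyword = character(0),
                      sentence_index = integer(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  sentences <- split_sentences(text)
  if (length(sentences) == 0L) return(empty)
  tab <- taxonomy_table(taxonomy)
  hits <- match_keyword_spans(sentences, tab$keyword)
  if (nrow(hits) == 0L) return(empty)
  hits$category <- tab$category[hits$kw_idx]
  hits$keyword <- tab$keyword[hits$kw_idx]
  # disambiguation: keep ambiguous-keyword hits only when a context keyword
  # occurs in the same sentence
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    rule <- taxonomy$rules[[hits$keyword[i]]]
    if (!is.null(rule)) {
      sent <- tolower(sentences[hits$sentence[i]])
      keep[i] <- any(vapply(rule$context, function(ck)
        grepl(keyword_regex(ck), sent, perl = TRUE), logical(1)))
    }
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  data.frame(post_id = post_id, taxonomy = taxonomy$name,
             category = hits$category, keyword = hits$keyword,
             sentence_index = hits$sentence - 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Locate keyword occurrences in a vector of sentences, longest-keyword-wins
# at overlapping character spans. `keywords` must be sorted longest first.
# Returns data.frame(sentence, kw_idx, start, end).
match_keyword_spans <- function(sentences, keywords) {
  low <- tolower(sentences)
  recs <- vector("list", length(keywords))
  for (k in seq_along(keywords)) {
    m <- gregexpr(keyword_regex(keywords[k]), low, perl = TRUE)
    nhit <- vapply(m, function(st) if (st[1] == -1L) 0L else length(st),
                   integer(1))
    if (sum(nhit) == 0L) next
    starts <- unlist(lapply(m[nhit > 0L], as.integer))
    lens <- unlist(lapply(m[nhit > 0L], attr, "match.length"))
    recs[[k]] <- data.frame(
      sentence = rep(which(nhit > 0L), nhit[nhit > 0L]),
      kw_idx = k, start = starts, end = starts + lens - 1L)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs)) {
    return(data.frame(sentence = integer(0), kw_idx = integer(0),
                      start = integer(0), end = integer(0)))
  }
  # greedy claim: longer keywords (lower kw_idx) claim spans first
  recs <- recs[order(recs$sentence, recs$kw_idx, recs$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(recs))
  for (s in unique(recs$sentence)) {
    idx <- which(recs$sentence == s)
    if (length(idx) < 2L) next
    claimed <- logical(nchar(low[s]))
    for (i in idx) {
      span <- recs$start[i]:recs$end[i]
      if (any(claimed[span])) keep[i] <- FALSE else claimed[span] <- TRUE
    }
  }
  recs <- recs[keep, , drop = FALSE]
  recs[order(recs$sentence, recs$start), , drop = FALSE]
}

#' Match taxonomy keywords across a whole corpus
#'
#' Vectorized equivalent of [match_keywords()] applied to every post:
#' identical records, computed with one regex pass per keyword over all
#' sentences, so large corpora are matched in seconds.
#'
#' @param posts Post data frame (`post_id`, `text`, ...).
#' @param taxonomy A `keyword_taxonomy`.
#' @return Data frame with columns `post_id`, `taxonomy`, `category`,
#'   `keyword`, `sentence_index`.
#' @export
match_corpus <- function(posts, taxonomy) {
  stopifnot(is.data.frame(posts), inherits(taxonomy, "keyword_taxonomy"))
  empty <- data.frame(post_id = character(0), taxonomy = character(0),
                      category = character(0), keyword = character(0),
                      sentence_index = integer(0), stringsAsFactors = FALSE)
  if (nrow(posts) == 0L) return(empty)
  sents <- lapply(posts$text, split_sentences)
  ns <- lengths(sents)
  if (sum(ns) == 0L) return(empty)
  flat <- unlist(sents, use.names = FALSE)
  post_of <- rep(seq_len(nrow(posts)), ns)
  sent_in_post <- sequence(ns)
  tab <- taxonomy_table(taxonomy)
  hits <- match_keyword_spans(flat, tab$keyword)
  if (nrow(hits) == 0L) return(empty)
  hits$keyword <- tab$keyword[hits$kw_idx]
  hits$category <- tab$category[hits$kw_idx]
  if (length(taxonomy$rules) > 0L) {
    keep <- rep(TRUE, nrow(hits))
    low <- tolower(flat)
    for (rule in taxonomy$rules) {
      amb <- which(hits$keyword == rule$keyword)
      if (length(amb) == 0L) next
      usents <- unique(hits$sentence[amb])
      ok_sent <- rep(FALSE, length(usents))
      for (ck in rule$context) {
        ok_sent <- ok_sent | grepl(keyword_regex(ck), low[usents], perl = TRUE)
      }
      keep[amb] <- ok_sent[match(hits$sentence[amb], usents)]
    }
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(empty)
  data.frame(post_id = posts$post_id[post_of[hits$sentence]],
             taxonomy = taxonomy$name, category = hits$category,
             keyword = hits$keyword,
             sentence_index = sent_in_post[hits$sentence] - 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a post stream down to taxonomy-matching, English posts
#'
#' Keeps exactly the posts with at least one surviving keyword match after
#' URL/email stripping, dropping empty and (heuristically) non-English texts.
#' Order is preserved.
#'
#' @param posts Data frame with columns `post_id`, `user_id`, `created_utc`,
#'   `text` (see [read_posts()]).
#' @param taxonomy A `keyword_taxonomy` (typically the e-cigarette list).
#' @param language_filter Predicate `function(text) -> logical` used for the
#'   language drop; default [is_english()]. `NULL` disables it.
#' @return The matching subset of `posts`, with an attribute
#'   `"n_dropped_language"` counting language/empty drops.
#' @export
filter_corpus <- function(posts, taxonomy, language_filter = is_english) {
  stopifnot(is.data.frame(posts))
  if (nrow(posts) == 0L) return(posts)
  clean <- strip_urls_emails(posts$text)
  ok <- nzchar(trimws(clean))
  if (!is.null(language_filter)) ok <- ok & language_filter(clean)
  n_lang <- sum(!ok)
  cand <- posts[ok, , drop = FALSE]
  cand$text <- clean[ok]
  mk <- match_corpus(cand, taxonomy)
  matched <- ok
  matched[ok] <- cand$post_id %in% mk$post_id
  out <- posts[matched, , drop = FALSE]
  out$text <- clean[matched]
  attr(out, "n_dropped_language") <- n_lang
  out
}

#' Assign health and flavor categories to a post
#'
#' Category sets are unions over surviving keyword matches; the per-keyword
#' counts of distinct matched keywords are retained because the association
#' stage needs posts with exactly one distinct flavor keyword.
#'
#' @param text Post text.
#' @param health,flavor `keyword_taxonomy` objects.
#' @param post_id Optional id.
#' @return List with `health_categories`, `flavor_categories` (character
#'   vectors), `health_keywords`, `flavor_keywords` (named occurrence counts
#'   per distinct keyword).
#' @export
classify_post <- function(text, health, flavor, post_id = NA_character_) {
  hm <- match_keywords(text, health, post_id)
  fm <- match_keywords(text, flavor, post_id)
  list(health_categories = sort(unique(hm$category)),
       flavor_categories = sort(unique(fm$category)),
       health_keywords = table_counts(hm$keyword),
       flavor_keywords = table_counts(fm$keyword))
}

#' Classify every post in a corpus against the health and flavor taxonomies
#'
#' @param posts Post data frame.
#' @param health,flavor `keyword_taxonomy` objects.
#' @return List with the raw `health_matches` / `flavor_matches` match-record
#'   frames plus `per_post`, a data frame (post_id, user_id,
#'   n_flavor_keywords, n_health_keywords) counting distinct matched keywords.
#' @export
classify_corpus <- function(posts, health, flavor) {
  hm <- match_corpus(posts, health)
  fm <- match_corpus(posts, flavor)
  nf <- vapply(split(fm$keyword, fm$post_id),
               function(k) length(unique(k)), integer(1))
  nh <- vapply(split(hm$keyword, hm$post_id),
               function(k) length(unique(k)), integer(1))
  per_post <- data.frame(post_id = posts$post_id, user_id = posts$user_id,
                         stringsAsFactors = FALSE)
  per_post$n_flavor_keywords <- unname(nf[match(per_post$post_id, names(nf))])
  per_post$n_health_keywords <- unname(nh[match(per_post$post_id, names(nh))])
  per_post$n_flavor_keywords[is.na(per_post$n_flavor_keywords)] <- 0L
  per_post$n_health_keywords[is.na(per_post$n_health_keywords)] <- 0L
  list(health_matches = hm, flavor_matches = fm, per_post = per_post)
}

table_counts <- function(x) {
  if (length(x) == 0L) return(integer(0))
  tb <- table(x)
  setNames(as.integer(tb), names(tb))
}

#' Sample matching posts for a manual precision audit
#'
#' Draws up to `n_sample` posts containing `keyword` (seeded), returning the
#' sampled ids and the sentences containing the keyword for manual labeling.
#' When `labels` (logical, aligned with the sample) are supplied, precision =
#' true positives / sample size is computed.
#'
#' @param posts Post data frame.
#' @param keyword Keyword audited (lowercase).
#' @param taxonomy Taxonomy the keyword belongs to (rules applied).
#' @param n_sample Sample size cap (audits typically use 100 per keyword).
#' @param seed Integer seed for the draw.
#' @param labels Optional logical vector of manual relevance labels.
#' @return List with `keyword`, `sample` (data frame: post_id, highlight) and
#'   `precision` (`NA` until labels are supplied).
#' @export
audit_filter_precision <- function(posts, keyword, taxonomy, n_sample = 100L,
                                   seed = 1L, labels = NULL) {
  stopifnot(n_sample >= 1L)
  keyword <- tolower(keyword)
  rows <- list()
  for (i in seq_len(nrow(posts))) {
    mk <- match_keywords(posts$text[i], taxonomy, posts$post_id[i])
    mk <- mk[mk$keyword == keyword, , drop = FALSE]
    if (nrow(mk) > 0L) {
      sents <- split_sentences(posts$text[i])
      rows[[length(rows) + 1L]] <- data.frame(
        post_id = posts$post_id[i],
        highlight = paste(sents[unique(mk$sentence_index) + 1L],
                          collapse = " | "),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning("keyword not found in corpus: ", keyword)
    return(list(keyword = keyword,
                sample = data.frame(post_id = character(0),
                                    highlight = character(0)),
                precision = NA_real_))
  }
  hits <- do.call(rbind, rows)
  n <- min(n_sample, nrow(hits))
  idx <- withr_seed(seed, sample.int(nrow(hits), n))
  sample_df <- hits[idx, , drop = FALSE]
  precision <- NA_real_
  if (!is.null(labels)) {
    stopifnot(length(labels) == n, is.logical(labels))
    precision <- sum(labels) / n
  }
  list(keyword = keyword, sample = sample_df, precision = precision)
}

# Evaluate expr under a local RNG seed without disturbing the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
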