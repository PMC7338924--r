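# Lexicon-based sentiment scoring of health-subset posts. Health keywords
# carry intrinsic negative valence ("headache", "cancer"), so they are first
# replaced by a sentiment-neutral placeholder; the remaining lexicon hits are
# summed (with an optional negation flip and exclamation/ALL-CAPS boosters)
# and the sum is squashed to [-1, 1] with the standard s/sqrt(s^2 + 15)
# compound normalization. Any scorer with the same text -> score interface
# (e.g. a binding to the reference VADER implementation) can be substituted.

#' Read a valence lexicon
#'
#' Whitespace/tab separated lines: token, valence (extra columns, as in the
#' published VADER lexicon file, are ignored). Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return Named numeric vector of valences.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "[\t ]+")
  tok <- vapply(parts, `[[`, "", 1L)
  val <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(val)) stop("non-numeric valence in lexicon: ", path)
  setNames(val, tolower(tok))
}

#' Bundled miniature valence lexicon
#'
#' A small VADER-format lexicon shipped with the package so scoring, tests
#' and the synthetic corpus are hermetic. It covers the sentiment-bearing
#' words used by the corpus templates plus negatively-valenced health
#' keywords.
#'
#' @return Named numeric vector of valences.
#' @export
vapelens_lexicon <- function() {
  read_lexicon(system.file("extdata", "sentiment_lexicon.txt",
                           package = "vapelens", mustWork = TRUE))
}

#' Replace health keywords with a neutral placeholder
#'
#' Every token-boundary occurrence of a health keyword (case-insensitive;
#' multi-word keywords replaced as one unit, longest first) becomes
#' `placeholder`. All other characters are unchanged, and the operation is
#' idempotent provided the placeholder is not itself a keyword.
#'
#' @param text Character vector.
#' @param health_keywords Character vector of keywords to neutralize. The
#'   usual choice is the health-taxonomy keywords that carry nonzero valence
#'   in the scoring lexicon (see [neutralizable_keywords()]).
#' @param placeholder Replacement token, zero-valence in the lexicon
#'   (default `"X"`).
#' @return Character vector with keywords neutralized.
#' @export
#' @examples
#' neutralize_keywords("this headache is awful", "headache")
neutralize_keywords <- function(text, health_keywords, placeholder = "X") {
  kws <- unique(tolower(health_keywords))
  kws <- kws[order(-nchar(kws))]
  for (kw in kws) {
    text <- gsub(keyword_regex(kw), placeholder, text,
                 perl = TRUE, ignore.case = TRUE)
  }
  text
}

#' Health keywords that would bias sentiment scoring
#'
#' The keywords of a taxonomy that carry nonzero valence in a lexicon; the
#' default neutralization set. Pass `all = TRUE` to neutralize every keyword
#' instead.
#'
#' @param taxonomy A `keyword_taxonomy`.
#' @param lexicon Named valence vector.
#' @param all Neutralize all keywords regardless of valence.
#' @return Character vector of keywords.
#' @export
neutralizable_keywords <- function(taxonomy, lexicon = vapelens_lexicon(),
                                   all = FALSE) {
  kws <- unlist(taxonomy$categories, use.names = FALSE)
  if (all) return(kws)
  # multi-word keywords count as biased if any component word has valence
  biased <- vapply(strsplit(kws, "[ -]+"), function(parts) {
    any(parts %in% names(lexicon) & lexicon[parts] != 0)
  }, logical(1))
  kws[biased]
}

NEGATORS <- c("not", "no", "never", "neither", "nor", "cannot", "can't",
              "don't", "doesn't", "didn't", "isn't", "aren't", "wasn't",
              "won't", "without", "hardly")

#' Compound sentiment score
#'
#' Sums the valences of lexicon hits in the text; a hit preceded by a
#' negator within a 3-token window has its valence flipped. Optional
#' boosters (`use_boosters = TRUE`): an ALL-CAPS lexicon hit gains 0.733
#' in magnitude and up to three trailing exclamation marks add 0.292 each in
#' the direction of the raw sum. The raw sum s is normalized to
#' s / sqrt(s^2 + 15), so scores lie strictly inside `[-1, 1]`.
#'
#' @param text Character vector.
#' @param lexicon Named valence vector (default the bundled lexicon).
#' @param use_boosters Apply the ALL-CAPS / exclamation boosters.
#' @param negation_window How many preceding tokens a negator can flip.
#' @return Numeric vector of scores in `[-1, 1]`; empty/hitless text scores
#'   0.
#' @export
#' @examples
#' score_sentiment("I love this juice", c(love = 2))
score_sentiment <- function(text, lexicon = vapelens_lexicon(),
                            use_boosters = FALSE, negation_window = 3L) {
  toks_raw <- tokenize(text, lower = FALSE)
  vapply(seq_along(toks_raw), function(i) {
    raw <- toks_raw[[i]]
    if (length(raw) == 0L) return(0)
    low <- tolower(raw)
    hit <- match(low, names(lexicon))
    s <- 0
    for (j in which(!is.na(hit))) {
      v <- unname(lexicon[hit[j]])
      if (v == 0) next
      pre <- low[max(1L, j - negation_window):max(1L, j - 1L)]
      if (j > 1L && any(pre %in% NEGATORS)) v <- -v
      if (use_boosters && raw[j] == toupper(raw[j]) &&
          grepl("[A-Z]{2,}", raw[j])) {
        v <- v + sign(v) * 0.733
      }
      s <- s + v
    }
    if (use_boosters && s != 0) {
      n_excl <- min(3L, lengths(regmatches(text[i], gregexpr("!", text[i],
                                                             fixed = TRUE))))
      s <- s + sign(s) * 0.292 * n_excl
    }
    s / sqrt(s^2 + 15)
  }, numeric(1))
}

#' Classify a score into a sentiment propensity
#'
#' positive when score >= +0.05, negative when score <= -0.05, neutral
#' strictly in between (the boundaries belong to the polar classes).
#'
#' @param score Numeric vector in `[-1, 1]`.
#' @return Character vector: `"positive"`, `"neutral"` or `"negative"`.
#' @export
#' @examples
#' classify_propensity(c(0.05, 0.049, -0.05))
classify_propensity <- function(score) {
  if (any(is.na(score)) || any(score < -1 | score > 1))
    stop("scores must lie in [-1, 1]")
  ifelse(score >= 0.05, "positive",
         ifelse(score <= -0.05, "negative", "neutral"))
}

#' Two-proportion z-test (pooled, no continuity correction)
#'
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with the pooled
#' p = (x1 + x2)/(n1 + n2); two-sided normal p-value. When the pooled
#' proportion is 0 or 1 the statistic is undefined: z is `NA`, p is 1 and
#' `degenerate` is flagged.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z`, `p_value`, `degenerate`.
#' @export
#' @examples
#' two_proportion_z_test(60, 100, 40, 100)
two_proportion_z_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    return(list(z = NA_real_, p_value = 1, degenerate = TRUE))
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p), order preserved. `m` defaults to the number of
#' p-values but can be fixed (e.g. at the nine health categories) when a
#' subset is adjusted.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param m Number of tests.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  pmin(1, m * p_values)
}

#' Sentiment summary for each health category
#'
#' For every category: neutralize the health keywords, score each post,
#' classify its propensity, then compare the positive and negative
#' proportions with the pooled two-proportion z-test; p-values are
#' Bonferroni-adjusted across categories. The positive and negative
#' proportions share a denominator (the same post set), so the independent
#' two-proportion test is an approximation used for fidelity with common
#' practice; see the methods vignette.
#'
#' @param posts Post data frame.
#' @param assignment Data frame (`post_id`, `category`) assigning posts to
#'   health categories (posts may appear in several categories).
#' @param health_taxonomy Health `keyword_taxonomy` (for neutralization).
#' @param lexicon Named valence vector.
#' @param neutralize_all Neutralize all health keywords, not only the
#'   valenced ones.
#' @param m Bonferroni multiplicity; default the number of categories
#'   summarized.
#' @param use_boosters Passed to [score_sentiment()].
#' @return Data frame, one row per category: `category`, `n`, `mean_score`,
#'   `p_pos`, `p_neu`, `p_neg`, `z`, `p_raw`, `p_adj`.
#' @export
summarize_sentiment <- function(posts, assignment, health_taxonomy,
                                lexicon = vapelens_lexicon(),
                                neutralize_all = FALSE, m = NULL,
                                use_boosters = FALSE) {
  kws <- neutralizable_keywords(health_taxonomy, lexicon,
                                all = neutralize_all)
  neut <- neutralize_keywords(posts$text, kws)
  score <- score_sentiment(neut, lexicon, use_boosters = use_boosters)
  prop <- classify_propensity(score)
  cats <- sort(unique(assignment$category))
  if (is.null(m)) m <- length(cats)
  rows <- lapply(cats, function(cat) {
    ids <- unique(assignment$post_id[assignment$category == cat])
    idx <- which(posts$post_id %in% ids)
    n <- length(idx)
    if (n == 0L) {
      return(data.frame(category = cat, n = 0L, mean_score = NA_real_,
                        p_pos = NA_real_, p_neu = NA_real_, p_neg = NA_real_,
                        z = NA_real_, p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    }
    np <- sum(prop[idx] == "positive"); nn <- sum(prop[idx] == "negative")
    zt <- two_proportion_z_test(np, n, nn, n)
    data.frame(category = cat, n = n, mean_score = mean(score[idx]),
               p_pos = np / n, p_neu = 1 - (np + nn) / n, p_neg = nn / n,
               z = zt$z, p_raw = zt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- ifelse(is.na(out$p_raw), NA_real_,
                      bonferroni_adjust(ifelse(is.na(out$p_raw), 0,
                                               out$p_raw), m))
  out
}
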