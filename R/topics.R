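# Topic modeling of the health subset: preprocessing, collocation merging
# (frequent bigrams/trigrams become single underscore-joined terms, so
# "throat hit" is one element of a document), and LDA fit by collapsed Gibbs
# sampling with seeded, bit-reproducible draws.

#' Preprocess texts into tokenized documents
#'
#' lowercase -> tokenize -> lemmatize -> remove stopwords. Documents that
#' empty out are dropped; their number is available in attribute
#' `"n_dropped"`.
#'
#' @param texts Character vector.
#' @param stopwords Character vector (default [default_stopwords()]).
#' @param lemmatizer Token -> lemma function (default [simple_lemmatize()];
#'   `identity` disables lemmatization).
#' @param ids Optional document ids (default positions).
#' @return Named list of token vectors.
#' @export
preprocess_docs <- function(texts, stopwords = default_stopwords(),
                            lemmatizer = simple_lemmatize, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(texts))
  toks <- tokenize(strip_urls_emails(texts))
  docs <- lapply(toks, function(tk) {
    tk <- lemmatizer(tk)
    tk[nzchar(tk) & !(tk %in% stopwords)]
  })
  names(docs) <- ids
  keep <- lengths(docs) > 0L
  out <- docs[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Merge frequent collocations into single terms
#'
#' An adjacent token pair (a, b) is merged to `"a_b"` wherever
#' `score(a, b) = (count(a, b) - min_count) * V / (count(a) * count(b))`
#' exceeds `threshold` (V = vocabulary size; the standard count-based phrase
#' score). Merging is greedy left-to-right and non-overlapping. A second
#' pass builds trigrams out of merged bigrams ("food_drug" + "administration"
#' -> "food_drug_administration").
#'
#' @param docs Token-vector list from [preprocess_docs()].
#' @param min_count Minimum pair count before a pair can score above 0.
#' @param threshold Score threshold for merging.
#' @param passes 1 (bigrams) or 2 (bigrams then trigrams).
#' @return Token-vector list with merged terms.
#' @export
detect_collocations <- function(docs, min_count = 20L, threshold = 10,
                                passes = 2L) {
  stopifnot(min_count >= 1L, passes %in% c(1L, 2L))
  for (pass in seq_len(passes)) {
    uni <- table(unlist(docs, use.names = FALSE))
    V <- length(uni)
    pairs_by_doc <- lapply(docs, function(tk) {
      if (length(tk) < 2L) return(character(0))
      paste(tk[-length(tk)], tk[-1L], sep = "\r")
    })
    pair_counts <- table(unlist(pairs_by_doc, use.names = FALSE))
    if (length(pair_counts) == 0L) break
    ab <- strsplit(names(pair_counts), "\r", fixed = TRUE)
    a <- vapply(ab, `[[`, "", 1L); b <- vapply(ab, `[[`, "", 2L)
    score <- (as.numeric(pair_counts) - min_count) * V /
      (as.numeric(uni[a]) * as.numeric(uni[b]))
    merged <- names(pair_counts)[score > threshold]
    if (length(merged) == 0L) break
    docs <- lapply(docs, function(tk) {
      n <- length(tk)
      if (n < 2L) return(tk)
      out <- character(0)
      i <- 1L
      while (i <= n) {
        if (i < n && paste(tk[i], tk[i + 1L], sep = "\r") %in% merged) {
          out <- c(out, paste(tk[i], tk[i + 1L], sep = "_"))
          i <- i + 2L
        } else {
          out <- c(out, tk[i])
          i <- i + 1L
        }
      }
      out
    })
  }
  docs
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Each token's topic is resampled from
#' `p(z = k | .) ~ (n_dk + alpha) (n_kw + beta) / (n_k + V beta)` with counts
#' excluding the token itself. Runs with the same seed are bit-reproducible.
#'
#' @param docs Token-vector list (after collocation merging).
#' @param K Number of topics (>= 2).
#' @param alpha Document-topic concentration (default `50 / K`).
#' @param beta Topic-word concentration (default 0.01).
#' @param n_iters Gibbs sweeps (default 1000).
#' @param seed Integer seed.
#' @return Object of class `lda_fit`: `K`, `alpha`, `beta`, `vocab`,
#'   `doc_ids`, `assignments` (topic per token, 1-based), `doc_topic` /
#'   `topic_word` count matrices, `theta` / `phi` posterior-mean
#'   distributions (rows sum to 1).
#' @export
fit_lda <- function(docs, K, alpha = 50 / K, beta = 0.01, n_iters = 1000L,
                    seed = 1L) {
  stopifnot(K >= 2L, n_iters >= 1L, length(docs) > 0L)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (length(vocab) == 0L) stop("empty vocabulary")
  tokens <- unlist(lapply(docs, function(tk) match(tk, vocab) - 1L),
                   use.names = FALSE)
  if (K > length(tokens)) stop("more topics than tokens")
  doc_idx <- rep(seq_along(docs) - 1L, lengths(docs))
  res <- withr_seed(seed, {
    init <- sample.int(K, length(tokens), replace = TRUE) - 1L
    lda_gibbs(tokens, doc_idx, length(docs), length(vocab), as.integer(K),
              alpha, beta, as.integer(n_iters), init)
  })
  ndk <- res$ndk; nkw <- res$nkw
  theta <- (ndk + alpha) / (rowSums(ndk) + K * alpha)
  phi <- (nkw + beta) / (rowSums(nkw) + length(vocab) * beta)
  colnames(phi) <- vocab
  rownames(theta) <- names(docs)
  structure(list(K = K, alpha = alpha, beta = beta, vocab = vocab,
                 doc_ids = names(docs), assignments = res$z + 1L,
                 doc_topic = ndk, topic_word = nkw,
                 theta = theta, phi = phi, n_iters = n_iters, seed = seed),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("<lda_fit: K=%d, %d docs, vocabulary %d, %d sweeps>\n",
              x$K, nrow(x$theta), length(x$vocab), x$n_iters))
  invisible(x)
}

#' Top terms per topic
#'
#' The `n` highest-probability terms of each topic, ties broken
#' lexicographically.
#'
#' @param fit An `lda_fit`.
#' @param n Terms per topic (truncated at the vocabulary size).
#' @return List of character vectors, one per topic.
#' @export
top_terms <- function(fit, n = 10L) {
  stopifnot(inherits(fit, "lda_fit"), n >= 0L)
  n <- min(n, length(fit$vocab))
  lapply(seq_len(fit$K), function(k) {
    ord <- order(-fit$phi[k, ], fit$vocab)
    fit$vocab[ord][seq_len(n)]
  })
}

#' Label topics as flavor, health or other
#'
#' A reproducible proxy for manual topic labeling: a topic is `flavor`
#' (resp. `health`) when at least `min_hits` of its `top_n` terms are flavor
#' (resp. health) keywords; flavor wins ties. Multi-word keywords are
#' compared in their underscore-merged form so collocation-merged terms
#' match.
#'
#' @param fit An `lda_fit`.
#' @param flavor_keywords,health_keywords Character vectors of keywords.
#' @param top_n Terms examined per topic.
#' @param min_hits Minimum keyword hits for a label.
#' @return Data frame: `topic`, `label`, `flavor_hits`, `health_hits`; the
#'   per-label counts are in attribute `"label_counts"`.
#' @export
label_topics <- function(fit, flavor_keywords, health_keywords,
                         top_n = 10L, min_hits = 2L) {
  stopifnot(top_n >= min_hits, min_hits >= 1L)
  as_term <- function(k) gsub("[ -]+", "_", tolower(k))
  fl <- unique(as_term(flavor_keywords))
  he <- unique(as_term(health_keywords))
  tops <- top_terms(fit, top_n)
  rows <- lapply(seq_along(tops), function(k) {
    fh <- sum(tops[[k]] %in% fl); hh <- sum(tops[[k]] %in% he)
    label <- if (fh >= min_hits && fh >= hh) "flavor"
             else if (hh >= min_hits) "health" else "other"
    data.frame(topic = k, label = label, flavor_hits = fh, health_hits = hh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "label_counts") <- table(factor(out$label,
                                            c("flavor", "health", "other")))
  out
}
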