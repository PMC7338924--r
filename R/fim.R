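# Frequent itemset mining (Apriori) over post token sets, used to propose
# conversational spelling variants and co-occurring terms that a seed keyword
# list misses. Candidates are ranked for manual review; nothing is ever
# appended to a taxonomy automatically.

#' Convert posts to token-set transactions
#'
#' One transaction per post: unique lowercase tokens with stopwords removed.
#' Posts whose token set empties out are dropped.
#'
#' @param posts Post data frame (or a character vector of texts).
#' @param stopwords Character vector; default [default_stopwords()].
#' @return List of transactions; each element is a character vector of unique
#'   items, named by post id.
#' @export
posts_to_transactions <- function(posts, stopwords = default_stopwords()) {
  if (is.character(posts)) {
    texts <- posts
    ids <- as.character(seq_along(posts))
  } else {
    texts <- posts$text
    ids <- posts$post_id
  }
  toks <- tokenize(strip_urls_emails(texts))
  tx <- lapply(toks, function(tk) sort(unique(setdiff(tk, stopwords))))
  names(tx) <- ids
  tx[lengths(tx) > 0L]
}

#' Mine frequent itemsets with Apriori
#'
#' Level-wise candidate generation with downward-closure pruning: an itemset
#' of size k is only counted when all of its (k-1)-subsets are frequent.
#' Returns exactly the itemsets of size <= `max_size` whose support (number
#' of transactions containing every item) is >= `min_support`.
#'
#' @param transactions List of character vectors (see
#'   [posts_to_transactions()]).
#' @param min_support Minimum support: an absolute transaction count when at
#'   least 1, or a fraction of the number of transactions when in (0, 1).
#' @param max_size Largest itemset size to mine (default 3).
#' @return Data frame sorted by (size, -support, items): columns `items`
#'   (items joined by `","` in lexicographic order), `size`, `support`,
#'   `support_fraction`.
#' @export
#' @examples
#' tx <- list(c("a", "b"), c("a", "b"), c("a", "c"))
#' mine_frequent_itemsets(tx, min_support = 2)
mine_frequent_itemsets <- function(transactions, min_support, max_size = 3L) {
  stopifnot(min_support > 0, max_size >= 1L)
  n_tx <- length(transactions)
  empty <- data.frame(items = character(0), size = integer(0),
                      support = integer(0), support_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_tx == 0L) return(empty)
  if (min_support < 1) min_support <- ceiling(min_support * n_tx)
  min_support <- as.integer(min_support)

  # item -> transaction-id list (vertical layout: supports are intersection
  # sizes, no corpus rescan per level)
  tid <- split(rep(seq_len(n_tx), lengths(transactions)),
               unlist(transactions, use.names = FALSE))
  tid <- tid[vapply(tid, length, integer(1)) >= min_support]
  if (length(tid) == 0L) return(empty)
  tid <- tid[order(names(tid))]

  levels_out <- list()
  freq_sets <- lapply(names(tid), identity)     # current level itemsets
  freq_tids <- unname(tid)
  levels_out[[1L]] <- data.frame(
    items = names(tid), size = 1L,
    support = vapply(freq_tids, length, integer(1)),
    stringsAsFactors = FALSE)

  k <- 1L
  while (k < max_size && length(freq_sets) > 1L) {
    prev_keys <- vapply(freq_sets, paste, "", collapse = ",")
    cand_sets <- list(); cand_tids <- list()
    # join step: extend each frequent k-set by a lexicographically larger item
    prefixes <- vapply(freq_sets, function(s)
      paste(s[-length(s)], collapse = ","), "")
    groups <- split(seq_along(freq_sets), prefixes)
    for (g in groups) {
      if (length(g) < 2L) next
      for (a in seq_along(g)) {
        for (b in seq_along(g)) {
          if (b <= a) next
          i <- g[a]; j <- g[b]
          new_set <- sort(union(freq_sets[[i]], freq_sets[[j]]))
          if (length(new_set) != k + 1L) next
          # prune: all k-subsets must be frequent
          subs_ok <- all(vapply(seq_along(new_set), function(d)
            paste(new_set[-d], collapse = ",") %in% prev_keys, logical(1)))
          if (!subs_ok) next
          tids <- intersect(freq_tids[[i]], freq_tids[[j]])
          if (length(tids) >= min_support) {
            cand_sets[[length(cand_sets) + 1L]] <- new_set
            cand_tids[[length(cand_tids) + 1L]] <- tids
          }
        }
      }
    }
    if (length(cand_sets) == 0L) break
    keys <- vapply(cand_sets, paste, "", collapse = ",")
    dup <- duplicated(keys)
    cand_sets <- cand_sets[!dup]; cand_tids <- cand_tids[!dup]
    k <- k + 1L
    levels_out[[k]] <- data.frame(
      items = vapply(cand_sets, paste, "", collapse = ","), size = k,
      support = vapply(cand_tids, length, integer(1)),
      stringsAsFactors = FALSE)
    freq_sets <- cand_sets; freq_tids <- cand_tids
  }
  out <- do.call(rbind, levels_out)
  out$support_fraction <- out$support / n_tx
  out <- out[order(out$size, -out$support, out$items), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank enrichment candidates for a seed keyword list
#'
#' Non-seed tokens that appear in a frequent itemset together with at least
#' one seed keyword, ranked by the support of their best co-itemset. Intended
#' for manual review, never auto-included in a taxonomy.
#'
#' @param itemsets Output of [mine_frequent_itemsets()].
#' @param seed_keywords Character vector of seed keywords.
#' @param top_k Truncate to the `top_k` best candidates (default all).
#' @return Data frame with `token`, `best_support`, `co_seed` (the seed in
#'   the best co-itemset), ranked by decreasing support.
#' @export
enrichment_candidates <- function(itemsets, seed_keywords, top_k = Inf) {
  seed_keywords <- tolower(seed_keywords)
  empty <- data.frame(token = character(0), best_support = integer(0),
                      co_seed = character(0), stringsAsFactors = FALSE)
  if (nrow(itemsets) == 0L) return(empty)
  sets <- strsplit(itemsets$items, ",", fixed = TRUE)
  best <- new.env(parent = emptyenv())
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    seeds_in <- intersect(s, seed_keywords)
    if (length(seeds_in) == 0L) next
    for (tok in setdiff(s, seed_keywords)) {
      cur <- best[[tok]]
      if (is.null(cur) || itemsets$support[i] > cur$support) {
        best[[tok]] <- list(support = itemsets$support[i],
                            co_seed = seeds_in[1L])
      }
    }
  }
  toks <- ls(best)
  if (length(toks) == 0L) return(empty)
  out <- data.frame(
    token = toks,
    best_support = vapply(toks, function(t) best[[t]]$support, integer(1)),
    co_seed = vapply(toks, function(t) best[[t]]$co_seed, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$best_support, out$token), , drop = FALSE]
  head(out, if (is.finite(top_k)) top_k else nrow(out))
}
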