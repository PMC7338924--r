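# Shared fixtures and independent oracles, built in code at test time.

# taxonomies ----------------------------------------------------------------

fixture_taxonomies <- function() vapelens_taxonomies()

# a tiny flavor taxonomy with the tobacco disambiguation rule, for focused
# rule tests
tiny_flavor_taxonomy <- function() {
  keyword_taxonomy(
    "flavor",
    list(Fruit = c("strawberry", "mango"),
         `Menthol or Mint` = c("menthol", "mint"),
         Tobacco = "tobacco",
         Sweet = "custard", Beverage = "coffee",
         Mixed = "fruit medley", Other = "cinnamon"),
    rules = list(disambiguation_rule(
      "tobacco", c("flavor", "e-liquid", "e-juice", "juice"))))
}

make_posts <- function(texts, users = NULL, ts = NULL) {
  n <- length(texts)
  data.frame(post_id = sprintf("p%03d", seq_len(n)),
             user_id = if (is.null(users)) sprintf("u%03d", seq_len(n))
                       else users,
             created_utc = if (is.null(ts))
               as.numeric(as.POSIXct("2015-03-15", tz = "UTC")) + seq_len(n)
               else ts,
             text = texts, stringsAsFactors = FALSE)
}

# FIM oracle ----------------------------------------------------------------

# exhaustive enumeration of all itemsets up to max_size with support >=
# min_support: the independent brute-force oracle for the Apriori miner
brute_force_itemsets <- function(transactions, min_support, max_size = 3L) {
  n_tx <- length(transactions)
  if (min_support < 1) min_support <- ceiling(min_support * n_tx)
  univ <- sort(unique(unlist(transactions)))
  rows <- list()
  for (k in seq_len(min(max_size, length(univ)))) {
    sets <- utils::combn(univ, k, simplify = FALSE)
    for (s in sets) {
      supp <- sum(vapply(transactions, function(tx) all(s %in% tx),
                         logical(1)))
      if (supp >= min_support) {
        rows[[length(rows) + 1L]] <- data.frame(
          items = paste(s, collapse = ","), size = k, support = supp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(items = character(0), size = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$size, -out$support, out$items), , drop = FALSE]
}

random_transactions <- function(n_tx, n_tokens, seed) {
  set.seed(seed)
  univ <- letters[seq_len(n_tokens)]
  lapply(seq_len(n_tx), function(i) {
    sort(sample(univ, sample.int(min(6L, n_tokens), 1L)))
  })
}

# GEE oracles ----------------------------------------------------------------

# independence-model logistic fit on the cell-means design: the reference
# solution the exchangeable GEE must match when alpha is forced to zero
glm_cellmeans_oracle <- function(entries, health_category) {
  y <- as.numeric(entries$health_category == health_category)
  f <- factor(entries$flavor_category)
  fit <- stats::glm(y ~ f - 1, family = binomial())
  setNames(coef(fit), levels(f))
}
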