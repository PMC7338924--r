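# Readers/writers and the end-to-end pipeline orchestrator.

#' Read posts from a JSON-lines file
#'
#' One JSON object per line. Field names are mapped through `field_mapping`
#' (default accepts the common pushshift-style names `id`, `author`,
#' `created_utc`, and `text`/`body`/`selftext` with `title` prepended when
#' present). Lines that fail to parse or miss a mapped field are skipped and
#' counted.
#'
#' @param path JSONL file path.
#' @param field_mapping Named list: canonical name (`post_id`, `user_id`,
#'   `created_utc`, `text`) -> source key (or vector of keys tried in
#'   order).
#' @param chunk_size Lines read per chunk (bounded memory).
#' @return Post data frame (`post_id`, `user_id`, `created_utc`, `text`)
#'   with attribute `"n_skipped"`.
#' @export
read_posts <- function(path,
                       field_mapping = list(post_id = c("id", "post_id"),
                                            user_id = c("author", "user_id"),
                                            created_utc = "created_utc",
                                            text = c("text", "body",
                                                     "selftext")),
                       chunk_size = 10000L) {
  if (!file.exists(path)) stop("cannot read posts file: ", path)
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  chunks <- list()
  n_skipped <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(ln) {
      obj <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
      if (is.null(obj) || !is.list(obj)) return(NULL)
      pick <- function(keys) {
        for (k in keys) if (!is.null(obj[[k]]) && !is.na(obj[[k]][1]))
          return(obj[[k]][1])
        NULL
      }
      vals <- lapply(field_mapping, pick)
      if (any(vapply(vals, is.null, logical(1)))) return(NULL)
      txt <- as.character(vals$text)
      if (!is.null(obj$title) && !is.na(obj$title[1]) &&
          nzchar(obj$title[1]) && !identical(obj$title[1], txt))
        txt <- paste(obj$title[1], txt)
      data.frame(post_id = as.character(vals$post_id),
                 user_id = as.character(vals$user_id),
                 created_utc = as.numeric(vals$created_utc),
                 text = txt, stringsAsFactors = FALSE)
    })
    bad <- vapply(rows, is.null, logical(1))
    n_skipped <- n_skipped + sum(bad)
    if (any(!bad)) chunks[[length(chunks) + 1L]] <- do.call(rbind, rows[!bad])
  }
  out <- if (length(chunks) > 0L) do.call(rbind, chunks) else
    data.frame(post_id = character(0), user_id = character(0),
               created_utc = numeric(0), text = character(0),
               stringsAsFactors = FALSE)
  if (n_skipped > 0L)
    warning(n_skipped, " malformed line(s) skipped in ", path)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write posts as JSON-lines
#'
#' Keys `id`, `author`, `created_utc`, `text`; byte-identical output for
#' identical input (internal truth columns starting with `.` are dropped).
#'
#' @param posts Post data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(id = posts$post_id[i], author = posts$user_id[i],
                          created_utc = posts$created_utc[i],
                          text = posts$text[i]),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' filter -> temporal -> sentiment -> topics -> entries -> GEE -> contrasts,
#' writing every artifact plus a manifest (input hashes, parameters, seed,
#' package version) to `out_dir`. Stage failures abort with the stage name;
#' the manifest written so far is kept.
#'
#' @param posts Post data frame (e.g. [read_posts()] output or a generated
#'   corpus), or a JSONL path.
#' @param out_dir Output directory (created if missing).
#' @param taxonomies List with `ecig`, `health`, `flavor` taxonomies
#'   (default the bundled fixtures).
#' @param lexicon Named valence vector (default the bundled lexicon).
#' @param lda_K,lda_iters,collocation_min_count,collocation_threshold Topic
#'   stage parameters.
#' @param min_entries Small-sample exclusion threshold for flavor levels in
#'   the GEE stage.
#' @param corstr Working correlation for the GEE stage.
#' @param seed Root seed; stage seeds are derived from it.
#' @param topic_sample Cap on the number of documents entering the topic
#'   stage (seeded subsample keeps desk-scale runtimes; `Inf` disables).
#' @return List with `trends`, `sentiment`, `topics`, `probabilities`,
#'   `contrasts`, `heatmap`, `entries`, `manifest` (also written to disk).
#' @export
run_pipeline <- function(posts, out_dir, taxonomies = vapelens_taxonomies(),
                         lexicon = vapelens_lexicon(), lda_K = 10L,
                         lda_iters = 200L, collocation_min_count = 20L,
                         collocation_threshold = 10, min_entries = 10L,
                         corstr = "exchangeable", seed = 1L,
                         topic_sample = 2000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "vapelens",
                   version = as.character(utils::packageVersion("vapelens")),
                   seed = seed,
                   parameters = list(lda_K = lda_K, lda_iters = lda_iters,
                                     collocation_min_count =
                                       collocation_min_count,
                                     collocation_threshold =
                                       collocation_threshold,
                                     min_entries = min_entries,
                                     corstr = corstr,
                                     topic_sample = topic_sample),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name, file, df, extra = list()) {
    path <- file.path(out_dir, file)
    if (is.data.frame(df)) write.csv(df, path, row.names = FALSE)
    else jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA)
    manifest$stages[[name]] <<- c(list(status = "ok", file = file,
                                       md5 = unname(tools::md5sum(path))),
                                  extra)
  }

  if (is.character(posts)) {
    manifest$input <- list(path = posts, md5 = unname(tools::md5sum(posts)))
    posts <- stage("read", read_posts(posts))
  } else {
    manifest$input <- list(path = NA,
                           n_posts = nrow(posts))
  }

  corpus <- stage("filter", {
    out <- filter_corpus(posts, taxonomies$ecig)
    if (nrow(out) == 0L) stop("no posts survive the keyword filter")
    out
  })
  emit("filter", "corpus.csv",
       corpus[, c("post_id", "user_id", "created_utc", "text")],
       list(n_in = nrow(posts), n_kept = nrow(corpus)))

  cls <- stage("classify", classify_corpus(corpus, taxonomies$health,
                                           taxonomies$flavor))

  trends <- stage("temporal", {
    window <- range(month_of(corpus$created_utc))
    counts <- monthly_counts(corpus, cls$health_matches, window)
    normalize_series(counts, monthly_totals(corpus, window))
  })
  emit("temporal", "trends.csv", trends)

  senti <- stage("sentiment",
                 summarize_sentiment(corpus,
                                     cls$health_matches,
                                     taxonomies$health, lexicon))
  emit("sentiment", "sentiment.csv", senti)

  topics <- stage("topics", {
    health_ids <- unique(cls$health_matches$post_id)
    hp <- corpus[corpus$post_id %in% health_ids, , drop = FALSE]
    if (nrow(hp) > topic_sample) {
      keep <- withr_seed(seed + 1L,
                         sample.int(nrow(hp), topic_sample))
      hp <- hp[keep, , drop = FALSE]
    }
    docs <- preprocess_docs(hp$text, ids = hp$post_id)
    docs <- detect_collocations(docs, collocation_min_count,
                                collocation_threshold)
    fit <- fit_lda(docs, K = lda_K, n_iters = lda_iters, seed = seed + 2L)
    labels <- label_topics(fit,
                           unlist(taxonomies$flavor$categories),
                           unlist(taxonomies$health$categories))
    tops <- top_terms(fit, 10L)
    lapply(seq_len(fit$K), function(k)
      list(id = k, label = labels$label[k], top_terms = tops[[k]]))
  })
  emit("topics", "topics.json", topics)

  entries <- stage("entries", extract_entries(corpus, classified = cls))
  emit("entries", "entries.csv", entries)

  gee <- stage("gee", {
    fits <- fit_gee_all(entries, min_entries = min_entries, corstr = corstr)
    probs <- do.call(rbind, lapply(names(fits), function(h) {
      pr <- estimate_probabilities(fits[[h]])
      cbind(health_category = h, pr)
    }))
    contrasts <- do.call(rbind, lapply(fits, pairwise_tukey))
    rownames(contrasts) <- NULL
    list(fits = fits, probs = probs, contrasts = contrasts,
         heatmap = heatmap_table(fits))
  })
  emit("probabilities", "probabilities.csv", gee$probs)
  emit("contrasts", "contrasts.csv", gee$contrasts)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(trends = trends, sentiment = senti, topics = topics,
                 probabilities = gee$probs, contrasts = gee$contrasts,
                 heatmap = gee$heatmap, entries = entries, fits = gee$fits,
                 manifest = manifest))
}
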