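# Construction of flavor-health association entries: the unit of analysis
# for the GEE. A post qualifies when it contains exactly one distinct flavor
# keyword and at least one health keyword; each distinct health keyword in a
# qualifying post yields one entry (user, post, flavor category, health
# category), and entries are clustered by user.

#' Extract association entries from a classified corpus
#'
#' @param posts Post data frame (`post_id`, `user_id`, `text`, ...).
#' @param health,flavor `keyword_taxonomy` objects, or pass `classified`
#'   directly.
#' @param classified Optional precomputed [classify_corpus()] result for
#'   these posts (avoids re-matching).
#' @return Data frame of entries: `user_id`, `post_id`, `flavor_category`,
#'   `health_category`.
#' @export
#' @examples
#' \dontrun{
#' entries <- extract_entries(posts, health_tx, flavor_tx)
#' }
extract_entries <- function(posts, health = NULL, flavor = NULL,
                            classified = NULL) {
  if (is.null(classified)) {
    stopifnot(!is.null(health), !is.null(flavor))
    classified <- classify_corpus(posts, health, flavor)
  }
  per <- classified$per_post
  eligible <- per$post_id[per$n_flavor_keywords == 1L &
                            per$n_health_keywords >= 1L]
  empty <- data.frame(user_id = character(0), post_id = character(0),
                      flavor_category = character(0),
                      health_category = character(0),
                      stringsAsFactors = FALSE)
  if (length(eligible) == 0L) return(empty)
  fm <- classified$flavor_matches
  hm <- classified$health_matches
  fm <- unique(fm[fm$post_id %in% eligible, c("post_id", "category")])
  hm <- unique(hm[hm$post_id %in% eligible,
                  c("post_id", "category", "keyword")])
  # one entry per distinct health keyword in the post
  hm <- unique(hm[, c("post_id", "category", "keyword")])
  out <- data.frame(
    post_id = hm$post_id,
    flavor_category = fm$category[match(hm$post_id, fm$post_id)],
    health_category = hm$category,
    stringsAsFactors = FALSE)
  out$user_id <- per$user_id[match(out$post_id, per$post_id)]
  out <- out[, c("user_id", "post_id", "flavor_category", "health_category")]
  out <- out[order(out$user_id, out$post_id, out$health_category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read association entries as CSV
#'
#' Columns: `user_id`, `post_id`, `flavor_category`, `health_category`.
#'
#' @param entries Entry data frame.
#' @param path CSV path.
#' @return `read_entries` returns the entry data frame.
#' @export
write_entries <- function(entries, path) {
  write.csv(entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_entries
#' @export
read_entries <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(user_id = "character", post_id = "character"))
}
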