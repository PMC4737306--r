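#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming_distance needs equal-length strings")
  sum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]])
}

max_homopolymer_run <- function(x) {
  r <- rle(strsplit(x, NULL)[[1]])
  max(r$lengths)
}

#' Design a sample-tag set with a minimum pairwise Hamming distance
#'
#' Enumerates all `4^length` tags, drops any with a homopolymer run longer
#' than 3, shuffles the candidates with the given seed and greedily accepts
#' tags that keep the pairwise Hamming distance at or above `min_dist`.
#' Dual-tagged demultiplexing relies on this distance so that a tag read with
#' fewer than `min_dist` errors can never be mistaken for another sample's tag.
#'
#' @param n_needed number of samples to tag.
#' @param length tag length in bases (default 6).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed integer seed; the same seed reproduces the same tag list.
#' @return an object of class `tag_set`: list with `tags` (character vector of
#'   at least `n_needed` tags), `tag_length`, `min_pairwise_distance` and
#'   `leading_pad` (the `NNN` spacer preceding each tag on the amplicon).
#' @export
design_tags <- function(n_needed, length = 6, min_dist = 3, seed = 1) {
  stopifnot(n_needed >= 1, min_dist <= length)
  bases <- c("A", "C", "G", "T")
  cand <- do.call(paste0, rev(expand.grid(rep(list(bases), length),
                                          stringsAsFactors = FALSE)))
  cand <- cand[vapply(cand, max_homopolymer_run, integer(1)) <= 3]
  set.seed(seed)
  cand <- sample(cand)
  chosen <- character(0)
  chosen_split <- list()
  for (tag in cand) {
    s <- strsplit(tag, NULL)[[1]]
    ok <- TRUE
    for (cs in chosen_split) {
      if (sum(cs != s) < min_dist) { ok <- FALSE; break }
    }
    if (ok) {
      chosen <- c(chosen, tag)
      chosen_split <- c(chosen_split, list(s))
      if (length(chosen) >= n_needed) break
    }
  }
  if (length(chosen) < n_needed)
    stop("tag design infeasible: only ", length(chosen), " of ", n_needed,
         " tags achievable at length ", length, ", min distance ", min_dist)
  structure(list(tags = chosen, tag_length = length,
                 min_pairwise_distance = min_dist, leading_pad = "NNN"),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("tag_set:", length(x$tags), "tags of length", x$tag_length,
      "| min pairwise Hamming distance", x$min_pairwise_distance, "\n")
  invisible(x)
}

#' Validate a tag set against its own invariants
#'
#' Recomputes every pairwise distance and homopolymer run exhaustively and
#' reports every violation; an empty report means the set is valid.
#'
#' @param tagset a [design_tags()] object (or a list with `tags`,
#'   `tag_length`, `min_pairwise_distance`).
#' @return list with `valid` (logical), `bad_pairs` (data.frame `tag_a`,
#'   `tag_b`, `distance` for pairs below the minimum) and `bad_tags`
#'   (data.frame `tag`, `reason` for length or homopolymer violations).
#' @export
validate_tagset <- function(tagset) {
  tags <- tagset$tags
  bad_tags <- data.frame(tag = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  wrong_len <- tags[nchar(tags) != tagset$tag_length]
  if (length(wrong_len))
    bad_tags <- rbind(bad_tags, data.frame(tag = wrong_len, reason = "length",
                                           stringsAsFactors = FALSE))
  runs <- tags[nchar(tags) == tagset$tag_length &
                 vapply(tags, max_homopolymer_run, integer(1)) > 3]
  if (length(runs))
    bad_tags <- rbind(bad_tags, data.frame(tag = runs, reason = "homopolymer",
                                           stringsAsFactors = FALSE))
  bad_pairs <- data.frame(tag_a = character(0), tag_b = character(0),
                          distance = integer(0), stringsAsFactors = FALSE)
  n <- length(tags)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (nchar(tags[i]) != nchar(tags[j])) next  # already reported as length
      d <- hamming_distance(tags[i], tags[j])
      if (d < tagset$min_pairwise_distance)
        bad_pairs <- rbind(bad_pairs,
                           data.frame(tag_a = tags[i], tag_b = tags[j],
                                      distance = d, stringsAsFactors = FALSE))
    }
  }
  list(valid = nrow(bad_pairs) == 0 && nrow(bad_tags) == 0,
       bad_pairs = bad_pairs, bad_tags = bad_tags)
}

#' Write / read a sample-to-tag assignment table
#'
#' @param tagset a `tag_set`.
#' @param sample_ids character vector (recycled over `tagset$tags` in order).
#' @param path TSV path.
#' @return the written data.frame (`sample_id`, `tag`), invisibly.
#' @export
write_tag_table <- function(tagset, sample_ids, path) {
  if (length(sample_ids) > length(tagset$tags))
    stop("more samples than tags")
  df <- data.frame(sample_id = sample_ids,
                   tag = tagset$tags[seq_along(sample_ids)],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
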