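#' Read a FASTQ file (Phred+33) into a read table
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `sequence`, `quality` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Expected number of sequencing errors in a read
#'
#' The sum over bases of the Phred error probability `10^(-Q/10)`; the
#' usual statistic for whole-read quality filtering of amplicon data.
#'
#' @param qualities integer vector of Phred scores, or a single Phred+33
#'   quality string.
#' @return nonnegative numeric.
#' @export
expected_errors <- function(qualities) {
  if (is.character(qualities)) {
    stopifnot(length(qualities) == 1)
    qualities <- utf8ToInt(qualities) - 33L
  }
  if (length(qualities) == 0) stop("empty quality vector")
  if (any(qualities < 0)) stop("negative Phred score")
  sum(10^(-qualities / 10))
}

#' Quality-filter reads by expected errors and minimum length
#'
#' Keeps reads with `expected_errors <= max_ee` (inclusive) and length at
#' least `min_length`. Reads failing both tests are tallied under the length
#' reason, which is checked first.
#'
#' @param reads read table from [read_fastq()].
#' @param max_ee maximum expected errors per read (default 0.5).
#' @param min_length minimum read length (default 154, sized for a ~106-bp
#'   insert flanked by tagged primers).
#' @return list with `reads` (kept rows) and `discarded`
#'   (named vector: `too_short`, `high_expected_errors`).
#' @export
quality_filter <- function(reads, max_ee = 0.5, min_length = 154) {
  len_ok <- nchar(reads$sequence) >= min_length
  ee <- vapply(reads$quality, expected_errors, numeric(1), USE.NAMES = FALSE)
  ee_ok <- ee <= max_ee
  keep <- len_ok & ee_ok
  list(reads = reads[keep, , drop = FALSE],
       discarded = c(too_short = sum(!len_ok),
                     high_expected_errors = sum(len_ok & !ee_ok)))
}

iupac_sets <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

primer_mismatches <- function(observed, primer) {
  obs <- strsplit(observed, NULL)[[1]]
  pri <- strsplit(primer, NULL)[[1]]
  stopifnot(length(obs) == length(pri))
  sum(!mapply(function(o, p) grepl(o, iupac_sets[[p]], fixed = TRUE), obs, pri))
}

#' Demultiplex reads by dual sample tags
#'
#' A read is assigned to a replicate only when, after skipping the leading
#' pad, the 5' tag and the reverse-complemented 3' tag both match that
#' replicate's tag exactly; mismatched or unknown tag combinations (the
#' signature of tag jumping and chimeras) are counted as unassigned. Pads and
#' tags are stripped from assigned reads.
#'
#' @param reads read table (`read_id`, `sequence`, optionally `quality`).
#' @param tag_table data.frame (`sample_id`, `tag`) mapping replicates to tags.
#' @param pad leading spacer preceding each tag (default `"NNN"`).
#' @return list with `reads` (data.frame `replicate_id`, `sequence`,
#'   `read_id`) and `unassigned` (count).
#' @export
demultiplex <- function(reads, tag_table, pad = "NNN") {
  if (anyDuplicated(tag_table$tag)) stop("tags must be unique per replicate")
  tag_len <- unique(nchar(tag_table$tag))
  if (length(tag_len) != 1) stop("tags must share one length")
  pad_len <- nchar(pad)
  n <- nchar(reads$sequence)
  tag5 <- substr(reads$sequence, pad_len + 1, pad_len + tag_len)
  tag3 <- reverse_complement(substr(reads$sequence, n - pad_len - tag_len + 1,
                                    n - pad_len))
  rep_of <- stats::setNames(tag_table$sample_id, tag_table$tag)
  assigned <- tag5 == tag3 & tag5 %in% tag_table$tag &
    n > 2 * (pad_len + tag_len)
  inner <- substr(reads$sequence, pad_len + tag_len + 1, n - pad_len - tag_len)
  out <- data.frame(replicate_id = unname(rep_of[tag5[assigned]]),
                    sequence = inner[assigned],
                    read_id = reads$read_id[assigned],
                    stringsAsFactors = FALSE)
  list(reads = out, unassigned = sum(!assigned))
}

#' Trim PCR primers off demultiplexed reads
#'
#' The forward primer is matched at the 5' end and the reverse primer, as its
#' reverse complement, at the 3' end, each allowing at most `max_mismatches`
#' mismatches (IUPAC degeneracy codes in the primers match their base
#' classes). Reads failing either primer are discarded.
#'
#' @param demuxed data.frame (`replicate_id`, `sequence`, `read_id`).
#' @param forward_primer,reverse_primer primer sequences, 5'->3' as supplied
#'   to the PCR.
#' @param max_mismatches per-primer mismatch cap (default 2).
#' @return list with `reads` (data.frame `replicate_id`, `insert`, `read_id`)
#'   and `discarded` (count).
#' @export
trim_primers <- function(demuxed, forward_primer, reverse_primer,
                         max_mismatches = 2) {
  stopifnot(nzchar(forward_primer), nzchar(reverse_primer))
  f_len <- nchar(forward_primer)
  rc_rev <- reverse_complement(reverse_primer)
  r_len <- nchar(rc_rev)
  # evaluate each distinct sequence once; amplicon data is highly redundant
  uniq <- unique(demuxed$sequence)
  n_u <- nchar(uniq)
  ok_u <- logical(length(uniq))
  insert_u <- character(length(uniq))
  for (i in seq_along(uniq)) {
    if (n_u[i] <= f_len + r_len) next
    f_mm <- primer_mismatches(substr(uniq[i], 1, f_len), forward_primer)
    r_mm <- primer_mismatches(substr(uniq[i], n_u[i] - r_len + 1, n_u[i]),
                              rc_rev)
    if (f_mm <= max_mismatches && r_mm <= max_mismatches) {
      ok_u[i] <- TRUE
      insert_u[i] <- substr(uniq[i], f_len + 1, n_u[i] - r_len)
    }
  }
  idx <- match(demuxed$sequence, uniq)
  ok <- ok_u[idx]
  insert <- insert_u[idx]
  list(reads = data.frame(replicate_id = demuxed$replicate_id[ok],
                          insert = insert[ok],
                          read_id = demuxed$read_id[ok],
                          stringsAsFactors = FALSE),
       discarded = sum(!ok))
}

#' Drop inserts containing long homopolymer runs
#'
#' @param inserts data.frame with an `insert` column.
#' @param max_run longest tolerated single-base run (default 7; runs strictly
#'   longer are discarded).
#' @return list with `reads` (kept rows) and `discarded` (count).
#' @export
homopolymer_filter <- function(inserts, max_run = 7) {
  runs <- vapply(inserts$insert, max_homopolymer_run, integer(1),
                 USE.NAMES = FALSE)
  keep <- runs <= max_run
  list(reads = inserts[keep, , drop = FALSE], discarded = sum(!keep))
}

#' Dereplicate identical inserts and drop low-abundance uniques
#'
#' Groups exact-identical insert sequences, keeping per-replicate counts, and
#' removes groups below `min_abundance` total reads (the default 2 removes
#' singletons). Output is sorted by decreasing abundance, ties broken
#' lexicographically by sequence, which fixes the downstream clustering order.
#'
#' @param inserts data.frame (`replicate_id`, `insert`).
#' @param min_abundance minimum total copies to keep a unique (default 2).
#' @return list with `sequences` (character), `abundance` (integer),
#'   `counts` (unique-by-replicate matrix) and `discarded_reads`
#'   (reads lost with dropped uniques).
#' @export
dereplicate <- function(inserts, min_abundance = 2) {
  tab <- table(factor(inserts$insert), factor(inserts$replicate_id))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  ab <- rowSums(counts)
  ord <- order(-ab, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  ab <- ab[ord]
  keep <- ab >= min_abundance
  list(sequences = rownames(counts)[keep],
       abundance = unname(ab[keep]),
       counts = counts[keep, , drop = FALSE],
       discarded_reads = sum(ab[!keep]))
}

#' Greedy centroid clustering of unique sequences into OTUs
#'
#' Scans uniques in decreasing-abundance order; each sequence joins the first
#' existing centroid whose global-alignment identity (see [align_stats()])
#' reaches the threshold, otherwise founds a new OTU. Per-replicate counts
#' aggregate over members.
#'
#' @param uniques output of [dereplicate()].
#' @param identity_threshold minimum identity to join a centroid
#'   (default 0.99).
#' @return list with `centroids` (named character, `OTU_1`, `OTU_2`, ... in
#'   founding order), `counts` (OTU-by-replicate matrix) and `members`
#'   (list of member sequences per OTU).
#' @export
cluster_otus <- function(uniques, identity_threshold = 0.99) {
  centroids <- character(0)
  members <- list()
  rows <- list()
  for (i in seq_along(uniques$sequences)) {
    s <- uniques$sequences[i]
    placed <- 0L
    for (j in seq_along(centroids)) {
      if (align_stats(centroids[j], s)$identity >= identity_threshold) {
        placed <- j; break
      }
    }
    if (placed == 0L) {
      centroids <- c(centroids, s)
      members <- c(members, list(s))
      rows <- c(rows, list(uniques$counts[i, ]))
    } else {
      members[[placed]] <- c(members[[placed]], s)
      rows[[placed]] <- rows[[placed]] + uniques$counts[i, ]
    }
  }
  ids <- paste0("OTU_", seq_along(centroids))
  counts <- do.call(rbind, rows)
  if (is.null(counts)) {
    counts <- matrix(integer(0), nrow = 0, ncol = ncol(uniques$counts),
                     dimnames = list(NULL, colnames(uniques$counts)))
  } else {
    rownames(counts) <- ids
  }
  list(centroids = stats::setNames(centroids, ids), counts = counts,
       members = stats::setNames(members, ids))
}

#' Run the full read-processing cascade
#'
#' Quality filter, dual-tag demultiplexing, primer trimming, homopolymer
#' filter, dereplication with singleton removal, and greedy OTU clustering,
#' with a per-stage ledger of reads kept and discarded.
#'
#' @param reads read table from [read_fastq()].
#' @param tag_table data.frame (`sample_id`, `tag`).
#' @param forward_primer,reverse_primer PCR primer sequences.
#' @param max_ee,min_length see [quality_filter()].
#' @param max_mismatches see [trim_primers()].
#' @param max_run see [homopolymer_filter()].
#' @param min_abundance see [dereplicate()].
#' @param identity_threshold see [cluster_otus()].
#' @param pad see [demultiplex()].
#' @return list with `otus` (the [cluster_otus()] result) and `log`
#'   (data.frame `stage`, `reads_in`, `reads_out`, `reads_discarded`).
#' @export
process_reads <- function(reads, tag_table,
                          forward_primer = "ACTGGGATTAGATACCCC",
                          reverse_primer = "TAGAACAGGCTCCTCTAG",
                          max_ee = 0.5, min_length = 154, max_mismatches = 2,
                          max_run = 7, min_abundance = 2,
                          identity_threshold = 0.99, pad = "NNN") {
  log <- list()
  note <- function(stage, n_in, n_out)
    data.frame(stage = stage, reads_in = n_in, reads_out = n_out,
               reads_discarded = n_in - n_out, stringsAsFactors = FALSE)

  qf <- quality_filter(reads, max_ee = max_ee, min_length = min_length)
  log[[1]] <- note("quality_filter", nrow(reads), nrow(qf$reads))
  dm <- demultiplex(qf$reads, tag_table, pad = pad)
  log[[2]] <- note("demultiplex", nrow(qf$reads), nrow(dm$reads))
  tp <- trim_primers(dm$reads, forward_primer, reverse_primer,
                     max_mismatches = max_mismatches)
  log[[3]] <- note("trim_primers", nrow(dm$reads), nrow(tp$reads))
  hp <- homopolymer_filter(tp$reads, max_run = max_run)
  log[[4]] <- note("homopolymer_filter", nrow(tp$reads), nrow(hp$reads))
  dr <- dereplicate(hp$reads, min_abundance = min_abundance)
  log[[5]] <- note("dereplicate_min_abundance", nrow(hp$reads),
                   sum(dr$abundance))
  ot <- cluster_otus(dr, identity_threshold = identity_threshold)
  log[[6]] <- note("cluster_otus", sum(dr$abundance), sum(ot$counts))
  list(otus = ot, log = do.call(rbind, log))
}
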