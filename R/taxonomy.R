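#' Build a taxonomy tree from lineage paths
#'
#' Lineages are `;`-delimited `rank:name` paths ordered root-to-tip, e.g.
#' `"class:Actinopterygii;family:Sebastidae;genus:Sebastes"`. Identical path
#' prefixes are merged, so all lineages hang off a single implicit root.
#'
#' @param lineages character vector of lineage paths.
#' @return an object of class `taxonomy`: a node table
#'   (`id`, `name`, `rank`, `parent`, `path`) with `parent = 0` for the root.
#' @export
build_taxonomy <- function(lineages) {
  lineages <- unique(lineages[!is.na(lineages)])
  nodes <- data.frame(id = 1L, name = "root", rank = "root", parent = 0L,
                      path = "root", stringsAsFactors = FALSE)
  path_id <- c(root = 1L)
  for (lin in lineages) {
    parts <- strsplit(lin, ";", fixed = TRUE)[[1]]
    parent <- 1L
    acc <- "root"
    for (part in parts) {
      rank <- sub(":.*$", "", part)
      name <- sub("^[^:]*:", "", part)
      acc <- paste(acc, part, sep = ";")
      if (is.na(path_id[acc])) {
        id <- nrow(nodes) + 1L
        nodes <- rbind(nodes, data.frame(id = id, name = name, rank = rank,
                                         parent = parent, path = acc,
                                         stringsAsFactors = FALSE))
        path_id[acc] <- id
      }
      parent <- path_id[[acc]]
    }
  }
  structure(list(nodes = nodes), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy:", nrow(x$nodes), "nodes,",
      length(unique(x$nodes$rank)) - 1L, "ranks\n")
  invisible(x)
}

#' Find the node id of a named taxon
#'
#' @param tree a [build_taxonomy()] object.
#' @param name taxon name.
#' @param rank optional rank to disambiguate homonyms.
#' @return integer node id.
#' @export
taxonomy_node <- function(tree, name, rank = NULL) {
  hit <- tree$nodes[tree$nodes$name == name, , drop = FALSE]
  if (!is.null(rank)) hit <- hit[hit$rank == rank, , drop = FALSE]
  if (nrow(hit) == 0) stop("taxon not found in tree: ", name)
  if (nrow(hit) > 1) stop("ambiguous taxon name (give a rank): ", name)
  hit$id
}

#' Ancestors of a node, self first, root last
#'
#' @param tree a taxonomy.
#' @param id node id.
#' @return integer vector of node ids.
#' @export
ancestors_of <- function(tree, id) {
  if (!id %in% tree$nodes$id) stop("node id not in tree: ", id)
  out <- integer(0)
  while (id != 0L) {
    out <- c(out, id)
    id <- tree$nodes$parent[match(id, tree$nodes$id)]
  }
  out
}

#' Lowest common ancestor of a set of nodes
#'
#' @param tree a taxonomy.
#' @param ids integer node ids (length >= 1).
#' @return the id of the deepest node that is an ancestor-or-self of every
#'   input node.
#' @export
lca_nodes <- function(tree, ids) {
  ids <- unique(ids)
  common <- ancestors_of(tree, ids[[1]])
  for (id in ids[-1]) common <- common[common %in% ancestors_of(tree, id)]
  common[[1]]  # ancestors are ordered deepest-first
}

#' Does `id` descend from (or equal) `ancestor`?
#'
#' @param tree a taxonomy.
#' @param id,ancestor node ids.
#' @return logical.
#' @export
descends_from <- function(tree, id, ancestor) {
  ancestor %in% ancestors_of(tree, id)
}

#' Lineage path string of a node
#'
#' @param tree a taxonomy.
#' @param id node id.
#' @return `;`-delimited `rank:name` path (without the root), or `""` for the
#'   root itself.
#' @export
node_lineage <- function(tree, id) {
  path <- tree$nodes$path[match(id, tree$nodes$id)]
  sub("^root;?", "", path)
}

#' Assemble a reference database for taxonomic assignment
#'
#' @param sequences named character vector: `ref_id` to DNA sequence.
#' @param lineages named character vector: `ref_id` to lineage path.
#' @return an object of class `reference_db` holding the entries and the
#'   taxonomy built from the lineages.
#' @export
reference_db <- function(sequences, lineages) {
  if (is.null(names(sequences)) || is.null(names(lineages)))
    stop("sequences and lineages must be named by ref_id")
  missing_lin <- setdiff(names(sequences), names(lineages))
  if (length(missing_lin))
    stop("no lineage for refs: ", paste(missing_lin, collapse = ", "))
  tree <- build_taxonomy(unname(lineages[names(sequences)]))
  node_id <- vapply(names(sequences), function(r) {
    path <- paste0("root;", lineages[[r]])
    tree$nodes$id[match(path, tree$nodes$path)]
  }, integer(1))
  structure(list(entries = data.frame(ref_id = names(sequences),
                                      sequence = unname(sequences),
                                      node_id = node_id,
                                      stringsAsFactors = FALSE),
                 taxonomy = tree),
            class = "reference_db")
}

#' Read a reference database from FASTA + lineage TSV
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param lineage_path two-column TSV (`ref_id`, `lineage`).
#' @return a [reference_db()].
#' @export
read_reference_db <- function(fasta_path, lineage_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  lin <- utils::read.table(lineage_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  reference_db(stats::setNames(as.character(seqs), names(seqs)),
               stats::setNames(lin$lineage, lin$ref_id))
}

#' Exhaustive reference search for an OTU centroid
#'
#' Aligns the centroid globally against every reference and keeps hits at or
#' above the identity and score floors. At desk scale the search is exhaustive,
#' with no heuristic seeding, so results are exactly reproducible.
#'
#' @param centroid DNA string.
#' @param db a [reference_db()].
#' @param min_identity minimum fraction identity (default 0.98, the usual
#'   cutoff for a ~106-bp vertebrate 12S fragment).
#' @param min_score absolute alignment-score floor on the +1/-1/-2 scheme
#'   (default 90: a perfect 106-bp match scores 106 and passes, a
#'   90%-identity match scores about 84 and fails).
#' @return data.frame of hits (`ref_id`, `identity`, `score`, `node_id`)
#'   sorted by decreasing score, ties by `ref_id`.
#' @export
search_reference <- function(centroid, db, min_identity = 0.98, min_score = 90) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$entries) == 0) stop("reference database is empty")
  if (!nzchar(centroid)) stop("empty centroid sequence")
  stats <- lapply(db$entries$sequence, align_stats, b = centroid)
  hits <- data.frame(ref_id = db$entries$ref_id,
                     identity = vapply(stats, `[[`, numeric(1), "identity"),
                     score = vapply(stats, `[[`, numeric(1), "score"),
                     node_id = db$entries$node_id,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= min_identity & hits$score >= min_score, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$ref_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Lowest-common-ancestor consensus over near-best hits
#'
#' Retains hits whose score is within `top_percent` percent of the best hit
#' (boundary inclusive) and returns the deepest taxonomy node ancestral to all
#' of them; with no hits the OTU is left unassigned.
#'
#' @param hits a hit data.frame from [search_reference()], sorted by score.
#' @param tree the taxonomy the hits' `node_id`s live in.
#' @param top_percent retention window as a percentage of the best score
#'   (default 2).
#' @return list with `node_id` (or `NA` if unassigned), `name`, `rank`,
#'   `lineage` and `n_hits` (number of retained hits).
#' @export
lca_assign <- function(hits, tree, top_percent = 2) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(node_id = NA_integer_, name = "UNASSIGNED", rank = NA_character_,
                lineage = NA_character_, n_hits = 0L))
  if (!all(hits$node_id %in% tree$nodes$id))
    stop("hit node missing from taxonomy tree")
  best <- max(hits$score)
  kept <- hits[hits$score >= (1 - top_percent / 100) * best, , drop = FALSE]
  node <- lca_nodes(tree, kept$node_id)
  i <- match(node, tree$nodes$id)
  list(node_id = node, name = tree$nodes$name[i], rank = tree$nodes$rank[i],
       lineage = node_lineage(tree, node), n_hits = nrow(kept))
}

#' Assign taxonomy to a whole set of OTUs
#'
#' @param centroids named character vector of OTU centroid sequences.
#' @param db a [reference_db()].
#' @param min_identity,min_score passed to [search_reference()].
#' @param top_percent passed to [lca_assign()].
#' @return data.frame (`otu_id`, `name`, `rank`, `lineage`, `n_hits`).
#' @export
assign_taxonomy <- function(centroids, db, min_identity = 0.98, min_score = 90,
                            top_percent = 2) {
  rows <- lapply(names(centroids), function(otu) {
    hits <- search_reference(centroids[[otu]], db, min_identity, min_score)
    a <- lca_assign(hits, db$taxonomy, top_percent)
    data.frame(otu_id = otu, name = a$name, rank = a$rank, lineage = a$lineage,
               n_hits = a$n_hits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse an OTU table into a taxon table using assignments
#'
#' OTUs sharing an assigned node are summed per replicate; unassigned OTUs are
#' routed to a side matrix so that no reads are silently dropped.
#'
#' @param assignments data.frame from [assign_taxonomy()].
#' @param otu_counts OTU-by-replicate count matrix (rownames = otu ids).
#' @param meta replicate metadata (see [taxon_table()]).
#' @return list with `table` (a [taxon_table] of assigned taxa) and
#'   `unassigned` (OTU-by-replicate matrix of unassigned counts).
#' @export
build_taxon_table <- function(assignments, otu_counts, meta) {
  if (!all(rownames(otu_counts) %in% assignments$otu_id))
    stop("every OTU needs an assignment")
  a <- assignments[match(rownames(otu_counts), assignments$otu_id), ]
  unassigned <- otu_counts[a$name == "UNASSIGNED", , drop = FALSE]
  kept <- a$name != "UNASSIGNED"
  counts <- rowsum(otu_counts[kept, , drop = FALSE], group = a$name[kept])
  taxa <- unique(data.frame(taxon_id = a$name[kept], rank = a$rank[kept],
                            lineage = a$lineage[kept], stringsAsFactors = FALSE))
  list(table = taxon_table(counts[order(rownames(counts)), , drop = FALSE],
                           meta, taxa),
       unassigned = unassigned)
}
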