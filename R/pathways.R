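# Pathway collection handling: GMT gene sets + per-pathway interaction edges.

new_pathway <- function(id, name, genes, edges_sym) {
  structure(list(id = id, name = name, genes = genes, edges = edges_sym),
            class = "pathway_definition")
}

#' Load pathways from a GMT gene-set file and an interaction edge list
#'
#' The GMT file supplies pathway membership (one record per line:
#' id, description, member genes, tab-separated).  The edge file supplies
#' gene-gene interactions, one row per edge with columns
#' `pathway_id`, `gene_a`, `gene_b` (tab-separated, header required; the SIF
#' dialect `gene_a  interaction  gene_b` grouped per pathway is accepted via
#' `dialect = "sif"`, where the interaction type is ignored and the pathway id
#' is taken from the first column).  Edges whose endpoints are not both
#' members of the named pathway are dropped with a warning; self-edges and
#' duplicates are removed.
#'
#' @param geneset_path path to the GMT file.
#' @param edges_path path to the edge list (may list zero edges).
#' @param dialect `"tsv"` (pathway_id, gene_a, gene_b) or `"sif"`
#'   (pathway_id, interaction, gene_a, gene_b).
#' @return a `pathway_collection`: list of pathway definitions plus
#'   provenance (source files, dropped-edge counters).
#' @export
load_pathways <- function(geneset_path, edges_path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(geneset_path), paste("cannot read", geneset_path))
  assert_that(file.exists(edges_path), paste("cannot read", edges_path))
  lines <- readLines(geneset_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0L, "GMT file contains no records")
  pw <- list()
  order_ids <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    assert_that(length(f) >= 3L, "malformed GMT record (need id, name, >=1 gene)")
    id <- f[1L]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    assert_that(length(genes) >= 1L, paste("GMT record with no genes:", id))
    assert_that(is.null(pw[[id]]), paste("duplicate pathway id in GMT:", id))
    pw[[id]] <- new_pathway(id, f[2L], genes, matrix(character(0), 0L, 2L))
    order_ids <- c(order_ids, id)
  }
  edf <- utils::read.delim(edges_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  dropped_endpoint <- 0L
  dropped_unknown <- 0L
  edges_by_pw <- list()
  if (nrow(edf) > 0L) {
    if (dialect == "sif") {
      assert_that(ncol(edf) >= 4L, "SIF edge file needs pathway_id, gene_a, interaction, gene_b")
      recs <- data.frame(pathway_id = edf[[1L]], gene_a = edf[[2L]],
                         gene_b = edf[[4L]], stringsAsFactors = FALSE)
    } else {
      assert_that(ncol(edf) >= 3L, "edge file needs pathway_id, gene_a, gene_b columns")
      recs <- data.frame(pathway_id = edf[[1L]], gene_a = edf[[2L]],
                         gene_b = edf[[3L]], stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(recs))) {
      pid <- recs$pathway_id[i]
      p <- pw[[pid]]
      if (is.null(p)) { dropped_unknown <- dropped_unknown + 1L; next }
      a <- recs$gene_a[i]; b <- recs$gene_b[i]
      if (a == b || !(a %in% p$genes) || !(b %in% p$genes)) {
        dropped_endpoint <- dropped_endpoint + 1L
        next
      }
      e <- sort(c(a, b))
      edges_by_pw[[pid]] <- rbind(edges_by_pw[[pid]], e)
    }
  }
  if (dropped_unknown > 0L) {
    warning(dropped_unknown, " edge row(s) referenced unknown pathway ids and were skipped")
  }
  if (dropped_endpoint > 0L) {
    warning(dropped_endpoint,
            " edge row(s) had endpoints outside the pathway gene set (or self-pairs) and were dropped")
  }
  for (pid in names(edges_by_pw)) {
    e <- unique(edges_by_pw[[pid]])
    dimnames(e) <- NULL
    pw[[pid]]$edges <- e
  }
  structure(list(
    pathways = pw[order_ids],
    provenance = list(geneset = geneset_path, edges = edges_path,
                      dropped_bad_endpoint = dropped_endpoint,
                      dropped_unknown_pathway = dropped_unknown,
                      filters = NULL)
  ), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$genes), integer(1))
  cat("Pathway collection:", length(x$pathways), "pathways,",
      length(unique(unlist(lapply(x$pathways, `[[`, "genes")))), "unique genes\n")
  if (length(sizes)) {
    cat("  gene counts: median", stats::median(sizes), " range [",
        min(sizes), ",", max(sizes), "]\n")
  }
  invisible(x)
}

#' Filter a pathway collection by size and deduplicate
#'
#' Retains pathways with `min_genes <= |genes| <= max_genes` and drops exact
#' duplicates (identical gene set and edge set), keeping the first by input
#' order.
#'
#' @param collection a `pathway_collection`.
#' @param min_genes,max_genes inclusive gene-count bounds (defaults 15 and 400).
#' @return the filtered collection; removal counts by reason are recorded in
#'   `provenance$filters`.
#' @export
filter_pathways <- function(collection, min_genes = 15L, max_genes = 400L) {
  assert_that(min_genes <= max_genes, "min_genes must not exceed max_genes")
  keys <- character(0)
  kept <- list()
  removed_size <- 0L
  removed_dup <- 0L
  for (p in collection$pathways) {
    n <- length(p$genes)
    if (n < min_genes || n > max_genes) { removed_size <- removed_size + 1L; next }
    gs <- paste(sort(p$genes), collapse = "|")
    es <- if (nrow(p$edges)) {
      paste(sort(paste(p$edges[, 1L], p$edges[, 2L], sep = "~")), collapse = "|")
    } else ""
    key <- paste(gs, es, sep = "##")
    if (key %in% keys) { removed_dup <- removed_dup + 1L; next }
    keys <- c(keys, key)
    kept[[p$id]] <- p
  }
  collection$pathways <- kept
  collection$provenance$filters <- list(min_genes = min_genes, max_genes = max_genes,
                                        removed_size = removed_size,
                                        removed_duplicate = removed_dup)
  collection
}

#' Summary statistics of a pathway collection
#'
#' @param collection a non-empty `pathway_collection`.
#' @return list with per-pathway gene counts (and median), per-gene
#'   pathway-membership counts (with quantiles and maximum), the number of
#'   genes belonging to exactly one pathway, and the total unique gene count.
#' @export
collection_stats <- function(collection) {
  assert_that(length(collection$pathways) > 0L, "empty pathway collection")
  sizes <- vapply(collection$pathways, function(p) length(p$genes), integer(1))
  membership <- table(unlist(lapply(collection$pathways, `[[`, "genes")))
  list(
    n_pathways = length(sizes),
    gene_counts = as.integer(sizes),
    median_genes = stats::median(sizes),
    n_unique_genes = length(membership),
    membership_counts = as.integer(membership),
    membership_quantiles = stats::quantile(as.integer(membership),
                                           c(0.5, 0.95, 1.0), names = TRUE),
    max_sharing = max(as.integer(membership)),
    n_single_pathway_genes = sum(membership == 1L)
  )
}

# integer edge index matrix for a pathway (relative to its gene order)
pathway_edge_index <- function(p) {
  if (nrow(p$edges) == 0L) return(matrix(integer(0), 0L, 2L))
  idx <- cbind(match(p$edges[, 1L], p$genes), match(p$edges[, 2L], p$genes))
  storage.mode(idx) <- "integer"
  idx
}

#' Write a pathway collection to GMT and edge-list files
#'
#' Inverse of [load_pathways()]; used by the synthetic-data generator.
#'
#' @param collection a `pathway_collection`.
#' @param geneset_path,edges_path output file paths.
#' @export
write_pathways <- function(collection, geneset_path, edges_path) {
  gmt <- vapply(collection$pathways, function(p) {
    paste(c(p$id, p$name, p$genes), collapse = "\t")
  }, character(1))
  writeLines(gmt, geneset_path)
  rows <- c("pathway_id\tgene_a\tgene_b")
  for (p in collection$pathways) {
    if (nrow(p$edges)) {
      rows <- c(rows, paste(p$id, p$edges[, 1L], p$edges[, 2L], sep = "\t"))
    }
  }
  writeLines(rows, edges_path)
  invisible(NULL)
}
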