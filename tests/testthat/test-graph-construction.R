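test_that("GMT and edge files parse into a pathway collection", {
  f <- write_micro_pathway_files()
  coll <- load_pathways(f$gmt, f$edges)
  expect_s3_class(coll, "pathway_collection")
  expect_equal(length(coll$pathways), 2L)
  expect_equal(sum(vapply(coll$pathways, function(p) nrow(p$edges), integer(1))), 3L)
  expect_equal(coll$pathways$P1$genes, c("gA", "gB", "gC"))
  # empty edge file: isolated-node graphs, load succeeds
  empty <- file.path(tempdir(), "empty_edges.tsv")
  writeLines("pathway_id\tgene_a\tgene_b", empty)
  coll0 <- load_pathways(f$gmt, empty)
  expect_equal(nrow(coll0$pathways$P1$edges), 0L)
})

test_that("edges with bad endpoints or unknown pathways are dropped and counted", {
  d <- withr_like_tempdir()
  gmt <- file.path(d, "s.gmt"); edg <- file.path(d, "e.tsv")
  writeLines("P1\tx\tgX\tgZ", gmt)
  writeLines(c("pathway_id\tgene_a\tgene_b",
               "P1\tgX\tgY",      # gY not a member
               "P1\tgX\tgX",      # self-pair
               "P9\tgX\tgZ",      # unknown pathway
               "P1\tgX\tgZ"), edg)
  expect_warning(expect_warning(coll <- load_pathways(gmt, edg),
                                "unknown pathway"), "dropped")
  expect_equal(coll$provenance$dropped_bad_endpoint, 2L)
  expect_equal(coll$provenance$dropped_unknown_pathway, 1L)
  expect_equal(nrow(coll$pathways$P1$edges), 1L)
})

make_sized_collection <- function(sizes, ids = NULL) {
  pw <- list()
  for (i in seq_along(sizes)) {
    id <- ids[i] %||% paste0("S", i)
    genes <- paste0("g", i, "_", seq_len(sizes[i]))
    pw[[id]] <- pathgnn:::new_pathway(id, id, genes, matrix(character(0), 0, 2))
  }
  structure(list(pathways = pw, provenance = list(filters = NULL)),
            class = "pathway_collection")
}
`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

test_that("size filter keeps the inclusive 15..400 range and dedups", {
  coll <- make_sized_collection(c(14, 15, 400, 401))
  filt <- filter_pathways(coll)
  sizes <- vapply(filt$pathways, function(p) length(p$genes), integer(1))
  expect_equal(unname(sort(sizes)), c(15L, 400L))
  expect_equal(filt$provenance$filters$removed_size, 2L)

  # identical genes+edges, different ids: first by input order survives
  dup <- make_sized_collection(c(20, 20), ids = c("A", "B"))
  dup$pathways$B$genes <- dup$pathways$A$genes
  filt2 <- filter_pathways(dup)
  expect_equal(names(filt2$pathways), "A")
  expect_equal(filt2$provenance$filters$removed_duplicate, 1L)

  # same genes but different edges: both retained
  dup$pathways$B$edges <- matrix(dup$pathways$A$genes[1:2], 1, 2)
  expect_equal(length(filter_pathways(dup)$pathways), 2L)

  # idempotence and empty input
  expect_equal(names(filter_pathways(filt)$pathways), names(filt$pathways))
  empty <- make_sized_collection(integer(0))
  expect_equal(length(filter_pathways(empty)$pathways), 0L)
  expect_error(filter_pathways(coll, min_genes = 10, max_genes = 5), "min_genes")
})

test_that("survival labelling partitions the cohort by the k-year rule", {
  cohort <- data.frame(
    sample_id = paste0("s", 1:6),
    time_years = c(4.0, 2.0, 2.0, 3.0, 5.0, NA),
    event = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  lab <- assign_survival_labels(cohort, k_years = 3)$label
  expect_equal(as.character(lab),
               c("LTS", "nonLTS", "excluded", "nonLTS", "LTS", "excluded"))
  # every row maps to exactly one category
  expect_false(anyNA(lab))
  expect_error(assign_survival_labels(
    data.frame(sample_id = "x", time_years = -1, event = TRUE), 3), "negative")
})

test_that("clinical feature selection uses t-test and chi-square correctly", {
  set.seed(21)
  n <- 100
  cohort <- data.frame(
    sample_id = paste0("s", 1:(2 * n)),
    time_years = c(rep(5, n), rep(1, n)),
    event = TRUE,
    age = c(rnorm(n, 50, 5), rnorm(n, 70, 5)),          # separated: selected
    noise = rnorm(2 * n),                               # null: not selected
    flat = 1,                                           # constant: skipped
    stringsAsFactors = FALSE
  )
  cohort <- assign_survival_labels(cohort, 3)
  expect_warning(sel <- select_clinical_features(cohort), "constant")
  expect_true(sel$selected[sel$feature == "age"])
  expect_false("flat" %in% sel$feature)

  # hand-computable chi-square: [[30,10],[10,30]] has statistic 20
  cohort2 <- data.frame(
    sample_id = paste0("q", 1:80),
    time_years = rep(c(5, 1), each = 40),
    event = TRUE,
    grp = c(rep("a", 30), rep("b", 10), rep("a", 10), rep("b", 30)),
    stringsAsFactors = FALSE
  )
  cohort2 <- assign_survival_labels(cohort2, 3)
  sel2 <- select_clinical_features(cohort2)
  expect_equal(sel2$p_value[sel2$feature == "grp"],
               stats::pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(sel2$selected[sel2$feature == "grp"])
})

test_that("patient graphs carry preprocessed node features in fixed order", {
  f <- write_micro_pathway_files()
  coll <- load_pathways(f$gmt, f$edges)
  expr <- matrix(c(3, 0, 1, 7,
                   1, 3, 3, 1), nrow = 4,
                 dimnames = list(c("gA", "gB", "gC", "gD"), c("s1", "s2")))
  cohort <- assign_survival_labels(data.frame(
    sample_id = c("s1", "s2", "s3"),
    time_years = c(5, 1, 5), event = c(FALSE, TRUE, TRUE)), 3)
  expect_warning(pgs <- build_patient_graphs(coll, expr, cohort, "log2p1"),
                 "missing")
  expect_equal(length(pgs), 2L)   # s3 missing from the matrix -> excluded
  expect_equal(pgs[[1]]$features$P1, c(2, 0, 1))  # log2(FPKM+1)
  expect_equal(attr(pgs, "pathway_ids"), c("P1", "P2"))
  # identical pathway/node ordering across samples
  expect_equal(names(pgs[[1]]$features), names(pgs[[2]]$features))

  # gene absent from the matrix gets fill value 0
  expr2 <- expr[c("gA", "gB", "gD"), ]
  expect_warning(
    expect_warning(pgs2 <- build_patient_graphs(coll, expr2, cohort, "log2p1"),
                   "filled with 0"),
    "missing")
  expect_equal(pgs2[[1]]$features$P1[3], 0)
})

test_that("collection statistics summarise sizes and gene sharing", {
  coll <- make_sized_collection(c(15, 50, 399))
  st <- collection_stats(coll)
  expect_equal(st$median_genes, 50)
  expect_equal(st$n_unique_genes, 15 + 50 + 399)
  expect_equal(st$n_single_pathway_genes, st$n_unique_genes)
  expect_equal(st$max_sharing, 1L)
  # one gene shared across all pathways
  coll$pathways$S1$genes[1] <- "shared"
  coll$pathways$S2$genes[1] <- "shared"
  coll$pathways$S3$genes[1] <- "shared"
  expect_equal(collection_stats(coll)$max_sharing, 3L)
})

test_that("preprocessing statistics are fitted on the requested samples only", {
  set.seed(2)
  m <- matrix(rexp(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  pp <- fit_preprocess(m, "log2p1_zscore", sample_ids = paste0("s", 1:5))
  lg <- log2(m[, 1:5] + 1)
  expect_equal(unname(pp$center), unname(rowMeans(lg)))
  out <- apply_preprocess(m, pp)
  expect_equal(unname(rowMeans(out[, 1:5])), rep(0, 4), tolerance = 1e-12)
  expect_false(all(abs(rowMeans(out[, 6:10])) < 1e-9))
})
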