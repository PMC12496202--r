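test_that("classifier matches the truth-table oracle over all patterns", {
  ## enumerate all 3^3 significance/sign patterns per comparison:
  ## significant-up, significant-down, non-significant
  states <- list(c(2, 0.01), c(-2, 0.01), c(0.5, 0.5))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    tabs <- one_row_tables(states[[i]], states[[j]], states[[k]])
    got <- as.character(classify_subsets(tabs$mvf, tabs$ivf,
                                         tabs$mvi)$label)
    want <- oracle_label(states[[i]], states[[j]], states[[k]])
    expect_identical(got, want,
                     label = sprintf("pattern (%d,%d,%d): %s", i, j, k, got))
  }
  ## spec worked example: up, up, ns -> full recovery
  tabs <- one_row_tables(c(2.0, 0.01), c(1.5, 0.02), c(0.3, 0.40))
  expect_identical(as.character(classify_subsets(tabs$mvf, tabs$ivf,
                                                 tabs$mvi)$label),
                   "full_recovery")
  ## MvF not significant gates everything
  tabs <- one_row_tables(c(2.0, 0.20), c(1.5, 0.001), c(1.5, 0.001))
  expect_identical(as.character(classify_subsets(tabs$mvf, tabs$ivf,
                                                 tabs$mvi)$label),
                   "not_male_upregulated")
})

test_that("male-up labels partition {up in MvF} on any simulated table", {
  sim <- simulate_de_tables(de_sim_params(n_genes = 5000,
                                          n_female_up = 500,
                                          spurious_nulls = TRUE,
                                          seed = 31))
  res <- classify_subsets(sim$mvf, sim$ivf, sim$mvi)
  cnt <- attr(res, "counts")
  expect_identical(sum(cnt), nrow(res)) # exhaustive
  up_mvf <- sum(sim$mvf$padj < 0.05 & sim$mvf$log2fc > 0)
  male_up <- sum(cnt[c("full_recovery", "male_independent",
                       "partial_recovery", "mvf_only")])
  expect_identical(male_up, up_mvf)
})

test_that("strong-effect round trip recovers the planted partition exactly", {
  sim <- simulate_de_tables(de_sim_params(n_genes = 20000, seed = 7))
  res <- classify_subsets(sim$mvf, sim$ivf, sim$mvi)
  cnt <- attr(res, "counts")
  expect_identical(as.integer(cnt[c("full_recovery", "male_independent",
                                    "partial_recovery", "mvf_only")]),
                   c(632L, 172L, 89L, 1092L))
  expect_identical(sum(cnt[1:4]), 1985L)
  ## per-transcript agreement with the planted labels
  merged <- merge(as.data.frame(res)[, c("transcript_id", "label")],
                  sim$truth, by = "transcript_id")
  male <- merged$label != "not_male_upregulated"
  expect_identical(as.character(merged$label[male]),
                   merged$label.y[male])
  ## separable limit with no nulls at all
  sim0 <- simulate_de_tables(de_sim_params(
    n_genes = 1985, n_female_up = 0, seed = 8))
  cnt0 <- attr(classify_subsets(sim0$mvf, sim0$ivf, sim0$mvi), "counts")
  expect_identical(unname(as.integer(cnt0)), c(632L, 172L, 89L, 1092L, 0L))
})

test_that("direction = 'down' mirrors the classification of negated tables", {
  sim <- simulate_de_tables(de_sim_params(n_genes = 3000,
                                          n_female_up = 300,
                                          spurious_nulls = TRUE,
                                          seed = 13))
  neg <- function(d) transform(d, log2fc = -log2fc)
  up <- classify_subsets(sim$mvf, sim$ivf, sim$mvi, direction = "up")
  dn <- classify_subsets(neg(sim$mvf), neg(sim$ivf), neg(sim$mvi),
                         direction = "down")
  expect_identical(up$label, dn$label)
})

test_that("lowering the threshold never promotes into a male-up subset", {
  sim <- simulate_de_tables(de_sim_params(n_genes = 3000,
                                          n_female_up = 300,
                                          spurious_nulls = TRUE,
                                          seed = 17))
  r1 <- classify_subsets(sim$mvf, sim$ivf, sim$mvi, fdr_threshold = 0.05)
  r2 <- classify_subsets(sim$mvf, sim$ivf, sim$mvi, fdr_threshold = 0.01)
  was_out <- r1$label == "not_male_upregulated"
  expect_true(all(r2$label[was_out] == "not_male_upregulated"))
})

test_that("missing padj and missing transcripts are handled as specified", {
  tabs <- one_row_tables(c(2, NA), c(1, 0.01), c(1, 0.01))
  res <- classify_subsets(tabs$mvf, tabs$ivf, tabs$mvi)
  expect_identical(as.character(res$label), "not_male_upregulated")
  expect_identical(attr(res, "n_missing_padj"), 1L)

  mvf <- data.frame(transcript_id = c("a", "b"), log2fc = c(2, 2),
                    padj = c(0.01, 0.01))
  sub <- data.frame(transcript_id = "a", log2fc = 2, padj = 0.01)
  expect_warning(res2 <- classify_subsets(mvf, sub, sub), "excluded")
  expect_identical(nrow(res2), 1L)
  expect_identical(attr(res2, "n_dropped"), 1L)

  bad <- data.frame(transcript_id = c("a", "a"), log2fc = 1, padj = 0.5)
  expect_error(classify_subsets(bad, sub, sub), "duplicate")
  expect_error(classify_subsets(mvf, sub, sub, fdr_threshold = 1.5),
               "fdr_threshold")
})

test_that("overlap counts equal a brute-force membership scan", {
  expect_identical(overlap_de_lists(letters[1:10], letters[1:10]),
                   list(shared = 10L, only_a = 0L, only_b = 0L,
                        shared_fraction_of_union = 1))
  ov <- overlap_de_lists(c("a", "b"), c("c", "d"))
  expect_identical(ov$shared, 0L)
  expect_identical(ov$shared_fraction_of_union, 0)

  set.seed(23)
  ids <- sprintf("g%05d", 1:6000)
  a <- sample(ids, 3000)
  b <- sample(ids, 3500)
  ov <- overlap_de_lists(a, b)
  shared_bf <- sum(vapply(a, function(e) any(e == b), logical(1)))
  expect_identical(ov$shared, shared_bf)
  expect_identical(ov$only_a, length(a) - shared_bf)
  expect_identical(ov$only_b, length(b) - shared_bf)
  expect_equal(ov$shared_fraction_of_union,
               shared_bf / (length(a) + length(b) - shared_bf))
})

test_that("DE tables and subset labels survive the TSV contract", {
  sim <- simulate_de_tables(de_sim_params(
    n_genes = 200,
    subset_sizes = c(full_recovery = 30, male_independent = 10,
                     partial_recovery = 5, mvf_only = 40),
    n_female_up = 20, seed = 2))
  paths <- vapply(c("mvf", "ivf", "mvi"), function(nm) {
    f <- withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame(3))
    write_de_table(sim[[nm]], f)
    f
  }, character(1))
  back <- read_de_table(paths[["mvf"]])
  expect_equal(back$log2fc, sim$mvf$log2fc, tolerance = 1e-9)
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- capture.output(
    cli <- earmech_main(c("classify-subsets",
                          "--mvf", paths[["mvf"]],
                          "--ivf", paths[["ivf"]],
                          "--mvi", paths[["mvi"]],
                          "--output", out)))
  expect_s3_class(cli, "subset_assignment")
  lab <- utils::read.delim(out)
  expect_identical(nrow(lab), 200L)
  expect_true("subset_label" %in% names(lab))
})
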