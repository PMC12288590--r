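mk_tracks <- function() {
  genes <- data.frame(contig = "c", start = c(5000L, 9000L),
                      end = c(7000L, 9500L), strand = c("+", "-"),
                      name = c("gA", "gB"), stringsAsFactors = FALSE)
  islands <- data.frame(contig = "c", start = c(20000L, 26000L),
                        end = c(20500L, 26300L), stringsAsFactors = FALSE)
  list(genes = genes, islands = islands)
}

test_that("feature flags follow the distance-band definitions", {
  tr <- mk_tracks()
  sites <- data.frame(contig = "c",
                      pos = c(4500L,   # 500 bp upstream of gA (+)
                              6000L,   # inside gA body
                              9600L,   # 100 bp "upstream" of gB (-)
                              20100L,  # in island
                              21000L,  # 500 bp from island end -> shore
                              23000L,  # 2,500+ bp -> shelf
                              25000L)) # equidistant-ish, nearer 26000 -> shore
  ann <- annotate_sites(sites, tr$genes, tr$islands)
  expect_equal(ann$promoter, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(ann$gene_body, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(ann$cpg_island[4], TRUE)
  expect_equal(ann$cpg_shore[5], TRUE)
  expect_equal(ann$cpg_shelf[6], TRUE)
  expect_equal(ann$cpg_shore[7], TRUE)
  # island/shore/shelf mutually exclusive everywhere
  expect_true(all(rowSums(ann[c("cpg_island", "cpg_shore", "cpg_shelf")]) <= 1))
})

test_that("band exclusivity survives adversarial island layouts", {
  # islands closer than 8 kb: bands of neighbouring islands interleave
  islands <- data.frame(contig = "c", start = c(0L, 3000L, 6500L),
                        end = c(500L, 3400L, 7000L))
  genes <- data.frame(contig = "c", start = 1L, end = 2L, strand = "+",
                      name = "g", stringsAsFactors = FALSE)
  sites <- data.frame(contig = "c", pos = seq(0L, 9000L, by = 37L))
  ann <- annotate_sites(sites, genes, islands)
  expect_true(all(rowSums(ann[c("cpg_island", "cpg_shore", "cpg_shelf")]) <= 1))
  # every in-island site is flagged island
  in_isl <- vapply(sites$pos, function(p) {
    any(p >= islands$start & p < islands$end)
  }, logical(1))
  expect_equal(ann$cpg_island, in_isl)
})

test_that("element enrichment reproduces 2x2 chi-squared arithmetic", {
  # target entirely inside a feature covering half the background -> fold 2
  bg <- data.frame(f = rep(c(TRUE, FALSE), each = 500))
  tg <- data.frame(f = rep(TRUE, 100))
  res <- element_enrichment(tg, bg, features = "f")
  expect_equal(res$fold, 2)
  # direct Pearson chi-squared formula on the same 2x2 counts
  a <- 100; b <- 0; c_ <- 500; d <- 500
  n <- a + b + c_ + d
  e <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / n
  o <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  chi <- sum((o - e)^2 / e)
  expect_equal(res$chisq, chi, tolerance = 1e-10)
  expect_equal(res$p, stats::pchisq(chi, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # background against itself: fold exactly 1 per feature
  res_bg <- element_enrichment(bg, bg, features = "f")
  expect_equal(res_bg$fold, 1)

  # null draw: folds near 1 on average across seeds
  folds <- vapply(1:20, function(s) {
    set.seed(s)
    idx <- sample(1000, 200)
    element_enrichment(bg[idx, , drop = FALSE], bg, features = "f")$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("repeat categories resolve by priority", {
  segdup <- data.frame(contig = "c", start = 100L, end = 200L)
  line <- data.frame(contig = "c", start = 150L, end = 300L)
  sine <- data.frame(contig = "c", start = 400L, end = 450L)
  satellite <- data.frame(contig = "c", start = c(250L, 500L),
                          end = c(320L, 560L))
  sites <- data.frame(contig = "c",
                      pos = c(150L, 250L, 420L, 520L, 900L))
  cat <- assign_repeat_category(sites, segdup, line, sine, satellite)
  expect_equal(as.character(cat),
               c("segdup",     # in segdup AND LINE -> segdup wins
                 "line_sine",  # in LINE and satellite -> line_sine wins
                 "line_sine",  # SINE merges into line_sine
                 "satellite",
                 "none"))
  fold <- repeat_category_fold(cat, cat)
  expect_true(all(fold$fold[fold$n_b > 0] == 1))
})

test_that("driver enrichment matches the hypergeometric expectation", {
  set.seed(19)
  universe <- paste0("g", 1:200)
  drivers <- paste0("g", 1:20)  # 10% of the universe
  # null: uniformly drawn targets give fold ~ 1 and p rarely small
  res_null <- lapply(1:20, function(s) {
    driver_gene_enrichment(sample(universe, 40), drivers, universe,
                           n_perm = 200, seed = s)
  })
  folds <- vapply(res_null, `[[`, numeric(1), "fold")
  ps <- vapply(res_null, `[[`, numeric(1), "p")
  expect_lt(abs(mean(folds) - 1), 0.25)
  expect_gte(mean(ps >= 0.05), 0.9)

  # extreme case: target wholly inside the driver set
  ex <- driver_gene_enrichment(drivers[1:10], drivers, universe,
                               n_perm = 1000, seed = 4)
  expect_equal(ex$observed, 10L)
  expect_equal(ex$p, 1 / 1001)
  # mean permuted overlap converges to |target||drivers|/|universe| = 1
  expect_lt(abs(ex$expected - 1), 3 * sqrt(1 * 0.9 / sqrt(1000)))

  expect_error(driver_gene_enrichment(c("zz"), drivers, universe), "universe")
})

test_that("over-representation p equals exhaustive draw enumeration", {
  universe <- paste0("g", 1:10)
  target <- universe[1:5]
  sets <- list(hit = universe[1:4], part = universe[c(1, 6, 7, 8)])
  res <- overrepresentation(target, sets, universe)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 oracle_hyper_enum(res$k[i], sets[[res$set[i]]], 5, universe),
                 tolerance = 1e-12)
  }
  # target equal to a set: maximal fold N/K
  res_eq <- overrepresentation(universe[1:4], sets["hit"], universe)
  expect_equal(res_eq$fold, 10 / 4)
  expect_warning(overrepresentation(target, list(empty = character(0)),
                                    universe), "empty")
  # random targets almost never flag a set
  set.seed(20)
  uni2 <- paste0("g", 1:300)
  sets2 <- lapply(1:5, function(i) sample(uni2, 25))
  names(sets2) <- paste0("s", 1:5)
  n_sig <- vapply(1:20, function(s) {
    set.seed(100 + s)
    sum(overrepresentation(sample(uni2, 30), sets2, uni2)$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.2)
})

test_that("site-to-gene mapping deduplicates and respects promoters", {
  tr <- mk_tracks()
  sites <- data.frame(contig = "c", pos = c(6000L, 6200L, 4500L, 40000L))
  genes <- map_sites_to_genes(sites, tr$genes)
  expect_equal(genes, "gA")  # two body sites + one promoter site, one gene
  none <- map_sites_to_genes(data.frame(contig = "c", pos = 1L), tr$genes)
  expect_equal(length(none), 0L)
})
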