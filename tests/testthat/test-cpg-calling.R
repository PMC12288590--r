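mk_report <- function(pos, cm, cu, contig = "chr1") {
  data.frame(contig = contig, pos = pos, count_meth = cm, count_unmeth = cu,
             beta = ifelse(cm + cu > 0, cm / (cm + cu), NA_real_),
             stringsAsFactors = FALSE)
}

test_that("coverage filter is per sample and autosome-aware", {
  r1 <- mk_report(c(10L, 20L, 30L), c(7L, 5L, 9L), c(3L, 5L, 1L))
  r2 <- mk_report(c(10L, 20L, 30L), c(7L, 5L, 2L), c(3L, 5L, 1L))
  out <- call_cpgs(list(r1, r2), coverage_min = 10L)
  # site 30 has coverage 3 in sample 2 -> dropped everywhere
  expect_equal(out$sites$pos, c(10L, 20L))
  expect_equal(out$samples[[1]]$pos, c(10L, 20L))

  rx <- rbind(r1, mk_report(5L, 8L, 8L, contig = "chrX"))
  out2 <- call_cpgs(list(rx), coverage_min = 10L, autosomes = "chr1")
  expect_false("chrX" %in% out2$sites$contig)

  expect_warning(call_cpgs(list(mk_report(1L, 1L, 1L)), coverage_min = 10L),
                 "no sites")
})

test_that("per-sample filtering commutes with intersecting", {
  set.seed(6)
  mk_rand <- function() {
    pos <- sort(sample(1000L, 200L))
    mk_report(pos, rpois(200, 8), rpois(200, 8))
  }
  reps <- list(mk_rand(), mk_rand(), mk_rand())
  joint <- call_cpgs(reps, coverage_min = 10L)
  # oracle: intersect positions first, then demand coverage in all samples
  common <- Reduce(intersect, lapply(reps, `[[`, "pos"))
  ok <- vapply(common, function(p) {
    all(vapply(reps, function(r) {
      i <- match(p, r$pos)
      r$count_meth[i] + r$count_unmeth[i] >= 10L
    }, logical(1)))
  }, logical(1))
  expect_setequal(joint$sites$pos, common[ok])
})

test_that("strand merging sums counts onto the cytosine position", {
  asm <- assembly(c(chr1 = "TTCGATTTCGTT"))
  # CpGs at 2 and 8; calls at C (2) and its G partner (3), plus a lone C
  calls <- mk_report(c(2L, 3L, 8L), c(5L, 3L, 4L), c(5L, 7L, 6L))
  merged <- merge_cpg_strands(calls, asm)
  expect_equal(merged$pos, c(2L, 8L))
  expect_equal(merged$count_meth[1], 8L)
  expect_equal(merged$count_unmeth[1], 12L)
  expect_equal(merged$beta[1], 0.4)
  expect_equal(merged$count_meth[2], 4L)  # lone forward call unchanged
  # no output position is the +1 partner of another call
  expect_false(any((merged$pos - 1L) %in% merged$pos &
                     merged$pos %in% (enumerate_cpgs(asm)$chr1 + 1L)))

  # a G-strand call without its C row still lands on the C position
  lone_g <- mk_report(3L, 2L, 2L)
  mg <- merge_cpg_strands(lone_g, asm)
  expect_equal(mg$pos, 2L)

  # calls not at a reference CpG are left unmerged with a warning
  expect_warning(um <- merge_cpg_strands(mk_report(5L, 1L, 1L), asm),
                 "unmerged")
  expect_equal(um$pos, 5L)
})

test_that("interval-covered CpG counting matches a containment scan", {
  cpgs <- list(chr1 = c(1L, 4L, 12L), chr2 = c(3L))
  iv <- data.frame(contig = "chr1", start = 0L, end = 10L)
  out <- count_cpgs_in_intervals(iv, cpgs)
  expect_equal(out$count, 2L)
  expect_equal(out$covered$chr1, c(1L, 4L))

  empty <- count_cpgs_in_intervals(iv[0, ], cpgs)
  expect_equal(empty$count, 0L)

  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  cp <- enumerate_cpgs(assembly(c(chr1 = s)))
  st <- sample(9900L, 1000L, replace = TRUE)
  ivr <- data.frame(contig = "chr1", start = st,
                    end = st + sample(10:80, 1000L, replace = TRUE))
  got <- count_cpgs_in_intervals(ivr, cp)
  expect_equal(got$count, oracle_cpgs_in_intervals(ivr, cp))
})

test_that("liftover maps by block offset and reports gaps unmapped", {
  # identity chain
  ch <- structure(data.frame(s_contig = "c", s_start = 0, s_end = 100,
                             t_contig = "c", t_start = 0, t_end = 100,
                             t_reversed = FALSE, stringsAsFactors = FALSE),
                  class = c("chain_map", "data.frame"))
  pos <- data.frame(contig = "c", pos = c(0L, 50L, 99L))
  lf <- liftover_positions(ch, pos)
  expect_equal(lf$t_pos, pos$pos)

  # two blocks with a source-side gap [40, 60)
  ch2 <- structure(data.frame(s_contig = "c", s_start = c(0, 60),
                              s_end = c(40, 100),
                              t_contig = "c", t_start = c(0, 40),
                              t_end = c(40, 80), t_reversed = FALSE,
                              stringsAsFactors = FALSE),
                   class = c("chain_map", "data.frame"))
  lf2 <- liftover_positions(ch2, data.frame(contig = "c",
                                            pos = c(10L, 45L, 70L)))
  expect_equal(lf2$mapped, c(TRUE, FALSE, TRUE))
  expect_equal(lf2$t_pos, c(10L, NA, 50L))

  # contig absent from the chain
  lf3 <- liftover_positions(ch, data.frame(contig = "zz", pos = 5L))
  expect_false(lf3$mapped)

  # order preservation within a block
  set.seed(8)
  p <- sort(sample(0:39, 20))
  lf4 <- liftover_positions(ch2, data.frame(contig = "c", pos = p))
  expect_true(all(diff(lf4$t_pos) > 0))

  # reverse-orientation block reflects coordinates
  chr <- structure(data.frame(s_contig = "c", s_start = 0, s_end = 10,
                              t_contig = "d", t_start = 100, t_end = 110,
                              t_reversed = TRUE, stringsAsFactors = FALSE),
                   class = c("chain_map", "data.frame"))
  lfr <- liftover_positions(chr, data.frame(contig = "c", pos = c(0L, 9L)))
  expect_equal(lfr$t_pos, c(109L, 100L))
})

test_that("liftover agrees with rtracklayer on the generator's chain", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  pan <- panel_fixture()
  tf <- tempfile(fileext = ".chain")
  write_chain(pan$chain, tf)
  ch <- rtracklayer::import.chain(tf)
  cp <- enumerate_cpgs(pan$base)
  pos <- data.frame(contig = rep(names(cp), lengths(cp)),
                    pos = unlist(cp, use.names = FALSE))
  ours <- liftover_positions(pan$chain, pos)
  gr <- GenomicRanges::GRanges(pos$contig,
                               IRanges::IRanges(pos$pos + 1L, width = 1L))
  lifted <- rtracklayer::liftOver(gr, ch)
  n_hit <- lengths(lifted)
  expect_equal(ours$mapped, n_hit == 1L)
  theirs <- rep(NA_integer_, nrow(pos))
  theirs[n_hit == 1L] <-
    GenomicRanges::start(unlist(lifted[n_hit == 1L])) - 1L
  expect_equal(ours$t_pos[ours$mapped], theirs[ours$mapped])
})

test_that("CpG-set comparison counts uniques and percent increase", {
  ch <- structure(data.frame(s_contig = "c", s_start = 0, s_end = 1000,
                             t_contig = "c", t_start = 0, t_end = 1000,
                             t_reversed = FALSE, stringsAsFactors = FALSE),
                  class = c("chain_map", "data.frame"))
  a <- data.frame(contig = "c", pos = c(1L, 5L, 9L, 20L))
  cmp <- compare_cpg_sets(a, a, ch)
  expect_equal(cmp$percent_increase, 0)
  expect_equal(cmp$a_unique, 0L)
  expect_equal(cmp$intersection, 4L)

  b <- data.frame(contig = "c", pos = c(1L, 5L, 1500L))  # 1500 unmappable
  cmp2 <- compare_cpg_sets(a, b, ch)
  expect_equal(cmp2$intersection, 2L)
  expect_equal(cmp2$a_unique, cmp2$n_a - cmp2$intersection)
  expect_equal(cmp2$b_unique, 1L)
  expect_equal(cmp2$n_b_lifted, 2L)
})
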