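# small dedicated genome for aligner unit tests
make_small_cset <- function(seed = 21L, len = 3000L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  build_converted_set(assembly(c(g = s), name = "small"))
}

test_that("R expansion is the Cartesian product over {A,G}", {
  expect_equal(expand_probe_sequence("ACGT"), "ACGT")
  one <- expand_probe_sequence("ACRT")
  expect_setequal(one, c("ACAT", "ACGT"))
  two <- expand_probe_sequence("RCRT")
  expect_equal(length(two), 4L)
  expect_equal(length(unique(two)), 4L)
  expect_true(all(!grepl("R", two)))
})

test_that("seed index enumerates sampled tiles and masks repeats", {
  idx <- build_seed_index(c(g = strrep("A", 30)), tile_size = 3L,
                          step_size = 1L)
  hits <- seed_lookup(idx, "AAA")
  expect_equal(hits$pos, 0:27)
  expect_equal(nrow(seed_lookup(idx, "CCC")), 0L)

  # brute-force agreement on a random genome at the genuine stride
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  idx <- build_seed_index(c(g = s), tile_size = 11L, step_size = 5L)
  starts <- seq(1L, 5000L - 10L, by = 5L)
  kmers <- substring(s, starts, starts + 10L)
  for (k in unique(sample(kmers, 25))) {
    expect_setequal(seed_lookup(idx, k)$pos, starts[kmers == k] - 1L)
  }

  # rep_match masking removes over-represented tiles
  idx <- build_seed_index(c(g = strrep("A", 100)), tile_size = 3L,
                          step_size = 1L, rep_match = 10L)
  expect_equal(nrow(seed_lookup(idx, "AAA")), 0L)
})

test_that("planted exact and near-exact probes hit at the thresholds", {
  cs <- make_small_cset()
  probe <- substr(cs$variants$meth_fwd[["g"]], 501, 550)
  h <- align_probe(probe, cs)
  expect_true(any(h$start == 500 & h$matches == 50 & h$identity == 1))

  sub_at <- function(s, i) {
    for (j in i) {
      old <- substr(s, j, j)
      substr(s, j, j) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  p5 <- sub_at(probe, c(2, 9, 16, 38, 47))
  h5 <- align_probe(p5, cs)
  i5 <- h5[h5$start == 500 & h5$variant == "meth_fwd", ]
  expect_equal(i5$matches, 45L)
  expect_equal(i5$identity, 0.90)

  p6 <- sub_at(probe, c(2, 9, 16, 24, 38, 47))
  h6 <- align_probe(p6, cs)
  expect_false(any(h6$start == 500 & h6$variant == "meth_fwd"))
})

test_that("reverse-variant hits come back in forward coordinates", {
  cs <- make_small_cset(seed = 22L)
  n <- nchar(cs$source[["g"]])
  # copy a probe from the reverse methylated variant
  probe <- substr(cs$variants$meth_rev[["g"]], 701, 750)
  h <- align_probe(probe, cs)
  rev_hit <- h[h$strand == "-" & h$matches == 50L, ]
  expect_gte(nrow(rev_hit), 1L)
  # rev positions [700, 750) map to forward [n-750, n-700)
  expect_true(any(rev_hit$start == n - 750L & rev_hit$end == n - 700L))
})

test_that("hit sets equal the exhaustive-scan oracle on random probes", {
  cs <- make_small_cset(seed = 23L, len = 2000L)
  params <- meth_params()
  set.seed(77)
  probes <- c(
    # planted (guaranteed hits), partially corrupted, and random 50-mers
    substr(cs$variants$meth_fwd[["g"]], 101, 150),
    substr(cs$variants$unmeth_rev[["g"]], 901, 950),
    vapply(1:6, function(i) {
      p <- substr(cs$variants$meth_fwd[["g"]], i * 200 + 1, i * 200 + 50)
      at <- sample(50, sample(0:7, 1))
      for (j in at) {
        substr(p, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(p, j, j)), 1)
      }
      p
    }, character(1)),
    vapply(1:4, function(i) paste(sample(c("A", "C", "G", "T"), 50,
                                         replace = TRUE), collapse = ""),
           character(1))
  )
  key <- function(h) {
    if (!nrow(h)) return(character(0))
    sort(paste(h$contig, h$start, h$end, h$strand, h$variant, h$matches))
  }
  for (p in probes) {
    got <- align_probe(p, cs, params)
    want <- oracle_align(p, cs, params)
    # soundness: every seed-derived hit is a genuine qualifying placement
    expect_true(all(key(got) %in% key(want)), info = p)
    # completeness for full-length matches: an exact copy always shares an
    # exact sampled tile, so no perfect hit may be missed. (Imperfect
    # secondary hits without a surviving sampled 11-mer can be skipped, as
    # in a tile-indexed aligner; classification-level agreement is checked
    # separately against the exhaustive oracle.)
    perfect <- key(want[want$matches == 50L, , drop = FALSE])
    expect_true(all(perfect %in% key(got)), info = p)
  }
})

test_that("seed aligner and exhaustive oracle reach identical decisions", {
  cs <- make_small_cset(seed = 25L, len = 2500L)
  params <- meth_params()
  cp <- enumerate_cpgs(assembly(cs$source, name = "s"))$g
  cp <- cp[cp > 30 & cp < 2400]
  set.seed(31)
  picks <- sample(cp, 10)
  for (p in picks) {
    probe <- substr(cs$variants$meth_fwd[["g"]], p - 24 + 1, p + 26)
    # corrupt 0-6 positions away from the target CpG
    at <- sample(setdiff(1:50, 24:27), sample(0:6, 1))
    for (j in at) {
      substr(probe, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(probe, j, j)), 1)
    }
    pr <- list(probe_id = "px", sequence = probe, contig = "g",
               target_pos = p)
    got <- classify_probe(pr, cs, params)
    want <- oracle_classify(pr, cs, params, align_fun = oracle_align)
    expect_equal(got$status, want$status, info = probe)
  }
})

test_that("the CpG-locus check demands perfection at the dinucleotide only", {
  cs <- make_small_cset(seed = 24L)
  cp <- enumerate_cpgs(assembly(cs$source, name = "s"))$g
  p <- cp[cp > 100 & cp < 2800][1]
  probe <- substr(cs$variants$meth_fwd[["g"]], p - 24 + 1, p + 26)
  h <- align_probe(probe, cs)
  hit <- h[h$variant == "meth_fwd" & h$start == p - 24, ][1, ]
  expect_true(check_cpg_locus(hit, probe, cs, "g", p))

  # substitution at the target C: locus check fails though the hit stands
  pc <- probe
  substr(pc, 25, 25) <- "A"
  hc <- align_probe(pc, cs)
  hitc <- hc[hc$variant == "meth_fwd" & hc$start == p - 24, ][1, ]
  expect_equal(hitc$matches, 49L)
  expect_false(check_cpg_locus(hitc, pc, cs, "g", p))

  # substitution 10 bp away: locus intact, hit still qualifies
  pd <- probe
  substr(pd, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                substr(pd, 15, 15))[1]
  hd <- align_probe(pd, cs)
  hitd <- hd[hd$variant == "meth_fwd" & hd$start == p - 24, ][1, ]
  expect_true(check_cpg_locus(hitd, pd, cs, "g", p))

  expect_error(check_cpg_locus(hit, probe, cs, "g", p + 500),
               "does not overlap")
})

test_that("classification is a partition and matches planted truth", {
  pan <- panel_fixture()
  pm <- generate_probe_manifest(pan$base, dup_intervals = pan$tracks$segdup,
                                exclude_intervals = pan$tracks$satellite,
                                n_unambiguous = 8L, n_cross_reactive = 8L,
                                n_mismatched = 8L, seed = 5L)
  res <- suppressMessages(classify_manifest(pm$manifest, pan$base))
  expect_equal(nrow(res), nrow(pm$manifest))
  # partition property
  expect_equal(sum(table(res$status)), nrow(pm$manifest))
  got <- res$status[match(pm$truth$probe_id, res$probe_id)]
  expect_equal(got, pm$truth$planted_status)
  expect_true(all(res$n_loci[got == "unambiguous"] == 1L))
  expect_true(all(res$n_loci[got == "cross_reactive"] >= 2L))
})

test_that("probes targeting an absent contig are mismatched, not an error", {
  pan <- panel_fixture()
  pm <- generate_probe_manifest(pan$base, dup_intervals = pan$tracks$segdup,
                                exclude_intervals = pan$tracks$satellite,
                                n_unambiguous = 2L, n_cross_reactive = 0L,
                                n_mismatched = 0L, seed = 6L)
  mani <- pm$manifest
  mani$contig <- "chrMissing"
  res <- suppressMessages(classify_manifest(mani, pan$base))
  expect_true(all(res$status == "mismatched"))
})

test_that("lowering thresholds never turns cross-reactive into unambiguous", {
  pan <- panel_fixture()
  pm <- generate_probe_manifest(pan$base, dup_intervals = pan$tracks$segdup,
                                exclude_intervals = pan$tracks$satellite,
                                n_unambiguous = 4L, n_cross_reactive = 4L,
                                n_mismatched = 0L, seed = 7L)
  strict <- suppressMessages(classify_manifest(pm$manifest, pan$base))
  loose <- suppressMessages(classify_manifest(
    pm$manifest, pan$base,
    params = meth_params(identity_min = 0.80, match_min = 35L)))
  was_cross <- strict$probe_id[strict$status == "cross_reactive"]
  now <- loose$status[match(was_cross, loose$probe_id)]
  expect_false(any(now == "unambiguous"))
})

test_that("strand symmetry: classifying against the reverse complement
           preserves the status multiset", {
  pan <- panel_fixture()
  pm <- generate_probe_manifest(pan$base, dup_intervals = pan$tracks$segdup,
                                exclude_intervals = pan$tracks$satellite,
                                n_unambiguous = 5L, n_cross_reactive = 5L,
                                n_mismatched = 5L, seed = 8L)
  fwd <- suppressMessages(classify_manifest(pm$manifest, pan$base))
  rc <- assembly(setNames(revcomp(pan$base$contigs), names(pan$base$contigs)),
                 name = "rc")
  n <- nchar(pan$base$contigs[[1]])
  mani_rc <- pm$manifest
  # the CpG at forward p sits at n-p-2 on the reverse complement
  mani_rc$target_pos <- n - mani_rc$target_pos - 2L
  mani_rc$position_1based <- mani_rc$target_pos + 1L
  rev_res <- suppressMessages(classify_manifest(mani_rc, rc))
  expect_equal(sort(table(fwd$status)), sort(table(rev_res$status)))
})
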