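## Seeded synthetic-data generators producing every input the pipeline
## consumes, with machine-readable planted truth. The generators define the
## study conditions used by the test-suite: small assemblies carrying
## planted segmental duplications, satellite-like tandem repeats and
## CpG-island-like segments; probe manifests with planted unambiguous,
## cross-reactive and mismatched probes; and two-group beta matrices with
## planted differential methylation, technical-replicate noise and
## matching binomial-sampled cytosine reports.

.random_dna <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.cpg_rich_dna <- function(n) {
  # alternate CG-dense dinucleotides to emulate an island-like segment
  units <- sample(c("CG", "GC", "CC", "GG", "CA", "TG"), ceiling(n / 2),
                  replace = TRUE, prob = c(0.45, 0.1, 0.1, 0.1, 0.125, 0.125))
  substr(paste(units, collapse = ""), 1, n)
}

.splice <- function(s, at0, replacement) {
  # overwrite s at 0-based position `at0` with `replacement`
  paste0(substr(s, 1, at0), replacement,
         substr(s, at0 + nchar(replacement) + 1, nchar(s)))
}

#' Generate a synthetic assembly panel with planted truth
#'
#' Builds a "base" assembly and a "complete" assembly sharing one backbone:
#' the complete assembly additionally carries `extra_n` inserted sequence
#' blocks (emulating sequence present only in a finished reference). Both
#' carry planted segmental duplications (a donor segment copied verbatim to
#' an acceptor locus), satellite-like tandem repeats and CpG-rich
#' island-like segments. `n_haplotypes` derived assemblies add independent
#' SNVs at `snv_rate` (and one private duplication in the first listed
#' population when `private_dup = TRUE`). The chain mapping base
#' coordinates into the complete assembly is emitted exactly from the edit
#' script, together with gene/island/repeat annotation tracks and a truth
#' table of every planted event.
#'
#' @param backbone_length named integer vector of contig lengths.
#' @param segdup_n,segdup_len planted duplication count and length.
#' @param satellite_n,satellite_unit,satellite_copies tandem-repeat
#'   plantings.
#' @param island_n,island_len planted CpG-rich segments.
#' @param extra_n,extra_len insert blocks present only in the complete
#'   assembly (placed on the first contig).
#' @param n_genes,gene_len planted gene annotations.
#' @param n_haplotypes,populations haplotype panel size and population
#'   labels recycled across haplotypes.
#' @param snv_rate per-base substitution rate in haplotypes.
#' @param private_dup plant one extra duplication private to the first
#'   population's haplotypes.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return list with `base`, `complete` (assemblies), `haplotypes` (named
#'   list of assemblies), `panel` (data.frame assembly/population/
#'   subpopulation), `chain` (a `chain_map`, base -> complete), `tracks`
#'   (list of BED-style data.frames: `genes`, `islands`, `segdup`,
#'   `satellite`, `line`, `sine`), `truth` (data.frame of planted events)
#'   and `config`.
#' @export
generate_assembly_panel <- function(backbone_length = c(chr1 = 20000L,
                                                        chr2 = 6000L),
                                    segdup_n = 2L, segdup_len = 400L,
                                    satellite_n = 2L,
                                    satellite_unit = 6L,
                                    satellite_copies = 30L,
                                    island_n = 3L, island_len = 400L,
                                    extra_n = 2L, extra_len = 800L,
                                    n_genes = 12L, gene_len = 1200L,
                                    n_haplotypes = 6L,
                                    populations = c("AFR", "EUR"),
                                    snv_rate = 0.001,
                                    private_dup = TRUE,
                                    seed = 1L) {
  set.seed(seed)
  truth <- list()
  note <- function(kind, id, contig, start, end, detail = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = kind, id = id, contig = contig, start = start, end = end,
      detail = detail, stringsAsFactors = FALSE)
  }
  contigs <- vapply(backbone_length, .random_dna, character(1))
  names(contigs) <- names(backbone_length)
  main <- names(contigs)[1]
  L <- nchar(contigs[[main]])
  budget <- island_n * island_len + satellite_n * satellite_unit *
    satellite_copies + segdup_n * 2L * segdup_len
  if (budget > 0.6 * L) stop("planted events exceed what the genome length accommodates")

  # carve non-overlapping slots on the main contig for all planted features
  slot_lens <- c(rep(island_len, island_n),
                 rep(satellite_unit * satellite_copies, satellite_n),
                 rep(segdup_len, segdup_n * 2L))
  n_slot <- length(slot_lens)
  gapped <- L - sum(slot_lens)
  gaps <- sort(sample.int(gapped - 100L, n_slot)) + 50L
  starts <- gaps + cumsum(c(0L, slot_lens[-n_slot]))
  si <- 0L
  isl_iv <- sat_iv <- dup_iv <- NULL
  for (i in seq_len(island_n)) {
    si <- si + 1L
    a <- starts[si]
    contigs[[main]] <- .splice(contigs[[main]], a, .cpg_rich_dna(island_len))
    isl_iv <- rbind(isl_iv, data.frame(contig = main, start = a,
                                       end = a + island_len))
    note("island", paste0("island", i), main, a, a + island_len)
  }
  for (i in seq_len(satellite_n)) {
    si <- si + 1L
    a <- starts[si]
    unit <- .random_dna(satellite_unit)
    rep_seq <- strrep(unit, satellite_copies)
    contigs[[main]] <- .splice(contigs[[main]], a, rep_seq)
    sat_iv <- rbind(sat_iv, data.frame(contig = main, start = a,
                                       end = a + nchar(rep_seq)))
    note("satellite", paste0("sat", i), main, a, a + nchar(rep_seq), unit)
  }
  for (i in seq_len(segdup_n)) {
    si <- si + 1L; don <- starts[si]
    si <- si + 1L; acc <- starts[si]
    donor_seq <- substr(contigs[[main]], don + 1L, don + segdup_len)
    contigs[[main]] <- .splice(contigs[[main]], acc, donor_seq)
    dup_iv <- rbind(dup_iv,
                    data.frame(contig = main, start = don, end = don + segdup_len),
                    data.frame(contig = main, start = acc, end = acc + segdup_len))
    note("segdup", paste0("segdup", i), main, don, don + segdup_len,
         paste0("copy_at=", acc))
  }
  base <- assembly(contigs, name = "base")

  # complete assembly: insert extra blocks on the main contig
  ins_pos <- sort(sample(seq(1000L, L - 1000L), extra_n))
  # do not split a backbone CpG at an insertion point, and pad inserts with
  # TT, so the complete assembly's CpG set is exactly base CpGs + insert
  # CpGs (junctions can neither create nor destroy a CG)
  bb <- contigs[[main]]
  for (i in seq_along(ins_pos)) {
    while (substr(bb, ins_pos[i], ins_pos[i] + 1L) == "CG") {
      ins_pos[i] <- ins_pos[i] + 1L
    }
  }
  ins_pos <- sort(ins_pos)
  extra_seqs <- vapply(seq_len(extra_n), function(i) {
    # CpG-dense at one end so the extra sequence adds island-like CpGs
    paste0("TT", .cpg_rich_dna(extra_len %/% 4L),
           .random_dna(extra_len - extra_len %/% 4L - 4L), "TT")
  }, character(1))
  comp <- contigs
  shift <- 0L
  for (i in seq_len(extra_n)) {
    at <- ins_pos[i] + shift
    comp[[main]] <- paste0(substr(comp[[main]], 1, at), extra_seqs[i],
                           substr(comp[[main]], at + 1L, nchar(comp[[main]])))
    note("extra_block", paste0("extra", i), main, ins_pos[i],
         ins_pos[i] + extra_len,
         paste0("complete_start=", ins_pos[i] + shift))
    shift <- shift + extra_len
  }
  complete <- assembly(comp, name = "complete")

  # chain base -> complete, exact from the edit script
  blocks <- list()
  cuts <- c(0L, ins_pos, L)
  off <- 0L
  for (i in seq_len(length(cuts) - 1L)) {
    blocks[[i]] <- data.frame(
      s_contig = main, s_start = cuts[i], s_end = cuts[i + 1L],
      t_contig = main, t_start = cuts[i] + off, t_end = cuts[i + 1L] + off,
      t_reversed = FALSE, stringsAsFactors = FALSE)
    off <- off + extra_len
  }
  for (nm in setdiff(names(contigs), main)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      s_contig = nm, s_start = 0L, s_end = nchar(contigs[[nm]]),
      t_contig = nm, t_start = 0L, t_end = nchar(contigs[[nm]]),
      t_reversed = FALSE, stringsAsFactors = FALSE)
  }
  chain <- do.call(rbind, blocks)
  chain <- structure(chain,
                     source_sizes = setNames(as.integer(nchar(contigs)),
                                             names(contigs)),
                     target_sizes = setNames(as.integer(nchar(comp)),
                                             names(comp)),
                     class = c("chain_map", "data.frame"))

  # haplotypes: SNVs (and a population-private duplication) on the backbone
  pops <- rep(populations, length.out = n_haplotypes)
  haps <- list()
  for (h in seq_len(n_haplotypes)) {
    hseq <- contigs
    if (private_dup && pops[h] == populations[1]) {
      don <- 2000L; accl <- L - segdup_len - 500L
      hseq[[main]] <- .splice(hseq[[main]], accl,
                              substr(hseq[[main]], don + 1L, don + segdup_len))
      note("private_dup", paste0("hap", h), main, don, don + segdup_len,
           paste0("population=", pops[h], ";copy_at=", accl))
    }
    for (nm in names(hseq)) {
      n <- nchar(hseq[[nm]])
      k <- stats::rbinom(1L, n, snv_rate)
      if (k > 0) {
        at <- sample.int(n, k)
        ch <- strsplit(hseq[[nm]], "", fixed = TRUE)[[1]]
        for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
        hseq[[nm]] <- paste(ch, collapse = "")
        note("snv", paste0("hap", h, ":", nm), nm, NA_integer_, NA_integer_,
             paste0("n_snv=", k))
      }
    }
    haps[[paste0("hap", h)]] <- assembly(hseq, name = paste0("hap", h))
  }
  panel <- data.frame(assembly = names(haps), population = pops,
                      subpopulation = paste0(pops, "1"),
                      stringsAsFactors = FALSE)

  # gene annotations on the base assembly
  gene_start <- sort(sample(seq(100L, L - gene_len - 100L), n_genes))
  genes <- data.frame(contig = main, start = gene_start,
                      end = gene_start + gene_len,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      name = paste0("gene", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  # two arbitrary LINE/SINE-like annotation intervals for repeat priority
  line <- data.frame(contig = main, start = c(500L, 4000L),
                     end = c(900L, 4300L), stringsAsFactors = FALSE)
  sine <- data.frame(contig = main, start = 7000L, end = 7200L,
                     stringsAsFactors = FALSE)
  tracks <- list(genes = genes,
                 islands = detect_cpg_islands(base),
                 segdup = dup_iv,
                 satellite = sat_iv,
                 line = line, sine = sine)
  truth <- do.call(rbind, truth)
  list(base = base, complete = complete, haplotypes = haps, panel = panel,
       chain = chain, tracks = tracks, truth = truth,
       config = list(backbone_length = backbone_length, segdup_n = segdup_n,
                     segdup_len = segdup_len, satellite_n = satellite_n,
                     island_n = island_n, extra_n = extra_n,
                     extra_len = extra_len, n_haplotypes = n_haplotypes,
                     snv_rate = snv_rate, seed = seed))
}

#' Generate a probe manifest with planted classification truth
#'
#' Unambiguous probes are copied verbatim from the CpG-preserving converted
#' genome at unique loci; cross-reactive probes are copied from inside
#' planted duplicated segments (both copies exist, so two loci qualify);
#' mismatched probes either carry a damaged target CpG (one substitution at
#' the target cytosine, so the alignment still qualifies but the CpG test
#' fails) or 11 substitutions (39/50 matches, below the qualification
#' floor). A fraction of type II probes has one original-base A/G position
#' replaced by the degenerate base R. A configurable fraction of probes is
#' taken from the minus strand.
#'
#' @param asm the `assembly` probes are designed against.
#' @param dup_intervals BED-style data.frame of planted duplication loci
#'   (donor and acceptor copies), e.g. `tracks$segdup` from
#'   [generate_assembly_panel()].
#' @param exclude_intervals further loci (e.g. satellites) probes must
#'   avoid.
#' @param n_unambiguous,n_cross_reactive,n_mismatched class counts.
#' @param r_fraction fraction of type II probes receiving an R base.
#' @param minus_fraction fraction of probes designed against the minus
#'   strand.
#' @param seed RNG seed.
#' @return list with `manifest` (data.frame in [read_probe_manifest()]
#'   layout plus 0-based `target_pos`) and `truth` (probe_id,
#'   planted_status).
#' @export
generate_probe_manifest <- function(asm, dup_intervals = NULL,
                                    exclude_intervals = NULL,
                                    n_unambiguous = 20L,
                                    n_cross_reactive = 20L,
                                    n_mismatched = 20L,
                                    r_fraction = 0.3,
                                    minus_fraction = 0.25,
                                    seed = 1L) {
  set.seed(seed)
  cset <- build_converted_set(asm)
  cpgs <- enumerate_cpgs(asm)
  main <- names(asm$contigs)[1]
  n <- nchar(asm$contigs[[main]])
  pos <- cpgs[[main]]
  pos <- pos[pos >= 26L & pos <= n - 28L]

  in_iv <- function(p, iv, pad = 0L) {
    if (is.null(iv) || !nrow(iv)) return(rep(FALSE, length(p)))
    iv <- iv[iv$contig == main, , drop = FALSE]
    vapply(p, function(x) any(x >= iv$start - pad & x < iv$end + pad),
           logical(1))
  }
  dup_ok <- in_iv(pos, dup_intervals, pad = -27L)  # fully interior CpGs
  avoid <- in_iv(pos, dup_intervals, pad = 55L) |
    in_iv(pos, exclude_intervals, pad = 55L)
  uniq_pos <- pos[!avoid]
  dup_pos <- pos[dup_ok]
  # keep chosen unique loci >= 60 bp apart so probe windows cannot overlap
  spread <- function(p, k, min_gap = 60L) {
    p <- sample(p)
    chosen <- integer(0)
    for (x in p) {
      if (!length(chosen) || min(abs(chosen - x)) >= min_gap) {
        chosen <- c(chosen, x)
      }
      if (length(chosen) == k) break
    }
    if (length(chosen) < k) {
      stop("requested probe count exceeds available loci")
    }
    chosen
  }
  need_uniq <- n_unambiguous + n_mismatched
  u_all <- spread(uniq_pos, need_uniq)
  u_pos <- u_all[seq_len(n_unambiguous)]
  m_pos <- u_all[n_unambiguous + seq_len(n_mismatched)]
  # duplicated loci: one probe per donor copy; dedupe nearby CpGs
  c_pos <- spread(dup_pos, n_cross_reactive, min_gap = 3L)

  probe_seq <- function(p, minus) {
    if (!minus) {
      substr(cset$variants$meth_fwd[[main]], p - 24L + 1L, p + 26L)
    } else {
      q <- n - p - 2L - 24L
      substr(cset$variants$meth_rev[[main]], q + 1L, q + 50L)
    }
  }
  rows <- list(); truth <- list()
  pid <- 0L
  add <- function(p, status, mutate = identity) {
    pid <<- pid + 1L
    id <- sprintf("cg%05d", pid)
    minus <- stats::runif(1) < minus_fraction
    s <- mutate(probe_seq(p, minus))
    rows[[length(rows) + 1L]] <<- data.frame(
      probe_id = id, sequence = s, design_type = "II", contig = main,
      position_1based = p + 1L, strand = if (minus) "-" else "+",
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      probe_id = id, planted_status = status, target_pos = p,
      stringsAsFactors = FALSE)
  }
  subst <- function(s, i, b) `substr<-`(s, i, i, b)
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  for (p in u_pos) add(p, "unambiguous")
  for (p in c_pos) add(p, "cross_reactive")
  half <- n_mismatched %/% 2L
  damaged <- rep(c(TRUE, FALSE), c(half, n_mismatched - half))
  for (i in seq_along(m_pos)) {
    p <- m_pos[i]
    if (damaged[i]) {
      # damage the target cytosine (probe index 25 covers the target C on
      # either strand): the alignment still qualifies (49/50) but the CpG
      # dinucleotide no longer matches the source genome
      add(p, "mismatched", mutate = function(s) subst(s, 25L, "A"))
    } else {
      # 11 substitutions outside the target CpG: 39/50 matches, below the
      # 40-base qualification floor everywhere
      add(p, "mismatched", mutate = function(s) {
        at <- sample(setdiff(1:50, 20:31), 11L)
        for (j in at) s <- subst(s, j, other_base(substr(s, j, j)))
        s
      })
    }
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  # degenerate R planting: replace an original A/G position in type II
  # probes, so one expansion restores the exact planted sequence. Probes
  # carrying the 11 planted substitutions are skipped: an R landing on a
  # substituted position would let one expansion reach 40 matches and
  # change the planted class.
  eligible <- which(truth$planted_status != "mismatched" |
                      seq_len(nrow(truth)) %in%
                      (n_unambiguous + n_cross_reactive + which(damaged)))
  n_r <- min(round(r_fraction * nrow(manifest)), length(eligible))
  if (n_r > 0) {
    for (i in sample(eligible, n_r)) {
      s <- manifest$sequence[i]
      cand <- setdiff(which(strsplit(s, "")[[1]] %in% c("A", "G")), 20:31)
      if (length(cand)) {
        manifest$sequence[i] <- subst(s, sample(cand, 1L), "R")
      }
    }
  }
  manifest$target_pos <- manifest$position_1based - 1L
  list(manifest = manifest, truth = truth, seed = seed)
}

#' Generate a two-group methylation dataset with planted DMCs
#'
#' Null sites share one group mean; planted DMC sites separate the case and
#' control means by `delta` (random sign), clipped into (0.02, 0.98) with
#' the clip recorded in the truth table. Per-sample betas follow a Beta
#' distribution in the mean/precision parameterisation; optional technical
#' replicates add Gaussian noise of `technical_sd` around a sample-level
#' mean; cytosine reports draw binomial counts at `coverage` so that
#' count-derived betas are noisy realisations of the matrix.
#'
#' @param n_sites number of CpG sites.
#' @param n_case,n_control group sizes.
#' @param dmc_frac fraction of sites planted as DMCs.
#' @param delta planted mean difference in beta units.
#' @param precision Beta-distribution precision (a+b).
#' @param coverage mean sequencing coverage for the cytosine reports
#'   (Poisson, floored at 1).
#' @param n_replicates technical replicates (0 to skip).
#' @param technical_sd replicate noise SD in beta units.
#' @param contig contig name for the emitted site coordinates.
#' @param seed RNG seed.
#' @return list: `betas` (sites x samples), `groups`, `truth`, `reports`
#'   (per-sample data.frames in cytosine-report layout), `replicates`
#'   (matrix or NULL), `positions` (data.frame `contig`,`pos`), `seed`.
#' @export
generate_methylation_dataset <- function(n_sites = 2000L, n_case = 10L,
                                         n_control = 10L, dmc_frac = 0.05,
                                         delta = 0.3, precision = 50,
                                         coverage = 30L, n_replicates = 0L,
                                         technical_sd = 0.02,
                                         contig = "chr1", seed = 1L) {
  set.seed(seed)
  pos <- sort(sample.int(50L * n_sites, n_sites)) - 1L
  site <- paste(contig, pos, sep = ":")
  mu0 <- stats::runif(n_sites, 0.05, 0.95)
  is_dmc <- rep(FALSE, n_sites)
  n_dmc <- round(dmc_frac * n_sites)
  if (n_dmc > 0) is_dmc[sample.int(n_sites, n_dmc)] <- TRUE
  sgn <- ifelse(stats::runif(n_sites) < 0.5, -1, 1)
  mu_case <- mu0
  mu_case[is_dmc] <- mu0[is_dmc] + sgn[is_dmc] * delta
  clipped <- mu_case < 0.02 | mu_case > 0.98
  mu_case <- pmin(pmax(mu_case, 0.02), 0.98)
  draw <- function(mu, m) {
    matrix(stats::rbeta(length(mu) * m, mu * precision, (1 - mu) * precision),
           nrow = length(mu))
  }
  betas <- cbind(draw(mu_case, n_case), draw(mu0, n_control))
  rownames(betas) <- site
  colnames(betas) <- c(paste0("case", seq_len(n_case)),
                       paste0("ctrl", seq_len(n_control)))
  groups <- rep(c("case", "control"), c(n_case, n_control))
  reports <- lapply(seq_len(ncol(betas)), function(j) {
    cov <- pmax(1L, stats::rpois(n_sites, coverage))
    cm <- stats::rbinom(n_sites, cov, betas[, j])
    data.frame(contig = contig, pos = pos, count_meth = cm,
               count_unmeth = cov - cm,
               beta = cm / cov, stringsAsFactors = FALSE)
  })
  names(reports) <- colnames(betas)
  replicates <- NULL
  if (n_replicates > 0) {
    centre <- betas[, 1L]
    replicates <- vapply(seq_len(n_replicates), function(r) {
      pmin(pmax(centre + stats::rnorm(n_sites, 0, technical_sd), 0), 1)
    }, numeric(n_sites))
    rownames(replicates) <- site
    colnames(replicates) <- paste0("rep", seq_len(n_replicates))
  }
  truth <- data.frame(site = site, is_dmc = is_dmc,
                      delta = ifelse(is_dmc, mu_case - mu0, 0),
                      mu_case = mu_case, mu_control = mu0,
                      clipped = clipped, stringsAsFactors = FALSE)
  list(betas = betas, groups = groups, truth = truth, reports = reports,
       replicates = replicates,
       positions = data.frame(contig = contig, pos = pos,
                              stringsAsFactors = FALSE),
       seed = seed)
}

#' Generate driver-gene and pathway gene sets with planted enrichment
#'
#' A configurable fraction of the universe is labelled driver; pathway
#' sets are uniform draws, except that `enriched_target` genes (when
#' given) are all placed into the first set so that over-representation
#' analysis has a planted positive.
#'
#' @param genes character vector, the gene universe.
#' @param driver_frac fraction of genes labelled drivers.
#' @param n_sets number of pathway sets.
#' @param set_size genes per set.
#' @param enriched_target optional genes forced into the first set.
#' @param seed RNG seed.
#' @return list: `drivers`, `gene_sets` (named list), `truth`, `seed`.
#' @export
generate_gene_sets <- function(genes, driver_frac = 0.1, n_sets = 5L,
                               set_size = 20L, enriched_target = NULL,
                               seed = 1L) {
  set.seed(seed)
  stopifnot(length(genes) > 0)
  n_driver <- max(1L, round(driver_frac * length(genes)))
  drivers <- sort(sample(genes, n_driver))
  sets <- list()
  for (i in seq_len(n_sets)) {
    nm <- paste0("pathway", i)
    if (i == 1L && length(enriched_target)) {
      extra <- sample(setdiff(genes, enriched_target),
                      max(0L, set_size - length(enriched_target)))
      sets[[nm]] <- unique(c(enriched_target, extra))
    } else {
      sets[[nm]] <- sort(sample(genes, min(set_size, length(genes))))
    }
  }
  truth <- data.frame(
    set = names(sets),
    planted_enrichment = c(length(enriched_target) > 0,
                           rep(FALSE, n_sets - 1L)),
    stringsAsFactors = FALSE)
  list(drivers = drivers, gene_sets = sets, truth = truth, seed = seed)
}
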