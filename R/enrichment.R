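## Genomic-feature annotation of sites and enrichment statistics:
## chi-squared element enrichment, prioritised repeat-category assignment,
## driver-gene permutation enrichment, and a local hypergeometric
## over-representation analysis.

.overlaps_any <- function(pos, iv) {
  if (!nrow(iv) || !length(pos)) return(rep(FALSE, length(pos)))
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  IRanges::overlapsAny(q, s)
}

#' Annotate sites with genomic features
#'
#' Per-site boolean flags: `promoter` (within `promoter_upstream` bp
#' upstream of a gene's transcription start, strand-aware), `gene_body`
#' (inside the gene span), and mutually exclusive `cpg_island` /
#' `cpg_shore` / `cpg_shelf` flags by distance band from the nearest island
#' edge: 0, (0, shore_width], (shore_width, shore_width + shelf_width].
#' When a site is equidistant from two islands the lower-coordinate island
#' wins (the band is the same either way). Unstranded gene records get no
#' promoter (with a warning). Promoter and gene-body flags are per-gene and
#' may both be set for a site in overlapping annotations.
#'
#' @param sites data.frame with `contig`, `pos` (0-based).
#' @param genes data.frame with `contig`, `start`, `end`, `strand`, `name`.
#' @param islands data.frame with `contig`, `start`, `end`.
#' @param params a [meth_params()] list.
#' @return `sites` with added logical columns `promoter`, `gene_body`,
#'   `cpg_island`, `cpg_shore`, `cpg_shelf`.
#' @export
annotate_sites <- function(sites, genes, islands, params = meth_params()) {
  unstranded <- !genes$strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sum(unstranded), " unstranded gene record(s): promoter undefined")
  }
  gs <- genes[!unstranded, , drop = FALSE]
  prom <- data.frame(
    contig = gs$contig,
    start = ifelse(gs$strand == "+",
                   pmax(0L, gs$start - params$promoter_upstream), gs$end),
    end = ifelse(gs$strand == "+", gs$start,
                 gs$end + params$promoter_upstream),
    stringsAsFactors = FALSE
  )
  prom <- prom[prom$end > prom$start, , drop = FALSE]
  out <- sites
  out$promoter <- FALSE; out$gene_body <- FALSE
  out$cpg_island <- FALSE; out$cpg_shore <- FALSE; out$cpg_shelf <- FALSE
  for (nm in unique(sites$contig)) {
    sel <- which(sites$contig == nm)
    pos <- sites$pos[sel]
    out$promoter[sel] <- .overlaps_any(pos, prom[prom$contig == nm, ,
                                                 drop = FALSE])
    out$gene_body[sel] <- .overlaps_any(pos, genes[genes$contig == nm, ,
                                                   drop = FALSE])
    isl <- islands[islands$contig == nm, , drop = FALSE]
    if (nrow(isl)) {
      # distance to the nearest island edge; ties between islands resolve to
      # the lower-coordinate island, which cannot change the band
      dmin <- vapply(pos, function(p) {
        gaps <- pmax(isl$start - p, p - isl$end + 1L, 0L)
        min(gaps)
      }, numeric(1))
      out$cpg_island[sel] <- dmin == 0
      out$cpg_shore[sel] <- dmin > 0 & dmin <= params$shore_width
      out$cpg_shelf[sel] <- dmin > params$shore_width &
        dmin <= params$shore_width + params$shelf_width
    }
  }
  out
}

#' Element enrichment of target sites over a background
#'
#' For each feature column, fold enrichment is the target in-feature
#' proportion over the background in-feature proportion, with a 2x2
#' Pearson chi-squared test (no continuity correction) of
#' in/out-of-feature counts between target and background, BH-adjusted
#' across features.
#'
#' @param target_ann,background_ann data.frames from [annotate_sites()]
#'   (or any data.frames of logical feature columns).
#' @param features feature column names to test.
#' @return data.frame: `feature`, `fold`, `chisq`, `p`, `fdr`. A feature
#'   absent from the background yields `fold = NA` and is flagged in a
#'   warning.
#' @export
element_enrichment <- function(target_ann, background_ann,
                               features = c("promoter", "gene_body",
                                            "cpg_island", "cpg_shore",
                                            "cpg_shelf")) {
  stopifnot(nrow(target_ann) > 0, nrow(background_ann) > 0)
  rows <- lapply(features, function(f) {
    a <- sum(target_ann[[f]]); b <- nrow(target_ann) - a
    c_ <- sum(background_ann[[f]]); d <- nrow(background_ann) - c_
    if (c_ == 0) {
      warning("feature absent from background: ", f)
      return(data.frame(feature = f, fold = NA_real_, chisq = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    fold <- (a / nrow(target_ann)) / (c_ / nrow(background_ann))
    tst <- suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                        correct = FALSE)
    )
    data.frame(feature = f, fold = fold,
               chisq = unname(tst$statistic), p = tst$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  out$fdr[!is.na(out$p)] <- bh_fdr(out$p[!is.na(out$p)])
  out
}

#' Assign each site a repeat category by priority
#'
#' Priority: segmental duplication > merged LINE/SINE > satellite > other
#' repeat > none; a higher-priority overlap always wins, mirroring the
#' removal of lower-priority overlaps from each track.
#'
#' @param sites data.frame with `contig`, `pos`.
#' @param segdup,line,sine,satellite BED-style data.frames
#'   (`contig`,`start`,`end`); `line` and `sine` are merged into one
#'   category.
#' @param other optional list of further BED-style tracks (any overlap
#'   gives `other_repeat`).
#' @return factor per site with levels `segdup`, `line_sine`, `satellite`,
#'   `other_repeat`, `none`.
#' @export
assign_repeat_category <- function(sites, segdup, line, sine, satellite,
                                   other = list()) {
  n <- nrow(sites)
  cat <- rep("none", n)
  line_sine <- rbind(line[c("contig", "start", "end")],
                     sine[c("contig", "start", "end")])
  hit <- function(track) {
    res <- rep(FALSE, n)
    for (nm in unique(sites$contig)) {
      sel <- which(sites$contig == nm)
      res[sel] <- .overlaps_any(sites$pos[sel],
                                track[track$contig == nm, , drop = FALSE])
    }
    res
  }
  if (length(other)) {
    oth <- do.call(rbind, lapply(other, `[`, c("contig", "start", "end")))
    cat[hit(oth)] <- "other_repeat"
  }
  cat[hit(satellite)] <- "satellite"
  cat[hit(line_sine)] <- "line_sine"
  cat[hit(segdup)] <- "segdup"
  factor(cat, levels = c("segdup", "line_sine", "satellite", "other_repeat",
                         "none"))
}

#' Repeat-category fold between two site groups
#'
#' Ratio of per-category counts (group A over group B), the comparative
#' statistic used to contrast two probe groups' repeat content.
#'
#' @param cat_a,cat_b factors from [assign_repeat_category()].
#' @return data.frame: `category`, `n_a`, `n_b`, `fold` (NA when `n_b` is
#'   zero).
#' @export
repeat_category_fold <- function(cat_a, cat_b) {
  lev <- levels(cat_a)
  na <- as.integer(table(cat_a)[lev])
  nb <- as.integer(table(factor(cat_b, levels = lev))[lev])
  data.frame(category = lev, n_a = na, n_b = nb,
             fold = ifelse(nb > 0, round(na / nb, 2), NA_real_),
             stringsAsFactors = FALSE)
}

#' Driver-gene enrichment by permutation
#'
#' Observed overlap of the target genes with the driver set is compared to
#' overlaps of `n_perm` uniform draws of `|target|` genes from the
#' universe (without replacement). `fold = observed / mean(permuted)`;
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)` (add-one
#' estimator, so the smallest attainable p at 1,000 permutations is
#' ~0.001). Deterministic given `seed`.
#'
#' @param target_genes,driver_genes character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all eligible genes.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list: `observed`, `expected` (mean permuted overlap), `fold`,
#'   `p`, `n_perm`.
#' @export
driver_gene_enrichment <- function(target_genes, driver_genes, universe,
                                   n_perm = 1000L, seed = 1L) {
  target_genes <- unique(target_genes); driver_genes <- unique(driver_genes)
  universe <- unique(universe)
  stopifnot(all(target_genes %in% universe), all(driver_genes %in% universe),
            length(target_genes) <= length(universe))
  observed <- length(intersect(target_genes, driver_genes))
  set.seed(seed)
  k <- length(target_genes)
  is_driver <- universe %in% driver_genes
  perm <- vapply(seq_len(n_perm), function(b) {
    sum(is_driver[sample.int(length(universe), k)])
  }, numeric(1))
  expected <- mean(perm)
  list(observed = observed,
       expected = expected,
       fold = if (expected > 0) round(observed / expected, 2) else NA_real_,
       p = (1 + sum(perm >= observed)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric p per gene set, with fold
#' enrichment `(k/n)/(K/N)` for overlap k, target size n, set size K,
#' universe N; BH adjustment across sets, significance at adjusted
#' p < 0.05. Empty sets are skipped with a warning.
#'
#' @param target_genes character vector, subset of `universe`.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all eligible genes.
#' @return data.frame: `set`, `k`, `set_size`, `fold`, `p`, `fdr`,
#'   `significant`.
#' @export
overrepresentation <- function(target_genes, gene_sets, universe) {
  target_genes <- unique(target_genes); universe <- unique(universe)
  stopifnot(all(target_genes %in% universe))
  n <- length(target_genes); N <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(gs)) {
      warning("empty gene set skipped: ", nm)
      return(NULL)
    }
    K <- length(gs)
    k <- length(intersect(target_genes, gs))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, set_size = K,
               fold = (k / n) / (K / N), p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set = character(0), k = integer(0),
                      set_size = integer(0), fold = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < 0.05
  out
}

#' Genes whose promoter or gene body contains at least one site
#'
#' @param sites data.frame with `contig`, `pos`.
#' @param genes data.frame with `contig`, `start`, `end`, `strand`, `name`.
#' @param params a [meth_params()] list (promoter width).
#' @return deduplicated character vector of gene names.
#' @export
map_sites_to_genes <- function(sites, genes, params = meth_params()) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pos <- sites$pos[sites$contig == g$contig]
    if (!length(pos)) next
    in_body <- pos >= g$start & pos < g$end
    in_prom <- if (g$strand == "+") {
      pos >= g$start - params$promoter_upstream & pos < g$start
    } else if (g$strand == "-") {
      pos >= g$end & pos < g$end + params$promoter_upstream
    } else rep(FALSE, length(pos))
    if (any(in_body | in_prom)) hits <- c(hits, g$name)
  }
  unique(hits)
}
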