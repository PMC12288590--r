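## Gapless seed-and-extend alignment of 50-nt array probes to the four
## bisulfite-converted genome variants, and the unambiguous /
## cross-reactive / mismatched trichotomy.
##
## A hit qualifies when it has at least `match_min` matching bases and
## identity >= `identity_min` over its in-bounds aligned span, with no gaps.
## Hits found on the reverse-complement variants are reported back in
## forward source coordinates (strand "-"). Qualifying hits from all four
## variants and all degenerate-base expansions are collapsed into physical
## loci (same contig, start within +/-2 bp) before uniqueness is counted:
## the same locus necessarily shows up in complementary variants and must
## not be double counted.

#' Expand degenerate R bases in a probe sequence
#'
#' Each `R` (purine) is replaced by `A` and `G` in all combinations, the
#' Cartesian expansion used when aligning Infinium type II probes.
#'
#' @param sequence a probe sequence over `{A,C,G,T,R}`.
#' @return character vector of concrete sequences over `{A,C,G,T}`;
#'   a singleton when the sequence has no `R`.
#' @export
expand_probe_sequence <- function(sequence) {
  pos <- gregexpr("R", sequence, fixed = TRUE)[[1]]
  if (pos[1] == -1) return(sequence)
  out <- sequence
  for (p in pos) {
    out <- c(
      vapply(out, function(s) `substr<-`(s, p, p, "A"), character(1)),
      vapply(out, function(s) `substr<-`(s, p, p, "G"), character(1))
    )
  }
  unname(out)
}

#' Build a k-mer seed index over one genome variant
#'
#' Tiles of `tile_size` sampled every `step_size` bases are hashed to their
#' positions, in the spirit of the BLAT genome index. Tiles occurring more
#' than `rep_match` times are masked from the index.
#'
#' @param contigs named character vector of sequences (one genome variant).
#' @param tile_size tile length.
#' @param step_size sampling stride.
#' @param rep_match occurrence count above which a tile is masked.
#' @return a `seed_index`: list with `tile_size` and `tiles`, an environment
#'   mapping each tile to a data.frame of `contig`, `pos` (0-based).
#' @export
build_seed_index <- function(contigs, tile_size = 11L, step_size = 5L,
                             rep_match = 1000000L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  kmer_all <- character(0); contig_all <- character(0); pos_all <- integer(0)
  for (nm in names(contigs)) {
    n <- nchar(contigs[[nm]])
    if (n < tile_size) next
    starts <- seq(1L, n - tile_size + 1L, by = step_size)
    km <- substring(contigs[[nm]], starts, starts + tile_size - 1L)
    kmer_all <- c(kmer_all, km)
    contig_all <- c(contig_all, rep(nm, length(starts)))
    pos_all <- c(pos_all, starts - 1L)
  }
  keep <- !grepl("N", kmer_all, fixed = TRUE)
  idx <- split(seq_along(kmer_all)[keep], kmer_all[keep])
  for (k in names(idx)) {
    i <- idx[[k]]
    if (length(i) > rep_match) next  # repeat-masked tile
    assign(k, data.frame(contig = contig_all[i], pos = pos_all[i],
                         stringsAsFactors = FALSE), envir = env)
  }
  structure(list(tile_size = as.integer(tile_size),
                 step_size = as.integer(step_size),
                 tiles = env),
            class = "seed_index")
}

#' Look up a tile in a seed index
#'
#' @param index a `seed_index`.
#' @param kmer a tile of length `index$tile_size`.
#' @return data.frame of `contig`, `pos`; zero rows when absent or masked.
#' @export
seed_lookup <- function(index, kmer) {
  if (exists(kmer, envir = index$tiles, inherits = FALSE)) {
    get(kmer, envir = index$tiles, inherits = FALSE)
  } else {
    data.frame(contig = character(0), pos = integer(0), stringsAsFactors = FALSE)
  }
}

# Score one gapless placement of `pch` (probe char vector) at 0-based
# offset `o` on variant sequence chars `gch` (length n). Returns NULL or a
# list(matches, aligned_length, a, b) where [a,b) is the in-bounds variant
# span (0-based).
.score_placement <- function(pch, gch, o, match_min, identity_min) {
  L <- length(pch)
  a <- max(0L, o); b <- min(length(gch), o + L)
  if (b - a < match_min) return(NULL)
  gi <- (a + 1L):b
  pi <- (a - o + 1L):(b - o)
  matches <- sum(pch[pi] == gch[gi])
  alen <- b - a
  if (matches < match_min || matches / alen < identity_min) return(NULL)
  list(matches = matches, aligned_length = alen, a = a, b = b)
}

#' Align one concrete probe sequence to the four converted genome variants
#'
#' Seed matches from the per-variant indexes propose gapless placements
#' (genome tile position minus in-probe tile offset); each distinct
#' placement is scored over its in-bounds span and kept when it meets the
#' qualification thresholds. Placements found on reverse-complement
#' variants are reported in forward source coordinates with strand `-`.
#'
#' @param sequence a concrete 50-mer over `{A,C,G,T}`.
#' @param cset a `converted_genome_set`.
#' @param params a [meth_params()] list.
#' @param indexes optional list of four `seed_index` objects keyed by
#'   variant name (built on the fly when `NULL`; pre-build with
#'   [build_variant_indexes()] when aligning many probes).
#' @return data.frame of qualifying hits: `contig`, `start`, `end`,
#'   `strand`, `variant`, `matches`, `aligned_length`, `identity`,
#'   `probe_offset` (0-based offset of probe base 1 in the variant's own
#'   coordinates).
#' @export
align_probe <- function(sequence, cset, params = meth_params(), indexes = NULL) {
  stopifnot(!grepl("[^ACGT]", sequence))
  if (is.null(indexes)) indexes <- build_variant_indexes(cset, params)
  pch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(pch)
  k <- params$tile_size
  qstarts <- 1:(L - k + 1L)
  qmers <- substring(sequence, qstarts, qstarts + k - 1L)
  hits <- list()
  for (v in names(cset$variants)) {
    gseqs <- cset$variants[[v]]
    idx <- indexes[[v]]
    cand <- list()
    for (j in seq_along(qmers)) {
      m <- seed_lookup(idx, qmers[j])
      if (nrow(m)) {
        cand[[length(cand) + 1L]] <-
          data.frame(contig = m$contig, o = m$pos - (qstarts[j] - 1L),
                     stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- unique(do.call(rbind, cand))
    rev_variant <- grepl("_rev$", v)
    for (r in seq_len(nrow(cand))) {
      nm <- cand$contig[r]; o <- cand$o[r]
      gch <- .variant_chars(cset, v, nm)
      sc <- .score_placement(pch, gch, o, params$match_min, params$identity_min)
      if (is.null(sc)) next
      n <- length(gch)
      if (rev_variant) {
        fstart <- n - sc$b; fend <- n - sc$a; strand <- "-"
      } else {
        fstart <- sc$a; fend <- sc$b; strand <- "+"
      }
      hits[[length(hits) + 1L]] <- data.frame(
        contig = nm, start = fstart, end = fend, strand = strand,
        variant = v, matches = sc$matches, aligned_length = sc$aligned_length,
        identity = sc$matches / sc$aligned_length, probe_offset = o,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      variant = character(0), matches = integer(0),
                      aligned_length = integer(0), identity = numeric(0),
                      probe_offset = integer(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, hits))
}

# cache of per-variant per-contig character vectors, attached to the cset
# by build_variant_indexes(); falls back to strsplit on demand.
.variant_chars <- function(cset, variant, contig) {
  cache <- attr(cset, "char_cache")
  if (!is.null(cache)) {
    key <- paste0(variant, "\r", contig)
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  strsplit(cset$variants[[variant]][[contig]], "", fixed = TRUE)[[1]]
}

#' Pre-build seed indexes (and character caches) for all four variants
#'
#' @param cset a `converted_genome_set`.
#' @param params a [meth_params()] list.
#' @return named list of four `seed_index` objects. As a side effect a
#'   per-contig character cache is attached to `cset` in the calling frame
#'   when possible; callers should use the returned value with the same
#'   `cset` object.
#' @export
build_variant_indexes <- function(cset, params = meth_params()) {
  lapply(cset$variants, build_seed_index,
         tile_size = params$tile_size, step_size = params$step_size,
         rep_match = params$rep_match)
}

# internal: attach char cache for speed when classifying many probes
.with_char_cache <- function(cset) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  store <- list()
  for (v in names(cset$variants)) {
    for (nm in names(cset$variants[[v]])) {
      store[[paste0(v, "\r", nm)]] <-
        strsplit(cset$variants[[v]][[nm]], "", fixed = TRUE)[[1]]
    }
  }
  attr(cset, "char_cache") <- store
  cset
}

#' Does a hit perfectly match the probe's target CpG dinucleotide?
#'
#' Both bases of the declared target CpG must be covered by the hit and the
#' probe base contributing to the forward strand at each position (the
#' complement of the probe base, for minus-strand hits) must equal the
#' source-genome base.
#'
#' @param hit one row of an [align_probe()] result.
#' @param sequence the concrete probe sequence that produced the hit.
#' @param cset the `converted_genome_set` (provides the source genome).
#' @param target_contig,target_pos declared target: contig and 0-based
#'   position of the CpG's C.
#' @return `TRUE` iff the CpG dinucleotide is perfectly matched.
#' @export
check_cpg_locus <- function(hit, sequence, cset, target_contig, target_pos) {
  if (hit$contig != target_contig) stop("hit does not overlap the target")
  if (hit$end <= target_pos || hit$start > target_pos + 1L) {
    stop("hit does not overlap the target")
  }
  src <- cset$source[[target_contig]]
  n <- nchar(src)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (x in c(target_pos, target_pos + 1L)) {
    if (x < hit$start || x >= hit$end) return(FALSE)
    if (hit$strand == "+") {
      i <- x - hit$probe_offset + 1L
      pbase <- substr(sequence, i, i)
    } else {
      r <- n - 1L - x
      i <- r - hit$probe_offset + 1L
      pbase <- comp[[substr(sequence, i, i)]]
    }
    if (pbase != substr(src, x + 1L, x + 1L)) return(FALSE)
  }
  TRUE
}

# Collapse qualifying hits into physical loci: same contig, start within
# +/- `tol` bp of the running cluster start. Returns the hit data.frame
# with a `locus` integer column.
.collapse_loci <- function(hits, tol = 2L) {
  hits$locus <- NA_integer_
  lid <- 0L
  for (nm in unique(hits$contig)) {
    sel <- which(hits$contig == nm)
    ord <- sel[order(hits$start[sel])]
    anchor <- -Inf
    for (i in ord) {
      if (hits$start[i] - anchor > tol) {
        lid <- lid + 1L
        anchor <- hits$start[i]
      }
      hits$locus[i] <- lid
    }
  }
  hits
}

#' Classify one probe against an assembly
#'
#' Collects qualifying hits over all degenerate-base expansions and all
#' four converted genome variants, collapses them into physical loci
#' (+/- 2 bp), and applies the trichotomy: a probe with no "good
#' alignment" (a locus overlapping its declared target whose CpG
#' dinucleotide is perfectly matched) is `mismatched`; otherwise it is
#' `unambiguous` when the total locus count is exactly 1 and
#' `cross_reactive` when more than one locus qualifies. A probe declaring a
#' target contig absent from the assembly can have no good alignment and is
#' `mismatched`.
#'
#' @param probe one row of a [read_probe_manifest()] data.frame (or a list
#'   with `probe_id`, `sequence`, `contig`, `target_pos`).
#' @param cset a `converted_genome_set`.
#' @param params a [meth_params()] list.
#' @param indexes optional pre-built [build_variant_indexes()] result.
#' @return one-row data.frame: `probe_id`, `status`, `n_loci`, plus the
#'   best target-overlapping (or overall) hit's `contig`, `start`, `end`,
#'   `strand`, `matches`, `identity` (NA when there is no qualifying hit).
#' @export
classify_probe <- function(probe, cset, params = meth_params(), indexes = NULL) {
  if (is.null(indexes)) indexes <- build_variant_indexes(cset, params)
  seqs <- expand_probe_sequence(probe$sequence)
  hits <- list()
  for (s in seqs) {
    h <- align_probe(s, cset, params, indexes)
    if (nrow(h)) {
      h$expansion <- s
      hits[[length(hits) + 1L]] <- h
    }
  }
  empty_best <- data.frame(contig = NA_character_, start = NA_integer_,
                           end = NA_integer_, strand = NA_character_,
                           matches = NA_integer_, identity = NA_real_,
                           stringsAsFactors = FALSE)
  if (!length(hits)) {
    return(cbind(data.frame(probe_id = probe$probe_id, status = "mismatched",
                            n_loci = 0L, stringsAsFactors = FALSE), empty_best))
  }
  hits <- do.call(rbind, hits)
  hits <- .collapse_loci(hits)
  n_loci <- length(unique(hits$locus))
  # a good alignment: a hit overlapping the declared target CpG whose
  # dinucleotide is perfectly matched
  tpos <- probe$target_pos
  over <- hits$contig == probe$contig &
    hits$start <= tpos + 1L & hits$end >= tpos + 1L & hits$end > tpos
  good <- FALSE
  best <- empty_best
  if (any(over)) {
    oi <- which(over)
    oi <- oi[order(-hits$matches[oi])]
    for (i in oi) {
      if (check_cpg_locus(hits[i, ], hits$expansion[i], cset,
                          probe$contig, tpos)) {
        good <- TRUE
        best <- hits[i, c("contig", "start", "end", "strand", "matches",
                          "identity")]
        break
      }
    }
  }
  if (!good) {
    i <- which.max(hits$matches)
    best <- hits[i, c("contig", "start", "end", "strand", "matches", "identity")]
    status <- "mismatched"
  } else {
    status <- if (n_loci == 1L) "unambiguous" else "cross_reactive"
  }
  rownames(best) <- NULL
  cbind(data.frame(probe_id = probe$probe_id, status = status,
                   n_loci = n_loci, stringsAsFactors = FALSE), best)
}

#' Classify every probe in a manifest against an assembly
#'
#' Builds the four converted genome variants and their seed indexes once,
#' then classifies each probe. Logs input/output bookkeeping via
#' `message()`.
#'
#' @param manifest a [read_probe_manifest()] data.frame.
#' @param asm an `assembly` (or a pre-built `converted_genome_set`).
#' @param params a [meth_params()] list.
#' @param verbose emit a bookkeeping message.
#' @return data.frame with one row per probe (see [classify_probe()]).
#' @export
classify_manifest <- function(manifest, asm, params = meth_params(),
                              verbose = TRUE) {
  cset <- if (inherits(asm, "converted_genome_set")) asm else
    build_converted_set(asm)
  cset <- .with_char_cache(cset)
  indexes <- build_variant_indexes(cset, params)
  res <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    classify_probe(manifest[i, ], cset, params, indexes)
  }))
  rownames(res) <- NULL
  if (verbose) {
    tab <- table(factor(res$status, levels = c("unambiguous", "cross_reactive",
                                               "mismatched")))
    message("classified ", nrow(manifest), " probes: ",
            paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  res
}
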