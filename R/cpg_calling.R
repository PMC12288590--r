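## Coverage-filtered CpG calling from cytosine reports, strand merging,
## read-interval CpG counting, chain liftover and cross-reference CpG-set
## comparison.

.site_key <- function(contig, pos) paste(contig, pos, sep = ":")

#' Call CpGs passing a per-sample coverage filter
#'
#' A site survives when its total read count is at least `coverage_min` in
#' every sample; the surviving set is the across-sample intersection of
#' per-sample filtered sites. Contigs outside `autosomes` are dropped
#' first when an autosome list is given.
#'
#' @param reports list of per-sample data.frames from
#'   [read_cytosine_report()] (all in one assembly's coordinates).
#' @param coverage_min minimum total count per sample (default 10).
#' @param autosomes optional character vector of contigs to keep.
#' @return list with `samples` (the filtered per-sample data.frames
#'   restricted to surviving sites) and `sites` (data.frame `contig`,
#'   `pos` of the surviving sites).
#' @export
call_cpgs <- function(reports, coverage_min = 10L, autosomes = NULL) {
  stopifnot(length(reports) >= 1)
  filt <- lapply(reports, function(df) {
    if (!is.null(autosomes)) df <- df[df$contig %in% autosomes, , drop = FALSE]
    df[df$count_meth + df$count_unmeth >= coverage_min, , drop = FALSE]
  })
  keys <- lapply(filt, function(df) .site_key(df$contig, df$pos))
  common <- Reduce(intersect, keys)
  if (!length(common)) warning("no sites survive the coverage filter")
  samples <- lapply(filt, function(df) {
    df[.site_key(df$contig, df$pos) %in% common, , drop = FALSE]
  })
  ref <- samples[[1]]
  ord <- order(ref$contig, ref$pos)
  sites <- data.frame(contig = ref$contig[ord], pos = ref$pos[ord],
                      stringsAsFactors = FALSE)
  list(samples = samples, sites = sites)
}

#' Merge opposite-strand CpG calls onto the cytosine position
#'
#' A Bismark-style report can carry a call at the C of a CpG (position p)
#' and at its G (position p+1, the cytosine of the minus strand). Counts at
#' p+1 are summed onto p whenever the reference carries `CG` at p, and the
#' beta is recomputed. Calls at p+1 without a reference CG at p are left
#' unmerged with a warning.
#'
#' @param calls data.frame as from [read_cytosine_report()].
#' @param asm the `assembly` the coordinates refer to.
#' @return merged data.frame; no position in the output is the `+1` partner
#'   of another call.
#' @export
merge_cpg_strands <- function(calls, asm) {
  cpg <- enumerate_cpgs(asm)
  is_c_of_cpg <- mapply(function(ctg, p) p %in% cpg[[ctg]],
                        calls$contig, calls$pos)
  is_g_of_cpg <- mapply(function(ctg, p) (p - 1L) %in% cpg[[ctg]],
                        calls$contig, calls$pos)
  orphan <- !is_c_of_cpg & !is_g_of_cpg
  if (any(orphan)) {
    warning(sum(orphan), " call(s) not at a reference CpG left unmerged")
  }
  keep <- calls[!is_g_of_cpg, , drop = FALSE]
  gcalls <- calls[is_g_of_cpg & !orphan, , drop = FALSE]
  if (nrow(gcalls)) {
    kk <- .site_key(keep$contig, keep$pos)
    for (r in seq_len(nrow(gcalls))) {
      key <- .site_key(gcalls$contig[r], gcalls$pos[r] - 1L)
      i <- match(key, kk)
      if (is.na(i)) {
        row <- gcalls[r, , drop = FALSE]
        row$pos <- row$pos - 1L
        keep <- rbind(keep, row)
        kk <- c(kk, key)
      } else {
        keep$count_meth[i] <- keep$count_meth[i] + gcalls$count_meth[r]
        keep$count_unmeth[i] <- keep$count_unmeth[i] + gcalls$count_unmeth[r]
      }
    }
  }
  total <- keep$count_meth + keep$count_unmeth
  keep$beta <- ifelse(total > 0, keep$count_meth / total, NA_real_)
  keep <- keep[order(keep$contig, keep$pos), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' CpGs covered by aligned-read intervals
#'
#' A CpG is covered when its C position lies inside at least one interval;
#' used for enrichment-based assays (MBD-seq / MeDIP-seq) where methylation
#' is read out as interval coverage rather than per-base conversion.
#'
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param cpg_set named list of per-contig CpG positions from
#'   [enumerate_cpgs()].
#' @return list with `covered` (named list of covered positions per contig)
#'   and `count`.
#' @export
count_cpgs_in_intervals <- function(intervals, cpg_set) {
  covered <- lapply(names(cpg_set), function(nm) {
    pos <- cpg_set[[nm]]
    iv <- intervals[intervals$contig == nm, , drop = FALSE]
    if (!nrow(iv) || !length(pos)) return(integer(0))
    q <- IRanges::IRanges(start = pos + 1L, width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    pos[IRanges::overlapsAny(q, s)]
  })
  names(covered) <- names(cpg_set)
  list(covered = covered, count = sum(lengths(covered)))
}

#' Lift positions through a chain map
#'
#' A position inside an aligned block maps by block offset (reflected for
#' reverse-orientation blocks); positions falling in inter-block gaps, or
#' on contigs absent from the chain, are reported unmapped.
#'
#' @param chain a `chain_map` from [read_chain()].
#' @param positions data.frame with `contig`, `pos` (0-based) in chain
#'   source coordinates.
#' @return `positions` with added columns `t_contig`, `t_pos` (NA when
#'   unmapped) and `mapped` (logical).
#' @export
liftover_positions <- function(chain, positions) {
  out <- positions
  out$t_contig <- NA_character_
  out$t_pos <- NA_integer_
  for (nm in unique(positions$contig)) {
    b <- chain[chain$s_contig == nm, , drop = FALSE]
    sel <- which(positions$contig == nm)
    if (!nrow(b)) next
    b <- b[order(b$s_start), , drop = FALSE]
    i <- findInterval(positions$pos[sel], b$s_start)
    ok <- i >= 1 & i <= nrow(b)
    ok[ok] <- positions$pos[sel][ok] < b$s_end[i[ok]]
    if (!any(ok)) next
    ii <- i[ok]; p <- positions$pos[sel][ok]
    off <- p - b$s_start[ii]
    tp <- ifelse(b$t_reversed[ii],
                 b$t_end[ii] - 1L - off,
                 b$t_start[ii] + off)
    out$t_contig[sel[ok]] <- b$t_contig[ii]
    out$t_pos[sel[ok]] <- as.integer(tp)
  }
  out$mapped <- !is.na(out$t_pos)
  out
}

#' Compare CpG sets called against two references
#'
#' Lifts the B-reference calls into A coordinates, counts the intersection
#' with the A calls, and reports each side's unique counts plus the percent
#' increase of A over B, `100 * (|A| - |B|) / |B|`. B calls that fail to
#' lift cannot intersect and count toward B-unique.
#'
#' @param calls_a,calls_b data.frames with `contig`, `pos` (the calls made
#'   against reference A and B respectively).
#' @param chain_b_to_a a `chain_map` mapping B coordinates into A.
#' @return list of class `cpg_comparison` with counts `n_a`, `n_b`,
#'   `n_b_lifted`, `intersection`, `a_unique`, `b_unique` and
#'   `percent_increase` (one decimal).
#' @export
compare_cpg_sets <- function(calls_a, calls_b, chain_b_to_a) {
  lift <- liftover_positions(chain_b_to_a, calls_b)
  a_keys <- .site_key(calls_a$contig, calls_a$pos)
  b_lifted_keys <- .site_key(lift$t_contig[lift$mapped],
                             lift$t_pos[lift$mapped])
  inter <- sum(b_lifted_keys %in% a_keys)
  n_a <- nrow(calls_a); n_b <- nrow(calls_b)
  structure(list(
    n_a = n_a, n_b = n_b,
    n_b_lifted = sum(lift$mapped),
    intersection = inter,
    a_unique = n_a - inter,
    b_unique = n_b - inter,
    percent_increase = round(100 * (n_a - n_b) / n_b, 1)
  ), class = "cpg_comparison")
}

#' @export
print.cpg_comparison <- function(x, ...) {
  cat("<cpg_comparison> A =", x$n_a, " B =", x$n_b,
      " intersect =", x$intersection,
      " A-unique =", x$a_unique,
      sprintf(" (%.1f%% increase of A over B)\n", x$percent_increase))
  invisible(x)
}
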