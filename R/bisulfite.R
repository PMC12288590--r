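## Bisulfite-converted genome variants, CpG enumeration and CpG islands.
##
## In-silico bisulfite conversion mirrors the chemistry: unmethylated C reads
## as T. Probes are therefore aligned against four genome variants: the
## fully-converted ("unmethylated") genome, the CpG-preserving
## ("methylated") genome, and the reverse complements of both, so that
## probes designed against either strand and either methylation state find
## their locus.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A,C,G,T,N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.convert_unmeth <- function(s) chartr("C", "T", s)
.convert_meth <- function(s) gsub("C(?!G)", "T", s, perl = TRUE)

#' Build the four bisulfite-converted genome variants
#'
#' Variant (1) `unmeth_fwd` converts every C to T; (2) `meth_fwd` converts
#' only non-CpG Cs (CpG cytosines are presumed methylated and protected);
#' (3) `unmeth_rev` and (4) `meth_rev` apply the same two conversions to the
#' reverse complement of each contig, i.e. to the other strand. N bases pass
#' through unchanged.
#'
#' @param asm an `assembly`.
#' @return a `converted_genome_set`: list with `source_name`, `source`
#'   (named contig vector) and `variants` (list of four named contig
#'   vectors keyed `unmeth_fwd`, `meth_fwd`, `unmeth_rev`, `meth_rev`).
#' @export
build_converted_set <- function(asm) {
  stopifnot(inherits(asm, "assembly"), length(asm$contigs) > 0)
  fwd <- asm$contigs
  rev <- setNames(revcomp(fwd), names(fwd))
  structure(list(
    source_name = asm$name,
    source = fwd,
    variants = list(
      unmeth_fwd = vapply(fwd, .convert_unmeth, character(1)),
      meth_fwd   = vapply(fwd, .convert_meth, character(1)),
      unmeth_rev = vapply(rev, .convert_unmeth, character(1)),
      meth_rev   = vapply(rev, .convert_meth, character(1))
    )
  ), class = "converted_genome_set")
}

#' Enumerate CpG sites
#'
#' Returns the 0-based position of the C of every forward-strand CG
#' dinucleotide, per contig.
#'
#' @param asm an `assembly` (or a named character vector of sequences).
#' @return named list (one element per contig) of sorted 0-based integer
#'   positions.
#' @export
enumerate_cpgs <- function(asm) {
  contigs <- if (inherits(asm, "assembly")) asm$contigs else asm
  lapply(contigs, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  })
}

#' Detect CpG islands
#'
#' Implements the classic definition directly: a CpG island is a maximal
#' merged run of qualifying 200-bp windows, where a window qualifies when
#' its GC fraction exceeds `cgi_gc_min` and its observed/expected CpG ratio
#' exceeds `cgi_oe_min` (expected = #C x #G / window length). Windows slide
#' at step 1. Merged regions are re-verified against both thresholds on the
#' full span and dropped if they fail. Windows with more than
#' `cgi_max_n_frac` N bases are ineligible.
#'
#' @param asm an `assembly`.
#' @param params a [meth_params()] list.
#' @return data.frame of islands: `contig`, `start`, `end` (0-based
#'   half-open).
#' @export
detect_cpg_islands <- function(asm, params = meth_params()) {
  w <- params$cgi_min_len
  out <- list()
  for (nm in names(asm$contigs)) {
    s <- asm$contigs[[nm]]
    n <- nchar(s)
    if (n < w) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- ch == "C"; isG <- ch == "G"; isN <- ch == "N"
    isCG <- c(isC[-n] & isG[-1], FALSE)
    cumC <- c(0, cumsum(isC)); cumG <- c(0, cumsum(isG))
    cumN <- c(0, cumsum(isN)); cumCG <- c(0, cumsum(isCG))
    starts <- 1:(n - w + 1L)   # 1-based window starts
    nC <- cumC[starts + w] - cumC[starts]
    nG <- cumG[starts + w] - cumG[starts]
    nN <- cumN[starts + w] - cumN[starts]
    # CG dinucleotides fully inside the window: C at starts .. starts+w-2
    nCG <- cumCG[starts + w - 1L] - cumCG[starts]
    gc <- (nC + nG) / w
    expct <- nC * nG / w
    oe <- ifelse(expct > 0, nCG / expct, 0)
    ok <- gc > params$cgi_gc_min & oe > params$cgi_oe_min &
      nN / w <= params$cgi_max_n_frac
    if (!any(ok)) next
    # merge overlapping qualifying windows [q, q+w)
    q <- starts[ok] - 1L   # 0-based
    brk <- which(diff(q) > w)
    reg_start <- q[c(1L, brk + 1L)]
    reg_end <- q[c(brk, length(q))] + w
    keep <- logical(length(reg_start))
    for (i in seq_along(reg_start)) {
      a <- reg_start[i] + 1L; b <- reg_end[i]
      L <- b - a + 1L
      rC <- cumC[b + 1L] - cumC[a]; rG <- cumG[b + 1L] - cumG[a]
      rCG <- cumCG[b] - cumCG[a]  # C of CG at a .. b-1 (1-based)
      rexp <- rC * rG / L
      keep[i] <- (rC + rG) / L > params$cgi_gc_min &&
        rexp > 0 && rCG / rexp > params$cgi_oe_min
    }
    if (any(keep)) {
      out[[nm]] <- data.frame(contig = nm, start = reg_start[keep],
                              end = reg_end[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
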