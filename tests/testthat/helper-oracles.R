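# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (seed index, cumulative-sum windows, phyper, wilcox.test)
# so that agreement is evidence, not tautology.

# naive character-scan CpG enumeration
oracle_cpg_scan <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2) return(integer(0))
  which(ch[-n] == "C" & ch[-1] == "G") - 1L
}

# exhaustive sliding-window island caller: per-window substring counting,
# then merge overlapping/adjacent qualifying windows and re-verify
oracle_islands <- function(seq, w = 200L, gc_min = 0.5, oe_min = 0.6,
                           n_max = 0.1) {
  n <- nchar(seq)
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  stats_of <- function(a, b) {  # 0-based half-open [a,b)
    s <- substr(seq, a + 1L, b)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    nC <- sum(ch == "C"); nG <- sum(ch == "G"); nN <- sum(ch == "N")
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    nCG <- if (m[1] == -1) 0L else length(m)
    L <- b - a
    list(gc = (nC + nG) / L, nN = nN / L,
         oe = if (nC * nG > 0) nCG / (nC * nG / L) else 0)
  }
  ok <- logical(n - w + 1L)
  for (a in 0:(n - w)) {
    st <- stats_of(a, a + w)
    ok[a + 1L] <- st$gc > gc_min && st$oe > oe_min && st$nN <= n_max
  }
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  q <- which(ok) - 1L
  brk <- which(diff(q) > w)
  rs <- q[c(1L, brk + 1L)]
  re <- q[c(brk, length(q))] + w
  keep <- vapply(seq_along(rs), function(i) {
    st <- stats_of(rs[i], re[i])
    st$gc > gc_min && st$oe > oe_min
  }, logical(1))
  data.frame(start = rs[keep], end = re[keep])
}

# exhaustive gapless aligner: slides the probe across every offset
# (including overhangs) of every variant contig, applies the thresholds
oracle_align <- function(sequence, cset, params) {
  pch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(pch)
  hits <- list()
  for (v in names(cset$variants)) {
    for (nm in names(cset$variants[[v]])) {
      gch <- strsplit(cset$variants[[v]][[nm]], "", fixed = TRUE)[[1]]
      n <- length(gch)
      rev_variant <- grepl("_rev$", v)
      for (o in (params$match_min - L):(n - params$match_min)) {
        a <- max(0L, o); b <- min(n, o + L)
        if (b - a < params$match_min) next
        matches <- sum(pch[(a - o + 1L):(b - o)] == gch[(a + 1L):b])
        alen <- b - a
        if (matches < params$match_min || matches / alen < params$identity_min)
          next
        fs <- if (rev_variant) n - b else a
        fe <- if (rev_variant) n - a else b
        hits[[length(hits) + 1L]] <- data.frame(
          contig = nm, start = fs, end = fe,
          strand = if (rev_variant) "-" else "+", variant = v,
          matches = matches, aligned_length = alen,
          identity = matches / alen, probe_offset = o,
          stringsAsFactors = FALSE)
      }
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

# fast variant of oracle_align for in-bounds offsets only, used where the
# genome is large; boundary offsets are handled by the slow loop above
oracle_align_fast <- function(sequence, cset, params) {
  pch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(pch)
  hits <- list()
  for (v in names(cset$variants)) {
    for (nm in names(cset$variants[[v]])) {
      g <- cset$variants[[v]][[nm]]
      gch <- strsplit(g, "", fixed = TRUE)[[1]]
      n <- length(gch)
      rev_variant <- grepl("_rev$", v)
      if (n >= L) {
        idx <- outer(0:(L - 1L), 0:(n - L), "+") + 1L
        mm <- matrix(gch[idx], nrow = L) == pch
        matches <- colSums(mm)
        qual <- which(matches >= params$match_min &
                        matches / L >= params$identity_min)
        for (o in qual - 1L) {
          fs <- if (rev_variant) n - (o + L) else o
          hits[[length(hits) + 1L]] <- data.frame(
            contig = nm, start = fs, end = fs + L,
            strand = if (rev_variant) "-" else "+", variant = v,
            matches = matches[o + 1L], aligned_length = L,
            identity = matches[o + 1L] / L, probe_offset = o,
            stringsAsFactors = FALSE)
        }
      }
      # overhanging offsets
      span <- c((params$match_min - L):(-1L),
                (n - L + 1L):(n - params$match_min))
      for (o in span) {
        a <- max(0L, o); b <- min(n, o + L)
        if (b - a < params$match_min) next
        matches <- sum(pch[(a - o + 1L):(b - o)] == gch[(a + 1L):b])
        alen <- b - a
        if (matches < params$match_min || matches / alen < params$identity_min)
          next
        fs <- if (rev_variant) n - b else a
        fe <- if (rev_variant) n - a else b
        hits[[length(hits) + 1L]] <- data.frame(
          contig = nm, start = fs, end = fe,
          strand = if (rev_variant) "-" else "+", variant = v,
          matches = matches, aligned_length = alen,
          identity = matches / alen, probe_offset = o,
          stringsAsFactors = FALSE)
      }
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

# fully independent classification on oracle hits: own locus collapsing and
# own CpG-dinucleotide check against the source genome
oracle_classify <- function(probe, cset, params, align_fun = oracle_align_fast) {
  seqs <- expand_probe_sequence(probe$sequence)
  hits <- list()
  for (s in seqs) {
    h <- align_fun(s, cset, params)
    if (nrow(h)) { h$expansion <- s; hits[[length(hits) + 1L]] <- h }
  }
  if (!length(hits)) return(list(status = "mismatched", n_loci = 0L))
  hits <- do.call(rbind, hits)
  # collapse: same contig, start within 2 of cluster anchor
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  locus <- integer(nrow(hits)); lid <- 0L
  anchor <- -Inf; actg <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$contig[i] != actg || hits$start[i] - anchor > 2L) {
      lid <- lid + 1L; anchor <- hits$start[i]; actg <- hits$contig[i]
    }
    locus[i] <- lid
  }
  n_loci <- length(unique(locus))
  tpos <- probe$target_pos
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  src <- cset$source[[probe$contig]]
  n <- nchar(src)
  good <- FALSE
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$contig != probe$contig) next
    if (h$start > tpos || h$end < tpos + 2L) next
    match_both <- TRUE
    for (x in c(tpos, tpos + 1L)) {
      if (h$strand == "+") {
        pi <- x - h$probe_offset + 1L
        pb <- substr(h$expansion, pi, pi)
      } else {
        r <- n - 1L - x
        pi <- r - h$probe_offset + 1L
        pb <- comp[[substr(h$expansion, pi, pi)]]
      }
      if (pb != substr(src, x + 1L, x + 1L)) { match_both <- FALSE; break }
    }
    if (match_both) { good <- TRUE; break }
  }
  status <- if (!good) "mismatched" else if (n_loci == 1L) "unambiguous"
  else "cross_reactive"
  list(status = status, n_loci = n_loci)
}

# exact Mann-Whitney two-sided p by enumerating all label assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); pool <- c(x, y); N <- length(pool)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# direct min-over-tail BH definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper-tail p by exhaustive enumeration of draws
oracle_hyper_enum <- function(k_obs, set_genes, target_size, universe) {
  combs <- utils::combn(length(universe), target_size)
  overl <- apply(combs, 2, function(idx) {
    length(intersect(universe[idx], set_genes))
  })
  mean(overl >= k_obs)
}

# per-site containment scan for interval-CpG intersection
oracle_cpgs_in_intervals <- function(intervals, cpg_set) {
  total <- 0L
  for (nm in names(cpg_set)) {
    iv <- intervals[intervals$contig == nm, , drop = FALSE]
    for (p in cpg_set[[nm]]) {
      if (nrow(iv) && any(p >= iv$start & p < iv$end)) total <- total + 1L
    }
  }
  total
}

# shared small fixtures (built once per test run)
panel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_assembly_panel(seed = 42L)
    }
    cache
  }
})
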