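## Differential-methylation testing with two FDR regimes: a permutation
## FDR (label shuffles, p-value threshold giving the target FDR) and
## Benjamini-Hochberg, plus replicate-variability and cross-platform
## difference metrics.

#' Mann-Whitney U test (two-sided)
#'
#' Thin, branch-explicit front end over [stats::wilcox.test()]: the exact
#' null distribution is enumerated when the smaller group has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used. Missing values are dropped.
#' When every value is tied across both groups, `p = 1` by convention and
#' the result is flagged `degenerate`.
#'
#' @param x,y numeric vectors.
#' @return list with `U` (the U statistic of `x`), `p`, `exact` (logical),
#'   `degenerate` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1, exact = FALSE,
                degenerate = TRUE))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact,
       degenerate = FALSE)
}

# Row-wise Mann-Whitney normal-approximation p-values from pre-computed
# row ranks. `ranks` is a sites x samples matrix of within-row ranks,
# `g1` the column indices of group 1. The tie correction per row is
# precomputed by .row_rank_setup(). Used by the permutation FDR, where the
# observed and every permuted p-value must come from the identical formula.
.row_mw_p <- function(setup, g1) {
  n1 <- length(g1); n2 <- setup$n - n1
  r1 <- rowSums(setup$ranks[, g1, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((setup$n + 1) - setup$tie_term / (setup$n * (setup$n - 1)))
  z <- (abs(u - mu) - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  z[sigma2 <= 0] <- 0
  p <- 2 * stats::pnorm(-z)
  pmin(p, 1)
}

.row_rank_setup <- function(m) {
  n <- ncol(m)
  ranks <- t(apply(m, 1L, rank))
  tie_term <- apply(m, 1L, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  })
  list(ranks = ranks, tie_term = tie_term, n = n)
}

#' Permutation-based FDR p-value threshold
#'
#' Group labels are shuffled `n_perm` times (preserving group sizes) and
#' per-site p-values recomputed under each shuffle. For a candidate
#' threshold t, `FDR(t) = mean_over_permutations #\{p_perm <= t\} /
#' max(1, #\{p_obs <= t\})`; the returned threshold is the largest observed
#' p-value with `FDR(t) <= target_fdr` (`NA` when none qualifies).
#' Observed and permuted p-values use one identical test formula (the
#' tie-corrected normal approximation), so exceedance counts are
#' comparable. Deterministic given `seed`.
#'
#' @param betas sites x samples numeric matrix.
#' @param groups character/factor vector over samples with two levels.
#' @param n_perm number of permutations (default 1000).
#' @param target_fdr target FDR (default 0.05).
#' @param seed RNG seed.
#' @return list with `threshold` (NA when no threshold attains the target),
#'   `fdr_at_threshold`, `n_discoveries`, `p_obs`.
#' @export
permutation_fdr_threshold <- function(betas, groups, n_perm = 1000L,
                                      target_fdr = 0.05, seed = 1L) {
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L, min(table(groups)) >= 2L, n_perm >= 1L)
  if (anyNA(betas)) {
    stop("the permutation FDR requires a complete beta matrix; ",
         "impute or drop sites with missing values first")
  }
  g1_obs <- which(groups == lv[1])
  setup <- .row_rank_setup(betas)
  p_obs <- .row_mw_p(setup, g1_obs)
  set.seed(seed)
  n1 <- length(g1_obs); n <- ncol(betas)
  perm_p <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm_p[[b]] <- .row_mw_p(setup, sample.int(n, n1))
  }
  pooled <- sort(unlist(perm_p))
  cand <- sort(unique(p_obs))
  n_obs_le <- findInterval(cand, sort(p_obs))
  n_perm_le <- findInterval(cand, pooled) / n_perm
  fdr <- n_perm_le / pmax(1, n_obs_le)
  ok <- fdr <= target_fdr
  if (!any(ok)) {
    return(list(threshold = NA_real_, fdr_at_threshold = NA_real_,
                n_discoveries = 0L, p_obs = p_obs))
  }
  t_star <- max(cand[ok])
  list(threshold = t_star,
       fdr_at_threshold = fdr[which(cand == t_star)],
       n_discoveries = sum(p_obs <= t_star),
       p_obs = p_obs)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment via [stats::p.adjust()]; order-preserving with
#' enforced monotonicity.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated CpGs
#'
#' Per-site two-sided Mann-Whitney test of case vs control betas plus the
#' effect-size filter: a site is significant when it passes the active FDR
#' rule and `|delta_beta| > delta_min`, where `delta_beta` is the case mean
#' minus the control mean. FDR rule: `"bh"` requires BH-adjusted
#' `p < fdr_max`; `"permutation"` requires `p <= t*` from
#' [permutation_fdr_threshold()]. Sites with fewer than 2 non-missing
#' values in either group are excluded (and counted in the message log).
#'
#' @param betas sites x samples matrix (rownames = site IDs).
#' @param groups vector over samples; the `case` level is
#'   `levels[1]`/first unique value unless a factor is supplied.
#' @param params a [meth_params()] list (`delta_min`, `fdr_max`, `n_perm`).
#' @param fdr_mode `"bh"` or `"permutation"`.
#' @param seed seed for the permutation mode.
#' @param verbose log bookkeeping.
#' @return data.frame: `site`, `p`, `delta_beta`, `fdr` (BH mode) or
#'   `below_threshold` (permutation mode), `significant`.
#' @export
call_dmcs <- function(betas, groups, params = meth_params(),
                      fdr_mode = c("bh", "permutation"), seed = 1L,
                      verbose = TRUE) {
  fdr_mode <- match.arg(fdr_mode)
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L)
  case <- betas[, groups == lv[1], drop = FALSE]
  ctrl <- betas[, groups == lv[2], drop = FALSE]
  enough <- rowSums(!is.na(case)) >= 2L & rowSums(!is.na(ctrl)) >= 2L
  if (verbose && any(!enough)) {
    message(sum(!enough), " site(s) with < 2 non-missing values per group excluded")
  }
  betas <- betas[enough, , drop = FALSE]
  case <- case[enough, , drop = FALSE]
  ctrl <- ctrl[enough, , drop = FALSE]
  delta <- rowMeans(case, na.rm = TRUE) - rowMeans(ctrl, na.rm = TRUE)
  sites <- rownames(betas)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(betas)))
  if (fdr_mode == "bh") {
    if (min(ncol(case), ncol(ctrl)) <= 8L || anyNA(betas)) {
      p <- vapply(seq_len(nrow(betas)), function(i) {
        mann_whitney_u(case[i, ], ctrl[i, ])$p
      }, numeric(1))
    } else {
      setup <- .row_rank_setup(betas)
      p <- .row_mw_p(setup, which(groups == lv[1]))
    }
    fdr <- bh_fdr(p)
    res <- data.frame(site = sites, p = p, delta_beta = delta, fdr = fdr,
                      significant = fdr < params$fdr_max &
                        abs(delta) > params$delta_min,
                      stringsAsFactors = FALSE)
  } else {
    pt <- permutation_fdr_threshold(betas, groups, n_perm = params$n_perm,
                                    target_fdr = params$fdr_max, seed = seed)
    below <- if (is.na(pt$threshold)) rep(FALSE, nrow(betas)) else
      pt$p_obs <= pt$threshold
    res <- data.frame(site = sites, p = pt$p_obs, delta_beta = delta,
                      below_threshold = below,
                      significant = below & abs(delta) > params$delta_min,
                      stringsAsFactors = FALSE)
    attr(res, "p_threshold") <- pt$threshold
  }
  rownames(res) <- NULL
  if (verbose) {
    message("tested ", nrow(res), " sites, ", sum(res$significant),
            " significant (", fdr_mode, " mode)")
  }
  res
}

#' Per-site standard deviation across technical replicates
#'
#' @param betas sites x replicates matrix (one replicate set).
#' @return named numeric vector of sample standard deviations (n-1
#'   denominator).
#' @export
replicate_sd <- function(betas) {
  stopifnot(ncol(betas) >= 2L)
  apply(betas, 1L, stats::sd, na.rm = TRUE)
}

#' Absolute array-vs-WGBS methylation difference per shared site
#'
#' WGBS sites below the coverage floor are excluded before the platforms
#' are intersected.
#'
#' @param array_betas named numeric vector of array betas (names = site
#'   keys, e.g. `"contig:pos"`).
#' @param wgbs_calls data.frame with `contig`, `pos`, `count_meth`,
#'   `count_unmeth` (beta is recomputed from counts).
#' @param coverage_min minimum WGBS coverage (default 10).
#' @return named numeric vector `|array - wgbs|` over the shared sites.
#' @export
platform_abs_diff <- function(array_betas, wgbs_calls, coverage_min = 10L) {
  total <- wgbs_calls$count_meth + wgbs_calls$count_unmeth
  wgbs_calls <- wgbs_calls[total >= coverage_min, , drop = FALSE]
  total <- total[total >= coverage_min]
  wb <- wgbs_calls$count_meth / total
  names(wb) <- .site_key(wgbs_calls$contig, wgbs_calls$pos)
  shared <- intersect(names(array_betas), names(wb))
  if (!length(shared)) {
    warning("no shared sites between platforms")
    return(setNames(numeric(0), character(0)))
  }
  abs(array_betas[shared] - wb[shared])
}

#' Compare a per-probe metric between probe groups
#'
#' Each requested pairwise comparison is tested with a two-sided
#' Mann-Whitney test; BH adjustment is applied across the comparison
#' family.
#'
#' @param values numeric vector of the metric (e.g. replicate SD).
#' @param labels group label per value.
#' @param comparisons list of length-2 character vectors of group labels.
#' @return data.frame: `group_a`, `group_b`, `p`, `fdr`.
#' @export
compare_probe_groups <- function(values, labels, comparisons) {
  labels <- as.character(labels)
  known <- unique(labels)
  res <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    if (!all(cmp %in% known)) stop("unknown group label: ",
                                   paste(setdiff(cmp, known), collapse = ", "))
    p <- mann_whitney_u(values[labels == cmp[1]], values[labels == cmp[2]])$p
    data.frame(group_a = cmp[1], group_b = cmp[2], p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out
}
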