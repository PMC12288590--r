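## Integration of per-assembly probe classifications into pangenome,
## population and cross-reference probe sets, with Table-style summaries.

#' Pangenome consensus unambiguous probe set
#'
#' A probe is included when it is classified unambiguous in at least
#' `ceiling(consensus_frac * N)` of the `N` panel assemblies; for small
#' panels (`N < 5`) the rule tightens to all assemblies, mirroring the
#' population-level clause used for sparsely represented populations.
#'
#' @param status_by_assembly a probes x assemblies matrix or data.frame of
#'   status strings (`"unambiguous"`, `"cross_reactive"`, `"mismatched"`),
#'   with probe IDs as row names.
#' @param assemblies which assembly columns to use (default: all).
#' @param consensus_frac consensus fraction, default 0.95.
#' @return character vector of probe IDs in the consensus set.
#' @export
consensus_unambiguous <- function(status_by_assembly,
                                  assemblies = colnames(status_by_assembly),
                                  consensus_frac = 0.95) {
  if (length(assemblies) == 0) stop("empty assembly panel")
  m <- as.matrix(status_by_assembly[, assemblies, drop = FALSE])
  if (anyNA(m)) stop("every probe needs a status in every panel assembly")
  n <- length(assemblies)
  need <- if (n < 5L) n else as.integer(ceiling(consensus_frac * n))
  cnt <- rowSums(m == "unambiguous")
  rownames(status_by_assembly)[cnt >= need]
}

#' Population and subpopulation unambiguous probe sets
#'
#' Applies [consensus_unambiguous()] separately to the assemblies carrying
#' each population (and, when given, subpopulation) label.
#'
#' @param status_by_assembly as in [consensus_unambiguous()].
#' @param panel data.frame with columns `assembly`, `population` and
#'   optionally `subpopulation`.
#' @param consensus_frac consensus fraction.
#' @return named list of probe-ID vectors, one per population label and one
#'   per subpopulation label (names prefixed `sub:`). Labels with zero
#'   assemblies are omitted with a warning.
#' @export
population_sets <- function(status_by_assembly, panel, consensus_frac = 0.95) {
  stopifnot(all(c("assembly", "population") %in% names(panel)))
  out <- list()
  groups <- split(panel$assembly, panel$population)
  if ("subpopulation" %in% names(panel)) {
    sub <- split(panel$assembly, panel$subpopulation)
    names(sub) <- paste0("sub:", names(sub))
    groups <- c(groups, sub)
  }
  for (g in names(groups)) {
    asms <- intersect(groups[[g]], colnames(status_by_assembly))
    if (!length(asms)) {
      warning("label with zero assemblies omitted: ", g)
      next
    }
    out[[g]] <- consensus_unambiguous(status_by_assembly, asms, consensus_frac)
  }
  out
}

#' Four-way partition of a manifest by two references
#'
#' Splits probes into those unambiguous under both references, under only
#' one, or under neither.
#'
#' @param status_a,status_b named character vectors of statuses (same probe
#'   names, any order).
#' @return a `four_way_partition`: list with sets `both`, `a_unique`,
#'   `b_unique`, `neither` and a `counts` vector.
#' @export
compare_reference_sets <- function(status_a, status_b) {
  if (is.null(names(status_a)) || is.null(names(status_b)) ||
      !setequal(names(status_a), names(status_b)) ||
      length(status_a) != length(status_b)) {
    stop("the two status maps must cover the same manifest")
  }
  status_b <- status_b[names(status_a)]
  ua <- status_a == "unambiguous"
  ub <- status_b == "unambiguous"
  ids <- names(status_a)
  out <- list(
    both = ids[ua & ub],
    a_unique = ids[ua & !ub],
    b_unique = ids[!ua & ub],
    neither = ids[!ua & !ub]
  )
  out$counts <- vapply(out, length, integer(1))
  class(out) <- "four_way_partition"
  out
}

#' @export
print.four_way_partition <- function(x, ...) {
  cat("<four_way_partition>\n")
  print(x$counts)
  invisible(x)
}

#' Summarise a classification or partition as a percentage table
#'
#' Percentages are reported to one decimal place against the manifest
#' size; for a four-way partition a `discordant` row (`a_unique` +
#' `b_unique`) is added.
#'
#' @param x a `four_way_partition`, or a named status vector, or a named
#'   vector/list of counts.
#' @param manifest_size total number of probes; inferred when possible.
#' @return data.frame with columns `set`, `count`, `percent`.
#' @export
summarize_classification <- function(x, manifest_size = NULL) {
  if (inherits(x, "four_way_partition")) {
    counts <- x$counts
    if (is.null(manifest_size)) manifest_size <- sum(counts)
    counts <- c(counts, discordant = unname(counts["a_unique"] +
                                              counts["b_unique"]))
  } else if (is.character(x)) {
    counts <- c(table(x))
    if (is.null(manifest_size)) manifest_size <- length(x)
  } else {
    counts <- unlist(x)
    if (is.null(manifest_size)) manifest_size <- sum(counts)
  }
  if (manifest_size <= 0) stop("zero manifest size")
  tot <- sum(counts[setdiff(names(counts), "discordant")])
  if (!inherits(x, "four_way_partition") && !is.character(x) &&
      tot != manifest_size && !is.null(manifest_size)) {
    # counts supplied with an explicit manifest size: allow partial tables
    tot <- manifest_size
  }
  data.frame(
    set = names(counts),
    count = as.integer(counts),
    percent = round(100 * as.numeric(counts) / manifest_size, 1),
    stringsAsFactors = FALSE
  )
}

#' Fold ratio between two counts
#'
#' @param a,b counts; returns `a / b` rounded to two decimals (NA with a
#'   warning when `b` is zero).
#' @export
fold_ratio <- function(a, b) {
  if (b == 0) {
    warning("zero denominator in fold ratio")
    return(NA_real_)
  }
  round(a / b, 2)
}
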