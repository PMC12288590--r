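#' Pipeline parameters
#'
#' Returns the full set of numeric constants used across the pipeline, with
#' the defaults used throughout: BLAT-style alignment qualification
#' (identity >= 0.90 over the aligned span and >= 40 of 50 matching bases,
#' gapless), the 11-mer/step-5 seed index with repeat masking at 1e6
#' occurrences, the 95% pangenome consensus fraction, the 10x per-sample
#' coverage filter, the |delta-beta| > 0.10 effect filter at FDR < 0.05 with
#' 1,000 permutations, 2-kb promoters/shores/shelves, and the classic CpG
#' island definition (>= 200 bp, GC > 50%, observed/expected CpG > 0.6).
#'
#' @param ... name-value pairs overriding individual defaults. Unknown names
#'   are an error, so typos cannot silently fall back to a default.
#' @return a named list of parameters with class `"methref_params"`.
#' @examples
#' p <- meth_params(coverage_min = 5)
#' p$identity_min
#' @export
meth_params <- function(...) {
  p <- list(
    identity_min      = 0.90,
    match_min         = 40L,
    tile_size         = 11L,
    step_size         = 5L,
    rep_match         = 1000000L,
    consensus_frac    = 0.95,
    coverage_min      = 10L,
    delta_min         = 0.10,
    fdr_max           = 0.05,
    n_perm            = 1000L,
    promoter_upstream = 2000L,
    shore_width       = 2000L,
    shelf_width       = 2000L,
    cgi_min_len       = 200L,
    cgi_gc_min        = 0.50,
    cgi_oe_min        = 0.6,
    cgi_max_n_frac    = 0.10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  stopifnot(
    p$identity_min > 0, p$identity_min <= 1,
    p$consensus_frac > 0, p$consensus_frac <= 1,
    p$cgi_gc_min > 0, p$cgi_gc_min <= 1,
    p$match_min > 0, p$tile_size > 0, p$step_size > 0,
    p$coverage_min > 0, p$n_perm >= 1,
    p$cgi_min_len > 0, p$promoter_upstream > 0
  )
  structure(p, class = "methref_params")
}
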