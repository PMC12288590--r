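## Readers and writers for every external format the pipeline touches.
## Internal coordinates are uniformly 0-based half-open; 1-based inputs
## (Illumina MAPINFO, Bismark coverage) are shifted exactly once here.

#' Read a FASTA file into an assembly
#'
#' Contigs are keyed by the first whitespace-delimited token of each header
#' line and sequences are upper-cased. Only `A`, `C`, `G`, `T`, `N` are
#' accepted; anything else is a format error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @param name assembly name; defaults to the file name without extension.
#' @return an `assembly`: a list with elements `name` and `contigs` (a named
#'   character vector of upper-case sequences).
#' @export
read_fasta <- function(path, name = sub("\\.(fa|fasta|fna)$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!length(lines) || !any(hdr)) stop("empty or header-less FASTA: ", path)
  if (!hdr[1]) stop("FASTA format error at line 1: sequence before first header")
  bad <- which(!hdr & grepl("[^ACGTNacgtn]", lines))
  if (length(bad)) {
    stop("FASTA format error at line ", bad[1],
         ": non-IUPAC character in sequence (allowed: A,C,G,T,N)")
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids)) {
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(
    split(lines[!hdr], grp[!hdr]),
    function(x) toupper(paste(x, collapse = "")),
    character(1)
  )
  contigs <- setNames(character(length(ids)), ids)
  contigs[as.integer(names(seqs))] <- seqs
  assembly(contigs, name = name)
}

#' Construct an assembly from named sequences
#'
#' @param contigs named character vector of upper-case DNA sequences.
#' @param name assembly name.
#' @return an object of class `assembly`.
#' @export
assembly <- function(contigs, name = "assembly") {
  stopifnot(is.character(contigs), length(contigs) > 0,
            !is.null(names(contigs)), all(nzchar(names(contigs))))
  structure(list(name = name, contigs = toupper(contigs)), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly> ", x$name, ": ", length(x$contigs), " contig(s), ",
      sum(nchar(x$contigs)), " bp\n", sep = "")
  invisible(x)
}

#' Write an assembly to FASTA
#'
#' @param x an `assembly`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x$contigs)) {
    s <- x$contigs[[nm]]
    writeLines(paste0(">", nm), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.read_delim_auto <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = header, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"", check.names = FALSE)
}

#' Read an Illumina-style probe manifest
#'
#' Expects delimited text (CSV or TSV) with at least the columns `probe_id`,
#' `sequence`, `design_type`, `contig`, `position_1based` (the 1-based
#' coordinate of the target CpG's cytosine, matching the Illumina MAPINFO
#' convention), and optionally `strand`. Sequences must be 50-mers over
#' `{A,C,G,T,R}`; the degenerate base `R` is only valid in Infinium type II
#' designs. The returned table stores a 0-based `target_pos`.
#'
#' @param path path to the manifest.
#' @return data.frame with columns `probe_id`, `sequence`, `design_type`,
#'   `contig`, `target_pos` (0-based), `strand`.
#' @export
read_probe_manifest <- function(path) {
  df <- .read_delim_auto(path)
  need <- c("probe_id", "sequence", "design_type", "contig", "position_1based")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  df$sequence <- toupper(df$sequence)
  bad <- grepl("[^ACGTR]", df$sequence)
  if (any(bad)) {
    stop("probe sequence with character outside {A,C,G,T,R}: ",
         df$probe_id[which(bad)[1]])
  }
  if (any(nchar(df$sequence) != 50L)) {
    stop("probe sequence not 50 nt: ",
         df$probe_id[which(nchar(df$sequence) != 50L)[1]])
  }
  r_in_I <- grepl("R", df$sequence) & df$design_type == "I"
  if (any(r_in_I)) {
    stop("degenerate base R in a type I probe: ", df$probe_id[which(r_in_I)[1]])
  }
  if (any(df$position_1based < 1)) {
    stop("non-positive target position: ",
         df$probe_id[which(df$position_1based < 1)[1]])
  }
  data.frame(
    probe_id = as.character(df$probe_id),
    sequence = df$sequence,
    design_type = as.character(df$design_type),
    contig = as.character(df$contig),
    target_pos = as.integer(df$position_1based) - 1L,
    strand = if ("strand" %in% names(df)) as.character(df$strand) else "+",
    stringsAsFactors = FALSE
  )
}

#' Read a Bismark-style cytosine coverage report
#'
#' Columns: contig, start (1-based), end, methylation percentage, count
#' methylated, count unmethylated. The beta value is recomputed from counts;
#' the percentage column is only cross-checked (a disagreement of more than
#' 0.5 percentage points raises a warning, and the counts win). Sites with
#' zero total count are retained with a missing beta.
#'
#' @param path path to the report.
#' @return data.frame with columns `contig`, `pos` (0-based position of the
#'   cytosine), `count_meth`, `count_unmeth`, `beta`.
#' @export
read_cytosine_report <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("cytosine report needs 6 columns, got ", ncol(df))
  names(df)[1:6] <- c("contig", "start", "end", "pct", "count_meth", "count_unmeth")
  if (any(df$count_meth < 0 | df$count_unmeth < 0)) {
    stop("negative count in cytosine report at row ",
         which(df$count_meth < 0 | df$count_unmeth < 0)[1])
  }
  total <- df$count_meth + df$count_unmeth
  beta <- ifelse(total > 0, df$count_meth / total, NA_real_)
  disagrees <- total > 0 & abs(df$pct - 100 * beta) > 0.5
  if (any(disagrees)) {
    warning(sum(disagrees), " row(s) with percentage disagreeing with counts",
            " by > 0.5 points; counts win")
  }
  data.frame(
    contig = as.character(df$contig),
    pos = as.integer(df$start) - 1L,
    count_meth = as.integer(df$count_meth),
    count_unmeth = as.integer(df$count_unmeth),
    beta = beta,
    stringsAsFactors = FALSE
  )
}

#' Read a BED file
#'
#' BED is consumed as 0-based half-open. Columns beyond the sixth are
#' ignored.
#'
#' @param path path to a BED file.
#' @return data.frame with `contig`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  cn <- c("contig", "start", "end", "name", "score", "strand")
  names(df) <- cn[seq_len(min(ncol(df), 6L))]
  df <- df[seq_len(min(ncol(df), 6L))]
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("invalid BED interval at row ",
         which(df$start < 0 | df$end <= df$start)[1])
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with at least `contig`, `start`, `end`; optional
#'   `name`, `score`, `strand` are written in BED column order.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("contig", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a TSV table with a header row
#'
#' `write_table()` and `read_table_tsv()` round-trip any data.frame of
#' atomic columns exactly (up to numeric print precision).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a UCSC chain file
#'
#' Parses the UCSC chain dialect (`chain score tName tSize tStrand tStart
#' tEnd qName qSize qStrand qStart qEnd id` followed by `size [dt dq]`
#' block lines). The "target" side of the chain header (tName) is treated as
#' the source assembly of the map, matching how liftOver chains are used.
#' Reverse-strand query blocks are normalised to forward coordinates at read
#' time and flagged `t_reversed`. Block sums are validated against the
#' header spans.
#'
#' @param path path to a chain file.
#' @return a `chain_map`: a data.frame of aligned blocks with columns
#'   `s_contig`, `s_start`, `s_end`, `t_contig`, `t_start`, `t_end`,
#'   `t_reversed`, plus attributes `source_sizes` and `target_sizes`.
#' @export
read_chain <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr_idx <- grep("^chain\\b", lines)
  if (!length(hdr_idx)) stop("no chain header in ", path)
  blocks <- list()
  s_sizes <- c(); t_sizes <- c()
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (h in seq_along(hdr_idx)) {
    f <- strsplit(lines[hdr_idx[h]], "\\s+")[[1]]
    if (length(f) < 12L) stop("malformed chain header at line ", hdr_idx[h])
    tName <- f[3]; tSize <- as.numeric(f[4]); tStrand <- f[5]
    tStart <- as.numeric(f[6]); tEnd <- as.numeric(f[7])
    qName <- f[8]; qSize <- as.numeric(f[9]); qStrand <- f[10]
    qStart <- as.numeric(f[11]); qEnd <- as.numeric(f[12])
    if (tStrand != "+") stop("chain with tStrand '-' is not valid UCSC chain")
    body <- lines[(hdr_idx[h] + 1L):(bounds[h + 1L] - 1L)]
    mat <- lapply(strsplit(body, "\\s+"), as.numeric)
    sizes <- vapply(mat, `[`, numeric(1), 1)
    dt <- vapply(mat, function(x) if (length(x) >= 2) x[2] else 0, numeric(1))
    dq <- vapply(mat, function(x) if (length(x) >= 3) x[3] else 0, numeric(1))
    if (sum(sizes) + sum(dt) != tEnd - tStart ||
        sum(sizes) + sum(dq) != qEnd - qStart) {
      stop("chain block sizes do not sum to header spans (chain at line ",
           hdr_idx[h], ")")
    }
    s_off <- tStart + cumsum(c(0, (sizes + dt)[-length(sizes)]))
    q_off <- qStart + cumsum(c(0, (sizes + dq)[-length(sizes)]))
    if (qStrand == "+") {
      bl <- data.frame(
        s_contig = tName, s_start = s_off, s_end = s_off + sizes,
        t_contig = qName, t_start = q_off, t_end = q_off + sizes,
        t_reversed = FALSE, stringsAsFactors = FALSE
      )
    } else {
      # q coordinates are on the reversed query; normalise to forward
      bl <- data.frame(
        s_contig = tName, s_start = s_off, s_end = s_off + sizes,
        t_contig = qName, t_start = qSize - (q_off + sizes),
        t_end = qSize - q_off,
        t_reversed = TRUE, stringsAsFactors = FALSE
      )
    }
    blocks[[h]] <- bl
    s_sizes[tName] <- tSize
    t_sizes[qName] <- qSize
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$s_contig, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  # non-overlap in source coordinates, per contig
  by_c <- split(out, out$s_contig)
  for (b in by_c) {
    if (nrow(b) > 1 && any(b$s_start[-1] < b$s_end[-nrow(b)])) {
      stop("chain blocks overlap in source coordinates on ", b$s_contig[1])
    }
  }
  structure(out, source_sizes = s_sizes, target_sizes = t_sizes,
            class = c("chain_map", "data.frame"))
}

#' Write a chain map as a UCSC chain file
#'
#' One chain per source contig; forward-strand only (the synthetic-data
#' generator emits forward chains).
#'
#' @param chain a `chain_map` as returned by [read_chain()] or emitted by
#'   the assembly-panel generator.
#' @param path output path.
#' @export
write_chain <- function(chain, path) {
  stopifnot(!any(chain$t_reversed))
  s_sizes <- attr(chain, "source_sizes")
  t_sizes <- attr(chain, "target_sizes")
  con <- file(path, "w")
  on.exit(close(con))
  id <- 0L
  for (sc in unique(chain$s_contig)) {
    b <- chain[chain$s_contig == sc, , drop = FALSE]
    b <- b[order(b$s_start), , drop = FALSE]
    id <- id + 1L
    tc <- b$t_contig[1]
    writeLines(sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
                       sc, s_sizes[[sc]], b$s_start[1], b$s_end[nrow(b)],
                       tc, t_sizes[[tc]], b$t_start[1], b$t_end[nrow(b)], id),
               con)
    sizes <- b$s_end - b$s_start
    if (nrow(b) > 1) {
      dt <- b$s_start[-1] - b$s_end[-nrow(b)]
      dq <- b$t_start[-1] - b$t_end[-nrow(b)]
      writeLines(paste(sizes[-nrow(b)], dt, dq), con)
    }
    writeLines(as.character(sizes[nrow(b)]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path path to a GMT file (set name, description, then member genes,
#'   tab separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
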