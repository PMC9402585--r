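## Readers and writers for every external representation the pipeline touches.
## Canonical dialect: tab-separated tables with a header row and '#' comments,
## GMT for gene sets, two-column (+ optional weight) edge lists for networks.
## Gene identity is the case-preserved symbol string throughout.

read_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_fmt("%s: missing required column(s): %s", what,
             paste(miss, collapse = ", "))
  }
}

## Format numbers at 10 significant digits for round-trip-stable TSV output.
fmt_num <- function(x) sprintf("%.10g", x)

#' Read a MAF-subset mutation table
#'
#' Reads a tab-separated table of tumor/normal variant calls. Required
#' columns: `sample_id`, `gene`, `chrom`, `pos`, `ref`, `alt`, plus variant
#' allele frequencies given either directly (`tumor_vaf`, `normal_vaf`) or as
#' read counts (`tumor_ref_reads`/`tumor_alt_reads`,
#' `normal_ref_reads`/`normal_alt_reads`). When read counts are present the
#' VAF is recomputed as `alt / (alt + ref)` and overrides any VAF column.
#' Optional columns: `copy_number_state` (default 2) and `purity` (default 1).
#'
#' Validation is strict: out-of-range VAFs, non-positive positions, negative
#' read counts or purities outside (0, 1] raise an error naming the offending
#' rows; no row is ever silently dropped.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a `data.frame` with one validated row per variant.
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample_id", "gene", "chrom", "pos", "ref", "alt"),
                  "mutation table")
  has_counts <- function(side) {
    all(c(paste0(side, "_ref_reads"), paste0(side, "_alt_reads")) %in% names(df))
  }
  recompute <- function(side) {
    ref <- df[[paste0(side, "_ref_reads")]]
    alt <- df[[paste0(side, "_alt_reads")]]
    if (any(ref < 0 | alt < 0, na.rm = TRUE)) {
      stop_fmt("mutation table: negative %s read counts", side)
    }
    depth <- ref + alt
    if (nrow(df) && any(depth == 0)) {
      stop_fmt("mutation table: zero %s depth at row(s) %s", side,
               paste(which(depth == 0), collapse = ", "))
    }
    alt / depth
  }
  for (side in c("tumor", "normal")) {
    vcol <- paste0(side, "_vaf")
    if (has_counts(side)) {
      df[[vcol]] <- recompute(side)
    } else if (!vcol %in% names(df)) {
      stop_fmt("mutation table: missing required column(s): %s (or %s read counts)",
               vcol, side)
    }
  }
  if (!"copy_number_state" %in% names(df)) {
    df$copy_number_state <- rep(2L, nrow(df))
  }
  if (!"purity" %in% names(df)) df$purity <- rep(1, nrow(df))
  if (nrow(df)) {
    bad_rows <- function(cond, msg) {
      if (any(cond, na.rm = TRUE)) {
        stop_fmt("mutation table: %s at row(s) %s", msg,
                 paste(head(which(cond), 5L), collapse = ", "))
      }
    }
    bad_rows(df$tumor_vaf < 0 | df$tumor_vaf > 1, "tumor VAF outside [0, 1]")
    bad_rows(df$normal_vaf < 0 | df$normal_vaf > 1, "normal VAF outside [0, 1]")
    bad_rows(df$pos < 1 | df$pos != round(df$pos), "invalid position (< 1)")
    bad_rows(df$purity <= 0 | df$purity > 1, "purity outside (0, 1]")
  }
  df$pos <- as.integer(df$pos)
  df$copy_number_state <- as.integer(df$copy_number_state)
  df
}

#' Read a clinical follow-up table
#'
#' Columns: `sample_id`, `dfs_time` (disease-free survival, months),
#' `dfs_event` (1 = recurred, 0 = censored), optional `er_status`
#' (`positive`/`negative`/`unknown`, default `unknown`).
#'
#' @param path path to a tab-separated file.
#' @return validated `data.frame`, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample_id", "dfs_time", "dfs_event"), "clinical table")
  if (anyDuplicated(df$sample_id)) {
    stop_fmt("clinical table: duplicate sample_id '%s'",
             df$sample_id[anyDuplicated(df$sample_id)])
  }
  if (nrow(df)) {
    if (any(df$dfs_time < 0)) stop_fmt("clinical table: dfs_time < 0")
    if (!all(df$dfs_event %in% c(0L, 1L))) {
      stop_fmt("clinical table: dfs_event must be 0/1")
    }
  }
  if (!"er_status" %in% names(df)) df$er_status <- "unknown"
  ok <- df$er_status %in% c("positive", "negative", "unknown")
  if (!all(ok)) stop_fmt("clinical table: invalid er_status '%s'", df$er_status[!ok][1L])
  df$dfs_event <- as.integer(df$dfs_event)
  df
}

#' Read a genes-by-samples expression matrix
#'
#' First column `gene`, remaining columns one per sample. Duplicate gene or
#' sample identifiers are errors.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  require_columns(df, "gene", "expression matrix")
  if (anyDuplicated(df$gene)) {
    stop_fmt("expression matrix: duplicate gene '%s'", df$gene[anyDuplicated(df$gene)])
  }
  samples <- setdiff(names(df), "gene")
  if (anyDuplicated(samples)) stop_fmt("expression matrix: duplicate sample ids")
  m <- as.matrix(df[, samples, drop = FALSE])
  if (!is.numeric(m)) stop_fmt("expression matrix: non-numeric values")
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression
#' @param mat numeric genes-by-samples matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), apply(mat, 2L, fmt_num),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read an undirected edge list
#'
#' Columns `gene1`, `gene2` and optionally `weight`. Edges are stored
#' symmetrically (endpoint order canonicalized), duplicate edges collapsed,
#' and self-loops dropped with a warning reporting their count.
#'
#' @param path path to a tab-separated file.
#' @return `data.frame` with columns `gene1`, `gene2` (and `weight` if given),
#'   `gene1 < gene2` for every row.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("gene1", "gene2"), "edge list")
  canonicalize_edges(df)
}

canonicalize_edges <- function(df) {
  loops <- df$gene1 == df$gene2
  if (any(loops)) {
    warn_fmt("edge list: dropped %d self-loop(s)", sum(loops))
    df <- df[!loops, , drop = FALSE]
  }
  a <- pmin(df$gene1, df$gene2)
  b <- pmax(df$gene1, df$gene2)
  df$gene1 <- a
  df$gene2 <- b
  dup <- duplicated(paste(a, b, sep = "\r"))
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_edge_list
#' @param edges edge `data.frame` as returned by `read_edge_list()`.
#' @export
write_edge_list <- function(edges, path) {
  if ("weight" %in% names(edges)) edges$weight <- fmt_num(edges$weight)
  write_tsv(edges[, intersect(c("gene1", "gene2", "weight"), names(edges))], path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT semantics: one set per line, fields `name`, `description`,
#' then member gene symbols, tab-separated. Duplicate members within a set
#' are deduplicated (order preserved); duplicate set names and lines with
#' fewer than three fields are errors.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) stop_fmt("GMT line %d: fewer than 3 fields", i)
    nm <- f[[1L]]
    if (nm %in% names(sets)) stop_fmt("GMT line %d: duplicate set name '%s'", i, nm)
    sets[[nm]] <- unique(f[-(1:2)])
    desc[[nm]] <- f[[2L]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a netMatrix of propagation scores
#'
#' The netMatrix is a genes-by-samples matrix of normalized heating scores,
#' written as a TSV with a leading `gene` column at 10 significant digits, so
#' a write/read round trip reproduces values within 1e-9.
#'
#' @param path file path.
#' @return numeric matrix (genes x samples).
#' @export
read_netmatrix <- function(path) read_expression(path)

#' @rdname read_netmatrix
#' @param mat numeric genes-by-samples matrix.
#' @export
write_netmatrix <- function(mat, path) write_expression(mat, path)

#' Read a variant annotation table
#'
#' One row per variant with the variant key (`sample_id`, `gene`, `chrom`,
#' `pos`, `ref`, `alt`) and any subset of the annotator columns
#' `cravat_score`, `mutationtaster_call`, `cadd_cscore`, `polyphen_call`,
#' `sift_call` (empty strings read as absent). At least one annotator column
#' must exist in the file.
#'
#' @param path path to a tab-separated file.
#' @return `data.frame` with `NA` for absent annotator fields.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample_id", "gene"), "annotation table")
  ann_cols <- intersect(annotator_columns(), names(df))
  if (!length(ann_cols)) {
    stop_fmt("annotation table: no annotator column present (expected any of %s)",
             paste(annotator_columns(), collapse = ", "))
  }
  for (col in ann_cols) {
    if (is.character(df[[col]])) df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  df
}

annotator_columns <- function() {
  c("cravat_score", "mutationtaster_call", "cadd_cscore",
    "polyphen_call", "sift_call")
}
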