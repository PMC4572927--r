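#' Read a gene-level expression table
#'
#' Reads a TSV with a header row (`gene_id` column plus one column per
#' sample) into an [expression_matrix()]. Blank and `NA` cells on the linear
#' scale are read as 0 ("not expressed"); on the log2 scale they stay `NA`.
#'
#' @param path TSV path.
#' @param scale `"linear"` or `"log2"`.
#' @param normalization `"count"`, `"FPKM"` or `"TMM"`.
#' @param groups optional named character vector (sample id -> group) or
#'   path to a two-column TSV `sample<TAB>group`.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path,
                                  scale = c("linear", "log2"),
                                  normalization = c("count", "FPKM", "TMM"),
                                  groups = NULL) {
  scale <- match.arg(scale)
  normalization <- match.arg(normalization)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2L)
    stop("format error: expected a gene_id column plus >=1 sample column")
  header <- names(raw)
  if (any(is.na(header)) || any(header == "") ||
      all(!is.na(suppressWarnings(as.numeric(header[-1])))))
    stop("format error: missing or numeric header row in ", path)
  gid <- raw[[1L]]
  if (anyDuplicated(gid)) {
    dup <- unique(gid[duplicated(gid)])
    stop("duplicated gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("parse error: non-numeric cell at row %d (gene %s), column %s",
                 bad[1, 1], gid[bad[1, 1]], header[-1][bad[1, 2]]))
  }
  if (scale == "linear") num[is.na(num)] <- 0
  dimnames(num) <- list(gid, header[-1])
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gm <- utils::read.delim(groups, header = TRUE, colClasses = "character")
    groups <- stats::setNames(gm[[2L]], gm[[1L]])
  }
  expression_matrix(num, scale = scale, normalization = normalization,
                    groups = groups)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]. Numbers are written with 6
#' significant digits so that write-then-read round-trips exactly at the
#' declared precision and repeated runs are byte-identical.
#'
#' @param expr an [expression_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = rownames(expr$values),
                   apply(expr$values, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", colnames(expr$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from TSV or BED
#'
#' TSV input needs a header with `gene_id` and `chromosome` columns and may
#' carry `band`, `length_bp` and `start`; BED4 input (`chrom start end name`,
#' 0-based half-open, no header) supplies chromosome, start and length.
#' Chromosome labels are normalized to `"chr*"`; genes outside the assembly's
#' chr1..chrN + chrX universe are retained but flagged excluded from the X:A
#' analysis.
#'
#' @param path input path.
#' @param assembly `"mouse"` or `"human"`.
#' @param format `"auto"` (by extension), `"tsv"` or `"bed"`.
#' @param one_based_start set `TRUE` when a TSV supplies 1-based start
#'   coordinates; they are converted to 0-based on read.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path, assembly = c("mouse", "human"),
                                 format = c("auto", "tsv", "bed"),
                                 one_based_start = FALSE) {
  assembly <- match.arg(assembly)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    bed <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) stop("BED input needs >= 4 columns")
    df <- data.frame(gene_id = as.character(bed[[4L]]),
                     chromosome = bed[[1L]],
                     start = as.numeric(bed[[2L]]),
                     length_bp = as.numeric(bed[[3L]]) - as.numeric(bed[[2L]]),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (isTRUE(one_based_start) && !is.null(df$start))
      df$start <- df$start - 1
  }
  gene_annotation(df, assembly = assembly)
}

#' Join expression matrix and annotation on gene id
#'
#' The joined universe is exactly the intersection of gene ids; counts of
#' genes dropped from each side are reported via `message()` and attached as
#' the `join_log` attribute, so no gene is lost silently.
#'
#' @param expr an [expression_matrix()].
#' @param annotation a [gene_annotation()].
#' @return list with the subset `expr`, aligned `annotation` and `join_log`.
#' @export
join_annotation <- function(expr, annotation) {
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(annotation, "gene_annotation"))
  common <- intersect(rownames(expr$values), annotation$gene_id)
  log <- c(n_expression = nrow(expr$values),
           n_annotation = nrow(annotation),
           n_joined = length(common),
           n_expr_only = nrow(expr$values) - length(common),
           n_annot_only = nrow(annotation) - length(common))
  message(sprintf("annotation join: %d genes kept (%d expression-only, %d annotation-only dropped)",
                  log[["n_joined"]], log[["n_expr_only"]],
                  log[["n_annot_only"]]))
  sub <- expression_matrix(expr$values[common, , drop = FALSE],
                           scale = expr$scale,
                           normalization = expr$normalization,
                           groups = expr$groups)
  ann <- annotation[match(common, annotation$gene_id), ]
  rownames(ann) <- NULL
  list(expr = sub, annotation = ann, join_log = log)
}

#' Read a UCSC-style cytoBand file
#'
#' Expects the five UCSC columns `chrom start end band stain` (0-based
#' half-open, no header). Bands on each chromosome must be non-overlapping;
#' they are returned sorted by start.
#'
#' @param path cytoBand file path.
#' @return data.frame of class `cytoband_map` with columns `chromosome`,
#'   `start`, `end`, `band`.
#' @export
read_cytobands <- function(path) {
  cb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(cb) < 4L) stop("cytoBand input needs >= 4 columns")
  df <- data.frame(chromosome = normalize_chromosome(cb[[1L]]),
                   start = as.numeric(cb[[2L]]),
                   end = as.numeric(cb[[3L]]),
                   band = as.character(cb[[4L]]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$start), ]
  for (chr in unique(df$chromosome)) {
    d <- df[df$chromosome == chr, ]
    if (nrow(d) > 1L && any(d$end[-nrow(d)] > d$start[-1L]))
      stop("overlapping cytobands on ", chr)
  }
  rownames(df) <- NULL
  structure(df, class = c("cytoband_map", "data.frame"))
}

#' Assign cytobands to genes by start coordinate
#'
#' Half-open interval convention: a gene whose start equals a band's `end`
#' belongs to the next band. Genes without a start coordinate or without a
#' covering band keep `NA`.
#'
#' @param annotation a [gene_annotation()].
#' @param bands a [read_cytobands()] map.
#' @return the annotation with its `band` column filled in.
#' @export
assign_cytobands <- function(annotation, bands) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(bands, "cytoband_map"))
  for (chr in unique(bands$chromosome)) {
    b <- bands[bands$chromosome == chr, ]
    idx <- which(annotation$chromosome == chr & !is.na(annotation$start))
    if (!length(idx)) next
    pos <- findInterval(annotation$start[idx], b$start)
    hit <- pos >= 1L & annotation$start[idx] < b$end[pmax(pos, 1L)]
    annotation$band[idx[hit]] <- b$band[pos[hit]]
  }
  annotation
}

# Write a data.frame as TSV with fixed 6-significant-digit numeric
# formatting (byte-stable across runs).
write_tsv_6g <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write a flat key-value summary file (sorted keys, byte-stable).
write_summary_kv <- function(kv, path) {
  keys <- names(kv)
  vals <- vapply(kv, function(v) {
    if (is.numeric(v)) paste(fmt_num(v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1))
  lines <- paste(keys, vals, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write stage results as deterministic TSV plus a key-value summary
#'
#' Every stage result (ratio curves, per-chromosome ratio matrices,
#' frequency tables, DE records, enrichment tables, or any plain
#' data.frame) is written as `<name>.tsv` with 6-significant-digit numeric
#' formatting, plus `<name>_summary.tsv` holding flat key-value metadata.
#' Re-running with identical inputs and seed produces byte-identical files.
#'
#' @param results a stage result (data.frame-based).
#' @param out_dir output directory (created if needed).
#' @param name file stem; defaults to the result's class.
#' @return character vector of written paths, invisibly.
#' @export
write_result_tables <- function(results, out_dir, name = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  name <- name %||% setdiff(class(results), "data.frame")[1] %||% "result"
  df <- as.data.frame(results)
  main <- file.path(out_dir, paste0(name, ".tsv"))
  write_tsv_6g(df, main)
  meta <- attributes(results)
  meta <- meta[setdiff(names(meta), c("names", "row.names", "class"))]
  kv <- list(n_rows = nrow(df))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.atomic(v)) kv[[k]] <- v
    else if (is.list(v)) for (kk in names(v)) {
      if (is.atomic(v[[kk]])) kv[[paste(k, kk, sep = ".")]] <- v[[kk]]
    }
  }
  smry <- file.path(out_dir, paste0(name, "_summary.tsv"))
  write_summary_kv(kv, smry)
  invisible(c(main, smry))
}
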