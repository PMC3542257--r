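# Readers and writers for the exchanged plain-text formats. Everything is
# TSV with "NA" for missing values; readers accept comma decimal separators
# (as printed in some source tables), writers always emit periods.

#' @importFrom data.table fread fwrite as.data.table data.table :=
NULL
.datatable.aware <- TRUE

# turn comma-decimal character columns into numerics where that converts
# every non-missing entry cleanly
convert_decimal_commas <- function(df) {
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      x <- gsub(",", ".", df[[j]], fixed = TRUE)
      num <- suppressWarnings(as.numeric(x))
      if (!any(is.na(num) & !is.na(df[[j]]) & nzchar(df[[j]])))
        df[[j]] <- num
    }
  }
  df
}

#' Read a genome annotation from BED6 or a GFF3 subset
#'
#' BED is the package's native 0-based half-open convention; GFF3 records
#' (1-based inclusive) are converted on input. Features with a strand other
#' than `+`/`-` are rejected with their line number. For GFF3, types `gene`
#' and `CDS` map to kind `coding`, everything else to `ncRNA`; for BED every
#' feature is `coding` unless a category sidecar says otherwise.
#'
#' @param path file path.
#' @param format `"bed6"` or `"gff3"`.
#' @param categories_path optional TSV sidecar `gene_id`, `category`.
#' @param genome_length optional; default: max feature end.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("bed6", "gff3"),
                            categories_path = NULL, genome_length = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  if (format == "bed6") {
    bad <- which(vapply(rows, length, 0L) < 6)
    if (length(bad) > 0)
      stop(sprintf("malformed BED6 record at line %d of %s", lineno[bad[1]], path),
           call. = FALSE)
    feats <- data.frame(
      id = vapply(rows, `[`, "", 4),
      chrom = vapply(rows, `[`, "", 1),
      start = as.numeric(vapply(rows, `[`, "", 2)),
      end = as.numeric(vapply(rows, `[`, "", 3)),
      strand = vapply(rows, `[`, "", 6),
      stringsAsFactors = FALSE)
    feats$kind <- "coding"
  } else {
    bad <- which(vapply(rows, length, 0L) < 9)
    if (length(bad) > 0)
      stop(sprintf("malformed GFF3 record at line %d of %s", lineno[bad[1]], path),
           call. = FALSE)
    attrs <- vapply(rows, `[`, "", 9)
    id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", attrs)
    type <- vapply(rows, `[`, "", 3)
    feats <- data.frame(
      id = id,
      chrom = vapply(rows, `[`, "", 1),
      start = as.numeric(vapply(rows, `[`, "", 4)) - 1,  # to 0-based
      end = as.numeric(vapply(rows, `[`, "", 5)),
      strand = vapply(rows, `[`, "", 7),
      kind = ifelse(type %in% c("gene", "CDS"), "coding", "ncRNA"),
      stringsAsFactors = FALSE)
  }
  badstrand <- which(!feats$strand %in% c("+", "-"))
  if (length(badstrand) > 0)
    stop(sprintf("unknown strand '%s' at line %d of %s",
                 feats$strand[badstrand[1]], lineno[badstrand[1]], path),
         call. = FALSE)
  feats$category <- NA_character_
  if (!is.null(categories_path)) {
    cm <- read_categories(categories_path)
    first <- cm[!duplicated(cm$gene_id), ]
    feats$category <- first$category[match(feats$id, first$gene_id)]
    if ("kind" %in% names(cm))
      feats$kind <- ifelse(is.na(cm$kind[match(feats$id, cm$gene_id)]),
                           feats$kind, cm$kind[match(feats$id, cm$gene_id)])
  }
  genome_annotation(feats, genome_length = genome_length %||% max(feats$end))
}

#' Write a genome annotation as BED6 plus a category sidecar
#' @param annotation a `genome_annotation`.
#' @param path BED output path.
#' @param categories_path optional sidecar TSV (`gene_id`, `category`,
#'   `kind`).
#' @return invisibly, `path`.
#' @export
write_annotation <- function(annotation, path, categories_path = NULL) {
  bed <- data.frame(annotation$chrom, as.integer(annotation$start),
                    as.integer(annotation$end), annotation$id, 0L,
                    annotation$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  if (!is.null(categories_path))
    fwrite(data.frame(gene_id = annotation$id, kind = annotation$kind,
                      category = annotation$category),
           categories_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a gene-to-category membership table
#'
#' Expects TSV columns `gene_id` and `category`; category names may be full
#' hierarchy paths with `" * "` separators and are kept verbatim.
#'
#' @param path file path.
#' @return data.frame `gene_id`, `category` (plus any extra columns).
#' @export
read_categories <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", na.strings = "NA"))
  assert_that(all(c("gene_id", "category") %in% names(df)),
              "category table needs gene_id and category columns")
  df
}

#' Read a probe-intensity table
#'
#' TSV with `chrom`, `position`, `strand` and one intensity column per
#' array. Intensities are assumed log2; with `linear = TRUE` they are
#' converted by `log2(pmax(x, pseudo))`.
#'
#' @param path file path.
#' @param linear intensities are on the linear scale.
#' @param pseudo floor applied before `log2` when `linear`.
#' @return data.frame suitable for [aggregate_gene_level()].
#' @export
read_probe_table <- function(path, linear = FALSE, pseudo = 1) {
  df <- convert_decimal_commas(as.data.frame(fread(path, sep = "\t",
                                                   na.strings = "NA")))
  assert_that(all(c("chrom", "position", "strand") %in% names(df)),
              "probe table needs chrom, position, strand columns")
  if (linear) {
    for (j in setdiff(names(df), c("chrom", "position", "strand", "probe_id")))
      df[[j]] <- log2(pmax(df[[j]], pseudo))
  }
  df
}

#' Write probe-level signals as a probe TSV
#' @param signals a `probe_signals` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_probe_table <- function(signals, path) {
  out <- cbind(signals$layout[, c("chrom", "position", "strand")],
               as.data.frame(signals$values))
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an array design table (`array_id`, `condition`, `replicate`)
#' @param path file path.
#' @return data.frame.
#' @export
read_design <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t"))
  assert_that(all(c("array_id", "condition", "replicate") %in% names(df)),
              "design table needs array_id, condition, replicate columns")
  assert_that(all(df$condition %in% c("depleted", "induced")),
              "conditions must be 'depleted' or 'induced'")
  df
}

#' Write a gene x array expression matrix as TSV (masked cells as NA)
#' @param mat an `expression_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path) {
  out <- data.frame(id = rownames(mat$values), mat$values,
                    check.names = FALSE)
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV written by [write_expression_matrix()]
#' @param path matrix TSV path.
#' @param design design table (data.frame or path).
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, design) {
  if (is.character(design)) design <- read_design(design)
  df <- convert_decimal_commas(as.data.frame(fread(path, sep = "\t",
                                                   na.strings = "NA")))
  v <- as.matrix(df[, design$array_id, drop = FALSE])
  rownames(v) <- df$id
  expression_matrix(v, design)
}

#' Write / read a differential table TSV
#' @param diff a `diff_table`.
#' @param path file path.
#' @return invisibly `path`; the reader returns a `diff_table`.
#' @export
write_diff_table <- function(diff, path) {
  fwrite(as.data.frame(diff), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_diff_table
#' @export
read_diff_table <- function(path) {
  df <- convert_decimal_commas(as.data.frame(fread(path, sep = "\t",
                                                   na.strings = "NA")))
  structure(df, class = c("diff_table", "data.frame"))
}

#' Read per-transcript decay series from a long-format TSV
#'
#' Expects columns `transcript_id`, `condition`, `time_min`, `intensity`.
#'
#' @param path file path.
#' @return named list of [decay_series()] (name:
#'   `"<transcript>:<condition>"`).
#' @export
read_decay_table <- function(path) {
  df <- convert_decimal_commas(as.data.frame(fread(path, sep = "\t",
                                                   na.strings = "NA")))
  assert_that(all(c("transcript_id", "condition", "time_min", "intensity")
                  %in% names(df)),
              "decay table needs transcript_id, condition, time_min, intensity")
  sp <- split(df, paste(df$transcript_id, df$condition, sep = ":"))
  lapply(sp, function(g) {
    g <- g[order(g$time_min), ]
    decay_series(data.frame(time = g$time_min, intensity = g$intensity),
                 transcript_id = g$transcript_id[1], condition = g$condition[1])
  })
}
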