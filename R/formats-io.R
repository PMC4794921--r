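## Readers and writers for the standard genomic and tabular formats consumed
## by the pipeline: BED3/BED5/narrowPeak, BEDPE loops, gene annotation (TSV or
## GFF3), TSV expression matrices and YAML/JSON configuration.
##
## Coordinate convention: everything inside the package is 0-based half-open.
## BED dialects already are; GFF3 (1-based inclusive) is converted on load.

split_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

parse_int_col <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("%s: line %d: malformed %s field '%s'",
                 path, lineno[bad][1L], what, x[bad][1L]))
  }
  v
}

#' Read a BED or narrowPeak file as a region set
#'
#' Supports 3+ column BED (optional 5th column stored as `score`) and
#' 10-column ENCODE narrowPeak, whose 10th field (summit offset from start;
#' -1 for unknown) is stored as `summit` and whose 7th field (signalValue)
#' is stored as `score`.
#'
#' @param path Path to a BED/narrowPeak file. `track`/`browser`/comment lines
#'   are skipped.
#' @return A region set `data.frame` (see [regions()]), rows in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- split_tsv_lines(path)
  nf <- lengths(p$fields)
  if (length(nf) == 0L) {
    return(regions(character(0), integer(0), integer(0)))
  }
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    stop(sprintf("%s: line %d: expected >= 3 tab-separated BED fields, got %d",
                 path, p$lineno[i], nf[i]))
  }
  get <- function(k) vapply(p$fields, function(f) {
    if (length(f) >= k) f[[k]] else NA_character_
  }, character(1))
  chrom <- get(1L)
  start <- parse_int_col(get(2L), p$lineno, path, "start")
  end <- parse_int_col(get(3L), p$lineno, path, "end")
  bad <- end <= start
  if (any(bad)) {
    stop(sprintf("%s: line %d: end (%d) must be greater than start (%d)",
                 path, p$lineno[bad][1L], end[bad][1L], start[bad][1L]))
  }
  score <- rep(NA_real_, length(chrom))
  summit <- rep(NA_integer_, length(chrom))
  if (all(nf >= 10L)) { # narrowPeak: signalValue col 7, summit offset col 10
    score <- suppressWarnings(as.numeric(get(7L)))
    summit <- parse_int_col(get(10L), p$lineno, path, "summit")
    summit[summit < 0L] <- NA_integer_
  } else if (all(nf >= 5L)) {
    score <- suppressWarnings(as.numeric(get(5L)))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   summit = summit, score = score, stringsAsFactors = FALSE)
  validate_regions(df, what = path)
  df
}

#' Write a region set as BED or narrowPeak
#'
#' @param df A region set (see [regions()]).
#' @param path Output path.
#' @param format `"auto"` writes narrowPeak when any summit is present, BED5
#'   when any score is present, else BED3.
#' @param name Optional name column (narrowPeak/BED name field); defaults to
#'   `region_<i>`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, format = c("auto", "bed3", "bed5", "narrowPeak"),
                      name = NULL) {
  validate_regions(df)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (nrow(df) && any(!is.na(df$summit))) "narrowPeak"
      else if (nrow(df) && any(!is.na(df$score))) "bed5" else "bed3"
  }
  if (is.null(name)) name <- sprintf("region_%d", seq_len(nrow(df)))
  score <- ifelse(is.na(df$score), 0, df$score)
  out <- switch(format,
    bed3 = df[, c("chrom", "start", "end")],
    bed5 = cbind(df[, c("chrom", "start", "end")], name = name, score = score),
    narrowPeak = cbind(df[, c("chrom", "start", "end")], name = name,
                       score = 0L, strand = ".", signalValue = score,
                       pValue = -1, qValue = -1,
                       peak = ifelse(is.na(df$summit), -1L, df$summit)))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin-interaction loops (BEDPE)
#'
#' Anchor order is canonicalized so that a loop and its anchor-swapped twin
#' compare equal. Trans-chromosomal pairs are rejected unless
#' `allow_trans = TRUE`.
#'
#' @param path Path to a BEDPE file (>= 6 columns).
#' @param allow_trans Keep loops whose anchors lie on different chromosomes?
#' @return A `loop_set` data.frame with columns `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`.
#' @export
read_loops <- function(path, allow_trans = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- split_tsv_lines(path)
  nf <- lengths(p$fields)
  if (any(nf < 6L)) {
    i <- which(nf < 6L)[1L]
    stop(sprintf("%s: line %d: expected >= 6 BEDPE fields, got %d",
                 path, p$lineno[i], nf[i]))
  }
  get <- function(k) vapply(p$fields, `[[`, character(1), k)
  df <- data.frame(chromA = get(1L),
                   startA = parse_int_col(get(2L), p$lineno, path, "startA"),
                   endA = parse_int_col(get(3L), p$lineno, path, "endA"),
                   chromB = get(4L),
                   startB = parse_int_col(get(5L), p$lineno, path, "startB"),
                   endB = parse_int_col(get(6L), p$lineno, path, "endB"),
                   stringsAsFactors = FALSE)
  loop_set(df, allow_trans = allow_trans)
}

#' Construct a validated loop set
#'
#' @param df Data frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB` (0-based half-open anchors).
#' @param allow_trans Keep trans-chromosomal pairs?
#' @return A `loop_set` data.frame with canonicalized anchor order.
#' @export
loop_set <- function(df, allow_trans = FALSE) {
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  stopifnot(all(need %in% names(df)))
  df <- df[, need]
  if (nrow(df)) {
    if (any(df$endA <= df$startA) || any(df$endB <= df$startB)) {
      stop("loop anchors must have end > start")
    }
    trans <- df$chromA != df$chromB
    if (any(trans) && !allow_trans) {
      stop("trans-chromosomal loop(s) present (anchors on different ",
           "chromosomes); set allow_trans = TRUE to keep them")
    }
    # canonical anchor order: (chrom, start, end) of A <= of B
    swap <- with(df, chromA > chromB |
                   (chromA == chromB & (startA > startB |
                                          (startA == startB & endA > endB))))
    if (any(swap)) {
      tmp <- df[swap, c("chromA", "startA", "endA")]
      df[swap, c("chromA", "startA", "endA")] <-
        df[swap, c("chromB", "startB", "endB")]
      df[swap, c("chromB", "startB", "endB")] <- tmp
    }
  }
  rownames(df) <- NULL
  class(df) <- c("loop_set", "data.frame")
  df
}

#' Write a loop set as BEDPE
#' @param loops A `loop_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  write.table(as.data.frame(loops), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix with sample group labels
#'
#' @param values Numeric matrix of log2 intensities; rownames are transcript
#'   cluster or gene ids, colnames are sample ids.
#' @param groups Named character vector mapping every sample id to its group
#'   label.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            nrow(values) == 0L || !is.null(rownames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicated row id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must all be finite")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("sample(s) missing from the group mapping: ",
         paste(missing, collapse = ", "))
  }
  obj <- list(values = values,
              groups = setNames(as.character(groups[colnames(values)]),
                                colnames(values)))
  class(obj) <- "expression_matrix"
  obj
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d rows x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a TSV expression matrix
#'
#' The file must have a header of sample ids and row ids in the first column.
#' Every sample must appear in `groups`; duplicated row ids are rejected.
#'
#' @param path Path to a tab-separated file.
#' @param groups Named character vector mapping sample id to group label.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, groups) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicated row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric expression values")
  rownames(m) <- ids
  expression_matrix(m, groups)
}

#' Write an expression matrix as TSV
#' @param em An [expression_matrix()].
#' @param path Output path; row ids go into a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene annotation
#'
#' @param genes Data frame with one row per gene: `gene_id`, `chrom`,
#'   `strand` (`+`/`-`), `tss` (0-based bp) and optionally `start`, `end`
#'   (gene body, 0-based half-open).
#' @param clusters Optional data frame mapping `cluster_id` to `gene_id`
#'   (many-to-one). Defaults to one cluster per gene with the gene's own id.
#' @param exons Optional data frame of exon intervals: `gene_id`, `start`,
#'   `end` (0-based half-open).
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(genes, clusters = NULL, exons = NULL) {
  need <- c("gene_id", "chrom", "strand", "tss")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop("each gene must have exactly one TSS record; duplicated: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = genes$gene_id, gene_id = genes$gene_id,
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("cluster_id", "gene_id") %in% names(clusters)))
  if (anyDuplicated(clusters$cluster_id)) {
    stop("transcript-cluster to gene mapping must be many-to-one ",
         "(duplicated cluster id)")
  }
  if (!all(clusters$gene_id %in% genes$gene_id)) {
    stop("cluster mapping refers to unknown gene id(s)")
  }
  obj <- list(genes = as.data.frame(genes, stringsAsFactors = FALSE),
              clusters = as.data.frame(clusters, stringsAsFactors = FALSE),
              exons = if (is.null(exons)) NULL
                else as.data.frame(exons, stringsAsFactors = FALSE))
  class(obj) <- "gene_annotation"
  obj
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d transcript clusters%s\n",
              nrow(x$genes), nrow(x$clusters),
              if (is.null(x$exons)) "" else
                sprintf(", %d exons", nrow(x$exons))))
  invisible(x)
}

#' Read gene annotation from TSV or GFF3
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `strand`, `tss` (0-based)
#' and optionally `start`, `end` and a comma-separated `clusters` column.
#' GFF3 input (via rtracklayer) is 1-based inclusive and converted on load:
#' TSS = start - 1 for `+` genes, end - 1 for `-` genes; exon records are
#' attached when present.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` decides by file extension (`.gff`/`.gff3` vs TSV).
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gff3")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    genes_gr <- gr[gr$type == "gene"]
    if (!length(genes_gr)) stop(path, ": no 'gene' records in GFF3")
    ids <- if (!is.null(genes_gr$gene_id)) genes_gr$gene_id else genes_gr$ID
    strand <- as.character(GenomicRanges::strand(genes_gr))
    strand[strand == "*"] <- "+"
    start0 <- GenomicRanges::start(genes_gr) - 1L # to 0-based
    end0 <- GenomicRanges::end(genes_gr)          # half-open
    genes <- data.frame(gene_id = as.character(ids),
                        chrom = as.character(GenomicRanges::seqnames(genes_gr)),
                        strand = strand,
                        tss = ifelse(strand == "+", start0, end0 - 1L),
                        start = start0, end = end0, stringsAsFactors = FALSE)
    exons_gr <- gr[gr$type == "exon"]
    exons <- NULL
    if (length(exons_gr)) {
      parent <- as.character(unlist(exons_gr$Parent))
      parent <- sub("^(gene|transcript):", "", parent)
      exons <- data.frame(gene_id = parent,
                          start = GenomicRanges::start(exons_gr) - 1L,
                          end = GenomicRanges::end(exons_gr),
                          stringsAsFactors = FALSE)
      exons <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]
      if (!nrow(exons)) exons <- NULL
    }
    return(gene_annotation(genes, exons = exons))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  clusters <- NULL
  if ("clusters" %in% names(df)) {
    parts <- strsplit(df$clusters, ",", fixed = TRUE)
    clusters <- data.frame(cluster_id = unlist(parts),
                           gene_id = rep(df$gene_id, lengths(parts)),
                           stringsAsFactors = FALSE)
    df$clusters <- NULL
  }
  gene_annotation(df, clusters = clusters)
}

#' Write gene annotation as TSV
#' @param ann A [gene_annotation()].
#' @param path Output path; transcript clusters are serialized into a
#'   comma-separated `clusters` column.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  df <- ann$genes
  cl <- split(ann$clusters$cluster_id, ann$clusters$gene_id)
  df$clusters <- vapply(df$gene_id,
                        function(g) paste(cl[[g]], collapse = ","),
                        character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML or JSON configuration file
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
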