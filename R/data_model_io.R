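# Domain types and readers/writers: expression studies, sample sheets,
# probe annotation, QTL intervals (BED), gene sets (GMT).

#' Construct an expression study
#'
#' An expression study couples a probes-by-samples intensity matrix (linear
#' arbitrary units, post-normalisation) with per-sample metadata. Two designs
#' are supported: `"snapshot"` (one pooled chip per line-by-tissue cell, no
#' replication) and `"quantitative"` (replicated 2-line x 2-diet design in a
#' single tissue).
#'
#' @param intensities Numeric matrix of non-negative intensities; rownames are
#'   probe ids, colnames are sample ids.
#' @param samples `data.frame` with columns `sample_id`, `line` (`"F"`/`"L"`),
#'   `tissue` (one of SC, EPI, MES, LIV, MUS, KID), `diet` (chow, control,
#'   highfat) and `replicate` (positive integer). One row per matrix column.
#' @param design `"snapshot"`, `"quantitative"`, or `NULL` to auto-detect from
#'   the replicate structure (any (line, tissue, diet) cell with more than one
#'   sample implies a quantitative design).
#'
#' @return An object of class `expression_study`: a list with elements
#'   `intensities`, `samples` and `design`.
#' @export
expression_study <- function(intensities, samples, design = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix")
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("`intensities` must carry probe rownames and sample colnames")
  }
  dup <- rownames(intensities)[duplicated(rownames(intensities))]
  if (length(dup)) stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(intensities)[duplicated(colnames(intensities))]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  neg <- which(intensities < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative intensity for probe ", rownames(intensities)[neg[1, 1]],
         ", sample ", colnames(intensities)[neg[1, 2]])
  }
  samples <- validate_sample_sheet(samples)
  missing_cols <- setdiff(colnames(intensities), samples$sample_id)
  if (length(missing_cols)) {
    stop("sample sheet is missing matrix column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(samples$sample_id, colnames(intensities))
  if (length(extra)) {
    stop("sample sheet row(s) without a matrix column: ",
         paste(extra, collapse = ", "))
  }
  samples <- samples[match(colnames(intensities), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(design)) design <- detect_design(samples)
  design <- match.arg(design, c("snapshot", "quantitative"))
  if (design == "snapshot") {
    cell <- table(paste(samples$line, samples$tissue))
    if (any(cell > 1)) {
      stop("snapshot design requires one sample per (line, tissue); duplicated: ",
           paste(names(cell)[cell > 1], collapse = ", "))
    }
  } else {
    grp <- table(paste(samples$line, samples$diet))
    if (any(grp < 2)) {
      stop("quantitative design requires >=2 replicates per (line, diet) group; short: ",
           paste(names(grp)[grp < 2], collapse = ", "))
    }
  }
  structure(list(intensities = intensities, samples = samples, design = design),
            class = "expression_study")
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "line", "tissue", "diet", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$line <- as.character(samples$line)
  samples$tissue <- as.character(samples$tissue)
  samples$diet <- as.character(samples$diet)
  samples$replicate <- as.integer(samples$replicate)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop("duplicate sample_id in sample sheet: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(samples$line, LINES)
  if (length(bad)) stop("unknown line value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(samples$tissue, TISSUES)
  if (length(bad)) stop("unknown tissue value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(samples$diet, DIETS)
  if (length(bad)) stop("unknown diet value(s): ", paste(bad, collapse = ", "))
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1)) {
    stop("replicate must be a positive integer for every sample")
  }
  samples[need]
}

detect_design <- function(samples) {
  cell <- table(paste(samples$line, samples$tissue, samples$diet))
  if (all(cell == 1)) "snapshot" else "quantitative"
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study (%s): %d probes x %d samples\n",
              x$design, nrow(x$intensities), ncol(x$intensities)))
  cat("tissues:", paste(sort(unique(x$samples$tissue)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression study from delimited text
#'
#' @param matrix_path TSV with first column `probe_id` and one column per
#'   sample (header row of sample ids).
#' @param sample_sheet_path TSV with columns `sample_id`, `line`, `tissue`,
#'   `diet`, `replicate`, covering every matrix column.
#' @param design Optional design override; auto-detected by default.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, sample_sheet_path, design = NULL) {
  raw <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "probe_id") stop("expression matrix must start with a probe_id column")
  ids <- as.character(raw$probe_id)
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity value(s) in ", matrix_path)
  rownames(m) <- ids
  sheet <- read.delim(sample_sheet_path, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character")
  expression_study(m, sheet, design = design)
}

#' Write an expression study as delimited text
#'
#' Writes full-precision intensities so that
#' `read_expression_study(write_expression_study(s))` round-trips exactly.
#'
#' @param study An [expression_study()].
#' @param matrix_path,sample_sheet_path Output TSV paths.
#' @return Invisibly, the study.
#' @export
write_expression_study <- function(study, matrix_path, sample_sheet_path) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$intensities
  df <- data.frame(probe_id = rownames(m),
                   apply(m, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$samples, sample_sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(study)
}

#' Read a probe annotation table
#'
#' @param path TSV with columns `probe_id`, `gene_id`, `symbol`,
#'   `chromosome`, `position_bp` (gene midpoint). Empty `gene_id`/`symbol`
#'   fields mark probes without a known gene; such probes count towards
#'   "total" but not "known" stratified summaries.
#' @return `data.frame` with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  ann <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = c(position_bp = "numeric"))
  need <- c("probe_id", "gene_id", "symbol", "chromosome", "position_bp")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  ann$probe_id <- as.character(ann$probe_id)
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup)) stop("duplicate probe_id in annotation: ", paste(unique(dup), collapse = ", "))
  ann$gene_id[!nzchar(ann$gene_id %||% "")] <- NA_character_
  ann$symbol[!nzchar(ann$symbol %||% "")] <- NA_character_
  if (any(ann$position_bp < 0, na.rm = TRUE)) stop("negative position_bp in annotation")
  ann[need]
}

#' @rdname read_probe_annotation
#' @param annotation Annotation `data.frame` to write.
#' @export
write_probe_annotation <- function(annotation, path) {
  out <- annotation
  out$gene_id[is.na(out$gene_id)] <- ""
  out$symbol[is.na(out$symbol)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annotation)
}

#' Read QTL intervals from BED-like text
#'
#' Input is 4-column BED (`chrom  start  end  name`). BED coordinates are
#' 0-based half-open; they are converted on read to the package-internal
#' 1-based inclusive convention, which all containment tests use.
#'
#' @param path BED file path. An empty file yields an empty interval set
#'   (downstream stratification then reports zero QTL-resident candidates).
#' @param dialect `"bed"` (default, converted) or `"one_based"` for input
#'   already in 1-based inclusive coordinates.
#' @return `data.frame` with columns `name`, `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive).
#' @export
read_qtl_intervals <- function(path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(name = character(), chromosome = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t| +")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad)) stop("interval line ", bad[1], " has fewer than 4 fields")
  df <- data.frame(
    chromosome = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    name = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  if (dialect == "bed") df$start <- df$start + 1
  qtl_intervals(df$name, df$chromosome, df$start, df$end)
}

#' Construct a validated QTL interval table (1-based inclusive)
#'
#' @param name,chromosome,start_bp,end_bp Parallel vectors describing the
#'   intervals.
#' @export
qtl_intervals <- function(name, chromosome, start_bp, end_bp) {
  df <- data.frame(name = as.character(name), chromosome = as.character(chromosome),
                   start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
                   stringsAsFactors = FALSE)
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) stop("duplicate interval name(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(df$start_bp > df$end_bp)
  if (length(bad)) stop("interval ", df$name[bad[1]], " has start_bp > end_bp")
  if (any(df$start_bp < 0)) stop("negative interval coordinate")
  df
}

#' @rdname read_qtl_intervals
#' @param intervals Interval `data.frame` to write (internal 1-based
#'   inclusive coordinates are converted back to the BED dialect).
#' @export
write_qtl_intervals <- function(intervals, path) {
  out <- data.frame(intervals$chromosome,
                    fmt_num(intervals$start_bp - 1),
                    fmt_num(intervals$end_bp),
                    intervals$name)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(intervals)
}

#' Read a gene-set collection in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are de-duplicated within a set.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene symbols, class
#'   `gene_set_collection`; set descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  short <- which(vapply(parts, length, 1L) < 3)
  if (length(short)) stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[`, "", 1)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate gene-set name(s): ", paste(unique(dup), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, descriptions = vapply(parts, `[`, "", 2))
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description strings.
#' @param source Optional source database label (e.g. `"GOBP"`, `"KEGG"`).
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = NA_character_) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(!nzchar(names(sets)))) stop("every gene set needs a name")
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) stop("empty gene set(s): ", paste(empty, collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, class = "gene_set_collection",
            descriptions = descriptions %||% rep("", length(sets)),
            source = source)
}

#' @rdname read_gene_sets
#' @param collection A `gene_set_collection` to write.
#' @export
write_gene_sets <- function(collection, path) {
  desc <- attr(collection, "descriptions") %||% rep("", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}
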