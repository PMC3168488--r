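# Positional filtering: assign gene midpoints to QTL confidence intervals
# and stratify candidate lists into per-QTL summaries.

#' Assign probes to QTL intervals by gene-midpoint containment
#'
#' Containment is tested for the single midpoint coordinate (`position_bp`)
#' against 1-based inclusive interval ends; a midpoint on either boundary is
#' contained. Overlapping intervals are not merged: every containing
#' interval is reported. Probes whose midpoint falls in no interval are
#' "genome-wide only" (likely secondary) candidates.
#'
#' @param annotation Probe annotation `data.frame` (see
#'   [read_probe_annotation()]).
#' @param intervals QTL interval `data.frame` (see [read_qtl_intervals()]).
#' @return `data.frame` with columns `probe_id`, `qtl_names` (list column of
#'   containing interval names) and `in_qtl` (logical).
#' @export
assign_to_qtls <- function(annotation, intervals) {
  stopifnot(is.data.frame(annotation), is.data.frame(intervals))
  n <- nrow(annotation)
  hits <- vector("list", n)
  bad <- is.na(annotation$chromosome) | !nzchar(annotation$chromosome) |
    is.na(annotation$position_bp)
  if (any(bad)) {
    warning("probe(s) with missing chromosome/position left unassigned: ",
            paste(utils::head(annotation$probe_id[bad], 5), collapse = ", "))
  }
  if (nrow(intervals) && any(!bad)) {
    gr_q <- GenomicRanges::GRanges(
      seqnames = intervals$chromosome,
      ranges = IRanges::IRanges(start = intervals$start_bp, end = intervals$end_bp),
      name = intervals$name)
    ok <- which(!bad)
    gr_p <- GenomicRanges::GRanges(
      seqnames = annotation$chromosome[ok],
      ranges = IRanges::IRanges(start = annotation$position_bp[ok], width = 1))
    ov <- GenomicRanges::findOverlaps(gr_p, gr_q)
    for (i in seq_along(ok)) hits[[ok[i]]] <- character()
    qh <- S4Vectors::subjectHits(ov)
    ph <- S4Vectors::queryHits(ov)
    if (length(ph)) {
      by_probe <- split(intervals$name[qh], ph)
      for (k in names(by_probe)) hits[[ok[as.integer(k)]]] <- unname(by_probe[[k]])
    }
  }
  hits[vapply(hits, is.null, TRUE)] <- list(character())
  data.frame(probe_id = annotation$probe_id,
             qtl_names = I(hits),
             in_qtl = lengths(hits) > 0,
             stringsAsFactors = FALSE)
}

#' Stratify candidate lists by QTL position
#'
#' Produces the per-QTL summary layout used for candidate-list reporting:
#' for each list and each QTL, the count of candidate probes inside the
#' interval, split into total probes and "known" probes (those with a gene
#' id), plus a genome-wide column. Because the printed percentage base in
#' this kind of table is ambiguous, two bases are emitted side by side:
#' `pct_known` = 100 x known-in-QTL / known-genome-wide, and `pct_total` =
#' 100 x total-in-QTL / total-genome-wide (both rounded to integers).
#'
#' @param candidates Either a `candidate_table` or a named list of probe-id
#'   character vectors (one summary row per list).
#' @param annotation Probe annotation `data.frame`. Candidate probes absent
#'   from the annotation are counted as total-only genome-wide.
#' @param intervals QTL interval `data.frame`.
#' @return `data.frame` with one row per candidate list and columns
#'   `genomewide_total`, `genomewide_known`, then per interval
#'   `<name>_total`, `<name>_known`, `<name>_pct_known`, `<name>_pct_total`.
#' @export
stratify <- function(candidates, annotation, intervals) {
  if (inherits(candidates, "candidate_table")) {
    candidates <- list(up_F = candidates$up_F, up_L = candidates$up_L)
  }
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  assign <- assign_to_qtls(annotation, intervals)
  known <- setNames(!is.na(annotation$gene_id), annotation$probe_id)
  rows <- lapply(names(candidates), function(nm) {
    ids <- unique(candidates[[nm]])
    is_known <- ids %in% names(known)[known]
    row <- list(list = nm,
                genomewide_total = length(ids),
                genomewide_known = sum(is_known))
    for (q in intervals$name) {
      in_q <- ids %in% assign$probe_id[vapply(assign$qtl_names,
                                              function(x) q %in% x, TRUE)]
      row[[paste0(q, "_total")]] <- sum(in_q)
      row[[paste0(q, "_known")]] <- sum(in_q & is_known)
      row[[paste0(q, "_pct_known")]] <- if (row$genomewide_known > 0) {
        round(100 * sum(in_q & is_known) / row$genomewide_known)
      } else NA_real_
      row[[paste0(q, "_pct_total")]] <- if (row$genomewide_total > 0) {
        round(100 * sum(in_q) / row$genomewide_total)
      } else NA_real_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
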