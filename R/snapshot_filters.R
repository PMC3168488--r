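# Qualitative "snapshot" filter cascade: signed fold changes, per-depot
# filters with a non-adipose exclusion window, coordinate 3-WAT filter and
# the stringent candidate filter with intensity floor.

#' Signed fold change between the Fat and Lean lines
#'
#' The field's +/- ratio convention: the ratio of the higher intensity over
#' the lower, signed `+` when the Fat (F) line is higher and `-` when the
#' Lean (L) line is higher. Magnitude is always >= 1; equal intensities give
#' `+1`.
#'
#' @param intensity_F,intensity_L Non-negative linear intensities (AU).
#'   Vectorised.
#' @param epsilon Floor applied to both intensities before the ratio
#'   (default 1 AU); guards zero intensities from synthetic edge cases.
#' @return Signed fold change(s), `sfc(a, b) = -sfc(b, a)` for `a != b`.
#' @examples
#' signed_fold_change(947, 14)   # +67.64, prints as 68 when rounded
#' signed_fold_change(50, 100)   # -2
#' @export
signed_fold_change <- function(intensity_F, intensity_L, epsilon = 1) {
  f <- floor_eps(intensity_F, epsilon)
  l <- floor_eps(intensity_L, epsilon)
  if (any(f <= 0) || any(l <= 0)) {
    stop("non-positive intensity after epsilon floor; raise `epsilon`")
  }
  ifelse(f >= l, f / l, -(l / f))
}

#' Per-tissue signed fold-change matrix for a snapshot study
#'
#' @param study A snapshot [expression_study()].
#' @param epsilon Intensity floor passed to [signed_fold_change()].
#' @return Numeric matrix, probes x tissues present in the study, of signed
#'   F-vs-L fold changes.
#' @export
sfc_matrix <- function(study, epsilon = 1) {
  stopifnot(inherits(study, "expression_study"))
  if (study$design != "snapshot") stop("sfc_matrix requires a snapshot design")
  tissues <- intersect(TISSUES, unique(study$samples$tissue))
  out <- sapply(tissues, function(tt) {
    fi <- which(study$samples$tissue == tt & study$samples$line == "F")
    li <- which(study$samples$tissue == tt & study$samples$line == "L")
    if (!length(fi) || !length(li)) stop("missing F or L sample for tissue ", tt)
    signed_fold_change(study$intensities[, fi], study$intensities[, li],
                       epsilon = epsilon)
  })
  out <- matrix(out, nrow = nrow(study$intensities),
                dimnames = list(rownames(study$intensities), tissues))
  out
}

#' Filter configuration for the snapshot cascade
#'
#' @param adipose_threshold Fold threshold a candidate must exceed in the
#'   adipose depot(s); 1.5 for the relaxed stage, 2 for the stringent stage.
#' @param nonadipose_window Half-width of the exclusion window: candidates
#'   must have `|sfc| < nonadipose_window` in liver, muscle and kidney.
#'   `NULL` disables the window (the unwindowed first pass).
#' @param intensity_floor Minimum expression (AU) for a candidate to count
#'   as meaningfully expressed (default 100 AU); only enforced by
#'   [stringent_candidates()].
#' @param floor_mode `"mean_3wat"`: mean of the higher-expressing line's
#'   three WAT intensities must exceed the floor (the stringent-table rule);
#'   `"higher_line"`: the higher line must exceed the floor in every WAT.
#' @param inclusive_threshold If `TRUE` the adipose threshold is `>=`
#'   (stringent stage, ">=2-fold"); if `FALSE` it is strict `>` (relaxed
#'   stage, ">1.5-fold"). The non-adipose window is always strict `<`.
#' @param epsilon Intensity floor before ratio arithmetic.
#' @export
filter_config <- function(adipose_threshold = 1.5, nonadipose_window = 1.5,
                          intensity_floor = 100,
                          floor_mode = c("mean_3wat", "higher_line"),
                          inclusive_threshold = FALSE, epsilon = 1) {
  floor_mode <- match.arg(floor_mode)
  if (adipose_threshold <= 1) stop("adipose_threshold must exceed 1")
  if (!is.null(nonadipose_window) && nonadipose_window <= 1) {
    stop("nonadipose_window must exceed 1 (or be NULL to disable)")
  }
  if (intensity_floor < 0) stop("intensity_floor must be >= 0")
  structure(list(adipose_threshold = adipose_threshold,
                 nonadipose_window = nonadipose_window,
                 intensity_floor = intensity_floor,
                 floor_mode = floor_mode,
                 inclusive_threshold = inclusive_threshold,
                 epsilon = epsilon),
            class = "filter_config")
}

#' @rdname filter_config
#' @export
stringent_config <- function(adipose_threshold = 2, nonadipose_window = 2,
                             intensity_floor = 100) {
  filter_config(adipose_threshold, nonadipose_window, intensity_floor,
                floor_mode = "mean_3wat", inclusive_threshold = TRUE)
}

# threshold comparison honouring the configured boundary strictness
passes_threshold <- function(sfc, cfg) {
  if (cfg$inclusive_threshold) sfc >= cfg$adipose_threshold else sfc > cfg$adipose_threshold
}

# TRUE where the probe's non-adipose folds all lie strictly inside the window
within_window <- function(sfc, cfg, tissues = NON_ADIPOSE) {
  if (is.null(cfg$nonadipose_window)) return(rep(TRUE, nrow(sfc)))
  miss <- setdiff(tissues, colnames(sfc))
  if (length(miss)) stop("missing tissue column(s): ", paste(miss, collapse = ", "))
  apply(abs(sfc[, tissues, drop = FALSE]) < cfg$nonadipose_window, 1, all)
}

#' Per-depot snapshot filter
#'
#' A probe enters the FAT (`up_F`) list for a depot when its signed fold
#' change in that depot exceeds the adipose threshold and, if the
#' non-adipose window is enabled, its folds in liver, muscle and kidney all
#' lie strictly inside `(-window, +window)`. The LEAN (`up_L`) list is the
#' mirror image.
#'
#' @param study Snapshot [expression_study()].
#' @param depot One of `"SC"`, `"EPI"`, `"MES"`.
#' @param cfg A [filter_config()].
#' @return List with character vectors `up_F` and `up_L` of probe ids.
#' @export
depot_filter <- function(study, depot, cfg = filter_config()) {
  depot <- match.arg(depot, WAT_TISSUES)
  sfc <- sfc_matrix(study, epsilon = cfg$epsilon)
  if (!depot %in% colnames(sfc)) stop("missing tissue column: ", depot)
  win <- within_window(sfc, cfg)
  up_F <- rownames(sfc)[passes_threshold(sfc[, depot], cfg) & win]
  up_L <- rownames(sfc)[passes_threshold(-sfc[, depot], cfg) & win]
  list(up_F = up_F, up_L = up_L)
}

#' Coordinate 3-WAT filter
#'
#' A probe passes when it passes the per-depot filter in *all three* white
#' adipose depots (SC, EPI, MES) with a common sign.
#'
#' @inheritParams depot_filter
#' @return List with character vectors `up_F` and `up_L`.
#' @export
coordinate_3wat_filter <- function(study, cfg = filter_config()) {
  per <- lapply(WAT_TISSUES, function(d) depot_filter(study, d, cfg))
  list(up_F = Reduce(intersect, lapply(per, `[[`, "up_F")),
       up_L = Reduce(intersect, lapply(per, `[[`, "up_L")))
}

#' Stringent candidate filter (coordinate 3-WAT + intensity floor)
#'
#' The high-stringency stage: >=2-fold in all three WAT depots with a common
#' sign, non-adipose folds strictly inside (-2, +2), and mean intensity of
#' the higher-expressing line across the three WATs above the floor
#' (default 100 AU).
#'
#' @inheritParams depot_filter
#' @param cfg A [filter_config()]; defaults to [stringent_config()].
#' @return A `candidate_table`: list with `stage`, `config`, probe-id vectors
#'   `up_F` and `up_L`, the per-tissue `sfc` matrix for retained probes and
#'   `mean_3wat_fold`, the per-candidate mean signed fold across the WATs.
#' @export
stringent_candidates <- function(study, cfg = stringent_config()) {
  coord <- coordinate_3wat_filter(study, cfg)
  keep <- function(ids, line) {
    if (!length(ids)) return(character())
    wat_cols <- vapply(WAT_TISSUES, function(tt) {
      which(study$samples$tissue == tt & study$samples$line == line)
    }, integer(1))
    wat <- study$intensities[ids, wat_cols, drop = FALSE]
    ok <- switch(cfg$floor_mode,
      mean_3wat = rowMeans(wat) > cfg$intensity_floor,
      higher_line = apply(wat > cfg$intensity_floor, 1, all))
    ids[ok]
  }
  up_F <- keep(coord$up_F, "F")
  up_L <- keep(coord$up_L, "L")
  sfc <- sfc_matrix(study, epsilon = cfg$epsilon)
  all_ids <- c(up_F, up_L)
  mean_fold <- if (length(all_ids)) {
    setNames(rowMeans(sfc[all_ids, WAT_TISSUES, drop = FALSE]), all_ids)
  } else {
    setNames(numeric(), character())
  }
  candidate_table("stringent", cfg, up_F, up_L,
                  sfc = sfc[all_ids, , drop = FALSE],
                  mean_3wat_fold = mean_fold)
}

#' @rdname stringent_candidates
#' @param stage Stage label.
#' @param up_F,up_L Probe-id vectors by direction.
#' @param sfc Per-tissue signed fold-change matrix for the listed probes.
#' @param mean_3wat_fold Named numeric of mean 3-WAT folds.
#' @export
candidate_table <- function(stage, cfg, up_F, up_L, sfc = NULL,
                            mean_3wat_fold = NULL) {
  if (length(intersect(up_F, up_L))) stop("FAT and LEAN lists must be disjoint")
  structure(list(stage = stage, config = cfg,
                 up_F = up_F, up_L = up_L,
                 sfc = sfc, mean_3wat_fold = mean_3wat_fold),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("candidate_table [%s]: %d up in F, %d up in L\n",
              x$stage, length(x$up_F), length(x$up_L)))
  invisible(x)
}

#' @export
as.data.frame.candidate_table <- function(x, ...) {
  ids <- c(x$up_F, x$up_L)
  df <- data.frame(stage = rep(x$stage, length(ids)),
                   direction = rep(c("up_F", "up_L"),
                                   c(length(x$up_F), length(x$up_L))),
                   probe_id = ids, stringsAsFactors = FALSE)
  if (!is.null(x$sfc) && length(ids)) {
    df <- cbind(df, as.data.frame(x$sfc[ids, , drop = FALSE]))
  }
  if (!is.null(x$mean_3wat_fold) && length(ids)) {
    df$mean_3wat_fold <- unname(x$mean_3wat_fold[ids])
  }
  rownames(df) <- NULL
  df
}

#' Mean signed fold change across the three WAT depots
#'
#' Arithmetic mean of the signed SC, EPI and MES fold changes. Defined only
#' for sign-consistent probes (folds of magnitude exactly 1 are
#' sign-neutral); sign-discordant folds are an error, as the summary is
#' meaningless for them.
#'
#' @param study Snapshot [expression_study()].
#' @param probe_id Probe to summarise.
#' @param epsilon Intensity floor before ratio arithmetic.
#' @return Signed mean fold (e.g. `+7` for a gene ~7-fold up in F in all
#'   three depots).
#' @export
mean_3wat_fold <- function(study, probe_id, epsilon = 1) {
  sfc <- sfc_matrix(study, epsilon = epsilon)
  if (!probe_id %in% rownames(sfc)) stop("unknown probe: ", probe_id)
  folds <- sfc[probe_id, WAT_TISSUES]
  if (any(folds > 1) && any(folds < -1)) {
    stop("sign-discordant WAT folds for probe ", probe_id,
         "; mean 3-WAT fold is undefined")
  }
  mean(folds)
}
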