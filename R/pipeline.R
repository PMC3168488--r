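# End-to-end orchestration of the stratified cascade, funnel reporting and
# plain-text report output.

#' Default pipeline configuration
#'
#' All thresholds default to the study's reporting criteria: relaxed
#' snapshot stage >1.5-fold with a <1.5 non-adipose window, stringent stage
#' >=2-fold with a <2 window and 100 AU floor, quantitative stage >2-fold
#' with adjusted p < 0.05 and 100 AU floor.
#'
#' @param mode `"simulate"` (generate synthetic inputs) or `"files"` (read
#'   the paths in `paths`).
#' @param seed Seed for simulation mode.
#' @param generator Optional list of [generator_config()] overrides.
#' @param snapshot List with `relaxed` and `stringent` threshold blocks.
#' @param quantitative List with `fold`, `alpha`, `floor`, or `NULL` to skip
#'   the quantitative stage.
#' @param ora List with `min_category`.
#' @param paths Named list of input file paths for `mode = "files"`:
#'   `matrix`, `samples`, `annotation`, `intervals`, `gene_sets`, and
#'   optionally `quant_matrix`, `quant_samples`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "files"), seed = 1,
                            generator = list(),
                            snapshot = list(
                              relaxed = list(adipose_threshold = 1.5,
                                             nonadipose_window = 1.5),
                              stringent = list(adipose_threshold = 2,
                                               nonadipose_window = 2,
                                               intensity_floor = 100)),
                            quantitative = list(fold = 2, alpha = 0.05,
                                                floor = 100),
                            ora = list(min_category = 3),
                            paths = list()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = seed, generator = generator,
                 snapshot = snapshot, quantitative = quantitative,
                 ora = ora, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

load_pipeline_inputs <- function(cfg) {
  if (cfg$mode == "simulate") {
    gen <- do.call(generator_config, cfg$generator)
    ann <- generate_annotation(gen, cfg$seed)
    snap <- generate_snapshot(gen, cfg$seed)
    quant <- if (!is.null(cfg$quantitative)) generate_quantitative(gen, cfg$seed)
    truth <- merge(snap$truth, ann$truth[, c("probe_id", "in_qtl")],
                   by = "probe_id", sort = FALSE)
    list(snapshot = snap$study,
         quantitative = quant$study %||% NULL,
         annotation = ann$annotation,
         intervals = ann$intervals,
         gene_sets = truth_gene_sets(ann$truth, ann$annotation),
         truth = truth)
  } else {
    p <- cfg$paths
    need <- c("matrix", "samples", "annotation", "intervals")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop("pipeline config lacks path(s): ", paste(miss, collapse = ", "))
    quant <- NULL
    if (!is.null(cfg$quantitative) &&
        !is.null(p$quant_matrix) && !is.null(p$quant_samples)) {
      quant <- read_expression_study(p$quant_matrix, p$quant_samples)
    }
    list(snapshot = read_expression_study(p$matrix, p$samples),
         quantitative = quant,
         annotation = read_probe_annotation(p$annotation),
         intervals = read_qtl_intervals(p$intervals),
         gene_sets = if (!is.null(p$gene_sets)) read_gene_sets(p$gene_sets),
         truth = NULL)
  }
}

#' Run the full stratified candidate-gene pipeline
#'
#' Executes the cascade in order: (1) per-depot >1.5-fold screens (no
#' non-adipose window), (2) coordinate 3-WAT filter with the <1.5 window,
#' (3) stringent >=2-fold candidates with the <2 window and 100 AU floor,
#' QTL stratification of stages 2 and 3, over-representation analysis of the
#' stringent candidates, and - when a quantitative study is present - the
#' moderated-t stage with the fold/FDR/floor filter and diet-response
#' classification. Every stage's thresholds and input/output counts are
#' logged, and outputs are deterministic given the config.
#'
#' @param cfg A [pipeline_config()], or a path to a YAML config.
#' @return A `pipeline_report`: list with `inputs`, `stages` (stage-1 lists,
#'   stage-2/3 `candidate_table`s), `stratified` summaries, `de` (per
#'   contrast results), `de_candidates` lists, `diet_labels`, `enrichment`,
#'   `funnel`, `log`, and in simulation mode `truth` and `recovery`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  inputs <- load_pipeline_inputs(cfg)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  rx <- cfg$snapshot$relaxed
  relaxed <- filter_config(adipose_threshold = rx$adipose_threshold %||% 1.5,
                           nonadipose_window = rx$nonadipose_window %||% 1.5)
  unwindowed <- filter_config(adipose_threshold = relaxed$adipose_threshold,
                              nonadipose_window = NULL)
  st <- cfg$snapshot$stringent
  stringent <- stringent_config(adipose_threshold = st$adipose_threshold %||% 2,
                                nonadipose_window = st$nonadipose_window %||% 2,
                                intensity_floor = st$intensity_floor %||% 100)

  note("stage 1 (per-depot, >%g-fold, no window)", unwindowed$adipose_threshold)
  stage1 <- lapply(WAT_TISSUES, function(d) depot_filter(inputs$snapshot, d, unwindowed))
  names(stage1) <- WAT_TISSUES
  s1_F <- unique(unlist(lapply(stage1, `[[`, "up_F")))
  s1_L <- unique(unlist(lapply(stage1, `[[`, "up_L")))
  note("stage 1 counts: up_F %d, up_L %d (union over depots)",
       length(s1_F), length(s1_L))

  note("stage 2 (coordinate 3-WAT, >%g-fold, window <%g)",
       relaxed$adipose_threshold, relaxed$nonadipose_window)
  coord <- coordinate_3wat_filter(inputs$snapshot, relaxed)
  sfc <- sfc_matrix(inputs$snapshot)
  coord_ids <- c(coord$up_F, coord$up_L)
  stage2 <- candidate_table("coordinate_3wat", relaxed, coord$up_F, coord$up_L,
                            sfc = sfc[coord_ids, , drop = FALSE],
                            mean_3wat_fold = if (length(coord_ids)) {
                              setNames(rowMeans(sfc[coord_ids, WAT_TISSUES,
                                                    drop = FALSE]), coord_ids)
                            })
  note("stage 2 counts: up_F %d, up_L %d",
       length(stage2$up_F), length(stage2$up_L))

  note("stage 3 (stringent, >=%g-fold, window <%g, floor %g AU %s)",
       stringent$adipose_threshold, stringent$nonadipose_window,
       stringent$intensity_floor, stringent$floor_mode)
  stage3 <- stringent_candidates(inputs$snapshot, stringent)
  note("stage 3 counts: up_F %d, up_L %d",
       length(stage3$up_F), length(stage3$up_L))

  stratified <- list(
    coordinate_3wat = stratify(stage2, inputs$annotation, inputs$intervals),
    stringent = stratify(stage3, inputs$annotation, inputs$intervals)
  )

  enrichment <- NULL
  if (!is.null(inputs$gene_sets)) {
    known <- inputs$annotation[!is.na(inputs$annotation$symbol), ]
    universe <- unique(known$symbol)
    selected <- unique(known$symbol[known$probe_id %in% stage3$up_F])
    enrichment <- enrich_all(selected, inputs$gene_sets, universe,
                             min_category = cfg$ora$min_category %||% 3)
    note("ORA: %d selected symbols against %d categories (universe %d)",
         length(selected), nrow(enrichment), length(universe))
  }

  de <- NULL; t5 <- NULL; diet_labels <- NULL
  if (!is.null(inputs$quantitative) && !is.null(cfg$quantitative)) {
    q <- cfg$quantitative
    note("quantitative stage (fold >%g, adjusted p <%g, floor %g AU)",
         q$fold %||% 2, q$alpha %||% 0.05, q$floor %||% 100)
    de <- do.call(rbind, lapply(CONTRASTS, function(ct) {
      moderated_t_test(inputs$quantitative, ct)
    }))
    t5 <- de_candidate_filter(de, fold = q$fold %||% 2, alpha = q$alpha %||% 0.05,
                        floor = q$floor %||% 100)
    for (ct in CONTRASTS) {
      note("  %s: %d up, %d down", ct, length(t5[[ct]]$up), length(t5[[ct]]$down))
    }
    means <- quant_group_means(inputs$quantitative)
    # significance flags for diet-response labels: the FDR criterion alone
    # (the fold/floor cuts govern reporting, not the presence of an effect)
    sig <- sapply(CONTRASTS, function(ct) {
      dct <- de[de$contrast == ct, ]
      dct$padj[match(means$probe_id, dct$probe_id)] < (q$alpha %||% 0.05)
    })
    diet_labels <- data.frame(
      probe_id = means$probe_id,
      label = classify_diet_response(means[, c("FC", "FF", "LC", "LF")], sig),
      stringsAsFactors = FALSE
    )
  }

  funnel <- data.frame(
    stage = rep(c("1_per_depot_any", "2_coordinate_3wat", "3_stringent"), each = 2),
    direction = rep(c("up_F", "up_L"), 3),
    count = c(length(s1_F), length(s1_L),
              length(stage2$up_F), length(stage2$up_L),
              length(stage3$up_F), length(stage3$up_L)),
    threshold = c(rep(sprintf(">%g, no window", unwindowed$adipose_threshold), 2),
                  rep(sprintf(">%g, window <%g", relaxed$adipose_threshold,
                              relaxed$nonadipose_window), 2),
                  rep(sprintf(">=%g, window <%g, floor %g AU",
                              stringent$adipose_threshold,
                              stringent$nonadipose_window,
                              stringent$intensity_floor), 2)),
    stringsAsFactors = FALSE
  )

  recovery <- NULL
  if (!is.null(inputs$truth)) {
    recovery <- list(
      coordinate_3wat_up_F = evaluate_recovery(stage2$up_F, inputs$truth,
                                               positive_classes = "adipose_F_up"),
      stringent_up_F = evaluate_recovery(stage3$up_F, inputs$truth,
                                         positive_classes = "adipose_F_up")
    )
  }

  structure(list(config = cfg, inputs = inputs,
                 stages = list(per_depot = stage1, coordinate_3wat = stage2,
                               stringent = stage3),
                 stratified = stratified, enrichment = enrichment,
                 de = de, de_candidates = t5, diet_labels = diet_labels,
                 funnel = funnel, recovery = recovery,
                 truth = inputs$truth, log = log),
            class = "pipeline_report")
}

#' Funnel summary of per-stage candidate counts
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @return `data.frame` with one row per stage and direction: `stage`,
#'   `direction`, `count`, `threshold`.
#' @export
render_funnel <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  report$funnel
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  print(x$funnel)
  invisible(x)
}

#' Write a pipeline report bundle as plain-text tables
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wt(report$funnel, "funnel.tsv"),
    wt(as.data.frame(report$stages$coordinate_3wat), "candidates_coordinate_3wat.tsv"),
    wt(as.data.frame(report$stages$stringent), "candidates_stringent.tsv"),
    wt(report$stratified$coordinate_3wat, "stratified_coordinate_3wat.tsv"),
    wt(report$stratified$stringent, "stratified_stringent.tsv")
  )
  if (!is.null(report$enrichment)) paths <- c(paths, wt(report$enrichment, "enrichment.tsv"))
  if (!is.null(report$de)) paths <- c(paths, wt(report$de, "de_results.tsv"))
  if (!is.null(report$diet_labels)) paths <- c(paths, wt(report$diet_labels, "diet_labels.tsv"))
  logpath <- file.path(dir, "run_log.txt")
  writeLines(report$log, logpath)
  invisible(c(paths, logpath))
}
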