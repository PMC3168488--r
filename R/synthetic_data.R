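# Synthetic snapshot and quantitative studies with planted truth, plus
# recovery-evaluation metrics. The generator starts at the
# normalized-intensity abstraction: per-individual log2 expression =
# log-normal baseline + planted class effect + Gaussian chip noise;
# snapshot chips pool individuals on the log2 scale.

PLANTED_CLASSES <- c("adipose_F_up", "adipose_L_up", "depot_specific",
                     "all_tissue_bystander", "diet_amplified")

#' Synthetic genome and placeholder QTL intervals
#'
#' A small synthetic genome (five 150-Mb chromosomes) with four synthetic
#' QTL intervals named after the fat-mass loci Fob1-Fob4. The coordinates
#' are placeholders on the synthetic genome, not assertions about the real
#' mouse loci (whose published confidence intervals must be user-supplied
#' for real-data work).
#'
#' @return For `synthetic_genome()`, a `data.frame` with `chromosome` and
#'   `length_bp`; for `synthetic_qtl_intervals()`, a QTL interval table in
#'   the internal 1-based inclusive convention.
#' @export
synthetic_genome <- function() {
  data.frame(chromosome = paste0("chr", 1:5),
             length_bp = rep(150e6, 5),
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_genome
#' @export
synthetic_qtl_intervals <- function() {
  qtl_intervals(name = paste0("Fob", 1:4),
                chromosome = paste0("chr", 1:4),
                start_bp = c(20e6, 50e6, 10e6, 70e6) + 1,
                end_bp = c(60e6, 90e6, 45e6, 110e6))
}

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' pooled snapshot of 3 individuals per tissue per line over 6 tissues, and
#' a 4-replicate 2-line x 2-diet subcutaneous design. Planted classes:
#' `adipose_F_up` / `adipose_L_up` (coordinate 4-fold in all three WATs),
#' `depot_specific` (one WAT only), `all_tissue_bystander` (8-fold in all
#' six tissues, the Depdc6-like exclusion target), `diet_amplified` (line
#' effect 2-fold on control diet, 4-fold on high fat, quantitative design
#' only) and `null` (the remainder).
#'
#' @param n_probes Number of probes (default 2000).
#' @param class_counts Named integer vector of planted-class sizes.
#' @param effects Named list of log2 effect sizes per class;
#'   `diet_amplified` is a length-2 vector `(control, highfat)`.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal probe baseline
#'   (default mean 9, sd 1.5 on log2 AU, i.e. median 512 AU).
#' @param noise_sd Per-chip log2 residual sd (default 0.2).
#' @param pool_size Individuals pooled per snapshot chip (default 3).
#' @param replicates Chips per quantitative group (default 4).
#' @param genome Synthetic genome table.
#' @param qtl QTL interval table used for placement.
#' @param qtl_fraction Fraction of each planted class placed inside QTL
#'   intervals (default 0.5).
#' @param annotated_fraction Share of probes assigned a gene id (default
#'   0.85), emulating the total/known split of probe annotation.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_probes = 2000,
                             class_counts = c(adipose_F_up = 100,
                                              adipose_L_up = 10,
                                              depot_specific = 50,
                                              all_tissue_bystander = 20,
                                              diet_amplified = 50),
                             effects = list(adipose_F_up = 2,
                                            adipose_L_up = 2,
                                            depot_specific = 2,
                                            all_tissue_bystander = 3,
                                            diet_amplified = c(1, 2)),
                             baseline_log2_mean = 9,
                             baseline_log2_sd = 1.5,
                             noise_sd = 0.2,
                             pool_size = 3,
                             replicates = 4,
                             genome = synthetic_genome(),
                             qtl = synthetic_qtl_intervals(),
                             qtl_fraction = 0.5,
                             annotated_fraction = 0.85) {
  class_counts <- unlist(class_counts)
  counts <- class_counts[PLANTED_CLASSES]
  counts[is.na(counts)] <- 0L
  names(counts) <- PLANTED_CLASSES
  # partial effect overrides fall back to the defaults
  default_effects <- list(adipose_F_up = 2, adipose_L_up = 2,
                          depot_specific = 2, all_tissue_bystander = 3,
                          diet_amplified = c(1, 2))
  effects <- utils::modifyList(default_effects, as.list(effects))
  if (sum(counts) > n_probes) stop("planted class counts exceed n_probes")
  bad <- setdiff(names(class_counts), PLANTED_CLASSES)
  if (length(bad)) stop("unknown planted class name(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(effects), PLANTED_CLASSES)
  if (length(bad)) stop("unknown effect class name(s): ", paste(bad, collapse = ", "))
  stopifnot(baseline_log2_sd > 0, noise_sd > 0,
            pool_size >= 1, replicates >= 2,
            qtl_fraction >= 0, qtl_fraction <= 1,
            annotated_fraction >= 0, annotated_fraction <= 1)
  structure(list(n_probes = as.integer(n_probes),
                 class_counts = counts,
                 effects = effects,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd,
                 pool_size = as.integer(pool_size),
                 replicates = as.integer(replicates),
                 genome = genome,
                 qtl = qtl,
                 qtl_fraction = qtl_fraction,
                 annotated_fraction = annotated_fraction),
            class = "generator_config")
}

# Deterministic class assignment: planted classes occupy the first probes in
# a fixed order, the remainder is null. Depot-specific probes cycle through
# SC/EPI/MES deterministically so truth is a pure function of the config.
probe_classes <- function(cfg) {
  cls <- rep("null", cfg$n_probes)
  i <- 1L
  for (cname in PLANTED_CLASSES) {
    k <- cfg$class_counts[[cname]]
    if (k > 0) {
      cls[i:(i + k - 1L)] <- cname
      i <- i + k
    }
  }
  cls
}

probe_ids_for <- function(cfg) sprintf("probe%05d", seq_len(cfg$n_probes))

depot_for_specific <- function(cfg) {
  cls <- probe_classes(cfg)
  depot <- rep(NA_character_, cfg$n_probes)
  idx <- which(cls == "depot_specific")
  if (length(idx)) depot[idx] <- WAT_TISSUES[((seq_along(idx) - 1L) %% 3L) + 1L]
  depot
}

# Per-probe x per-tissue true log2 effect applied to the F line in the
# snapshot design (F minus L on the log2 scale).
snapshot_effect_matrix <- function(cfg) {
  cls <- probe_classes(cfg)
  depot <- depot_for_specific(cfg)
  eff <- matrix(0, cfg$n_probes, length(TISSUES),
                dimnames = list(probe_ids_for(cfg), TISSUES))
  eff[cls == "adipose_F_up", WAT_TISSUES] <- cfg$effects$adipose_F_up
  eff[cls == "adipose_L_up", WAT_TISSUES] <- -cfg$effects$adipose_L_up
  for (i in which(cls == "depot_specific")) {
    eff[i, depot[i]] <- cfg$effects$depot_specific
  }
  eff[cls == "all_tissue_bystander", ] <- cfg$effects$all_tissue_bystander
  eff
}

#' Generate a synthetic probe annotation with QTL placement
#'
#' Probes are placed uniformly on the synthetic genome, except planted
#' (non-null) probes, which are placed inside a QTL interval with
#' probability `qtl_fraction` (and explicitly outside all intervals
#' otherwise). A configurable share of probes receives no gene id.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; all placement is a pure function of
#'   `(cfg, seed)`.
#' @return List with `annotation` (probe annotation `data.frame`),
#'   `intervals` (the config's QTL table) and `truth` (`data.frame` with
#'   `probe_id`, `class`, `depot`, `in_qtl`).
#' @export
generate_annotation <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  cls <- probe_classes(cfg)
  planted <- cls != "null"
  if (cfg$qtl_fraction > 0 && any(planted) && !nrow(cfg$qtl)) {
    stop("qtl_fraction > 0 requires a non-empty QTL interval list")
  }
  ids <- probe_ids_for(cfg)
  with_seed(sub_seed(seed, 101), {
    n <- cfg$n_probes
    chrom <- character(n)
    pos <- numeric(n)
    genome <- cfg$genome
    draw_uniform <- function(k, outside = FALSE) {
      ch <- sample(genome$chromosome, k, replace = TRUE,
                   prob = genome$length_bp / sum(genome$length_bp))
      ps <- floor(runif(k) * genome$length_bp[match(ch, genome$chromosome)]) + 1
      if (outside && nrow(cfg$qtl)) {
        repeat {
          inside <- vapply(seq_len(k), function(i) {
            any(cfg$qtl$chromosome == ch[i] &
                  cfg$qtl$start_bp <= ps[i] & ps[i] <= cfg$qtl$end_bp)
          }, TRUE)
          if (!any(inside)) break
          kk <- sum(inside)
          ch[inside] <- sample(genome$chromosome, kk, replace = TRUE,
                               prob = genome$length_bp / sum(genome$length_bp))
          ps[inside] <- floor(runif(kk) *
                                genome$length_bp[match(ch[inside], genome$chromosome)]) + 1
        }
      }
      list(chrom = ch, pos = ps)
    }
    in_qtl_flag <- rep(FALSE, n)
    if (any(planted)) {
      in_qtl_flag[planted] <- runif(sum(planted)) < cfg$qtl_fraction
    }
    idx_in <- which(in_qtl_flag)
    if (length(idx_in)) {
      pick <- sample.int(nrow(cfg$qtl), length(idx_in), replace = TRUE)
      chrom[idx_in] <- cfg$qtl$chromosome[pick]
      width <- cfg$qtl$end_bp[pick] - cfg$qtl$start_bp[pick] + 1
      pos[idx_in] <- cfg$qtl$start_bp[pick] + floor(runif(length(idx_in)) * width)
    }
    idx_out_planted <- which(planted & !in_qtl_flag)
    if (length(idx_out_planted)) {
      d <- draw_uniform(length(idx_out_planted), outside = TRUE)
      chrom[idx_out_planted] <- d$chrom
      pos[idx_out_planted] <- d$pos
    }
    idx_null <- which(!planted)
    if (length(idx_null)) {
      d <- draw_uniform(length(idx_null))
      chrom[idx_null] <- d$chrom
      pos[idx_null] <- d$pos
    }
    has_gene <- runif(n) < cfg$annotated_fraction
    annotation <- data.frame(
      probe_id = ids,
      gene_id = ifelse(has_gene, sprintf("gene%05d", seq_len(n)), NA_character_),
      symbol = ifelse(has_gene, sprintf("Gm%05d", seq_len(n)), NA_character_),
      chromosome = chrom,
      position_bp = pos,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(probe_id = ids, class = cls,
                        depot = depot_for_specific(cfg),
                        in_qtl = in_qtl_flag,
                        stringsAsFactors = FALSE)
    list(annotation = annotation, intervals = cfg$qtl, truth = truth)
  })
}

# pooled chip value: mean of pool_size individual log2 draws
pool_chip <- function(mu, pool_size, noise_sd) {
  n <- length(mu)
  noise <- matrix(rnorm(n * pool_size, 0, noise_sd), n, pool_size)
  mu + rowMeans(noise)
}

#' Generate a pooled snapshot study with planted truth
#'
#' One pooled chip per (line, tissue) over the six tissues. Per probe,
#' tissue and line, each pooled individual contributes
#' `baseline + class effect + N(0, noise_sd)` on the log2 scale; the chip
#' value is the mean of `pool_size` individuals and intensities are
#' `2^pooled`. Class effects follow the class definitions: all three WATs
#' for the adipose classes, one WAT for `depot_specific`, all six tissues
#' for `all_tissue_bystander`; `diet_amplified` and `null` probes carry no
#' effect in this chow-fed design.
#'
#' @inheritParams generate_annotation
#' @return List with `study` (snapshot [expression_study()]) and `truth`
#'   (`data.frame` of class labels and per-tissue true log2 effects,
#'   columns `eff_SC` ... `eff_KID`, F minus L).
#' @export
generate_snapshot <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  eff <- snapshot_effect_matrix(cfg)
  ids <- probe_ids_for(cfg)
  with_seed(sub_seed(seed, 202), {
    baseline <- rnorm(cfg$n_probes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    cols <- list()
    for (tt in TISSUES) {
      for (ln in LINES) {
        mu <- baseline + if (ln == "F") eff[, tt] else 0
        cols[[paste(ln, tt, sep = "_")]] <-
          2^pool_chip(mu, cfg$pool_size, cfg$noise_sd)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    samples <- data.frame(
      sample_id = colnames(m),
      line = sub("_.*", "", colnames(m)),
      tissue = sub(".*_", "", colnames(m)),
      diet = "chow",
      replicate = 1L,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(probe_id = ids, class = probe_classes(cfg),
                        depot = depot_for_specific(cfg),
                        stringsAsFactors = FALSE)
    colnames(eff) <- paste0("eff_", colnames(eff))
    truth <- cbind(truth, as.data.frame(eff, row.names = NULL))
    list(study = expression_study(m, samples, design = "snapshot"),
         truth = truth)
  })
}

#' Generate a replicated quantitative study with planted truth
#'
#' Four groups (FC, FF, LC, LF) of `replicates` subcutaneous-fat chips.
#' Line effects (applied to the F line, log2 F minus L): adipose classes
#' and bystanders carry their snapshot SC effect on both diets;
#' `depot_specific` probes only if their depot is SC; `diet_amplified`
#' probes carry the smaller effect on control diet and the larger one on
#' high fat. Chip noise is independent per chip.
#'
#' @inheritParams generate_annotation
#' @return List with `study` (quantitative [expression_study()]) and
#'   `truth` (`data.frame` with `eff_control` and `eff_highfat` log2 line
#'   effects).
#' @export
generate_quantitative <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$replicates < 2) stop("quantitative design requires replicates >= 2")
  cls <- probe_classes(cfg)
  depot <- depot_for_specific(cfg)
  base_eff <- snapshot_effect_matrix(cfg)[, "SC"]
  eff_control <- base_eff
  eff_highfat <- base_eff
  amp <- cls == "diet_amplified"
  de <- cfg$effects$diet_amplified
  if (length(de) == 1) de <- c(de, 2 * de)
  eff_control[amp] <- de[1]
  eff_highfat[amp] <- de[2]
  ids <- probe_ids_for(cfg)
  with_seed(sub_seed(seed, 303), {
    baseline <- rnorm(cfg$n_probes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    groups <- c("FC", "FF", "LC", "LF")
    cols <- list()
    for (g in groups) {
      line <- substr(g, 1, 1)
      diet <- if (substr(g, 2, 2) == "F") "highfat" else "control"
      eff <- if (line == "F") {
        if (diet == "highfat") eff_highfat else eff_control
      } else 0
      for (r in seq_len(cfg$replicates)) {
        mu <- baseline + eff
        cols[[paste(g, r, sep = "_")]] <-
          2^(mu + rnorm(cfg$n_probes, 0, cfg$noise_sd))
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    samples <- data.frame(
      sample_id = colnames(m),
      line = substr(colnames(m), 1, 1),
      tissue = "SC",
      diet = ifelse(substr(colnames(m), 2, 2) == "F", "highfat", "control"),
      replicate = as.integer(sub(".*_", "", colnames(m))),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(probe_id = ids, class = cls, depot = depot,
                        eff_control = eff_control, eff_highfat = eff_highfat,
                        stringsAsFactors = FALSE)
    list(study = expression_study(m, samples, design = "quantitative"),
         truth = truth)
  })
}

#' Gene sets derived from the planted truth
#'
#' Builds a small gene-set collection from the planted classes (using
#' annotated symbols only), for exercising the over-representation stage on
#' synthetic data with known enrichment.
#'
#' @param truth Truth `data.frame` with `probe_id` and `class`.
#' @param annotation Probe annotation (symbols).
#' @return A [gene_set_collection()] with one set per non-empty planted
#'   class and one random-membership decoy set.
#' @export
truth_gene_sets <- function(truth, annotation) {
  sym <- setNames(annotation$symbol, annotation$probe_id)
  sets <- list()
  for (cname in PLANTED_CLASSES) {
    s <- sym[truth$probe_id[truth$class == cname]]
    s <- s[!is.na(s)]
    if (length(s)) sets[[paste0("planted_", cname)]] <- unname(s)
  }
  all_sym <- sym[!is.na(sym)]
  if (length(all_sym) >= 20) {
    # deterministic decoy: every 7th annotated gene
    sets[["decoy_uniform"]] <- unname(all_sym[seq(1, length(all_sym), by = 7)])
  }
  gene_set_collection(sets, source = "synthetic_truth")
}

#' Recovery metrics against the planted truth
#'
#' @param selected Character vector of probe ids from a filter stage or DE
#'   list. Every id must appear in `truth`.
#' @param truth Truth `data.frame` with `probe_id` and `class`.
#' @param positive_classes Classes counted as true positives for the
#'   false-discovery proportion (default: every planted, non-null class).
#' @return List with `per_class` (`data.frame` of planted/recovered counts
#'   and sensitivity per class), `fdp`, `fdp_defined` (`FALSE` and `fdp = 0`
#'   for an empty list) and `n_selected`.
#' @export
evaluate_recovery <- function(selected, truth,
                              positive_classes = setdiff(unique(truth$class), "null")) {
  selected <- unique(selected)
  unknown <- setdiff(selected, truth$probe_id)
  if (length(unknown)) {
    stop("selected probe(s) absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  cls <- split(truth$probe_id, truth$class)
  per_class <- do.call(rbind, lapply(names(cls), function(cname) {
    planted <- cls[[cname]]
    data.frame(class = cname,
               planted = length(planted),
               recovered = length(intersect(selected, planted)),
               sensitivity = length(intersect(selected, planted)) / length(planted),
               stringsAsFactors = FALSE)
  }))
  positives <- unlist(cls[intersect(positive_classes, names(cls))], use.names = FALSE)
  n_sel <- length(selected)
  fdp_defined <- n_sel > 0
  fdp <- if (fdp_defined) length(setdiff(selected, positives)) / n_sel else 0
  list(per_class = per_class, fdp = fdp, fdp_defined = fdp_defined,
       n_selected = n_sel)
}

#' Write a full synthetic study bundle to disk
#'
#' Materialises one simulated dataset as plain-text files: snapshot and
#' quantitative matrices + sample sheets (TSV), probe annotation (TSV), QTL
#' intervals (BED), truth-derived gene sets (GMT) and the truth table (TSV).
#'
#' @inheritParams generate_annotation
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_study_files <- function(cfg, dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(cfg, seed)
  snap <- generate_snapshot(cfg, seed)
  quant <- generate_quantitative(cfg, seed)
  paths <- list(
    snapshot_matrix = file.path(dir, "snapshot_matrix.tsv"),
    snapshot_samples = file.path(dir, "snapshot_samples.tsv"),
    quant_matrix = file.path(dir, "quant_matrix.tsv"),
    quant_samples = file.path(dir, "quant_samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    intervals = file.path(dir, "qtl_intervals.bed"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_study(snap$study, paths$snapshot_matrix, paths$snapshot_samples)
  write_expression_study(quant$study, paths$quant_matrix, paths$quant_samples)
  write_probe_annotation(ann$annotation, paths$annotation)
  write_qtl_intervals(ann$intervals, paths$intervals)
  write_gene_sets(truth_gene_sets(ann$truth, ann$annotation), paths$gene_sets)
  truth <- merge(snap$truth, ann$truth[, c("probe_id", "in_qtl")], by = "probe_id")
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
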