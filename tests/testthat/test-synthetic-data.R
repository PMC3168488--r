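small_cfg <- function(...) {
  generator_config(n_probes = 200,
                   class_counts = c(adipose_F_up = 20, adipose_L_up = 5,
                                    depot_specific = 9,
                                    all_tissue_bystander = 10,
                                    diet_amplified = 10),
                   ...)
}

test_that("all generator outputs are pure functions of (config, seed)", {
  cfg <- small_cfg()
  a <- generate_snapshot(cfg, seed = 4)
  b <- generate_snapshot(cfg, seed = 4)
  expect_identical(a$study$intensities, b$study$intensities)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$study$intensities,
                         generate_snapshot(cfg, seed = 5)$study$intensities))
  qa <- generate_quantitative(cfg, seed = 4)
  qb <- generate_quantitative(cfg, seed = 4)
  expect_identical(qa$study$intensities, qb$study$intensities)
  na_ <- generate_annotation(cfg, seed = 4)
  nb <- generate_annotation(cfg, seed = 4)
  expect_identical(na_$annotation, nb$annotation)
})

test_that("in the near-noise-free limit planted folds are exact", {
  cfg <- generator_config(n_probes = 50,
                          class_counts = c(adipose_F_up = 10,
                                           all_tissue_bystander = 5),
                          effects = list(adipose_F_up = 2,
                                         all_tissue_bystander = 6),
                          noise_sd = 1e-9)
  out <- generate_snapshot(cfg, seed = 1)
  sfc <- sfc_matrix(out$study)
  up <- out$truth$class == "adipose_F_up"
  expect_equal(unname(sfc[up, c("SC", "EPI", "MES")]),
               matrix(4, sum(up), 3), tolerance = 1e-6)
  # sfc magnitude is exactly 1 in the limit; its sign is undefined at equality
  expect_equal(abs(unname(sfc[up, c("LIV", "MUS", "KID")])),
               matrix(1, sum(up), 3), tolerance = 1e-6)
  by <- out$truth$class == "all_tissue_bystander"
  expect_equal(unname(sfc[by, ]), matrix(64, sum(by), 6), tolerance = 1e-5)
})

test_that("log2 pooling shrinks chip noise by sqrt(pool size)", {
  cfg <- generator_config(n_probes = 10000, class_counts = c(adipose_F_up = 0),
                          noise_sd = 0.3, pool_size = 3)
  out <- generate_snapshot(cfg, seed = 9)
  # F - L difference of two pooled chips of a null probe:
  # sd = sqrt(2) * noise_sd / sqrt(pool)
  d <- log2(out$study$intensities[, "F_SC"]) -
    log2(out$study$intensities[, "L_SC"])
  expect_equal(sd(d), sqrt(2) * 0.3 / sqrt(3), tolerance = 0.1)
})

test_that("QTL placement honours the configured planted fraction", {
  cfg <- generator_config(n_probes = 400,
                          class_counts = c(adipose_F_up = 200),
                          qtl_fraction = 0.5)
  out <- generate_annotation(cfg, seed = 21)
  planted <- out$truth$class == "adipose_F_up"
  hits <- assign_to_qtls(out$annotation[planted, ], out$intervals)
  expect_identical(hits$in_qtl, out$truth$in_qtl[planted])
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(sum(hits$in_qtl), bounds[1])
  expect_lte(sum(hits$in_qtl), bounds[2])

  cfg1 <- generator_config(n_probes = 60, class_counts = c(adipose_F_up = 30),
                           qtl_fraction = 1)
  out1 <- generate_annotation(cfg1, seed = 3)
  h1 <- assign_to_qtls(out1$annotation, out1$intervals)
  expect_true(all(h1$in_qtl[out1$truth$class == "adipose_F_up"]))

  cfg0 <- generator_config(n_probes = 60, class_counts = c(adipose_F_up = 30),
                           qtl_fraction = 0)
  out0 <- generate_annotation(cfg0, seed = 3)
  h0 <- assign_to_qtls(out0$annotation, out0$intervals)
  expect_false(any(h0$in_qtl[out0$truth$class == "adipose_F_up"]))

  expect_error(
    generate_annotation(
      generator_config(n_probes = 10, class_counts = c(adipose_F_up = 5),
                       qtl = synthetic_qtl_intervals()[0, ],
                       qtl_fraction = 0.5), seed = 1),
    "non-empty QTL")
})

test_that("bystander probes behave like the all-tissue exclusion example", {
  cfg <- small_cfg()
  out <- generate_snapshot(cfg, seed = 6)
  by <- out$truth$probe_id[out$truth$class == "all_tissue_bystander"]
  # large same-sign folds everywhere...
  sfc <- sfc_matrix(out$study)
  expect_true(all(sfc[by, ] > 2))
  # ...so any windowed filter rejects them
  lists <- coordinate_3wat_filter(out$study, filter_config(1.5, 1.5))
  expect_length(intersect(by, c(lists$up_F, lists$up_L)), 0)
  # without a window they would flood the coordinate list
  open <- coordinate_3wat_filter(out$study, filter_config(1.5, NULL))
  expect_true(all(by %in% open$up_F))
})

test_that("recovery metrics match their definitions on constructed lists", {
  truth <- data.frame(probe_id = paste0("p", 1:10),
                      class = rep(c("adipose_F_up", "null"), each = 5),
                      stringsAsFactors = FALSE)
  planted <- paste0("p", 1:5)
  r <- evaluate_recovery(planted, truth, positive_classes = "adipose_F_up")
  expect_equal(r$per_class$sensitivity[r$per_class$class == "adipose_F_up"], 1)
  expect_equal(r$fdp, 0)
  r <- evaluate_recovery(character(), truth)
  expect_equal(r$per_class$sensitivity, c(0, 0))
  expect_false(r$fdp_defined)
  expect_equal(r$fdp, 0)
  r <- evaluate_recovery(c(planted[1:4], "p9"), truth,
                         positive_classes = "adipose_F_up")
  expect_equal(r$fdp, 0.2)
  expect_error(evaluate_recovery("nope", truth), "absent from truth")
})

test_that("diet-amplified probes are labelled correctly in most replicates", {
  cfg <- generator_config(n_probes = 500,
                          class_counts = c(diet_amplified = 100),
                          effects = list(diet_amplified = c(1, 2)),
                          noise_sd = 0.2, replicates = 4)
  hits <- 0; total <- 0
  for (seed in 1:2) {
    out <- generate_quantitative(cfg, seed = seed)
    de <- do.call(rbind, lapply(
      c("FCvsLC", "FFvsLF", "FFvsFC", "LFvsLC"),
      function(ct) moderated_t_test(out$study, ct)))
    means <- quant_group_means(out$study)
    sig <- sapply(c("FCvsLC", "FFvsLF", "FFvsFC", "LFvsLC"), function(ct) {
      d <- de[de$contrast == ct, ]
      d$padj[match(means$probe_id, d$probe_id)] < 0.05
    })
    lab <- classify_diet_response(means[, c("FC", "FF", "LC", "LF")], sig)
    amp <- out$truth$class == "diet_amplified"
    hits <- hits + sum(lab[amp] == "diet_amplified")
    total <- total + sum(amp)
  }
  expect_gte(hits / total, 0.95)
})

test_that("under a pure-null generator the reporting filter retains almost nothing", {
  cfg <- generator_config(n_probes = 1000, class_counts = c(adipose_F_up = 0))
  out <- generate_quantitative(cfg, seed = 12)
  de <- moderated_t_test(out$study, "FFvsLF")
  t5 <- de_candidate_filter(de)
  expect_lte(length(c(t5$FFvsLF$up, t5$FFvsLF$down)), 1)
})

test_that("simulated study bundles round-trip from disk", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  paths <- simulate_study_files(cfg, dir, seed = 8)
  snap <- read_expression_study(paths$snapshot_matrix, paths$snapshot_samples)
  expect_identical(snap$intensities,
                   generate_snapshot(cfg, seed = 8)$study$intensities)
  ann <- read_probe_annotation(paths$annotation)
  expect_equal(nrow(ann), cfg$n_probes)
  iv <- read_qtl_intervals(paths$intervals)
  expect_identical(iv$name, paste0("Fob", 1:4))
  expect_equal(iv$start_bp, synthetic_qtl_intervals()$start_bp)
  gs <- read_gene_sets(paths$gene_sets)
  expect_true("planted_adipose_F_up" %in% names(gs))
})
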