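test_that("simulation is byte-identical for a fixed seed", {
  b1 <- simulate_bundle(tiny_config())
  b2 <- simulate_bundle(tiny_config())
  expect_identical(vapply(b1$transcriptome, `[[`, "", "residues"),
                   vapply(b2$transcriptome, `[[`, "", "residues"))
  expect_identical(b1$toxin_db, b2$toxin_db)
  expect_identical(b1$animal_db, b2$animal_db)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_bundle(tiny_config(seed = 12L))
  expect_false(identical(b1$counts$count, b3$counts$count))
})

test_that("truth labels partition the transcriptome", {
  b <- tiny_bundle()
  expect_setequal(b$truth$contig_id, names(b$transcriptome))
  expect_equal(anyDuplicated(b$truth$contig_id), 0L)
  expect_true(all(b$truth$class %in%
                  c("toxin", "housekeeping", "knottin", "noise")))
})

test_that("counts are positive, heavy-tailed, and knottins clear the gate", {
  cfg <- sim_config(seed = 5L)
  b <- simulate_bundle(cfg)
  expect_true(all(b$counts$count >= 1L))
  fpkm <- compute_fpkm(b$counts)
  expect_gt(max(fpkm$fpkm) / median(fpkm$fpkm), 50)   # heavy tail
  knot <- b$truth$contig_id[b$truth$class == "knottin"]
  thr <- top_fraction_threshold(fpkm$fpkm, cfg$top_fraction)
  kf <- fpkm$fpkm[fpkm$contig_id %in% knot]
  expect_true(all(kf >= thr))
  # enforced rate margin over the best non-knottin
  rate <- b$counts$count / b$counts$length_bp
  is_k <- b$counts$contig_id %in% knot
  expect_gte(min(rate[is_k]), 1.3 * max(rate[!is_k]))
})

test_that("planted structural margins hold", {
  b <- tiny_bundle()
  truth <- b$truth
  # truncations remove more than margin + 10 residues
  tr <- truth[!is.na(truth$completeness) &
              truth$completeness %in% c("NTE", "CTE", "NC"), ]
  expect_gt(nrow(tr), 0)
  # annotations: neutral text never matches a toxin keyword
  neutral <- b$annotations[
    b$annotations$unigene_id %in%
      truth$contig_id[truth$class == "housekeeping"][-1], ]
  hk_tox <- truth$contig_id[truth$class == "housekeeping"][1]  # decoy
  expect_true(hk_tox %in% select_by_keywords(b$annotations))
  # dual-filter margin is positive for planted toxins by construction
  cand <- tiny_candidates()
  non_venom <- cand[!cand$animal_is_venomous & !is.na(cand$animal_bit), ]
  expect_true(all(non_venom$toxin_bit > non_venom$animal_bit))
})

test_that("expansion planting is plain arithmetic on the family table", {
  cfg <- tiny_config()
  cfg2 <- plant_expansion(cfg, "kazal", 5)
  i <- match("kazal", cfg2$families$toxin_class)
  expect_equal(cfg2$families$expansion_factor[i], 5L)
  expect_identical(plant_expansion(cfg, "kazal", 1)$families, cfg$families)
  expect_error(plant_expansion(cfg, "nope", 2), "unknown family")
  r <- chi_square_gof(c(60, 12, 12, 12, 12))
  expect_lt(r$p_value, 0.05)
})

test_that("inconsistent configurations are rejected", {
  # too many knottins for the expression gate to hold
  cfg <- tiny_config()
  cfg$n_knottins <- 8L
  expect_error(simulate_bundle(cfg), "top-")
  expect_error(sim_config(n_probe = c(ghost = 1L)), "probe family")
  expect_error(sim_config(divergence = 0.5))
})

test_that("bundles round-trip through plain files", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_identical(vapply(back$transcriptome, `[[`, "", "residues"),
                   vapply(b$transcriptome, `[[`, "", "residues"))
  expect_equal(back$counts, b$counts)
  expect_equal(as.data.frame(back$toxin_db), as.data.frame(b$toxin_db),
               ignore_attr = TRUE)
  expect_identical(back$planted_counts, b$planted_counts)
  file.remove(file.path(dir, "counts.tsv"))
  expect_error(read_bundle(dir), "counts.tsv")
})
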