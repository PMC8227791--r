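# Packaged reference tables and the planted-motif promoter generator.

test_that("the packaged per-mask reference tables load with full fidelity", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$table1_edr), 48L)
  expect_equal(nrow(fx$table1_ked), 48L)
  # every row's best sequence carries the row's mask (96-row sweep)
  expect_equal(mask_of(fx$table1_edr$best_sequence), fx$table1_edr$mask)
  expect_equal(mask_of(fx$table1_ked$best_sequence), fx$table1_ked$mask)
  # anchor rows used to calibrate the synthetic model
  edr <- fx$table1_edr
  expect_equal(edr$mean_score[edr$mask == "WWWWWW"], -31.76)
  expect_equal(edr$mean_score[edr$mask == "SSSSSS"], -37.31)
  row <- edr[edr$mask == "SWSWSS", ]
  expect_equal(row$mean_score, -38.67)
  expect_equal(row$std_score, 3.24)
  expect_equal(row$best_score, -44.71)
  expect_equal(row$best_sequence, "GAGTGG")
  ked <- fx$table1_ked
  last <- ked[ked$mask == "WWWSWW", ]
  expect_equal(last$mean_score, -11.90)
  expect_equal(last$best_score, -22.18)
  expect_equal(last$best_sequence, "ATAGTA")
})

test_that("the packaged occurrence reference covers 9 masks of the gene panel", {
  fx <- load_fixtures()
  expect_length(fx$genes, 11L)
  expect_setequal(fx$genes, c("CASP3", "TP53", "SOD2", "GPX1", "PPARA",
                              "PPARG", "NES", "GAP43", "SUMO1", "APOE",
                              "IGF1"))
  expect_equal(length(unique(fx$table2$mask)), 9L)
  expect_true(all(fx$table2$gene %in% fx$genes))
  expect_true(all(fx$table2$count >= 1))
  # occurrence reference masks are top EDR clusters
  expect_true(all(fx$table2$mask %in% fx$table1_edr$mask))
})

test_that("plant specifications are validated", {
  expect_error(plant_spec("GAGTGG", 2, positions = c(1, 3)),
               "planted windows overlap")
  expect_error(plant_spec("GAGTGG", 2, positions = 1), "length")
  expect_error(plant_spec("GAGTG1", 1), "invalid base")
  expect_silent(plant_spec("GAGTGG", 0))
})

test_that("generated promoters carry exactly the planted counts", {
  gp <- generate_promoter(600, plants = list(plant_spec("GAGTGG", 3)),
                          seed = 31, gene = "NES")
  expect_equal(nchar(gp$record$sequence), 600L)
  # verified against the naive counting oracle over all four variants
  v <- compile_variants(gp$record$sequence, dedup = TRUE)
  expect_equal(sum(vapply(v, function(t) oracle_count("GAGTGG", t), 0L)), 3L)
  expect_equal(gp$truth$count, 3L)

  # a zero plant means verified absence
  gp0 <- generate_promoter(400, plants = list(plant_spec("GAGTGG", 0)),
                           seed = 32)
  v0 <- compile_variants(gp0$record$sequence, dedup = TRUE)
  expect_equal(sum(vapply(v0, function(t) oracle_count("GAGTGG", t), 0L)), 0L)
})

test_that("plants land on the requested variant and explicit positions", {
  for (var in c("original", "complement", "reverse", "reverse_complement")) {
    gp <- generate_promoter(400, plants = list(plant_spec("GAGTGG", 2,
                                                          variant = var)),
                            seed = 41, gene = var)
    v <- compile_variants(gp$record$sequence)
    expect_equal(oracle_count("GAGTGG", v[[var]]), 2L,
                 label = paste("variant", var))
  }
  gp <- generate_promoter(50, plants = list(plant_spec("GAGTGG", 2,
                                                       positions = c(5, 30))),
                          seed = 42)
  expect_equal(substr(gp$record$sequence, 5, 10), "GAGTGG")
  expect_equal(substr(gp$record$sequence, 30, 35), "GAGTGG")
})

test_that("the generator is deterministic and fails cleanly when infeasible", {
  g1 <- generate_promoter(300, plants = list(plant_spec("GAGTGG", 2)),
                          seed = 9)
  g2 <- generate_promoter(300, plants = list(plant_spec("GAGTGG", 2)),
                          seed = 9)
  expect_identical(g1$record$sequence, g2$record$sequence)
  g3 <- generate_promoter(300, plants = list(plant_spec("GAGTGG", 2)),
                          seed = 10)
  expect_false(identical(g1$record$sequence, g3$record$sequence))

  expect_error(generate_promoter(10, plants = list(plant_spec("GAGTGG", 3))),
               "do not fit")
  # absence of "A" is unverifiable: every base's variant set contains both
  # the base and its complement, so the retry budget must be exhausted
  expect_error(generate_promoter(1, gc_fraction = 0,
                                 plants = list(plant_spec("A", 0)),
                                 seed = 1, max_tries = 3),
               "could not realise")
})

test_that("demo bundles are self-consistent and reproducible", {
  d1 <- tempfile("bundle")
  d2 <- tempfile("bundle")
  make_demo_bundle(d1, seed = 2)
  make_demo_bundle(d2, seed = 2)
  files <- list.files(d1)
  expect_setequal(files, c("duplexes_k6.tsv", "manifest.json",
                           "occurrences.json", "occurrences.tsv",
                           "promoters.fasta", "scores_EDR.tsv",
                           "scores_KED.tsv", "summary_EDR.tsv",
                           "summary_KED.tsv"))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$n_duplexes, 2080L)
  # rescan the bundle promoters: totals must reproduce the manifest
  proms <- read_promoters(file.path(d1, "promoters.fasta"))
  rep <- scan_promoters(list(needle(manifest$needle)), proms)
  for (g in names(manifest$planted_counts)) {
    expect_equal(rep$total[rep$gene == g],
                 manifest$planted_counts[[g]], label = g)
  }
  # summaries conserve the simulated records
  sm <- read_mask_summary(file.path(d1, "summary_EDR.tsv"))
  expect_equal(sum(sm$n), 2080L)
})
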