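test_that("the generator is fully deterministic under its seed", {
  cfg <- synthetic_config(n_genes = 300, n_pathways = 10,
                          pathway_size_range = c(5, 20), seed = 9,
                          profiles = platform_profile("SYN", 2e4, 0.3, 2))
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$matrices, b$matrices)

  cfg2 <- synthetic_config(n_genes = 300, n_pathways = 10,
                           pathway_size_range = c(5, 20), seed = 10,
                           profiles = platform_profile("SYN", 2e4, 0.3, 2))
  c <- simulate_experiment(cfg2)
  expect_false(identical(a$matrices$SYN$`SYN-1`, c$matrices$SYN$`SYN-1`))

  # replicates within one experiment are distinct draws
  expect_false(identical(a$matrices$SYN$`SYN-1`, a$matrices$SYN$`SYN-2`))
})

test_that("degenerate abundance spread gives equal abundances", {
  cfg <- synthetic_config(n_genes = 50, abundance_meanlog = 1,
                          abundance_sdlog = 0, n_pathways = 2,
                          pathway_size_range = c(3, 5), seed = 1)
  cat <- generate_catalog(cfg)
  expect_equal(cat$genes$abundance, rep(exp(1), 50))
})

test_that("catalog draws follow the configured log-normal", {
  cfg <- synthetic_config(n_genes = 10000, abundance_meanlog = 0.5,
                          abundance_sdlog = 2.2, seed = 3)
  cat <- generate_catalog(cfg)
  se <- 2.2 / sqrt(10000)
  expect_lt(abs(mean(log(cat$genes$abundance)) - 0.5), 3 * se)
  expect_true(all(cat$genes$abundance > 0))
  # transcript shares sum to one per gene
  sums <- tapply(cat$transcripts$share, cat$transcripts$gene_id, sum)
  expect_equal(unname(c(sums)), rep(1, 10000), tolerance = 1e-12)
})

test_that("each simulated replicate's TPM sums to exactly one million", {
  sim <- small_sim(seed = 5)
  for (r in replicate_ids(sim$matrices$SYN)) {
    expect_equal(sum(sim$matrices$SYN[[r]]), 1e6)
  }
  expect_equal(dim(sim$matrices$SYN), c(400L, 4L))
})

test_that("activation injection scales exactly its member genes and inverts", {
  cfg <- synthetic_config(n_genes = 200, n_pathways = 5,
                          pathway_size_range = c(5, 10), seed = 21)
  cat0 <- generate_catalog(cfg)
  cat2 <- inject_activation(cat0, "pw002", 2)
  members <- cat0$pathways$genes[[2]]
  idx <- cat0$genes$gene_id %in% members
  expect_equal(cat2$genes$abundance[idx], 2 * cat0$genes$abundance[idx])
  expect_equal(cat2$genes$abundance[!idx], cat0$genes$abundance[!idx])
  expect_identical(inject_activation(cat2, "pw002", 1), cat2)
  restored <- inject_activation(cat2, "pw002", 0.5)
  expect_equal(restored$genes$abundance, cat0$genes$abundance)
  expect_error(inject_activation(cat0, "nope", 2), "Unknown pathway")
})

test_that("detection increases with sequencing depth", {
  cfg <- synthetic_config(n_genes = 2000, n_pathways = 2,
                          pathway_size_range = c(5, 10), seed = 31)
  cat <- generate_catalog(cfg)
  shallow <- platform_profile("lo", 5e4, 0.3, 1)
  deep <- platform_profile("hi", 5e6, 0.3, 1)
  wins <- 0
  for (s in 1:8) {
    n_lo <- sum(simulate_replicate(cat, shallow, s)$tpm > 0)
    n_hi <- sum(simulate_replicate(cat, deep, s)$tpm > 0)
    wins <- wins + (n_hi > n_lo)
  }
  expect_gte(wins, 7)
})

test_that("TPM proportions converge to normalized abundances at high depth", {
  cfg <- synthetic_config(n_genes = 500, n_pathways = 2,
                          pathway_size_range = c(3, 5), seed = 41)
  cat <- generate_catalog(cfg)
  prof <- platform_profile("deep", 1e8, 0, 1)
  tpm <- simulate_replicate(cat, prof, 7)$tpm
  expected <- 1e6 * cat$genes$abundance / sum(cat$genes$abundance)
  big <- expected > 1000  # relative error meaningful only off the floor
  expect_lt(max(abs(tpm[big] - expected[big]) / expected[big]), 0.01)
})

test_that("transcript expansion conserves gene TPM through aggregation", {
  sim <- small_sim(seed = 51)
  rep1 <- tibble::tibble(gene_id = sim$matrices$SYN$gene_id,
                         tpm = sim$matrices$SYN[[2]])
  quant <- transcript_quant(sim$catalog, rep1)
  map <- sim$catalog$transcripts[, c("transcript_id", "gene_id")]
  agg <- aggregate_to_genes(quant, map)
  merged <- dplyr::left_join(rep1, agg, by = "gene_id")
  expect_equal(merged$tpm.x, merged$tpm.y, tolerance = 1e-9)
})

test_that("replicate noise lands the median CV in a plausible band", {
  # ONT-like noise at moderate scale: median per-gene CV between 20 and 55%
  meds <- vapply(1:3, function(s) {
    sim <- small_sim(seed = 300 + s, n_replicates = 4, depth = 2e5,
                     n_genes = 2000)
    cv_report(sim$matrices$SYN)$median_cv
  }, numeric(1))
  expect_true(all(meds > 20 & meds < 55))
})
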