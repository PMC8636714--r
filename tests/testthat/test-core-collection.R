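test_that("allele coverage counts (locus, allele) pairs through any carrier", {
  g <- random_geno(20, 10, seed = 41)
  expect_equal(allele_coverage(g, accession_ids(g)), 100)

  # one fully homozygous accession on an all-polymorphic panel covers half
  n <- 10
  tab <- tibble::as_tibble(matrix("AA", n, 6), .name_repair = "minimal")
  names(tab) <- paste0("M", 1:6)
  tab[2, ] <- "BB" # makes every locus polymorphic
  g2 <- geno_tbl(dplyr::bind_cols(
    tibble::tibble(accession_id = paste0("a", 1:n)), tab
  ))
  expect_equal(allele_coverage(g2, "a1"), 50)
  expect_equal(allele_coverage(g2, c("a1", "a2")), 100)

  # a heterozygote carries both alleles
  g3 <- geno_tbl(tibble::tibble(
    accession_id = c("a1", "a2", "a3"), M1 = c("AB", "AA", "BB")
  ))
  expect_equal(allele_coverage(g3, "a1"), 100)

  expect_error(allele_coverage(g, character(0)), "empty")
  expect_error(allele_coverage(g, "nope"), "unknown")
})

# panel where a1 and a2 are the sole carriers of two private alleles
private_allele_panel <- function() {
  n <- 10
  tab <- tibble::as_tibble(matrix("AA", n, 8), .name_repair = "minimal")
  names(tab) <- paste0("M", 1:8)
  tab$M1[3:10] <- "BB" # polymorphic background
  tab$M7 <- "AA"; tab$M7[1] <- "BB" # private to a1
  tab$M8 <- "BB"; tab$M8[2] <- "AA" # private to a2
  geno_tbl(dplyr::bind_cols(
    tibble::tibble(accession_id = paste0("a", 1:n)), tab
  ))
}

test_that("coverage necessity forces private-allele carriers into the core", {
  g <- private_allele_panel()
  for (seed in 1:3) {
    core <- select_core(g, core_config(
      target_count = 4, seed = seed, max_swap_iters = 200
    ))
    expect_true(all(c("a1", "a2") %in% core$core_ids))
    expect_equal(core$metrics$CV, 100)
  }
})

test_that("infeasible coverage targets fail with the minimum feasible size", {
  g <- private_allele_panel()
  expect_error(
    select_core(g, core_config(target_count = 1)),
    "at least"
  )
})

test_that("evaluation metrics match a brute-force recomputation", {
  g <- random_geno(8, 6, seed = 52, missing_rate = 0.05)
  ids <- accession_ids(g)[c(1, 3, 5, 7)]
  ev <- evaluate_core(g, ids)

  sub <- geno_subset(g, accessions = ids)
  mr <- oracle_distance(sub, "modified_rogers")
  ce <- oracle_distance(sub, "cavalli_sforza_edwards")
  expect_equal(ev$MR, mean(mr[upper.tri(mr)]), tolerance = 1e-12)
  expect_equal(ev$CE, mean(ce[upper.tri(ce)]), tolerance = 1e-12)

  per_locus <- lapply(marker_ids(sub), function(m) oracle_locus_stats(sub, m))
  expect_equal(ev$HE, mean(vapply(per_locus, `[[`, 1, "he")), tolerance = 1e-12)
  expect_equal(ev$PIC, mean(vapply(per_locus, `[[`, 1, "pic")), tolerance = 1e-12)
  ne <- vapply(per_locus, function(o) 1 / (o$p^2 + (1 - o$p)^2), 1)
  expect_equal(ev$NE, mean(ne), tolerance = 1e-12)
  expect_equal(ev$SH, shannon_index_pooled(sub))
  expect_equal(ev$CV, allele_coverage(g, ids))

  # core = whole reproduces whole-panel statistics
  ev_all <- evaluate_core(g, accession_ids(g))
  s <- panel_summary(g)
  expect_equal(ev_all$HE, mean(s$he))
  expect_equal(ev_all$CV, 100)

  # identical accessions have zero mean distance
  same <- geno_tbl(tibble::tibble(
    accession_id = c("x", "y", "z"),
    M1 = "AA", M2 = "AB", M3 = "BB"
  ))
  expect_equal(evaluate_core(same, c("x", "y", "z"))$MR, 0)
})

test_that("optimized cores keep full coverage and never lose objective", {
  for (seed in 1:3) {
    g <- simulate_structured_panel(panel_sim_config(
      n_accessions = 60, n_markers = 30, seed = 60 + seed
    ))
    no_swap <- select_core(g, core_config(
      target_fraction = 0.5, seed = seed, n_restarts = 1, max_swap_iters = 0
    ))
    core <- select_core(g, core_config(
      target_fraction = 0.5, seed = seed, max_swap_iters = 500
    ))
    # coverage asserted post hoc, independent of optimizer internals
    expect_equal(allele_coverage(g, core$core_ids), 100)
    expect_gte(core$objective, no_swap$objective)
    expect_equal(length(core$core_ids), 30L)
  }
})

test_that("optimized cores beat random same-size cores on mean E-NE", {
  g <- simulate_structured_panel(panel_sim_config(
    n_accessions = 60, n_markers = 30, seed = 71
  ))
  core <- select_core(g, core_config(target_fraction = 0.5, seed = 1,
                                     max_swap_iters = 500))
  D <- as.matrix(pairwise_distance(g, "modified_rogers"))
  wins <- withr::with_seed(99, {
    sum(vapply(1:100, function(i) {
      rnd <- sample(accession_ids(g), length(core$core_ids))
      core$objective >= oracle_mean_ene(D, rnd)
    }, logical(1)))
  })
  expect_gte(wins, 99L)
})

test_that("coverage is monotone under nested greedy initialization", {
  g <- simulate_structured_panel(panel_sim_config(
    n_accessions = 50, n_markers = 25, maf_floor = 0.02, seed = 83
  ))
  # without the coverage constraint the greedy+farthest-point initial cores
  # are nested as the target grows, so CV cannot decrease
  cvs <- vapply(seq(5, 50, by = 5), function(target) {
    core <- select_core(g, core_config(
      target_count = target, require_full_coverage = FALSE,
      n_restarts = 1, max_swap_iters = 0, seed = 1
    ))
    allele_coverage(g, core$core_ids)
  }, numeric(1))
  expect_true(all(diff(cvs) >= -1e-9))
})

test_that("forced accessions are always retained", {
  g <- simulate_structured_panel(panel_sim_config(
    n_accessions = 40, n_markers = 20, seed = 90
  ))
  forced <- c("acc001", "acc040")
  core <- select_core(g, core_config(
    target_count = 10, forced_ids = forced, seed = 4, max_swap_iters = 300
  ))
  expect_true(all(forced %in% core$core_ids))
  expect_true(all(tidy(core)$forced == (tidy(core)$accession_id %in% forced)))
  expect_error(
    select_core(g, core_config(target_count = 5, forced_ids = "ghost")),
    "unknown"
  )
})
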