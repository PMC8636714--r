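test_that("codes use the A/H/B/N alphabet in panel order", {
  g <- geno_tbl(tibble::tibble(
    accession_id = c("s1", "s2"),
    M1 = c("AA", "AA"), M2 = c("AB", "AB"), M3 = c("BB", "BB"), M4 = c(NA, NA)
  ))
  fp <- fingerprint(g, c("M1", "M2", "M3", "M4"), "s1")
  expect_equal(fp$code, "AHBN")
  expect_equal(fp$payload, fp$code)

  # identical calls give identical codes; reordering the panel reorders symbols
  fps <- fingerprints(g, c("M1", "M2", "M3", "M4"))
  expect_equal(fps$code[1], fps$code[2])
  expect_equal(fingerprint(g, c("M3", "M1"), "s1")$code, "BA")

  expect_error(fingerprint(g, "M9", "s1"), "unknown marker")
  expect_error(fingerprint(g, "M1", "s9"), "unknown accession")
})

test_that("code space over n markers is exactly 3^n excluding no-calls", {
  g <- random_geno(30, 2, seed = 3, missing_rate = 0)
  fps <- fingerprints(g, c("M1", "M2"))
  expect_true(all(fps$code %in% as.vector(outer(
    c("A", "H", "B"), c("A", "H", "B"), paste0
  ))))
  expect_identical(panel_capacity(2), 9)
})

test_that("distinct code count agrees with the saturation curve endpoint", {
  g <- simulate_structured_panel(panel_sim_config(
    n_accessions = 40, n_markers = 30, seed = 14
  ))
  p <- select_core_panel(g, max_per_chrom = 3)
  fps <- fingerprints(g, p)
  expect_equal(
    dplyr::n_distinct(fps$code),
    utils::tail(p$saturation$n_distinct, 1)
  )
})

test_that("duplicate grouping is single-linkage over the mismatch graph", {
  g <- random_geno(10, 22, seed = 9, missing_rate = 0)
  g <- plant_known_duplicates(g, list(c("acc1", "acc2")))
  fps <- fingerprints(g, marker_ids(g))
  groups <- find_duplicates(fps)
  expect_equal(nrow(groups), 2L)
  expect_setequal(groups$accession_id, c("acc1", "acc2"))

  # all-distinct panel: no groups at zero tolerance
  g2 <- random_geno(8, 22, seed = 10, missing_rate = 0)
  fps2 <- fingerprints(g2, marker_ids(g2))
  expect_equal(nrow(find_duplicates(fps2)), 0L)

  # a single-locus difference is grouped at tolerance 1 but not 0
  tab <- tibble::as_tibble(g2)
  tab[2, -1] <- tab[1, -1]
  tab$M2[2] <- setdiff(c("AA", "AB", "BB"), tab$M2[1])[1]
  g3 <- geno_tbl(tab)
  fps3 <- fingerprints(g3, marker_ids(g3))
  mm <- sum(strsplit(fps3$code[1], "")[[1]] != strsplit(fps3$code[2], "")[[1]])
  expect_equal(mm, 1L)
  grouped <- find_duplicates(fps3, max_mismatch = 1)
  expect_true(all(c(fps3$accession_id[1:2]) %in% grouped$accession_id))
  strict <- find_duplicates(fps3, max_mismatch = 0)
  expect_false(any(fps3$accession_id[1:2] %in% strict$accession_id))
})

test_that("authentication verdicts follow the completeness floor", {
  g <- random_geno(2, 22, seed = 25, missing_rate = 0)
  panel <- marker_ids(g)
  ref <- fingerprint(g, panel, "acc1")

  expect_equal(authenticate(ref, ref)$verdict, "match")
  expect_equal(authenticate(ref, ref)$match_rate, 1)

  # one mismatch in 22: mismatch verdict at 21/22
  tab <- tibble::as_tibble(g)
  tab[2, -1] <- tab[1, -1]
  tab$M5[2] <- setdiff(c("AA", "AB", "BB"), tab$M5[1])[1]
  g2 <- geno_tbl(tab)
  rep <- authenticate(
    fingerprint(g2, panel, "acc2"), fingerprint(g2, panel, "acc1")
  )
  expect_equal(rep$verdict, "mismatch")
  expect_equal(rep$n_compared, 22)
  expect_equal(rep$match_rate, 21 / 22, tolerance = 1e-12)

  # 17 of 22 loci missing: 5 compared < floor(0.8 * 22) = 17 -> inconclusive
  tab2 <- tibble::as_tibble(g)
  tab2[2, -1] <- tab2[1, -1]
  tab2[2, 1 + 1:17] <- NA_character_
  g3 <- geno_tbl(tab2)
  rep2 <- authenticate(
    fingerprint(g3, panel, "acc2"), fingerprint(g3, panel, "acc1")
  )
  expect_equal(rep2$n_compared, 5)
  expect_equal(rep2$verdict, "inconclusive")

  # self-match is perfect on complete data for every accession
  g4 <- random_geno(6, 12, seed = 26, missing_rate = 0)
  for (id in accession_ids(g4)) {
    fp <- fingerprint(g4, marker_ids(g4), id)
    expect_equal(authenticate(fp, fp)$verdict, "match")
  }
})

test_that("hybrid purity classifies seeds over diagnostic loci", {
  panel <- paste0("M", 1:5)
  p1 <- structure(
    tibble::tibble(accession_id = "P1", code = "AAAAA", payload = "AAAAA"),
    panel = panel
  )
  p2 <- structure(
    tibble::tibble(accession_id = "P2", code = "BBBBB", payload = "BBBBB"),
    panel = panel
  )
  lot <- tibble::as_tibble(matrix("AB", 100, 5), .name_repair = "minimal")
  names(lot) <- panel
  lot[96:100, ] <- "AA"
  lot <- geno_tbl(dplyr::bind_cols(
    tibble::tibble(accession_id = sprintf("seed%03d", 1:100)), lot
  ))
  rep <- hybrid_purity(lot, p1, p2, panel)
  expect_equal(rep$summary$purity, 0.95)
  expect_equal(rep$summary$n_selfed, 5)
  expect_equal(rep$summary$n_diagnostic, 5)

  expect_error(hybrid_purity(lot, p1, p1, panel), "diagnostic")
})

test_that("purity recovers a known selfing rate within binomial error", {
  n_seeds <- 400
  selfing <- 0.02
  panel <- paste0("M", 1:8)
  withr::with_seed(55, {
    selfed <- stats::runif(n_seeds) < selfing
    calls <- matrix("AB", n_seeds, 8)
    calls[selfed, ] <- "AA"
    calls[stats::runif(length(calls)) < 0.03] <- NA_character_
  })
  tab <- tibble::as_tibble(calls, .name_repair = "minimal")
  names(tab) <- panel
  lot <- geno_tbl(dplyr::bind_cols(
    tibble::tibble(accession_id = sprintf("s%04d", 1:n_seeds)), tab
  ))
  p1 <- structure(
    tibble::tibble(accession_id = "P1", code = strrep("A", 8), payload = strrep("A", 8)),
    panel = panel
  )
  p2 <- structure(
    tibble::tibble(accession_id = "P2", code = strrep("B", 8), payload = strrep("B", 8)),
    panel = panel
  )
  rep <- hybrid_purity(lot, p1, p2, panel)
  se <- sqrt(selfing * (1 - selfing) / n_seeds)
  expect_lt(abs((1 - rep$summary$purity) - selfing), 3 * se + 1e-9)
})
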