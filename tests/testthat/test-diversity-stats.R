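test_that("locus statistics match hand-counted allele frequencies", {
  # 10 AA, 2 AB, 8 BB: p = (20 + 2) / 40 = 0.55
  calls <- c(rep("AA", 10), rep("AB", 2), rep("BB", 8))
  g <- geno_tbl(tibble::tibble(
    accession_id = paste0("a", 1:20), M1 = calls
  ))
  s <- locus_stats(g, "M1")
  expect_equal(s$p_ref, 0.55)
  expect_equal(s$maf, 0.45)
  expect_equal(s$ho, 0.10)
  expect_equal(s$he, 2 * 0.55 * 0.45)
  expect_equal(s$missing_rate, 0)

  # closed forms at p = q = 0.5
  g2 <- geno_tbl(tibble::tibble(
    accession_id = paste0("a", 1:4), M1 = c("AA", "AA", "BB", "BB")
  ))
  s2 <- locus_stats(g2, "M1")
  expect_equal(s2$he, 0.5)
  expect_equal(s2$pic_botstein, 0.375)
  expect_equal(s2$ne, 2)

  # maf 0.20 gives gene diversity 2 * 0.2 * 0.8 = 0.32
  g3 <- geno_tbl(tibble::tibble(
    accession_id = paste0("a", 1:10), M1 = c(rep("AA", 8), rep("BB", 2))
  ))
  expect_equal(locus_stats(g3, "M1")$he, 0.32)

  g4 <- geno_tbl(tibble::tibble(accession_id = c("a1", "a2"), M1 = c(NA, NA)))
  expect_error(locus_stats(g4, "M1"), "M1")
  expect_error(panel_summary(g4), "M1")
})

test_that("panel summary equals the naive per-column loop", {
  g <- random_geno(25, 12, seed = 8)
  s <- panel_summary(g)
  for (i in seq_len(nrow(s))) {
    o <- oracle_locus_stats(g, s$marker_id[i])
    expect_equal(s$p_ref[i], o$p)
    expect_equal(s$maf[i], o$maf)
    expect_equal(s$ho[i], o$ho)
    expect_equal(s$he[i], o$he)
    expect_equal(s$pic_botstein[i], o$pic)
    # also identical to the single-locus entry point
    ls <- locus_stats(g, s$marker_id[i])
    expect_equal(s$he[i], ls$he)
    expect_equal(s$missing_rate[i], ls$missing_rate)
  }
  # PIC <= He <= 2*MAF and He <= 0.5 at every biallelic locus
  expect_true(all(s$pic_botstein <= s$he + 1e-12))
  expect_true(all(s$he <= 2 * s$maf + 1e-12))
  expect_true(all(s$he <= 0.5 + 1e-12))

  mono <- geno_tbl(tibble::tibble(
    accession_id = paste0("a", 1:5), M1 = rep("AA", 5), M2 = rep("AA", 5)
  ))
  sm <- panel_summary(mono)
  expect_true(all(sm$maf == 0) && all(sm$he == 0) && all(sm$pic_botstein == 0))
})

test_that("published per-marker gene diversity is reproduced from printed MAF", {
  ref <- read_reference_stats(reference_stats_path())
  expect_equal(nrow(ref), 22L)
  he <- 2 * ref$maf * (1 - ref$maf)
  # the printed informativeness column is gene diversity; agreement is at
  # the table's printed precision (inputs are rounded to 2 dp)
  expect_true(all(abs(round(he, 2) - ref$pic) <= 0.01 + 1e-9))
  expect_equal(he[ref$marker_id == "C9"], 0.32)
})

test_that("pooled Shannon index matches closed forms and its entropy bound", {
  # 22 loci all at p = 0.5 pool to a uniform distribution over 44 alleles
  tab <- tibble::as_tibble(
    matrix(rep(c("AA", "BB"), each = 2, times = 22), nrow = 4),
    .name_repair = "minimal"
  )
  names(tab) <- paste0("L", 1:22)
  g <- geno_tbl(dplyr::bind_cols(
    tibble::tibble(accession_id = paste0("a", 1:4)), tab
  ))
  expect_equal(shannon_index_pooled(g), log(44))

  fixed <- geno_tbl(tibble::tibble(
    accession_id = paste0("a", 1:3), M1 = rep("AA", 3)
  ))
  expect_equal(shannon_index_pooled(fixed), 0)

  r <- random_geno(30, 9, seed = 4)
  expect_lte(shannon_index_pooled(r), log(2 * 9))
})

test_that("genetic distances agree with the brute-force pair loop", {
  g <- random_geno(5, 8, seed = 77)
  for (metric in c("modified_rogers", "cavalli_sforza_edwards", "nei_standard")) {
    d <- pairwise_distance(g, metric)
    expect_equal(as.matrix(d), oracle_distance(g, metric), tolerance = 1e-10)
    expect_true(isSymmetric(as.matrix(d)))
    expect_true(all(diag(as.matrix(d)) == 0))
    expect_true(all(as.matrix(d) >= 0))
  }
})

test_that("distance edge cases: identity, maximal divergence, degeneracies", {
  g <- geno_tbl(tibble::tibble(
    accession_id = c("x", "y"), M1 = c("AA", "AA"), M2 = c("AB", "AB")
  ))
  for (metric in c("modified_rogers", "cavalli_sforza_edwards", "nei_standard")) {
    expect_equal(as.matrix(pairwise_distance(g, metric))["x", "y"], 0)
  }

  opp <- geno_tbl(tibble::tibble(accession_id = c("x", "y"), M1 = c("AA", "BB")))
  expect_equal(as.matrix(pairwise_distance(opp, "modified_rogers"))["x", "y"], 1)
  expect_equal(
    as.matrix(pairwise_distance(opp, "cavalli_sforza_edwards"))["x", "y"], 1
  )
  expect_error(pairwise_distance(opp, "nei_standard"), "undefined")

  disjoint <- geno_tbl(tibble::tibble(
    accession_id = c("x", "y"), M1 = c("AA", NA), M2 = c(NA, "BB")
  ))
  expect_error(pairwise_distance(disjoint, "modified_rogers"), "no shared")
})

test_that("modified Rogers satisfies the triangle inequality on complete data", {
  g <- random_geno(8, 10, seed = 15, missing_rate = 0)
  d <- as.matrix(pairwise_distance(g, "modified_rogers"))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  expect_true(all(d <= 1 + 1e-12))
  ce <- as.matrix(pairwise_distance(g, "cavalli_sforza_edwards"))
  expect_true(all(ce <= 1 + 1e-12))
})

test_that("distance tidiers and writers expose every unordered pair once", {
  g <- random_geno(6, 6, seed = 19)
  d <- pairwise_distance(g, "modified_rogers")
  td <- tidy(d)
  expect_equal(nrow(td), choose(6, 2))
  expect_true(all(td$metric == "modified_rogers"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(as.matrix(back[, -1]), unname(as.matrix(d)), tolerance = 1e-12,
               ignore_attr = TRUE)

  phy <- withr::local_tempfile(fileext = ".dist")
  write_distance_matrix(d, phy, format = "phylip")
  expect_equal(readLines(phy)[1], sprintf("%5d", 6))
})
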