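# Fixtures built in code and naive reference implementations used as
# independent oracles. Oracles deliberately use slow per-element loops so
# they share nothing with the vectorised package internals.

toy_geno <- function(rows, markers = NULL) {
  # rows: named list accession_id -> character vector of calls
  tab <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(tab) <- paste0("M", seq_len(ncol(tab)))
  tab <- dplyr::bind_cols(tibble::tibble(accession_id = names(rows)), tab)
  geno_tbl(tab, markers = markers)
}

random_geno <- function(n, L, seed, missing_rate = 0.1, het_rate = 0.2) {
  withr::with_seed(seed, {
    calls <- sample(c("AA", "AB", "BB"), n * L, replace = TRUE,
                    prob = c((1 - het_rate) / 2, het_rate, (1 - het_rate) / 2))
    calls[stats::runif(n * L) < missing_rate] <- NA_character_
    tab <- tibble::as_tibble(matrix(calls, n, L), .name_repair = "minimal")
    names(tab) <- paste0("M", seq_len(L))
    tab <- dplyr::bind_cols(
      tibble::tibble(accession_id = paste0("acc", seq_len(n))), tab
    )
    geno_tbl(tab)
  })
}

# 100 fully homozygous accessions; marker names encode their exact MAF
make_maf_panel <- function() {
  n <- 100
  col <- function(n_bb) c(rep("BB", n_bb), rep("AA", n - n_bb))
  geno_tbl(tibble::tibble(
    accession_id = sprintf("a%03d", 1:n),
    Mmono = col(0), M04 = col(4), M05 = col(5), M06 = col(6), M30 = col(30)
  ))
}

reference_stats_path <- function() {
  system.file("extdata", "magic_reference_stats.tsv", package = "gourdcore")
}

core_markers_path <- function() {
  system.file("extdata", "core_markers.tsv", package = "gourdcore")
}

# per-individual within-locus allele-frequency vector
oracle_freq_vec <- function(call) {
  switch(call, AA = c(1, 0), AB = c(0.5, 0.5), BB = c(0, 1))
}

# naive per-pair, per-locus genetic distance
oracle_distance <- function(g, metric) {
  ids <- g$accession_id
  L <- length(marker_ids(g))
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      sq <- 0; chord <- 0; jxy <- 0; jx <- 0; jy <- 0; lp <- 0
      for (m in marker_ids(g)) {
        ci <- g[[m]][i]; cj <- g[[m]][j]
        if (is.na(ci) || is.na(cj)) next
        x <- oracle_freq_vec(ci); y <- oracle_freq_vec(cj)
        lp <- lp + 1
        sq <- sq + sum((x - y)^2)
        chord <- chord + sum((sqrt(x) - sqrt(y))^2)
        jxy <- jxy + sum(x * y); jx <- jx + sum(x^2); jy <- jy + sum(y^2)
      }
      d[i, j] <- switch(metric,
        modified_rogers = sqrt(sq / (2 * lp)),
        cavalli_sforza_edwards = sqrt(chord / (2 * lp)),
        nei_standard = -log(jxy / sqrt(jx * jy))
      )
    }
  }
  d
}

# naive per-column statistics via table()
oracle_locus_stats <- function(g, m) {
  v <- g[[m]]
  v <- v[!is.na(v)]
  n_aa <- sum(v == "AA"); n_ab <- sum(v == "AB"); n_bb <- sum(v == "BB")
  p <- (2 * n_aa + n_ab) / (2 * length(v))
  list(
    p = p, maf = min(p, 1 - p), ho = n_ab / length(v),
    he = 2 * p * (1 - p),
    pic = 1 - (p^2 + (1 - p)^2) - 2 * p^2 * (1 - p)^2
  )
}

# does the marker subset resolve every accession pair (both calls present
# and different)?
oracle_resolves_all <- function(g, subset_ids) {
  n <- nrow(g)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- FALSE
      for (m in subset_ids) {
        ci <- g[[m]][i]; cj <- g[[m]][j]
        if (!is.na(ci) && !is.na(cj) && ci != cj) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

# exhaustive minimum discriminating subset size (NA when even the full
# marker set fails)
oracle_min_panel_size <- function(g) {
  ids <- marker_ids(g)
  if (!oracle_resolves_all(g, ids)) return(NA_integer_)
  for (k in seq_along(ids)) {
    subs <- utils::combn(ids, k, simplify = FALSE)
    for (s in subs) {
      if (oracle_resolves_all(g, s)) return(k)
    }
  }
  length(ids)
}

# mean entry-to-nearest-entry distance, naive
oracle_mean_ene <- function(D, ids) {
  vals <- vapply(ids, function(a) {
    min(D[a, setdiff(ids, a)])
  }, numeric(1))
  mean(vals)
}

# mean silhouette width of binary labels on a 1-D coordinate
oracle_silhouette_1d <- function(x, labels) {
  s <- vapply(seq_along(x), function(i) {
    same <- which(labels == labels[i] & seq_along(x) != i)
    other <- which(labels != labels[i])
    a <- mean(abs(x[i] - x[same]))
    b <- mean(abs(x[i] - x[other]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
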