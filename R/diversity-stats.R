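#' Per-locus diversity statistics
#'
#' For one biallelic marker, computes over the called samples: the
#' reference-allele frequency `p = (2 n_AA + n_AB) / (2 n_called)`, the
#' minor allele frequency `maf = min(p, 1 - p)`, observed heterozygosity
#' `ho = n_AB / n_called`, gene diversity (expected heterozygosity)
#' `he = 2 p (1 - p)`, Botstein's polymorphism information content
#' `pic = 1 - (p^2 + q^2) - 2 p^2 q^2`, and the missing rate over all
#' samples. For a biallelic locus `pic <= he <= 0.5`, with `pic` capped at
#' 0.375; published "PIC" columns that reach 0.5 are gene diversity, which
#' is why both are reported side by side.
#'
#' @param g A [geno_tbl()].
#' @param marker_id Marker to summarise.
#' @return A one-row tibble: `marker_id`, `p_ref`, `maf`, `ho`, `he`,
#'   `pic_botstein`, `ne`, `missing_rate`, `n_called`.
#' @export
locus_stats <- function(g, marker_id) {
  cnt <- count_calls(g, marker_id)
  if (cnt$n_called == 0L) {
    stop("all calls missing at marker ", marker_id, call. = FALSE)
  }
  p <- (2 * cnt$n_aa + cnt$n_ab) / (2 * cnt$n_called)
  q <- 1 - p
  tibble::tibble(
    marker_id = marker_id,
    p_ref = p,
    maf = pmin(p, q),
    ho = cnt$n_ab / cnt$n_called,
    he = 2 * p * q,
    pic_botstein = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
    ne = 1 / (p^2 + q^2),
    missing_rate = cnt$n_missing / (cnt$n_called + cnt$n_missing),
    n_called = cnt$n_called
  )
}

#' Panel-wide diversity summary
#'
#' One [locus_stats()] row per marker (computed in a single vectorised
#' pass), carrying the marker's chromosome and position. Column means,
#' minima and maxima are available through [glance()] on the result.
#'
#' @param g A [geno_tbl()].
#' @return A tibble of class `gourd_locus_summary` with one row per marker.
#' @examples
#' g <- simulate_structured_panel(panel_sim_config(n_accessions = 30, n_markers = 10))
#' s <- panel_summary(g)
#' glance(s)
#' @export
panel_summary <- function(g) {
  mk <- markers(g)
  dos <- geno_dosage(g)
  if (ncol(dos) == 0L) stop("empty genotype table", call. = FALSE)
  n <- nrow(dos)
  n_missing <- colSums(is.na(dos))
  n_called <- n - n_missing
  if (any(n_called == 0L)) {
    stop(
      "all calls missing at marker(s): ",
      paste(colnames(dos)[n_called == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  n_called <- unname(n_called)
  n_missing <- unname(n_missing)
  n_ab <- unname(colSums(dos == 1L, na.rm = TRUE))
  alt <- unname(colSums(dos, na.rm = TRUE))
  p <- 1 - alt / (2 * n_called)
  q <- 1 - p
  out <- tibble::tibble(
    marker_id = colnames(dos),
    chromosome = mk$chromosome,
    position_bp = mk$position_bp,
    p_ref = p,
    maf = pmin(p, q),
    ho = n_ab / n_called,
    he = 2 * p * q,
    pic_botstein = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
    ne = 1 / (p^2 + q^2),
    missing_rate = n_missing / n,
    n_called = as.integer(n_called)
  )
  class(out) <- c("gourd_locus_summary", class(out))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Column means and ranges of a panel summary
#'
#' @param x A `gourd_locus_summary` from [panel_summary()].
#' @param ... Unused.
#' @return A one-row tibble of means plus `maf_min`/`maf_max`,
#'   `he_min`/`he_max`, and the marker count.
#' @export
glance.gourd_locus_summary <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x),
    maf_mean = mean(x$maf), maf_min = min(x$maf), maf_max = max(x$maf),
    ho_mean = mean(x$ho), ho_max = max(x$ho),
    he_mean = mean(x$he), he_min = min(x$he), he_max = max(x$he),
    pic_mean = mean(x$pic_botstein),
    ne_mean = mean(x$ne),
    missing_mean = mean(x$missing_rate)
  )
}

#' Pooled Shannon diversity index
#'
#' Shannon's index over the allele distribution pooled across loci:
#' with `p_la` the frequency of allele `a` at locus `l` and `L` loci,
#' `SH = -sum( (p_la / L) * ln(p_la / L) )`, zero-frequency alleles
#' contributing nothing. For `L` loci all at `p = 0.5` this is `ln(2 L)`;
#' the pooled form is the one under which a 22-locus panel can reach
#' values near 3, which per-locus averaging (bounded by `ln 2`) cannot.
#'
#' @param g A [geno_tbl()].
#' @return A single nonnegative number.
#' @export
shannon_index_pooled <- function(g) {
  s <- panel_summary(g)
  L <- nrow(s)
  pr <- c(s$p_ref, 1 - s$p_ref) / L
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

#' Pairwise genetic distances between accessions
#'
#' An individual's within-locus allele-frequency vector is `(1, 0)` for a
#' reference homozygote, `(0.5, 0.5)` for a heterozygote and `(0, 1)` for
#' an alternate homozygote. Loci with a no-call in either accession are
#' dropped pairwise, leaving `L'` shared loci. Supported metrics:
#'
#' * `modified_rogers`: `sqrt( sum_l sum_a (x_la - y_la)^2 / (2 L') )`,
#'   in `[0, 1]`.
#' * `cavalli_sforza_edwards`: the chord-type
#'   `sqrt( sum_l sum_a (sqrt(x_la) - sqrt(y_la))^2 / (2 L') )`, in `[0, 1]`.
#' * `nei_standard`: `-ln( J_xy / sqrt(J_x J_y) )` with
#'   `J_xy = sum_l sum_a x_la y_la` etc., sums over shared loci.
#'
#' @param g A [geno_tbl()] with at least two accessions.
#' @param metric One of `"modified_rogers"`, `"cavalli_sforza_edwards"`,
#'   `"nei_standard"`.
#' @return A `gourd_dist` object: list with `ids`, the symmetric matrix
#'   `d`, and `metric`. Coerce with `as.matrix()` or `as.dist()`, or
#'   [tidy()] into a long tibble of pairs.
#' @export
pairwise_distance <- function(g, metric = c("modified_rogers",
                                            "cavalli_sforza_edwards",
                                            "nei_standard")) {
  metric <- match.arg(metric)
  dos <- geno_dosage(g)
  if (nrow(dos) < 2L) stop("need at least two accessions", call. = FALSE)
  ids <- rownames(dos)
  W <- 1 - is.na(dos) # called indicator
  Lp <- W %*% t(W) # shared called loci per pair
  off <- Lp[upper.tri(Lp)]
  if (any(off == 0)) {
    bad <- which(Lp == 0 & upper.tri(Lp), arr.ind = TRUE)[1, ]
    stop(
      "no shared called loci for pair ", ids[bad[1]], " / ", ids[bad[2]],
      call. = FALSE
    )
  }

  d <- switch(metric,
    modified_rogers = {
      Z <- dos
      Z[is.na(Z)] <- 0L
      Z2 <- Z^2
      # sum over shared loci of (dx - dy)^2, via the cross-product identity
      sq <- Z2 %*% t(W) + W %*% t(Z2) - 2 * Z %*% t(Z)
      sq[sq < 0] <- 0
      sqrt(sq / (4 * Lp))
    },
    cavalli_sforza_edwards = {
      Ur <- sqrt(1 - dos / 2)
      Ua <- sqrt(dos / 2)
      Ur[is.na(Ur)] <- 0
      Ua[is.na(Ua)] <- 0
      cc <- 1 - (Ur %*% t(Ur) + Ua %*% t(Ua)) / Lp
      cc[cc < 0] <- 0
      sqrt(cc)
    },
    nei_standard = {
      Xr <- 1 - dos / 2
      Xa <- dos / 2
      Xr[is.na(Xr)] <- 0
      Xa[is.na(Xa)] <- 0
      Jxy <- Xr %*% t(Xr) + Xa %*% t(Xa)
      Q <- Xr^2 + Xa^2 # per-locus self-product (1 hom, 0.5 het)
      Q[is.na(dos)] <- 0
      Jx <- Q %*% t(W) # self-product restricted to the pair's shared loci
      Jy <- t(Jx)
      ratio <- Jxy / sqrt(Jx * Jy)
      if (any(ratio[upper.tri(ratio)] <= 0)) {
        bad <- which(ratio <= 0 & upper.tri(ratio), arr.ind = TRUE)[1, ]
        stop(
          "Nei distance undefined (zero shared identity) for pair ",
          ids[bad[1]], " / ", ids[bad[2]],
          call. = FALSE
        )
      }
      ratio[ratio > 1] <- 1
      -log(ratio)
    }
  )
  diag(d) <- 0
  d <- (d + t(d)) / 2 # enforce exact symmetry against float noise
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, metric = metric), class = "gourd_dist")
}

#' @export
as.matrix.gourd_dist <- function(x, ...) x$d

#' @export
as.dist.gourd_dist <- function(m, ...) stats::as.dist(m$d)

#' @rdname pairwise_distance
#' @param x A `gourd_dist`.
#' @param ... Unused.
#' @export
tidy.gourd_dist <- function(x, ...) {
  ut <- upper.tri(x$d)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    accession_1 = x$ids[idx[, 1]],
    accession_2 = x$ids[idx[, 2]],
    distance = x$d[ut],
    metric = x$metric
  )
}

#' @export
print.gourd_dist <- function(x, ...) {
  cat(
    "# Pairwise ", x$metric, " distances over ", length(x$ids),
    " accessions (mean ", signif(mean(x$d[upper.tri(x$d)]), 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Write a distance matrix as labelled square TSV or PHYLIP
#'
#' @param d A `gourd_dist`.
#' @param path Output path.
#' @param format `"tsv"` (labelled square table) or `"phylip"` (square
#'   PHYLIP dialect for tree tools).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- tibble::as_tibble(d$d, rownames = "accession_id")
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    rows <- vapply(seq_along(d$ids), function(i) {
      paste0(
        formatC(d$ids[i], width = 10, flag = "-"),
        paste(sprintf("%.6f", d$d[i, ]), collapse = " ")
      )
    }, character(1))
    writeLines(c(sprintf("%5d", length(d$ids)), rows), path)
  }
  invisible(path)
}

#' Read a per-marker reference statistics table
#'
#' Loads a transcription of a published per-marker diversity table
#' (columns `Marker`, `PIC`, `MAF`, `Heterozygosity`, `Missing value`) for
#' regression against freshly computed statistics, and summarises it the
#' same way [glance()] summarises [panel_summary()] output.
#'
#' @param path TSV path. A clear error is raised when the file is absent
#'   (e.g. a supplement that was never published alongside the article).
#' @return A tibble with columns `marker_id`, `pic`, `maf`, `ho`,
#'   `missing_rate`.
#' @export
read_reference_stats <- function(path) {
  if (!file.exists(path)) {
    stop(
      "reference statistics table not found: ", path,
      " (transcribe the published table to this path to enable the check)",
      call. = FALSE
    )
  }
  raw <- readr::read_tsv(path, col_types = "cdddd", progress = FALSE)
  names(raw) <- c("marker_id", "pic", "maf", "ho", "missing_rate")
  raw
}
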