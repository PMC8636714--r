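#' Filter markers on minor allele frequency and missing rate
#'
#' Retains markers with `maf > maf_min` and `missing_rate < missing_max`
#' — both inequalities strict, matching the usual ">5% MAF, <5% missing"
#' screen applied before panel selection. Rejected markers are listed,
#' with the criterion they failed, in the `rejected` attribute.
#'
#' @param g A [geno_tbl()].
#' @param maf_min Exclusive lower bound on minor allele frequency
#'   (default 0.05).
#' @param missing_max Exclusive upper bound on missing rate (default 0.05).
#' @return A filtered [geno_tbl()] (possibly with zero markers, in which
#'   case a warning is emitted) with attribute `rejected`, a tibble of
#'   `marker_id`, `reason` (`"maf"` or `"missing"`), `maf`, `missing_rate`.
#' @export
filter_markers <- function(g, maf_min = 0.05, missing_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  s <- panel_summary(g)
  # round away float fuzz so printed thresholds behave as exact boundaries
  fail_maf <- !(round(s$maf, 12) > maf_min)
  fail_mis <- !(round(s$missing_rate, 12) < missing_max)
  keep <- !fail_maf & !fail_mis
  rejected <- tibble::tibble(
    marker_id = s$marker_id[!keep],
    reason = ifelse(fail_maf[!keep], "maf", "missing"),
    maf = s$maf[!keep],
    missing_rate = s$missing_rate[!keep]
  )
  if (!any(keep)) {
    warning("no markers pass the filter", call. = FALSE)
    out <- g[, "accession_id", drop = FALSE]
    attr(out, "markers") <- markers(g)[0, ]
    attr(out, "rejected") <- rejected
    return(out)
  }
  out <- geno_subset(g, markers = s$marker_id[keep])
  attr(out, "rejected") <- rejected
  out
}

#' Thin markers to an even per-chromosome spacing
#'
#' Places `k_per_chrom` anchor points evenly between the first and last
#' marker position on each chromosome and, for each anchor in turn, keeps
#' the nearest not-yet-chosen marker. Distance ties are broken by higher
#' score (e.g. gene diversity), then by lower position. Chromosomes with
#' at most `k_per_chrom` markers keep them all.
#'
#' @param markers Marker metadata tibble (see [geno_tbl()]).
#' @param k_per_chrom Markers to keep per chromosome (>= 1).
#' @param scores Optional named numeric vector (names = marker ids) used
#'   to break distance ties; unnamed markers score 0.
#' @return The thinned marker tibble, ordered by chromosome then position.
#' @export
thin_per_chromosome <- function(markers, k_per_chrom, scores = NULL) {
  markers <- validate_markers(markers)
  stopifnot(k_per_chrom >= 1)
  sc <- rep(0, nrow(markers))
  if (!is.null(scores)) {
    hit <- match(markers$marker_id, names(scores))
    sc[!is.na(hit)] <- scores[hit[!is.na(hit)]]
  }
  keep <- character(0)
  for (cc in unique(markers$chromosome)) {
    idx <- which(markers$chromosome == cc)
    if (length(idx) <= k_per_chrom) {
      keep <- c(keep, markers$marker_id[idx])
      next
    }
    pos <- markers$position_bp[idx]
    anchors <- seq(min(pos), max(pos), length.out = k_per_chrom)
    avail <- rep(TRUE, length(idx))
    for (a in anchors) {
      cand <- which(avail)
      dd <- abs(pos[cand] - a)
      best <- cand[order(dd, -sc[idx][cand], pos[cand])][1]
      keep <- c(keep, markers$marker_id[idx[best]])
      avail[best] <- FALSE
    }
  }
  out <- markers[markers$marker_id %in% keep, ]
  out[order(out$chromosome, out$position_bp), ]
}

#' Select a minimal chromosome-balanced discriminating marker panel
#'
#' Greedy forward selection of the core panel: at each step the eligible
#' marker (its chromosome's quota of `max_per_chrom` not yet exhausted)
#' that resolves the largest number of currently unresolved accession
#' pairs is added. A marker resolves a pair only when both calls are
#' non-missing and different — a no-call is never allowed to fake a
#' difference. Ties are broken by higher gene diversity, then by the
#' chromosome with fewest selected markers, then by marker id. Selection
#' stops once every pair is resolved (or no eligible marker helps); with
#' `target_size` it continues under the same rule to the requested size,
#' e.g. to complete a balanced two-per-chromosome panel.
#'
#' The saturation curve — distinct multilocus fingerprints and resolved
#' pairs after each step — is recorded along the way. For the distinct
#' count a no-call is a symbol of its own, so two accessions differing
#' only by missingness fall in different classes; such pairs are flagged
#' separately as resolved by missingness only.
#'
#' @param g A (typically filtered) [geno_tbl()].
#' @param max_per_chrom Per-chromosome marker quota (default 2).
#' @param target_size Optional total panel size to reach after full
#'   resolution.
#' @return A `gourd_panel` object: `selected` (ordered marker ids),
#'   `saturation` (tibble `size`, `n_distinct`, `n_resolved_pairs`),
#'   `fully_resolving`, `capacity` (`3^|selected|`),
#'   `per_chromosome_counts`, `unresolved_pairs`, `missing_only_pairs`.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' g <- simulate_structured_panel(panel_sim_config(n_accessions = 40, n_markers = 30))
#' p <- select_core_panel(g, max_per_chrom = 2)
#' glance(p)
#' @export
select_core_panel <- function(g, max_per_chrom = 2, target_size = NULL) {
  stopifnot(max_per_chrom >= 1)
  mk <- markers(g)
  dos <- geno_dosage(g)
  if (ncol(dos) == 0L || nrow(dos) == 0L) stop("empty genotype table", call. = FALSE)
  n <- nrow(dos)
  he <- panel_summary(g)$he
  names(he) <- colnames(dos)

  if (n < 2L) {
    ii <- jj <- integer(0)
  } else {
    pr <- utils::combn(n, 2)
    ii <- pr[1, ]
    jj <- pr[2, ]
  }
  unresolved <- seq_along(ii)
  n_pairs <- length(ii)

  chrom <- mk$chromosome
  chrom_count <- stats::setNames(rep(0L, length(unique(chrom))), unique(chrom))
  selected <- character(0)
  avail <- rep(TRUE, ncol(dos))
  class_id <- rep(1L, n) # fingerprint class per accession, refined stepwise
  sat <- list()
  n_resolved <- 0L
  max_size <- if (is.null(target_size)) Inf else target_size

  repeat {
    eligible <- which(avail & chrom_count[chrom] < max_per_chrom)
    if (length(eligible) == 0L || length(selected) >= max_size) break
    gain <- vapply(eligible, function(m) {
      v <- dos[, m]
      sum(!is.na(v[ii[unresolved]]) & !is.na(v[jj[unresolved]]) &
            v[ii[unresolved]] != v[jj[unresolved]])
    }, integer(1))
    if (length(unresolved) == 0L && is.null(target_size)) break
    ord <- order(
      -gain,
      -he[eligible],
      chrom_count[chrom[eligible]],
      colnames(dos)[eligible],
      method = "radix"
    )
    pick <- eligible[ord[1]]
    if (gain[ord[1]] == 0L && length(unresolved) > 0L && is.null(target_size)) {
      break # nothing eligible helps; remaining pairs are unresolvable here
    }
    selected <- c(selected, colnames(dos)[pick])
    chrom_count[chrom[pick]] <- chrom_count[chrom[pick]] + 1L
    avail[pick] <- FALSE

    v <- dos[, pick]
    res <- !is.na(v[ii[unresolved]]) & !is.na(v[jj[unresolved]]) &
      v[ii[unresolved]] != v[jj[unresolved]]
    unresolved <- unresolved[!res]
    n_resolved <- n_pairs - length(unresolved)
    sym <- ifelse(is.na(v), 3L, v)
    class_id <- as.integer(factor(paste(class_id, sym)))
    sat[[length(sat) + 1L]] <- c(
      size = length(selected),
      n_distinct = length(unique(class_id)),
      n_resolved_pairs = n_resolved
    )
    if (length(unresolved) == 0L &&
        (is.null(target_size) || length(selected) >= target_size)) break
  }

  sat <- tibble::as_tibble(do.call(rbind, sat))
  ids <- rownames(dos)
  unresolved_tbl <- tibble::tibble(
    accession_1 = ids[ii[unresolved]],
    accession_2 = ids[jj[unresolved]]
  )
  # pairs in distinct fingerprint classes only because of no-call symbols
  miss_only <- unresolved_tbl[
    class_id[match(unresolved_tbl$accession_1, ids)] !=
      class_id[match(unresolved_tbl$accession_2, ids)], ]

  structure(
    list(
      selected = selected,
      saturation = sat,
      fully_resolving = length(unresolved) == 0L,
      capacity = panel_capacity(length(selected)),
      per_chromosome_counts = tibble::tibble(
        chromosome = names(chrom_count),
        n_selected = as.integer(chrom_count)
      ),
      unresolved_pairs = unresolved_tbl,
      missing_only_pairs = miss_only,
      n_accessions = n,
      n_pairs = n_pairs,
      markers = mk[match(selected, mk$marker_id), ]
    ),
    class = "gourd_panel"
  )
}

#' Theoretical discrimination capacity of a codominant panel
#'
#' A biallelic codominant marker takes three genotype states, so `k`
#' markers distinguish at most `3^k` multilocus genotypes. Computed by
#' exact integer accumulation (exact up to `k = 33` in double precision).
#'
#' @param n_markers Panel size `k >= 0`.
#' @return `3^k` as an exactly represented whole number.
#' @examples
#' panel_capacity(22) # 31381059609
#' @export
panel_capacity <- function(n_markers) {
  stopifnot(n_markers >= 0, n_markers <= 33)
  out <- 1
  for (i in seq_len(n_markers)) out <- out * 3
  out
}

#' Saturation curve of an ordered marker panel
#'
#' For each prefix of `ordered_panel`, the number of distinct multilocus
#' fingerprints among the accessions, with a no-call counted as its own
#' symbol. The zero-size prefix counts one class; the curve is
#' nondecreasing.
#'
#' @param g A [geno_tbl()].
#' @param ordered_panel Character vector of marker ids in panel order.
#' @return A tibble with columns `size` (0..length) and `n_distinct`.
#' @export
saturation_curve <- function(g, ordered_panel) {
  unknown <- setdiff(ordered_panel, marker_ids(g))
  if (length(unknown)) stop("unknown marker(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  dos <- geno_dosage(g)
  class_id <- rep(1L, nrow(dos))
  out <- integer(length(ordered_panel) + 1L)
  out[1] <- 1L
  for (k in seq_along(ordered_panel)) {
    v <- dos[, ordered_panel[k]]
    sym <- ifelse(is.na(v), 3L, v)
    class_id <- as.integer(factor(paste(class_id, sym)))
    out[k + 1L] <- length(unique(class_id))
  }
  tibble::tibble(size = 0:length(ordered_panel), n_distinct = out)
}

#' @rdname select_core_panel
#' @param x A `gourd_panel`.
#' @param ... Unused.
#' @export
tidy.gourd_panel <- function(x, ...) x$saturation

#' @rdname select_core_panel
#' @export
glance.gourd_panel <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    fully_resolving = x$fully_resolving,
    n_distinct = utils::tail(x$saturation$n_distinct, 1),
    n_accessions = x$n_accessions,
    n_resolved_pairs = utils::tail(x$saturation$n_resolved_pairs, 1),
    n_pairs = x$n_pairs,
    n_unresolved_pairs = nrow(x$unresolved_pairs),
    capacity = x$capacity
  )
}

#' @export
print.gourd_panel <- function(x, ...) {
  cat(
    "# Core marker panel: ", length(x$selected), " markers; ",
    utils::tail(x$saturation$n_distinct, 1), "/", x$n_accessions,
    " distinct fingerprints; ",
    if (x$fully_resolving) "all pairs resolved" else
      paste0(nrow(x$unresolved_pairs), " unresolved pair(s)"),
    "\n", sep = ""
  )
  cat("  markers: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Saturation-curve plot of a selected panel
#'
#' @param object A `gourd_panel` from [select_core_panel()].
#' @param ... Unused.
#' @return A ggplot: distinct fingerprints against cumulative panel size,
#'   with the accession count as a dashed reference line.
#' @export
autoplot.gourd_panel <- function(object, ...) {
  ggplot2::ggplot(object$saturation, ggplot2::aes(x = .data$size, y = .data$n_distinct)) +
    ggplot2::geom_hline(yintercept = object$n_accessions, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Cumulative panel size (markers)",
      y = "Distinct multilocus fingerprints"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
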