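#' Multilocus SNP fingerprints
#'
#' A fingerprint is the accession's calls over an ordered marker panel,
#' written as a string over the alphabet `A` (homozygous reference), `H`
#' (heterozygous), `B` (homozygous alternate), `N` (no call) — one symbol
#' per panel marker. The barcode payload is the code string itself
#' (Code128-compatible text); rendering images is out of scope.
#'
#' `fingerprints()` returns one row per accession; `fingerprint()` a
#' single accession's row. The panel (ordered marker ids) is carried in
#' the `panel` attribute of the result.
#'
#' @param g A [geno_tbl()].
#' @param panel Ordered character vector of marker ids, or a
#'   `gourd_panel` from [select_core_panel()].
#' @param accession_id Single accession id (for `fingerprint()`).
#' @return A tibble with columns `accession_id`, `code`, `payload` and
#'   attribute `panel`.
#' @examples
#' g <- geno_tbl(data.frame(
#'   accession_id = "acc1",
#'   M1 = "AA", M2 = "AB", M3 = "BB", M4 = NA
#' ))
#' fingerprint(g, c("M1", "M2", "M3", "M4"), "acc1")$code # "AHBN"
#' @export
fingerprints <- function(g, panel) {
  panel <- as_panel_ids(panel)
  unknown <- setdiff(panel, marker_ids(g))
  if (length(unknown)) stop("unknown marker(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  dos <- geno_dosage(g)[, panel, drop = FALSE]
  sym <- matrix(c("A", "H", "B")[dos + 1L], nrow = nrow(dos))
  sym[is.na(dos)] <- "N"
  code <- apply(sym, 1, paste, collapse = "")
  out <- tibble::tibble(
    accession_id = rownames(dos),
    code = code,
    payload = code
  )
  attr(out, "panel") <- panel
  out
}

#' @rdname fingerprints
#' @export
fingerprint <- function(g, panel, accession_id) {
  if (!accession_id %in% g$accession_id) {
    stop("unknown accession: ", accession_id, call. = FALSE)
  }
  fps <- fingerprints(g, panel)
  out <- fps[fps$accession_id == accession_id, ]
  attr(out, "panel") <- attr(fps, "panel", exact = TRUE)
  out
}

as_panel_ids <- function(panel) {
  if (inherits(panel, "gourd_panel")) panel$selected else as.character(panel)
}

fp_panel <- function(fp) attr(fp, "panel", exact = TRUE)

check_same_panel <- function(a, b) {
  pa <- fp_panel(a)
  pb <- fp_panel(b)
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb)) {
    stop("fingerprints come from different marker panels", call. = FALSE)
  }
  if (length(unique(nchar(c(a$code, b$code)))) != 1L) {
    stop("fingerprint codes differ in length (mixed panels?)", call. = FALSE)
  }
}

# per-position mismatch count between two equal-length codes;
# positions with N in either are skipped when ignore_missing
code_mismatches <- function(x, y, ignore_missing = TRUE) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  if (ignore_missing) {
    keep <- a != "N" & b != "N"
    a <- a[keep]
    b <- b[keep]
  }
  c(n_compared = length(a), n_mismatch = sum(a != b))
}

#' Group accessions with (near-)identical fingerprints
#'
#' Accessions whose codes differ at no more than `max_mismatch` compared
#' loci are linked, and groups are the connected components of that link
#' graph (single linkage). With `ignore_missing` (default) positions
#' carrying `N` in either code are skipped from the comparison.
#'
#' @param fps A fingerprint tibble from [fingerprints()].
#' @param max_mismatch Maximum tolerated mismatches within a group
#'   (default 0: exact duplicates/synonyms).
#' @param ignore_missing Skip `N` positions pairwise (default `TRUE`).
#' @return A tibble `group`, `accession_id` listing only groups of two or
#'   more accessions; zero rows when all fingerprints are distinct.
#' @export
find_duplicates <- function(fps, max_mismatch = 0, ignore_missing = TRUE) {
  if (length(unique(nchar(fps$code))) > 1L) {
    stop("fingerprint codes differ in length (mixed panels?)", call. = FALSE)
  }
  n <- nrow(fps)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        mm <- code_mismatches(fps$code[i], fps$code[j], ignore_missing)
        if (mm["n_mismatch"] <= max_mismatch) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- tibble::tibble(
    group = as.integer(factor(root)),
    accession_id = fps$accession_id
  )
  keep <- grp |>
    dplyr::count(.data$group) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$group)
  out <- grp |>
    dplyr::filter(.data$group %in% keep) |>
    dplyr::arrange(.data$group, .data$accession_id)
  out$group <- as.integer(factor(out$group))
  out
}

#' Authenticate a sample fingerprint against a reference
#'
#' Compares the two codes locus by locus over positions called in both.
#' The verdict is `"match"` when there is no mismatch and at least
#' `floor(completeness_floor * panel size)` loci could be compared,
#' `"inconclusive"` when fewer loci than that floor were comparable, and
#' `"mismatch"` otherwise.
#'
#' @param sample,reference One-row fingerprint tibbles (see
#'   [fingerprint()]) on the same panel.
#' @param completeness_floor Fraction of the panel that must be comparable
#'   for a verdict (default 0.8).
#' @return A one-row tibble: `n_compared`, `n_match`, `n_mismatch`,
#'   `match_rate`, `verdict`.
#' @export
authenticate <- function(sample, reference, completeness_floor = 0.8) {
  stopifnot(nrow(sample) == 1L, nrow(reference) == 1L)
  check_same_panel(sample, reference)
  mm <- code_mismatches(sample$code, reference$code, ignore_missing = TRUE)
  n_compared <- unname(mm["n_compared"])
  n_mismatch <- unname(mm["n_mismatch"])
  floor_n <- floor(completeness_floor * nchar(sample$code))
  verdict <- if (n_compared < floor_n) {
    "inconclusive"
  } else if (n_mismatch == 0L) {
    "match"
  } else {
    "mismatch"
  }
  tibble::tibble(
    n_compared = n_compared,
    n_match = n_compared - n_mismatch,
    n_mismatch = n_mismatch,
    match_rate = if (n_compared > 0) (n_compared - n_mismatch) / n_compared else NA_real_,
    verdict = verdict
  )
}

#' Hybrid seed-lot purity from parental fingerprints
#'
#' Diagnostic loci are panel positions where the two parents are opposite
#' homozygotes (`A` vs `B`); a true F1 hybrid is heterozygous (`H`) there.
#' Each seed is classified over its *called* diagnostic loci: a true
#' hybrid when heterozygous at at least `het_fraction` of them (default
#' 1.0, i.e. all), selfed towards a parent when it reproduces that
#' parent's homozygote at every called diagnostic locus, otherwise
#' off-type. Purity is the fraction of true hybrids among seeds with at
#' least one called diagnostic locus.
#'
#' @param lot A [geno_tbl()] of the seed lot, genotyped on the panel.
#' @param parent1,parent2 One-row fingerprint tibbles of the two parents.
#' @param panel Ordered marker ids or a `gourd_panel`.
#' @param het_fraction Minimum fraction of called diagnostic loci that
#'   must be heterozygous for a true hybrid (default 1.0).
#' @return A list of class `gourd_purity`: `summary` (one-row tibble with
#'   `purity`, class counts, `n_diagnostic`), `seeds` (per-seed tibble)
#'   and `diagnostic_loci`.
#' @export
hybrid_purity <- function(lot, parent1, parent2, panel, het_fraction = 1) {
  panel <- as_panel_ids(panel)
  check_same_panel(parent1, parent2)
  p1 <- strsplit(parent1$code, "")[[1]]
  p2 <- strsplit(parent2$code, "")[[1]]
  stopifnot(length(p1) == length(panel))
  diag_idx <- which((p1 == "A" & p2 == "B") | (p1 == "B" & p2 == "A"))
  if (length(diag_idx) == 0L) {
    stop(
      "no diagnostic loci: parents are nowhere opposite homozygotes; ",
      "extend the marker panel",
      call. = FALSE
    )
  }
  diag_loci <- panel[diag_idx]
  fps <- fingerprints(lot, diag_loci)
  seeds <- purrr::map_dfr(seq_len(nrow(fps)), function(i) {
    s <- strsplit(fps$code[i], "")[[1]]
    called <- which(s != "N")
    n_called <- length(called)
    if (n_called == 0L) {
      cls <- "uninformative"
    } else {
      n_het <- sum(s[called] == "H")
      if (n_het / n_called >= het_fraction) {
        cls <- "true_hybrid"
      } else if (all(s[called] == p1[diag_idx][called])) {
        cls <- "selfed_parent1"
      } else if (all(s[called] == p2[diag_idx][called])) {
        cls <- "selfed_parent2"
      } else {
        cls <- "off_type"
      }
    }
    tibble::tibble(
      accession_id = fps$accession_id[i],
      n_called_diagnostic = n_called,
      n_het = if (n_called) sum(s[called] == "H") else 0L,
      class = cls
    )
  })
  informative <- seeds$class != "uninformative"
  summary <- tibble::tibble(
    n_seeds = nrow(seeds),
    n_informative = sum(informative),
    n_true_hybrid = sum(seeds$class == "true_hybrid"),
    n_selfed = sum(seeds$class %in% c("selfed_parent1", "selfed_parent2")),
    n_off_type = sum(seeds$class == "off_type"),
    n_diagnostic = length(diag_loci),
    purity = sum(seeds$class == "true_hybrid") / sum(informative)
  )
  structure(
    list(summary = summary, seeds = seeds, diagnostic_loci = diag_loci),
    class = "gourd_purity"
  )
}

#' @export
print.gourd_purity <- function(x, ...) {
  s <- x$summary
  cat(
    "# Seed-lot purity: ", round(100 * s$purity, 1), "% true hybrids (",
    s$n_true_hybrid, "/", s$n_informative, " informative seeds; ",
    s$n_diagnostic, " diagnostic loci)\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname hybrid_purity
#' @param x A `gourd_purity`.
#' @param ... Unused.
#' @export
tidy.gourd_purity <- function(x, ...) x$seeds

#' @rdname hybrid_purity
#' @export
glance.gourd_purity <- function(x, ...) x$summary

#' Write fingerprints as TSV
#'
#' @param fps Fingerprint tibble from [fingerprints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  readr::write_tsv(fps, path, progress = FALSE)
  invisible(path)
}
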