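#' Genotype tables for codominant biallelic SNP calls
#'
#' A genotype table (`geno_tbl`) is a tibble with one row per accession and
#' one column per marker. The first column, `accession_id`, holds unique
#' accession labels; every other column holds KASP-style codominant calls
#' coded `"AA"` (homozygous reference), `"AB"` (heterozygous), `"BB"`
#' (homozygous alternate) or `NA` (no call). Marker metadata — chromosome,
#' 1-based physical position, the allele pair and optionally the three KASP
#' primers — travels with the table as the `markers` attribute, a tibble
#' with one row per marker column.
#'
#' Heterozygote phase is never tracked: `"BA"` is accepted on input and
#' normalised to `"AB"`. Positions are 1-based everywhere, matching both
#' VCF and marker-table conventions.
#'
#' @param calls A data frame with an `accession_id` column and one character
#'   column per marker containing calls in `c("AA", "AB", "BB", NA)`.
#' @param markers Optional marker metadata tibble with columns `marker_id`,
#'   `chromosome`, `position_bp`, `allele_ref`, `allele_alt` and optionally
#'   `primer_f1`, `primer_f2`, `primer_common`. When omitted, placeholder
#'   metadata is synthesised (single chromosome `"un"`, positions equal to
#'   column order, generic `A`/`B` alleles).
#'
#' @return A `geno_tbl` (tibble subclass) with the `markers` attribute set.
#' @examples
#' g <- geno_tbl(data.frame(
#'   accession_id = c("acc1", "acc2"),
#'   M1 = c("AA", "BB"), M2 = c("AB", NA)
#' ))
#' markers(g)
#' @export
geno_tbl <- function(calls, markers = NULL) {
  calls <- tibble::as_tibble(calls)
  if (!"accession_id" %in% names(calls)) {
    stop("`calls` must contain an `accession_id` column", call. = FALSE)
  }
  calls <- dplyr::relocate(calls, "accession_id")
  calls$accession_id <- as.character(calls$accession_id)
  marker_ids <- setdiff(names(calls), "accession_id")
  if (length(marker_ids) == 0L) {
    stop("genotype table has no marker columns", call. = FALSE)
  }
  if (anyDuplicated(calls$accession_id)) {
    dup <- unique(calls$accession_id[duplicated(calls$accession_id)])
    stop("duplicate accession ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids in genotype table", call. = FALSE)
  }
  for (m in marker_ids) {
    calls[[m]] <- normalize_calls(calls[[m]], m)
  }
  if (is.null(markers)) {
    markers <- tibble::tibble(
      marker_id = marker_ids,
      chromosome = "un",
      position_bp = seq_along(marker_ids),
      allele_ref = "A",
      allele_alt = "B"
    )
  }
  markers <- validate_markers(markers)
  if (!setequal(markers$marker_id, marker_ids)) {
    stop("marker metadata does not match genotype table columns", call. = FALSE)
  }
  markers <- markers[match(marker_ids, markers$marker_id), ]
  attr(calls, "markers") <- markers
  class(calls) <- c("geno_tbl", class(calls))
  calls
}

#' @rdname geno_tbl
#' @param x A `geno_tbl`.
#' @export
markers <- function(x) {
  mk <- attr(x, "markers", exact = TRUE)
  if (is.null(mk)) stop("no marker metadata attached; not a geno_tbl?", call. = FALSE)
  mk
}

#' @rdname geno_tbl
#' @export
marker_ids <- function(x) setdiff(names(x), "accession_id")

#' @rdname geno_tbl
#' @export
accession_ids <- function(x) x$accession_id

# canonical call symbols; BA folded into AB (no phase), "-"/"" read as no-call
normalize_calls <- function(v, marker) {
  v <- toupper(trimws(as.character(v)))
  v[v %in% c("", "-", "NA", "./.", ".")] <- NA_character_
  v[v == "BA"] <- "AB"
  bad <- !is.na(v) & !v %in% c("AA", "AB", "BB")
  if (any(bad)) {
    stop(
      "unparseable genotype call(s) at marker ", marker, ": ",
      paste(unique(v[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  v
}

validate_markers <- function(markers) {
  markers <- tibble::as_tibble(markers)
  need <- c("marker_id", "chromosome", "position_bp", "allele_ref", "allele_alt")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    stop("marker metadata lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker ids in metadata", call. = FALSE)
  }
  if (any(is.na(markers$position_bp)) || any(markers$position_bp < 1L)) {
    stop("marker positions must be integers >= 1 (1-based)", call. = FALSE)
  }
  same <- !is.na(markers$allele_ref) & markers$allele_ref == markers$allele_alt
  if (any(same)) {
    stop(
      "reference and alternate allele identical for marker(s): ",
      paste(markers$marker_id[same], collapse = ", "),
      call. = FALSE
    )
  }
  for (p in c("primer_f1", "primer_f2", "primer_common")) {
    if (!p %in% names(markers)) markers[[p]] <- NA_character_
  }
  markers
}

#' Integer dosage codes for a genotype table
#'
#' Returns the n x L integer matrix of alternate-allele dosages
#' (AA = 0, AB = 1, BB = 2, no-call = NA) with accession ids as row names
#' and marker ids as column names. This is the numeric substrate shared by
#' the statistics, panel-selection and ordination code.
#'
#' @param g A [geno_tbl()].
#' @return Integer matrix, accessions x markers.
#' @export
geno_dosage <- function(g) {
  ids <- marker_ids(g)
  codes <- c(AA = 0L, AB = 1L, BB = 2L)
  m <- vapply(
    ids,
    function(j) unname(codes[g[[j]]]),
    integer(nrow(g))
  )
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(g))
  dimnames(m) <- list(g$accession_id, ids)
  m
}

#' Per-marker genotype class counts
#'
#' Counting helper used throughout: for one marker column, the number of
#' AA / AB / BB calls, the number of no-calls, and the allele bookkeeping
#' identity that 2 n_AA + n_AB + ... equals twice the called sample count.
#'
#' @param g A [geno_tbl()].
#' @param marker_id Marker column to count.
#' @return A one-row tibble with columns `marker_id`, `n_aa`, `n_ab`,
#'   `n_bb`, `n_missing`, `n_called`.
#' @export
count_calls <- function(g, marker_id) {
  if (!marker_id %in% marker_ids(g)) {
    stop("unknown marker: ", marker_id, call. = FALSE)
  }
  v <- g[[marker_id]]
  tibble::tibble(
    marker_id = marker_id,
    n_aa = sum(v == "AA", na.rm = TRUE),
    n_ab = sum(v == "AB", na.rm = TRUE),
    n_bb = sum(v == "BB", na.rm = TRUE),
    n_missing = sum(is.na(v)),
    n_called = sum(!is.na(v))
  )
}

#' Read and write wide genotype tables
#'
#' The wide dialect is a CSV with a header row of marker ids, a first
#' column of accession ids, and cells in `AA`, `AB`/`BA`, `BB`, `NA`, `-`
#' or empty (case-insensitive). Unparseable cells are an error — they are
#' never silently coerced to missing. `write_genotype_table()` emits `NA`
#' for no-calls so the round trip is the identity.
#'
#' @param path File path.
#' @param markers Optional marker metadata to attach (see [geno_tbl()]).
#' @param dialect Table dialect; only `"wide_csv"` is defined.
#' @return `read_genotype_table()` returns a validated [geno_tbl()];
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path, markers = NULL, dialect = "wide_csv") {
  dialect <- match.arg(dialect, "wide_csv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), # keep literal "NA"/"-"/"" for normalize_calls to interpret
    progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed genotype table (ragged rows?) in ", path, call. = FALSE)
  }
  names(raw)[1] <- "accession_id"
  geno_tbl(raw, markers = markers)
}

#' @rdname read_genotype_table
#' @param g A [geno_tbl()] to write.
#' @export
write_genotype_table <- function(g, path) {
  out <- tibble::as_tibble(g)
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Reads GT fields from a VCF and maps `0/0` to `AA`, `0/1` or `1/0` to
#' `AB`, `1/1` to `BB` and `./.` to a no-call (phased separators are
#' accepted). Only biallelic SNP records are kept; multiallelic records are
#' rejected and listed, with reasons, in the `skipped` attribute of the
#' result. Positions stay 1-based as in the VCF.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF with a GT field.
#' @return A [geno_tbl()] whose markers carry the VCF CHROM/POS/REF/ALT;
#'   attribute `skipped` is a tibble of rejected records and reasons.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) stop("no variant records in ", path, call. = FALSE)
  fmt <- v@gt
  if (is.null(fmt) || !"FORMAT" %in% colnames(fmt)) {
    stop("VCF has no genotype (FORMAT/GT) section: ", path, call. = FALSE)
  }
  has_gt <- vapply(
    strsplit(fmt[, "FORMAT"], ":", fixed = TRUE),
    function(f) "GT" %in% f, logical(1)
  )
  if (!all(has_gt)) stop("GT missing from FORMAT in some records", call. = FALSE)

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  not_snp <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | is.na(alt))
  keep <- !multi & !not_snp
  skipped <- tibble::tibble(
    chromosome = fix$CHROM[!keep],
    position_bp = as.integer(fix$POS[!keep]),
    reason = ifelse(multi[!keep], "multiallelic", "not a SNP")
  )
  if (!any(keep)) stop("no biallelic SNP records kept from ", path, call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  map_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_character_, length(x))
    out[x == "0/0"] <- "AA"
    out[x %in% c("0/1", "1/0")] <- "AB"
    out[x == "1/1"] <- "BB"
    bad <- !is.na(x) & !x %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (any(bad)) stop("unsupported GT value(s): ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    out
  }
  calls <- apply(gt, 2, map_gt)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = sum(keep))

  ids <- fix$ID[keep]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[keep][no_id], "_", fix$POS[keep][no_id])
  mk <- tibble::tibble(
    marker_id = ids,
    chromosome = fix$CHROM[keep],
    position_bp = as.integer(fix$POS[keep]),
    allele_ref = ref[keep],
    allele_alt = alt[keep]
  )
  tab <- tibble::as_tibble(t(calls), .name_repair = "minimal")
  names(tab) <- ids
  tab <- dplyr::bind_cols(tibble::tibble(accession_id = colnames(gt)), tab)
  out <- geno_tbl(tab, markers = mk)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype table as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 text file with one biallelic SNP record
#' per marker (GT-only FORMAT), suitable for re-reading with [read_vcf()].
#'
#' @param g A [geno_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  mk <- markers(g)
  dos <- geno_dosage(g)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      g$accession_id
    ), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(mk)), function(j) {
    gts <- gt_code[as.character(dos[, j])]
    gts[is.na(gts)] <- "./."
    paste(c(
      mk$chromosome[j], mk$position_bp[j], mk$marker_id[j],
      mk$allele_ref[j], mk$allele_alt[j], ".", ".", ".", "GT", gts
    ), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read and write marker metadata tables
#'
#' Marker tables are TSVs with the columns `Name`, `Chromosome`,
#' `Position`, `Variation type` (allele pair as `REF/ALT`) and the three
#' KASP primer sequences `F1`, `F2`, `R` (allele-specific forwards and the
#' common reverse). Empty primer cells are allowed.
#'
#' @param markers Marker metadata tibble (see [geno_tbl()]).
#' @param path File path.
#' @return `write_marker_table()` returns `path` invisibly;
#'   `read_marker_table()` returns a marker metadata tibble.
#' @export
write_marker_table <- function(markers, path) {
  markers <- validate_markers(markers)
  if (nrow(markers) == 0L) stop("empty marker list", call. = FALSE)
  out <- tibble::tibble(
    Name = markers$marker_id,
    Chromosome = markers$chromosome,
    Position = markers$position_bp,
    `Variation type` = paste0(markers$allele_ref, "/", markers$allele_alt),
    F1 = ifelse(is.na(markers$primer_f1), "", markers$primer_f1),
    F2 = ifelse(is.na(markers$primer_f2), "", markers$primer_f2),
    R = ifelse(is.na(markers$primer_common), "", markers$primer_common)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  alle <- strsplit(raw$`Variation type`, "/", fixed = TRUE)
  blank_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  validate_markers(tibble::tibble(
    marker_id = raw$Name,
    chromosome = raw$Chromosome,
    position_bp = as.integer(raw$Position),
    allele_ref = vapply(alle, `[`, character(1), 1),
    allele_alt = vapply(alle, `[`, character(1), 2),
    primer_f1 = blank_na(raw$F1),
    primer_f2 = blank_na(raw$F2),
    primer_common = blank_na(raw$R)
  ))
}

#' Subset a genotype table by markers and/or accessions
#'
#' @param g A [geno_tbl()].
#' @param markers Character vector of marker ids to keep (default all).
#' @param accessions Character vector of accession ids to keep (default all).
#' @return A [geno_tbl()] with metadata subset accordingly.
#' @export
geno_subset <- function(g, markers = NULL, accessions = NULL) {
  mk <- gourdcore::markers(g)
  keep_m <- if (is.null(markers)) mk$marker_id else markers
  unknown <- setdiff(keep_m, mk$marker_id)
  if (length(unknown)) stop("unknown marker(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keep_a <- if (is.null(accessions)) g$accession_id else accessions
  unknown <- setdiff(keep_a, g$accession_id)
  if (length(unknown)) stop("unknown accession(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  tab <- tibble::as_tibble(g)[match(keep_a, g$accession_id), c("accession_id", keep_m)]
  geno_tbl(tab, markers = mk[match(keep_m, mk$marker_id), ])
}

#' @export
print.geno_tbl <- function(x, ...) {
  mk <- attr(x, "markers", exact = TRUE)
  cat(
    "# Genotype table: ", nrow(x), " accessions x ", length(marker_ids(x)),
    " markers (", length(unique(mk$chromosome)), " chromosome(s))\n",
    sep = ""
  )
  NextMethod()
}
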