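#' Simulation configurations for synthetic genotype panels
#'
#' `panel_sim_config()` parameterises a structured collection of inbred
#' accessions: each marker gets an ancestral allele frequency drawn
#' uniformly on `[maf_floor, 1 - maf_floor]`, subpopulation frequencies are
#' drawn around it from the Balding-Nichols Beta compound with
#' differentiation parameter `fst`, and each accession is homozygous at
#' each locus with its subpopulation's allele frequency. Residual
#' heterozygosity (`het_rate`) and missingness (`missing_rate`) are applied
#' as independent per-call noise, mirroring the low rates seen in KASP
#' genotyping of inbred germplasm.
#'
#' Defaults emulate the study conditions the package's analyses assume: a
#' 206-accession collection in two subpopulations genotyped at 93
#' high-quality SNPs on 11 chromosomes, with mean observed heterozygosity
#' around 0.02 and a few percent missing data.
#'
#' @param n_accessions Number of accessions (>= 2).
#' @param n_markers Number of markers; assigned round-robin to chromosomes.
#' @param n_chromosomes Number of chromosomes (default 11).
#' @param n_subpops Number of subpopulations (default 2).
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param maf_floor Lower bound on the ancestral minor allele frequency.
#' @param het_rate Per-call residual heterozygosity probability in `[0, 0.1]`.
#' @param missing_rate Per-call no-call probability in `[0, 0.1]`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_accessions = 206, n_markers = 93,
                             n_chromosomes = 11, n_subpops = 2,
                             fst = 0.1, maf_floor = 0.05,
                             het_rate = 0.02, missing_rate = 0.03,
                             seed = 1) {
  stopifnot(
    n_accessions >= 2, n_markers >= 1, n_chromosomes >= 1, n_subpops >= 1,
    fst >= 0, fst < 1,
    maf_floor >= 0, maf_floor < 0.5,
    het_rate >= 0, het_rate <= 0.1,
    missing_rate >= 0, missing_rate <= 0.1
  )
  structure(
    list(
      n_accessions = as.integer(n_accessions), n_markers = as.integer(n_markers),
      n_chromosomes = as.integer(n_chromosomes), n_subpops = as.integer(n_subpops),
      fst = fst, maf_floor = maf_floor, het_rate = het_rate,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "panel_sim_config"
  )
}

#' @rdname panel_sim_config
#' @param n_founders Number of founder lines (>= 2, default 8).
#' @param n_lines Number of recombinant inbred lines (default 377).
#' @param block_len_markers Mean founder-block length in markers
#'   (geometric blocks, >= 1).
#' @export
magic_sim_config <- function(n_founders = 8, n_lines = 377,
                             n_markers = 22, n_chromosomes = 11,
                             block_len_markers = 5,
                             het_rate = 0.02, missing_rate = 0.02,
                             seed = 1) {
  stopifnot(
    n_founders >= 2, n_lines >= 1, n_markers >= 1, n_chromosomes >= 1,
    block_len_markers >= 1,
    het_rate >= 0, het_rate <= 0.1,
    missing_rate >= 0, missing_rate <= 0.1
  )
  structure(
    list(
      n_founders = as.integer(n_founders), n_lines = as.integer(n_lines),
      n_markers = as.integer(n_markers), n_chromosomes = as.integer(n_chromosomes),
      block_len_markers = block_len_markers,
      het_rate = het_rate, missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "magic_sim_config"
  )
}

# round-robin chromosome assignment + sorted uniform positions per chromosome
sim_marker_map <- function(n_markers, n_chromosomes, chrom_len = 3e7) {
  chrom <- as.character(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- integer(n_markers)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(chrom_len, length(idx)))
  }
  tibble::tibble(
    marker_id = sprintf("S%03d", seq_len(n_markers)),
    chromosome = chrom,
    position_bp = pos,
    allele_ref = "A",
    allele_alt = "B"
  )
}

# independent per-call noise shared by both simulators:
# residual heterozygosity first, then no-call masking
apply_call_noise <- function(calls, het_rate, missing_rate) {
  n <- length(calls)
  if (het_rate > 0) {
    calls[stats::runif(n) < het_rate] <- "AB"
  }
  if (missing_rate > 0) {
    calls[stats::runif(n) < missing_rate] <- NA_character_
  }
  calls
}

#' Simulate a structured panel of inbred accessions
#'
#' Draws genotypes under the Balding-Nichols island model described in
#' [panel_sim_config()]: subpopulation allele frequencies are
#' `Beta(p0 (1 - fst) / fst, (1 - p0) (1 - fst) / fst)` around the
#' ancestral frequency `p0` (degenerating to `p0` itself at `fst = 0`),
#' accessions are fully inbred draws from their subpopulation frequency,
#' and per-call heterozygosity/missingness noise is applied afterwards.
#' Accessions are split across subpopulations as evenly as possible.
#' Deterministic for a fixed `seed`.
#'
#' @param cfg A [panel_sim_config()].
#' @return A [geno_tbl()] with attributes `subpop` (integer subpopulation
#'   label per accession, in row order), `ancestral_freq` (the drawn
#'   ancestral reference-allele frequency per marker) and `subpop_freq`
#'   (subpopulation x marker frequency matrix) so tests can recover the
#'   generating parameters.
#' @export
simulate_structured_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  withr::with_seed(cfg$seed, {
    mk <- sim_marker_map(cfg$n_markers, cfg$n_chromosomes)
    subpop <- rep_len(seq_len(cfg$n_subpops), cfg$n_accessions)
    p0 <- stats::runif(cfg$n_markers, cfg$maf_floor, 1 - cfg$maf_floor)
    # subpop x marker allele frequencies under the Beta compound
    pk <- if (cfg$fst == 0) {
      matrix(rep(p0, each = cfg$n_subpops), nrow = cfg$n_subpops)
    } else {
      a <- p0 * (1 - cfg$fst) / cfg$fst
      b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
      matrix(
        stats::rbeta(cfg$n_subpops * cfg$n_markers, rep(a, each = cfg$n_subpops),
                     rep(b, each = cfg$n_subpops)),
        nrow = cfg$n_subpops
      )
    }
    pmat <- pk[subpop, , drop = FALSE] # accession x marker P(hom ref)
    calls <- ifelse(stats::runif(length(pmat)) < pmat, "AA", "BB")
    calls <- apply_call_noise(calls, cfg$het_rate, cfg$missing_rate)
    calls <- matrix(calls, nrow = cfg$n_accessions)
    tab <- tibble::as_tibble(calls, .name_repair = "minimal")
    names(tab) <- mk$marker_id
    tab <- dplyr::bind_cols(
      tibble::tibble(accession_id = sprintf("acc%03d", seq_len(cfg$n_accessions))),
      tab
    )
    out <- geno_tbl(tab, markers = mk)
    attr(out, "subpop") <- subpop
    attr(out, "ancestral_freq") <- p0
    attr(out, "subpop_freq") <- pk
    out
  })
}

#' Simulate a MAGIC-style recombinant inbred panel
#'
#' Founders are fully homozygous random mosaics of the two alleles; each
#' recombinant inbred line is, per chromosome, a mosaic of founder
#' haplotypes whose block lengths (in markers) are geometric with mean
#' `block_len_markers`. Lines are fully inbred before the per-call
#' heterozygosity/missingness noise is applied. Deterministic for a fixed
#' `seed`.
#'
#' @param cfg A [magic_sim_config()].
#' @return A [geno_tbl()] of the recombinant lines, with attribute
#'   `founders` holding the founder [geno_tbl()].
#' @export
simulate_magic_panel <- function(cfg) {
  stopifnot(inherits(cfg, "magic_sim_config"))
  withr::with_seed(cfg$seed, {
    mk <- sim_marker_map(cfg$n_markers, cfg$n_chromosomes)
    # founder haplotypes: founder x marker, allele 0 (A) or 1 (B)
    found <- matrix(
      stats::rbinom(cfg$n_founders * cfg$n_markers, 1L, 0.5),
      nrow = cfg$n_founders
    )
    p_switch <- 1 / cfg$block_len_markers
    line_calls <- matrix(NA_character_, cfg$n_lines, cfg$n_markers)
    for (i in seq_len(cfg$n_lines)) {
      donor <- integer(cfg$n_markers)
      for (cc in unique(mk$chromosome)) {
        idx <- which(mk$chromosome == cc)
        cur <- sample.int(cfg$n_founders, 1L)
        for (j in idx) {
          if (j != idx[1] && stats::runif(1) < p_switch) {
            cur <- sample.int(cfg$n_founders, 1L)
          }
          donor[j] <- cur
        }
      }
      allele <- found[cbind(donor, seq_len(cfg$n_markers))]
      line_calls[i, ] <- ifelse(allele == 0L, "AA", "BB")
    }
    line_calls <- matrix(
      apply_call_noise(as.vector(line_calls), cfg$het_rate, cfg$missing_rate),
      nrow = cfg$n_lines
    )
    tab <- tibble::as_tibble(line_calls, .name_repair = "minimal")
    names(tab) <- mk$marker_id
    tab <- dplyr::bind_cols(
      tibble::tibble(accession_id = sprintf("ril%03d", seq_len(cfg$n_lines))),
      tab
    )
    out <- geno_tbl(tab, markers = mk)

    ftab <- tibble::as_tibble(
      matrix(ifelse(found == 0L, "AA", "BB"), nrow = cfg$n_founders),
      .name_repair = "minimal"
    )
    names(ftab) <- mk$marker_id
    ftab <- dplyr::bind_cols(
      tibble::tibble(accession_id = sprintf("founder%d", seq_len(cfg$n_founders))),
      ftab
    )
    attr(out, "founders") <- geno_tbl(ftab, markers = mk)
    out
  })
}

#' Plant exact genotype duplicates into a panel
#'
#' For each pair `c(a, b)`, accession `b`'s calls are overwritten with an
#' exact copy of `a`'s. Used to construct known-unresolvable fixtures for
#' discrimination and duplicate-detection tests.
#'
#' @param g A [geno_tbl()].
#' @param pairs List of length-2 character vectors `c(source, copy)`.
#' @return The modified [geno_tbl()].
#' @export
plant_known_duplicates <- function(g, pairs) {
  if (length(pairs) == 0L) return(g)
  mk <- markers(g)
  tab <- tibble::as_tibble(g)
  for (pr in pairs) {
    stopifnot(length(pr) == 2L)
    i <- match(pr[1], tab$accession_id)
    j <- match(pr[2], tab$accession_id)
    if (is.na(i) || is.na(j)) {
      stop("unknown accession id in pair: ", paste(pr, collapse = ", "), call. = FALSE)
    }
    tab[j, -1] <- tab[i, -1]
  }
  out <- geno_tbl(tab, markers = mk)
  for (a in c("subpop", "founders")) {
    if (!is.null(attr(g, a, exact = TRUE))) attr(out, a) <- attr(g, a, exact = TRUE)
  }
  out
}
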