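# accession x (locus, allele) incidence: which alleles each accession carries.
# Heterozygotes carry both; no-calls carry neither.
allele_incidence <- function(dos) {
  carries_ref <- !is.na(dos) & dos <= 1L
  carries_alt <- !is.na(dos) & dos >= 1L
  inc <- matrix(FALSE, nrow(dos), 2L * ncol(dos))
  inc[, seq(1L, 2L * ncol(dos), by = 2L)] <- carries_ref
  inc[, seq(2L, 2L * ncol(dos), by = 2L)] <- carries_alt
  rownames(inc) <- rownames(dos)
  inc
}

#' Allele coverage of a core subset
#'
#' The percentage of (locus, allele) pairs observed anywhere in the whole
#' collection that are also observed in the core subset. An allele is
#' observed through any carrier, homozygous or heterozygous.
#'
#' @param whole A [geno_tbl()] of the full collection.
#' @param core_ids Accession ids of the core subset.
#' @return Coverage percentage in `[0, 100]`.
#' @examples
#' g <- simulate_structured_panel(panel_sim_config(n_accessions = 20, n_markers = 10))
#' allele_coverage(g, accession_ids(g)) # 100
#' @export
allele_coverage <- function(whole, core_ids) {
  if (length(core_ids) == 0L) stop("empty core", call. = FALSE)
  unknown <- setdiff(core_ids, whole$accession_id)
  if (length(unknown)) stop("unknown accession(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  inc <- allele_incidence(geno_dosage(whole))
  observed <- colSums(inc) > 0L
  in_core <- colSums(inc[match(core_ids, rownames(inc)), , drop = FALSE]) > 0L
  100 * sum(in_core & observed) / sum(observed)
}

#' Configuration for core-collection selection
#'
#' @param target_fraction Fraction of accessions to keep in `(0, 1]`
#'   (default 0.5, the usual halving of a collection); ignored when
#'   `target_count` is given.
#' @param target_count Absolute core size (optional).
#' @param metric Distance metric driving the optimization (default
#'   `"modified_rogers"`; see [pairwise_distance()]).
#' @param require_full_coverage Keep 100% allele coverage as a hard
#'   constraint (default `TRUE`).
#' @param forced_ids Accessions that must be in the core (e.g. breeder
#'   picks added to an algorithmic core).
#' @param n_restarts Independent local-search restarts (default 2).
#' @param max_swap_iters Cap on evaluated candidate swaps per restart
#'   (default 2000).
#' @param seed Integer seed for the (shuffled) swap neighborhood.
#' @return A `core_config` list.
#' @export
core_config <- function(target_fraction = 0.5, target_count = NULL,
                        metric = c("modified_rogers", "cavalli_sforza_edwards",
                                   "nei_standard"),
                        require_full_coverage = TRUE, forced_ids = character(0),
                        n_restarts = 2, max_swap_iters = 2000, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(
    is.null(target_count) || target_count >= 1,
    target_fraction > 0, target_fraction <= 1,
    n_restarts >= 1, max_swap_iters >= 0
  )
  structure(
    list(
      target_fraction = target_fraction,
      target_count = if (is.null(target_count)) NULL else as.integer(target_count),
      metric = metric, require_full_coverage = require_full_coverage,
      forced_ids = as.character(forced_ids),
      n_restarts = as.integer(n_restarts),
      max_swap_iters = as.integer(max_swap_iters),
      seed = as.integer(seed)
    ),
    class = "core_config"
  )
}

# mean entry-to-nearest-entry distance of a core (indices into D)
mean_ene <- function(D, idx) {
  dc <- D[idx, idx, drop = FALSE]
  diag(dc) <- Inf
  mean(apply(dc, 1, min))
}

#' Select a coverage-constrained core collection
#'
#' Builds a core subset of the collection in three phases:
#'
#' 1. **Coverage greedy**: starting from `forced_ids`, repeatedly add the
#'    accession covering the most still-uncovered (locus, allele) pairs;
#'    ties go to the candidate with the larger mean distance to the
#'    current core, then to the smaller id. This phase alone attains 100%
#'    allele coverage (or proves the target infeasible).
#' 2. **Farthest-point completion**: fill up to the target size with the
#'    accession maximizing its minimum distance to the current core.
#' 3. **Swap search**: first-improvement local search over a seeded,
#'    shuffled remove/add neighborhood, maximizing the mean
#'    entry-to-nearest-entry distance; swaps that would break full
#'    coverage (when required) or evict a forced accession are rejected.
#'    The best of `n_restarts` restarts is kept.
#'
#' @param whole A [geno_tbl()] of the full collection.
#' @param cfg A [core_config()].
#' @return A `gourd_core` object: `core_ids`, `metrics` (the
#'   [evaluate_core()] row), `objective` (mean entry-to-nearest-entry
#'   distance), `config`. Supports [tidy()] and [glance()].
#' @examples
#' g <- simulate_structured_panel(panel_sim_config(n_accessions = 40, n_markers = 20))
#' core <- select_core(g, core_config(target_fraction = 0.5, max_swap_iters = 200))
#' glance(core)
#' @export
select_core <- function(whole, cfg = core_config()) {
  stopifnot(inherits(cfg, "core_config"))
  ids <- whole$accession_id
  n <- length(ids)
  target <- if (!is.null(cfg$target_count)) cfg$target_count else
    max(1L, round(cfg$target_fraction * n))
  if (target > n) stop("target exceeds collection size", call. = FALSE)
  unknown <- setdiff(cfg$forced_ids, ids)
  if (length(unknown)) stop("unknown forced accession(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  dos <- geno_dosage(whole)
  inc <- allele_incidence(dos)
  observed <- colSums(inc) > 0L
  D <- as.matrix(pairwise_distance(whole, cfg$metric))

  # --- phase 1: greedy allele-coverage completion from the forced set
  core <- match(cfg$forced_ids, ids)
  cnt <- colSums(inc[core, , drop = FALSE])
  if (cfg$require_full_coverage) {
    repeat {
      uncovered <- observed & cnt == 0L
      if (!any(uncovered)) break
      out_idx <- setdiff(seq_len(n), core)
      gains <- rowSums(inc[out_idx, uncovered, drop = FALSE])
      mean_d <- if (length(core)) rowMeans(D[out_idx, core, drop = FALSE]) else rep(0, length(out_idx))
      pick <- out_idx[order(-gains, -mean_d, ids[out_idx], method = "radix")[1]]
      core <- c(core, pick)
      cnt <- cnt + inc[pick, ]
    }
    if (length(core) > target) {
      stop(
        "full allele coverage needs at least ", length(core),
        " accessions (greedy bound); target ", target, " is infeasible",
        call. = FALSE
      )
    }
  }

  # --- phase 2: farthest-point completion to the target size
  while (length(core) < target) {
    out_idx <- setdiff(seq_len(n), core)
    min_d <- if (length(core)) {
      apply(D[out_idx, core, drop = FALSE], 1, min)
    } else {
      rep(0, length(out_idx))
    }
    pick <- out_idx[order(-min_d, ids[out_idx], method = "radix")[1]]
    core <- c(core, pick)
    cnt <- cnt + inc[pick, ]
  }
  init_core <- core
  init_cnt <- cnt
  forced_idx <- match(cfg$forced_ids, ids)

  # --- phase 3: first-improvement swap search, best of n_restarts
  best_core <- init_core
  best_obj <- if (length(init_core) >= 2) mean_ene(D, init_core) else 0
  run_restart <- function(restart_seed) {
    withr::with_seed(restart_seed, {
      core <- init_core
      cnt <- init_cnt
      obj <- if (length(core) >= 2) mean_ene(D, core) else 0
      evals <- 0L
      improved <- TRUE
      while (improved && evals < cfg$max_swap_iters && length(core) >= 2 &&
             length(core) < n) {
        improved <- FALSE
        removable <- setdiff(core, forced_idx)
        outside <- setdiff(seq_len(n), core)
        nb <- expand.grid(out = removable, into = outside)
        nb <- nb[sample.int(nrow(nb)), , drop = FALSE]
        for (s in seq_len(nrow(nb))) {
          if (evals >= cfg$max_swap_iters) break
          a <- nb$out[s]
          b <- nb$into[s]
          if (cfg$require_full_coverage) {
            lost <- observed & inc[a, ] & cnt == 1L & !inc[b, ]
            if (any(lost)) next
          }
          cand <- c(setdiff(core, a), b)
          evals <- evals + 1L
          cand_obj <- mean_ene(D, cand)
          if (cand_obj > obj + 1e-12) {
            core <- cand
            cnt <- cnt - inc[a, ] + inc[b, ]
            obj <- cand_obj
            improved <- TRUE
            break
          }
        }
      }
      list(core = core, obj = obj)
    })
  }
  for (r in seq_len(cfg$n_restarts)) {
    res <- run_restart(cfg$seed + r - 1L)
    if (res$obj > best_obj) {
      best_obj <- res$obj
      best_core <- res$core
    }
  }

  core_ids <- sort(ids[best_core])
  structure(
    list(
      core_ids = core_ids,
      metrics = evaluate_core(whole, core_ids),
      objective = if (length(best_core) >= 2) mean_ene(D, best_core) else 0,
      config = cfg
    ),
    class = "gourd_core"
  )
}

#' Evaluate a core subset against the whole collection
#'
#' The standard one-row evaluation report: mean pairwise modified Rogers
#' (`MR`) and Cavalli-Sforza-Edwards (`CE`) distances within the core,
#' pooled Shannon index (`SH`), mean gene diversity (`HE`), mean number
#' of effective alleles (`NE`, per-locus `1 / sum(p^2)` averaged), mean
#' Botstein PIC (`PIC`) and allele coverage (`CV`, %) — all computed on
#' the core, with coverage relative to the whole collection.
#'
#' @param whole A [geno_tbl()] of the full collection.
#' @param core_ids Accession ids of the core subset.
#' @return A one-row tibble: `n_whole`, `n_core`, `MR`, `CE`, `SH`, `HE`,
#'   `NE`, `PIC`, `CV`.
#' @export
evaluate_core <- function(whole, core_ids) {
  core <- geno_subset(whole, accessions = core_ids)
  s <- panel_summary(core)
  mr <- pairwise_distance(core, "modified_rogers")
  ce <- pairwise_distance(core, "cavalli_sforza_edwards")
  ut <- upper.tri(mr$d)
  tibble::tibble(
    n_whole = nrow(whole),
    n_core = length(core_ids),
    MR = mean(mr$d[ut]),
    CE = mean(ce$d[ut]),
    SH = shannon_index_pooled(core),
    HE = mean(s$he),
    NE = mean(s$ne),
    PIC = mean(s$pic_botstein),
    CV = allele_coverage(whole, core_ids)
  )
}

#' @rdname select_core
#' @param x A `gourd_core`.
#' @param ... Unused.
#' @export
tidy.gourd_core <- function(x, ...) {
  tibble::tibble(
    accession_id = x$core_ids,
    forced = x$core_ids %in% x$config$forced_ids
  )
}

#' @rdname select_core
#' @export
glance.gourd_core <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::tibble(objective = x$objective))
}

#' @export
print.gourd_core <- function(x, ...) {
  m <- x$metrics
  cat(
    "# Core collection: ", m$n_core, "/", m$n_whole, " accessions; CV ",
    round(m$CV, 1), "%; MR ", round(m$MR, 3), "; CE ", round(m$CE, 3),
    "; objective (mean E-NE) ", round(x$objective, 4), "\n",
    sep = ""
  )
  invisible(x)
}
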