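#' Principal component analysis of a genotype table
#'
#' Accessions are encoded as alternate-allele dosages (AA = 0, AB = 1,
#' BB = 2); no-calls are imputed with the per-marker mean dosage so the
#' decomposition stays dense and deterministic (distances elsewhere use
#' pairwise deletion instead — imputation is confined to ordination).
#' Columns are mean-centred and decomposed by singular value
#' decomposition. Component signs are fixed by making each component's
#' largest-magnitude loading positive, so results do not depend on the
#' underlying LAPACK's sign convention.
#'
#' @param g A [geno_tbl()] with at least two accessions.
#' @param n_components Number of components to keep (default all).
#' @return A `gourd_pca` object: `coordinates` (tibble, `accession_id` +
#'   `PC1..PCk`), `explained` (variance fractions, nonincreasing),
#'   `center` (per-marker mean dosages used). Supports [tidy()] and
#'   [ggplot2::autoplot()].
#' @export
geno_pca <- function(g, n_components = NULL) {
  dos <- geno_dosage(g)
  if (nrow(dos) < 2L) stop("need at least two accessions", call. = FALSE)
  if (ncol(dos) < 1L) stop("need at least one marker", call. = FALSE)
  X <- apply(dos, 2, function(v) {
    mu <- mean(v, na.rm = TRUE)
    v[is.na(v)] <- mu
    v
  })
  if (is.null(dim(X))) X <- matrix(X, nrow = nrow(dos))
  center <- colMeans(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) ncol(pc$x) else min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- dplyr::bind_cols(
    tibble::tibble(accession_id = rownames(dos)),
    tibble::as_tibble(scores)
  )
  structure(
    list(
      coordinates = coords,
      explained = expl[seq_len(k)],
      center = stats::setNames(center, colnames(dos))
    ),
    class = "gourd_pca"
  )
}

#' @rdname geno_pca
#' @param x A `gourd_pca`.
#' @param ... Unused.
#' @export
tidy.gourd_pca <- function(x, ...) x$coordinates

#' @export
print.gourd_pca <- function(x, ...) {
  cat(
    "# PCA of ", nrow(x$coordinates), " accessions; PC1 explains ",
    round(100 * x$explained[1], 1), "% of dosage variance\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname geno_pca
#' @param object A `gourd_pca`.
#' @param colour_by Optional vector (length = accessions) to colour points.
#' @export
autoplot.gourd_pca <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$explained[i])
  p <- if (is.null(colour_by)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  } else {
    df$group <- as.factor(colour_by)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Neighbor-joining tree from a genetic distance matrix
#'
#' Canonical neighbor-joining agglomeration (via [ape::nj()]) on a
#' [pairwise_distance()] result. Negative branch lengths — an occasional
#' artefact of NJ on noisy distances — are clamped to zero, with the
#' affected edges recorded.
#'
#' @param d A `gourd_dist` (or symmetric distance matrix with labels).
#' @return A `gourd_tree` object: `tree` (an [ape] `phylo`), `newick`
#'   (serialized string) and `n_clamped` (edges clamped to zero length).
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "gourd_dist")) d$d else as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (nrow(m) < 3L) stop("need at least three taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  structure(
    list(
      tree = tr,
      newick = ape::write.tree(tr),
      n_clamped = sum(neg)
    ),
    class = "gourd_tree"
  )
}

#' @export
print.gourd_tree <- function(x, ...) {
  cat(
    "# Neighbor-joining tree over ", length(x$tree$tip.label), " taxa",
    if (x$n_clamped > 0) paste0(" (", x$n_clamped, " negative branch(es) clamped to 0)"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a tree to a newick file
#'
#' @param x A `gourd_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  writeLines(x$newick, path)
  invisible(path)
}

#' Heuristic group assignment from principal components
#'
#' k-means on the leading principal components (up to 10 by default), a
#' deliberately lightweight stand-in for Bayesian admixture analysis:
#' the labels are a hard clustering of the dosage geometry, not admixture
#' proportions, and are suitable for checking that a reduced marker panel
#' recovers the same broad groups as a full panel.
#'
#' @param p A `gourd_pca` from [geno_pca()].
#' @param k Number of groups (>= 2).
#' @param seed Integer seed for the k-means restarts.
#' @param n_components Components to cluster on (default
#'   `min(10, available)`).
#' @param n_start k-means restarts (default 20).
#' @return A tibble `accession_id`, `group` (integer labels `1..k`).
#' @export
assign_groups <- function(p, k, seed = 1, n_components = NULL, n_start = 20) {
  stopifnot(inherits(p, "gourd_pca"))
  n <- nrow(p$coordinates)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of accessions", call. = FALSE)
  avail <- ncol(p$coordinates) - 1L
  kc <- if (is.null(n_components)) min(10L, avail) else min(n_components, avail)
  X <- as.matrix(p$coordinates[, 1L + seq_len(kc), drop = FALSE])
  km <- withr::with_seed(seed, stats::kmeans(X, centers = k, nstart = n_start))
  tibble::tibble(
    accession_id = p$coordinates$accession_id,
    group = as.integer(km$cluster)
  )
}

#' Agreement between two group assignments, up to label switching
#'
#' Fraction of accessions on which two clusterings agree under the best
#' one-to-one relabelling (exhaustive over permutations; intended for
#' small k).
#'
#' @param a,b Tibbles from [assign_groups()] over the same accessions.
#' @return Agreement fraction in `[0, 1]`.
#' @export
group_agreement <- function(a, b) {
  m <- dplyr::inner_join(a, b, by = "accession_id", suffix = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no shared accessions", call. = FALSE)
  ka <- sort(unique(m$group_a))
  perms <- all_permutations(sort(unique(m$group_b)))
  best <- 0
  for (pp in perms) {
    relab <- pp[match(m$group_b, sort(unique(m$group_b)))]
    best <- max(best, mean(m$group_a == relab))
  }
  best
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
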