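#' Rank a per-sample expression profile
#'
#' Orders the universe by decreasing statistic value. Ties in the statistic are
#' midranked for weighting purposes and broken by gene id in the ordering, so
#' the profile is fully deterministic.
#'
#' @param values named numeric vector (one statistic per gene).
#' @return object of class `ranked_profile`: `genes` (ordered ids), `values`
#'   (same order), `ranks` (midranks of the original values, higher = more
#'   expressed), `tie_policy`.
#' @export
ranked_profile <- function(values) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be named with unique gene ids")
  ord <- order(-values, names(values))
  structure(list(genes = names(values)[ord],
                 values = unname(values[ord]),
                 ranks = unname(rank(values)[ord]),
                 tie_policy = "midrank; ties in ordering broken by gene id"),
            class = "ranked_profile")
}

check_set_vs_universe <- function(inset, n) {
  m <- sum(inset)
  if (m == 0L) stop("gene set does not overlap the expression universe")
  if (m == n) stop("gene set covers the whole universe; out-of-set ECDF undefined")
  m
}

#' Single-sample GSEA score
#'
#' The ssGSEA statistic: walking down the expression-ranked gene list, the
#' score is the sum over all positions of the difference between the
#' rank-weighted empirical CDF of in-set genes and the unweighted empirical CDF
#' of out-of-set genes. In-set genes are weighted by `rank^alpha` (midranks;
#' the most expressed gene of a tie-free universe of size N has rank N), so the
#' score depends on the expression values only through their rank order.
#'
#' @param expr named numeric vector: one sample's expression over the universe.
#' @param set a `gene_set` or character vector; must overlap the universe and
#'   not cover it entirely.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize if `TRUE`, divide by the range of scores attainable by a
#'   set of this size on a tie-free universe of this size (bounds computed from
#'   the extreme orderings), mapping the score to `[-1, 1]`-comparable units.
#' @return a single numeric score.
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25, normalize = FALSE) {
  prof <- ranked_profile(expr)
  genes <- as_gene_ids(set)
  inset <- prof$genes %in% genes
  n <- length(prof$genes)
  m <- check_set_vs_universe(inset, n)
  score <- ssgsea_walk(prof$ranks, inset, alpha)
  if (normalize) {
    r_ideal <- seq(n, 1)                      # untied ranks, best at the top
    top <- ssgsea_walk(r_ideal, seq_len(n) <= m, alpha)
    bottom <- ssgsea_walk(r_ideal, seq_len(n) > n - m, alpha)
    score <- score / (top - bottom)
  }
  score
}

# core ssGSEA running sum; `ranks` aligned with the descending ordering
ssgsea_walk <- function(ranks, inset, alpha) {
  w <- abs(ranks)^alpha
  p_in <- cumsum(w * inset) / sum(w[inset])
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

#' Weighted running-sum enrichment score (GSEA)
#'
#' The weighted Kolmogorov-Smirnov-style statistic: walking down the ranked
#' list, in-set genes add `|statistic|^weight_exponent` (normalised over the
#' in-set genes) and out-of-set genes subtract `1 / (N - N_set)`. The
#' enrichment score is the signed maximal deviation of this walk from zero;
#' the walk itself ends at zero by construction.
#'
#' @param profile a `ranked_profile` (or named numeric vector, ranked
#'   internally).
#' @param set `gene_set` or character vector, strictly smaller than the
#'   universe.
#' @param weight_exponent exponent on `|statistic|` for hit steps (default 1;
#'   0 gives the classic unweighted KS walk).
#' @return list of class `enrichment_result`: `es`, `curve` (running sum, one
#'   value per position), `hit_positions`.
#' @export
running_es <- function(profile, set, weight_exponent = 1) {
  if (!inherits(profile, "ranked_profile")) profile <- ranked_profile(profile)
  genes <- as_gene_ids(set)
  inset <- profile$genes %in% genes
  n <- length(profile$genes)
  check_set_vs_universe(inset, n)
  w <- abs(profile$values)^weight_exponent
  if (weight_exponent > 0 && all(w[inset] == 0))
    stop("all in-set statistics are zero; hit weights undefined")
  if (weight_exponent == 0) w <- rep(1, n)
  step <- ifelse(inset, w / sum(w[inset]), -1 / (n - sum(inset)))
  curve <- cumsum(step)
  es <- curve[which.max(abs(curve))]
  structure(list(es = es, curve = curve, hit_positions = which(inset)),
            class = "enrichment_result")
}

#' Gene-set permutation p-value for an enrichment score
#'
#' Significance of a running-sum enrichment score against a null of random
#' same-size gene sets drawn from the universe: the p-value is
#' `(1 + #permuted |ES| >= |ES_obs|) / (n_perm + 1)`.
#'
#' @param profile `ranked_profile` or named numeric vector.
#' @param set `gene_set` or character vector.
#' @param n_perm number of random sets (>= 100).
#' @param seed integer seed making the draw reproducible.
#' @param weight_exponent passed to [running_es()].
#' @return list: `es`, `p`, `n_perm`, `seed`, `warning` (NULL or text).
#' @export
geneset_permutation_p <- function(profile, set, n_perm = 1000, seed = 1,
                                  weight_exponent = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!inherits(profile, "ranked_profile")) profile <- ranked_profile(profile)
  genes <- as_gene_ids(set)
  m <- sum(profile$genes %in% genes)
  n <- length(profile$genes)
  obs <- running_es(profile, set, weight_exponent)
  warn <- NULL
  if (m > n / 2 && choose(n, m) < n_perm) {
    warn <- sprintf("only %d distinct sets of size %d exist in a %d-gene universe",
                    choose(n, m), m, n)
    warning(warn)
  }
  null_abs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    rs <- sample(profile$genes, m)
    abs(running_es(profile, rs, weight_exponent)$es)
  }, numeric(1)))
  p <- (1 + sum(null_abs >= abs(obs$es))) / (n_perm + 1)
  list(es = obs$es, p = p, n_perm = n_perm, seed = seed, warning = warn)
}

#' Contrast signature scores between two cell groups
#'
#' Median difference (first label minus second, labels in sorted order) and
#' two-sided rank-sum p-value between exactly two groups of per-cell scores.
#'
#' @param scores numeric vector of per-cell signature scores.
#' @param labels group label per cell; exactly two distinct labels, each with
#'   at least 3 cells.
#' @return list: `labels` (the two labels, order used), `median_diff`, `U`, `p`.
#' @export
signature_contrast <- function(scores, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop(sprintf("need exactly 2 labels, got %d", length(lv)))
  a <- scores[labels == lv[1]]; b <- scores[labels == lv[2]]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 cells")
  ts <- rank_sum_test(a, b, "two.sided")
  list(labels = lv, median_diff = stats::median(a) - stats::median(b),
       U = ts$U, p = ts$p)
}

#' Spearman correlation between signature and pathway scores
#'
#' Spearman's rho on midranks with the t-distribution approximation for the
#' p-value.
#'
#' @param subtype_scores,pathway_scores paired numeric vectors, `n >= 4`.
#' @return list: `rho`, `p`, `n`.
#' @export
pathway_correlation <- function(subtype_scores, pathway_scores) {
  x <- as.numeric(subtype_scores); y <- as.numeric(pathway_scores)
  if (length(x) != length(y)) stop("score vectors must be paired")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector; rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

#' Score gene sets across all cells of an expression matrix
#'
#' Convenience wrapper applying [ssgsea_score()] per cell for each set.
#'
#' @param sce log-normalised `SingleCellExperiment`.
#' @param sets list of `gene_set` objects (e.g. from [read_gmt()]).
#' @param alpha,normalize passed to [ssgsea_score()].
#' @return numeric matrix, sets x cells.
#' @export
ssgsea_matrix <- function(sce, sets, alpha = 0.25, normalize = FALSE) {
  expr <- as.matrix(get_logcounts(sce))
  out <- vapply(seq_len(ncol(expr)), function(j) {
    v <- expr[, j]
    vapply(sets, function(s) ssgsea_score(v, s, alpha, normalize), numeric(1))
  }, numeric(length(sets)))
  out <- matrix(out, nrow = length(sets),
                dimnames = list(vapply(sets, function(s) as_set_name(s), ""),
                                colnames(expr)))
  out
}

as_set_name <- function(set) if (inherits(set, "gene_set")) set$name else "set"
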