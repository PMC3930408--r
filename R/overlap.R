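# Finite-universe overlap significance: the probability of seeing an
# intersection at least as large as observed when two lists of the given
# sizes are drawn at random from a universe of N genes.

#' Define the gene universe for overlap testing
#'
#' The universe is the unstated parameter of every list-overlap statistic:
#' the number of genes the lists could in principle have drawn from. It may
#' be given as a bare size, or as an explicit member set (in which case every
#' tested list must be a subset and the size is the member count). Every
#' overlap report records which form was used.
#'
#' @param size positive integer universe size N, ignored when `members` is
#'   given.
#' @param members optional character vector of GeneIDs making up the
#'   universe.
#' @return object of class `gene_universe` with fields `size`, `members`
#'   (possibly `NULL`).
#' @export
gene_universe <- function(size = NULL, members = NULL) {
  if (!is.null(members)) {
    members <- unique(trimws(as.character(members)))
    assert_that(all(nzchar(members)), "universe members must be non-empty")
    size <- length(members)
  }
  assert_that(is.numeric(size) && length(size) == 1L && size >= 1 &&
                size == floor(size), "universe size must be a positive integer")
  structure(list(size = as.integer(size), members = members),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> N = %d (%s)\n", x$size,
              if (is.null(x$members)) "size only" else "explicit members"))
  invisible(x)
}

#' Intersect two gene lists
#'
#' Exact, direction-agnostic set intersection on GeneIDs (symmetric in its
#' arguments). Direction-stratified intersections (up with up, down with
#' down) are available through `direction`.
#'
#' @param a,b `gene_list` objects.
#' @param direction `"any"` (default) ignores directions; `"up"` or
#'   `"down"` intersects only records with that direction on both sides.
#' @return character vector of shared GeneIDs.
#' @export
intersect_lists <- function(a, b, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  assert_that(inherits(a, "gene_list") && inherits(b, "gene_list"),
              "expected gene_list arguments")
  pick <- function(x) if (direction == "any") gene_ids(x) else
    x$records$id[x$records$direction == direction]
  intersect(pick(a), pick(b))
}

check_hyper_args <- function(N, K, n, k) {
  chk <- function(ok, ineq) assert_that(ok, sprintf(
    "hypergeometric precondition violated: %s (N=%s, K=%s, n=%s, k=%s)",
    ineq, N, K, n, k))
  for (v in list(N = N, K = K, n = n, k = k))
    assert_that(is.numeric(v) && length(v) == 1L && v == floor(v),
                "N, K, n, k must be single integers")
  chk(N >= 1, "N >= 1")
  chk(K >= 0 && K <= N, "0 <= K <= N")
  chk(n >= 0 && n <= N, "0 <= n <= N")
  chk(k >= 0, "k >= 0")
  chk(k <= min(K, n), "k <= min(K, n)")
  chk(k >= max(0, K + n - N), "k >= max(0, K + n - N)")
}

#' Upper-tail hypergeometric probability of a list overlap
#'
#' Probability of observing an intersection of size at least `k` (or, with
#' `strict = TRUE`, strictly greater than `k`) when a list of `n` genes is
#' drawn from a universe of `N` genes of which `K` belong to the other list.
#' Computed by summing hypergeometric point masses assembled from
#' log-binomial coefficients, so large universes do not overflow.
#'
#' The inclusive tail \eqn{P(X \ge k)} is the conventional enrichment
#' reading and the only one that returns 1 at `k = 0`.
#'
#' @param N universe size.
#' @param K size of the first list.
#' @param n size of the second list.
#' @param k observed intersection size.
#' @param strict if `TRUE` return \eqn{P(X > k)} instead of
#'   \eqn{P(X \ge k)}.
#' @return probability in `[0, 1]` (in `(0, 1]` for the inclusive tail).
#' @examples
#' hypergeom_tail(10, 5, 5, 5)  # 1/252
#' hypergeom_tail(10, 5, 5, 0)  # 1
#' @export
hypergeom_tail <- function(N, K, n, k, strict = FALSE) {
  check_hyper_args(N, K, n, k)
  lo <- if (strict) k + 1L else k
  hi <- min(K, n)
  if (lo > hi) return(0)
  i <- seq(lo, hi)
  # P(X = i) = C(K,i) C(N-K, n-i) / C(N,n), on the log scale
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(logp)))
}

#' Grade a p-value with significance stars
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, otherwise `ns`.
#'
#' @param p probability in `[0, 1]`.
#' @return character grade, vectorized over `p`.
#' @export
grade_significance <- function(p) {
  assert_that(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Overlap significance test for a pair of gene lists
#'
#' @param a,b `gene_list` objects.
#' @param universe a [gene_universe()]; both lists must fit in it (and be
#'   subsets of it when it has explicit members).
#' @param strict use the strict tail \eqn{P(X > k)}.
#' @param direction passed to [intersect_lists()]; when stratified, list
#'   sizes are the per-direction record counts.
#' @return object of class `overlap_result` with fields `k`, `n1`, `n2`,
#'   `N`, `p_value`, `grade`, `shared`, `universe_mode`, `names`.
#' @examples
#' u <- gene_universe(10)
#' a <- gene_list(as.character(1:5)); b <- gene_list(as.character(1:5))
#' overlap_test(a, b, u)
#' @export
overlap_test <- function(a, b, universe, strict = FALSE,
                         direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  assert_that(inherits(universe, "gene_universe"),
              "universe must be a gene_universe")
  if (!is.null(universe$members)) {
    out_a <- setdiff(gene_ids(a), universe$members)
    out_b <- setdiff(gene_ids(b), universe$members)
    assert_that(length(out_a) == 0L && length(out_b) == 0L, sprintf(
      "%d GeneID(s) fall outside the explicit universe (e.g. %s)",
      length(out_a) + length(out_b),
      paste(utils::head(c(out_a, out_b), 3), collapse = ", ")))
  }
  sz <- function(x) if (direction == "any") length(x) else
    sum(x$records$direction == direction)
  n1 <- sz(a); n2 <- sz(b)
  assert_that(n1 <= universe$size && n2 <= universe$size,
              "list sizes must not exceed the universe size")
  shared <- intersect_lists(a, b, direction)
  k <- length(shared)
  p <- hypergeom_tail(universe$size, n1, n2, k, strict = strict)
  structure(list(k = k, n1 = n1, n2 = n2, N = universe$size,
                 p_value = p, grade = grade_significance(p), shared = shared,
                 universe_mode = if (is.null(universe$members)) "size"
                                 else "members",
                 names = c(a$name, b$name), strict = strict,
                 direction = direction),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> k = %d (n1 = %d, n2 = %d, N = %d): p = %.4g [%s]\n",
    x$k, x$n1, x$n2, x$N, x$p_value, x$grade))
  invisible(x)
}

#' Many-vs-many overlap significance matrix
#'
#' Tests every (row list, column list) pair against one shared universe and
#' assembles the complete rectangular grid, mirroring a published
#' dystrophy-by-cancer intersection table whose cells read like `"30***"`.
#'
#' @param row_lists,col_lists non-empty lists of `gene_list` objects (e.g.
#'   dystrophy DE lists as rows, cancer-related lists as columns).
#' @param universe a [gene_universe()].
#' @param strict,direction passed to [overlap_test()].
#' @param adjust optional multiple-testing adjustment across all cells
#'   (`"none"`, default as published, or `"BH"` for Benjamini-Hochberg);
#'   adjusted p-values are reported alongside, never replacing, the raw
#'   grades.
#' @return object of class `overlap_matrix`: list with `results` (row-major
#'   list of `overlap_result`), `k`, `p`, `grades`, `cells` matrices,
#'   optional `p_adjusted`, and the settings used.
#' @export
overlap_matrix <- function(row_lists, col_lists, universe, strict = FALSE,
                           direction = c("any", "up", "down"),
                           adjust = c("none", "BH")) {
  direction <- match.arg(direction)
  adjust <- match.arg(adjust)
  assert_that(is.list(row_lists) && length(row_lists) > 0L,
              "row_lists must be a non-empty list of gene_list objects")
  assert_that(is.list(col_lists) && length(col_lists) > 0L,
              "col_lists must be a non-empty list of gene_list objects")
  nm <- function(lists, prefix) {
    n <- vapply(lists, function(g) g$name, character(1))
    ifelse(nzchar(n), n, paste0(prefix, seq_along(lists)))
  }
  rn <- nm(row_lists, "row"); cn <- nm(col_lists, "col")
  res <- vector("list", length(row_lists) * length(col_lists))
  dim(res) <- c(length(row_lists), length(col_lists))
  for (i in seq_along(row_lists))
    for (j in seq_along(col_lists))
      res[[i, j]] <- overlap_test(row_lists[[i]], col_lists[[j]], universe,
                                  strict = strict, direction = direction)
  get <- function(f) matrix(vapply(res, f, numeric(1)),
                            nrow = length(row_lists),
                            dimnames = list(rn, cn))
  k <- get(function(r) r$k)
  p <- get(function(r) r$p_value)
  grades <- matrix(grade_significance(p), nrow = nrow(p), dimnames = dimnames(p))
  cells <- matrix(paste0(k, ifelse(grades == "ns", " (ns)", grades)),
                  nrow = nrow(p), dimnames = dimnames(p))
  out <- list(results = res, k = k, p = p, grades = grades, cells = cells,
              N = universe$size,
              universe_mode = if (is.null(universe$members)) "size"
                              else "members",
              strict = strict, direction = direction, adjust = adjust)
  if (adjust == "BH")
    out$p_adjusted <- matrix(stats::p.adjust(p, method = "BH"),
                             nrow = nrow(p), dimnames = dimnames(p))
  class(out) <- "overlap_matrix"
  out
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d x %d lists, N = %d\n",
              nrow(x$k), ncol(x$k), x$N))
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' Export an overlap matrix
#'
#' Writes a tab-separated grid of `"k grade"` cells plus a companion JSON
#' file carrying full p-values, list sizes, the universe, and all settings.
#'
#' @param x an `overlap_matrix`.
#' @param path TSV output path; the JSON companion is written next to it
#'   with extension `.json`.
#' @return invisibly, the two paths written.
#' @export
write_overlap_matrix <- function(x, path) {
  assert_that(inherits(x, "overlap_matrix"), "expected an overlap_matrix")
  tab <- data.frame(list = rownames(x$cells), x$cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jpath <- paste0(sub("\\.[^.]*$", "", path), ".json")
  n1 <- vapply(x$results[, 1], function(r) r$n1, numeric(1))
  n2 <- vapply(x$results[1, ], function(r) r$n2, numeric(1))
  payload <- list(
    N = x$N, universe_mode = x$universe_mode, strict = x$strict,
    direction = x$direction, adjust = x$adjust,
    row_sizes = as.list(stats::setNames(n1, rownames(x$k))),
    col_sizes = as.list(stats::setNames(n2, colnames(x$k))),
    k = as.data.frame(x$k), p = as.data.frame(x$p),
    grades = as.data.frame(x$grades))
  if (!is.null(x$p_adjusted)) payload$p_adjusted <- as.data.frame(x$p_adjusted)
  jsonlite::write_json(payload, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tsv = path, json = jpath))
}
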