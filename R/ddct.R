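# Relative quantification of qPCR Ct matrices by the delta-delta-Ct method,
# with one-way ANOVA significance calls on the delta-Ct scale.

#' Construct a Ct matrix container
#'
#' Holds a gene x sample table of qPCR threshold-cycle (Ct) values together
#' with the sample grouping and the set of endogenous reference genes used
#' for normalization. Undetermined Ct values (no amplification) are stored
#' as `NA` and treated as missing downstream, except for reference genes,
#' which must amplify in every sample.
#'
#' @param values numeric matrix, rows genes, columns samples (Ct in PCR
#'   cycles, typically 10-40; `NA` = undetermined).
#' @param sample_groups named character vector sample -> group label, or an
#'   unnamed vector in column order.
#' @param reference_genes non-empty character vector of reference gene rows.
#' @return object of class `ct_matrix`.
#' @export
ct_matrix <- function(values, sample_groups, reference_genes) {
  values <- as.matrix(values)
  assert_that(is.numeric(values) && !is.null(rownames(values)) &&
                !is.null(colnames(values)),
              "values must be a numeric matrix with gene and sample names")
  if (is.null(names(sample_groups))) {
    assert_that(length(sample_groups) == ncol(values),
                "sample_groups must cover every sample")
    names(sample_groups) <- colnames(values)
  }
  assert_that(all(colnames(values) %in% names(sample_groups)),
              "every sample needs a group label")
  sample_groups <- as.character(sample_groups[colnames(values)])
  names(sample_groups) <- colnames(values)
  reference_genes <- as.character(reference_genes)
  assert_that(length(reference_genes) > 0L &&
                all(reference_genes %in% rownames(values)),
              "reference_genes must be a non-empty subset of the gene rows")
  assert_that(!anyNA(values[reference_genes, , drop = FALSE]),
              "reference genes must have a finite Ct in every sample")
  structure(list(values = values, sample_groups = sample_groups,
                 reference_genes = reference_genes),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d genes x %d samples; groups: %s; refs: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_groups), collapse = "/"),
              paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}

#' Delta-Ct: target Ct minus reference Ct
#'
#' With several reference genes the arithmetic mean of their Ct values (a
#' per-sample scalar) is the reference; averaging on the Ct (log) scale is
#' the geometric mean on the expression scale.
#'
#' @param ct_target numeric vector of target-gene Ct values.
#' @param ct_reference numeric vector (recycled) of reference Ct values, or
#'   a matrix with one row per reference gene whose column means are used.
#' @return delta-Ct values in cycles.
#' @examples
#' delta_ct(25, 20)                        # 5
#' delta_ct(25, matrix(c(18, 22), 2, 1))   # mean ref 20 -> 5
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (is.matrix(ct_reference)) ct_reference <- colMeans(ct_reference)
  assert_that(all(is.finite(ct_target)) && all(is.finite(ct_reference)),
              "missing reference or target Ct measurement")
  ct_target - ct_reference
}

#' Relative quantity from the double delta-Ct
#'
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}};
#' relative quantity \eqn{RQ = 2^{-\Delta\Delta Ct}} (fold change versus the
#' calibrator, assuming perfect doubling per cycle).
#'
#' @param dct_sample,dct_calibrator delta-Ct values in cycles.
#' @return positive fold change(s).
#' @examples
#' relative_quantity(5, 5)  # 1
#' relative_quantity(6, 5)  # 0.5
#' @export
relative_quantity <- function(dct_sample, dct_calibrator) {
  assert_that(all(is.finite(dct_sample)) && all(is.finite(dct_calibrator)),
              "delta-Ct values must be finite")
  2^(-(dct_sample - dct_calibrator))
}

#' Classical one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance from the between/within
#' sums-of-squares decomposition; the p-value is the upper tail of the F
#' distribution with (g - 1, n - g) degrees of freedom. In the qPCR pipeline
#' it is applied to per-gene delta-Ct values across subject groups.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return list with `statistic` (F), `p_value`, `df` (length-2).
#' @examples
#' anova_oneway(list(c(1, 2), c(5, 6)))  # F = 32, p ~ 0.0299
#' @export
anova_oneway <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2L,
              "need at least two groups")
  sizes <- lengths(groups)
  assert_that(all(sizes >= 2L), "every group needs >= 2 observations")
  y <- unlist(groups, use.names = FALSE)
  assert_that(all(is.finite(y)), "observations must be finite")
  n <- length(y); g <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(y)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  assert_that(ss_within > 0,
              "degenerate input: zero within-group variance",
              class = "dystroscore_degenerate_error")
  df <- c(g - 1L, n - g)
  f <- (ss_between / df[1]) / (ss_within / df[2])
  list(statistic = f, p_value = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       df = df)
}

#' Call the expression direction of a gene
#'
#' A gene is called up-regulated when its relative quantity reaches the fold
#' threshold and the p-value beats `alpha`; down-regulated when RQ falls at
#' or below the reciprocal threshold with the same significance; otherwise
#' unchanged.
#'
#' @param rq positive fold change.
#' @param p p-value.
#' @param fc_threshold fold-change threshold (>= 1, default 2).
#' @param alpha significance level (default 0.05).
#' @return `"up"`, `"down"`, or `"unchanged"` (vectorized).
#' @export
call_differential <- function(rq, p, fc_threshold = 2, alpha = 0.05) {
  assert_that(all(rq > 0), "rq must be positive")
  assert_that(fc_threshold >= 1, "fc_threshold must be >= 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  ifelse(p < alpha & rq >= fc_threshold, "up",
         ifelse(p < alpha & rq <= 1 / fc_threshold, "down", "unchanged"))
}

#' Run the delta-delta-Ct pipeline on a Ct matrix
#'
#' Per sample, the reference Ct is the arithmetic mean over the reference
#' genes; per target gene, delta-Ct = Ct - reference Ct. The calibrator is
#' the mean delta-Ct of the calibrator group (group mean rather than a
#' single sample, for stability). The per-gene relative quantity reported
#' for a group is `2^-(mean delta-delta-Ct)` over that group's samples,
#' i.e. the geometric mean of the per-sample fold changes. Significance is
#' one-way ANOVA on the delta-Ct values across groups (the standard scale
#' for qPCR inference; fold changes are log-normal there). Genes whose
#' fraction of missing Ct values exceeds `max_missing` are excluded and
#' listed in the attached report.
#'
#' @param ct a [ct_matrix()].
#' @param calibrator_group group label used as calibrator (default: first
#'   group in column order).
#' @param fc_threshold,alpha thresholds for [call_differential()].
#' @param max_missing maximum tolerated fraction of missing Ct values per
#'   gene (default 0.2).
#' @return data frame of class `expression_calls` with columns `gene`,
#'   `rq`, `p_value`, `direction` (one row per non-reference gene retained),
#'   with attributes `settings` and `excluded`.
#' @export
ddct_analyze <- function(ct, calibrator_group = NULL, fc_threshold = 2,
                         alpha = 0.05, max_missing = 0.2) {
  assert_that(inherits(ct, "ct_matrix"), "expected a ct_matrix")
  groups <- ct$sample_groups
  calibrator_group <- calibrator_group %||% groups[[1]]
  assert_that(calibrator_group %in% groups,
              sprintf("calibrator group '%s' not present", calibrator_group))
  ref_ct <- colMeans(ct$values[ct$reference_genes, , drop = FALSE])
  targets <- setdiff(rownames(ct$values), ct$reference_genes)
  assert_that(length(targets) > 0L, "no target genes besides the references")

  excluded <- character()
  rows <- lapply(targets, function(g) {
    ctg <- ct$values[g, ]
    miss <- mean(!is.finite(ctg))
    if (miss > max_missing) {
      excluded <<- c(excluded, g)
      return(NULL)
    }
    keep <- is.finite(ctg)
    dct <- delta_ct(ctg[keep], ref_ct[keep])
    grp <- groups[keep]
    by_group <- split(dct, grp)
    assert_that(calibrator_group %in% names(by_group) &&
                  length(by_group) >= 2L,
                sprintf("gene '%s': need calibrator and >= 1 other group", g))
    calib <- mean(by_group[[calibrator_group]])
    case_groups <- setdiff(names(by_group), calibrator_group)
    # geometric-mean RQ over all non-calibrator samples
    ddct <- unlist(by_group[case_groups], use.names = FALSE) - calib
    rq <- 2^(-mean(ddct))
    p <- anova_oneway(by_group)$p_value
    data.frame(gene = g, rq = rq, p_value = p,
               direction = call_differential(rq, p, fc_threshold, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  assert_that(!is.null(out), "all target genes were excluded as missing")
  rownames(out) <- NULL
  attr(out, "settings") <- list(
    calibrator = paste0("group mean: ", calibrator_group),
    reference = paste0("arithmetic mean Ct of: ",
                       paste(ct$reference_genes, collapse = ", ")),
    anova_scale = "delta-Ct", fc_threshold = fc_threshold, alpha = alpha,
    max_missing = max_missing)
  attr(out, "excluded") <- excluded
  class(out) <- c("expression_calls", class(out))
  out
}

#' Build a direction profile from expression calls
#'
#' @param calls an `expression_calls` data frame (or any data frame with
#'   `gene` and `direction` columns); gene labels must be unique.
#' @return a [direction_profile()] mapping gene -> direction, the scorer's
#'   input.
#' @export
profile_from_calls <- function(calls) {
  calls <- as.data.frame(calls)
  assert_that(all(c("gene", "direction") %in% names(calls)),
              "calls need 'gene' and 'direction' columns")
  assert_that(!anyDuplicated(calls$gene),
              "duplicate gene labels in expression calls")
  direction_profile(calls$gene, calls$direction)
}

#' Read a Ct matrix plus sample annotation from CSV
#'
#' The Ct CSV has gene labels in the first column and one column per sample
#' (empty cells or the token `Undetermined` become `NA`). The sidecar
#' annotation is tab-separated with columns `sample`, `group` and an
#' optional third file listing reference genes is replaced by a
#' `reference_genes` argument or a `#reference:` comment line in the sidecar.
#'
#' @param ct_path CSV of Ct values.
#' @param annot_path sample -> group sidecar (TSV). Lines starting with
#'   `#reference:` name reference genes (comma-separated).
#' @param reference_genes overrides the sidecar's reference annotation.
#' @return a [ct_matrix()].
#' @export
read_ct_matrix <- function(ct_path, annot_path, reference_genes = NULL) {
  raw <- utils::read.csv(ct_path, row.names = 1, check.names = FALSE,
                         comment.char = "#",
                         na.strings = c("", "NA", "Undetermined"))
  values <- as.matrix(raw)
  storage.mode(values) <- "double"
  lines <- readLines(annot_path)
  ref_line <- grep("^#reference:", lines, value = TRUE)
  if (is.null(reference_genes) && length(ref_line))
    reference_genes <- trimws(strsplit(sub("^#reference:", "", ref_line[1]),
                                       ",")[[1]])
  ann <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           header = TRUE, colClasses = "character")
  assert_that(all(c("sample", "group") %in% names(ann)),
              "annotation needs 'sample' and 'group' columns")
  groups <- stats::setNames(ann$group, ann$sample)
  ct_matrix(values, groups, reference_genes)
}

#' Write expression calls as TSV
#' @param calls an `expression_calls` data frame.
#' @param path output path.
#' @export
write_expression_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
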