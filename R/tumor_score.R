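# Rank-based multi-category tumour-signature scoring.
#
# Each marker gene carries, per category, a sign (+1 up / -1 down in that
# tumour type) and a rank R (lower rank = stronger marker). A profile gene
# whose observed direction matches the sign contributes B = 1 - C*R, with
# C = 1/HR and HR the category's highest rank; a mismatch contributes 0 to
# the category (and B to its complement "not X" score). Summed scores are
# normalized by the score of an "ideal tumour" profile in which every gene
# matches its sign, giving relative scores in [0, 1].

#' Construct a scoring table
#'
#' @param gene gene labels.
#' @param category category label per entry (e.g. `"EWS"`, `"RMS"`, `"NB"`,
#'   `"BL"`; any label set works).
#' @param sign `+1` (marker up-regulated in the category) or `-1` (down).
#' @param rank positive integer rank, lower = stronger marker; ties are
#'   permitted. `(gene, category)` pairs must be unique.
#' @param specific optional category-specificity label per gene, used by
#'   [count_category_hits()] (a gene can carry ranks in several categories
#'   but is specific to at most one).
#' @return data frame of class `scoring_table`.
#' @examples
#' tab <- scoring_table(gene = c("g1", "g2", "g3"), category = "EWS",
#'                      sign = c(1, -1, 1), rank = c(1, 2, 3))
#' compute_coefficients(tab)
#' @export
scoring_table <- function(gene, category, sign, rank, specific = NULL) {
  gene <- trimws(as.character(gene))
  n <- length(gene)
  category <- rep_len(as.character(category), n)
  sign <- rep_len(as.numeric(sign), n)
  rank <- rep_len(as.numeric(rank), n)
  assert_that(all(nzchar(gene)), "gene labels must be non-empty")
  assert_that(all(sign %in% c(-1, 1)), "signs must be +1 or -1")
  assert_that(all(is.finite(rank) & rank >= 1 & rank == floor(rank)),
              "ranks must be integers >= 1")
  assert_that(!anyDuplicated(paste(gene, category, sep = "\r")),
              "(gene, category) pairs must be unique")
  out <- data.frame(gene = gene, category = category, sign = sign,
                    rank = rank, stringsAsFactors = FALSE)
  if (!is.null(specific)) out$specific <- rep_len(as.character(specific), n)
  class(out) <- c("scoring_table", class(out))
  out
}

#' Table categories
#' @param table a `scoring_table`.
#' @return character vector of category labels, in order of appearance.
#' @export
score_categories <- function(table) {
  assert_that(inherits(table, "scoring_table"), "expected a scoring_table")
  unique(table$category)
}

#' Category coefficients C = 1/HR
#'
#' Per category, `C = 1 / HR` where HR is the highest rank assigned within
#' that category, so the weakest (highest-rank) marker contributes exactly
#' zero. Full precision is kept internally; use `round(x, 6)` to mirror the
#' 6-decimal presentation convention.
#'
#' @param table a [scoring_table()].
#' @return named numeric vector category -> C, with `0 < C <= 1` and
#'   `C * HR == 1` exactly.
#' @export
compute_coefficients <- function(table) {
  assert_that(inherits(table, "scoring_table"), "expected a scoring_table")
  assert_that(nrow(table) > 0L, "scoring table has no entries")
  hr <- tapply(table$rank, table$category, max)
  cc <- 1 / hr
  cats <- score_categories(table)
  stats::setNames(as.vector(cc[cats]), cats)
}

#' Per-gene contribution to a category score
#'
#' `B = 1 - C * R` when the profile direction matches the entry's sign, and
#' 0 otherwise.
#'
#' @param matches_sign logical: does the observed direction match the sign?
#' @param C category coefficient in `(0, 1]`.
#' @param R entry rank (>= 1, with `C * R <= 1`).
#' @return contribution in `[0, 1)` (vectorized).
#' @export
gene_contribution <- function(matches_sign, C, R) {
  assert_that(all(C > 0 & C <= 1), "C must lie in (0, 1]")
  assert_that(all(R >= 1), "R must be >= 1")
  assert_that(all(C * R <= 1 + 1e-12),
              "rank exceeds category maximum (C * R > 1)")
  ifelse(matches_sign, 1 - C * R, 0)
}

#' Ideal-tumour scores
#'
#' The score of a hypothetical profile in which every gene's direction
#' matches its sign: `S_ideal(category) = sum over entries of (1 - C * R)`.
#' Because the complement score counts exact sign opposites with the same
#' weights, the ideal score of a category and of its complement coincide.
#'
#' @param table a [scoring_table()].
#' @return named numeric vector category -> ideal score.
#' @export
ideal_scores <- function(table) {
  cc <- compute_coefficients(table)
  s <- tapply(1 - cc[table$category] * table$rank, table$category, sum)
  out <- as.numeric(s[score_categories(table)])
  names(out) <- score_categories(table)
  out
}

#' Construct a direction profile
#'
#' The ternary per-gene abstraction of an expression measurement: each gene
#' is `up`, `down`, or `unchanged` relative to control.
#'
#' @param gene unique gene labels.
#' @param direction direction per gene (recycled if length 1).
#' @return named character vector of class `direction_profile`.
#' @export
direction_profile <- function(gene, direction = "unchanged") {
  gene <- trimws(as.character(gene))
  assert_that(all(nzchar(gene)), "gene labels must be non-empty")
  assert_that(!anyDuplicated(gene), "gene labels must be unique")
  direction <- check_directions(rep_len(as.character(direction),
                                        length(gene)), .CALL_DIRECTIONS)
  structure(stats::setNames(direction, gene), class = "direction_profile")
}

#' @export
print.direction_profile <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = .CALL_DIRECTIONS))
  cat(sprintf("<direction_profile> %d genes (up %d, down %d, unchanged %d)\n",
              length(x), tab[["up"]], tab[["down"]], tab[["unchanged"]]))
  invisible(x)
}

#' Score a direction profile against a scoring table
#'
#' For every category, the raw score S sums the contributions `B = 1 - C*R`
#' of entries whose profile direction matches the entry sign; the complement
#' score `S_not` sums B over entries whose direction is the exact opposite
#' of the sign. Unchanged or absent genes contribute to neither side.
#' Relative scores divide by the ideal score, so an all-matching profile
#' scores exactly 1 and a profile unrelated to the category scores 0.
#' Profile genes absent from the table are ignored (reported in the
#' `ignored` attribute).
#'
#' @param profile a [direction_profile()] (any subset of the table's genes).
#' @param table a [scoring_table()].
#' @param threshold relative-score cutoff for the diagnosable flag
#'   (default 0.4).
#' @return data frame of class `score_report` with one row per category:
#'   `category`, `S`, `S_not`, `S_ideal`, `relative`, `relative_not`,
#'   `diagnosable`; attribute `settings` echoes the threshold and table
#'   size, attribute `ignored` lists profile genes unknown to the table.
#' @examples
#' tab <- scoring_table(c("g1", "g2", "g3"), "EWS", c(1, 1, 1), c(1, 2, 3))
#' prof <- direction_profile(c("g1", "g2", "g3"), "up")
#' score_profile(prof, tab)$relative  # 1
#' @export
score_profile <- function(profile, table, threshold = 0.4) {
  assert_that(inherits(profile, "direction_profile"),
              "expected a direction_profile")
  assert_that(inherits(table, "scoring_table"), "expected a scoring_table")
  cc <- compute_coefficients(table)
  ideal <- unname(ideal_scores(table)[score_categories(table)])
  dirs <- unclass(profile)
  obs <- dirs[table$gene]                       # NA where absent
  obs_sign <- ifelse(is.na(obs), 0,
                     ifelse(obs == "up", 1, ifelse(obs == "down", -1, 0)))
  b <- 1 - cc[table$category] * table$rank
  match_b <- ifelse(obs_sign == table$sign, b, 0)
  oppose_b <- ifelse(obs_sign == -table$sign, b, 0)
  cats <- score_categories(table)
  sum_by <- function(v) {
    s <- tapply(v, table$category, sum)
    as.numeric(s[cats])
  }
  S <- sum_by(match_b)
  S_not <- sum_by(oppose_b)
  rel <- ifelse(ideal > 0, S / ideal, 0)
  rel_not <- ifelse(ideal > 0, S_not / ideal, 0)
  out <- data.frame(category = cats, S = S, S_not = S_not, S_ideal = ideal,
                    relative = rel, relative_not = rel_not,
                    diagnosable = rel >= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "settings") <- list(threshold = threshold,
                                n_entries = nrow(table),
                                n_profile = length(profile))
  attr(out, "ignored") <- setdiff(names(dirs), table$gene)
  class(out) <- c("score_report", class(out))
  out
}

#' Diagnosability flags from a score report
#'
#' A category is flagged diagnosable when its relative score reaches the
#' threshold (relative scores between 0.4 and 1.0 were reported sufficient
#' for a correct tumour diagnosis by the source classifier).
#'
#' @param report a `score_report`.
#' @param threshold relative-score cutoff (default 0.4).
#' @return named logical vector category -> flag.
#' @export
classify <- function(report, threshold = 0.4) {
  assert_that(inherits(report, "score_report"), "expected a score_report")
  assert_that(all(report$relative >= -1e-12 & report$relative <= 1 + 1e-12),
              "relative scores must lie in [0, 1]")
  stats::setNames(report$relative >= threshold, report$category)
}

#' Count genes specific to each category
#'
#' Counts, per category, how many of the input genes the table marks as
#' specific to that category (via the `specific` column; a gene ranked in
#' several categories is specific to at most one). Genes absent from the
#' table, or without a specificity label, are counted under `unassigned`.
#'
#' @param genes character vector (or `gene_list`) of gene labels.
#' @param table a [scoring_table()] with a `specific` column.
#' @return named integer vector with one element per table category plus
#'   `unassigned`.
#' @export
count_category_hits <- function(genes, table) {
  assert_that(inherits(table, "scoring_table"), "expected a scoring_table")
  assert_that(!is.null(table$specific),
              "scoring table has no 'specific' column")
  if (inherits(genes, "gene_list")) genes <- gene_ids(genes)
  genes <- unique(trimws(as.character(genes)))
  cats <- score_categories(table)
  spec <- tapply(table$specific, table$gene, function(s) {
    u <- unique(s[!is.na(s) & nzchar(s)])
    if (length(u) == 1L) u else NA_character_
  })
  hit <- spec[genes]
  hit[is.na(hit) | !(hit %in% cats)] <- "unassigned"
  counts <- table(factor(hit, levels = c(cats, "unassigned")))
  stats::setNames(as.integer(counts), names(counts))
}

#' Read a scoring table from TSV
#'
#' Tab-separated columns `gene`, `category`, `sign` (+1/-1), `rank`, and
#' optionally `specific_category`.
#'
#' @param path file path.
#' @return a [scoring_table()].
#' @export
read_scoring_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("gene", "category", "sign", "rank")
  assert_that(all(need %in% names(raw)), sprintf(
    "scoring table needs columns: %s", paste(need, collapse = ", ")))
  spec <- raw$specific_category %||% raw$specific
  scoring_table(raw$gene, raw$category, raw$sign, raw$rank, specific = spec)
}

#' Write a scoring table as TSV
#' @param table a `scoring_table`.
#' @param path output path.
#' @param header optional comment line(s) written atop the file.
#' @export
write_scoring_table <- function(table, path, header = NULL) {
  assert_that(inherits(table, "scoring_table"), "expected a scoring_table")
  df <- as.data.frame(table)
  if ("specific" %in% names(df))
    names(df)[names(df) == "specific"] <- "specific_category"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a direction profile from 2-column TSV
#' @param path file path (columns gene, direction).
#' @return a [direction_profile()].
#' @export
read_direction_profile <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (nrow(raw) && tolower(trimws(raw[1, 1])) == "gene")
    raw <- raw[-1, , drop = FALSE]
  assert_that(ncol(raw) >= 2L, "profile needs columns gene, direction")
  direction_profile(raw[[1]], trimws(raw[[2]]))
}

#' Write a direction profile as 2-column TSV
#' @param profile a `direction_profile`.
#' @param path output path.
#' @param header optional comment line(s).
#' @export
write_direction_profile <- function(profile, path, header = NULL) {
  assert_that(inherits(profile, "direction_profile"),
              "expected a direction_profile")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("gene\tdirection", con)
  writeLines(paste(names(profile), unclass(profile), sep = "\t"), con)
  invisible(path)
}

#' Export a score report
#'
#' Writes the full report as JSON plus a plain-text "radar" table (one
#' spoke per category with its relative score) as CSV.
#'
#' @param report a `score_report`.
#' @param path JSON output path; the CSV radar table is written next to it
#'   with extension `.radar.csv`.
#' @return invisibly, the paths written.
#' @export
write_score_report <- function(report, path) {
  assert_that(inherits(report, "score_report"), "expected a score_report")
  payload <- list(settings = attr(report, "settings"),
                  ignored_genes = attr(report, "ignored"),
                  scores = as.data.frame(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  radar <- paste0(sub("\\.[^.]*$", "", path), ".radar.csv")
  utils::write.csv(data.frame(spoke = report$category,
                              relative_score = report$relative),
                   radar, row.names = FALSE, quote = FALSE)
  invisible(c(json = path, radar = radar))
}
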