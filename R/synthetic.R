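# Seeded generators for every input the pipeline consumes. All generators
# are pure functions of their arguments: the same seed gives byte-identical
# output, and the caller's global RNG state is never touched.

#' Bundle simulation settings
#'
#' A light container of the generator parameters; each generator also
#' accepts the same settings as plain arguments.
#'
#' @param seed integer seed.
#' @param universe_size universe size N (genes).
#' @param n1,n2 list sizes for [gen_list_pair()].
#' @param forced_overlap forced intersection size `k`, or `NULL` to draw
#'   both lists independently under the hypergeometric null.
#' @param genes_per_category,categories,max_rank scoring-table shape for
#'   [gen_scoring_table()].
#' @param match_fraction fraction of sign matches for
#'   [gen_profile_with_match()].
#' @param n_genes,n_per_group,group_shift,noise_sd Ct-simulation shape for
#'   [gen_ct_dataset()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, universe_size = 20000L, n1 = 300L,
                       n2 = 200L, forced_overlap = NULL,
                       genes_per_category = 24L,
                       categories = c("EWS", "RMS", "NB", "BL"),
                       max_rank = 100L, match_fraction = 0.5,
                       n_genes = 24L, n_per_group = 10L, group_shift = -1,
                       noise_sd = 0.3) {
  cfg <- list(seed = as.integer(seed), universe_size = as.integer(universe_size),
              n1 = as.integer(n1), n2 = as.integer(n2),
              forced_overlap = if (!is.null(forced_overlap))
                as.integer(forced_overlap),
              genes_per_category = as.integer(genes_per_category),
              categories = as.character(categories),
              max_rank = as.integer(max_rank),
              match_fraction = as.numeric(match_fraction),
              n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              group_shift = as.numeric(group_shift),
              noise_sd = as.numeric(noise_sd))
  assert_that(all(c(cfg$universe_size, cfg$n1, cfg$n2, cfg$genes_per_category,
                    cfg$max_rank, cfg$n_genes, cfg$n_per_group) > 0),
              "all sizes must be positive")
  assert_that(cfg$match_fraction >= 0 && cfg$match_fraction <= 1,
              "match_fraction must lie in [0, 1]")
  if (!is.null(cfg$forced_overlap))
    assert_that(cfg$forced_overlap <= min(cfg$n1, cfg$n2),
                "forced overlap exceeds the smaller list")
  structure(cfg, class = "sim_config")
}

#' Generate a pair of gene lists with controlled overlap
#'
#' Lists are drawn from the universe `g1 .. gN`. With `k = NULL` both lists
#' are independent uniform draws without replacement — the hypergeometric
#' null, under which the intersection size follows
#' Hypergeometric(N, n1, n2). With `k` given, the intersection is forced to
#' exactly `k` genes.
#'
#' @param universe_size universe size N.
#' @param n1,n2 list sizes.
#' @param k forced intersection size or `NULL` for null draws.
#' @param seed integer seed.
#' @return list with components `a`, `b` ([gene_list()]s, directions drawn
#'   uniformly from up/down) and `universe` (a [gene_universe()]).
#' @export
gen_list_pair <- function(universe_size, n1, n2, k = NULL, seed = 1L) {
  assert_that(n1 >= 1 && n2 >= 1 && universe_size >= max(n1, n2),
              "lists must fit in the universe")
  genes <- paste0("g", seq_len(universe_size))
  if (!is.null(k)) {
    assert_that(k >= 0 && k <= min(n1, n2),
                "infeasible forced overlap: k must be <= min(n1, n2)")
    assert_that(n1 + n2 - k <= universe_size,
                "infeasible forced overlap: n1 + n2 - k exceeds the universe")
  }
  with_seed(seed, {
    if (is.null(k)) {
      ida <- sample(genes, n1)
      idb <- sample(genes, n2)
    } else {
      pool <- sample(genes, n1 + n2 - k)
      shared <- pool[seq_len(k)]
      ida <- c(shared, pool[k + seq_len(n1 - k)])
      idb <- c(shared, pool[n1 + seq_len(n2 - k)])
    }
    list(a = gene_list(ida, sample(c("up", "down"), n1, replace = TRUE),
                       name = "sim_a", provenance = "synthetic"),
         b = gene_list(idb, sample(c("up", "down"), n2, replace = TRUE),
                       name = "sim_b", provenance = "synthetic"),
         universe = gene_universe(universe_size))
  })
}

#' Generate a random scoring table
#'
#' Per category, `genes_per_category` distinct ranks are sampled from
#' `1 .. max_rank` with the maximum always included, so every category's
#' highest rank equals `max_rank` and `C = 1/max_rank` by construction.
#' Signs are independent fair coin flips; gene labels are distinct across
#' categories and each entry's `specific` label is its own category.
#'
#' @param genes_per_category entries per category (<= `max_rank`).
#' @param categories category labels.
#' @param max_rank highest rank in every category.
#' @param seed integer seed.
#' @return a [scoring_table()].
#' @export
gen_scoring_table <- function(genes_per_category = 24L,
                              categories = c("EWS", "RMS", "NB", "BL"),
                              max_rank = 100L, seed = 1L) {
  assert_that(genes_per_category >= 1, "need >= 1 gene per category")
  assert_that(length(categories) >= 1, "need >= 1 category")
  assert_that(max_rank >= genes_per_category,
              "max_rank must be >= genes_per_category (ranks are distinct)")
  with_seed(seed, {
    parts <- lapply(categories, function(cat) {
      ranks <- if (genes_per_category == 1L) max_rank else
        c(sort(sample(seq_len(max_rank - 1L), genes_per_category - 1L)),
          max_rank)
      data.frame(
        gene = sprintf("%s_m%02d", cat, seq_len(genes_per_category)),
        category = cat,
        sign = sample(c(-1, 1), genes_per_category, replace = TRUE),
        rank = ranks, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts)
    scoring_table(df$gene, df$category, df$sign, df$rank,
                  specific = df$category)
  })
}

#' Generate a direction profile with a controlled match fraction
#'
#' A seeded choice of `round(f * n)` of the category's entries (ties at .5
#' rounded toward more matches) receives the direction its sign encodes;
#' the remaining entries of that category get the opposite direction; genes
#' of all other categories are set to `unchanged`. At `f = 1` the profile
#' is the category's ideal tumour (relative score 1); at `f = 0` every
#' entry opposes its sign, so the category scores 0 and its complement
#' scores 1.
#'
#' @param table a [scoring_table()].
#' @param category the category to target.
#' @param match_fraction fraction `f` in `[0, 1]` of sign matches.
#' @param seed integer seed.
#' @return a [direction_profile()] covering every table gene.
#' @export
gen_profile_with_match <- function(table, category, match_fraction = 1,
                                   seed = 1L) {
  assert_that(inherits(table, "scoring_table"), "expected a scoring_table")
  assert_that(category %in% table$category,
              sprintf("category '%s' not in table", category))
  assert_that(match_fraction >= 0 && match_fraction <= 1,
              "match_fraction must lie in [0, 1]")
  idx <- which(table$category == category)
  n <- length(idx)
  n_match <- min(n, floor(match_fraction * n + 0.5))  # ties -> more matches
  with_seed(seed, {
    chosen <- if (n_match > 0) sample(idx, n_match) else integer()
    dirs <- rep("unchanged", nrow(table))
    as_dir <- function(s) ifelse(s > 0, "up", "down")
    dirs[idx] <- as_dir(-table$sign[idx])          # default: opposite
    dirs[chosen] <- as_dir(table$sign[chosen])     # chosen: matching
    direction_profile(table$gene, dirs)
  })
}

#' Generate a synthetic qPCR Ct dataset
#'
#' Emulates a two-group TLDA-style experiment: a reference gene with Ct
#' around 20 cycles, target genes with gene-specific baseline delta-Ct
#' (uniform on 2-8 cycles), and a planted per-gene group shift on the
#' delta-Ct scale for the non-control group (a shift of -1 cycle means the
#' gene is twofold up-regulated, since RQ = 2^-shift). Independent Gaussian
#' measurement noise is added to every well.
#'
#' @param n_genes number of target genes.
#' @param n_per_group samples per group (groups `control` and `case`).
#' @param group_shift planted shift in cycles: a scalar applied to every
#'   target gene, or a (possibly named) vector with one shift per gene.
#' @param noise_sd well-to-well Gaussian noise sd in cycles (> 0).
#' @param seed integer seed.
#' @param gene_names optional target gene labels (default `t1 .. tn`).
#' @return a [ct_matrix()] with reference gene `REF`; the planted shifts
#'   are attached as attribute `planted_shift`.
#' @export
gen_ct_dataset <- function(n_genes = 24L, n_per_group = 10L,
                           group_shift = -1, noise_sd = 0.3, seed = 1L,
                           gene_names = NULL) {
  assert_that(noise_sd > 0, "noise_sd must be positive")
  assert_that(n_genes >= 1 && n_per_group >= 2,
              "need >= 1 gene and >= 2 samples per group")
  genes <- gene_names %||% paste0("t", seq_len(n_genes))
  assert_that(length(genes) == n_genes, "gene_names length mismatch")
  shifts <- if (length(group_shift) == 1L)
    stats::setNames(rep(group_shift, n_genes), genes)
  else {
    assert_that(length(group_shift) == n_genes,
                "group_shift must be scalar or one per gene")
    if (is.null(names(group_shift))) names(group_shift) <- genes
    group_shift[genes]
  }
  n_samp <- 2L * n_per_group
  samples <- c(paste0("ctrl_", seq_len(n_per_group)),
               paste0("case_", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("control", "case"), each = n_per_group),
                            samples)
  with_seed(seed, {
    ref_ct <- stats::rnorm(n_samp, mean = 20, sd = noise_sd)
    baseline <- stats::runif(n_genes, 2, 8)
    is_case <- groups == "case"
    target <- matrix(0, n_genes, n_samp, dimnames = list(genes, samples))
    for (i in seq_len(n_genes)) {
      dct <- baseline[i] + ifelse(is_case, shifts[i], 0)
      target[i, ] <- ref_ct + dct + stats::rnorm(n_samp, 0, noise_sd)
    }
    values <- rbind(target, REF = ref_ct)
    out <- ct_matrix(values, groups, reference_genes = "REF")
    attr(out, "planted_shift") <- shifts
    out
  })
}

#' Write a Ct matrix (and sidecar annotation) as CSV/TSV
#'
#' @param ct a [ct_matrix()].
#' @param ct_path CSV output for the Ct values.
#' @param annot_path TSV output for the sample annotation; a
#'   `#reference:` comment line records the reference genes.
#' @param header optional comment line for the CSV.
#' @return invisibly, the paths written.
#' @export
write_ct_matrix <- function(ct, ct_path, annot_path, header = NULL) {
  assert_that(inherits(ct, "ct_matrix"), "expected a ct_matrix")
  con <- file(ct_path, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(data.frame(gene = rownames(ct$values), ct$values,
                              check.names = FALSE), con, row.names = FALSE,
                   quote = FALSE)
  close(con)
  con2 <- file(annot_path, "w")
  writeLines(sprintf("#reference: %s",
                     paste(ct$reference_genes, collapse = ",")), con2)
  writeLines("sample\tgroup", con2)
  writeLines(paste(names(ct$sample_groups), ct$sample_groups, sep = "\t"),
             con2)
  close(con2)
  invisible(c(ct = ct_path, annot = annot_path))
}
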