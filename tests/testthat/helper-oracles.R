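# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (exhaustive enumeration, per-entry loops) and never
# share code with the implementation they check.

# Tail probability by exhaustive enumeration: draw every n-subset of an
# N-gene universe whose first K genes form the other list, and count draws
# overlapping it in at least k genes. Exact for small N.
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Per-gene loop scorer: recomputes HR, C, B and the category sums entry by
# entry, straight from the definitions.
score_brute <- function(profile, table) {
  cats <- unique(table$category)
  dirs <- unclass(profile)
  out <- data.frame(category = cats, S = 0, S_not = 0, S_ideal = 0)
  for (ci in seq_along(cats)) {
    rows <- which(table$category == cats[ci])
    hr <- max(table$rank[rows])
    for (i in rows) {
      b <- 1 - (1 / hr) * table$rank[i]
      out$S_ideal[ci] <- out$S_ideal[ci] + b
      d <- if (table$gene[i] %in% names(dirs)) dirs[[table$gene[i]]]
           else "unchanged"
      want <- if (table$sign[i] > 0) "up" else "down"
      anti <- if (table$sign[i] > 0) "down" else "up"
      if (d == want) out$S[ci] <- out$S[ci] + b
      if (d == anti) out$S_not[ci] <- out$S_not[ci] + b
    }
  }
  out$relative <- ifelse(out$S_ideal > 0, out$S / out$S_ideal, 0)
  out
}

withr_local_tempfile <- function(ext = "") tempfile(fileext = ext)

# seed a block of test code without leaking RNG state
with_seed_local <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(),
                          inherits = FALSE)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Random scoring table via a route independent of gen_scoring_table
random_table <- function(seed, max_entries = 200) {
  set.seed(seed)
  n_cat <- sample(1:4, 1)
  cats <- paste0("C", seq_len(n_cat))
  parts <- lapply(cats, function(cat) {
    n <- sample(2:min(50, max_entries %/% n_cat), 1)
    data.frame(gene = paste0(cat, "_g", seq_len(n)), category = cat,
               sign = sample(c(-1, 1), n, replace = TRUE),
               rank = sample(1:100, n, replace = TRUE),  # ties permitted
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  scoring_table(df$gene, df$category, df$sign, df$rank)
}

random_profile <- function(table, seed) {
  set.seed(seed)
  genes <- unique(table$gene)
  direction_profile(genes, sample(c("up", "down", "unchanged"),
                                  length(genes), replace = TRUE))
}
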