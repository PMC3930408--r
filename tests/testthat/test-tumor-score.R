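toy_table <- function() {
  # one category with ranks 1,2,4 (HR 4, C 0.25), one with ranks 1,2,3
  scoring_table(gene = c("a", "b", "c", "x", "y", "z"),
                category = rep(c("EWS", "RMS"), each = 3),
                sign = c(1, -1, 1, 1, 1, -1),
                rank = c(1, 2, 4, 1, 2, 3))
}

test_that("compute_coefficients is 1/highest-rank per category", {
  tab <- scoring_table(c("a", "b"), "X", 1, c(1, 2))
  expect_equal(compute_coefficients(tab), c(X = 0.5))

  # 6-decimal report rounding mirrors the printed convention
  big <- scoring_table(paste0("g", 1:2), "BL", 1, c(1, 1020))
  expect_equal(round(compute_coefficients(big), 6), c(BL = 0.000980))
  expect_equal(round(1 / 1841, 6), 0.000543)  # printed EWS-style rounding

  # full precision internally: C * HR == 1 exactly
  tt <- toy_table()
  cc <- compute_coefficients(tt)
  hr <- as.vector(tapply(tt$rank, tt$category, max)[names(cc)])
  expect_identical(unname(cc * hr), c(1, 1))

  expect_error(compute_coefficients(scoring_table(character(), character(),
                                                  numeric(), numeric())),
               "no entries")
})

test_that("gene_contribution is 1 - C*R on a sign match, else zero", {
  expect_equal(gene_contribution(TRUE, 0.25, 1), 0.75)
  expect_equal(gene_contribution(TRUE, 1 / 7, 7), 0)  # top rank -> 0
  expect_equal(gene_contribution(FALSE, 0.25, 1), 0)
  expect_error(gene_contribution(TRUE, 0.25, 5), "exceeds")
  # 0 <= B < 1 everywhere on random valid input
  set.seed(8)
  for (i in 1:50) {
    hr <- sample(1:500, 1)
    r <- sample(1:hr, 1)
    b <- gene_contribution(TRUE, 1 / hr, r)
    expect_true(b >= 0 && b < 1)
  }
})

test_that("ideal_scores sums 1 - C*R and equals its complement", {
  expect_equal(ideal_scores(toy_table()),
               c(EWS = 0.75 + 0.5 + 0, RMS = 2 / 3 + 1 / 3 + 0))
  # degenerate single-entry category: its only gene sits at HR
  expect_equal(ideal_scores(scoring_table("g", "X", 1, 5)), c(X = 0))
  # complement equality: an exactly-opposite profile attains S_not = S_ideal
  for (seed in 1:20) {
    tab <- random_table(seed)
    for (cat in score_categories(tab)) {
      prof <- gen_profile_with_match(tab, cat, 0, seed = seed)
      rep0 <- score_profile(prof, tab)
      row <- rep0[rep0$category == cat, ]
      expect_equal(row$S_not, row$S_ideal)
    }
  }
})

test_that("score_profile worked examples", {
  # category ranks {1,2,3}: C = 1/3, B = 2/3, 1/3, 0; S_ideal = 1
  tab <- scoring_table(c("x", "y", "z"), "RMS", c(1, 1, -1), c(1, 2, 3))
  # matching only the rank-1 gene
  prof <- direction_profile(c("x", "y", "z"), c("up", "unchanged",
                                                "unchanged"))
  rep1 <- score_profile(prof, tab)
  expect_equal(rep1$S, 2 / 3)
  expect_equal(rep1$S_ideal, 1)
  expect_equal(rep1$relative, 2 / 3)

  # all-matching profile normalizes to exactly 1 (full-precision C)
  ideal <- direction_profile(c("x", "y", "z"), c("up", "up", "down"))
  expect_identical(score_profile(ideal, tab)$relative, 1)

  # all-unchanged profile scores zero everywhere
  flat <- direction_profile(c("x", "y", "z"), "unchanged")
  rep0 <- score_profile(flat, tab)
  expect_identical(rep0$S, 0)
  expect_identical(rep0$relative, 0)
  expect_identical(rep0$S_not, 0)

  # profile genes unknown to the table are ignored but reported
  extra <- direction_profile(c("x", "nope"), c("up", "up"))
  repx <- score_profile(extra, tab)
  expect_equal(attr(repx, "ignored"), "nope")
  expect_equal(repx$S, 2 / 3)
})

test_that("score_profile equals the brute-force per-gene loop oracle", {
  for (seed in 1:40) {
    tab <- random_table(seed)
    prof <- random_profile(tab, seed + 1000)
    mine <- score_profile(prof, tab)
    ref <- score_brute(prof, tab)
    expect_equal(mine$S, ref$S, tolerance = 1e-12)
    expect_equal(mine$S_not, ref$S_not, tolerance = 1e-12)
    expect_equal(mine$S_ideal, ref$S_ideal, tolerance = 1e-12)
    expect_equal(mine$relative, ref$relative, tolerance = 1e-12)
    expect_true(all(mine$relative >= 0 & mine$relative <= 1 + 1e-12))
  }
})

test_that("relative scores are non-decreasing as matches are added", {
  set.seed(77)
  tab <- gen_scoring_table(genes_per_category = 10, max_rank = 30, seed = 5)
  cat <- "EWS"
  idx <- which(tab$category == cat)
  dirs <- rep("unchanged", nrow(tab))
  prev <- -Inf
  for (m in seq_along(idx)) {
    i <- idx[m]
    dirs[i] <- if (tab$sign[i] > 0) "up" else "down"
    rel <- score_profile(direction_profile(tab$gene, dirs),
                         tab)[["relative"]][
                           score_categories(tab) == cat]
    expect_gte(rel, prev)
    prev <- rel
  }
  expect_equal(prev, 1)  # all matched at the end
})

test_that("classify flags categories at the 0.4 relative-score cutoff", {
  tab <- toy_table()
  prof <- gen_profile_with_match(tab, "EWS", 1, seed = 1)
  rep1 <- score_profile(prof, tab)
  fl <- classify(rep1)
  expect_true(fl[["EWS"]])
  expect_false(fl[["RMS"]])
  # published myoblast/myotube-style relatives fall below the cutoff
  fake <- rep1
  fake$relative <- c(0.124, 0.45)
  expect_equal(unname(classify(fake)), c(FALSE, TRUE))
  fake$relative <- c(0, 0.233)
  expect_equal(unname(classify(fake)), c(FALSE, FALSE))
})

test_that("count_category_hits counts table-declared specificity", {
  tab <- scoring_table(c("a", "b"), c("EWS", "RMS"), 1, 1,
                       specific = c("EWS", "RMS"))
  expect_equal(count_category_hits(c("a", "b"), tab),
               c(EWS = 1L, RMS = 1L, unassigned = 0L))
  expect_equal(count_category_hits(character(), tab),
               c(EWS = 0L, RMS = 0L, unassigned = 0L))
  # genes missing from the table land in "unassigned"
  expect_equal(count_category_hits(c("a", "mystery"), tab)[["unassigned"]],
               1L)
  expect_error(count_category_hits("a", toy_table()), "specific")
})

test_that("the 12-gene myoblast panel counts 5/2/2/3 by category", {
  tab <- read_scoring_table(
    system.file("extdata", "myoblast12_categories_synthetic.tsv",
                package = "dystroscore"))
  shared <- read_gene_list(
    system.file("extdata", "myoblast_shared_up.tsv",
                package = "dystroscore"))
  specific <- read_gene_list(
    system.file("extdata", "myoblast_specific_up.tsv",
                package = "dystroscore"))
  genes <- gene_list_union(shared, specific)
  hits <- count_category_hits(genes, tab)
  expect_equal(hits[c("EWS", "RMS", "NB", "BL")],
               c(EWS = 5L, RMS = 2L, NB = 2L, BL = 3L))
  expect_equal(hits[["unassigned"]], 0L)
})

test_that("scoring table and profile files round-trip", {
  tab <- gen_scoring_table(genes_per_category = 5, max_rank = 20, seed = 42)
  f <- withr_local_tempfile(".tsv")
  write_scoring_table(tab, f, header = "round trip")
  back <- read_scoring_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  prof <- gen_profile_with_match(tab, "NB", 0.5, seed = 2)
  pf <- withr_local_tempfile(".tsv")
  write_direction_profile(prof, pf)
  expect_identical(unclass(read_direction_profile(pf)), unclass(prof))
})

test_that("write_score_report emits JSON plus the radar CSV", {
  tab <- toy_table()
  rep1 <- score_profile(gen_profile_with_match(tab, "EWS", 1, seed = 3), tab)
  jf <- withr_local_tempfile(".json")
  paths <- write_score_report(rep1, jf)
  j <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(j$scores$relative, rep1$relative)
  radar <- read.csv(paths[["radar"]])
  expect_equal(radar$spoke, rep1$category)
  expect_equal(radar$relative_score, rep1$relative)
})

test_that("scoring_table validates signs, ranks and duplicates", {
  expect_error(scoring_table("a", "X", 2, 1), "\\+1 or -1")
  expect_error(scoring_table("a", "X", 1, 0), ">= 1")
  expect_error(scoring_table(c("a", "a"), "X", 1, c(1, 2)), "unique")
  # tied ranks are permitted
  expect_silent(scoring_table(c("a", "b"), "X", 1, c(3, 3)))
})
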