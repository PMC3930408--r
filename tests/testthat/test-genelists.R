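test_that("standardize_list fans out, drops unmapped, collapses duplicates", {
  m <- id_mapping(c("pA", "pA", "pB", "pC"), c("1", "2", "7", "7"))

  # one-to-many fan-out: one probe can yield several GeneIDs
  gl <- standardize_list(data.frame(source_id = "pA", direction = "up"), m)
  expect_s3_class(gl, "gene_list")
  expect_length(gl, 2L)
  expect_setequal(gene_ids(gl), c("1", "2"))
  expect_true(all(gl$records$direction == "up"))

  # unmapped identifiers are dropped and counted, never guessed
  gl2 <- standardize_list(data.frame(source_id = "pZ", direction = "up"), m)
  expect_length(gl2, 0L)
  expect_equal(attr(gl2, "report")$dropped, 1L)
  expect_equal(attr(gl2, "report")$dropped_ids, "pZ")

  # two probes mapping to the same GeneID collapse by set semantics
  gl3 <- standardize_list(
    data.frame(source_id = c("pB", "pC"), direction = "up"), m)
  expect_length(gl3, 1L)
  expect_equal(gene_ids(gl3), "7")
  expect_equal(gl3$records$direction, "up")

  # standardization report totals
  r <- attr(standardize_list(
    data.frame(source_id = c("pA", "pB", "pZ"), direction = "up"), m),
    "report")
  expect_equal(r[c("input", "mapped", "dropped", "fanout")],
               list(input = 3L, mapped = 2L, dropped = 1L, fanout = 3L))
})

test_that("conflicting directions collapse to unspecified with a warning", {
  m <- id_mapping(c("pUp", "pDn"), c("7", "7"))
  expect_warning(
    gl <- standardize_list(
      data.frame(source_id = c("pUp", "pDn"), direction = c("up", "down")),
      m),
    "conflict")
  expect_equal(gl$records$direction, "unspecified")
  expect_length(gl, 1L)
})

test_that("standardize_list rejects empty input and empty mappings", {
  m <- id_mapping("pA", "1")
  expect_error(standardize_list(data.frame(source_id = character(),
                                           direction = character()), m),
               "empty")
  expect_error(id_mapping(character(), character()), "equal length|empty")
  expect_error(id_mapping("", ""), "empty")
})

test_that("standardized size equals a brute-force union of mapped IDs", {
  for (seed in 1:25) {
    set.seed(seed)
    src <- paste0("p", 1:30)
    map <- data.frame(
      source_id = sample(src, 60, replace = TRUE),
      gene_id = as.character(sample(1:40, 60, replace = TRUE)))
    map <- unique(map)
    m <- id_mapping(map$source_id, map$gene_id)
    entries <- data.frame(source_id = sample(src, 12),
                          direction = "unspecified")
    gl <- standardize_list(entries, m)
    expected <- unique(map$gene_id[map$source_id %in% entries$source_id])
    expect_setequal(gene_ids(gl), expected)
  }
})

test_that("aggregate_call_scores applies strict +/-5.5 cutoffs to row sums", {
  m <- rbind(all_I = rep(1.1, 6), all_D = rep(-1.1, 6),
             mixed = c(1.1, 1.1, 0, 0, -1.0, -1.1))
  out <- aggregate_call_scores(m)
  # sums: 6.6 > 5.5, -6.6 < -5.5, 0.1 in between
  expect_equal(out, c(all_I = "up", all_D = "down", mixed = "unchanged"))

  # cutoffs are strict inequalities: a sum of exactly 5.5 stays unchanged
  expect_equal(unname(aggregate_call_scores(rbind(p = c(1.1, 1.1, 1.1, 1.1,
                                                        1.1, 0)))),
               "unchanged")

  # token form is equivalent to numeric form
  tok <- rbind(p1 = c("I", "I", "NC", "NC", "MD", "D"))
  expect_equal(unname(aggregate_call_scores(tok)), "unchanged")
})

test_that("aggregate_call_scores is invariant to comparison order and
           rejects bad cells", {
  set.seed(42)
  for (i in 1:10) {
    m <- matrix(sample(c(1.1, 1.0, 0.0, -1.0, -1.1), 40, replace = TRUE),
                nrow = 5, dimnames = list(paste0("p", 1:5), NULL))
    perm <- sample(ncol(m))
    expect_identical(aggregate_call_scores(m),
                     aggregate_call_scores(m[, perm, drop = FALSE]))
  }
  bad <- rbind(probeX = c(1.1, 0.5, 0))
  expect_error(aggregate_call_scores(bad), "probeX")
  expect_error(aggregate_call_scores(rbind(pY = c("I", "XX"))), "pY")
  expect_error(aggregate_call_scores(rbind(p = c(1.1, 0)),
                                     up_threshold = -1, down_threshold = 1),
               "below")
})

test_that("split_directions partitions up/down and drops unspecified", {
  gl <- gene_list(as.character(1:6),
                  c("up", "up", "up", "down", "down", "unspecified"))
  parts <- split_directions(gl)
  expect_length(parts$up, 3L)
  expect_length(parts$down, 2L)
  expect_length(intersect(gene_ids(parts$up), gene_ids(parts$down)), 0L)
  expect_true(all(c(gene_ids(parts$up), gene_ids(parts$down)) %in%
                    gene_ids(gl)))

  empty <- split_directions(gene_list(c("1", "2"), "unspecified"))
  expect_length(empty$up, 0L)
  expect_length(empty$down, 0L)
})

test_that("a 539-record list with the published split partitions 301/238", {
  # mimics the printed muscle-biopsy list: 539 GeneIDs, 301 up, 238 down
  fixture <- gene_list(as.character(seq_len(539)),
                       rep(c("up", "down"), c(301, 238)))
  parts <- split_directions(fixture)
  expect_length(parts$up, 301L)
  expect_length(parts$down, 238L)
})

test_that("gene_list enforces unique, non-empty GeneIDs", {
  expect_error(gene_list(c("1", "1")), "unique")
  expect_error(gene_list(c("1", "  ")), "non-empty")
  expect_error(gene_list("1", "sideways"), "invalid direction")
})

test_that("gene_list_union collapses shared IDs and resolves conflicts", {
  a <- gene_list(c("1", "2"), c("up", "up"))
  b <- gene_list(c("2", "3"), c("down", "down"))
  u <- gene_list_union(a, b)
  expect_length(u, 3L)
  expect_equal(u$records$direction[u$records$id == "2"], "unspecified")
  expect_equal(u$records$direction[u$records$id == "3"], "down")
})

test_that("gene list TSV and GMT round-trips preserve what they can", {
  gl <- gene_list(c("11", "22", "33"), c("up", "down", "unspecified"),
                  name = "rt")
  tsv <- withr_local_tempfile(".tsv")
  write_gene_list(gl, tsv)
  back <- read_gene_list(tsv, name = "rt")
  expect_setequal(gene_ids(back), gene_ids(gl))
  expect_equal(sort(back$records$direction), sort(gl$records$direction))

  gmt <- withr_local_tempfile(".gmt")
  write_gmt(list(gl), gmt)
  sets <- read_gmt(gmt)
  expect_setequal(gene_ids(sets[["rt"]]), gene_ids(gl))
  # direction is not representable in GMT
  expect_true(all(sets[["rt"]]$records$direction == "unspecified"))
})

test_that("read_call_matrix accepts tokens and numeric cells", {
  csv <- withr_local_tempfile(".csv")
  writeLines(c("probe,c1,c2", "p1,I,D", "p2,NC,MI"), csv)
  m <- read_call_matrix(csv)
  expect_equal(unname(aggregate_call_scores(m, up_threshold = 0.5)),
               c("unchanged", "up"))
  csv2 <- withr_local_tempfile(".csv")
  writeLines(c("probe,c1,c2", "p1,1.1,-1.1", "p2,0,1.0"), csv2)
  expect_true(is.numeric(read_call_matrix(csv2)))
})
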