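# Gene-list standardization: heterogeneous published DE lists are brought
# into a common GeneID space with per-gene direction annotations.

#' Construct a gene list
#'
#' A `gene_list` is a named, provenance-tagged set of gene records, unique by
#' GeneID, each carrying a regulation direction (`up`, `down`, or
#' `unspecified`). GeneIDs are treated as opaque non-empty strings compared by
#' exact equality (GenBank GeneIDs are decimal digits, but any token works).
#'
#' @param ids character vector of gene identifiers (whitespace is trimmed).
#' @param directions direction per id; recycled if length 1. One of
#'   `"up"`, `"down"`, `"unspecified"`.
#' @param name list name.
#' @param sample_type free-text sample type (e.g. `"biopsy"`, `"myoblast"`).
#' @param provenance free-text provenance note.
#' @param source_labels original probe/symbol strings, if any.
#' @return An object of class `gene_list`: a list with a `records` data frame
#'   (`id`, `direction`, `source_label`) and metadata fields.
#' @examples
#' gl <- gene_list(c("101", "202"), c("up", "down"), name = "toy")
#' length(gl)
#' @export
gene_list <- function(ids, directions = "unspecified", name = "",
                      sample_type = "", provenance = "",
                      source_labels = "") {
  ids <- trimws(as.character(ids))
  assert_that(all(nzchar(ids)), "GeneIDs must be non-empty after trimming")
  n <- length(ids)
  directions <- check_directions(rep_len(as.character(directions), n))
  source_labels <- rep_len(as.character(source_labels), max(n, 1L))[seq_len(n)]
  assert_that(!anyDuplicated(ids),
              "gene_list records must be unique by GeneID")
  structure(
    list(records = data.frame(id = ids, direction = directions,
                              source_label = source_labels,
                              stringsAsFactors = FALSE),
         name = name, sample_type = sample_type, provenance = provenance),
    class = "gene_list")
}

#' @export
length.gene_list <- function(x) nrow(x$records)

#' @export
print.gene_list <- function(x, ...) {
  tab <- table(factor(x$records$direction, levels = .DIRECTIONS))
  cat(sprintf("<gene_list> %s: %d GeneIDs (up %d, down %d, unspecified %d)\n",
              if (nzchar(x$name)) x$name else "(unnamed)", length(x),
              tab[["up"]], tab[["down"]], tab[["unspecified"]]))
  invisible(x)
}

#' GeneIDs of a gene list
#' @param x a `gene_list`.
#' @return character vector of GeneIDs.
#' @export
gene_ids <- function(x) {
  assert_that(inherits(x, "gene_list"), "expected a gene_list")
  x$records$id
}

#' Read an identifier-mapping table
#'
#' Two tab-separated columns (`source_id`, `gene_id`); repeated source rows
#' express many-to-many mappings. Lookups are case-sensitive.
#'
#' @param path file path.
#' @return data frame of class `id_mapping` with columns `source_id`,
#'   `gene_id`.
#' @export
read_id_mapping <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  assert_that(ncol(raw) >= 2L, "mapping table needs two columns")
  if (identical(tolower(raw[1, 1]), "source_id")) raw <- raw[-1, , drop = FALSE]
  id_mapping(raw[[1]], raw[[2]])
}

#' Construct an identifier-mapping table in code
#' @param source_id,gene_id equal-length character vectors; repeated
#'   `source_id` values express one-to-many fan-out.
#' @return data frame of class `id_mapping`.
#' @export
id_mapping <- function(source_id, gene_id) {
  source_id <- trimws(as.character(source_id))
  gene_id <- trimws(as.character(gene_id))
  assert_that(length(source_id) == length(gene_id),
              "source_id and gene_id must have equal length")
  keep <- nzchar(source_id) & nzchar(gene_id)
  out <- unique(data.frame(source_id = source_id[keep],
                           gene_id = gene_id[keep],
                           stringsAsFactors = FALSE))
  assert_that(nrow(out) > 0L, "mapping table is empty")
  class(out) <- c("id_mapping", class(out))
  out
}

#' Standardize a raw gene list into GeneID space
#'
#' Each source identifier is expanded to all GeneIDs it maps to (one-to-many
#' fan-out, which is why a standardized list can hold more GeneIDs than input
#' probes). Unmapped identifiers are dropped, never guessed, and counted in
#' the attached standardization report. Duplicate GeneIDs are collapsed by
#' set semantics; when the same GeneID arrives with conflicting directions
#' (one probe up, another down) the collapsed record is marked
#' `unspecified` and a warning is raised, since silently excluding it would
#' bias downstream overlap counts.
#'
#' @param raw_entries data frame (or 2-column matrix) with columns
#'   `source_id` and `direction`.
#' @param mapping an [id_mapping()] table.
#' @param name name for the resulting list.
#' @param sample_type,provenance metadata passed to [gene_list()].
#' @return A [gene_list()] with attribute `report`: a list with fields
#'   `input`, `mapped`, `dropped`, `fanout`, `conflicts`, `dropped_ids`.
#' @examples
#' m <- id_mapping(c("pA", "pA", "pB"), c("1", "2", "7"))
#' gl <- standardize_list(data.frame(source_id = c("pA", "pB"),
#'                                   direction = c("up", "down")), m)
#' attr(gl, "report")$fanout
#' @export
standardize_list <- function(raw_entries, mapping, name = "",
                             sample_type = "", provenance = "") {
  assert_that(inherits(mapping, "id_mapping"), "mapping must be an id_mapping")
  raw_entries <- as.data.frame(raw_entries, stringsAsFactors = FALSE)
  if (!all(c("source_id", "direction") %in% names(raw_entries)) &&
      ncol(raw_entries) >= 2L)
    names(raw_entries)[1:2] <- c("source_id", "direction")
  assert_that(nrow(raw_entries) > 0L, "raw_entries is empty")
  src <- trimws(as.character(raw_entries$source_id))
  dir <- check_directions(as.character(raw_entries$direction))

  hit <- merge(data.frame(source_id = src, direction = dir,
                          stringsAsFactors = FALSE),
               mapping, by = "source_id")
  mapped_src <- unique(hit$source_id)
  dropped_ids <- setdiff(unique(src), mapped_src)

  if (nrow(hit) == 0L) {
    out <- structure(
      list(records = data.frame(id = character(), direction = character(),
                                source_label = character(),
                                stringsAsFactors = FALSE),
           name = name, sample_type = sample_type, provenance = provenance),
      class = "gene_list")
  } else {
    # collapse by GeneID; conflicting up/down -> unspecified + warning
    collapse <- function(d) {
      u <- unique(d[d != "unspecified"])
      if (length(u) == 1L) u else if (length(u) == 0L) "unspecified" else NA_character_
    }
    agg <- tapply(hit$direction, hit$gene_id, collapse)
    conflicts <- names(agg)[is.na(agg)]
    if (length(conflicts))
      warning(sprintf(
        "direction conflict for %d GeneID(s) (%s); marked unspecified",
        length(conflicts), paste(utils::head(conflicts, 5), collapse = ", ")),
        call. = FALSE)
    agg[is.na(agg)] <- "unspecified"
    lab <- tapply(hit$source_id, hit$gene_id,
                  function(s) paste(unique(s), collapse = ";"))
    ids <- names(agg)
    out <- gene_list(ids, as.character(agg), name = name,
                     sample_type = sample_type, provenance = provenance,
                     source_labels = as.character(lab[ids]))
  }
  attr(out, "report") <- list(
    input = length(unique(src)),
    mapped = length(mapped_src),
    dropped = length(dropped_ids),
    fanout = length(out),
    conflicts = if (nrow(hit)) sum(is.na(tapply(hit$direction, hit$gene_id,
      function(d) { u <- unique(d[d != "unspecified"])
                    if (length(u) > 1L) NA_character_ else "x" }))) else 0L,
    dropped_ids = dropped_ids)
  out
}

# permitted detection-call scores and their textual tokens
.CALL_VALUES <- c(I = 1.1, MI = 1.0, NC = 0.0, MD = -1.0, D = -1.1)

#' Aggregate detection-call scores into per-probe directions
#'
#' Detection calls across pairwise sample comparisons are encoded as scores
#' (increase I = +1.1, marginal increase MI = +1.0, no change NC = 0, marginal
#' decrease MD = -1.0, decrease D = -1.1). Per probe the scores are summed
#' across comparisons; a sum strictly above `up_threshold` calls the probe
#' up-regulated, strictly below `down_threshold` down-regulated, anything
#' else is left unchanged. Comparisons are exchangeable, so the result is
#' invariant to column order.
#'
#' @param calls numeric matrix (probes x comparisons) of call scores, or a
#'   character matrix of the tokens `I`, `MI`, `NC`, `MD`, `D`. Row names are
#'   probe identifiers.
#' @param up_threshold,down_threshold strict cutoffs on the row sum
#'   (defaults +5.5 / -5.5).
#' @return named character vector probe -> `"up"`/`"down"`/`"unchanged"`.
#' @examples
#' m <- matrix(1.1, 1, 6, dimnames = list("p1", NULL))
#' aggregate_call_scores(m)  # sum 6.6 > 5.5 -> up
#' @export
aggregate_call_scores <- function(calls, up_threshold = 5.5,
                                  down_threshold = -5.5) {
  assert_that(down_threshold < up_threshold,
              "down_threshold must be below up_threshold")
  calls <- as.matrix(calls)
  if (is.character(calls)) {
    tok <- trimws(calls)
    bad <- which(!(tok %in% names(.CALL_VALUES)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(calls))
      abort_ds(sprintf("invalid call token '%s' at probe '%s', column %d",
                       tok[bad[1]],
                       rownames(calls)[rc[1]] %||% rc[1], rc[2]),
               "dystroscore_input_error")
    }
    num <- matrix(.CALL_VALUES[tok], nrow = nrow(calls),
                  dimnames = dimnames(calls))
  } else {
    num <- calls
    ok <- matrix(num %in% .CALL_VALUES, nrow = nrow(num))
    if (!all(ok)) {
      rc <- arrayInd(which(!ok)[1], dim(num))
      abort_ds(sprintf(
        "invalid call score %s at probe '%s', column %d (allowed: %s)",
        format(num[rc]), rownames(num)[rc[1]] %||% rc[1], rc[2],
        paste(.CALL_VALUES, collapse = ", ")), "dystroscore_input_error")
    }
  }
  s <- rowSums(num)
  out <- ifelse(s > up_threshold, "up",
                ifelse(s < down_threshold, "down", "unchanged"))
  names(out) <- rownames(calls)
  out
}

#' Read a detection-call matrix from CSV
#'
#' First column probe labels, remaining columns comparisons; cells hold the
#' five call tokens (`I`/`MI`/`NC`/`MD`/`D`) or their numeric scores.
#'
#' @param path CSV file path.
#' @return matrix suitable for [aggregate_call_scores()].
#' @export
read_call_matrix <- function(path) {
  raw <- utils::read.csv(path, row.names = 1, colClasses = "character",
                         check.names = FALSE)
  m <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  if (!anyNA(num)) num else m
}

#' Partition a gene list by direction
#'
#' @param x a `gene_list`.
#' @return list with components `up` and `down`, both `gene_list`s;
#'   `unspecified` records appear in neither.
#' @export
split_directions <- function(x) {
  assert_that(inherits(x, "gene_list"), "expected a gene_list")
  pick <- function(d) {
    r <- x$records[x$records$direction == d, , drop = FALSE]
    gene_list(r$id, r$direction,
              name = paste0(x$name, "_", d), sample_type = x$sample_type,
              provenance = x$provenance, source_labels = r$source_label)
  }
  list(up = pick("up"), down = pick("down"))
}

#' Union of two gene lists
#'
#' GeneID set union; a GeneID present in both with conflicting up/down
#' directions is marked `unspecified` (same rule as [standardize_list()]).
#'
#' @param a,b `gene_list` objects.
#' @param name name of the result.
#' @return a `gene_list`.
#' @export
gene_list_union <- function(a, b, name = "") {
  assert_that(inherits(a, "gene_list") && inherits(b, "gene_list"),
              "expected gene_list arguments")
  rec <- rbind(a$records, b$records)
  collapse <- function(d) {
    u <- unique(d[d != "unspecified"])
    if (length(u) == 1L) u else "unspecified"
  }
  agg <- tapply(rec$direction, rec$id, collapse)
  gene_list(names(agg), as.character(agg), name = name)
}

#' Read a gene list from 2-column delimited text
#'
#' Tab-separated `gene_id`, `direction` (direction optional, defaulting to
#' `unspecified`); a header line is detected and skipped.
#'
#' @param path file path.
#' @param name list name (default: file base name).
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (nrow(raw) && tolower(trimws(raw[1, 1])) %in% c("gene_id", "gene", "id"))
    raw <- raw[-1, , drop = FALSE]
  dirs <- if (ncol(raw) >= 2L) {
    d <- trimws(raw[[2]])
    d[!nzchar(d)] <- "unspecified"
    d
  } else "unspecified"
  gene_list(raw[[1]], dirs, name = name)
}

#' Write a gene list as 2-column delimited text
#' @param x a `gene_list`.
#' @param path output path.
#' @export
write_gene_list <- function(x, path) {
  assert_that(inherits(x, "gene_list"), "expected a gene_list")
  utils::write.table(x$records[, c("id", "direction")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("gene_id", "direction"))
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT carries no direction information, so every record is `unspecified`.
#'
#' @param path GMT file path.
#' @return named list of [gene_list()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    assert_that(length(f) >= 3L, "GMT lines need name, description, >=1 gene")
    gene_list(unique(f[-(1:2)]), "unspecified", name = f[1],
              provenance = f[2])
  })
  names(out) <- vapply(out, function(g) g$name, character(1))
  out
}

#' Write gene lists to a GMT file
#'
#' Directions are lost on GMT export; a comment line in the file records
#' this.
#'
#' @param lists a `gene_list` or list of them.
#' @param path output path.
#' @export
write_gmt <- function(lists, path) {
  if (inherits(lists, "gene_list")) lists <- list(lists)
  body <- vapply(lists, function(g) {
    paste(c(if (nzchar(g$name)) g$name else "gene_set",
            g$provenance %||% "", gene_ids(g)), collapse = "\t")
  }, character(1))
  writeLines(c("# GMT export: direction annotations are not representable",
               body), path)
  invisible(path)
}
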