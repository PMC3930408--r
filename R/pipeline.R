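# Pipeline driver: ties standardize -> overlap and ddct -> score together
# behind a JSON config, with a run manifest for reproducibility.

pkg_version <- function() {
  as.character(utils::packageVersion("dystroscore"))
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

collect_list_paths <- function(x, config_dir) {
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p
                         else file.path(config_dir, p)
  x <- vapply(as.character(x), resolve, character(1), USE.NAMES = FALSE)
  paths <- if (length(x) == 1L && dir.exists(x))
    list.files(x, pattern = "\\.(tsv|txt)$", full.names = TRUE)
  else x
  assert_that(length(paths) > 0L, "no gene-list files found")
  paths
}

#' Run the analysis pipeline from a JSON config
#'
#' Stages present in the config run in a fixed order:
#' `simulate` -> `standardize` -> `overlap` -> `ddct` -> `score`. All input
#' paths are resolved relative to the config file. Every referenced input
#' is checked before any stage runs, so a malformed config fails without
#' partial outputs. The output directory receives per-stage files, a
#' combined `report.json`, and a single `manifest.json` recording the
#' config digest, input digests, seed, package version and timestamp.
#'
#' All tunable thresholds are surfaced in the config with their published
#' defaults: `fc_threshold` 2, `alpha` 0.05, score `threshold` 0.4, call
#' aggregation cutoffs +5.5/-5.5, and an explicit overlap `universe_size`.
#'
#' @param config_path path to a JSON configuration file.
#' @param out_dir output directory (created; default: `"<config>_out"`).
#' @return invisibly, the combined report (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  assert_that(file.exists(config_path),
              sprintf("config file not found: %s", config_path))
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  config_dir <- dirname(normalizePath(config_path))
  out_dir <- out_dir %||% paste0(sub("\\.[^.]*$", "", config_path), "_out")

  # resolve and validate every referenced input up front
  inputs <- character()
  need <- function(p, what) {
    p <- file.path(config_dir, p)
    assert_that(file.exists(p), sprintf("%s not found: %s", what, p))
    inputs <<- c(inputs, p)
    p
  }
  if (!is.null(cfg$standardize)) {
    cfg$standardize$input <- need(cfg$standardize$input, "standardize input")
    cfg$standardize$mapping <- need(cfg$standardize$mapping, "mapping table")
  }
  if (!is.null(cfg$overlap)) {
    cfg$overlap$lists_a <- collect_list_paths(cfg$overlap$lists_a, config_dir)
    cfg$overlap$lists_b <- collect_list_paths(cfg$overlap$lists_b, config_dir)
    for (p in c(cfg$overlap$lists_a, cfg$overlap$lists_b)) {
      assert_that(file.exists(p), sprintf("gene list not found: %s", p))
      inputs <- c(inputs, p)
    }
    assert_that(!is.null(cfg$overlap$universe_size),
                "overlap stage requires universe_size")
  }
  if (!is.null(cfg$ddct)) {
    cfg$ddct$ct <- need(cfg$ddct$ct, "Ct matrix")
    cfg$ddct$annot <- need(cfg$ddct$annot, "sample annotation")
  }
  if (!is.null(cfg$score)) {
    cfg$score$table <- need(cfg$score$table, "scoring table")
    if (!isTRUE(cfg$score$from_ddct))
      cfg$score$profile <- need(cfg$score$profile, "direction profile")
    else assert_that(!is.null(cfg$ddct),
                     "score.from_ddct requires a ddct stage")
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg)
  seed <- cfg$seed %||% 1L

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    what <- sim$what %||% "list_pair"
    if (what == "ct") {
      ct <- gen_ct_dataset(n_genes = sim$n_genes %||% 24L,
                           n_per_group = sim$n_per_group %||% 10L,
                           group_shift = sim$group_shift %||% -1,
                           noise_sd = sim$noise_sd %||% 0.3, seed = seed)
      write_ct_matrix(ct, file.path(out_dir, "sim_ct.csv"),
                      file.path(out_dir, "sim_annot.tsv"),
                      header = sprintf("seed=%d", seed))
      report$simulate <- list(what = what, files = c("sim_ct.csv",
                                                     "sim_annot.tsv"))
    } else if (what == "scoring_table") {
      tab <- gen_scoring_table(
        genes_per_category = sim$genes_per_category %||% 24L,
        categories = sim$categories %||% c("EWS", "RMS", "NB", "BL"),
        max_rank = sim$max_rank %||% 100L, seed = seed)
      write_scoring_table(tab, file.path(out_dir, "sim_scoring_table.tsv"),
                          header = sprintf("seed=%d", seed))
      report$simulate <- list(what = what, files = "sim_scoring_table.tsv")
    } else {
      pair <- gen_list_pair(sim$universe_size %||% 20000L,
                            sim$n1 %||% 300L, sim$n2 %||% 200L,
                            k = sim$forced_overlap, seed = seed)
      write_gene_list(pair$a, file.path(out_dir, "sim_list_a.tsv"))
      write_gene_list(pair$b, file.path(out_dir, "sim_list_b.tsv"))
      report$simulate <- list(what = "list_pair",
                              files = c("sim_list_a.tsv", "sim_list_b.tsv"))
    }
  }

  if (!is.null(cfg$standardize)) {
    raw <- utils::read.delim(cfg$standardize$input, header = FALSE,
                             colClasses = "character")
    names(raw)[1:2] <- c("source_id", "direction")
    if (tolower(raw$source_id[1]) == "source_id") raw <- raw[-1, ]
    gl <- standardize_list(raw, read_id_mapping(cfg$standardize$mapping),
                           name = cfg$standardize$name %||% "standardized")
    write_gene_list(gl, file.path(out_dir, "standardized.tsv"))
    report$standardize <- attr(gl, "report")
  }

  if (!is.null(cfg$overlap)) {
    la <- lapply(cfg$overlap$lists_a, read_gene_list)
    lb <- lapply(cfg$overlap$lists_b, read_gene_list)
    u <- gene_universe(cfg$overlap$universe_size)
    m <- overlap_matrix(la, lb, u,
                        strict = isTRUE(cfg$overlap$strict),
                        direction = cfg$overlap$direction %||% "any",
                        adjust = if (isTRUE(cfg$overlap$bh)) "BH" else "none")
    write_overlap_matrix(m, file.path(out_dir, "overlap_matrix.tsv"))
    report$overlap <- list(N = m$N, k = as.data.frame(m$k),
                           p = as.data.frame(m$p),
                           grades = as.data.frame(m$grades))
  }

  calls <- NULL
  if (!is.null(cfg$ddct)) {
    ct <- read_ct_matrix(cfg$ddct$ct, cfg$ddct$annot,
                         reference_genes = cfg$ddct$reference_genes)
    calls <- ddct_analyze(ct,
                          calibrator_group = cfg$ddct$calibrator_group,
                          fc_threshold = cfg$ddct$fc_threshold %||% 2,
                          alpha = cfg$ddct$alpha %||% 0.05,
                          max_missing = cfg$ddct$max_missing %||% 0.2)
    write_expression_calls(calls, file.path(out_dir, "expression_calls.tsv"))
    write_direction_profile(profile_from_calls(calls),
                            file.path(out_dir, "direction_profile.tsv"))
    report$ddct <- list(n_genes = nrow(calls),
                        n_up = sum(calls$direction == "up"),
                        n_down = sum(calls$direction == "down"),
                        excluded = attr(calls, "excluded"),
                        settings = attr(calls, "settings"))
  }

  if (!is.null(cfg$score)) {
    tab <- read_scoring_table(cfg$score$table)
    prof <- if (isTRUE(cfg$score$from_ddct)) profile_from_calls(calls)
            else read_direction_profile(cfg$score$profile)
    rep_sc <- score_profile(prof, tab,
                            threshold = cfg$score$threshold %||% 0.4)
    write_score_report(rep_sc, file.path(out_dir, "score_report.json"))
    report$score <- as.data.frame(rep_sc)
  }

  manifest <- list(command = "run_pipeline",
                   config = basename(config_path),
                   config_digest = unname(tools::md5sum(config_path)),
                   input_digests = file_digest(unique(inputs)),
                   seed = seed, tool_version = pkg_version(),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

parse_cli_args <- function(args) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", sub("^--", "", a))
      if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        out[[key]] <- args[[i + 1L]]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

cli_log <- function(level, msg, threshold = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[threshold]])
    message(sprintf("[%s] %s", toupper(level), msg))
}

#' Command-line entry point
#'
#' Subcommands: `standardize`, `overlap`, `ddct`, `score`, `simulate`,
#' `run`. Invoked by the installed `dystroscore` script
#' (`exec/dystroscore`) as
#' `dystroscore <subcommand> [--option value ...]`; see the README for the
#' per-subcommand options. Returns the exit status instead of calling
#' `quit()` so it is testable in-process.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly (0 on success).
#' @export
dystroscore_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dystroscore <standardize|overlap|ddct|score|simulate|run> [options]",
    "  standardize --input raw.tsv --mapping map.tsv --out list.tsv",
    "  overlap     --universe-size N --lists-a dir/ --lists-b dir/ --out m.tsv",
    "              [--stratify-direction up|down] [--bh] [--strict]",
    "  ddct        --ct ct.csv --annot annot.tsv --out calls.tsv",
    "              [--calibrator-group g] [--fc-threshold 2] [--alpha 0.05]",
    "  score       --table table.tsv --profile profile.tsv --out report.json",
    "              [--threshold 0.4]",
    "  simulate    --what list_pair|scoring_table|ct --out-dir dir [--seed s]",
    "  run         --config config.json [--out-dir dir]",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opt <- parse_cli_args(args[-1])
  lvl <- opt$log_level %||% "info"
  status <- tryCatch({
    switch(cmd,
      run = {
        run_pipeline(opt$config, opt$out_dir)
        cli_log("info", "pipeline complete", lvl)
      },
      standardize = {
        raw <- utils::read.delim(opt$input, header = FALSE,
                                 colClasses = "character")
        names(raw)[1:2] <- c("source_id", "direction")
        gl <- standardize_list(raw, read_id_mapping(opt$mapping))
        write_gene_list(gl, opt$out %||% "standardized.tsv")
        r <- attr(gl, "report")
        cli_log("info", sprintf(
          "standardized: %d input, %d mapped, %d dropped, %d GeneIDs out",
          r$input, r$mapped, r$dropped, r$fanout), lvl)
      },
      overlap = {
        la <- lapply(collect_list_paths(opt$lists_a, "."), read_gene_list)
        lb <- lapply(collect_list_paths(opt$lists_b, "."), read_gene_list)
        m <- overlap_matrix(
          la, lb, gene_universe(as.integer(opt$universe_size)),
          strict = isTRUE(opt$strict),
          direction = if (is.null(opt$stratify_direction)) "any"
                      else opt$stratify_direction,
          adjust = if (isTRUE(opt$bh)) "BH" else "none")
        write_overlap_matrix(m, opt$out %||% "overlap_matrix.tsv")
        cli_log("info", sprintf("%d x %d overlap matrix written",
                                nrow(m$k), ncol(m$k)), lvl)
      },
      ddct = {
        ct <- read_ct_matrix(opt$ct, opt$annot)
        calls <- ddct_analyze(
          ct, calibrator_group = opt$calibrator_group,
          fc_threshold = as.numeric(opt$fc_threshold %||% 2),
          alpha = as.numeric(opt$alpha %||% 0.05))
        write_expression_calls(calls, opt$out %||% "expression_calls.tsv")
        cli_log("info", sprintf("%d genes called", nrow(calls)), lvl)
      },
      score = {
        rep_sc <- score_profile(
          read_direction_profile(opt$profile),
          read_scoring_table(opt$table),
          threshold = as.numeric(opt$threshold %||% 0.4))
        write_score_report(rep_sc, opt$out %||% "score_report.json")
        cli_log("info", paste("relative scores:",
                              paste(sprintf("%s=%.3f", rep_sc$category,
                                            rep_sc$relative),
                                    collapse = " ")), lvl)
      },
      simulate = {
        cfgfile <- tempfile(fileext = ".json")
        jsonlite::write_json(
          list(seed = as.integer(opt$seed %||% 1),
               simulate = list(what = opt$what %||% "list_pair")),
          cfgfile, auto_unbox = TRUE)
        run_pipeline(cfgfile, opt$out_dir %||% "sim_out")
      },
      {
        message(usage)
        return(invisible(1L))
      })
    0L
  }, error = function(e) {
    cli_log("error", conditionMessage(e), lvl)
    1L
  })
  invisible(status)
}
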