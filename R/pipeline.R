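# Orchestration: run every stage of the analysis from one configuration and
# emit a structured report. The report is the single artifact of record;
# figures, if drawn, are renderings of report tables. Results go to stdout /
# files; log messages go to stderr via message().

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full paralog-diagnosis pipeline
#'
#' Stages, in dependency order: read alignment -> discover diagnostic
#' positions -> pocket partition -> classify queries -> indel blocks ->
#' identity matrix -> reconciliation (if trees given) -> species-clustering
#' test -> scenario comparison (if >= 2 gene trees) -> RMSD comparison (if a
#' paired RMSD table is given). Stages whose inputs are absent are marked
#' `"skipped"`. Fails fast with a stage-tagged error.
#'
#' @param config list (or path to a JSON file) with entries: `alignment`
#'   (FASTA path) or `aln` (a [ref_alignment()]); `labels` (TSV path, if
#'   `alignment` used); `reference_id`; `distal_positions` (optional integer
#'   vector); `strict`, `min_group_size`, `rule`, `min_indel_length`
#'   (optional); `gene_tree`, `species_tree` (Newick paths or `phylo`
#'   objects, optional); `scenarios` (named list, optional); `dup_cost`,
#'   `loss_cost`; `rmsd_table` (optional data frame or TSV path with columns
#'   `model`, `rmsd_to_a`, `rmsd_to_b`); `seed` (recorded in provenance).
#' @return an `analysis_report`: list of stage outputs plus a `provenance`
#'   block (package version, seed, config hash, timestamp).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))

  aln <- with_stage("alignment", {
    if (!is.null(config$aln)) config$aln
    else if (!is.null(config$alignment)) {
      read_alignment(config$alignment, reference_id = config$reference_id,
                     labels = config$labels)
    } else stop("config needs 'aln' or 'alignment'")
  })

  message("stage discover: ", appendLF = FALSE)
  profile <- with_stage("discover", {
    discover_diagnostic_positions(
      aln, strict = config$strict %||% TRUE,
      min_group_size = config$min_group_size %||% 2L)
  })
  message(nrow(profile), " diagnostic positions")

  if (!is.null(config$distal_positions)) {
    profile <- with_stage("pocket_partition",
      partition_by_pocket(profile, config$distal_positions)$profile)
  }

  classification <- with_stage("classify", {
    if (nrow(profile) > 0L) {
      classify_cohort(aln, profile, rule = config$rule %||% "pocket")$summary
    } else "skipped"
  })

  indels <- with_stage("indels",
    detect_indel_blocks(aln, min_length = config$min_indel_length %||% 3L))
  identity <- with_stage("identity", identity_matrix(aln))

  get_tree <- function(x, reader) {
    if (is.null(x)) NULL else if (inherits(x, "phylo")) x else reader(x)
  }
  species_tree <- get_tree(config$species_tree, read_species_tree)
  gene_tree <- get_tree(config$gene_tree, read_gene_tree)

  reconciliation <- if (!is.null(gene_tree) && !is.null(species_tree)) {
    with_stage("reconcile", {
      r <- lca_reconcile(gene_tree, species_tree)
      list(n_duplications = r$n_duplications, n_losses = r$n_losses,
           loss_branches = r$loss_branches)
    })
  } else "skipped"

  clustering <- if (!is.null(gene_tree)) {
    with_stage("clustering_test", species_clustering_test(gene_tree))
  } else "skipped"

  scenarios <- if (!is.null(config$scenarios) &&
                   length(config$scenarios) >= 2L) {
    with_stage("scenarios", {
      sc <- lapply(config$scenarios, get_tree, reader = read_gene_tree)
      cmp <- compare_scenarios(sc, species_tree,
                               dup_cost = config$dup_cost %||% 1,
                               loss_cost = config$loss_cost %||% 1)
      list(table = as.data.frame(cmp), preferred = attr(cmp, "preferred"),
           tie = attr(cmp, "tie"))
    })
  } else "skipped"

  rmsd <- if (!is.null(config$rmsd_table)) {
    with_stage("rmsd_compare", {
      tab <- config$rmsd_table
      if (is.character(tab)) tab <- utils::read.delim(tab)
      tt <- paired_ttest(tab$rmsd_to_a, tab$rmsd_to_b)
      list(table = tab,
           mean_rmsd_to_a = mean(tab$rmsd_to_a),
           mean_rmsd_to_b = mean(tab$rmsd_to_b),
           t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value)
    })
  } else "skipped"

  hashable <- config[setdiff(names(config), "aln")]
  structure(list(
    profile = as.data.frame(profile),
    classification = classification,
    indels = indels,
    identity = identity,
    reconciliation = reconciliation,
    clustering = if (is.list(clustering)) clustering$table else clustering,
    clustering_fraction = if (is.list(clustering)) clustering$fraction else NA,
    scenarios = scenarios,
    rmsd = rmsd,
    provenance = list(package = "paralogdx",
                      version = as.character(utils::packageVersion("paralogdx")),
                      seed = config$seed,
                      config_hash = rlang::hash(hashable),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as a JSON + TSV bundle (atomically)
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param timestamp include the provenance timestamp (set `FALSE` for
#'   byte-reproducible output).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, timestamp = TRUE) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep2 <- unclass(report)
  if (!timestamp) rep2$provenance$timestamp <- NULL
  rep2$identity <- as.data.frame(rep2$identity)

  atomically <- function(path, writer) {
    tmp <- tempfile(tmpdir = dir)
    writer(tmp)
    file.rename(tmp, path)
    path
  }
  paths <- c(
    atomically(file.path(dir, "report.json"), function(p)
      jsonlite::write_json(rep2, p, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)),
    atomically(file.path(dir, "profile.tsv"), function(p)
      utils::write.table(report$profile, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)))
  if (is.data.frame(report$classification)) {
    paths <- c(paths, atomically(file.path(dir, "classification.tsv"),
      function(p) utils::write.table(report$classification, p, sep = "\t",
                                     quote = FALSE, row.names = FALSE)))
  }
  paths <- c(paths,
    atomically(file.path(dir, "indels.tsv"), function(p)
      utils::write.table(report$indels, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)),
    atomically(file.path(dir, "identity.tsv"), function(p)
      utils::write.table(report$identity, p, sep = "\t", quote = FALSE,
                         row.names = TRUE, col.names = NA)))
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (paralogdx ", x$provenance$version, ")\n", sep = "")
  cat("  diagnostic positions: ", nrow(x$profile), "\n", sep = "")
  if (is.data.frame(x$classification)) {
    cat("  queries classified:   ", nrow(x$classification), "\n", sep = "")
  }
  cat("  indel blocks:         ", nrow(x$indels), "\n", sep = "")
  if (is.list(x$reconciliation)) {
    cat("  reconciliation:       ", x$reconciliation$n_duplications,
        " dup, ", x$reconciliation$n_losses, " loss\n", sep = "")
  }
  invisible(x)
}
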