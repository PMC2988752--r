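# File formats and reporting.  Canonical carriers are plain
# tab-separated tables: study summaries (gene, p_value, direction, n1,
# n2 with a '#' pragma line holding study metadata), signed-Z tables,
# GMT gene sets, two-column edge lists, and a JSON manifest per run
# directory.  Gene symbols are uppercased at every boundary.

read_pragma <- function(path) {
  first <- readLines(path, n = 1L)
  out <- list()
  if (startsWith(first, "#")) {
    toks <- strsplit(trimws(sub("^#", "", first)), "[ \t]+")[[1L]]
    toks <- toks[grepl("=", toks, fixed = TRUE)]
    kv <- strsplit(toks, "=", fixed = TRUE)
    out <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  }
  out
}

#' Read a study summary TSV
#'
#' Expects a header line `gene  p_value  direction` (optionally `n1`,
#' `n2`), preceded by an optional pragma line such as
#' `# study_id=breast_01 cancer_type=breast contrast=normal_vs_tumor`.
#' Direction tokens are case insensitive; malformed tokens raise an
#' error naming the offending line; duplicate gene symbols raise an
#' error naming the symbols; boundary p-values are clamped with a
#' logged count.
#'
#' @param path file path.
#' @param study_id,cancer_type,contrast metadata overrides; default to
#'   the pragma values, then to the file name / `"unknown"`.
#' @return A [study_summary()].
#' @export
read_study_tsv <- function(path, study_id = NULL, cancer_type = NULL,
                           contrast = NULL) {
  meta <- read_pragma(path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  req <- c("gene", "p_value", "direction")
  if (!all(req %in% names(df))) {
    stop("study TSV must have columns gene, p_value, direction: ", path,
         call. = FALSE)
  }
  dirs <- tolower(trimws(df$direction))
  bad <- which(!dirs %in% c("up", "down"))
  if (length(bad)) {
    stop("malformed direction token at line ", bad[1L] + 1L, " of ", path,
         ": '", df$direction[bad[1L]], "'", call. = FALSE)
  }
  pick <- function(override, key, fallback) {
    if (!is.null(override)) override
    else if (!is.null(meta[[key]])) meta[[key]]
    else fallback
  }
  study_summary(
    study_id = pick(study_id, "study_id",
                    tools::file_path_sans_ext(basename(path))),
    cancer_type = pick(cancer_type, "cancer_type", "unknown"),
    contrast = pick(contrast, "contrast", "normal_vs_tumor"),
    gene = df$gene, p_value = df$p_value, direction = dirs,
    n1 = if ("n1" %in% names(df)) df$n1[1L] else
      as.integer(meta$n1 %||% NA),
    n2 = if ("n2" %in% names(df)) df$n2[1L] else
      as.integer(meta$n2 %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_study_tsv
#' @param study a [study_summary()].
#' @export
write_study_tsv <- function(study, path) {
  stopifnot(inherits(study, "study_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# study_id=%s cancer_type=%s contrast=%s",
                     study$study_id, study$cancer_type, study$contrast),
             con)
  df <- study$data
  df$n1 <- study$n1
  df$n2 <- study$n2
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write signed-Z tables as TSV
#'
#' Columns `gene`, `z`, `n_studies`; the provenance label travels on a
#' `# label=` pragma line.
#'
#' @param path file path.
#' @return [read_signed_z_tsv()]: a [signed_z_table()].
#' @export
read_signed_z_tsv <- function(path) {
  meta <- read_pragma(path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("gene", "z") %in% names(df))) {
    stop("signed-Z TSV must have columns gene, z: ", path, call. = FALSE)
  }
  signed_z_table(df$gene, df$z,
                 if ("n_studies" %in% names(df)) df$n_studies else 1L,
                 label = meta$label %||% "")
}

#' @rdname read_signed_z_tsv
#' @param table a [signed_z_table()].
#' @export
write_signed_z_tsv <- function(table, path) {
  assert_ztab(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s", ztab_label(table)), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.  Lines without members are skipped with a
#' warning.
#'
#' @param path file path.
#' @return [read_gmt()]: list of [gene_set()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (length(f) < 3L || !length(members)) {
      warning("GMT line without members skipped: '", f[1L], "'")
      next
    }
    sets[[length(sets) + 1L]] <- gene_set(f[1L], members)
  }
  sets
}

#' @rdname read_gmt
#' @param sets list of [gene_set()]s.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' First line is a `# groups=` sample-annotation pragma, then a
#' gene-by-sample table with a `gene` column.
#'
#' @param path file path.
#' @param matrix an `expression_matrix`.
#' @export
write_expression_tsv <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# groups=", paste(matrix$groups, collapse = ",")), con)
  df <- data.frame(gene = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  meta <- read_pragma(path)
  if (is.null(meta$groups)) {
    stop("expression TSV is missing the '# groups=' pragma", call. = FALSE)
  }
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#", check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- toupper(df[[1L]])
  groups <- strsplit(meta$groups, ",", fixed = TRUE)[[1L]]
  if (length(groups) != ncol(vals)) {
    stop("groups pragma length does not match sample count", call. = FALSE)
  }
  structure(list(values = vals,
                 groups = factor(groups, levels = unique(groups))),
            class = "expression_matrix")
}

#' Read a run configuration (YAML or JSON)
#'
#' The configuration mirrors the `config` argument of [run_pipeline()]:
#' study file paths by role, optional `k`, policies, thresholds and
#' `seed`.  All referenced paths are checked at load.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param base_dir directory against which relative study paths are
#'   resolved; defaults to the config file's directory.
#' @return config list ready for [run_pipeline()].
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$k) && cfg$k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed)) {
    stop("seed must be an integer", call. = FALSE)
  }
  cfg$studies <- lapply(cfg$studies, function(paths) {
    paths <- as.character(unlist(paths, use.names = FALSE))
    full <- ifelse(file.exists(paths), paths, file.path(base_dir, paths))
    missing <- full[!file.exists(full)]
    if (length(missing)) {
      stop("study file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    as.list(full)
  })
  cfg
}

#' Write a run report directory
#'
#' Emits the three level tables, balancing factors, ranked candidate
#' lists, optional validation and hub sections, and a manifest JSON with
#' an MD5 checksum per file.  Identical runs produce byte-identical
#' manifests (no timestamps).
#'
#' @param result a [run_pipeline()] result.
#' @param validations optional list of validation statistics (written as
#'   `validation.json`).
#' @param hubs optional [select_hubs()] data.frame (written as
#'   `hubs.json`).
#' @param outdir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
write_report <- function(result, validations = NULL, hubs = NULL, outdir) {
  stopifnot(inherits(result, "meta_run_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)

  files <- character(0)
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    files <<- c(files, name)
  }
  emit("level1.tsv", function(p) write_signed_z_tsv(result$level1, p))
  emit("level2.tsv", function(p) write_signed_z_tsv(result$level2, p))
  emit("level3.tsv", function(p) write_signed_z_tsv(result$level3, p))
  emit("top_up.tsv", function(p)
    write.table(result$top_up, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("top_down.tsv", function(p)
    write.table(result$top_down, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("factors.json", function(p)
    jsonlite::write_json(list(factors = as.list(result$factors_by_group),
                              target = result$balance_target),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  if (!is.null(validations)) {
    emit("validation.json", function(p)
      jsonlite::write_json(validations, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE))
  }
  if (!is.null(hubs)) {
    emit("hubs.json", function(p)
      jsonlite::write_json(hubs, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE))
  }
  checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(checksums) <- files
  manifest <- list(
    files = checksums,
    sections = list(validation = !is.null(validations),
                    hubs = !is.null(hubs)),
    config_echo = result$config_echo)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
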