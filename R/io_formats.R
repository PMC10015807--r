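# Readers and writers for the three tab-separated exchange formats
# (drug/SMILES table, KG triples, labeled DDI pairs), the YAML config, the
# JSON metrics report and the model checkpoint. All text formats are UTF-8
# TSV without header; lines starting with '#' are comments.

read_tsv_lines <- function(path, n_fields, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    warning("no records in ", what, " file: ", path, call. = FALSE)
    return(list(
      fields = matrix(character(0), 0L, n_fields),
      malformed = integer(0)
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == n_fields
  fields <- if (any(ok)) {
    do.call(rbind, parts[ok])
  } else {
    matrix(character(0), 0L, n_fields)
  }
  list(fields = fields, malformed = line_no[!ok])
}

check_malformed <- function(parsed, path, max_malformed_fraction) {
  n_bad <- length(parsed$malformed)
  if (n_bad > 0L) {
    n_all <- nrow(parsed$fields) + n_bad
    if (n_bad / n_all > max_malformed_fraction) {
      stop(
        n_bad, " of ", n_all, " lines malformed in ", path,
        " (lines ", paste(utils::head(parsed$malformed, 5L), collapse = ", "),
        if (n_bad > 5L) ", ..." else "", ")",
        call. = FALSE
      )
    }
    warning(n_bad, " malformed line(s) skipped in ", path, call. = FALSE)
  }
  invisible(parsed)
}

#' Read a knowledge-graph triple file
#'
#' One `head<TAB>relation<TAB>tail` triple per line, string identifiers
#' (DRKG-style), `#` comments allowed. Order is preserved. Malformed lines
#' are counted and skipped with a warning; if more than
#' `max_malformed_fraction` of the records are malformed the read aborts.
#'
#' @param path File path.
#' @param max_malformed_fraction Abort threshold.
#' @return A tibble with columns `head`, `relation`, `tail` and a
#'   `vocabulary` attribute (list of `entities` and `relations` in order of
#'   first appearance).
#' @export
read_triples <- function(path, max_malformed_fraction = 0.1) {
  parsed <- check_malformed(
    read_tsv_lines(path, 3L, "triple"), path, max_malformed_fraction
  )
  f <- parsed$fields
  out <- tibble::tibble(
    head = as.character(f[, 1L]),
    relation = as.character(f[, 2L]),
    tail = as.character(f[, 3L])
  )
  attr(out, "vocabulary") <- list(
    entities = unique(c(out$head, out$tail)),
    relations = unique(out$relation)
  )
  out
}

#' Read a drug-to-SMILES table
#'
#' One `drug_id<TAB>smiles` record per line.
#'
#' @param path File path.
#' @param max_malformed_fraction Abort threshold as in [read_triples()].
#' @return Tibble with columns `drug_id`, `smiles` (duplicated drug ids are
#'   dropped with a warning, first record kept).
#' @export
read_smiles_file <- function(path, max_malformed_fraction = 0.1) {
  parsed <- check_malformed(
    read_tsv_lines(path, 2L, "SMILES"), path, max_malformed_fraction
  )
  f <- parsed$fields
  out <- tibble::tibble(
    drug_id = as.character(f[, 1L]),
    smiles = as.character(f[, 2L])
  )
  if (anyDuplicated(out$drug_id)) {
    warning("duplicate drug ids dropped (first kept)", call. = FALSE)
    out <- out[!duplicated(out$drug_id), ]
  }
  out
}

#' Read a labeled DDI pair file
#'
#' One `drug_i<TAB>drug_j<TAB>label` record per line. Binary labels must be
#' 0/1; multi-class labels must lie in `0 .. n_classes - 1`. A header line
#' is autodetected (non-numeric label field) and skipped. Duplicate pairs
#' (in either order) are deduplicated with a warning, first label kept.
#'
#' @param path File path.
#' @param task `"binary"` or `"multiclass"`.
#' @param n_classes Required for label validation of the multi-class task.
#' @param max_malformed_fraction Abort threshold as in [read_triples()].
#' @return Tibble with columns `drug_i`, `drug_j`, `label` (integer).
#' @export
read_ddi_pairs <- function(path, task = c("binary", "multiclass"),
                           n_classes = if (task == "binary") 2L else NULL,
                           max_malformed_fraction = 0.1) {
  task <- match.arg(task)
  if (task == "multiclass" && is.null(n_classes)) {
    stop("n_classes is required for the multiclass task", call. = FALSE)
  }
  parsed <- check_malformed(
    read_tsv_lines(path, 3L, "DDI pair"), path, max_malformed_fraction
  )
  f <- parsed$fields
  if (nrow(f) > 0L && is.na(suppressWarnings(as.numeric(f[1L, 3L])))) {
    f <- f[-1L, , drop = FALSE] # header line
  }
  label <- suppressWarnings(as.numeric(f[, 3L]))
  bad <- which(is.na(label) | label != floor(label) |
    label < 0 | label >= (if (task == "binary") 2L else n_classes))
  if (length(bad)) {
    stop("out-of-range or non-integer label at record ", bad[1L],
      " of ", path,
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    drug_i = as.character(f[, 1L]),
    drug_j = as.character(f[, 2L]),
    label = as.integer(label)
  )
  dup <- duplicated(unordered_key(out$drug_i, out$drug_j))
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) dropped (first label kept)",
      call. = FALSE
    )
    out <- out[!dup, ]
  }
  out
}

#' Write the exchange formats
#'
#' Writers matching [read_smiles_file()], [read_triples()] and
#' [read_ddi_pairs()]: UTF-8 TSV, no header, no quoting.
#'
#' @param x The tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(x, path) {
  write_tsv_plain(x[, c("drug_id", "smiles")], path)
}

#' @rdname write_smiles_file
#' @export
write_triples <- function(x, path) {
  write_tsv_plain(x[, c("head", "relation", "tail")], path)
}

#' @rdname write_smiles_file
#' @export
write_ddi_pairs <- function(x, path) {
  write_tsv_plain(x[, c("drug_i", "drug_j", "label")], path)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Write a toy world to a directory
#'
#' Emits `drugs.tsv`, `kg.tsv` and `ddi.tsv` in the exchange formats.
#'
#' @param world A `toy_world` from [generate_toy_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_world <- function(world, dir) {
  stopifnot(inherits(world, "toy_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_smiles_file(world$drugs, file.path(dir, "drugs.tsv"))
  write_triples(world$triples, file.path(dir, "kg.tsv"))
  write_ddi_pairs(world$pairs, file.path(dir, "ddi.tsv"))
  invisible(dir)
}

#' Load a training configuration from YAML
#'
#' Keys mirror the [ddi_config()] and [kg_config()] argument names; a `kg:`
#' sub-map is passed through to [kg_config()].
#'
#' @param path YAML file path.
#' @return A `ddi_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  kg_args <- y$kg
  y$kg <- NULL
  cfg_args <- y
  if (!is.null(kg_args)) cfg_args$kg <- do.call(kg_config, kg_args)
  do.call(ddi_config, cfg_args)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-archive serialized list with a versioned
#' schema (`schema = 1`) holding the configuration, drug vocabulary, all
#' parameter blocks and the frozen representation matrices.
#'
#' @param fit A `ddi_fit` object from [ddi_train()].
#' @param path Checkpoint file path (`.rds`).
#' @return `path` (write) or the restored `ddi_fit` (read).
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ddi_fit"))
  saveRDS(c(list(schema = 1L), unclass(fit)), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, 1L)) {
    stop("unsupported checkpoint schema: ", x$schema, call. = FALSE)
  }
  x$schema <- NULL
  structure(x, class = "ddi_fit")
}

#' Write a metrics report as JSON
#'
#' @param metrics A `ddi_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "ddi_metrics"))
  jsonlite::write_json(
    list(
      summary = as.list(glance(metrics)),
      per_class = metrics$per_class
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
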