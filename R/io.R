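# Readers and writers for the pipeline's plain-text formats: TSV matrices
# (features x samples, sample ids crew<k>_T<j>), GMT gene-set collections,
# and schema-commented TSV result tables.

#' Parse crew/timepoint metadata out of sample ids
#'
#' @param ids Character vector of sample ids formatted `crew<k>_T<j>`.
#' @return data.frame with columns sample, crew, timepoint.
#' @export
parse_sample_ids <- function(ids) {
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sample ids must be present and unique")
  }
  ok <- grepl("^crew[0-9]+_T[0-9]+$", ids)
  if (!all(ok)) {
    stop("unparsable sample id(s): ", paste(utils::head(ids[!ok], 5), collapse = ", "),
         " (expected crew<k>_T<j>; supply a metadata sidecar otherwise)")
  }
  data.frame(sample = ids,
             crew = as.integer(sub("^crew([0-9]+)_T[0-9]+$", "\\1", ids)),
             timepoint = as.integer(sub("^crew[0-9]+_T([0-9]+)$", "\\1", ids)),
             stringsAsFactors = FALSE)
}

#' Write a feature-by-sample matrix as TSV
#'
#' First column is the feature id, remaining columns are samples; a leading
#' `#` comment line declares the column schema.
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# columns: feature_id, then one column per sample (%d samples)",
                     ncol(m)), con)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' Validates unique feature ids, rectangular rows and the sample-id
#' convention; format errors carry the offending line number or id.
#'
#' @param path Input path.
#' @param type `"expression"` or `"microbe"`.
#' @param cell_type Cell-type label attached when `type = "expression"`.
#' @param domain,rank Taxonomy labels attached when `type = "microbe"`.
#' @param metadata Optional sidecar: path to (or data.frame of) a TSV with
#'   columns sample, crew, timepoint, allowing sample ids that do not
#'   follow `crew<k>_T<j>`.
#' @return Typed matrix (see [expression_matrix()] / [microbe_matrix()]).
#' @export
read_matrix_tsv <- function(path, type = c("expression", "microbe"),
                            cell_type = NULL, domain = NULL, rank = NULL,
                            metadata = NULL) {
  type <- match.arg(type)
  lines <- readLines(path)
  data_ln <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(data_ln) < 2L) stop("format error: no data rows in ", path)
  fields <- strsplit(lines[data_ln], "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- data_ln[which(widths != widths[1])[1]]
    stop(sprintf("format error: ragged row at line %d of %s", bad, path))
  }
  header <- fields[[1L]]
  samples <- header[-1L]
  body <- fields[-1L]
  ids <- vapply(body, `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("format error: duplicated feature id '%s' in %s", dup[1], path))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      stop(sprintf("format error: non-numeric value at line %d of %s",
                   data_ln[i + 1L], path))
    }
    vals[i, ] <- v
  }
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata)) {
      utils::read.delim(metadata, stringsAsFactors = FALSE)
    } else {
      metadata
    }
    need <- c("sample", "crew", "timepoint")
    if (!all(need %in% names(meta)) || !all(samples %in% meta$sample)) {
      stop("metadata sidecar must cover every sample with columns sample, crew, timepoint")
    }
    meta <- meta[match(samples, meta$sample), ]
    colnames(vals) <- sprintf("crew%d_T%d", meta$crew, meta$timepoint)
  }
  if (type == "expression") {
    expression_matrix(vals, cell_type = cell_type %||% "unknown")
  } else {
    microbe_matrix(vals, domain = domain %||% "bacteria", rank = rank %||% "species")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GMT gene-set file
#'
#' Standard three-plus-column GMT: set name, description, then genes.
#' Duplicate genes within a set are deduplicated with a warning; duplicate
#' set names and short lines are errors carrying the line number.
#'
#' @param path Input path.
#' @return Named list of gene sets, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("format error: line %d of %s has fewer than 3 tab-separated fields",
                 short[1], path))
  }
  nms <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop(sprintf("format error: duplicated set name '%s' in %s",
                 nms[duplicated(nms)][1], path))
  }
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gmt: duplicated genes in set '%s' deduplicated", nms[i]))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nms
  attr(sets, "descriptions") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param pathways Named list of gene sets.
#' @param path Output path.
#' @param descriptions Optional descriptions (default `"na"`).
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with a schema comment line
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @export
write_tsv_schema <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(df), collapse = ", ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a schema-commented TSV written by [write_tsv_schema()]
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv_schema <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
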