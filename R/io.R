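## Plain-text input/output: TSV block matrices, metadata, GMT gene sets,
## and JSON model serialization.

#' Write an OmicsBlock as TSV
#'
#' Features as rows; first column `feature_id`, remaining columns one per
#' sample. Missing entries are written as `NA`.
#' @param block an [OmicsBlock-class].
#' @param path output file.
#' @export
writeBlockTsv <- function(block, path) {
  v <- blockValues(block)
  df <- cbind(data.frame(feature_id = rownames(v)), as.data.frame(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OmicsBlock from TSV
#'
#' @param path TSV written by [writeBlockTsv()] (first column feature ids,
#'   header row of sample ids).
#' @param name block label; defaults to the file name stem.
#' @return an [OmicsBlock-class].
#' @export
readBlockTsv <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("^block_", "", sub("\\.tsv$", "", basename(path)))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  omicsBlock(name, m)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `group`, and optionally `patient_id`.
#' @param path metadata TSV.
#' @return data.frame.
#' @export
readMetadataTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.
#' @param path GMT file.
#' @return named list of character vectors of member symbols.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Loadings are stored as sparse feature-id to weight maps per block and
#' component, together with the scaling vectors, keepX and the design
#' matrix, so the model can be archived or inspected as plain text.
#' @param model a [BlockSplsdaModel-class].
#' @param path output JSON file.
#' @export
writeModelJson <- function(model, path) {
  sparse <- lapply(model@loadings, function(L) {
    lapply(seq_len(ncol(L)), function(h) {
      nz <- which(L[, h] != 0)
      as.list(stats::setNames(L[nz, h], rownames(L)[nz]))
    })
  })
  obj <- list(blockNames = model@blockNames, ncomp = model@ncomp,
              keepX = model@keepX, design = as.data.frame(model@design),
              classLevels = model@classLevels,
              centers = model@centers, scales = model@scales,
              loadings = sparse)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
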