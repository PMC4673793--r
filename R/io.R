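## Delimited-text I/O for expression matrices, label files and gene
## reports. The delimiter is taken from the file extension (.csv = comma,
## anything else = tab).

io_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a delimited expression matrix
#'
#' Expects one header row and one identifier column. The matrix is
#' returned oriented samples x genes regardless of the file orientation;
#' identifiers are preserved verbatim.
#'
#' @param path TSV or CSV file.
#' @param orientation `"genes_in_rows"` (default; columns are samples) or
#'   `"samples_in_rows"`.
#' @return numeric matrix, samples in rows and genes in columns.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, sep = io_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated identifiers in ", path, ": ", paste(dup, collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
    if (!nrow(bad)) bad <- which(is.na(num), arr.ind = TRUE)
    stop("non-numeric or missing value at row ", ids[bad[1L, 1L]],
         ", column ", colnames(body)[bad[1L, 2L]], " of ", path)
  }
  dimnames(num) <- list(ids, colnames(body))
  if (orientation == "genes_in_rows") num <- t(num)
  cn <- colnames(num)
  dup <- unique(cn[duplicated(cn)])
  if (length(dup))
    stop("duplicated identifiers in ", path, ": ", paste(dup, collapse = ", "))
  num
}

#' Write an expression matrix as delimited text
#'
#' Values are written with 17 significant digits so a write-then-read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param x numeric matrix, samples in rows and genes in columns.
#' @param path output file; extension selects the delimiter.
#' @param orientation layout to write (default `"genes_in_rows"`).
#' @param id_header header of the identifier column.
#' @export
write_expression <- function(x, path,
                             orientation = c("genes_in_rows", "samples_in_rows"),
                             id_header = "id") {
  orientation <- match.arg(orientation)
  m <- if (orientation == "genes_in_rows") t(x) else x
  sep <- io_sep(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(m)), collapse = sep), con)
  rows <- apply(m, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = sep))
  writeLines(paste(rownames(m), rows, sep = sep), con)
  invisible(path)
}

#' Read a class-label file
#'
#' Accepts either one label per line (optionally with a header `label`),
#' or a two-column `(sample_id, label)` file in any row order. Labels are
#' mapped to 0/1 with the lexicographically smaller original label
#' becoming 0.
#'
#' @param path TSV or CSV file.
#' @param sample_ids sample identifiers of the companion matrix; required
#'   to align a two-column file and to validate the length of a
#'   one-column file.
#' @return integer 0/1 vector with attribute `levels` giving the original
#'   two labels in `(0, 1)` order.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  raw <- utils::read.table(path, sep = io_sep(path), header = FALSE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  if (ncol(raw) == 1L) {
    lab <- raw[[1L]]
    if (identical(tolower(lab[1L]), "label")) lab <- lab[-1L]
    if (!is.null(sample_ids)) {
      if (length(lab) != length(sample_ids))
        stop("label file has ", length(lab), " entries but the matrix has ",
             length(sample_ids), " samples")
      names(lab) <- sample_ids
    }
  } else {
    ids <- raw[[1L]]
    lab <- raw[[2L]]
    if (identical(tolower(lab[1L]), "label")) { ids <- ids[-1L]; lab <- lab[-1L] }
    names(lab) <- ids
    if (!is.null(sample_ids)) {
      missing <- setdiff(sample_ids, ids)
      if (length(missing))
        stop("label file lacks sample(s): ", paste(missing, collapse = ", "))
      extra <- setdiff(ids, sample_ids)
      if (length(extra))
        stop("label file has unmatched sample id(s): ",
             paste(extra, collapse = ", "))
      lab <- lab[sample_ids]
    }
  }
  encode_labels(lab)
}

#' Write a candidate-gene report
#'
#' Writes a TSV with columns `rank`, `gene_id`, `seed_set_index`,
#' `R1_value` (deterministic ordering) and, when `config` is given, a JSON
#' sidecar `<path>.json` recording the run configuration. An empty result
#' writes a header-only file with a warning.
#'
#' @param candidates candidate data frame (from an [irda()] fit's
#'   `$candidates`) or an `"irda"` fit.
#' @param path output TSV path.
#' @param config optional run-configuration list for the JSON sidecar
#'   (taken from the fit if one is supplied).
#' @export
write_gene_report <- function(candidates, path, config = NULL) {
  if (inherits(candidates, "irda")) {
    config <- config %||% candidates$config
    candidates <- candidates$candidates
  }
  if (!nrow(candidates)) warning("empty candidate set; writing header only")
  out <- data.frame(rank = candidates$rank, gene_id = candidates$gene_id,
                    seed_set_index = candidates$seed_set_index,
                    R1_value = candidates$r1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}
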