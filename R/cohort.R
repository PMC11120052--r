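#' @keywords internal
"_PACKAGE"

STAGE_LEVELS <- c("normal", "1", "2", "3", "4", "X")
SAMPLE_TYPES <- c("tissue", "blood")
TUMOR_STAGES <- c("1", "2", "3", "4")

#' Construct a labeled miRNA expression cohort
#'
#' Bundles a samples x miRNAs reads-per-million (rpm) matrix with per-sample
#' stage labels and sample-type flags into a validated `mirna_cohort` object,
#' the container every downstream analysis consumes.
#'
#' @param expr numeric matrix, samples in rows, miRNAs in columns; rownames are
#'   sample identifiers, colnames miRNA identifiers. All values must be finite
#'   and nonnegative (rpm scale).
#' @param stage character or factor of per-sample stage labels; accepted values
#'   (case-insensitive) are `"normal"`, `"1"`..`"4"` and `"X"`.
#' @param sample_type character or factor, `"tissue"` or `"blood"` per sample.
#' @return An object of class `mirna_cohort`: a list with elements `expr`,
#'   `stage` (factor) and `sample_type` (factor), aligned 1:1 with the rows of
#'   `expr`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("mir-a", "mir-b")))
#' mirna_cohort(m, c("normal", "1"), c("tissue", "tissue"))
#' @export
mirna_cohort <- function(expr, stage, sample_type) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix (samples x miRNAs)")
  if (is.null(rownames(expr)) && nrow(expr) > 0)
    rownames(expr) <- paste0("sample-", seq_len(nrow(expr)))
  if (is.null(colnames(expr)) && ncol(expr) > 0)
    stop("`expr` must have miRNA identifiers as column names")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate sample identifiers in `expr`")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate miRNA identifiers in `expr`")
  if (nrow(expr) > 0 && ncol(expr) > 0) {
    if (any(!is.finite(expr)))
      stop("expression values must be finite (no NA/NaN/Inf)")
    if (any(expr < 0))
      stop("expression values must be nonnegative rpm")
  }
  stage <- normalize_stage(as.character(stage))
  sample_type <- as.character(sample_type)
  if (!all(sample_type %in% SAMPLE_TYPES))
    stop("sample_type values must be one of: ", paste(SAMPLE_TYPES, collapse = ", "))
  if (length(stage) != nrow(expr) || length(sample_type) != nrow(expr))
    stop("`stage` and `sample_type` must have one entry per sample")
  structure(
    list(expr = expr,
         stage = factor(stage, levels = STAGE_LEVELS),
         sample_type = factor(sample_type, levels = SAMPLE_TYPES)),
    class = "mirna_cohort")
}

#' Normalize stage labels
#'
#' Case-insensitive normalization to the coarse stage vocabulary
#' `normal`, `1`, `2`, `3`, `4`, `X`. Sub-stages (e.g. "IIA") are out of scope
#' and rejected.
#'
#' @param x character vector of stage labels.
#' @return character vector with canonical labels.
#' @export
normalize_stage <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[out == "x"] <- "X"
  bad <- !(out %in% STAGE_LEVELS)
  if (any(bad))
    stop("invalid stage label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (accepted: ", paste(STAGE_LEVELS, collapse = ", "), ")")
  out
}

#' @export
print.mirna_cohort <- function(x, ...) {
  cat("miRNA cohort: ", nrow(x$expr), " samples x ", ncol(x$expr), " miRNAs\n",
      sep = "")
  tab <- table(stage = x$stage, type = x$sample_type)
  print(tab)
  invisible(x)
}

#' @export
dim.mirna_cohort <- function(x) dim(x$expr)

#' Number of samples in a cohort
#' @param cohort a `mirna_cohort`.
#' @return integer sample count.
#' @export
n_samples <- function(cohort) nrow(cohort$expr)

#' Subset a cohort by sample index
#' @param x a `mirna_cohort`.
#' @param i integer or logical sample index.
#' @param ... unused.
#' @return the subsetted `mirna_cohort` (relative sample order preserved).
#' @export
`[.mirna_cohort` <- function(x, i, ...) {
  mirna_cohort(x$expr[i, , drop = FALSE],
               as.character(x$stage[i]),
               as.character(x$sample_type[i]))
}

#' Read a per-sample miRNA quantification file
#'
#' Parses a tab-separated quantification file in the GDC-portal layout: a
#' header row naming a miRNA identifier column, a read-count column and a
#' reads-per-million column, followed by one row per miRNA.
#'
#' @param path path to a TSV file. Column names are matched loosely:
#'   the miRNA column is the first whose name contains "mirna" or "mir",
#'   the count column contains "count", and the rpm column contains
#'   "per_million" or "rpm".
#' @return data.frame with columns `mirna_id` (character), `read_count`
#'   (integer) and `rpm` (numeric), one row per data row, file order preserved.
#' @export
read_quantification_file <- function(path) {
  if (!file.exists(path)) stop("quantification file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  find_col <- function(patterns, what) {
    hit <- which(Reduce(`|`, lapply(patterns, function(p) grepl(p, nm))))
    if (length(hit) == 0)
      stop("quantification format error: no column matching '", what,
           "' in ", path)
    hit[1]
  }
  rpm_col   <- find_col(c("per_million", "rpm"), "reads per million")
  count_col <- find_col(c("count"), "read count")
  id_col    <- find_col(c("mirna", "^mir"), "miRNA identifier")
  out <- data.frame(mirna_id = as.character(df[[id_col]]),
                    read_count = df[[count_col]],
                    rpm = as.numeric(df[[rpm_col]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(out)
  if (any(!nzchar(out$mirna_id)))
    stop("validation error: empty miRNA identifier in ", path)
  if (anyDuplicated(out$mirna_id)) {
    dup <- unique(out$mirna_id[duplicated(out$mirna_id)])
    stop("duplicate miRNA identifier(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- which(!is.finite(out$rpm) | out$rpm < 0 |
                 !is.finite(out$read_count) | out$read_count < 0)
  if (length(bad))
    stop("validation error: negative or non-finite value at row ", bad[1],
         " of ", path)
  out
}

#' Read clinical metadata from JSON
#'
#' Reads a flat JSON array of clinical records (fields `case_id`, `file_id`,
#' `stage`, `sample_type`, optional `age`, `gender`). Nested GDC-style files
#' where those fields live under a `cases` sub-object are handled permissively.
#'
#' @param path path to a JSON file.
#' @return data.frame with columns `case_id`, `file_id`, `stage`,
#'   `sample_type`, `age`, `gender`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(raw) && !is.null(raw$cases) && is.null(raw$stage)) {
    # nested GDC-style: hoist fields from the cases sub-object
    cases <- raw$cases
    if (is.list(cases) && !is.data.frame(cases))
      cases <- do.call(rbind, lapply(cases, as.data.frame))
    for (f in c("case_id", "stage", "sample_type", "age", "gender"))
      if (is.null(raw[[f]]) && !is.null(cases[[f]])) raw[[f]] <- cases[[f]]
    raw$cases <- NULL
  }
  req <- c("case_id", "file_id", "stage", "sample_type")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("clinical format error: missing field(s) ", paste(miss, collapse = ", "))
  out <- data.frame(case_id = as.character(raw$case_id),
                    file_id = as.character(raw$file_id),
                    stage = normalize_stage(raw$stage),
                    sample_type = as.character(raw$sample_type),
                    age = if (is.null(raw$age)) NA_integer_ else as.integer(raw$age),
                    gender = if (is.null(raw$gender)) NA_character_ else as.character(raw$gender),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("case_id", "file_id")]))
    stop("clinical validation error: duplicated (case_id, file_id) pair")
  if (!all(out$sample_type %in% SAMPLE_TYPES))
    stop("clinical validation error: sample_type must be tissue or blood")
  out
}

#' Join quantification files with clinical records into a labeled cohort
#'
#' Matches each quantification file to its clinical record by file id, checks
#' that all samples share one miRNA universe, and assembles the expression
#' matrix. Rows follow clinical record order; miRNA columns are sorted
#' lexicographically so downstream rankings are reproducible.
#'
#' Clinical records without a matching quantification file are dropped with a
#' warning; a quantification file without a clinical match is an error.
#'
#' @param quant named list of quantification data.frames (as returned by
#'   [read_quantification_file()]), names are file ids.
#' @param clinical clinical data.frame from [read_clinical()].
#' @return a [mirna_cohort()].
#' @export
assemble_cohort <- function(quant, clinical) {
  if (is.null(names(quant)) || any(!nzchar(names(quant))))
    stop("`quant` must be a named list keyed by file_id")
  orphans <- setdiff(names(quant), clinical$file_id)
  if (length(orphans))
    stop("join error: quantification file(s) with no clinical record: ",
         paste(orphans, collapse = ", "))
  keep <- clinical$file_id %in% names(quant)
  if (any(!keep))
    warning("dropping ", sum(!keep),
            " clinical record(s) without a quantification file")
  clinical <- clinical[keep, , drop = FALSE]
  if (nrow(clinical) == 0)
    return(mirna_cohort(matrix(numeric(0), 0, 0), character(0), character(0)))
  universe <- sort(quant[[clinical$file_id[1]]]$mirna_id)
  expr <- matrix(NA_real_, nrow(clinical), length(universe),
                 dimnames = list(clinical$case_id, universe))
  for (i in seq_len(nrow(clinical))) {
    q <- quant[[clinical$file_id[i]]]
    if (length(q$mirna_id) != length(universe) ||
        !setequal(q$mirna_id, universe))
      stop("alignment error: file ", clinical$file_id[i],
           " has a different miRNA universe")
    expr[i, ] <- q$rpm[match(universe, q$mirna_id)]
  }
  if (anyDuplicated(clinical$case_id))
    rownames(expr) <- paste(clinical$case_id, clinical$file_id, sep = ":")
  mirna_cohort(expr, clinical$stage, clinical$sample_type)
}

#' Apply the study's sample exclusions
#'
#' Retains exactly the tissue samples whose stage is normal or 1-4: Stage X
#' samples and blood-derived samples are removed (blood shows the same miRNA
#' composition in cancer and normal tissue and is uninformative for staging).
#' Relative sample order is preserved; the operation is idempotent.
#'
#' @param cohort a `mirna_cohort`.
#' @return the filtered `mirna_cohort` (possibly with zero samples).
#' @export
filter_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mirna_cohort"))
  keep <- cohort$sample_type == "tissue" &
    cohort$stage %in% c("normal", TUMOR_STAGES)
  cohort[which(keep)]
}

#' Write / read a cohort as plain-text files
#'
#' The expression matrix is a TSV whose first column is the sample id and whose
#' remaining header names are miRNA ids; cells are rpm values at full
#' precision. Labels live in a sidecar TSV (`sample_id`, `stage`,
#' `sample_type`). `read_cohort(write_cohort(c))` is an identity.
#'
#' @param cohort a `mirna_cohort`.
#' @param expr_path path of the expression TSV.
#' @param labels_path path of the labels TSV.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` returns a
#'   `mirna_cohort`.
#' @export
write_cohort <- function(cohort, expr_path, labels_path) {
  stopifnot(inherits(cohort, "mirna_cohort"))
  expr <- cohort$expr
  df <- data.frame(sample_id = if (is.null(rownames(expr))) character(0)
                               else rownames(expr),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(expr))) df[[colnames(expr)[j]]] <- sprintf("%.17g", expr[, j])
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  lab <- data.frame(sample_id = if (is.null(rownames(expr))) character(0)
                                else rownames(expr),
                    stage = as.character(cohort$stage),
                    sample_type = as.character(cohort$sample_type))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(c(expr_path, labels_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(expr_path, labels_path) {
  df <- utils::read.delim(expr_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 || names(df)[1] != "sample_id") {
    if (names(df)[1] != "sample_id")
      stop("format error: expression file must start with a sample_id column")
  }
  lab <- utils::read.delim(labels_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!identical(sort(names(lab)), sort(c("sample_id", "stage", "sample_type"))))
    stop("format error: labels file needs sample_id, stage, sample_type")
  if (!identical(as.character(df$sample_id), as.character(lab$sample_id)))
    stop("format error: sample ids differ between expression and labels files")
  expr <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(expr) > 0 && any(!is.finite(expr)))
    stop("validation error: non-numeric or non-finite expression value")
  storage.mode(expr) <- "double"
  rownames(expr) <- df$sample_id
  mirna_cohort(expr, lab$stage, lab$sample_type)
}

#' Export a cohort as per-sample quantification files plus clinical JSON
#'
#' Writes one GDC-style quantification TSV per sample (miRNA_ID, read_count,
#' reads_per_million_miRNA_mapped; read counts are derived from rpm by
#' rounding at a nominal library size) and a flat clinical JSON array, i.e.
#' the input layout [assemble_cohort()] consumes.
#'
#' @param cohort a `mirna_cohort`.
#' @param dir output directory (created if needed).
#' @param library_size nominal miRNA-mapped reads per sample used to derive
#'   integer read counts from rpm.
#' @return invisibly, the clinical JSON path.
#' @export
export_cohort_files <- function(cohort, dir, library_size = 1e6) {
  stopifnot(inherits(cohort, "mirna_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(cohort$expr)
  file_ids <- paste0("file-", seq_along(ids))
  for (i in seq_along(ids)) {
    q <- data.frame(miRNA_ID = colnames(cohort$expr),
                    read_count = as.integer(round(cohort$expr[i, ] * library_size / 1e6)),
                    reads_per_million_miRNA_mapped = sprintf("%.17g", cohort$expr[i, ]))
    utils::write.table(q, file.path(dir, paste0(file_ids[i], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  clin <- data.frame(case_id = ids, file_id = file_ids,
                     stage = as.character(cohort$stage),
                     sample_type = as.character(cohort$sample_type))
  path <- file.path(dir, "clinical.json")
  jsonlite::write_json(clin, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
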