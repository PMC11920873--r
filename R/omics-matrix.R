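#' Construct a molecule-by-sample omics matrix
#'
#' The central container of the package: a complete, log-scale signal matrix
#' whose rows are molecules (genes, histone-signal genes, metabolites) and
#' whose columns are timed samples. Columns are kept in ascending time order.
#'
#' @param values Numeric matrix, molecules in rows, samples in columns.
#' @param molecule_ids Character vector of unique row identifiers.
#' @param sample_ids Character vector of unique column identifiers.
#' @param sample_times Numeric vector of collection times in hours, one per
#'   sample; after construction they are strictly increasing.
#' @param omics_label Single string naming the dataset (e.g. "transcriptome",
#'   "H3K9ac", "metabolome").
#' @param provenance List of processing flags carried through the pipeline
#'   (log transform applied, normalization method, dropped molecules).
#'
#' @return An object of class `omics_matrix`: a list with elements `values`
#'   (matrix with dimnames), `sample_times`, `omics_label` and `provenance`.
#' @export
omics_matrix <- function(values, molecule_ids = rownames(values),
                         sample_ids = colnames(values), sample_times,
                         omics_label = "omics", provenance = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(molecule_ids) || is.null(sample_ids))
    stop("molecule_ids and sample_ids are required")
  molecule_ids <- as.character(molecule_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(molecule_ids))
    stop("duplicate molecule ids: ",
         paste(unique(molecule_ids[duplicated(molecule_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(values) != length(molecule_ids) || ncol(values) != length(sample_ids))
    stop("dimension mismatch between values and ids")
  if (length(sample_times) != ncol(values))
    stop("sample_times must have one entry per sample")
  if (nrow(values) < 2L) stop("need at least 2 molecules")
  if (ncol(values) < 3L) stop("need at least 3 samples")
  if (any(!is.finite(values)))
    stop("non-finite values in matrix; drop or repair before construction")
  sample_times <- as.numeric(sample_times)
  ord <- order(sample_times)
  values <- values[, ord, drop = FALSE]
  sample_ids <- sample_ids[ord]
  sample_times <- sample_times[ord]
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing (ties not allowed)")
  dimnames(values) <- list(molecule_ids, sample_ids)
  structure(
    list(values = values, sample_times = sample_times,
         omics_label = as.character(omics_label)[1], provenance = provenance),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d molecules x %d samples, t = [%g, %g] h\n",
              x$omics_label, nrow(x$values), ncol(x$values),
              min(x$sample_times), max(x$sample_times)))
  if (isTRUE(x$provenance$log_transformed)) cat("  log2-transformed\n")
  if (!is.null(x$provenance$normalization))
    cat("  normalized:", x$provenance$normalization, "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

molecule_ids <- function(mat) rownames(mat$values)
sample_ids <- function(mat) colnames(mat$values)

#' Read an omics table and its sample metadata
#'
#' The table is TSV/CSV with a header row of sample ids and the first column
#' holding molecule ids. Metadata maps each sample id to a collection time in
#' hours (columns `sample_id`, `time_h`, optionally `dataset_label`).
#' Columns are reordered by ascending time; molecules with any missing value
#' are dropped and recorded in the provenance.
#'
#' @param path Path to the matrix file.
#' @param meta_path Path to the metadata file.
#' @param omics_label Dataset label; defaults to the metadata's
#'   `dataset_label` when present, else the file name.
#' @param sep Field separator; `NULL` guesses from the file extension
#'   (".csv" means comma, otherwise tab).
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, meta_path, omics_label = NULL, sep = NULL) {
  read_any <- function(p) {
    s <- if (is.null(sep)) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t" else sep
    utils::read.table(p, header = TRUE, sep = s, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  }
  tab <- read_any(path)
  meta <- read_any(meta_path)
  if (!all(c("sample_id", "time_h") %in% names(meta)))
    stop("metadata must have columns sample_id and time_h")
  mol <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  sids <- colnames(vals)
  missing_meta <- setdiff(sids, as.character(meta$sample_id))
  if (length(missing_meta))
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  times <- meta$time_h[match(sids, meta$sample_id)]
  complete <- stats::complete.cases(vals)
  dropped <- mol[!complete]
  vals <- vals[complete, , drop = FALSE]
  mol <- mol[complete]
  if (ncol(vals) < 3L) stop("fewer than 3 complete samples")
  if (is.null(omics_label)) {
    omics_label <- if ("dataset_label" %in% names(meta))
      as.character(meta$dataset_label[1]) else basename(path)
  }
  if (length(dropped))
    message(length(dropped), " molecule(s) dropped for missing values: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  omics_matrix(vals, mol, sids, times, omics_label,
               provenance = list(dropped_molecules = dropped))
}

#' Write an omics matrix and its metadata to TSV
#'
#' @param mat An [omics_matrix()].
#' @param path Matrix output path (TSV, first column `molecule_id`).
#' @param meta_path Metadata output path (columns `sample_id`, `time_h`,
#'   `dataset_label`).
#' @return Invisibly, `mat`.
#' @export
write_omics_table <- function(mat, path, meta_path) {
  df <- data.frame(molecule_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(mat$values),
                     time_h = mat$sample_times,
                     dataset_label = mat$omics_label)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}

#' Construct an indicator curve (e.g. dissolved oxygen vs time)
#'
#' @param times Strictly increasing numeric times in hours (length >= 4).
#' @param values Numeric concentrations (arbitrary units), same length.
#' @param dataset_label Single string naming the source dataset.
#' @return An object of class `indicator_curve`.
#' @export
indicator_curve <- function(times, values, dataset_label = "curve") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (length(times) < 4L) stop("need at least 4 points")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("non-finite entries in curve")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values,
                 dataset_label = as.character(dataset_label)[1]),
            class = "indicator_curve")
}

#' @export
print.indicator_curve <- function(x, ...) {
  cat(sprintf("<indicator_curve> %s: %d points, t = [%g, %g] h\n",
              x$dataset_label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read a two-column indicator curve (time_h, value)
#'
#' @param path TSV path with columns `time_h` and `value` (header required).
#' @param dataset_label Label for the curve; default the file name.
#' @return An [indicator_curve()].
#' @export
read_curve <- function(path, dataset_label = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  indicator_curve(tab[[1]], tab[[2]], dataset_label)
}

#' Write an indicator curve to TSV
#' @param curve An [indicator_curve()].
#' @param path Output path.
#' @return Invisibly, `curve`.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(data.frame(time_h = curve$times, value = curve$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curve)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(sets)
}
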