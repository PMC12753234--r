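#' Construct a protein-by-sample quantification matrix
#'
#' A `quant_matrix` is the package's basic container: a numeric matrix of
#' log-scale, reference-normalized protein quantifications with proteins as
#' rows and mass-spectrometry samples as columns. Missing quantifications are
#' coded as `NA` (and only as `NA`; zeros are treated as observed values).
#' Each sample optionally carries a dataset label recording which cohort or
#' acquisition it came from.
#'
#' @param values Numeric matrix with unique row names (protein IDs) and unique
#'   column names (sample IDs). `NA`/`NaN` entries denote missing values.
#' @param dataset_of_sample Optional character vector of per-sample dataset
#'   labels, length `ncol(values)`. Defaults to a single unnamed label.
#'
#' @return An object of class `quant_matrix`: a list with elements `values`
#'   (the matrix, `NaN` normalised to `NA`) and `dataset` (character vector
#'   named by sample ID).
#' @export
#' @examples
#' m <- matrix(c(10.2, NA, 11.5, 9.8), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("S1", "S2")))
#' qm <- quant_matrix(m)
#' n_missing(qm)
quant_matrix <- function(values, dataset_of_sample = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  pids <- rownames(values)
  sids <- colnames(values)
  if (nrow(values) > 0 && is.null(pids)) stop("`values` must have protein IDs as row names")
  if (ncol(values) > 0 && is.null(sids)) stop("`values` must have sample IDs as column names")
  if (anyDuplicated(pids)) {
    stop("duplicate protein ID: ", pids[duplicated(pids)][1L])
  }
  if (anyDuplicated(sids)) {
    stop("duplicate sample ID: ", sids[duplicated(sids)][1L])
  }
  storage.mode(values) <- "double"
  values[is.nan(values)] <- NA_real_
  if (is.null(dataset_of_sample)) {
    dataset_of_sample <- rep("dataset1", ncol(values))
  }
  if (length(dataset_of_sample) != ncol(values)) {
    stop("`dataset_of_sample` must have one label per sample")
  }
  dataset_of_sample <- as.character(dataset_of_sample)
  names(dataset_of_sample) <- sids
  structure(list(values = values, dataset = dataset_of_sample),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  v <- x$values
  miss <- if (length(v) > 0) mean(is.na(v)) else 0
  cat(sprintf("quant_matrix: %d proteins x %d samples (%.1f%% missing, %d dataset%s)\n",
              nrow(v), ncol(v), 100 * miss,
              length(unique(x$dataset)),
              if (length(unique(x$dataset)) == 1) "" else "s"))
  invisible(x)
}

#' @rdname quant_matrix
#' @param x A `quant_matrix`.
#' @export
protein_ids <- function(x) rownames(x$values)

#' @rdname quant_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname quant_matrix
#' @export
n_missing <- function(x) sum(is.na(x$values))

stopifnot_quant_matrix <- function(x) {
  if (!inherits(x, "quant_matrix")) stop("expected a `quant_matrix`")
  invisible(x)
}

#' Read a quantification matrix from a wide TSV file
#'
#' Expects a tab-separated file whose first column holds protein IDs and whose
#' header row holds sample IDs. Empty cells, `"NA"`, and `"NaN"` all parse to
#' missing values.
#'
#' @param path Path to a tab-separated file.
#' @param dataset_label Dataset label assigned to every sample in the file.
#' @return A [quant_matrix].
#' @export
read_quant_matrix <- function(path, dataset_label = "dataset1") {
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(nf) == 0) stop("empty file: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0) {
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = c("", "NA", "NaN"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  pids <- df[[1L]]
  if (anyDuplicated(pids)) {
    stop("duplicate protein ID in ", path, ": ", pids[duplicated(pids)][1L])
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- pids
  quant_matrix(vals, rep(dataset_label, ncol(vals)))
}

#' Write a quantification matrix to a wide TSV file
#'
#' Values are written with full decimal precision (`%.17g`) so that reading
#' the file back with [read_quant_matrix()] reproduces the matrix exactly.
#' Missing entries are written as `NA`.
#'
#' @param X A [quant_matrix].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_quant_matrix <- function(X, path) {
  stopifnot_quant_matrix(X)
  v <- X$values
  chr <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  chr[is.na(v)] <- "NA"
  header <- paste(c("protein", colnames(v)), collapse = "\t")
  body <- if (nrow(v) > 0) {
    paste(rownames(v), apply(chr, 1L, paste, collapse = "\t"),
          sep = if (ncol(v) > 0) "\t" else "")
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Default sample-exclusion keywords
#'
#' Sample IDs containing any of these substrings are reference channels,
#' quality-control runs, or pooled samples rather than biological samples, and
#' are dropped before model fitting.
#'
#' @return Character vector of keywords.
#' @export
default_exclude_keywords <- function() {
  c("RefInt", "QC", "pool", "pooled", "reference", "NCI", "NX", "ref")
}

#' Drop samples whose IDs contain any of a set of keywords
#'
#' Matching is case-sensitive substring matching (fixed strings, no regular
#' expressions), so the keyword `"ref"` drops a sample named `"myrefchan"`.
#'
#' @param X A [quant_matrix].
#' @param keywords Character vector of substrings; defaults to
#'   [default_exclude_keywords()]. An empty vector drops nothing.
#' @return A [quant_matrix] restricted to the surviving samples. Values of
#'   retained columns are untouched. Dropping every sample is allowed.
#' @export
exclude_samples_by_keyword <- function(X, keywords = default_exclude_keywords()) {
  stopifnot_quant_matrix(X)
  sids <- sample_ids(X)
  hit <- rep(FALSE, length(sids))
  for (kw in keywords) {
    hit <- hit | grepl(kw, sids, fixed = TRUE)
  }
  keep <- !hit
  quant_matrix(X$values[, keep, drop = FALSE], X$dataset[keep])
}

#' Outer-join several quantification matrices into one joint matrix
#'
#' Rows of the joint matrix are the union of all protein IDs (sorted
#' lexicographically for determinism); columns are the concatenation of all
#' samples. Where a protein was not quantified in a contributing dataset, the
#' entry is missing. Proteins quantified in fewer than `min_present` samples
#' across the joint matrix are removed.
#'
#' @param datasets List of [quant_matrix] objects with globally unique sample
#'   IDs.
#' @param min_present Minimum number of present values a protein must have to
#'   be kept (default 18).
#' @return A [quant_matrix] whose `dataset` field records each sample's
#'   source.
#' @export
build_joint_matrix <- function(datasets, min_present = 18) {
  if (length(datasets) < 1) stop("at least one dataset is required")
  lapply(datasets, stopifnot_quant_matrix)
  all_sids <- unlist(lapply(datasets, sample_ids), use.names = FALSE)
  if (anyDuplicated(all_sids)) {
    stop("duplicate sample ID across datasets: ",
         all_sids[duplicated(all_sids)][1L])
  }
  all_pids <- sort(unique(unlist(lapply(datasets, protein_ids), use.names = FALSE)))
  joint <- matrix(NA_real_, length(all_pids), length(all_sids),
                  dimnames = list(all_pids, all_sids))
  dataset <- character(0)
  for (d in datasets) {
    joint[protein_ids(d), sample_ids(d)] <- d$values
    dataset <- c(dataset, d$dataset)
  }
  out <- quant_matrix(joint, dataset)
  filter_min_present(out, min_present)
}

#' Remove proteins with too few present values
#'
#' When a `partition_mask` is supplied, only entries labelled `train` count as
#' present; this matches benchmark practice where proteins with sparse
#' training data are removed from both the training and test views. Setting
#' `k = 0` is the identity, and the operation is idempotent.
#'
#' @param X A [quant_matrix].
#' @param k Minimum number of counted present values (non-negative integer).
#' @param mask Optional `partition_mask` aligned to `X`; if supplied, counting
#'   is restricted to train-labelled entries and the mask is subset
#'   consistently with the matrix.
#' @return If `mask` is `NULL`, the filtered [quant_matrix]; otherwise a list
#'   with elements `X` and `mask`, both restricted to surviving proteins.
#' @export
filter_min_present <- function(X, k, mask = NULL) {
  stopifnot_quant_matrix(X)
  if (k < 0) stop("`k` must be non-negative")
  if (is.null(mask)) {
    counts <- rowSums(!is.na(X$values))
    keep <- counts >= k
    return(quant_matrix(X$values[keep, , drop = FALSE], X$dataset))
  }
  stopifnot_partition_mask(mask, X)
  counts <- rowSums(mask$labels == 1L, na.rm = TRUE)
  keep <- counts >= k
  Xf <- quant_matrix(X$values[keep, , drop = FALSE], X$dataset)
  mf <- mask
  mf$labels <- mask$labels[keep, , drop = FALSE]
  list(X = Xf, mask = mf)
}
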