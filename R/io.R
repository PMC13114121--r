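#' Read a sample-by-feature abundance table
#'
#' Reads a tab-separated abundance table (RPKM units) into a tibble. The
#' first column of the file holds sample identifiers; the header row holds
#' feature (contig) identifiers. Row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `sample_id` and whose remaining
#'   columns are numeric, non-negative feature values.
#' @export
read_abundance_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE,
                   colClasses = NA, na.strings = character())
  if (ncol(df) < 1) abort("abundance file has no columns")
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (nrow(df) == 0) df[-1] <- lapply(df[-1], as.numeric)
  ab <- tibble::as_tibble(df, .name_repair = "minimal")
  validate_abundance(ab)
  ab
}

#' Write an abundance table to TSV
#'
#' Values are written with shortest round-trip float formatting so that
#' `read_abundance_tsv()` recovers the numbers exactly.
#'
#' @param ab Abundance tibble (`sample_id` + numeric feature columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(ab, path) {
  validate_abundance(ab)
  readr::write_tsv(ab, path)
  invisible(path)
}

validate_abundance <- function(ab, nonnegative = TRUE) {
  if (!is.data.frame(ab) || names(ab)[1] != "sample_id") {
    abort("abundance table must have `sample_id` as its first column")
  }
  feats <- names(ab)[-1]
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    abort(paste0("duplicated feature id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (length(feats) && nrow(ab) > 0) {
    vals <- as.matrix(ab[, -1, drop = FALSE])
    if (!is.numeric(vals)) abort("abundance values must be numeric")
    if (anyNA(vals) || any(!is.finite(vals))) abort("abundance values must be finite (no missing entries)")
    if (nonnegative && any(vals < 0)) abort("abundance values must be non-negative")
  }
  invisible(ab)
}

#' Convert an abundance tibble to a numeric matrix
#'
#' @param ab Abundance tibble.
#' @return Numeric matrix with sample ids as row names.
#' @export
abundance_matrix <- function(ab) {
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$sample_id
  m
}

#' Build an abundance tibble from a matrix
#'
#' @param values Numeric matrix (samples in rows).
#' @param sample_ids,feature_ids Identifiers; default taken from dimnames.
#' @return Abundance tibble.
#' @export
as_abundance <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- NULL
  out <- tibble::as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(out) <- feature_ids
  out <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)), out)
  validate_abundance(out)
  out
}

#' Read / write a binary response label table
#'
#' Columns: `sample_id`, `response` (0 = non-responder, 1 = responder).
#'
#' @param path TSV path.
#' @return Tibble with `sample_id` (character) and `response` (integer 0/1).
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, fill = FALSE)
  if (!all(c("sample_id", "response") %in% names(df))) {
    abort("label file must have columns sample_id and response")
  }
  lab <- tibble::tibble(sample_id = as.character(df$sample_id),
                        response = as.integer(df$response))
  validate_labels(lab)
  lab
}

#' @rdname read_labels_tsv
#' @param labels Label tibble.
#' @export
write_labels_tsv <- function(labels, path) {
  validate_labels(labels)
  readr::write_tsv(labels[, c("sample_id", "response")], path)
  invisible(path)
}

validate_labels <- function(labels) {
  if (anyNA(labels$response) || !all(labels$response %in% c(0L, 1L))) {
    abort("response labels must be 0 or 1")
  }
  if (anyDuplicated(labels$sample_id)) abort("duplicated sample_id in labels")
  invisible(labels)
}

#' Read / write a protein-embedding prior matrix
#'
#' The prior is a fixed P x E table of protein embeddings (default width
#' E = 320); it conditions the latent space and is never updated during
#' training.
#'
#' @param path TSV path: first column `protein_id`, then E numeric columns.
#' @return Tibble with `protein_id` plus numeric embedding columns.
#' @export
read_prior_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE)
  names(df)[1] <- "protein_id"
  df$protein_id <- as.character(df$protein_id)
  pr <- tibble::as_tibble(df)
  validate_prior(pr)
  pr
}

#' @rdname read_prior_tsv
#' @param prior Prior tibble.
#' @export
write_prior_tsv <- function(prior, path) {
  validate_prior(prior)
  readr::write_tsv(prior, path)
  invisible(path)
}

validate_prior <- function(prior) {
  if (!is.data.frame(prior) || names(prior)[1] != "protein_id") {
    abort("prior table must have `protein_id` as its first column")
  }
  if (ncol(prior) < 2) abort("prior table needs at least one embedding column")
  vals <- as.matrix(prior[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    abort("prior embeddings must be finite numerics")
  }
  invisible(prior)
}

#' @rdname read_prior_tsv
#' @export
prior_matrix <- function(prior) {
  m <- as.matrix(prior[, -1, drop = FALSE])
  rownames(m) <- prior$protein_id
  m
}

#' Read / write a taxonomic annotation table
#'
#' GTDB-style per-contig annotations: columns `feature_id`, `family`,
#' `family_conf`, `genus`, `genus_conf`. The literal string `"null"` in the
#' file denotes a missing name or confidence and maps to `NA`.
#'
#' @param path TSV path.
#' @return Tibble with one row per feature id.
#' @export
read_annotations_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   fill = FALSE, na.strings = "null")
  need <- c("feature_id", "family", "family_conf", "genus", "genus_conf")
  if (!all(need %in% names(df))) {
    abort(paste0("annotation file must have columns: ", paste(need, collapse = ", ")))
  }
  ann <- tibble::as_tibble(df[need])
  ann$feature_id <- as.character(ann$feature_id)
  ann$family <- as.character(ann$family)
  ann$genus <- as.character(ann$genus)
  ann$family_conf <- as.numeric(ann$family_conf)
  ann$genus_conf <- as.numeric(ann$genus_conf)
  validate_annotations(ann)
  ann
}

#' @rdname read_annotations_tsv
#' @param annotations Annotation tibble.
#' @export
write_annotations_tsv <- function(annotations, path) {
  validate_annotations(annotations)
  out <- annotations
  out$family <- ifelse(is.na(out$family), "null", out$family)
  out$genus <- ifelse(is.na(out$genus), "null", out$genus)
  out$family_conf <- ifelse(is.na(out$family_conf), "null",
                            format(out$family_conf, trim = TRUE))
  out$genus_conf <- ifelse(is.na(out$genus_conf), "null",
                           format(out$genus_conf, trim = TRUE))
  readr::write_tsv(out, path)
  invisible(path)
}

validate_annotations <- function(annotations) {
  if (anyDuplicated(annotations$feature_id)) abort("duplicated feature_id in annotations")
  cf <- c(annotations$family_conf, annotations$genus_conf)
  cf <- cf[!is.na(cf)]
  if (length(cf) && (any(cf < 0) || any(cf > 1))) {
    abort("annotation confidences must lie in [0, 1]")
  }
  invisible(annotations)
}

#' Align an abundance table to a fixed reference feature set
#'
#' Cross-cohort models require a shared feature space: every cohort is
#' projected onto the reference contig set. Features absent from the cohort
#' are filled with 0 RPKM; features absent from the reference are dropped.
#' The counts of dropped/filled features are reported via [rlang::inform()]
#' and attached as attributes `dropped` and `filled`.
#'
#' @param ab Abundance tibble.
#' @param reference_feature_ids Character vector of unique feature ids
#'   defining the output column set and order.
#' @return Abundance tibble with columns `sample_id` +
#'   `reference_feature_ids`, in that order.
#' @export
align_to_reference <- function(ab, reference_feature_ids) {
  if (anyDuplicated(reference_feature_ids)) abort("reference feature ids must be unique")
  validate_abundance(ab)
  feats <- names(ab)[-1]
  missing <- setdiff(reference_feature_ids, feats)
  dropped <- setdiff(feats, reference_feature_ids)
  out <- ab[, c("sample_id", intersect(reference_feature_ids, feats)), drop = FALSE]
  if (length(missing)) {
    fill <- tibble::as_tibble(matrix(0, nrow(ab), length(missing)),
                              .name_repair = "minimal")
    names(fill) <- missing
    out <- dplyr::bind_cols(out, fill)
  }
  out <- out[, c("sample_id", reference_feature_ids), drop = FALSE]
  inform(sprintf("align_to_reference: dropped %d feature(s), filled %d with 0",
                 length(dropped), length(missing)))
  attr(out, "dropped") <- length(dropped)
  attr(out, "filled") <- length(missing)
  out
}

#' Fit a per-feature z-score scaler
#'
#' Standardization is fitted on one matrix (by default the training fold
#' only, to avoid leakage into validation data) and applied elsewhere.
#' The default uses the population standard deviation (divide by n);
#' `convention = "sample"` divides by n - 1. Zero-variance features map to
#' 0 when the scaler is applied, so the feature count (and hence the model
#' input width) is preserved.
#'
#' @param ab Abundance tibble with at least two samples.
#' @param convention `"population"` (default) or `"sample"` SD.
#' @return An object of class `pvae_scaler`.
#' @export
fit_scaler <- function(ab, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  validate_abundance(ab)
  x <- abundance_matrix(ab)
  if (nrow(x) < 2) abort("fit_scaler needs at least 2 samples")
  ctr <- colMeans(x)
  v <- colMeans(x^2) - ctr^2
  v[v < 0] <- 0  # guard tiny negative from cancellation
  if (convention == "sample") v <- v * nrow(x) / (nrow(x) - 1)
  structure(list(feature_ids = colnames(x), center = ctr, scale = sqrt(v),
                 convention = convention),
            class = "pvae_scaler")
}

#' Apply a fitted z-score scaler
#'
#' @param ab Abundance tibble whose feature columns match the scaler.
#' @param scaler A `pvae_scaler` from [fit_scaler()].
#' @return Standardized abundance-shaped tibble (values may be negative).
#' @export
apply_scaler <- function(ab, scaler) {
  stopifnot(inherits(scaler, "pvae_scaler"))
  feats <- names(ab)[-1]
  if (!identical(feats, scaler$feature_ids)) {
    if (length(feats) != length(scaler$feature_ids) || !setequal(feats, scaler$feature_ids)) {
      abort("feature columns do not match the fitted scaler")
    }
    ab <- ab[, c("sample_id", scaler$feature_ids), drop = FALSE]
  }
  x <- as.matrix(ab[, -1, drop = FALSE])
  s <- scaler$scale
  nz <- s > 0
  x <- sweep(x, 2, scaler$center, "-")
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, s[nz], "/")
  x[, !nz] <- 0
  out <- ab
  out[, -1] <- x
  out
}

#' @export
print.pvae_scaler <- function(x, ...) {
  cat(sprintf("<pvae_scaler> %d features, %s SD convention (%d zero-variance)\n",
              length(x$feature_ids), x$convention, sum(x$scale == 0)))
  invisible(x)
}

# Inner-join abundance and labels on sample_id (never positional), keeping
# the abundance row order.
join_cohort <- function(ab, labels) {
  validate_abundance(ab, nonnegative = FALSE)
  validate_labels(labels)
  keep <- ab$sample_id %in% labels$sample_id
  if (!all(keep)) {
    inform(sprintf("dropping %d sample(s) without labels", sum(!keep)))
  }
  ab <- ab[keep, , drop = FALSE]
  y <- labels$response[match(ab$sample_id, labels$sample_id)]
  list(abundance = ab, labels = tibble::tibble(sample_id = ab$sample_id, response = y))
}
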