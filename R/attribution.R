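#' Integrated-gradients attribution for one sample
#'
#' Attributes the predicted positive-class probability `F(x)` to input
#' features along the straight-line path from `baseline` to `x`:
#' `attr_j = (x_j - baseline_j) * mean_t dF/dx_j(baseline + t (x -
#' baseline))`, with the path integral approximated by the midpoint rule
#' over `steps` points. Satisfies completeness: the attributions sum to
#' `F(x) - F(baseline)` (within 1% relative at `steps >= 200`). The
#' default baseline is the all-zero vector in standardized space, i.e. the
#' per-feature training mean in raw space.
#'
#' @param model A trained `pvae_model`, or a list with elements `value`
#'   (function of one input row) and `gradient` (its gradient function)
#'   for custom scorers.
#' @param x Single standardized sample: numeric vector of length M.
#' @param baseline Baseline vector (default all zeros).
#' @param steps Path resolution (default 50; use 200 for tight
#'   completeness checks).
#' @param ... Unused.
#' @return Numeric vector of per-feature attributions, named by feature
#'   when the model carries feature ids.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 50, ...) {
  UseMethod("integrated_gradients")
}

#' @export
integrated_gradients.pvae_model <- function(model, x, baseline = NULL,
                                            steps = 50, ...) {
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  stopifnot(length(baseline) == length(x), steps >= 1)
  tgrid <- (seq_len(steps) - 0.5) / steps
  path <- outer(tgrid, x - baseline) + matrix(baseline, steps, length(x), byrow = TRUE)
  grads <- pvae_input_gradient(model, path)
  if (any(!is.finite(grads))) abort("non-finite gradient along the attribution path")
  out <- (x - baseline) * colMeans(grads)
  if (!is.null(model$feature_ids)) names(out) <- model$feature_ids
  out
}

#' @export
integrated_gradients.default <- function(model, x, baseline = NULL,
                                         steps = 50, ...) {
  stopifnot(is.list(model), is.function(model$gradient))
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  tgrid <- (seq_len(steps) - 0.5) / steps
  gsum <- numeric(length(x))
  for (t in tgrid) gsum <- gsum + model$gradient(baseline + t * (x - baseline))
  (x - baseline) * gsum / steps
}

# Evaluation-mode probability for a matrix of standardized samples.
pvae_prob <- function(model, x) {
  pvae_classify(model, pvae_encode(model, x, training = FALSE), training = FALSE)
}

#' Cross-validated attribution table
#'
#' Computes integrated gradients for every *correctly predicted*
#' validation sample (thresholded at 0.5) of every fold of a [run_cv()]
#' result, then averages the per-feature attributions separately within
#' predicted responders and predicted non-responders, pooled across folds.
#' Both groups attribute the same output — the positive-class probability —
#' so non-responder attributions typically carry mixed signs.
#'
#' @param cv A `pvae_cv` from [run_cv()] with `keep_models = TRUE`.
#' @param ab The raw abundance tibble the run was made from.
#' @param steps Integrated-gradients path resolution (default 50).
#' @return Tibble of class `pvae_attribution`: `feature_id`,
#'   `mean_ig_responder`, `n_responder`, `mean_ig_nonresponder`,
#'   `n_nonresponder`. A group with no correctly predicted samples gets
#'   `NA` scores (reported via a message).
#' @export
attribute_cv <- function(cv, ab, steps = 50) {
  stopifnot(inherits(cv, "pvae_cv"))
  if (is.null(cv$fits[[1]]$model)) abort("run_cv must be called with keep_models = TRUE")
  acc <- list()  # per-fold per-group sums
  for (fit in cv$fits) {
    f <- fit$fold
    pred_f <- cv$predictions[cv$predictions$fold == f, ]
    correct <- pred_f[(pred_f$prob >= 0.5) == (pred_f$truth == 1), ]
    if (nrow(correct) == 0) next
    ab_f <- ab[match(correct$sample_id, ab$sample_id), , drop = FALSE]
    if (!is.null(fit$selected)) ab_f <- ab_f[, c("sample_id", fit$selected), drop = FALSE]
    x_std <- abundance_matrix(apply_scaler(ab_f, fit$scaler))
    for (i in seq_len(nrow(correct))) {
      ig <- integrated_gradients(fit$model, x_std[i, ], steps = steps)
      grp <- if (correct$truth[i] == 1) "responder" else "nonresponder"
      key <- paste0(grp)
      if (is.null(acc[[key]])) acc[[key]] <- list(sum = setNames(numeric(0), character(0)), n = 0L)
      s <- acc[[key]]$sum
      ids <- union(names(s), names(ig))
      s2 <- setNames(numeric(length(ids)), ids)
      s2[names(s)] <- s
      s2[names(ig)] <- s2[names(ig)] + ig
      acc[[key]] <- list(sum = s2, n = acc[[key]]$n + 1L)
    }
  }
  all_features <- names(ab)[-1]
  col_for <- function(grp) {
    if (is.null(acc[[grp]])) {
      inform(sprintf("no correctly predicted %s sample; attribution column is NA", grp))
      return(list(mean = rep(NA_real_, length(all_features)), n = 0L))
    }
    m <- setNames(rep(NA_real_, length(all_features)), all_features)
    s <- acc[[grp]]$sum / acc[[grp]]$n
    m[names(s)] <- s
    # features never selected in any fold carry no attribution; treat as 0
    # only when they were part of the model input, NA otherwise
    list(mean = unname(m), n = acc[[grp]]$n)
  }
  r <- col_for("responder")
  nr <- col_for("nonresponder")
  out <- tibble::tibble(feature_id = all_features,
                        mean_ig_responder = r$mean, n_responder = r$n,
                        mean_ig_nonresponder = nr$mean, n_nonresponder = nr$n)
  class(out) <- c("pvae_attribution", class(out))
  out
}

#' Top-k features by absolute mean attribution
#'
#' @param attribution A `pvae_attribution` table.
#' @param group `"responder"` or `"nonresponder"`.
#' @param k Number of features (default 20).
#' @return Tibble `feature_id`, `mean_ig`, ordered by descending
#'   `abs(mean_ig)` with ties broken by ascending feature id.
#' @export
top_k_by_attribution <- function(attribution, group = c("responder", "nonresponder"),
                                 k = 20) {
  group <- match.arg(group)
  col <- paste0("mean_ig_", group)
  if (all(is.na(attribution[[col]]))) abort(sprintf("the %s column is all-NA", group))
  tb <- tibble::tibble(feature_id = attribution$feature_id,
                       mean_ig = attribution[[col]])
  tb <- tb[!is.na(tb$mean_ig), ]
  ord <- order(-abs(tb$mean_ig), tb$feature_id)
  tb[ord, ][seq_len(min(k, nrow(tb))), ]
}

#' GTDB-style display label for a feature
#'
#' Formats per-contig taxonomy as
#' `"FamilyName-confidence > GenusName-confidence"` with confidences to
#' two decimals; a missing name (or a fully unannotated contig) renders as
#' the literal `"null"`.
#'
#' @param feature_id Character vector of feature ids.
#' @param annotations Annotation tibble (see [read_annotations_tsv()]).
#' @return Character vector of display labels.
#' @export
format_feature_label <- function(feature_id, annotations) {
  i <- match(feature_id, annotations$feature_id)
  side <- function(name, conf) {
    ifelse(is.na(name), "null",
           paste0(name, "-", ifelse(is.na(conf), "null", sprintf("%.2f", conf))))
  }
  fam <- side(annotations$family[i], annotations$family_conf[i])
  gen <- side(annotations$genus[i], annotations$genus_conf[i])
  paste0(fam, " > ", gen)
}

#' Aggregate attributions at a taxonomic level
#'
#' Sums per-feature mean attributions within each genus (or family);
#' unannotated features pool under `"null"`. The total over aggregates
#' equals the total over features (conservation).
#'
#' @param attribution A `pvae_attribution` table.
#' @param annotations Annotation tibble.
#' @param level `"genus"` or `"family"`.
#' @param group `"responder"` or `"nonresponder"`.
#' @return Tibble `taxon`, `cumulative_ig`, `n_features`, sorted by
#'   descending cumulative score.
#' @export
aggregate_by_taxon <- function(attribution, annotations,
                               level = c("genus", "family"),
                               group = c("responder", "nonresponder")) {
  level <- match.arg(level)
  group <- match.arg(group)
  col <- paste0("mean_ig_", group)
  i <- match(attribution$feature_id, annotations$feature_id)
  taxon <- annotations[[level]][i]
  taxon[is.na(taxon)] <- "null"
  tb <- tibble::tibble(taxon = taxon, ig = attribution[[col]])
  tb <- tb[!is.na(tb$ig), ]
  tb %>%
    dplyr::group_by(.data$taxon) %>%
    dplyr::summarise(cumulative_ig = sum(.data$ig), n_features = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$cumulative_ig))
}
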