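#' Parameterization of a synthetic cohort
#'
#' The generator emulates the statistical shape of gene-level RPKM tables:
#' sparse (zero-inflated), non-negative and heavy-tailed (log-normal), with
#' a planted subset of class-informative features whose log-mean is shifted
#' upward in responders. Defaults are the conditions used throughout the
#' package's property checks: n = 200 samples, M = 500 features, 20
#' planted features with a 2-SD log-scale effect, 60% zeros, balanced
#' classes.
#'
#' @param n Number of samples.
#' @param m Number of features.
#' @param p_prior Number of prior rows P (default 64).
#' @param e_dim Prior embedding width E (default 320).
#' @param k_inf Number of planted informative features.
#' @param delta Effect size in units of the within-class log-scale SD.
#' @param pi0 Zero-inflation probability in \[0, 1).
#' @param responder_fraction Fraction of responders in (0, 1); realized as
#'   an exact count so stratified folds are always well posed.
#' @param shift_scale SD of the per-cohort, per-feature log-mean shift used
#'   by [generate_multi_cohort()] to model cohort-level distribution shift.
#' @param seed Seed; every draw flows from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 200, m = 500, p_prior = 64, e_dim = 320,
                           k_inf = 20, delta = 2, pi0 = 0.6,
                           responder_fraction = 0.5, shift_scale = 0.5,
                           seed = 42) {
  if (k_inf > m) abort("k_inf must not exceed the feature count m")
  stopifnot(pi0 >= 0, pi0 < 1, responder_fraction > 0, responder_fraction < 1,
            delta >= 0, n >= 2, p_prior >= 1)
  structure(list(n = as.integer(n), m = as.integer(m),
                 p_prior = as.integer(p_prior), e_dim = as.integer(e_dim),
                 k_inf = as.integer(k_inf), delta = delta, pi0 = pi0,
                 responder_fraction = responder_fraction,
                 shift_scale = shift_scale, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic cohort
#'
#' Log-abundances are standard normal; planted features gain `+delta` on
#' the log scale in responders; abundances are `exp()` of these, masked to
#' zero with probability `pi0` independently of class. Features receive
#' synthetic family/genus annotations round-robin over ten genera in five
#' families, with the planted features concentrated in two "signal"
#' genera.
#'
#' @param spec A [synthetic_spec()].
#' @param cohort_shift Optional per-feature log-mean offset vector
#'   (length `m`) modeling cohort-level shift; default none.
#' @param planted Optional explicit planted feature indices (used by
#'   [generate_multi_cohort()]).
#' @return List with `abundance` (tibble), `labels` (tibble),
#'   `annotations` (tibble) and `planted` (character feature ids).
#' @export
generate_cohort <- function(spec, cohort_shift = NULL, planted = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n; m <- spec$m
  feature_ids <- sprintf("contig_%04d", seq_len(m))
  sample_ids <- sprintf("s%03d", seq_len(n))
  n_resp <- max(1L, min(n - 1L, round(n * spec$responder_fraction)))
  y <- sample(c(rep(1L, n_resp), rep(0L, n - n_resp)))
  if (is.null(planted)) planted <- seq_len(spec$k_inf)
  logab <- matrix(rnorm(n * m), n, m)
  if (length(planted)) {
    logab[y == 1, planted] <- logab[y == 1, planted] + spec$delta
  }
  if (!is.null(cohort_shift)) logab <- sweep(logab, 2, cohort_shift, "+")
  ab <- exp(logab)
  if (spec$pi0 > 0) {
    mask <- matrix(runif(n * m) < spec$pi0, n, m)
    ab[mask] <- 0
  }
  annotations <- synth_annotations(feature_ids, planted)
  list(abundance = as_abundance(ab, sample_ids, feature_ids),
       labels = tibble::tibble(sample_id = sample_ids, response = y),
       annotations = annotations,
       planted = feature_ids[planted])
}

# Round-robin synthetic taxonomy: ten genera in five families; planted
# features concentrated in the two signal genera; a sprinkle of
# unannotated contigs mimics GTDB classification failures.
synth_annotations <- function(feature_ids, planted) {
  m <- length(feature_ids)
  genera <- sprintf("Genus%02d", 1:10)
  families <- sprintf("Family%02d", rep(1:5, each = 2))
  gi <- rep_len(3:10, m)  # background features rotate over genera 3..10
  gi[planted] <- rep_len(1:2, length(planted))  # signal genera
  fam <- families[gi]
  gen <- genera[gi]
  fam_conf <- round(runif(m, 0.7, 1), 2)
  gen_conf <- round(pmin(fam_conf, runif(m, 0.6, 1)), 2)
  unann <- seq_len(m) %% 20 == 0  # every 20th contig unclassified
  fam[unann] <- NA; gen[unann] <- NA
  fam_conf[unann] <- NA; gen_conf[unann] <- NA
  tibble::tibble(feature_id = feature_ids, family = fam,
                 family_conf = fam_conf, genus = gen, genus_conf = gen_conf)
}

#' Generate a synthetic protein-embedding prior
#'
#' Standard-normal P x E matrix, a synthetic stand-in for protein-language-
#' model embeddings. It carries no injected label signal: the model must
#' learn to use or ignore it.
#'
#' @param spec A [synthetic_spec()].
#' @return Prior tibble (`protein_id` + `e1..eE` columns).
#' @export
generate_prior <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  vals <- matrix(rnorm(spec$p_prior * spec$e_dim), spec$p_prior, spec$e_dim)
  out <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
  names(out) <- paste0("e", seq_len(spec$e_dim))
  dplyr::bind_cols(tibble::tibble(protein_id = sprintf("prot_%04d", seq_len(spec$p_prior))),
                   out)
}

#' Generate multiple cohorts over a shared feature space
#'
#' With `shared_signal = TRUE` every cohort plants the same feature set
#' with the same effect direction, plus an independent per-cohort,
#' per-feature log-mean shift of SD `shift_scale` (multiplicative in
#' abundance) modeling cross-cohort distribution shift. With
#' `shared_signal = FALSE` the planted sets are pairwise disjoint.
#'
#' @param spec A [synthetic_spec()].
#' @param n_cohorts Number of cohorts (>= 2).
#' @param shared_signal Share the planted set across cohorts?
#' @return Named list of cohorts as returned by [generate_cohort()].
#' @export
generate_multi_cohort <- function(spec, n_cohorts = 2, shared_signal = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"), n_cohorts >= 2)
  if (!shared_signal && n_cohorts * spec$k_inf > spec$m) {
    abort("disjoint planted sets need n_cohorts * k_inf <= m")
  }
  out <- vector("list", n_cohorts)
  names(out) <- sprintf("cohort_%d", seq_len(n_cohorts))
  for (i in seq_len(n_cohorts)) {
    planted <- if (shared_signal) seq_len(spec$k_inf)
      else ((i - 1) * spec$k_inf) + seq_len(spec$k_inf)
    set.seed(spec$seed + 100L * i)
    shift <- if (spec$shift_scale > 0) rnorm(spec$m, 0, spec$shift_scale) else NULL
    spec_i <- spec
    spec_i$seed <- spec$seed + 1000L * i
    out[[i]] <- generate_cohort(spec_i, cohort_shift = shift, planted = planted)
  }
  out
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `abundance.tsv`, `labels.tsv`, `annotations.tsv`, `prior.tsv`
#' and `planted.tsv` (the planted feature ids).
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param prior A prior tibble from [generate_prior()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, prior, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_tsv(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_labels_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  write_annotations_tsv(cohort$annotations, file.path(dir, "annotations.tsv"))
  write_prior_tsv(prior, file.path(dir, "prior.tsv"))
  readr::write_tsv(tibble::tibble(feature_id = cohort$planted),
                   file.path(dir, "planted.tsv"))
  invisible(dir)
}
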