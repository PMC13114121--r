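#' Read contig records from a FASTA file
#'
#' Parses contig ids and lengths from an assembly FASTA and, optionally,
#' joins a contig-to-bin assignment table (two-column TSV: `contig_id`,
#' `bin_id`). Sequences themselves are not retained; reference-set
#' construction only needs ids, lengths and bin membership.
#'
#' @param fasta_path Path to a (multi-)FASTA of contigs.
#' @param bin_path Optional path to a two-column TSV mapping contig to bin.
#' @return Tibble with `contig_id`, `length_bp` and (if provided) `bin_id`.
#' @export
read_contigs_fasta <- function(fasta_path, bin_path = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required to read FASTA files")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  contigs <- tibble::tibble(contig_id = ids, length_bp = Biostrings::width(seqs))
  if (!is.null(bin_path)) {
    bins <- read.delim(bin_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, fill = FALSE)
    names(bins)[1:2] <- c("contig_id", "bin_id")
    contigs <- dplyr::left_join(contigs,
                                tibble::tibble(contig_id = as.character(bins$contig_id),
                                               bin_id = as.character(bins$bin_id)),
                                by = "contig_id")
  }
  contigs
}

#' Drop contigs below a minimum length
#'
#' Short assembled fragments are removed before reference construction to
#' keep reference quality; the threshold is inclusive-keep, i.e. a contig of
#' exactly `min_len` bp is retained (only contigs strictly shorter are
#' removed).
#'
#' @param contigs Tibble with at least `contig_id` and `length_bp`.
#' @param min_len Minimum retained length in bp (default 500).
#' @return The input rows with `length_bp >= min_len`, order preserved.
#' @export
filter_short_contigs <- function(contigs, min_len = 500) {
  stopifnot(min_len >= 1)
  if (any(contigs$length_bp < 1)) abort("contig lengths must be positive")
  contigs[contigs$length_bp >= min_len, , drop = FALSE]
}

#' Select the top-k longest contigs per bin
#'
#' Builds a non-redundant reference set: within each bin, contigs are ranked
#' by length (descending, ties broken by ascending `contig_id` so reference
#' sets are deterministic across runs) and the top `k` are kept — all of
#' them when a bin holds fewer than `k`. `k = 1` yields one representative
#' contig per bin (used for protein-level prior construction); `k = 200`
#' yields the abundance reference database.
#'
#' @param contigs Length-filtered tibble with `contig_id`, `length_bp`,
#'   `bin_id`.
#' @param k Number of contigs retained per bin.
#' @return Tibble of class `pvae_refset` with `bin_id`, `contig_id`,
#'   `length_bp`, `rank` (1 = longest in bin), grouped by ascending
#'   `bin_id`.
#' @export
select_top_per_bin <- function(contigs, k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  if (!"bin_id" %in% names(contigs)) abort("contigs need a bin_id column")
  if (anyNA(contigs$bin_id)) abort("every contig must have a bin assignment")
  if (anyDuplicated(contigs$contig_id)) abort("duplicated contig ids")
  out <- contigs %>%
    dplyr::arrange(.data$bin_id, dplyr::desc(.data$length_bp), .data$contig_id) %>%
    dplyr::group_by(.data$bin_id) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::filter(.data$rank <= k) %>%
    dplyr::ungroup()
  out <- out[, c("bin_id", "contig_id", "length_bp", "rank")]
  class(out) <- c("pvae_refset", class(out))
  out
}

#' Reference feature ids of a reference set
#'
#' @param refset A `pvae_refset` from [select_top_per_bin()].
#' @return Character vector of contig ids in reference order.
#' @export
refset_feature_ids <- function(refset) refset$contig_id

#' Reads per kilobase per million mapped reads
#'
#' RPKM normalizes a per-contig mapped-read count by contig length (in
#' kilobases) and sequencing depth (total mapped reads, in millions):
#' `rpkm = count / ((length_bp / 1000) * (total_mapped_reads / 1e6))`.
#'
#' @param read_counts Non-negative per-contig read counts.
#' @param contig_lengths_bp Positive per-contig lengths in bp.
#' @param total_mapped_reads Total mapped reads in the sample (>= 1).
#' @return Numeric vector of RPKM values, same length as `read_counts`.
#' @export
compute_rpkm <- function(read_counts, contig_lengths_bp, total_mapped_reads) {
  if (length(read_counts) != length(contig_lengths_bp)) {
    abort("read_counts and contig_lengths_bp must have equal length")
  }
  if (any(contig_lengths_bp <= 0)) abort("contig lengths must be positive")
  if (length(total_mapped_reads) != 1 || total_mapped_reads < 1) {
    abort("total_mapped_reads must be a single value >= 1")
  }
  if (any(read_counts < 0)) abort("read counts must be non-negative")
  read_counts / ((contig_lengths_bp / 1000) * (total_mapped_reads / 1e6))
}
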