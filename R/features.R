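#' @importFrom stats setNames
NULL

# integer codes 1..20 (alphabetical) for one sequence; error on unknowns
seq_codes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  codes <- match(strsplit(sequence, "")[[1]], AA_ALPHABET20)
  if (anyNA(codes))
    stop("sequence contains non-standard residue letters")
  codes
}

# letter -> group index (1,2,3) lookup for one grouping
grouping_map <- function(grouping) {
  m <- integer(20)
  for (i in 1:3) m[match(grouping$groups[[i]], AA_ALPHABET20)] <- i
  m
}

#' Amino-acid composition of a sequence
#'
#' Fraction of each of the 20 standard amino acids (alphabetical order),
#' i.e. occurrence count over sequence length.  The 20 values sum to 1.
#'
#' @param sequence A single amino-acid sequence (uppercase string).
#' @return Named numeric vector of length 20.
#' @examples
#' aa_composition("AAC")
#' @export
aa_composition <- function(sequence) {
  codes <- seq_codes(sequence)
  setNames(tabulate(codes, nbins = 20L) / length(codes), AA_ALPHABET20)
}

#' Group content of a sequence under one physicochemical grouping
#'
#' The fraction of residues falling in each of the grouping's three
#' groups; the triple sums to 1.
#'
#' @param sequence A single amino-acid sequence.
#' @param grouping One grouping from [ctd_groupings()].
#' @return Numeric vector of length 3.
#' @export
group_content <- function(sequence, grouping) {
  codes <- seq_codes(sequence)
  g <- grouping_map(grouping)[codes]
  tabulate(g, nbins = 3L) / length(codes)
}

#' Group distribution descriptors of a sequence
#'
#' For each group i, the normalized 1-based positions of the first, 25%,
#' 50%, 75% and last (100%) residue belonging to the group.  With n
#' occurrences at sorted positions p_1 < ... < p_n, the j-th descriptor
#' uses position p_k with k = ceiling(q * n) for q in \{0.25, 0.5, 0.75\}
#' and p_1 / p_n at the ends; each is divided by the sequence length.
#' A group with no occurrences contributes five zeros.
#'
#' @inheritParams group_content
#' @return Numeric vector of length 15 (group 1's five values, then
#'   group 2's, then group 3's).
#' @export
group_distribution <- function(sequence, grouping) {
  codes <- seq_codes(sequence)
  distribution_from_codes(grouping_map(grouping)[codes], length(codes))
}

distribution_from_codes <- function(g, L) {
  out <- numeric(15)
  for (i in 1:3) {
    pos <- which(g == i)
    n <- length(pos)
    if (n > 0) {
      k <- c(1L, ceiling(c(0.25, 0.5, 0.75) * n), n)
      out[(i - 1L) * 5L + 1:5] <- pos[k] / L
    }
  }
  out
}

#' Cross-group dipeptide composition of a sequence
#'
#' Scans the L-1 adjacent residue pairs and counts, order-insensitively,
#' pairs spanning groups 1 and 2, groups 1 and 3, and groups 2 and 3.
#' Counts are divided by the sequence length L by default; set
#' `normalizer = "pairs"` to divide by the number of pairs L-1 instead.
#'
#' @inheritParams group_content
#' @param normalizer `"length"` (divide by L, the default) or `"pairs"`
#'   (divide by L-1).
#' @return Numeric vector of length 3.  A length-1 sequence yields
#'   `c(0, 0, 0)`.
#' @export
group_dipeptide <- function(sequence, grouping,
                            normalizer = c("length", "pairs")) {
  normalizer <- match.arg(normalizer)
  codes <- seq_codes(sequence)
  dipeptide_from_codes(grouping_map(grouping)[codes], length(codes),
                       normalizer)
}

dipeptide_from_codes <- function(g, L, normalizer = "length") {
  if (L < 2L) return(numeric(3))
  a <- g[-L]
  b <- g[-1L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  counts <- c(sum(lo == 1L & hi == 2L),
              sum(lo == 1L & hi == 3L),
              sum(lo == 2L & hi == 3L))
  counts / if (normalizer == "length") L else L - 1L
}

#' Names of the feature-vector entries
#'
#' @param groupings A list of groupings (default the 8 standard ones).
#' @return Character vector: `comp_<AA>` for the composition block, then
#'   per property `<prop>_content<i>`, `<prop>_distr<i>_q<j>`,
#'   `<prop>_dipep<i>`.
#' @export
feature_names <- function(groupings = ctd_groupings()) {
  per_prop <- function(nm) {
    c(paste0(nm, "_content", 1:3),
      paste0(nm, rep(paste0("_distr", 1:3), each = 5), "_q",
             rep(1:5, times = 3)),
      paste0(nm, "_dipep", 1:3))
  }
  c(paste0("comp_", AA_ALPHABET20),
    unlist(lapply(vapply(groupings, `[[`, "", "name"), per_prop),
           use.names = FALSE))
}

#' Extract the full physicochemical feature vector of one sequence
#'
#' Concatenates the 20 amino-acid composition values with, for each
#' physicochemical grouping in order, 3 content values, 15 distribution
#' values and 3 cross-group dipeptide values (21 per property).  With
#' the 8 standard groupings the result has 20 + 8 * 21 = 188 entries,
#' all in \[0, 1\].
#'
#' @param sequence A single amino-acid sequence (uppercase string over
#'   the 20 standard letters).
#' @param groupings List of physicochemical groupings; defaults to the 8
#'   standard ones from [ctd_groupings()].
#' @param dipeptide_norm Normalizer for the dipeptide block, `"length"`
#'   (default) or `"pairs"`; see [group_dipeptide()].
#' @return Named numeric feature vector (length 20 + 21 * n_groupings).
#' @examples
#' v <- extract_features("MKRISTTITTTITITTGNGAG")
#' length(v)  # 188
#' @export
extract_features <- function(sequence, groupings = ctd_groupings(),
                             dipeptide_norm = c("length", "pairs")) {
  dipeptide_norm <- match.arg(dipeptide_norm)
  for (g in groupings) validate_grouping(g)
  codes <- seq_codes(sequence)
  maps <- lapply(groupings, grouping_map)
  setNames(features_from_codes(codes, maps, dipeptide_norm),
           feature_names(groupings))
}

features_from_codes <- function(codes, maps, dipeptide_norm) {
  L <- length(codes)
  blocks <- vector("list", 1L + length(maps))
  blocks[[1]] <- tabulate(codes, nbins = 20L) / L
  for (k in seq_along(maps)) {
    g <- maps[[k]][codes]
    blocks[[k + 1L]] <- c(tabulate(g, nbins = 3L) / L,
                          distribution_from_codes(g, L),
                          dipeptide_from_codes(g, L, dipeptide_norm))
  }
  unlist(blocks, use.names = FALSE)
}

#' Feature matrix for a collection of protein records
#'
#' @param records Protein records (see [protein_records()]) or a
#'   character vector of sequences.
#' @inheritParams extract_features
#' @return Numeric matrix, one row per record (rownames = ids), columns
#'   named as in [feature_names()].
#' @export
feature_matrix <- function(records, groupings = ctd_groupings(),
                           dipeptide_norm = c("length", "pairs")) {
  dipeptide_norm <- match.arg(dipeptide_norm)
  records <- as_protein_records(records)
  for (g in groupings) validate_grouping(g)
  maps <- lapply(groupings, grouping_map)
  nms <- feature_names(groupings)
  out <- t(vapply(records$sequence, function(s) {
    features_from_codes(seq_codes(s), maps, dipeptide_norm)
  }, numeric(length(nms)), USE.NAMES = FALSE))
  dimnames(out) <- list(records$id, nms)
  out
}

#' Feature table for a collection of protein records
#'
#' One row per record: `id`, an optional `label` column, and the named
#' feature columns.  Suitable for writing as tab-separated text with
#' [utils::write.table()].
#'
#' @inheritParams feature_matrix
#' @param labels Optional vector of labels in `{-1, 1}` aligned with
#'   `records`.
#' @return A `data.frame`.
#' @export
features_to_table <- function(records, labels = NULL,
                              groupings = ctd_groupings(),
                              dipeptide_norm = c("length", "pairs")) {
  records <- as_protein_records(records)
  x <- feature_matrix(records, groupings, dipeptide_norm)
  if (!is.null(labels)) {
    if (length(labels) != nrow(records))
      stop("length of 'labels' (", length(labels),
           ") does not match number of records (", nrow(records), ")")
    if (!all(labels %in% c(-1, 1)))
      stop("labels must be -1 or 1")
    cbind(data.frame(id = records$id, label = as.integer(labels),
                     stringsAsFactors = FALSE),
          as.data.frame(x, row.names = NULL))
  } else {
    cbind(data.frame(id = records$id, stringsAsFactors = FALSE),
          as.data.frame(x, row.names = NULL))
  }
}
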