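#' Standard physicochemical groupings of the amino-acid alphabet
#'
#' Each of eight physicochemical properties partitions the 20 standard
#' amino acids into three groups (e.g. for charge: positive \{K,R\},
#' neutral, negative \{D,E\}).  The content, distribution and dipeptide
#' feature blocks are computed per grouping.  One widely circulated
#' version of the hydrophobicity row lists its neutral group as
#' "GASTPHT", which repeats T and leaves the row one letter short of a
#' partition; this function uses the completed group "GASTPHY" so that
#' every row partitions the alphabet (Y is the only letter missing from
#' the row).
#'
#' @return A named list of 8 groupings in canonical property order
#'   (hydrophobicity, normalized van der Waals volume, polarity,
#'   polarizability, charge, surface tension, secondary structure,
#'   solvent accessibility).  Each grouping is a list with `name` and
#'   `groups`, an ordered list of three character vectors.
#' @seealso [read_groupings()] to supply alternative groupings from a
#'   file, [validate_grouping()] for the partition check.
#' @examples
#' g <- ctd_groupings()
#' g$charge$groups
#' @export
ctd_groupings <- function() {
  rows <- list(
    hydrophobicity      = c("RKEDQN",   "GASTPHY",          "CVLIMFW"),
    vdw_volume          = c("GASCTPD",  "NVEQIL",           "MHKFRYW"),
    polarity            = c("LIFWCMVY", "PATGS",            "HQRKNED"),
    polarizability      = c("GASDT",    "CPNVEQIL",         "KMHFRYW"),
    charge              = c("KR",       "ANCQGHILMFPSTWYV", "DE"),
    surface_tension     = c("GQDNAHR",  "KTSEC",            "ILMFPWYV"),
    secondary_structure = c("EALMQKRH", "VIYCWFT",          "GNPSD"),
    solvent_accessibility = c("ALFCGIVW", "RKQEND",         "MPSTHY")
  )
  out <- lapply(names(rows), function(nm) {
    g <- list(name = nm, groups = lapply(rows[[nm]],
                                         function(s) strsplit(s, "")[[1]]))
    validate_grouping(g)
    g
  })
  names(out) <- names(rows)
  out
}

#' Validate that a grouping partitions the amino-acid alphabet
#'
#' @param grouping A list with elements `name` and `groups` (three
#'   character vectors of one-letter codes).
#' @return Invisibly `TRUE`; otherwise an error describing the defect.
#' @export
validate_grouping <- function(grouping) {
  if (!is.list(grouping) || !all(c("name", "groups") %in% names(grouping)))
    stop("a grouping must be a list with 'name' and 'groups'")
  gs <- grouping$groups
  if (length(gs) != 3)
    stop("grouping '", grouping$name, "' must have exactly 3 groups")
  all_letters <- unlist(gs)
  if (anyDuplicated(all_letters))
    stop("grouping '", grouping$name, "' has overlapping groups (",
         paste(unique(all_letters[duplicated(all_letters)]), collapse = ","),
         ")")
  if (!setequal(all_letters, AA_ALPHABET20))
    stop("grouping '", grouping$name,
         "' does not cover the 20 standard amino acids (missing: ",
         paste(setdiff(AA_ALPHABET20, all_letters), collapse = ","), ")")
  invisible(TRUE)
}

#' Read physicochemical groupings from a config file
#'
#' The file is tab-separated with four columns and no header:
#' `property<TAB>group1<TAB>group2<TAB>group3`, each group a string of
#' one-letter codes.  Every row must partition the 20-letter alphabet.
#'
#' @param path Path to the config file.
#' @return A named list of groupings as returned by [ctd_groupings()].
#' @export
read_groupings <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 4)
    stop("groupings file '", path,
         "' must have 4 tab-separated columns (property + 3 groups)")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    g <- list(name = tab[i, 1],
              groups = lapply(toupper(tab[i, 2:4]),
                              function(s) strsplit(s, "")[[1]]))
    validate_grouping(g)
    g
  })
  names(out) <- tab[[1]]
  out
}
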