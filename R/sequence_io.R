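#' Construct a set of protein records
#'
#' A protein set is a plain `data.frame` with columns `id` (non-empty
#' character) and `sequence` (uppercase strings over the 20 standard
#' amino-acid letters).  All feature-extraction and modelling functions in
#' the package accept this representation.
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino-acid sequences (same length
#'   as `id`).
#' @return A validated `data.frame` with columns `id` and `sequence`.
#' @examples
#' protein_records(c("p1", "p2"), c("ACDE", "RKRK"))
#' @export
protein_records <- function(id, sequence) {
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id)) || anyNA(id))
    stop("record ids must be non-empty")
  bad <- which(!grepl(valid_seq_regex(), sequence) | !nzchar(sequence))
  if (length(bad))
    stop("invalid amino-acid sequence for record '", id[bad[1]],
         "': only the 20 standard letters are allowed")
  data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
}

valid_seq_regex <- function() {
  paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$")
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on input.  In `strict` mode (the default) any
#' letter outside the 20 standard amino acids is an error; feature
#' descriptors are only defined over the standard alphabet.  In `lenient`
#' mode non-standard letters (`X`, `B`, `Z`, `U`, `O`, gaps, ...) are
#' removed with a warning and records left empty are dropped with a
#' warning.
#'
#' @param path Path to a FASTA file.
#' @param mode `"strict"` or `"lenient"`; how to treat non-standard
#'   residue letters.
#' @return A protein-record `data.frame` (see [protein_records()]), one
#'   row per FASTA entry in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "" & !startsWith(lines, ";"))
  if (length(nonblank) && !startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA in '", path, "': sequence data at line ",
         nonblank[1], " before any '>' header")
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  ids[!nzchar(ids)] <- paste0("record_", which(!nzchar(ids)))
  if (anyDuplicated(ids))
    warning("duplicate FASTA ids in '", path, "': ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- NULL

  ok <- grepl(valid_seq_regex(), seqs)
  if (!all(ok)) {
    if (mode == "strict") {
      i <- which(!ok)[1]
      offending <- setdiff(strsplit(seqs[i], "")[[1]], AA_ALPHABET20)
      stop("non-standard residue '", offending[1], "' in record '",
           ids[i], "' (strict mode); use mode = \"lenient\" to drop ",
           "such letters")
    }
    pattern <- paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]")
    cleaned <- gsub(pattern, "", seqs[!ok])
    warning("removed non-standard residues from ", sum(!ok),
            " record(s): ", paste(utils::head(ids[!ok], 5), collapse = ", "),
            if (sum(!ok) > 5) ", ...")
    seqs[!ok] <- cleaned
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning("dropped ", sum(empty), " record(s) with no standard ",
            "residues: ", paste(utils::head(ids[empty], 5), collapse = ", "))
    ids <- ids[!empty]
    seqs <- seqs[!empty]
  }
  protein_records(ids, seqs)
}

#' Write protein records to a FASTA file
#'
#' Output is standard FASTA with sequence lines wrapped at 60 columns;
#' [read_fasta()] on the result reproduces the input records.
#'
#' @param records Protein records (see [protein_records()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  records <- as_protein_records(records)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

as_protein_records <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x)))
      stop("protein records need 'id' and 'sequence' columns")
    return(protein_records(x$id, x$sequence))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq_", seq_along(x))
    return(protein_records(ids, x))
  }
  stop("cannot interpret object of class '", class(x)[1],
       "' as protein records")
}

#' Read a two-column id/label table
#'
#' Expects tab-separated lines `id<TAB>label` with labels in `{1, -1}`
#' (a header line is optional and detected automatically).
#'
#' @param path Path to the label file.
#' @return Named integer vector of labels in `{-1, 1}`, names = ids.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2)
    stop("label table '", path, "' must have exactly two columns")
  if (is.na(suppressWarnings(as.integer(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]
  lab <- as.integer(tab[[2]])
  if (anyNA(lab) || !all(lab %in% c(-1L, 1L)))
    stop("labels in '", path, "' must be 1 or -1")
  stats::setNames(lab, tab[[1]])
}
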