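# Independent brute-force reference for the 188-D feature vector.
# Deliberately naive (character loops, no shared code with the package
# internals) so it can serve as an oracle for the fast extractor.

oracle_features <- function(sequence, groupings = ctd_groupings(),
                            dipeptide_norm = "length") {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- vapply(AA_ALPHABET20, function(a) sum(chars == a) / L, 0)
  for (g in groupings) {
    which_group <- function(ch) {
      for (i in 1:3) if (ch %in% g$groups[[i]]) return(i)
      stop("letter not in grouping: ", ch)
    }
    gi <- vapply(chars, which_group, 0L)
    content <- vapply(1:3, function(i) sum(gi == i) / L, 0)
    distr <- numeric(0)
    for (i in 1:3) {
      pos <- which(gi == i)
      n <- length(pos)
      if (n == 0) {
        distr <- c(distr, rep(0, 5))
      } else {
        distr <- c(distr,
                   c(pos[1],
                     pos[ceiling(0.25 * n)],
                     pos[ceiling(0.50 * n)],
                     pos[ceiling(0.75 * n)],
                     pos[n]) / L)
      }
    }
    dip <- c(0, 0, 0)
    if (L >= 2) {
      for (k in 1:(L - 1)) {
        pr <- sort(c(gi[k], gi[k + 1]))
        if (pr[1] == 1 && pr[2] == 2) dip[1] <- dip[1] + 1
        else if (pr[1] == 1 && pr[2] == 3) dip[2] <- dip[2] + 1
        else if (pr[1] == 2 && pr[2] == 3) dip[3] <- dip[3] + 1
      }
    }
    dip <- dip / (if (dipeptide_norm == "length") L else L - 1)
    out <- c(out, content, distr, dip)
  }
  unname(out)
}

random_sequence <- function(L) {
  paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
}

# small fast registry for tests that exercise training machinery
tiny_registry <- function() {
  lapply(c("cart", "stump", "logistic"), base_learner_spec)
}
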