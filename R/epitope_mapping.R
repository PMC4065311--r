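#' Substitution matrices for peptide-proteome alignment
#'
#' `substitution_matrix("BLOSUM62")` returns the standard BLOSUM62 matrix
#' (from Biostrings); `substitution_matrix("identity")` builds a simple
#' match/mismatch matrix over the amino-acid alphabet including the
#' ambiguity codes. Matrices are validated to be symmetric with a complete
#' pairwise lookup.
#'
#' @param name `"BLOSUM62"` or `"identity"`.
#' @param match,mismatch Scores for the identity matrix.
#' @return Numeric matrix with identical row/column names (the alphabet).
#' @export
substitution_matrix <- function(name = c("BLOSUM62", "identity"),
                                match = 1, mismatch = 0) {
  name <- match.arg(name)
  if (name == "BLOSUM62") {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    smat <- env$BLOSUM62
  } else {
    alphabet <- c(AA20, AA_AMBIGUOUS)
    smat <- matrix(mismatch, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
    diag(smat) <- match
  }
  validate_substitution_matrix(smat)
}

validate_substitution_matrix <- function(smat) {
  if (!is.matrix(smat) || is.null(rownames(smat)) ||
      !identical(rownames(smat), colnames(smat))) {
    abort("substitution matrix needs identical row and column names")
  }
  if (!isSymmetric(unname(smat))) abort("substitution matrix must be symmetric")
  smat
}

encode_residues <- function(seq, alphabet) {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, alphabet)
  if (anyNA(codes)) {
    unknown <- unique(chars[is.na(codes)])
    if ("X" %in% alphabet) {
      codes[is.na(codes)] <- match("X", alphabet)
    } else {
      abort(paste0("residue(s) not in substitution alphabet: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  codes
}

#' Trim the C-terminal attachment linker
#'
#' The invariant linker is array chemistry, not epitope content, so it is
#' removed before alignment by default.
#'
#' @param seqs Character vector of peptide sequences.
#' @param linker Linker suffix; sequences not ending in it pass unchanged.
#' @export
trim_linker <- function(seqs, linker = "GSC") {
  if (!nzchar(linker)) return(seqs)
  ifelse(endsWith(seqs, linker),
         substr(seqs, 1, nchar(seqs) - nchar(linker)), seqs)
}

#' Gapless local alignment of a peptide against a protein
#'
#' Slides the full (linker-trimmed) peptide along the protein without gaps
#' and returns the best-scoring placement; ties are broken by the smallest
#' offset.
#'
#' @param peptide Peptide sequence.
#' @param protein Protein sequence, at least as long as the trimmed peptide.
#' @param matrix Substitution matrix from [substitution_matrix()].
#' @param linker Linker trimmed from the peptide before alignment
#'   (`""` to disable).
#' @return List with `offset` (0-based start on the protein), `score`,
#'   `per_position` (residue-wise scores summing to `score`) and
#'   `peptide` (the aligned, trimmed sequence).
#' @export
gapless_local_align <- function(peptide, protein,
                                matrix = substitution_matrix("BLOSUM62"),
                                linker = "GSC") {
  pep <- trim_linker(peptide, linker)
  if (nchar(pep) > nchar(protein)) {
    abort("protein is shorter than the (trimmed) peptide")
  }
  alphabet <- rownames(matrix)
  pc <- encode_residues(pep, alphabet)
  qc <- encode_residues(protein, alphabet)
  scores <- offset_scores_cpp(pc, qc, matrix)
  offset <- which.max(scores) - 1L  # first maximum = smallest offset
  per_position <- matrix[cbind(pc, qc[offset + seq_along(pc)])]
  list(offset = offset, score = scores[offset + 1L],
       per_position = unname(per_position), peptide = pep)
}

# best placement (offset, score, length) of every peptide on every protein;
# peptides longer than a protein get no placement there
best_placements <- function(pep_seqs, proteome, matrix, linker = "GSC") {
  alphabet <- rownames(matrix)
  peps <- lapply(trim_linker(pep_seqs, linker), encode_residues,
                 alphabet = alphabet)
  lapply(proteome$sequence, function(prot) {
    qc <- encode_residues(prot, alphabet)
    n_ok <- lengths(peps) <= length(qc)
    offs <- integer(length(peps)); scrs <- numeric(length(peps))
    for (i in which(n_ok)) {
      s <- offset_scores_cpp(peps[[i]], qc, matrix)
      offs[i] <- which.max(s) - 1L
      scrs[i] <- s[offs[i] + 1L]
    }
    list(ok = n_ok, offset = offs, score = scrs, len = lengths(peps),
         prot_len = length(qc))
  })
}

# summary score of one protein for a subset of peptides (indices into the
# placement table): each peptide deposits its placement score on every
# position it covers; summary = max of the positional profile, or the plain
# sum of placement scores when summary = "sum"
protein_summary <- function(pl, idx, summary = "max", profile = FALSE) {
  idx <- idx[pl$ok[idx]]
  if (length(idx) == 0) {
    return(if (profile) list(summary = 0, profile = numeric(pl$prot_len))
           else 0)
  }
  if (summary == "sum" && !profile) return(sum(pl$score[idx]))
  d <- numeric(pl$prot_len + 1L)
  starts <- pl$offset[idx] + 1L
  ends <- pl$offset[idx] + pl$len[idx]
  for (k in seq_along(idx)) {
    d[starts[k]] <- d[starts[k]] + pl$score[idx[k]]
    d[ends[k] + 1L] <- d[ends[k] + 1L] - pl$score[idx[k]]
  }
  prof <- cumsum(d[-length(d)])
  s <- if (summary == "sum") sum(pl$score[idx]) else max(prof)
  if (profile) list(summary = s, profile = prof) else s
}

#' Score a proteome against a peptide set
#'
#' Every peptide's best gapless placement deposits its total score onto the
#' protein positions it covers; the positional profile is summed over
#' peptides and each protein is summarized by the profile maximum (or, with
#' `summary = "sum"`, by the plain sum of best placement scores). Proteins
#' are ranked by summary score, descending, ties broken by protein id.
#'
#' @param peptides A [peptide_set()] or character vector of sequences.
#' @param proteome Tibble from [read_proteome()]; must be non-empty.
#' @param matrix Substitution matrix.
#' @param summary `"max"` (default) or `"sum"`.
#' @param linker Linker trimmed before alignment.
#' @param profiles Attach the positional profiles as a list column.
#' @return Tibble `(protein_id, summary_score, rank)`, ordered by rank.
#' @export
score_proteome <- function(peptides, proteome,
                           matrix = substitution_matrix("BLOSUM62"),
                           summary = c("max", "sum"), linker = "GSC",
                           profiles = FALSE) {
  summary <- match.arg(summary)
  pep_seqs <- if (inherits(peptides, "peptide_set")) {
    peptides$members$sequence
  } else {
    as.character(peptides)
  }
  if (length(pep_seqs) == 0) abort("peptide set is empty")
  if (nrow(proteome) == 0) abort("proteome is empty")
  placements <- best_placements(pep_seqs, proteome, matrix, linker)
  idx <- seq_along(pep_seqs)
  res <- lapply(placements, protein_summary, idx = idx, summary = summary,
                profile = profiles)
  scores <- if (profiles) vapply(res, `[[`, 0, "summary") else unlist(res)
  out <- tibble(protein_id = proteome$protein_id, summary_score = scores)
  ord <- order(-out$summary_score, out$protein_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  if (profiles) out$profile <- lapply(res, `[[`, "profile")[ord]
  out
}

#' Empirical permutation p-values for protein scores
#'
#' The null distribution of each protein's summary score is estimated by
#' repeatedly drawing `|test|` peptides uniformly without replacement from
#' the whole library and rescoring the proteome. The one-sided p-value uses
#' the add-one estimator `p = (1 + #{draws >= observed}) / (n_perm + 1)`, so
#' p is never zero.
#'
#' @param test A [peptide_set()] (members must be library peptides) or
#'   character vector of peptide ids.
#' @param library The full [peptide_library()] the null draws come from.
#' @param proteome Tibble from [read_proteome()].
#' @param matrix Substitution matrix.
#' @param n_perm Number of null draws (>= 1).
#' @param seed Integer seed; results are deterministic per seed.
#' @inheritParams score_proteome
#' @return Tibble `(protein_id, summary_score, rank, p_value)`, ordered by
#'   rank.
#' @export
empirical_pvalues <- function(test, library, proteome,
                              matrix = substitution_matrix("BLOSUM62"),
                              n_perm = 200, seed = 1,
                              summary = c("max", "sum"), linker = "GSC") {
  summary <- match.arg(summary)
  if (n_perm < 1) abort("n_perm must be >= 1")
  test_ids <- if (inherits(test, "peptide_set")) {
    test$members$peptide_id
  } else {
    as.character(test)
  }
  test_idx <- match(test_ids, library$peptide_id)
  if (anyNA(test_idx)) abort("test peptides must belong to the library")
  n_test <- length(test_idx)
  if (n_test == 0) abort("test set is empty")
  if (n_test > nrow(library)) abort("test set larger than the library")
  if (nrow(proteome) == 0) abort("proteome is empty")

  placements <- best_placements(library$sequence, proteome, matrix, linker)
  observed <- vapply(placements, protein_summary, 0, idx = test_idx,
                     summary = summary)
  withr::with_seed(seed, {
    draws <- matrix(replicate(n_perm, sample.int(nrow(library), n_test)),
                    nrow = n_test)
  })
  exceed <- integer(nrow(proteome))
  for (b in seq_len(n_perm)) {
    null_scores <- vapply(placements, protein_summary, 0, idx = draws[, b],
                          summary = summary)
    exceed <- exceed + (null_scores >= observed)
  }
  out <- tibble(protein_id = proteome$protein_id, summary_score = observed,
                p_value = (1 + exceed) / (n_perm + 1))
  out <- out[order(-out$summary_score, out$protein_id), ]
  out$rank <- seq_len(nrow(out))
  out[, c("protein_id", "summary_score", "rank", "p_value")]
}
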