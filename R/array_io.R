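#' Peptide library
#'
#' An ordered table of array peptides: identifier, amino-acid sequence and
#' 1-based GenePix-style block/row/column coordinates. Every sequence on the
#' arrays modeled here ends in the invariant C-terminal "GSC" linker, an
#' attachment-chemistry artifact rather than epitope content.
#'
#' @param entries Tibble/data.frame with columns `peptide_id`, `sequence`,
#'   `block`, `row`, `column`.
#' @param linker Expected C-terminal linker; `""` disables enforcement.
#' @return A tibble of class `peptide_library` with a `linker` attribute.
#' @export
peptide_library <- function(entries, linker = "GSC") {
  entries <- as_tibble(entries)
  required <- c("peptide_id", "sequence", "block", "row", "column")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    abort(paste0("peptide library lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(entries) == 0) abort("peptide library is empty")
  if (anyDuplicated(entries$peptide_id)) {
    dup <- entries$peptide_id[duplicated(entries$peptide_id)][1]
    abort(sprintf("duplicate peptide_id in library: '%s'", dup))
  }
  seqs <- entries$sequence
  if (any(!nzchar(seqs)) || anyNA(seqs)) abort("peptide sequences must be non-empty")
  if (any(seqs != toupper(seqs))) abort("peptide sequences must be uppercase")
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  alien <- setdiff(letters_used, AA20)
  if (length(alien) > 0) {
    abort(paste0("sequences contain non amino-acid letters: ",
                 paste(alien, collapse = ", ")))
  }
  if (nzchar(linker) && !all(endsWith(seqs, linker))) {
    abort(sprintf("every peptide sequence must end with the '%s' linker", linker))
  }
  structure(entries, class = c("peptide_library", class(entries)),
            linker = linker)
}

#' Read / write a peptide library as TSV
#'
#' Plain tab-separated layout with the [peptide_library()] columns; the GAL
#' information the workflow needs (identity plus coordinates) without the
#' GenePix header block.
#'
#' @param path File path.
#' @param linker Linker passed to [peptide_library()].
#' @return `read_peptide_library()` returns a `peptide_library`.
#' @export
read_peptide_library <- function(path, linker = "GSC") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  peptide_library(df, linker = linker)
}

#' @rdname read_peptide_library
#' @param library A `peptide_library`.
#' @export
write_peptide_library <- function(library, path) {
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- GPR (GenePix Results, minimal single-channel dialect) -----------------

#' Read a single-sample GPR intensity file
#'
#' Minimal GenePix Results dialect for single-channel scans: an optional
#' `ATF 1.0` preamble, a line giving the number of header records, a block of
#' `"Key=Value"` header lines, then a tab-separated table whose required
#' columns are `ID` and one intensity column (default `F635 Median`, the
#' foreground median of the scan channel). Rows may appear in any order; the
#' returned matrix always follows library order.
#'
#' @param path GPR file path.
#' @param library [peptide_library()] the file must cover exactly.
#' @param sample Named list of sample metadata (`sample_id`, `mouse_id`,
#'   `strain`, `age_months`, `phenotype`, `replicate`, `study`). Fields not
#'   given default to the header block's values or `NA`.
#' @param intensity_column Name of the intensity column to read.
#' @return Single-column [intensity_matrix()] with `scale = "raw"`.
#' @export
read_gpr <- function(path, library, sample = list(),
                     intensity_column = "F635 Median") {
  lines <- readLines(path)
  if (length(lines) < 2) abort(sprintf("'%s' is not a GPR file", path))
  i <- 1L
  if (grepl("^ATF", lines[1])) i <- 2L
  counts <- strsplit(lines[i], "\t")[[1]]
  n_header <- suppressWarnings(as.integer(counts[1]))
  if (is.na(n_header)) abort(sprintf("'%s': malformed GPR header count line", path))
  header_lines <- gsub('^"|"$', "", lines[i + seq_len(n_header)])
  kv <- strsplit(header_lines, "=", fixed = TRUE)
  header <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                     vapply(kv, `[`, "", 1))
  table_start <- i + n_header + 1L
  tab <- read.delim(text = paste(lines[table_start:length(lines)],
                                 collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("ID", intensity_column)) {
    if (!col %in% names(tab)) {
      abort(sprintf("'%s': GPR table lacks required column '%s'", path, col))
    }
  }
  if (anyDuplicated(tab$ID)) {
    dup <- tab$ID[duplicated(tab$ID)][1]
    abort(sprintf("'%s': duplicate peptide id '%s'", path, dup))
  }
  missing <- setdiff(library$peptide_id, tab$ID)
  if (length(missing) > 0) {
    abort(sprintf("'%s': missing peptide id(s): %s%s", path,
                  paste(head(missing, 3), collapse = ", "),
                  if (length(missing) > 3) ", ..." else ""))
  }
  vals <- tab[[intensity_column]]
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(vals))))[1]
    abort(sprintf("'%s': non-numeric intensity at table line %d", path,
                  bad + table_start))
  }
  vals <- as.double(vals)
  ord <- match(library$peptide_id, tab$ID)
  meta <- list(sample_id = sample$sample_id %||% header[["Sample"]] %||%
                 sub("\\.gpr$", "", basename(path)),
               mouse_id = sample$mouse_id %||% NA_character_,
               strain = sample$strain %||% NA_character_,
               age_months = sample$age_months %||% NA_real_,
               phenotype = sample$phenotype %||% NA_character_,
               replicate = sample$replicate %||% 1L,
               study = sample$study %||% NA_integer_)
  intensity_matrix(matrix(vals[ord], ncol = 1), library,
                   as_tibble(meta), scale = "raw")
}

#' Write one sample of an intensity matrix as a GPR file
#'
#' @param m Raw-scale [intensity_matrix()].
#' @param path Output path.
#' @param sample Column index or `sample_id` to write (default first column).
#' @inheritParams read_gpr
#' @export
write_gpr <- function(m, path, sample = 1L, intensity_column = "F635 Median") {
  stop_if_not_scale(m, "raw", "write_gpr")
  if (is.character(sample)) sample <- match(sample, m$samples$sample_id)
  if (is.na(sample) || sample < 1 || sample > ncol(m$values)) {
    abort("write_gpr: unknown sample")
  }
  header <- c("Type=GenePix Results 3",
              sprintf("Sample=%s", m$samples$sample_id[sample]),
              "Wavelengths=650")
  tab_header <- paste(c("Block", "Row", "Column", "ID", intensity_column),
                      collapse = "\t")
  rows <- sprintf("%d\t%d\t%d\t%s\t%s",
                  m$peptides$block, m$peptides$row, m$peptides$column,
                  m$peptides$peptide_id,
                  format(m$values[, sample], trim = TRUE, digits = 15))
  writeLines(c("ATF\t1.0",
               sprintf("%d\t%d", length(header), 5L),
               sprintf('"%s"', header),
               tab_header, rows), path)
  invisible(path)
}

# ---- proteome FASTA --------------------------------------------------------

#' Read an amino-acid proteome from FASTA
#'
#' @param path FASTA file of protein sequences.
#' @return Tibble with columns `protein_id` (first word of the header),
#'   `description` (remainder), `sequence` (uppercased) and `has_ambiguous`
#'   (TRUE when the sequence contains U/B/Z/X residues).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("'%s': empty FASTA file", path))
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate protein id '%s' in '%s'",
                  ids[duplicated(ids)][1], path))
  }
  seqs <- unname(toupper(as.character(aa)))
  tibble(protein_id = ids, description = desc, sequence = seqs,
         has_ambiguous = grepl(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"),
                               seqs))
}

#' @rdname read_proteome
#' @param proteome Tibble as returned by `read_proteome()`.
#' @export
write_proteome <- function(proteome, path) {
  headers <- ifelse(nzchar(proteome$description),
                    paste(proteome$protein_id, proteome$description),
                    proteome$protein_id)
  writeLines(paste0(">", headers, "\n", proteome$sequence), path)
  invisible(path)
}

# ---- peptide signature sets ------------------------------------------------

#' A named peptide signature
#'
#' A signature is the outcome of a selection rule: member peptides with the
#' binding ratios that passed the threshold, plus provenance (which contrast,
#' which rule, which study).
#'
#' @param name Signature name.
#' @param members Tibble with at least `peptide_id` and `sequence`; ratio
#'   columns (`ratio`, `ratio_study1`, `ratio_study2`) and logical
#'   cross-membership flag columns are carried along.
#' @param provenance Arbitrary list recording how the set was produced.
#' @return Object of class `peptide_set`.
#' @export
peptide_set <- function(name, members, provenance = list()) {
  members <- as_tibble(members)
  if (!"peptide_id" %in% names(members)) {
    abort("peptide_set members need a peptide_id column")
  }
  if (!"sequence" %in% names(members)) members$sequence <- members$peptide_id
  if (anyDuplicated(members$peptide_id)) abort("peptide_set members must be unique")
  structure(list(name = name, members = members, provenance = provenance),
            class = "peptide_set")
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("<peptide_set> '%s': %d peptides\n", x$name, nrow(x$members)))
  invisible(x)
}

#' @export
length.peptide_set <- function(x) nrow(x$members)

#' Write / read a signature table
#'
#' Tab-separated layout mirroring published signature tables: one row per
#' peptide sorted lexicographically by sequence, ratio columns per study, and
#' logical cross-membership flag columns.
#'
#' @param set A [peptide_set()]; must be non-empty.
#' @param path Output path.
#' @export
write_signature_table <- function(set, path) {
  if (length(set) == 0) abort("refusing to write an empty signature table")
  df <- as.data.frame(set$members)
  df <- df[order(df$sequence), , drop = FALSE]
  front <- intersect(c("sequence", "peptide_id", "ratio",
                       "ratio_study1", "ratio_study2"), names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_table
#' @param name Name for the parsed set (default: file name).
#' @export
read_signature_table <- function(path, name = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"peptide_id" %in% names(df) && "sequence" %in% names(df)) {
    df$peptide_id <- df$sequence
  }
  peptide_set(name %||% sub("\\.tsv$", "", basename(path)), df)
}

#' Published reference signatures packaged with immunosig
#'
#' Three reference peptide sets from the two-study MRL/lpr immunosignaturing
#' experiments: `diagnostic_lupus` (58 peptides shared by both studies'
#' 4-month MRL/lpr vs C3H/HeJ contrasts), `diagnostic_behavior` (39 peptides
#' diagnostic of high-floater behavior in the forced swim test) and
#' `predictive_lupus` (18 peptides elevated presymptomatically). Each carries
#' the two studies' binding ratios and cross-membership flags; see the
#' `NOTES.md` shipped alongside for two known printed flag inconsistencies.
#'
#' @param name One of `"diagnostic_lupus"`, `"diagnostic_behavior"`,
#'   `"predictive_lupus"`.
#' @return A [peptide_set()].
#' @export
load_reference_signature <- function(name = c("diagnostic_lupus",
                                              "diagnostic_behavior",
                                              "predictive_lupus")) {
  name <- match.arg(name)
  path <- system.file("extdata", "signatures", paste0(name, ".tsv"),
                      package = "immunosig", mustWork = TRUE)
  read_signature_table(path, name = name)
}
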