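#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Reads the `--domtblout` output of `hmmscan`, producing one hit per domain
#' row. The protein id is the query sequence name (column 4), the template
#' id the profile name (column 1), and the score the per-domain bit score
#' (column 14) — individual domain hits are kept separate because the
#' neural response maximizes over single hits, not sequence-level scores.
#' Envelope coordinates (columns 20-21, 1-based inclusive) are retained.
#'
#' @param path path to a domtblout file.
#' @return A hit table: data frame with columns `protein_id`, `template_id`,
#'   `score`, `start`, `end`.
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) .stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) return(.empty_hits(coords = TRUE))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 22) {
      .stop(sprintf("domtblout line %d: expected >= 22 columns, got %d", i, length(f)))
    }
    score <- suppressWarnings(as.numeric(f[14]))
    from <- suppressWarnings(as.integer(f[20]))
    to <- suppressWarnings(as.integer(f[21]))
    if (is.na(score)) .stop(sprintf("domtblout line %d: non-numeric domain score '%s'", i, f[14]))
    if (is.na(from) || is.na(to)) {
      .stop(sprintf("domtblout line %d: non-integer envelope coordinates", i))
    }
    data.frame(protein_id = f[4], template_id = f[1], score = score,
               start = from, end = to)
  })
  hits <- do.call(rbind, rows)
  .validate_hits(hits)
  hits
}

.empty_hits <- function(coords = FALSE) {
  h <- data.frame(protein_id = character(), template_id = character(),
                  score = numeric())
  if (coords) { h$start <- integer(); h$end <- integer() }
  h
}

# internal: shared hit-table invariants
.validate_hits <- function(hits) {
  if (any(!is.finite(hits$score))) .stop("hit scores must be finite")
  if (!is.null(hits$start)) {
    bad <- !is.na(hits$start) & (hits$start < 1 | hits$start > hits$end)
    if (any(bad)) .stop("hit coordinates must satisfy 1 <= start <= end")
  }
  invisible(hits)
}

#' Read / write a generic TSV hit table
#'
#' The plain interchange format for template hits: a tab-separated file with
#' a header and at least the columns `protein_id`, `template_id`, `score`
#' (optional `start`, `end`). Row order is preserved and duplicate
#' (protein, template) rows are legal — repeat hits of one template on one
#' sequence are resolved later by taking the maximum score.
#'
#' @param path file path.
#' @param hits a hit table data frame.
#' @return `parse_hit_table`: the hit table; `write_hit_table`: `path`,
#'   invisibly.
#' @export
parse_hit_table <- function(path) {
  if (!file.exists(path)) .stop("no such file: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("protein_id", "template_id", "score")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    .stop("hit table ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) return(.empty_hits())
  tab$protein_id <- as.character(tab$protein_id)
  tab$template_id <- as.character(tab$template_id)
  tab$score <- as.numeric(tab$score)
  .validate_hits(tab)
  tab[, intersect(c(need, "start", "end"), names(tab)), drop = FALSE]
}

#' @rdname parse_hit_table
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file of protein sequences
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector. Ids are the first whitespace-delimited token of each
#' header and must be unique; sequences are uppercased, and letters outside
#' the 20-letter amino-acid alphabet (plus `BJOUXZ*-`) trigger a warning but
#' are preserved.
#'
#' @param path path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stop("no such file: ", path)
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    .stop("duplicate FASTA id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  odd <- grepl("[^ACDEFGHIKLMNPQRSTVWYBJOUXZ*-]", seqs)
  if (any(odd)) {
    .warn("non-standard letters in sequence(s): ",
          paste(ids[odd], collapse = ", "))
  }
  seqs
}

#' Read / write a numeric matrix as TSV
#'
#' Square matrices are stored with a header row and a leading id column;
#' `read_matrix_tsv(write_matrix_tsv(M))` is the identity (up to float
#' printing, which uses full precision).
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return `read_matrix_tsv`: the matrix; `write_matrix_tsv`: `path`,
#'   invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) .stop("no such file: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  rn <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' Read / write protein-to-GO annotation tables
#'
#' Annotations are a long-form TSV with header columns `protein_id` and
#' `go_term`, one row per (protein, term) association.
#'
#' @param path file path.
#' @param annotations annotation data frame.
#' @param go_graph optional [go_graph]; when given, every annotated term
#'   must exist in it.
#' @return `read_annotations`: data frame with columns `protein_id`,
#'   `go_term`; `write_annotations`: `path`, invisibly.
#' @export
read_annotations <- function(path, go_graph = NULL) {
  if (!file.exists(path)) .stop("no such file: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "go_term")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    .stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab$protein_id <- as.character(tab$protein_id)
  tab$go_term <- as.character(tab$go_term)
  if (any(!nzchar(tab$protein_id))) .stop("empty protein_id in annotations")
  if (!is.null(go_graph)) {
    unknown <- setdiff(unique(tab$go_term), go_graph$terms)
    if (length(unknown)) {
      .stop("annotated term(s) absent from the GO graph: ",
            paste(head(unknown, 5), collapse = ", "))
    }
  }
  tab[, need]
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations[, c("protein_id", "go_term")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: terms annotated to a protein / proteins annotated to a term
.ann_terms <- function(annotations, protein) {
  unique(annotations$go_term[annotations$protein_id == protein])
}
.ann_proteins <- function(annotations, term) {
  unique(annotations$protein_id[annotations$go_term == term])
}
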