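#' Template libraries
#'
#' The ordered set of m motif templates (PROSITE patterns, Pfam domains or
#' custom profiles) forming the bottom layer of the model. The order is the
#' coordinate system of every neural response vector, so it is fixed at
#' construction.
#'
#' @param ids character vector of unique template ids.
#' @param source template provenance, recycled over ids: `"prosite"`,
#'   `"pfam"` or `"custom"`.
#' @return An object of class `template_library`.
#' @export
template_library <- function(ids, source = "custom") {
  ids <- as.character(ids)
  if (length(ids) == 0) .stop("a template library needs at least one template")
  if (anyDuplicated(ids)) .stop("duplicate template ids")
  source <- match.arg(rep(source, length.out = length(ids)),
                      c("custom", "prosite", "pfam"), several.ok = TRUE)
  structure(list(ids = ids, source = source), class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("template_library: %d templates (%s)\n", length(x$ids),
              paste(unique(x$source), collapse = ", ")))
  invisible(x)
}

#' @export
length.template_library <- function(x) length(x$ids)

#' Read / write a template library TSV
#'
#' A header TSV with columns `template_id` and optionally `source`.
#'
#' @param path file path.
#' @param library a [template_library].
#' @return `read_library`: a [template_library]; `write_library`: `path`,
#'   invisibly.
#' @export
read_library <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"template_id" %in% names(tab)) .stop("library file lacks 'template_id' column")
  template_library(tab$template_id,
                   source = if ("source" %in% names(tab)) tab$source else "custom")
}

#' @rdname read_library
#' @export
write_library <- function(library, path) {
  write.table(data.frame(template_id = library$ids, source = library$source),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Template similarity matrices (the initial kernel)
#'
#' Wraps the m x m matrix S of template-template similarity scores — in
#' practice exported profile-profile alignment scores — that serves as the
#' initial kernel of the model. A valid S is symmetric, has each off-diagonal
#' bounded by its diagonal (a motif is most similar to itself) and is
#' positive definite.
#'
#' @param library a [template_library].
#' @param S numeric m x m matrix; dimnames are set to the library ids.
#' @param tol symmetry/eigenvalue tolerance recorded on the object.
#' @return An object of class `template_similarity`.
#' @export
template_similarity <- function(library, S, tol = 1e-8) {
  stopifnot(inherits(library, "template_library"))
  m <- length(library$ids)
  S <- as.matrix(S)
  if (!all(dim(S) == c(m, m))) {
    .stop(sprintf("S must be %d x %d to match the library", m, m))
  }
  dimnames(S) <- list(library$ids, library$ids)
  structure(list(library = library, S = S, tol = tol),
            class = "template_similarity")
}

#' @export
print.template_similarity <- function(x, ...) {
  cat(sprintf("template_similarity: %d x %d, tol %g\n",
              nrow(x$S), ncol(x$S), x$tol))
  invisible(x)
}

#' Load a template similarity matrix from TSV
#'
#' Accepts either a full square matrix (header row of template ids, leading
#' id column) or a long-form table with columns `id1`, `id2`, `score`. In
#' long form, a pair given in one orientation only is mirrored; pairs never
#' mentioned default to 0 with a warning. Directional raw scores (full
#' matrix input) are symmetrized as `(S + t(S))/2`, with the maximum
#' asymmetry reported.
#'
#' @param path TSV file path.
#' @param library a [template_library]; all ids in the file must belong to
#'   it, and the result covers every library id.
#' @param tol tolerance forwarded to [template_similarity()].
#' @return A [template_similarity].
#' @export
load_similarity <- function(path, library, tol = 1e-8) {
  if (!file.exists(path)) .stop("no such file: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  m <- length(library$ids)
  long_form <- ncol(tab) == 3 &&
    all(c("id1", "id2", "score") %in% names(tab))
  if (long_form) {
    unknown <- setdiff(unique(c(tab$id1, tab$id2)), library$ids)
    if (length(unknown)) {
      .stop("unknown template id(s) in similarity file: ",
            paste(head(unknown, 5), collapse = ", "))
    }
    S <- matrix(NA_real_, m, m, dimnames = list(library$ids, library$ids))
    for (r in seq_len(nrow(tab))) {
      S[tab$id1[r], tab$id2[r]] <- tab$score[r]
    }
    # symmetry fill: mirror present entries into absent ones
    miss <- is.na(S) & !is.na(t(S))
    S[miss] <- t(S)[miss]
    if (any(is.na(S))) {
      .warn(sum(is.na(S)), " similarity entr(ies) absent from ", basename(path),
            "; set to 0")
      S[is.na(S)] <- 0
    }
  } else {
    M <- tryCatch(read_matrix_tsv(path), error = function(e) {
      .stop("cannot read ", path, " as a square similarity matrix: ",
            conditionMessage(e))
    })
    if (nrow(M) != ncol(M)) {
      .stop(sprintf("similarity matrix in %s is %d x %d, not square",
                    basename(path), nrow(M), ncol(M)))
    }
    unknown <- setdiff(unique(c(rownames(M), colnames(M))), library$ids)
    if (length(unknown)) {
      .stop("unknown template id(s) in similarity file: ",
            paste(head(unknown, 5), collapse = ", "))
    }
    missing <- setdiff(library$ids, rownames(M))
    if (length(missing)) {
      .stop("similarity matrix does not cover library id(s): ",
            paste(head(missing, 5), collapse = ", "))
    }
    M <- M[library$ids, library$ids]
    asym <- max(abs(M - t(M)))
    if (asym > tol) {
      message(sprintf("symmetrizing similarity matrix (max asymmetry %.4g)", asym))
      M <- (M + t(M)) / 2
    }
    S <- M
  }
  template_similarity(library, S, tol = tol)
}

#' Write a template similarity matrix
#'
#' @param ts a [template_similarity].
#' @param path output TSV path (square-matrix form).
#' @return `path`, invisibly.
#' @export
write_similarity <- function(ts, path) {
  write_matrix_tsv(ts$S, path)
  invisible(path)
}

#' Validate a template similarity matrix
#'
#' Checks the three conditions the initial kernel must satisfy: symmetry
#' (within `tol`), self-maximality `s(q_i, q_j) <= s(q_i, q_i)` for `i != j`,
#' and positive definiteness (minimum eigenvalue `> -tol`). Always returns a
#' report rather than erroring, so that raw alignment-score matrices can be
#' inspected before repair.
#'
#' @param ts a [template_similarity].
#' @param tol numeric tolerance; defaults to the tolerance stored on `ts`.
#' @return An object of class `similarity_validation` with elements
#'   `symmetry_violations`, `dominance_violations` (data frames),
#'   `min_eigenvalue` and logical `pass`.
#' @export
validate_similarity <- function(ts, tol = ts$tol) {
  stopifnot(inherits(ts, "template_similarity"))
  S <- ts$S
  ids <- rownames(S)
  D <- S - t(S)
  sym_idx <- which(abs(D) > tol & upper.tri(D), arr.ind = TRUE)
  sym <- data.frame(id1 = ids[sym_idx[, 1]], id2 = ids[sym_idx[, 2]],
                    delta = D[sym_idx])
  diagS <- diag(S)
  over <- which(S > diagS + tol & !diag(TRUE, nrow(S)), arr.ind = TRUE)
  dom <- data.frame(id1 = ids[over[, 1]], id2 = ids[over[, 2]],
                    value = S[over], self = diagS[over[, 1]])
  min_eig <- min(eigen((S + t(S)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values)
  structure(list(symmetry_violations = sym, dominance_violations = dom,
                 min_eigenvalue = min_eig, tol = tol,
                 pass = nrow(sym) == 0 && nrow(dom) == 0 && min_eig > -tol),
            class = "similarity_validation")
}

#' @export
print.similarity_validation <- function(x, ...) {
  cat(sprintf("similarity validation: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  symmetry violations:  %d\n", nrow(x$symmetry_violations)))
  cat(sprintf("  dominance violations: %d\n", nrow(x$dominance_violations)))
  cat(sprintf("  min eigenvalue:       %.6g (tol %g)\n", x$min_eigenvalue, x$tol))
  invisible(x)
}

#' Repair a similarity matrix to a valid initial kernel
#'
#' Raw profile-profile alignment scores need not form a positive definite
#' matrix. The repair projects a symmetric S onto the validated class in two
#' moves that are each idempotent and PSD-preserving: eigenvalues are
#' clipped from below at `floor`, and every diagonal entry is then raised to
#' the largest off-diagonal in its row/column so that self-similarity
#' dominates. Inputs that already validate are returned unchanged.
#'
#' @param ts a [template_similarity] with symmetric S (symmetrize first;
#'   asymmetric input is an error).
#' @param floor eigenvalue floor, a small positive number.
#' @return A repaired [template_similarity] that passes
#'   [validate_similarity()].
#' @export
repair_psd <- function(ts, floor = 1e-8) {
  stopifnot(inherits(ts, "template_similarity"))
  if (floor <= 0) .stop("'floor' must be positive")
  S <- ts$S
  if (max(abs(S - t(S))) > ts$tol) {
    .stop("similarity matrix is not symmetric; symmetrize before repair")
  }
  v <- validate_similarity(ts)
  if (v$pass && v$min_eigenvalue >= floor) return(ts)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lambda <- pmax(e$values, floor)
  R <- e$vectors %*% (lambda * t(e$vectors))
  R <- (R + t(R)) / 2
  off_max <- apply(R - diag(diag(R)), 1, max)
  diag(R) <- pmax(diag(R), off_max)
  dimnames(R) <- dimnames(S)
  template_similarity(ts$library, R, tol = ts$tol)
}
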