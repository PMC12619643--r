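#' Construct a PAE matrix object
#'
#' A `pae_matrix` holds an n-by-n matrix of Predicted Aligned Error values
#' (in Angstrom) together with the JSON dialect it was read from and, when
#' the source declared one, the maximum possible PAE value. PAE matrices are
#' asymmetric in general: entry (i, j) is the expected error in residue i's
#' position when the prediction is aligned on residue j. Diagonal entries
#' are kept exactly as found in the source.
#'
#' @param values Square numeric matrix of non-negative PAE values (Angstrom).
#' @param dialect One of `"afdb"`, `"colabfold"`, `"pairlist"`.
#' @param max_pae Declared maximum PAE (Angstrom), or `NULL` when the source
#'   did not declare one.
#' @return An object of class `pae_matrix`.
#' @examples
#' pae_matrix(matrix(c(0, 3, 4, 0), 2, 2, byrow = TRUE))
#' @export
pae_matrix <- function(values, dialect = "afdb", max_pae = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_shape("`values` must be a numeric matrix")
  }
  n <- nrow(values)
  if (ncol(values) != n) {
    stop_shape(sprintf("PAE matrix must be square, got %d x %d", n, ncol(values)))
  }
  if (n < 2L) {
    stop_shape(sprintf("PAE matrix needs at least 2 residues, got %d", n))
  }
  if (anyNA(values)) stop_domain("PAE matrix contains missing values")
  if (any(values < 0)) {
    stop_domain(sprintf("PAE values must be non-negative; smallest found: %g", min(values)))
  }
  dialect <- match.arg(dialect, c("afdb", "colabfold", "pairlist"))
  if (!is.null(max_pae)) {
    if (!is_scalar_number(max_pae)) stop_domain("`max_pae` must be a single finite number")
    if (any(values > max_pae)) {
      stop_domain(sprintf(
        "PAE values exceed the declared maximum %g (largest found: %g)",
        max_pae, max(values)
      ))
    }
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, n = n, dialect = dialect, max_pae = max_pae),
    class = "pae_matrix"
  )
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf(
    "<pae_matrix> %d x %d residues, dialect '%s'%s\n",
    x$n, x$n, x$dialect,
    if (is.null(x$max_pae)) "" else sprintf(", max_pae %g", x$max_pae)
  ))
  cat(sprintf(
    "  PAE range: %.2f - %.2f Angstrom\n",
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.pae_matrix <- function(x) dim(x$values)

#' Read a PAE matrix from AlphaFold-style JSON
#'
#' Auto-detects the three PAE JSON dialects in circulation:
#' \describe{
#'   \item{afdb}{AlphaFold DB: `{"predicted_aligned_error": [[...]], "max_predicted_aligned_error": x}`,
#'     usually wrapped in a one-element top-level array (which is unwrapped).}
#'   \item{colabfold}{ColabFold: `{"pae": [[...]]}`, optionally with `"max_pae"`.}
#'   \item{pairlist}{Legacy AF2 pair list: parallel arrays `"residue1"`,
#'     `"residue2"`, `"distance"` with 1-based residue indices. May be
#'     sparse; missing pairs default to the declared `max_pae` when present,
#'     else to the largest observed distance (conservative low-confidence
#'     imputation).}
#' }
#'
#' @param source Path to a JSON file, a JSON string, or a raw vector.
#' @return A [pae_matrix] with the source dialect recorded.
#' @examples
#' read_pae('{"pae": [[0, 5], [5, 0]]}')
#' @export
read_pae <- function(source) {
  txt <- pae_source_text(source)
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = TRUE),
    error = function(e) {
      stop_parse(sprintf("malformed PAE JSON: %s", conditionMessage(e)))
    }
  )
  # AlphaFold DB serves a one-element top-level array; unwrap it.
  if (is.list(parsed) && is.null(names(parsed)) && length(parsed) == 1L) {
    parsed <- parsed[[1L]]
  }
  if (!is.list(parsed) || is.null(names(parsed))) {
    stop_dialect("PAE JSON must be an object (or a one-element array of objects)")
  }
  keys <- names(parsed)
  if ("predicted_aligned_error" %in% keys) {
    values <- as_dense_matrix(parsed[["predicted_aligned_error"]])
    pae_matrix(values, "afdb", max_pae = parsed[["max_predicted_aligned_error"]] %||% NULL)
  } else if ("pae" %in% keys) {
    values <- as_dense_matrix(parsed[["pae"]])
    pae_matrix(values, "colabfold", max_pae = parsed[["max_pae"]] %||% NULL)
  } else if ("residue1" %in% keys) {
    densify_pairlist(parsed)
  } else {
    stop_dialect(sprintf(
      "unrecognized PAE JSON dialect; keys found: %s",
      paste(keys, collapse = ", ")
    ))
  }
}

pae_source_text <- function(source) {
  if (is.raw(source)) return(rawToChar(source))
  if (!is.character(source) || length(source) != 1L) {
    stop_parse("`source` must be a file path, a JSON string, or a raw vector")
  }
  looks_like_json <- grepl("^\\s*[\\[{]", source)
  if (!looks_like_json) {
    if (!file.exists(source)) {
      stop_parse(sprintf("PAE file not found: '%s'", source))
    }
    return(readChar(source, file.size(source), useBytes = TRUE))
  }
  source
}

as_dense_matrix <- function(x) {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L) {
      stop_shape(sprintf(
        "ragged PAE matrix: row lengths %s", paste(unique(lens), collapse = ", ")
      ))
    }
    x <- do.call(rbind, lapply(x, as.numeric))
  }
  if (!is.matrix(x)) stop_shape("PAE values are not a two-dimensional matrix")
  storage.mode(x) <- "double"
  x
}

densify_pairlist <- function(parsed) {
  needed <- c("residue1", "residue2", "distance")
  missing <- setdiff(needed, names(parsed))
  if (length(missing)) {
    stop_dialect(sprintf(
      "pairlist dialect is missing key(s): %s", paste(missing, collapse = ", ")
    ))
  }
  r1 <- as.integer(parsed[["residue1"]])
  r2 <- as.integer(parsed[["residue2"]])
  d <- as.numeric(parsed[["distance"]])
  if (length(r1) != length(r2) || length(r1) != length(d)) {
    stop_shape(sprintf(
      "pairlist arrays differ in length: residue1=%d residue2=%d distance=%d",
      length(r1), length(r2), length(d)
    ))
  }
  if (any(r1 < 1L) || any(r2 < 1L)) {
    stop_domain("pairlist residue indices must be 1-based positive integers")
  }
  max_pae <- parsed[["max_predicted_aligned_error"]] %||% parsed[["max_pae"]] %||% NULL
  n <- max(r1, r2)
  fill <- if (!is.null(max_pae)) max_pae else max(d)
  values <- matrix(fill, n, n)
  values[cbind(r1, r2)] <- d
  diag(values)[!(seq_len(n) %in% r1[r1 == r2])] <- 0
  pae_matrix(values, "pairlist", max_pae = max_pae)
}

#' Write a PAE matrix as AlphaFold DB-dialect JSON
#'
#' Serializes in the `afdb` dialect (a one-element array holding
#' `predicted_aligned_error` and, when known, `max_predicted_aligned_error`)
#' at 17 significant digits, so that [read_pae()] reproduces the matrix
#' exactly.
#'
#' @param pae A [pae_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pae_json <- function(pae, path) {
  stopifnot(inherits(pae, "pae_matrix"))
  body <- list(predicted_aligned_error = pae$values)
  if (!is.null(pae$max_pae)) body$max_predicted_aligned_error <- pae$max_pae
  json <- jsonlite::toJSON(list(body), digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}
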