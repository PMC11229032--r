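# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Format a value for TSV output: numerics at 6 significant digits, plain
# decimal notation where reasonable; everything else as character.
format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else sprintf("%.6g", v)
    }, character(1L))
    out
  } else if (is.logical(x)) {
    ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  } else {
    as.character(x)
  }
}

#' Write a result table as TSV
#'
#' Fixed formatting shared by every command-line output: tab separators,
#' Unix newlines, no quoting, numerics at 6 significant digits with a
#' \code{.} decimal point — so identical inputs always produce
#' byte-identical files.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_result_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  colnames(out) <- colnames(df)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con,
               sep = "\n")
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression()]: first column \code{gene}, one column per
#' sample, values on the matrix's current scale at 6 significant digits.
#'
#' @param m An [expr_matrix()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- cbind(data.frame(gene = genes(m), stringsAsFactors = FALSE),
              as.data.frame(m$values, check.names = FALSE))
  write_result_tsv(df, path)
}
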